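#' Minutes in each vigilance state per zeitgeber hour
#'
#' Tabulates the minutes spent in each vigilance state for every
#' ZT-aligned calendar hour of the recording. Artifact epochs are
#' excluded from the state totals by default (so per-hour minutes sum
#' to 60 minus artifact-excluded time); pass
#' `exclude_artifacts = FALSE` to count them. A trailing partial hour is
#' dropped with a warning.
#'
#' @param hyp A [hypnogram()].
#' @param exclude_artifacts Drop artifact epochs from the totals?
#' @return A tibble of class `"state_time_table"` with columns `hour`
#'   (integer ZT hour), `state`, `minutes`, covering every complete
#'   recorded hour and every state in the species vocabulary.
#' @export
#' @examples
#' time_in_state_per_hour(hypnogram(rep("NREM", 900)))
time_in_state_per_hour <- function(hyp, exclude_artifacts = TRUE) {
  epoch_s <- epoch_length_s(hyp)
  per_hour <- as.integer(round(3600 / epoch_s))
  hour <- floor(hyp$zt + 1e-9)
  complete <- table(hour)
  partial <- as.integer(names(complete)[complete < per_hour])
  if (length(partial) > 0) {
    warning(sprintf(
      "dropping partial hour(s): %s", paste(partial, collapse = ", ")
    ))
  }
  keep <- !(hour %in% partial)
  if (exclude_artifacts) keep <- keep & !hyp$artifact
  vocab <- state_vocabulary(attr(hyp, "species"))
  hours <- setdiff(sort(unique(hour)), partial)
  out <- tibble(hour = hour[keep], state = hyp$state[keep]) |>
    count(.data$hour, .data$state) |>
    mutate(minutes = .data$n * epoch_s / 60) |>
    select(-"n") |>
    tidyr::complete(
      hour = hours,
      state = vocab,
      fill = list(minutes = 0)
    ) |>
    arrange(.data$hour, match(.data$state, vocab))
  structure(out,
    class = c("state_time_table", class(tibble())),
    epoch_s = epoch_s, species = attr(hyp, "species")
  )
}

#' Accumulated difference from baseline across recovery
#'
#' For each recovery hour, the hourly difference from the mean baseline
#' value at the same zeitgeber hour is computed per state and these
#' differences are summed cumulatively, giving the accumulated change
#' relative to baseline (positive = time regained). Because every
#' hour's minutes are conserved across states, the three state series
#' sum to zero at every hour.
#'
#' @param recovery A `state_time_table` for the recovery period (hours
#'   indexed in cumulative ZT).
#' @param baseline_days A list of `state_time_table`s, one per baseline
#'   day, aligned by ZT hour (hours are matched modulo 24).
#' @return A tibble of class `"accumulated_curve"` with columns `hour`,
#'   `state`, `hourly_diff_min`, `accumulated_min`.
#' @export
accumulated_difference <- function(recovery, baseline_days) {
  if (inherits(baseline_days, "state_time_table")) {
    baseline_days <- list(baseline_days)
  }
  base <- purrr::imap(baseline_days, function(tbl, day) {
    tibble(
      zt24 = as.integer(tbl$hour) %% 24L, state = tbl$state,
      minutes = tbl$minutes, day = day
    )
  }) |>
    purrr::list_rbind() |>
    summarise(
      base_minutes = mean(.data$minutes),
      .by = c("zt24", "state")
    )
  rec <- tibble(
    hour = as.integer(recovery$hour),
    zt24 = as.integer(recovery$hour) %% 24L,
    state = recovery$state, minutes = recovery$minutes
  )
  joined <- left_join(rec, base, by = c("zt24", "state"))
  if (anyNA(joined$base_minutes)) {
    stop("recovery hours not aligned with baseline ZT hours", call. = FALSE)
  }
  out <- joined |>
    mutate(hourly_diff_min = .data$minutes - .data$base_minutes) |>
    arrange(.data$state, .data$hour) |>
    mutate(accumulated_min = cumsum(.data$hourly_diff_min), .by = "state") |>
    select("hour", "state", "hourly_diff_min", "accumulated_min") |>
    arrange(.data$hour, .data$state)
  structure(out, class = c("accumulated_curve", class(tibble())))
}

#' Percentage of stage-1 sleep in a recording window
#'
#' The fraction of N1-scored epochs among all non-artifact epochs in
#' the window, in percent — the "wake instability" measure for
#' recordings during which the subject was instructed to stay awake.
#'
#' @param hyp A human [hypnogram()].
#' @param window Optional integer range of epoch indices (0-based,
#'   inclusive) to restrict to; defaults to the whole recording.
#' @return Percentage in `[0, 100]`.
#' @export
stage1_percentage <- function(hyp, window = NULL) {
  stopifnot(attr(hyp, "species") == "human")
  keep <- !hyp$artifact
  if (!is.null(window)) {
    stopifnot(length(window) == 2)
    keep <- keep & hyp$epoch >= window[1] & hyp$epoch <= window[2]
  }
  if (!any(keep)) stop("window contains no scorable epochs", call. = FALSE)
  100 * sum(hyp$state[keep] == "N1") / sum(keep)
}

#' Locate the first NREM sleep episode
#'
#' Finds the first run of NREM stages (N1-N3) reaching
#' `min_duration_min` of continuous NREM sleep; the episode then runs
#' until the onset of the first REM episode lasting at least
#' `rem_break_min` (standard NREM-REM cycle convention). Shorter REM
#' intrusions do not terminate the episode. If no qualifying REM
#' follows, the episode ends at the last sleep-stage epoch.
#'
#' @param hyp A human [hypnogram()].
#' @param min_duration_min Minimum NREM run length to start an episode
#'   (minutes).
#' @param rem_break_min Minimum REM run length to terminate it
#'   (minutes).
#' @return One-row tibble with `found`, `start_epoch`, `end_epoch`,
#'   `n_epochs`, `duration_min` (`found = FALSE` and `NA`s when no
#'   episode qualifies).
#' @export
first_nrem_episode <- function(hyp, min_duration_min = 15,
                               rem_break_min = 5) {
  stopifnot(attr(hyp, "species") == "human")
  epoch_s <- epoch_length_s(hyp)
  no_episode <- tibble(
    found = FALSE, start_epoch = NA_integer_, end_epoch = NA_integer_,
    n_epochs = NA_integer_, duration_min = NA_real_
  )
  nrem <- hyp$state %in% c("N1", "N2", "N3")
  r <- rle(nrem)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_epochs <- ceiling(min_duration_min * 60 / epoch_s)
  cand <- which(r$values & r$lengths >= min_epochs)
  if (length(cand) == 0) return(no_episode)
  start <- starts[cand[1]]
  # first sufficiently long REM run after the episode start
  rem <- hyp$state == "REM"
  rr <- rle(rem)
  rends <- cumsum(rr$lengths)
  rstarts <- rends - rr$lengths + 1L
  rem_epochs <- ceiling(rem_break_min * 60 / epoch_s)
  term <- which(rr$values & rr$lengths >= rem_epochs & rstarts > start)
  if (length(term) > 0) {
    end <- rstarts[term[1]] - 1L
  } else {
    sleep_idx <- which(hyp$state %in% human_sleep_stages())
    end <- max(sleep_idx[sleep_idx >= start])
  }
  # trim trailing wake so the span ends on a sleep stage
  while (end > start && !(hyp$state[end] %in% human_sleep_stages())) {
    end <- end - 1L
  }
  tibble(
    found = TRUE,
    start_epoch = hyp$epoch[start], end_epoch = hyp$epoch[end],
    n_epochs = end - start + 1L,
    duration_min = (end - start + 1L) * epoch_s / 60
  )
}
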