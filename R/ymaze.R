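#' Spontaneous alternation score
#'
#' The percentage of successful entry triplets: windows of three
#' consecutive arm entries containing all three arms, relative to the
#' number of possible triplets (total entries minus two). The chance
#' level of a never-stay random walker is 50 %.
#'
#' @param entries Character vector of visited arms (consecutive entries
#'   always differ).
#' @return Percentage in `[0, 100]`, or `NA` (with a warning) for
#'   sequences of fewer than 3 entries, for which the score is
#'   undefined.
#' @export
#' @examples
#' alternation_score(c("A", "B", "C", "A", "B")) # 100
alternation_score <- function(entries) {
  n <- length(entries)
  if (any(entries[-1] == entries[-n])) {
    stop("consecutive entries must differ (an entry requires leaving the arm)",
      call. = FALSE
    )
  }
  if (n < 3) {
    warning("alternation score undefined for fewer than 3 entries")
    return(NA_real_)
  }
  success <- vapply(
    seq_len(n - 2),
    function(i) length(unique(entries[i:(i + 2)])) == 3L,
    logical(1)
  )
  100 * sum(success) / (n - 2)
}

#' Total number of arm entries
#'
#' The exploratory-behavior measure: how many arm entries the animal
#' made during the test.
#'
#' @param entries Character vector of visited arms.
#' @return Integer count.
#' @export
total_entries <- function(entries) length(entries)

#' Habituation: change in entries relative to the first maze exposure
#'
#' Exploration declines across repeated exposures to the same maze;
#' normalizing later runs to the first exposure isolates that
#' habituation from baseline differences in exploratory drive.
#'
#' @param counts Numeric vector of per-run total entry counts.
#' @param runs Run numbers for `counts` (default `1, 2, ...`); run 1
#'   must be present.
#' @return Tibble with `run` and `delta_entries`
#'   (`entries_run - entries_run1`) for every run after the first.
#' @export
#' @examples
#' habituation_delta(c(20, 12, 10)) # -8, -10
habituation_delta <- function(counts, runs = seq_along(counts)) {
  stopifnot(length(counts) == length(runs))
  if (!1 %in% runs) stop("run 1 (first exposure) is required", call. = FALSE)
  ref <- counts[match(1, runs)]
  keep <- runs != 1
  tibble(run = runs[keep], delta_entries = counts[keep] - ref)
}

#' Score a Y-maze cohort table
#'
#' Applies [alternation_score()], [total_entries()] and
#' [habituation_delta()] across a cohort tibble with an `entries`
#' list-column (from [read_entries()] or [simulate_ymaze_runs()]).
#'
#' @param tbl Cohort tibble with `subject`, `run`, `condition`,
#'   `entries`.
#' @return Tibble with per-subject/run `n_entries`, `alternation_pct`,
#'   and `delta_entries` (NA for run 1).
#' @export
score_ymaze <- function(tbl) {
  scored <- tbl |>
    mutate(
      n_entries = vapply(.data$entries, total_entries, integer(1)),
      alternation_pct = vapply(.data$entries, alternation_score, numeric(1))
    ) |>
    select(-"entries")
  scored |>
    arrange(.data$subject, .data$run) |>
    mutate(
      delta_entries = .data$n_entries -
        .data$n_entries[match(1, .data$run)],
      .by = c("subject", "condition")
    ) |>
    mutate(delta_entries = ifelse(.data$run == 1, NA_integer_, .data$delta_entries))
}
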