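#' Vigilance-state-weighted total power reference
#'
#' To account for inter-individual differences in absolute EEG power,
#' state-specific power is normalized by a per-animal reference: the
#' area under the baseline PSD curve is computed per vigilance state
#' (mean full-band power of that state's clean epochs, integrated over
#' `area_band`), each area is weighted by the state's share of
#' contributing clean epochs in baseline, and the weighted areas are
#' summed. Only artifact-free epochs flanked by the same state
#' contribute (see [mark_transition_epochs()]).
#'
#' @param spec Baseline [spectra()].
#' @param hyp Matching baseline [hypnogram()].
#' @param area_band Band over which the PSD area is taken (Hz); default
#'   0.75-49, the analysis range of the mouse spectra.
#' @return A tibble of class `"total_power_reference"` with one row per
#'   state (`state`, `area`, `fraction`) and attribute `reference`
#'   (the weighted sum). A state with no clean epochs gets weight 0
#'   with a warning.
#' @export
total_power_reference <- function(spec, hyp,
                                  area_band = somnostat_config()$psd_area_band) {
  stopifnot(nrow(spec$psd) == nrow(hyp))
  clean <- clean_epoch_mask(hyp)
  if (!any(clean)) stop("no clean epochs in baseline", call. = FALSE)
  full <- band_power(spec, area_band)
  vocab <- state_vocabulary(attr(hyp, "species"))
  tab <- purrr::map(vocab, function(st) {
    idx <- clean & hyp$state == st
    if (!any(idx)) {
      warning(sprintf("state %s has no clean epochs; weight 0", st))
      tibble(state = st, area = 0, fraction = 0)
    } else {
      tibble(state = st, area = mean(full[idx]), fraction = sum(idx) / sum(clean))
    }
  }) |> purrr::list_rbind()
  reference <- sum(tab$area * tab$fraction)
  structure(tab,
    class = c("total_power_reference", class(tibble())),
    reference = reference, area_band = area_band
  )
}

#' Interval scheme for the delta-power time course
#'
#' The recording is subdivided into segments (light/dark phases of each
#' baseline day, and the recovery light and dark phases), each split
#' into a fixed number of intervals containing equal numbers of NREM
#' epochs: 12 intervals per 12-h light phase, 6 per 12-h dark phase,
#' and 8 for the 6-h recovery light phase after sleep deprivation.
#'
#' @param protocol Protocol window list (see [somnostat_config()]).
#' @param intervals Named counts for `light`, `dark`,
#'   `recovery_light` segments.
#' @return Tibble with `segment`, `zt_start`, `zt_end`, `n_intervals`.
#' @export
interval_scheme <- function(protocol = somnostat_config()$protocol,
                            intervals = somnostat_config()$intervals) {
  sd_end <- protocol$sd_start_zt + protocol$sd_h
  light_end <- protocol$sd_start_zt + 12 # end of the recovery-day light phase
  rec_end <- sd_end + protocol$recovery_h
  tibble(
    segment = c(
      "baseline1_light", "baseline1_dark",
      "baseline2_light", "baseline2_dark",
      "recovery_light", "recovery_dark"
    ),
    zt_start = c(0, 12, 24, 36, sd_end, light_end),
    zt_end = c(12, 24, 36, 48, light_end, rec_end),
    n_intervals = as.integer(c(
      intervals["light"], intervals["dark"],
      intervals["light"], intervals["dark"],
      intervals["recovery_light"], intervals["dark"]
    ))
  )
}

# Split n sorted epochs into k intervals whose counts differ by at most
# one; remainder epochs go to the earliest intervals.
equal_count_partition <- function(n, k) {
  if (n < k) stop(sprintf("only %d epochs for %d intervals", n, k), call. = FALSE)
  base <- n %/% k
  extra <- n %% k
  counts <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  rep(seq_len(k), times = counts)
}

# Shared engine: bin an arbitrary per-epoch value over clean NREM
# epochs into the equal-count interval scheme, normalized to the mean
# of baseline-day reference-window values (equal weight per day).
timecourse_engine <- function(values, hyp, scheme, reference_zt,
                              baseline_day_starts = c(0, 24)) {
  clean <- clean_epoch_mask(hyp) & hyp$state == "NREM"
  day_means <- vapply(baseline_day_starts, function(d0) {
    idx <- clean & hyp$zt >= d0 + reference_zt[1] & hyp$zt < d0 + reference_zt[2]
    if (!any(idx)) {
      stop("no clean NREM epochs in a baseline reference window", call. = FALSE)
    }
    mean(values[idx])
  }, numeric(1))
  reference <- mean(day_means)
  rows <- purrr::pmap(scheme, function(segment, zt_start, zt_end, n_intervals) {
    idx <- which(clean & hyp$zt >= zt_start & hyp$zt < zt_end)
    if (length(idx) < n_intervals) {
      stop(sprintf(
        "segment %s has %d clean NREM epochs for %d intervals",
        segment, length(idx), n_intervals
      ), call. = FALSE)
    }
    part <- equal_count_partition(length(idx), n_intervals)
    tibble(
      segment = segment,
      interval = seq_len(n_intervals),
      mean_zt = as.numeric(tapply(hyp$zt[idx], part, mean)),
      value_pct = 100 * as.numeric(tapply(values[idx], part, mean)) / reference,
      n_epochs = as.integer(tabulate(part, n_intervals))
    )
  })
  out <- purrr::list_rbind(rows)
  structure(out,
    class = c("delta_timecourse", class(tibble())),
    reference = reference, reference_zt = reference_zt, scheme = scheme
  )
}

#' Equal-NREM-epoch time course of normalized delta power
#'
#' The canonical marker of homeostatic sleep pressure: NREM delta power
#' (0.75-4 Hz) expressed as a percentage of the baseline late-light
#' reference (mean delta power of clean NREM epochs with ZT in
#' `[8, 12)`, averaged over the two baseline days with equal weight),
#' binned into intervals containing equal numbers of clean NREM epochs
#' per segment. The abscissa of each interval is the mean zeitgeber
#' time of its contributing epochs.
#'
#' Only artifact-free NREM epochs flanked by NREM are used. Within a
#' segment the interval epoch counts differ by at most one (remainder
#' epochs are assigned to the earliest intervals).
#'
#' @param spec A [spectra()] for the full recording.
#' @param hyp Matching [hypnogram()] (with artifact flags).
#' @param scheme Segment table from [interval_scheme()].
#' @param delta_band Delta band in Hz.
#' @param reference_zt ZT window (hours, within a day) of the baseline
#'   reference, default `c(8, 12)`.
#' @return A tibble of class `"delta_timecourse"` with columns
#'   `segment`, `interval`, `mean_zt`, `value_pct`, `n_epochs`;
#'   attribute `reference` holds the absolute reference delta power.
#' @export
delta_timecourse <- function(spec, hyp,
                             scheme = interval_scheme(),
                             delta_band = somnostat_config()$bands$delta_mouse,
                             reference_zt = somnostat_config()$reference_zt) {
  stopifnot(nrow(spec$psd) == nrow(hyp))
  delta <- band_power(spec, delta_band)
  timecourse_engine(delta, hyp, scheme, reference_zt)
}

#' Exclude recordings with aberrant summary power
#'
#' Flags animals whose per-animal summary value deviates from the group
#' mean by more than `k_sd` standard deviations (mean and SD over all
#' animals, single pass).
#'
#' @param values Named numeric vector, one summary value per animal.
#' @param k_sd Exclusion threshold in SD units (default 2).
#' @return Tibble with `animal`, `value`, `z`, `excluded`.
#' @export
detect_outlier_recordings <- function(values, k_sd = 2) {
  if (length(values) < 3) stop("need at least 3 animals", call. = FALSE)
  nm <- names(values) %||% as.character(seq_along(values))
  mu <- mean(values)
  s <- sd(values)
  z <- if (s == 0) rep(0, length(values)) else (values - mu) / s
  tibble(
    animal = nm, value = as.numeric(values), z = z,
    excluded = abs(values - mu) > k_sd * s
  )
}
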