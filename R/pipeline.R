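#' End-to-end analysis of a mouse sleep-deprivation recording
#'
#' Runs the full quantification chain on a 72-h recording (48 h
#' baseline, 6 h sleep deprivation, 18 h recovery): hourly state times,
#' baseline-relative accumulated rebound curves over the recovery
#' period, the vigilance-state-weighted total power reference, and the
#' equal-NREM-epoch delta-power time course.
#'
#' @param hyp A mouse [hypnogram()] covering the full protocol.
#' @param spec The matching [spectra()].
#' @param protocol Protocol windows (see [somnostat_config()]).
#' @param scheme Interval scheme; defaults to [interval_scheme()] for
#'   `protocol`.
#' @return List with `state_time` (full-recording
#'   [time_in_state_per_hour()] table), `accumulated`
#'   ([accumulated_difference()] over recovery vs. the mean of the two
#'   baseline days), `reference` ([total_power_reference()] from the
#'   baseline), and `timecourse` ([delta_timecourse()]).
#' @export
analyze_mouse_recording <- function(hyp, spec,
                                    protocol = somnostat_config()$protocol,
                                    scheme = interval_scheme(protocol)) {
  state_time <- time_in_state_per_hour(hyp)
  sd_end <- protocol$sd_start_zt + protocol$sd_h
  baseline_days <- purrr::map(
    seq_len(protocol$baseline_h %/% 24),
    function(d) {
      state_time[state_time$hour >= (d - 1) * 24 & state_time$hour < d * 24, ]
    }
  )
  recovery <- state_time[state_time$hour >= sd_end, ]
  accumulated <- accumulated_difference(recovery, baseline_days)
  base_idx <- hyp$zt < protocol$baseline_h
  base_hyp <- hypnogram(
    hyp$state[base_idx],
    species = attr(hyp, "species"),
    artifact = hyp$artifact[base_idx],
    epoch_s = epoch_length_s(hyp)
  )
  base_spec <- spectra(spec$psd[base_idx, , drop = FALSE], spec$freq)
  reference <- total_power_reference(base_spec, base_hyp)
  timecourse <- delta_timecourse(spec, hyp, scheme = scheme)
  list(
    state_time = state_time, accumulated = accumulated,
    reference = reference, timecourse = timecourse
  )
}

#' File-level mouse analysis
#'
#' Reads a hypnogram/spectra pair (as written by [simulate_study()] or
#' any compatible source), runs [analyze_mouse_recording()], and writes
#' the state-time, accumulated-rebound, and delta-time-course tables as
#' TSV next to the outputs.
#'
#' @param hypnogram_path,spectra_path Input files.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the [analyze_mouse_recording()] result.
#' @export
analyze_mouse_files <- function(hypnogram_path, spectra_path, out_dir) {
  hyp <- read_hypnogram(hypnogram_path, species = "mouse")
  spec <- read_spectra(spectra_path)
  res <- analyze_mouse_recording(hyp, spec)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_tsv(as_tibble(res$state_time),
    file.path(out_dir, "state_time.tsv"),
    progress = FALSE
  )
  readr::write_tsv(as_tibble(res$accumulated),
    file.path(out_dir, "accumulated.tsv"),
    progress = FALSE
  )
  readr::write_tsv(as_tibble(res$timecourse),
    file.path(out_dir, "delta_timecourse.tsv"),
    progress = FALSE
  )
  invisible(res)
}

#' Accumulated total-sleep change at the end of recovery
#'
#' Convenience summary of an [accumulated_difference()] curve: the
#' summed accumulated change of the sleep states (all states except
#' wakefulness) at the last recovery hour, in minutes. Positive values
#' mean the animal regained sleep relative to baseline; negative values
#' mean net sleep loss despite the preceding deprivation.
#'
#' @param curve An `accumulated_curve`.
#' @param wake_state Label of the wake state.
#' @return Scalar minutes.
#' @export
final_sleep_change <- function(curve, wake_state = "WAKE") {
  last_hour <- max(curve$hour)
  sleep <- curve$state != wake_state & curve$hour == last_hour
  sum(curve$accumulated_min[sleep])
}

#' Human first-NREM-episode spectral markers
#'
#' Computes the two sleep-need markers of a human night: slow-wave
#' activity (0.5-4.5 Hz) and slow-oscillation (<1 Hz, i.e.
#' 0.25-1.0 Hz) power averaged over the artifact-free NREM epochs of
#' the first NREM sleep episode. The 4-s spectra are first averaged
#' over five consecutive epochs to match the 20-s scoring epochs. A
#' log10-transformed column is included, the scale on which EEG power
#' statistics are performed.
#'
#' @param spec 4-s epoch [spectra()] of the night (0.25 Hz bins).
#' @param hyp Matching human [hypnogram()] in 20-s epochs.
#' @param ... Passed to [first_nrem_episode()].
#' @return One-row tibble: episode bounds plus `swa`, `slow_osc`,
#'   `log_swa`, `log_slow_osc`.
#' @export
first_episode_markers <- function(spec, hyp, ...) {
  avg <- average_blocks(spec, k = 5)
  if (nrow(avg$psd) < nrow(hyp)) {
    hyp <- hypnogram(
      hyp$state[seq_len(nrow(avg$psd))],
      species = "human",
      artifact = hyp$artifact[seq_len(nrow(avg$psd))],
      epoch_s = epoch_length_s(hyp)
    )
  }
  stopifnot(nrow(avg$psd) == nrow(hyp))
  ep <- first_nrem_episode(hyp, ...)
  if (!ep$found) {
    return(mutate(ep,
      swa = NA_real_, slow_osc = NA_real_,
      log_swa = NA_real_, log_slow_osc = NA_real_
    ))
  }
  idx <- hyp$epoch >= ep$start_epoch & hyp$epoch <= ep$end_epoch &
    hyp$state %in% c("N1", "N2", "N3") & !hyp$artifact
  bands <- somnostat_config()$bands
  swa <- mean(band_power(avg, bands$swa_human)[idx])
  so <- mean(band_power(avg, bands$slow_oscillation)[idx])
  mutate(ep,
    swa = swa, slow_osc = so,
    log_swa = log10(swa), log_slow_osc = log10(so)
  )
}
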