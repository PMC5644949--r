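#' Default PET volume-of-interest set
#'
#' The nine bilateral brain regions with high mGluR5 expression used for
#' regional availability quantification.
#'
#' @return Character vector of region names.
#' @export
pet_regions <- function() {
  c(
    "medial superior frontal cortex", "orbitofrontal cortex",
    "dorsolateral prefrontal cortex", "anterior cingulate cortex",
    "inferior parietal cortex", "precuneus", "insula", "striatum",
    "parahippocampal gyrus"
  )
}

#' Human cohort simulation parameters
#'
#' Describes a two-condition (baseline vs. sleep deprivation)
#' within-subject imaging cohort with a planted global mGluR5
#' availability increase and a planted rank correlation between global
#' availability and an EEG marker of sleep need (first-NREM-episode
#' slow-wave activity). Defaults mirror the published cohort scale:
#' n = 23 subjects, global DV_norm 1.51 at baseline rising by 0.05
#' after deprivation (about +3.3 %), and a deprivation-induced increase
#' of slow-wave activity of 47.9 %.
#'
#' @param n_subjects Number of subjects.
#' @param baseline_global Mean global DV_norm at baseline.
#' @param subject_sd Between-subject SD of global DV_norm.
#' @param condition_effect Absolute DV_norm increase after sleep
#'   deprivation.
#' @param condition_sd Between-subject SD of the condition effect.
#' @param rho Planted rank (Spearman) correlation between global
#'   availability and the EEG marker, `|rho| <= 1`. Internally the
#'   latent normal factors are given Pearson correlation
#'   `2 sin(pi rho / 6)`, the bivariate-normal value whose population
#'   Spearman coefficient equals `rho`, so the planted value is
#'   recoverable on the scale the inference layer uses.
#' @param region_noise_sd SD of independent per-region/hemisphere
#'   measurement noise on DV_norm.
#' @param cb_mean,cb_sd Mean and SD of the cerebellar reference activity
#'   concentration (arbitrary units).
#' @param marker_log_mean,marker_log_sd Mean and SD of log10 first-NREM
#'   SWA (uV^2).
#' @param marker_rebound Multiplicative SWA increase after deprivation
#'   (1.479 = +47.9 %).
#' @param marker_noise_sd SD of log10-scale measurement noise on the
#'   marker.
#' @return A list of class `"cohort_params"`.
#' @export
cohort_params <- function(n_subjects = 23,
                          baseline_global = 1.51,
                          subject_sd = 0.10,
                          condition_effect = 0.05,
                          condition_sd = 0.02,
                          rho = 0.8,
                          region_noise_sd = 0.05,
                          cb_mean = 800, cb_sd = 30,
                          marker_log_mean = 2.5,
                          marker_log_sd = 0.2,
                          marker_rebound = 1.479,
                          marker_noise_sd = 0.02) {
  stopifnot(abs(rho) <= 1, subject_sd >= 0, region_noise_sd >= 0)
  structure(
    as.list(environment()),
    class = "cohort_params"
  )
}

#' Simulate a two-condition PET/EEG cohort
#'
#' Each subject carries a latent availability factor `g` and a latent
#' EEG-marker factor `m` with correlation `rho`. Global DV_norm is
#' `baseline_global + subject_sd * g` (plus the condition effect after
#' deprivation); regional values are the global value times a fixed
#' region profile plus independent measurement noise, stored as activity
#' concentrations `c_t = DV * c_cb` against a per-scan cerebellar
#' reference `c_cb`. The EEG marker table holds first-NREM-episode
#' slow-wave activity and slow-oscillation (<1 Hz) power, log-normal
#' across subjects, rescaled by `marker_rebound` after deprivation.
#'
#' @param params A [cohort_params()] object.
#' @param seed Integer seed; pure function of `(params, seed)`.
#' @return List with tibbles `roi` (subject, condition, region,
#'   hemisphere, c_t, c_cb) and `markers` (subject, condition, swa,
#'   slow_osc), plus `truth` (the latent factors, for recovery tests).
#' @export
simulate_pet_cohort <- function(params = cohort_params(), seed = 1) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  regions <- pet_regions()
  # fixed multiplicative region profile around the global mean
  profile <- setNames(
    c(1.05, 1.00, 1.03, 1.02, 0.98, 0.97, 1.00, 1.08, 0.87),
    regions
  )
  subjects <- sprintf("S%02d", seq_len(p$n_subjects))
  conditions <- c("baseline", "sleep_deprivation")
  with_seed(child_seed(seed, "cohort"), {
    g <- rnorm(p$n_subjects)
    rho_lat <- 2 * sin(pi * p$rho / 6) # latent Pearson for Spearman rho
    m <- rho_lat * g + sqrt(max(0, 1 - rho_lat^2)) * rnorm(p$n_subjects)
    eff <- p$condition_effect + p$condition_sd * rnorm(p$n_subjects)
    global <- tibble(
      subject = rep(subjects, times = 2),
      condition = rep(conditions, each = p$n_subjects),
      global_true = rep(p$baseline_global + p$subject_sd * g, 2) +
        rep(c(0, 1), each = p$n_subjects) * rep(eff, 2)[seq_len(2 * p$n_subjects)]
    )
    roi <- tidyr::expand_grid(
      subject = subjects, condition = conditions,
      region = regions, hemisphere = c("left", "right")
    ) |>
      left_join(global, by = c("subject", "condition")) |>
      mutate(
        dv = .data$global_true * profile[.data$region] +
          rnorm(dplyr::n(), sd = p$region_noise_sd)
      )
    c_cb <- tidyr::expand_grid(subject = subjects, condition = conditions) |>
      mutate(c_cb = rnorm(dplyr::n(), p$cb_mean, p$cb_sd))
    roi <- roi |>
      left_join(c_cb, by = c("subject", "condition")) |>
      mutate(c_t = .data$dv * .data$c_cb) |>
      select("subject", "condition", "region", "hemisphere", "c_t", "c_cb")
    log_swa <- p$marker_log_mean + p$marker_log_sd * m
    markers <- tibble(
      subject = rep(subjects, 2),
      condition = rep(conditions, each = p$n_subjects),
      swa = 10^(rep(log_swa, 2) +
        rnorm(2 * p$n_subjects, sd = p$marker_noise_sd)) *
        rep(c(1, p$marker_rebound), each = p$n_subjects),
      slow_osc = 10^(rep(log_swa - 0.6, 2) +
        rnorm(2 * p$n_subjects, sd = p$marker_noise_sd)) *
        rep(c(1, 1.385), each = p$n_subjects)
    )
  })
  list(
    roi = roi, markers = markers,
    truth = tibble(subject = subjects, g = g, m = m, effect = eff)
  )
}

#' Simulate a Y-maze arm-entry sequence
#'
#' A continuous spontaneous-alternation walk on arms A/B/C: an entry
#' never repeats the current arm, and from the third entry on the
#' animal completes an alternation (enters the arm not visited in the
#' last two entries) with probability `p_alternate`, otherwise it
#' returns to the arm visited two entries ago. `p_alternate = 0.5` is
#' the never-stay random walker, whose alternation score converges to
#' the 50 % chance level.
#'
#' @param n_entries Number of entries (>= 3).
#' @param p_alternate Probability of completing an alternation.
#' @param seed Integer seed.
#' @return Character vector of visited arms.
#' @export
simulate_ymaze <- function(n_entries, p_alternate = 0.5, seed = 1) {
  stopifnot(n_entries >= 3, p_alternate >= 0, p_alternate <= 1)
  arms <- c("A", "B", "C")
  out <- character(n_entries)
  with_seed(child_seed(seed, "ymaze"), {
    out[1] <- sample(arms, 1)
    out[2] <- sample(setdiff(arms, out[1]), 1)
    alt <- runif(n_entries) < p_alternate
    for (i in 3:n_entries) {
      third <- setdiff(arms, c(out[i - 1], out[i - 2]))
      out[i] <- if (alt[i]) third else out[i - 2]
    }
  })
  out
}

#' Simulate a Y-maze cohort with repeated runs and habituation
#'
#' Generates entry sequences for a cohort tested in three runs. Entry
#' counts per run are Poisson around run-specific means (floored at 3),
#' expressing habituation as a declining mean; the alternation bias is
#' constant per subject.
#'
#' @param n_subjects Subjects per condition.
#' @param run_means Numeric vector of mean entry counts per run (run 1
#'   first). The default declines across runs, as for a habituating
#'   animal.
#' @param p_alternate Alternation probability (0.5 = chance).
#' @param condition Condition label to attach.
#' @param seed Integer seed.
#' @return Tibble with `subject`, `run`, `condition`, `n_entries`, and
#'   an `entries` list-column.
#' @export
simulate_ymaze_runs <- function(n_subjects = 8,
                                run_means = c(25, 15, 12),
                                p_alternate = 0.7,
                                condition = "control",
                                seed = 1) {
  stopifnot(all(run_means >= 3))
  grid <- tidyr::expand_grid(
    subject = sprintf("m%02d", seq_len(n_subjects)),
    run = seq_along(run_means)
  )
  with_seed(child_seed(seed, "ymaze_runs"), {
    n_entries <- pmax(3L, rpois(nrow(grid), run_means[grid$run]))
    seeds <- sample.int(.Machine$integer.max, nrow(grid))
  })
  grid$condition <- condition
  grid$n_entries <- n_entries
  grid$entries <- purrr::map2(
    n_entries, seeds,
    function(n, s) simulate_ymaze(n, p_alternate, seed = s)
  )
  grid
}

#' Write a complete synthetic study to disk
#'
#' Runs the mouse recording, cohort, and Y-maze generators under one
#' master seed and writes `hypnogram.tsv`, `spectra.csv`, `roi.csv`,
#' `markers.csv`, `entries.tsv`, and a `manifest.json` recording the
#' seed, generator parameters, and per-file row counts so downstream
#' parameter-recovery analyses are auditable.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master integer seed.
#' @param genotype Mouse preset for the recording.
#' @return Invisibly, the manifest as a list.
#' @export
simulate_study <- function(dir, seed = 1, genotype = "wt") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec <- simulate_mouse_recording(genotype, seed = seed)
  cohort <- simulate_pet_cohort(seed = seed)
  runs <- simulate_ymaze_runs(seed = seed)
  write_hypnogram(rec$hypnogram, file.path(dir, "hypnogram.tsv"))
  write_spectra(rec$spectra, file.path(dir, "spectra.csv"))
  write_roi_table(cohort$roi, file.path(dir, "roi.csv"))
  readr::write_csv(cohort$markers, file.path(dir, "markers.csv"),
    progress = FALSE
  )
  write_entries(runs, file.path(dir, "entries.tsv"))
  manifest <- list(
    seed = seed,
    genotype = genotype,
    process_s = rec$params$pressure[c("s0", "ua", "la", "tau_i", "tau_d")],
    sigma = rec$params$sigma,
    rows = list(
      hypnogram = nrow(rec$hypnogram),
      spectra = nrow(rec$spectra$psd),
      roi = nrow(cohort$roi),
      markers = nrow(cohort$markers),
      entries = nrow(runs)
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}
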