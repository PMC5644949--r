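#' Sleep-wake architecture parameters for the mouse protocol
#'
#' Describes a 72-h recording: 48 h undisturbed baseline, 6 h sleep
#' deprivation starting at light onset of day 3 (ZT48-54 in cumulative
#' zeitgeber time), and 18 h recovery, under a 12:12 light:dark cycle.
#' Sleep-wake architecture is a first-order Markov chain over
#' WAKE/NREM/REM at the 4-s epoch level, with one transition matrix per
#' lighting phase and, optionally, separate matrices for the recovery
#' light and dark phases to express the post-deprivation rebound (or its
#' genotype-dependent failure). Direct WAKE to REM transitions are
#' disabled by default (physiological constraint) but any row-stochastic
#' matrix is accepted.
#'
#' The genotype presets are descriptive, not mechanistic: the wild-type
#' (`"wt"`) preset increases sleep propensity throughout recovery so the
#' animal regains sleep relative to baseline; the knock-out (`"ko"`)
#' preset shows the same immediate light-phase rebound but suppressed
#' sleep in the recovery dark phase, so it ends recovery with a net
#' sleep loss; `"ht"` is intermediate.
#'
#' @param genotype Preset: `"wt"`, `"ht"` or `"ko"`.
#' @param matrices Optional named list of 3x3 row-stochastic matrices
#'   (`light`, `dark`, and optionally `recovery_light`,
#'   `recovery_dark`), rows/columns ordered WAKE, NREM, REM. Overrides
#'   the preset.
#' @param protocol List with `baseline_h`, `sd_start_zt`, `sd_h`,
#'   `recovery_h` (hours).
#' @param epoch_s Epoch length in seconds.
#' @return A list of class `"architecture_params"`.
#' @export
mouse_architecture <- function(genotype = c("wt", "ht", "ko"),
                               matrices = NULL,
                               protocol = somnostat_config()$protocol,
                               epoch_s = 4) {
  genotype <- match.arg(genotype)
  states <- state_vocabulary("mouse")
  tm <- function(p) {
    m <- matrix(p, 3, 3, byrow = TRUE, dimnames = list(states, states))
    if (max(abs(rowSums(m) - 1)) > 1e-9) {
      stop("transition matrix rows must sum to 1", call. = FALSE)
    }
    m
  }
  # Baseline per-4-s-epoch probabilities; stationary state fractions are
  # about 40/50/10 % (W/N/R) in the light and 75/21/4 % in the dark,
  # with mean bout lengths of a few minutes.
  base <- list(
    light = tm(c(
      0.960, 0.040, 0.000,
      0.025, 0.965, 0.010,
      0.035, 0.015, 0.950
    )),
    dark = tm(c(
      0.985, 0.015, 0.000,
      0.045, 0.945, 0.010,
      0.050, 0.010, 0.940
    ))
  )
  # Recovery rebound: all genotypes rebound in the 6-h light phase;
  # during the recovery dark phase wild types keep regaining sleep while
  # knock-outs suppress it below baseline.
  rebound_light <- tm(c(
    0.940, 0.060, 0.000,
    0.015, 0.975, 0.010,
    0.035, 0.015, 0.950
  ))
  preset <- switch(genotype,
    wt = c(base, list(
      recovery_light = rebound_light,
      recovery_dark = tm(c(
        0.9825, 0.0175, 0.000,
        0.040, 0.950, 0.010,
        0.050, 0.010, 0.940
      ))
    )),
    ht = c(base, list(
      recovery_light = rebound_light,
      recovery_dark = tm(c(
        0.983, 0.017, 0.000,
        0.041, 0.949, 0.010,
        0.050, 0.010, 0.940
      ))
    )),
    ko = c(base, list(
      recovery_light = rebound_light,
      recovery_dark = tm(c(
        0.990, 0.010, 0.000,
        0.065, 0.925, 0.010,
        0.070, 0.010, 0.920
      ))
    ))
  )
  if (!is.null(matrices)) {
    for (nm in names(matrices)) preset[[nm]] <- tm(t(matrices[[nm]])[TRUE])
  }
  structure(
    list(
      genotype = genotype, matrices = preset, protocol = protocol,
      epoch_s = epoch_s, states = states
    ),
    class = "architecture_params"
  )
}

#' Stationary distribution of a transition matrix
#'
#' @param P Row-stochastic square matrix.
#' @return Named probability vector.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  setNames(v / sum(v), colnames(P))
}

#' Simulate a 72-h mouse hypnogram
#'
#' Draws 4-s epochs from the phase-specific Markov chains of
#' [mouse_architecture()]. Lighting alternates every 12 h (ZT0 = light
#' onset); all epochs inside the sleep-deprivation window are forced to
#' WAKE. The first epoch is drawn from the light-phase stationary
#' distribution.
#'
#' @param params An [mouse_architecture()] object.
#' @param seed Integer seed; the generator is a pure function of
#'   `(params, seed)`.
#' @return A [hypnogram()] covering the full protocol (64,800 epochs for
#'   the default 72-h protocol).
#' @export
simulate_hypnogram <- function(params = mouse_architecture(), seed = 1) {
  stopifnot(inherits(params, "architecture_params"))
  pr <- params$protocol
  total_h <- pr$baseline_h + pr$sd_h + pr$recovery_h
  n <- as.integer(round(total_h * 3600 / params$epoch_s))
  zt <- (seq_len(n) - 1L) * params$epoch_s / 3600
  light <- (zt %% 24) < 12
  recovery <- zt >= (pr$sd_start_zt + pr$sd_h)
  forced_wake <- zt >= pr$sd_start_zt & zt < (pr$sd_start_zt + pr$sd_h)
  m <- params$matrices
  phase_names <- c("light", "dark", "recovery_light", "recovery_dark")
  # fall back to the baseline matrices when no recovery-specific ones given
  if (is.null(m$recovery_light)) m$recovery_light <- m$light
  if (is.null(m$recovery_dark)) m$recovery_dark <- m$dark
  phase_id <- ifelse(light, 1L, 2L)
  phase_id[recovery & light] <- 3L
  phase_id[recovery & !light] <- 4L
  phase_id[forced_wake] <- 0L
  cum <- array(0, c(4, 3, 3))
  for (k in 1:4) cum[k, , ] <- t(apply(m[[phase_names[k]]], 1, cumsum))
  states <- params$states
  out <- integer(n)
  with_seed(child_seed(seed, "hypnogram"), {
    u <- runif(n)
    p0 <- cumsum(stationary_distribution(m$light))
    out[1] <- if (forced_wake[1]) 1L else findInterval(u[1], p0) + 1L
    for (i in 2:n) {
      pid <- phase_id[i]
      if (pid == 0L) {
        out[i] <- 1L
      } else {
        ui <- u[i]
        prev <- out[i - 1L]
        out[i] <- if (ui < cum[pid, prev, 1]) {
          1L
        } else if (ui < cum[pid, prev, 2]) 2L else 3L
      }
    }
  })
  hypnogram(states[out],
    species = "mouse",
    epoch_s = params$epoch_s
  )
}

#' Two-process sleep-pressure parameters
#'
#' Process S builds exponentially towards an upper asymptote during
#' wakefulness and REM sleep (time constant `tau_i`) and decays towards
#' a lower asymptote during NREM sleep (`tau_d`). Values are expressed
#' in percent of the baseline late-light-phase NREM delta-power
#' reference. Defaults (`tau_i` = 8 h, `tau_d` = 2 h, asymptotes 280 %
#' and 60 %) are in the range reported for inbred mouse strains. The
#' knock-out preset expresses an attenuated homeostat: smaller dynamic
#' range and slower build-up.
#'
#' @param genotype Preset: `"wt"`, `"ht"` or `"ko"`.
#' @param s0 Initial pressure (%).
#' @param ua,la Upper and lower asymptotes (%), `la < s0 <= ua`.
#' @param tau_i Build-up time constant, hours (WAKE and REM).
#' @param tau_d Decay time constant, hours (NREM).
#' @param sigma Multiplicative log-normal noise SD on emitted NREM delta
#'   power (see [simulate_spectra()]).
#' @return A list of class `"process_s_params"`.
#' @export
process_s_params <- function(genotype = c("wt", "ht", "ko"),
                             s0 = NULL, ua = NULL, la = NULL,
                             tau_i = NULL, tau_d = NULL, sigma = 0.2) {
  genotype <- match.arg(genotype)
  d <- switch(genotype,
    wt = list(s0 = 150, ua = 280, la = 60, tau_i = 8, tau_d = 2),
    ht = list(s0 = 140, ua = 220, la = 67, tau_i = 11, tau_d = 2),
    ko = list(s0 = 120, ua = 160, la = 75, tau_i = 16, tau_d = 2)
  )
  p <- list(
    genotype = genotype,
    s0 = s0 %||% d$s0, ua = ua %||% d$ua, la = la %||% d$la,
    tau_i = tau_i %||% d$tau_i, tau_d = tau_d %||% d$tau_d,
    sigma = sigma
  )
  stopifnot(p$la < p$s0, p$s0 <= p$ua, p$tau_i > 0, p$tau_d > 0, p$sigma >= 0)
  structure(p, class = "process_s_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the Process-S pressure trajectory along a hypnogram
#'
#' Per epoch of length `dt` hours the pressure is updated as
#' `S <- UA - (UA - S) * exp(-dt / tau_i)` in WAKE and REM, and
#' `S <- LA + (S - LA) * exp(-dt / tau_d)` in NREM. The returned value
#' at epoch i is the pressure at the *start* of epoch i (so `S[1] = s0`
#' and epoch i's state determines the step to `S[i+1]`). Implemented via
#' the closed-form solution over runs of constant state, which is
#' algebraically identical to the per-epoch iteration.
#'
#' @param hyp A mouse [hypnogram()].
#' @param params A [process_s_params()] object.
#' @return Numeric vector of pressures (%) with one value per epoch,
#'   bounded in `[la, ua]`.
#' @export
simulate_process_s <- function(hyp, params = process_s_params()) {
  stopifnot(inherits(params, "process_s_params"))
  dt <- epoch_length_s(hyp) / 3600
  build <- hyp$state != "NREM"
  r <- rle(build)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  s <- numeric(nrow(hyp))
  s_cur <- params$s0
  for (k in seq_along(r$lengths)) {
    len <- r$lengths[k]
    steps <- seq_len(len) - 1
    if (r$values[k]) {
      decay <- exp(-steps * dt / params$tau_i)
      s[starts[k]:ends[k]] <- params$ua - (params$ua - s_cur) * decay
      s_cur <- params$ua - (params$ua - s_cur) * exp(-len * dt / params$tau_i)
    } else {
      decay <- exp(-steps * dt / params$tau_d)
      s[starts[k]:ends[k]] <- params$la + (s_cur - params$la) * decay
      s_cur <- params$la + (s_cur - params$la) * exp(-len * dt / params$tau_d)
    }
  }
  s
}

#' State-specific spectral templates
#'
#' Mean PSD shapes per vigilance state over 0.25-49 Hz in 0.25-Hz bins
#' (units uV^2/Hz, arbitrary but consistent). The shapes are smooth
#' caricatures of rodent EEG: a 1/f background, a theta peak in WAKE and
#' (more pronounced) in REM, and a delta-dominated NREM spectrum whose
#' delta band is scaled by the instantaneous Process-S pressure.
#'
#' @param artifact_rate Probability that an epoch is flagged as an
#'   artifact.
#' @param delta_band Frequency band (Hz) that the pressure drive scales.
#' @return A list of class `"spectral_template"` with elements `freq`,
#'   `shapes` (3 x nbins matrix), `delta_band`, `artifact_rate`.
#' @export
spectral_template <- function(artifact_rate = 0.02,
                              delta_band = c(0.75, 4)) {
  stopifnot(artifact_rate >= 0, artifact_rate <= 1)
  freq <- seq(0.25, 49, by = 0.25)
  backbone <- 1 / (0.5 + freq)
  bump <- function(f0, w, h) h * exp(-(freq - f0)^2 / (2 * w^2))
  shapes <- rbind(
    WAKE = 0.8 * backbone + bump(8, 1.5, 0.15),
    NREM = 2.0 * backbone + bump(12, 1.0, 0.10),
    REM = 0.7 * backbone + bump(7, 1.0, 0.30)
  )
  colnames(shapes) <- format(freq, trim = TRUE)
  structure(
    list(
      freq = freq, shapes = shapes, delta_band = delta_band,
      artifact_rate = artifact_rate
    ),
    class = "spectral_template"
  )
}

#' Simulate per-epoch EEG power spectra
#'
#' Each epoch receives its state's template spectrum. NREM epochs have
#' the delta-band bins multiplied by `S/100` (so delta power is
#' proportional to the sleep pressure); every epoch is then multiplied
#' by a mean-one log-normal factor `exp(sigma Z - sigma^2/2)`, making
#' expected NREM delta power exactly proportional to `S`. Artifact flags
#' are drawn i.i.d. at the template's `artifact_rate` and returned as
#' the `"artifact"` attribute (merge them into the hypnogram with
#' [simulate_mouse_recording()]).
#'
#' @param hyp A mouse [hypnogram()].
#' @param s Pressure trajectory from [simulate_process_s()], same length
#'   as `hyp`.
#' @param tmpl A [spectral_template()].
#' @param sigma Log-normal noise SD (dimensionless); 0 gives
#'   deterministic spectra.
#' @param seed Integer seed.
#' @return A [spectra()] object with a logical `"artifact"` attribute.
#' @export
simulate_spectra <- function(hyp, s, tmpl = spectral_template(),
                             sigma = 0.2, seed = 1) {
  stopifnot(inherits(tmpl, "spectral_template"), length(s) == nrow(hyp))
  n <- nrow(hyp)
  state_idx <- match(hyp$state, rownames(tmpl$shapes))
  psd <- tmpl$shapes[state_idx, , drop = FALSE]
  dbins <- band_bins(tmpl$freq, tmpl$delta_band)
  nrem <- hyp$state == "NREM"
  psd[nrem, dbins] <- psd[nrem, dbins, drop = FALSE] * (s[nrem] / 100)
  with_seed(child_seed(seed, "spectra"), {
    if (sigma > 0) {
      fac <- exp(rnorm(n, mean = -sigma^2 / 2, sd = sigma))
      psd <- psd * fac
    }
    artifact <- runif(n) < tmpl$artifact_rate
  })
  out <- spectra(psd, tmpl$freq)
  attr(out, "artifact") <- artifact
  out
}

#' Simulate a complete mouse sleep-deprivation recording
#'
#' Chains [simulate_hypnogram()], [simulate_process_s()] and
#' [simulate_spectra()] under one master seed, merging the drawn
#' artifact flags into the hypnogram.
#'
#' @param genotype Preset passed to [mouse_architecture()] and
#'   [process_s_params()].
#' @param seed Master integer seed.
#' @param architecture,pressure,template Optional parameter objects
#'   overriding the presets.
#' @param sigma Log-normal noise SD on emitted power (overrides the
#'   pressure preset's `sigma`).
#' @return List with elements `hypnogram`, `spectra`, `pressure`, and
#'   `params` (the parameter objects used, for recovery tests).
#' @export
simulate_mouse_recording <- function(genotype = c("wt", "ht", "ko"),
                                     seed = 1,
                                     architecture = NULL,
                                     pressure = NULL,
                                     template = spectral_template(),
                                     sigma = NULL) {
  genotype <- match.arg(genotype)
  architecture <- architecture %||% mouse_architecture(genotype)
  pressure <- pressure %||% process_s_params(genotype)
  sigma <- sigma %||% pressure$sigma
  hyp <- simulate_hypnogram(architecture, seed = seed)
  s <- simulate_process_s(hyp, pressure)
  spec <- simulate_spectra(hyp, s, template, sigma = sigma, seed = seed)
  hyp$artifact <- attr(spec, "artifact")
  list(
    hypnogram = hyp, spectra = spec, pressure = s,
    params = list(
      architecture = architecture, pressure = pressure,
      template = template, sigma = sigma, seed = seed
    )
  )
}
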