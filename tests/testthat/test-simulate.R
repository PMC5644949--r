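test_that("an absorbing WAKE matrix yields an all-WAKE hypnogram", {
  absorbing <- matrix(
    c(1, 0, 0, 1, 0, 0, 1, 0, 0),
    3, 3,
    byrow = TRUE
  )
  params <- mouse_architecture(
    matrices = list(
      light = absorbing, dark = absorbing,
      recovery_light = absorbing, recovery_dark = absorbing
    )
  )
  hyp <- simulate_hypnogram(params, seed = 1)
  expect_true(all(hyp$state == "WAKE"))
})

test_that("the deprivation window is all WAKE and generators are pure in the seed", {
  params <- mouse_architecture("wt")
  hyp <- simulate_hypnogram(params, seed = 7)
  sd_window <- hyp$zt >= 48 & hyp$zt < 54
  expect_equal(sum(sd_window), 5400)
  expect_true(all(hyp$state[sd_window] == "WAKE"))
  expect_identical(
    simulate_hypnogram(params, seed = 7)$state, hyp$state
  )
  expect_false(identical(
    simulate_hypnogram(params, seed = 8)$state, hyp$state
  ))
})

test_that("long-run state fractions match the phase stationary distributions", {
  params <- mouse_architecture("wt")
  hyp <- simulate_hypnogram(params, seed = 1)
  baseline <- hyp$zt < 48
  for (phase in c("light", "dark")) {
    in_phase <- if (phase == "light") {
      (hyp$zt %% 24) < 12
    } else {
      (hyp$zt %% 24) >= 12
    }
    sel <- baseline & in_phase # 21,600 epochs per phase
    obs <- table(factor(hyp$state[sel], params$states)) / sum(sel)
    expected <- stationary_distribution(params$matrices[[phase]])
    expect_lt(max(abs(as.numeric(obs) - expected)), 0.02)
  }
})

test_that("Process-S iteration matches the closed-form exponential", {
  p <- process_s_params(s0 = 150, ua = 280, la = 60, tau_i = 8, tau_d = 2)
  # single uninterrupted 6-h wake bout
  hyp <- runs_hypnogram(WAKE = 5400)
  s <- simulate_process_s(hyp, p)
  k <- seq_len(5400) - 1
  closed <- p$ua - (p$ua - p$s0) * exp(-k * (4 / 3600) / p$tau_i)
  expect_lt(max(abs(s - closed) / closed), 1e-9)
  # an uninterrupted NREM bout decays towards the lower asymptote
  hyp_n <- runs_hypnogram(NREM = 36000)
  s_n <- simulate_process_s(hyp_n, p)
  closed_n <- p$la + (p$s0 - p$la) * exp(-(seq_len(36000) - 1) * (4 / 3600) / p$tau_d)
  expect_lt(max(abs(s_n - closed_n)), 1e-6)
  expect_equal(s_n[36000], p$la, tolerance = 1e-4)
  # S[i] is the pressure at the start of epoch i: after the full 6-h
  # bout (5400 steps) the closed form is reached exactly
  dt_h <- 4 / 3600
  s_end <- p$la + # one NREM step after the bout confirms the bout total
    (p$ua - (p$ua - p$s0) * exp(-5400 * dt_h / p$tau_i) - p$la) *
      exp(-dt_h / p$tau_d)
  mixed <- hypnogram(c(rep("WAKE", 5400), "NREM", "NREM", "NREM"))
  expect_equal(simulate_process_s(mixed, p)[5402], s_end, tolerance = 1e-9)
  # trajectory bounded and per-epoch steps bounded by the one-epoch update
  rec_hyp <- simulate_hypnogram(mouse_architecture(), seed = 3)
  s_full <- simulate_process_s(rec_hyp, p)
  expect_true(all(s_full >= p$la - 1e-9 & s_full <= p$ua + 1e-9))
  dt <- 4 / 3600
  max_step <- max(
    (p$ua - p$la) * (1 - exp(-dt / p$tau_i)),
    (p$ua - p$la) * (1 - exp(-dt / p$tau_d))
  )
  expect_lte(max(abs(diff(s_full))), max_step + 1e-12)
})

test_that("spectra are deterministic at sigma 0 and delta power scales with S", {
  tmpl <- spectral_template(artifact_rate = 0)
  hyp <- runs_hypnogram(NREM = 1000)
  s_const <- rep(120, 1000)
  sp <- simulate_spectra(hyp, s_const, tmpl, sigma = 0, seed = 1)
  expect_equal(max(apply(sp$psd, 2, function(col) diff(range(col)))), 0)

  # doubling S doubles expected NREM delta power (law of large numbers)
  sp1 <- simulate_spectra(hyp, rep(100, 1000), tmpl, sigma = 0.2, seed = 5)
  sp2 <- simulate_spectra(hyp, rep(200, 1000), tmpl, sigma = 0.2, seed = 6)
  d1 <- mean(band_power(sp1, c(0.75, 4)))
  d2 <- mean(band_power(sp2, c(0.75, 4)))
  expect_equal(d2 / d1, 2, tolerance = 0.02)
})

test_that("artifact flags are drawn at the template rate", {
  tmpl <- spectral_template(artifact_rate = 0.1)
  hyp <- runs_hypnogram(NREM = 10000)
  sp <- simulate_spectra(hyp, rep(100, 10000), tmpl, sigma = 0, seed = 9)
  expect_equal(mean(attr(sp, "artifact")), 0.10, tolerance = 0.1)
  expect_lt(abs(mean(attr(sp, "artifact")) - 0.10), 0.01)
})

test_that("cohort generator plants a recoverable condition effect and correlation", {
  # no effect, no noise: paired differences exactly zero
  quiet <- cohort_params(
    condition_effect = 0, condition_sd = 0,
    region_noise_sd = 0, marker_noise_sd = 0
  )
  co <- simulate_pet_cohort(quiet, seed = 3)
  ch <- availability_change(global_availability(co$roi))
  expect_equal(ch$pct_change, rep(0, nrow(ch)))

  # planted rho = 0: sample Spearman r stays inside the null band
  r0 <- vapply(1:200, function(s) {
    co <- simulate_pet_cohort(cohort_params(rho = 0), seed = s)
    g <- global_availability(co$roi)
    j <- dplyr::inner_join(
      g[g$condition == "baseline", ],
      co$markers[co$markers$condition == "baseline", ],
      by = "subject"
    )
    correlate_pair(j$global_dv, log10(j$swa))$r_spearman
  }, numeric(1))
  expect_lt(abs(mean(r0)), 0.05)
  # about 95 % of null replicates inside the large-sample null band
  crit <- qnorm(0.975) / sqrt(23 - 1)
  expect_gte(mean(abs(r0) < crit), 0.90)

  # planted rho = 0.8 at n = 23: mean recovered r in [0.6, 0.9]
  r8 <- vapply(1:200, function(s) {
    co <- simulate_pet_cohort(cohort_params(rho = 0.8), seed = s)
    g <- global_availability(co$roi)
    j <- dplyr::inner_join(
      g[g$condition == "baseline", ],
      co$markers[co$markers$condition == "baseline", ],
      by = "subject"
    )
    correlate_pair(j$global_dv, log10(j$swa))$r_spearman
  }, numeric(1))
  expect_gt(mean(r8), 0.6)
  expect_lt(mean(r8), 0.9)
})

test_that("Y-maze walker hits the exact alternation extremes", {
  expect_equal(alternation_score(simulate_ymaze(300, 1, seed = 2)), 100)
  expect_equal(alternation_score(simulate_ymaze(300, 0, seed = 2)), 0)
  entries <- simulate_ymaze(50, 0.5, seed = 4)
  expect_true(all(entries[-1] != entries[-50]))
})

test_that("the full synthetic recording generates quickly", {
  elapsed <- system.time(simulate_mouse_recording("wt", seed = 11))["elapsed"]
  expect_lt(elapsed, 30)
})
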