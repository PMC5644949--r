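test_that("the Hann periodogram concentrates, nulls, and flattens correctly", {
  fs <- 200
  t <- seq(0, 4, length.out = 4 * fs + 1)[-(4 * fs + 1)]
  sine <- sin(2 * pi * 10 * t)
  ps <- compute_psd(sine, fs = fs)
  in_peak <- abs(ps$freq - 10) <= 0.25 + 1e-9
  expect_gte(sum(ps$psd[1, in_peak]) / sum(ps$psd), 0.95)

  expect_true(all(compute_psd(rep(0, 800), fs = 200)$psd == 0))

  # white noise: mean PSD flat within 10 % (interior bins; the Nyquist
  # bin of a one-sided PSD carries half power by construction)
  set.seed(5)
  x <- matrix(rnorm(2000 * 800), 2000)
  mm <- colMeans(compute_psd(x, fs = 200)$psd)
  interior <- mm[-length(mm)]
  expect_lt(max(abs(interior - mean(interior))) / mean(interior), 0.10)

  expect_error(compute_psd(rep(0, 700), fs = 200), "4-s epochs")
})

test_that("block averaging equals the brute-force block mean", {
  freq <- seq(0.25, 2, 0.25)
  same <- spectra(matrix(3, 10, 8), freq)
  expect_equal(average_blocks(same, 5)$psd, matrix(3, 2, 8))

  two <- spectra(rbind(rep(0, 8), rep(2, 8)), freq)
  expect_equal(as.numeric(average_blocks(two, 2)$psd), rep(1, 8))

  set.seed(3)
  x <- matrix(rexp(17 * 8), 17, 8)
  sp <- spectra(x, freq)
  expect_warning(avg <- average_blocks(sp, 5), "trailing")
  oracle <- rbind(
    colMeans(x[1:5, ]), colMeans(x[6:10, ]), colMeans(x[11:15, ])
  )
  expect_equal(unname(avg$psd), unname(oracle))
})

test_that("band power integrates PSD x bin width and is additive", {
  freq <- seq(0.25, 49, 0.25)
  # constant PSD 2.0 over the 14 bins of 0.75-4 Hz -> 14 x 2 x 0.25 = 7
  expect_equal(band_power(rep(2, length(freq)), c(0.75, 4), freq), 7)
  expect_equal(band_power(rep(0, length(freq)), c(0.75, 4), freq), 0)

  set.seed(9)
  p <- rexp(length(freq))
  expect_equal(
    band_power(p, c(0.5, 2), freq) + band_power(p, c(2.25, 4.5), freq),
    band_power(p, c(0.5, 4.5), freq)
  )
  expect_error(band_power(p, c(40, 60), freq), "outside")
  expect_error(band_power(p, c(0.6, 4), freq), "multiples of 0.25")
})

test_that("the weighted total power reference matches hand arithmetic", {
  # NREM area 10 at 50 % and WAKE area 6 at 50 % -> reference 8
  hyp <- runs_hypnogram(NREM = 10, WAKE = 10)
  freq <- seq(0.25, 49, 0.25)
  psd <- matrix(0, 20, length(freq))
  in_band <- which(freq >= 1 & freq <= 2)
  psd[1:10, in_band] <- 10 / (length(in_band) * 0.25)
  psd[11:20, in_band] <- 6 / (length(in_band) * 0.25)
  expect_warning(
    ref <- total_power_reference(spectra(psd, freq), hyp, area_band = c(1, 2)),
    "REM"
  )
  expect_equal(attr(ref, "reference"), 8)
  expect_equal(ref$fraction[ref$state == "NREM"], 0.5)

  # single state: reference equals that state's area
  hyp1 <- runs_hypnogram(NREM = 10)
  sp1 <- flat_spectra(10, 2)
  # both absent states (WAKE and REM) warn
  expect_warning(
    expect_warning(ref1 <- total_power_reference(sp1, hyp1), "WAKE"),
    "REM"
  )
  expect_equal(attr(ref1, "reference"), ref1$area[ref1$state == "NREM"])

  # scale equivariance
  rec <- noise_free_recording()
  base <- rec$hypnogram$zt < 48
  bh <- hypnogram(rec$hypnogram$state[base],
    artifact = rec$hypnogram$artifact[base]
  )
  bs <- spectra(rec$spectra$psd[base, ], rec$spectra$freq)
  r1 <- attr(total_power_reference(bs, bh), "reference")
  bs3 <- spectra(3 * rec$spectra$psd[base, ], rec$spectra$freq)
  expect_equal(attr(total_power_reference(bs3, bh), "reference"), 3 * r1)
})

test_that("the weighted-normalization identity holds on simulated baseline", {
  rec <- noise_free_recording()
  base <- rec$hypnogram$zt < 48
  bh <- hypnogram(rec$hypnogram$state[base],
    artifact = rec$hypnogram$artifact[base]
  )
  bs <- spectra(rec$spectra$psd[base, ], rec$spectra$freq)
  ref <- total_power_reference(bs, bh)
  reference <- attr(ref, "reference")
  expect_lt(abs(sum((ref$area / reference) * ref$fraction) - 1), 1e-9)
  expect_equal(sum(ref$fraction), 1)
})

test_that("delta time course self-normalizes, partitions equally, and tracks S", {
  rec <- noise_free_recording()

  # constant spectra: every interval is exactly 100 %
  const <- flat_spectra(nrow(rec$hypnogram), 1)
  tc100 <- delta_timecourse(const, rec$hypnogram)
  expect_true(all(abs(tc100$value_pct - 100) < 1e-9))

  tc <- delta_timecourse(rec$spectra, rec$hypnogram)
  counts_ok <- tapply(tc$n_epochs, tc$segment, function(x) diff(range(x)) <= 1)
  expect_true(all(counts_ok))
  zt_ok <- tapply(tc$mean_zt, tc$segment, function(x) all(diff(x) > 0))
  expect_true(all(zt_ok))

  # 13 epochs into 12 intervals: earliest interval takes the extra epoch
  expect_equal(
    somnostat:::equal_count_partition(13, 12),
    rep(1:12, times = c(2, rep(1, 11)))
  )
  expect_error(somnostat:::equal_count_partition(5, 12), "5 epochs")

  # with sigma = 0 the interval values reproduce the generator's S
  s_engine <- somnostat:::timecourse_engine(
    rec$pressure, rec$hypnogram, interval_scheme(), c(8, 12)
  )
  expect_lt(
    max(abs(tc$value_pct - s_engine$value_pct) / s_engine$value_pct), 0.03
  )

  # mean of the baseline reference-window intervals is 100 % by construction
  ref_iv <- tc$mean_zt %% 24 >= 8 & tc$mean_zt %% 24 < 12 &
    tc$segment %in% c(
      "baseline1_light", "baseline2_light"
    )
  expect_equal(
    sum(tc$value_pct[ref_iv] * tc$n_epochs[ref_iv]) / sum(tc$n_epochs[ref_iv]),
    100,
    tolerance = 0.02
  )

  # a segment with too few NREM epochs errors by name
  tiny <- hypnogram(
    c(rep("NREM", 5), rep("WAKE", 64795)),
    species = "mouse"
  )
  expect_error(
    delta_timecourse(flat_spectra(64800, 1), tiny),
    "baseline1_dark|clean NREM"
  )
})

test_that("outlier screening flags animals beyond k SD", {
  expect_true(all(!detect_outlier_recordings(c(a = 1, b = 1, c = 1))$excluded))
  # hand z-score: values rep(1, 7) and 10 -> mean 2.125, sd 3.182, so
  # the aberrant animal sits 2.47 SD out and is excluded at k = 2
  vals <- c(rep(1, 7), 10)
  res <- detect_outlier_recordings(vals)
  expect_equal(which(res$excluded), 8L)
  expect_equal(res$z[8], (10 - mean(vals)) / sd(vals))
  expect_true(all(!detect_outlier_recordings(vals, k_sd = Inf)$excluded))
  expect_error(detect_outlier_recordings(c(1, 2)), "at least 3")
})

test_that("pressure-model fits recover the generator time constants under noise", {
  errs <- vapply(1:3, function(s) {
    rec <- simulate_mouse_recording("wt", seed = s, sigma = 0.2)
    tc <- delta_timecourse(rec$spectra, rec$hypnogram)
    est <- tidy(fit_sleep_pressure(tc, rec$hypnogram))$estimate
    c(abs(est[1] - 8) / 8, abs(est[2] - 2) / 2)
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.25)
  expect_lt(median(errs[2, ]), 0.25)
})
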