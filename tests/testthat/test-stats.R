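test_that("correlations match the rank-then-Pearson oracle and monotone invariance", {
  x <- c(0.3, 1.7, -0.4, 2.2, 0.9, -1.1, 0.05)
  y <- c(1.1, 0.2, 0.8, 2.5, -0.3, 0.7, 1.9)
  res <- correlate_pair(x, y)
  expect_equal(res$r_spearman, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_equal(
    res$r_pearson,
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)),
    tolerance = 1e-12
  )
  # ties use average ranks
  xt <- c(1, 2, 2, 3, 4)
  yt <- c(5, 4, 4, 2, 1)
  expect_equal(
    correlate_pair(xt, yt)$r_spearman, cor(rank(xt), rank(yt)),
    tolerance = 1e-12
  )

  # monotone transforms leave Spearman untouched
  expect_equal(correlate_pair(x, exp(x))$r_spearman, 1)
  expect_equal(correlate_pair(x, -x)$r_spearman, -1)
  set.seed(2)
  a <- rnorm(15)
  b <- rnorm(15)
  expect_equal(
    correlate_pair(a, b)$r_spearman,
    correlate_pair(exp(a), b^3)$r_spearman
  )

  # constant input is flagged, not silently zero
  cst <- correlate_pair(rep(1, 5), 1:5)
  expect_true(cst$constant_input)
  expect_true(is.na(cst$r_spearman))
})

test_that("variance explained and the Bonferroni threshold are exact", {
  expect_equal(variance_explained(0.80), 64)
  expect_equal(variance_explained(0), 0)
  expect_equal(variance_explained(-0.5), 25)
  expect_error(variance_explained(1.2), "<= 1")

  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.10, 2), 0.05)
  expect_equal(round(bonferroni_threshold(0.05, 18), 5), 0.00278)
})

test_that("Holm adjustment reproduces the hand step-down and its bounds", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(0.02, 4)), rep(0.08, 4))

  set.seed(8)
  for (rep in 1:10) {
    p <- runif(sample(2:12, 1))
    h <- holm_adjust(p)
    expect_true(all(h >= p))
    expect_true(all(h <= pmin(length(p) * p, 1)))
    o <- order(p)
    expect_true(all(diff(h[o]) >= -1e-15))
  }
})

test_that("paired t matches the textbook formula and flags degeneracy", {
  x <- c(3.1, 2.7, 3.9, 3.3, 2.5, 3.8)
  y <- c(2.8, 2.9, 3.1, 3.0, 2.2, 3.0)
  res <- paired_t(x, y)
  d <- x - y
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  p_oracle <- 2 * pt(-abs(t_oracle), length(d) - 1)
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  expect_equal(res$df, 5)

  same <- paired_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  const <- paired_t(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_true(is.infinite(const$t) && const$t > 0)
  expect_true(const$degenerate)

  # log10 option: equal ratios give a degenerate zero-spread difference
  lg <- paired_t(c(10, 100, 1000), c(1, 10, 100), log10_transform = TRUE)
  expect_equal(lg$mean_diff, 1)
  expect_true(lg$degenerate)
})

test_that("median split assigns the median and straddling ties to the low group", {
  df <- tibble::tibble(subject = letters[1:4], v = c(1, 2, 3, 4))
  sp <- median_split(df, v)
  expect_equal(sp$group, factor(c("low", "low", "high", "high"),
    levels = c("low", "high")
  ))

  odd <- median_split(tibble::tibble(v = c(1, 2, 3)), v)
  expect_equal(as.character(odd$group), c("low", "low", "high"))

  ties <- median_split(tibble::tibble(v = c(1, 2, 2, 2, 3)), v)
  expect_equal(sum(ties$group == "low"), 4)
  expect_equal(unname(attr(ties, "sizes")["low"]), 4L)
})

test_that("repeated-measures ANOVA agrees with hand sums of squares", {
  # all-equal responses: F = 0 for every effect
  flat <- tidyr::expand_grid(
    subject = sprintf("s%d", 1:6), hour = factor(1:4)
  )
  flat$genotype <- rep(c("wt", "ko"), each = 12)
  flat$y <- 5
  res <- rm_anova(flat, y, subject, hour, genotype)
  expect_true(all(res$f == 0))

  # one-way case vs. textbook between/within SS on a 3 x 4 toy table
  toy <- tibble::tibble(
    group = rep(c("a", "b", "c"), each = 4),
    y = c(1, 2, 3, 4, 2, 4, 4, 6, 5, 5, 7, 7)
  )
  grand <- mean(toy$y)
  ss_between <- sum(tapply(toy$y, toy$group, function(v) {
    length(v) * (mean(v) - grand)^2
  }))
  ss_within <- sum((toy$y - ave(toy$y, toy$group))^2)
  f_oracle <- (ss_between / 2) / (ss_within / 9)
  fit <- aov(y ~ group, data = toy)
  expect_equal(unname(summary(fit)[[1]]["group", "F value"]), f_oracle)

  # the wrapper's F for the between factor on a balanced design matches
  # a direct aov call
  set.seed(21)
  dat <- tidyr::expand_grid(
    subject = sprintf("s%d", 1:9), hour = factor(1:3)
  )
  dat$genotype <- rep(c("wt", "ht", "ko"), each = 9)
  dat$y <- rnorm(27) + as.integer(factor(dat$genotype))
  res <- rm_anova(dat, y, subject, hour, genotype)
  direct <- summary(aov(
    y ~ genotype * hour + Error(factor(subject)),
    data = dat
  ))
  f_direct <- direct[["Error: factor(subject)"]][[1]]["genotype", "F value"]
  expect_equal(res$f[res$effect == "genotype"], unname(f_direct))

  # missing design cells error with their names
  miss <- dat[!(dat$subject == "s1" & dat$hour == "2"), ]
  expect_error(rm_anova(miss, y, subject, hour, genotype), "s1 x 2")
})

test_that("a planted genotype effect is detected with high power", {
  detect <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      dat <- tidyr::expand_grid(
        subject = sprintf("s%02d", 1:24), hour = factor(1:4)
      )
      gt <- rep(c("wt", "ht", "ko"), each = 8)
      dat$genotype <- gt[match(dat$subject, sprintf("s%02d", 1:24))]
      eff <- c(wt = 0, ht = 0.6, ko = 1.2)
      subj_re <- rnorm(24, 0, 0.5)
      dat$y <- eff[dat$genotype] +
        subj_re[match(dat$subject, sprintf("s%02d", 1:24))] +
        rnorm(nrow(dat), 0, 0.4)
    })
    res <- rm_anova(dat, y, subject, hour, genotype)
    res$p[res$effect == "genotype"] < 0.05
  }, logical(1))
  expect_gte(mean(detect), 0.90)
})

test_that("regional correlation tables gate at alpha / (regions x conditions)", {
  co <- simulate_pet_cohort(cohort_params(rho = 0.9), seed = 5)
  tab <- correlate_regional(co$roi, co$markers)
  expect_equal(nrow(tab), 18) # 9 regions x 2 conditions
  expect_equal(attr(tab, "per_test_alpha"), 0.05 / 18)
  expect_true(all(abs(tab$r_spearman) <= 1))
  # a strongly planted correlation should clear the gate in most regions
  expect_gt(mean(tab$significant), 0.5)

  # mismatched subject identifiers are an error, not an empty result
  bad <- co$markers
  bad$subject <- paste0("X", bad$subject)
  expect_error(correlate_regional(co$roi, bad), "no matching")
})

test_that("Fisher-z intervals widen appropriately for Spearman coefficients", {
  ci_p <- fisher_z_interval(0.8, 23, "pearson")
  ci_s <- fisher_z_interval(0.8, 23, "spearman")
  expect_lt(ci_p[1], 0.8)
  expect_gt(ci_p[2], 0.8)
  expect_lt(ci_s[1], ci_p[1]) # Bonett-Wright SE is larger
  expect_gt(ci_s[2], ci_p[2])
})
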