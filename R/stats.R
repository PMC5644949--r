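#' Spearman and Pearson correlation for a marker pair
#'
#' Associations between imaging availability and EEG markers of sleep
#' need are assessed primarily by Spearman rank correlation (robust to
#' monotone transforms); the Pearson product-moment coefficient is
#' computed on the same pairs for table-style reporting. Spearman uses
#' average ranks for ties. Two-sided p-values come from
#' [stats::cor.test()]: the exact permutation distribution for
#' `n < 10` (without ties), the t/AS89 approximation otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return One-row tibble: `n`, `r_pearson`, `r_spearman`,
#'   `p_pearson`, `p_spearman`, `constant_input`. A constant vector
#'   yields `NA` coefficients with `constant_input = TRUE`.
#' @export
correlate_pair <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(
      n = n, r_pearson = NA_real_, r_spearman = NA_real_,
      p_pearson = NA_real_, p_spearman = NA_real_, constant_input = TRUE
    ))
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = n < 10 && !ties)
  )
  tibble(
    n = n,
    r_pearson = unname(pe$estimate),
    r_spearman = unname(sp$estimate),
    p_pearson = pe$p.value,
    p_spearman = sp$p.value,
    constant_input = FALSE
  )
}

#' Variance explained by a correlation
#'
#' The squared correlation coefficient as a percentage: a coefficient
#' of 0.80 explains 64 % of the variance.
#'
#' @param r Correlation coefficient(s), `|r| <= 1`.
#' @return Percentage(s) `100 * r^2`.
#' @export
variance_explained <- function(r) {
  if (any(abs(r) > 1)) stop("|r| must be <= 1", call. = FALSE)
  100 * r^2
}

#' Bonferroni per-test significance threshold
#'
#' For a family of `m` tests at family-wise level `alpha`, each test is
#' assessed at `alpha / m`; for the 18-test family of 2 conditions x 9
#' regions at alpha 0.05 this is 0.00278.
#'
#' @param alpha Family-wise significance level.
#' @param m Family size (>= 1).
#' @return Per-test alpha.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  alpha / m
}

#' Holm step-down adjusted p-values
#'
#' Step-down Holm correction (uniformly more powerful than Bonferroni,
#' still controlling the family-wise error rate); delegates to
#' [stats::p.adjust()].
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, element-wise >= the raw values and <= the
#'   Bonferroni-adjusted values, capped at 1.
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "holm")
}

#' Two-tailed paired t test
#'
#' Paired Student's t on the per-subject differences, optionally on
#' log10-transformed values (the convention for EEG power statistics).
#' Degenerate inputs are flagged rather than erroring: identical
#' vectors give `t = 0, p = 1`; constant non-zero differences give an
#' infinite t with `p = 0`.
#'
#' @param x,y Paired numeric vectors, length >= 2.
#' @param log10_transform Test `log10(x)` vs `log10(y)`?
#' @return One-row tibble: `n`, `mean_diff`, `t`, `df`, `p`,
#'   `degenerate`.
#' @export
paired_t <- function(x, y, log10_transform = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (log10_transform) {
    x <- log10(x)
    y <- log10(y)
  }
  d <- x - y
  n <- length(d)
  if (sd(d) == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(tibble(
      n = n, mean_diff = mean(d), t = t, df = n - 1L,
      p = if (mean(d) == 0) 1 else 0, degenerate = TRUE
    ))
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble(
    n = n, mean_diff = unname(tt$estimate), t = unname(tt$statistic),
    df = unname(tt$parameter), p = tt$p.value, degenerate = FALSE
  )
}

#' Median split into low and high groups
#'
#' Subjects at or below the median are assigned to the low group,
#' subjects above it to the high group, so for distinct values the
#' group sizes differ by at most one and ties straddling the median all
#' fall in the low group (sizes are reported so unbalanced splits are
#' visible).
#'
#' @param df Tibble with one row per subject.
#' @param value Column (bare name) to split on.
#' @return `df` with an added factor column `group` (`"low"`/`"high"`);
#'   attribute `sizes` holds the group sizes.
#' @export
median_split <- function(df, value) {
  v <- dplyr::pull(df, {{ value }})
  if (length(v) < 2) stop("need at least 2 subjects", call. = FALSE)
  med <- median(v)
  out <- dplyr::mutate(
    df,
    group = factor(ifelse({{ value }} <= med, "low", "high"),
      levels = c("low", "high")
    )
  )
  attr(out, "sizes") <- table(out$group)
  out
}

#' Repeated-measures ANOVA (thin contract)
#'
#' Standard sums-of-squares F tests for a design with one
#' between-subject factor (e.g. genotype) and one within-subject factor
#' (e.g. hour), delegated to [stats::aov()] with an `Error(subject)`
#' stratum; used only to gate post-hoc tests. Effects with zero sum of
#' squares report `F = 0`. Sphericity correction is not applied.
#'
#' @param df Long-format tibble.
#' @param response,subject,within,between Bare column names.
#' @return Tibble with `effect`, `df1`, `df2`, `ss`, `f`, `p`.
#' @export
rm_anova <- function(df, response, subject, within, between = NULL) {
  rsp <- as.character(rlang::ensym(response))
  sub <- as.character(rlang::ensym(subject))
  wth <- as.character(rlang::ensym(within))
  btw <- if (!rlang::quo_is_null(rlang::enquo(between))) {
    as.character(rlang::ensym(between))
  }
  dat <- as.data.frame(df)
  dat[[sub]] <- factor(dat[[sub]])
  dat[[wth]] <- factor(dat[[wth]])
  if (!is.null(btw)) dat[[btw]] <- factor(dat[[btw]])
  # check for missing design cells
  cells <- if (is.null(btw)) dat[c(sub, wth)] else dat[c(sub, wth)]
  miss <- tidyr::expand_grid(
    !!sub := unique(dat[[sub]]), !!wth := unique(dat[[wth]])
  ) |>
    anti_join(dat, by = c(sub, wth))
  if (nrow(miss) > 0) {
    stop(sprintf(
      "missing design cell(s): %s",
      paste(sprintf("%s x %s", miss[[sub]], miss[[wth]]), collapse = ", ")
    ), call. = FALSE)
  }
  rhs <- if (is.null(btw)) wth else sprintf("%s * %s", btw, wth)
  form <- stats::as.formula(sprintf("%s ~ %s + Error(%s)", rsp, rhs, sub))
  fit <- aov(form, data = dat)
  tabs <- summary(fit)
  rows <- purrr::map(tabs, function(stratum) {
    tb <- stratum[[1]]
    eff <- trimws(rownames(tb))
    keep <- eff != "Residuals"
    resid_df <- tb[!keep, "Df"]
    tibble(
      effect = eff[keep],
      df1 = tb[keep, "Df"],
      df2 = if (length(resid_df) > 0) resid_df else NA_real_,
      ss = tb[keep, "Sum Sq"],
      f = tb[keep, "F value"],
      p = tb[keep, "Pr(>F)"]
    )
  }) |> purrr::list_rbind()
  rows <- rows |>
    mutate(
      f = ifelse(.data$ss <= 1e-12, 0, .data$f),
      p = ifelse(.data$ss <= 1e-12, 1, .data$p)
    )
  rows[!is.na(rows$df1), ]
}

#' Region-by-condition correlation table with a multiplicity gate
#'
#' Joins the regional availability table with an EEG marker table on
#' subject and condition and computes, per region and condition, the
#' Spearman and Pearson correlations between regional DV_norm
#' (hemispheres averaged, or kept separate) and the (optionally
#' log10-transformed) marker. The Bonferroni gate column flags
#' correlations whose Spearman p-value passes the per-test threshold
#' `alpha / (n_regions x n_conditions)`.
#'
#' @param roi ROI table (`subject`, `condition`, `region`,
#'   `hemisphere`, `c_t`, `c_cb`).
#' @param markers Marker table with `subject`, `condition`, and the
#'   marker column.
#' @param marker Bare name of the marker column (default `swa`).
#' @param log10_marker Correlate against `log10(marker)`? (Monotone, so
#'   Spearman is unaffected; affects Pearson only.)
#' @param hemispheres `"average"` (default; 9 regions x 2 conditions =
#'   18 tests) or `"separate"`.
#' @param alpha Family-wise level for the gate.
#' @return Tibble of class `"regional_correlations"`: `region`
#'   (x `hemisphere`), `condition`, `n`, `r_pearson`, `r_spearman`,
#'   `p_spearman`, `significant`; attribute `per_test_alpha`.
#' @export
correlate_regional <- function(roi, markers, marker = swa,
                               log10_marker = TRUE,
                               hemispheres = c("average", "separate"),
                               alpha = 0.05) {
  hemispheres <- match.arg(hemispheres)
  mk <- as.character(rlang::ensym(marker))
  if (!mk %in% names(markers)) {
    stop(sprintf("marker column %s not found", mk), call. = FALSE)
  }
  dv_tbl <- roi |> mutate(dv = dv_norm(.data$c_t, .data$c_cb))
  grp <- if (hemispheres == "average") {
    dv_tbl |> summarise(dv = mean(.data$dv), .by = c("subject", "condition", "region"))
  } else {
    dv_tbl |>
      summarise(
        dv = mean(.data$dv),
        .by = c("subject", "condition", "region", "hemisphere")
      )
  }
  joined <- inner_join(
    grp, markers[c("subject", "condition", mk)],
    by = c("subject", "condition")
  )
  if (nrow(joined) == 0) {
    stop("no matching subject/condition rows between tables", call. = FALSE)
  }
  mval <- if (log10_marker) log10(joined[[mk]]) else joined[[mk]]
  joined$marker_value <- mval
  keys <- setdiff(
    c("region", if (hemispheres == "separate") "hemisphere", "condition"),
    NULL
  )
  out <- joined |>
    summarise(
      correlate_pair(.data$dv, .data$marker_value),
      .by = all_of(keys)
    )
  m <- nrow(distinct(out[keys]))
  gate <- bonferroni_threshold(alpha, m)
  out <- out |>
    mutate(significant = .data$p_spearman < gate) |>
    select(all_of(keys), "n", "r_pearson", "r_spearman", "p_spearman", "significant")
  structure(out,
    class = c("regional_correlations", class(tibble())),
    per_test_alpha = gate, m = m
  )
}

#' Fisher-z confidence interval for a correlation
#'
#' Classic Fisher z interval for a Pearson coefficient
#' (`SE = 1/sqrt(n-3)`); for a Spearman coefficient the wider
#' Bonett-Wright standard error `sqrt((1 + r^2/2)/(n-3))` is used,
#' which accounts for the larger sampling variance of the rank
#' correlation.
#'
#' @param r Sample correlation coefficient.
#' @param n Number of pairs (> 3).
#' @param type `"spearman"` (default) or `"pearson"`.
#' @param conf Confidence level.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
fisher_z_interval <- function(r, n, type = c("spearman", "pearson"),
                              conf = 0.95) {
  type <- match.arg(type)
  stopifnot(n > 3, abs(r) < 1)
  se <- switch(type,
    pearson = 1 / sqrt(n - 3),
    spearman = sqrt((1 + r^2 / 2) / (n - 3))
  )
  z <- atanh(r)
  q <- qnorm(1 - (1 - conf) / 2)
  c(lower = tanh(z - q * se), upper = tanh(z + q * se))
}
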