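#' Normalized distribution volume (DV_norm)
#'
#' Regional tracer availability expressed as the ratio of the regional
#' activity concentration to the cerebellar (reference region)
#' concentration: `DV_norm = C_t[VOI] / C_t[Cb]`. Invariant under a
#' common rescaling of both inputs.
#'
#' @param c_t Regional activity concentration(s), > 0.
#' @param c_cb Cerebellar activity concentration(s), > 0.
#' @return Numeric ratio(s).
#' @export
#' @examples
#' dv_norm(1200, 800)
dv_norm <- function(c_t, c_cb) {
  if (any(c_t <= 0) || any(c_cb <= 0)) {
    stop("activity concentrations must be positive", call. = FALSE)
  }
  c_t / c_cb
}

#' Global mGluR5 availability per subject and condition
#'
#' A "global" availability is not uniquely defined by a region table;
#' if a whole-brain VOI row (`region == "whole brain"`) is present it
#' is used directly, otherwise the unweighted mean of all regional
#' DV_norm values (both hemispheres of the nine standard regions) is
#' taken. The method actually used is recorded in the `"method"`
#' attribute.
#'
#' @param roi ROI table with columns `subject`, `condition`, `region`,
#'   `hemisphere`, `c_t`, `c_cb`.
#' @return Tibble with `subject`, `condition`, `global_dv`.
#' @export
global_availability <- function(roi) {
  wb <- roi$region == "whole brain"
  if (any(wb)) {
    src <- roi[wb, ]
    method <- "whole_brain"
  } else {
    src <- roi
    method <- "region_mean"
  }
  out <- src |>
    mutate(dv = dv_norm(.data$c_t, .data$c_cb)) |>
    summarise(global_dv = mean(.data$dv), .by = c("subject", "condition"))
  attr(out, "method") <- method
  out
}

#' Per-subject percent change in global availability
#'
#' @param global_tbl Output of [global_availability()].
#' @param baseline,deprived Condition labels.
#' @return Tibble with `subject`, `baseline_dv`, `deprived_dv`,
#'   `pct_change` (`100 * (SD - BL) / BL`).
#' @export
availability_change <- function(global_tbl,
                                baseline = "baseline",
                                deprived = "sleep_deprivation") {
  wide <- global_tbl |>
    tidyr::pivot_wider(names_from = "condition", values_from = "global_dv")
  if (!all(c(baseline, deprived) %in% names(wide)) ||
    anyNA(wide[[baseline]]) || anyNA(wide[[deprived]])) {
    stop("each subject needs a value in both conditions", call. = FALSE)
  }
  tibble(
    subject = wide$subject,
    baseline_dv = wide[[baseline]],
    deprived_dv = wide[[deprived]],
    pct_change = 100 * (wide[[deprived]] - wide[[baseline]]) / wide[[baseline]]
  )
}

#' Filter metabolite estimates by Cramer-Rao lower bound
#'
#' Metabolite fits with CRLB strictly greater than the threshold are
#' unreliable and removed; estimates at exactly the threshold are
#' retained. Filtering is idempotent. The removed rows are attached as
#' the `"excluded"` attribute (the exclusion log), so that
#' `nrow(result) + nrow(attr(result, "excluded"))` equals the input row
#' count.
#'
#' @param tbl Metabolite table with a `crlb_pct` column.
#' @param threshold_pct CRLB threshold in percent (default 20).
#' @return Filtered tibble with attribute `excluded`.
#' @export
crlb_filter <- function(tbl, threshold_pct = 20) {
  keep <- tbl$crlb_pct <= threshold_pct
  out <- tbl[keep, , drop = FALSE]
  attr(out, "excluded") <- tbl[!keep, , drop = FALSE]
  out
}

#' Paired condition contrast for one metabolite
#'
#' Computes per-subject sleep-deprivation minus baseline differences
#' for one metabolite using pairwise-complete subjects (subjects whose
#' estimate survived [crlb_filter()] in both conditions), the mean
#' percent change, and a two-tailed paired t test.
#'
#' @param tbl (Filtered) metabolite table.
#' @param metabolite Metabolite name to contrast.
#' @param baseline,deprived Condition labels.
#' @return One-row tibble: `metabolite`, `n_pairs`, `mean_diff`,
#'   `pct_change`, `t`, `df`, `p`.
#' @export
condition_contrast <- function(tbl, metabolite,
                               baseline = "baseline",
                               deprived = "sleep_deprivation") {
  sub <- tbl[tbl$metabolite == metabolite, ]
  wide <- sub |>
    select("subject", "condition", "concentration") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "concentration")
  for (cond in c(baseline, deprived)) {
    if (!cond %in% names(wide)) wide[[cond]] <- NA_real_
  }
  complete <- !is.na(wide[[baseline]]) & !is.na(wide[[deprived]])
  if (sum(complete) < 2) {
    stop("fewer than 2 complete pairs after filtering", call. = FALSE)
  }
  bl <- wide[[baseline]][complete]
  sd_ <- wide[[deprived]][complete]
  tt <- paired_t(sd_, bl)
  tibble(
    metabolite = metabolite,
    n_pairs = sum(complete),
    mean_diff = mean(sd_ - bl),
    pct_change = 100 * mean((sd_ - bl) / bl),
    t = tt$t, df = tt$df, p = tt$p
  )
}
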