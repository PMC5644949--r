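#' Plot a delta-power time course
#'
#' One line per recording segment, with the 100 % baseline reference
#' and (when the scheme attribute is present) shaded dark phases.
#'
#' @param object A [delta_timecourse()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.delta_timecourse <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(.data$mean_zt, .data$value_pct, group = .data$segment))
  scheme <- attr(object, "scheme")
  if (!is.null(scheme)) {
    dark <- scheme[grepl("dark", scheme$segment), ]
    p <- p + geom_rect(
      data = dark,
      aes(
        xmin = .data$zt_start, xmax = .data$zt_end,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, fill = "grey85", alpha = 0.6
    )
  }
  p +
    geom_hline(yintercept = 100, linetype = "dashed", colour = "grey40") +
    geom_line() +
    geom_point(size = 1.4) +
    labs(
      x = "Zeitgeber time (h)",
      y = "NREM delta power (% of baseline ZT8-12)",
      title = "Time course of NREM delta power"
    ) +
    theme_minimal()
}

#' Plot accumulated state-time differences from baseline
#'
#' @param object An [accumulated_difference()] curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.accumulated_curve <- function(object, ...) {
  ggplot(
    as_tibble(object),
    aes(.data$hour, .data$accumulated_min, colour = .data$state)
  ) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    geom_line() +
    geom_point(size = 1.2) +
    labs(
      x = "Zeitgeber time (h)",
      y = "Accumulated difference from baseline (min)",
      colour = "State",
      title = "Accumulated sleep-wake rebound"
    ) +
    theme_minimal()
}

#' Plot a regional correlation table
#'
#' Tile map of Spearman coefficients per region and condition;
#' Bonferroni-gated cells are outlined.
#'
#' @param object A [correlate_regional()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.regional_correlations <- function(object, ...) {
  df <- as_tibble(object)
  if ("hemisphere" %in% names(df)) {
    df$region <- paste(df$region, df$hemisphere)
  }
  ggplot(df, aes(.data$condition, .data$region, fill = .data$r_spearman)) +
    geom_tile() +
    geom_tile(
      data = df[df$significant, ],
      colour = "black", linewidth = 0.7, fill = NA
    ) +
    scale_fill_gradient2(limits = c(-1, 1), name = "Spearman r") +
    labs(
      x = NULL, y = NULL,
      title = "Regional availability vs. EEG marker",
      subtitle = sprintf(
        "outlined: p < %.5f (Bonferroni, m = %d)",
        attr(object, "per_test_alpha"), attr(object, "m")
      )
    ) +
    theme_minimal()
}

#' Plot a hypnogram
#'
#' Step plot of the vigilance-state sequence over zeitgeber time, with
#' artifact epochs marked underneath.
#'
#' @param hyp A [hypnogram()].
#' @return A ggplot.
#' @export
plot_hypnogram <- function(hyp) {
  vocab <- state_vocabulary(attr(hyp, "species"))
  df <- tibble(
    zt = hyp$zt,
    state = factor(hyp$state, levels = rev(vocab)),
    artifact = hyp$artifact
  )
  p <- ggplot(df, aes(.data$zt, as.integer(.data$state))) +
    geom_step(linewidth = 0.2) +
    scale_y_continuous(
      breaks = seq_along(vocab), labels = rev(vocab),
      name = NULL
    ) +
    labs(x = "Zeitgeber time (h)", title = "Hypnogram") +
    theme_minimal()
  if (any(df$artifact)) {
    p <- p + geom_rug(
      data = df[df$artifact, ], sides = "b",
      colour = "red", alpha = 0.4, length = unit(0.02, "npc")
    )
  }
  p
}
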