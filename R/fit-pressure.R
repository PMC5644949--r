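#' Fit a two-process pressure model to a delta-power time course
#'
#' Recovers the Process-S time constants from an observed
#' [delta_timecourse()] by simulating the pressure trajectory along the
#' known hypnogram for candidate parameters, passing it through the
#' identical interval-binning and reference normalization, and
#' minimizing the sum of squared differences to the observed interval
#' values (Nelder-Mead on log/logit-transformed parameters).
#'
#' Because the time course is self-normalized to the baseline ZT8-12
#' reference, the absolute pressure scale is not identifiable; the
#' upper asymptote is fixed at 100 and the lower asymptote and initial
#' pressure are estimated as fractions of it. The estimated `tau_i`
#' (build-up, h) and `tau_d` (decay, h) are scale-free and directly
#' comparable to generator ground truth.
#'
#' @param tc A [delta_timecourse()].
#' @param hyp The [hypnogram()] the time course was computed from
#'   (with the same artifact flags).
#' @param init Optional named list of starting values (`tau_i`,
#'   `tau_d`, `la_frac`, `s0_frac`).
#' @param control Passed to [stats::optim()].
#' @return Object of class `"sleep_pressure_fit"`; see [tidy()] and
#'   [glance()] methods.
#' @export
fit_sleep_pressure <- function(tc, hyp, init = NULL,
                               control = list(maxit = 500)) {
  stopifnot(inherits(tc, "delta_timecourse"))
  scheme <- attr(tc, "scheme")
  reference_zt <- attr(tc, "reference_zt")
  observed <- tc$value_pct
  start <- list(tau_i = 6, tau_d = 1.5, la_frac = 0.3, s0_frac = 0.5)
  if (!is.null(init)) start[names(init)] <- init
  to_par <- function(p) {
    c(log(p$tau_i), log(p$tau_d), stats::qlogis(p$la_frac), stats::qlogis(p$s0_frac))
  }
  from_par <- function(par) {
    la <- 100 * stats::plogis(par[3])
    list(
      tau_i = exp(par[1]), tau_d = exp(par[2]),
      la = la, ua = 100,
      s0 = la + (100 - la) * stats::plogis(par[4])
    )
  }
  predict_tc <- function(par) {
    p <- from_par(par)
    prm <- process_s_params(
      s0 = p$s0, ua = p$ua, la = p$la,
      tau_i = p$tau_i, tau_d = p$tau_d, sigma = 0
    )
    s <- simulate_process_s(hyp, prm)
    timecourse_engine(s, hyp, scheme, reference_zt)$value_pct
  }
  objective <- function(par) sum((predict_tc(par) - observed)^2)
  opt <- stats::optim(to_par(start), objective, control = control)
  est <- from_par(opt$par)
  fitted <- predict_tc(opt$par)
  structure(
    list(
      estimate = tibble(
        term = c("tau_i", "tau_d", "la_frac", "s0_frac"),
        estimate = c(
          est$tau_i, est$tau_d, est$la / 100,
          (est$s0 - est$la) / (100 - est$la)
        )
      ),
      sse = opt$value, convergence = opt$convergence,
      n_intervals = length(observed),
      observed = observed, fitted = fitted, timecourse = tc
    ),
    class = "sleep_pressure_fit"
  )
}

#' @export
print.sleep_pressure_fit <- function(x, ...) {
  cat("<sleep_pressure_fit>\n")
  cat(sprintf(
    "  tau_i = %.2f h, tau_d = %.2f h (%d intervals, rmse %.2f%%)\n",
    x$estimate$estimate[1], x$estimate$estimate[2],
    x$n_intervals, sqrt(x$sse / x$n_intervals)
  ))
  invisible(x)
}

#' Tidy a fitted sleep-pressure model
#'
#' @param x A `sleep_pressure_fit`.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate`.
#' @export
tidy.sleep_pressure_fit <- function(x, ...) x$estimate

#' One-row fit summary of a sleep-pressure model
#'
#' @param x A `sleep_pressure_fit`.
#' @param ... Unused.
#' @return Tibble with `sse`, `rmse_pct`, `n_intervals`, `converged`.
#' @export
glance.sleep_pressure_fit <- function(x, ...) {
  tibble(
    sse = x$sse,
    rmse_pct = sqrt(x$sse / x$n_intervals),
    n_intervals = x$n_intervals,
    converged = x$convergence == 0
  )
}
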