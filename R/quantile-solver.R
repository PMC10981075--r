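# User-facing solvers for the Kuiper pair <critical value c, quantile v>,
# upper/lower tail quantiles and the inverse CDF, for the one-sample V_n and
# the equal-size two-sample V_{n,n} statistics.

#' Solve a Kuiper pair
#'
#' Finds the critical value \eqn{c_n^\alpha} on the scale of the scaled
#' statistic \eqn{\sqrt{n} V} such that the second-order tail approximation
#' equals \code{alpha}, together with the quantile on the scale of \eqn{V}
#' itself, \eqn{v_n^\alpha = c_n^\alpha / \sqrt{n}}.
#'
#' The equation is solved by fixed-point iteration: either Newton's method on
#' the log-domain residual \code{\link{kuiper_f_nonlinear}} (default) or
#' direct substitution of the contractive map
#' \code{\link{kuiper_f_contractive}}.  Converged roots at or below
#' \eqn{1/\sqrt{2}} are spurious intersections of the fixed-point map and are
#' rejected; the solve then restarts once from 2.45.
#'
#' With \code{n = Inf} the exact limiting coefficients are used (every
#' \eqn{1/\sqrt{n}} or \eqn{1/n} term dropped); the quantile \eqn{v} is
#' reported as \code{NA} since \eqn{V} degenerates to 0 in the limit while
#' the critical value stays meaningful.
#'
#' @param alpha upper tail probability in (0, 1).
#' @param n sample size (for the two-sample test, the common size of both
#'   samples) or \code{Inf}.
#' @param test \code{"vn"} (one-sample) or \code{"vnn"} (two-sample).
#' @param control a \code{\link{kuiper_control}} list.
#' @return An object of class \code{"kuiper_pair"}: a list with
#'   \code{alpha}, \code{n}, \code{test}, \code{critical_value},
#'   \code{quantile}, \code{method} and \code{trace}.
#' @examples
#' kuiper_pair(0.01, 30)                     # critical value 1.9252
#' kuiper_pair(0.05, 100)$quantile           # 0.1711
#' kuiper_pair(0.01, 10, test = "vnn")       # critical value 2.6124
#' @export
kuiper_pair <- function(alpha, n = Inf, test = c("vn", "vnn"),
                        control = kuiper_control()) {
  test <- match.arg(test)
  check_alpha(alpha)
  check_n(n)
  update <- if (control$method == "newton") {
    function(c, a, n.) update_newton(
      function(cc, aa, nn) kuiper_f_nonlinear(cc, aa, nn, test),
      c, a, n., step = control$derivative_step)
  } else {
    function(c, a, n.) update_direct(
      function(cc, aa, nn) kuiper_f_contractive(cc, aa, nn, test),
      c, a, n.)
  }
  # At very small n the feasible window of the log-domain forms shrinks and
  # the universal starting value 2.45 can fall outside it; retry from smaller
  # guesses before giving up.
  guesses <- unique(c(control$c_guess, 1.6, 1.0))
  sol <- NULL
  for (g in guesses) {
    ctl <- control
    ctl$c_guess <- g
    sol <- tryCatch(solve_fixed_point(update, alpha, n, ctl),
                    kuiperq_infeasible = function(e) NULL)
    if (!is.null(sol)) break
  }
  if (is.null(sol))
    stop_kuiper(
      "no feasible starting value found; the asymptotic approximation may not admit a root at this (alpha, n)",
      "kuiperq_infeasible")
  if (sol$root <= 1 / sqrt(2)) {
    # spurious low intersection; restart once from the universal guess
    control2 <- control
    control2$c_guess <- 2.45
    sol <- solve_fixed_point(update, alpha, n, control2)
    if (sol$root <= 1 / sqrt(2))
      stop_kuiper("solver converged to a spurious root at or below 1/sqrt(2)",
                  "kuiperq_spurious_root")
  }
  structure(list(alpha = alpha, n = n, test = test,
                 critical_value = sol$root,
                 quantile = if (is.infinite(n)) NA_real_
                            else sol$root / sqrt(n),
                 method = control$method, trace = sol$trace),
            class = "kuiper_pair")
}

#' @export
print.kuiper_pair <- function(x, digits = 4, ...) {
  lbl <- if (x$test == "vn") "one-sample V_n" else "two-sample V_{n,n}"
  cat(sprintf("Kuiper pair (%s), alpha = %g, n = %s\n", lbl, x$alpha,
              format(x$n)))
  cat(sprintf("  critical value c = %.*f\n", digits, x$critical_value))
  if (is.na(x$quantile)) {
    cat("  quantile v = NA (V degenerates to 0 as n -> Inf)\n")
  } else {
    cat(sprintf("  quantile v = %.*f\n", digits, x$quantile))
  }
  cat(sprintf("  %s iteration, %d steps, final distance %.2e\n",
              x$method, x$trace$n_iter, x$trace$final_distance))
  invisible(x)
}

#' Limiting critical value (n = Inf)
#'
#' Convenience wrapper of \code{\link{kuiper_pair}} with the exact limiting
#' coefficients.
#' @inheritParams kuiper_pair
#' @return A \code{"kuiper_pair"} object with \code{n = Inf}.
#' @examples
#' kuiper_pair_infinite(1e-10)$critical_value   # 3.7226
#' @export
kuiper_pair_infinite <- function(alpha, test = c("vn", "vnn"),
                                 control = kuiper_control()) {
  kuiper_pair(alpha, Inf, test = test, control = control)
}

#' Critical value of the scaled Kuiper statistic
#'
#' @inheritParams kuiper_pair
#' @return The critical value \eqn{c_n^\alpha} (numeric scalar; vectorized
#'   over \code{alpha}).
#' @export
kuiper_critical_value <- function(alpha, n = Inf, test = c("vn", "vnn"),
                                  control = kuiper_control()) {
  test <- match.arg(test)
  vapply(alpha, function(a)
    kuiper_pair(a, n, test = test, control = control)$critical_value,
    numeric(1))
}

#' Upper tail quantile of Kuiper's V statistic
#'
#' The value \eqn{v_n^\alpha} with \eqn{\Pr\{V_n > v_n^\alpha\} = \alpha}
#' under the second-order approximation, i.e. the solved critical value
#' divided by \eqn{\sqrt{n}}.
#'
#' @inheritParams kuiper_pair
#' @return Numeric (vectorized over \code{alpha}).
#' @examples
#' kuiper_upper_quantile(0.10, 30)    # 0.2830
#' @export
kuiper_upper_quantile <- function(alpha, n, test = c("vn", "vnn"),
                                  control = kuiper_control()) {
  test <- match.arg(test)
  check_n(n, allow_inf = FALSE)
  vapply(alpha, function(a)
    kuiper_pair(a, n, test = test, control = control)$quantile, numeric(1))
}

#' Lower tail quantile of Kuiper's V statistic
#'
#' By the tail identity the lower tail quantile at probability \code{p}
#' equals the upper tail quantile at \code{1 - p}.
#' @param p lower tail probability in (0, 1).
#' @inheritParams kuiper_upper_quantile
#' @return Numeric (vectorized over \code{p}).
#' @examples
#' kuiper_lower_quantile(0.90, 30)    # = kuiper_upper_quantile(0.10, 30)
#' @export
kuiper_lower_quantile <- function(p, n, test = c("vn", "vnn"),
                                  control = kuiper_control()) {
  vapply(p, function(pp) {
    check_alpha(pp, "p")
    kuiper_upper_quantile(1 - pp, n, test = test, control = control)
  }, numeric(1))
}

#' Inverse CDF of Kuiper's V statistic
#'
#' \eqn{F_{V_n}^{-1}(x)}, computed as the lower tail quantile at \code{x}.
#' The asymptotic form has no finite preimage at 0 or 1, so the open interval
#' is enforced.
#' @param x probability strictly inside (0, 1).
#' @inheritParams kuiper_upper_quantile
#' @return Numeric (vectorized over \code{x}).
#' @examples
#' kuiper_inv_cdf(0.95, 30)     # 0.3060
#' @export
kuiper_inv_cdf <- function(x, n, test = c("vn", "vnn"),
                           control = kuiper_control()) {
  if (any(x <= 0 | x >= 1))
    stop_kuiper("'x' must lie strictly inside (0, 1)", "kuiperq_range_error")
  kuiper_lower_quantile(x, n, test = test, control = control)
}
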