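# Second-order asymptotic tail approximations for Kuiper's statistics.
#
# For the one-sample statistic the scaled quantity is K_n = sqrt(n) * V_n and
#   Pr{K_n > c} ~ A1(c,n) exp(-2c^2) + A2(c,n) exp(-8c^2)
# with
#   A1(c,n) = -2 + 8c/sqrt(n) + 8c^2 - 32c^3/(3 sqrt(n))
#   A2(c,n) = -2 + 32c/sqrt(n) + 32c^2 - 512c^3/(3 sqrt(n)).
# For the equal-size two-sample statistic the scaled quantity is
# sqrt(n) * V_{n,n} and
#   Pr{sqrt(n) V_{n,n} > c} ~ U1(c,n) exp(-c^2) + U2(c,n) exp(-4c^2)
# with
#   U1(c,n) = 2(2c^2-1) - c^2(2c^2-7)/(6n) - exp(c^2)/(6n)
#   U2(c,n) = 2(8c^2-1) - 2c^2(8c^2-7)/(3n).
# n = Inf selects the exact limiting coefficients (all 1/sqrt(n), 1/n terms
# dropped), not a large-n numerical proxy.

stop_kuiper <- function(msg, class, call. = FALSE) {
  stop(structure(class = c(class, "kuiperq_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_c_positive <- function(c) {
  if (!is.numeric(c) || any(!is.finite(c)) || any(c <= 0))
    stop_kuiper("'c' must be a finite positive number", "kuiperq_domain_error")
}

check_n <- function(n, allow_inf = TRUE) {
  if (length(n) != 1L || !is.numeric(n) || is.na(n))
    stop_kuiper("'n' must be a single numeric value", "kuiperq_domain_error")
  if (is.infinite(n)) {
    if (!allow_inf)
      stop_kuiper("'n' must be finite here", "kuiperq_domain_error")
  } else if (n < 1 || n != round(n)) {
    stop_kuiper("'n' must be a positive integer (or Inf)", "kuiperq_domain_error")
  }
}

check_alpha <- function(alpha, name = "alpha") {
  if (length(alpha) != 1L || !is.numeric(alpha) || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop_kuiper(sprintf("'%s' must lie strictly inside (0, 1)", name),
                "kuiperq_argument_error")
}

#' Series coefficients of the Kuiper tail approximation
#'
#' Evaluates the bracketed coefficients of the second-order tail expansion:
#' \eqn{A_1(c,n), A_2(c,n)} for the one-sample statistic \eqn{V_n}
#' (\code{test = "vn"}) or \eqn{U_1(c,n), U_2(c,n)} for the equal-size
#' two-sample statistic \eqn{V_{n,n}} (\code{test = "vnn"}).
#'
#' With \code{n = Inf} the finite-sample correction terms are dropped exactly,
#' giving \eqn{A_1 = -2 + 8c^2}, \eqn{A_2 = -2 + 32c^2} (and
#' \eqn{U_1 = 2(2c^2-1)}, \eqn{U_2 = 2(8c^2-1)}).
#'
#' @param c positive numeric vector, the critical-value argument on the scale
#'   of \eqn{\sqrt{n} V}.
#' @param n sample size (positive integer) or \code{Inf} for the limit.
#' @param test \code{"vn"} (one-sample) or \code{"vnn"} (two-sample, equal
#'   sizes).
#' @return A list with numeric components \code{a1} and \code{a2}.
#' @examples
#' kuiper_coeffs(1, Inf)            # a1 = 6, a2 = 30
#' kuiper_coeffs(1.2, 30)
#' @export
kuiper_coeffs <- function(c, n, test = c("vn", "vnn")) {
  test <- match.arg(test)
  check_c_positive(c)
  check_n(n)
  if (test == "vn") {
    if (is.infinite(n)) {
      list(a1 = -2 + 8 * c^2, a2 = -2 + 32 * c^2)
    } else {
      rn <- sqrt(n)
      list(a1 = -2 + 8 * c / rn + 8 * c^2 - 32 * c^3 / (3 * rn),
           a2 = -2 + 32 * c / rn + 32 * c^2 - 512 * c^3 / (3 * rn))
    }
  } else {
    if (is.infinite(n)) {
      list(a1 = 2 * (2 * c^2 - 1), a2 = 2 * (8 * c^2 - 1))
    } else {
      if (any(c^2 > 700))   # exp(c^2) would overflow double precision
        stop_kuiper("'c' too large: exp(c^2) overflows in the two-sample coefficients",
                    "kuiperq_domain_error")
      list(a1 = 2 * (2 * c^2 - 1) - c^2 * (2 * c^2 - 7) / (6 * n) -
             exp(c^2) / (6 * n),
           a2 = 2 * (8 * c^2 - 1) - 2 * c^2 * (8 * c^2 - 7) / (3 * n))
    }
  }
}

#' Tail probability of the scaled Kuiper statistic
#'
#' Approximates \eqn{\Pr\{\sqrt{n} V > c\}} for Kuiper's statistic.  The
#' default \code{"second_order_vn"} keeps the first two terms of both series
#' of the asymptotic expansion; \code{"first_order_kuiper"} is Kuiper's
#' original one-term approximation, \code{"first_order_stephens"} is the
#' n-free one-term form \eqn{(8c^2-2)e^{-2c^2}}, and \code{"second_order_vnn"}
#' is the two-term form for the equal-size two-sample statistic.
#'
#' The series value can leave \eqn{[0,1]} outside its useful range (small
#' \eqn{c}, or large \eqn{c} at small \eqn{n}); the returned probability is
#' clamped to \eqn{[0,1]} and the unclamped value is kept in the
#' \code{"raw"} attribute.
#'
#' @param c positive numeric vector, on the scale of \eqn{\sqrt{n} V}.
#' @param n sample size or \code{Inf}.
#' @param kind which approximation to evaluate.
#' @return Numeric vector of probabilities in \eqn{[0,1]}, with attribute
#'   \code{"raw"} carrying the unclamped series value.
#' @examples
#' kuiper_tail_prob(1.6, 10)                 # ~ 0.0521
#' kuiper_tail_prob(1.7472, Inf)             # ~ 0.05
#' @export
kuiper_tail_prob <- function(c, n,
                             kind = c("second_order_vn", "second_order_vnn",
                                      "first_order_kuiper",
                                      "first_order_stephens")) {
  kind <- match.arg(kind)
  check_c_positive(c)
  check_n(n)
  raw <- switch(kind,
    second_order_vn = {
      co <- kuiper_coeffs(c, n, "vn")
      co$a1 * exp(-2 * c^2) + co$a2 * exp(-8 * c^2)
    },
    second_order_vnn = {
      co <- kuiper_coeffs(c, n, "vnn")
      co$a1 * exp(-c^2) + co$a2 * exp(-4 * c^2)
    },
    first_order_kuiper = {
      co <- kuiper_coeffs(c, n, "vn")
      co$a1 * exp(-2 * c^2)
    },
    first_order_stephens = (8 * c^2 - 2) * exp(-2 * c^2))
  p <- pmin(1, pmax(0, raw))
  attr(p, "raw") <- raw
  p
}

kind_for_test <- function(test) {
  switch(test, vn = "second_order_vn", vnn = "second_order_vnn")
}

#' Log-domain residual whose root is the Kuiper critical value
#'
#' The nonlinear form used by the Newton solver.  For the one-sample test the
#' residual is \eqn{2c^2 + \log\alpha - \log[A_1 + A_2 e^{-6c^2}]}; for the
#' two-sample test it is \eqn{c^2 + \log\alpha - \log[U_1 + U_2 e^{-3c^2}]}.
#' Its root in \eqn{c} is the critical value with upper tail probability
#' \code{alpha}.
#'
#' @param c positive numeric vector.
#' @param alpha upper tail probability in (0, 1).
#' @param n sample size or \code{Inf}.
#' @param test \code{"vn"} or \code{"vnn"}.
#' @return Numeric vector of residual values.  Points where the logarithm
#'   argument is non-positive raise a classed infeasible-point error (the
#'   solver backtracks on it).
#' @export
kuiper_f_nonlinear <- function(c, alpha, n, test = c("vn", "vnn")) {
  test <- match.arg(test)
  check_alpha(alpha)
  co <- kuiper_coeffs(c, n, test)
  if (test == "vn") {
    arg <- co$a1 + co$a2 * exp(-6 * c^2)
    if (any(arg <= 0))
      stop_kuiper("log argument A1 + A2 exp(-6c^2) is not positive",
                  "kuiperq_infeasible")
    2 * c^2 + log(alpha) - log(arg)
  } else {
    arg <- co$a1 + co$a2 * exp(-3 * c^2)
    if (any(arg <= 0))
      stop_kuiper("log argument U1 + U2 exp(-3c^2) is not positive",
                  "kuiperq_infeasible")
    c^2 + log(alpha) - log(arg)
  }
}

#' Contractive map whose fixed point is the Kuiper critical value
#'
#' The updating function of the direct iteration: for the one-sample test
#' \eqn{c \mapsto \sqrt{(\log[A_1 + A_2 e^{-6c^2}] - \log\alpha)/2}}, for the
#' two-sample test \eqn{c \mapsto \sqrt{\log[U_1 + U_2 e^{-3c^2}] -
#' \log\alpha}}.  Both are algebraic rearrangements of
#' \code{\link{kuiper_f_nonlinear}} = 0.
#'
#' @inheritParams kuiper_f_nonlinear
#' @return The next iterate (positive numeric).
#' @export
kuiper_f_contractive <- function(c, alpha, n, test = c("vn", "vnn")) {
  test <- match.arg(test)
  check_alpha(alpha)
  co <- kuiper_coeffs(c, n, test)
  if (test == "vn") {
    arg <- co$a1 + co$a2 * exp(-6 * c^2)
    if (any(arg <= 0))
      stop_kuiper("log argument A1 + A2 exp(-6c^2) is not positive",
                  "kuiperq_infeasible")
    s <- (log(arg) - log(alpha)) / 2
  } else {
    arg <- co$a1 + co$a2 * exp(-3 * c^2)
    if (any(arg <= 0))
      stop_kuiper("log argument U1 + U2 exp(-3c^2) is not positive",
                  "kuiperq_infeasible")
    s <- log(arg) - log(alpha)
  }
  if (any(s < 0))
    stop_kuiper("quantity under the square root is negative",
                "kuiperq_infeasible")
  sqrt(s)
}

#' Exponential-form residual (alternative nonlinear equation)
#'
#' The residual \eqn{A_1 e^{-2c^2} + A_2 e^{-8c^2} - \alpha} (one-sample) or
#' \eqn{U_1 e^{-c^2} + U_2 e^{-4c^2} - \alpha} (two-sample).  It has the same
#' roots as \code{\link{kuiper_f_nonlinear}} wherever both are defined, is
#' defined for every positive \eqn{c}, and is the form used by the bisection
#' cross-checks.  Its derivative is nearly zero to the right of the root, so
#' Newton iteration on it fails from too-large starting values; the log-domain
#' form is preferred for solving.
#'
#' @inheritParams kuiper_f_nonlinear
#' @return Numeric vector of residual values.
#' @export
kuiper_f_residual <- function(c, alpha, n, test = c("vn", "vnn")) {
  test <- match.arg(test)
  check_alpha(alpha)
  raw <- attr(kuiper_tail_prob(c, n, kind_for_test(test)), "raw")
  raw - alpha
}
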