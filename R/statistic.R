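# Kuiper's statistic from data and the associated hypothesis test.
#
# V = D+ + D- where D+ and D- are the largest deviations of one CDF above and
# below the other.  Unlike the Kolmogorov-Smirnov statistic, V weighs the
# tails like the centre and is invariant under cyclic shifts of the variable,
# which makes it the standard choice for observations on a circle.

#' Kuiper's statistic, one sample against a reference CDF
#'
#' With order statistics \eqn{x_{(1)} \le \dots \le x_{(n)}} and reference
#' CDF \eqn{F}: \eqn{D^+ = \max_i(i/n - F(x_{(i)}))},
#' \eqn{D^- = \max_i(F(x_{(i)}) - (i-1)/n)} (both floored at 0),
#' \eqn{V = D^+ + D^-} and \eqn{K = \sqrt{n} V}.
#'
#' @param x numeric vector of observations.
#' @param cdf reference CDF: a nondecreasing function into [0, 1]
#'   (e.g. \code{punif}, \code{pnorm}), called as \code{cdf(x, ...)}.
#' @param ... further arguments passed to \code{cdf}.
#' @return An object of class \code{"kuiper_statistic"}: a list with
#'   \code{n}, \code{d_plus}, \code{d_minus}, \code{v}, \code{k} and
#'   \code{test = "vn"}.
#' @examples
#' set.seed(1)
#' kuiper_statistic(runif(50), punif)
#' @export
kuiper_statistic <- function(x, cdf = stats::punif, ...) {
  if (length(x) < 1L || !is.numeric(x) || any(!is.finite(x)))
    stop_kuiper("'x' must be a non-empty vector of finite numbers",
                "kuiperq_argument_error")
  n <- length(x)
  Fx <- cdf(sort(x), ...)
  if (any(!is.finite(Fx)) || any(Fx < 0) || any(Fx > 1))
    stop_kuiper("reference CDF values must lie in [0, 1]",
                "kuiperq_data_error")
  if (is.unsorted(Fx))
    stop_kuiper("reference CDF must be nondecreasing", "kuiperq_data_error")
  i <- seq_len(n)
  d_plus <- max(i / n - Fx, 0)
  d_minus <- max(Fx - (i - 1) / n, 0)
  new_kuiper_statistic(n, d_plus, d_minus, "vn")
}

#' Kuiper's statistic, two samples of equal size
#'
#' \eqn{D^+} and \eqn{D^-} are the extrema of the difference of the two
#' empirical CDFs over the pooled sample.  Only equal sizes are supported:
#' the tail approximation implemented here is for \eqn{V_{n,n}}, and no
#' closed form is provided for unequal sizes.
#'
#' @param x,y numeric vectors of the same length.
#' @return A \code{"kuiper_statistic"} object with \code{test = "vnn"};
#'   its \code{k} component is \eqn{\sqrt{n} V} with \eqn{n} the common size.
#' @examples
#' set.seed(1)
#' kuiper_statistic2(runif(30), runif(30))
#' @export
kuiper_statistic2 <- function(x, y) {
  if (length(x) < 1L || any(!is.finite(x)) || any(!is.finite(y)))
    stop_kuiper("samples must be non-empty vectors of finite numbers",
                "kuiperq_argument_error")
  if (length(x) != length(y))
    stop_kuiper(paste("unequal sample sizes: the two-sample V_{n,m} statistic",
                      "with n != m is not supported"),
                "kuiperq_unsupported")
  n <- length(x)
  pooled <- sort(c(x, y))
  # right-continuous ECDF difference evaluated at every pooled point; the
  # difference is a step function constant between pooled points, so its
  # extrema are attained on these values
  ex <- vapply(pooled, function(t) sum(x <= t), numeric(1)) / n
  ey <- vapply(pooled, function(t) sum(y <= t), numeric(1)) / n
  d <- ex - ey
  d_plus <- max(d, 0)
  d_minus <- max(-d, 0)
  new_kuiper_statistic(n, d_plus, d_minus, "vnn")
}

new_kuiper_statistic <- function(n, d_plus, d_minus, test) {
  structure(list(n = n, d_plus = d_plus, d_minus = d_minus,
                 v = d_plus + d_minus, k = sqrt(n) * (d_plus + d_minus),
                 test = test),
            class = "kuiper_statistic")
}

#' @export
print.kuiper_statistic <- function(x, ...) {
  cat(sprintf("Kuiper statistic (%s), n = %d\n",
              if (x$test == "vn") "one-sample" else "two-sample", x$n))
  cat(sprintf("  D+ = %.6f, D- = %.6f, V = %.6f, sqrt(n) V = %.6f\n",
              x$d_plus, x$d_minus, x$v, x$k))
  invisible(x)
}

#' Kuiper goodness-of-fit test
#'
#' One-sample test of \code{x} against a reference CDF, or (when \code{y} is
#' given) the equal-size two-sample test.  The p-value is the second-order
#' tail approximation evaluated at the observed \eqn{\sqrt{n} V}; the
#' rejection decision at level \code{alpha} compares \eqn{V} with the solved
#' upper tail quantile, which is consistent with \code{p < alpha} because
#' both come from the same approximation.
#'
#' For \code{n < 5} the asymptotic approximation is crude (its error term is
#' of order \eqn{1/n}) and a warning is attached rather than refusing.
#'
#' @param x numeric vector of observations, or a precomputed
#'   \code{"kuiper_statistic"} object.
#' @param y optional second sample (equal length) for the two-sample test.
#' @param cdf reference CDF for the one-sample test (default standard
#'   uniform).
#' @param ... passed to \code{cdf}.
#' @param alpha significance level for the reported decision.
#' @return An object of classes \code{"kuiper_test"} and \code{"htest"} with
#'   the usual components (\code{statistic}, \code{p.value}, \code{method},
#'   \code{data.name}) plus \code{d_plus}, \code{d_minus}, \code{n},
#'   \code{alpha}, \code{critical_quantile} and \code{reject}.
#' @examples
#' set.seed(7)
#' kuiper_test(runif(40))
#' kuiper_test(rbeta(40, 2, 2))     # against punif: departs from uniform
#' @export
kuiper_test <- function(x, y = NULL, cdf = stats::punif, ..., alpha = 0.05) {
  check_alpha(alpha)
  if (inherits(x, "kuiper_statistic")) {
    st <- x
    dname <- deparse(substitute(x))
  } else if (!is.null(y)) {
    st <- kuiper_statistic2(x, y)
    dname <- paste(deparse(substitute(x)), "and", deparse(substitute(y)))
  } else {
    st <- kuiper_statistic(x, cdf, ...)
    dname <- deparse(substitute(x))
  }
  kind <- kind_for_test(st$test)
  p <- as.numeric(kuiper_tail_prob(st$k, st$n, kind))
  vq <- kuiper_upper_quantile(alpha, st$n, test = st$test)
  out <- structure(list(
    statistic = c(V = st$v),
    parameter = c(n = st$n),
    p.value = p,
    method = if (st$test == "vn")
      "One-sample Kuiper test (second-order tail approximation)"
    else
      "Two-sample Kuiper test, equal sizes (second-order tail approximation)",
    data.name = dname,
    d_plus = st$d_plus, d_minus = st$d_minus,
    n = st$n, alpha = alpha,
    critical_quantile = vq,
    reject = st$v > vq),
    class = c("kuiper_test", "htest"))
  if (st$n < 5)
    warning("n < 5: the asymptotic tail approximation is unreliable for ",
            "very small samples", call. = FALSE)
  out
}
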