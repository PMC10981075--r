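# Seeded Monte-Carlo simulation of the null distribution of Kuiper's V,
# used as an independent check of the asymptotic solver: the empirical
# exceedance frequency of a solved quantile should match its nominal tail
# probability up to binomial sampling error plus the O(1/n) error of the
# approximation itself.

#' Simulate the null distribution of Kuiper's V
#'
#' Draws \code{reps} independent values of \eqn{V} under the null: uniform
#' samples tested against the uniform CDF (\code{test = "vn"}), or two
#' independent uniform samples of common size \code{n} (\code{test = "vnn"}).
#' The null distribution of \eqn{V} is distribution-free, so the uniform
#' choice is without loss of generality.
#'
#' The generator is R's Mersenne-Twister with the given seed; the caller's
#' RNG state is saved and restored, and identical \code{(n, reps, seed)}
#' reproduce identical draws.
#'
#' @param n sample size per replicate.
#' @param reps number of replicates.
#' @param seed integer seed.
#' @param test \code{"vn"} or \code{"vnn"}.
#' @return An object of class \code{"kuiper_null_sim"}: a list with
#'   \code{n}, \code{reps}, \code{seed}, \code{test}, \code{rng} and
#'   \code{statistics} (numeric vector of simulated V values, all in [0, 2]).
#' @examples
#' sim <- kuiper_null_sim(30, 1000, seed = 42)
#' quantile(sim, 0.95)
#' @export
kuiper_null_sim <- function(n, reps, seed, test = c("vn", "vnn")) {
  test <- match.arg(test)
  check_n(n, allow_inf = FALSE)
  if (reps < 1)
    stop_kuiper("'reps' must be >= 1", "kuiperq_argument_error")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  i <- seq_len(n)
  hi <- i / n
  lo <- (i - 1) / n
  stats <- if (test == "vn") {
    vapply(seq_len(reps), function(r) {
      u <- sort(runif(n))
      max(hi - u, 0) + max(u - lo, 0)
    }, numeric(1))
  } else {
    vapply(seq_len(reps), function(r) {
      x <- runif(n); y <- runif(n)
      # ECDF difference at pooled order: +1/n at an x, -1/n at a y
      s <- cumsum(c(rep(1 / n, n), rep(-1 / n, n))[order(c(x, y))])
      max(s, 0) + max(-s, 0)
    }, numeric(1))
  }
  structure(list(n = n, reps = as.integer(reps), seed = as.integer(seed),
                 test = test, rng = "Mersenne-Twister",
                 statistics = stats),
            class = "kuiper_null_sim")
}

#' Empirical quantile of a simulated null distribution
#'
#' @param x a \code{"kuiper_null_sim"} object.
#' @param probs probabilities.
#' @param ... passed to \code{stats::quantile}.
#' @return Numeric vector of empirical quantiles.
#' @export
quantile.kuiper_null_sim <- function(x, probs = c(0.90, 0.95, 0.99), ...) {
  stats::quantile(x$statistics, probs = probs, names = TRUE, ...)
}

#' Empirical exceedance probability
#'
#' Fraction of simulated statistics strictly above a threshold \code{v}; for
#' a well-calibrated solver, \code{kuiper_exceedance(sim,
#' kuiper_upper_quantile(alpha, n))} is close to \code{alpha}.
#' @param sim a \code{"kuiper_null_sim"} object.
#' @param v threshold(s) on the scale of V.
#' @return Numeric vector of exceedance frequencies.
#' @export
kuiper_exceedance <- function(sim, v) {
  vapply(v, function(t) mean(sim$statistics > t), numeric(1))
}

#' @export
print.kuiper_null_sim <- function(x, ...) {
  cat(sprintf("Kuiper null simulation (%s): n = %d, reps = %d, seed = %d\n",
              x$test, x$n, x$reps, x$seed))
  print(quantile(x))
  invisible(x)
}
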