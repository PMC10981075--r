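# Generic scalar fixed-point machinery: iterate an updating function until
# successive iterates are closer than a tolerance (Cauchy stopping rule).
# Two updaters are provided: direct substitution c <- f(c) for a contractive
# map, and Newton's step c <- c - f(c)/f'(c) with the derivative by central
# finite difference.

#' Solver configuration
#'
#' @param method \code{"newton"} (default) or \code{"direct"}.
#' @param c_guess starting value.  2.45 works for both the one-sample and the
#'   equal-size two-sample problem at every tabulated \eqn{(\alpha, n)}; the
#'   direct map is contractive for guesses in roughly (0.5, 2.5) and the
#'   log-form Newton iteration for guesses in roughly (1.1, 2.5).
#' @param tol convergence tolerance on \eqn{|c_{i+1} - c_i|}.
#' @param max_iter iteration cap.
#' @param derivative_step relative step of the central finite difference used
#'   by the Newton updater.
#' @return A list of class \code{"kuiper_control"}.
#' @export
kuiper_control <- function(method = c("newton", "direct"), c_guess = 2.45,
                           tol = 1e-12, max_iter = 200L,
                           derivative_step = 1e-6) {
  method <- match.arg(method)
  if (!is.numeric(c_guess) || length(c_guess) != 1L || c_guess <= 0)
    stop_kuiper("'c_guess' must be a single positive number",
                "kuiperq_argument_error")
  if (!is.numeric(tol) || tol <= 0)
    stop_kuiper("'tol' must be positive", "kuiperq_argument_error")
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L)
    stop_kuiper("'max_iter' must be >= 1", "kuiperq_argument_error")
  if (!is.numeric(derivative_step) || derivative_step <= 0)
    stop_kuiper("'derivative_step' must be positive", "kuiperq_argument_error")
  structure(list(method = method, c_guess = c_guess, tol = tol,
                 max_iter = max_iter, derivative_step = derivative_step),
            class = "kuiper_control")
}

#' Distance between successive iterates
#'
#' The metric of the Cauchy stopping rule: \code{abs(x - y)}.
#' @param x,y numeric.
#' @return Non-negative numeric.
#' @export
fp_distance <- function(x, y) abs(x - y)

#' Direct (substitution) update
#'
#' One step of the direct scheme: returns \code{f(c, alpha, n)}.
#' @param f updating function of \code{(c, alpha, n)} (a contractive map such
#'   as \code{\link{kuiper_f_contractive}}).
#' @param c current iterate.
#' @param alpha,n extra parameters passed through to \code{f}.
#' @return The next iterate.
#' @export
update_direct <- function(f, c, alpha, n) f(c, alpha, n)

#' Newton update
#'
#' One Newton step \eqn{c - f(c)/f'(c)} with \eqn{f'} by central finite
#' difference of relative step \code{max(step, step * |c|)}.
#'
#' @param f residual function of \code{(c, alpha, n)} whose root is sought
#'   (such as \code{\link{kuiper_f_nonlinear}}).
#' @param c current iterate.
#' @param alpha,n extra parameters passed through to \code{f}.
#' @param step relative finite-difference step.
#' @return The next iterate.  A derivative smaller than 1e-14 in magnitude
#'   raises a classed flat-derivative error: this is the known failure mode of
#'   Newton iteration on the exponential-form residual started to the right of
#'   the root, where the curve is nearly flat.
#' @export
update_newton <- function(f, c, alpha, n, step = 1e-6) {
  h <- max(step, step * abs(c))
  fp <- (f(c + h, alpha, n) - f(c - h, alpha, n)) / (2 * h)
  if (!is.finite(fp) || abs(fp) < 1e-14)
    stop_kuiper("derivative too close to zero for a Newton step",
                "kuiperq_flat_derivative")
  c - f(c, alpha, n) / fp
}

#' Iterate an updating function to its fixed point
#'
#' Repeats \code{c[i+1] <- update(c[i], alpha, n)} until
#' \code{fp_distance(c[i+1], c[i]) < control$tol} or \code{control$max_iter}
#' steps have been taken.  If a proposed iterate leaves the domain of the
#' updating function (classed infeasible-point error, e.g. the logarithm of a
#' non-positive number), the step is halved toward the previous iterate up to
#' 30 times before giving up.
#'
#' @param update function of \code{(c, alpha, n)} returning the next iterate;
#'   build one from \code{\link{update_direct}} or \code{\link{update_newton}}.
#' @param alpha,n extra parameters passed through to \code{update}.
#' @param control a \code{\link{kuiper_control}} list (its \code{c_guess},
#'   \code{tol} and \code{max_iter} are used).
#' @return A list with \code{root} (the final iterate) and \code{trace}, a
#'   list of class \code{"kuiper_trace"} with components \code{iterates}
#'   (length \code{n_iter + 1}), \code{converged}, \code{n_iter} and
#'   \code{final_distance}.
#' @export
solve_fixed_point <- function(update, alpha, n, control = kuiper_control()) {
  cur <- control$c_guess
  prev <- NA_real_
  iterates <- cur
  converged <- FALSE
  dist <- NA_real_
  for (i in seq_len(control$max_iter)) {
    cand <- NULL
    attempt <- cur
    for (k in 0:30) {
      cand <- tryCatch(update(attempt, alpha, n),
                       kuiperq_infeasible = function(e) e)
      if (!inherits(cand, "condition") && is.finite(cand) && cand > 0) break
      if (is.na(prev))
        stop_kuiper(
          "starting value is outside the feasible domain of the updating function",
          "kuiperq_infeasible")
      attempt <- (attempt + prev) / 2
      cand <- NULL
    }
    if (is.null(cand) || inherits(cand, "condition"))
      stop_kuiper("backtracking exhausted: iterate left the feasible domain",
                  "kuiperq_infeasible")
    cur <- attempt                      # possibly pulled back toward prev
    dist <- fp_distance(cand, cur)
    prev <- cur
    cur <- cand
    iterates <- c(iterates, cand)
    if (dist < control$tol) {
      converged <- TRUE
      break
    }
  }
  trace <- structure(list(iterates = iterates, converged = converged,
                          n_iter = length(iterates) - 1L,
                          final_distance = dist),
                     class = "kuiper_trace")
  if (!converged)
    stop(structure(class = c("kuiperq_no_convergence", "kuiperq_error",
                             "error", "condition"),
                   list(message = sprintf(
                     "no convergence after %d iterations (last distance %.3g)",
                     control$max_iter, dist),
                     call = sys.call(-1), iteration_trace = trace)))
  list(root = cur, trace = trace)
}
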