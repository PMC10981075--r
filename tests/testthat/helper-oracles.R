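# Shared fixtures: published table values (typed from the source tables) and
# independent oracles used to cross-check the solver and the statistic.

# One-sample Kuiper pairs (c, v), alpha in rows {0.10, 0.05, 0.01},
# n in columns {10, 20, 30, 40, 100, 180, 1e6}.
published_pairs_vn <- function() {
  tab <- rbind(
    c(1.4877, 0.4704, 1.5322, 0.3426, 1.5503, 0.2830, 1.5606, 0.2468,
      1.5838, 0.1584, 1.5934, 0.1188, 1.6193, 0.0016),
    c(1.6066, 0.5080, 1.6563, 0.3704, 1.6758, 0.3060, 1.6868, 0.2667,
      1.7110, 0.1711, 1.7208, 0.1283, 1.7469, 0.0017),
    c(1.8401, 0.5819, 1.9026, 0.4254, 1.9252, 0.3515, 1.9374, 0.3063,
      1.9636, 0.1964, 1.9739, 0.1471, 2.0006, 0.0020))
  ns <- c(10, 20, 30, 40, 100, 180, 1e6)
  data.frame(alpha = rep(c(0.10, 0.05, 0.01), each = length(ns)),
             n = rep(ns, 3),
             c = as.vector(t(tab[, seq(1, 13, 2)])),
             v = as.vector(t(tab[, seq(2, 14, 2)])))
}

# n = 10 rows (c, v, alpha) as printed in the historical-style table.
published_pairs_n10 <- function() {
  data.frame(
    c = seq(1.0, 1.9, by = 0.1),
    v = c(0.3163, 0.3482, 0.3795, 0.4110, 0.4427,
          0.4746, 0.5060, 0.5382, 0.5692, 0.6006),
    alpha = c(0.6930, 0.5280, 0.3770, 0.2520, 0.1580,
              0.0930, 0.0520, 0.0270, 0.0135, 0.0063))
}

# Large-sample critical values of the one-sample test.
published_c_infinity <- function() {
  data.frame(
    alpha = c(seq(0.10, 0.02, by = -0.01), 1e-2, 1e-6, 1e-10),
    c = c(1.6196, 1.6400, 1.6623, 1.6871, 1.7150, 1.7472, 1.7855, 1.8331,
          1.8974, 2.0009, 3.0056, 3.7226))
}

# Two-sample (equal-size) Kuiper pairs, alpha = 0.10 ... 0.01 by
# n in {10, 20, 30, 40, 100, 1e8}.
published_pairs_vnn <- function() {
  tab <- rbind(
    c(2.2431, 0.7093, 2.2660, 0.5067, 2.2740, 0.4152, 2.2780, 0.3602, 2.2854, 0.2285, 2.2905, 0.0002),
    c(2.2682, 0.7173, 2.2929, 0.5127, 2.3015, 0.4202, 2.3058, 0.3646, 2.3139, 0.2314, 2.3193, 0.0002),
    c(2.2953, 0.7258, 2.3220, 0.5192, 2.3314, 0.4257, 2.3362, 0.3694, 2.3449, 0.2345, 2.3509, 0.0002),
    c(2.3248, 0.7352, 2.3540, 0.5264, 2.3643, 0.4317, 2.3696, 0.3747, 2.3793, 0.2379, 2.3860, 0.0002),
    c(2.3572, 0.7454, 2.3896, 0.5343, 2.4011, 0.4384, 2.4070, 0.3806, 2.4180, 0.2418, 2.4255, 0.0002),
    c(2.3933, 0.7568, 2.4298, 0.5433, 2.4430, 0.4460, 2.4497, 0.3873, 2.4623, 0.2462, 2.4710, 0.0002),
    c(2.4343, 0.7698, 2.4764, 0.5537, 2.4918, 0.4549, 2.4998, 0.3952, 2.5147, 0.2515, 2.5251, 0.0003),
    c(2.4819, 0.7849, 2.5321, 0.5662, 2.5508, 0.4657, 2.5607, 0.4049, 2.5793, 0.2579, 2.5924, 0.0003),
    c(2.5393, 0.8030, 2.6021, 0.5819, 2.6266, 0.4796, 2.6397, 0.4174, 2.6650, 0.2665, 2.6834, 0.0003),
    c(2.6124, 0.8261, 2.6986, 0.6034, 2.7351, 0.4994, 2.7556, 0.4357, 2.7973, 0.2797, 2.8297, 0.0003))
  ns <- c(10, 20, 30, 40, 100, 1e8)
  data.frame(alpha = rep(seq(0.10, 0.01, by = -0.01), each = length(ns)),
             n = rep(ns, 10),
             c = as.vector(t(tab[, seq(1, 11, 2)])),
             v = as.vector(t(tab[, seq(2, 12, 2)])))
}

# Independent root oracle: bisection (stats::uniroot) on the exponential-form
# residual, which is defined for every positive c.
bisect_critical_value <- function(alpha, n, test = "vn",
                                  bracket = c(0.71, 4)) {
  stats::uniroot(function(c) kuiper_f_residual(c, alpha, n, test),
                 interval = bracket, tol = 1e-13)$root
}

# Independent statistic oracle: sup of (ECDF - F) over the breakpoint
# structure, using stats::ecdf.  On each interval [x_(i), x_(i+1)) the ECDF
# is constant and F is nondecreasing, so D+ is attained at the left endpoint
# (right-continuous value) and D- as the supremum approaching the next
# breakpoint from the left.
oracle_kuiper_one_sample <- function(x, cdf, ...) {
  e <- stats::ecdf(x)
  xs <- sort(unique(x))
  Fx <- cdf(xs, ...)
  d_plus <- max(e(xs) - Fx, 0)
  left_vals <- c(0, e(xs))            # ECDF value just below each breakpoint
  d_minus <- max(Fx - left_vals[seq_along(xs)], 0)
  list(d_plus = d_plus, d_minus = d_minus, v = d_plus + d_minus)
}

# Two-sample oracle: evaluate both ECDFs at every pooled point.
oracle_kuiper_two_sample <- function(x, y) {
  ex <- stats::ecdf(x); ey <- stats::ecdf(y)
  g <- sort(c(x, y))
  d <- ex(g) - ey(g)
  list(d_plus = max(d, 0), d_minus = max(-d, 0),
       v = max(d, 0) + max(-d, 0))
}
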