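# Closed-form coefficients and tail probabilities of the second-order
# approximation.  Pinned reference numbers were computed independently with
# 50-digit arithmetic (mpmath) from the printed formulas.

test_that("limiting coefficients take their closed-form values", {
  co <- kuiper_coeffs(1, Inf)
  expect_equal(co$a1, 6)
  expect_equal(co$a2, 30)
  # boundary of the necessary condition c > 1/sqrt(2): a1 vanishes at c = 1/2
  co <- kuiper_coeffs(0.5, Inf)
  expect_equal(co$a1, 0)
  expect_equal(co$a2, 6)
  co <- kuiper_coeffs(1, Inf, test = "vnn")
  expect_equal(co$a1, 2)
  expect_equal(co$a2, 14)
})

test_that("finite-n coefficients match high-precision evaluation", {
  co <- kuiper_coeffs(1.2, 30)
  expect_equal(co$a1, 7.9075047907047910, tolerance = 1e-14)
  expect_equal(co$a2, -2.7524695569217234, tolerance = 1e-13)
  co <- kuiper_coeffs(2.5, 20, test = "vnn")
  expect_equal(co$a1, 18.396768127763816, tolerance = 1e-14)
  expect_equal(co$a2, 2137 / 24, tolerance = 1e-15)   # exactly rational
})

test_that("limiting coefficients are positive beyond c = 1/sqrt(2)", {
  cs <- seq(1 / sqrt(2) + 1e-6, 4, length.out = 50)
  co <- kuiper_coeffs(cs, Inf)
  expect_true(all(co$a1 > 0))
  expect_true(all(co$a2 > 0))
})

test_that("coefficient domain errors fire", {
  expect_error(kuiper_coeffs(-1, 30), class = "kuiperq_domain_error")
  expect_error(kuiper_coeffs(0, Inf), class = "kuiperq_domain_error")
  expect_error(kuiper_coeffs(1, 2.5), class = "kuiperq_domain_error")
  # exp(c^2) overflow guard in the two-sample coefficients
  expect_error(kuiper_coeffs(30, 10, test = "vnn"),
               class = "kuiperq_domain_error")
})

test_that("tail probabilities match high-precision evaluation", {
  expect_equal(as.numeric(kuiper_tail_prob(1.0, 10)),
               0.69324072666697817, tolerance = 1e-13)
  expect_equal(as.numeric(kuiper_tail_prob(1.6, 10)),
               0.052060044701683640, tolerance = 1e-12)
  expect_equal(as.numeric(kuiper_tail_prob(1.9, 10)),
               0.0062573463340711223, tolerance = 1e-12)
  expect_equal(as.numeric(kuiper_tail_prob(2.2431, 10, "second_order_vnn")),
               0.10000147663927412, tolerance = 1e-12)
})

test_that("tail probability is clamped to [0, 1] with raw value retained", {
  p <- kuiper_tail_prob(0.2, 10)       # series < 0 far below the valid range
  expect_equal(as.numeric(p), 0)
  expect_lt(attr(p, "raw"), 0)
  p <- kuiper_tail_prob(6, 30)
  expect_gte(as.numeric(p), 0)
  expect_lt(as.numeric(p), 1e-20)
})

test_that("tail probability decreases in c over the working range", {
  for (n in c(10, 30, 100, Inf)) {
    cs <- seq(0.75, 2.3, by = 0.05)
    raw <- attr(kuiper_tail_prob(cs, n), "raw")
    expect_true(all(diff(raw) < 0), info = paste("n =", n))
  }
  cs <- seq(1.6, 3.0, by = 0.05)
  raw <- attr(kuiper_tail_prob(cs, 30, "second_order_vnn"), "raw")
  expect_true(all(diff(raw) < 0))
})

test_that("finite-n tail converges to the exact limit at the 1/sqrt(n) rate", {
  cs <- seq(1, 3, by = 0.1)
  gap <- function(n) max(abs(as.numeric(kuiper_tail_prob(cs, n)) -
                             as.numeric(kuiper_tail_prob(cs, Inf))))
  # the finite-n correction enters at order 1/sqrt(n)
  expect_lt(gap(1e8), 1e-4)
  expect_lt(gap(1e12), 1e-6)
  expect_lt(gap(1e12), gap(1e8) / 50)
})

test_that("nonlinear, contractive and residual forms are algebraically consistent", {
  # identities: fctm(c)^2 = c^2 - fnlm(c)/2 (one-sample),
  #             fctm(c)^2 = c^2 - fnlm(c)  (two-sample),
  # and fnlm(c) = 0 <=> tail = alpha <=> c is a fixed point of fctm.
  for (n in c(10, 30, Inf)) {
    for (alpha in c(0.10, 0.01)) {
      cs <- seq(0.9, 2.2, by = 0.1)
      fn <- kuiper_f_nonlinear(cs, alpha, n)
      fc <- kuiper_f_contractive(cs, alpha, n)
      expect_equal(fc^2, cs^2 - fn / 2, tolerance = 1e-12)
    }
  }
  cs <- seq(1.8, 2.8, by = 0.1)
  fn <- kuiper_f_nonlinear(cs, 0.05, 20, test = "vnn")
  fc <- kuiper_f_contractive(cs, 0.05, 20, test = "vnn")
  expect_equal(fc^2, cs^2 - fn, tolerance = 1e-12)

  root <- bisect_critical_value(0.05, 30)
  expect_equal(as.numeric(kuiper_tail_prob(root, 30)), 0.05,
               tolerance = 1e-10)
  expect_lt(abs(kuiper_f_nonlinear(root, 0.05, 30)), 1e-9)
  expect_lt(abs(kuiper_f_contractive(root, 0.05, 30) - root), 1e-9)
})

test_that("log-form residuals match pinned values and vanish at table roots", {
  expect_equal(kuiper_f_nonlinear(1.2, 0.01, 30),
               -3.7929208947744981, tolerance = 1e-13)
  expect_equal(kuiper_f_contractive(2.45, 0.05, 10, test = "vnn"),
               2.3850029111471255, tolerance = 1e-13)
  # at the published 4-decimal root the residual is zero to table precision
  expect_lt(abs(kuiper_f_nonlinear(1.6758, 0.05, 30)), 5e-4)
  expect_lt(abs(kuiper_f_contractive(1.5503, 0.10, 30) - 1.5503), 5e-5)
})

test_that("infeasible points raise classed errors", {
  # far right of the root at small n the log argument goes negative
  expect_error(kuiper_f_nonlinear(3.5, 0.05, 10),
               class = "kuiperq_infeasible")
  expect_error(kuiper_f_contractive(3.5, 0.05, 10),
               class = "kuiperq_infeasible")
  # the exponential-form residual stays defined there
  expect_true(is.finite(kuiper_f_residual(3.5, 0.05, 10)))
})

test_that("first-order variants behave as cruder versions of the same tail", {
  # Stephens' form is n-free; Kuiper's one-term form approaches it as n grows
  expect_equal(as.numeric(kuiper_tail_prob(1.7, 1e10, "first_order_kuiper")),
               as.numeric(kuiper_tail_prob(1.7, 10, "first_order_stephens")),
               tolerance = 1e-4)
  # at moderate c the missing j = 2 term is small but nonzero
  p1 <- as.numeric(kuiper_tail_prob(1.2, 30, "first_order_kuiper"))
  p2 <- as.numeric(kuiper_tail_prob(1.2, 30, "second_order_vn"))
  expect_false(isTRUE(all.equal(p1, p2, tolerance = 1e-6)))
  expect_equal(p1, p2, tolerance = 0.01)
})
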