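---
title: "Computing critical values and quantiles of Kuiper's statistic"
author: "kuiperq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing critical values and quantiles of Kuiper's statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kuiperq)
```

## The statistic and why its quantiles are hard

Kuiper's statistic compares two cumulative distribution functions by

$$V = D^+ + D^- = \sup_x\,[F_1(x) - F_2(x)] + \sup_x\,[F_2(x) - F_1(x)],$$

the sum of the largest deviation above and below.  Replacing the
Kolmogorov–Smirnov $\sup|F_1-F_2|$ by this sum makes the test equally
sensitive in the tails and the centre and — decisive for circular data such
as directions, phases or times of day — invariant under cyclic shifts of the
variable.  `kuiperq` covers the one-sample statistic $V_n$ (a sample of size
$n$ against a reference CDF) and the equal-size two-sample statistic
$V_{n,n}$.

The null CDF of $V_n$ has no closed form.  What is available is an
asymptotic series for the scaled statistic $K_n = \sqrt{n}\,V_n$:

$$\Pr\{K_n > c\} \;\approx\; A_1(c,n)\,e^{-2c^2} + A_2(c,n)\,e^{-8c^2},$$

where the coefficients keep the first two terms ($j = 1, 2$) of both sums of
the expansion,

$$A_1(c,n) = -2 + \frac{8c}{\sqrt{n}} + 8c^2 - \frac{32c^3}{3\sqrt{n}},
\qquad
A_2(c,n) = -2 + \frac{32c}{\sqrt{n}} + 32c^2 - \frac{512c^3}{3\sqrt{n}}.$$

This *second-order* truncation is markedly more accurate than the classical
one-term approximations (Kuiper's own, and Stephens' $n$-free variant, both
provided for comparison as `kind = "first_order_kuiper"` and
`"first_order_stephens"`), whose error is dominated by the missing $j = 2$
term.  The overall error of the expansion is still $O(1/n)$ in the sample
size.

For the two-sample statistic the same construction on $\sqrt{n}\,V_{n,n}$
gives

$$\Pr\{\sqrt{n}\,V_{n,n} > c\} \;\approx\; U_1(c,n)\,e^{-c^2} +
U_2(c,n)\,e^{-4c^2},$$

$$U_1(c,n) = 2(2c^2-1) - \frac{c^2(2c^2-7)}{6n} - \frac{e^{c^2}}{6n},
\qquad
U_2(c,n) = 2(8c^2-1) - \frac{2c^2(8c^2-7)}{3n},$$

where the stray $-1/(6n)$ constant of the expansion is folded into $U_1$ as
the $e^{c^2}/(6n)$ term.  Its error is $O(1/n^2)$.

A *Kuiper pair* $\langle c_n^\alpha, v_n^\alpha \rangle$ is the critical
value on the $K_n$ scale together with the quantile on the $V_n$ scale,
linked exactly by $v_n^\alpha = c_n^\alpha/\sqrt{n}$.  Because the lower
tail quantile at $p$ is the upper tail quantile at $1-p$, solving the upper
tail also yields the full inverse CDF (`kuiper_inv_cdf`).

## Solving for the critical value

Setting the tail approximation equal to $\alpha$ and moving to the log
domain gives the residual solved by Newton iteration,

$$f(c) = 2c^2 + \ln\alpha - \ln\!\big[A_1(c,n) + A_2(c,n)e^{-6c^2}\big],$$

(and $c^2 + \ln\alpha - \ln[U_1 + U_2 e^{-3c^2}]$ for the two-sample case),
or, rearranged, the fixed-point identity iterated by direct substitution,

$$c = \sqrt{\tfrac12\big(\ln[A_1 + A_2 e^{-6c^2}] - \ln\alpha\big)}.$$

Both updaters plug into one generic solver (`solve_fixed_point`) that stops
when successive iterates differ by less than the tolerance.  Design choices
that matter in practice:

* **Derivatives** are central finite differences with relative step
  $\max(h, h|c|)$, $h = 10^{-6}$ by default: second-order accurate, no
  symbolic algebra, and the $\approx 10^{-12}$ derivative error is far below
  the solver tolerance.
* **Feasibility and backtracking.**  The log argument
  $A_1 + A_2e^{-6c^2}$ turns negative to the right of the root at finite
  $n$, so an overshooting iterate can leave the domain.  Such excursions
  raise a classed condition and the solver halves the step back toward the
  previous iterate (up to 30 times) before giving up.
* **Starting values.**  The guess 2.45 works for both statistics at every
  tabulated $(\alpha, n)$; the direct map is contractive for guesses in
  roughly $(0.5, 2.5)$ and log-form Newton for $(1.1, 2.5)$.  For very small
  $n$ (about $n \le 4$) the feasible window shrinks below 2.45 and
  `kuiper_pair` retries from 1.6 and 1.0 before failing.
* **Root filtering.**  The tail equation can have a spurious intersection
  below $1/\sqrt{2}$ (where the limiting $A_1 = 8c^2 - 2$ changes sign);
  converged roots at or below that bound are rejected and the solve restarts
  once from 2.45.
* **Why not Newton on the exponential form?**  The residual
  $A_1e^{-2c^2} + A_2e^{-8c^2} - \alpha$ is defined everywhere but is nearly
  flat to the right of the root, so Newton steps from a too-large guess are
  wild or hit the flat-derivative guard.  The package keeps this form
  (`kuiper_f_residual`) for bisection cross-checks, where its global
  definition is an advantage.

The limit $n = \infty$ is implemented as its own code path with the
$1/\sqrt{n}$ (or $1/n$) terms dropped exactly, rather than only as a large
finite $n$ — this avoids round-off in the correction terms and makes the
limit testable.  Note that the conventional numerical stand-in $n = 10^8$
differs from the exact limit by about $10^{-4}$ (the correction terms enter
at order $1/\sqrt{n}$); `kuiper_table("c_infinity")` uses $n = 10^8$, under
which the published large-sample row was produced, while
`kuiper_pair(alpha, Inf)` is exact.

## The test on data

`kuiper_statistic` uses the standard order-statistic formulas for a
right-continuous empirical CDF with jumps $1/n$:
$D^+ = \max_i(i/n - F(x_{(i)}))$, $D^- = \max_i(F(x_{(i)}) - (i-1)/n)$,
floored at zero; ties are handled naturally by the sorted order.  The
two-sample version takes the extrema of the ECDF difference over the pooled
points, which is exact because the difference is a step function constant
between pooled values.  P-values evaluate the tail approximation at the
observed $\sqrt{n}V$ and are clamped to $[0,1]$ (the raw series value is
kept as an attribute); the rejection decision compares $V$ against the
solved quantile, which agrees with `p < alpha` because both derive from the
same approximation.  For $n < 5$ the $O(1/n)$ error makes the approximation
crude and the test attaches a warning rather than refusing.

## Monte-Carlo validation

The null distribution of $V$ is distribution-free, so
`kuiper_null_sim` draws uniform samples (two independent ones for the
two-sample statistic) with R's Mersenne–Twister under an explicit recorded
seed, and reduces each replicate with the same order-statistic formulas.
This emulates exactly the sampling situation the solver's quantiles refer
to; what it does **not** emulate is any departure from the null or any
finite-precision feature of real measurements (rounding, heavy ties), so
calibration results transfer to real data only insofar as those are absent.
The validation tolerance combines three binomial standard errors with a
$2/n$ allowance, because the solver targets the asymptotic approximation
rather than the exact finite-$n$ law.  The shipped checks use $2\times10^5$
replicates at $n \in \{30, 100\}$ (a few minutes of CPU), and smaller
sanity runs of $10^4$–$2\times10^4$ replicates elsewhere.

## Accuracy and known limitations

* **Published-table agreement.**  The solver reproduces all 21 one-sample
  pairs, all 60 two-sample pairs and all 12 large-sample critical values of
  the published verification tables at 4-decimal precision, and corrects the
  long-standing transcription error in Kuiper's original table at
  $(\alpha, n) = (0.01, 30)$: 1.9252, not 1.9153
  (`kuiper_table_discrepancy()` isolates the cell).
* **The historical $n = 10$ table carries last-digit slop.**  Its printed
  quantile column is not $c/\sqrt{10}$ under any rounding (e.g. the row
  $c = 1.1$ prints 0.3482 where $1.1/\sqrt{10} = 0.34785$) and its tail
  probabilities deviate from the second-order formula by up to
  $1.6\times10^{-3}$.  Recomputation (`kuiper_table("pairs_n10")`) is
  internally exact; tests compare against the historical print only within
  $2\times10^{-3}$.
* **The direct iteration is not universally contractive.**  For the
  two-sample map at $(\alpha, n) = (0.01, 10)$ the $e^{c^2}/(6n)$ term makes
  the substitution map's derivative $\approx -1.27$ at its fixed point: the
  fixed point is repelling and plain direct iteration enters a 2-cycle.
  This is a property of the scheme, not a bug; Newton (the default) and
  bisection agree there to $10^{-8}$.  No damping or acceleration is
  applied — the direct updater is kept exactly as defined.
* **Breakdown region of the truncated series.**  At finite small $n$ the
  bracket $A_1(c,n)$ goes negative for large $c$ (around $c \gtrsim 1.95$
  at $n = 5$, $c \gtrsim 2.6$ at $n = 10$), where the raw series value dips
  below zero before decaying; clamping keeps reported probabilities valid
  but the approximation is meaningless out there.  Monotonicity of the tail
  in $c$ holds on the working range (checked for $c \in [0.75, 2.3]$ at
  $n \ge 10$).
* **Scope.**  Unequal two-sample sizes ($V_{n,m}$, $n \ne m$) have no
  implemented tail form and are refused explicitly; Stephens' modified
  small-sample statistic and third- or higher-order series terms are out of
  scope.

## Problem sizes used by the shipped validation

Deterministic checks (tables, method agreement across the 81 grid cells,
quantile round-trips at $10^{-9}$) run in seconds.  The stochastic
calibration uses $2\times10^5$ null replicates per sample size, chosen so
the binomial standard error at $\alpha = 0.01$ (about $2\times10^{-4}$) is
negligible against the $2/n$ approximation allowance.
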