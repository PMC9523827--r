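---
title: "Group sequential rank tests for the Mann-Whitney parameter: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group sequential rank tests: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsrank)
```

## Estimand and tests

`gsrank` monitors two-arm trials on the rank scale. With independent
responses $X_{1i} \sim F_1$ and $X_{2j} \sim F_2$ (real-valued or ordered
categorical), the estimand is the nonparametric relative effect

$$p = P(X_1 < X_2) + \tfrac12 P(X_1 = X_2) = \int F_1\, dF_2,$$

where all distribution functions are used in their *normalised* form
$F = \tfrac12(F^- + F^+)$ so that ties are split evenly. At analysis $k$
with cumulative group sizes $n_{1k}, n_{2k}$ ($N_k = n_{1k} + n_{2k}$), the
estimate is the rank-mean form
$\hat p^{(k)} = (\bar R_{2\cdot} - \bar R_{1\cdot})/N_k + 1/2$ computed from
pooled midranks, which is algebraically identical to the normalised pairwise
double sum (this identity is enforced by test against a brute-force oracle).

Three standardized statistics $Z_k = (\text{effect} - \text{null})
\sqrt{\hat I_k}$ share this estimate and differ only in their information:

* **WMW**: $\hat I_k = N_k n_{1k} n_{2k} / \hat\sigma^2_{Rk}$ with the
  pooled midrank variance $\hat\sigma^2_{Rk} = \sum_{g,i} (R_{gi} -
  \frac{N_k+1}{2})^2 / (N_k - 1)$. For tie-free data this reduces exactly to
  $12\, n_{1k} n_{2k} / (N_k + 1)$. Its null reference requires $F_1 = F_2$.
* **Brunner-Munzel**: $\hat I_k = (\hat\sigma^2_{1k}/n_{1k} +
  \hat\sigma^2_{2k}/n_{2k})^{-1}$, where $\hat\sigma^2_{gk}$ estimates the
  placement variances $V\{F_2(X_1)\}$ and $V\{F_1(X_2)\}$ from the centred
  differences of pooled and within-group midranks, $R_{gi} - R^{(g)}_{gi} -
  \bar R_{g\cdot} + (n_{gk}+1)/2$. The centring constant is the standard
  $(n_{gk}+1)/2$; the implementation verifies the resulting bound
  $\hat\sigma^2_{gk} \le \tfrac14\, n_{gk}/(n_{gk}-1)$ on random data. A
  Satterthwaite-Smith-Welch $t$-approximation with estimated degrees of
  freedom is available as `bm_t`; it changes only the computation of the
  repeated p-value, not the stage levels.
* **log win odds**: $\hat\psi = \operatorname{logit} \hat p$ with
  delta-method information $\{\hat p(1-\hat p)\}^2 \hat I_k^{BM}$. It is the
  same test on a variance-stabilised scale and addresses the BM test's
  finite-sample liberality at the cost of some conservatism.

All three sequences asymptotically follow the canonical joint distribution:
jointly normal, $E(Z_k) = \theta \sqrt{I_k}$, and $\mathrm{Corr}(Z_{k_1},
Z_{k_2}) = \sqrt{I_{k_1}/I_{k_2}}$. The covariance property is verified
empirically in the test suite (50,000 two-stage replicates per statistic,
Fisher-$z$ tolerance $3/\sqrt{n-3}$).

## Error spending and boundary computation

Designs are specified through a spending function $f$, an overall one-sided
level $\alpha$ (default 0.025) and a prespecified maximum information
$I_{\max}$. The implemented spending functions are the Lan-DeMets
O'Brien-Fleming-type $f(t) = \min\{2 - 2\Phi(z_{1-\alpha/2}/\sqrt t),
\alpha\}$ and the Pocock-type $f(t) = \min[\alpha \ln\{1 + (e-1)t\},
\alpha]$. Information fractions $\hat\tau_k = \hat I_k / I_{\max}$ are
capped at 1 before spending; at the final analysis the *remainder* rule
spends $\alpha - f(\hat\tau_{K-1})$ regardless of whether $\hat I_K$
reaches $I_{\max}$, and the covariance of each interim statistic with the
final one uses $I_{\max}$ in place of $\hat I_K$. When fewer analyses than
`K` have been observed, the remainder rule is deliberately *not* applied --
an interim look mid-trial spends $f(\hat\tau_k) - f(\hat\tau_{k-1})$ only,
so earlier stage levels never change as later data arrive (estimated
information is frozen at the stage where it is first computed).

Critical values solve $P(Z_1 < c_1, \dots, Z_{k-1} < c_{k-1}, Z_k \ge c_k)
= \pi_k$ recursively under the canonical correlation. The Markov structure
of the joint distribution lets us propagate the sub-density of the statistic
restricted to the continuation region with one-dimensional Gauss-Legendre
quadrature (default 512 nodes spanning $\pm 8$ standard deviations, domain
truncation error $\approx 6 \times 10^{-16}$) and root-find each $c_k$ by
`uniroot` at tolerance $10^{-10}$. The same recursion evaluates the
$K$-variate orthant probabilities needed by the power formulas, so no
multivariate-normal library and no Monte-Carlo integration is involved; the
solved boundaries are validated against an independent adaptive-quadrature
bivariate normal oracle and by the requirement that the total crossing
probability under the null equals $\alpha$ to $10^{-6}$.

## Repeated p-values and repeated confidence intervals

The repeated p-value at stage $k$ is $p_k = 1 - \Phi(Z_k)$ (or $1 -
F_{\hat\nu_k}(Z_k)$ for `bm_t`); the null is rejected and the trial stopped
the first time $p_k \le \alpha_k$, where $\alpha_k = 1 - \Phi(c_k)$. No
futility boundaries are set.

Repeated confidence intervals invert the two-sided analogue: the same
spending machinery is run at total level $2\alpha'$ ($\alpha' = 0.025$ for
95% intervals) with the symmetric continuation region $|Z_k| < c_k$, and the
interval at stage $k$ is $\hat p \pm c_k/\sqrt{\hat I_k^{BM}}$ on the
probability scale (truncated to $[0,1]$), with the $t$-quantile rescaling
for `bm_t`, or $\hat\psi \pm c_k/\sqrt{\hat I_k^{LWO}}$ mapped through the
inverse logit for the log win odds (always inside $(0,1)$). These sequences
are simultaneously valid across all $K$ analyses. The WMW statistic is not
inverted: its variance is a null-hypothesis quantity, so `gs_monitor(...,
"wmw")` reports decisions and p-values only.

Simultaneous coverage is asymptotically exactly the nominal level; in
finite samples the interval inherits the small-sample behaviour of its
test. At the ordinal planning scenario below ($N = (142, 284)$) the
measured two-stage simultaneous coverage of nominal 95% intervals is about
94.6% for the plain BM interval (the BM test's documented liberality),
95.0% for the $t$-approximate variant and 95.7% for the log win odds
interval; the package's coverage guarantee test therefore exercises the
logit-scale interval, which is conservative by construction.

## Analytic models and power

Power planning requires fully specified arms. Two families are built in,
plus raw per-category probabilities:

* `dist_normal(mean1, sd1, mean2, sd2)`, with closed forms
  $p = \Phi\{(\mu_2 - \mu_1)/\sqrt{\sigma_1^2 + \sigma_2^2}\}$ and
  quadrature (absolute tolerance $10^{-11}$) for the placement variances;
* `dist_latent_beta_ordinal(a1, b1, a2, b2)`: five ordered categories
  obtained by cutting latent $\mathrm{Beta}(a_g, b_g)$ variables at the
  equidistant 0.2 grid; all moments are exact finite sums. The default
  planning model in examples and tests, $\mathrm{Beta}(0.6974797, 1)$ vs
  $\mathrm{Beta}(3, 3)$, has $p = 0.6$ exactly to more than four decimals.

The WMW information under planning uses the mixture $F = tF_1 + (1-t)F_2$
of the pooled data with allocation $t = n_{1k}/N_k$ held constant over
stages, through the finite-sample rank variance
$\sigma^2_R(N) = N\{(N-2)\int F^2 dF - (N-3)/4\} - (N/4)\int (F^+ - F^-)
dF$, which reduces to $N(N+1)/12$ for continuous $F$.

The approximate power of the one-sided test is $1 - \Phi_R(b_1, \dots,
b_K)$ with correlation $\sqrt{N_i/N_j}$ and arguments $b_k =
\sqrt{I_k^{BM}/I_k^{WMW}}\, c_k - \sqrt{I_k^{BM}}(p - 1/2)$ for WMW
(boundaries from the WMW information sequence, shift from the BM
information, since the WMW variance is a null quantity while sampling
variability under the alternative follows the placement variances),
$b_k = c_k - \sqrt{I_k^{BM}}(p - 1/2)$ for BM, and $b_k = c_k -
\sqrt{I_k^{LWO}}\,\psi$ for the log win odds. With $K = 1$ these collapse
to the familiar fixed-sample normal approximations (verified to $10^{-6}$).

`gs_sample_size()` searches the smallest $N_K$ on the feasible lattice --
the step that keeps every cumulative per-arm stage size integral, e.g.
multiples of 4 for $t = 1/2$ and two equal stages, of 6 for $t = 2/3$ --
by geometric bracketing and bisection, exploiting monotonicity of power in
$N_K$.

## Simulation engine

`sim_scenario()`/`run_scenario()` reproduce the operating characteristics
of a design by seeded Monte Carlo. Each replicate draws the full trial once
and reveals it cumulatively, so stage one is a prefix of the final data, as
in an actually accruing trial; all requested test variants are evaluated on
the same replicate. $I_{\max}$ is set to the *true* information of the
generating model at $N_K$ (known truth at planning, not an estimate), and
stage levels are recomputed per replicate from the estimated information
fractions. The generator emulates iid accrual under a fixed allocation with
no drift, no dropout, no covariates and no dependence between stages beyond
accumulation -- passing simulations therefore validate the sequential
machinery under the stated sampling models, not robustness to accrual
patterns or missingness found in real trials.

Two numerical paths produce identical decisions (checked replicate by
replicate in the suite):

* **K = 2**: the stage-2 critical value depends on the design only through
  the stage-1 information fraction, so it is tabulated once per scenario on
  a $\tau$-grid with the exact solver and spline-interpolated per replicate
  (interpolation error $< 10^{-8}$); everything else is vectorized across
  replicates, with ordinal data handled entirely through category counts.
* **K > 2**: boundaries are solved exactly per replicate with a coarser
  48-node rule.

Finite-sample breakdowns are handled by an explicit, counted policy
(`exception_policy()`): a zero variance estimate makes the stage
non-rejecting and spends no alpha; information that decreases between
analyses is clamped (previous value $+10^{-8}$) for spending while the
statistic keeps the raw estimate; a boundary estimate $\hat p \in \{0, 1\}$
makes the log win odds statistic fall back on the BM repeated p-value at
that stage -- under complete separation that p-value itself has zero
variance, so the stage does not reject. All three event types are reported
in the result. These defaults are this package's own choices for rules that
the asymptotic theory does not fix; they matter only in very small samples.

## Problem sizes and reproducibility

The test suite validates stochastic claims at sizes chosen to keep
Monte-Carlo error well below the assertion tolerances while running in a
few minutes: 10,000 replications for the planning-scenario power agreement
(tolerance $\pm 0.012 \approx 3$ SE), 20,000 per spending function for
type-I error control at $N_K = 576$, 50,000 for the canonical covariance
property and 10,000 two-stage trials for simultaneous interval coverage.
`scripts/acceptance.R` runs the headline simulations at the full 100,000
replications. All randomness flows through `set.seed()` on user-supplied
seeds; results are bit-reproducible for a fixed seed and chunk size.

## Known limitations

* All results are asymptotic; below roughly 30 subjects per arm the BM test
  is visibly liberal and the log win odds test conservative, as the
  simulations show.
* The WMW test's variance presumes $F_1 = F_2$; under heteroskedasticity
  its sequential type-I error can be badly off (in either direction,
  depending on the allocation), while BM/LWO remain valid -- this is the
  nonparametric Behrens-Fisher motivation for preferring them when
  confidence intervals for $p$ are wanted.
* No futility bounds, no adaptive sample-size re-estimation, no covariate
  adjustment, no censored or hierarchical composite endpoints, and no
  multi-arm extensions (all-pairwise comparisons of relative effects can be
  nontransitive).
* Ordinal endpoints must arrive as (or be mapped to) numeric codes; any
  order-preserving coding gives identical results by rank invariance, but
  the mapping must be declared explicitly.
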