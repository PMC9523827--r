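# shared fixtures, all generated in code

# the ordinal planning model used throughout (latent Beta arms cut at the
# 0.2 grid, true relative effect 0.6)
planning_model <- function() dist_latent_beta_ordinal(0.6974797, 1, 3, 3)

# a two-stage staged dataset with equal per-arm accrual at each stage
staged_data <- function(x1, x2, k1_frac = 0.5) {
  n1 <- length(x1); n2 <- length(x2)
  m1 <- round(k1_frac * n1); m2 <- round(k1_frac * n2)
  two_arm_stage_data(
    arm = c(rep(1L, n1), rep(2L, n2)),
    value = c(x1, x2),
    stage = c(rep(1:2, c(m1, n1 - m1)), rep(1:2, c(m2, n2 - m2))))
}

# brute-force pairwise estimate of p: (1/(n1 n2)) sum_ij c(x2j, x1i)
brute_force_p <- function(x1, x2) {
  cc <- outer(x2, x1, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cc)
}

# independent bivariate normal upper-tail oracle via adaptive quadrature:
# P(Z1 < c1, Z2 >= c2) with correlation rho
bvn_tail <- function(c1, c2, rho) {
  stats::integrate(function(u)
    stats::dnorm(u) * stats::pnorm((c2 - rho * u) / sqrt(1 - rho^2),
                                   lower.tail = FALSE),
    -Inf, c1, rel.tol = 1e-10)$value
}

# random dataset with ties (integer support keeps ties frequent)
random_tied_sample <- function(n, support = 6L) {
  sample.int(support, n, replace = TRUE) + 0
}
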