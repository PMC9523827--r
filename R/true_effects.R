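# Analytic two-arm distribution models: true relative effect, variance
# components and information, used as ground truth by the power formulas and
# the simulation engine.

new_model <- function(family, ...) {
  structure(list(family = family, ...), class = "gsr_model")
}

#' Two-arm normal model
#'
#' @param mean1,sd1 mean and standard deviation of arm 1.
#' @param mean2,sd2 mean and standard deviation of arm 2.
#' @return A `gsr_model` object.
#' @examples
#' m <- dist_normal(0, 1, 1, 1)
#' true_relative_effect(m)  # pnorm(1 / sqrt(2))
#' @export
dist_normal <- function(mean1 = 0, sd1 = 1, mean2 = 0, sd2 = 1) {
  if (sd1 <= 0 || sd2 <= 0) stop_invalid_input("standard deviations must be > 0")
  new_model("normal", mean = c(mean1, mean2), sd = c(sd1, sd2))
}

#' Two-arm ordinal model via a latent Beta distribution
#'
#' Five ordered categories obtained by cutting a latent `Beta(alpha_g,
#' beta_g)` variable at an equidistant grid on `[0, 1]`: category `k` occurs
#' when the latent value falls in `[cuts[k], cuts[k+1])`.
#'
#' @param alpha1,beta1 latent Beta shapes of arm 1 (both `> 0`).
#' @param alpha2,beta2 latent Beta shapes of arm 2.
#' @param cuts increasing cut grid from 0 to 1; default `0.2 * (0:5)`
#'   (5 categories).
#' @return A `gsr_model` object; sampled values are category codes `1..5`.
#' @export
dist_latent_beta_ordinal <- function(alpha1, beta1, alpha2, beta2,
                                     cuts = 0.2 * (0:5)) {
  if (min(alpha1, beta1, alpha2, beta2) <= 0)
    stop_invalid_input("Beta shape parameters must be > 0")
  if (length(cuts) < 3L || is.unsorted(cuts, strictly = TRUE) ||
      cuts[1] != 0 || cuts[length(cuts)] != 1)
    stop_invalid_input("'cuts' must increase strictly from 0 to 1")
  m <- new_model("latent_beta_ordinal",
                 shape1 = c(alpha1, alpha2), shape2 = c(beta1, beta2),
                 cuts = cuts,
                 pmf1 = ordinal_from_latent_beta(alpha1, beta1, cuts),
                 pmf2 = ordinal_from_latent_beta(alpha2, beta2, cuts))
  check_pmf_model(m)
  m
}

#' Two-arm model from explicit category probabilities
#'
#' @param pmf1,pmf2 per-arm category probabilities on a shared ordered
#'   support `1..length(pmf)`; each must sum to 1.
#' @return A `gsr_model` object.
#' @export
dist_pmf <- function(pmf1, pmf2) {
  if (length(pmf1) != length(pmf2))
    stop_invalid_input("both arms need the same number of categories")
  for (p in list(pmf1, pmf2)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop_invalid_input("category probabilities must be nonnegative and sum to 1")
  }
  m <- new_model("empirical_pmf", pmf1 = pmf1 / sum(pmf1),
                 pmf2 = pmf2 / sum(pmf2))
  check_pmf_model(m)
  m
}

check_pmf_model <- function(m) {
  if (max(m$pmf1) >= 1 - 1e-12 || max(m$pmf2) >= 1 - 1e-12)
    stop_invalid_input("degenerate model: an arm is a one-point distribution")
  p <- true_relative_effect(m)
  if (p <= 0 || p >= 1)
    stop_invalid_input("degenerate model: relative effect on the boundary")
  invisible(m)
}

#' Category probabilities induced by a latent Beta distribution
#'
#' `P(C_k) = BetaCDF(cuts[k+1]) - BetaCDF(cuts[k])`.
#'
#' @param alpha,beta Beta shape parameters (`> 0`).
#' @param cuts increasing cut grid from 0 to 1.
#' @return Probability vector over the categories (sums to 1).
#' @examples
#' ordinal_from_latent_beta(1, 1)  # uniform: 0.2 each
#' @export
ordinal_from_latent_beta <- function(alpha, beta, cuts = 0.2 * (0:5)) {
  if (alpha <= 0 || beta <= 0) stop_invalid_input("shapes must be > 0")
  diff(stats::pbeta(cuts, alpha, beta))
}

is_discrete <- function(model) model$family %in% c("latent_beta_ordinal",
                                                   "empirical_pmf")

# normalised CDF F = (F- + F+)/2 evaluated at the atoms of a pmf
pmf_normalised_cdf <- function(pmf) cumsum(pmf) - pmf / 2

#' True relative effect of a two-arm model
#'
#' `p = P(X1 < X2) + P(X1 = X2)/2 = int F1 dF2` with `F1` the normalised CDF
#' of arm 1. Closed form `pnorm((mean2 - mean1) / sqrt(sd1^2 + sd2^2))` for
#' the normal family, exact finite sums for discrete models.
#'
#' @param model a `gsr_model` object.
#' @export
true_relative_effect <- function(model) {
  stopifnot(inherits(model, "gsr_model"))
  if (model$family == "normal") {
    stats::pnorm((model$mean[2] - model$mean[1]) /
                 sqrt(model$sd[1]^2 + model$sd[2]^2))
  } else {
    sum(pmf_normalised_cdf(model$pmf1) * model$pmf2)
  }
}

#' True Brunner-Munzel variance components
#'
#' `sigma1^2 = V(F2(X1))` and `sigma2^2 = V(F1(X2))` with normalised CDFs;
#' both lie in `[0, 1/4]` and equal `1/12` when the two continuous
#' distributions coincide.
#'
#' @param model a `gsr_model` object.
#' @return Named vector `c(s1sq =, s2sq =)`.
#' @export
true_bm_variances <- function(model) {
  stopifnot(inherits(model, "gsr_model"))
  if (model$family == "normal") {
    c(s1sq = normal_placement_var(model$mean[1], model$sd[1],
                                  model$mean[2], model$sd[2]),
      s2sq = normal_placement_var(model$mean[2], model$sd[2],
                                  model$mean[1], model$sd[1]))
  } else {
    F1 <- pmf_normalised_cdf(model$pmf1)
    F2 <- pmf_normalised_cdf(model$pmf2)
    c(s1sq = sum(model$pmf1 * F2^2) - sum(model$pmf1 * F2)^2,
      s2sq = sum(model$pmf2 * F1^2) - sum(model$pmf2 * F1)^2)
  }
}

# V{Fb(Xa)} for Xa ~ N(ma, sa), Fb the CDF of N(mb, sb), by quadrature
normal_placement_var <- function(ma, sa, mb, sb) {
  m1 <- stats::integrate(function(x)
    stats::dnorm(x, ma, sa) * stats::pnorm(x, mb, sb),
    -Inf, Inf, rel.tol = 1e-11)$value
  m2 <- stats::integrate(function(x)
    stats::dnorm(x, ma, sa) * stats::pnorm(x, mb, sb)^2,
    -Inf, Inf, rel.tol = 1e-11)$value
  max(m2 - m1^2, 0)
}

#' True pooled rank variance of the Wilcoxon-Mann-Whitney statistic
#'
#' Population version under the mixture `F = t F1 + (1 - t) F2` of the whole
#' data (allocation `t = n1/N`):
#' `sigma^2_R = N {(N - 2) int F^2 dF - (N - 3)/4} - (N/4) int (F+ - F-) dF`.
#' Reduces to `N (N + 1) / 12` for continuous `F`.
#'
#' @param model a `gsr_model` object.
#' @param t arm-1 allocation share in (0, 1).
#' @param N total pooled sample size at the analysis.
#' @export
true_wmw_variance <- function(model, t, N) {
  stopifnot(inherits(model, "gsr_model"))
  if (t <= 0 || t >= 1) stop_invalid_input("'t' must lie strictly in (0, 1)")
  if (N < 2) stop_invalid_input("'N' must be at least 2")
  if (model$family == "normal") return(N * (N + 1) / 12)
  pm <- t * model$pmf1 + (1 - t) * model$pmf2
  Fm <- pmf_normalised_cdf(pm)
  int_F2_dF <- sum(Fm^2 * pm)
  int_gap_dF <- sum(pm * pm)  # F+ - F- equals the atom mass
  N * ((N - 2) * int_F2_dF - (N - 3) / 4) - (N / 4) * int_gap_dF
}

#' True information of a test at given group sizes
#'
#' Wilcoxon-Mann-Whitney: `N n1 n2 / sigma^2_R(N)` with the mixture rank
#' variance; Brunner-Munzel: `(sigma1^2/n1 + sigma2^2/n2)^(-1)`; log win
#' odds: `{p (1 - p)}^2` times the Brunner-Munzel information. Monotone
#' increasing in both group sizes.
#'
#' @param model a `gsr_model` object.
#' @param method one of `"wmw"`, `"bm"`, `"lwo"` (the t-approximate
#'   Brunner-Munzel test shares the `"bm"` information).
#' @param n1,n2 group sizes.
#' @export
true_information <- function(model, method, n1, n2) {
  stopifnot(inherits(model, "gsr_model"))
  method <- match.arg(method, c("wmw", "bm", "bm_t", "lwo"))
  if (n1 < 1 || n2 < 1) stop_invalid_input("group sizes must be >= 1")
  N <- n1 + n2
  if (method == "wmw")
    return(N * n1 * n2 / true_wmw_variance(model, n1 / N, N))
  v <- true_bm_variances(model)
  info_bm <- 1 / (v[["s1sq"]] / n1 + v[["s2sq"]] / n2)
  if (method %in% c("bm", "bm_t")) return(info_bm)
  p <- true_relative_effect(model)
  (p * (1 - p))^2 * info_bm
}

#' Draw a sample from one arm of a model
#'
#' Normal arms draw `rnorm`; ordinal arms draw the latent Beta variable and
#' bin it at the cut grid, returning category codes; pmf arms sample the
#' categories directly. Reproducible under `set.seed()`.
#'
#' @param model a `gsr_model` object.
#' @param n number of draws (`>= 0`).
#' @param arm arm label, 1 or 2.
#' @return Numeric vector of length `n`.
#' @export
sample_model <- function(model, n, arm) {
  stopifnot(inherits(model, "gsr_model"), arm %in% c(1, 2))
  if (n < 0) stop_invalid_input("'n' must be nonnegative")
  if (n == 0) return(numeric(0))
  if (model$family == "normal")
    return(stats::rnorm(n, model$mean[arm], model$sd[arm]))
  if (model$family == "latent_beta_ordinal") {
    y <- stats::rbeta(n, model$shape1[arm], model$shape2[arm])
    return(as.numeric(findInterval(y, model$cuts,
                                   rightmost.closed = TRUE,
                                   all.inside = TRUE)))
  }
  pmf <- if (arm == 1) model$pmf1 else model$pmf2
  as.numeric(sample.int(length(pmf), n, replace = TRUE, prob = pmf))
}

#' @export
print.gsr_model <- function(x, ...) {
  if (x$family == "normal") {
    cat(sprintf("Two-arm normal model: N(%g, %g^2) vs N(%g, %g^2)\n",
                x$mean[1], x$sd[1], x$mean[2], x$sd[2]))
  } else if (x$family == "latent_beta_ordinal") {
    cat(sprintf(
      "Two-arm latent-Beta ordinal model (%d categories):\n  Beta(%g, %g) vs Beta(%g, %g)\n",
      length(x$pmf1), x$shape1[1], x$shape2[1], x$shape1[2], x$shape2[2]))
  } else {
    cat(sprintf("Two-arm categorical model (%d categories)\n", length(x$pmf1)))
  }
  cat(sprintf("  true relative effect p = %.6f\n", true_relative_effect(x)))
  invisible(x)
}
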