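# Rank estimators for the Mann-Whitney parameter p = P(X1 < X2) + P(X1 = X2)/2
# and the per-stage variance / information estimators of the three tests
# (Wilcoxon-Mann-Whitney, Brunner-Munzel, log win odds).

#' Midranks of a sample
#'
#' Midrank of `x[i]`: `1/2 + sum_j c(x[i], x[j])` with the pairwise score
#' `c(a, b)` equal to 0, 1/2, 1 for `a < b`, `a == b`, `a > b`. Tied values
#' share the average of their ordinary ranks; the midranks always sum to
#' `n (n + 1) / 2`.
#'
#' @param values nonempty numeric vector.
#' @return Numeric vector of midranks.
#' @examples
#' midranks(c(1, 2, 2, 7))  # 1, 2.5, 2.5, 4
#' @export
midranks <- function(values) {
  if (length(values) == 0L) stop_invalid_input("empty input to midranks()")
  if (!is.numeric(values) || anyNA(values))
    stop_invalid_input("midranks() needs numeric values without NA")
  rank(values, ties.method = "average")
}

#' Estimated relative effect p-hat at an analysis
#'
#' Estimates `p = P(X1 < X2) + P(X1 = X2)/2` from the cumulative data at
#' analysis `stage` via the rank-mean representation
#' `p^ = (Rbar2 - Rbar1)/N + 1/2`, identical to the normalised pairwise
#' double sum over all `n1 * n2` pairs.
#'
#' @param data a [two_arm_stage_data] object.
#' @param stage analysis index.
#' @return Estimate in `[0, 1]`; swapping the arms maps it to its complement.
#' @export
relative_effect <- function(data, stage = data$K) {
  x1 <- stage_values(data, stage, 1L)
  x2 <- stage_values(data, stage, 2L)
  if (length(x1) == 0L || length(x2) == 0L)
    stop_invalid_input("both arms need observations at the analyzed stage")
  r <- midranks(c(x1, x2))
  n1 <- length(x1)
  (mean(r[-seq_len(n1)]) - mean(r[seq_len(n1)])) / (n1 + length(x2)) + 0.5
}

#' Pooled rank variance of the Wilcoxon-Mann-Whitney statistic
#'
#' `sigma^2_R = sum_i (R_i - (N+1)/2)^2 / (N - 1)` over the pooled midranks.
#' Equals `N (N + 1) / 12` when all pooled values are distinct and 0 when all
#' are identical.
#'
#' @param pooled_ranks midranks of the pooled sample at the analysis.
#' @return Nonnegative variance estimate.
#' @export
wmw_variance <- function(pooled_ranks) {
  N <- length(pooled_ranks)
  if (N < 2L) stop_invalid_input("need at least two pooled observations")
  sum((pooled_ranks - (N + 1) / 2)^2) / (N - 1)
}

#' Information of the Wilcoxon-Mann-Whitney statistic
#'
#' `I = N n1 n2 / sigma^2_R`; for tie-free data this equals
#' `12 n1 n2 / (N + 1)` exactly.
#'
#' @param n1,n2 cumulative group sizes.
#' @param sigmaR2 pooled rank variance, see [wmw_variance()].
#' @export
wmw_information <- function(n1, n2, sigmaR2) {
  if (n1 < 2L || n2 < 2L)
    stop_invalid_input("need at least two observations per arm")
  if (sigmaR2 <= 0)
    stop_degenerate_variance("pooled rank variance is zero")
  (n1 + n2) * n1 * n2 / sigmaR2
}

# pooled and within-group midranks plus group means at one analysis
rank_summary <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  r <- midranks(c(x1, x2))
  r1 <- r[seq_len(n1)]
  r2 <- r[n1 + seq_len(n2)]
  list(n1 = n1, n2 = n2, N = n1 + n2,
       pooled1 = r1, pooled2 = r2,
       within1 = midranks(x1), within2 = midranks(x2),
       mean1 = mean(r1), mean2 = mean(r2))
}

#' Brunner-Munzel variance components
#'
#' Rank-based estimators of `sigma1^2 = V(F2(X11))` and
#' `sigma2^2 = V(F1(X21))` from the placements
#' `R_gi - R_gi(g) - Rbar_g + (n_g + 1)/2`, where `R_gi` is the pooled and
#' `R_gi(g)` the within-group midrank. Both are invariant under strictly
#' increasing transformations of the data.
#'
#' @inheritParams relative_effect
#' @return Named numeric vector `c(s1sq =, s2sq =)`.
#' @export
bm_variance_components <- function(data, stage = data$K) {
  x1 <- stage_values(data, stage, 1L)
  x2 <- stage_values(data, stage, 2L)
  rs <- rank_summary_checked(x1, x2)
  bm_components_from_ranks(rs)
}

rank_summary_checked <- function(x1, x2) {
  if (length(x1) < 2L || length(x2) < 2L)
    stop_invalid_input("need at least two observations per arm")
  rank_summary(x1, x2)
}

bm_components_from_ranks <- function(rs) {
  d1 <- rs$pooled1 - rs$within1 - rs$mean1 + (rs$n1 + 1) / 2
  d2 <- rs$pooled2 - rs$within2 - rs$mean2 + (rs$n2 + 1) / 2
  c(s1sq = sum(d1^2) / (rs$n2^2 * (rs$n1 - 1)),
    s2sq = sum(d2^2) / (rs$n1^2 * (rs$n2 - 1)))
}

#' Information of the Brunner-Munzel statistic
#'
#' `I = (s1sq/n1 + s2sq/n2)^(-1)`.
#'
#' @param n1,n2 cumulative group sizes.
#' @param s1sq,s2sq variance components, see [bm_variance_components()].
#' @export
bm_information <- function(n1, n2, s1sq, s2sq) {
  v <- s1sq / n1 + s2sq / n2
  if (v <= 0)
    stop_degenerate_variance("both Brunner-Munzel variance components are zero")
  1 / v
}

#' Satterthwaite-Smith-Welch degrees of freedom
#'
#' `nu = (s1sq/n1 + s2sq/n2)^2 / (s1sq^2 / (n1^2 (n1-1)) +
#' s2sq^2 / (n2^2 (n2-1)))`; collapses to `2 (n - 1)` for equal group sizes
#' and equal components.
#'
#' @inheritParams bm_information
#' @export
bm_degrees_of_freedom <- function(n1, n2, s1sq, s2sq) {
  den <- s1sq^2 / (n1^2 * (n1 - 1)) + s2sq^2 / (n2^2 * (n2 - 1))
  if (den <= 0)
    stop_degenerate_variance("degrees of freedom undefined: zero variance")
  (s1sq / n1 + s2sq / n2)^2 / den
}

#' Log win odds and its information
#'
#' Delta-method transform of the relative effect: `psi = logit(p^)` with
#' information `{p^ (1 - p^)}^2` times the Brunner-Munzel information.
#'
#' @param p_hat estimated relative effect, strictly inside (0, 1).
#' @param info_bm Brunner-Munzel information at the same analysis.
#' @return List with elements `psi` and `info`.
#' @export
lwo_effect_and_information <- function(p_hat, info_bm) {
  if (p_hat <= 0 || p_hat >= 1)
    stop_boundary_effect("p-hat on the boundary of [0, 1]: logit undefined")
  if (info_bm <= 0) stop_invalid_input("info_bm must be positive")
  list(psi = stats::qlogis(p_hat), info = (p_hat * (1 - p_hat))^2 * info_bm)
}

#' Standardized group sequential statistic
#'
#' `Z = (effect - null) * sqrt(info)`, the common form of all three tests
#' (null 1/2 on the p-scale, 0 on the log win odds scale).
#'
#' @param effect point estimate.
#' @param null_value null value of the effect.
#' @param info estimated information.
#' @export
z_statistic <- function(effect, null_value, info) {
  if (!is.finite(info) || info <= 0)
    stop_invalid_input("information must be positive and finite")
  (effect - null_value) * sqrt(info)
}

#' All per-stage estimates in one pass
#'
#' Computes, from the cumulative data at one analysis, the relative effect,
#' the pooled rank variance, the Brunner-Munzel variance components, the
#' information of all three tests, the t-approximation degrees of freedom and
#' the standardized statistics. Degenerate quantities are reported as `NA`
#' with the corresponding flag set rather than raising, so that monitoring
#' code can apply its exception policy.
#'
#' @inheritParams relative_effect
#' @return List with elements `stage`, `n1`, `n2`, `p_hat`, `psi_hat`,
#'   `sigmaR2`, `s1sq`, `s2sq`, `info_wmw`, `info_bm`, `info_lwo`, `df`,
#'   `z_wmw`, `z_bm`, `z_lwo`, `degenerate_wmw`, `degenerate_bm`,
#'   `boundary_effect`.
#' @export
stage_estimate <- function(data, stage = data$K) {
  x1 <- stage_values(data, stage, 1L)
  x2 <- stage_values(data, stage, 2L)
  rs <- rank_summary_checked(x1, x2)
  est <- stage_estimate_from_ranks(rs)
  est$stage <- stage
  est
}

# core computation shared with the simulation engine (already has ranks)
stage_estimate_from_ranks <- function(rs) {
  N <- rs$N
  p_hat <- (rs$mean2 - rs$mean1) / N + 0.5
  sigmaR2 <- sum((c(rs$pooled1, rs$pooled2) - (N + 1) / 2)^2) / (N - 1)
  cmp <- bm_components_from_ranks(rs)
  s1sq <- cmp[["s1sq"]]; s2sq <- cmp[["s2sq"]]
  vsum <- s1sq / rs$n1 + s2sq / rs$n2

  degenerate_wmw <- sigmaR2 <= 0
  degenerate_bm <- vsum <= 0
  boundary <- p_hat <= 0 || p_hat >= 1

  info_wmw <- if (degenerate_wmw) NA_real_ else N * rs$n1 * rs$n2 / sigmaR2
  info_bm <- if (degenerate_bm) NA_real_ else 1 / vsum
  df <- if (degenerate_bm) NA_real_ else
    vsum^2 / (s1sq^2 / (rs$n1^2 * (rs$n1 - 1)) +
              s2sq^2 / (rs$n2^2 * (rs$n2 - 1)))
  psi_hat <- if (boundary) NA_real_ else stats::qlogis(p_hat)
  info_lwo <- if (boundary || degenerate_bm) NA_real_ else
    (p_hat * (1 - p_hat))^2 * info_bm

  list(stage = NA_integer_, n1 = rs$n1, n2 = rs$n2,
       p_hat = p_hat, psi_hat = psi_hat,
       sigmaR2 = sigmaR2, s1sq = s1sq, s2sq = s2sq,
       info_wmw = info_wmw, info_bm = info_bm, info_lwo = info_lwo, df = df,
       z_wmw = if (degenerate_wmw) NA_real_ else (p_hat - 0.5) * sqrt(info_wmw),
       z_bm = if (degenerate_bm) NA_real_ else (p_hat - 0.5) * sqrt(info_bm),
       z_lwo = if (boundary || degenerate_bm) NA_real_ else
         psi_hat * sqrt(info_lwo),
       degenerate_wmw = degenerate_wmw, degenerate_bm = degenerate_bm,
       boundary_effect = boundary)
}
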