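# Sequential monitoring: per-stage decisions, repeated p-values and
# repeated confidence intervals for accumulating two-arm data.

method_choices <- c("wmw", "bm", "bm_t", "lwo")

# effect / null / information / df of one method from a stage_estimate()
method_components <- function(est, method) {
  switch(method,
    wmw = list(effect = est$p_hat, null = 0.5, info = est$info_wmw,
               df = NULL, degenerate = est$degenerate_wmw),
    bm = list(effect = est$p_hat, null = 0.5, info = est$info_bm,
              df = NULL, degenerate = est$degenerate_bm),
    bm_t = list(effect = est$p_hat, null = 0.5, info = est$info_bm,
                df = est$df, degenerate = est$degenerate_bm),
    lwo = list(effect = est$psi_hat, null = 0, info = est$info_lwo,
               df = NULL,
               degenerate = est$degenerate_bm || est$boundary_effect))
}

#' Monitor a group sequential trial
#'
#' Processes the analyses of a staged two-arm data set in order: estimates
#' the relative effect, computes the chosen test's information (frozen at
#' the stage where it is first estimated), derives the error-spending stage
#' level and critical value, the repeated p-value and -- for the invertible
#' tests -- the repeated confidence interval, and stops at the first
#' rejection. No futility stopping is performed.
#'
#' @param data a [two_arm_stage_data] object.
#' @param design a one-sided [sequential_design()] object (efficacy testing
#'   of `H0: p <= 1/2`).
#' @param method `"wmw"`, `"bm"`, `"bm_t"` (Satterthwaite-Smith-Welch
#'   t-approximation) or `"lwo"`.
#' @param ci_level level of the repeated confidence intervals (default 0.95,
#'   two-sided, constructed from the same spending machinery); intervals are
#'   produced for `"bm"`, `"bm_t"` and `"lwo"` only, since the
#'   Wilcoxon-Mann-Whitney statistic is not a pivot for `p` unless
#'   `F1 = F2`.
#' @param nodes Gauss-Legendre nodes for the boundary recursion.
#' @return A data frame of class `gsr_monitoring` with one row per evaluated
#'   stage: `stage`, `n1`, `n2`, `p_hat`, `info`, `info_fraction`,
#'   `stage_level`, `z`, `p_value`, `reject`, `ci_lo`, `ci_hi`, `df`.
#'   Stages after the first rejection are not evaluated.
#' @export
gs_monitor <- function(data, design, method = method_choices,
                       ci_level = 0.95, nodes = 512L) {
  stopifnot(inherits(data, "two_arm_stage_data"),
            inherits(design, "gsr_design"))
  method <- match.arg(method)
  if (design$sided != "one")
    stop_invalid_input("monitoring expects a one-sided efficacy design")
  counts <- stage_counts(data)
  k_obs <- min(max(data$stage), design$K)  # analyses with new data so far
  if (any(counts[seq_len(k_obs), c("n1", "n2")] < 2L))
    stop_invalid_input("each arm needs >= 2 cumulative observations at every analyzed stage")

  ests <- lapply(seq_len(k_obs), function(k) stage_estimate(data, k))
  comps <- lapply(ests, method_components, method = method)
  info <- vapply(comps, `[[`, numeric(1), "info")
  if (anyNA(info))
    stop_degenerate_variance(
      sprintf("degenerate %s information at stage %d",
              method, which(is.na(info))[1]))
  if (k_obs > 1L && any(diff(info) <= 0))
    stop_monotonicity("estimated information decreased between analyses")

  # stage levels depend only on earlier information, so one call suffices;
  # with fewer observed analyses than K the remainder rule stays pending
  bnd <- boundaries(design, info, nodes = nodes)
  ci_design <- sequential_design(design$K, 1 - ci_level, design$spending,
                                 design$imax, sided = "two")
  bnd_ci <- boundaries(ci_design, info, nodes = nodes)

  rows <- vector("list", k_obs)
  for (k in seq_len(k_obs)) {
    est <- ests[[k]]; cmp <- comps[[k]]
    z <- (cmp$effect - cmp$null) * sqrt(cmp$info)
    pval <- repeated_p_value(z, cmp$df)
    reject <- pval <= bnd$levels[k]
    ci <- if (method == "wmw") c(NA_real_, NA_real_) else
      repeated_ci(est, bnd_ci, k, method)
    rows[[k]] <- data.frame(
      stage = k, n1 = est$n1, n2 = est$n2, p_hat = est$p_hat,
      info = cmp$info, info_fraction = bnd$tau[k],
      stage_level = bnd$levels[k], z = z, p_value = pval, reject = reject,
      ci_lo = ci[1], ci_hi = ci[2],
      df = if (is.null(cmp$df)) NA_real_ else cmp$df)
    if (reject) break
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  attr(out, "design") <- design
  attr(out, "method") <- method
  attr(out, "boundaries") <- bnd
  attr(out, "ci_boundaries") <- bnd_ci
  class(out) <- c("gsr_monitoring", "data.frame")
  out
}

#' Repeated confidence interval at one analysis
#'
#' Inverts the two-sided analogue of the sequential test: on the p-scale the
#' interval is `p^ +- c_k / sqrt(I_bm)` truncated to `[0, 1]`; the
#' t-variant rescales the critical value through the t-quantile with the
#' estimated degrees of freedom; the log win odds interval is
#' `psi^ +- c_k / sqrt(I_lwo)` mapped back through the inverse logit and
#' therefore always lies inside `(0, 1)`. Valid simultaneously over all
#' analyses of the design.
#'
#' @param estimate a [stage_estimate()] result.
#' @param boundary a two-sided `gsr_boundaries` object (see [boundaries()]).
#' @param stage analysis index into `boundary`.
#' @param method `"bm"`, `"bm_t"` or `"lwo"`.
#' @return `c(lo, hi)` on the p-scale.
#' @export
repeated_ci <- function(estimate, boundary, stage,
                        method = c("bm", "bm_t", "lwo")) {
  method <- match.arg(method)
  stopifnot(inherits(boundary, "gsr_boundaries"))
  ck <- boundary$crit[stage]
  if (method == "lwo") {
    if (estimate$boundary_effect)
      stop_boundary_effect("p-hat on the boundary: no log win odds interval")
    if (is.na(estimate$info_lwo) || estimate$info_lwo <= 0)
      stop_degenerate_variance("nonpositive log win odds information")
    hw <- ck / sqrt(estimate$info_lwo)
    return(stats::plogis(estimate$psi_hat + c(-hw, hw)))
  }
  if (is.na(estimate$info_bm) || estimate$info_bm <= 0)
    stop_degenerate_variance("nonpositive Brunner-Munzel information")
  mult <- if (method == "bm_t")
    stats::qt(stats::pnorm(ck), df = estimate$df) else ck
  hw <- mult / sqrt(estimate$info_bm)
  pmin(pmax(estimate$p_hat + c(-hw, hw), 0), 1)
}

#' @export
print.gsr_monitoring <- function(x, ...) {
  method <- attr(x, "method")
  design <- attr(x, "design")
  cat(sprintf("Group sequential monitoring (%s test, %s spending, alpha = %g)\n",
              toupper(method), design$spending, design$alpha))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 5))
  print(df, row.names = FALSE)
  if (any(x$reject))
    cat(sprintf("H0 rejected at stage %d.\n", x$stage[which(x$reject)[1]]))
  else cat("No rejection at the analyzed stages.\n")
  invisible(x)
}
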