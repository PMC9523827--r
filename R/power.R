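# Approximate power of the group sequential WMW / Brunner-Munzel / log win
# odds tests under a specified alternative, and rank-based sample-size
# search.

#' Approximate power of a group sequential rank test
#'
#' Evaluates the multivariate-normal power approximation for the one-sided
#' test of `H0: p <= 1/2` against `H1: p > 1/2` under a fully specified
#' two-arm model. Critical values `c_k` come from the error-spending
#' machinery with the test's own true information sequence; the power is
#' `1 - Phi_R(b_1, ..., b_K)` with correlation `sqrt(N_i / N_j)` and
#' arguments
#' `b_k = sqrt(I_k^BM / I_k^WMW) c_k - sqrt(I_k^BM) (p - 1/2)` (WMW),
#' `b_k = c_k - sqrt(I_k^BM) (p - 1/2)` (Brunner-Munzel), or
#' `b_k = c_k - sqrt(I_k^LWO) psi` (log win odds), where the WMW information
#' uses the mixture rank variance of the pooled null distribution and the
#' Brunner-Munzel information the alternative's placement variances.
#'
#' @param model a `gsr_model` under the alternative (`p > 1/2`).
#' @param method `"wmw"`, `"bm"` or `"lwo"`.
#' @param t arm-1 allocation share `n1k / Nk`, constant over stages.
#' @param stage_n strictly increasing cumulative total sample sizes
#'   `N_1 < ... < N_K`.
#' @param spending error spending function kind.
#' @param alpha one-sided overall level.
#' @param nodes Gauss-Legendre nodes for the boundary recursion.
#' @return List of class `gsr_power`: `power`, `crit`, `info` (the test's
#'   true information per stage), `p`, `psi`, plus the call parameters.
#' @examples
#' m <- dist_latent_beta_ordinal(0.6974797, 1, 3, 3)
#' gs_power(m, "wmw", t = 0.5, stage_n = c(142, 284), spending = "pocock")
#' @export
gs_power <- function(model, method = c("wmw", "bm", "lwo"), t, stage_n,
                     spending = c("obrien_fleming", "pocock"),
                     alpha = 0.025, nodes = 512L) {
  method <- match.arg(method)
  spending <- match.arg(spending)
  stopifnot(inherits(model, "gsr_model"))
  if (t <= 0 || t >= 1) stop_invalid_input("'t' must lie strictly in (0, 1)")
  K <- length(stage_n)
  if (K < 1L || (K > 1L && any(diff(stage_n) <= 0)))
    stop_invalid_input("'stage_n' must be strictly increasing")
  p <- true_relative_effect(model)
  if (p <= 0.5)
    stop_invalid_input("one-sided power needs true p > 1/2 (swap the arms otherwise)")

  n1 <- t * stage_n
  n2 <- (1 - t) * stage_n
  info_bm <- vapply(seq_len(K), function(k)
    true_information(model, "bm", n1[k], n2[k]), numeric(1))
  psi <- log(p / (1 - p))

  if (method == "wmw") {
    info_wmw <- vapply(seq_len(K), function(k)
      true_information(model, "wmw", n1[k], n2[k]), numeric(1))
    des <- sequential_design(K, alpha, spending, imax = info_wmw[K])
    cc <- boundaries(des, info_wmw, nodes = nodes)$crit
    b <- sqrt(info_bm / info_wmw) * cc - sqrt(info_bm) * (p - 0.5)
    info <- info_wmw
  } else {
    info <- if (method == "bm") info_bm else (p * (1 - p))^2 * info_bm
    des <- sequential_design(K, alpha, spending, imax = info[K])
    cc <- boundaries(des, info, nodes = nodes)$crit
    b <- if (method == "bm") cc - sqrt(info_bm) * (p - 0.5)
         else cc - sqrt(info) * psi
  }
  pw <- 1 - gs_joint_lower(b, jinfo = stage_n, nodes = nodes)
  structure(list(power = pw, crit = cc, info = info, p = p, psi = psi,
                 method = method, spending = spending, alpha = alpha,
                 t = t, stage_n = stage_n),
            class = "gsr_power")
}

#' @export
print.gsr_power <- function(x, ...) {
  cat(sprintf(
    "Approximate power of the group sequential %s test: %.5f\n",
    toupper(x$method), x$power))
  cat(sprintf("  p = %.4f, t = %.3f, %s spending, alpha = %g, N = (%s)\n",
              x$p, x$t, x$spending, x$alpha,
              paste(x$stage_n, collapse = ", ")))
  invisible(x)
}

# smallest stage-size step so that every cumulative t*N_k and (1-t)*N_k is
# an integer (e.g. 4 for t = 1/2 and two equal stages, 6 for t = 2/3)
stage_size_unit <- function(t, fractions, max_unit = 100000L) {
  for (m in seq_len(max_unit)) {
    nk <- fractions * m
    if (all(abs(nk - round(nk)) < 1e-9)) {
      n1 <- t * round(nk)
      if (all(abs(n1 - round(n1)) < 1e-9)) return(m)
    }
  }
  stop_invalid_input("no feasible integer stage sizes for this allocation")
}

#' Sample-size search for a target power
#'
#' Finds the smallest maximum sample size `N_K` on the feasible integer
#' lattice (all cumulative per-arm stage sizes integral under the allocation
#' `t` and stage fractions) whose approximate power reaches the target.
#'
#' @inheritParams gs_power
#' @param target_power required power, in `(alpha, 1)`.
#' @param K number of analyses.
#' @param fractions cumulative stage fractions of `N_K` (default equally
#'   spaced, e.g. `c(0.5, 1)` for `K = 2`).
#' @param n_max search cap on `N_K`.
#' @return List of class `gsr_samplesize`: `n_total` (`N_K`), `stage_n`,
#'   `power` (achieved), and the call parameters.
#' @examples
#' m <- dist_latent_beta_ordinal(0.6974797, 1, 3, 3)
#' gs_sample_size(m, "wmw", t = 0.5, target_power = 0.8, K = 2,
#'                spending = "pocock")  # N = (142, 284)
#' @export
gs_sample_size <- function(model, method = c("wmw", "bm", "lwo"), t,
                           target_power = 0.8, K = 2L,
                           fractions = seq_len(K) / K,
                           spending = c("obrien_fleming", "pocock"),
                           alpha = 0.025, n_max = 100000L, nodes = 512L) {
  method <- match.arg(method)
  spending <- match.arg(spending)
  if (target_power <= alpha || target_power >= 1)
    stop_invalid_input("'target_power' must lie in (alpha, 1)")
  if (length(fractions) != K || fractions[K] != 1 ||
      (K > 1L && any(diff(fractions) <= 0)))
    stop_invalid_input("'fractions' must increase to 1 with one entry per stage")
  unit <- stage_size_unit(t, fractions)
  pw_at <- function(NK) {
    sn <- round(fractions * NK)
    if (any(pmin(t, 1 - t) * sn[1] < 2)) return(NA_real_)
    gs_power(model, method, t, sn, spending, alpha, nodes = nodes)$power
  }
  # smallest feasible lattice point, then geometric bracketing + bisection
  lo <- unit
  while (lo <= n_max && is.na(pw_at(lo))) lo <- lo + unit
  hi <- lo
  while (hi <= n_max && pw_at(hi) < target_power) hi <- 2 * hi
  hi <- min(hi, (n_max %/% unit) * unit)
  if (pw_at(hi) < target_power)
    stop_search_bound(sprintf("target power %.3f not reachable below N = %d",
                              target_power, n_max))
  lo_i <- lo %/% unit; hi_i <- hi %/% unit
  while (hi_i - lo_i > 1L) {
    mid <- (lo_i + hi_i) %/% 2
    if (!is.na(pw_at(mid * unit)) && pw_at(mid * unit) >= target_power)
      hi_i <- mid
    else lo_i <- mid
  }
  NK <- hi_i * unit
  if (!is.na(pw_at(lo_i * unit)) && pw_at(lo_i * unit) >= target_power)
    NK <- lo_i * unit
  sn <- round(fractions * NK)
  structure(list(n_total = NK, stage_n = sn, power = pw_at(NK),
                 method = method, spending = spending, alpha = alpha, t = t,
                 target_power = target_power),
            class = "gsr_samplesize")
}

#' @export
print.gsr_samplesize <- function(x, ...) {
  cat(sprintf(
    "Sample size for the group sequential %s test (target power %.2f):\n",
    toupper(x$method), x$target_power))
  cat(sprintf("  N = (%s), achieved power %.5f (t = %.3f, %s spending)\n",
              paste(x$stage_n, collapse = ", "), x$power, x$t, x$spending))
  invisible(x)
}
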