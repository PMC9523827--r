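# Error-spending group sequential designs: spending functions, stage levels
# and critical values under the canonical joint distribution, computed by
# recursive Gauss-Legendre integration (deterministic, no Monte Carlo).

#' Group sequential design
#'
#' @param K number of planned analyses (`>= 1`).
#' @param alpha overall type-I error level; one-sided efficacy testing uses
#'   the default 0.025, the two-sided variant (used for repeated confidence
#'   intervals) interprets `alpha` as the total two-tailed error.
#' @param spending `"obrien_fleming"` (Lan-DeMets O'Brien-Fleming-type) or
#'   `"pocock"` spending function.
#' @param imax prespecified maximum information `Imax`, the denominator of
#'   the information fractions during monitoring.
#' @param sided `"one"` (upper-tailed) or `"two"` (symmetric).
#' @return An object of class `gsr_design`.
#' @examples
#' sequential_design(K = 2, alpha = 0.025, spending = "pocock", imax = 100)
#' @export
sequential_design <- function(K, alpha = 0.025,
                              spending = c("obrien_fleming", "pocock"),
                              imax, sided = c("one", "two")) {
  spending <- match.arg(spending)
  sided <- match.arg(sided)
  K <- as.integer(K)
  if (K < 1L) stop_invalid_input("'K' must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop_invalid_input("'alpha' must be in (0, 1)")
  if (imax <= 0) stop_invalid_input("'imax' must be positive")
  structure(list(K = K, alpha = alpha, spending = spending, imax = imax,
                 sided = sided),
            class = "gsr_design")
}

#' @export
print.gsr_design <- function(x, ...) {
  cat(sprintf(
    "Group sequential design: K = %d, alpha = %g (%s-sided), %s spending, Imax = %g\n",
    x$K, x$alpha, x$sided, x$spending, x$imax))
  invisible(x)
}

#' Error spending function value
#'
#' O'Brien-Fleming-type: `f(t) = min{2 - 2 Phi(z_{1-alpha/2} / sqrt(t)),
#' alpha}`; Pocock-type: `f(t) = min[alpha ln{1 + (e - 1) t}, alpha]`. Both
#' are nondecreasing with `f(0) = 0` and `f(t) = alpha` for `t >= 1`.
#'
#' @param kind `"obrien_fleming"` or `"pocock"`.
#' @param alpha overall level.
#' @param t information fraction(s), `>= 0` (vectorized).
#' @export
spending_value <- function(kind = c("obrien_fleming", "pocock"), alpha, t) {
  kind <- match.arg(kind)
  if (any(t < 0)) stop_invalid_input("information fraction must be >= 0")
  out <- if (kind == "pocock") {
    alpha * log(1 + (exp(1) - 1) * t)
  } else {
    ifelse(t > 0,
           2 - 2 * stats::pnorm(stats::qnorm(1 - alpha / 2) / sqrt(t)),
           0)
  }
  pmin(out, alpha)
}

#' Alpha increments spent per stage
#'
#' `pi_1 = f(tau_1)`, `pi_k = f(tau_k) - f(tau_{k-1})` for interim stages and
#' `pi_K = alpha - f(tau_{K-1})`: whatever alpha is still available is spent
#' at the final analysis regardless of whether the observed information
#' reaches `Imax`. Fractions are capped at 1 before spending.
#'
#' @param design a [sequential_design()] object.
#' @param observed_info estimated information per analysis, strictly
#'   increasing; length `K` for a complete trial, or fewer entries while
#'   monitoring is still underway (the remainder rule then does not yet
#'   apply, since later analyses are pending).
#' @return Numeric vector of increments; sums exactly to `alpha` when all
#'   `K` analyses are supplied.
#' @export
spend_increments <- function(design, observed_info) {
  stopifnot(inherits(design, "gsr_design"))
  K <- design$K
  k_obs <- length(observed_info)
  if (k_obs < 1L || k_obs > K)
    stop_invalid_input("'observed_info' needs between 1 and K entries")
  if (any(!is.finite(observed_info)) || any(observed_info <= 0))
    stop_invalid_input("information values must be positive and finite")
  if (k_obs > 1L && any(diff(observed_info) <= 0))
    stop_monotonicity("estimated information must be strictly increasing")
  if (K == 1L) return(design$alpha)
  tau <- pmin(observed_info / design$imax, 1)
  fval <- spending_value(design$spending, design$alpha, tau)
  incr <- c(fval[1], diff(fval))
  if (k_obs == K) incr[K] <- design$alpha - fval[K - 1]
  pmax(incr, 0)
}

# Gauss-Legendre nodes/weights on [a, b]
gl_rule <- function(n, a, b) {
  r <- pracma::gaussLegendre(n, a, b)
  list(x = r$x, w = r$w)
}

# Recursive boundary solver under the canonical Markov structure.
# incr: alpha increments per stage; jinfo: strictly increasing pseudo-
# information driving the correlations sqrt(jinfo[i]/jinfo[j]); sided:
# continuation region (-Inf, c_k) or (-c_k, c_k), truncated at +-zmax.
gs_solve_boundaries <- function(incr, jinfo, sided = "one",
                                nodes = 512L, zmax = 8) {
  K <- length(incr)
  if (K != length(jinfo))
    stop_invalid_input("increments and information must have equal length")
  if (K > 1L && any(diff(jinfo) <= 0))
    stop_monotonicity("pseudo-information must be strictly increasing")
  crit <- numeric(K)
  achieved <- numeric(K)
  u <- NULL; w <- NULL; f <- NULL   # sub-density of Z_{k} on its continuation
  for (k in seq_len(K)) {
    if (k == 1L) {
      tailp <- function(c) {
        p <- stats::pnorm(c, lower.tail = FALSE)
        if (sided == "two") 2 * p else p
      }
    } else {
      s_prev <- sqrt(jinfo[k - 1]); s_cur <- sqrt(jinfo[k])
      sd_inc <- sqrt(jinfo[k] - jinfo[k - 1])
      fw <- f * w
      tailp <- function(c) {
        up <- stats::pnorm((c * s_cur - u * s_prev) / sd_inc,
                           lower.tail = FALSE)
        if (sided == "two")
          up <- up + stats::pnorm((-c * s_cur - u * s_prev) / sd_inc)
        sum(fw * up)
      }
    }
    if (incr[k] <= 0) {
      crit[k] <- Inf
      achieved[k] <- 0
    } else {
      lo <- if (sided == "two") 1e-6 else -zmax
      g <- function(c) tailp(c) - incr[k]
      if (g(lo) < 0) {
        # more alpha allotted than probability left in the continuation
        # region: boundary collapses to the region edge
        crit[k] <- lo
      } else {
        crit[k] <- stats::uniroot(g, c(lo, zmax + 2), tol = 1e-10)$root
      }
      achieved[k] <- tailp(crit[k])
    }
    if (k < K) {
      upperk <- if (is.finite(crit[k])) crit[k] else zmax
      lowerk <- if (sided == "two") -upperk else -zmax
      rule <- gl_rule(nodes, lowerk, upperk)
      fnew <- if (k == 1L) {
        stats::dnorm(rule$x)
      } else {
        s_prev <- sqrt(jinfo[k - 1]); s_cur <- sqrt(jinfo[k])
        sd_inc <- sqrt(jinfo[k] - jinfo[k - 1])
        dens <- outer(rule$x * s_cur, u * s_prev, "-") / sd_inc
        as.vector((stats::dnorm(dens) * (s_cur / sd_inc)) %*% (f * w))
      }
      u <- rule$x; w <- rule$w; f <- fnew
    }
  }
  list(crit = crit, achieved = achieved)
}

# P(Z_1 < b_1, ..., Z_K < b_K) under the canonical correlation structure
# sqrt(jinfo[i]/jinfo[j]) (one-sided orthant probability), by the same
# recursion.  Used by the power formulas.
gs_joint_lower <- function(b, jinfo, nodes = 512L, zmax = 8) {
  K <- length(b)
  stopifnot(length(jinfo) == K)
  if (K > 1L && any(diff(jinfo) <= 0))
    stop_monotonicity("pseudo-information must be strictly increasing")
  if (K == 1L) return(stats::pnorm(b))
  rule <- gl_rule(nodes, -zmax, min(b[1], zmax + 2))
  u <- rule$x; w <- rule$w; f <- stats::dnorm(u)
  for (k in 2:K) {
    s_prev <- sqrt(jinfo[k - 1]); s_cur <- sqrt(jinfo[k])
    sd_inc <- sqrt(jinfo[k] - jinfo[k - 1])
    if (k == K) {
      return(sum(f * w *
                   stats::pnorm((b[K] * s_cur - u * s_prev) / sd_inc)))
    }
    rule <- gl_rule(nodes, -zmax, min(b[k], zmax + 2))
    dens <- outer(rule$x * s_cur, u * s_prev, "-") / sd_inc
    f <- as.vector((stats::dnorm(dens) * (s_cur / sd_inc)) %*% (f * w))
    u <- rule$x; w <- rule$w
  }
}

#' Error-spending boundaries at observed information levels
#'
#' Computes the per-stage alpha increments, stage levels and critical values
#' of a group sequential design given the information observed (or planned)
#' at each analysis. The critical value `c_k` solves
#' `P(Z_1 < c_1, ..., Z_{k-1} < c_{k-1}, Z_k >= c_k) = pi_k` under the
#' multivariate normal with correlations `sqrt(J_i / J_j)`, where `J`
#' equals the observed information at interim analyses and `Imax` at the
#' final one (the prespecified covariance of an interim statistic with the
#' final statistic). Two-sided designs use the symmetric region
#' `|Z_k| >= c_k`.
#'
#' @param design a [sequential_design()] object.
#' @param observed_info estimated information per analysis (up to `K`
#'   entries; see [spend_increments()] for the partial-monitoring rule).
#' @param nodes number of Gauss-Legendre nodes for the recursion.
#' @return An object of class `gsr_boundaries`: list with `tau` (capped
#'   information fractions), `increments`, `crit`, `levels` (stage levels
#'   `alpha_k`, one-sided tail mass of `c_k`), `jinfo` and `crossing`
#'   (achieved total rejection probability under the null).
#' @examples
#' d <- sequential_design(2, 0.025, "pocock", imax = 200)
#' boundaries(d, c(100, 200))
#' @export
boundaries <- function(design, observed_info, nodes = 512L) {
  stopifnot(inherits(design, "gsr_design"))
  incr <- spend_increments(design, observed_info)
  k_obs <- length(observed_info)
  jinfo <- observed_info
  if (k_obs == design$K && k_obs > 1L) {
    # final-stage covariance with interims is prespecified through Imax
    jinfo[k_obs] <- max(design$imax, jinfo[k_obs - 1] * (1 + 1e-9))
    jinfo[seq_len(k_obs - 1)] <- pmin(jinfo[seq_len(k_obs - 1)],
                                      jinfo[k_obs] * (1 - 1e-9))
  }
  sol <- gs_solve_boundaries(incr, jinfo, sided = design$sided, nodes = nodes)
  lev <- stats::pnorm(sol$crit, lower.tail = FALSE)
  if (design$sided == "two") lev <- 2 * lev
  structure(list(tau = pmin(observed_info / design$imax, 1),
                 increments = incr, crit = sol$crit, levels = lev,
                 jinfo = jinfo, crossing = sum(sol$achieved),
                 design = design),
            class = "gsr_boundaries")
}

#' @export
print.gsr_boundaries <- function(x, ...) {
  cat(sprintf("Error-spending boundaries (%s, %s-sided alpha = %g):\n",
              x$design$spending, x$design$sided, x$design$alpha))
  print(data.frame(stage = seq_along(x$crit),
                   info_fraction = round(x$tau, 4),
                   alpha_spent = signif(x$increments, 4),
                   stage_level = signif(x$levels, 4),
                   critical_value = round(x$crit, 4)),
        row.names = FALSE)
  cat(sprintf("  total crossing probability under H0: %.6f\n", x$crossing))
  invisible(x)
}

#' Repeated p-value of a standardized statistic
#'
#' `p_k = 1 - Phi(Z_k)`, or `1 - F_nu(Z_k)` for the t-approximate
#' Brunner-Munzel test with estimated degrees of freedom `nu`.
#'
#' @param z standardized statistic.
#' @param df optional Satterthwaite-Smith-Welch degrees of freedom; `NULL`
#'   for the normal approximation.
#' @export
repeated_p_value <- function(z, df = NULL) {
  if (is.null(df)) return(stats::pnorm(z, lower.tail = FALSE))
  if (any(df <= 0)) stop_invalid_input("'df' must be positive")
  stats::pt(z, df, lower.tail = FALSE)
}
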