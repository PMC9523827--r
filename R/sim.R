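# Monte-Carlo engine: seeded replication of group sequential trials under a
# known two-arm model, with per-stage cumulative and overall rejection rates
# and explicit accounting of numerical exception events.

#' Define a simulation scenario
#'
#' @param model a `gsr_model` data-generating process.
#' @param n_max total maximum sample size `N_K`.
#' @param K number of analyses.
#' @param t arm-1 allocation share (0.5 for 1:1, 2/3 for 2:1).
#' @param spending error spending function kind.
#' @param alpha one-sided overall level.
#' @param methods test variants to evaluate on the same replicate data.
#' @param reps number of replications.
#' @param seed base seed; the engine derives a deterministic stream from it.
#' @param stage_fractions cumulative fractions of `n_max` per stage.
#' @return List of class `gsr_scenario`, including the per-stage cumulative
#'   group sizes and the true per-method maximum information `Imax` computed
#'   from the model (known truth, not an estimate).
#' @export
sim_scenario <- function(model, n_max, K = 2L, t = 0.5,
                         spending = c("obrien_fleming", "pocock"),
                         alpha = 0.025,
                         methods = c("wmw", "bm", "bm_t", "lwo"),
                         reps = 100000L, seed = 1L,
                         stage_fractions = seq_len(K) / K) {
  spending <- match.arg(spending)
  stopifnot(inherits(model, "gsr_model"))
  methods <- match.arg(methods, several.ok = TRUE)
  K <- as.integer(K)
  if (K < 1L) stop_invalid_input("'K' must be at least 1")
  if (length(stage_fractions) != K || stage_fractions[K] != 1 ||
      (K > 1L && any(diff(stage_fractions) <= 0)))
    stop_invalid_input("'stage_fractions' must increase to 1, one per stage")
  Nk <- round(stage_fractions * n_max)
  n1k <- round(t * Nk)
  n2k <- Nk - n1k
  if (any(n1k < 2L) || any(n2k < 2L))
    stop_invalid_input("every stage needs >= 2 cumulative subjects per arm")
  imax <- vapply(c(wmw = "wmw", bm = "bm", lwo = "lwo"), function(m)
    true_information(model, m, n1k[K], n2k[K]), numeric(1))
  structure(list(model = model, n_max = n_max, K = K, t = t,
                 spending = spending, alpha = alpha, methods = methods,
                 reps = as.integer(reps), seed = as.integer(seed),
                 n1k = n1k, n2k = n2k, Nk = Nk, imax = imax),
            class = "gsr_scenario")
}

#' Expand a scenario grid
#'
#' Cartesian product of the supplied dimension vectors, with deterministic
#' per-scenario seeds `base_seed + index` so that any scenario (and through
#' the engine's chunked stream, any replicate) can be reproduced in
#' isolation.
#'
#' @param models list of `gsr_model` objects.
#' @param n_max,t,K,spending vectors of scenario dimensions.
#' @param reps replications per scenario.
#' @param base_seed integer base seed.
#' @param ... passed to [sim_scenario()] (e.g. `methods`).
#' @return List of `gsr_scenario` objects.
#' @export
scenario_grid <- function(models, n_max, t = 0.5, K = 2L,
                          spending = c("obrien_fleming", "pocock"),
                          reps = 100000L, base_seed = 1L, ...) {
  if (inherits(models, "gsr_model")) models <- list(models)
  dims <- list(model = seq_along(models), n_max = n_max, t = t, K = K,
               spending = spending)
  if (any(lengths(dims) == 0L))
    stop_invalid_input("empty scenario dimension")
  grid <- expand.grid(dims, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    sim_scenario(models[[grid$model[i]]], grid$n_max[i], K = grid$K[i],
                 t = grid$t[i], spending = grid$spending[i], reps = reps,
                 seed = base_seed + i, ...))
}

#' Resolution of a numerical exception during monitoring
#'
#' Default policy of the simulation engine for the rare finite-sample
#' breakdowns of the rank statistics:
#' * `zero_variance` -- the stage's variance estimate is exactly zero: the
#'   stage is treated as non-rejecting and spends no alpha; the information
#'   carried forward for spending is unchanged.
#' * `decreasing_information` -- the estimated information decreased between
#'   analyses: for spending purposes it is clamped to the previous value
#'   plus `1e-8` while the standardized statistic keeps the raw estimate.
#' * `boundary_effect` -- `p^` is 0 or 1 so the log win odds statistic is
#'   undefined: the repeated p-value of the Brunner-Munzel statistic is used
#'   at that stage (with complete separation this in turn has zero variance,
#'   so the stage does not reject).
#' Every event is counted in the simulation result.
#'
#' @param event one of `"zero_variance"`, `"decreasing_information"`,
#'   `"boundary_effect"`.
#' @param state list with the quantities the rule needs: `info` (current raw
#'   estimate) and `info_prev` (previous stage).
#' @return List describing the resolution: `action` plus, for the clamp
#'   rule, the `info_spend` value to use in the spending fractions.
#' @export
exception_policy <- function(event = c("zero_variance",
                                       "decreasing_information",
                                       "boundary_effect"),
                             state = list()) {
  event <- match.arg(event)
  switch(event,
    zero_variance = list(action = "skip_stage", reject = FALSE,
                         spend = 0, info_spend = state$info_prev),
    decreasing_information = list(
      action = "clamp_information",
      info_spend = max(state$info %||% -Inf, state$info_prev + 1e-8)),
    boundary_effect = list(action = "fallback_bm"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- per-replicate stage statistics ---------------------------------------

# vectorized over replicates: category-count representation of ordinal data.
# C1, C2: reps x ncat cumulative count matrices of the two arms at one
# stage.  Returns per-replicate vectors of everything the tests need.
count_stage_stats <- function(C1, C2) {
  n1 <- sum(C1[1, ]); n2 <- sum(C2[1, ]); N <- n1 + n2
  ncat <- ncol(C1)
  U <- upper.tri(matrix(1, ncat, ncat), diag = TRUE) * 1  # cumsum operator
  M <- C1 + C2
  cumM <- M %*% U
  R <- cumM - M + (M + 1) / 2          # pooled midrank of each category
  cum1 <- C1 %*% U
  cum2 <- C2 %*% U
  r1 <- cum1 - C1 + (C1 + 1) / 2       # within-group midranks
  r2 <- cum2 - C2 + (C2 + 1) / 2
  Rb1 <- rowSums(C1 * R) / n1
  Rb2 <- rowSums(C2 * R) / n2
  p_hat <- (Rb2 - Rb1) / N + 0.5
  sigmaR2 <- rowSums(M * (R - (N + 1) / 2)^2) / (N - 1)
  d1 <- R - r1 - Rb1 + (n1 + 1) / 2
  d2 <- R - r2 - Rb2 + (n2 + 1) / 2
  s1sq <- rowSums(C1 * d1^2) / (n2^2 * (n1 - 1))
  s2sq <- rowSums(C2 * d2^2) / (n1^2 * (n2 - 1))
  finish_stage_stats(n1, n2, p_hat, sigmaR2, s1sq, s2sq)
}

# single replicate, arbitrary (possibly continuous) data
numeric_stage_stats <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2); N <- n1 + n2
  r <- rank(c(x1, x2))
  R1 <- r[seq_len(n1)]; R2 <- r[n1 + seq_len(n2)]
  Rb1 <- mean(R1); Rb2 <- mean(R2)
  p_hat <- (Rb2 - Rb1) / N + 0.5
  sigmaR2 <- (sum((R1 - (N + 1) / 2)^2) + sum((R2 - (N + 1) / 2)^2)) / (N - 1)
  d1 <- R1 - rank(x1) - Rb1 + (n1 + 1) / 2
  d2 <- R2 - rank(x2) - Rb2 + (n2 + 1) / 2
  s1sq <- sum(d1^2) / (n2^2 * (n1 - 1))
  s2sq <- sum(d2^2) / (n1^2 * (n2 - 1))
  finish_stage_stats(n1, n2, p_hat, sigmaR2, s1sq, s2sq)
}

finish_stage_stats <- function(n1, n2, p_hat, sigmaR2, s1sq, s2sq) {
  N <- n1 + n2
  vsum <- s1sq / n1 + s2sq / n2
  deg_wmw <- sigmaR2 <= 0
  deg_bm <- vsum <= 0
  boundary <- p_hat <= 0 | p_hat >= 1
  info_wmw <- ifelse(deg_wmw, NA_real_, N * n1 * n2 / sigmaR2)
  info_bm <- ifelse(deg_bm, NA_real_, 1 / vsum)
  df <- ifelse(deg_bm, NA_real_,
               vsum^2 / (s1sq^2 / (n1^2 * (n1 - 1)) +
                         s2sq^2 / (n2^2 * (n2 - 1))))
  info_lwo <- ifelse(deg_bm | boundary, NA_real_,
                     (p_hat * (1 - p_hat))^2 * info_bm)
  list(p_hat = p_hat,
       z_wmw = (p_hat - 0.5) * sqrt(info_wmw),
       z_bm = (p_hat - 0.5) * sqrt(info_bm),
       z_lwo = ifelse(deg_bm | boundary, NA_real_,
                      stats::qlogis(p_hat) * sqrt(info_lwo)),
       info_wmw = info_wmw, info_bm = info_bm, info_lwo = info_lwo, df = df,
       deg_wmw = deg_wmw, deg_bm = deg_bm, boundary = boundary)
}

# ---- two-stage decision logic (vectorized) --------------------------------

# exact stage-2 critical value as a function of the stage-1 information
# fraction (K = 2: the final spend is the remainder and the correlation is
# sqrt(tau1)), tabulated once per scenario and spline-interpolated
make_c2_fun <- function(spending, alpha, nodes = 256L) {
  tg <- seq(0.005, 0.999, length.out = 160L)
  c2 <- vapply(tg, function(tau) {
    pi1 <- spending_value(spending, alpha, tau)
    gs_solve_boundaries(c(pi1, alpha - pi1), c(tau, 1),
                        nodes = nodes)$crit[2]
  }, numeric(1))
  sf <- stats::splinefun(tg, c2, method = "natural")
  function(tau) sf(pmin(pmax(tau, tg[1]), tg[length(tg)]))
}

# rejection stage (0 = none) for one method over vectorized replicates,
# two analyses
decide_two_stage <- function(s1, s2, method, imax, spending, alpha, c2_fun,
                             counts) {
  pick <- function(s) switch(method,
    wmw = list(z = s$z_wmw, info = s$info_wmw, df = NULL, deg = s$deg_wmw),
    bm = list(z = s$z_bm, info = s$info_bm, df = NULL, deg = s$deg_bm),
    bm_t = list(z = s$z_bm, info = s$info_bm, df = s$df, deg = s$deg_bm),
    lwo = list(z = s$z_lwo, info = s$info_lwo, df = NULL,
               deg = s$deg_bm | s$boundary))
  a1 <- pick(s1); a2 <- pick(s2)
  pv <- function(a) {
    out <- if (is.null(a$df)) stats::pnorm(a$z, lower.tail = FALSE)
           else stats::pt(a$z, a$df, lower.tail = FALSE)
    out[a$deg] <- NA_real_
    out
  }
  pv1 <- pv(a1); pv2 <- pv(a2)
  if (method == "lwo") {
    # boundary effect: fall back on the BM p-value at the affected stage
    # (degenerate there too under complete separation, hence usually NA)
    fb1 <- s1$boundary & !s1$deg_bm
    fb2 <- s2$boundary & !s2$deg_bm
    pv1[fb1] <- stats::pnorm(s1$z_bm[fb1], lower.tail = FALSE)
    pv2[fb2] <- stats::pnorm(s2$z_bm[fb2], lower.tail = FALSE)
    counts$boundary_effect <- counts$boundary_effect +
      sum(s1$boundary) + sum(s2$boundary)
  }
  counts$zero_variance <- counts$zero_variance + sum(a1$deg) + sum(a2$deg)
  counts$decreasing_information <- counts$decreasing_information +
    sum(!a1$deg & !a2$deg & a2$info <= a1$info)

  tau1 <- pmin(a1$info / imax, 1)
  lvl1 <- spending_value(spending, alpha, ifelse(is.na(tau1), 0, tau1))
  rej1 <- !is.na(pv1) & pv1 <= lvl1
  # stage 2: skipped degenerate stage 1 leaves the full alpha for a single
  # look; otherwise the remainder is spent against the solved c2(tau1)
  lvl2 <- ifelse(is.na(tau1), alpha,
                 stats::pnorm(c2_fun(tau1), lower.tail = FALSE))
  lvl2[!is.na(tau1) & tau1 >= 0.999] <- 0
  rej2 <- !rej1 & !is.na(pv2) & pv2 <= lvl2
  stage <- integer(length(pv1))
  stage[rej2] <- 2L
  stage[rej1] <- 1L
  list(stage = stage, counts = counts)
}

# ---- general-K decision logic (per replicate) -----------------------------

decide_multi_stage <- function(stats_by_stage, method, imax, spending, alpha,
                               K, counts, nodes = 48L) {
  pick <- function(s, i) switch(method,
    wmw = list(z = s$z_wmw[i], info = s$info_wmw[i], df = NULL,
               deg = s$deg_wmw[i], bz = NA_real_),
    bm = list(z = s$z_bm[i], info = s$info_bm[i], df = NULL,
              deg = s$deg_bm[i], bz = NA_real_),
    bm_t = list(z = s$z_bm[i], info = s$info_bm[i], df = s$df[i],
                deg = s$deg_bm[i], bz = NA_real_),
    lwo = list(z = s$z_lwo[i], info = s$info_lwo[i], df = NULL,
               deg = s$deg_bm[i] | s$boundary[i], bz = s$z_bm[i]))
  reps <- length(stats_by_stage[[1]]$p_hat)
  stage_out <- integer(reps)
  for (i in seq_len(reps)) {
    f_prev <- 0; info_prev <- NA_real_
    jinfo <- numeric(0); incr <- numeric(0); zs <- numeric(0)
    pvals <- numeric(0); dfs <- list()
    for (k in seq_len(K)) {
      a <- pick(stats_by_stage[[k]], i)
      z <- a$z; df <- a$df
      if (method == "lwo" && stats_by_stage[[k]]$boundary[i]) {
        counts$boundary_effect <- counts$boundary_effect + 1L
        if (!stats_by_stage[[k]]$deg_bm[i]) { z <- a$bz; a$deg <- FALSE }
      }
      if (a$deg) { counts$zero_variance <- counts$zero_variance + 1L; next }
      info_spend <- a$info
      if (!is.na(info_prev) && info_spend <= info_prev) {
        counts$decreasing_information <- counts$decreasing_information + 1L
        info_spend <- exception_policy("decreasing_information",
                                       list(info = info_spend,
                                            info_prev = info_prev))$info_spend
      }
      info_prev <- info_spend
      tau <- min(info_spend / imax, 1)
      pik <- if (k == K) alpha - f_prev
             else spending_value(spending, alpha, tau) - f_prev
      pik <- max(pik, 0)
      if (k < K) f_prev <- max(f_prev, spending_value(spending, alpha, tau))
      jk <- if (k == K) max(imax, if (length(jinfo)) jinfo[length(jinfo)] *
                                    (1 + 1e-9) else imax)
            else min(info_spend, imax * (1 - 1e-9))
      if (length(jinfo) && jk <= jinfo[length(jinfo)])
        jk <- jinfo[length(jinfo)] * (1 + 1e-9)
      jinfo <- c(jinfo, jk); incr <- c(incr, pik)
      sol <- gs_solve_boundaries(incr, jinfo, nodes = nodes)
      ck <- sol$crit[length(incr)]
      lvl <- stats::pnorm(ck, lower.tail = FALSE)
      pv <- if (is.null(df)) stats::pnorm(z, lower.tail = FALSE)
            else stats::pt(z, df, lower.tail = FALSE)
      if (pv <= lvl) { stage_out[i] <- k; break }
    }
  }
  list(stage = stage_out, counts = counts)
}

# ---- engine ---------------------------------------------------------------

#' Run a simulation scenario
#'
#' Draws full-trial data once per replicate, reveals it cumulatively by
#' stage, evaluates every requested test variant on the same replicate data
#' against the error-spending boundaries (with `Imax` fixed at the true
#' maximum information of the model), and reports per-stage cumulative and
#' overall rejection rates with Monte-Carlo standard errors and exception
#' counts. Deterministic given the scenario seed.
#'
#' @param scn a [sim_scenario()] object.
#' @param chunk replicates per generation chunk (memory control).
#' @return An object of class `gsr_sim_result`: list with `rates` (data
#'   frame: method, stage, cumulative rejection rate, SE), `overall` (named
#'   vector), `exceptions` (per-method counts), `reps`, `scenario`.
#' @examples
#' scn <- sim_scenario(dist_normal(0, 1, 0, 1), n_max = 48, K = 2,
#'                     spending = "pocock", reps = 200, seed = 7)
#' run_scenario(scn)
#' @export
run_scenario <- function(scn, chunk = 4000L) {
  stopifnot(inherits(scn, "gsr_scenario"))
  set.seed(scn$seed)
  K <- scn$K
  methods <- scn$methods
  imax_of <- function(m) scn$imax[[if (m == "bm_t") "bm" else m]]
  c2_fun <- if (K == 2L) make_c2_fun(scn$spending, scn$alpha) else NULL

  counts <- lapply(methods, function(m)
    list(zero_variance = 0L, decreasing_information = 0L,
         boundary_effect = 0L))
  names(counts) <- methods
  stage_tab <- matrix(0L, nrow = length(methods), ncol = K + 1L,
                      dimnames = list(methods, NULL))

  discrete <- is_discrete(scn$model)
  ncat <- if (discrete) length(scn$model$pmf1) else 0L
  done <- 0L
  while (done < scn$reps) {
    m <- min(chunk, scn$reps - done)
    if (discrete) {
      x1 <- matrix(sample_model(scn$model, m * scn$n1k[K], 1L), nrow = m)
      x2 <- matrix(sample_model(scn$model, m * scn$n2k[K], 2L), nrow = m)
      stats_by_stage <- lapply(seq_len(K), function(k) {
        C1 <- vapply(seq_len(ncat), function(cc)
          rowSums(x1[, seq_len(scn$n1k[k]), drop = FALSE] == cc), numeric(m))
        C2 <- vapply(seq_len(ncat), function(cc)
          rowSums(x2[, seq_len(scn$n2k[k]), drop = FALSE] == cc), numeric(m))
        count_stage_stats(matrix(C1, nrow = m), matrix(C2, nrow = m))
      })
    } else {
      x1 <- matrix(sample_model(scn$model, m * scn$n1k[K], 1L), nrow = m)
      x2 <- matrix(sample_model(scn$model, m * scn$n2k[K], 2L), nrow = m)
      stats_by_stage <- lapply(seq_len(K), function(k) {
        per <- lapply(seq_len(m), function(i)
          numeric_stage_stats(x1[i, seq_len(scn$n1k[k])],
                              x2[i, seq_len(scn$n2k[k])]))
        fields <- names(per[[1]])
        out <- lapply(fields, function(f)
          vapply(per, function(pp) as.numeric(pp[[f]]), numeric(1)))
        names(out) <- fields
        out$deg_wmw <- out$deg_wmw > 0
        out$deg_bm <- out$deg_bm > 0
        out$boundary <- out$boundary > 0
        out
      })
    }
    for (meth in methods) {
      res <- if (K == 2L) {
        decide_two_stage(stats_by_stage[[1]], stats_by_stage[[2]], meth,
                         imax_of(meth), scn$spending, scn$alpha, c2_fun,
                         counts[[meth]])
      } else if (K == 1L) {
        a <- stats_by_stage[[1]]
        z <- switch(meth, wmw = a$z_wmw, bm = a$z_bm, bm_t = a$z_bm,
                    lwo = a$z_lwo)
        pvv <- if (meth == "bm_t") stats::pt(z, a$df, lower.tail = FALSE)
               else stats::pnorm(z, lower.tail = FALSE)
        st <- ifelse(!is.na(pvv) & pvv <= scn$alpha, 1L, 0L)
        cn <- counts[[meth]]
        cn$zero_variance <- cn$zero_variance + sum(is.na(pvv))
        list(stage = st, counts = cn)
      } else {
        decide_multi_stage(stats_by_stage, meth, imax_of(meth),
                           scn$spending, scn$alpha, K, counts[[meth]])
      }
      counts[[meth]] <- res$counts
      tb <- tabulate(res$stage + 1L, nbins = K + 1L)
      stage_tab[meth, ] <- stage_tab[meth, ] + tb
    }
    done <- done + m
  }

  reps <- scn$reps
  rates <- do.call(rbind, lapply(methods, function(meth) {
    rej_by_stage <- stage_tab[meth, -1L]
    cum <- cumsum(rej_by_stage) / reps
    data.frame(method = meth, stage = seq_len(K), cum_reject = cum,
               se = sqrt(cum * (1 - cum) / reps))
  }))
  overall <- vapply(methods, function(meth)
    sum(stage_tab[meth, -1L]) / reps, numeric(1))
  structure(list(rates = rates, overall = overall, exceptions = counts,
                 reps = reps, scenario = scn),
            class = "gsr_sim_result")
}

#' @export
print.gsr_sim_result <- function(x, ...) {
  scn <- x$scenario
  cat(sprintf(
    "Simulated group sequential trial: %s spending, K = %d, N = (%s), %d reps\n",
    scn$spending, scn$K, paste(scn$Nk, collapse = ", "), x$reps))
  for (meth in names(x$overall)) {
    se <- sqrt(x$overall[[meth]] * (1 - x$overall[[meth]]) / x$reps)
    ex <- x$exceptions[[meth]]
    cat(sprintf("  %-5s overall rejection %.5f (SE %.5f)%s\n",
                toupper(meth), x$overall[[meth]], se,
                if (sum(unlist(ex)) > 0)
                  sprintf("  [events: %s]",
                          paste(names(ex)[unlist(ex) > 0], collapse = ", "))
                else ""))
  }
  invisible(x)
}

#' Tidy per-stage simulation rates
#'
#' @param x a `gsr_sim_result`.
#' @return Data frame with scenario descriptors, per-stage cumulative
#'   rejection rates, standard errors and exception counts.
#' @export
sim_result_table <- function(x) {
  stopifnot(inherits(x, "gsr_sim_result"))
  scn <- x$scenario
  ex <- vapply(x$rates$method, function(m)
    sum(unlist(x$exceptions[[m]])), numeric(1))
  cbind(data.frame(n_max = scn$n_max, t = scn$t, K = scn$K,
                   spending = scn$spending, reps = x$reps),
        x$rates, exceptions = ex, row.names = NULL)
}
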