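test_that("scenarios validate inputs and derive stage sizes and true Imax", {
  m <- planning_model()
  scn <- sim_scenario(m, 284, K = 2, t = 0.5, spending = "pocock",
                      reps = 10, seed = 1)
  expect_equal(scn$Nk, c(142, 284))
  expect_equal(scn$n1k, c(71, 142))
  expect_equal(scn$imax[["wmw"]], true_information(m, "wmw", 142, 142))
  expect_equal(scn$imax[["bm"]], true_information(m, "bm", 142, 142))
  expect_error(sim_scenario(m, 6, K = 2, t = 0.5, reps = 1),
               class = "gsr_invalid_input")
})

test_that("the engine is deterministic given the scenario seed", {
  scn <- sim_scenario(planning_model(), 48, K = 2, t = 0.5,
                      spending = "pocock", reps = 300, seed = 42)
  r1 <- run_scenario(scn)
  r2 <- run_scenario(scn)
  expect_identical(r1$overall, r2$overall)
  expect_identical(r1$rates, r2$rates)
})

test_that("cumulative stage rates are nondecreasing and end at the overall rate", {
  scn <- sim_scenario(dist_normal(0, 1, 0.6, 1), 60, K = 3, t = 0.5,
                      spending = "pocock", reps = 250, seed = 5)
  r <- run_scenario(scn)
  for (meth in names(r$overall)) {
    cum <- r$rates$cum_reject[r$rates$method == meth]
    expect_true(all(diff(cum) >= 0))
    expect_equal(cum[length(cum)], r$overall[[meth]])
  }
})

test_that("Pocock spends more at stage one than O'Brien-Fleming", {
  m <- planning_model()
  r_po <- run_scenario(sim_scenario(m, 144, K = 2, t = 0.5,
                                    spending = "pocock", reps = 2000,
                                    seed = 8, methods = "wmw"))
  r_of <- run_scenario(sim_scenario(m, 144, K = 2, t = 0.5,
                                    spending = "obrien_fleming", reps = 2000,
                                    seed = 8, methods = "wmw"))
  s1_po <- r_po$rates$cum_reject[r_po$rates$stage == 1]
  s1_of <- r_of$rates$cum_reject[r_of$rates$stage == 1]
  expect_gt(s1_po, s1_of)
})

test_that("engine decisions match the monitoring function replicate by replicate", {
  m <- planning_model()
  imax <- vapply(c(wmw = "wmw", bm = "bm", lwo = "lwo"), function(x)
    true_information(m, x, 30, 30), numeric(1))
  c2_by_kind <- lapply(c(pocock = "pocock", obrien_fleming = "obrien_fleming"),
                       function(k) gsrank:::make_c2_fun(k, 0.025))
  set.seed(9)
  for (i in 1:12) {
    x1 <- sample_model(m, 30, 1); x2 <- sample_model(m, 30, 2)
    d <- staged_data(x1, x2)
    s1 <- gsrank:::numeric_stage_stats(x1[1:15], x2[1:15])
    s2 <- gsrank:::numeric_stage_stats(x1, x2)
    for (kind in c("pocock", "obrien_fleming")) {
      for (meth in c("wmw", "bm", "bm_t", "lwo")) {
        im <- imax[[if (meth == "bm_t") "bm" else meth]]
        des <- sequential_design(2, 0.025, kind, imax = im)
        mon <- try(gs_monitor(d, des, meth), silent = TRUE)
        if (inherits(mon, "try-error")) next
        mstage <- if (any(mon$reject)) mon$stage[which(mon$reject)[1]] else 0L
        dec <- gsrank:::decide_two_stage(
          s1, s2, meth, im, kind, 0.025, c2_by_kind[[kind]],
          list(zero_variance = 0L, decreasing_information = 0L,
               boundary_effect = 0L))
        expect_equal(dec$stage, mstage)
      }
    }
  }
})

test_that("exception policy resolutions follow the documented rules", {
  r1 <- exception_policy("zero_variance", list(info_prev = 12))
  expect_equal(r1$action, "skip_stage")
  expect_false(r1$reject)
  expect_equal(r1$info_spend, 12)
  r2 <- exception_policy("decreasing_information",
                         list(info = 10, info_prev = 11))
  expect_equal(r2$info_spend, 11 + 1e-8)
  r3 <- exception_policy("boundary_effect")
  expect_equal(r3$action, "fallback_bm")
  expect_error(exception_policy("meltdown"))
})

test_that("degenerate replicates are counted, not fatal", {
  # two-point arms at tiny sizes make complete separation frequent
  m <- dist_pmf(c(0.85, 0.1, 0.05, 0, 0), c(0, 0, 0.05, 0.1, 0.85))
  scn <- sim_scenario(m, 8, K = 2, t = 0.5, spending = "pocock",
                      reps = 400, seed = 13, methods = c("bm", "lwo"))
  r <- run_scenario(scn)
  expect_gt(r$exceptions$bm$zero_variance, 0)
  expect_gt(r$exceptions$lwo$boundary_effect, 0)
  expect_true(all(unlist(r$overall) >= 0 & unlist(r$overall) <= 1))
})

test_that("scenario grids expand the Cartesian product with distinct seeds", {
  m <- planning_model()
  g <- scenario_grid(m, n_max = c(144, 288, 576, 864, 1008),
                     t = c(0.5, 2 / 3), K = c(2, 3, 4),
                     spending = c("obrien_fleming", "pocock"),
                     reps = 10, base_seed = 7)
  expect_length(g, 60)
  expect_length(unique(vapply(g, `[[`, integer(1), "seed")), 60)
  g1 <- scenario_grid(m, n_max = 144, t = 0.5, K = 2, spending = "pocock",
                      reps = 10)
  expect_length(g1, 1)
  expect_error(scenario_grid(m, n_max = integer(0)),
               class = "gsr_invalid_input")
})

test_that("single-stage scenarios reduce to the fixed-sample test", {
  m0 <- dist_normal(0, 1, 0, 1)
  scn <- sim_scenario(m0, 200, K = 1, t = 0.5, spending = "pocock",
                      reps = 4000, seed = 17, methods = "wmw")
  r <- run_scenario(scn)
  se <- sqrt(0.025 * 0.975 / 4000)
  expect_lt(abs(r$overall[["wmw"]] - 0.025), 3 * se)
})
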