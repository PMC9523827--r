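test_that("midranks handle ties and satisfy the pairwise definition", {
  expect_equal(midranks(c(10, 20, 30)), c(1, 2, 3))
  expect_equal(midranks(c(5, 5, 5)), c(2, 2, 2))
  expect_equal(midranks(c(1, 2, 2, 7)), c(1, 2.5, 2.5, 4))
  expect_error(midranks(numeric(0)), class = "gsr_invalid_input")

  # pairwise c-sum definition and the fixed-sum property, random tied data
  set.seed(101)
  for (i in 1:25) {
    x <- random_tied_sample(sample(3:40, 1))
    r <- midranks(x)
    r_brute <- vapply(x, function(xi)
      0.5 + sum((xi > x) + 0.5 * (xi == x)), numeric(1))
    expect_equal(r, r_brute)
    expect_equal(sum(r), length(x) * (length(x) + 1) / 2)
  }
})

test_that("relative effect equals the pairwise double sum and is in [0,1]", {
  d_sep <- staged_data(c(1, 2), c(3, 4), 1)
  expect_equal(relative_effect(d_sep, 1), 1)
  d_eq <- staged_data(c(1, 2, 3), c(1, 2, 3), 1)
  expect_equal(relative_effect(d_eq, 1), 0.5)
  d_tie <- staged_data(c(1, 2), c(2, 3), 1)
  expect_equal(relative_effect(d_tie, 1), 0.875)

  set.seed(202)
  for (i in 1:40) {
    x1 <- random_tied_sample(sample(2:25, 1))
    x2 <- random_tied_sample(sample(2:25, 1))
    d <- staged_data(x1, x2, 1)
    d_swap <- staged_data(x2, x1, 1)
    p <- relative_effect(d, 1)
    expect_equal(p, brute_force_p(x1, x2))
    expect_equal(relative_effect(d_swap, 1), 1 - p)
    expect_true(p >= 0 && p <= 1)
  }
})

test_that("pooled rank variance matches its closed forms", {
  expect_equal(wmw_variance(midranks(1:10)), 110 / 12)
  expect_equal(wmw_variance(midranks(rep(3, 7))), 0)
  expect_equal(wmw_variance(midranks(c(1, 1, 2, 2))), 4 / 3)
})

test_that("WMW information equals N n1 n2 / sigmaR2 and 12 n1 n2/(N+1) tie-free", {
  expect_equal(wmw_information(5, 5, wmw_variance(midranks(1:10))), 300 / 11)
  expect_equal(wmw_information(5, 5, wmw_variance(midranks(1:10))),
               12 * 25 / 11)
  expect_error(wmw_information(1, 1, 1), class = "gsr_invalid_input")
  expect_error(wmw_information(5, 5, 0), class = "gsr_degenerate_variance")
})

test_that("Brunner-Munzel variance components match hand-computed cases", {
  d <- staged_data(c(1, 3), c(2, 4), 1)
  cmp <- bm_variance_components(d, 1)
  expect_equal(unname(cmp), c(1 / 8, 1 / 8))

  # complete separation: all placements equal, both components zero
  d_sep <- staged_data(c(1, 1, 2), c(5, 6, 7), 1)
  expect_equal(unname(bm_variance_components(d_sep, 1)), c(0, 0))
  expect_error(bm_information(3, 3, 0, 0), class = "gsr_degenerate_variance")

  # equal samples as multisets give symmetric components
  d_sym <- staged_data(c(1, 2, 3), c(1, 2, 3), 1)
  cmp_sym <- bm_variance_components(d_sym, 1)
  expect_equal(cmp_sym[["s1sq"]], cmp_sym[["s2sq"]])

  expect_error(bm_variance_components(staged_data(c(1), c(2, 3), 1), 1),
               class = "gsr_invalid_input")
})

test_that("estimators are invariant under strictly increasing transforms", {
  set.seed(303)
  for (i in 1:15) {
    x1 <- random_tied_sample(12)
    x2 <- random_tied_sample(15)
    trans <- function(v) exp(v) + 3 * v   # strictly increasing
    d <- staged_data(x1, x2, 1)
    dt <- staged_data(trans(x1), trans(x2), 1)
    expect_equal(relative_effect(dt, 1), relative_effect(d, 1))
    expect_equal(bm_variance_components(dt, 1), bm_variance_components(d, 1))
    cmp <- bm_variance_components(d, 1)
    # components bounded by the Bernoulli-type maximum
    expect_true(all(cmp >= 0))
    expect_true(cmp[["s1sq"]] <= 0.25 * 12 / 11 + 1e-12)
    expect_true(cmp[["s2sq"]] <= 0.25 * 15 / 14 + 1e-12)
  }
})

test_that("BM information, degrees of freedom and LWO transform evaluate correctly", {
  expect_equal(bm_information(10, 10, 0.05, 0.05), 100)
  expect_equal(bm_information(20, 10, 0.04, 0.08), 100)
  expect_equal(bm_degrees_of_freedom(10, 10, 0.05, 0.05), 18)
  expect_equal(bm_degrees_of_freedom(7, 7, 0.12, 0.12), 2 * 6)
  # independent arithmetic oracle for the unbalanced case
  nu <- (0.04 / 20 + 0.08 / 10)^2 /
    (0.04^2 / (20^2 * 19) + 0.08^2 / (10^2 * 9))
  expect_equal(bm_degrees_of_freedom(20, 10, 0.04, 0.08), nu)
  expect_equal(round(nu, 3), 13.658)

  lw <- lwo_effect_and_information(0.75, 50)
  expect_equal(lw$psi, log(3))
  lw0 <- lwo_effect_and_information(0.5, 64)
  expect_equal(lw0$psi, 0)
  expect_equal(lw0$info, 4)
  expect_error(lwo_effect_and_information(1, 10),
               class = "gsr_boundary_effect")
})

test_that("standardized statistic is (effect - null) sqrt(info), antisymmetric under arm swap", {
  expect_equal(z_statistic(0.5, 0.5, 123), 0)
  expect_equal(z_statistic(0.6, 0.5, 100), 1)
  expect_equal(z_statistic(0.43, 0.5, 81), -z_statistic(0.57, 0.5, 81))
  expect_error(z_statistic(0.6, 0.5, 0), class = "gsr_invalid_input")
})

test_that("stage_estimate recovers the true effect under a normal shift", {
  model <- dist_normal(0, 1, 1, 1)
  p_true <- true_relative_effect(model)
  set.seed(404)
  reps <- 4000
  p_hat <- numeric(reps)
  for (i in seq_len(reps)) {
    d <- staged_data(sample_model(model, 100, 1), sample_model(model, 100, 2), 1)
    p_hat[i] <- stage_estimate(d, 1)$p_hat
  }
  se <- stats::sd(p_hat) / sqrt(reps)
  expect_lt(abs(mean(p_hat) - p_true), 3 * se)
})
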