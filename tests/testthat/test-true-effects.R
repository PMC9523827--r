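test_that("latent Beta binning yields the right category probabilities", {
  expect_equal(ordinal_from_latent_beta(1, 1), rep(0.2, 5))
  # Beta(a, 1) has CDF x^a: closed-form check on the 0.2 grid
  a <- 0.6974797
  expect_equal(ordinal_from_latent_beta(a, 1),
               diff((0.2 * (0:5))^a))
  # Monte-Carlo binning oracle for a non-trivial shape
  pmf <- ordinal_from_latent_beta(3, 3)
  set.seed(11)
  draws <- stats::rbeta(1e6, 3, 3)
  emp <- tabulate(findInterval(draws, 0.2 * (0:5), all.inside = TRUE), 5) / 1e6
  expect_true(all(abs(pmf - emp) < 3 * sqrt(pmf * (1 - pmf) / 1e6) + 1e-6))
  expect_equal(sum(pmf), 1)
  expect_error(ordinal_from_latent_beta(-1, 2), class = "gsr_invalid_input")
})

test_that("true relative effect: identity, closed forms, planning model", {
  expect_equal(true_relative_effect(dist_normal(2, 3, 2, 3)), 0.5)
  expect_equal(true_relative_effect(dist_pmf(c(.2, .3, .5), c(.2, .3, .5))), 0.5)
  expect_equal(true_relative_effect(dist_normal(0, 1, 1, 1)),
               stats::pnorm(1 / sqrt(2)))
  # Monte-Carlo pairwise oracle for the normal shift model
  set.seed(21)
  x1 <- stats::rnorm(1e6); x2 <- stats::rnorm(1e6, 1)
  expect_lt(abs(mean(x2 > x1) - true_relative_effect(dist_normal(0, 1, 1, 1))),
            3 * 0.5 / sqrt(1e6) + 2e-3)
  expect_equal(true_relative_effect(planning_model()), 0.6, tolerance = 1e-5)
})

test_that("complement identity p(F1,F2) + p(F2,F1) = 1 over random models", {
  set.seed(31)
  for (i in 1:20) {
    a <- stats::runif(2, 0.3, 4); b <- stats::runif(2, 0.3, 4)
    m <- dist_latent_beta_ordinal(a[1], b[1], a[2], b[2])
    m_swap <- dist_latent_beta_ordinal(a[2], b[2], a[1], b[1])
    expect_equal(true_relative_effect(m) + true_relative_effect(m_swap), 1)
    mu <- stats::rnorm(2); sd <- stats::runif(2, 0.5, 2)
    mn <- dist_normal(mu[1], sd[1], mu[2], sd[2])
    mn_swap <- dist_normal(mu[2], sd[2], mu[1], sd[1])
    expect_equal(true_relative_effect(mn) + true_relative_effect(mn_swap), 1)
  }
})

test_that("true BM variance components: identity case and Monte-Carlo plug-in", {
  v <- true_bm_variances(dist_normal(1, 2, 1, 2))
  expect_equal(unname(v), c(1 / 12, 1 / 12), tolerance = 1e-8)
  # degenerate constructions are rejected, not silently produced
  expect_error(dist_pmf(c(1, 0), c(0, 1)), class = "gsr_invalid_input")
  expect_error(dist_pmf(c(.5, .5, 0, 0), c(0, 0, .5, .5)),
               class = "gsr_invalid_input")

  m <- planning_model()
  v_ord <- true_bm_variances(m)
  expect_true(all(v_ord >= 0 & v_ord <= 0.25))
  # plug-in oracle: V{F2(X1)} from 1e6 latent draws
  set.seed(41)
  F2 <- cumsum(m$pmf2) - m$pmf2 / 2
  x1 <- sample.int(5, 1e6, replace = TRUE, prob = m$pmf1)
  expect_lt(abs(stats::var(F2[x1]) - v_ord[["s1sq"]]), 3 * 0.25 / sqrt(1e6))
})

test_that("mixture rank variance reduces correctly and matches simulated midranks", {
  expect_equal(true_wmw_variance(dist_normal(0, 1, 1, 1), 0.5, 10), 110 / 12)
  m <- planning_model()
  N <- 284; t <- 0.5
  v <- true_wmw_variance(m, t, N)
  set.seed(51)
  reps <- 4000
  vr <- numeric(reps)
  for (i in seq_len(reps)) {
    pooled <- c(sample_model(m, N / 2, 1), sample_model(m, N / 2, 2))
    r <- midranks(pooled)
    vr[i] <- sum((r - (N + 1) / 2)^2) / (N - 1)
  }
  expect_lt(abs(mean(vr) - v), 3 * stats::sd(vr) / sqrt(reps))
})

test_that("true information: per-method formulas and monotonicity", {
  m0 <- dist_normal(0, 1, 0, 1)
  expect_equal(true_information(m0, "bm", 30, 30), 6 * 30)
  expect_equal(true_information(m0, "wmw", 20, 10), 12 * 200 / 31)
  expect_equal(true_information(m0, "lwo", 30, 30),
               true_information(m0, "bm", 30, 30) / 16)
  m <- planning_model()
  i_small <- true_information(m, "bm", 50, 50)
  i_big <- true_information(m, "bm", 100, 100)
  expect_gt(i_big, i_small)
  expect_error(true_information(m, "nope", 10, 10))
})

test_that("sampling is reproducible, binned correctly and centered correctly", {
  m <- planning_model()
  expect_identical(sample_model(m, 0, 1), numeric(0))
  set.seed(61); a <- sample_model(m, 50, 2)
  set.seed(61); b <- sample_model(m, 50, 2)
  expect_identical(a, b)
  expect_true(all(a %in% 1:5))

  set.seed(62)
  u <- sample_model(dist_latent_beta_ordinal(1, 1, 1, 1), 20000, 1)
  chi <- stats::chisq.test(tabulate(u, 5), p = rep(0.2, 5))
  expect_gt(chi$p.value, 1e-4)

  set.seed(63)
  x <- sample_model(dist_normal(0, 1, 5, 2), 20000, 1)
  expect_lt(abs(mean(x)), 3 / sqrt(20000))
})
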