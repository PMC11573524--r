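test_that("Wald ratio follows the first-order closed form", {
  r <- wald_ratio(0.1, 0.01, 0.05, 0.01)
  expect_equal(r$beta, 0.5)
  expect_equal(r$se, 0.1)
  expect_equal(r$or, exp(0.5))

  expect_equal(wald_ratio(0.1, 0.01, 0, 0.01)$pval, 1)  # null outcome effect
  expect_equal(wald_ratio(-0.1, 0.01, 0.05, 0.01)$beta, -0.5)
  expect_error(wald_ratio(0, 0.01, 0.05, 0.01), "gamma = 0")
})

test_that("IVW equals the through-origin WLS oracle", {
  # degenerate J = 1 delegates to the Wald ratio
  hs1 <- harmonized_set(0.1, 0.01, 0.05, 0.01)
  expect_equal(mr_ivw(hs1)$beta, wald_ratio(0.1, 0.01, 0.05, 0.01)$beta)
  expect_equal(mr_ivw(hs1)$method, "wald")

  # two equally weighted SNPs average their ratios
  hs2 <- harmonized_set(c(0.1, 0.1), c(0.01, 0.01), c(0.04, 0.06),
                        c(0.02, 0.02))
  expect_equal(mr_ivw(hs2)$beta, 0.5)

  # 5-SNP fixture against the independent normal-equations solve
  hs5 <- random_hs(5, seed = 3)
  o <- ivw_oracle(hs5)
  r <- mr_ivw(hs5)
  expect_equal(r$beta, o$beta, tolerance = 1e-10)
  expect_equal(r$se, o$se_fe, tolerance = 1e-10)

  expect_error(mr_ivw(harmonized_set(c(0, 0.1), c(0.01, 0.01),
                                     c(0.01, 0.01), c(0.01, 0.01))),
               "gamma = 0")
})

test_that("multiplicative random effects never narrow the interval", {
  for (seed in 1:20) {
    hs <- random_hs(8, seed = seed)
    fe <- mr_ivw(hs, mode = "fixed")
    mre <- mr_ivw(hs, mode = "multiplicative_random")
    expect_equal(fe$beta, mre$beta)
    expect_gte(mre$se, fe$se)
    Q <- attr(fe, "Q")
    if (Q <= nrow(hs) - 1) expect_equal(mre$se, fe$se)
    else expect_gt(mre$se, fe$se)
  }
})

test_that("identical ratios collapse every estimator to that value", {
  gamma <- c(0.1, 0.2, -0.15, 0.25)
  hs <- harmonized_set(gamma, rep(0.01, 4), 0.4 * gamma, rep(0.02, 4))
  expect_equal(mr_ivw(hs)$beta, 0.4)
  expect_equal(attr(mr_ivw(hs), "Q"), 0)
  expect_equal(cochran_q(hs)$pval, 1)
  expect_equal(mr_weighted_median(hs, n_boot = 50, seed = 1)$beta, 0.4)
  expect_equal(mr_egger(hs)$beta, 0.4, tolerance = 1e-12)
})

test_that("MR-Egger matches the weighted-regression oracle and is exact on noiseless data", {
  # data generated exactly as Gamma = 0.02 + 0.5 * gamma
  gamma <- c(0.05, 0.1, 0.15, 0.2)
  hs <- harmonized_set(gamma, rep(0.005, 4), 0.02 + 0.5 * gamma,
                       rep(0.01, 4))
  r <- mr_egger(hs)
  expect_equal(r$intercept, 0.02, tolerance = 1e-12)
  expect_equal(r$beta, 0.5, tolerance = 1e-12)
  expect_equal(attr(r, "Q"), 0, tolerance = 1e-20)

  # orientation invariance: negating every (gamma, Gamma) changes nothing
  hs_neg <- harmonized_set(-hs$gamma, hs$se_gamma, -hs$Gamma, hs$se_Gamma)
  r_neg <- mr_egger(hs_neg)
  expect_equal(r_neg$beta, r$beta)
  expect_equal(r_neg$intercept, r$intercept)

  # noisy 10-SNP fixture against the independent lm() oracle
  hs10 <- random_hs(10, seed = 7)
  o <- egger_oracle(hs10)
  r10 <- mr_egger(hs10)
  expect_equal(r10$beta, o$slope, tolerance = 1e-10)
  expect_equal(r10$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(r10$se, o$se_slope_fe, tolerance = 1e-10)
  expect_equal(r10$intercept_se, o$se_int_fe, tolerance = 1e-10)

  expect_error(mr_egger(random_hs(2)), "at least 3")
  expect_error(mr_egger(harmonized_set(rep(0.1, 4), rep(0.01, 4),
                                       rep(0.05, 4), rep(0.01, 4))),
               "collinear")
})

test_that("weighted median interpolates the cumulative weight midpoints", {
  # equal weights: plain median
  hs <- harmonized_set(c(0.1, 0.1, 0.1), rep(0.01, 3),
                       0.1 * c(0.2, 0.5, 0.9), rep(0.02, 3))
  expect_equal(mr_weighted_median(hs, n_boot = 50, seed = 1)$beta, 0.5)

  # ratios {0.1, 0.2, 0.3} with raw weights {1, 1, 2}:
  # midpoints {0.125, 0.375, 0.75}, interpolate at 0.5 -> 0.2333...
  se_G <- c(1, 1, sqrt(0.5))
  hs2 <- harmonized_set(rep(1, 3), rep(0.01, 3), c(0.1, 0.2, 0.3), se_G)
  expect_equal(mr_weighted_median(hs2, n_boot = 50, seed = 1)$beta,
               0.2 + 0.1 * (0.5 - 0.375) / (0.75 - 0.375))

  # dominant first weight pins the estimate at b_1 (midpoint p_1 -> 0.5)
  hs3 <- harmonized_set(rep(1, 3), rep(0.01, 3), c(0.1, 0.2, 0.3),
                        c(0.05, 50, 50))
  expect_equal(mr_weighted_median(hs3, n_boot = 50, seed = 1)$beta, 0.1,
               tolerance = 1e-4)

  # same seed, same input -> identical bootstrap SE
  a <- mr_weighted_median(random_hs(6, seed = 2), n_boot = 200, seed = 99)
  b <- mr_weighted_median(random_hs(6, seed = 2), n_boot = 200, seed = 99)
  expect_identical(a$se, b$se)

  expect_error(mr_weighted_median(random_hs(2), seed = 1), "at least 3")
})

test_that("result rows keep log and OR scales coherent", {
  for (seed in 1:10) {
    r <- mr_ivw(random_hs(6, seed = seed))
    expect_lt(r$ci_low, r$beta)
    expect_gt(r$ci_high, r$beta)
    expect_equal(r$or, exp(r$beta))
    expect_equal(r$or_ci_low, exp(r$ci_low))
  }
})

test_that("Egger is less biased than IVW under directional pleiotropy", {
  # all pleiotropic effects positive; true slope 0.1
  reps <- 500
  J <- 50
  bias_ivw <- numeric(reps)
  bias_egger <- numeric(reps)
  set.seed(2024)
  for (i in seq_len(reps)) {
    gamma_t <- runif(J, 0.05, 0.15)
    theta <- abs(rnorm(J, 0, 0.01))
    se_g <- rep(0.002, J)
    se_G <- runif(J, 0.005, 0.01)
    hs <- harmonized_set(rnorm(J, gamma_t, se_g), se_g,
                         rnorm(J, 0.1 * gamma_t + theta, se_G), se_G)
    bias_ivw[i] <- mr_ivw(hs)$beta - 0.1
    bias_egger[i] <- mr_egger(hs)$beta - 0.1
  }
  expect_lt(abs(mean(bias_egger)), abs(mean(bias_ivw)))
})
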