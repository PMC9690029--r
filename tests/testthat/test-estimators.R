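test_that("IVW reproduces the closed-form two-instrument case", {
  set <- make_set(bx = c(0.1, 0.2), sx = c(0.01, 0.01),
                  by = c(0.05, 0.08), sy = c(0.01, 0.02))
  fit <- mr_ivw(set, "fixed")
  expect_equal(fit$theta, 0.45)
  expect_equal(fit$se, 1 / sqrt(200))
  expect_equal(fit$or, exp(0.45))
})

test_that("a single instrument degenerates to its Wald ratio with a warning", {
  set <- make_set(bx = 0.1, sx = 0.01, by = 0.05, sy = 0.01)
  expect_warning(fit <- mr_ivw(set), "single instrument")
  expect_equal(fit$method, "wald")
  expect_equal(fit$theta, 0.5)
  expect_equal(fit$se, 0.1)
})

test_that("IVW fixed matches the lm weighted-least-squares oracle on random sets", {
  set.seed(201)
  for (i in 1:25) {
    set <- random_set(J = sample(3:15, 1))
    inst <- set$instruments
    got <- mr_ivw(set, "fixed")
    want <- oracle_ivw_fixed(inst$beta_exposure, inst$beta_outcome,
                             inst$se_outcome)
    expect_equal(got$theta, want$theta, tolerance = 1e-12)
    expect_equal(got$se, want$se, tolerance = 1e-12)
  }
})

test_that("homogeneous ratio sets collapse to the common ratio with zero heterogeneity", {
  bx <- c(0.1, 0.2, 0.15)
  set <- make_set(bx, sx = 0.01, by = 0.3 * bx, sy = c(0.01, 0.02, 0.015))
  f <- mr_ivw(set, "fixed"); r <- mr_ivw(set, "random")
  expect_equal(f$theta, 0.3)
  expect_equal(r$theta, 0.3)
  expect_equal(attr(r, "Q"), 0)
  expect_equal(r$se, f$se)  # max(1, sqrt(Q/(J-1))) floors at 1
})

test_that("random-effects SE never undercuts the fixed-effect SE", {
  set.seed(202)
  for (i in 1:20) {
    set <- random_set(J = sample(3:20, 1))
    expect_gte(mr_ivw(set, "random")$se, mr_ivw(set, "fixed")$se)
  }
})

test_that("MR-Egger is exact on noiseless data and matches the lm oracle", {
  bx <- c(0.05, 0.1, 0.15, 0.2)
  set <- make_set(bx, sx = 0.01, by = 0.4 * bx, sy = c(0.01, 0.02, 0.01, 0.015))
  eg <- mr_egger(set)
  expect_equal(eg$slope$theta, 0.4, tolerance = 1e-10)
  expect_equal(eg$intercept$estimate, 0, tolerance = 1e-10)
  expect_equal(eg$Q, 0, tolerance = 1e-15)

  set.seed(203)
  for (i in 1:20) {
    set <- random_set(J = sample(4:15, 1))
    inst <- set$instruments
    got <- mr_egger(set)
    want <- oracle_egger(inst$beta_exposure, inst$beta_outcome,
                         inst$se_outcome)
    expect_equal(got$slope$theta, want$slope, tolerance = 1e-10)
    expect_equal(got$intercept$estimate, want$intercept, tolerance = 1e-10)
    expect_equal(got$slope$se, want$se_slope, tolerance = 1e-10)
    expect_equal(got$intercept$se, want$se_intercept, tolerance = 1e-10)
    expect_equal(got$slope$pvalue, unname(want$p_slope), tolerance = 1e-10)
  }
})

test_that("MR-Egger refuses underdetermined sets", {
  set <- make_set(bx = c(0.1, 0.2), sx = 0.01, by = c(0.04, 0.08), sy = 0.01)
  expect_error(mr_egger(set), "at least 3")
})

test_that("the Egger intercept recovers a constant directional pleiotropy effect", {
  # every instrument carries the same direct effect alpha; InSIDE holds,
  # so the intercept estimates alpha while IVW is biased away from theta
  alpha <- 0.02; theta <- 0.1
  n_rep <- 500
  ints <- ivws <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    # a very large exposure GWAS keeps exposure-effect measurement noise
    # negligible (the NOME condition Egger's intercept relies on)
    truth <- mr_truth(theta = theta, n_snps = 20,
                      pleiotropy_mode = "directional",
                      alpha_dist = list(mean = alpha, sd = 0),
                      invalid_fraction = 1, palindromic_fraction = 0,
                      n_exposure = 5e6, seed = 5000 + r)
    sim <- generate_two_sample(truth)
    set <- harmonize(sim$exposure, sim$outcome)
    ints[r] <- mr_egger(set)$intercept$estimate
    ivws[r] <- mr_ivw(set)$theta
  }
  mc_se <- sd(ints) / sqrt(n_rep)
  expect_lt(abs(mean(ints) - alpha), 3 * mc_se)
  # IVW absorbs the pleiotropy: biased upward by roughly alpha / mean(gamma)
  expect_gt(mean(ivws), theta + 0.05)
})

test_that("weighted median matches hand values and the brute-force oracle", {
  set <- make_set(bx = c(0.1, 0.1, 0.1), sx = 0.01,
                  by = c(0.01, 0.04, 0.09), sy = 0.01)
  wm <- mr_weighted_median(set, n_boot = 200, seed = 1)
  expect_equal(wm$theta, 0.4)

  # degenerate distribution: all ratios equal
  setc <- make_set(bx = c(0.1, 0.2, 0.4), sx = 0.01,
                   by = 0.25 * c(0.1, 0.2, 0.4), sy = 0.01)
  expect_equal(mr_weighted_median(setc, n_boot = 200, seed = 1)$theta, 0.25)

  # unequal weights against the explicit cumulative-weight scan
  set.seed(204)
  for (i in 1:25) {
    set <- random_set(J = sample(3:15, 1))
    inst <- set$instruments
    got <- mr_weighted_median(set, n_boot = 100, seed = i)
    want <- oracle_weighted_median(inst$wald_ratio, 1 / inst$wald_se^2)
    expect_equal(got$theta, want, tolerance = 1e-12)
    expect_gte(got$theta, min(inst$wald_ratio))
    expect_lte(got$theta, max(inst$wald_ratio))
  }
})

test_that("weighted median bootstrap is seeded and leaves the RNG alone", {
  set <- random_set(J = 8)
  set.seed(42); before <- runif(1)
  a <- mr_weighted_median(set, n_boot = 200, seed = 9)
  b <- mr_weighted_median(set, n_boot = 200, seed = 9)
  expect_identical(a, b)
  set.seed(42)
  expect_identical(runif(1), before)
  expect_error(mr_weighted_median(set, n_boot = 10), "at least 100")
})

test_that("contamination mixture recovers an uncontaminated common effect", {
  bx <- rep(0.1, 5)
  set <- make_set(bx, sx = 0.001, by = 0.3 * bx, sy = 0.0005)
  cm <- mr_conmix(set, psi = 0.1)
  expect_lt(abs(cm$theta_hat - 0.3), 1e-3)
  expect_true(all(cm$valid))
  expect_equal(nrow(cm$ci_set), 1)
  expect_true(cm$theta_hat >= cm$ci_set$low[1] &&
              cm$theta_hat <= cm$ci_set$high[1])
})

test_that("a symmetric two-mode set yields a (possibly disconnected) confidence set", {
  c0 <- 0.4
  ratios <- c(rep(c0, 4), rep(-c0, 4))
  set <- make_set(bx = rep(0.1, 8), sx = 0.001, by = 0.1 * ratios, sy = 0.002)
  cm <- mr_conmix(set, psi = 0.3, grid = seq(-1, 1, length.out = 4001))
  expect_lt(abs(abs(cm$theta_hat) - c0), 0.01)
  expect_gt(nrow(cm$ci_set), 1)  # two separated modes
})

test_that("contamination mixture recovers the causal effect under 1/3 contamination", {
  theta <- 0.27
  n_rep <- 200
  est <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    truth <- mr_truth(theta = theta, n_snps = 30,
                      pleiotropy_mode = "balanced",
                      alpha_dist = list(mean = 0, sd = 0.05),
                      invalid_fraction = 1 / 3, palindromic_fraction = 0,
                      seed = 6000 + r)
    sim <- generate_two_sample(truth)
    set <- harmonize(sim$exposure, sim$outcome)
    est[r] <- mr_conmix(set)$theta_hat
  }
  mc_se <- sd(est) / sqrt(n_rep)
  expect_lt(abs(mean(est) - theta), 3 * mc_se)
})

test_that("grid warnings and psi validation behave", {
  set <- random_set(J = 6, theta = 0.3)
  expect_warning(mr_conmix(set, psi = 0.1, grid = seq(5, 6, 0.01)),
                 "wider grid")
  expect_error(mr_conmix(set, psi = -1), "psi")
})

test_that("all estimators are equivariant under negating the exposure coding", {
  set.seed(205)
  set <- random_set(J = 10, theta = 0.25)
  neg <- set
  neg$instruments$beta_exposure <- -neg$instruments$beta_exposure
  neg$instruments$beta_outcome <- -neg$instruments$beta_outcome
  # ratios and their SEs are unchanged by construction
  expect_equal(neg$instruments$wald_ratio, set$instruments$wald_ratio)
  expect_equal(mr_ivw(set)$theta, mr_ivw(neg)$theta)
  expect_equal(mr_egger(set)$slope$theta, mr_egger(neg)$slope$theta)
  expect_equal(mr_egger(set)$intercept$estimate,
               mr_egger(neg)$intercept$estimate)
  expect_equal(mr_weighted_median(set, n_boot = 100, seed = 2)$theta,
               mr_weighted_median(neg, n_boot = 100, seed = 2)$theta)
  expect_equal(mr_conmix(set, psi = 0.1)$theta_hat,
               mr_conmix(neg, psi = 0.1)$theta_hat)
})
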