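test_that("null_variance follows the overlap-corrected formula", {
  expect_equal(null_variance(0.1, 0.2, 0, 0), 0.04)
  expect_equal(null_variance(0.1, 0.2, 2, 0), 0.08)
  expect_equal(null_variance(0.1, 0.2, 1, 0.01), 0.03)
  # with no overlap it reduces exactly to s_y^2 + theta^2 s_x^2
  sx <- runif(5, 0.01, 0.1); sy <- runif(5, 0.01, 0.1)
  expect_equal(null_variance(sx, sy, 0.7, 0), sy^2 + 0.49 * sx^2)
  expect_error(null_variance(0.01, 0.01, 1, 0.1), "non-positive")
})

test_that("EM identifies a pure null component in degenerate cases", {
  # all-zero residuals: the constrained free component has strictly lower
  # density at 0 than the null, so all mass goes to the null
  fit0 <- em_fit_two_component(rep(0, 10), 1)
  expect_equal(fit0$pi0_hat, 1)

  # residuals {+1, -1} with unit null variance: brute-force maximization
  # over (pi0, sigma2 >= 1 + eps) puts all mass on the null
  oracle <- brute_force_two_component(c(1, -1), 1)
  expect_equal(oracle$pi0, 1)
  fit1 <- em_fit_two_component(c(1, -1), 1)
  expect_equal(fit1$pi0_hat, 1)
  expect_equal(fit1$loglik, oracle$ll, tolerance = 1e-10)
})

test_that("EM fit matches the dense 2-D likelihood-grid oracle", {
  set.seed(101)
  r <- c(rnorm(1000, 0, 1), rnorm(1000, 0, 10))
  fit <- em_fit_two_component(r, 1)
  oracle <- brute_force_two_component(r, 1, pi_step = 0.005,
                                      sigma2_max = 400, n_sigma2 = 600)
  expect_equal(fit$pi0_hat, oracle$pi0, tolerance = 0.01)
  # oracle sigma2 grid is log-spaced; one step is ~2% relative
  expect_equal(fit$sigma2_hat, oracle$sigma2, tolerance = 0.05)
  expect_gte(fit$loglik, oracle$ll - 1e-6)
})

test_that("EM log-likelihood is non-decreasing at every iteration", {
  set.seed(202)
  for (case in 1:5) {
    n <- sample(50:300, 1)
    v <- runif(n, 0.5, 2)
    r <- ifelse(runif(n) < 0.6, rnorm(n, 0, sqrt(v)), rnorm(n, 0, 6))
    fit <- em_fit_two_component(r, v, trace = TRUE,
                                init = c(runif(1, 0.1, 0.9), runif(1, 3, 50)))
    expect_true(all(diff(fit$loglik_trace) >= -1e-8 *
                      pmax(abs(fit$loglik_trace[-1]), 1)))
    expect_true(fit$pi0_hat >= 0 && fit$pi0_hat <= 1)
    expect_gte(fit$sigma2_hat, max(v))
  }
})

test_that("pi0 profile peaks at the proportionality constant", {
  inst <- proportional_instruments(K = 60, slope = 0.5, se = 1e-4)
  prof <- pi0_profile(inst, grid = c(-0.5, 0, 0.25, 0.5, 0.9))
  at <- function(th) prof$pi0_hat[prof$theta_tilde == th]
  expect_equal(at(0.5), 1)
  expect_lt(at(-0.5), 1)
  expect_lt(at(0), 1)
  expect_error(pi0_profile(inst, grid = numeric(0)), "non-empty")
  expect_error(pi0_profile(inst[1, ], grid = 0), "at least 2")
})

test_that("pi0 profile separates the true effect on generated data", {
  sim <- scenario_a_replicate(n_x = 5e5, theta = 0.2, seed = 31)
  prof <- pi0_profile(sim$instruments, grid = c(-0.3, 0.2, 0.48))
  expect_gt(prof$pi0_hat[2], prof$pi0_hat[1])
  expect_gt(prof$pi0_hat[2], prof$pi0_hat[3])
})

test_that("exact proportionality is recovered for any slope in the grid", {
  for (slope in c(-0.6, 0.3)) {
    inst <- proportional_instruments(K = 40, slope = slope, se = 5e-5,
                                     seed = 8)
    fit <- suppressWarnings(mrmix_estimate(inst, se_method = "none"))
    expect_equal(fit$theta_hat, slope)
    expect_equal(fit$pi0_at_max, 1)
  }
})

test_that("the estimate is sign- and scale-equivariant", {
  sim <- scenario_a_replicate(n_x = 5e5, theta = 0.2, seed = 17)
  inst <- sim$instruments
  fit <- mrmix_estimate(inst, se_method = "none")

  neg <- inst
  neg$beta_y <- -inst$beta_y
  fit_neg <- mrmix_estimate(neg, se_method = "none")
  expect_equal(fit_neg$theta_hat, -fit$theta_hat)

  # scaling the outcome study by c scales theta_hat by c
  c_ <- 2
  sc <- inst
  sc$beta_y <- c_ * inst$beta_y
  sc$se_y <- c_ * inst$se_y
  fit_sc <- mrmix_estimate(sc, grid = seq(-2, 2, by = 0.02),
                           se_method = "none")
  expect_equal(fit_sc$theta_hat, c_ * fit$theta_hat, tolerance = 1e-12)

  # scaling the exposure study by c scales theta_hat by 1/c
  sx <- inst
  sx$beta_x <- c_ * inst$beta_x
  sx$se_x <- c_ * inst$se_x
  fit_sx <- mrmix_estimate(sx, grid = seq(-0.5, 0.5, by = 0.005),
                           se_method = "none")
  expect_equal(fit_sx$theta_hat, fit$theta_hat / c_, tolerance = 1e-12)
})

test_that("grid argmax equals a cold-start brute-force recomputation", {
  sim <- scenario_a_replicate(n_x = 2e5, theta = 0.2, seed = 23)
  inst <- sim$instruments
  grid <- seq(-0.4, 0.6, by = 0.05)
  fit <- mrmix_estimate(inst, grid = grid, se_method = "none")

  # independent recomputation: one cold-started EM per grid point, no
  # warm starts, same tie-break (largest pi0, then smallest |theta|)
  pi0s <- vapply(grid, function(th) {
    v <- null_variance(inst$se_x, inst$se_y, th)
    em_fit_two_component(inst$beta_y - th * inst$beta_x, v)$pi0_hat
  }, numeric(1))
  best <- which(pi0s == max(pi0s))
  best <- best[order(abs(grid[best]), grid[best])][1]
  expect_equal(fit$theta_hat, grid[best])
  expect_equal(fit$pi0_at_max, max(pi0s), tolerance = 1e-6)
})

test_that("valid-only instruments at large n give pi0 near 1 at theta", {
  cfg <- sim_config(n_x = 5e5, theta = 0.2, pi = c(0.02, 0, 0, 0.98))
  set.seed(41)
  eff <- simulate_true_effects(cfg)
  sim <- simulate_sumstats(eff, cfg)
  fit <- mrmix_estimate(sim$instruments, se_method = "none")
  expect_equal(fit$theta_hat, 0.2, tolerance = 0.011)
  expect_gt(fit$pi0_at_max, 0.95)
})

test_that("a flat profile triggers the non-identifiability warning", {
  set.seed(6)
  # null exposure effects with a tiny exposure SE: the residuals and their
  # null variances are essentially invariant in theta, so pi0 cannot
  # discriminate between candidate values
  inst <- data.frame(beta_x = rep(0, 60), se_x = 1e-6,
                     beta_y = rnorm(60, 0, 0.01), se_y = 0.01)
  expect_warning(mrmix_estimate(inst, se_method = "none"),
                 "flat|identified")
})

test_that("continuous refinement improves on a coarse grid argmax", {
  sim <- scenario_a_replicate(n_x = 5e5, theta = 0.2, seed = 47)
  grid <- seq(-1, 1, by = 0.05)
  coarse <- mrmix_estimate(sim$instruments, grid = grid,
                           se_method = "none")
  refined <- mrmix_estimate(sim$instruments, grid = grid, refine = TRUE,
                            se_method = "none")
  # refinement stays within one grid step of the argmax and cannot lower
  # the attained null mass
  expect_lte(abs(refined$theta_hat - coarse$theta_hat), 0.05)
  expect_gte(refined$pi0_at_max, coarse$pi0_at_max)
  # on this replicate the refined value should sit near the true 0.2
  expect_lt(abs(refined$theta_hat - 0.2), 0.05)
})
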