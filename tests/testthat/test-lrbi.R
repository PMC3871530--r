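test_that("prior_spec and lrbi_config validate their fields", {
  expect_error(prior_spec(c(0, 1), diag(3)), "2 x 2")
  expect_error(prior_spec(c(0, 1), matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
  expect_error(prior_spec(c(0, 1), -diag(2)), "positive definite")
  expect_error(prior_spec(0, alpha0 = 0), "alpha0")
  expect_error(lrbi_config(min_iters = 100, max_iters = 100), "min_iters")
  expect_error(lrbi_config(epsilon = -1), "epsilon")
})

test_that("conjugate posterior matches the hand-computed single-observation case", {
  # m = 3 coefficients, one observation with design column e1, response 2:
  # Lambda_n = I + e1 e1' = diag(2,1,1); mu_n = diag(1/2,1,1) (2,0,0)' = e1
  ds <- grn_dataset(Y = matrix(c(2, 1, 0), 3, 1), X = matrix(0, 3, 1))
  rr <- build_row_regression(ds, 1) # design rows: Y2=1, Y3=0, X1=0 -> e1
  prior <- prior_spec(rep(0, 3), diag(3), alpha0 = 1, beta0 = 1)
  post <- conjugate_posterior(rr, prior)
  expect_equal(unname(post$Lambda_n), diag(c(2, 1, 1)))
  expect_equal(post$mu_n, c(1, 0, 0))
  expect_equal(post$alpha_n, 1.5)
  # beta_n = 1 + (y'y - mu_n' Lambda_n mu_n)/2 = 1 + (4 - 2)/2 = 2
  expect_equal(post$beta_n, 2)
})

test_that("an overwhelming prior pins the posterior mean at mu0", {
  sim <- simulate_grn(sim_config(m = 4, n_samples = 10, ne = 2, seed = 31))
  rr <- build_row_regression(sim$dataset, 2)
  mu0 <- c(0.3, -0.2, 0.1, 0.9)
  post <- conjugate_posterior(rr, prior_spec(mu0, 1e8 * diag(4)))
  expect_equal(post$mu_n, mu0, tolerance = 1e-4)
})

test_that("the posterior mean approaches the OLS solution at large N", {
  sim <- simulate_grn(sim_config(m = 5, n_samples = 10000, ne = 2,
                                 sigma2 = 0.01, seed = 17))
  for (i in c(1, 4)) {
    rr <- build_row_regression(sim$dataset, i)
    post <- conjugate_posterior(rr, default_prior_builder()(rr))
    expect_equal(post$mu_n, unname(ols_row(rr)), tolerance = 1e-3)
  }
})

test_that("gibbs_step draws are reproducible and tracked in the state", {
  sim <- simulate_grn(sim_config(m = 4, n_samples = 30, ne = 2, seed = 41))
  rr <- build_row_regression(sim$dataset, 1)
  prior <- default_prior_builder()(rr)
  run <- function() {
    withr::with_seed(5, {
      st <- init_posterior_state(rr, prior)
      for (k in 1:20) st <- gibbs_step(st)
      st
    })
  }
  s1 <- run(); s2 <- run()
  expect_identical(s1$sample_history, s2$sample_history)
  expect_equal(s1$iteration, 20L)
  expect_equal(nrow(s1$sample_history), 20)
  expect_gt(s1$tau_sample, 0)
  expect_gt(s1$alpha_n, prior$alpha0)
})

test_that("the sampler's coefficient mean matches the closed-form mu_n", {
  sim <- simulate_grn(sim_config(m = 5, n_samples = 60, ne = 2, seed = 53))
  rr <- build_row_regression(sim$dataset, 3)
  prior <- default_prior_builder()(rr)
  draws <- withr::with_seed(7, {
    st <- init_posterior_state(rr, prior)
    for (k in 1:4000) st <- gibbs_step(st)
    st$sample_history
  })
  post <- conjugate_posterior(rr, prior)
  kept <- draws[2001:4000, ]
  mc_se <- apply(kept, 2, sd) / sqrt(nrow(kept))
  expect_true(all(abs(colMeans(kept) - post$mu_n) < 3 * mc_se + 1e-8))
})

test_that("draws concentrate on the generating coefficients when noise vanishes", {
  cfg <- sim_config(m = 5, n_samples = 1000, ne = 2, sigma2 = 1e-6, seed = 61)
  sim <- simulate_grn(cfg)
  rr <- build_row_regression(sim$dataset, 2)
  fit <- withr::with_seed(9, infer_row(rr, default_prior_builder()(rr),
                                       lrbi_config(max_iters = 1500)))
  truth <- c(sim$model$B[2, setdiff(1:5, 2)], 1)
  expect_lt(max(abs(fit$estimate - truth)), 0.02)
})

test_that("infer_row obeys the stopping rule bounds", {
  sim <- simulate_grn(sim_config(m = 4, n_samples = 50, ne = 2, seed = 71))
  rr <- build_row_regression(sim$dataset, 1)
  prior <- default_prior_builder()(rr)
  # huge epsilon: converges at the first checkpoint after the baseline
  fit <- withr::with_seed(1, infer_row(rr, prior,
    lrbi_config(epsilon = 1e6, min_iters = 200, check_every = 50)))
  expect_true(fit$converged)
  expect_equal(fit$iterations, 250L)
  expect_equal(fit$n_averaged, 250L - 125L)
  # max_iters cap: flagged non-converged but an estimate is still returned
  fit2 <- withr::with_seed(1, infer_row(rr, prior,
    lrbi_config(epsilon = 1e-300, min_iters = 200, max_iters = 400)))
  expect_false(fit2$converged)
  expect_equal(fit2$iterations, 400L)
  expect_true(all(is.finite(fit2$estimate)))
})

test_that("tightening epsilon does not hurt agreement with mu_n", {
  sim <- simulate_grn(sim_config(m = 5, n_samples = 100, ne = 2, seed = 81))
  rr <- build_row_regression(sim$dataset, 4)
  prior <- default_prior_builder()(rr)
  post <- conjugate_posterior(rr, prior)
  gap <- function(eps) {
    gaps <- vapply(1:20, function(s) {
      fit <- withr::with_seed(s, infer_row(rr, prior,
        lrbi_config(epsilon = eps, min_iters = 200, max_iters = 4000)))
      sqrt(sum((fit$estimate - post$mu_n)^2))
    }, numeric(1))
    mean(gaps)
  }
  expect_lte(gap(5e-6), gap(1e-5) * 1.05)
})

test_that("infer_network recovers a noise-free identifiable network", {
  cfg <- sim_config(m = 6, n_samples = 400, ne = 2, sigma2 = 1e-8, seed = 91)
  sim <- simulate_grn(cfg)
  fit <- infer_network(sim$dataset, lrbi_config(seed = 91))
  expect_lt(max(abs(fit$B_hat - sim$model$B)), 1e-2)
  expect_lt(max(abs(fit$F_hat - 1)), 1e-2)
})

test_that("infer_network output honors its structural invariants", {
  sim <- simulate_grn(sim_config(m = 8, n_samples = 40, ne = 3, seed = 101))
  cfg <- lrbi_config(seed = 101)
  fit <- infer_network(sim$dataset, cfg)
  expect_true(all(diag(fit$B_hat) == 0))
  expect_true(all(abs(fit$edges$weight) >= cfg$threshold))
  expect_length(fit$per_gene_iters, 8)
  # determinism under a fixed seed
  fit2 <- infer_network(sim$dataset, cfg)
  expect_identical(fit$B_hat, fit2$B_hat)
  # threshold nesting on one fixed inference
  e05 <- apply_threshold(fit, 0.05)$edges
  e10 <- apply_threshold(fit, 0.10)$edges
  e20 <- apply_threshold(fit, 0.20)$edges
  key <- function(e) paste(e$target_index, e$regulator_index)
  expect_true(all(key(e10) %in% key(e05)))
  expect_true(all(key(e20) %in% key(e10)))
})

test_that("an empty network yields few spurious edges at large N", {
  false_rates <- vapply(1:20, function(s) {
    m <- 5; N <- 300
    model <- grn_model(matrix(0, m, m))
    X <- withr::with_seed(s, matrix(sample(0:2, m * N, replace = TRUE,
                                           prob = c(0.25, 0.5, 0.25)), m, N))
    ds <- generate_expression(model, X, noise_spec(0.01), seed = s)
    fit <- infer_network(ds, lrbi_config(seed = s))
    nrow(fit$edges) / (m * (m - 1))
  }, numeric(1))
  expect_lt(mean(false_rates), 0.05)
})

test_that("standardized inference runs and preserves the edge directionality", {
  sim <- simulate_grn(sim_config(m = 5, n_samples = 100, ne = 2, seed = 111))
  fit <- infer_network(sim$dataset, lrbi_config(seed = 111, standardize = TRUE))
  expect_true(all(diag(fit$B_hat) == 0))
  expect_true(all(is.finite(fit$B_hat)))
})
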