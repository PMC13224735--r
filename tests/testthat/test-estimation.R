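test_that("regression-derived starts recover a single-class configuration", {
  d <- one_class_data(404, N = 150, n_i = 10, beta = c(7, 0), tau = c(-2, 0))
  st <- init_from_regressions(d, lcls_model(1, 1))
  expect_lt(abs(st$beta[1, 1] - 7), 0.1)
  expect_lt(abs(st$beta[1, 2]), 0.1)
  expect_lt(abs(st$tau[1, 1] + 2), 0.5)
})

test_that("starts are deterministic given the seed and spread across classes", {
  d <- one_class_data(405)
  a <- init_from_regressions(d, lcls_model(3, 2), seed = 9, jitter_sd = 0.3)
  b <- init_from_regressions(d, lcls_model(3, 2), seed = 9, jitter_sd = 0.3)
  expect_identical(a, b)
  noj <- init_from_regressions(d, lcls_model(3, 2))
  expect_true(all(diff(noj$beta[, 1]) > 0))  # distinct, ordered intercepts
  expect_true(all(diff(noj$tau[, 1]) > 0))
  expect_equal(noj$pi_location, rep(1 / 3, 3))
})

test_that("degenerate designs fall back to intercept-only starts", {
  d <- lcls_data(rep(1:3, each = 2), rep(2, 6), rep(5, 6))
  expect_warning(st <- init_from_regressions(d, lcls_model(1, 1)),
                 "intercept-only")
  expect_equal(st$beta[1, 2], 0)
  expect_equal(st$beta[1, 1], 5)
})

test_that("single-class MAP matches the closed-form heteroscedastic MLE", {
  # two time points saturate the linear mean and log-linear variance models,
  # so the MLE is available in closed form from the group moments
  set.seed(77)
  N <- 40
  id <- rep(1:N, each = 4); tt <- rep(c(0, 0, 1, 1), N)
  y <- rnorm(4 * N, 5 + 0.7 * tt, sd = ifelse(tt == 0, 0.4, 0.9))
  d <- lcls_data(id, tt, y)
  fit <- fit_map(d, lcls_model(1, 1), fit_config(engine = "map", seed = 1))
  m0 <- mean(y[tt == 0]); m1 <- mean(y[tt == 1])
  v0 <- mean((y[tt == 0] - m0)^2); v1 <- mean((y[tt == 1] - m1)^2)
  expect_equal(unname(fit$estimate$beta[1, ]), c(m0, m1 - m0),
               tolerance = 1e-6)
  expect_equal(unname(fit$estimate$tau[1, ]), c(log(v0), log(v1) - log(v0)),
               tolerance = 1e-6)
})

test_that("the fitted optimum dominates the generating parameters", {
  sim <- simulate_lcls(scenario1_spec(seed = 17, n_subjects = 40,
                                      obs_per_period = 3))
  fit <- fit_map(sim$data, lcls_model(3, 3), fit_config(engine = "map", seed = 2))
  expect_gte(fit$loglik, marginal_loglik(sim$data, sim$truth$params)$total)
})

test_that("MAP reports classes in canonical order and relabeling is idempotent", {
  sim <- simulate_lcls(scenario1_spec(seed = 18, n_subjects = 60,
                                      obs_per_period = 4))
  fit <- fit_map(sim$data, lcls_model(3, 3), fit_config(engine = "map", seed = 3))
  expect_true(all(diff(fit$estimate$beta[, 1]) > 0))
  expect_true(all(diff(fit$estimate$tau[, 1]) > 0))
  expect_equal(relabel_params(fit$estimate), fit$estimate)
  # relabeling an intentionally scrambled set restores the same object
  scrambled <- permute_classes(fit$estimate, c(3, 1, 2), c(2, 1, 3))
  expect_equal(relabel_params(scrambled), fit$estimate)
})

test_that("MAP recovers scenario parameters on a reduced design", {
  sim <- simulate_lcls(scenario1_spec(seed = 19, n_subjects = 120,
                                      obs_per_period = 5))
  fit <- fit_map(sim$data, lcls_model(3, 3), fit_config(engine = "map", seed = 4))
  expect_true(fit$diagnostics$converged)
  perm <- align_labels(fit$estimate, sim$truth$params)
  est <- permute_classes(fit$estimate, perm$location, perm$scale)
  expect_lt(max(abs(est$beta - sim$truth$params$beta)), 0.08)
  expect_lt(max(abs(est$tau[, 1] - sim$truth$params$tau[, 1])), 0.3)
  expect_lt(max(abs(est$pi_location - 1 / 3)), 0.15)
})

test_that("Wald intervals are ordered and finite for a converged MAP fit", {
  d <- one_class_data(406, N = 60, n_i = 8)
  fit <- fit_map(d, lcls_model(1, 1), fit_config(engine = "map", seed = 5))
  expect_true(all(fit$ci$lower <= fit$ci$upper))
  expect_true(all(is.finite(fit$ci$estimate)))
  expect_true(all(is.finite(fit$ci$lower[1:4])))  # beta/tau rows
})
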