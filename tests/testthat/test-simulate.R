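test_that("scenario 1 carries the benchmark generating configuration", {
  sp <- scenario1_spec()
  expect_equal(unname(sp$truth$beta[1, ]), c(6.92, -0.02))
  expect_equal(unname(sp$truth$beta[, 1]), c(6.92, 7.15, 7.38))
  expect_equal(unname(sp$truth$tau[3, ]), c(-0.78, 0.02))
  expect_equal(unname(sp$truth$tau[, 2]), c(0.02, 0.06, 0.02))
  expect_equal(sp$truth$pi_location, rep(1 / 3, 3))
  expect_equal(c(sp$n_subjects, sp$n_periods, sp$obs_per_period),
               c(250, 12, 10))
})

test_that("generation yields the designed dimensions and is seed-deterministic", {
  sim <- simulate_lcls(scenario1_spec(seed = 7))
  expect_equal(length(sim$data$outcomes), 250 * 12 * 10)
  expect_equal(sim$data$n_subjects, 250)
  expect_true(all(sim$data$n_per_subject == 120))
  again <- simulate_lcls(scenario1_spec(seed = 7))
  expect_identical(sim$data$outcomes, again$data$outcomes)
  expect_identical(sim$truth$location_class, again$truth$location_class)
  other <- simulate_lcls(scenario1_spec(seed = 8))
  expect_false(identical(sim$data$outcomes, other$data$outcomes))
})

test_that("generated within-period variance follows exp(tau0 + tau1 t)", {
  # tau1 = 0, tau0 = log 4: every period's pooled variance should sit in the
  # central 95% chi-square band for var = 4
  truth <- lcls_params(beta = cbind(0, 0), tau = cbind(log(4), 0))
  spec <- scenario2_spec(seed = 13, n_subjects = 50, n_periods = 6,
                         obs_per_period = 10, truth = truth)
  sim <- simulate_lcls(spec)
  for (per in 0:5) {
    v <- var(sim$data$outcomes[sim$data$times == per])
    n <- sum(sim$data$times == per)
    band <- 4 * c(qchisq(0.025, n - 1), qchisq(0.975, n - 1)) / (n - 1)
    expect_gt(v, band[1]); expect_lt(v, band[2])
  }
})

test_that("a near-zero noise surrogate recovers the mean line", {
  truth <- lcls_params(beta = cbind(0, 1), tau = cbind(-20, 0))
  sim <- simulate_lcls(scenario2_spec(seed = 3, n_subjects = 5, n_periods = 8,
                                      obs_per_period = 2, truth = truth))
  expect_equal(sim$data$outcomes, sim$data$times, tolerance = 1e-3)
})

test_that("class draws follow the multinomial probabilities", {
  sim <- simulate_lcls(scenario1_spec(seed = 99, n_subjects = 3000,
                                      n_periods = 1, obs_per_period = 1))
  props <- tabulate(sim$truth$location_class, 3) / 3000
  # 1/3 each, binomial 99.9% band
  half_width <- 3.3 * sqrt((1 / 3) * (2 / 3) / 3000)
  expect_true(all(abs(props - 1 / 3) < half_width))
})

test_that("the observation filter drops sparse weeks then sparse subjects", {
  # subject A: week counts (3, 3, 2) -> week 2 dropped, subject kept (6 obs)
  # subject B: week counts (2, 2, 2) -> dropped entirely
  id <- c(rep("A", 8), rep("B", 6))
  wk <- c(rep(0, 3), rep(1, 3), rep(2, 2), rep(0, 2), rep(1, 2), rep(2, 2))
  d <- lcls_data(id, wk, seq_along(id))
  f <- smart_filter(d)
  expect_equal(f$n_subjects, 1L)
  expect_equal(f$subjects, "A")
  expect_equal(length(f$outcomes), 6L)
  expect_equal(unique(floor(f$times)), c(0, 1))
  # order preserved and values untouched
  expect_equal(f$outcomes, 1:6)
})

test_that("the observation filter is the identity when every subject qualifies", {
  sim <- simulate_lcls(scenario1_spec(seed = 5, n_subjects = 10))
  f <- smart_filter(sim$data)
  expect_identical(f$outcomes, sim$data$outcomes)
  expect_identical(f$subject_ids, sim$data$subject_ids)
})

test_that("the observation filter returns an empty dataset with a warning", {
  d <- lcls_data(c("a", "a"), c(0, 1), c(1, 2))
  expect_warning(f <- smart_filter(d), "empty")
  expect_equal(f$n_subjects, 0L)
})
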