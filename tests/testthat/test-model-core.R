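test_that("conditional subject log-likelihood matches closed forms", {
  d <- lcls_data("a", 0, 0)
  p0 <- lcls_params(beta = cbind(0, 0), tau = cbind(0, 0))
  expect_equal(conditional_subject_loglik(d, 1, 1, 1, p0),
               -0.5 * log(2 * pi))
  # zero residual at arbitrary log-variance intercept
  for (tau0 in c(-2, 0, 1.3)) {
    d2 <- lcls_data("a", 0, 4.2)
    p2 <- lcls_params(beta = cbind(4.2, 0), tau = cbind(tau0, 0))
    expect_equal(conditional_subject_loglik(d2, 1, 1, 1, p2),
                 -0.5 * log(2 * pi) - 0.5 * tau0)
  }
})

test_that("conditional subject log-likelihood equals a per-observation dnorm sum", {
  truth <- table6_truth()
  set.seed(808)
  tt <- 0:4
  y <- rnorm(5, truth$beta[1, 1] + truth$beta[1, 2] * tt,
             sqrt(exp(truth$tau[1, 1] + truth$tau[1, 2] * tt)))
  d <- lcls_data(rep("s1", 5), tt, y)
  oracle <- sum(dnorm(y, truth$beta[1, 1] + truth$beta[1, 2] * tt,
                      sqrt(exp(truth$tau[1, 1] + truth$tau[1, 2] * tt)),
                      log = TRUE))
  expect_equal(conditional_subject_loglik(d, 1, 1, 1, truth), oracle)
})

test_that("conditional subject log-likelihood validates its indices", {
  d <- lcls_data(c("a", "b"), c(0, 0), c(1, 2))
  p <- lcls_params(beta = cbind(0, 0), tau = cbind(0, 0))
  expect_error(conditional_subject_loglik(d, 1, 2, 1, p), "out of range")
  expect_error(conditional_subject_loglik(d, 1, 1, 5, p), "out of range")
  expect_error(conditional_subject_loglik(d, 3, 1, 1, p), "out of range")
})

test_that("marginal log-likelihood reduces to the conditional when L = S = 1", {
  inst <- toy_instance(21, L = 1, S = 1)
  ml <- marginal_loglik(inst$data, inst$params)
  direct <- vapply(seq_len(inst$data$n_subjects), function(i)
    conditional_subject_loglik(inst$data, i, 1, 1, inst$params), 0)
  expect_equal(ml$per_subject, direct)
  expect_equal(ml$total, sum(direct))
})

test_that("marginal log-likelihood is invariant under class relabeling", {
  for (seed in c(31, 32, 33)) {
    inst <- toy_instance(seed, L = 3, S = 2)
    base <- marginal_loglik(inst$data, inst$params)$total
    pl <- sample(3); ps <- sample(2)
    permuted <- permute_classes(inst$params, pl, ps)
    expect_equal(marginal_loglik(inst$data, permuted)$total, base,
                 tolerance = 1e-10)
  }
})

test_that("marginal log-likelihood matches naive probability-space enumeration", {
  truth <- table6_truth()
  set.seed(55)
  id <- rep(1:10, each = 8)
  tt <- rep(0:7, 10)
  loc <- sample(3, 10, replace = TRUE); sca <- sample(3, 10, replace = TRUE)
  y <- rnorm(80, truth$beta[loc[id %/% 8 + 1], 1], 0.5)  # arbitrary data
  d <- lcls_data(id, tt, y)
  expect_equal(marginal_loglik(d, truth)$per_subject, naive_marginal(d, truth),
               tolerance = 1e-8)
  # and on random parameter sets
  for (seed in c(61, 62)) {
    inst <- toy_instance(seed, N = 8, n_i = 6, L = 3, S = 3)
    expect_equal(marginal_loglik(inst$data, inst$params)$per_subject,
                 naive_marginal(inst$data, inst$params), tolerance = 1e-8)
  }
})

test_that("marginal log-likelihood rejects non-simplex class probabilities", {
  expect_error(lcls_params(beta = cbind(c(0, 1), c(0, 0)),
                           tau = cbind(0, 0), pi_location = c(0.7, 0.2)),
               "sum to 1")
  expect_error(lcls_params(beta = cbind(c(0, 1), c(0, 0)), tau = cbind(0, 0),
                           pi_location = c(1.2, -0.2)), "nonnegative")
})

test_that("posterior memberships fall back to the prior when classes are identical", {
  inst <- toy_instance(71, L = 1, S = 1)
  pi_l <- c(0.2, 0.5, 0.3); pi_s <- c(0.6, 0.4)
  p <- lcls_params(beta = inst$params$beta[c(1, 1, 1), ],
                   tau = inst$params$tau[c(1, 1), ],
                   pi_location = pi_l, pi_scale = pi_s)
  mem <- posterior_memberships(inst$data, p)
  for (i in seq_len(inst$data$n_subjects)) {
    expect_equal(unname(mem$eta_location[i, ]), pi_l, tolerance = 1e-12)
    expect_equal(unname(mem$eta_scale[i, ]), pi_s, tolerance = 1e-12)
  }
})

test_that("posterior memberships are exactly 1 in the degenerate single-class model", {
  inst <- toy_instance(72, L = 1, S = 1)
  mem <- posterior_memberships(inst$data, inst$params)
  expect_true(all(mem$eta_location == 1))
  expect_true(all(mem$eta_scale == 1))
})

test_that("posterior memberships match the naive joint-table oracle", {
  for (seed in c(81, 82, 83)) {
    inst <- toy_instance(seed, N = 7, n_i = 6, L = 3, S = 2)
    mem <- posterior_memberships(inst$data, inst$params)
    oracle <- naive_memberships(inst$data, inst$params)
    expect_equal(unname(mem$eta_location), oracle$eta_location,
                 tolerance = 1e-8)
    expect_equal(unname(mem$eta_scale), oracle$eta_scale, tolerance = 1e-8)
    expect_equal(rowSums(mem$eta_location), rep(1, 7), tolerance = 1e-10)
    expect_equal(rowSums(mem$eta_scale), rep(1, 7), tolerance = 1e-10)
  }
})

test_that("modal assignment takes the argmax and breaks ties low", {
  mem <- mk_membership(rbind(c(0.2, 0.5, 0.3), c(0.5, 0.3, 0.2)),
                       rbind(c(0.5, 0.5), c(0.1, 0.9)))
  asg <- assign_classes(mem)
  expect_identical(asg$location_class, c(2L, 1L))
  expect_identical(asg$scale_class, c(1L, 2L))
})

test_that("modal assignment agrees with the joint-table oracle marginals", {
  inst <- toy_instance(91, N = 9, n_i = 7, L = 3, S = 3)
  mem <- posterior_memberships(inst$data, inst$params)
  oracle <- naive_memberships(inst$data, inst$params)
  asg <- assign_classes(mem)
  expect_identical(asg$location_class,
                   max.col(oracle$eta_location, ties.method = "first"))
  expect_identical(asg$scale_class,
                   max.col(oracle$eta_scale, ties.method = "first"))
})

test_that("entropy hits its endpoints and matches the hand formula", {
  crisp <- mk_membership(diag(3)[c(1, 2, 3, 1), ], diag(2)[c(1, 2, 1, 2), ])
  e <- entropy_summary(crisp)
  expect_equal(e$e_location, 1)
  expect_equal(e$e_scale, 1)
  unif <- mk_membership(matrix(1 / 3, 4, 3), matrix(0.5, 4, 2))
  e0 <- entropy_summary(unif)
  expect_equal(e0$e_location, 0)
  expect_equal(e0$e_scale, 0)
  # two subjects, rows (0.9, 0.1) and (0.6, 0.4): hand-computed Shannon terms
  h <- function(p) -(p * log(p) + (1 - p) * log(1 - p))
  mem <- mk_membership(rbind(c(0.9, 0.1), c(0.6, 0.4)),
                       rbind(c(1, 0), c(1, 0)))
  expect_equal(entropy_summary(mem)$e_location,
               1 - (h(0.9) + h(0.6)) / (2 * log(2)))
})

test_that("entropy is flagged undefined for a single class", {
  mem <- mk_membership(matrix(1, 3, 1), matrix(0.5, 3, 2))
  e <- entropy_summary(mem)
  expect_false(e$defined_location)
  expect_true(is.na(e$e_location))
  expect_true(e$defined_scale)
})

test_that("entropy stays in [0, 1] and never decreases under concentration", {
  set.seed(99)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    eta <- matrix(rexp(5 * k), 5, k)
    eta <- eta / rowSums(eta)
    mem <- mk_membership(eta, eta)
    e <- entropy_summary(mem)$e_location
    expect_gte(e, 0); expect_lte(e, 1)
    # push one row halfway toward its modal vertex: strictly more concentrated
    i <- sample(5, 1)
    vertex <- diag(k)[max.col(eta, ties.method = "first")[i], ]
    eta2 <- eta
    eta2[i, ] <- 0.5 * (eta[i, ] + vertex)
    e2 <- entropy_summary(mk_membership(eta2, eta2))$e_location
    expect_gte(e2, e - 1e-12)
  }
})

test_that("reporting transforms reproduce the published summary values", {
  p <- lcls_params(beta = cbind(c(6.916, 7.151, 7.375),
                                c(-0.023, -0.011, -0.009)),
                   tau = cbind(c(-2.411, -1.738, -0.775),
                               c(0.024, 0.058, 0.022)))
  tr <- report_transforms(p, elapsed_time = 11)
  expect_equal(round(tr$location$pct_decrease, 1), c(22.4, 11.4, 9.4))
  expect_equal(round(tr$scale$baseline_ws_variance, 3), c(0.090, 0.176, 0.461))
  # zero slope means zero change
  p0 <- lcls_params(beta = cbind(7, 0), tau = cbind(-1, 0))
  expect_equal(report_transforms(p0, 11)$location$pct_decrease, 0)
})
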