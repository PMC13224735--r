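test_that("label alignment recovers identity, swaps, and noisy matches", {
  truth <- table6_truth()
  expect_equal(align_labels(truth, truth),
               list(location = 1:3, scale = 1:3))
  swapped <- permute_classes(truth, c(2, 1, 3), c(3, 2, 1))
  al <- align_labels(swapped, truth)
  expect_equal(al$location, c(2, 1, 3))
  expect_equal(al$scale, c(3, 2, 1))
  expect_equal(permute_classes(swapped, al$location, al$scale)$beta,
               truth$beta)
  # noisy estimates: exhaustive alignment agrees with nearest-row matching
  set.seed(51)
  for (rep in 1:5) {
    noisy <- lcls_params(beta = truth$beta + rnorm(6, 0, 0.02),
                         tau = truth$tau + rnorm(6, 0, 0.02))
    pl <- sample(3); ps <- sample(3)
    est <- permute_classes(noisy, pl, ps)
    al <- align_labels(est, truth)
    aligned <- permute_classes(est, al$location, al$scale)
    expect_equal(aligned$beta, noisy$beta, tolerance = 1e-12)
    expect_equal(aligned$tau, noisy$tau, tolerance = 1e-12)
  }
})

# minimal hand-built fit object accepted by evaluate_replications
fake_fit <- function(est, ci_width = 0.2, eta_loc, eta_sca, converged = TRUE) {
  cv <- lcls:::params_to_constrained(est)
  ci <- data.frame(parameter = names(cv), estimate = unname(cv),
                   lower = unname(cv) - ci_width / 2,
                   upper = unname(cv) + ci_width / 2)
  structure(list(engine = "map", estimate = est, ci = ci,
                 membership = mk_membership(eta_loc, eta_sca),
                 diagnostics = list(converged = converged)),
            class = "lcls_fit")
}

test_that("perfect estimates give zero bias and full coverage", {
  truth <- table6_truth()
  tr <- structure(list(params = truth, location_class = c(1L, 2L),
                       scale_class = c(3L, 1L)), class = "lcls_truth")
  eta_l <- rbind(c(1, 0, 0), c(0, 1, 0))
  eta_s <- rbind(c(0, 0, 1), c(1, 0, 0))
  fit <- fake_fit(truth, 0.2, eta_l, eta_s)
  rep <- evaluate_replications(list(fit), list(tr))
  expect_equal(rep$parameters$bias, rep(0, 18))
  expect_equal(rep$parameters$coverage, rep(100, 18))
  expect_equal(rep$parameters$aiw, rep(0.2, 18))
  expect_equal(rep$loc_correct_rate, 100)
  expect_equal(rep$scale_correct_rate, 100)
  expect_equal(rep$loc_confident_rate, 100)
  expect_equal(rep$n_label_switched, 0)
})

test_that("classification rates match a hand count on two subjects", {
  truth <- table6_truth()
  tr <- structure(list(params = truth, location_class = c(1L, 2L),
                       scale_class = c(1L, 2L)), class = "lcls_truth")
  # subject 1 misclassified on location, confident; subject 2 correct, fuzzy
  eta_l <- rbind(c(0.05, 0.95, 0), c(0.2, 0.6, 0.2))
  eta_s <- rbind(c(0.95, 0.05, 0), c(0.1, 0.85, 0.05))
  fit <- fake_fit(truth, 0.2, eta_l, eta_s)
  rep <- evaluate_replications(list(fit), list(tr))
  expect_equal(rep$loc_correct_rate, 50)
  expect_equal(rep$scale_correct_rate, 100)
  expect_equal(rep$loc_confident_rate, 50)
  expect_equal(rep$scale_confident_rate, 50)
})

test_that("metrics are invariant to how the truth labels its classes", {
  truth <- table6_truth()
  set.seed(52)
  est <- lcls_params(beta = truth$beta + rnorm(6, 0, 0.01),
                     tau = truth$tau + rnorm(6, 0, 0.01))
  eta_l <- diag(3)[c(1, 2, 3, 2), ]
  eta_s <- diag(3)[c(3, 1, 2, 2), ]
  tr1 <- structure(list(params = truth,
                        location_class = c(1L, 2L, 3L, 2L),
                        scale_class = c(3L, 1L, 2L, 2L)),
                   class = "lcls_truth")
  fit1 <- fake_fit(est, 0.3, eta_l, eta_s)
  rep1 <- evaluate_replications(list(fit1), list(tr1))
  # permute the truth's class labels (and its class codes) the same way
  perm <- c(3, 1, 2)  # new order of old classes
  truth2 <- permute_classes(truth, perm, perm)
  relab <- match(seq_len(3), perm)
  tr2 <- structure(list(params = truth2,
                        location_class = relab[tr1$location_class],
                        scale_class = relab[tr1$scale_class]),
                   class = "lcls_truth")
  rep2 <- evaluate_replications(list(fit1), list(tr2))
  expect_equal(rep1$loc_correct_rate, rep2$loc_correct_rate)
  expect_equal(rep1$scale_correct_rate, rep2$scale_correct_rate)
  expect_equal(sort(rep1$parameters$bias), sort(rep2$parameters$bias),
               tolerance = 1e-12)
})

test_that("non-converged replications are excluded and counted", {
  truth <- table6_truth()
  tr <- structure(list(params = truth, location_class = 1L, scale_class = 1L),
                  class = "lcls_truth")
  ok <- fake_fit(truth, 0.2, matrix(c(1, 0, 0), 1), matrix(c(1, 0, 0), 1))
  bad <- fake_fit(truth, 0.2, matrix(c(1, 0, 0), 1), matrix(c(1, 0, 0), 1),
                  converged = FALSE)
  rep <- evaluate_replications(list(ok, bad), list(tr, tr))
  expect_equal(rep$n_converged, 1)
  expect_equal(rep$n_excluded, 1)
  expect_error(evaluate_replications(list(bad), list(tr)), "no converged")
})
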