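core_call <- function(data, params, want_grad = FALSE, want_cond = FALSE) {
  lcls_core(data$outcomes, data$time_unique,
            as.integer(data$time_index) - 1L,
            as.integer(data$subject_index) - 1L,
            data$n_subjects, params$beta, params$tau,
            params$pi_location, params$pi_scale, want_grad, want_cond)
}

#' Conditional subject log-likelihood given class memberships
#'
#' Log-likelihood of one subject's observations conditional on a specific
#' pair of location and scale classes: the sum over occasions of the normal
#' log density with mean `beta0_l + beta1_l * t` and variance
#' `exp(tau0_s + tau1_s * t)`.
#'
#' @param data an [lcls_data] object.
#' @param subject subject ordinal (1..N).
#' @param loc_class,scale_class class indices (1..L, 1..S).
#' @param params an [lcls_params] object.
#' @return a single numeric value.
#' @export
conditional_subject_loglik <- function(data, subject, loc_class, scale_class,
                                       params) {
  L <- n_loc(params); S <- n_scale_classes(params)
  subject <- as.integer(subject)
  if (is.na(subject) || subject < 1L || subject > data$n_subjects)
    stop("'subject' out of range 1..", data$n_subjects)
  if (loc_class < 1L || loc_class > L)
    stop("'loc_class' out of range 1..", L)
  if (scale_class < 1L || scale_class > S)
    stop("'scale_class' out of range 1..", S)
  sel <- data$subject_index == subject
  if (!any(sel)) stop("subject ", subject, " has no observations")
  t <- data$times[sel]; y <- data$outcomes[sel]
  mu <- params$beta[loc_class, 1] + params$beta[loc_class, 2] * t
  lv <- params$tau[scale_class, 1] + params$tau[scale_class, 2] * t
  sum(-0.5 * (log(2 * pi) + lv + (y - mu)^2 * exp(-lv)))
}

#' Marginal log-likelihood of a latent-class location-scale model
#'
#' For each subject, integrates the conditional likelihood over the L x S
#' grid of joint class memberships weighted by the class probabilities,
#' using log-sum-exp throughout; the total sums the per-subject values.
#'
#' @param data an [lcls_data] object.
#' @param params an [lcls_params] object.
#' @return list with `per_subject` (length N) and `total`.
#' @export
marginal_loglik <- function(data, params) {
  stopifnot(inherits(data, "lcls_data"), inherits(params, "lcls_params"))
  res <- core_call(data, params, want_grad = FALSE)
  list(per_subject = as.numeric(res$per_subject), total = res$total)
}

#' Posterior class-membership probabilities
#'
#' Bayes-rule posterior probabilities that each subject belongs to each
#' location class and each scale class, given the subject's data and a
#' parameter set. Computed in log space; each row sums to 1.
#'
#' @inheritParams marginal_loglik
#' @return an object of class `lcls_membership` with matrices
#'   `eta_location` (N x L) and `eta_scale` (N x S).
#' @export
posterior_memberships <- function(data, params) {
  stopifnot(inherits(data, "lcls_data"), inherits(params, "lcls_params"))
  res <- core_call(data, params, want_grad = FALSE)
  new_membership(res$eta_loc, res$eta_scale)
}

new_membership <- function(eta_location, eta_scale) {
  eta_location <- as.matrix(eta_location)
  eta_scale <- as.matrix(eta_scale)
  structure(list(eta_location = eta_location, eta_scale = eta_scale),
            class = "lcls_membership")
}

#' @export
print.lcls_membership <- function(x, ...) {
  cat(sprintf("posterior memberships for %d subjects (%d location x %d scale classes)\n",
              nrow(x$eta_location), ncol(x$eta_location), ncol(x$eta_scale)))
  invisible(x)
}

#' Modal class assignment
#'
#' Assigns each subject the class with the highest posterior membership
#' probability; ties are broken toward the smallest class index.
#'
#' @param membership an `lcls_membership` object.
#' @return list of class `lcls_assignment` with integer vectors
#'   `location_class` and `scale_class`.
#' @export
assign_classes <- function(membership) {
  stopifnot(inherits(membership, "lcls_membership"))
  structure(list(location_class = max.col(membership$eta_location,
                                          ties.method = "first"),
                 scale_class = max.col(membership$eta_scale,
                                       ties.method = "first")),
            class = "lcls_assignment")
}

#' Relative entropy of a classification
#'
#' One minus the average Shannon entropy of the membership rows, normalized
#' by `log(K)`: 1 for crisp (one-hot) memberships, 0 for uniform ones. The
#' convention `0 * log(0) = 0` applies. With a single class the quantity is
#' undefined (the `log(1)` normalizer vanishes) and is returned as `NA` with
#' the corresponding `defined_*` flag set to `FALSE`.
#'
#' @param membership an `lcls_membership` object.
#' @return list of class `lcls_entropy` with `e_location`, `e_scale` and
#'   logical flags `defined_location`, `defined_scale`.
#' @export
entropy_summary <- function(membership) {
  stopifnot(inherits(membership, "lcls_membership"))
  rel_entropy <- function(eta) {
    k <- ncol(eta)
    if (k < 2L) return(NA_real_)
    h <- -eta * log(eta)
    h[!is.finite(h)] <- 0  # 0 * log 0
    1 - sum(h) / (nrow(eta) * log(k))
  }
  structure(list(e_location = rel_entropy(membership$eta_location),
                 e_scale = rel_entropy(membership$eta_scale),
                 defined_location = ncol(membership$eta_location) >= 2L,
                 defined_scale = ncol(membership$eta_scale) >= 2L),
            class = "lcls_entropy")
}

#' @export
print.lcls_entropy <- function(x, ...) {
  fmt <- function(e, def) if (def) sprintf("%.3f", e) else "undefined (single class)"
  cat("relative entropy - location:", fmt(x$e_location, x$defined_location),
      "| scale:", fmt(x$e_scale, x$defined_scale), "\n")
  invisible(x)
}

#' Interpretation transforms for fitted classes
#'
#' For a log-transformed outcome, the location slope acts multiplicatively on
#' the original scale: over `elapsed_time` units the median outcome changes
#' by `100 * (1 - exp(beta1 * elapsed_time))` percent (reported as percent
#' decrease). On the scale side, `exp(tau0)` is the baseline within-subject
#' variance of each scale class.
#'
#' @param params an [lcls_params] object.
#' @param elapsed_time elapsed time span for the percent-change transform
#'   (e.g. 11 when time is coded 0 for the first week through 11 for the
#'   twelfth).
#' @return list of class `lcls_transforms` with data frames `location`
#'   (class, beta0, beta1, pct_decrease) and `scale` (class, tau0, tau1,
#'   baseline_ws_variance).
#' @export
report_transforms <- function(params, elapsed_time) {
  stopifnot(inherits(params, "lcls_params"), elapsed_time >= 0)
  L <- n_loc(params); S <- n_scale_classes(params)
  structure(list(
    location = data.frame(
      class = seq_len(L),
      beta0 = params$beta[, 1], beta1 = params$beta[, 2],
      pct_decrease = 100 * (1 - exp(params$beta[, 2] * elapsed_time)),
      row.names = NULL),
    scale = data.frame(
      class = seq_len(S),
      tau0 = params$tau[, 1], tau1 = params$tau[, 2],
      baseline_ws_variance = exp(params$tau[, 1]),
      row.names = NULL),
    elapsed_time = elapsed_time), class = "lcls_transforms")
}

#' @export
print.lcls_transforms <- function(x, digits = 3, ...) {
  cat(sprintf("location classes (percent decrease over %g time units):\n",
              x$elapsed_time))
  print(cbind(x$location[1] ,round(x$location[-1], digits)), row.names = FALSE)
  cat("scale classes (baseline within-subject variance exp(tau0)):\n")
  print(cbind(x$scale[1], round(x$scale[-1], digits)), row.names = FALSE)
  invisible(x)
}
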