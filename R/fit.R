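#' Fit configuration
#'
#' @param engine `"hmc"` for the Bayesian Hamiltonian Monte Carlo engine
#'   (flat priors, two-stage warm start) or `"map"` for the fast
#'   maximum-likelihood engine (multi-start quasi-Newton with
#'   observed-information intervals).
#' @param n_chains number of MCMC chains in the final stage.
#' @param n_iter total iterations per chain (including warm-up).
#' @param n_warmup warm-up iterations discarded from each chain.
#' @param seed integer seed controlling every stochastic step of the fit.
#' @param rhat_threshold convergence flag threshold for split-chain R-hat.
#' @param n_starts number of optimizer starts for the MAP engine.
#' @param max_leapfrog,target_accept HMC tuning knobs.
#' @return list of class `lcls_config`.
#' @export
fit_config <- function(engine = c("hmc", "map"), n_chains = 4L,
                       n_iter = 2000L, n_warmup = 500L, seed = 1L,
                       rhat_threshold = 1.01, n_starts = 5L,
                       max_leapfrog = 20L, target_accept = 0.8) {
  engine <- match.arg(engine)
  n_iter <- as.integer(n_iter); n_warmup <- as.integer(n_warmup)
  if (n_warmup >= n_iter) stop("'n_warmup' must be smaller than 'n_iter'")
  if (n_chains < 1L) stop("'n_chains' must be at least 1")
  structure(list(engine = engine, n_chains = as.integer(n_chains),
                 n_iter = n_iter, n_warmup = n_warmup,
                 seed = as.integer(seed), rhat_threshold = rhat_threshold,
                 n_starts = as.integer(n_starts),
                 max_leapfrog = as.integer(max_leapfrog),
                 target_accept = target_accept),
            class = "lcls_config")
}

#' Fit a latent-class location-scale model
#'
#' Dispatches to [fit_bayes()] or [fit_map()] according to
#' `config$engine`.
#'
#' @param data an [lcls_data] object.
#' @param model an [lcls_model].
#' @param config an [fit_config()] list.
#' @return an `lcls_fit` object; see [fit_bayes()] / [fit_map()].
#' @export
fit_lcls <- function(data, model, config = fit_config()) {
  stopifnot(inherits(config, "lcls_config"))
  switch(config$engine,
         hmc = fit_bayes(data, model, config),
         map = fit_map(data, model, config))
}

# log marginal likelihood and gradient on the unconstrained scale;
# include_jacobian adds the uniform-simplex (flat Dirichlet) prior term of
# the softmax parameterization, giving the Bayesian log posterior under flat
# priors. Without it the function is the profile used by the ML engine.
make_logpost <- function(data, L, S, include_jacobian = TRUE) {
  N <- data$n_subjects
  force(L); force(S)
  function(theta) {
    if (!all(is.finite(theta)) || max(abs(theta)) > 1e6)
      return(list(value = -Inf, grad = rep(0, length(theta))))
    pr <- tryCatch(unconstrained_to_params(theta, L, S),
                   error = function(e) NULL)
    if (is.null(pr)) return(list(value = -Inf, grad = rep(0, length(theta))))
    res <- core_call(data, pr, want_grad = TRUE)
    lp <- res$total
    if (!is.finite(lp)) return(list(value = -Inf, grad = rep(0, length(theta))))
    g_zl <- g_zs <- numeric(0)
    if (L > 1) g_zl <- colSums(res$eta_loc)[-1] - N * pr$pi_location[-1]
    if (S > 1) g_zs <- colSums(res$eta_scale)[-1] - N * pr$pi_scale[-1]
    if (include_jacobian) {
      lp <- lp + sum(log(pr$pi_location)) + sum(log(pr$pi_scale))
      if (L > 1) g_zl <- g_zl + (1 - L * pr$pi_location[-1])
      if (S > 1) g_zs <- g_zs + (1 - S * pr$pi_scale[-1])
    }
    grad <- c(res$gbeta[, 1], res$gbeta[, 2], res$gtau[, 1], res$gtau[, 2],
              g_zl, g_zs)
    list(value = lp, grad = grad)
  }
}

central_diff_hessian <- function(grad_fn, theta, h_rel = 1e-5) {
  d <- length(theta)
  H <- matrix(0, d, d)
  for (j in seq_len(d)) {
    h <- h_rel * (1 + abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    H[, j] <- (grad_fn(tp) - grad_fn(tm)) / (2 * h)
  }
  (H + t(H)) / 2
}

pinv_sym <- function(A, tol = 1e-10) {
  e <- eigen(A, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values), 1)
  if (!any(pos)) return(matrix(0, nrow(A), ncol(A)))
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

# delta-method covariance of the constrained parameter vector given the
# covariance of the unconstrained one
constrained_vcov <- function(vcov_u, params, L, S) {
  d <- nrow(vcov_u)
  nc <- 3 * L + 3 * S
  J <- matrix(0, nc, d)
  # beta/tau blocks map one-to-one
  for (j in seq_len(2 * L + 2 * S)) J[j, j] <- diag(1, 1)
  off_u <- 2 * L + 2 * S
  # pi_loc block: dp_k/dz_m = p_k (delta_km - p_m), m = 2..L
  if (L > 1) {
    p <- params$pi_location
    for (k in seq_len(L))
      for (m in 2:L)
        J[off_u + k, off_u + m - 1] <- p[k] * ((k == m) - p[m])
  }
  if (S > 1) {
    p <- params$pi_scale
    for (k in seq_len(S))
      for (m in 2:S)
        J[off_u + L + k, off_u + (L - 1) + m - 1] <- p[k] * ((k == m) - p[m])
  }
  J %*% vcov_u %*% t(J)
}

new_fit <- function(engine, model, data, config, estimate, ...) {
  structure(c(list(engine = engine, model = model, data = data,
                   config = config, estimate = estimate,
                   posterior_means = estimate), list(...)),
            class = "lcls_fit")
}

#' Maximum-likelihood fit (MAP under flat priors)
#'
#' Maximizes the marginal log-likelihood by multi-start BFGS with analytic
#' gradients, starting from [init_from_regressions()] plus jittered
#' replicates. Intervals come from the inverse observed information (Wald);
#' class probabilities use the delta method through the softmax
#' parameterization. Classes are relabeled to the canonical order
#' (ascending `beta0` / `tau0`) before reporting.
#'
#' @inheritParams fit_lcls
#' @return an `lcls_fit` with elements `estimate` ([lcls_params]), `ci`
#'   (data frame of 95% Wald intervals), `vcov`, `loglik`,
#'   `pointwise_loglik` (1 x N), `membership` (posterior memberships at the
#'   estimate) and `diagnostics`.
#' @export
fit_map <- function(data, model, config = fit_config(engine = "map")) {
  stopifnot(inherits(data, "lcls_data"), inherits(model, "lcls_model"))
  L <- model$n_location; S <- model$n_scale
  lp <- make_logpost(data, L, S, include_jacobian = FALSE)
  fn <- function(th) -lp(th)$value
  gr <- function(th) -lp(th)$grad
  best <- NULL; tried <- 0L; errors <- character(0)
  for (k in seq_len(config$n_starts)) {
    start_par <- init_from_regressions(data, model,
                                       seed = config$seed + 7L * k,
                                       jitter_sd = if (k == 1L) 0 else 0.35)
    th0 <- params_to_unconstrained(start_par)
    opt <- tryCatch(optim(th0, fn, gr, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12)),
                    error = function(e) e)
    tried <- tried + 1L
    if (inherits(opt, "error")) { errors <- c(errors, conditionMessage(opt)); next }
    if (!is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("all ", tried, " optimizer starts failed: ",
         paste(unique(errors), collapse = "; "))
  est <- relabel_params(unconstrained_to_params(best$par, L, S))
  theta <- params_to_unconstrained(est)
  grad_fn <- function(th) lp(th)$grad
  info <- -central_diff_hessian(grad_fn, theta)
  vcov_u <- tryCatch(solve(info), error = function(e) NULL)
  info_ok <- TRUE
  if (is.null(vcov_u) || any(!is.finite(vcov_u)) || any(diag(vcov_u) < 0)) {
    vcov_u <- pinv_sym(info)
    info_ok <- FALSE
  }
  vc <- constrained_vcov(vcov_u, est, L, S)
  cv <- params_to_constrained(est)
  se <- sqrt(pmax(diag(vc), 0))
  ci <- data.frame(parameter = names(cv), estimate = unname(cv),
                   se = se,
                   lower = unname(cv) - qnorm(0.975) * se,
                   upper = unname(cv) + qnorm(0.975) * se,
                   row.names = NULL)
  res <- core_call(data, est, want_grad = FALSE)
  grad_norm <- sqrt(sum(grad_fn(theta)^2))
  converged <- best$convergence == 0 && info_ok
  new_fit("map", model, data, config, est,
          theta = theta, vcov = vc, vcov_unconstrained = vcov_u, ci = ci,
          loglik = res$total,
          pointwise_loglik = matrix(res$per_subject, nrow = 1),
          membership = new_membership(res$eta_loc, res$eta_scale),
          draws = NULL, chain_id = NULL, rhat = NULL,
          diagnostics = list(converged = converged,
                             optim_convergence = best$convergence,
                             information_positive_definite = info_ok,
                             grad_norm = grad_norm, n_starts = tried,
                             rhat_threshold = config$rhat_threshold,
                             seed = config$seed))
}

#' Bayesian fit by Hamiltonian Monte Carlo
#'
#' Implements the two-stage estimation protocol: a single exploratory chain
#' started at regression-derived values, then `n_chains` chains all started
#' at the stage-1 posterior means, which tempers label switching. Priors are
#' flat: improper uniform on `beta` and `tau` and uniform (flat Dirichlet)
#' on each class-probability simplex via the softmax parameterization.
#' After sampling, every draw is relabeled to the canonical class order
#' (ascending `beta0` / `tau0`); the number of draws whose class order had
#' to be permuted is reported as `label_order_violations`.
#'
#' @inheritParams fit_lcls
#' @return an `lcls_fit` with posterior draws (`draws`, constrained scale,
#'   with `chain_id`), `posterior_means`, quantile `ci`, per-parameter
#'   `rhat`, `pointwise_loglik` (draws x N subject-level marginal
#'   log-likelihoods), posterior-mean `membership` and `diagnostics`
#'   (divergence counts, convergence flag).
#' @export
fit_bayes <- function(data, model, config = fit_config()) {
  stopifnot(inherits(data, "lcls_data"), inherits(model, "lcls_model"))
  L <- model$n_location; S <- model$n_scale
  lp <- make_logpost(data, L, S, include_jacobian = TRUE)
  start1 <- init_from_regressions(data, model, seed = config$seed)
  th0 <- params_to_unconstrained(start1)
  stage1 <- tryCatch(
    hmc_chain(lp, th0, config$n_iter, config$n_warmup,
              seed = config$seed + 101L, max_leapfrog = config$max_leapfrog,
              target_accept = config$target_accept),
    error = function(e) stop("stage-1 sampler failure: ", conditionMessage(e)))
  th_start2 <- colMeans(stage1$draws)
  chains <- vector("list", config$n_chains)
  divergences <- stage1$divergences
  for (ch in seq_len(config$n_chains)) {
    chains[[ch]] <- tryCatch(
      hmc_chain(lp, th_start2, config$n_iter, config$n_warmup,
                seed = config$seed + 1000L + ch,
                max_leapfrog = config$max_leapfrog,
                target_accept = config$target_accept),
      error = function(e) stop("sampler failure in chain ", ch, ": ",
                               conditionMessage(e)))
    divergences <- divergences + chains[[ch]]$divergences
  }
  n_keep <- config$n_iter - config$n_warmup
  theta_draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  chain_id <- rep(seq_len(config$n_chains), each = n_keep)
  # map to the constrained scale and relabel draw by draw
  cons <- matrix(NA_real_, nrow(theta_draws), 3 * L + 3 * S)
  violations <- 0L
  for (dd in seq_len(nrow(theta_draws))) {
    pr <- unconstrained_to_params(theta_draws[dd, ], L, S)
    ord <- class_order(pr)
    if (is.unsorted(ord$location) || is.unsorted(ord$scale))
      violations <- violations + 1L
    pr <- permute_classes(pr, ord$location, ord$scale)
    cons[dd, ] <- params_to_constrained(pr)
  }
  colnames(cons) <- par_names(L, S)
  post_mean <- colMeans(cons)
  est <- lcls_params(
    beta = cbind(post_mean[seq_len(L)], post_mean[L + seq_len(L)]),
    tau = cbind(post_mean[2 * L + seq_len(S)], post_mean[2 * L + S + seq_len(S)]),
    pi_location = normalize_simplex(post_mean[2 * L + 2 * S + seq_len(L)]),
    pi_scale = normalize_simplex(post_mean[2 * L + 2 * S + L + seq_len(S)]))
  qs <- t(apply(cons, 2, quantile, probs = c(0.025, 0.975), names = FALSE))
  ci <- data.frame(parameter = colnames(cons), estimate = unname(post_mean),
                   lower = qs[, 1], upper = qs[, 2], row.names = NULL)
  rhat <- apply(cons, 2, split_rhat, chain_id = chain_id)
  pw <- lcls_pointwise(data$outcomes, data$time_unique,
                       as.integer(data$time_index) - 1L,
                       as.integer(data$subject_index) - 1L,
                       data$n_subjects, cons, L, S)
  converged <- all(rhat[is.finite(rhat)] <= config$rhat_threshold) &&
    !any(is.infinite(rhat))
  new_fit("hmc", model, data, config, est,
          draws = cons, chain_id = chain_id, ci = ci, rhat = rhat,
          loglik = sum(pw$pointwise[which.max(rowSums(pw$pointwise)), ]),
          pointwise_loglik = pw$pointwise,
          membership = new_membership(pw$eta_loc, pw$eta_scale),
          stage1_means = th_start2,
          diagnostics = list(converged = converged, divergences = divergences,
                             label_order_violations = violations,
                             accept_rates = vapply(chains, `[[`, 0, "accept_rate"),
                             step_sizes = vapply(chains, `[[`, 0, "step_size"),
                             rhat_threshold = config$rhat_threshold,
                             seed = config$seed))
}

normalize_simplex <- function(p) {
  p <- pmax(p, 0)
  p / sum(p)
}

#' @export
print.lcls_fit <- function(x, ...) {
  cat(sprintf("lcls fit (%s engine): %d location x %d scale classes, %d subjects\n",
              x$engine, x$model$n_location, x$model$n_scale,
              x$data$n_subjects))
  cat(sprintf("  converged: %s", x$diagnostics$converged))
  if (x$engine == "hmc")
    cat(sprintf(" | max R-hat %.3f | divergences %d",
                suppressWarnings(max(x$rhat, na.rm = TRUE)),
                x$diagnostics$divergences))
  cat("\n")
  print(x$estimate)
  invisible(x)
}

#' @export
coef.lcls_fit <- function(object, ...) params_to_constrained(object$estimate)

#' @export
logLik.lcls_fit <- function(object, ...) {
  structure(object$loglik, df = n_unconstrained(object$model$n_location,
                                                object$model$n_scale),
            class = "logLik")
}

#' Posterior membership probabilities of a fit
#'
#' For the HMC engine the default is the posterior mean of the membership
#' probabilities across draws (matching modal classification by posterior
#' mean probability); `at_point = TRUE` instead evaluates memberships at the
#' posterior-mean parameters. The MAP engine always evaluates at the point
#' estimate.
#'
#' @param fit an `lcls_fit`.
#' @param at_point evaluate at the point estimate instead of averaging over
#'   draws (HMC only).
#' @return an `lcls_membership`.
#' @export
membership <- function(fit, at_point = FALSE) {
  stopifnot(inherits(fit, "lcls_fit"))
  if (fit$engine == "hmc" && at_point)
    return(posterior_memberships(fit$data, fit$estimate))
  fit$membership
}

#' Convergence diagnostics table
#'
#' @param fit an `lcls_fit` from the HMC engine.
#' @return data frame of class `lcls_convergence` with per-parameter
#'   split-chain R-hat and a flag for values above the configured threshold.
#' @export
convergence_report <- function(fit) {
  stopifnot(inherits(fit, "lcls_fit"))
  if (is.null(fit$rhat)) stop("convergence report requires the HMC engine")
  out <- data.frame(parameter = names(fit$rhat), rhat = unname(fit$rhat),
                    flagged = unname(!is.na(fit$rhat) &
                                       (fit$rhat > fit$diagnostics$rhat_threshold |
                                          is.infinite(fit$rhat))),
                    row.names = NULL)
  attr(out, "rhat_threshold") <- fit$diagnostics$rhat_threshold
  attr(out, "divergences") <- fit$diagnostics$divergences
  class(out) <- c("lcls_convergence", "data.frame")
  out
}

#' Extract trace data for plotting
#'
#' @param fit an `lcls_fit` from the HMC engine.
#' @return long data frame with columns `chain`, `iteration`, `parameter`,
#'   `value` suitable for trace plots.
#' @export
trace_data <- function(fit) {
  stopifnot(inherits(fit, "lcls_fit"))
  if (is.null(fit$draws)) stop("trace data requires the HMC engine")
  d <- as.data.frame(fit$draws)
  n_keep <- nrow(d) / length(unique(fit$chain_id))
  out <- data.frame(chain = rep(fit$chain_id, ncol(d)),
                    iteration = rep(rep(seq_len(n_keep),
                                        length(unique(fit$chain_id))), ncol(d)),
                    parameter = rep(names(d), each = nrow(d)),
                    value = unlist(d, use.names = FALSE))
  out
}
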