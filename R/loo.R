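# Pareto-smoothed importance-sampling leave-one-out cross-validation with
# the subject (marginal over classes) as the pointwise unit.

# Generalized Pareto fit to exceedances (Zhang & Stephens 2009 profile
# posterior-mean estimator with the weak shape prior used for PSIS).
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5L || x[n] <= 0) return(list(k = NA_real_, sigma = NA_real_))
  prior_bs <- 3; prior_k <- 10
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  if (xstar <= 0) xstar <- x[n] / 2
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  k_of <- vapply(theta, function(b) -mean(log1p(-b * x)), 0)
  l_theta <- n * (log(theta / k_of) + k_of - 1)
  l_theta[!is.finite(l_theta)] <- -Inf
  w <- exp(l_theta - max(l_theta))
  w <- w / sum(w)
  b_hat <- sum(theta * w)
  k_hat <- -mean(log1p(-b_hat * x))
  sigma <- k_hat / b_hat
  # regularize k toward 0.5 with prior_k pseudo-observations
  k_hat <- k_hat * n / (n + prior_k) + prior_k * 0.5 / (n + prior_k)
  list(k = k_hat, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

# smooth one vector of log importance ratios; returns normalized log weights
# and the Pareto shape k
psis_smooth <- function(lr) {
  D <- length(lr)
  lr <- lr - max(lr)
  if (sd(lr) == 0) return(list(log_weights = lr - log_sum_exp(lr), k = 0))
  M <- ceiling(min(0.2 * D, 3 * sqrt(D)))
  r <- exp(lr)
  ord <- order(r)
  tail_ids <- ord[(D - M + 1):D]
  cutoff <- r[ord[D - M]]
  exceed <- r[tail_ids] - cutoff
  fit <- gpd_fit(exceed)
  k <- fit$k
  if (is.finite(k) && is.finite(fit$sigma) && fit$sigma > 0) {
    pq <- (seq_len(M) - 0.5) / M
    smoothed <- cutoff + vapply(pq, qgpd, 0, k = k, sigma = fit$sigma)
    smoothed <- pmin(smoothed, max(r))
    r[tail_ids[order(r[tail_ids])]] <- sort(smoothed)
  } else {
    k <- if (is.finite(k)) k else Inf
  }
  lw <- log(pmax(r, 1e-300))
  list(log_weights = lw - log_sum_exp(lw), k = k)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' PSIS-LOO expected log pointwise predictive density
#'
#' Leave-one-subject-out cross-validation estimated by Pareto-smoothed
#' importance sampling from the posterior draws of the subject-level
#' marginal log-likelihood. The pointwise unit is the subject (its
#' likelihood already integrated over the latent classes). The importance
#' ratios for subject i are `1 / p(y_i | theta_d)`; the upper tail of each
#' ratio vector is smoothed by a generalized Pareto fit whose shape
#' parameter `k` diagnoses reliability (`k > 0.7` is problematic).
#'
#' @param x an `lcls_fit` from the HMC engine, or a draws-by-subjects
#'   matrix of pointwise log-likelihoods.
#' @param ... unused.
#' @return an object of class `lcls_loo` with `elpd`, `se`, `pointwise`
#'   (per-subject elpd contributions), `pareto_k` and `n_bad_k`
#'   (count of `k > 0.7`).
#' @export
psis_loo <- function(x, ...) UseMethod("psis_loo")

#' @rdname psis_loo
#' @export
psis_loo.lcls_fit <- function(x, ...) {
  if (is.null(x$draws))
    stop("PSIS-LOO requires posterior draws; fit with the HMC engine")
  psis_loo(x$pointwise_loglik)
}

#' @rdname psis_loo
#' @export
psis_loo.matrix <- function(x, ...) {
  D <- nrow(x); N <- ncol(x)
  if (D < 25L)
    stop("PSIS-LOO needs at least 25 draws for a stable Pareto tail fit (got ",
         D, ")")
  pointwise <- numeric(N)
  pareto_k <- numeric(N)
  for (i in seq_len(N)) {
    ll <- x[, i]
    sm <- psis_smooth(-ll)
    pointwise[i] <- log_sum_exp(sm$log_weights + ll)
    pareto_k[i] <- sm$k
  }
  structure(list(elpd = sum(pointwise),
                 se = sqrt(N * var(pointwise)),
                 pointwise = pointwise, pareto_k = pareto_k,
                 n_bad_k = sum(pareto_k > 0.7, na.rm = TRUE),
                 n_draws = D, n_subjects = N),
            class = "lcls_loo")
}

#' @export
print.lcls_loo <- function(x, ...) {
  cat(sprintf("elpd_loo %.1f (SE %.1f) from %d draws, %d subjects; %d Pareto k > 0.7\n",
              x$elpd, x$se, x$n_draws, x$n_subjects, x$n_bad_k))
  invisible(x)
}

#' Paired elpd difference between two models
#'
#' The standard error of the difference uses the paired pointwise elpd
#' contributions (never the two marginal SEs in quadrature).
#'
#' @param loo1,loo2 `lcls_loo` objects for the same subjects.
#' @return list with `delta` (elpd1 - elpd2) and `se`.
#' @export
elpd_diff <- function(loo1, loo2) {
  stopifnot(inherits(loo1, "lcls_loo"), inherits(loo2, "lcls_loo"))
  if (loo1$n_subjects != loo2$n_subjects)
    stop("elpd difference requires the same subjects in both models")
  d <- loo1$pointwise - loo2$pointwise
  list(delta = sum(d), se = sqrt(length(d) * var(d)))
}

#' Class enumeration over an (L, S) grid by PSIS-LOO
#'
#' Fits every model with `1..L_max` location and `1..S_max` scale classes,
#' computes PSIS-LOO for each, forms pairwise elpd differences between
#' grid-adjacent models, and selects the number of classes by walking the
#' grid (scale classes inner, location classes outer) and keeping the last
#' model whose improvement over its predecessor is at least
#' `se_rule` standard errors. Cells whose fit fails or does not converge
#' are excluded from selection; cells with any Pareto `k > 0.7` are flagged
#' unreliable but retained.
#'
#' @param data an [lcls_data].
#' @param L_max,S_max grid bounds.
#' @param config an [fit_config()]; must use the HMC engine.
#' @param se_rule improvement rule multiplier (default 4).
#' @return an object of class `lcls_grid`: `results` data frame (one row
#'   per cell), `deltas` data frame of adjacent differences, `selected`
#'   `(L, S)`, plus the underlying `fits` and `loos`.
#' @export
compare_grid <- function(data, L_max, S_max, config = fit_config(),
                         se_rule = 4) {
  stopifnot(L_max >= 1, S_max >= 1)
  if (config$engine != "hmc")
    stop("grid comparison requires posterior draws; use the HMC engine")
  cells <- expand.grid(S = seq_len(S_max), L = seq_len(L_max))[, c("L", "S")]
  cells <- cells[order(cells$L, cells$S), ]
  fits <- list(); loos <- list()
  res <- data.frame(L = cells$L, S = cells$S, elpd = NA_real_, se = NA_real_,
                    n_bad_k = NA_integer_, converged = NA, failed = FALSE)
  for (r in seq_len(nrow(cells))) {
    key <- cell_key(cells$L[r], cells$S[r])
    fit <- tryCatch(fit_bayes(data, lcls_model(cells$L[r], cells$S[r]), config),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("fit failed for (L=%d, S=%d): %s", cells$L[r],
                      cells$S[r], conditionMessage(fit)))
      res$failed[r] <- TRUE
      next
    }
    lo <- psis_loo(fit)
    fits[[key]] <- fit; loos[[key]] <- lo
    res$elpd[r] <- lo$elpd; res$se[r] <- lo$se
    res$n_bad_k[r] <- lo$n_bad_k
    res$converged[r] <- fit$diagnostics$converged
  }
  deltas <- grid_deltas(res, loos)
  selected <- select_by_se_rule(res, loos, se_rule)
  structure(list(results = res, deltas = deltas, selected = selected,
                 fits = fits, loos = loos, se_rule = se_rule),
            class = "lcls_grid")
}

cell_key <- function(L, S) sprintf("L%d_S%d", L, S)

grid_deltas <- function(res, loos) {
  out <- NULL
  for (r in seq_len(nrow(res))) {
    L <- res$L[r]; S <- res$S[r]
    for (nb in list(c(L - 1, S), c(L, S - 1))) {
      if (nb[1] < 1 || nb[2] < 1) next
      k1 <- cell_key(L, S); k2 <- cell_key(nb[1], nb[2])
      if (is.null(loos[[k1]]) || is.null(loos[[k2]])) next
      d <- elpd_diff(loos[[k1]], loos[[k2]])
      out <- rbind(out, data.frame(L1 = L, S1 = S, L2 = nb[1], S2 = nb[2],
                                   delta = d$delta, se = d$se))
    }
  }
  if (is.null(out))
    out <- data.frame(L1 = integer(0), S1 = integer(0), L2 = integer(0),
                      S2 = integer(0), delta = numeric(0), se = numeric(0))
  out
}

# walk S within L, then L; a cell improves if its elpd exceeds its walk
# predecessor's by at least se_rule paired SEs; the selected model is the
# last improving cell among converged fits
select_by_se_rule <- function(res, loos, se_rule) {
  eligible <- !res$failed & !is.na(res$elpd) & (is.na(res$converged) | res$converged)
  selected <- NULL
  prev <- NULL
  for (r in seq_len(nrow(res))) {
    if (!eligible[r]) next
    L <- res$L[r]; S <- res$S[r]
    if (is.null(selected)) { selected <- c(L, S); prev <- r; next }
    d <- elpd_diff(loos[[cell_key(L, S)]],
                   loos[[cell_key(res$L[prev], res$S[prev])]])
    if (d$delta >= se_rule * d$se) selected <- c(L, S)
    prev <- r
  }
  if (is.null(selected)) stop("no eligible model in the grid")
  c(L = selected[1], S = selected[2])
}

#' @export
print.lcls_grid <- function(x, ...) {
  cat("elpd_loo grid:\n")
  print(x$results, row.names = FALSE)
  cat(sprintf("selected: %d location, %d scale class(es) (last improvement >= %g SE)\n",
              x$selected["L"], x$selected["S"], x$se_rule))
  invisible(x)
}

#' Export a selection grid as a table-style CSV
#'
#' Writes one row per grid cell with elpd (SE), convergence and Pareto-k
#' flags, followed by the adjacent-model differences.
#'
#' @param grid an `lcls_grid` from [compare_grid()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  res <- grid$results
  res$cell <- sprintf("%.1f (%.1f)", res$elpd, res$se)
  utils::write.csv(res, path, row.names = FALSE)
  dpath <- sub("\\.csv$", "_deltas.csv", path)
  utils::write.csv(grid$deltas, dpath, row.names = FALSE)
  invisible(path)
}
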