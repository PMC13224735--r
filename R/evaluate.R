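# Scoring fitted models against known simulation truth: label alignment,
# bias, average interval width, coverage and classification metrics.

perms_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (k in seq_len(n)) {
    rest <- perms_of(n - 1L)
    for (p in rest) out[[length(out) + 1L]] <- c(k, (seq_len(n)[-k])[p])
  }
  out
}

#' Align estimated classes with the generating truth
#'
#' Exhaustive search over all permutations of the location classes and,
#' independently, the scale classes, minimizing the summed squared distance
#' between matched `(beta0, beta1)` rows and matched `(tau0, tau1)` rows.
#' Deterministic; limited to at most 5 classes per part.
#'
#' @param estimate,truth [lcls_params] objects with equal class counts.
#' @return list with integer permutations `location` and `scale`;
#'   `estimate$beta[location, ]` is the estimate matched to the truth's row
#'   order (same for `tau[scale, ]`).
#' @export
align_labels <- function(estimate, truth) {
  stopifnot(inherits(estimate, "lcls_params"), inherits(truth, "lcls_params"))
  L <- n_loc(truth); S <- n_scale_classes(truth)
  if (n_loc(estimate) != L || n_scale_classes(estimate) != S)
    stop("estimate and truth must have the same numbers of classes")
  if (L > 5L || S > 5L) stop("exhaustive label alignment supports at most 5 classes")
  best_perm <- function(est_mat, true_mat) {
    k <- nrow(true_mat)
    perms <- perms_of(k)
    costs <- vapply(perms, function(p)
      sum((est_mat[p, , drop = FALSE] - true_mat)^2), 0)
    perms[[which.min(costs)]]
  }
  list(location = best_perm(estimate$beta, truth$beta),
       scale = best_perm(estimate$tau, truth$tau))
}

#' Run replicated scenario simulations and fits
#'
#' Convenience driver for simulation studies: generates `n_reps` datasets
#' from a scenario, fits the requested model to each, and returns the fits
#' and truth records. Replication seeds are drawn deterministically from
#' `seed`.
#'
#' @param scenario_fn one of [scenario1_spec], [scenario2_spec],
#'   [scenario3_spec] (or any function taking `seed` and returning an
#'   `lcls_scenario`).
#' @param n_reps number of replications.
#' @param model an [lcls_model] to fit.
#' @param config an [fit_config()].
#' @param seed master seed; per-replication data and fit seeds derive from it.
#' @param ... passed to `scenario_fn` (e.g. reduced design sizes).
#' @return list with `fits`, `truths` and `datasets`.
#' @export
run_replications <- function(scenario_fn, n_reps, model, config, seed = 1L,
                             ...) {
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(1000000L, n_reps)
  fits <- truths <- datasets <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sim <- simulate_lcls(scenario_fn(seed = rep_seeds[r], ...))
    cfg <- config
    cfg$seed <- rep_seeds[r] + 500000L
    fits[[r]] <- fit_lcls(sim$data, model, cfg)
    truths[[r]] <- sim$truth
    datasets[[r]] <- sim$data
  }
  list(fits = fits, truths = truths, datasets = datasets)
}

#' Score replicated fits against known truth
#'
#' For each converged replication, aligns the estimated classes with the
#' truth, then accumulates per-parameter bias (mean of estimate minus
#' truth), average 95% interval width, and coverage (share of replications
#' whose interval contains the truth), along with classification metrics:
#' the rate of subjects whose modal class equals their true class and the
#' rate whose maximal membership probability exceeds `conf_threshold`.
#' Non-converged replications are excluded and counted; a replication whose
#' alignment is non-identity (after the within-fit canonical ordering)
#' counts as label-switched.
#'
#' @param fits list of `lcls_fit` objects with the same class structure as
#'   the truth.
#' @param truths list of `lcls_truth` records from [simulate_lcls()].
#' @param conf_threshold confident-classification threshold (default 0.9).
#' @return object of class `lcls_simeval`: `parameters` data frame
#'   (parameter, truth, bias, aiw, coverage in percent), classification
#'   rates in percent (`loc_correct_rate`, `scale_correct_rate`,
#'   `loc_confident_rate`, `scale_confident_rate`), `n_converged`,
#'   `n_excluded`, `n_label_switched`.
#' @export
evaluate_replications <- function(fits, truths, conf_threshold = 0.9) {
  stopifnot(length(fits) == length(truths), length(fits) >= 1L)
  keep <- vapply(fits, function(f) isTRUE(f$diagnostics$converged), TRUE)
  if (!any(keep)) stop("no converged fits to evaluate")
  n_excl <- sum(!keep)
  fits <- fits[keep]; truths <- truths[keep]
  R <- length(fits)
  truth_par <- truths[[1]]$params
  true_vec <- params_to_constrained(truth_par)
  L <- n_loc(truth_par); S <- n_scale_classes(truth_par)
  dev <- width <- cover <- matrix(NA_real_, R, length(true_vec),
                                  dimnames = list(NULL, names(true_vec)))
  loc_ok <- sca_ok <- loc_conf <- sca_conf <- numeric(R)
  n_switched <- 0L
  for (r in seq_len(R)) {
    fit <- fits[[r]]; tr <- truths[[r]]
    perm <- align_labels(fit$estimate, tr$params)
    if (is.unsorted(perm$location) || is.unsorted(perm$scale))
      n_switched <- n_switched + 1L
    est <- permute_classes(fit$estimate, perm$location, perm$scale)
    dev[r, ] <- params_to_constrained(est) - true_vec
    ci <- fit$ci
    rownames(ci) <- ci$parameter
    aligned_names <- par_names(L, S)[c(
      rep(0, 0),
      perm$location, L + perm$location,
      2 * L + perm$scale, 2 * L + S + perm$scale,
      2 * L + 2 * S + perm$location, 2 * L + 2 * S + L + perm$scale)]
    ci <- ci[aligned_names, ]
    width[r, ] <- ci$upper - ci$lower
    cover[r, ] <- ci$lower <= true_vec & true_vec <= ci$upper
    mem <- membership(fit)
    eta_loc <- mem$eta_location[, perm$location, drop = FALSE]
    eta_sca <- mem$eta_scale[, perm$scale, drop = FALSE]
    loc_ok[r] <- mean(max.col(eta_loc, ties.method = "first") ==
                        tr$location_class)
    sca_ok[r] <- mean(max.col(eta_sca, ties.method = "first") ==
                        tr$scale_class)
    loc_conf[r] <- mean(apply(eta_loc, 1, max) > conf_threshold)
    sca_conf[r] <- mean(apply(eta_sca, 1, max) > conf_threshold)
  }
  params_df <- data.frame(parameter = names(true_vec),
                          truth = unname(true_vec),
                          bias = colMeans(dev),
                          aiw = colMeans(width),
                          coverage = 100 * colMeans(cover),
                          row.names = NULL)
  structure(list(parameters = params_df,
                 loc_correct_rate = 100 * mean(loc_ok),
                 scale_correct_rate = 100 * mean(sca_ok),
                 loc_confident_rate = 100 * mean(loc_conf),
                 scale_confident_rate = 100 * mean(sca_conf),
                 n_converged = R, n_excluded = n_excl,
                 n_label_switched = n_switched,
                 conf_threshold = conf_threshold),
            class = "lcls_simeval")
}

#' @export
print.lcls_simeval <- function(x, digits = 4, ...) {
  cat(sprintf("simulation evaluation over %d converged replication(s) (%d excluded, %d label-switched)\n",
              x$n_converged, x$n_excluded, x$n_label_switched))
  df <- x$parameters
  df$bias <- signif(df$bias, 3); df$aiw <- signif(df$aiw, 3)
  df$coverage <- round(df$coverage, 1)
  print(df, row.names = FALSE)
  cat(sprintf("classification: location %.1f%% correct, %.1f%% confident (>%.2g); scale %.1f%% correct, %.1f%% confident\n",
              x$loc_correct_rate, x$loc_confident_rate, x$conf_threshold,
              x$scale_correct_rate, x$scale_confident_rate))
  invisible(x)
}

#' Write a simulation evaluation report
#'
#' @param report an `lcls_simeval`.
#' @param path output path; `.csv` writes the parameter table with the
#'   scalar rates as attributes in a companion JSON, `.json` writes
#'   everything as JSON.
#' @return `path`, invisibly.
#' @export
write_simeval <- function(report, path) {
  stopifnot(inherits(report, "lcls_simeval"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(report$parameters, path, row.names = FALSE)
    jsonlite::write_json(unclass(report)[-1],
                         sub("\\.csv$", "_rates.json", path),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
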