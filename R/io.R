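# Serialization and pipeline plumbing: parameter JSON, fit directories,
# an emitted probabilistic-program source for external samplers, and the
# config-driven pipeline behind the command-line interface.

#' Read and write parameter sets as JSON
#'
#' @param params an [lcls_params] object.
#' @param path JSON path.
#' @return `write_params_json` returns `path` invisibly;
#'   `read_params_json` returns an [lcls_params].
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "lcls_params"))
  obj <- list(L = n_loc(params), S = n_scale_classes(params),
              beta = unname(as.matrix(params$beta)),
              tau = unname(as.matrix(params$tau)),
              pi_location = params$pi_location,
              pi_scale = params$pi_scale)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lcls_params(beta = matrix(obj$beta, nrow = obj$L),
              tau = matrix(obj$tau, nrow = obj$S),
              pi_location = obj$pi_location, pi_scale = obj$pi_scale)
}

#' Serialize a fit to a directory
#'
#' Writes `parameters.json` (point estimates / posterior means),
#' `ci.csv`, `diagnostics.json`, `pointwise_loglik.csv`,
#' `membership_location.csv` / `membership_scale.csv` and, for the HMC
#' engine, `draws.csv` (post-warm-up posterior draws with their chain ids).
#' `read_fit()` reconstructs the result (without the original data).
#'
#' @param fit an `lcls_fit`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "lcls_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_params_json(fit$estimate, file.path(dir, "parameters.json"))
  write.csv(fit$ci, file.path(dir, "ci.csv"), row.names = FALSE)
  diag <- fit$diagnostics
  diag$engine <- fit$engine
  diag$n_location <- fit$model$n_location
  diag$n_scale <- fit$model$n_scale
  diag$loglik <- fit$loglik
  if (!is.null(fit$rhat)) diag$rhat <- as.list(fit$rhat)
  jsonlite::write_json(diag, file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(as.data.frame(fit$pointwise_loglik),
            file.path(dir, "pointwise_loglik.csv"), row.names = FALSE)
  write.csv(as.data.frame(fit$membership$eta_location),
            file.path(dir, "membership_location.csv"), row.names = FALSE)
  write.csv(as.data.frame(fit$membership$eta_scale),
            file.path(dir, "membership_scale.csv"), row.names = FALSE)
  if (!is.null(fit$draws)) {
    dd <- data.frame(chain = fit$chain_id, fit$draws, check.names = FALSE)
    write.csv(dd, file.path(dir, "draws.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_fit
#' @export
read_fit <- function(dir) {
  est <- read_params_json(file.path(dir, "parameters.json"))
  diag <- jsonlite::read_json(file.path(dir, "diagnostics.json"),
                              simplifyVector = TRUE)
  ci <- read.csv(file.path(dir, "ci.csv"), check.names = FALSE)
  pw <- as.matrix(read.csv(file.path(dir, "pointwise_loglik.csv")))
  eta_l <- as.matrix(read.csv(file.path(dir, "membership_location.csv")))
  eta_s <- as.matrix(read.csv(file.path(dir, "membership_scale.csv")))
  draws <- chain_id <- rhat <- NULL
  dpath <- file.path(dir, "draws.csv")
  if (file.exists(dpath)) {
    dd <- read.csv(dpath, check.names = FALSE)
    chain_id <- dd$chain
    draws <- as.matrix(dd[, -1, drop = FALSE])
  }
  if (!is.null(diag$rhat)) {
    rhat <- unlist(diag$rhat)
    diag$rhat <- NULL
  }
  model <- lcls_model(diag$n_location, diag$n_scale)
  fit <- new_fit(diag$engine, model, data = NULL,
                 config = NULL, estimate = est,
                 ci = ci, loglik = diag$loglik,
                 pointwise_loglik = pw,
                 membership = new_membership(eta_l, eta_s),
                 draws = draws, chain_id = chain_id, rhat = rhat,
                 diagnostics = diag[setdiff(names(diag),
                                            c("engine", "n_location",
                                              "n_scale", "loglik"))])
  fit
}

#' Emit probabilistic-program source for an external HMC backend
#'
#' Generates a self-contained Stan-language program for the marginal
#' (classes integrated out) latent-class location-scale likelihood with
#' flat priors, so the model can also be run under an external sampler.
#' The emitted text is a pure function of the model structure and is
#' byte-identical across runs.
#'
#' @param model an [lcls_model].
#' @return a single string of program source.
#' @export
stan_source <- function(model) {
  stopifnot(inherits(model, "lcls_model"))
  paste0(
    "// latent-class location-scale regression, marginal likelihood\n",
    "data {\n",
    "  int<lower=1> M;              // observations\n",
    "  int<lower=1> N;              // subjects\n",
    "  array[M] int<lower=1, upper=N> subj;\n",
    "  vector[M] t;\n",
    "  vector[M] y;\n",
    "}\n",
    "transformed data {\n",
    sprintf("  int L = %d;\n  int S = %d;\n", model$n_location, model$n_scale),
    "}\n",
    "parameters {\n",
    "  vector[L] beta0;\n  vector[L] beta1;\n",
    "  vector[S] tau0;\n  vector[S] tau1;\n",
    "  simplex[L] pi_loc;\n  simplex[S] pi_scale;\n",
    "}\n",
    "model {\n",
    "  array[N] matrix[L, S] lps;\n",
    "  for (i in 1:N) lps[i] = rep_matrix(0, L, S);\n",
    "  for (m in 1:M) {\n",
    "    for (l in 1:L) {\n",
    "      for (s in 1:S) {\n",
    "        lps[subj[m]][l, s] += normal_lpdf(y[m] | beta0[l] + beta1[l] * t[m],\n",
    "                                          exp(0.5 * (tau0[s] + tau1[s] * t[m])));\n",
    "      }\n",
    "    }\n",
    "  }\n",
    "  for (i in 1:N) {\n",
    "    matrix[L, S] a = lps[i];\n",
    "    for (l in 1:L)\n",
    "      for (s in 1:S)\n",
    "        a[l, s] += log(pi_loc[l]) + log(pi_scale[s]);\n",
    "    target += log_sum_exp(to_vector(a));\n",
    "  }\n",
    "}\n")
}

log_msg <- function(..., log_file = NULL) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                 paste0(..., collapse = ""))
  message(msg)
  if (!is.null(log_file)) cat(msg, "\n", file = log_file, append = TRUE)
}

#' Run a configured pipeline step
#'
#' Declarative front end used by the command-line interface. `config` is a
#' named list (or path to a JSON/YAML file) with a `command` field --
#' one of `simulate`, `fit`, `select`, `classify`, `evaluate` -- plus the
#' fields that command needs (`input`, `out`, `scenario`, `n_location`,
#' `n_scale`, `engine`, `n_chains`, `n_iter`, `n_warmup`, `seed`,
#' `log_outcome`, `n_reps`, `L_max`, `S_max`). Seeds, package version and
#' thresholds in force are logged to standard error (and to `log_file` if
#' given). Identical config and seed give identical outputs.
#'
#' @param config named list or path to a JSON/YAML config file.
#' @return 0 invisibly on success; errors propagate to the caller.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configs need the 'yaml' package; use JSON instead")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$command))
    stop("config must name a 'command' (simulate, fit, select, classify, evaluate)")
  defaults <- list(seed = 1L, engine = "hmc", n_chains = 4L, n_iter = 2000L,
                   n_warmup = 500L, n_location = 1L, n_scale = 1L,
                   scenario = 1L, log_outcome = FALSE, n_reps = 5L,
                   L_max = 3L, S_max = 3L, log_file = NULL)
  design <- config[intersect(names(config),
                             c("n_subjects", "n_periods", "obs_per_period"))]
  cfg <- modifyList(defaults, config[!vapply(config, is.null, TRUE)])
  lf <- cfg$log_file
  log_msg(sprintf("lcls %s | command=%s seed=%d engine=%s",
                  as.character(utils::packageVersion("lcls")), cfg$command,
                  as.integer(cfg$seed), cfg$engine), log_file = lf)
  load_input <- function() {
    if (is.null(cfg$input)) stop("config needs an 'input' CSV path")
    if (!file.exists(cfg$input)) stop("input file not found: ", cfg$input)
    dat <- read_long_csv(cfg$input)
    if (isTRUE(cfg$log_outcome)) {
      if (any(dat$outcomes <= 0))
        stop("--log-outcome requires strictly positive outcomes")
      dat <- lcls_data(dat$subject_ids, dat$times, log(dat$outcomes))
    }
    dat
  }
  make_cfg <- function(engine = cfg$engine)
    fit_config(engine = engine, n_chains = cfg$n_chains, n_iter = cfg$n_iter,
               n_warmup = cfg$n_warmup, seed = as.integer(cfg$seed))
  out <- cfg$out
  if (is.null(out)) stop("config needs an 'out' path")
  switch(
    as.character(cfg$command),
    simulate = {
      spec_fn <- switch(as.character(cfg$scenario), "1" = scenario1_spec,
                        "2" = scenario2_spec, "3" = scenario3_spec,
                        stop("unknown scenario: ", cfg$scenario))
      sim <- simulate_lcls(do.call(spec_fn, c(list(seed = as.integer(cfg$seed)),
                                              design)))
      dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
      write_long_csv(sim$data, out)
      truth_path <- sub("\\.csv$", "_truth.json", out)
      write_params_json(sim$truth$params, truth_path)
      classes_path <- sub("\\.csv$", "_classes.csv", out)
      write.csv(data.frame(subject_id = sim$data$subjects,
                           location_class = sim$truth$location_class,
                           scale_class = sim$truth$scale_class),
                classes_path, row.names = FALSE)
      log_msg("wrote ", out, ", ", truth_path, ", ", classes_path,
              log_file = lf)
    },
    fit = {
      dat <- load_input()
      fit <- fit_lcls(dat, lcls_model(cfg$n_location, cfg$n_scale),
                      make_cfg())
      log_msg(sprintf("fit done: converged=%s loglik=%.2f (rhat threshold %.3f)",
                      fit$diagnostics$converged, fit$loglik,
                      fit$config$rhat_threshold), log_file = lf)
      write_fit(fit, out)
      writeLines(stan_source(fit$model), file.path(out, "model.stan"))
      log_msg("wrote fit directory ", out, log_file = lf)
    },
    select = {
      dat <- load_input()
      grid <- compare_grid(dat, cfg$L_max, cfg$S_max, make_cfg("hmc"))
      dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
      write_grid_csv(grid, out)
      log_msg(sprintf("selected L=%d S=%d", grid$selected["L"],
                      grid$selected["S"]), log_file = lf)
    },
    classify = {
      dat <- load_input()
      fit <- fit_lcls(dat, lcls_model(cfg$n_location, cfg$n_scale),
                      make_cfg())
      mem <- membership(fit)
      asg <- assign_classes(mem)
      ent <- entropy_summary(mem)
      dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
      write.csv(data.frame(subject_id = dat$subjects,
                           location_class = asg$location_class,
                           scale_class = asg$scale_class,
                           max_eta_location = apply(mem$eta_location, 1, max),
                           max_eta_scale = apply(mem$eta_scale, 1, max)),
                out, row.names = FALSE)
      log_msg(sprintf("entropy: location %s scale %s",
                      format(ent$e_location), format(ent$e_scale)),
              log_file = lf)
    },
    evaluate = {
      spec_fn <- switch(as.character(cfg$scenario), "1" = scenario1_spec,
                        "2" = scenario2_spec, "3" = scenario3_spec,
                        stop("unknown scenario: ", cfg$scenario))
      truth0 <- spec_fn(seed = 1L)$truth
      reps <- do.call(run_replications,
                      c(list(spec_fn, cfg$n_reps,
                             lcls_model(n_loc(truth0),
                                        n_scale_classes(truth0)),
                             make_cfg(), seed = as.integer(cfg$seed)),
                        design))
      report <- evaluate_replications(reps$fits, reps$truths)
      dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
      write_simeval(report, out)
      log_msg("wrote evaluation report ", out, log_file = lf)
    },
    stop("unknown command: ", cfg$command))
  invisible(0L)
}
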