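#' Model specification: numbers of location and scale classes
#'
#' Declares the structure of a latent-class location-scale model: `L`
#' location classes with linear mean trajectories `beta0_l + beta1_l * t` and
#' `S` scale classes with log-linear within-subject variance trajectories
#' `exp(tau0_s + tau1_s * t)`. The regressor defaults to study time; any
#' time-varying covariate stored in the `time` slot of the data plays the
#' same role.
#'
#' @param n_location number of location classes (L >= 1).
#' @param n_scale number of scale classes (S >= 1).
#' @param location_covariate,scale_covariate names of the regressor used in
#'   each part of the model (informational; both default to `"time"`).
#' @return an object of class `lcls_model`.
#' @export
#' @examples
#' lcls_model(3, 3)
lcls_model <- function(n_location = 1L, n_scale = 1L,
                       location_covariate = "time",
                       scale_covariate = "time") {
  L <- as.integer(n_location); S <- as.integer(n_scale)
  if (is.na(L) || L < 1L) stop("'n_location' must be a positive integer")
  if (is.na(S) || S < 1L) stop("'n_scale' must be a positive integer")
  structure(list(n_location = L, n_scale = S,
                 location_covariate = location_covariate,
                 scale_covariate = scale_covariate),
            class = "lcls_model")
}

#' @export
print.lcls_model <- function(x, ...) {
  cat(sprintf("Latent-class location-scale model: %d location class(es), %d scale class(es)\n",
              x$n_location, x$n_scale))
  invisible(x)
}

#' Parameter set for a latent-class location-scale model
#'
#' @param beta L x 2 matrix; row l holds the intercept `beta0_l` (outcome
#'   units at time 0) and slope `beta1_l` (outcome units per time unit) of
#'   location class l.
#' @param tau S x 2 matrix; row s holds the log baseline within-subject
#'   variance `tau0_s` and its log-linear slope `tau1_s` for scale class s.
#' @param pi_location,pi_scale class-probability simplices of lengths L and
#'   S; default to uniform.
#' @return an object of class `lcls_params`.
#' @export
#' @examples
#' lcls_params(beta = rbind(c(7, -0.02), c(7.4, -0.01)),
#'             tau  = rbind(c(-2, 0.02)))
lcls_params <- function(beta, tau, pi_location = NULL, pi_scale = NULL) {
  beta <- rbind(beta); tau <- rbind(tau)
  storage.mode(beta) <- "double"; storage.mode(tau) <- "double"
  if (ncol(beta) != 2L) stop("'beta' must have two columns (intercept, slope)")
  if (ncol(tau) != 2L) stop("'tau' must have two columns (intercept, slope)")
  L <- nrow(beta); S <- nrow(tau)
  if (is.null(pi_location)) pi_location <- rep(1 / L, L)
  if (is.null(pi_scale)) pi_scale <- rep(1 / S, S)
  check_simplex(pi_location, L, "pi_location")
  check_simplex(pi_scale, S, "pi_scale")
  if (!all(is.finite(beta)) || !all(is.finite(tau)))
    stop("'beta' and 'tau' must be finite")
  dimnames(beta) <- list(paste0("loc", seq_len(L)), c("beta0", "beta1"))
  dimnames(tau) <- list(paste0("scale", seq_len(S)), c("tau0", "tau1"))
  structure(list(beta = beta, tau = tau,
                 pi_location = as.numeric(pi_location),
                 pi_scale = as.numeric(pi_scale)),
            class = "lcls_params")
}

check_simplex <- function(p, k, name) {
  if (length(p) != k) stop(sprintf("'%s' must have length %d", name, k))
  if (!all(is.finite(p)) || any(p < 0))
    stop(sprintf("'%s' must be a nonnegative probability vector", name))
  if (abs(sum(p) - 1) > 1e-12)
    stop(sprintf("'%s' must sum to 1 (within 1e-12)", name))
  invisible(TRUE)
}

#' @export
print.lcls_params <- function(x, digits = 4, ...) {
  L <- nrow(x$beta); S <- nrow(x$tau)
  cat(sprintf("lcls parameter set (%d location x %d scale classes)\n", L, S))
  cat("location (beta0, beta1), pi:\n")
  print(cbind(round(x$beta, digits), pi = round(x$pi_location, digits)))
  cat("scale (tau0, tau1), pi:\n")
  print(cbind(round(x$tau, digits), pi = round(x$pi_scale, digits)))
  invisible(x)
}

n_loc <- function(params) nrow(params$beta)
n_scale_classes <- function(params) nrow(params$tau)

par_names <- function(L, S) {
  c(sprintf("beta0[%d]", seq_len(L)), sprintf("beta1[%d]", seq_len(L)),
    sprintf("tau0[%d]", seq_len(S)), sprintf("tau1[%d]", seq_len(S)),
    sprintf("pi_loc[%d]", seq_len(L)), sprintf("pi_scale[%d]", seq_len(S)))
}

# constrained vector layout: beta0(L), beta1(L), tau0(S), tau1(S),
# pi_loc(L), pi_scale(S) -- shared with the C++ pointwise kernel
params_to_constrained <- function(params) {
  L <- n_loc(params); S <- n_scale_classes(params)
  out <- c(params$beta[, 1], params$beta[, 2], params$tau[, 1],
           params$tau[, 2], params$pi_location, params$pi_scale)
  names(out) <- par_names(L, S)
  out
}

constrained_to_params <- function(x, L, S) {
  lcls_params(beta = cbind(x[seq_len(L)], x[L + seq_len(L)]),
              tau = cbind(x[2 * L + seq_len(S)], x[2 * L + S + seq_len(S)]),
              pi_location = x[2 * L + 2 * S + seq_len(L)],
              pi_scale = x[2 * L + 2 * S + L + seq_len(S)])
}

softmax0 <- function(z) {
  # z are K-1 free logits relative to class 1
  x <- c(0, z)
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

logits_from_simplex <- function(p) {
  if (length(p) == 1L) return(numeric(0))
  log(pmax(p[-1], 1e-300)) - log(max(p[1], 1e-300))
}

# unconstrained vector: beta0(L), beta1(L), tau0(S), tau1(S),
# z_loc(L-1), z_scale(S-1)
params_to_unconstrained <- function(params) {
  c(params$beta[, 1], params$beta[, 2], params$tau[, 1], params$tau[, 2],
    logits_from_simplex(params$pi_location),
    logits_from_simplex(params$pi_scale))
}

unconstrained_to_params <- function(theta, L, S) {
  nb <- 2 * L + 2 * S
  z_loc <- if (L > 1) theta[nb + seq_len(L - 1)] else numeric(0)
  z_scale <- if (S > 1) theta[nb + (L - 1) + seq_len(S - 1)] else numeric(0)
  lcls_params(beta = cbind(theta[seq_len(L)], theta[L + seq_len(L)]),
              tau = cbind(theta[2 * L + seq_len(S)], theta[2 * L + S + seq_len(S)]),
              pi_location = softmax0(z_loc), pi_scale = softmax0(z_scale))
}

n_unconstrained <- function(L, S) 2 * L + 2 * S + (L - 1) + (S - 1)

#' Class-ordering permutations for a parameter set
#'
#' Reported classes follow a fixed convention: location classes sorted by
#' ascending intercept `beta0`, scale classes by ascending `tau0`, so that
#' "class 1" is reproducible across runs and engines.
#'
#' @param params an `lcls_params` object.
#' @return list with integer permutations `location` and `scale` such that
#'   `params$beta[location, ]` is sorted by intercept.
#' @export
class_order <- function(params) {
  list(location = order(params$beta[, 1]), scale = order(params$tau[, 1]))
}

#' Apply class permutations to a parameter set
#'
#' @param params an `lcls_params` object.
#' @param perm_location,perm_scale integer permutations of `1:L` and `1:S`.
#' @return the relabeled `lcls_params`.
#' @export
permute_classes <- function(params, perm_location = NULL, perm_scale = NULL) {
  if (is.null(perm_location)) perm_location <- seq_len(n_loc(params))
  if (is.null(perm_scale)) perm_scale <- seq_len(n_scale_classes(params))
  lcls_params(beta = params$beta[perm_location, , drop = FALSE],
              tau = params$tau[perm_scale, , drop = FALSE],
              pi_location = params$pi_location[perm_location],
              pi_scale = params$pi_scale[perm_scale])
}

#' Relabel a parameter set to the canonical class order
#'
#' @param params an `lcls_params` object.
#' @return the parameter set with location classes sorted by `beta0` and
#'   scale classes by `tau0`, both ascending. Idempotent.
#' @export
relabel_params <- function(params) {
  ord <- class_order(params)
  permute_classes(params, ord$location, ord$scale)
}
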