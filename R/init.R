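#' Starting values from separate mean and variability regressions
#'
#' Derives starting values the way a practitioner would by hand: a single
#' least-squares line of the outcome on time for the location part, and a
#' least-squares line of the log squared residuals on time for the scale
#' part (with the `E[log chi^2_1] = digamma(1/2) + log 2` bias correction on
#' the intercept). The single lines are replicated across classes with a
#' deterministic spread -- class intercepts offset by multiples of the
#' between-subject standard deviation, spread symmetrically over classes --
#' so that classes start distinct. Class probabilities start uniform.
#'
#' @param data an [lcls_data] object.
#' @param model an [lcls_model].
#' @param seed seed for the optional random jitter.
#' @param jitter_sd standard deviation (as a fraction of each spread unit)
#'   of additional random jitter; 0 (the default) gives fully deterministic
#'   starts.
#' @return an [lcls_params] starting value.
#' @export
init_from_regressions <- function(data, model, seed = 1L, jitter_sd = 0) {
  stopifnot(inherits(data, "lcls_data"), inherits(model, "lcls_model"))
  if (length(data$outcomes) == 0L) stop("cannot initialize from empty data")
  L <- model$n_location; S <- model$n_scale
  t <- data$times; y <- data$outcomes
  if (length(unique(t)) < 2L) {
    warning("all observation times identical; using intercept-only starts")
    b <- c(mean(y), 0)
    resid <- y - b[1]
    lr <- log(pmax(resid^2, 1e-12))
    tl <- c(mean(lr) + 1.2703628, 0)
  } else {
    fit_loc <- lm(y ~ t)
    b <- unname(coef(fit_loc))
    resid <- unname(fit_loc$residuals)
    lr <- log(pmax(resid^2, 1e-12))
    fit_sc <- lm(lr ~ t)
    # E[log chi^2_1] = digamma(1/2) + log 2 = -1.2703628
    tl <- unname(coef(fit_sc)) + c(1.2703628, 0)
    if (!all(is.finite(tl))) tl <- c(mean(lr) + 1.2703628, 0)
  }
  # between-subject spread used to separate the class starts
  subj_mean_resid <- tapply(resid, data$subject_index, mean)
  s_loc <- sd(subj_mean_resid)
  if (!is.finite(s_loc) || s_loc == 0) s_loc <- max(sd(resid) / 2, 0.1)
  subj_log_msr <- tapply(resid^2, data$subject_index, function(r) log(max(mean(r), 1e-12)))
  s_sc <- sd(subj_log_msr)
  if (!is.finite(s_sc) || s_sc == 0) s_sc <- 0.5
  q_loc <- if (L > 1) seq(-1, 1, length.out = L) else 0
  q_sc <- if (S > 1) seq(-1, 1, length.out = S) else 0
  set.seed(as.integer(seed) %% .Machine$integer.max)
  jit <- function(n, scale) if (jitter_sd > 0) rnorm(n, 0, jitter_sd * scale) else rep(0, n)
  beta <- cbind(b[1] + q_loc * s_loc + jit(L, s_loc),
                b[2] + jit(L, max(abs(b[2]), 0.01)))
  tau <- cbind(tl[1] + q_sc * s_sc + jit(S, s_sc),
               tl[2] + jit(S, max(abs(tl[2]), 0.01)))
  lcls_params(beta = beta, tau = tau)
}
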