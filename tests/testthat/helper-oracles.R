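# Independent oracles and tiny fixture builders used across the suite.
# The oracles work in plain probability space with stats::dnorm so they share
# no code path with the package's log-space C++ kernels.

# naive probability-space marginal likelihood: per-subject sum over the
# (location, scale) grid of pi_l * pi_s * prod_j N(y | mu, sigma)
naive_marginal <- function(data, params) {
  N <- data$n_subjects
  L <- nrow(params$beta); S <- nrow(params$tau)
  out <- numeric(N)
  for (i in seq_len(N)) {
    sel <- data$subject_index == i
    y <- data$outcomes[sel]; t <- data$times[sel]
    tot <- 0
    for (l in seq_len(L)) {
      for (s in seq_len(S)) {
        mu <- params$beta[l, 1] + params$beta[l, 2] * t
        sdv <- sqrt(exp(params$tau[s, 1] + params$tau[s, 2] * t))
        tot <- tot + params$pi_location[l] * params$pi_scale[s] *
          prod(dnorm(y, mu, sdv))
      }
    }
    out[i] <- log(tot)
  }
  out
}

# naive Bayes-rule memberships from the full joint (l, s) probability table
naive_memberships <- function(data, params) {
  N <- data$n_subjects
  L <- nrow(params$beta); S <- nrow(params$tau)
  eta_loc <- matrix(0, N, L); eta_sca <- matrix(0, N, S)
  for (i in seq_len(N)) {
    sel <- data$subject_index == i
    y <- data$outcomes[sel]; t <- data$times[sel]
    joint <- matrix(0, L, S)
    for (l in seq_len(L)) {
      for (s in seq_len(S)) {
        mu <- params$beta[l, 1] + params$beta[l, 2] * t
        sdv <- sqrt(exp(params$tau[s, 1] + params$tau[s, 2] * t))
        joint[l, s] <- params$pi_location[l] * params$pi_scale[s] *
          prod(dnorm(y, mu, sdv))
      }
    }
    joint <- joint / sum(joint)
    eta_loc[i, ] <- rowSums(joint)
    eta_sca[i, ] <- colSums(joint)
  }
  list(eta_location = eta_loc, eta_scale = eta_sca)
}

# small random-but-reproducible instance: N subjects, n_i obs each
toy_instance <- function(seed, N = 6, n_i = 5, L = 2, S = 2) {
  set.seed(seed)
  params <- lcls_params(
    beta = cbind(rnorm(L, 7, 0.5), rnorm(L, 0, 0.05)),
    tau = cbind(rnorm(S, -1.5, 0.5), rnorm(S, 0, 0.03)),
    pi_location = as.numeric(prop.table(runif(L, 0.5, 1.5))),
    pi_scale = as.numeric(prop.table(runif(S, 0.5, 1.5))))
  id <- rep(seq_len(N), each = n_i)
  tt <- rep(seq_len(n_i) - 1, N)
  y <- rnorm(N * n_i, 7, 0.6)
  list(data = lcls_data(id, tt, y), params = params)
}

# hand-built membership object
mk_membership <- function(eta_loc, eta_sca) {
  lcls:::new_membership(eta_loc, eta_sca)
}

table6_truth <- function() scenario1_spec()$truth

# small homoscedastic one-class dataset
one_class_data <- function(seed, N = 25, n_i = 8, beta = c(7, -0.05),
                           tau = c(-1.5, 0.02)) {
  set.seed(seed)
  id <- rep(seq_len(N), each = n_i)
  tt <- rep(seq_len(n_i) - 1, N)
  mu <- beta[1] + beta[2] * tt
  sdv <- sqrt(exp(tau[1] + tau[2] * tt))
  lcls_data(id, tt, rnorm(N * n_i, mu, sdv))
}
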