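# Adaptive Hamiltonian Monte Carlo with dual-averaging step-size adaptation
# and a diagonal mass matrix estimated during warm-up. The target density is
# supplied as lp_fn(theta) -> list(value, grad) on an unconstrained space.

hmc_chain <- function(lp_fn, theta0, n_iter, n_warmup, seed,
                      max_leapfrog = 20L, target_accept = 0.8,
                      divergence_threshold = 1000) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  d <- length(theta0)
  draws <- matrix(NA_real_, n_iter, d)
  theta <- theta0
  cur <- lp_fn(theta)
  if (!is.finite(cur$value)) stop("initial point has non-finite log posterior")
  mass <- rep(1, d)          # diagonal mass (precision of momentum = 1/mass?) see below
  # momentum p ~ N(0, diag(1/mass_var)) with kinetic 0.5 * sum(p^2 * mass_var)
  # where mass_var approximates the posterior variances, so step sizes are
  # scale-free. mass here stores the estimated posterior variances.
  eps <- find_reasonable_eps(lp_fn, theta, cur, mass)
  # dual averaging state; da_m restarts when the mass matrix is refreshed
  mu <- log(10 * eps); log_eps_bar <- log(eps); h_bar <- 0; da_m <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  adapt_end <- n_warmup
  var_window <- seq(from = max(1L, floor(n_warmup * 0.3)),
                    to = max(2L, floor(n_warmup * 0.85)))
  divergences <- 0L; n_accept <- 0
  for (it in seq_len(n_iter)) {
    p0 <- rnorm(d, 0, sqrt(1 / mass))
    n_leap <- sample.int(max_leapfrog, 1L)
    st <- leapfrog(lp_fn, theta, cur, p0, eps, n_leap, mass)
    h0 <- -cur$value + 0.5 * sum(p0^2 * mass)
    h1 <- if (is.finite(st$lp$value)) -st$lp$value + 0.5 * sum(st$p^2 * mass) else Inf
    dh <- h0 - h1
    accept_prob <- if (is.finite(dh)) min(1, exp(dh)) else 0
    if (it > n_warmup && (!is.finite(dh) || -dh > divergence_threshold))
      divergences <- divergences + 1L
    if (runif(1) < accept_prob) {
      theta <- st$theta; cur <- st$lp; n_accept <- n_accept + 1
    }
    draws[it, ] <- theta
    if (it <= adapt_end) {
      # dual averaging (Hoffman & Gelman)
      da_m <- da_m + 1
      h_bar <- (1 - 1 / (da_m + t0)) * h_bar +
        (target_accept - accept_prob) / (da_m + t0)
      log_eps <- mu - sqrt(da_m) / gamma * h_bar
      w <- da_m^(-kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      if (it == max(var_window)) {
        v <- apply(draws[var_window, , drop = FALSE], 2, var)
        v[!is.finite(v) | v <= 0] <- 1e-6
        mass <- v
        eps <- find_reasonable_eps(lp_fn, theta, cur, mass)
        mu <- log(10 * eps); log_eps_bar <- log(eps); h_bar <- 0; da_m <- 0
      }
    } else if (it == adapt_end + 1L) {
      eps <- exp(log_eps_bar)
      if (!is.finite(eps) || eps <= 0) eps <- exp(mu) / 10
    }
  }
  list(draws = draws[(n_warmup + 1):n_iter, , drop = FALSE],
       accept_rate = n_accept / n_iter, divergences = divergences,
       step_size = eps)
}

leapfrog <- function(lp_fn, theta, lp, p, eps, n_steps, mass) {
  g <- lp$grad
  for (k in seq_len(n_steps)) {
    p <- p + 0.5 * eps * g
    theta <- theta + eps * p * mass
    lp <- lp_fn(theta)
    if (!is.finite(lp$value)) {
      lp$value <- -Inf
      return(list(theta = theta, p = p, lp = lp))
    }
    g <- lp$grad
    p <- p + 0.5 * eps * g
  }
  list(theta = theta, p = -p, lp = lp)
}

find_reasonable_eps <- function(lp_fn, theta, cur, mass) {
  eps <- 0.1
  p0 <- rnorm(length(theta), 0, sqrt(1 / mass))
  h_of <- function(eps) {
    st <- leapfrog(lp_fn, theta, cur, p0, eps, 1L, mass)
    h0 <- -cur$value + 0.5 * sum(p0^2 * mass)
    h1 <- if (is.finite(st$lp$value)) -st$lp$value + 0.5 * sum(st$p^2 * mass) else Inf
    exp(h0 - h1)
  }
  a0 <- h_of(eps)
  if (!is.finite(a0) || a0 == 0) { dir <- -1 } else { dir <- if (a0 > 0.5) 1 else -1 }
  for (k in seq_len(50)) {
    eps_new <- eps * 2^dir
    a <- h_of(eps_new)
    ok <- is.finite(a) && a > 0
    if (dir > 0 && (!ok || a < 0.5)) break
    if (dir < 0 && ok && a > 0.5) { eps <- eps_new; break }
    eps <- eps_new
    if (eps < 1e-10 || eps > 1e4) break
  }
  eps
}

# split-chain potential scale reduction factor (R-hat)
split_rhat <- function(x, chain_id) {
  chains <- split(x, chain_id)
  halves <- list()
  for (ch in chains) {
    n <- length(ch)
    if (n < 4L) return(NA_real_)
    h <- floor(n / 2)
    halves <- c(halves, list(ch[1:h]), list(ch[(h + 1):(2 * h)]))
  }
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (!is.finite(W) || W <= 0) {
    # constant within chains: identical means -> 1, else divergent
    return(if (isTRUE(all.equal(max(means), min(means)))) 1 else Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}
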