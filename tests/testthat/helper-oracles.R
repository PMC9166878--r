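# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's vectorized/log-space code paths:
# plain loops, direct products of densities, enumeration of the latent
# attentiveness states.

# GPCM category probabilities by explicit double loop over r and l
oracle_gpcm_probs <- function(eta, v, b) {
  K <- length(b)
  num <- numeric(K + 1)
  for (k in 0:K) {
    acc <- 0
    if (k >= 1) for (l in 1:k) acc <- acc + (v * eta - b[l])
    num[k + 1] <- exp(acc)
  }
  num / sum(num)
}

# Eq.-style person-screen mixture by direct enumeration of the two states,
# multiplying raw densities (no log-sum-exp)
oracle_screen_loglik <- function(x, t, psi, tau, eta, iota, v, bmat, bstar,
                                 gamma, beta_C, sigma_A, sigma_C, kappa) {
  p1 <- exp(psi - iota) / (1 + exp(psi - iota))
  att <- 1
  cie <- 1
  for (j in seq_along(x)) {
    b <- bmat[j, ]
    o <- if (length(b) %% 2 == 1) b[(length(b) + 1) / 2] else
      mean(b[c(length(b) / 2, length(b) / 2 + 1)])
    if (!is.na(x[j])) {
      att <- att * oracle_gpcm_probs(eta, v[j], b)[x[j] + 1]
      cie <- cie * kappa[x[j] + 1]
    }
    if (!is.na(t[j])) {
      mu <- (beta_C + bstar[j]) - tau - gamma * abs(v[j] * eta - o)
      att <- att * stats::dlnorm(t[j], mu, sigma_A)
      cie <- cie * stats::dlnorm(t[j], beta_C, sigma_C)
    }
  }
  log(p1 * att + (1 - p1) * cie)
}

# Person-level mixture of the screen-level model by direct enumeration
oracle_screenlevel_loglik <- function(pi_i, tau, eta, x, tbar, v, b,
                                      bstar_s, gamma, beta_C, sigma_A,
                                      sigma_C, kappa) {
  att <- 1
  cie <- 1
  for (s in seq_along(x)) {
    bs <- rbind(b[[s]])
    o <- apply(bs, 1, function(bb)
      if (length(bb) %% 2 == 1) bb[(length(bb) + 1) / 2] else
        mean(bb[c(length(bb) / 2, length(bb) / 2 + 1)]))
    v_dot <- exp(mean(log(v[[s]])))
    o_dot <- mean(o)
    for (j in seq_along(x[[s]])) {
      if (!is.na(x[[s]][j])) {
        att <- att * oracle_gpcm_probs(eta[s], v[[s]][j], bs[j, ])[x[[s]][j] + 1]
        cie <- cie * kappa[x[[s]][j] + 1]
      }
    }
    if (!is.na(tbar[s])) {
      mu <- (beta_C + bstar_s[s]) - tau - gamma * abs(v_dot * eta[s] - o_dot)
      att <- att * stats::dlnorm(tbar[s], mu, sigma_A)
      cie <- cie * stats::dlnorm(tbar[s], beta_C, sigma_C)
    }
  }
  log(pi_i * att + (1 - pi_i) * cie)
}

# Textbook split Gelman-Rubin statistic, written independently of psrf()
oracle_split_rhat <- function(chains) {
  n0 <- length(chains[[1]])
  half <- n0 %/% 2
  sp <- list()
  for (ch in chains) {
    sp[[length(sp) + 1]] <- ch[1:half]
    sp[[length(sp) + 1]] <- ch[(n0 - half + 1):n0]
  }
  m <- length(sp)
  n <- half
  mu <- sapply(sp, mean)
  s2 <- sapply(sp, function(z) sum((z - mean(z))^2) / (n - 1))
  W <- sum(s2) / m
  B <- n / (m - 1) * sum((mu - mean(mu))^2)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# brute-force longest-run scan, O(n^2)
oracle_long_string <- function(x) {
  best <- 0
  n <- length(x)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    run <- 1
    j <- i + 1
    while (j <= n && !is.na(x[j]) && x[j] == x[i + (j - i) - 1] &&
           x[j] == x[i]) {
      run <- run + 1
      j <- j + 1
    }
    if (run > best) best <- run
  }
  best
}

# random small person-screen instance for likelihood oracle tests
random_screen_instance <- function(J = 3, K = 3, miss = 0) {
  list(
    x = ifelse(runif(J) < miss, NA_integer_, sample(0:K, J, replace = TRUE)),
    t = ifelse(runif(J) < miss, NA_real_, rlnorm(J, 1, 0.5)),
    psi = rnorm(1), tau = rnorm(1, 0, 0.4), eta = rnorm(1),
    iota = rnorm(1, -2, 1),
    v = runif(J, 0.6, 1.8),
    bmat = matrix(rnorm(J * K, 0, 1), J, K),
    bstar = runif(J, 0, 1),
    gamma = runif(1, 0, 0.1), beta_C = rnorm(1, 0.7, 0.2),
    sigma_A = runif(1, 0.3, 0.8), sigma_C = runif(1, 0.5, 1.2),
    kappa = {
      k <- runif(K + 1, 0.5, 1.5)
      k / sum(k)
    }
  )
}
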