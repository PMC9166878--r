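test_that("GPCM probabilities match direct summation and normalize", {
  expect_equal(gpcm_probs(0, v = 1, b = 0), c(0.5, 0.5))
  expect_equal(gpcm_probs(0.7, v = 1.3, b = c(-1.0, 0.2, 1.1)),
               oracle_gpcm_probs(0.7, 1.3, c(-1.0, 0.2, 1.1)),
               tolerance = 1e-12)
  set.seed(1)
  for (rep in 1:25) {
    K <- sample(1:5, 1)
    eta <- rnorm(1, 0, 2); v <- runif(1, 0.2, 2.5)
    b <- rnorm(K, 0, 1.5)
    p <- gpcm_probs(eta, v, b)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
    expect_equal(p, oracle_gpcm_probs(eta, v, b), tolerance = 1e-10)
  }
  expect_error(gpcm_probs(NaN, 1, 0), "finite")
  expect_error(gpcm_probs(0, -1, 0), "positive")
})

test_that("probability of the top category increases with the trait", {
  grid <- seq(-4, 4, by = 0.25)
  for (v in c(0.5, 1, 2)) {
    pK <- vapply(grid, function(e) gpcm_probs(e, v, c(-1, 0.3, 1.2))[4],
                 numeric(1))
    expect_true(all(diff(pK) > 0))
  }
})

test_that("middle step difficulty follows the median rule", {
  expect_equal(middle_step_difficulty(c(-1, 0.3, 2)), 0.3)
  expect_equal(middle_step_difficulty(5), 5)
  expect_equal(middle_step_difficulty(c(-1, 1)), 0)
  expect_equal(middle_step_difficulty(c(0, 2, 4, 10)), 3)
  expect_error(middle_step_difficulty(numeric(0)))
})

test_that("attentive log-RT mean composes intensity, speed and distance", {
  expect_equal(attentive_logrt_mean(eta = 3, tau = 0, v = 1, o = 0,
                                    beta_star = 0.5, gamma = 0,
                                    beta_C = 1), 1.5)
  # one unit more distance scales expected RT by exp(-gamma)
  m1 <- attentive_logrt_mean(1, 0, 1, 0, 0.3, 0.04, 0.74)
  m2 <- attentive_logrt_mean(2, 0, 1, 0, 0.3, 0.04, 0.74)
  expect_equal(exp(m2 - m1), exp(-0.04))
  expect_equal(report_distance_factor(0.04), 0.96)
  # Monte-Carlo: simulated mean log RT converges to the formula value
  set.seed(42)
  mu <- attentive_logrt_mean(0.8, 0.2, 1.2, -0.4, 0.6, 0.04, 0.74)
  lt <- log(rlnorm(1e5, mu, 0.5))
  expect_lt(abs(mean(lt) - mu), 3 * 0.5 / sqrt(1e5))
  expect_error(attentive_logrt_mean(0, 0, 1, 0, -0.1, 0, 0), "non-negative")
})

test_that("C/IER RT density is a proper lognormal", {
  # median of the distribution is exp(beta_C)
  expect_equal(plnorm(exp(0.74), 0.74, 0.9), 0.5)
  expect_equal(report_seconds(0.74), 2.10)
  q <- integrate(function(t) exp(cier_logrt_logdensity(t, 0.74, 0.88)),
                 lower = 0, upper = Inf, rel.tol = 1e-9)
  expect_equal(q$value, 1, tolerance = 1e-6)
  # representation invariance: evaluating at t and exp(log t) agree exactly
  t0 <- 3.7
  expect_identical(cier_logrt_logdensity(t0, 0.5, 1),
                   cier_logrt_logdensity(exp(log(t0)), 0.5, 1))
  expect_error(cier_logrt_logdensity(-1, 0, 1), "positive")
})

test_that("attentiveness probability is a stable logistic", {
  expect_equal(attentiveness_prob(1.3, 1.3), 0.5)
  expect_equal(attentiveness_prob(1e4, 0), 1)
  expect_equal(attentiveness_prob(-1e4, 0), 0)
  expect_equal(attentiveness_prob(2.74, -2.74), 1 / (1 + exp(-5.48)),
               tolerance = 1e-15)
})

test_that("person-screen mixture equals enumeration of the latent state", {
  set.seed(7)
  for (miss in c(0, 0.3)) {
    for (rep in 1:20) {
      z <- random_screen_instance(J = sample(1:3, 1), K = sample(1:3, 1),
                                  miss = miss)
      got <- screen_mixture_loglik(z$x, z$t, z$psi, z$tau, z$eta, z$iota,
                                   z$v, z$bmat, z$bstar, z$gamma, z$beta_C,
                                   z$sigma_A, z$sigma_C, z$kappa)
      want <- oracle_screen_loglik(z$x, z$t, z$psi, z$tau, z$eta, z$iota,
                                   z$v, z$bmat, z$bstar, z$gamma, z$beta_C,
                                   z$sigma_A, z$sigma_C, z$kappa)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("fully missing and collapsed mixtures behave as limits", {
  z <- random_screen_instance(J = 3, K = 3)
  # everything missing: both products are 1, the mixture of two 1s is 1
  expect_equal(screen_mixture_loglik(rep(NA_integer_, 3), rep(NA_real_, 3),
                                     z$psi, z$tau, z$eta, z$iota, z$v,
                                     z$bmat, z$bstar, z$gamma, z$beta_C,
                                     z$sigma_A, z$sigma_C, z$kappa), 0)
  # identical components (RT-only data, beta_star = gamma = tau = 0,
  # sigma_A = sigma_C): the mixture collapses to a single component
  t <- c(1.5, 2.5, 2.0)
  got <- screen_mixture_loglik(rep(NA_integer_, 3), t, z$psi, tau = 0,
                               z$eta, z$iota, z$v, z$bmat, rep(0, 3),
                               gamma = 0, z$beta_C,
                               sigma_A = z$sigma_C, sigma_C = z$sigma_C,
                               z$kappa)
  single <- sum(dlnorm(t, z$beta_C, z$sigma_C, log = TRUE))
  expect_equal(got, single, tolerance = 1e-12)
})

test_that("screen-level aggregates and log-mean follow the stated means", {
  agg <- screen_aggregates(c(2, 8), c(-1, 3))
  expect_equal(agg$v_dot, 4)
  expect_equal(agg$o_dot, 1)
  expect_equal(screen_aggregates(c(1, 4), c(0, 2))$v_dot, 2)
  set.seed(3)
  for (rep in 1:10) {
    v <- runif(5, 0.3, 3)
    expect_equal(screen_aggregates(v, rnorm(5))$v_dot,
                 exp(mean(log(v))), tolerance = 1e-12)
  }
  expect_error(screen_aggregates(c(1, -1), c(0, 0)), "positive")
  # single-item screen: identical to the item-level mean
  expect_equal(
    screenlevel_logrt_mean(0.4, 0.1, 1.3, -0.2, 0.5, 0.04, 0.74),
    attentive_logrt_mean(0.4, 0.1, 1.3, -0.2, 0.5, 0.04, 0.74))
  # hand-computed scalar value
  expect_equal(screenlevel_logrt_mean(1, 0.5, 2, 1, 0.3, 0.1, 0.7),
               (0.7 + 0.3) - 0.5 - 0.1 * abs(2 * 1 - 1))
})

test_that("person-level mixture of the screen model matches enumeration", {
  set.seed(11)
  for (rep in 1:15) {
    S <- 2
    J <- c(3, 2)
    v <- lapply(J, function(j) runif(j, 0.6, 1.8))
    b <- lapply(J, function(j) matrix(rnorm(j * 3), j, 3))
    x <- lapply(J, function(j) sample(c(0:3, NA), j, replace = TRUE))
    tbar <- ifelse(runif(S) < 0.2, NA, rlnorm(S, 1, 0.4))
    kappa <- c(0.14, 0.34, 0.41, 0.11)
    pi_i <- runif(1)
    tau <- rnorm(1, 0, 0.4); eta <- rnorm(S)
    bstar_s <- runif(S, 0, 1)
    got <- screenlevel_mixture_loglik(pi_i, tau, eta, x, tbar, v, b,
                                      bstar_s, 0.04, 0.74, 0.5, 0.9, kappa)
    want <- oracle_screenlevel_loglik(pi_i, tau, eta, x, tbar, v, b,
                                      bstar_s, 0.04, 0.74, 0.5, 0.9, kappa)
    expect_equal(got, want, tolerance = 1e-10)
    # boundaries: pure attentive / pure C/IER
    expect_equal(screenlevel_mixture_loglik(1, tau, eta, x, tbar, v, b,
                                            bstar_s, 0.04, 0.74, 0.5, 0.9,
                                            kappa),
                 oracle_screenlevel_loglik(1 - 1e-300, tau, eta, x, tbar, v,
                                           b, bstar_s, 0.04, 0.74, 0.5, 0.9,
                                           kappa), tolerance = 1e-8)
  }
  expect_error(screenlevel_mixture_loglik(1.2, 0, c(0, 0),
                                          list(0L, 0L), c(1, 1),
                                          list(1, 1),
                                          list(matrix(0, 1, 1),
                                               matrix(0, 1, 1)),
                                          c(0, 0), 0, 0, 1, 1, c(0.5, 0.5)),
               "pi_i")
})

test_that("marginal C/IER rate integral matches Monte Carlo", {
  # degenerate attentiveness distribution: plain logistic at psi = 0
  expect_equal(marginal_cier_rate(0, 1e-8), 0.5, tolerance = 1e-6)
  expect_lt(marginal_cier_rate(-30, 1), 1e-10)
  set.seed(5)
  n <- 1e6
  psi <- rnorm(n, 0, sqrt(1.98))
  mc <- mean(plogis(-(psi - (-2.74))))
  se <- sd(plogis(-(psi - (-2.74)))) / sqrt(n)
  expect_lt(abs(marginal_cier_rate(-2.74, sqrt(1.98)) - mc), 3 * se)
  # inversion round-trip
  iota <- iota_for_rate(0.05, sqrt(1.98))
  expect_equal(marginal_cier_rate(iota, sqrt(1.98)), 0.05,
               tolerance = 1e-8)
})
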