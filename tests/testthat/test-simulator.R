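test_that("the generator is deterministic given configuration and seed", {
  cfg <- sim_config(seed = 99, N = 40)
  s1 <- simulate_cier_data(cfg)
  s2 <- simulate_cier_data(cfg)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cier_data(sim_config(seed = 100, N = 40))
  expect_false(identical(s1$data$x, s3$data$x))
  expect_error(sim_config(N = 10), "seed")
})

test_that("person parameters follow the population covariance", {
  set.seed(1)
  z <- draw_persons(1e5, diag(4))
  cc <- cor(z)
  expect_true(all(abs(cc[upper.tri(cc)]) < 3 / sqrt(1e5)))
  Sg <- default_person_cov(2)
  expect_equal(Sg[1, 1], 1.98)
  expect_equal(diag(Sg)[3:4], c(1, 1))
  z <- draw_persons(1e5, Sg)
  r <- cor(z[, "eta1"], z[, "eta2"])
  expect_lt(abs(r - 0.43), 3 * (1 - 0.43^2) / sqrt(1e5))
  expect_error(draw_persons(5, matrix(c(1, 2, 2, 1), 2)), "positive-definite")
})

test_that("attentiveness indicators match the marginal rate integral", {
  set.seed(2)
  expect_true(all(simulate_attentiveness(rnorm(200), -1e9) == 1L))
  # target 5%: realized fraction within binomial error at N*S = 10^4
  sigma_psi <- sqrt(1.98)
  iota <- iota_for_rate(0.05, sigma_psi)
  psi <- rnorm(5e3, 0, sigma_psi)
  delta <- simulate_attentiveness(psi, rep(iota, 2))
  p <- mean(delta == 0L)
  expect_lt(abs(p - 0.05), 3 * sqrt(0.05 * 0.95 / 1e4))
  # quadrature prediction matches realized rates across a grid of iota
  for (i0 in c(-4, -2.5, -1)) {
    pr <- marginal_cier_rate(i0, sigma_psi)
    psi <- rnorm(2e4, 0, sigma_psi)
    d <- simulate_attentiveness(psi, i0)
    expect_lt(abs(mean(d == 0) - pr), 3 * sqrt(pr * (1 - pr) / 2e4))
  }
})

test_that("attentive screens reproduce the GPCM and RT structure", {
  set.seed(3)
  v <- c(1.2, 0.9); b <- rbind(c(-1, 0, 1), c(-0.5, 0.2, 0.8))
  bstar <- c(0.5, 0.3)
  n <- 2e4
  xs <- matrix(0L, n, 2); ts <- matrix(0, n, 2)
  for (r in seq_len(n)) {
    sim <- simulate_attentive_screen(tau = 0.1, eta = 0.6, v, b, bstar,
                                     gamma = 0.04, beta_C = 0.74,
                                     sigma_A = 0.5)
    xs[r, ] <- sim$x; ts[r, ] <- sim$t
  }
  for (j in 1:2) {
    p_hat <- tabulate(xs[, j] + 1L, 4) / n
    p <- gpcm_probs(0.6, v[j], b[j, ])
    expect_true(all(abs(p_hat - p) < 3 * sqrt(p * (1 - p) / n) + 1e-3))
    mu <- attentive_logrt_mean(0.6, 0.1, v[j],
                               middle_step_difficulty(b[j, ]), bstar[j],
                               0.04, 0.74)
    expect_lt(abs(mean(log(ts[, j])) - mu), 3 * 0.5 / sqrt(n))
    expect_lt(abs(sd(log(ts[, j])) - 0.5), 3 * 0.5 / sqrt(2 * n))
  }
  # gamma = 0: mean log RT no longer depends on the trait
  set.seed(4)
  etas <- seq(-2, 2, length.out = 9)
  m <- vapply(etas, function(e) {
    mean(log(replicate(300, simulate_attentive_screen(0, e, 1, rbind(c(0)),
                                                      0.4, 0, 0.74,
                                                      0.3)$t)))
  }, numeric(1))
  slope <- coef(lm(m ~ etas))[2]
  expect_lt(abs(slope), 0.02)
})

test_that("C/IER patterns produce their characteristic responses", {
  set.seed(5)
  sl <- simulate_cier_screen("straight_line", J = 7, K = 3, 0.74, 0.9)
  expect_equal(long_string(sl$x), 7)
  # diagonal with wraparound from a fixed start
  repeat {
    dg <- simulate_cier_screen("diagonal_line", J = 5, K = 3, 0.74, 0.9)
    if (dg$x[1] == 2L) break
  }
  expect_equal(dg$x, c(2L, 3L, 0L, 1L, 2L))
  dd <- simulate_cier_screen("diagonal_line", J = 5, K = 3, 0.74, 0.9,
                             descending = TRUE)
  expect_true(all(diff(dd$x) %in% c(-1L, 3L)))
  ep <- simulate_cier_screen("endpoint_random", J = 200, K = 3, 0.74, 0.9)
  expect_true(all(ep$x %in% c(0L, 3L)))
  expect_error(simulate_cier_screen("zigzag", 5, 3, 0, 1), "unknown")
})

test_that("C/IER response marginals match the analytic pattern mixture", {
  set.seed(6)
  K <- 3; J <- 6; n <- 4000
  pats <- c("uniform_random", "endpoint_random", "straight_line",
            "diagonal_line")
  counts <- numeric(K + 1)
  for (r in seq_len(n)) {
    x <- simulate_cier_screen(sample(pats, 1), J, K, 0.74, 0.9)$x
    counts <- counts + tabulate(x + 1L, K + 1)
  }
  p_hat <- counts / sum(counts)
  # uniform, straight and diagonal are marginally uniform; endpoints put
  # half the mass on each extreme: mixture = (3/4)*1/4 + (1/4)*(1/2,0,0,1/2)
  p <- c(0.3125, 0.1875, 0.1875, 0.3125)
  expect_true(all(abs(p_hat - p) < 4 * sqrt(p * (1 - p) / (n * J))))
})

test_that("C/IER RTs are pattern-independent", {
  set.seed(7)
  t_straight <- unlist(replicate(400, simulate_cier_screen(
    "straight_line", 5, 3, 0.74, 0.9)$t, simplify = FALSE))
  t_unif <- unlist(replicate(400, simulate_cier_screen(
    "uniform_random", 5, 3, 0.74, 0.9)$t, simplify = FALSE))
  expect_gt(suppressWarnings(ks.test(t_straight, t_unif)$p.value), 0.01)
  # and they follow the common lognormal
  expect_gt(ks.test(t_straight, plnorm, 0.74, 0.9)$p.value, 0.01)
})

test_that("full datasets have the configured C/IER rate and structure", {
  cfg <- sim_config(seed = 11, N = 1000, target_cier_rate = 0.05)
  sim <- simulate_cier_data(cfg)
  expect_equal(nrow(sim$data), 1000 * 12)
  expect_true(all(sim$data$d_x == 0L) && all(sim$data$d_t == 0L))
  p <- mean(sim$truth$delta == 0L)
  expect_lt(abs(p - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  # pattern labels exactly for C/IER screens
  expect_true(all(is.na(sim$truth$pattern) == (sim$truth$delta == 1L)))
  # time intensities: beta = beta_C + beta* >= beta_C for every item
  expect_true(all(sim$items$beta_star >= 0))
  expect_true(all(cfg$beta_C + sim$items$beta_star >= cfg$beta_C))
  # missingness switch
  cfg2 <- sim_config(seed = 12, N = 50, miss_x = 0.2, miss_t = 0.1)
  sim2 <- simulate_cier_data(cfg2)
  expect_equal(is.na(sim2$data$x), sim2$data$d_x == 1L)
  expect_equal(is.na(sim2$data$t), sim2$data$d_t == 1L)
  expect_gt(mean(sim2$data$d_x), 0.1)
})

test_that("an all-C/IER uniform-random dataset has uniform categories", {
  cfg <- sim_config(seed = 13, N = 400, iota = c(1e9, 1e9),
                    pattern_mix = c(uniform_random = 1, endpoint_random = 0,
                                    straight_line = 0, diagonal_line = 0))
  sim <- simulate_cier_data(cfg)
  expect_true(all(sim$truth$delta == 0L))
  tab <- table(factor(sim$data$x, levels = 0:3))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})
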