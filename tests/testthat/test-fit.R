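test_that("split-Rhat matches a textbook implementation", {
  set.seed(51)
  chains <- replicate(4, rnorm(400), simplify = FALSE)
  expect_equal(psrf(chains), oracle_split_rhat(chains), tolerance = 1e-8)
  # identical stationary chains give values at one up to half-vs-half
  # drift (split-Rhat compares chain halves, so it is not exactly one)
  one <- rnorm(400)
  expect_equal(psrf(list(one, one, one)),
               oracle_split_rhat(list(one, one, one)), tolerance = 1e-8)
  expect_lt(abs(psrf(list(one, one)) - 1), 0.01)
  # chains exploring disjoint regions are flagged
  expect_gt(psrf(list(rnorm(400), rnorm(400, 10))), 1.10)
  # constant chains have no variance to compare
  expect_equal(psrf(list(rep(1, 100), rep(1, 100))), 1)
  expect_error(psrf(list(rnorm(10))), "2 chains")
  expect_error(psrf(list(rnorm(10), rnorm(20))), "equal lengths")
})

test_that("the sampler's likelihood equals the enumeration oracle", {
  # item-level model: 2 persons x 1 screen x 3 items plus a second screen,
  # evaluated at arbitrary fixed parameters
  set.seed(52)
  cfg <- sim_config(seed = 53, N = 3, S = 2, J = c(3, 2), miss_x = 0.2,
                    miss_t = 0.2)
  sim <- simulate_cier_data(cfg)
  K <- 3
  it <- sim$items
  pars <- list(
    sigma_psi = 1.2, sigma_tau = 0.5, sigma_A = 0.45, sigma_C = 0.95,
    gamma = 0.06, beta_C = 0.8, iota = c(-2.5, -3.1),
    kappa = c(0.2, 0.3, 0.4, 0.1),
    v = it$v, beta_star = it$beta_star,
    b = as.matrix(it[, paste0("b", 1:K)]),
    persons = cbind(rnorm(3), rnorm(3), rnorm(3), rnorm(3)),
    R = diag(4)
  )
  got <- cier_item_loglik(sim, pars, K = K)
  want <- 0
  for (i in 1:3) for (s in 1:2) {
    rows <- sim$data$person == i & sim$data$screen == s
    idx <- which(it$screen == s)
    want <- want + oracle_screen_loglik(
      sim$data$x[rows], sim$data$t[rows],
      psi = pars$persons[i, 1], tau = pars$persons[i, 2],
      eta = pars$persons[i, 2 + s], iota = pars$iota[s],
      v = pars$v[idx], bmat = pars$b[idx, , drop = FALSE],
      bstar = pars$beta_star[idx], gamma = pars$gamma,
      beta_C = pars$beta_C, sigma_A = pars$sigma_A,
      sigma_C = pars$sigma_C, kappa = pars$kappa)
  }
  expect_equal(got, want, tolerance = 1e-10)

  # screen-level model: person-level mixture on a 2-person toy
  tbar <- data.frame(person = rep(1:3, each = 2), screen = rep(1:2, 3),
                     t_bar = rlnorm(6, 1, 0.3))
  pars2 <- list(
    sigma_tau = 0.5, sigma_A = 0.45, sigma_C = 0.95, gamma = 0.06,
    beta_C = 0.8, pi_pop = 0.9, lambda = 4,
    kappa = c(0.2, 0.3, 0.4, 0.1), v = it$v,
    b = as.matrix(it[, paste0("b", 1:K)]),
    beta_star_s = c(0.4, 0.2), pi = c(0.95, 0.6, 0.85),
    persons = cbind(rnorm(3), rnorm(3), rnorm(3)), R = diag(3)
  )
  got2 <- cier_screen_loglik(sim, tbar, pars2, K = K)
  want2 <- 0
  for (i in 1:3) {
    xs <- lapply(1:2, function(s)
      sim$data$x[sim$data$person == i & sim$data$screen == s])
    want2 <- want2 + oracle_screenlevel_loglik(
      pars2$pi[i], tau = pars2$persons[i, 1],
      eta = pars2$persons[i, 2:3], x = xs,
      tbar = tbar$t_bar[tbar$person == i],
      v = lapply(1:2, function(s) it$v[it$screen == s]),
      b = lapply(1:2, function(s)
        as.matrix(it[it$screen == s, paste0("b", 1:K)])),
      bstar_s = pars2$beta_star_s, gamma = pars2$gamma,
      beta_C = pars2$beta_C, sigma_A = pars2$sigma_A,
      sigma_C = pars2$sigma_C, kappa = pars2$kappa)
  }
  expect_equal(got2, want2, tolerance = 1e-10)
})

test_that("the likelihood is invariant to relabeling screens and items", {
  cfg <- sim_config(seed = 54, N = 4)
  sim <- simulate_cier_data(cfg)
  K <- 3
  it <- sim$items
  pars <- list(sigma_psi = 1, sigma_tau = 0.4, sigma_A = 0.5,
               sigma_C = 0.9, gamma = 0.04, beta_C = 0.74,
               iota = c(-3, -2.5), kappa = c(0.25, 0.25, 0.25, 0.25),
               v = it$v, beta_star = it$beta_star,
               b = as.matrix(it[, paste0("b", 1:K)]),
               persons = matrix(rnorm(16, 0, 0.5), 4, 4), R = diag(4))
  base <- cier_item_loglik(sim, pars, K = K)
  # swap the two screens (and the corresponding person/eta columns)
  d2 <- sim$data
  d2$screen <- 3L - d2$screen
  it2_ord <- order(3L - it$screen, ave(seq_len(nrow(it)), it$screen,
                                       FUN = seq_along))
  pars2 <- pars
  pars2$iota <- rev(pars$iota)
  pars2$v <- pars$v[it2_ord]
  pars2$beta_star <- pars$beta_star[it2_ord]
  pars2$b <- pars$b[it2_ord, ]
  pars2$persons <- pars$persons[, c(1, 2, 4, 3)]
  pars2$R <- pars$R
  expect_equal(cier_item_loglik(d2, pars2, K = K), base, tolerance = 1e-12)
})

test_that("boundary data without C/IER yields a near-zero estimated rate", {
  cfg <- sim_config(seed = 55, N = 120, iota = c(-1e9, -1e9))
  sim <- simulate_cier_data(cfg)
  expect_true(all(sim$truth$delta == 1L))
  fit <- suppressWarnings(fit_cier(sim, variant = "item",
                                   mcmc = cier_mcmc(chains = 2,
                                                    iterations = 400,
                                                    warmup = 200, thin = 4,
                                                    seed = 56)))
  expect_lt(cier_rate(fit)$overall, 2)
})

test_that("posterior classification is bounded, ordered by ground truth,
           and reproduces the prior on fully missing screens", {
  cfg <- sim_config(seed = 57, N = 150)
  sim <- simulate_cier_data(cfg)
  # make person 1's first screen fully missing
  sel <- sim$data$person == 1 & sim$data$screen == 1
  sim$data$x[sel] <- NA_integer_
  sim$data$t[sel] <- NA_real_
  sim$data$d_x[sel] <- 1L
  sim$data$d_t[sel] <- 1L
  fit <- suppressWarnings(fit_cier(sim, variant = "item",
                                   mcmc = cier_mcmc(chains = 2,
                                                    iterations = 500,
                                                    warmup = 250, thin = 4,
                                                    seed = 58)))
  cl <- classify_attentiveness(fit)
  expect_true(all(cl$p_cier >= 0 & cl$p_cier <= 1))
  truth0 <- matrix(sim$truth$delta == 0L, ncol = 2, byrow = TRUE)
  truth0[1, 1] <- NA  # the blanked unit no longer carries data
  expect_gt(mean(fit$p_cier[which(truth0)]),
            mean(fit$p_cier[which(!truth0)]))
  # fully missing screen: posterior P(C/IER) equals the posterior mean of
  # 1 - logistic(psi - iota), i.e. the data contribute nothing
  prior_p <- mean(unlist(lapply(fit$draws, function(dm)
    plogis(-(dm[, "psi[1]"] - dm[, "iota[1]"])))))
  expect_equal(fit$p_cier[1, 1], prior_p, tolerance = 0.02)
  # beta_star draws respect the non-negativity constraint
  for (dm in fit$draws)
    expect_true(all(dm[, grep("beta_star", colnames(dm))] >= 0))
  # kappa draws stay on the simplex
  for (dm in fit$draws) {
    ks <- dm[, grep("^kappa", colnames(dm))]
    expect_true(all(ks >= 0))
    expect_equal(unname(rowSums(ks)), rep(1, nrow(ks)), tolerance = 1e-9)
  }
})

test_that("strongly separated RT components give accurate classification", {
  it <- data.frame(screen = rep(1:2, c(7, 5)),
                   v = rep(1.2, 12),
                   b1 = rep(-1.1, 12), b2 = rep(0, 12), b3 = rep(1.1, 12),
                   beta_star = rep(2, 12))
  cfg <- sim_config(seed = 59, N = 300, items = it,
                    target_cier_rate = 0.08)
  sim <- simulate_cier_data(cfg)
  fit <- suppressWarnings(fit_cier(sim, variant = "item",
                                   mcmc = cier_mcmc(chains = 1,
                                                    iterations = 500,
                                                    warmup = 250, thin = 4,
                                                    seed = 60)))
  truth0 <- matrix(sim$truth$delta == 0L, ncol = 2, byrow = TRUE)
  acc <- mean((fit$p_cier > 0.5) == truth0)
  expect_gt(acc, 0.95)
})

test_that("a prior-only run reproduces the prior marginals", {
  # all responses and RTs missing: the sampler explores the prior
  d <- expand.grid(person = 1:25, item = 1:6)
  d$screen <- ifelse(d$item <= 3, 1L, 2L)
  d$pos <- ifelse(d$item <= 3, d$item, d$item - 3L)
  d$x <- NA_integer_
  d$t <- NA_real_
  fit <- suppressWarnings(fit_cier(d, variant = "item", K = 3,
                                   mcmc = cier_mcmc(chains = 2,
                                                    iterations = 1500,
                                                    warmup = 500, thin = 10,
                                                    seed = 61)))
  dm <- do.call(rbind, fit$draws)
  # LKJ(1) marginal of one correlation in a 4x4 matrix is Beta(2,2) on
  # (-1, 1): mean 0, variance 0.2
  r <- dm[, "cor_eta1_eta2"]
  expect_lt(abs(mean(r)), 0.1)
  expect_lt(abs(var(r) - 0.2), 0.08)
  # kappa marginals are Dirichlet(1): mean 1/4
  expect_lt(max(abs(colMeans(dm[, grep("^kappa", colnames(dm))]) - 0.25)),
            0.06)
  # diffuse normal prior on gamma: sd 10
  expect_lt(abs(sd(dm[, "gamma"]) - 10), 2)
  # trait variances are fixed at one by construction (not sampled): the
  # eta draws are standard normal under the prior
  expect_lt(abs(sd(dm[, "eta1[3]"]) - 1), 0.15)
})
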