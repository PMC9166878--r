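test_that("long string index finds the longest constant run", {
  expect_equal(long_string(c(1, 1, 1, 2, 2)), 3)
  expect_equal(long_string(rep(2, 13)), 13)
  expect_equal(long_string(integer(0)), 0L)
  expect_equal(long_string(c(NA, NA)), 0L)
  expect_equal(long_string(c(1, 1, NA, 1, 1, 1)), 3)  # NA breaks runs
  set.seed(31)
  for (rep in 1:40) {
    x <- sample(c(0:3, NA), sample(1:25, 1), replace = TRUE)
    expect_equal(long_string(x), oracle_long_string(x))
  }
})

test_that("even-odd index rewards within-scale consistency", {
  # identical half scores across scales correlate perfectly
  x <- c(2, 2, 2, 2, 1, 1, 1, 1, 3, 3, 3, 3)
  scales <- rep(1:3, each = 4)
  expect_equal(even_odd(x, scales), 1)
  # constant responses everywhere: zero variance, undefined
  expect_true(is.na(even_odd(rep(2, 12), scales)))
  expect_warning(out <- even_odd(x[1:4], scales[1:4]), "two scales")
  expect_true(is.na(out))
  # consistent (attentive-like) responders beat uniform-random ones
  set.seed(32)
  cfg <- sim_config(seed = 33, N = 150, S = 3, J = c(5, 5, 5),
                    Sigma = default_person_cov(3), iota = rep(-1e9, 3),
                    v_range = c(1.8, 2.6))
  att <- simulate_cier_data(cfg)
  Xa <- matrix(att$data$x, nrow = 150, byrow = TRUE)
  Xr <- matrix(sample(0:3, 150 * 15, replace = TRUE), 150)
  sc <- rep(1:3, each = 5)
  ea <- even_odd(Xa, sc); er <- even_odd(Xr, sc)
  expect_gt(median(ea, na.rm = TRUE), median(er, na.rm = TRUE))
})

test_that("Mahalanobis distances and chi-square cutoffs are correct", {
  set.seed(34)
  X <- matrix(rnorm(200 * 5), 200, 5)
  md <- mahalanobis_flags(X, quantile = 0.99, df = 5)
  S <- cov(X)
  d2 <- mahalanobis(X, colMeans(X), S)
  expect_equal(md$d2, unname(d2))
  expect_equal(md$cutoff, qchisq(0.99, 5))
  # cutoff equals the quantile found by inverting the chi-square CDF
  inv <- uniroot(function(q) pchisq(q, 13) - 0.99, c(0, 100),
                 tol = 1e-12)$root
  expect_equal(mahalanobis_flags(matrix(rnorm(100 * 13), 100, 13),
                                 0.99, 13)$cutoff, inv, tolerance = 1e-8)
  # one dimension: squared z-score with the n-1 variance convention
  x1 <- rnorm(50)
  md1 <- mahalanobis_flags(cbind(x1), 0.99, 1)
  expect_equal(md1$d2, (x1 - mean(x1))^2 / var(x1))
  # incomplete rows are excluded listwise and reported
  X[3, 2] <- NA
  mdm <- mahalanobis_flags(X, 0.99, 5)
  expect_true(is.na(mdm$d2[3]))
  expect_equal(mdm$n_excluded, 1)
  expect_error(mahalanobis_flags(cbind(x1, x1), 0.99), "singular")
})

test_that("multiple hurdle flags sequentially and partitions the flags", {
  set.seed(35)
  N <- 300
  X <- matrix(sample(0:3, N * 12, replace = TRUE, prob = c(1, 2, 2, 1)),
              N, 12)
  scales <- rep(1:2, c(7, 5))
  aat <- runif(N, 3, 6)
  # a synthetic rapid respondent is caught at the RT hurdle in both configs
  aat[1] <- 0.5
  X[2, ] <- 2           # full straight line
  for (preset in c("conservative", "liberal")) {
    mh <- multiple_hurdle(X, scales, aat, hurdle_config(preset))
    expect_equal(mh$flags$hurdle[1], "rt")
    expect_true(mh$flags$flagged[2])
    # partition: every flagged person has exactly one hurdle, counts add up
    expect_equal(sum(mh$counts), sum(mh$flags$flagged))
    expect_true(all(!mh$flags$flagged == is.na(mh$flags$hurdle)))
  }
  # liberal RT and Mahalanobis thresholds flag supersets at those hurdles
  mh_c <- multiple_hurdle(X, scales, aat, hurdle_config("conservative"))
  mh_l <- multiple_hurdle(X, scales, aat, hurdle_config("liberal"))
  rt_c <- which(mh_c$flags$hurdle == "rt")
  rt_l <- which(mh_l$flags$hurdle == "rt")
  expect_true(all(rt_c %in% rt_l))
  # nobody flagged when all indicators are unremarkable
  mh0 <- multiple_hurdle(X[-(1:2), ], scales, rep(5, N - 2),
                         hurdle_config("conservative",
                                       mahalanobis_quantile = 1 - 1e-12))
  expect_equal(sum(mh0$flags$flagged), 0)
})

test_that("true all-screen C/IER respondents are flagged more often", {
  cfg <- sim_config(seed = 36, N = 400)
  sim <- simulate_cier_data(cfg)
  X <- matrix(sim$data$x, nrow = 400, byrow = TRUE)
  tm <- compute_timing_measures(sim)
  aat_person <- tapply(tm$aat, tm$person, mean)
  mh <- multiple_hurdle(X, rep(1:2, c(7, 5)), aat_person,
                        hurdle_config("liberal"))
  cier_person <- tapply(sim$truth$delta == 0, sim$truth$person, all)
  if (any(cier_person)) {
    expect_gt(mean(mh$flags$flagged[cier_person]),
              mean(mh$flags$flagged[!cier_person]))
  }
})
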