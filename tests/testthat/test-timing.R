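make_timing_data <- function(t_by_screen, reading_time) {
  # single person, screens defined by the list of RT vectors
  S <- length(t_by_screen)
  data.frame(
    person = 1L,
    screen = rep(seq_len(S), lengths(t_by_screen)),
    pos = unlist(lapply(t_by_screen, seq_along)),
    t = unlist(t_by_screen)
  ) -> d
  list(data = d,
       reading = data.frame(person = 1L, screen = seq_len(S),
                            reading_time = reading_time))
}

test_that("timing measures reproduce the defining arithmetic", {
  z <- make_timing_data(list(c(2, 3, 4)), 5)
  tm <- compute_timing_measures(z$data, z$reading)
  expect_equal(tm$tt, 14)
  expect_equal(tm$frt, 7)
  expect_equal(tm$tt_per_item, 14 / 3)
  expect_equal(tm$ttfrt, (14 - 7) / 2)
  expect_equal(tm$aat, (3 + 4) / 2)
  expect_equal(tm$ttfrt, tm$aat)  # identical on complete data
})

test_that("TTFRT equals AAT on complete data and diverges under missingness", {
  cfg <- sim_config(seed = 21, N = 60)
  sim <- simulate_cier_data(cfg)
  tm <- compute_timing_measures(sim)
  expect_true(all(abs(tm$ttfrt - tm$aat) < 1e-12))
  expect_true(all(tm$tt >= tm$frt))
  # TT - FRT equals the sum of the later item RTs exactly
  for (r in sample(nrow(tm), 10)) {
    rows <- sim$data$person == tm$person[r] & sim$data$screen == tm$screen[r]
    later <- sim$data$t[rows][-1]
    expect_equal(tm$tt[r] - tm$frt[r], sum(later))
  }
  # with one later RT missing, aat averages the remaining observed ones
  z <- make_timing_data(list(c(2, NA, 4)), 5)
  tm2 <- compute_timing_measures(z$data, z$reading)
  expect_equal(tm2$aat, 4)              # mean of observed later items
  expect_equal(tm2$tt, 11)              # observed total only
  expect_equal(tm2$ttfrt, (11 - 7) / 2) # differs from aat by construction
  expect_false(isTRUE(all.equal(tm2$aat, tm2$ttfrt)))
})

test_that("trimming excludes aberrant RTs but never touches TT", {
  tr <- trim_rts(c(2.5, 91, 3))
  expect_equal(tr$n_excluded, 1)
  expect_equal(tr$fraction_excluded, 1 / 3)
  expect_equal(tr$values, c(2.5, NA, 3))
  expect_equal(trim_rts(c(2.5, 91, 3), threshold = Inf)$n_excluded, 0)
  z <- make_timing_data(list(c(2, 95, 3)), 5)
  tm <- compute_timing_measures(z$data, z$reading, trim = 90)
  expect_equal(tm$tt, 105)     # TT keeps the raw values
  expect_equal(tm$aat, 3)      # trimmed out of the AAT average
  expect_true(tm$trimmed_any)
  expect_equal(attr(tm, "exclusions")[["item_rts"]], 1)
})

test_that("trimmed fraction matches the lognormal tail probability", {
  set.seed(22)
  n <- 2e5
  vals <- rlnorm(n, 2.5, 0.8)
  p <- 1 - plnorm(90, 2.5, 0.8)
  fr <- trim_rts(vals, 90)$fraction_excluded
  expect_lt(abs(fr - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("single-item screens yield undefined ttfrt and aat", {
  z <- make_timing_data(list(c(2, 3), 4), c(5, 6))
  expect_warning(tm <- compute_timing_measures(z$data, z$reading),
                 "single-item")
  expect_true(is.na(tm$ttfrt[tm$screen == 2]))
  expect_true(is.na(tm$aat[tm$screen == 2]))
})
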