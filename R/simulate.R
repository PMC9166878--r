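#' Configuration for the synthetic C/IER data generator
#'
#' Collects every quantity needed to generate data under the item-level
#' data-generating model: design sizes, the person-parameter covariance,
#' item parameters (or generation ranges), screen attentiveness
#' difficulties (or a target marginal C/IER rate), global RT parameters,
#' the C/IER pattern mix, a per-screen stem-reading-time model (so that
#' screen-level timing measures TT and FRT are derivable), and missingness
#' rates. Defaults resemble the parameter estimates of the motivating
#' empirical analysis (attentiveness variance 1.98, trait correlation .43,
#' gamma = 0.04, beta_C = 0.74, sigma_C^2 = 0.78, four-point Likert items)
#' and a 5% marginal C/IER rate.
#'
#' @param seed integer RNG seed (mandatory; the generator is fully
#'   reproducible given the configuration).
#' @param N number of respondents.
#' @param S number of screens (= traits).
#' @param J integer vector of items per screen (length `S`).
#' @param K highest response category (categories are `0..K`).
#' @param Sigma person-parameter covariance over
#'   (`psi`, `tau`, `eta_1`, ..., `eta_S`); trait variances must be one and
#'   means are zero. Default: paper-resembling covariance built by
#'   [default_person_cov()].
#' @param items optional data frame of explicit item parameters with
#'   columns `screen`, `v`, `b1..bK`, `beta_star`; if `NULL`, parameters
#'   are drawn once from `v_range` and `b_center_range` with default
#'   time-intensity offsets.
#' @param v_range,b_center_range ranges for generated discriminations and
#'   step-difficulty centers (steps are the center plus an equally spaced
#'   spread of width 2.2).
#' @param iota attentiveness difficulty per screen; if `NULL`, a common
#'   value is derived from `target_cier_rate` by [iota_for_rate()].
#' @param target_cier_rate marginal C/IER rate used when `iota` is `NULL`.
#' @param gamma,beta_C,sigma_C,sigma_A global RT parameters.
#' @param pattern_mix named probabilities over the four C/IER patterns
#'   `uniform_random`, `endpoint_random`, `straight_line`, `diagonal_line`.
#' @param pattern_per_person if `TRUE`, one pattern is drawn per C/IE
#'   respondent and reused on all their C/IE screens; default draws a
#'   pattern per C/IE person--screen (the weaker assumption).
#' @param diagonal_descending direction of diagonal lining.
#' @param reading_meanlog,reading_sdlog lognormal parameters of the
#'   per-screen stem-reading time (default median 8 s); plumbing so that
#'   TT/FRT are well defined, not part of the response model.
#' @param miss_x,miss_t independent missingness rates for responses and
#'   item RTs.
#' @return An object of class `cier_sim_config` (a validated list).
#' @seealso [simulate_cier_data()]
#' @export
sim_config <- function(seed,
                       N = 300L, S = 2L, J = c(7L, 5L), K = 3L,
                       Sigma = default_person_cov(S),
                       items = NULL,
                       v_range = c(0.8, 1.5),
                       b_center_range = c(-1, 1),
                       iota = NULL, target_cier_rate = 0.05,
                       gamma = 0.04, beta_C = 0.74,
                       sigma_C = sqrt(0.78), sigma_A = 0.5,
                       pattern_mix = c(uniform_random = 0.25,
                                       endpoint_random = 0.25,
                                       straight_line = 0.25,
                                       diagonal_line = 0.25),
                       pattern_per_person = FALSE,
                       diagonal_descending = FALSE,
                       reading_meanlog = log(8), reading_sdlog = 0.4,
                       miss_x = 0, miss_t = 0) {
  if (missing(seed)) stop("'seed' is mandatory")
  stopifnot(length(J) == S, all(J >= 1L), K >= 1L, N >= 1L)
  d <- 2L + S
  if (!isTRUE(all.equal(dim(Sigma), c(d, d))))
    stop("'Sigma' must be ", d, " x ", d,
         " over (psi, tau, eta_1, ..., eta_S)")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("'Sigma' must be positive-definite")
  if (any(abs(diag(Sigma)[-(1:2)] - 1) > 1e-8))
    stop("trait variances in 'Sigma' must equal one (identification)")
  pm <- pattern_mix[c("uniform_random", "endpoint_random",
                      "straight_line", "diagonal_line")]
  if (anyNA(pm) || any(pm < 0) || abs(sum(pm) - 1) > 1e-8)
    stop("'pattern_mix' must be a probability vector over the four patterns")
  if (any(c(sigma_C, sigma_A, reading_sdlog) <= 0))
    stop("scale parameters must be positive")
  if (any(c(miss_x, miss_t) < 0) || any(c(miss_x, miss_t) >= 1))
    stop("missingness rates must lie in [0, 1)")
  if (is.null(iota)) {
    iota <- rep(iota_for_rate(target_cier_rate, sqrt(Sigma[1, 1])), S)
  }
  stopifnot(length(iota) == S)
  cfg <- list(seed = as.integer(seed), N = as.integer(N), S = as.integer(S),
              J = as.integer(J), K = as.integer(K), Sigma = Sigma,
              items = items, v_range = v_range,
              b_center_range = b_center_range,
              iota = iota, gamma = gamma, beta_C = beta_C,
              sigma_C = sigma_C, sigma_A = sigma_A,
              pattern_mix = pm, pattern_per_person = pattern_per_person,
              diagonal_descending = diagonal_descending,
              reading_meanlog = reading_meanlog,
              reading_sdlog = reading_sdlog,
              miss_x = miss_x, miss_t = miss_t)
  class(cfg) <- "cier_sim_config"
  cfg
}

#' Paper-resembling person-parameter covariance matrix
#'
#' Covariance of (`psi`, `tau`, `eta_1`, ..., `eta_S`) with attentiveness
#' variance 1.98, speed variance 0.11, unit trait variances, and the
#' correlation pattern of the motivating empirical analysis
#' (psi--tau .05, psi--eta .24/.17, tau--eta -.14/-.06, eta_1--eta_2 .43;
#' traits beyond the second reuse the second trait's values).
#'
#' @param S number of traits/screens.
#' @return A `(2 + S) x (2 + S)` positive-definite covariance matrix.
#' @export
default_person_cov <- function(S = 2L) {
  d <- 2L + S
  R <- diag(d)
  r_psi_eta <- c(0.24, rep(0.17, max(0L, S - 1L)))
  r_tau_eta <- c(-0.14, rep(-0.06, max(0L, S - 1L)))
  R[1, 2] <- R[2, 1] <- 0.05
  for (s in seq_len(S)) {
    R[1, 2 + s] <- R[2 + s, 1] <- r_psi_eta[s]
    R[2, 2 + s] <- R[2 + s, 2] <- r_tau_eta[s]
  }
  if (S >= 2L) {
    for (s1 in 2:S) for (s2 in seq_len(s1 - 1L))
      R[2 + s1, 2 + s2] <- R[2 + s2, 2 + s1] <- 0.43
  }
  sds <- c(sqrt(1.98), sqrt(0.11), rep(1, S))
  diag(sds) %*% R %*% diag(sds)
}

# default time-intensity offsets: printed first/last two offsets per screen
# with linear interpolation in between; uniform draws for other designs
.default_beta_star <- function(J, screen) {
  if (screen == 1L && J == 7L)
    return(c(0.46, 0.68, 0.55, 0.41, 0.27, 0.13, 0.00))
  if (screen == 2L && J == 5L)
    return(c(0.04, 0.24, 0.38, 0.51, 0.29))
  round(runif(J, 0, 0.7), 2)
}

.generate_items <- function(cfg) {
  if (!is.null(cfg$items)) {
    it <- cfg$items
    need <- c("screen", "v", paste0("b", seq_len(cfg$K)), "beta_star")
    if (!all(need %in% names(it)))
      stop("'items' must have columns ", paste(need, collapse = ", "))
    if (any(it$v <= 0)) stop("discriminations must be positive")
    if (any(it$beta_star < 0)) stop("'beta_star' must be non-negative")
    it$item <- seq_len(nrow(it))
    return(it)
  }
  spread <- seq(-1.1, 1.1, length.out = cfg$K)
  rows <- lapply(seq_len(cfg$S), function(s) {
    J <- cfg$J[s]
    ctr <- runif(J, cfg$b_center_range[1], cfg$b_center_range[2])
    b <- t(vapply(ctr, function(ci) ci + spread, numeric(cfg$K)))
    df <- data.frame(screen = s, v = round(runif(J, cfg$v_range[1],
                                                 cfg$v_range[2]), 2))
    colnames(b) <- paste0("b", seq_len(cfg$K))
    cbind(df, round(b, 2), beta_star = .default_beta_star(J, s))
  })
  it <- do.call(rbind, rows)
  it$item <- seq_len(nrow(it))
  it
}

#' Draw person parameters from the multivariate normal population model
#'
#' @param n number of respondents.
#' @param Sigma covariance of (`psi`, `tau`, `eta_1`, ..., `eta_S`);
#'   means are zero.
#' @return An `n x (2 + S)` matrix with columns `psi`, `tau`, `eta1`, ...
#' @export
draw_persons <- function(n, Sigma) {
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("'Sigma' must be positive-definite")
  d <- ncol(Sigma)
  z <- matrix(rnorm(n * d), n, d)
  out <- z %*% chol(Sigma)
  colnames(out) <- c("psi", "tau",
                     if (d > 2L) paste0("eta", seq_len(d - 2L)))
  out
}

#' Simulate latent attentiveness indicators
#'
#' Bernoulli draws of the per person--screen attentiveness indicator with
#' success probability `logistic(psi - iota_s)`, independent across
#' screens given the parameters.
#'
#' @param psi attentiveness values (length `N`).
#' @param iota screen attentiveness difficulties (length `S`).
#' @return An `N x S` 0/1 matrix (`1` = attentive).
#' @export
simulate_attentiveness <- function(psi, iota) {
  N <- length(psi); S <- length(iota)
  p <- plogis(outer(psi, iota, `-`))
  matrix(rbinom(N * S, 1L, p), N, S)
}

#' Simulate one attentive person--screen
#'
#' Responses from the GPCM at the person's trait level, item RTs lognormal
#' around the attentive mean (distance--difficulty included) with residual
#' SD `sigma_A`.
#'
#' @param tau,eta person speed and trait level.
#' @param v,b,beta_star item parameters for the screen (`b` a `J x K`
#'   matrix).
#' @param gamma,beta_C,sigma_A global parameters.
#' @return List with integer `x` and numeric `t` of length `J`.
#' @export
simulate_attentive_screen <- function(tau, eta, v, b, beta_star,
                                      gamma, beta_C, sigma_A) {
  b <- rbind(b)
  J <- nrow(b)
  x <- integer(J); t <- numeric(J)
  for (j in seq_len(J)) {
    p <- gpcm_probs(eta, v[j], b[j, ])
    x[j] <- sample.int(length(p), 1L, prob = p) - 1L
    mu <- attentive_logrt_mean(eta, tau, v[j],
                               middle_step_difficulty(b[j, ]),
                               beta_star[j], gamma, beta_C)
    t[j] <- rlnorm(1L, mu, sigma_A)
  }
  list(x = x, t = t)
}

#' Simulate one C/IER person--screen
#'
#' Responses follow the requested pattern; RTs are iid lognormal with the
#' common C/IER parameters regardless of pattern.
#'
#' * `uniform_random`: iid uniform over `0..K`;
#' * `endpoint_random`: iid over the two extreme categories `{0, K}`;
#' * `straight_line`: one uniformly drawn category repeated;
#' * `diagonal_line`: uniformly drawn start, then +1 per item with
#'   wraparound modulo `K + 1` (descending optional).
#'
#' @param pattern one of the four pattern labels.
#' @param J number of items on the screen.
#' @param K highest category.
#' @param beta_C,sigma_C common C/IER lognormal parameters.
#' @param descending use a descending diagonal.
#' @return List with integer `x` and numeric `t` of length `J`.
#' @export
simulate_cier_screen <- function(pattern, J, K, beta_C, sigma_C,
                                 descending = FALSE) {
  x <- switch(pattern,
    uniform_random  = sample(0:K, J, replace = TRUE),
    endpoint_random = sample(c(0L, K), J, replace = TRUE),
    straight_line   = rep(sample(0:K, 1L), J),
    diagonal_line   = {
      start <- sample(0:K, 1L)
      step <- if (descending) -1L else 1L
      (start + step * (seq_len(J) - 1L)) %% (K + 1L)
    },
    stop("unknown C/IER pattern: ", pattern)
  )
  list(x = as.integer(x), t = rlnorm(J, beta_C, sigma_C))
}

#' Generate a fully synthetic C/IER dataset with ground truth
#'
#' Draws person parameters, latent attentiveness states, responses and
#' item-level RTs under the item-level data-generating model, per-screen
#' stem-reading times, and independent missingness, and returns the
#' long-format dataset together with the complete ground truth.
#'
#' @param cfg a [sim_config()] object.
#' @return An object of class `cier_sim`: list with
#' \describe{
#'   \item{data}{long data frame: `person`, `screen`, `item` (global id),
#'     `pos` (position on screen), `x`, `t` (`NA` when missing), `d_x`,
#'     `d_t` (1 = missing).}
#'   \item{reading}{per person--screen stem-reading time (seconds).}
#'   \item{truth}{per person--screen `delta` (1 = attentive) and the
#'     C/IER `pattern` (`NA` for attentive screens).}
#'   \item{persons}{true person parameters.}
#'   \item{items}{true item parameters (including the middle step
#'     difficulty `o`).}
#'   \item{config}{the generating configuration.}
#' }
#' @export
simulate_cier_data <- function(cfg) {
  stopifnot(inherits(cfg, "cier_sim_config"))
  set.seed(cfg$seed)
  items <- .generate_items(cfg)
  bmat <- as.matrix(items[, paste0("b", seq_len(cfg$K)), drop = FALSE])
  items$o <- apply(bmat, 1L, middle_step_difficulty)
  persons <- draw_persons(cfg$N, cfg$Sigma)
  delta <- simulate_attentiveness(persons[, "psi"], cfg$iota)

  pat_labels <- names(cfg$pattern_mix)
  person_pattern <- if (cfg$pattern_per_person)
    sample(pat_labels, cfg$N, replace = TRUE, prob = cfg$pattern_mix)

  n_rows <- cfg$N * sum(cfg$J)
  person <- integer(n_rows); screen <- integer(n_rows)
  item <- integer(n_rows); pos <- integer(n_rows)
  x <- integer(n_rows); t <- numeric(n_rows)
  pattern <- matrix(NA_character_, cfg$N, cfg$S)
  reading <- matrix(rlnorm(cfg$N * cfg$S, cfg$reading_meanlog,
                           cfg$reading_sdlog), cfg$N, cfg$S)
  row <- 0L
  for (i in seq_len(cfg$N)) {
    for (s in seq_len(cfg$S)) {
      idx <- which(items$screen == s)
      J <- length(idx)
      if (delta[i, s] == 1L) {
        sim <- simulate_attentive_screen(
          persons[i, "tau"], persons[i, paste0("eta", s)],
          items$v[idx], bmat[idx, , drop = FALSE], items$beta_star[idx],
          cfg$gamma, cfg$beta_C, cfg$sigma_A)
      } else {
        pat <- if (cfg$pattern_per_person) person_pattern[i] else
          sample(pat_labels, 1L, prob = cfg$pattern_mix)
        pattern[i, s] <- pat
        sim <- simulate_cier_screen(pat, J, cfg$K, cfg$beta_C, cfg$sigma_C,
                                    cfg$diagonal_descending)
      }
      rr <- row + seq_len(J)
      person[rr] <- i; screen[rr] <- s; item[rr] <- items$item[idx]
      pos[rr] <- seq_len(J); x[rr] <- sim$x; t[rr] <- sim$t
      row <- row + J
    }
  }
  d_x <- rbinom(n_rows, 1L, cfg$miss_x)
  d_t <- rbinom(n_rows, 1L, cfg$miss_t)
  x[d_x == 1L] <- NA_integer_
  t[d_t == 1L] <- NA_real_
  data <- data.frame(person = person, screen = screen, item = item,
                     pos = pos, x = x, t = t, d_x = d_x, d_t = d_t)
  truth <- data.frame(person = rep(seq_len(cfg$N), each = cfg$S),
                      screen = rep(seq_len(cfg$S), cfg$N),
                      delta = as.integer(t(delta)),
                      pattern = as.character(t(pattern)),
                      stringsAsFactors = FALSE)
  reading_df <- data.frame(person = rep(seq_len(cfg$N), each = cfg$S),
                           screen = rep(seq_len(cfg$S), cfg$N),
                           reading_time = as.numeric(t(reading)))
  out <- list(data = data, reading = reading_df, truth = truth,
              persons = as.data.frame(persons), items = items,
              config = cfg)
  class(out) <- "cier_sim"
  out
}

#' @export
print.cier_sim <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic C/IER dataset: ", cfg$N, " respondents, ", cfg$S,
      " screens, items per screen: ", paste(cfg$J, collapse = ", "),
      "\n  categories 0..", cfg$K, "; realized C/IER screen fraction: ",
      sprintf("%.3f", mean(x$truth$delta == 0L)), "\n", sep = "")
  invisible(x)
}
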