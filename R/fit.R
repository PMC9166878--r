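#' Prior settings for the C/IER mixture models
#'
#' Default priors: LKJ with shape 1 on the person-parameter correlation
#' matrix (uniform over positive-definite correlation matrices),
#' half-Cauchy(0, 5) on all standard deviations and on item
#' discriminations, Normal(0, 10) on step difficulties, time-intensity
#' offsets, the distance--difficulty coefficient and the common C/IER
#' mean, and a diffuse Dirichlet (all-ones) on the C/IER category
#' probabilities. The screen-level model additionally places a uniform
#' Dirichlet on the population attentiveness proportion and
#' half-Cauchy(0, 5) on the concentration of the per-person
#' attentiveness-probability prior.
#'
#' @param lkj_shape LKJ shape for the correlation matrix.
#' @param half_cauchy_scale scale of the half-Cauchy priors.
#' @param normal_sd SD of the diffuse normal priors.
#' @param dirichlet_kappa Dirichlet concentration(s) for kappa (scalar or
#'   length `K + 1`).
#' @return An object of class `cier_priors`.
#' @export
cier_priors <- function(lkj_shape = 1, half_cauchy_scale = 5,
                        normal_sd = 10, dirichlet_kappa = 1) {
  stopifnot(lkj_shape > 0, half_cauchy_scale > 0, normal_sd > 0,
            all(dirichlet_kappa > 0))
  out <- list(lkj_shape = lkj_shape,
              half_cauchy_scale = half_cauchy_scale,
              normal_sd = normal_sd, dirichlet_kappa = dirichlet_kappa)
  class(out) <- "cier_priors"
  out
}

#' MCMC settings
#'
#' Sampler configuration. `iterations` counts recorded iterations per
#' chain including warmup; the first `warmup` iterations (default half)
#' adapt the proposal scales and are discarded. Each iteration comprises
#' `thin` full update sweeps of the adaptive random-walk
#' Metropolis-within-Gibbs sampler, which compensates for the higher
#' autocorrelation of random-walk updates relative to gradient-based
#' samplers.
#'
#' @param chains number of chains (at least 2 for convergence checks).
#' @param iterations iterations per chain, warmup included.
#' @param warmup warmup iterations (adaptation phase).
#' @param thin update sweeps per recorded iteration.
#' @param seed integer RNG seed.
#' @param psrf_threshold convergence threshold for the potential scale
#'   reduction factor.
#' @return An object of class `cier_mcmc`.
#' @export
cier_mcmc <- function(chains = 4, iterations = 4000,
                      warmup = floor(iterations / 2), thin = 10, seed = 1,
                      psrf_threshold = 1.10) {
  stopifnot(chains >= 1, iterations >= 2, warmup >= 1,
            warmup < iterations, thin >= 1)
  out <- list(chains = as.integer(chains),
              iterations = as.integer(iterations),
              warmup = as.integer(warmup), thin = as.integer(thin),
              seed = as.integer(seed), psrf_threshold = psrf_threshold)
  class(out) <- "cier_mcmc"
  out
}

# long data -> wide matrices ordered by (screen, pos); returns list with
# x (N x J), t (N x J), item_screen (0-based), item table, person ids
.wide_data <- function(data) {
  need <- c("person", "screen", "item", "x", "t")
  if (!all(need %in% names(data)))
    stop("'data' must have columns ", paste(need, collapse = ", "))
  if (is.null(data$pos)) {
    key <- interaction(data$person, data$screen, drop = TRUE)
    data$pos <- stats::ave(rep(1L, nrow(data)), key, FUN = seq_along)
  }
  items <- unique(data[c("screen", "item", "pos")])
  items <- items[order(items$screen, items$pos), ]
  if (anyDuplicated(items$item)) stop("items assigned to multiple screens")
  persons <- sort(unique(data$person))
  N <- length(persons); J <- nrow(items)
  xm <- matrix(NA_integer_, N, J)
  tm <- matrix(NA_real_, N, J)
  pi_ <- match(data$person, persons)
  ji <- match(data$item, items$item)
  xm[cbind(pi_, ji)] <- as.integer(data$x)
  tm[cbind(pi_, ji)] <- data$t
  if (any(!is.na(tm) & tm <= 0)) stop("response times must be positive")
  list(x = xm, t = tm, item_screen = as.integer(items$screen) - 1L,
       items = items, persons = persons,
       S = length(unique(items$screen)),
       J_s = as.integer(table(items$screen)))
}

.init_chain <- function(variant, wd, K, chain_seed) {
  set.seed(chain_seed)
  J <- ncol(wd$x); S <- wd$S; N <- nrow(wd$x)
  lt <- log(wd$t[!is.na(wd$t)])
  if (length(lt) < 2L) lt <- c(log(2), log(4))  # no observed RTs: neutral start
  base <- list(
    sigma_A = max(0.2, 0.6 * sd(lt)) * exp(rnorm(1, 0, 0.1)),
    sigma_C = max(0.3, sd(lt)) * exp(rnorm(1, 0, 0.1)),
    gamma = rnorm(1, 0, 0.02),
    beta_C = median(lt) - 0.5 + rnorm(1, 0, 0.1),
    kappa = {
      k <- runif(K + 1, 0.8, 1.2); k / sum(k)
    },
    v = exp(rnorm(J, 0, 0.15)),
    b = t(vapply(seq_len(J),
                 function(j) seq(-1, 1, length.out = K) + rnorm(K, 0, 0.2),
                 numeric(K)))
  )
  if (K == 1L) base$b <- matrix(base$b, J, K)  # vapply drops dims for K=1
  if (variant == "item") {
    c(base, list(
      sigma_psi = exp(rnorm(1, 0.2, 0.1)),
      sigma_tau = exp(rnorm(1, -1, 0.1)),
      iota = runif(S, -3, -1.5),
      beta_star = runif(J, 0.1, 0.5),
      persons = matrix(rnorm(N * (2 + S), 0, 0.3), N, 2 + S),
      R = diag(2 + S)
    ))
  } else {
    c(base, list(
      sigma_tau = exp(rnorm(1, -1, 0.1)),
      beta_star_s = runif(S, 0.1, 0.5),
      pi = runif(N, 0.7, 0.95),
      pi_pop = runif(1, 0.8, 0.95),
      lambda = exp(rnorm(1, log(5), 0.2)),
      persons = matrix(rnorm(N * (1 + S), 0, 0.3), N, 1 + S),
      R = diag(1 + S)
    ))
  }
}

.param_names <- function(variant, N, S, J, K, J_s) {
  lab <- if (variant == "item") c("psi", "tau", paste0("eta", seq_len(S)))
         else c("tau", paste0("eta", seq_len(S)))
  d <- length(lab)
  rho <- character(0)
  for (p in seq_len(d - 1)) for (q in (p + 1):d)
    rho <- c(rho, paste0("cor_", lab[p], "_", lab[q]))
  bnames <- as.vector(t(outer(seq_len(J), seq_len(K),
                              function(j, k) paste0("b[", j, ",", k, "]"))))
  if (variant == "item") {
    c("sigma_psi", "sigma_tau", "sigma_A", "sigma_C", "gamma", "beta_C",
      paste0("iota[", seq_len(S), "]"), paste0("kappa[", 0:K, "]"), rho,
      paste0("v[", seq_len(J), "]"), paste0("beta_star[", seq_len(J), "]"),
      bnames,
      paste0("psi[", seq_len(N), "]"), paste0("tau[", seq_len(N), "]"),
      unlist(lapply(seq_len(S),
                    function(s) paste0("eta", s, "[", seq_len(N), "]"))))
  } else {
    c("sigma_tau", "sigma_A", "sigma_C", "gamma", "beta_C", "pi_pop",
      "lambda", paste0("kappa[", 0:K, "]"), rho,
      paste0("beta_star_s[", seq_len(S), "]"),
      paste0("v[", seq_len(J), "]"), bnames,
      paste0("tau[", seq_len(N), "]"),
      unlist(lapply(seq_len(S),
                    function(s) paste0("eta", s, "[", seq_len(N), "]"))),
      paste0("pi[", seq_len(N), "]"))
  }
}

#' Fit the response-time-based C/IER mixture model
#'
#' Bayesian estimation of the latent response mixture model for careless
#' and insufficient effort responding, in one of two variants:
#'
#' * `variant = "item"`: item-level RTs; the latent attentiveness
#'   indicator varies per person--screen and is governed by a Rasch model
#'   in attentiveness \eqn{\psi_i} and screen difficulty \eqn{\iota_s};
#'   person parameters \eqn{(\psi, \tau, \eta_1, \dots, \eta_S)} are
#'   multivariate normal with zero means and unit trait variances.
#' * `variant = "screen"`: aggregated timing data; a respondent-specific
#'   attentiveness probability \eqn{\pi_i} (constant across screens, with
#'   a hierarchical Dirichlet prior) mixes the full attentive and C/IER
#'   response vectors at the person level; \eqn{\psi} is dropped.
#'
#' The discrete attentiveness states are marginalized inside the sampler,
#' an adaptive random-walk Metropolis-within-Gibbs scheme; posterior
#' C/IER probabilities are recovered per retained draw from the component
#' responsibilities. RT trimming is not applied here; pass pre-trimmed
#' data (see [trim_rts()]).
#'
#' @param data long-format data frame (`person`, `screen`, `item`, `x`,
#'   `t`, optional `pos`, `d_x`, `d_t`) or a [simulate_cier_data()]
#'   object.
#' @param variant `"item"` or `"screen"`.
#' @param K highest response category; inferred from the data when `NULL`.
#' @param tbar for the screen variant: data frame (`person`, `screen`,
#'   `t_bar`) of mean seconds per item. When `NULL`, it is derived from
#'   the item-level data via `timing_measure`.
#' @param timing_measure aggregate feeding `t_bar` when `tbar` is `NULL`:
#'   `"mean_rt"` (mean of the item RTs), or `"tt"`, `"ttfrt"`, `"aat"`
#'   computed by [compute_timing_measures()] (these require `reading`).
#' @param reading per-screen stem-reading times (needed for `"tt"` and
#'   `"ttfrt"`); taken from a simulation object automatically.
#' @param priors a [cier_priors()] object.
#' @param mcmc a [cier_mcmc()] object.
#' @return An object of class `cier_fit` with components `draws` (list of
#'   per-chain matrices of retained draws), `summary` (structural
#'   parameters: posterior median, central 95% interval, PSRF),
#'   `psrf` (all parameters), `converged`, `p_cier` (posterior C/IER
#'   probabilities: `N x S` matrix for the item variant, length-`N`
#'   vector for the screen variant), and bookkeeping fields.
#' @seealso [cier_rate()], [classify_attentiveness()], [psrf()]
#' @export
fit_cier <- function(data, variant = c("item", "screen"), K = NULL,
                     tbar = NULL,
                     timing_measure = c("mean_rt", "tt", "ttfrt", "aat"),
                     reading = NULL,
                     priors = cier_priors(), mcmc = cier_mcmc()) {
  variant <- match.arg(variant)
  timing_measure <- match.arg(timing_measure)
  if (inherits(data, "cier_sim")) {
    if (is.null(reading)) reading <- data$reading
    data <- data$data
  }
  wd <- .wide_data(data)
  xmax <- suppressWarnings(max(wd$x, na.rm = TRUE))
  if (is.null(K)) K <- xmax
  K <- as.integer(K)
  if (K < 1L) stop("'K' must be at least 1")
  if (is.finite(xmax) && xmax > K)
    stop("responses exceed K = ", K,
         "; a common K across all items is required")
  N <- nrow(wd$x); S <- wd$S; J <- ncol(wd$x)
  if (variant == "item" && S < 2L)
    warning("fewer than 2 screens; attentiveness difficulties are weakly ",
            "identified")

  tb <- NULL
  if (variant == "screen") {
    if (is.null(tbar)) {
      if (timing_measure == "mean_rt") {
        tb <- matrix(NA_real_, N, S)
        for (s in seq_len(S)) {
          cols <- which(wd$item_screen == s - 1L)
          m <- rowMeans(wd$t[, cols, drop = FALSE], na.rm = TRUE)
          m[!is.finite(m)] <- NA_real_
          tb[, s] <- m
        }
      } else {
        if (is.null(reading))
          stop("'reading' times are required for timing_measure = '",
               timing_measure, "'")
        tm <- compute_timing_measures(data, reading)
        col <- switch(timing_measure, tt = "tt_per_item",
                      ttfrt = "ttfrt", aat = "aat")
        tb <- matrix(NA_real_, N, S)
        tb[cbind(match(tm$person, wd$persons), tm$screen)] <- tm[[col]]
      }
    } else {
      need <- c("person", "screen", "t_bar")
      if (!all(need %in% names(tbar)))
        stop("'tbar' must have columns ", paste(need, collapse = ", "))
      tb <- matrix(NA_real_, N, S)
      tb[cbind(match(tbar$person, wd$persons), tbar$screen)] <- tbar$t_bar
    }
    if (any(!is.na(tb) & tb <= 0)) stop("screen times must be positive")
  }

  pr <- list(lkj_shape = priors$lkj_shape,
             half_cauchy_scale = priors$half_cauchy_scale,
             normal_sd = priors$normal_sd,
             kappa_alpha = rep_len(priors$dirichlet_kappa, K + 1L))
  nm <- .param_names(variant, N, S, J, K, wd$J_s)

  draws <- vector("list", mcmc$chains)
  pd_acc <- NULL
  for (ch in seq_len(mcmc$chains)) {
    chain_seed <- (mcmc$seed + 1009L * ch) %% .Machine$integer.max
    init <- .init_chain(variant, wd, K, chain_seed)
    set.seed(chain_seed + 1L)
    res <- if (variant == "item") {
      mcmc_item_cpp(wd$x, wd$t, wd$item_screen, K, init, pr,
                    mcmc$iterations, mcmc$warmup, mcmc$thin)
    } else {
      mcmc_screen_cpp(wd$x, tb, wd$item_screen, K, init, pr,
                      mcmc$iterations, mcmc$warmup, mcmc$thin)
    }
    dm <- res$draws
    colnames(dm) <- nm
    draws[[ch]] <- dm
    pd <- if (variant == "item") res$pdelta0 else res$pcier
    pd_acc <- if (is.null(pd_acc)) pd else pd_acc + pd
  }
  p_cier <- pd_acc / mcmc$chains

  rhat <- if (mcmc$chains >= 2) {
    vapply(seq_along(nm), function(k) {
      psrf(lapply(draws, function(dm) dm[, k]))
    }, numeric(1))
  } else rep(NA_real_, length(nm))
  names(rhat) <- nm
  n_person <- N * (2L + S)   # person-level parameters in both variants
  n_struct <- length(nm) - n_person
  struct <- seq_len(n_struct)
  all_draws <- do.call(rbind, draws)
  summ <- data.frame(
    parameter = nm[struct],
    median = apply(all_draws[, struct, drop = FALSE], 2, median),
    q2.5 = apply(all_draws[, struct, drop = FALSE], 2, quantile,
                 probs = 0.025),
    q97.5 = apply(all_draws[, struct, drop = FALSE], 2, quantile,
                  probs = 0.975),
    psrf = rhat[struct], row.names = NULL)

  out <- list(variant = variant, draws = draws, summary = summ,
              psrf = rhat,
              converged = if (mcmc$chains >= 2)
                all(rhat < mcmc$psrf_threshold, na.rm = TRUE) else NA,
              p_cier = p_cier, N = N, S = S, J = J, K = K,
              J_s = wd$J_s, persons = wd$persons, items = wd$items,
              priors = priors, mcmc = mcmc, call = match.call())
  class(out) <- "cier_fit"
  if (isFALSE(out$converged))
    warning("PSRF >= ", mcmc$psrf_threshold, " for ",
            sum(rhat >= mcmc$psrf_threshold, na.rm = TRUE),
            " parameter(s); treat results with caution")
  out
}

#' Potential scale reduction factor (split Gelman--Rubin diagnostic)
#'
#' Split-\eqn{\hat R}: each chain is split in half, the between- and
#' within-chain variances of the resulting sequences are combined into
#' the variance-ratio statistic. Values near 1 indicate convergence;
#' below 1.10 is conventionally taken as satisfactory.
#'
#' @param chains list of equal-length numeric vectors (one per chain), or
#'   a matrix with one column per chain.
#' @return The PSRF (scalar, `>= 1` up to floating point; 1 for chains
#'   with zero total variance).
#' @export
psrf <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  if (length(chains) < 2L) stop("at least 2 chains are required")
  n0 <- unique(lengths(chains))
  if (length(n0) != 1L) stop("chains must have equal lengths")
  half <- n0 %/% 2L
  if (half < 2L) stop("chains too short to split")
  sp <- unlist(lapply(chains, function(x)
    list(x[seq_len(half)], x[(n0 - half + 1L):n0])), recursive = FALSE)
  m <- length(sp); n <- half
  means <- vapply(sp, mean, numeric(1))
  vars <- vapply(sp, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (!is.finite(W) || W <= .Machine$double.eps)
    return(if (is.finite(B) && B > .Machine$double.eps) Inf else 1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior C/IER classification
#'
#' Posterior probabilities of the C/IER state: for the item-level variant
#' one probability per person--screen (posterior mean over draws of the
#' C/IER component responsibility); for the screen-level variant one
#' probability per person.
#'
#' @param fit a [fit_cier()] result.
#' @return Data frame with `person`, `screen` (item variant only) and
#'   `p_cier`.
#' @export
classify_attentiveness <- function(fit) {
  stopifnot(inherits(fit, "cier_fit"))
  if (fit$variant == "item") {
    data.frame(person = rep(fit$persons, each = fit$S),
               screen = rep(seq_len(fit$S), fit$N),
               p_cier = as.vector(t(fit$p_cier)))
  } else {
    data.frame(person = fit$persons, p_cier = as.numeric(fit$p_cier))
  }
}

#' Estimated C/IER rates
#'
#' For the item-level variant: per-screen rates (mean posterior C/IER
#' probability over respondents) and the overall response-level rate
#' (screen rates weighted by the number of items per screen). For the
#' screen-level variant: the population respondent-level rate. By default
#' rates are posterior means of the C/IER probabilities; `threshold`
#' switches to hard-classification counts (probability above the
#' threshold).
#'
#' @param fit a [fit_cier()] result.
#' @param threshold optional hard-classification cut in `(0, 1)`.
#' @return List with `overall` (percent) and, for the item variant,
#'   `per_screen` (percent per screen).
#' @export
cier_rate <- function(fit, threshold = NULL) {
  stopifnot(inherits(fit, "cier_fit"))
  p <- fit$p_cier
  if (!is.null(threshold)) p <- (p > threshold) * 1
  if (fit$variant == "item") {
    per_screen <- colMeans(p)
    overall <- sum(fit$J_s * per_screen) / sum(fit$J_s)
    list(overall = 100 * overall, per_screen = 100 * per_screen)
  } else {
    list(overall = 100 * mean(p))
  }
}

#' @export
print.cier_fit <- function(x, ...) {
  cat("C/IER latent response mixture model (",
      if (x$variant == "item") "item-level RTs" else "screen-level timing",
      ")\n", sep = "")
  cat("  ", x$N, " respondents, ", x$S, " screens, items per screen: ",
      paste(x$J_s, collapse = ", "), ", categories 0..", x$K, "\n", sep = "")
  cat("  ", x$mcmc$chains, " chains x ", x$mcmc$iterations,
      " iterations (warmup ", x$mcmc$warmup, ", thin ", x$mcmc$thin,
      ")\n", sep = "")
  if (any(!is.na(x$psrf)))
    cat("  max PSRF: ", sprintf("%.3f", max(x$psrf, na.rm = TRUE)),
        if (isTRUE(x$converged)) "  (converged)" else "", "\n", sep = "")
  r <- cier_rate(x)
  cat("  estimated C/IER rate: ", sprintf("%.2f%%", r$overall), "\n",
      sep = "")
  bc <- coef(x)["beta_C"]
  g <- coef(x)["gamma"]
  cat("  C/IER median RT: ", sprintf("%.2f", report_seconds(bc)),
      " s; distance-difficulty factor: ",
      sprintf("%.2f", report_distance_factor(g)), " per unit\n", sep = "")
  invisible(x)
}

#' @export
coef.cier_fit <- function(object, ...) {
  setNames(object$summary$median, object$summary$parameter)
}

#' @export
summary.cier_fit <- function(object, ...) {
  out <- list(variant = object$variant, table = object$summary,
              rate = cier_rate(object), converged = object$converged,
              max_psrf = if (any(!is.na(object$psrf)))
                max(object$psrf, na.rm = TRUE) else NA_real_)
  class(out) <- "summary.cier_fit"
  out
}

#' @export
print.summary.cier_fit <- function(x, ...) {
  cat("Posterior summaries (structural parameters):\n")
  tab <- x$table
  tab[2:5] <- lapply(tab[2:5], round, digits = 3)
  print(tab, row.names = FALSE)
  cat("\nOverall C/IER rate: ", sprintf("%.2f%%", x$rate$overall),
      "; max PSRF ", sprintf("%.3f", x$max_psrf), "\n", sep = "")
  invisible(x)
}

#' Trace plots for a fitted C/IER model
#'
#' @param x a [fit_cier()] result.
#' @param pars parameter names to plot (default: first structural
#'   parameters).
#' @param ... passed to [graphics::matplot()].
#' @importFrom graphics matplot par
#' @export
plot.cier_fit <- function(x, pars = NULL, ...) {
  if (is.null(pars)) pars <- utils::head(x$summary$parameter, 6L)
  old <- par(mfrow = c(ceiling(length(pars) / 2), min(2, length(pars))),
             mar = c(3, 3, 2, 1))
  on.exit(par(old))
  for (p in pars) {
    tr <- sapply(x$draws, function(dm) dm[, p])
    matplot(tr, type = "l", lty = 1, main = p, xlab = "", ylab = "", ...)
  }
  invisible(x)
}

#' Data log-likelihood of the item-level model at fixed parameters
#'
#' Sum over all person--screen mixture terms (attentive vs. C/IER
#' components), conditional on the supplied person parameters; the
#' multivariate normal population density of the person parameters is not
#' included. Mainly useful for verification and for composing the
#' log-posterior externally.
#'
#' @param data long-format data (or a simulation object).
#' @param pars named list of parameter values: `sigma_psi`, `sigma_tau`,
#'   `sigma_A`, `sigma_C`, `gamma`, `beta_C`, `iota`, `kappa`, `v`,
#'   `beta_star`, `b` (J x K matrix), `persons` (N x (2+S) matrix), `R`.
#' @param K highest category (inferred when `NULL`).
#' @return Scalar log-likelihood.
#' @export
cier_item_loglik <- function(data, pars, K = NULL) {
  if (inherits(data, "cier_sim")) data <- data$data
  wd <- .wide_data(data)
  if (is.null(K)) K <- max(wd$x, na.rm = TRUE)
  pr <- list(lkj_shape = 1, half_cauchy_scale = 5, normal_sd = 10,
             kappa_alpha = rep(1, K + 1))
  item_loglik_cpp(wd$x, wd$t, wd$item_screen, as.integer(K), pars, pr)
}

#' Data log-likelihood of the screen-level model at fixed parameters
#'
#' Person-level mixture log-likelihood of the screen-level model,
#' conditional on person parameters and attentiveness probabilities.
#'
#' @param data long-format response data (or a simulation object).
#' @param tbar data frame `person`, `screen`, `t_bar`.
#' @param pars named list: `sigma_tau`, `sigma_A`, `sigma_C`, `gamma`,
#'   `beta_C`, `pi_pop`, `lambda`, `kappa`, `v`, `b`, `beta_star_s`,
#'   `pi`, `persons` (N x (1+S)), `R`.
#' @param K highest category (inferred when `NULL`).
#' @return Scalar log-likelihood.
#' @export
cier_screen_loglik <- function(data, tbar, pars, K = NULL) {
  if (inherits(data, "cier_sim")) data <- data$data
  wd <- .wide_data(data)
  if (is.null(K)) K <- max(wd$x, na.rm = TRUE)
  N <- nrow(wd$x); S <- wd$S
  tb <- matrix(NA_real_, N, S)
  tb[cbind(match(tbar$person, wd$persons), tbar$screen)] <- tbar$t_bar
  pr <- list(lkj_shape = 1, half_cauchy_scale = 5, normal_sd = 10,
             kappa_alpha = rep(1, K + 1))
  screen_loglik_cpp(wd$x, tb, wd$item_screen, as.integer(K), pars, pr)
}
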