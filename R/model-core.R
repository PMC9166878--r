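#' @useDynLib carelessRT, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dlnorm dnorm plogis qlogis rnorm runif rbinom rlnorm
#'   median cor cov sd var quantile mahalanobis qchisq uniroot
#'   complete.cases setNames coef
NULL

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Category probabilities of the generalized partial credit model
#'
#' Probability of each response category \eqn{k = 0, \dots, K} for an
#' attentive response, given trait level `eta`, discrimination `v` and step
#' difficulties `b`. The numerator for category \eqn{k} is
#' \eqn{\exp\{\sum_{l=0}^{k} (v\eta - b_l)\}} with the \eqn{l = 0} summand
#' fixed at zero, normalized over all categories.
#'
#' @param eta trait level (finite scalar).
#' @param v item discrimination, positive.
#' @param b numeric vector of step difficulties \eqn{b_1, \dots, b_K};
#'   `length(b)` determines the number of categories (`K + 1`).
#' @return Numeric vector of `length(b) + 1` probabilities summing to one.
#' @examples
#' gpcm_probs(0, v = 1, b = 0)           # symmetric two-category case
#' gpcm_probs(0.7, v = 1.3, b = c(-1, 0.2, 1.1))
#' @export
gpcm_probs <- function(eta, v, b) {
  stopifnot(length(eta) == 1L, length(v) == 1L)
  if (!is.finite(eta)) stop("'eta' must be finite")
  if (!is.finite(v) || v <= 0) stop("'v' must be a positive finite scalar")
  if (length(b) < 1L || any(!is.finite(b))) stop("'b' must be a non-empty finite vector")
  cum <- c(0, cumsum(v * eta - b))   # cumulative logits, category 0 pinned at 0
  p <- exp(cum - .logsumexp(cum))
  p / sum(p)
}

#' Middle step difficulty of an item
#'
#' The step difficulty against which the distance--difficulty effect is
#' measured: the middle element of the step-difficulty vector (for four
#' response categories, the second of three steps). For an even number of
#' steps the mean of the two central elements is used, which reduces to the
#' single middle element when the number of steps is odd.
#'
#' @param b numeric vector of step difficulties (non-empty).
#' @return The middle step difficulty (scalar).
#' @examples
#' middle_step_difficulty(c(-1, 0.3, 2))  # 0.3
#' @export
middle_step_difficulty <- function(b) {
  if (length(b) < 1L) stop("'b' must contain at least one step difficulty")
  n <- length(b)
  if (n %% 2L == 1L) b[(n + 1L) %/% 2L] else mean(b[c(n %/% 2L, n %/% 2L + 1L)])
}

#' Mean of attentive log response times
#'
#' Expected log RT under attentive responding:
#' \eqn{(\beta_C + \beta^*) - \tau - \gamma |v\eta - o|}, where the item's
#' time intensity is the common C/IER mean plus a non-negative offset, and
#' the distance--difficulty term shortens RTs for items poorly targeted to
#' the respondent's trait level.
#'
#' @param eta trait level.
#' @param tau respondent speed.
#' @param v item discrimination.
#' @param o item middle step difficulty (see [middle_step_difficulty()]).
#' @param beta_star non-negative time-intensity offset (log-seconds).
#' @param gamma distance--difficulty coefficient.
#' @param beta_C common mean of C/IER log RTs (log-seconds).
#' @return Mean of the normal distribution of log RT (SD `sigma_A`).
#' @export
attentive_logrt_mean <- function(eta, tau, v, o, beta_star, gamma, beta_C) {
  if (any(beta_star < 0)) stop("'beta_star' must be non-negative")
  (beta_C + beta_star) - tau - gamma * abs(v * eta - o)
}

#' Log density of a C/IER response time
#'
#' Lognormal log density with log-mean `beta_C` and log-SD `sigma_C`,
#' shared by all C/IER responses regardless of person, item, or pattern.
#'
#' @param t response time in seconds, positive.
#' @param beta_C common mean of C/IER log RTs.
#' @param sigma_C common SD of C/IER log RTs, positive.
#' @return Log density (includes the `1/t` Jacobian).
#' @export
cier_logrt_logdensity <- function(t, beta_C, sigma_C) {
  if (any(t <= 0)) stop("'t' must be positive")
  if (sigma_C <= 0) stop("'sigma_C' must be positive")
  dlnorm(t, meanlog = beta_C, sdlog = sigma_C, log = TRUE)
}

#' Probability of attentive responding on a screen
#'
#' Rasch model for the latent attentiveness indicator:
#' \eqn{P(\Delta = 1) = \mathrm{logistic}(\psi - \iota)}, where \eqn{\psi}
#' is the respondent's attentiveness and \eqn{\iota} the screen's
#' attentiveness difficulty. Numerically stable for large \eqn{|\psi-\iota|}.
#'
#' @param psi respondent attentiveness.
#' @param iota screen attentiveness difficulty.
#' @return Probability in `[0, 1]`.
#' @export
attentiveness_prob <- function(psi, iota) {
  plogis(psi - iota)
}

# log P(Delta=1) and log P(Delta=0), stable in both tails
.log_p1 <- function(psi, iota) plogis(psi - iota, log.p = TRUE)
.log_p0 <- function(psi, iota) plogis(-(psi - iota), log.p = TRUE)

#' Screen aggregates of item parameters
#'
#' Aggregation used by the screen-level model: geometric mean of the member
#' items' discriminations and arithmetic mean of their middle step
#' difficulties.
#'
#' @param v positive discriminations of the items on the screen.
#' @param o their middle step difficulties.
#' @return List with components `v_dot` and `o_dot`.
#' @examples
#' screen_aggregates(c(1, 4), c(0, 2))  # v_dot = 2, o_dot = 1
#' @export
screen_aggregates <- function(v, o) {
  if (any(v <= 0)) stop("all discriminations must be positive")
  if (length(v) != length(o)) stop("'v' and 'o' must have equal length")
  list(v_dot = exp(mean(log(v))), o_dot = mean(o))
}

#' Mean of attentive log screen times
#'
#' Screen-level analogue of [attentive_logrt_mean()] for the mean time per
#' item on a screen: \eqn{(\beta_C + \beta^*_s) - \tau -
#' \gamma |v_{\cdot s}\eta_s - o_{\cdot s}|}, with the screen-aggregated
#' discrimination and middle step difficulty.
#'
#' @param eta trait level for the screen's trait.
#' @param tau respondent speed.
#' @param v_dot geometric mean of member discriminations.
#' @param o_dot arithmetic mean of member middle step difficulties.
#' @param beta_star_s non-negative screen-level time-intensity offset.
#' @param gamma distance--difficulty coefficient.
#' @param beta_C common mean of C/IER log RTs.
#' @return Mean of the normal distribution of the log mean screen time.
#' @export
screenlevel_logrt_mean <- function(eta, tau, v_dot, o_dot, beta_star_s,
                                   gamma, beta_C) {
  if (any(beta_star_s < 0)) stop("'beta_star_s' must be non-negative")
  (beta_C + beta_star_s) - tau - gamma * abs(v_dot * eta - o_dot)
}

#' Mixture log-likelihood of one person--screen (item-level model)
#'
#' Log of the two-component mixture for one respondent on one screen,
#' conditional on the person parameters: attentive component
#' (GPCM response probabilities and lognormal RTs with the
#' distance--difficulty mean) weighted by \eqn{P(\Delta = 1)}, plus the
#' C/IER component (content-free category probabilities `kappa` and the
#' common lognormal RT distribution) weighted by \eqn{P(\Delta = 0)}.
#' Missing responses or RTs (`NA`) contribute a factor of one; a fully
#' missing screen yields zero.
#'
#' @param x integer responses in `0..K` for the screen's items (`NA` =
#'   missing), in item order.
#' @param t item RTs in seconds (`NA` = missing), aligned with `x`.
#' @param psi,tau respondent attentiveness and speed.
#' @param eta respondent trait level for this screen's trait.
#' @param iota screen attentiveness difficulty.
#' @param v,beta_star per-item discriminations and time-intensity offsets.
#' @param b matrix of step difficulties, one row per item (`J x K`).
#' @param gamma,beta_C,sigma_A,sigma_C global RT parameters.
#' @param kappa C/IER category probabilities (length `K + 1`, sums to one).
#' @return Log mixture likelihood (scalar), computed via log-sum-exp.
#' @export
screen_mixture_loglik <- function(x, t, psi, tau, eta, iota,
                                  v, b, beta_star,
                                  gamma, beta_C, sigma_A, sigma_C, kappa) {
  b <- rbind(b)
  J <- nrow(b)
  stopifnot(length(x) == J, length(t) == J, length(v) == J,
            length(beta_star) == J)
  if (abs(sum(kappa) - 1) > 1e-8 || any(kappa < 0))
    stop("'kappa' must be a probability vector")
  if (any(x[!is.na(x)] < 0L | x[!is.na(x)] > ncol(b)))
    stop("responses outside 0..K")
  la <- 0; lc <- 0
  for (j in seq_len(J)) {
    o_j <- middle_step_difficulty(b[j, ])
    if (!is.na(x[j])) {
      la <- la + log(gpcm_probs(eta, v[j], b[j, ])[x[j] + 1L])
      lc <- lc + log(kappa[x[j] + 1L])
    }
    if (!is.na(t[j])) {
      mu <- attentive_logrt_mean(eta, tau, v[j], o_j, beta_star[j],
                                 gamma, beta_C)
      la <- la + dlnorm(t[j], mu, sigma_A, log = TRUE)
      lc <- lc + cier_logrt_logdensity(t[j], beta_C, sigma_C)
    }
  }
  .logsumexp(c(.log_p1(psi, iota) + la, .log_p0(psi, iota) + lc))
}

#' Mixture log-likelihood of one person (screen-level model)
#'
#' Log likelihood contribution of one respondent under the screen-level
#' model: the two-component mixture is at the person level, mixing (with
#' the respondent-specific attentiveness probability `pi_i`) the product
#' over all screens of attentive factors against the product over all
#' screens of C/IER factors. Attentive screen factors combine GPCM response
#' probabilities with the lognormal density of the mean time per item;
#' C/IER factors combine `kappa` probabilities with the common lognormal.
#'
#' @param pi_i respondent attentiveness probability in `[0, 1]`.
#' @param tau respondent speed.
#' @param eta trait vector, one entry per screen.
#' @param x list of response vectors, one per screen (`NA` = missing).
#' @param tbar mean time per item for each screen (`NA` = missing).
#' @param v,b,beta_star_s item discriminations, step-difficulty matrices
#'   (lists/vectors indexed per screen) and screen time-intensity offsets:
#'   `v` and `b` are lists with one element per screen (`v[[s]]` a vector,
#'   `b[[s]]` a `J_s x K` matrix).
#' @param gamma,beta_C,sigma_A,sigma_C global RT parameters.
#' @param kappa C/IER category probabilities.
#' @return Log mixture likelihood for the person (scalar).
#' @export
screenlevel_mixture_loglik <- function(pi_i, tau, eta, x, tbar,
                                       v, b, beta_star_s,
                                       gamma, beta_C, sigma_A, sigma_C,
                                       kappa) {
  if (!is.finite(pi_i) || pi_i < 0 || pi_i > 1)
    stop("'pi_i' must lie in [0, 1]")
  S <- length(x)
  stopifnot(length(eta) == S, length(tbar) == S, length(v) == S,
            length(b) == S, length(beta_star_s) == S)
  la <- 0; lc <- 0
  for (s in seq_len(S)) {
    bs <- rbind(b[[s]])
    agg <- screen_aggregates(v[[s]], apply(bs, 1L, middle_step_difficulty))
    xs <- x[[s]]
    for (j in seq_along(xs)) {
      if (!is.na(xs[j])) {
        la <- la + log(gpcm_probs(eta[s], v[[s]][j], bs[j, ])[xs[j] + 1L])
        lc <- lc + log(kappa[xs[j] + 1L])
      }
    }
    if (!is.na(tbar[s])) {
      mu <- screenlevel_logrt_mean(eta[s], tau, agg$v_dot, agg$o_dot,
                                   beta_star_s[s], gamma, beta_C)
      la <- la + dlnorm(tbar[s], mu, sigma_A, log = TRUE)
      lc <- lc + cier_logrt_logdensity(tbar[s], beta_C, sigma_C)
    }
  }
  if (pi_i == 1) return(la)
  if (pi_i == 0) return(lc)
  .logsumexp(c(log(pi_i) + la, log1p(-pi_i) + lc))
}

#' Marginal C/IER rate implied by a screen's attentiveness difficulty
#'
#' Population-level probability of a C/IER state on a screen with
#' attentiveness difficulty `iota` when attentiveness \eqn{\psi} is normal
#' with mean zero and SD `sigma_psi`:
#' \eqn{\int (1 - \mathrm{logistic}(\psi - \iota))\,
#' \mathcal{N}(\psi \mid 0, \sigma_\psi^2)\, d\psi},
#' evaluated by Gauss--Hermite quadrature.
#'
#' @param iota screen attentiveness difficulty.
#' @param sigma_psi SD of attentiveness, positive.
#' @param nodes number of quadrature nodes (default 64).
#' @return Probability in `(0, 1)`.
#' @export
marginal_cier_rate <- function(iota, sigma_psi, nodes = 64L) {
  if (sigma_psi <= 0) stop("'sigma_psi' must be positive")
  gh <- pracma::gaussHermite(nodes)
  psi <- sqrt(2) * sigma_psi * gh$x
  sum(gh$w * plogis(-(psi - iota))) / sqrt(pi)
}

#' Attentiveness difficulty matching a target marginal C/IER rate
#'
#' Inverts [marginal_cier_rate()] in `iota` for a given attentiveness SD.
#'
#' @param rate target marginal C/IER rate in `(0, 1)`.
#' @param sigma_psi SD of attentiveness.
#' @return The `iota` whose marginal C/IER rate equals `rate`.
#' @export
iota_for_rate <- function(rate, sigma_psi) {
  if (rate <= 0 || rate >= 1) stop("'rate' must lie in (0, 1)")
  uniroot(function(i) marginal_cier_rate(i, sigma_psi) - rate,
          lower = -50, upper = 50, tol = 1e-10)$root
}
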