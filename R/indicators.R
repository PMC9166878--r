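#' Long string index
#'
#' Length of the longest run of identical consecutive responses in
#' administration order. Missing entries break runs; an empty vector
#' yields zero.
#'
#' @param x vector of responses (any atomic type; `NA` breaks runs).
#' @return Integer run length.
#' @examples
#' long_string(c(1, 1, 1, 2, 2))  # 3
#' @export
long_string <- function(x) {
  if (length(x) == 0L) return(0L)
  obs <- !is.na(x)
  if (!any(obs)) return(0L)
  grp <- cumsum(!obs)          # NA positions split the vector
  runs <- unlist(lapply(split(x[obs], grp[obs]), function(v) rle(v)$lengths),
                 use.names = FALSE)
  if (length(runs) == 0L) 0L else max(runs)
}

#' Even--odd consistency index
#'
#' Within-person consistency of responses: for each scale, the mean of the
#' odd-positioned and the mean of the even-positioned items are computed;
#' the index is the correlation between the vectors of odd-half and
#' even-half scale scores across scales. High values indicate internally
#' consistent (presumably attentive) response patterns. The index is
#' undefined (returned as `NA`) when either half-score vector has zero
#' variance across scales; fewer than two scales yield `NA` with a
#' warning.
#'
#' @param X responses: a numeric matrix (respondents in rows, items in
#'   columns, administration order within scale) or a single person's
#'   vector.
#' @param scales vector assigning each column/item to a scale.
#' @return Numeric vector of per-person indices in `[-1, 1]` (or `NA`).
#' @export
even_odd <- function(X, scales) {
  X <- rbind(X)
  if (ncol(X) != length(scales))
    stop("'scales' must assign every item column to a scale")
  ids <- unique(scales)
  if (length(ids) < 2L) {
    warning("even-odd index requires at least two scales; returning NA")
    return(rep(NA_real_, nrow(X)))
  }
  half_means <- function(xi) {
    vapply(ids, function(s) {
      v <- xi[scales == s]
      pos <- seq_along(v)
      c(mean(v[pos %% 2L == 1L], na.rm = TRUE),
        mean(v[pos %% 2L == 0L], na.rm = TRUE))
    }, numeric(2L))
  }
  unname(apply(X, 1L, function(xi) {
    hm <- half_means(xi)
    if (anyNA(hm) || sd(hm[1L, ]) == 0 || sd(hm[2L, ]) == 0)
      return(NA_real_)
    cor(hm[1L, ], hm[2L, ])
  }))
}

#' Mahalanobis outlier screening
#'
#' Squared Mahalanobis distances of response vectors from the sample mean
#' using the sample covariance (`n - 1` denominator), with flags for
#' distances exceeding a chi-square quantile with `df` degrees of freedom
#' (the large-sample approximation for multivariate outliers). Rows with
#' missing entries are excluded listwise and reported.
#'
#' @param X numeric response matrix (respondents in rows).
#' @param quantile chi-square quantile for the cutoff (e.g. `.99`
#'   conservative, `.95` liberal).
#' @param df degrees of freedom; defaults to the number of items.
#' @return List with `d2` (squared distances, `NA` for incomplete rows),
#'   `flag` (logical, `FALSE` for incomplete rows), `cutoff`, `df`,
#'   `n_used`, and `n_excluded` (listwise removals).
#' @export
mahalanobis_flags <- function(X, quantile = 0.99, df = ncol(X)) {
  X <- as.matrix(X)
  if (quantile <= 0 || quantile >= 1) stop("'quantile' must lie in (0, 1)")
  cc <- complete.cases(X)
  if (sum(cc) <= ncol(X))
    stop("too few complete rows to estimate the covariance")
  S <- cov(X[cc, , drop = FALSE])
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("sample covariance is singular; consider dropping constant items ",
         "or using a regularized covariance estimate"))
  ctr <- colMeans(X[cc, , drop = FALSE])
  d2 <- rep(NA_real_, nrow(X))
  d2[cc] <- mahalanobis(X[cc, , drop = FALSE], center = ctr, cov = S)
  cutoff <- qchisq(quantile, df)
  flag <- !is.na(d2) & d2 > cutoff
  list(d2 = d2, flag = flag, cutoff = cutoff, df = df,
       n_used = sum(cc), n_excluded = sum(!cc))
}

#' Multiple-hurdle screening configuration
#'
#' Threshold settings for the sequential indicator-based screening
#' (RT hurdle, long string hurdle, Mahalanobis hurdle). The two presets
#' mirror common practice: conservative (mean time per item below 1 s; a
#' constant run over all investigated items; 99th chi-square percentile)
#' and liberal (2 s; per-scale run thresholds such as 5 of 7 and 4 of 5;
#' 95th percentile).
#'
#' @param preset `"conservative"` or `"liberal"`.
#' @param rt_threshold RT hurdle threshold in seconds (flag strictly
#'   below); overrides the preset.
#' @param long_string_rule either `list(type = "total")` (run must span
#'   all items) or `list(type = "per_scale", min_run = c(...))` with one
#'   minimum run length per scale; `min_run = NULL` defaults to
#'   `ceiling(0.7 * J_s)` per scale (5 of 7, 4 of 5).
#' @param mahalanobis_quantile chi-square quantile for the outlier hurdle.
#' @return An object of class `hurdle_config`.
#' @export
hurdle_config <- function(preset = c("conservative", "liberal"),
                          rt_threshold = NULL, long_string_rule = NULL,
                          mahalanobis_quantile = NULL) {
  preset <- match.arg(preset)
  cfg <- if (preset == "conservative") {
    list(rt_threshold = 1, long_string_rule = list(type = "total"),
         mahalanobis_quantile = 0.99)
  } else {
    list(rt_threshold = 2,
         long_string_rule = list(type = "per_scale", min_run = NULL),
         mahalanobis_quantile = 0.95)
  }
  if (!is.null(rt_threshold)) cfg$rt_threshold <- rt_threshold
  if (!is.null(long_string_rule)) cfg$long_string_rule <- long_string_rule
  if (!is.null(mahalanobis_quantile))
    cfg$mahalanobis_quantile <- mahalanobis_quantile
  if (cfg$rt_threshold <= 0) stop("'rt_threshold' must be positive")
  if (cfg$mahalanobis_quantile <= 0 || cfg$mahalanobis_quantile >= 1)
    stop("'mahalanobis_quantile' must lie in (0, 1)")
  cfg$preset <- preset
  class(cfg) <- "hurdle_config"
  cfg
}

#' Sequential multiple-hurdle C/IER screening
#'
#' Applies the three indicator hurdles in order -- RT threshold, long
#' string, Mahalanobis distance -- removing respondents flagged at each
#' hurdle before the next is computed (the Mahalanobis covariance is
#' re-estimated on the survivors, since later indicators depend on who has
#' already been filtered out). Every flagged respondent is attributed to
#' exactly one hurdle.
#'
#' @param X wide response matrix (respondents in rows, items in columns in
#'   administration order).
#' @param scales scale/screen assignment of the columns.
#' @param rt per-person RT measure in seconds fed to the RT hurdle
#'   (typically AAT); `NA` values are not flagged at the RT hurdle.
#' @param cfg a [hurdle_config()].
#' @return List with `flags` (data frame: `person`, `flagged`, `hurdle`),
#'   `counts` (named per-hurdle counts), and `cfg`.
#' @export
multiple_hurdle <- function(X, scales, rt, cfg = hurdle_config()) {
  X <- as.matrix(X)
  stopifnot(inherits(cfg, "hurdle_config"), length(rt) == nrow(X),
            length(scales) == ncol(X))
  N <- nrow(X)
  hurdle <- rep(NA_character_, N)

  flag_rt <- !is.na(rt) & rt < cfg$rt_threshold
  hurdle[flag_rt] <- "rt"

  alive <- is.na(hurdle)
  rule <- cfg$long_string_rule
  flag_ls <- rep(FALSE, N)
  if (identical(rule$type, "total")) {
    flag_ls[alive] <- apply(X[alive, , drop = FALSE], 1L, long_string) ==
      ncol(X)
  } else if (identical(rule$type, "per_scale")) {
    ids <- unique(scales)
    min_run <- rule$min_run
    if (is.null(min_run))
      min_run <- vapply(ids, function(s) ceiling(0.7 * sum(scales == s)),
                        numeric(1))
    stopifnot(length(min_run) == length(ids))
    per_scale <- sapply(seq_along(ids), function(k) {
      apply(X[alive, scales == ids[k], drop = FALSE], 1L, long_string) >=
        min_run[k]
    })
    flag_ls[alive] <- apply(rbind(per_scale), 1L, any)
  } else stop("unknown long string rule type: ", rule$type)
  hurdle[flag_ls] <- "long_string"

  alive <- is.na(hurdle)
  flag_md <- rep(FALSE, N)
  if (sum(alive) > ncol(X) + 1L) {
    md <- mahalanobis_flags(X[alive, , drop = FALSE],
                            quantile = cfg$mahalanobis_quantile,
                            df = ncol(X))
    flag_md[alive] <- md$flag
  } else warning("too few survivors for the Mahalanobis hurdle; skipped")
  hurdle[flag_md] <- "mahalanobis"

  flags <- data.frame(person = seq_len(N), flagged = !is.na(hurdle),
                      hurdle = hurdle, stringsAsFactors = FALSE)
  counts <- c(rt = sum(hurdle == "rt", na.rm = TRUE),
              long_string = sum(hurdle == "long_string", na.rm = TRUE),
              mahalanobis = sum(hurdle == "mahalanobis", na.rm = TRUE))
  list(flags = flags, counts = counts, cfg = cfg)
}
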