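#' Trim aberrantly large response times
#'
#' Sets values exceeding a threshold to missing and reports how many were
#' excluded. The default threshold of 90 seconds mirrors the rule of
#' removing item-level RTs in the extreme upper tail before model fitting.
#'
#' @param values numeric vector of RTs in seconds (may contain `NA`).
#' @param threshold exclusion threshold in seconds (values strictly above
#'   are excluded).
#' @return List with `values` (trimmed vector), `n_excluded`, and
#'   `fraction_excluded` (relative to non-missing input values).
#' @examples
#' trim_rts(c(2.5, 91, 3))
#' @export
trim_rts <- function(values, threshold = 90) {
  if (threshold <= 0) stop("'threshold' must be positive")
  obs <- !is.na(values)
  drop <- obs & values > threshold
  values[drop] <- NA_real_
  list(values = values, n_excluded = sum(drop),
       fraction_excluded = if (any(obs)) sum(drop) / sum(obs) else 0)
}

#' Screen-level timing measures from item-level data
#'
#' Computes, per person--screen, the four RT measures used as inputs to
#' the screen-level model and the RT hurdle:
#' total time on screen `TT` (stem-reading time plus all item RTs), time
#' to first response `FRT` (stem-reading time plus the first item's RT),
#' `tt_per_item = TT / J`, `ttfrt = (TT - FRT) / (J - 1)`, and `aat`, the
#' mean of the item RTs excluding the first answered item (mirroring that
#' reconstructed RTs are unavailable for the first item). On complete data
#' `ttfrt` and `aat` coincide; both are undefined for single-item screens.
#'
#' Trimming is applied to item RTs before aggregation and to the computed
#' `aat` and `ttfrt` values, but never to `TT`.
#'
#' @param data long-format data frame with columns `person`, `screen`,
#'   `pos` (presentation order on screen) and `t` (item RT seconds, `NA`
#'   missing); a [simulate_cier_data()] result may be passed directly.
#' @param reading data frame with `person`, `screen`, `reading_time`
#'   (seconds); taken from the simulation object when `data` is one.
#' @param trim trimming threshold in seconds (`Inf` to disable).
#' @return Data frame with one row per person--screen: `person`, `screen`,
#'   `J`, `tt`, `frt`, `tt_per_item`, `ttfrt`, `aat`, and logical
#'   `trimmed_any` marking units where item RTs were excluded. Exclusion
#'   counts are attached as attribute `"exclusions"`.
#' @export
compute_timing_measures <- function(data, reading = NULL, trim = Inf) {
  if (inherits(data, "cier_sim")) {
    reading <- data$reading
    data <- data$data
  }
  if (is.null(reading)) stop("per-screen reading times are required")
  need <- c("person", "screen", "pos", "t")
  if (!all(need %in% names(data)))
    stop("'data' must have columns ", paste(need, collapse = ", "))
  tr_items <- trim_rts(data$t, threshold = trim)
  t_trim <- tr_items$values
  key <- interaction(data$person, data$screen, drop = TRUE)
  ord <- order(data$person, data$screen, data$pos)
  sp <- split(ord, key[ord])
  one <- function(rows) {
    i <- data$person[rows[1L]]; s <- data$screen[rows[1L]]
    J <- length(rows)
    t_raw <- data$t[rows]; t_tr <- t_trim[rows]
    r <- reading$reading_time[reading$person == i & reading$screen == s]
    if (length(r) != 1L) stop("missing reading time for person ", i,
                              ", screen ", s)
    tt <- r + sum(t_raw, na.rm = TRUE)          # TT is never trimmed
    frt <- if (is.na(t_raw[1L])) NA_real_ else r + t_raw[1L]
    ttfrt <- if (J > 1L && !is.na(frt)) (tt - frt) / (J - 1L) else NA_real_
    aat <- if (J > 1L) {
      later <- t_tr[-1L]
      if (all(is.na(later))) NA_real_ else mean(later, na.rm = TRUE)
    } else NA_real_
    c(person = i, screen = s, J = J, tt = tt, frt = frt,
      tt_per_item = tt / J, ttfrt = ttfrt, aat = aat,
      trimmed_any = as.numeric(any(!is.na(t_raw) & is.na(t_tr))))
  }
  out <- as.data.frame(do.call(rbind, lapply(sp, one)), row.names = FALSE)
  if (any(out$J == 1L))
    warning("single-item screens present: ttfrt and aat are undefined there")
  tr_aat <- trim_rts(out$aat, threshold = trim)
  tr_ttfrt <- trim_rts(out$ttfrt, threshold = trim)
  out$aat <- tr_aat$values
  out$ttfrt <- tr_ttfrt$values
  out$trimmed_any <- out$trimmed_any > 0
  attr(out, "exclusions") <- c(item_rts = tr_items$n_excluded,
                               aat = tr_aat$n_excluded,
                               ttfrt = tr_ttfrt$n_excluded)
  out[order(out$person, out$screen), ]
}
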