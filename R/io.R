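#' Read a long-format response dataset from CSV
#'
#' Reads and validates the canonical on-disk format: one row per
#' person--item with columns `person`, `screen`, `item`, `x` (response in
#' `0..K`), `t` (RT seconds), and optional `pos`, `d_x`, `d_t`
#' missingness indicators (derived from `NA` entries when absent).
#'
#' @param path path to a CSV file.
#' @param K highest response category; when given, out-of-range responses
#'   are rejected with their row numbers.
#' @param one_based set to `TRUE` for survey exports coded `1..K+1`;
#'   responses are shifted down to the internal `0..K` coding.
#' @return Validated long-format data frame.
#' @export
read_long_csv <- function(path, K = NULL, one_based = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("person", "screen", "item", "x", "t")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (one_based) df$x <- df$x - 1L
  if (is.null(df$pos)) {
    key <- interaction(df$person, df$screen, drop = TRUE)
    df$pos <- stats::ave(rep(1L, nrow(df)), key, FUN = seq_along)
  }
  if (is.null(df$d_x)) df$d_x <- as.integer(is.na(df$x))
  if (is.null(df$d_t)) df$d_t <- as.integer(is.na(df$t))
  bad_t <- which(!is.na(df$t) & df$t <= 0)
  if (length(bad_t))
    stop("non-positive RTs in rows: ",
         paste(utils::head(bad_t, 10L), collapse = ", "))
  obs <- !is.na(df$x)
  bad <- which(obs & (df$x < 0L | (if (!is.null(K)) df$x > K else FALSE) |
                        df$x != floor(df$x)))
  if (length(bad))
    stop("responses outside 0..", if (is.null(K)) "K" else K,
         " in rows: ", paste(utils::head(bad, 10L), collapse = ", "))
  df[c("person", "screen", "item", "pos", "x", "t", "d_x", "d_t")]
}

#' Write a long-format response dataset to CSV
#'
#' @param data long-format data frame (or a [simulate_cier_data()] object,
#'   whose `data` element is written).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(data, path) {
  if (inherits(data, "cier_sim")) data <- data$data
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert wide response data to the long format
#'
#' Convenience converter for wide files (one row per respondent, one
#' column per item).
#'
#' @param X wide response matrix; rows are respondents.
#' @param screen_of_item screen id per column, in administration order.
#' @param t optional matrix of item RTs with the same shape.
#' @return Long-format data frame as used by [fit_cier()].
#' @export
wide_to_long <- function(X, screen_of_item, t = NULL) {
  X <- as.matrix(X)
  J <- ncol(X)
  stopifnot(length(screen_of_item) == J)
  if (!is.null(t)) stopifnot(all(dim(t) == dim(X)))
  pos <- stats::ave(rep(1L, J), screen_of_item, FUN = seq_along)
  data.frame(
    person = rep(seq_len(nrow(X)), each = J),
    screen = rep(screen_of_item, nrow(X)),
    item = rep(seq_len(J), nrow(X)),
    pos = rep(pos, nrow(X)),
    x = as.integer(t(X)),
    t = if (is.null(t)) NA_real_ else as.numeric(t(t)),
    d_x = as.integer(is.na(as.integer(t(X)))),
    d_t = if (is.null(t)) 1L else as.integer(is.na(as.numeric(t(t))))
  )
}

#' Convert a log-scale time parameter to seconds
#'
#' Reporting helper: `exp()` of a log-second parameter such as the common
#' C/IER mean `beta_C`, rounded to report precision (2 decimals). E.g. a
#' common mean of 0.74 corresponds to 2.10 seconds.
#'
#' @param beta_like parameter on the log-seconds scale.
#' @return Seconds, rounded to 2 decimals.
#' @examples
#' report_seconds(0.74)  # 2.10
#' @export
report_seconds <- function(beta_like) {
  if (any(!is.finite(beta_like))) stop("input must be finite")
  round(exp(beta_like), 2)
}

#' Multiplicative RT factor per unit of distance
#'
#' Reporting helper for the distance--difficulty coefficient: attentive
#' RTs change by the factor `exp(-gamma)` per unit increase of the
#' absolute weighted distance between trait level and middle step
#' difficulty (e.g. `gamma = 0.04` gives 0.96).
#'
#' @param gamma distance--difficulty coefficient.
#' @return Factor, rounded to 2 decimals.
#' @examples
#' report_distance_factor(0.04)  # 0.96
#' @export
report_distance_factor <- function(gamma) {
  if (any(!is.finite(gamma))) stop("input must be finite")
  round(exp(-gamma), 2)
}

#' Agreement table between two C/IER classifications
#'
#' Cross-tabulates two per-person flag vectors (e.g. conservative vs.
#' liberal multiple hurdle, or hurdle vs. model-based classification) and,
#' when model-based attentiveness summaries are supplied, reports the
#' median attentiveness per cell.
#'
#' @param flags_a,flags_b logical vectors over the same respondents
#'   (`TRUE` = flagged as C/IER).
#' @param attentiveness optional numeric per-person attentiveness summary
#'   (e.g. posterior median `psi` or attentiveness probability).
#' @param labels length-2 character vector naming the two methods.
#' @return Object of class `cier_agreement`: list with `counts` (2 x 2
#'   table), `median_attentiveness` (2 x 2 or `NULL`), `n`.
#' @export
build_agreement_table <- function(flags_a, flags_b, attentiveness = NULL,
                                  labels = c("method A", "method B")) {
  if (length(flags_a) != length(flags_b))
    stop("flag vectors must cover the same respondents")
  if (!is.null(attentiveness) &&
      length(attentiveness) != length(flags_a))
    stop("'attentiveness' must cover the same respondents")
  fa <- factor(flags_a, levels = c(FALSE, TRUE),
               labels = c("attentive", "careless"))
  fb <- factor(flags_b, levels = c(FALSE, TRUE),
               labels = c("attentive", "careless"))
  counts <- table(fa, fb, dnn = labels)
  med <- NULL
  if (!is.null(attentiveness)) {
    med <- matrix(NA_real_, 2, 2,
                  dimnames = unname(dimnames(counts)))
    for (i in 1:2) for (j in 1:2) {
      sel <- as.integer(fa) == i & as.integer(fb) == j
      if (any(sel)) med[i, j] <- median(attentiveness[sel], na.rm = TRUE)
    }
  }
  out <- list(counts = counts, median_attentiveness = med,
              n = length(flags_a), labels = labels)
  class(out) <- "cier_agreement"
  out
}

#' @export
print.cier_agreement <- function(x, ...) {
  cat("Classification agreement (n = ", x$n, ")\n\n", sep = "")
  print(x$counts)
  if (!is.null(x$median_attentiveness)) {
    cat("\nMedian attentiveness per cell:\n")
    print(round(x$median_attentiveness, 3))
  }
  invisible(x)
}

#' Write a simulated dataset to a directory
#'
#' Writes the long-format data, ground truth, reading times, true item and
#' person parameters as CSV files, plus a JSON sidecar with the generating
#' configuration (including the seed), sufficient to regenerate the dataset
#' bit for bit.
#'
#' @param sim a [simulate_cier_data()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cier_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "cier_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$data, file.path(dir, "data.csv"), row.names = FALSE)
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$reading, file.path(dir, "reading.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$items, file.path(dir, "items.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$persons, file.path(dir, "persons.csv"),
                   row.names = FALSE)
  cfg <- unclass(sim$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(dir)
}
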