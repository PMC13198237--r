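# Shared numeric helpers: rank AUC, stratified resampling, significance tiers.

#' Area under the ROC curve by rank statistic
#'
#' Computes the probability that a randomly chosen positive scores higher
#' than a randomly chosen negative (ties count 1/2), i.e. the Mann-Whitney
#' form of the AUC. Used throughout the cross-validation machinery.
#'
#' @param scores numeric vector of classifier scores (higher = more positive).
#' @param positive logical vector, `TRUE` for the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, positive) {
  stopifnot(length(scores) == length(positive), is.logical(positive))
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Significance stars for the reporting tiers
#'
#' Maps p-values onto the conventional tiers: `ns` (p >= 0.05), `*` (< 0.05),
#' `**` (< 0.01), `***` (< 0.001), `****` (< 0.0001).
#'
#' @param p numeric vector of p-values.
#' @return character vector of star labels.
#' @export
significance_stars <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ifelse(p[ok] < 1e-4, "****",
             ifelse(p[ok] < 1e-3, "***",
             ifelse(p[ok] < 1e-2, "**",
             ifelse(p[ok] < 5e-2, "*", "ns"))))
  out
}

# Class-stratified train/holdout partition of indices. Guarantees at least
# one unit of every class on both sides (floor/ceil allocation).
stratified_split_idx <- function(classes, ratio) {
  stopifnot(ratio > 0, ratio < 1)
  train <- integer(0)
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    n <- length(idx)
    if (n < 2L) {
      stop("class '", cl, "' has fewer than 2 units; cannot split", call. = FALSE)
    }
    n_tr <- floor(ratio * n)
    n_tr <- max(1L, min(n - 1L, n_tr))
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

# Class-stratified k-fold assignment; returns integer fold id per unit.
stratified_fold_ids <- function(classes, k) {
  fold <- integer(length(classes))
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    if (length(idx) < k) {
      stop("class '", cl, "' has fewer units (", length(idx),
           ") than folds (", k, ")", call. = FALSE)
    }
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

# Derived per-stream seed: one run seed, documented integer offsets per
# random stream, kept within 32-bit integer range.
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((as.numeric(seed) + as.numeric(stream) * 10007) %% 2147483647)
}

# Trapezoid integral on an arbitrary (increasing) grid.
trapz <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2L)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
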