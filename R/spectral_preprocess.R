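# Spectral preprocessing: truncation, EMSC, silent-region excision, min-max
# normalization and replicate averaging. All operations return a new
# SpectrumSet with the corresponding state flag set; flags never reset.

#' Truncate spectra to a wavenumber window
#'
#' Retains wavenumbers in `[lo, hi]` inclusive. The defaults keep the
#' biologically informative 1000-3500 cm^-1 window.
#'
#' @param spectra a [spectrum_set()].
#' @param lo,hi window bounds (cm^-1).
#' @return truncated [spectrum_set()].
#' @export
truncate_spectra <- function(spectra, lo = 1000, hi = 3500) {
  stopifnot(inherits(spectra, "SpectrumSet"))
  if (lo > hi) stop("lo must not exceed hi", call. = FALSE)
  keep <- spectra$wavenumbers >= lo & spectra$wavenumbers <= hi
  if (!any(keep)) {
    stop("truncation to [", lo, ", ", hi, "] leaves no wavenumbers",
         call. = FALSE)
  }
  out <- spectrum_set(spectra$wavenumbers[keep],
                      spectra$intensities[, keep, drop = FALSE],
                      spectra$replicates, spectra$state)
  advance_state(out, "truncated")
}

#' Extended multiplicative signal correction
#'
#' Fits every spectrum `s` by least squares as
#' `s ~ b * r + sum_k c_k * w^k` where `r` is the reference spectrum and `w`
#' is the wavenumber grid rescaled to `[-1, 1]`, then returns the corrected
#' spectrum `(s - sum_k c_k w^k) / b`. This removes multiplicative scatter
#' and a polynomial baseline in one step; any spectrum inside the model span
#' is restored to the reference exactly.
#'
#' @param spectra a [spectrum_set()].
#' @param reference `"mean"` (mean of the supplied spectra) or a numeric
#'   reference spectrum on the same grid.
#' @param poly_order baseline polynomial order (default 2).
#' @return list with `spectra` (corrected [spectrum_set()]) and
#'   `coefficients` (data.frame of `b` and `c0..c<poly_order>` per replicate).
#' @export
emsc_correct <- function(spectra, reference = "mean", poly_order = 2) {
  stopifnot(inherits(spectra, "SpectrumSet"), poly_order >= 0)
  ref <- if (identical(reference, "mean")) {
    colMeans(spectra$intensities)
  } else {
    as.numeric(reference)
  }
  if (length(ref) != length(spectra$wavenumbers)) {
    stop("reference must lie on the same wavenumber grid", call. = FALSE)
  }
  fit <- emsc_fit(spectra$intensities, spectra$wavenumbers, ref, poly_order,
                  replicate_ids = paste0(spectra$replicates$sample_id, "/",
                                         spectra$replicates$well_id, "/",
                                         spectra$replicates$scan_id))
  out <- spectrum_set(spectra$wavenumbers, fit$corrected, spectra$replicates,
                      spectra$state)
  list(spectra = advance_state(out, "emsc_corrected"),
       coefficients = fit$coefficients)
}

# Core EMSC least-squares; shared by emsc_correct() and the ensemble's
# frozen-reference transform.
emsc_fit <- function(X, wn, ref, poly_order, replicate_ids = NULL) {
  wtil <- 2 * (wn - min(wn)) / (max(wn) - min(wn)) - 1
  D <- cbind(ref, outer(wtil, 0:poly_order, `^`))
  colnames(D) <- c("b", paste0("c", 0:poly_order))
  coefs <- t(qr.coef(qr(D), t(X)))     # one least-squares fit per spectrum
  b <- coefs[, 1]
  bad <- which(abs(b) < 1e-8)
  if (length(bad)) {
    nm <- if (is.null(replicate_ids)) as.character(bad) else replicate_ids[bad]
    stop("degenerate EMSC fit (|b| < 1e-8) for replicate(s): ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  baseline <- coefs[, -1, drop = FALSE] %*% t(D[, -1, drop = FALSE])
  corrected <- (X - baseline) / b
  list(corrected = corrected,
       coefficients = as.data.frame(coefs))
}

#' Remove the spectroscopically silent region
#'
#' Drops wavenumbers in the silent band (default `[1801, 2799]` cm^-1,
#' inclusive at both ends), where no biologically relevant molecular bonds
#' absorb, leaving the fingerprint and high-wavenumber blocks.
#'
#' @param spectra a [spectrum_set()].
#' @param band inclusive bounds of the silent region (cm^-1).
#' @return a [spectrum_set()] without the silent band.
#' @export
remove_silent <- function(spectra, band = c(1801, 2799)) {
  stopifnot(inherits(spectra, "SpectrumSet"), length(band) == 2L,
            band[1] <= band[2])
  keep <- spectra$wavenumbers < band[1] | spectra$wavenumbers > band[2]
  if (!any(keep)) stop("silent-region removal leaves no wavenumbers",
                       call. = FALSE)
  out <- spectrum_set(spectra$wavenumbers[keep],
                      spectra$intensities[, keep, drop = FALSE],
                      spectra$replicates, spectra$state)
  advance_state(out, "silent_removed")
}

#' Min-max normalize spectra to [0, 1]
#'
#' Per spectrum: `(x - min) / (max - min)`. Constant spectra are degenerate
#' and rejected.
#'
#' @param spectra a [spectrum_set()].
#' @return normalized [spectrum_set()].
#' @export
minmax_normalize <- function(spectra) {
  stopifnot(inherits(spectra, "SpectrumSet"))
  rng <- apply(spectra$intensities, 1L, range)
  span <- rng[2, ] - rng[1, ]
  if (any(span == 0)) {
    stop("constant spectrum cannot be min-max normalized (row ",
         paste(which(span == 0), collapse = ", "), ")", call. = FALSE)
  }
  out <- spectrum_set(spectra$wavenumbers,
                      (spectra$intensities - rng[1, ]) / span,
                      spectra$replicates, spectra$state)
  advance_state(out, "minmax_normalized")
}

#' Average replicate spectra
#'
#' Arithmetic mean of replicate spectra at the well level (across scans of a
#' well) or the sample level (across all replicates of a sample).
#'
#' @param spectra a [spectrum_set()].
#' @param level `"well"` or `"sample"`.
#' @return averaged [spectrum_set()] (one row per well or sample).
#' @export
average_replicates <- function(spectra, level = c("sample", "well")) {
  stopifnot(inherits(spectra, "SpectrumSet"))
  level <- match.arg(level)
  key <- if (level == "well") spectra$replicates$well_id else
    spectra$replicates$sample_id
  groups <- unique(key)
  idx <- split(seq_along(key), key)[groups]
  avg <- t(vapply(idx, function(i)
    colMeans(spectra$intensities[i, , drop = FALSE]),
    numeric(length(spectra$wavenumbers))))
  meta <- spectra$replicates[vapply(idx, `[`, integer(1), 1L), , drop = FALSE]
  meta$scan_id <- "avg"
  if (level == "sample") meta$well_id <- "avg"
  rownames(meta) <- NULL
  out <- spectrum_set(spectra$wavenumbers, avg, meta, spectra$state)
  advance_state(out, "averaged")
}

#' Recursive feature elimination over wavenumbers
#'
#' Backward elimination removing one wavenumber per step, scored by the
#' absolute standardized (univariate) linear-model coefficient of class on
#' intensity, until `k` wavenumbers remain. Deterministic given the data.
#'
#' @param spectra a preprocessed [spectrum_set()].
#' @param labels class label per replicate row, or a named vector keyed by
#'   sample id; exactly two classes.
#' @param k number of wavenumbers to retain.
#' @return data.frame of the `k` selected wavenumbers with their scores,
#'   strongest first.
#' @export
rfe_peaks <- function(spectra, labels = NULL, k = 10) {
  stopifnot(inherits(spectra, "SpectrumSet"))
  y <- resolve_replicate_labels(spectra, labels)
  if (length(unique(y)) != 2L) stop("exactly two classes required", call. = FALSE)
  if (k > length(spectra$wavenumbers)) {
    stop("k exceeds the number of wavenumbers", call. = FALSE)
  }
  yn <- as.numeric(factor(y)) - 1
  X <- spectra$intensities
  # standardized univariate coefficient = cor(x_j, y); elimination one per
  # step by lowest |score| reduces to ranking since scores are marginal
  score <- suppressWarnings(abs(apply(X, 2L, function(x) {
    if (sd(x) == 0) 0 else cor(x, yn)
  })))
  remaining <- seq_along(score)
  while (length(remaining) > k) {
    drop_i <- remaining[which.min(score[remaining])]
    remaining <- setdiff(remaining, drop_i)
  }
  sel <- remaining[order(score[remaining], decreasing = TRUE)]
  data.frame(wavenumber = spectra$wavenumbers[sel], score = score[sel])
}

# Map per-sample labels to replicate rows; accept per-row labels as is.
resolve_replicate_labels <- function(spectra, labels) {
  if (is.null(labels)) {
    if (!"class" %in% names(spectra$replicates) ||
        anyNA(spectra$replicates$class)) {
      stop("no labels supplied and replicate metadata has no class",
           call. = FALSE)
    }
    return(as.character(spectra$replicates$class))
  }
  if (!is.null(names(labels))) {
    miss <- setdiff(unique(spectra$replicates$sample_id), names(labels))
    if (length(miss)) {
      stop("labels missing for samples: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    return(as.character(labels[spectra$replicates$sample_id]))
  }
  stopifnot(length(labels) == nrow(spectra$intensities))
  as.character(labels)
}
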