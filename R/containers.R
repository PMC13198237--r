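# Core data containers shared across the workflow. All are lightweight S3
# lists with validating constructors; matrices keep feature/sample or
# replicate/wavenumber orientation fixed so downstream code never guesses.

#' Construct a feature table
#'
#' A features-by-samples abundance matrix with sample metadata (cohort, class,
#' timepoint) and per-feature annotations (modality, unique peptide counts,
#' contaminant class). Protein abundances are log2-scale; miRNA expression is
#' log2(count + 1). Missing values encode non-detection.
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param samples data.frame with columns `sample_id`, `cohort`, `class` and
#'   optionally `timepoint`/`patient`; one row per column of `values`.
#' @param features data.frame with columns `feature_id`, `modality` and
#'   optionally `unique_peptides`, `contaminant_class`; one row per row of
#'   `values`.
#' @return object of class `FeatureTable`.
#' @export
feature_table <- function(values, samples, features) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values))
  if (nrow(values) > 0L && is.null(rownames(values))) {
    stop("values must carry feature rownames", call. = FALSE)
  }
  if (ncol(values) > 0L && is.null(colnames(values))) {
    stop("values must carry sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate feature ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    stop("duplicate sample ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  samples <- as.data.frame(samples)
  features <- as.data.frame(features)
  req_s <- c("sample_id", "cohort", "class")
  if (!all(req_s %in% names(samples))) {
    stop("sample metadata must contain columns: ",
         paste(setdiff(req_s, names(samples)), collapse = ", "), call. = FALSE)
  }
  if (!all(c("feature_id", "modality") %in% names(features))) {
    stop("feature metadata must contain feature_id and modality", call. = FALSE)
  }
  if (ncol(values) > 0L &&
      !identical(as.character(samples$sample_id), colnames(values))) {
    stop("sample metadata rows must match value columns in order", call. = FALSE)
  }
  if (nrow(values) > 0L &&
      !identical(as.character(features$feature_id), rownames(values))) {
    stop("feature metadata rows must match value rows in order", call. = FALSE)
  }
  stopifnot(nrow(samples) == ncol(values), nrow(features) == nrow(values))
  if (anyNA(samples$class) || anyNA(samples$cohort)) {
    stop("sample metadata incomplete: class/cohort must be non-missing", call. = FALSE)
  }
  if (is.null(samples$timepoint)) samples$timepoint <- NA_character_
  structure(list(values = values, samples = samples, features = features),
            class = "FeatureTable")
}

#' @export
print.FeatureTable <- function(x, ...) {
  cat("<FeatureTable> ", nrow(x$values), " features x ", ncol(x$values),
      " samples\n", sep = "")
  cat("  modalities: ", paste(unique(x$features$modality), collapse = ", "),
      "; cohorts: ", paste(unique(x$samples$cohort), collapse = ", "), "\n",
      sep = "")
  cat("  missing: ", sum(is.na(x$values)), " cells\n", sep = "")
  invisible(x)
}

#' @export
dim.FeatureTable <- function(x) dim(x$values)

#' Subset a feature table
#'
#' Row/column subset preserving metadata alignment.
#'
#' @param t a [feature_table()].
#' @param features row indices (or `NULL` for all).
#' @param samples column indices (or `NULL` for all).
#' @return a [feature_table()].
#' @export
subset_feature_table <- function(t, features = NULL, samples = NULL) {
  stopifnot(inherits(t, "FeatureTable"))
  fi <- if (is.null(features)) seq_len(nrow(t$values)) else features
  si <- if (is.null(samples)) seq_len(ncol(t$values)) else samples
  feature_table(t$values[fi, si, drop = FALSE],
                t$samples[si, , drop = FALSE],
                t$features[fi, , drop = FALSE])
}

#' Construct a replicate spectrum set
#'
#' Rows of `intensities` are individual replicate spectra; full lineage
#' (sample, well, scan) is mandatory so cross-validation can split at the
#' sample level. Preprocessing state flags are monotone: an operation may
#' set them but never unset them.
#'
#' @param wavenumbers strictly monotone numeric grid (cm^-1).
#' @param intensities numeric matrix, replicates x wavenumbers.
#' @param replicates data.frame with columns `sample_id`, `well_id`,
#'   `scan_id` and optionally `class`, `timepoint`; one row per spectrum.
#' @param state named logical vector of preprocessing flags.
#' @return object of class `SpectrumSet`.
#' @export
spectrum_set <- function(wavenumbers, intensities, replicates,
                         state = NULL) {
  intensities <- as.matrix(intensities)
  wavenumbers <- as.numeric(wavenumbers)
  d <- diff(wavenumbers)
  if (length(wavenumbers) < 2L || !(all(d > 0) || all(d < 0))) {
    stop("wavenumbers must be a strictly monotone grid", call. = FALSE)
  }
  stopifnot(ncol(intensities) == length(wavenumbers))
  replicates <- as.data.frame(replicates)
  req <- c("sample_id", "well_id", "scan_id")
  if (!all(req %in% names(replicates)) ||
      anyNA(replicates[, req])) {
    stop("replicate lineage (sample_id, well_id, scan_id) must be complete",
         call. = FALSE)
  }
  stopifnot(nrow(replicates) == nrow(intensities))
  flags <- c(truncated = FALSE, emsc_corrected = FALSE, silent_removed = FALSE,
             minmax_normalized = FALSE, averaged = FALSE)
  if (!is.null(state)) flags[names(state)] <- state
  structure(list(wavenumbers = wavenumbers, intensities = intensities,
                 replicates = replicates, state = flags),
            class = "SpectrumSet")
}

#' @export
print.SpectrumSet <- function(x, ...) {
  cat("<SpectrumSet> ", nrow(x$intensities), " spectra x ",
      length(x$wavenumbers), " wavenumbers [",
      min(x$wavenumbers), ", ", max(x$wavenumbers), "] cm-1\n", sep = "")
  cat("  samples: ", length(unique(x$replicates$sample_id)),
      "; state: ", paste(names(x$state)[x$state], collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# Internal: carry state forward, never backwards.
advance_state <- function(spectra, flag) {
  spectra$state[flag] <- TRUE
  spectra
}

#' Construct a particle size distribution
#'
#' A binned nanoparticle-tracking-style concentration density: particles per
#' mL per nm on a strictly increasing size grid.
#'
#' @param bin_centers strictly increasing bin centers (nm).
#' @param density nonnegative concentration density (particles/mL/nm).
#' @param sample_id sample identifier.
#' @param class group label (e.g. "case"/"control").
#' @return object of class `SizeDistribution`.
#' @export
size_distribution <- function(bin_centers, density, sample_id = NA_character_,
                              class = NA_character_) {
  bin_centers <- as.numeric(bin_centers)
  density <- as.numeric(density)
  stopifnot(length(bin_centers) == length(density), length(bin_centers) >= 2L)
  if (any(diff(bin_centers) <= 0)) {
    stop("bin_centers must be strictly increasing", call. = FALSE)
  }
  if (any(density < 0)) stop("density must be nonnegative", call. = FALSE)
  structure(list(bin_centers = bin_centers, density = density,
                 sample_id = sample_id, class = class),
            class = "SizeDistribution")
}

#' @export
print.SizeDistribution <- function(x, ...) {
  cat("<SizeDistribution> sample ", x$sample_id, " (", x$class, "): ",
      length(x$bin_centers), " bins over [", min(x$bin_centers), ", ",
      max(x$bin_centers), "] nm\n", sep = "")
  invisible(x)
}
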