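# Plain-text interchange for every core container. Omics tables are CSV with
# features in rows and samples in columns, feature annotations as leading
# columns, and sample metadata in a sidecar CSV; spectra are long-format CSV.
# Missing values are written as "NA". Every writer's output is re-readable
# by the matching reader.

sample_sidecar_path <- function(path) sub("(\\.[^.]*)?$", ".samples.csv", path)

#' Write a feature table to CSV
#'
#' Writes the abundance matrix with feature annotations
#' (feature_id, modality, unique_peptides, contaminant_class) as leading
#' columns to `path`, and sample metadata to the sidecar
#' `<path stem>.samples.csv`.
#'
#' @param t a [feature_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(t, path) {
  stopifnot(inherits(t, "FeatureTable"))
  ann_cols <- intersect(c("feature_id", "modality", "unique_peptides",
                          "contaminant_class"), names(t$features))
  df <- cbind(t$features[, ann_cols, drop = FALSE],
              as.data.frame(t$values, check.names = FALSE))
  write.csv(df, path, row.names = FALSE, na = "NA")
  write.csv(t$samples, sample_sidecar_path(path), row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Inverse of [write_feature_table()]. Duplicate feature or sample ids and
#' missing metadata columns are schema errors naming the offenders.
#'
#' @param path CSV path written by [write_feature_table()].
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"feature_id" %in% names(df)) {
    stop("file lacks a feature_id column: ", path, call. = FALSE)
  }
  ann_cols <- intersect(c("feature_id", "modality", "unique_peptides",
                          "contaminant_class"), names(df))
  features <- df[, ann_cols, drop = FALSE]
  if (anyDuplicated(features$feature_id)) {
    dup <- unique(features$feature_id[duplicated(features$feature_id)])
    stop("duplicate feature id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  values <- as.matrix(df[, setdiff(names(df), ann_cols), drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- features$feature_id
  samples <- read.csv(sample_sidecar_path(path), stringsAsFactors = FALSE)
  feature_table(values, samples, features)
}

#' Write spectra as long-format CSV
#'
#' One row per (replicate, wavenumber): columns `wavenumber_cm1`,
#' `intensity`, `sample_id`, `well_id`, `scan_id` and any further replicate
#' metadata (class, timepoint).
#'
#' @param spectra a [spectrum_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "SpectrumSet"))
  n_wn <- length(spectra$wavenumbers)
  n_rep <- nrow(spectra$intensities)
  meta <- spectra$replicates[rep(seq_len(n_rep), each = n_wn), , drop = FALSE]
  df <- cbind(data.frame(wavenumber_cm1 = rep(spectra$wavenumbers, n_rep),
                         intensity = as.vector(t(spectra$intensities))),
              meta)
  rownames(df) <- NULL
  write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read long-format spectra CSV
#'
#' Inverse of [write_spectra()]; every replicate must cover the same
#' wavenumber grid.
#'
#' @param path CSV path.
#' @return a [spectrum_set()].
#' @export
read_spectra <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("wavenumber_cm1", "intensity", "sample_id", "well_id", "scan_id")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("spectra file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  key <- paste(df$sample_id, df$well_id, df$scan_id, sep = "\r")
  reps <- unique(key)
  wn <- df$wavenumber_cm1[key == reps[1]]
  meta_cols <- setdiff(names(df), c("wavenumber_cm1", "intensity"))
  intens <- matrix(NA_real_, nrow = length(reps), ncol = length(wn))
  meta <- vector("list", length(reps))
  for (i in seq_along(reps)) {
    block <- df[key == reps[i], , drop = FALSE]
    if (!isTRUE(all.equal(block$wavenumber_cm1, wn))) {
      stop("replicate ", reps[i], " is not on the common wavenumber grid",
           call. = FALSE)
    }
    intens[i, ] <- block$intensity
    meta[[i]] <- block[1L, meta_cols, drop = FALSE]
  }
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  spectrum_set(wn, intens, meta)
}
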