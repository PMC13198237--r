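# Cross-cohort biomarker triage: which features replicate their fold-change
# direction across cohorts/platforms, which flip, and which reverse in a
# non-glioma contrast. Concordance is defined by direction only; statistical
# significance enters afterwards through training-cohort tiers.

#' Cross-reference features across cohort results
#'
#' Features testable in every supplied cohort result, honoring a
#' unique-peptide floor where that annotation exists (features without the
#' annotation, e.g. miRNA, are not subject to the floor).
#'
#' @param results named list of [differential()] results (>= 1 cohort).
#' @param min_unique_peptides required unique peptide count where annotated
#'   (default 2, i.e. "> 1 unique peptide").
#' @return character vector of shared feature ids.
#' @export
cross_reference <- function(results, min_unique_peptides = 2) {
  stopifnot(is.list(results), length(results) >= 1, !is.null(names(results)))
  sets <- lapply(results, function(r) {
    stopifnot(inherits(r, "DifferentialResult"))
    ok <- r$testable
    annotated <- !is.na(r$unique_peptides)
    ok[annotated] <- ok[annotated] &
      r$unique_peptides[annotated] >= min_unique_peptides
    r$feature_id[ok]
  })
  Reduce(intersect, sets)
}

#' Classify cross-cohort fold-change concordance
#'
#' A shared feature is `concordant` when its signed fold change has the same
#' direction in every cohort, `discordant` when directions differ, and
#' `partial` when any cohort's direction is undefined (fold change exactly
#' 1, i.e. no change). The classification is invariant to cohort order.
#'
#' @param results named list of [differential()] results (>= 2 cohorts).
#' @param features feature ids to classify; defaults to
#'   [cross_reference()] of the results with no peptide floor.
#' @return `ConcordanceRecords` data.frame: `feature_id`, one
#'   `signed_fc_<cohort>` column per cohort, and `classification`.
#' @export
classify_concordance <- function(results, features = NULL) {
  stopifnot(is.list(results), length(results) >= 2, !is.null(names(results)))
  if (is.null(features)) {
    features <- cross_reference(results, min_unique_peptides = 1)
  }
  fc <- sapply(results, function(r) {
    r$signed_fc[match(features, r$feature_id)]
  })
  fc <- matrix(fc, nrow = length(features),
               dimnames = list(NULL, names(results)))
  if (anyNA(fc)) {
    bad <- features[apply(is.na(fc), 1L, any)]
    stop("signed fold change undefined in some cohort for: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  signs <- sign(log(abs(fc)) * sign(fc))  # +1 up, -1 down, 0 at |FC| == 1
  classification <- apply(signs, 1L, function(s) {
    if (any(s == 0)) "partial"
    else if (length(unique(s)) == 1L) "concordant"
    else "discordant"
  })
  out <- data.frame(feature_id = features, stringsAsFactors = FALSE)
  for (nm in names(results)) out[[paste0("signed_fc_", nm)]] <- fc[, nm]
  out$classification <- classification
  class(out) <- c("ConcordanceRecords", "data.frame")
  out
}

#' Concordance class counts
#'
#' @param records a [classify_concordance()] result.
#' @return named integer vector over `concordant`, `discordant`, `partial`
#'   (Venn-style summary; the three counts partition the shared features).
#' @export
concordance_counts <- function(records) {
  stopifnot(inherits(records, "ConcordanceRecords"))
  vapply(c("concordant", "discordant", "partial"), function(k)
    sum(records$classification == k), integer(1))
}

#' Intersect concordant features with training-cohort tiers
#'
#' Filters the concordant records by named training-cohort tier flags and
#' reports the nested sets (each tier's concordant members) with their
#' sizes.
#'
#' @param records a [classify_concordance()] result.
#' @param tiers a [tier_candidates()] data.frame computed on the training
#'   cohort.
#' @param tier_names tiers to apply, in nesting order; defaults to all flag
#'   columns of `tiers`.
#' @return list with `sets` (named list of feature-id vectors) and `sizes`.
#' @export
tier_intersection <- function(records, tiers, tier_names = NULL) {
  stopifnot(inherits(records, "ConcordanceRecords"), is.data.frame(tiers))
  available <- setdiff(names(tiers), "feature_id")
  if (is.null(tier_names)) tier_names <- available
  unknown <- setdiff(tier_names, available)
  if (length(unknown)) {
    stop("unknown tier name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  concordant <- records$feature_id[records$classification == "concordant"]
  sets <- lapply(tier_names, function(nm) {
    flagged <- tiers$feature_id[tiers[[nm]]]
    intersect(concordant, flagged)
  })
  names(sets) <- tier_names
  list(concordant = concordant, sets = sets,
       sizes = c(concordant = length(concordant),
                 vapply(sets, length, integer(1))))
}

#' Detect reversed differential patterns in a contrast group
#'
#' Among concordant features, finds those whose direction in the contrast
#' comparison (e.g. non-glioma brain tumors vs controls) is opposite to
#' their shared glioma-vs-control direction. Features missing from the
#' contrast, or with undefined contrast direction, are excluded and listed.
#'
#' @param records a [classify_concordance()] result.
#' @param contrast_result a [differential()] result for the contrast
#'   comparison.
#' @return list with `reversed` (feature ids), `detail` (per-feature signs)
#'   and `excluded` (features not evaluable in the contrast).
#' @export
reversed_pattern <- function(records, contrast_result) {
  stopifnot(inherits(records, "ConcordanceRecords"),
            inherits(contrast_result, "DifferentialResult"))
  conc <- records[records$classification == "concordant", , drop = FALSE]
  fc_cols <- grep("^signed_fc_", names(conc), value = TRUE)
  glioma_sign <- sign(conc[[fc_cols[1]]])  # concordant: same in all cohorts
  m <- match(conc$feature_id, contrast_result$feature_id)
  contrast_fc <- contrast_result$signed_fc[m]
  testable <- !is.na(m) & contrast_result$testable[m] & !is.na(contrast_fc) &
    abs(contrast_fc) != 1
  contrast_sign <- ifelse(testable, sign(contrast_fc), NA_real_)
  detail <- data.frame(feature_id = conc$feature_id,
                       glioma_sign = glioma_sign,
                       contrast_sign = contrast_sign,
                       reversed = !is.na(contrast_sign) &
                         contrast_sign == -glioma_sign,
                       stringsAsFactors = FALSE)
  list(reversed = detail$feature_id[detail$reversed],
       detail = detail,
       excluded = detail$feature_id[is.na(detail$contrast_sign)])
}
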