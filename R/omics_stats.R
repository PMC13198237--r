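# Per-cohort differential abundance/expression with detection, contaminant
# and tier filters. Statistics run on the log2 scale (protein abundances are
# stored log2; miRNA expression is log2(count + 1)); fold changes are
# reported on the linear scale with the signed convention FC if >= 1 else
# -1/FC, so "fold change > +/-1.5" means a 1.5-fold change either way.

#' Filter features by detection fraction
#'
#' Keeps features whose non-missing fraction across all samples is at least
#' `min_fraction` (default 0.67, i.e. reliably identified in >= 67% of
#' samples).
#'
#' @param t a [feature_table()].
#' @param min_fraction required detection fraction in `(0, 1]`.
#' @return filtered [feature_table()]; the dropped features and their
#'   detection fractions are attached as attribute `"dropped_features"`.
#' @export
detection_filter <- function(t, min_fraction = 0.67) {
  stopifnot(inherits(t, "FeatureTable"))
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must lie in (0, 1]", call. = FALSE)
  }
  frac <- rowMeans(!is.na(t$values))
  keep <- frac >= min_fraction
  out <- subset_feature_table(t, features = which(keep))
  attr(out, "dropped_features") <- data.frame(
    feature_id = t$features$feature_id[!keep],
    detection = unname(frac[!keep]), stringsAsFactors = FALSE)
  out
}

#' Remove annotated contaminant features
#'
#' Drops features whose contaminant class is among the given classes
#' (default: the common plasma contaminants keratin, immunoglobulin,
#' apolipoprotein and albumin).
#'
#' @param t a [feature_table()] with a `contaminant_class` annotation.
#' @param classes contaminant classes to remove.
#' @return filtered [feature_table()] with attribute `"removed_contaminants"`
#'   listing the removed features.
#' @export
remove_contaminants <- function(t, classes = c("keratin", "immunoglobulin",
                                               "apolipoprotein", "albumin")) {
  stopifnot(inherits(t, "FeatureTable"))
  if (is.null(t$features$contaminant_class)) {
    stop("feature metadata lacks contaminant_class", call. = FALSE)
  }
  drop <- t$features$contaminant_class %in% classes
  out <- subset_feature_table(t, features = which(!drop))
  attr(out, "removed_contaminants") <- data.frame(
    feature_id = t$features$feature_id[drop],
    contaminant_class = t$features$contaminant_class[drop],
    stringsAsFactors = FALSE)
  out
}

#' Per-feature differential analysis
#'
#' Tests every feature between two groups on the log2 scale with Welch's
#' unequal-variance t test (or one-way ANOVA across more groups, in which
#' case the fold change still contrasts `groups[2]` vs `groups[1]`).
#' Missing values are excluded pairwise per feature; a feature with fewer
#' than two values in a compared group is flagged untestable and excluded
#' from the Benjamini-Hochberg adjustment.
#'
#' @param t a [feature_table()].
#' @param groups character of class labels to compare; the second is the
#'   "case" (numerator) group. Default `c("control", "case")`.
#' @param test `"welch"` (two groups) or `"anova"`.
#' @return a `DifferentialResult` data.frame: per feature `log2FC`, linear
#'   `fc`, `signed_fc`, `p`, BH `q`, per-group detection fractions,
#'   `direction` and `testable`.
#' @export
differential <- function(t, groups = c("control", "case"),
                         test = c("welch", "anova")) {
  stopifnot(inherits(t, "FeatureTable"))
  test <- match.arg(test)
  missing_groups <- setdiff(groups, t$samples$class)
  if (length(missing_groups)) {
    stop("class label(s) not in table: ", paste(missing_groups, collapse = ", "),
         call. = FALSE)
  }
  if (test == "welch" && length(groups) != 2L) {
    stop("Welch's t compares exactly two groups", call. = FALSE)
  }
  keep_s <- t$samples$class %in% groups
  vals <- t$values[, keep_s, drop = FALSE]
  cls <- t$samples$class[keep_s]
  ref <- groups[1]
  alt <- groups[2]
  n_f <- nrow(vals)
  res <- data.frame(
    feature_id = t$features$feature_id,
    modality = t$features$modality,
    unique_peptides = if (!is.null(t$features$unique_peptides))
      t$features$unique_peptides else NA_integer_,
    log2FC = NA_real_, fc = NA_real_, signed_fc = NA_real_,
    p = NA_real_, q = NA_real_,
    detection_case = NA_real_, detection_control = NA_real_,
    direction = NA_character_, testable = FALSE,
    stringsAsFactors = FALSE)
  for (j in seq_len(n_f)) {
    x <- vals[j, ]
    ok <- !is.na(x)
    res$detection_case[j] <- mean(ok[cls == alt])
    res$detection_control[j] <- mean(ok[cls == ref])
    n_per <- vapply(groups, function(g) sum(ok & cls == g), integer(1))
    if (any(n_per < 2L)) next
    xa <- x[ok & cls == alt]
    xr <- x[ok & cls == ref]
    l2fc <- mean(xa) - mean(xr)
    p <- if (test == "welch") {
      if (sd(xa) == 0 && sd(xr) == 0) {
        if (mean(xa) == mean(xr)) 1 else 0
      } else t.test(xa, xr, var.equal = FALSE)$p.value
    } else {
      xx <- x[ok]
      gg <- factor(cls[ok])
      summary(aov(xx ~ gg))[[1]][["Pr(>F)"]][1]
    }
    fc <- 2^l2fc
    res$log2FC[j] <- l2fc
    res$fc[j] <- fc
    res$signed_fc[j] <- if (fc >= 1) fc else -1 / fc
    res$p[j] <- p
    res$direction[j] <- if (l2fc > 0) "up" else if (l2fc < 0) "down" else "none"
    res$testable[j] <- TRUE
  }
  res$q[res$testable] <- p.adjust(res$p[res$testable], method = "BH")
  attr(res, "groups") <- groups
  attr(res, "test") <- test
  class(res) <- c("DifferentialResult", "data.frame")
  res
}

#' Built-in candidate tier rule sets
#'
#' `protein_loose`: q < 0.05. `protein_stringent`: q < 0.01, |signed FC| >
#' 1.5, unique peptides > 1. `mirna_loose`: adjusted p (q) < 0.05.
#' `mirna_stringent`: q < 0.05 and |signed FC| > 2.
#'
#' @return named list of rule lists with fields `q_lt`, `abs_fc_gt`,
#'   `unique_peptides_gt` (any may be absent).
#' @export
default_tier_rules <- function() {
  list(
    protein_loose = list(q_lt = 0.05),
    protein_stringent = list(q_lt = 0.01, abs_fc_gt = 1.5,
                             unique_peptides_gt = 1),
    mirna_loose = list(q_lt = 0.05),
    mirna_stringent = list(q_lt = 0.05, abs_fc_gt = 2)
  )
}

#' Flag candidate biomarkers by tier rules
#'
#' Applies named rule sets to a differential result and returns one logical
#' flag column per rule. Untestable features are `FALSE` in every tier.
#'
#' @param r a [differential()] result.
#' @param rules named list of rule lists (see [default_tier_rules()], the
#'   default).
#' @return data.frame with `feature_id` and one logical column per rule.
#' @export
tier_candidates <- function(r, rules = default_tier_rules()) {
  stopifnot(inherits(r, "DifferentialResult"), length(rules) >= 1,
            !is.null(names(rules)))
  out <- data.frame(feature_id = r$feature_id, stringsAsFactors = FALSE)
  for (nm in names(rules)) {
    rule <- rules[[nm]]
    unknown <- setdiff(names(rule), c("q_lt", "abs_fc_gt", "unique_peptides_gt"))
    if (length(unknown)) {
      stop("unknown rule field(s) in '", nm, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    flag <- r$testable
    if (!is.null(rule$q_lt)) flag <- flag & !is.na(r$q) & r$q < rule$q_lt
    if (!is.null(rule$abs_fc_gt)) {
      flag <- flag & !is.na(r$signed_fc) & abs(r$signed_fc) > rule$abs_fc_gt
    }
    if (!is.null(rule$unique_peptides_gt)) {
      if (all(is.na(r$unique_peptides))) {
        stop("rule '", nm, "' requires unique_peptides, which the table lacks",
             call. = FALSE)
      }
      flag <- flag & !is.na(r$unique_peptides) &
        r$unique_peptides > rule$unique_peptides_gt
    }
    out[[nm]] <- flag
  }
  out
}

#' Write a differential result as TSV
#'
#' @param r a [differential()] result.
#' @param path output path.
#' @param tiers optional [tier_candidates()] data.frame to append.
#' @return `path`, invisibly.
#' @export
write_differential <- function(r, path, tiers = NULL) {
  out <- as.data.frame(r)
  if (!is.null(tiers)) {
    stopifnot(identical(tiers$feature_id, out$feature_id))
    out <- cbind(out, tiers[, setdiff(names(tiers), "feature_id"),
                            drop = FALSE])
  }
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
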