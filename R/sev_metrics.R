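# Particle-size and concentration summaries with the group comparisons used
# for sEV characterization: trapezoidal quadrature on the native bin grid,
# Welch's t for two groups, one-way ANOVA with Tukey HSD for three.

#' Summarize a particle size distribution
#'
#' Total concentration is the trapezoidal integral of the density over the
#' bin grid; mean size is the density-weighted average of bin centers; median
#' size is where the cumulative integral reaches half the total, with linear
#' interpolation inside the crossing bin.
#'
#' @param d a [size_distribution()].
#' @return list with `mean_nm`, `median_nm`, `total_particles_ml`.
#' @export
summarize_distribution <- function(d) {
  stopifnot(inherits(d, "SizeDistribution"))
  x <- d$bin_centers
  y <- d$density
  total <- trapz(x, y)
  if (total <= 0) {
    stop("zero total concentration: mean/median undefined", call. = FALSE)
  }
  mean_nm <- trapz(x, x * y) / total
  # cumulative trapezoid integral at each bin center
  cum <- c(0, cumsum(diff(x) * (y[-1] + y[-length(y)]) / 2))
  half <- total / 2
  i <- which(cum >= half)[1]
  if (i == 1L) {
    median_nm <- x[1]
  } else {
    # invert the (monotone) cumulative integral linearly within the bin
    median_nm <- x[i - 1] + (half - cum[i - 1]) / (cum[i] - cum[i - 1]) *
      (x[i] - x[i - 1])
  }
  list(mean_nm = mean_nm, median_nm = median_nm, total_particles_ml = total)
}

#' Particle yield above a size threshold
#'
#' Trapezoidal integral of the density restricted to sizes greater than
#' `threshold_nm`; the bin straddling the threshold is split by linear
#' interpolation of the density, so the open/closed convention at the
#' threshold is numerically immaterial. The default threshold of 80 nm
#' matches the exclusion limit of alternative size exclusion chromatography
#' columns.
#'
#' @param d a [size_distribution()].
#' @param threshold_nm size threshold in nm.
#' @param allow_below_grid if `TRUE`, a threshold below the grid minimum
#'   returns the total concentration instead of erroring.
#' @return particles/mL above the threshold.
#' @export
yield_above_threshold <- function(d, threshold_nm = 80,
                                  allow_below_grid = FALSE) {
  stopifnot(inherits(d, "SizeDistribution"))
  x <- d$bin_centers
  y <- d$density
  if (threshold_nm < x[1]) {
    if (allow_below_grid) return(trapz(x, y))
    stop("threshold ", threshold_nm, " nm below grid minimum ", x[1],
         " nm", call. = FALSE)
  }
  if (threshold_nm >= x[length(x)]) {
    if (threshold_nm == x[length(x)]) return(0)
    stop("threshold ", threshold_nm, " nm above grid maximum ",
         x[length(x)], " nm", call. = FALSE)
  }
  i <- findInterval(threshold_nm, x)   # x[i] <= thr < x[i+1]
  y_thr <- y[i] + (y[i + 1] - y[i]) * (threshold_nm - x[i]) / (x[i + 1] - x[i])
  partial <- (x[i + 1] - threshold_nm) * (y_thr + y[i + 1]) / 2
  rest <- if (i + 1 < length(x)) {
    trapz(x[(i + 1):length(x)], y[(i + 1):length(x)])
  } else 0
  partial + rest
}

#' Compare a per-sample metric between groups
#'
#' Two groups are compared by Welch's unequal-variance t test; three or more
#' by one-way ANOVA with post-hoc Tukey HSD pairwise comparisons. P-values
#' map to the reporting tiers via [significance_stars()].
#'
#' @param values numeric vector, one value per sample.
#' @param labels group label per sample (2 or more groups, each with at least
#'   2 values).
#' @return object of class `GroupComparison`: group means, the test used,
#'   statistic, p-value(s) and stars. For >= 3 groups, `pairwise` holds all
#'   Tukey pairwise comparisons.
#' @export
compare_groups <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- as.character(labels[keep])
  counts <- table(labels)
  if (length(counts) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(counts < 2L)) {
    stop("insufficient data: every group needs >= 2 values (",
         paste(names(counts)[counts < 2], collapse = ", "), ")",
         call. = FALSE)
  }
  means <- tapply(values, labels, mean)
  if (length(counts) == 2L) {
    groups <- names(counts)
    a <- values[labels == groups[1]]
    b <- values[labels == groups[2]]
    if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
      tt <- list(statistic = c(t = 0), p.value = 1, parameter = c(df = NA))
    } else {
      tt <- t.test(a, b, var.equal = FALSE)
    }
    out <- list(test = "welch_t", group_means = means,
                statistic = unname(tt$statistic), p_value = tt$p.value,
                stars = significance_stars(tt$p.value), pairwise = NULL)
  } else {
    fit <- aov(values ~ factor(labels))
    an <- summary(fit)[[1]]
    p_global <- an[["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)[[1]]
    pairwise <- data.frame(comparison = rownames(tk),
                           diff = tk[, "diff"], p_adj = tk[, "p adj"],
                           stars = significance_stars(tk[, "p adj"]),
                           row.names = NULL)
    out <- list(test = "anova_tukey", group_means = means,
                statistic = an[["F value"]][1], p_value = p_global,
                stars = significance_stars(p_global), pairwise = pairwise)
  }
  structure(out, class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat("<GroupComparison> ", x$test, ": p = ", format(x$p_value, digits = 4),
      " (", x$stars, ")\n", sep = "")
  print(round(x$group_means, 4))
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' Read a nanoparticle-tracking CSV export
#'
#' Accepts either a two-column export (`size_nm`, `concentration`) for a
#' single sample, or a long format with an additional `sample_id` (and
#' optional `class`) column covering several samples.
#'
#' @param path CSV file path.
#' @param sample_id id to assign when the file is a single two-column export.
#' @param class optional class label for the two-column form.
#' @return a [size_distribution()] or a list of them (long form).
#' @export
read_size_distribution <- function(path, sample_id = NA_character_,
                                   class = NA_character_) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("size_nm", "concentration") %in% names(df))) {
    stop("expected columns size_nm and concentration in ", path, call. = FALSE)
  }
  if ("sample_id" %in% names(df)) {
    split_df <- split(df, df$sample_id)
    lapply(split_df, function(s) {
      size_distribution(s$size_nm, s$concentration,
                        sample_id = s$sample_id[1],
                        class = if ("class" %in% names(s)) s$class[1]
                        else NA_character_)
    })
  } else {
    size_distribution(df$size_nm, df$concentration, sample_id = sample_id,
                      class = class)
  }
}

#' Write size distributions as a long-format CSV
#'
#' @param distributions a [size_distribution()] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_size_distribution <- function(distributions, path) {
  if (inherits(distributions, "SizeDistribution")) {
    distributions <- list(distributions)
  }
  rows <- lapply(distributions, function(d) {
    data.frame(size_nm = d$bin_centers, concentration = d$density,
               sample_id = d$sample_id, class = d$class,
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
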