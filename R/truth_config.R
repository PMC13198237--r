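# Full specification of the synthetic study: cohort sizes, planted effects,
# spectral physics stand-ins, particle-size parameters and the longitudinal
# design. One config object drives every generator so that a single seed
# reproduces the whole study bit-identically.

#' Cohort specification for the synthetic study
#'
#' @param n_case,n_control group sizes.
#' @param n_nonglioma optional third group (non-glioma brain tumors), used in
#'   the validation cohort for reversed-pattern contrasts.
#' @param batch_scale,batch_offset affine per-cohort batch distortion applied
#'   to every feature on the log/intensity scale (scale then offset). Per-cohort
#'   z-scoring removes it exactly.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_case, n_control, n_nonglioma = 0L,
                        batch_scale = 1, batch_offset = 0) {
  stopifnot(n_case > 0, n_control > 0, n_nonglioma >= 0, batch_scale > 0)
  list(n_case = as.integer(n_case), n_control = as.integer(n_control),
       n_nonglioma = as.integer(n_nonglioma),
       batch_scale = batch_scale, batch_offset = batch_offset)
}

#' Planted differential effect
#'
#' @param feature_id id of the planted feature (must index into the feature
#'   space of its modality, e.g. `"prot_0005"`).
#' @param modality `"protein"` or `"mirna"`.
#' @param effects named numeric vector of signed effect sizes (within-group SD
#'   units on the log2 scale), one per cohort; a single unnamed value recycles
#'   to every cohort.
#' @param type `"concordant"` (same sign in all cohorts), `"discordant"`
#'   (signs differ across cohorts), or `"reversed"` (concordant in glioma, sign
#'   flipped in the non-glioma group only).
#' @return a `planted_effect` list.
#' @export
planted_effect <- function(feature_id, modality, effects,
                           type = c("concordant", "discordant", "reversed")) {
  type <- match.arg(type)
  stopifnot(is.numeric(effects), length(effects) >= 1)
  list(feature_id = feature_id, modality = modality,
       effects = effects, type = type)
}

#' Synthetic study configuration
#'
#' Defaults reproduce the study conditions the workflow is designed around:
#' three cohorts (training 56 glioma / 48 control, validation 13 glioma /
#' 16 non-glioma / 20 control, longitudinal 6 / 6), nine replicate spectra
#' per sample (3 wells x 3 scans), particle-size medians of 121.6 nm (case)
#' vs 100.5 nm (control), and a longitudinal design whose planted effects
#' attenuate on treatment and re-diverge at recurrence.
#'
#' @param seed integer run seed; every generator derives its own stream from
#'   it (documented integer offsets), so identical configs give bit-identical
#'   output.
#' @param cohorts named list of [cohort_spec()] entries.
#' @param n_protein_features,n_mirna_features feature-space sizes.
#' @param planted_effects list of [planted_effect()] entries; `NULL` uses a
#'   default panel of concordant/discordant/reversed features in both
#'   modalities.
#' @param dropout_rate probability in `[0, 1)` that any single omics
#'   measurement is missing (missing completely at random).
#' @param spectra list of spectral generator settings; see Details.
#' @param size_dist list of particle-size settings; see Details.
#' @param longitudinal list with `timepoints` (character; the first is the
#'   pre-operative baseline), `attenuation` in `[0, 1]` (fraction of the
#'   planted effect removed at on-treatment timepoints) and
#'   `recurrence_factor` (multiplier restoring the effect at timepoints named
#'   `"recurrence"`).
#'
#' @details
#' `spectra` fields: `wn_lo`, `wn_hi`, `step` (cm^-1 grid); `peaks` data.frame
#' with `center`, `height`, `width`, `class_shift` (additive case height
#' shift); `baseline_range` (uniform range for each order-0..2 polynomial
#' coefficient); `scatter_range` (multiplicative scatter); `noise_sd`;
#' `n_wells`, `n_scans` (replicates per sample = wells x scans);
#' `well_effect_sd` (additive well-level intercept shared by the scans of a
#' well); `sample_effect_sd` (additive sample-level intercept).
#'
#' `size_dist` fields: `control_median`, `case_median` (nm), `gsd` (geometric
#' SD of the log-normal), `control_total`, `case_total` (particles/mL),
#' `median_sdlog`, `total_sdlog` (between-sample log-scale variability),
#' `grid_lo`, `grid_hi`, `grid_step` (nm binning).
#'
#' @return object of class `truth_config`.
#' @export
truth_config <- function(seed = 1L,
                         cohorts = NULL,
                         n_protein_features = 500L,
                         n_mirna_features = 150L,
                         planted_effects = NULL,
                         dropout_rate = 0.1,
                         spectra = NULL,
                         size_dist = NULL,
                         longitudinal = NULL) {
  if (is.null(cohorts)) {
    cohorts <- list(
      training     = cohort_spec(56, 48, batch_scale = 1.0, batch_offset = 0.0),
      validation   = cohort_spec(13, 20, n_nonglioma = 16,
                                 batch_scale = 1.15, batch_offset = 0.8),
      longitudinal = cohort_spec(6, 6, batch_scale = 0.9, batch_offset = -0.5)
    )
  }
  stopifnot(length(cohorts) >= 1, !is.null(names(cohorts)),
            all(nzchar(names(cohorts))))
  if (is.null(planted_effects)) {
    planted_effects <- default_planted_effects(names(cohorts))
  }
  stopifnot(n_protein_features > 0, n_mirna_features > 0)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  }
  spectra_default <- list(
    wn_lo = 600, wn_hi = 4000, step = 1,
    peaks = data.frame(
      center      = c(1080, 1240, 1400, 1550, 1650, 2850, 2920, 3300),
      height      = c(0.30, 0.35, 0.25, 0.50, 0.90, 0.25, 0.35, 0.45),
      width       = c(25, 22, 20, 22, 25, 18, 20, 60),
      class_shift = c(0.05, 0.06, 0.00, 0.04, 0.08, 0.00, 0.03, 0.02)
    ),
    baseline_range = c(-0.05, 0.05),
    scatter_range = c(0.85, 1.15),
    noise_sd = 0.01,
    n_wells = 3L, n_scans = 3L,
    well_effect_sd = 0.02, sample_effect_sd = 0.02
  )
  spectra <- if (is.null(spectra)) list() else spectra
  user_peaks <- spectra$peaks   # replace wholesale, never merge row-wise
  spectra$peaks <- NULL
  spectra <- modifyList(spectra_default, spectra)
  if (!is.null(user_peaks)) spectra$peaks <- user_peaks
  if (spectra$step <= 0) stop("spectra step must be positive", call. = FALSE)
  size_default <- list(
    control_median = 100.5, case_median = 121.6, gsd = 1.45,
    control_total = 1.09e11, case_total = 1.30e11,
    median_sdlog = 0.05, total_sdlog = 0.15,
    grid_lo = 30, grid_hi = 700, grid_step = 1
  )
  size_dist <- modifyList(size_default, if (is.null(size_dist)) list() else size_dist)
  if (size_dist$control_median <= 0 || size_dist$case_median <= 0) {
    stop("size-distribution medians must be positive", call. = FALSE)
  }
  if (size_dist$gsd <= 1) stop("geometric SD must exceed 1", call. = FALSE)
  long_default <- list(timepoints = c("pre_op", "on_treatment", "recurrence"),
                       attenuation = 0.6, recurrence_factor = 1.0)
  longitudinal <- modifyList(long_default,
                             if (is.null(longitudinal)) list() else longitudinal)
  if (longitudinal$attenuation < 0 || longitudinal$attenuation > 1) {
    stop("longitudinal attenuation must lie in [0, 1]", call. = FALSE)
  }
  cohort_names <- names(cohorts)
  planted_effects <- lapply(planted_effects, function(pe) {
    eff <- pe$effects
    if (is.null(names(eff))) {
      if (length(eff) == 1L) {
        eff <- setNames(rep(eff, length(cohort_names)), cohort_names)
      } else {
        stop("multi-cohort effects must be named by cohort", call. = FALSE)
      }
    }
    missing <- setdiff(cohort_names, names(eff))
    if (length(missing)) {
      stop("planted effect for ", pe$feature_id, " lacks cohorts: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (pe$type %in% c("concordant", "reversed") &&
        length(unique(sign(eff[cohort_names]))) != 1L) {
      stop("'", pe$type, "' effect for ", pe$feature_id,
           " must keep one sign across cohorts", call. = FALSE)
    }
    pe$effects <- eff[cohort_names]
    pe
  })
  structure(list(seed = as.integer(seed), cohorts = cohorts,
                 n_protein_features = as.integer(n_protein_features),
                 n_mirna_features = as.integer(n_mirna_features),
                 planted_effects = planted_effects,
                 dropout_rate = dropout_rate, spectra = spectra,
                 size_dist = size_dist, longitudinal = longitudinal),
            class = "truth_config")
}

# Default planted panel: 12 concordant + 5 discordant + 4 reversed proteins,
# 8 concordant + 4 discordant + 4 reversed miRNAs, effect magnitude 1.5 SD
# with alternating direction. Discordant features flip sign in the second
# cohort; reversed features keep one glioma sign everywhere and flip only in
# the non-glioma group at generation time.
default_planted_effects <- function(cohort_names) {
  flip_cohort <- if (length(cohort_names) >= 2) cohort_names[2] else cohort_names[1]
  mk <- function(prefix, idx, type, base_sign) {
    lapply(seq_along(idx), function(i) {
      s <- base_sign[i]
      eff <- setNames(rep(1.5 * s, length(cohort_names)), cohort_names)
      if (type == "discordant") eff[flip_cohort] <- -eff[flip_cohort]
      planted_effect(sprintf("%s_%04d", prefix, idx[i]),
                     if (prefix == "prot") "protein" else "mirna",
                     eff, type)
    })
  }
  c(
    mk("prot", 1:12,  "concordant", rep(c(1, -1), 6)),
    mk("prot", 13:17, "discordant", rep(c(1, -1), length.out = 5)),
    mk("prot", 18:21, "reversed",   rep(c(1, -1), 2)),
    mk("mir",  1:8,   "concordant", rep(c(1, -1), 4)),
    mk("mir",  9:12,  "discordant", rep(c(1, -1), 2)),
    mk("mir",  13:16, "reversed",   rep(c(1, -1), 2))
  )
}

#' @export
print.truth_config <- function(x, ...) {
  cat("<truth_config> seed ", x$seed, "\n", sep = "")
  for (nm in names(x$cohorts)) {
    co <- x$cohorts[[nm]]
    cat("  ", nm, ": ", co$n_case, " case / ", co$n_control, " control",
        if (co$n_nonglioma > 0) paste0(" / ", co$n_nonglioma, " nonglioma"),
        " (batch ", co$batch_scale, "x + ", co$batch_offset, ")\n", sep = "")
  }
  cat("  features: ", x$n_protein_features, " protein, ",
      x$n_mirna_features, " miRNA; planted: ", length(x$planted_effects),
      "; dropout ", x$dropout_rate, "\n", sep = "")
  invisible(x)
}

#' Write a truth configuration to JSON
#'
#' Serializes every field of a [truth_config()] so a study specification can
#' live in version control and be rebuilt with [read_truth_config()].
#'
#' @param cfg a [truth_config()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "truth_config"))
  spec <- unclass(cfg)
  spec$planted_effects <- lapply(spec$planted_effects, function(pe) {
    pe$effects <- as.list(pe$effects)
    pe
  })
  spec$spectra$peaks <- as.list(spec$spectra$peaks)
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a truth configuration from JSON
#'
#' @param path JSON file written by [write_truth_config()].
#' @return a validated [truth_config()].
#' @export
read_truth_config <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  planted <- lapply(spec$planted_effects, function(pe) {
    planted_effect(pe$feature_id, pe$modality, unlist(pe$effects), pe$type)
  })
  cohorts <- lapply(spec$cohorts, function(co) do.call(cohort_spec, co))
  spectra <- spec$spectra
  spectra$peaks <- as.data.frame(spectra$peaks)
  truth_config(seed = spec$seed, cohorts = cohorts,
               n_protein_features = spec$n_protein_features,
               n_mirna_features = spec$n_mirna_features,
               planted_effects = planted,
               dropout_rate = spec$dropout_rate,
               spectra = spectra, size_dist = spec$size_dist,
               longitudinal = spec$longitudinal)
}

#' Write the ground-truth manifest
#'
#' Records the seed, cohort structure and the full planted-effect panel as
#' JSON so that recovery tests can compare estimated against planted truth.
#' All generator distributions are synthetic stand-ins (no claim about the
#' distributional form of real analytes), and the manifest says so.
#'
#' @param cfg a [truth_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth_manifest <- function(cfg, path) {
  stopifnot(inherits(cfg, "truth_config"))
  manifest <- list(
    note = paste("synthetic stand-in distributions: log-normal protein",
                 "abundances, negative-binomial miRNA counts, Gaussian",
                 "spectral peaks; not fitted to any real dataset"),
    seed = cfg$seed,
    cohorts = cfg$cohorts,
    n_protein_features = cfg$n_protein_features,
    n_mirna_features = cfg$n_mirna_features,
    dropout_rate = cfg$dropout_rate,
    planted_effects = lapply(cfg$planted_effects, function(pe) {
      list(feature_id = pe$feature_id, modality = pe$modality,
           type = pe$type, effects = as.list(pe$effects))
    }),
    longitudinal = cfg$longitudinal
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
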