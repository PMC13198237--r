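# Synthetic three-cohort study generator with planted ground truth.
#
# Random-stream layout (documented offsets from the single run seed):
#   1, 2                      feature-level parameters (protein, miRNA); these
#                             are cohort-independent so the same analytes exist
#                             in every cohort
#   100 + 10*cohort + mod     omics measurement noise per cohort and modality
#   200 + cohort              replicate spectra per cohort
#   300 + cohort              particle-size distributions per cohort
#   400 + 10*tp + mod         longitudinal omics per timepoint
#   500 + tp                  longitudinal spectra per timepoint
# ("cohort" and "tp" are 1-based indices; "mod" is 1 protein / 2 miRNA.)

modality_code <- function(modality) {
  switch(modality, protein = 1L, mirna = 2L,
         stop("unknown modality '", modality, "'", call. = FALSE))
}

cohort_index <- function(cfg, cohort) {
  i <- match(cohort, names(cfg$cohorts))
  if (is.na(i)) stop("unknown cohort '", cohort, "'", call. = FALSE)
  i
}

# Cohort-independent feature parameters, drawn from their own stream.
feature_params <- function(cfg, modality) {
  set.seed(stream_seed(cfg$seed, modality_code(modality)))
  if (modality == "protein") {
    n <- cfg$n_protein_features
    ids <- sprintf("prot_%04d", seq_len(n))
    mu <- runif(n, 18, 26)          # log2 abundance baseline
    sdv <- runif(n, 0.4, 1.2)       # within-group SD, log2 scale
    planted <- vapply(cfg$planted_effects, function(pe)
      pe$modality == "protein", logical(1))
    planted_ids <- vapply(cfg$planted_effects[planted], `[[`, "", "feature_id")
    up <- ifelse(ids %in% planted_ids,
                 sample(2:12, n, replace = TRUE),
                 sample(1:12, n, replace = TRUE))
    list(ids = ids, mu = mu, sd = sdv, unique_peptides = up)
  } else {
    n <- cfg$n_mirna_features
    ids <- sprintf("mir_%04d", seq_len(n))
    mu <- 2^runif(n, 3, 10)         # negative-binomial mean counts
    size <- runif(n, 2, 10)         # NB dispersion
    # Delta-method SD of log2(x + 1): var(log x) ~ 1/mu + 1/size.
    sdv <- sqrt(1 / mu + 1 / size) / log(2)
    list(ids = ids, mu = mu, size = size, sd = sdv)
  }
}

# Signed effect (SD units) per planted feature for a given cohort/class.
planted_shift_matrix <- function(cfg, modality, cohort, ids, classes,
                                 effect_scale = 1) {
  shift <- matrix(0, nrow = length(ids), ncol = length(classes),
                  dimnames = list(ids, NULL))
  for (pe in cfg$planted_effects) {
    if (pe$modality != modality) next
    j <- match(pe$feature_id, ids)
    if (is.na(j)) next
    e <- pe$effects[[cohort]] * effect_scale
    shift[j, classes == "case"] <- e
    # Non-glioma group: reversed features flip sign; other planted features
    # keep the glioma direction (so only the planted reversals look reversed).
    shift[j, classes == "nonglioma"] <- if (pe$type == "reversed") -e else e
  }
  shift
}

#' Generate a synthetic omics feature table
#'
#' Proteins are drawn log-normal (log2 abundances normal per feature); miRNA
#' are drawn negative-binomial and stored as log2(count + 1) expression.
#' Planted features are shifted by their signed effect (within-group SD
#' units) in cases; the cohort's affine batch distortion is then applied to
#' every feature, and measurements drop out (missing completely at random) at
#' the configured rate.
#'
#' @param cfg a [truth_config()].
#' @param modality `"protein"` or `"mirna"`.
#' @param cohort cohort name present in `cfg`.
#' @return a [feature_table()].
#' @export
generate_feature_table <- function(cfg, modality = c("protein", "mirna"),
                                   cohort) {
  modality <- match.arg(modality)
  generate_feature_table_impl(cfg, modality, cohort,
                              stream = 100L + 10L * cohort_index(cfg, cohort) +
                                modality_code(modality))
}

generate_feature_table_impl <- function(cfg, modality, cohort, stream,
                                        effect_scale = 1, timepoint = NA,
                                        id_suffix = "") {
  co <- cfg$cohorts[[cohort]]
  par <- feature_params(cfg, modality)
  set.seed(stream_seed(cfg$seed, stream))
  classes <- c(rep("control", co$n_control), rep("case", co$n_case),
               rep("nonglioma", co$n_nonglioma))
  sample_ids <- paste0(cohort, "_",
                       c(sprintf("control_%03d", seq_len(co$n_control)),
                         sprintf("case_%03d", seq_len(co$n_case)),
                         if (co$n_nonglioma > 0)
                           sprintf("nonglioma_%03d", seq_len(co$n_nonglioma))),
                       id_suffix)
  n_f <- length(par$ids)
  n_s <- length(classes)
  shift <- planted_shift_matrix(cfg, modality, cohort, par$ids, classes,
                                effect_scale)
  if (modality == "protein") {
    m <- matrix(rnorm(n_f * n_s, mean = par$mu + shift * par$sd,
                      sd = par$sd), nrow = n_f)
  } else {
    mu_shifted <- par$mu * 2^(shift * par$sd)
    counts <- matrix(rnbinom(n_f * n_s, mu = mu_shifted, size = par$size),
                     nrow = n_f)
    m <- log2(counts + 1)
  }
  m <- m * co$batch_scale + co$batch_offset
  if (cfg$dropout_rate > 0) {
    m[matrix(runif(n_f * n_s) < cfg$dropout_rate, nrow = n_f)] <- NA_real_
  }
  dimnames(m) <- list(par$ids, sample_ids)
  features <- data.frame(
    feature_id = par$ids, modality = modality,
    unique_peptides = if (modality == "protein") par$unique_peptides else NA_integer_,
    contaminant_class = "none", stringsAsFactors = FALSE
  )
  samples <- data.frame(sample_id = sample_ids, cohort = cohort,
                        class = classes, timepoint = timepoint,
                        stringsAsFactors = FALSE)
  feature_table(m, samples, features)
}

# Smooth class-independent base spectrum plus Gaussian peaks.
base_spectrum <- function(wn, peaks) {
  bg <- 0.1 + 0.2 * exp(-((wn - 1500) / 700)^2) +
    0.15 * exp(-((wn - 3050) / 500)^2)
  for (i in seq_len(nrow(peaks))) {
    bg <- bg + peaks$height[i] *
      exp(-((wn - peaks$center[i]) / peaks$width[i])^2)
  }
  bg
}

class_shift_spectrum <- function(wn, peaks) {
  s <- numeric(length(wn))
  for (i in seq_len(nrow(peaks))) {
    s <- s + peaks$class_shift[i] *
      exp(-((wn - peaks$center[i]) / peaks$width[i])^2)
  }
  s
}

#' Generate replicate infrared spectra for a cohort
#'
#' Each sample contributes `n_wells * n_scans` replicate spectra (default
#' 3 x 3 = 9). A replicate is
#' `m * (base + class shift + sample effect + well effect) + baseline + noise`
#' with multiplicative scatter `m` drawn uniformly from the configured range,
#' an order-2 polynomial baseline, a well-level additive intercept shared by
#' the scans of a well, and Gaussian noise. Full sample/well/scan lineage is
#' recorded.
#'
#' @param cfg a [truth_config()].
#' @param cohort cohort name present in `cfg`.
#' @return a [spectrum_set()].
#' @export
generate_spectra <- function(cfg, cohort) {
  generate_spectra_impl(cfg, cohort,
                        stream = 200L + cohort_index(cfg, cohort))
}

generate_spectra_impl <- function(cfg, cohort, stream, effect_scale = 1,
                                  timepoint = NA, id_suffix = "") {
  co <- cfg$cohorts[[cohort]]
  sp <- cfg$spectra
  if (sp$step <= 0) stop("wavenumber step must be positive", call. = FALSE)
  set.seed(stream_seed(cfg$seed, stream))
  wn <- seq(sp$wn_lo, sp$wn_hi, by = sp$step)
  base <- base_spectrum(wn, sp$peaks)
  cls_shift <- class_shift_spectrum(wn, sp$peaks) * effect_scale
  wtil <- 2 * (wn - min(wn)) / (max(wn) - min(wn)) - 1
  classes <- c(rep("control", co$n_control), rep("case", co$n_case))
  sample_ids <- paste0(cohort, "_",
                       c(sprintf("control_%03d", seq_len(co$n_control)),
                         sprintf("case_%03d", seq_len(co$n_case))),
                       id_suffix)
  n_rep <- sp$n_wells * sp$n_scans
  n_spec <- length(sample_ids) * n_rep
  intens <- matrix(0, nrow = n_spec, ncol = length(wn))
  meta <- vector("list", n_spec)
  row <- 0L
  for (i in seq_along(sample_ids)) {
    signal <- base + if (classes[i] == "case") cls_shift else 0
    samp_eff <- rnorm(1, 0, sp$sample_effect_sd)
    for (w in seq_len(sp$n_wells)) {
      well_eff <- rnorm(1, 0, sp$well_effect_sd)
      for (s in seq_len(sp$n_scans)) {
        row <- row + 1L
        m <- runif(1, sp$scatter_range[1], sp$scatter_range[2])
        coefs <- runif(3, sp$baseline_range[1], sp$baseline_range[2])
        baseline <- coefs[1] + coefs[2] * wtil + coefs[3] * wtil^2
        noise <- if (sp$noise_sd > 0) rnorm(length(wn), 0, sp$noise_sd) else 0
        intens[row, ] <- m * (signal + samp_eff + well_eff) + baseline + noise
        meta[[row]] <- data.frame(sample_id = sample_ids[i],
                                  well_id = paste0(sample_ids[i], "_w", w),
                                  scan_id = s, class = classes[i],
                                  timepoint = timepoint,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  spectrum_set(wn, intens, do.call(rbind, meta))
}

#' Generate per-sample particle size distributions
#'
#' Log-normal number densities binned on a regular nm grid and scaled to the
#' class total concentration. Default class medians are 121.6 nm (case) and
#' 100.5 nm (control) with totals 1.30e11 and 1.09e11 particles/mL; each
#' sample's median and total vary log-normally around its class value.
#'
#' @param cfg a [truth_config()].
#' @param cohort cohort name present in `cfg`.
#' @return list of [size_distribution()] objects (one per sample).
#' @export
generate_size_distributions <- function(cfg, cohort) {
  i_co <- cohort_index(cfg, cohort)
  co <- cfg$cohorts[[cohort]]
  sdist <- cfg$size_dist
  set.seed(stream_seed(cfg$seed, 300L + i_co))
  grid <- seq(sdist$grid_lo, sdist$grid_hi, by = sdist$grid_step)
  sdlog <- log(sdist$gsd)
  classes <- c(rep("control", co$n_control), rep("case", co$n_case))
  sample_ids <- paste0(cohort, "_",
                       c(sprintf("control_%03d", seq_len(co$n_control)),
                         sprintf("case_%03d", seq_len(co$n_case))))
  lapply(seq_along(sample_ids), function(i) {
    med <- (if (classes[i] == "case") sdist$case_median else
      sdist$control_median) * rlnorm(1, 0, sdist$median_sdlog)
    tot <- (if (classes[i] == "case") sdist$case_total else
      sdist$control_total) * rlnorm(1, 0, sdist$total_sdlog)
    dens <- tot * dlnorm(grid, meanlog = log(med), sdlog = sdlog)
    size_distribution(grid, dens, sample_id = sample_ids[i],
                      class = classes[i])
  })
}

# Effect multiplier for a longitudinal timepoint: the first timepoint is the
# pre-operative baseline (full effect), timepoints named "recurrence" use the
# re-divergence factor, all others are attenuated by the treatment factor.
timepoint_factor <- function(long, tp) {
  if (tp == long$timepoints[1]) 1
  else if (tp == "recurrence") long$recurrence_factor
  else 1 - long$attenuation
}

#' Generate the longitudinal arm of the synthetic study
#'
#' Re-samples the longitudinal cohort at every configured timepoint with the
#' planted effects multiplied by `1` pre-operatively, `1 - attenuation` on
#' treatment, and `recurrence_factor` at recurrence; spectra scale their
#' class peak shifts by the same factor. Controls are re-sampled at each
#' timepoint with no effect.
#'
#' @param cfg a [truth_config()] whose cohorts include `"longitudinal"`.
#' @return list with elements `protein` and `mirna` ([feature_table()]s
#'   spanning all timepoints) and `spectra` (a [spectrum_set()]).
#' @export
generate_longitudinal <- function(cfg) {
  long <- cfg$longitudinal
  if (!"longitudinal" %in% names(cfg$cohorts)) {
    stop("config has no 'longitudinal' cohort", call. = FALSE)
  }
  if (long$attenuation < 0 || long$attenuation > 1) {
    stop("attenuation must lie in [0, 1]", call. = FALSE)
  }
  tps <- long$timepoints
  tables <- list(protein = list(), mirna = list())
  spectra <- list()
  for (k in seq_along(tps)) {
    f <- timepoint_factor(long, tps[k])
    for (mod in c("protein", "mirna")) {
      tables[[mod]][[k]] <- generate_feature_table_impl(
        cfg, mod, "longitudinal",
        stream = 400L + 10L * k + modality_code(mod),
        effect_scale = f, timepoint = tps[k],
        id_suffix = paste0("_", tps[k]))
    }
    spectra[[k]] <- generate_spectra_impl(
      cfg, "longitudinal", stream = 500L + k, effect_scale = f,
      timepoint = tps[k], id_suffix = paste0("_", tps[k]))
  }
  bind_tables <- function(lst) {
    feature_table(do.call(cbind, lapply(lst, function(t) t$values)),
                  do.call(rbind, lapply(lst, function(t) t$samples)),
                  lst[[1]]$features)
  }
  bind_spectra <- function(lst) {
    spectrum_set(lst[[1]]$wavenumbers,
                 do.call(rbind, lapply(lst, function(s) s$intensities)),
                 do.call(rbind, lapply(lst, function(s) s$replicates)))
  }
  list(protein = bind_tables(tables$protein),
       mirna = bind_tables(tables$mirna),
       spectra = bind_spectra(spectra))
}
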