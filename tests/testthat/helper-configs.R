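# Shared synthetic-study configurations, kept small so the suite stays fast.

# Planted effects of one magnitude/type on consecutive protein features.
plant <- function(ids, cohorts, effect = 1.5, type = "concordant",
                  modality = "protein") {
  lapply(seq_along(ids), function(i) {
    e <- setNames(rep(effect[[((i - 1) %% length(effect)) + 1]],
                      length(cohorts)), cohorts)
    if (type == "discordant" && length(cohorts) >= 2) e[2] <- -e[2]
    planted_effect(ids[i], modality, e, type)
  })
}

# Single-cohort omics config with 10 planted features among noise.
omics_cfg <- function(seed = 1, n_case = 30, n_control = 30,
                      n_features = 60, dropout = 0, effect = 1.5,
                      n_planted = 10) {
  ids <- sprintf("prot_%04d", seq_len(n_planted))
  truth_config(
    seed = seed,
    cohorts = list(training = cohort_spec(n_case, n_control)),
    n_protein_features = n_features, n_mirna_features = 20,
    planted_effects = plant(ids, "training",
                            effect = effect * c(1, -1)),
    dropout_rate = dropout)
}

# Three-cohort config with the default concordant/discordant/reversed panel.
triage_cfg <- function(seed = 1, n = 30, dropout = 0) {
  truth_config(
    seed = seed,
    cohorts = list(
      training = cohort_spec(n, n),
      validation = cohort_spec(n, n, n_nonglioma = n),
      longitudinal = cohort_spec(n, n)),
    n_protein_features = 80, n_mirna_features = 40,
    dropout_rate = dropout)
}

# Spectral config on a coarse grid for fast ensemble fits.
spectra_cfg <- function(seed = 1, n_case = 12, n_control = 12, step = 8,
                        class_shift_scale = 1, noise_sd = 0.01) {
  peaks <- data.frame(
    center = c(1240, 1550, 1650, 2920, 3300),
    height = c(0.35, 0.5, 0.9, 0.35, 0.45),
    width = c(22, 22, 25, 20, 60),
    class_shift = class_shift_scale * c(0.06, 0.04, 0.08, 0.03, 0.02))
  truth_config(
    seed = seed,
    cohorts = list(training = cohort_spec(n_case, n_control),
                   longitudinal = cohort_spec(6, 6)),
    n_protein_features = 10, n_mirna_features = 10,
    planted_effects = plant("prot_0001", c("training", "longitudinal")),
    dropout_rate = 0,
    spectra = list(wn_lo = 900, wn_hi = 3600, step = step, peaks = peaks,
                   noise_sd = noise_sd))
}

# Hand-built feature table for contract tests.
toy_table <- function(values, classes, cohort = "training",
                      modality = "protein", unique_peptides = NULL,
                      contaminant_class = NULL) {
  n_f <- nrow(values)
  n_s <- ncol(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("f%02d", seq_len(n_f))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(n_s))
  }
  feature_table(
    values,
    data.frame(sample_id = colnames(values), cohort = cohort,
               class = classes, stringsAsFactors = FALSE),
    data.frame(feature_id = rownames(values), modality = modality,
               unique_peptides = unique_peptides %||% NA_integer_,
               contaminant_class = contaminant_class %||% "none",
               stringsAsFactors = FALSE))
}

# Hand-built spectrum set; by default one replicate per synthetic sample.
toy_spectra <- function(wn, X, sample_id = NULL, class = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  sample_id <- sample_id %||% sprintf("s%02d", seq_len(n))
  meta <- data.frame(sample_id = sample_id,
                     well_id = paste0(sample_id, "_w1"),
                     scan_id = 1L, stringsAsFactors = FALSE)
  if (!is.null(class)) meta$class <- class
  spectrum_set(wn, X, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
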