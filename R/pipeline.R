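# End-to-end orchestration of the workflow on a synthetic study:
# characterization -> spectral ensemble -> differential omics ->
# cross-cohort concordance -> machine-learning signatures. Each stage only
# chains the exported stage functions, so every number in the report can be
# recomputed by calling those functions directly with the same seed.

#' Pipeline run configuration
#'
#' @param truth a [truth_config()] describing the synthetic study (cohort
#'   sizes, planted effects, seed).
#' @param stages character subset of
#'   `c("characterization", "spectral", "omics", "concordance", "ml")`.
#' @param out_dir output directory (created if needed); `NULL` disables file
#'   output.
#' @param detection_min detection-fraction filter threshold.
#' @param signature_k signature size for RFE.
#' @param folds cross-validation folds in the ML stage.
#' @param n_outer,inner_folds spectral ensemble dimensions.
#' @param ncomp_grid PLS component grid for the spectral ensemble.
#' @param shuffle_repeats label-shuffle control repeats in the ML stage
#'   (0 skips the control).
#' @param holdout_ratio training fraction of the ML stage's stratified
#'   split.
#' @return object of class `run_config`.
#' @export
run_config <- function(truth = truth_config(), stages = c("characterization",
                                                          "spectral", "omics",
                                                          "concordance", "ml"),
                       out_dir = NULL, detection_min = 0.67,
                       signature_k = 10, folds = 5, n_outer = 51,
                       inner_folds = 5, ncomp_grid = 1:10,
                       shuffle_repeats = 0, holdout_ratio = 0.8) {
  stopifnot(inherits(truth, "truth_config"))
  known <- c("characterization", "spectral", "omics", "concordance", "ml")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (detection_min <= 0 || detection_min > 1) {
    stop("detection_min must lie in (0, 1]", call. = FALSE)
  }
  structure(list(truth = truth, stages = stages, out_dir = out_dir,
                 detection_min = detection_min, signature_k = signature_k,
                 folds = folds, n_outer = n_outer, inner_folds = inner_folds,
                 ncomp_grid = ncomp_grid, shuffle_repeats = shuffle_repeats,
                 holdout_ratio = holdout_ratio),
            class = "run_config")
}

#' Run the full workflow on a synthetic study
#'
#' Executes the toggled stages in order and returns a consolidated report:
#' particle characterization summaries with group comparisons, the spectral
#' ensemble's training ROC AUC, per-cohort differential counts, cross-cohort
#' concordance counts (with reversed-pattern detection when the study has a
#' non-glioma group), and the ML signature with holdout/external metrics.
#' When `out_dir` is set, per-stage tables, the JSON report and a
#' reproducibility manifest (seed + config) are written there. The report
#' contains no timestamps, so identical configs give identical reports.
#'
#' @param cfg a [run_config()].
#' @return the report, a named list keyed by stage.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  truth <- cfg$truth
  report <- list(seed = truth$seed, stages = cfg$stages)
  out <- cfg$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  first_cohort <- names(truth$cohorts)[1]

  if ("characterization" %in% cfg$stages) {
    dists <- generate_size_distributions(truth, first_cohort)
    summ <- do.call(rbind, lapply(dists, function(d) {
      s <- summarize_distribution(d)
      data.frame(sample_id = d$sample_id, class = d$class,
                 mean_nm = s$mean_nm, median_nm = s$median_nm,
                 total = s$total_particles_ml,
                 yield_over_80 = yield_above_threshold(d, 80),
                 stringsAsFactors = FALSE)
    }))
    cmp_median <- compare_groups(summ$median_nm, summ$class)
    cmp_yield <- compare_groups(summ$yield_over_80, summ$class)
    report$characterization <- list(
      n_samples = nrow(summ),
      median_nm = as.list(cmp_median$group_means),
      median_p = cmp_median$p_value, median_stars = cmp_median$stars,
      yield_over_80 = as.list(cmp_yield$group_means),
      yield_p = cmp_yield$p_value)
    if (!is.null(out)) {
      write.csv(summ, file.path(out, "characterization.csv"),
                row.names = FALSE)
    }
  }

  if ("spectral" %in% cfg$stages) {
    spectra <- generate_spectra(truth, first_cohort)
    model <- fit_spectral_ensemble(spectra, n_outer = cfg$n_outer,
                                   inner_folds = cfg$inner_folds,
                                   ncomp_grid = cfg$ncomp_grid,
                                   seed = truth$seed)
    roc <- ensemble_roc(model, spectra)
    report$spectral <- list(n_members = model$n_outer,
                            n_wavenumbers = length(model$wavenumbers),
                            training_auc = roc$auc)
    if (!is.null(out)) {
      write.csv(roc$roc, file.path(out, "spectral_roc.csv"),
                row.names = FALSE)
    }
  }

  diffs <- NULL
  if (any(c("omics", "concordance", "ml") %in% cfg$stages)) {
    tables <- list()
    for (mod in c("protein", "mirna")) {
      tables[[mod]] <- lapply(setNames(nm = names(truth$cohorts)), function(co)
        generate_feature_table(truth, mod, co))
    }
  }

  if (any(c("omics", "concordance") %in% cfg$stages)) {
    diffs <- list()
    omics_report <- list()
    for (mod in c("protein", "mirna")) {
      diffs[[mod]] <- list()
      for (co in names(truth$cohorts)) {
        t_f <- remove_contaminants(detection_filter(tables[[mod]][[co]],
                                                    cfg$detection_min))
        diffs[[mod]][[co]] <- differential(t_f)
        omics_report[[paste(mod, co, sep = "_")]] <- list(
          n_features_tested = sum(diffs[[mod]][[co]]$testable),
          n_dropped_detection =
            nrow(attr(t_f, "dropped_features") %||% data.frame()),
          n_q_lt_0.05 = sum(diffs[[mod]][[co]]$q < 0.05, na.rm = TRUE))
        if (!is.null(out)) {
          write_differential(diffs[[mod]][[co]],
                             file.path(out, paste0("diff_", mod, "_", co,
                                                   ".tsv")))
        }
      }
    }
    if ("omics" %in% cfg$stages) report$omics <- omics_report
  }

  if ("concordance" %in% cfg$stages) {
    conc_report <- list()
    for (mod in c("protein", "mirna")) {
      records <- classify_concordance(diffs[[mod]])
      counts <- concordance_counts(records)
      entry <- list(counts = as.list(counts))
      contrast_cohort <- names(Filter(function(co) co$n_nonglioma > 0,
                                      truth$cohorts))
      if (length(contrast_cohort)) {
        contrast <- differential(tables[[mod]][[contrast_cohort[1]]],
                                 groups = c("control", "nonglioma"))
        rev <- reversed_pattern(records, contrast)
        entry$reversed <- rev$reversed
      }
      tier_name <- if (mod == "protein") "protein_stringent" else
        "mirna_stringent"
      tiers <- tier_candidates(diffs[[mod]][[first_cohort]],
                               default_tier_rules()[tier_name])
      ti <- tier_intersection(records, tiers, tier_name)
      entry$tiered_concordant <- as.list(ti$sizes)
      entry$concordant_features <- ti$concordant
      conc_report[[mod]] <- entry
      if (!is.null(out)) {
        jsonlite::write_json(entry, file.path(out, paste0("concordance_",
                                                          mod, ".json")),
                             auto_unbox = TRUE, digits = NA)
      }
    }
    report$concordance <- conc_report
  }

  if ("ml" %in% cfg$stages) {
    ml_report <- list()
    train_tab <- tables$protein[[first_cohort]]
    merged <- multimodal_merge(tables$protein[[first_cohort]],
                               tables$mirna[[first_cohort]])
    for (setting in list(list(name = "protein", tab = train_tab),
                         list(name = "multimodal", tab = merged))) {
      z <- zscore_by_cohort(setting$tab, impute = "zero")
      parts <- split_holdout(z, ratio = cfg$holdout_ratio, seed = truth$seed)
      sel <- rfe_top_k(parts$train, k = cfg$signature_k, seed = truth$seed)
      sig <- train_select(subset_feature_table(
        parts$train, features = match(sel, rownames(parts$train$values))),
        folds = cfg$folds, seed = truth$seed)
      hold <- evaluate_signature(
        sig, subset_feature_table(parts$holdout,
                                  features = match(sel,
                                                   rownames(parts$holdout$values))))
    entry <- list(features = sig$features, learner = sig$learner,
                  cv_auc_mean = unname(sig$metrics$mean["auc"]),
                  cv_auc_sd = unname(sig$metrics$sd["auc"]),
                  holdout_accuracy = hold$confusion$accuracy,
                  holdout_auc = hold$auc)
      if (cfg$shuffle_repeats > 0) {
        sc <- shuffle_control(z, learner = sig$learner,
                              repeats = cfg$shuffle_repeats,
                              k = cfg$signature_k, folds = cfg$folds,
                              seed = truth$seed)
        entry$shuffle_mean_auc <- sc$mean_auc
      }
      ml_report[[setting$name]] <- entry
    }
    report$ml <- ml_report
  }

  if (!is.null(out)) {
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_truth_manifest(truth, file.path(out, "manifest.json"))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
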