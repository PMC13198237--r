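# Replicate-aware spectral ensemble classifier. 51 outer repeats of a
# class-stratified 70:30 split at the sample level; an inner sample-level
# 5-fold cross-validation selects the PLS component count; consensus is
# hierarchical: majority vote across a sample's replicate spectra within
# each member, then across the ensemble. Replicates of one sample never
# straddle a train/test boundary, at either cross-validation level.

#' Fit the spectral ensemble classifier
#'
#' Preprocessing (truncation, EMSC against a frozen mean reference,
#' silent-region removal) is applied internally and its parameters are
#' frozen into the model so held-out data is transformed identically. Each
#' ensemble member is a PLS1 regression on 0/1-coded labels with a 0.5
#' decision threshold; its component count is chosen by inner
#' cross-validated mean AUC over `ncomp_grid`.
#'
#' @param spectra a [spectrum_set()] with full replicate lineage.
#' @param labels per-sample class labels (named by sample id), or `NULL` to
#'   use the `class` column of the replicate metadata. Exactly two classes.
#' @param n_outer number of outer 70:30 repeats (default 51).
#' @param inner_folds inner cross-validation folds (default 5).
#' @param ncomp_grid candidate PLS component counts.
#' @param positive label of the positive class (default `"case"`).
#' @param outer_ratio training fraction of the outer split.
#' @param poly_order EMSC baseline order.
#' @param truncate_range,silent_band preprocessing windows (cm^-1).
#' @param seed run seed; member `i` uses the derived stream `seed + 1000 + i`.
#' @return object of class `EnsembleModel`.
#' @export
fit_spectral_ensemble <- function(spectra, labels = NULL, n_outer = 51,
                                  inner_folds = 5, ncomp_grid = 1:10,
                                  positive = "case", outer_ratio = 0.7,
                                  poly_order = 2,
                                  truncate_range = c(1000, 3500),
                                  silent_band = c(1801, 2799), seed = 1) {
  stopifnot(inherits(spectra, "SpectrumSet"), n_outer >= 1, inner_folds >= 2)
  rep_labels <- resolve_replicate_labels(spectra, labels)
  classes <- sort(unique(rep_labels))
  if (length(classes) != 2L) stop("exactly two classes required", call. = FALSE)
  if (!positive %in% classes) {
    stop("positive class '", positive, "' not among labels", call. = FALSE)
  }

  trunc <- truncate_spectra(spectra, truncate_range[1], truncate_range[2])
  reference <- colMeans(trunc$intensities)
  prep <- remove_silent(
    emsc_correct(trunc, reference = reference,
                 poly_order = poly_order)$spectra, silent_band)

  X <- prep$intensities
  sample_of_row <- prep$replicates$sample_id
  samples <- unique(sample_of_row)
  sample_class <- vapply(samples, function(s)
    rep_labels[match(s, sample_of_row)], character(1))
  if (any(table(sample_class) < 2L)) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  y <- as.numeric(rep_labels == positive)
  rows_of_sample <- split(seq_along(sample_of_row), sample_of_row)[samples]

  members <- vector("list", n_outer)
  for (i in seq_len(n_outer)) {
    set.seed(stream_seed(seed, 1000L + i))
    tr_idx <- stratified_split_idx(sample_class, outer_ratio)
    train_samples <- samples[tr_idx]
    test_samples <- setdiff(samples, train_samples)
    # leakage contract: sample sets disjoint, every sample on exactly one side
    stopifnot(length(intersect(train_samples, test_samples)) == 0L,
              length(train_samples) + length(test_samples) == length(samples))
    fold_of_sample <- stratified_fold_ids(sample_class[tr_idx], inner_folds)
    names(fold_of_sample) <- train_samples
    fold_auc <- matrix(NA_real_, inner_folds, length(ncomp_grid))
    for (f in seq_len(inner_folds)) {
      fit_samples <- train_samples[fold_of_sample != f]
      val_samples <- train_samples[fold_of_sample == f]
      stopifnot(length(intersect(fit_samples, val_samples)) == 0L)
      fit_rows <- unlist(rows_of_sample[fit_samples], use.names = FALSE)
      val_rows <- unlist(rows_of_sample[val_samples], use.names = FALSE)
      fit <- pls1_fit(X[fit_rows, , drop = FALSE], y[fit_rows],
                      max(ncomp_grid))
      usable <- ncomp_grid[ncomp_grid <= fit$ncomp]
      pred <- predict(fit, X[val_rows, , drop = FALSE], ncomp = usable)
      pos <- y[val_rows] == 1
      if (any(pos) && any(!pos)) {
        for (ci in seq_along(usable)) {
          fold_auc[f, match(usable[ci], ncomp_grid)] <-
            auc_rank(pred[, ci], pos)
        }
      }
    }
    mean_auc <- colMeans(fold_auc, na.rm = TRUE)
    best_ncomp <- ncomp_grid[which.max(mean_auc)]
    train_rows <- unlist(rows_of_sample[train_samples], use.names = FALSE)
    fit <- pls1_fit(X[train_rows, , drop = FALSE], y[train_rows], best_ncomp)
    fit$B <- fit$B[, fit$ncomp, drop = FALSE]   # keep final coefficients only
    fit$ncomp <- 1L
    members[[i]] <- list(train_samples = train_samples,
                         test_samples = test_samples,
                         inner_fold_of_sample = fold_of_sample,
                         ncomp = best_ncomp, inner_mean_auc = mean_auc,
                         fit = fit)
  }
  structure(list(members = members, n_outer = n_outer,
                 inner_folds = inner_folds, positive = positive,
                 classes = classes, reference = reference,
                 poly_order = poly_order, truncate_range = truncate_range,
                 silent_band = silent_band,
                 wavenumbers_input = trunc$wavenumbers,
                 wavenumbers = prep$wavenumbers, seed = seed),
            class = "EnsembleModel")
}

#' @export
print.EnsembleModel <- function(x, ...) {
  cat("<EnsembleModel> ", x$n_outer, " PLS members (inner ", x$inner_folds,
      "-fold), positive class '", x$positive, "'\n", sep = "")
  cat("  grid: ", length(x$wavenumbers), " wavenumbers after preprocessing\n",
      sep = "")
  invisible(x)
}

# Apply the model's frozen preprocessing to new spectra.
preprocess_for_model <- function(model, spectra) {
  trunc <- truncate_spectra(spectra, model$truncate_range[1],
                            model$truncate_range[2])
  if (!isTRUE(all.equal(trunc$wavenumbers, model$wavenumbers_input))) {
    stop("wavenumber grid mismatch with the fitted model", call. = FALSE)
  }
  prep <- remove_silent(
    emsc_correct(trunc, reference = model$reference,
                 poly_order = model$poly_order)$spectra, model$silent_band)
  stopifnot(isTRUE(all.equal(prep$wavenumbers, model$wavenumbers)))
  prep
}

#' Hierarchical consensus prediction
#'
#' For every ensemble member, each replicate spectrum is classified
#' (PLS score > 0.5); a sample's call within the member is the majority of
#' its replicate calls (ties resolve to the positive class). The ensemble
#' probability is the fraction of members calling the sample positive, and
#' the ensemble class is positive when the probability reaches 0.5.
#'
#' @param model an [fit_spectral_ensemble()] model.
#' @param spectra a [spectrum_set()] on the model's input grid (raw; the
#'   model's frozen preprocessing is applied internally).
#' @return data.frame with one row per sample: `sample_id`, `probability`,
#'   `class`, `votes_positive`, `n_members`.
#' @export
predict_consensus <- function(model, spectra) {
  stopifnot(inherits(model, "EnsembleModel"))
  prep <- preprocess_for_model(model, spectra)
  X <- prep$intensities
  sample_of_row <- prep$replicates$sample_id
  samples <- unique(sample_of_row)
  rows_of_sample <- split(seq_along(sample_of_row), sample_of_row)[samples]
  votes <- matrix(0L, nrow = length(samples), ncol = model$n_outer,
                  dimnames = list(samples, NULL))
  for (i in seq_len(model$n_outer)) {
    score <- predict(model$members[[i]]$fit, X)
    call_pos <- score > 0.5
    votes[, i] <- vapply(rows_of_sample, function(rows)
      as.integer(mean(call_pos[rows]) >= 0.5), integer(1))
  }
  prob <- rowMeans(votes)
  data.frame(sample_id = samples, probability = prob,
             class = ifelse(prob >= 0.5, model$positive,
                            setdiff(model$classes, model$positive)),
             votes_positive = rowSums(votes), n_members = model$n_outer,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ensemble ROC curve
#'
#' Sweeps the ensemble vote fraction as the decision score and reports the
#' ROC curve plus its trapezoid-rule AUC.
#'
#' @param model an [fit_spectral_ensemble()] model.
#' @param spectra a [spectrum_set()] to score.
#' @param labels per-sample labels (named), or `NULL` to use replicate
#'   metadata. Both classes must be present.
#' @return list with `roc` (data.frame `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
ensemble_roc <- function(model, spectra, labels = NULL) {
  pred <- predict_consensus(model, spectra)
  rep_labels <- resolve_replicate_labels(spectra, labels)
  lab <- vapply(pred$sample_id, function(s)
    rep_labels[match(s, spectra$replicates$sample_id)], character(1))
  pos <- lab == model$positive
  if (all(pos) || !any(pos)) {
    stop("AUC undefined: labels contain a single class", call. = FALSE)
  }
  roc_from_scores(pred$probability, pos)
}

# ROC sweep over unique score thresholds; trapezoid AUC (ties get half
# credit, matching the rank/pair-counting AUC).
roc_from_scores <- function(scores, positive) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[positive] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!positive] >= t), numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] < 1 || roc$tpr[nrow(roc)] < 1) {
    roc <- rbind(roc, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  list(roc = roc, auc = trapz(roc$fpr, roc$tpr))
}

#' Longitudinal trajectory of ensemble probabilities
#'
#' Groups consensus probabilities by ordered timepoint and reports the mean
#' trajectory alongside per-sample values.
#'
#' @param model an [fit_spectral_ensemble()] model.
#' @param spectra a [spectrum_set()] whose replicate metadata carries a
#'   `timepoint` column.
#' @param timepoint_order explicit ordering of timepoints; defaults to order
#'   of first appearance. Observed timepoints outside this ordering are an
#'   error.
#' @return list with `trajectory` (data.frame `timepoint`,
#'   `mean_probability`, `n_samples`) and `per_sample`.
#' @export
longitudinal_trajectory <- function(model, spectra, timepoint_order = NULL) {
  tp_of_rep <- spectra$replicates$timepoint
  if (is.null(tp_of_rep) || anyNA(tp_of_rep)) {
    stop("replicate metadata lacks timepoints", call. = FALSE)
  }
  pred <- predict_consensus(model, spectra)
  tp <- vapply(pred$sample_id, function(s)
    as.character(tp_of_rep[match(s, spectra$replicates$sample_id)]),
    character(1))
  if (is.null(timepoint_order)) timepoint_order <- unique(tp_of_rep)
  unknown <- setdiff(unique(tp), timepoint_order)
  if (length(unknown)) {
    stop("timepoint(s) outside the given ordering: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  per_sample <- data.frame(sample_id = pred$sample_id,
                           timepoint = factor(tp, levels = timepoint_order),
                           probability = pred$probability,
                           stringsAsFactors = FALSE)
  observed <- timepoint_order[timepoint_order %in% tp]
  traj <- data.frame(
    timepoint = observed,
    mean_probability = vapply(observed, function(t)
      mean(per_sample$probability[tp == t]), numeric(1)),
    n_samples = vapply(observed, function(t) sum(tp == t), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(trajectory = traj, per_sample = per_sample)
}
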