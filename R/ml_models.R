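# Harmonized multi-cohort signature learning: per-cohort z-scoring, PCA
# batch check, recursive feature elimination to a compact signature,
# grid-searched random forest / kNN / gradient boosting with stratified
# 5-fold cross-validation, best-model selection (max mean AUC, ties by min
# SD, then fixed learner order), holdout evaluation, and the 50% label
# shuffle chance control.

#' Z-score features within each cohort
#'
#' Per cohort and feature: subtract the cohort mean and divide by the cohort
#' sample SD. Any affine per-cohort batch distortion (scale then offset) is
#' removed exactly. Zero-variance features are set to 0 and flagged.
#'
#' @param t a [feature_table()].
#' @param impute `"none"` (keep missing values) or `"zero"` (set missing
#'   values to 0, the cohort mean, after scaling).
#' @return z-scored [feature_table()]; attribute `"zero_variance"` lists
#'   flagged cohort/feature pairs.
#' @export
zscore_by_cohort <- function(t, impute = c("none", "zero")) {
  stopifnot(inherits(t, "FeatureTable"))
  impute <- match.arg(impute)
  v <- t$values
  flagged <- list()
  for (co in unique(t$samples$cohort)) {
    cols <- which(t$samples$cohort == co)
    if (length(cols) < 2L) {
      stop("cohort '", co, "' has a single sample; cannot z-score",
           call. = FALSE)
    }
    block <- v[, cols, drop = FALSE]
    mu <- rowMeans(block, na.rm = TRUE)
    sdv <- apply(block, 1L, sd, na.rm = TRUE)
    zero <- !is.na(sdv) & sdv == 0
    sdv[zero | is.na(sdv)] <- 1
    z <- (block - mu) / sdv
    z[zero, ] <- 0
    v[, cols] <- z
    if (any(zero)) {
      flagged[[co]] <- t$features$feature_id[zero]
    }
  }
  if (impute == "zero") v[is.na(v)] <- 0
  out <- feature_table(v, t$samples, t$features)
  attr(out, "zero_variance") <- flagged
  out
}

#' PCA batch-effect check
#'
#' Projects samples onto the top principal components and scores how
#' separated the cohorts are in the PC1/PC2 plane with the mean silhouette
#' width of the cohort labels. Values near 0 mean the cohorts are well
#' mixed (no residual batch effect); values above ~0.5 indicate strong
#' cohort structure.
#'
#' @param t a [feature_table()] with at least two cohorts and no missing
#'   values (z-score with `impute = "zero"` first if needed).
#' @param n_pc components to return (silhouette always uses the first two).
#' @return list with `scores` (samples x PCs), `variance_explained` and
#'   `silhouette` (mean cohort silhouette width).
#' @export
batch_check <- function(t, n_pc = 2) {
  stopifnot(inherits(t, "FeatureTable"))
  cohorts <- t$samples$cohort
  if (length(unique(cohorts)) < 2L) {
    stop("batch check needs at least two cohorts", call. = FALSE)
  }
  if (anyNA(t$values)) {
    stop("missing values present; z-score with impute = 'zero' first",
         call. = FALSE)
  }
  X <- t(t$values)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  n_pc <- min(n_pc, ncol(pc$x))
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  sil <- cluster::silhouette(as.integer(factor(cohorts)),
                             dist(pc$x[, 1:2, drop = FALSE]))
  list(scores = scores,
       variance_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_pc)],
       silhouette = mean(sil[, "sil_width"]))
}

#' Recursive feature elimination to the top k features
#'
#' Backward elimination dropping one feature per step, scored by the base
#' learner's native importance (mean decrease in Gini impurity of a random
#' forest), until `k` features remain. A tree-based importance is used
#' regardless of the final classification learner. Deterministic given the
#' seed.
#'
#' @param t a [feature_table()] (no missing values).
#' @param labels per-sample class labels, or `NULL` to use metadata.
#'   Exactly two classes.
#' @param k features to retain.
#' @param ntree trees per elimination step.
#' @param seed RNG seed for the forest fits.
#' @return character vector of `k` feature ids ranked by final importance,
#'   strongest first.
#' @export
rfe_top_k <- function(t, labels = NULL, k = 10, ntree = 100, seed = 1) {
  stopifnot(inherits(t, "FeatureTable"))
  y <- resolve_sample_labels(t, labels)
  if (length(unique(y)) != 2L) stop("exactly two classes required", call. = FALSE)
  if (k > nrow(t$values)) {
    stop("k (", k, ") exceeds the number of features (", nrow(t$values), ")",
         call. = FALSE)
  }
  if (anyNA(t$values)) stop("missing values present; impute first", call. = FALSE)
  set.seed(stream_seed(seed, 3L))
  X <- base::t(t$values)
  yf <- factor(y)
  remaining <- colnames(X)
  imp <- NULL
  while (length(remaining) >= k) {
    fit <- randomForest::randomForest(X[, remaining, drop = FALSE], yf,
                                      ntree = ntree)
    imp <- fit$importance[, "MeanDecreaseGini"]
    if (length(remaining) == k) break
    remaining <- remaining[-which.min(imp)]
  }
  remaining[order(imp, decreasing = TRUE)]
}

#' Default hyperparameter grids
#'
#' Random forest: trees in \{100, 500\}, feature fraction per split in
#' \{sqrt(p), 0.5 p\}. kNN: k in \{3, 5, 7, 9, 11\}. Gradient boosting:
#' rounds in \{100, 300\}, depth in \{2, 4\}, learning rate in \{0.1, 0.3\}.
#'
#' @return named list of data.frame grids keyed by learner.
#' @export
default_grids <- function() {
  list(
    random_forest = expand.grid(ntree = c(100, 500),
                                mtry_rule = c("sqrt", "half"),
                                stringsAsFactors = FALSE),
    knn = data.frame(k = c(3, 5, 7, 9, 11)),
    gradient_boosting = expand.grid(nrounds = c(100, 300),
                                    max_depth = c(2, 4), eta = c(0.1, 0.3))
  )
}

# Fit one learner configuration and return P(positive) on Xte.
fit_predict_learner <- function(learner, params, Xtr, ytr, Xte, positive) {
  ytr <- as.character(ytr)
  if (learner == "random_forest") {
    p <- ncol(Xtr)
    mtry <- if (params$mtry_rule == "sqrt") max(1L, floor(sqrt(p)))
            else max(1L, floor(0.5 * p))
    fit <- randomForest::randomForest(Xtr, factor(ytr), ntree = params$ntree,
                                      mtry = mtry)
    unname(predict(fit, Xte, type = "prob")[, positive])
  } else if (learner == "knn") {
    pred <- class::knn(Xtr, Xte, factor(ytr), k = params$k, prob = TRUE)
    pr <- attr(pred, "prob")
    ifelse(as.character(pred) == positive, pr, 1 - pr)
  } else if (learner == "gradient_boosting") {
    dtr <- xgboost::xgb.DMatrix(Xtr, label = as.numeric(ytr == positive))
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = params$max_depth,
                    eta = params$eta, nthread = 1),
      data = dtr, nrounds = params$nrounds, verbose = 0)
    predict(fit, xgboost::xgb.DMatrix(Xte))
  } else {
    stop("unknown learner '", learner, "'", call. = FALSE)
  }
}

# Refit a learner configuration on the full training data; returns an object
# predict_signature() can apply.
refit_learner <- function(learner, params, X, y, positive) {
  if (learner == "knn") {
    list(learner = learner, params = params, X = X, y = as.character(y),
         positive = positive)
  } else if (learner == "random_forest") {
    p <- ncol(X)
    mtry <- if (params$mtry_rule == "sqrt") max(1L, floor(sqrt(p)))
            else max(1L, floor(0.5 * p))
    list(learner = learner, params = params, positive = positive,
         fit = randomForest::randomForest(X, factor(as.character(y)),
                                          ntree = params$ntree, mtry = mtry))
  } else {
    dtr <- xgboost::xgb.DMatrix(X, label = as.numeric(y == positive))
    list(learner = learner, params = params, positive = positive,
         fit = xgboost::xgb.train(
           params = list(objective = "binary:logistic",
                         max_depth = params$max_depth, eta = params$eta,
                         nthread = 1),
           data = dtr, nrounds = params$nrounds, verbose = 0))
  }
}

predict_signature_prob <- function(model, Xte) {
  if (model$learner == "knn") {
    pred <- class::knn(model$X, Xte, factor(model$y), k = model$params$k,
                       prob = TRUE)
    pr <- attr(pred, "prob")
    ifelse(as.character(pred) == model$positive, pr, 1 - pr)
  } else if (model$learner == "random_forest") {
    unname(predict(model$fit, Xte, type = "prob")[, model$positive])
  } else {
    predict(model$fit, xgboost::xgb.DMatrix(Xte))
  }
}

# Per-fold classification metrics at the 0.5 probability threshold.
fold_metrics <- function(prob, truth_pos) {
  pred_pos <- prob >= 0.5
  tp <- sum(pred_pos & truth_pos); fp <- sum(pred_pos & !truth_pos)
  tn <- sum(!pred_pos & !truth_pos); fn <- sum(!pred_pos & truth_pos)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  c(auc = auc_rank(prob, truth_pos), accuracy = (tp + tn) / length(prob),
    precision = precision, recall = recall, f1 = f1)
}

# Cross-validated metrics for one learner configuration with a fixed fold
# assignment (shared across configurations for comparability).
cv_config_metrics <- function(learner, params, X, y, fold_id, positive,
                              seed) {
  folds <- sort(unique(fold_id))
  per_fold <- matrix(NA_real_, length(folds), 5,
                     dimnames = list(NULL, c("auc", "accuracy", "precision",
                                             "recall", "f1")))
  for (f in folds) {
    tr <- fold_id != f
    set.seed(stream_seed(seed, 100L * f + 7L))
    prob <- fit_predict_learner(learner, params, X[tr, , drop = FALSE], y[tr],
                                X[!tr, , drop = FALSE], positive)
    per_fold[f, ] <- fold_metrics(prob, y[!tr] == positive)
  }
  list(mean = colMeans(per_fold, na.rm = TRUE),
       sd = apply(per_fold, 2L, sd, na.rm = TRUE),
       per_fold = per_fold)
}

#' Grid-search learners and select the best model
#'
#' For each learner, every grid configuration is scored by stratified
#' k-fold cross-validated mean AUC (with accuracy, precision, recall and F1
#' reported alongside, each as mean and SD over folds). The winner is the
#' configuration/learner with the highest mean AUC; ties break to the
#' lowest AUC SD, then to the fixed learner order given in `learners`.
#'
#' @param t a z-scored [feature_table()] restricted to the training portion
#'   (use [split_holdout()] first) and to the selected features.
#' @param labels per-sample labels or `NULL` for metadata. Two classes.
#' @param learners learners to try, in tie-break order.
#' @param folds cross-validation folds.
#' @param grids named list of hyperparameter grids (default
#'   [default_grids()]).
#' @param positive positive class label.
#' @param seed RNG seed (fold assignment and learner fits derive from it).
#' @return object of class `Signature`: selected features, winning learner
#'   and hyperparameters, the fitted model, and the full metric table.
#' @export
train_select <- function(t, labels = NULL,
                         learners = c("random_forest", "knn",
                                      "gradient_boosting"),
                         folds = 5, grids = default_grids(),
                         positive = "case", seed = 1) {
  stopifnot(inherits(t, "FeatureTable"))
  y <- resolve_sample_labels(t, labels)
  if (length(unique(y)) != 2L) stop("exactly two classes required", call. = FALSE)
  if (!positive %in% y) stop("positive class absent from labels", call. = FALSE)
  if (anyNA(t$values)) stop("missing values present; impute first", call. = FALSE)
  X <- base::t(t$values)
  set.seed(stream_seed(seed, 11L))
  fold_id <- stratified_fold_ids(y, folds)
  results <- list()
  for (learner in learners) {
    grid <- grids[[learner]]
    if (is.null(grid)) stop("no grid for learner '", learner, "'", call. = FALSE)
    for (g in seq_len(nrow(grid))) {
      cm <- cv_config_metrics(learner, grid[g, , drop = FALSE], X, y, fold_id,
                              positive, stream_seed(seed, 13L * g))
      results[[length(results) + 1L]] <- list(
        learner = learner, params = grid[g, , drop = FALSE], metrics = cm)
    }
  }
  summary_df <- do.call(rbind, lapply(results, function(r) {
    data.frame(learner = r$learner,
               params = paste(names(r$params), unlist(r$params), sep = "=",
                              collapse = ","),
               auc_mean = r$metrics$mean["auc"], auc_sd = r$metrics$sd["auc"],
               accuracy_mean = r$metrics$mean["accuracy"],
               precision_mean = r$metrics$mean["precision"],
               recall_mean = r$metrics$mean["recall"],
               f1_mean = r$metrics$mean["f1"],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  # selection: max mean AUC -> min AUC SD -> fixed learner order -> grid order
  learner_rank <- match(summary_df$learner, learners)
  ord <- order(-summary_df$auc_mean, summary_df$auc_sd, learner_rank)
  best <- results[[ord[1]]]
  set.seed(stream_seed(seed, 17L))
  model <- refit_learner(best$learner, best$params, X, y, positive)
  structure(list(features = rownames(t$values), learner = best$learner,
                 hyperparameters = as.list(best$params), model = model,
                 metrics = list(mean = best$metrics$mean,
                                sd = best$metrics$sd,
                                per_fold = best$metrics$per_fold),
                 all_results = summary_df, positive = positive,
                 classes = sort(unique(y)), folds = folds, seed = seed),
            class = "Signature")
}

#' @export
print.Signature <- function(x, ...) {
  cat("<Signature> ", length(x$features), " features; learner ", x$learner,
      " (", paste(names(x$hyperparameters), unlist(x$hyperparameters),
                  sep = "=", collapse = ", "), ")\n", sep = "")
  cat("  CV AUC ", round(x$metrics$mean["auc"], 3), " +/- ",
      round(x$metrics$sd["auc"], 3), " over ", x$folds, " folds\n", sep = "")
  invisible(x)
}

#' Stratified train/holdout split
#'
#' Class-stratified partition of the samples; per-class proportions are
#' within one sample of the requested ratio. Deterministic given the seed.
#'
#' @param t a [feature_table()].
#' @param labels per-sample labels or `NULL` for metadata.
#' @param ratio training fraction in `(0, 1)`.
#' @param seed RNG seed.
#' @return list of [feature_table()]s `train` and `holdout`.
#' @export
split_holdout <- function(t, labels = NULL, ratio = 0.8, seed = 1) {
  stopifnot(inherits(t, "FeatureTable"))
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)", call. = FALSE)
  y <- resolve_sample_labels(t, labels)
  set.seed(stream_seed(seed, 5L))
  tr <- stratified_split_idx(y, ratio)
  list(train = subset_feature_table(t, samples = tr),
       holdout = subset_feature_table(t, samples = setdiff(seq_along(y), tr)))
}

#' Evaluate a signature on a cohort
#'
#' Applies the frozen model to the signature's features (the table should be
#' z-scored within its own cohort) and reports the confusion matrix at the
#' 0.5 probability threshold. AUC is reported when both classes are present,
#' otherwise accuracy alone (e.g. an all-case external cohort).
#'
#' @param sig a [train_select()] signature.
#' @param t a [feature_table()] containing the signature's features.
#' @param labels per-sample labels or `NULL` for metadata.
#' @return list with `confusion` (class `ConfusionMatrix`), `auc` (or `NA`),
#'   and per-sample `probabilities`.
#' @export
evaluate_signature <- function(sig, t, labels = NULL) {
  stopifnot(inherits(sig, "Signature"), inherits(t, "FeatureTable"))
  missing <- setdiff(sig$features, rownames(t$values))
  if (length(missing)) {
    stop("table lacks signature feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  y <- resolve_sample_labels(t, labels)
  X <- base::t(t$values[sig$features, , drop = FALSE])
  if (anyNA(X)) stop("missing values present; impute first", call. = FALSE)
  prob <- predict_signature_prob(sig$model, X)
  truth_pos <- y == sig$positive
  pred_pos <- prob >= 0.5
  cm <- structure(list(
    tp = sum(pred_pos & truth_pos), fp = sum(pred_pos & !truth_pos),
    tn = sum(!pred_pos & !truth_pos), fn = sum(!pred_pos & truth_pos)),
    class = "ConfusionMatrix")
  cm$accuracy <- (cm$tp + cm$tn) / length(prob)
  cm$sensitivity <- if (any(truth_pos)) cm$tp / sum(truth_pos) else NA_real_
  cm$specificity <- if (any(!truth_pos)) cm$tn / sum(!truth_pos) else NA_real_
  auc <- if (any(truth_pos) && any(!truth_pos)) {
    auc_rank(prob, truth_pos)
  } else NA_real_
  list(confusion = cm, auc = auc,
       probabilities = setNames(prob, t$samples$sample_id))
}

#' @export
print.ConfusionMatrix <- function(x, ...) {
  cat("<ConfusionMatrix> TP ", x$tp, " FP ", x$fp, " TN ", x$tn, " FN ",
      x$fn, "\n  accuracy ", round(x$accuracy, 3), ", sensitivity ",
      round(x$sensitivity, 3), ", specificity ", round(x$specificity, 3),
      "\n", sep = "")
  invisible(x)
}

#' Nested cross-validated pipeline AUC for one learner
#'
#' Runs the signature pipeline for a single learner with feature selection
#' nested inside the cross-validation: for every fold, RFE picks `k`
#' features from the fold's training portion only, each grid configuration
#' is fit on those features and scored on the held-out fold, and the best
#' configuration's mean fold AUC is returned. Nesting the selection keeps
#' the estimate free of feature-selection bias, which is what lets the
#' label-shuffle control sit at chance (~0.5) when the labels carry no
#' signal.
#'
#' @param t a z-scored [feature_table()].
#' @param labels per-sample labels or `NULL` for metadata.
#' @param learner one of the [default_grids()] learners.
#' @param k signature size for RFE.
#' @param folds cross-validation folds.
#' @param grids hyperparameter grids.
#' @param positive positive class label.
#' @param seed RNG seed.
#' @param rfe_ntree trees per RFE elimination step.
#' @param config optional single hyperparameter configuration (a one-row
#'   data.frame or named list); when given, only that configuration is
#'   cross-validated instead of searching the learner's grid. Fixing the
#'   configuration avoids the small optimism of taking the best of several
#'   grid points.
#' @return best mean CV AUC (numeric scalar).
#' @export
signature_cv_auc <- function(t, labels = NULL, learner = "random_forest",
                             k = 10, folds = 5, grids = default_grids(),
                             positive = "case", seed = 1, rfe_ntree = 100,
                             config = NULL) {
  stopifnot(inherits(t, "FeatureTable"))
  y <- resolve_sample_labels(t, labels)
  grid <- if (!is.null(config)) as.data.frame(config) else grids[[learner]]
  if (is.null(grid)) stop("no grid for learner '", learner, "'", call. = FALSE)
  set.seed(stream_seed(seed, 11L))
  fold_id <- stratified_fold_ids(y, folds)
  auc <- matrix(NA_real_, folds, nrow(grid))
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    t_tr <- subset_feature_table(t, samples = tr)
    sel <- rfe_top_k(t_tr, y[tr], k = k, ntree = rfe_ntree,
                     seed = stream_seed(seed, 300L + f))
    fi <- match(sel, rownames(t$values))
    Xtr <- base::t(t$values[fi, tr, drop = FALSE])
    Xte <- base::t(t$values[fi, te, drop = FALSE])
    for (g in seq_len(nrow(grid))) {
      set.seed(stream_seed(seed, 100L * f + 7L * g))
      prob <- fit_predict_learner(learner, grid[g, , drop = FALSE],
                                  Xtr, y[tr], Xte, positive)
      auc[f, g] <- auc_rank(prob, y[te] == positive)
    }
  }
  max(colMeans(auc))
}

#' Class-shuffle chance control
#'
#' Within each class independently, flips the labels of a random fraction
#' (default 50%, i.e. `floor(n/2)` samples per class) and reruns the full
#' signature pipeline (RFE + grid search + cross-validation) for the given
#' learner. With half of each class reassigned in a balanced design, labels
#' are independent of the features and the mean CV AUC should sit near 0.5;
#' in imbalanced designs the flip differential changes class sizes, which is
#' reported alongside.
#'
#' @param t a z-scored [feature_table()].
#' @param labels per-sample labels or `NULL` for metadata.
#' @param learner learner to retrain (typically the unshuffled winner).
#' @param fraction fraction of each class to flip.
#' @param repeats number of independent shuffle repeats.
#' @param k,folds,grids,positive,seed,config as in [signature_cv_auc()];
#'   pass the winning signature's `hyperparameters` as `config` to retrain
#'   exactly the selected model, as opposed to re-running the grid search
#'   under every shuffle.
#' @return list with `auc` (per-repeat mean CV AUC), `mean_auc`, and
#'   `shuffled_class_sizes`.
#' @export
shuffle_control <- function(t, labels = NULL, learner = "random_forest",
                            fraction = 0.5, repeats = 1, k = 10, folds = 5,
                            grids = default_grids(), positive = "case",
                            seed = 1, config = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  y <- resolve_sample_labels(t, labels)
  classes <- sort(unique(y))
  if (length(classes) != 2L) stop("exactly two classes required", call. = FALSE)
  aucs <- numeric(repeats)
  sizes <- NULL
  for (r in seq_len(repeats)) {
    y_sh <- y
    if (fraction > 0) {
      set.seed(stream_seed(seed, 9000L + r))
      for (cl in classes) {
        idx <- which(y == cl)
        flip <- sample(idx, floor(length(idx) * fraction))
        y_sh[flip] <- setdiff(classes, cl)
      }
    }
    sizes <- table(y_sh)
    aucs[r] <- signature_cv_auc(t, y_sh, learner = learner, k = k,
                                folds = folds, grids = grids,
                                positive = positive, config = config,
                                seed = stream_seed(seed, 9500L + r))
  }
  list(auc = aucs, mean_auc = mean(aucs), shuffled_class_sizes = sizes)
}

#' Merge protein and miRNA tables into one multimodal table
#'
#' Column-binds the two modalities on the intersection of their samples;
#' feature ids are namespaced by modality so downstream feature selection
#' can pick any mixture.
#'
#' @param protein,mirna [feature_table()]s sharing sample ids.
#' @return merged [feature_table()].
#' @export
multimodal_merge <- function(protein, mirna) {
  stopifnot(inherits(protein, "FeatureTable"), inherits(mirna, "FeatureTable"))
  shared <- intersect(protein$samples$sample_id, mirna$samples$sample_id)
  if (!length(shared)) stop("no shared samples between modalities", call. = FALSE)
  pi <- match(shared, protein$samples$sample_id)
  mi <- match(shared, mirna$samples$sample_id)
  pv <- protein$values[, pi, drop = FALSE]
  mv <- mirna$values[, mi, drop = FALSE]
  rownames(pv) <- paste0("protein:", rownames(pv))
  rownames(mv) <- paste0("mirna:", rownames(mv))
  pf <- protein$features; pf$feature_id <- rownames(pv)
  mf <- mirna$features; mf$feature_id <- rownames(mv)
  common_cols <- intersect(names(pf), names(mf))
  feature_table(rbind(pv, mv),
                protein$samples[pi, , drop = FALSE],
                rbind(pf[, common_cols, drop = FALSE],
                      mf[, common_cols, drop = FALSE]))
}

# Per-sample labels from argument or table metadata.
resolve_sample_labels <- function(t, labels) {
  if (is.null(labels)) return(as.character(t$samples$class))
  if (!is.null(names(labels))) {
    miss <- setdiff(t$samples$sample_id, names(labels))
    if (length(miss)) {
      stop("labels missing for samples: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    return(as.character(labels[t$samples$sample_id]))
  }
  stopifnot(length(labels) == ncol(t$values))
  as.character(labels)
}
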