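# Harmonized signature stage: z-scoring contracts, PCA batch check,
# RFE recovery, model selection and tie rules, holdout hygiene, external
# evaluation, shuffle control identity and multimodal merging.

test_that("per-cohort z-scoring standardizes and removes affine batches", {
  v <- matrix(rnorm(20 * 30), 20,
              dimnames = list(sprintf("f%02d", 1:20), sprintf("s%02d", 1:30)))
  t <- feature_table(v, data.frame(sample_id = colnames(v),
                                   cohort = rep(c("a", "b"), each = 15),
                                   class = rep(c("case", "control"), 15)),
                     data.frame(feature_id = rownames(v),
                                modality = "protein"))
  z <- zscore_by_cohort(t)
  for (co in c("a", "b")) {
    block <- z$values[, t$samples$cohort == co]
    expect_lt(max(abs(rowMeans(block))), 1e-12)
    expect_lt(max(abs(apply(block, 1, sd) - 1)), 1e-12)
  }
  # column [1,2,3] -> [-1,0,1] under the sample SD
  t3 <- toy_table(matrix(c(1, 2, 3), 1), c("case", "control", "case"))
  expect_equal(as.numeric(zscore_by_cohort(t3)$values), c(-1, 0, 1))

  # affine batch distortion is removed exactly
  v_dist <- v
  v_dist[, t$samples$cohort == "b"] <- 3.2 * v_dist[, t$samples$cohort == "b"] - 7
  t_dist <- feature_table(v_dist, t$samples, t$features)
  expect_equal(zscore_by_cohort(t_dist)$values, z$values, tolerance = 1e-10)

  # zero-variance features flagged and set to 0
  v0 <- rbind(v, f99 = 5)
  rownames(v0) <- c(rownames(v), "f99")
  t0 <- feature_table(v0, t$samples,
                      data.frame(feature_id = rownames(v0),
                                 modality = "protein"))
  z0 <- zscore_by_cohort(t0)
  expect_true(all(z0$values["f99", ] == 0))
  expect_identical(attr(z0, "zero_variance")$a, "f99")
})

test_that("the PCA batch check separates raw batches and clears z-scored ones", {
  set.seed(6)
  n <- 100  # per cohort
  v <- matrix(rnorm(40 * 2 * n), 40)
  rownames(v) <- sprintf("f%02d", 1:40)
  colnames(v) <- sprintf("s%03d", seq_len(2 * n))
  cohort <- rep(c("a", "b"), each = n)
  samples <- data.frame(sample_id = colnames(v), cohort = cohort,
                        class = rep(c("case", "control"), n))
  features <- data.frame(feature_id = rownames(v), modality = "protein")
  # identical distributions: cohorts mix, silhouette near 0
  t_null <- feature_table(v, samples, features)
  expect_lt(abs(batch_check(t_null)$silhouette), 0.1)
  # strong additive batch (5 SD) separates cohorts
  v_batch <- v
  v_batch[, cohort == "b"] <- v_batch[, cohort == "b"] + 5
  t_batch <- feature_table(v_batch, samples, features)
  expect_gt(batch_check(t_batch)$silhouette, 0.5)
  # z-scoring restores mixing
  expect_lt(batch_check(zscore_by_cohort(t_batch))$silhouette, 0.1)
})

test_that("RFE keeps planted features and handles the k boundary", {
  cfg <- omics_cfg(seed = 31, n_case = 50, n_control = 50, n_features = 60)
  z <- zscore_by_cohort(generate_feature_table(cfg, "protein", "training"))
  sel <- rfe_top_k(z, k = 10, seed = 4)
  planted <- sprintf("prot_%04d", 1:10)
  expect_gte(sum(sel %in% planted), 8)
  # determinism under a fixed seed
  expect_identical(rfe_top_k(z, k = 10, seed = 4), sel)
  # k = n_features returns everything
  expect_setequal(rfe_top_k(z, k = 60, seed = 4), rownames(z$values))
  expect_error(rfe_top_k(z, k = 61, seed = 4), "exceeds")
})

test_that("duplicated feature columns share tree importance (degeneracy probe)", {
  cfg <- omics_cfg(seed = 41, n_case = 30, n_control = 30, n_features = 20,
                   n_planted = 1, effect = 2.5)
  t <- generate_feature_table(cfg, "protein", "training")
  dup <- t$values
  dup <- rbind(dup, "prot_dup" = dup["prot_0001", ])
  t2 <- feature_table(dup, t$samples,
                      rbind(t$features,
                            data.frame(feature_id = "prot_dup",
                                       modality = "protein",
                                       unique_peptides = 2L,
                                       contaminant_class = "none")))
  sel <- rfe_top_k(zscore_by_cohort(t2), k = 3, seed = 9)
  # the planted signal survives through at least one copy; which copy (or
  # both) is seed-dependent because duplicates split impurity importance
  expect_true(any(c("prot_0001", "prot_dup") %in% sel))
})

test_that("train_select reports 5-fold metrics and breaks ties by order", {
  cfg <- omics_cfg(seed = 51, n_case = 25, n_control = 25, n_features = 12,
                   n_planted = 4, effect = 3)
  z <- zscore_by_cohort(generate_feature_table(cfg, "protein", "training"))
  sig <- train_select(z, folds = 5, seed = 2)
  expect_s3_class(sig, "Signature")
  expect_identical(nrow(sig$metrics$per_fold), 5L)
  expect_true(all(sig$metrics$mean[c("auc", "accuracy")] <= 1))
  expect_true(all(sig$metrics$sd >= 0))
  # cleanly separable data: winner is near-perfect
  expect_gt(sig$metrics$mean["auc"], 0.95)
  # the winner obeys the documented rule applied to the reported table:
  # max mean AUC, then min AUC SD, then fixed learner order
  tab <- sig$all_results
  rule_order <- order(-tab$auc_mean, tab$auc_sd,
                      match(tab$learner, c("random_forest", "knn",
                                           "gradient_boosting")))
  expect_identical(sig$learner, tab$learner[rule_order[1]])
  # selection determinism, including tie-breaks
  sig2 <- train_select(z, folds = 5, seed = 2)
  expect_identical(sig2$learner, sig$learner)
  expect_identical(sig2$hyperparameters, sig$hyperparameters)
  expect_identical(sig2$all_results, sig$all_results)
})

test_that("stratified holdout splits preserve class balance deterministically", {
  cfg <- omics_cfg(seed = 61, n_case = 50, n_control = 50, n_features = 10)
  t <- generate_feature_table(cfg, "protein", "training")
  parts <- split_holdout(t, ratio = 0.8, seed = 3)
  expect_identical(table(parts$train$samples$class),
                   table(rep(c("case", "control"), each = 40)))
  expect_identical(table(parts$holdout$samples$class),
                   table(rep(c("case", "control"), each = 10)))
  parts2 <- split_holdout(t, ratio = 0.8, seed = 3)
  expect_identical(parts2$train$samples$sample_id,
                   parts$train$samples$sample_id)
  expect_error(split_holdout(t, ratio = 1.2), "ratio")

  # odd sizes: proportions within one sample of the ratio per class
  cfg2 <- omics_cfg(seed = 62, n_case = 13, n_control = 21, n_features = 10)
  t2 <- generate_feature_table(cfg2, "protein", "training")
  p2 <- split_holdout(t2, ratio = 0.8, seed = 1)
  n_tr <- table(p2$train$samples$class)
  expect_lte(abs(n_tr[["case"]] - 0.8 * 13), 1)
  expect_lte(abs(n_tr[["control"]] - 0.8 * 21), 1)
})

test_that("evaluation reports confusion matrices and handles one-class sets", {
  cfg <- omics_cfg(seed = 71, n_case = 30, n_control = 30, n_features = 12,
                   n_planted = 4, effect = 3)
  z <- zscore_by_cohort(generate_feature_table(cfg, "protein", "training"))
  parts <- split_holdout(z, ratio = 0.8, seed = 5)
  sig <- train_select(parts$train, folds = 5, seed = 5)
  ev <- evaluate_signature(sig, parts$holdout)
  cm <- ev$confusion
  expect_identical(cm$tp + cm$fp + cm$tn + cm$fn,
                   ncol(parts$holdout$values))
  expect_equal(cm$accuracy, (cm$tp + cm$tn) / ncol(parts$holdout$values))
  expect_gt(ev$auc, 0.8)

  # single-class external set: accuracy defined, AUC undefined
  cases_only <- subset_feature_table(
    parts$holdout, samples = which(parts$holdout$samples$class == "case"))
  ev1 <- evaluate_signature(sig, cases_only)
  expect_true(is.na(ev1$auc))
  expect_true(ev1$confusion$accuracy >= 0 && ev1$confusion$accuracy <= 1)
  expect_true(is.na(ev1$confusion$specificity))

  # missing signature features are named
  broken <- subset_feature_table(parts$holdout, features = 1:3)
  expect_error(evaluate_signature(sig, broken), "lacks signature feature")
})

test_that("a noise-trained model scores near chance on a balanced set", {
  cfg <- truth_config(seed = 81,
                      cohorts = list(training = cohort_spec(120, 120)),
                      n_protein_features = 20, n_mirna_features = 10,
                      planted_effects = list(), dropout_rate = 0)
  z <- zscore_by_cohort(generate_feature_table(cfg, "protein", "training"))
  parts <- split_holdout(z, ratio = 1 / 6, seed = 2)  # train 40, eval 200
  sig <- train_select(parts$train, learners = "random_forest", folds = 5,
                      seed = 2)
  ev <- evaluate_signature(sig, parts$holdout)
  expect_gte(ev$confusion$accuracy, 0.4)
  expect_lte(ev$confusion$accuracy, 0.6)
})

test_that("holdout data never influences feature selection or training", {
  cfg <- omics_cfg(seed = 91, n_case = 25, n_control = 25, n_features = 20,
                   n_planted = 4, effect = 2)
  z <- zscore_by_cohort(generate_feature_table(cfg, "protein", "training"))
  parts <- split_holdout(z, ratio = 0.8, seed = 7)
  sel1 <- rfe_top_k(parts$train, k = 5, seed = 7)
  sig1 <- train_select(subset_feature_table(
    parts$train, features = match(sel1, rownames(parts$train$values))),
    folds = 5, seed = 7)
  # corrupt the holdout: selection and training must not change
  parts$holdout$values[] <- rnorm(length(parts$holdout$values), 100, 50)
  sel2 <- rfe_top_k(parts$train, k = 5, seed = 7)
  sig2 <- train_select(subset_feature_table(
    parts$train, features = match(sel2, rownames(parts$train$values))),
    folds = 5, seed = 7)
  expect_identical(sel2, sel1)
  expect_identical(sig2$all_results, sig1$all_results)
})

test_that("shuffle control at fraction 0 reproduces the pipeline AUC", {
  cfg <- omics_cfg(seed = 101, n_case = 20, n_control = 20, n_features = 15,
                   n_planted = 3, effect = 2)
  z <- zscore_by_cohort(generate_feature_table(cfg, "protein", "training"))
  sc <- shuffle_control(z, learner = "knn", fraction = 0, repeats = 1,
                        k = 5, folds = 4, seed = 6)
  direct <- signature_cv_auc(z, learner = "knn", k = 5, folds = 4,
                             seed = sevmark:::stream_seed(6, 9501L))
  expect_equal(sc$auc, direct)
  # a 50% flip leaves balanced class sizes unchanged
  sc2 <- shuffle_control(z, learner = "knn", fraction = 0.5, repeats = 1,
                         k = 5, folds = 4, seed = 6)
  expect_identical(as.integer(sc2$shuffled_class_sizes),
                   c(20L, 20L))
})

test_that("multimodal merging intersects samples and namespaces features", {
  cfg <- triage_cfg(seed = 111, n = 10)
  prot <- generate_feature_table(cfg, "protein", "training")
  mir <- generate_feature_table(cfg, "mirna", "training")
  # drop some samples from each side: merge keeps the intersection
  prot_sub <- subset_feature_table(prot, samples = 1:18)
  mir_sub <- subset_feature_table(mir, samples = 3:20)
  merged <- multimodal_merge(prot_sub, mir_sub)
  expect_identical(ncol(merged$values), 16L)
  expect_identical(nrow(merged$values),
                   nrow(prot$values) + nrow(mir$values))
  expect_true(all(grepl("^(protein|mirna):", rownames(merged$values))))

  # identical raw ids across modalities stay distinct after namespacing
  collide <- mir_sub
  rownames(collide$values) <- rownames(prot_sub$values)[seq_len(nrow(collide$values))]
  collide$features$feature_id <- rownames(collide$values)
  merged2 <- multimodal_merge(prot_sub, collide)
  expect_false(anyDuplicated(rownames(merged2$values)) > 0)

  no_shared <- subset_feature_table(mir, samples = 1:2)
  no_shared$samples$sample_id <- c("x1", "x2")
  colnames(no_shared$values) <- c("x1", "x2")
  expect_error(multimodal_merge(prot_sub, no_shared), "no shared samples")
})
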