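# Generator contracts: determinism, dropout, planted-effect calibration,
# replicate structure, size-distribution parameters, longitudinal scaling.

test_that("generators are deterministic and dropout behaves", {
  cfg <- omics_cfg(seed = 11, dropout = 0)
  a <- generate_feature_table(cfg, "protein", "training")
  b <- generate_feature_table(cfg, "protein", "training")
  expect_identical(a, b)
  expect_identical(sum(is.na(a$values)), 0L)

  cfg_dp <- omics_cfg(seed = 11, dropout = 0.2)
  d <- generate_feature_table(cfg_dp, "protein", "training")
  frac <- mean(is.na(d$values))
  expect_gt(frac, 0.15)
  expect_lt(frac, 0.25)

  s1 <- generate_spectra(spectra_cfg(seed = 4), "training")
  s2 <- generate_spectra(spectra_cfg(seed = 4), "training")
  expect_identical(s1, s2)

  expect_error(generate_feature_table(cfg, "protein", "nope"), "unknown cohort")
  expect_error(generate_feature_table(cfg, "rna", "training"))
})

test_that("planted effect sizes are recovered empirically", {
  # Monte-Carlo check against the generator's own stated parameters:
  # +1.5 SD planted effect, n = 200/group, empirical SMD within +/-0.25.
  cfg <- truth_config(
    seed = 5,
    cohorts = list(training = cohort_spec(200, 200)),
    n_protein_features = 30, n_mirna_features = 10,
    planted_effects = plant("prot_0001", "training", effect = 1.5),
    dropout_rate = 0)
  t <- generate_feature_table(cfg, "protein", "training")
  x <- t$values["prot_0001", ]
  case <- t$samples$class == "case"
  smd <- (mean(x[case]) - mean(x[!case])) /
    sqrt((var(x[case]) + var(x[!case])) / 2)
  expect_lt(abs(smd - 1.5), 0.25)
  # effect-size recovery invariant at +/-3 SE (SE of an SMD ~ sqrt(2/n))
  expect_lt(abs(smd - 1.5), 3 * sqrt(2 / 200 + 1.5^2 / (4 * 200)) * 2)
})

test_that("replicate spectra carry full lineage with 9 replicates/sample", {
  cfg <- spectra_cfg(seed = 2, n_case = 4, n_control = 4)
  s <- generate_spectra(cfg, "training")
  counts <- table(s$replicates$sample_id)
  expect_true(all(counts == 9L))
  # 3 wells x 3 scans per sample
  wells <- table(unique(s$replicates[, c("sample_id", "well_id")])$sample_id)
  expect_true(all(wells == 3L))

  # degenerate config: no noise, unit scatter, flat baseline => the scans of
  # a well are identical and replicates differ only by well effect
  cfg0 <- spectra_cfg(seed = 2, n_case = 2, n_control = 2, noise_sd = 0)
  cfg0$spectra$scatter_range <- c(1, 1)
  cfg0$spectra$baseline_range <- c(0, 0)
  s0 <- generate_spectra(cfg0, "training")
  one <- s0$replicates$sample_id == s0$replicates$sample_id[1]
  w <- s0$replicates$well_id[one]
  for (wid in unique(w)) {
    block <- s0$intensities[one, , drop = FALSE][w == wid, , drop = FALSE]
    expect_lt(max(abs(sweep(block, 2, block[1, ]))), 1e-12)
  }

  bad <- spectra_cfg(seed = 2)
  bad$spectra$step <- 0
  expect_error(generate_spectra(bad, "training"), "step")
})

test_that("size distributions hit the configured medians and totals", {
  cfg <- truth_config(seed = 9,
                      cohorts = list(training = cohort_spec(56, 48)))
  dists <- generate_size_distributions(cfg, "training")
  med <- vapply(dists, function(d) summarize_distribution(d)$median_nm,
                numeric(1))
  cls <- vapply(dists, function(d) d$class, character(1))
  expect_lt(abs(median(med[cls == "case"]) - 121.6), 3)
  expect_lt(abs(median(med[cls == "control"]) - 100.5), 3)

  # unit total concentration integrates to ~1
  cfg1 <- truth_config(seed = 9,
                       cohorts = list(training = cohort_spec(2, 2)),
                       size_dist = list(case_total = 1, control_total = 1,
                                        total_sdlog = 0, median_sdlog = 0))
  d1 <- generate_size_distributions(cfg1, "training")[[1]]
  expect_lt(abs(summarize_distribution(d1)$total_particles_ml - 1), 1e-3)

  # geometric SD -> 1: mass concentrates at the median bin
  cfg2 <- truth_config(seed = 9,
                       cohorts = list(training = cohort_spec(2, 2)),
                       size_dist = list(gsd = 1.001, median_sdlog = 0,
                                        total_sdlog = 0))
  d2 <- generate_size_distributions(cfg2, "training")[[3]]  # a case sample
  total <- summarize_distribution(d2)$total_particles_ml
  near <- abs(d2$bin_centers - 121.6) <= 2
  expect_gt(trapz_mass <- sum(d2$density[near]) /
              sum(d2$density), 0.99)

  bad <- truth_config(seed = 9)
  expect_error(truth_config(seed = 9, size_dist = list(case_median = -5)),
               "positive")
})

test_that("longitudinal effects attenuate on treatment and re-diverge", {
  base <- list(
    seed = 3,
    cohorts = list(longitudinal = cohort_spec(40, 40)),
    n_protein_features = 20, n_mirna_features = 10,
    planted_effects = plant("prot_0001", "longitudinal", effect = 1.5),
    dropout_rate = 0)

  mean_case_shift <- function(lg) {
    t <- lg$protein
    x <- t$values["prot_0001", ]
    sapply(split(seq_along(x), t$samples$timepoint), function(i) {
      cls <- t$samples$class[i]
      mean(x[i][cls == "case"]) - mean(x[i][cls == "control"])
    })
  }

  # full normalization: on-treatment cases match controls
  cfg1 <- do.call(truth_config, c(base, list(
    longitudinal = list(attenuation = 1, recurrence_factor = 1))))
  d1 <- mean_case_shift(generate_longitudinal(cfg1))
  expect_gt(d1[["pre_op"]], 0.8)
  expect_lt(abs(d1[["on_treatment"]]), 0.4)

  # attenuation 0: flat trajectory
  cfg0 <- do.call(truth_config, c(base, list(
    longitudinal = list(attenuation = 0, recurrence_factor = 1))))
  d0 <- mean_case_shift(generate_longitudinal(cfg0))
  expect_lt(max(d0) - min(d0), 0.6)

  # attenuation 0.6 with full re-divergence: recurrence exceeds on-treatment
  cfg6 <- do.call(truth_config, c(base, list(
    longitudinal = list(attenuation = 0.6, recurrence_factor = 1))))
  d6 <- mean_case_shift(generate_longitudinal(cfg6))
  expect_gt(d6[["recurrence"]], d6[["on_treatment"]])

  expect_error(do.call(truth_config, c(base, list(
    longitudinal = list(attenuation = 1.2)))), "attenuation")
})

test_that("the truth manifest records seeds and the planted panel", {
  cfg <- triage_cfg(seed = 21)
  path <- tempfile(fileext = ".json")
  write_truth_manifest(cfg, path)
  m <- jsonlite::read_json(path)
  expect_identical(m$seed, 21L)
  expect_identical(length(m$planted_effects), length(cfg$planted_effects))
  types <- vapply(m$planted_effects, function(p) p$type, character(1))
  expect_true(all(c("concordant", "discordant", "reversed") %in% types))
  expect_match(m$note, "stand-in")
})
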