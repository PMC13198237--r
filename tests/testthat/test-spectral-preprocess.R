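# Preprocessing: truncation and silent-region counts against filtering
# oracles, EMSC exactness and noisy-baseline recovery, normalization and
# replicate averaging.

test_that("truncation retains the inclusive window", {
  wn <- seq(600, 4000, by = 1)
  s <- toy_spectra(wn, matrix(rnorm(2 * length(wn)), 2))
  tr <- truncate_spectra(s)
  # filtering oracle: count grid points inside [1000, 3500]
  expect_identical(length(tr$wavenumbers), sum(wn >= 1000 & wn <= 3500))
  expect_identical(length(tr$wavenumbers), 2501L)
  expect_true(tr$state["truncated"])

  # already inside the window: identity on the data
  tr2 <- truncate_spectra(tr)
  expect_identical(tr2$intensities, tr$intensities)

  expect_error(truncate_spectra(s, 3500, 1000), "lo")
  expect_error(truncate_spectra(s, 10, 20), "no wavenumbers")
})

test_that("silent-region removal drops [1801, 2799] inclusive", {
  wn <- seq(1000, 3500, by = 1)
  s <- toy_spectra(wn, matrix(rnorm(length(wn)), 1))
  s <- truncate_spectra(s)
  rs <- remove_silent(s)
  # filtering oracle: 2501 - 999 points in the band
  expect_identical(length(rs$wavenumbers), 2501L - 999L)
  expect_false(any(rs$wavenumbers >= 1801 & rs$wavenumbers <= 2799))
  expect_true(all(c(1800, 2800) %in% rs$wavenumbers))
  expect_false(any(c(1801, 2799) %in% rs$wavenumbers))
  expect_true(rs$state["silent_removed"])

  # idempotence: applying twice equals once
  expect_identical(remove_silent(rs)$intensities, rs$intensities)

  # grid with no points in the band: identity
  wn2 <- seq(1000, 1500, by = 1)
  s2 <- toy_spectra(wn2, matrix(rnorm(length(wn2)), 1))
  expect_identical(remove_silent(s2)$intensities, s2$intensities)
})

test_that("EMSC restores spectra in the model span exactly", {
  wn <- seq(1000, 2000, by = 2)
  ref <- 1 + exp(-((wn - 1650) / 30)^2) + 0.5 * exp(-((wn - 1240) / 25)^2)
  wtil <- 2 * (wn - min(wn)) / (max(wn) - min(wn)) - 1

  X <- rbind(ref,                                  # identity
             2 * ref + 0.3,                        # scale + offset
             1.4 * ref + 0.2 - 0.5 * wtil + 0.8 * wtil^2)  # full span
  out <- emsc_correct(toy_spectra(wn, X), reference = ref)
  for (i in 1:3) {
    expect_lt(max(abs(out$spectra$intensities[i, ] - ref)), 1e-10)
  }
  expect_equal(out$coefficients$b, c(1, 2, 1.4), tolerance = 1e-10)
  expect_equal(out$coefficients$c0, c(0, 0.3, 0.2), tolerance = 1e-10)
  expect_true(out$spectra$state["emsc_corrected"])
})

test_that("EMSC recovers noisy baselined spectra near the noise floor", {
  set.seed(8)
  wn <- seq(1000, 2000, by = 2)
  ref <- 1 + exp(-((wn - 1650) / 30)^2)
  wtil <- 2 * (wn - min(wn)) / (max(wn) - min(wn)) - 1
  sigma <- 0.02
  X <- t(replicate(20, {
    ref + 0.3 * wtil^2 - 0.1 * wtil + rnorm(length(wn), 0, sigma)
  }))
  out <- emsc_correct(toy_spectra(wn, X), reference = ref)
  rmse <- sqrt(rowMeans((out$spectra$intensities -
                           matrix(ref, 20, length(wn), byrow = TRUE))^2))
  expect_true(all(rmse < 1.1 * sigma))

  # degenerate fit: spectrum orthogonal to the reference direction
  flat <- matrix(0, 1, length(wn))
  expect_error(emsc_correct(toy_spectra(wn, rbind(ref, flat)),
                            reference = ref), "degenerate")
})

test_that("min-max normalization maps to [0, 1] and is affine invariant", {
  wn <- c(100, 200, 300)
  s <- toy_spectra(wn, matrix(c(2, 4, 6), 1))
  n1 <- minmax_normalize(s)
  expect_equal(as.numeric(n1$intensities), c(0, 0.5, 1))

  set.seed(3)
  x <- rnorm(50)
  both <- toy_spectra(seq_len(50), rbind(x, 3.7 * x + 11))
  nb <- minmax_normalize(both)
  expect_equal(nb$intensities[1, ], nb$intensities[2, ], tolerance = 1e-12)

  expect_error(minmax_normalize(toy_spectra(wn, matrix(1, 1, 3))),
               "constant")
})

test_that("replicate averaging reduces noise at the expected rate", {
  # two spectra [0,1] and [1,0] of one sample -> [0.5, 0.5]
  s <- spectrum_set(c(100, 200), rbind(c(0, 1), c(1, 0)),
                    data.frame(sample_id = "a", well_id = c("w1", "w2"),
                               scan_id = 1L))
  avg <- average_replicates(s, "sample")
  expect_equal(as.numeric(avg$intensities), c(0.5, 0.5))
  expect_true(avg$state["averaged"])

  # CLT: mean of 9 replicates has noise SD ~ sigma/3
  set.seed(12)
  n_samp <- 60
  sigma <- 0.3
  wn <- seq_len(20)
  meta <- data.frame(sample_id = rep(sprintf("s%02d", 1:n_samp), each = 9),
                     well_id = rep(sprintf("s%02d_w%d", rep(1:n_samp, each = 3),
                                           1:3), each = 3),
                     scan_id = rep(1:3, n_samp * 3))
  X <- matrix(rnorm(n_samp * 9 * length(wn), 0, sigma), ncol = length(wn))
  avg9 <- average_replicates(spectrum_set(wn, X, meta), "sample")
  expect_equal(sd(as.numeric(avg9$intensities)), sigma / 3, tolerance = 0.1)

  # 12 identical spectra average to themselves
  X12 <- matrix(rep(sin(wn), 12), nrow = 12, byrow = TRUE)
  meta12 <- data.frame(sample_id = "s", well_id = paste0("w", 1:12),
                       scan_id = 1L)
  expect_equal(as.numeric(average_replicates(
    spectrum_set(wn, X12, meta12), "sample")$intensities), sin(wn))
})

test_that("RFE on wavenumbers finds a planted peak and is unstable on null", {
  set.seed(5)
  wn <- seq(1000, 1500, by = 10)
  n <- 40
  y <- rep(c("case", "control"), each = n / 2)
  peak <- which(wn == 1240)
  X <- matrix(rnorm(n * length(wn), 0, 1), n)
  X[y == "case", peak] <- X[y == "case", peak] + 3
  sel <- rfe_peaks(toy_spectra(wn, X, class = y), k = 1)
  expect_identical(sel$wavenumber, 1240)

  # k = n_features: identity ranking of all wavenumbers; larger k rejected
  all_sel <- rfe_peaks(toy_spectra(wn, X, class = y), k = length(wn))
  expect_setequal(all_sel$wavenumber, wn)
  expect_error(rfe_peaks(toy_spectra(wn, X, class = y), k = length(wn) + 1),
               "exceeds")

  # label-free data: selected sets are unstable across reseeds
  sets <- lapply(1:10, function(i) {
    set.seed(100 + i)
    Xn <- matrix(rnorm(n * length(wn)), n)
    rfe_peaks(toy_spectra(wn, Xn, class = y), k = 10)$wavenumber
  })
  jac <- combn(10, 2, function(ij) {
    a <- sets[[ij[1]]]; b <- sets[[ij[2]]]
    length(intersect(a, b)) / length(union(a, b))
  })
  expect_lt(mean(jac), 0.5)
})

test_that("state flags are monotone through the pipeline", {
  cfg <- spectra_cfg(seed = 6, n_case = 2, n_control = 2)
  s <- generate_spectra(cfg, "training")
  s1 <- truncate_spectra(s)
  s2 <- emsc_correct(s1)$spectra
  s3 <- remove_silent(s2)
  expect_true(all(s3$state[c("truncated", "emsc_corrected",
                             "silent_removed")]))
  expect_false(any(s3$state[c("minmax_normalized", "averaged")]))
})
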