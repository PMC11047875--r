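test_that("basic statistics match closed forms", {
  expect_equal(unname(basic_stats(c(1, 2, 3))["mean"]), 2)
  expect_equal(unname(basic_stats(c(3, 4, 0))["rms"]), sqrt(25 / 3),
               tolerance = 1e-12)
  ## any sequence symmetric about its mean has zero skewness
  expect_lt(abs(basic_stats(c(-2, -1, 0, 1, 2))["skewness"]), 1e-10)
  expect_lt(abs(basic_stats(tone(5, n = 400))["skewness"]), 1e-10)
  expect_warning(basic_stats(rep(1, 10)), "zero variance")
})

test_that("Hjorth parameters match the sine closed form and scale laws", {
  s <- tone(5, fs = 200, n = 400)  # 10 full periods
  h <- hjorth(s)
  expect_equal(unname(h["activity"]), 0.5, tolerance = 0.01)
  expect_equal(unname(h["mobility"]), 2 * sin(pi * 5 / 200), tolerance = 0.01)

  x <- add_noise(tone(7), 10, seed = 5)
  h1 <- hjorth(x); h3 <- hjorth(3 * x)
  expect_equal(unname(h3["activity"]), unname(9 * h1["activity"]),
               tolerance = 1e-9)
  expect_equal(unname(h3["mobility"]), unname(h1["mobility"]),
               tolerance = 1e-9)
  expect_equal(unname(h3["complexity"]), unname(h1["complexity"]),
               tolerance = 1e-9)
  expect_warning(hc <- hjorth(rep(4, 100)), "zero variance")
  expect_equal(unname(hc), c(0, 0, 0))
})

test_that("histogram entropy matches known distributions and its bound", {
  expect_equal(shannon_entropy(rep(1, 100)), 0)
  square <- rep(c(0, 1), 64)
  expect_equal(shannon_entropy(square, bins = 2), log(2), tolerance = 1e-6)
  x <- add_noise(tone(5), 0, seed = 8)
  for (b in c(4, 16, 64))
    expect_lte(shannon_entropy(x, bins = b), log(b))
})

test_that("Teager energy matches the tone closed form and scales quadratically", {
  s <- tone(5, fs = 200, n = 400)  # omega = 0.157 rad/sample
  expect_equal(mean_teager_energy(s), sin(0.05 * pi)^2, tolerance = 0.02)
  expect_equal(mean_teager_energy(2 * s), 4 * mean_teager_energy(s),
               tolerance = 1e-9)
  expect_equal(mean_teager_energy(rep(3, 100)), 0)
})

test_that("fluctuation index is the mean absolute first difference", {
  expect_equal(fluctuation_index(rep(2, 50)), 0)
  expect_equal(fluctuation_index(seq(0, 9.8, by = 0.2)), 0.2,
               tolerance = 1e-12)
  ## not permutation invariant
  x <- c(0, 1, 0, 1, 0, 1, 5)
  expect_false(isTRUE(all.equal(fluctuation_index(x),
                                fluctuation_index(sort(x)))))
})

test_that("spectral band powers integrate the periodogram correctly", {
  s <- signal_segment(tone(10), 200)
  sp <- spectral_features(s, bands = list(c(8, 13)))
  expect_gte(sp[[1]], 0.95)
  expect_equal(unname(sp["peak_freq"]), 10, tolerance = 0.2)

  ## full partition of (0, fs/2) sums to 1
  x <- add_noise(tone(15), 3, seed = 2)
  parts <- spectral_features(x, fs = 200,
                             bands = list(c(0.15, 33.33), c(33.34, 66.66),
                                          c(66.67, 99.9)))
  expect_equal(sum(parts[1:3]), 1, tolerance = 1e-6)

  ## white noise spreads power evenly between equal-width bands
  w <- withr::with_seed(0, rnorm(4096))
  p <- spectral_features(w, fs = 200, bands = list(c(10, 40), c(50, 80)))
  expect_lt(abs(p[[1]] - p[[2]]) / p[[1]], 0.2)
  expect_error(spectral_features(x, fs = 200, bands = list(c(90, 110))),
               "Nyquist|fs/2|intervals")
})

test_that("wavelet sub-band energies are a distribution and localize tones", {
  x <- add_noise(tone(12), 5, seed = 4)
  wf <- wavelet_subband_features(x, wavelet_spec())
  rel <- wf[setdiff(names(wf), "energy_entropy")]
  expect_equal(sum(rel), 1, tolerance = 1e-6)
  ## slow tone concentrates in the deepest approximation level
  slow <- wavelet_subband_features(tone(2), wavelet_spec())
  slow <- slow[setdiff(names(slow), "energy_entropy")]
  expect_equal(names(which.max(slow)), "approx")
  ## constant signal has zero detail energy
  cst <- wavelet_subband_features(rep(5, 256), wavelet_spec())
  expect_lt(max(cst[paste0("d", 1:2)]), 1e-12)
})

test_that("feature matrix has the documented shape and standardization", {
  ds <- generate_dataset(synth_config(n_per_class = 10, seed = 0))
  fm <- extract_feature_matrix(ds$segments)
  expect_equal(dim(fm$values), c(30L, 12L))
  expect_true(all(is.finite(fm$values)))
  expect_lt(max(abs(colMeans(fm$values))), 1e-9)
  expect_equal(unname(apply(fm$values, 2, var)), rep(1, 12),
               tolerance = 1e-6)

  ## at least one feature separates the classes (F-ratio > 1)
  raw <- extract_feature_matrix(ds$segments, standardize = FALSE)
  fstat <- apply(raw$values, 2, function(v) {
    fit <- stats::aov(v ~ factor(ds$labels))
    summary(fit)[[1]]$`F value`[1]
  })
  expect_gt(max(fstat), 1)

  ## extraction preserves segment order
  expect_equal(fm$segment_ids,
               vapply(ds$segments, function(s) s$id, character(1)))
})

test_that("feature matrices survive a CSV round trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  ds <- generate_dataset(synth_config(n_per_class = 3, seed = 1))
  fm <- extract_feature_matrix(ds$segments)
  write_feature_csv(fm, path)
  back <- read_feature_csv(path)
  expect_equal(back$values, fm$values, tolerance = 1e-12)
  expect_equal(back$segment_ids, fm$segment_ids)
})
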