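test_that("IMF correlations behave like Pearson correlation", {
  s <- tone(5, n = 400)
  fake <- structure(list(imfs = rbind(s, -s), residue = numeric(400),
                         source_length = 400L), class = "imfset")
  rho <- imf_correlations(fake, s)
  expect_equal(rho, c(1, -1), tolerance = 1e-12)

  ## orthogonal pair over full periods
  orth <- structure(list(imfs = rbind(cos(2 * pi * 5 * (0:399) / 200)),
                         residue = numeric(400), source_length = 400L),
                    class = "imfset")
  expect_lt(abs(imf_correlations(orth, s)), 1e-10)

  ## invariance to positive affine scaling
  dec <- emd(add_noise(tone(5), 10, seed = 1))
  r1 <- imf_correlations(dec, add_noise(tone(5), 10, seed = 1))
  scaled <- structure(list(imfs = dec$imfs * 7, residue = dec$residue,
                           source_length = dec$source_length),
                      class = "imfset")
  r2 <- imf_correlations(scaled, 3 * add_noise(tone(5), 10, seed = 1) + 2)
  expect_equal(r1, r2, tolerance = 1e-9)

  ## zero-variance mode warns and scores 0
  degen <- structure(list(imfs = rbind(rep(0, 400)), residue = s,
                          source_length = 400L), class = "imfset")
  expect_warning(rho0 <- imf_correlations(degen, s), "zero-variance")
  expect_equal(rho0, 0)
})

test_that("correlation screening selects the documented component set", {
  rho <- c(0.1698, 0.1525, 0.3884, 0.5431, 0.6904, 0.7746, 0.3233,
           0.0466, 0.0235, 0.0193)
  expect_equal(select_imfs(rho, 0.3), c(3L, 4L, 5L, 6L, 7L))
  expect_equal(select_imfs(rho, 0), seq_along(rho))
  expect_warning(empty <- select_imfs(rep(0, 10), 0.3), "no IMF")
  expect_length(empty, 0)
  expect_error(select_imfs(rho, 1.5), "0, 1")
})

test_that("partial reconstruction telescopes back to the signal", {
  x <- add_noise(tone(5), 10, seed = 3)
  dec <- emd(x)
  k <- nrow(dec$imfs)
  full <- partial_reconstruct(dec, seq_len(k))
  expect_lt(sqrt(sum((full - x)^2)) / sqrt(sum(x^2)), 1e-8)
  expect_equal(partial_reconstruct(dec, integer(0)), dec$residue)
  expect_length(partial_reconstruct(dec, 1L), length(x))
  expect_error(partial_reconstruct(dec, k + 1L), "out of range")
})

test_that("wavelet thresholding preserves structure and removes noise", {
  x <- tone(10)
  ## zero threshold scale = perfect reconstruction
  expect_equal(wavelet_threshold_denoise(x, wavelet_spec(threshold_scale = 0)),
               x, tolerance = 1e-6)
  ## constant signal is untouched
  cst <- rep(2, 256)
  expect_equal(wavelet_threshold_denoise(cst, wavelet_spec()), cst,
               tolerance = 1e-9)
  ## 5 dB noisy sine comes out at >= 8 dB
  noisy <- add_noise(x, 5, seed = 7)
  den <- wavelet_threshold_denoise(noisy, wavelet_spec())
  expect_gte(denoise_report(x, den)$snr_db, 8)
  ## soft rule also denoises
  den_soft <- wavelet_threshold_denoise(noisy,
                                        wavelet_spec(threshold_rule = "soft"))
  expect_gt(denoise_report(x, den_soft)$snr_db, 5)
  expect_error(wavelet_spec("nosuchwavelet"), "unknown wavelet")
})

test_that("joint denoising is deterministic, length-preserving and faithful on clean input", {
  x <- tone(5, amp = 2)
  y1 <- joint_denoise(x, ensemble_size = 10, seed = 0)
  y2 <- joint_denoise(x, ensemble_size = 10, seed = 0)
  expect_identical(y1, y2)
  expect_length(y1, length(x))
  expect_gte(denoise_report(x, y1)$ncc, 0.99)
})

test_that("quality metrics match hand calculations", {
  r <- denoise_report(c(1, 1, 1, 1), c(1, 1, 1, 0))
  expect_equal(r$snr_db, 6.0206, tolerance = 1e-3)
  expect_equal(r$rmse, 0.5, tolerance = 1e-12)
  expect_equal(r$ncc, 0.8660, tolerance = 1e-3)
  expect_equal(r$psnr_db, 6.0206, tolerance = 1e-3)

  ident <- denoise_report(tone(5), tone(5))
  expect_equal(ident$rmse, 0)
  expect_equal(ident$ncc, 1)
  expect_identical(ident$snr_db, Inf)
  expect_identical(ident$psnr_db, Inf)

  expect_equal(denoise_report(tone(5), -tone(5))$ncc, -1, tolerance = 1e-12)
  expect_error(denoise_report(1:4, 1:5), "same length")
})

test_that("SNR decreases monotonically along a noise ladder", {
  x <- tone(10)
  snrs <- vapply(c(20, 10, 0), function(s)
    denoise_report(x, add_noise(x, s, seed = 11))$snr_db, numeric(1))
  expect_true(all(diff(snrs) < 0))
})
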