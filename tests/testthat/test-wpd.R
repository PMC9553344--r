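t128 <- (0:127) / 128

test_that("pure tones land in their nominal bands", {
  probes <- list(Theta = 6, Alpha = 10, Beta1 = 16, Beta2 = 25)
  for (band in names(probes)) {
    x <- sin(2 * pi * probes[[band]] * t128)
    recon <- wpd_subband_signals(x, 128, wpd_config())
    energy <- vapply(recon, function(s) sum(s^2), numeric(1))
    expect_gt(energy[[band]] / sum(x^2), 0.90)
    # the FFT oracle agrees that the reconstructed band signal is in band
    b <- wpd_config()$bands[[band]]
    expect_gt(fft_band_fraction(recon[[band]], 128, b[1] - 1, b[2] + 1), 0.9)
  }
})

test_that("mixed tones separate into their bands", {
  x <- sin(2 * pi * 10 * t128) + sin(2 * pi * 25 * t128)
  recon <- wpd_subband_signals(x, 128, wpd_config())
  expect_gt(fft_band_fraction(recon$Alpha, 128, 9, 11), 0.8)
  expect_gt(fft_band_fraction(recon$Beta2, 128, 24, 26), 0.8)
})

test_that("the transform conserves energy and the bands partition leaves", {
  withr::with_seed(1, {
    for (rep in 1:5) {
      x <- rnorm(128)
      coeffs <- wpd_leaf_coeffs(x, 128)
      expect_equal(sum(coeffs^2), sum(x^2), tolerance = 1e-9)
    }
  })
  # the four band projections use disjoint leaf sets: their energies are
  # additive and bounded by the total
  withr::with_seed(2, x <- rnorm(128))
  an <- eegchansel:::wpd_band_analysis(128, 128, wpd_config())
  band_coeffs <- lapply(an$bands, function(W) W %*% x)
  expect_identical(sum(vapply(an$bands, nrow, 1L)), 52L)  # 4+5+7+10 leaves x 2
  expect_lte(sum(vapply(band_coeffs, function(cc) sum(cc^2), numeric(1))),
             sum(x^2) + 1e-9)
})

test_that("zero input gives zero band signals and amplitude scales linearly", {
  z <- wpd_subband_signals(rep(0, 128), 128, wpd_config())
  for (s in z) expect_identical(s, rep(0, 128))
  ep <- random_epochs(n_ep = 6, n_ch = 2, seed = 3)
  doubled <- make_epochs(ep$epochs * 2, ep$labels, montage = ep$montage)
  f1 <- subband_std_features(ep)$Theta_Std
  f2 <- subband_std_features(doubled)$Theta_Std
  expect_equal(f2$values, 2 * f1$values, tolerance = 1e-12)
})

test_that("subband feature matrices have epoch-by-channel shape", {
  ep <- random_epochs(n_ep = 12, n_ch = 5, seed = 4)
  mats <- subband_std_features(ep)
  expect_named(mats, c("Theta_Std", "Alpha_Std", "Beta1_Std", "Beta2_Std"))
  for (fm in mats) {
    expect_identical(dim(fm$values), c(12L, 5L))
    expect_identical(fm$labels, ep$labels)
  }
  # zero signal -> all-zero features
  zep <- make_epochs(array(0, dim = c(3, 2, 128)), c(0L, 1L, 0L))
  expect_true(all(subband_std_features(zep)$Theta_Std$values == 0))
  # direct agreement with the per-epoch reconstruction path
  recon <- wpd_subband_signals(ep$epochs[3, 2, ], 128, wpd_config())
  expect_equal(unname(mats$Alpha_Std$values[3, 2]), epoch_std(recon$Alpha),
               tolerance = 1e-12)
})

test_that("configuration errors are caught", {
  expect_error(wpd_config(bands = list(Theta = c(4, 8), Alpha = c(7, 13))),
               "disjoint", class = "eegchansel_config_error")
  expect_error(wpd_subband_signals(rnorm(100), 128, wpd_config()),
               class = "eegchansel_config_error")  # 100 not divisible by 64
  expect_error(wpd_subband_signals(rnorm(128), 128,
                                   wpd_config(bands = list(Odd = c(4, 8.5)))),
               "leaf bandwidth", class = "eegchansel_config_error")
  expect_error(wpd_subband_signals(rnorm(128), 32, wpd_config()),
               "Nyquist", class = "eegchansel_config_error")
})

test_that("epoch_std is the population standard deviation", {
  expect_identical(epoch_std(c(5, 5, 5)), 0)
  expect_identical(epoch_std(c(0, 2)), 1)
  withr::with_seed(5, x <- rnorm(1000))
  expect_equal(epoch_std(x), sqrt(mean((x - mean(x))^2)), tolerance = 1e-14)
  expect_gt(epoch_std(x), 0.9); expect_lt(epoch_std(x), 1.1)
  expect_error(epoch_std(numeric(0)), class = "eegchansel_config_error")
})
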