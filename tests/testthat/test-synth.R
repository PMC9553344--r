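tiny_spec <- function(seed, ...) {
  synth_spec(n_subjects = 1L, seconds_per_state = 20L, seed = seed, ...)
}

test_that("generation is deterministic and shaped by the spec", {
  sp <- tiny_spec(1)
  d1 <- synth_generate(sp)
  d2 <- synth_generate(sp)
  expect_identical(d1$recordings[[1]]$JX$data, d2$recordings[[1]]$JX$data)
  expect_identical(d1$recordings[[1]]$ZD$data, d2$recordings[[1]]$ZD$data)
  expect_identical(dim(d1$recordings[[1]]$JX$data), c(30L, 20000L))
  expect_identical(d1$ground_truth, c(27L, 28L, 29L, 17L, 24L, 9L))
  d3 <- synth_generate(tiny_spec(2))
  expect_false(identical(d1$recordings[[1]]$JX$data, d3$recordings[[1]]$JX$data))
})

test_that("default spec matches the full study's data volume per subject", {
  sp <- synth_spec()
  expect_identical(sp$n_subjects, 10L)
  expect_identical(sp$seconds_per_state * sp$fs * 2, 600000)  # samples per subject
  expect_identical(sp$n_channels, 30L)
})

test_that("informative channels raise theta power in the fatigue state only", {
  ds <- synth_generate(tiny_spec(3))
  ep <- dataset_epochs(ds)
  theta <- subband_std_features(ep)$Theta_Std
  m_jx <- colMeans(theta$values[theta$labels == 0L, ])
  m_zd <- colMeans(theta$values[theta$labels == 1L, ])
  inf <- ds$ground_truth
  expect_true(all(m_zd[inf] > 1.3 * m_jx[inf]))
  ratio_null <- m_zd[-inf] / m_jx[-inf]
  expect_lt(max(abs(ratio_null - 1)), 0.5)
})

test_that("a null spec carries no class signal", {
  accs <- vapply(1:3, function(seed) {
    ds <- synth_generate(synth_spec(n_subjects = 1L, seconds_per_state = 40L,
                                    theta_power_shift = 1, complexity_shift = 0,
                                    seed = seed))
    ep <- dataset_epochs(ds)
    fm <- extract_feature_set(ep, "Theta_Std")
    knn_cv_accuracy(fm, seq_len(30L), eval_params(seed = seed))
  }, numeric(1))
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.6)
})

test_that("non-informative channels are exchangeable", {
  # channels 1 and 2 are both null: their per-dataset feature means should
  # differ only by sampling noise (paired CI over seeds covers zero)
  diffs <- vapply(1:10, function(seed) {
    ds <- synth_generate(tiny_spec(seed))
    theta <- subband_std_features(dataset_epochs(ds))$Theta_Std
    mean(theta$values[, 1]) - mean(theta$values[, 2])
  }, numeric(1))
  ci <- t.test(diffs)$conf.int
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("stronger theta shifts push informative channels up the ranking", {
  mean_rank <- function(shift) {
    ranks <- vapply(1:6, function(seed) {
      ds <- synth_generate(synth_spec(n_subjects = 1L, seconds_per_state = 30L,
                                      theta_power_shift = shift,
                                      complexity_shift = 0, seed = seed))
      theta <- extract_feature_set(dataset_epochs(ds), "Theta_Std")
      rk <- relieff_weights(theta, relieff_params(seed = seed))
      mean(match(ds$ground_truth, rk$order))
    }, numeric(1))
    mean(ranks)
  }
  grid <- vapply(c(1, 1.5, 2.5), mean_rank, numeric(1))
  expect_gt(grid[1], grid[2])
  expect_gt(grid[2], grid[3])
})

test_that("datasets round-trip through disk with a manifest", {
  ds <- synth_generate(synth_spec(n_subjects = 1L, seconds_per_state = 5L,
                                  fs = 200, seed = 4))
  dir <- withr::local_tempdir()
  manifest <- write_synth_dataset(ds, dir, format = "delimited")
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  expect_identical(sort(man$ground_truth), sort(ds$ground_truth))
  expect_identical(man$spec$seed, 4L)
  expect_identical(nrow(man$files), 2L)
  back <- load_recording(file.path(dir, man$files$path[1]), "delimited",
                         montage = ds$recordings[[1]]$JX$montage, fs = man$fs)
  expect_equal(back$data, ds$recordings[[1]]$JX$data, tolerance = 1e-10)
})

test_that("invalid specs are rejected", {
  expect_error(synth_spec(informative_channels = 31L), class = "eegchansel_config_error")
  expect_error(synth_spec(theta_power_shift = 0), class = "eegchansel_config_error")
  expect_error(synth_spec(n_subjects = 0), class = "eegchansel_config_error")
})
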