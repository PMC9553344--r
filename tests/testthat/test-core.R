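test_that("default montage maps the 30 standard electrodes in order", {
  m <- default_montage()
  expect_length(m, 30L)
  expect_identical(unclass(m)[c(1, 2, 3)], c("Fp1", "Fp2", "F7"))
  expect_identical(which(m == "T6"), 27L)
  expect_identical(which(m == "O2"), 30L)
  expect_error(montage(c("Fp1", "Fp1")), class = "eegchansel_config_error")
})

test_that("montage file round-trips, including shuffled rows", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_montage(default_montage(), path)
  expect_identical(read_montage(path), default_montage())
  writeLines(c("O1 2", "Fp1 1"), path)
  expect_identical(unclass(read_montage(path)), c("Fp1", "O1"))
})

test_that("delimited loading drops references and enforces the montage", {
  mont <- montage(c("Fp1", "Fp2", "Cz"))
  withr::with_seed(1, {
    dat <- matrix(rnorm(5 * 100), 5, 100)
  })
  labels32 <- c("A1", "Fp2", "Cz", "Fp1", "A2")  # scrambled, with references
  path <- withr::local_tempfile(fileext = ".csv")
  write.table(t(dat), path, sep = ",", quote = FALSE, row.names = FALSE,
              col.names = labels32)
  rec <- load_recording(path, "delimited", montage = mont, fs = 100)
  expect_identical(nrow(rec$data), 3L)
  expect_equal(rec$data["Fp1", ], dat[4, ])   # reordered to montage order
  expect_equal(rec$data["Cz", ], dat[3, ])

  # already reference-free file loads identically
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.table(t(dat[c(4, 2, 3), ]), path2, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = c("Fp1", "Fp2", "Cz"))
  rec2 <- load_recording(path2, "delimited", montage = mont, fs = 100)
  expect_equal(rec2$data, rec$data)

  # header not a superset of the montage
  path3 <- withr::local_tempfile(fileext = ".csv")
  write.table(t(dat[1:3, ]), path3, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = c("Fp1", "XX", "Cz"))
  expect_error(load_recording(path3, "delimited", montage = mont, fs = 100),
               "Fp2", class = "eegchansel_config_error")
})

test_that("non-finite samples are rejected with the channel named", {
  bad <- matrix(1, 2, 10)
  bad[2, 3] <- NaN
  expect_error(recording(bad, 10, montage(c("Fp1", "Oz"))), "Oz",
               class = "eegchansel_data_error")
})

test_that("resampling preserves duration, tone location, and identity", {
  withr::with_seed(2, {
    dat <- matrix(rnorm(2 * 10000), 2, 10000)
  })
  t1k <- (0:9999) / 1000
  dat[1, ] <- sin(2 * pi * 5 * t1k)
  rec <- recording(dat, 1000, montage(c("Fp1", "Oz")))
  out <- resample_recording(rec, 128)
  expect_equal(out$fs, 128)
  expect_equal(ncol(out$data), 1280L)  # 10 s preserved
  # dominant FFT bin of the 5 Hz tone stays at 5 Hz within one bin
  spec <- Mod(fft(out$data[1, ]))[1:640]
  peak_hz <- (which.max(spec) - 1) * 128 / 1280
  expect_lt(abs(peak_hz - 5), 128 / 1280 + 1e-9)
  expect_identical(resample_recording(rec, 1000)$data, rec$data)
  expect_error(resample_recording(rec, 2000), class = "eegchansel_config_error")
})

test_that("epoching floors to whole windows and carries one label", {
  rec <- recording(matrix(seq_len(27), 1, 27), 10, montage("Cz"))
  ep <- epoch_recording(rec, 1L)  # 2.7 s at 10 Hz
  expect_identical(dim(ep$epochs), c(2L, 1L, 10L))
  expect_identical(ep$labels, c(1L, 1L))
  expect_equal(ep$epochs[2, 1, ], 11:20)  # contiguous, non-overlapping
  expect_error(epoch_recording(recording(matrix(1:5, 1), 10, montage("Cz")), 0L),
               class = "eegchansel_data_error")
  expect_error(epoch_recording(rec, 2), class = "eegchansel_config_error")
})

test_that("epoch counts add up when binding state sets", {
  withr::with_seed(3, {
    jx <- recording(matrix(rnorm(2 * 200), 2, 200), 10, montage(c("Fp1", "Oz")))
    zd <- recording(matrix(rnorm(2 * 200), 2, 200), 10, montage(c("Fp1", "Oz")))
  })
  both <- bind_epochs(epoch_recording(jx, 0L), epoch_recording(zd, 1L))
  expect_identical(dim(both$epochs)[1], 40L)
  expect_identical(sum(both$labels == 0L), 20L)
  expect_identical(sum(both$labels == 1L), 20L)
})

test_that("epoch count after resampling depends only on duration", {
  for (fs in c(256, 640)) {
    withr::with_seed(4, {
      rec <- recording(matrix(rnorm(7.5 * fs), 1), fs, montage("Cz"))
    })
    ep <- epoch_recording(resample_recording(rec, 128), 0L)
    expect_identical(dim(ep$epochs)[1], 7L)
  }
})

test_that("permuting channels and montage together leaves named features unchanged", {
  ep <- random_epochs(n_ep = 10, n_ch = 4, seed = 5)
  perm <- c(3L, 1L, 4L, 2L)
  ep_perm <- make_epochs(ep$epochs[, perm, , drop = FALSE], ep$labels,
                         montage = montage(unclass(ep$montage)[perm]))
  f1 <- subband_std_features(ep)$Theta_Std
  f2 <- subband_std_features(ep_perm)$Theta_Std
  expect_equal(f2$values[, match(colnames(f1$values), colnames(f2$values))],
               f1$values, ignore_attr = TRUE)
})
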