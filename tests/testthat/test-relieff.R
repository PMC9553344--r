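test_that("weights match the hand-enumerated update on small instances", {
  withr::with_seed(1, {
    for (case in 1:25) {
      n <- sample(c(6L, 8L, 10L), 1)
      n_ch <- sample(2:4, 1)
      y <- rep(c(0L, 1L), each = n / 2)
      X <- matrix(rnorm(n * n_ch), n, n_ch)
      fm <- feature_matrix(X, y, paste0("Ch", seq_len(n_ch)), "F")
      p <- relieff_params(m_iter = n, k_nn = 2L, seed = case)
      got <- relieff_weights(fm, p)
      expect_equal(got$feature_weights, relieff_oracle(X, y, n, 2L, case),
                   tolerance = 1e-12)
    }
  })
})

test_that("an explicit 8-sample toy matches the oracle with sampling fixed", {
  X <- cbind(c(0.1, 0.2, 0.15, 0.05, 0.9, 0.95, 0.85, 1.0),
             c(5, -3, 2, 1, -2, 4, 0, 3))
  y <- rep(c(0L, 1L), each = 4)
  fm <- feature_matrix(X, y, c("A", "B"), "F")
  got <- relieff_weights(fm, relieff_params(m_iter = 8, k_nn = 3, seed = 42))
  expect_equal(got$feature_weights, relieff_oracle(X, y, 8, 3, 42),
               tolerance = 1e-12)
  expect_identical(got$order[1], 1L)  # the class-separated feature wins
})

test_that("a label-copy channel outranks noise channels", {
  wins <- vapply(1:20, function(seed) {
    fm <- planted_fm(n = 40, n_ch = 10, planted = 1L, seed = seed)
    rk <- relieff_weights(fm, relieff_params(m_iter = 80, k_nn = 10, seed = seed))
    rk$order[1] == 1L && all(rk$weights[1] > rk$weights[-1])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("constant columns contribute exactly zero weight", {
  withr::with_seed(2, {
    X <- cbind(rnorm(20), rep(3.7, 20))
    fm <- feature_matrix(X, rep(0:1, 10), c("A", "B"), "F")
  })
  rk <- relieff_weights(fm, relieff_params(m_iter = 20, k_nn = 3, seed = 1))
  expect_identical(rk$weights[2], 0)
})

test_that("channel weights average column weights for fused features", {
  withr::with_seed(3, {
    a <- feature_matrix(matrix(rnorm(40), 20, 2), rep(0:1, 10), c("A", "B"), "F1")
    b <- feature_matrix(matrix(rnorm(40), 20, 2), rep(0:1, 10), c("A", "B"), "F2")
  })
  rk <- relieff_weights(fuse(a, b), relieff_params(m_iter = 20, k_nn = 3, seed = 4))
  expect_equal(rk$weights,
               c(mean(rk$feature_weights[1:2]), mean(rk$feature_weights[3:4])))
})

test_that("ordering breaks weight ties toward the lower channel index", {
  # duplicated columns get identical weights; order must prefer channel 1
  withr::with_seed(4, x <- rnorm(20))
  fm <- feature_matrix(cbind(x, x), rep(0:1, 10), c("A", "B"), "F")
  rk <- relieff_weights(fm, relieff_params(m_iter = 20, k_nn = 3, seed = 5))
  expect_identical(rk$weights[1], rk$weights[2])
  expect_identical(rk$order, c(1L, 2L))
})

test_that("undersized classes are rejected", {
  fm <- planted_fm(n = 10, n_ch = 3, planted = NA, seed = 5)
  expect_error(relieff_weights(fm, relieff_params(k_nn = 10)),
               class = "eegchansel_config_error")
})

test_that("adding a pure-noise channel barely perturbs the ranking", {
  fm <- planted_fm(n = 60, n_ch = 6, planted = 1L, seed = 6)
  withr::with_seed(7, noise <- rnorm(60))
  fm_plus <- feature_matrix(cbind(fm$values, noise), fm$labels,
                            c(fm$channels, "Ch7"), "F")
  p <- relieff_params(m_iter = 60, k_nn = 10, seed = 8)
  w1 <- relieff_weights(fm, p)$weights
  w2 <- relieff_weights(fm_plus, p)$weights[1:6]
  expect_identical(which.max(w2), which.max(w1))  # signal channel still leads
  expect_gt(min(w2[1] - w2[-1]), 0)               # and by a clear margin
  expect_lt(max(abs(w2 - w1)), 0.05)              # null weights barely move
})

test_that("ranking tables report in scaled units", {
  fm <- planted_fm(n = 20, n_ch = 3, planted = 1L, seed = 9)
  rk <- relieff_weights(fm, relieff_params(m_iter = 20, k_nn = 5, seed = 1))
  tab <- ranking_table(rk, unit = 1e-3)
  expect_identical(names(tab), c("number", "channel", "weight"))
  expect_equal(tab$weight, rk$weights[rk$order] / 1e-3)
  expect_true(!is.unsorted(rev(tab$weight)))
})
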