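# The R/S estimator is checked three ways: against a brute-force
# transcription of the definition on a tiny series, against exact power-law
# curves (machine-precision recovery), and against the fGn generator whose
# true H is known.

brute_rs <- function(x, n) {
  segs <- split(x[seq_len((length(x) %/% n) * n)],
                rep(seq_len(length(x) %/% n), each = n))
  vals <- vapply(segs, function(s) {
    z <- cumsum(s - mean(s))
    S <- sqrt(mean((s - mean(s))^2))
    if (S > 0) (max(z) - min(z)) / S else NA_real_
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

test_that("rs_curve matches a brute-force transcription of the definition", {
  x <- c(1, 2, 1, 2, 1, 2, 1, 2)
  cur <- rs_curve(x, 4)
  expect_equal(cur$mean_rs, brute_rs(x, 4), tolerance = 1e-12)
  set.seed(4)
  y <- rnorm(64)
  cur <- rs_curve(y, c(4, 8, 16, 32))
  expect_equal(cur$mean_rs,
               vapply(c(4, 8, 16, 32), function(n) brute_rs(y, n), numeric(1)),
               tolerance = 1e-12)
  expect_identical(cur$n_segments_used, c(16L, 8L, 4L, 2L))
})

test_that("constant input is a degenerate-input error", {
  expect_error(rs_curve(rep(2.5, 64), c(4, 8, 16)),
               class = "boldhurst_degenerate_input")
})

test_that("R/S is invariant under affine rescaling of the series", {
  set.seed(5)
  x <- rnorm(256)
  sc <- c(4, 8, 16, 32, 64)
  base <- rs_curve(x, sc)$mean_rs
  expect_equal(rs_curve(-3.2 * x + 17, sc)$mean_rs, base, tolerance = 1e-9)
  expect_equal(rs_curve(0.001 * x, sc)$mean_rs, base, tolerance = 1e-9)
})

test_that("exact power-law curves are recovered to machine precision, with beta = 2H - 1", {
  sc <- c(8, 16, 32, 64, 128)
  cur <- structure(list(scales = sc, mean_rs = sc^0.7,
                        n_segments_used = rep(1L, 5)), class = "rs_curve")
  est <- fit_hurst(cur)
  expect_equal(est$H, 0.7, tolerance = 1e-12)
  expect_equal(est$beta, 0.4, tolerance = 1e-12)
  expect_equal(est$r_squared, 1, tolerance = 1e-12)
  for (H in c(0.2, 0.5, 0.95)) {
    cur$mean_rs <- 2.7 * sc^H
    e <- fit_hurst(cur)
    expect_equal(e$H, H, tolerance = 1e-12)
    expect_identical(e$beta, 2 * e$H - 1)
  }
  cur$mean_rs <- sc^0.5
  expect_error(fit_hurst(structure(list(scales = sc[1:2], mean_rs = sc[1:2]^0.5,
                                        n_segments_used = c(1L, 1L)),
                                   class = "rs_curve")),
               class = "boldhurst_insufficient_scales")
})

test_that("estimates increase monotonically with the true H of fGn", {
  N <- 1024
  sc <- default_scales(N)
  means <- vapply(c(0.3, 0.5, 0.7, 0.9), function(H) {
    X <- simulate_fgn(H, N, n_series = 15, seed = 100 + round(100 * H))
    mean(apply(X, 2, function(x) fit_hurst(rs_curve(x, sc))$H))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("the corrected estimator is centred near 0.5 on white noise", {
  set.seed(11)
  X <- matrix(rnorm(1024 * 30), 1024, 30)
  sc <- default_scales(1024)
  h <- apply(X, 2, function(x) fit_hurst(rs_curve(x, sc), correction = TRUE)$H)
  expect_lt(abs(mean(h) - 0.5), 0.05)
})

test_that("the white-noise expected R/S approaches sqrt(n pi / 2) from below", {
  n <- c(64, 256, 1024, 4096, 16384)
  ratio <- expected_rs_white(n) / sqrt(n * pi / 2)
  expect_true(all(ratio < 1))
  expect_true(all(diff(ratio) > 0))
  expect_gt(ratio[5], 0.99)
  expect_true(all(diff(expected_rs_white(n)) > 0))
})

test_that("hurst_map matches per-voxel scalar estimation exactly and flags degenerate voxels", {
  set.seed(12)
  d <- c(3, 2, 1, 128)
  bold <- array(rnorm(prod(d)), d)
  bold[2, 1, 1, ] <- 4  # constant voxel
  mask <- array(TRUE, d[1:3])
  expect_message(hm <- hurst_map(bold, mask), "degenerate")
  expect_true(is.na(hm$values[2, 1, 1]))
  expect_true(hm$undefined[2, 1, 1])
  sc <- default_scales(128)
  expect_equal(hm$values[1, 1, 1],
               fit_hurst(rs_curve(bold[1, 1, 1, ], sc))$H, tolerance = 1e-12)
  expect_equal(hm$values[3, 2, 1],
               fit_hurst(rs_curve(bold[3, 2, 1, ], sc))$H, tolerance = 1e-12)
  expect_error(hurst_map(bold, array(FALSE, d[1:3])),
               class = "boldhurst_invalid_input")
})

test_that("a two-region phantom orders region means by true H", {
  spec_lo <- simulate_fgn(0.4, 256, n_series = 8, seed = 21)
  spec_hi <- simulate_fgn(0.8, 256, n_series = 8, seed = 22)
  bold <- array(0, c(4, 4, 1, 256))
  for (v in 1:8) bold[((v - 1) %% 4) + 1, ((v - 1) %/% 4) + 1, 1, ] <- spec_lo[, v]
  for (v in 1:8) bold[((v - 1) %% 4) + 1, ((v - 1) %/% 4) + 3, 1, ] <- spec_hi[, v]
  mask <- array(TRUE, c(4, 4, 1))
  hm <- hurst_map(bold, mask)
  lo <- mean(hm$values[, 1:2, 1]); hi <- mean(hm$values[, 3:4, 1])
  expect_lt(lo, hi)
})
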