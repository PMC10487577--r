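test_that("resampling bins by round-half-up and takes the bin maximum", {
  g <- grid_spec(2000, 20000, 1)
  raw <- suppressWarnings(raw_spectrum(c(3005.4, 3005.6), c(10, 7)))
  s <- resample_to_grid(raw, g)
  expect_equal(s$intensity[3005 - 2000 + 1], 10)
  expect_equal(s$intensity[3006 - 2000 + 1], 7)
  expect_equal(sum(s$intensity != 0), 2)
  expect_true(s$flags$resampled)

  one <- resample_to_grid(raw_spectrum(2000.0, 5), g)
  expect_equal(one$intensity[1], 5)
  expect_equal(sum(one$intensity), 5)

  expect_error(resample_to_grid(raw_spectrum(numeric(0), numeric(0)), g),
               "empty")
})

test_that("resampling never creates more nonzero points than raw peaks", {
  set.seed(11)
  g <- grid_spec(2000, 20000, 1)
  for (i in 1:50) {
    raw <- random_raw_spectrum(sample(1:80, 1))
    s <- resample_to_grid(raw, g)
    expect_lte(sum(s$intensity != 0), length(raw$mz))
  }
})

test_that("log conversion is log10(1 + I) with zero fixed at zero", {
  g <- grid_spec(2000, 2004, 1)
  s <- new_test_grid_spectrum(c(0, 9, 999, 1, 3),
                              g, flags = list(resampled = TRUE,
                                              log_transformed = FALSE,
                                              denoised = FALSE))
  out <- log_transform(s)
  expect_equal(out$intensity[1:3], c(0, 1, 3))
  # order preservation
  x <- sort(runif(5, 0, 100))
  s$intensity <- x
  expect_false(is.unsorted(log_transform(s)$intensity, strictly = TRUE))
  expect_error(log_transform(out), "already")
})

test_that("denoiser reproduces the hand-enumerated window example", {
  g <- grid_spec(2000, 2009, 1)
  s <- new_test_grid_spectrum(c(5, 1, 1, 1, 1, 9, 1, 1, 1, 1), g)
  p <- denoise_params(window_width = 5, keep_fraction = 0.2)
  out <- denoise(s, p)
  expect_equal(out$intensity, c(5, 0, 0, 0, 0, 9, 0, 0, 0, 0))
  expect_true(out$flags$denoised)
})

test_that("all-zero and constant spectra are handled deterministically", {
  g <- grid_spec(2000, 2019, 1)
  z <- new_test_grid_spectrum(numeric(20), g)
  expect_equal(denoise(z, denoise_params(5, 0.2))$intensity, numeric(20))
  cst <- new_test_grid_spectrum(rep(3, 20), g)
  out1 <- denoise(cst, denoise_params(5, 0.2))$intensity
  out2 <- denoise(cst, denoise_params(5, 0.2))$intensity
  expect_identical(out1, out2)
  expect_equal(out1, naive_denoise(rep(3, 20), 5, 0.2))
})

test_that("denoiser equals the naive re-ranking oracle on random spectra", {
  set.seed(101)
  for (i in 1:120) {
    n <- sample(50:400, 1)
    w <- sample(2:min(n, 120), 1)
    kf <- runif(1, 0.05, 1)
    rule <- sample(c("union", "per_window"), 1)
    x <- numeric(n)
    nz <- sample.int(n, sample(1:n, 1))
    x[nz] <- rlnorm(length(nz), 3, 1)
    g <- grid_spec(2000, 2000 + n - 1, 1)
    s <- new_test_grid_spectrum(x, g)
    out <- denoise(s, denoise_params(w, kf, combine_rule = rule))
    expect_identical(out$intensity, naive_denoise(x, w, kf, rule = rule))
  }
})

test_that("denoiser output support is a subset and windows keep <= ceil(fw)", {
  set.seed(5)
  for (i in 1:20) {
    s <- random_grid_spectrum(n = 300, density = 0.5)
    w <- 50
    kf <- 0.2
    out <- denoise(s, denoise_params(w, kf))
    expect_true(all(out$intensity[s$intensity == 0] == 0))
    expect_true(all(out$intensity %in% c(0, s$intensity)))
    # per-window marking keeps exactly ceil(kf*w) points by construction;
    # check via the oracle's marking on a few windows
    k <- ceiling(kf * w)
    for (st in c(1, 100, 251)) {
      idx <- st:(st + w - 1)
      marked <- idx[order(-s$intensity[idx], idx)][seq_len(k)]
      expect_length(marked, k)
    }
  }
})

test_that("retained support is invariant to strictly increasing transforms", {
  set.seed(9)
  for (i in 1:25) {
    s <- random_grid_spectrum(n = 250, density = 0.3)
    p <- denoise_params(40, 0.2)
    base <- denoise(s, p)$intensity != 0
    s2 <- s
    s2$intensity <- sqrt(s$intensity) + 2 * s$intensity  # strictly increasing
    expect_identical(denoise(s2, p)$intensity != 0, base)
  }
})

test_that("pipeline composes stages and both orders share a support", {
  set.seed(13)
  g <- grid_spec(2000, 20000, 1)
  p <- denoise_params()
  raw <- random_raw_spectrum(60)
  out <- preprocess_pipeline(raw, g, p)
  expect_equal(out$intensity,
               denoise(log_transform(resample_to_grid(raw, g)), p)$intensity)
  expect_true(all(unlist(out$flags)))
  expect_equal(attr(out, "provenance")$order, "log_then_denoise")

  alt <- preprocess_pipeline(raw, g, p, order = "denoise_then_log")
  expect_identical(alt$intensity != 0, out$intensity != 0)

  expect_error(preprocess_pipeline(raw_spectrum(numeric(0), numeric(0)), g, p),
               "empty")
})

test_that("denoise parameter validation rejects bad configurations", {
  expect_error(denoise_params(keep_fraction = 0), "keep_fraction")
  expect_error(denoise_params(keep_fraction = 1.2), "keep_fraction")
  expect_error(denoise_params(window_width = 0.5, step = 1), "window_width")
  g <- grid_spec(2000, 2009, 1)
  s <- new_test_grid_spectrum(rep(1, 10), g)
  expect_error(denoise(s, denoise_params(window_width = 50)), "larger")
})
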