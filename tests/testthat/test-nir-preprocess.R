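test_that("MSC recovers affine-scattered spectra and matches a direct regression", {
  set.seed(1)
  ref <- sin(seq(0, 3 * pi, length.out = 200)) + 2
  expect_equal(as.numeric(msc(ref, ref)), ref)              # identity
  expect_equal(as.numeric(msc(3 + 2 * ref, ref)), ref)      # affine invariance
  x <- ref + rnorm(200, 0, 0.1)
  got <- as.numeric(msc(x, ref))
  # oracle: two-parameter least squares via the normal equations
  A <- cbind(1, ref)
  ab <- solve(crossprod(A), crossprod(A, x))
  expect_equal(got, (x - ab[1]) / ab[2], tolerance = 1e-12)
})

test_that("MSC is idempotent for a fixed reference and flags degenerate spectra", {
  set.seed(2)
  ref <- cumsum(rnorm(80))
  X <- rbind(0.5 + 1.4 * ref + rnorm(80, 0, 0.05),
             -0.2 + 0.7 * ref + rnorm(80, 0, 0.05))
  once <- msc(X, ref)
  twice <- msc(once, ref)
  expect_equal(unclass(twice), unclass(once), tolerance = 1e-9,
               ignore_attr = TRUE)
  flat <- rbind(rep(1, 80))
  expect_error(msc(flat, ref), "degenerate")
  expect_error(msc(X, rep(2, 80)), "constant")
})

test_that("first derivative has closed-form behavior and keeps the length", {
  grid <- seq(100, 1, length.out = 50)  # descending, like a wavenumber axis
  h <- diff(grid)[1]
  expect_equal(first_derivative(rep(3, 50), grid), rep(0, 50))
  ramp <- 2 * seq_len(50)
  expect_equal(first_derivative(ramp, grid), rep(2 / h, 50))
  quad <- grid^2
  d <- first_derivative(quad, grid)
  expect_length(d, 50)
  expect_equal(d[2:49], 2 * grid[2:49], tolerance = 1e-9)  # analytic interior
  expect_error(first_derivative(1:2, c(1, 2)), "at least 3")
  expect_error(first_derivative(1:5, c(1, 2, 4, 8, 16)), "evenly spaced")
})

test_that("Savitzky-Golay reproduces low-degree polynomials and known weights", {
  x <- seq_len(60)
  for (deg in 0:2) {
    poly <- (x / 10)^deg
    expect_equal(savitzky_golay_smooth(poly, 11, 2), poly, tolerance = 1e-9)
  }
  # impulse response, window 5 / order 2: central weight from the solved
  # 5-point quadratic least-squares system
  A <- outer(-2:2, 0:2, `^`)
  w0 <- (solve(crossprod(A), t(A)))[1, 3]
  expect_equal(w0, 17 / 35, tolerance = 1e-12)
  impulse <- c(rep(0, 10), 1, rep(0, 10))
  sm <- savitzky_golay_smooth(impulse, 5, 2)
  expect_equal(sm[11], 17 / 35, tolerance = 1e-12)
  expect_error(savitzky_golay_smooth(1:10, 4, 2), "odd")
  expect_error(savitzky_golay_smooth(1:10, 11, 2), "shorter")
})

test_that("Savitzky-Golay smoothing reduces white-noise variance", {
  set.seed(3)
  for (i in 1:5) {
    noise <- rnorm(500)
    expect_lt(var(savitzky_golay_smooth(noise, 11, 2)), var(noise))
  }
})

test_that("Savitzky-Golay agrees with the signal package filter", {
  skip_if_not_installed("signal")
  set.seed(4)
  x <- cumsum(rnorm(120))
  ours <- savitzky_golay_smooth(x, 11, 3)
  ref <- as.numeric(signal::sgolayfilt(x, p = 3, n = 11))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("binning has the documented lengths and arithmetic", {
  expect_length(bin_spectrum(rnorm(3720), 5), 744)
  x <- rnorm(17)
  expect_equal(as.numeric(bin_spectrum(x, 1)), x)
  expect_equal(as.numeric(bin_spectrum(1:7, 5)), c(3, 6.5))
  # length invariant over sizes and widths
  for (p in c(1, 7, 20, 33)) {
    for (w in c(1, 2, 5, 7)) {
      expect_length(bin_spectrum(seq_len(p), w), ceiling(p / w))
    }
  }
  # binned axis = mean wavenumber per group
  b <- bin_spectrum(rnorm(10), 4, grid = 1:10)
  expect_equal(attr(b, "grid"), c(2.5, 6.5, 9.5))
  expect_error(bin_spectrum(numeric(0), 5), "empty")
})

test_that("replicate median is the pointwise sort-and-middle value", {
  one <- rbind(1:5)
  expect_equal(replicate_median(one), 1:5)
  reps <- rbind(rep(0, 4), rep(1, 4), rep(100, 4))
  expect_equal(replicate_median(reps), rep(1, 4))
  set.seed(5)
  R <- matrix(rnorm(5 * 30), 5, 30)
  oracle <- vapply(seq_len(30), function(j) sort(R[, j])[3], numeric(1))
  expect_equal(replicate_median(R), oracle)
})

test_that("the full NIR chain yields 744 variables from 3720 points", {
  d <- default_dataset()
  ft <- preprocess_nir(d$nir)
  expect_equal(ncol(ft$values), 744)
  expect_equal(nrow(ft$values), 60)
  expect_true(all(is.finite(ft$values)))
  expect_true(all(ft$variables$block == "nir"))
  st <- attr(ft, "preprocess_state")
  expect_length(st$msc_reference, 3720)
})

test_that("MSC shrinks the replicate spread of affine-scattered spectra by >= 50%", {
  set.seed(6)
  truth <- 1 + 0.5 * sin(seq(0, 2 * pi, length.out = 300))
  a <- rnorm(5, 0, 0.3)
  b <- rlnorm(5, 0, 0.2)
  raw <- a + b %o% truth + matrix(rnorm(1500, 0, 0.002), 5, 300)
  corrected <- msc(raw)
  spread <- function(m) mean(apply(m, 2, sd))
  expect_lt(spread(corrected), 0.5 * spread(raw))
})

test_that("single-sample single-replicate input produces a one-row table", {
  grid <- seq(8000, 4000, length.out = 100)
  rs <- replicate_spectra(rbind(1 + exp(-((grid - 6000) / 300)^2)), grid,
                          "s1", c(s1 = "organic"))
  ft <- preprocess_nir(rs, sg_window = 7, bin_width = 5)
  expect_equal(nrow(ft$values), 1)
  expect_equal(ncol(ft$values), 20)
})

test_that("replicate spectra round-trip through CSV", {
  d <- generate_dataset(sim_config(n_organic = 3, n_conventional = 3,
                                   p_lcms = 10, p_nir_raw = 40,
                                   n_nir_replicates = 2, k_exclusive = 1,
                                   k_shift = 1, latent_block_lcms = 3:4,
                                   seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_replicate_spectra(d$nir, path)
  r <- read_replicate_spectra(path)
  expect_equal(r$values, d$nir$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(r$grid, d$nir$grid)
  expect_identical(r$sample_ids, d$nir$sample_ids)
})
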