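test_that("frequency-domain wavelet forms are analytic with unit peaks", {
  specs <- list(morse_wavelet(3, 10), morse_wavelet(3, 20),
                morlet_wavelet(6), bump_wavelet(5, 0.6))
  w_neg <- c(-3, -0.5, 0)
  for (sp in specs) {
    expect_identical(wavelet_freq(sp, 1.3, w_neg), c(0, 0, 0))
    # peak-frequency mapping: value at a*w = peak is exactly 2
    expect_equal(wavelet_freq(sp, 2, peak_omega(sp) / 2), 2,
                 tolerance = 1e-12)
  }
  # morse peak identity at (10/3)^(1/3)
  expect_equal(peak_omega(morse_wavelet(3, 10)), (10 / 3)^(1 / 3))
  # bump support is exactly (mu - sigma, mu + sigma)/a
  bp <- bump_wavelet(5, 0.6)
  a <- 2
  expect_identical(wavelet_freq(bp, a, c(4.39 / a, 5.61 / a)), c(0, 0))
  expect_gt(wavelet_freq(bp, a, 4.5 / a), 0)
  expect_equal(wavelet_freq(bp, a, 5 / a), 2, tolerance = 1e-12)
})

test_that("scale grids are geometric with the documented frequency count", {
  sp <- morse_wavelet(3, 20)
  g <- make_scale_grid(1, 350, 10, sp, 1250)
  expect_identical(length(g$freqs_hz), 85L)
  # one octave at V voices has V frequencies
  g2 <- make_scale_grid(20, 40, 4, sp, 1250)
  expect_identical(length(g2$freqs_hz), 4L)
  # exact geometric spacing and exact peak-frequency scale mapping
  expect_equal(g$freqs_hz[-1] / g$freqs_hz[-85], rep(2^(1 / 10), 84),
               tolerance = 1e-12)
  expect_equal(g$scales * 2 * pi * g$freqs_hz / 1250,
               rep(peak_omega(sp), 85), tolerance = 1e-12)
  expect_error(make_scale_grid(10, 5, 10, sp, 1250), "f_hi")
})

test_that("blockwise overlap-save reproduces the exact full transform", {
  set.seed(31)
  x <- rnorm(10000)
  sp <- morse_wavelet(3, 20)
  g <- make_scale_grid(10, 150, 10, sp, 1250)
  expect_identical(length(g$scales), 40L)
  full <- cwt(x, sp, g, 1250, method = "full")
  ols <- cwt(x, sp, g, 1250, method = "overlap_save")
  expect_lt(max(Mod(full$coefs - ols$coefs)), 1e-8 * max(Mod(full$coefs)))

  # zero in, zero out
  z <- cwt(numeric(2000), sp, g, 1250)
  expect_equal(max(Mod(z$coefs)), 0)
  # a grid built for a faster-sampled recording is rejected at this fs
  g_fast <- make_scale_grid(10, 600, 10, sp, 1250)
  expect_error(cwt(x, sp, g_fast, 1000), "Nyquist")
})

test_that("coefficient rows stay analytic up to near-Nyquist scales", {
  set.seed(32)
  x <- rnorm(4000)
  sp <- morse_wavelet(3, 20)
  g <- make_scale_grid(20, 490, 10, sp, 1000)   # top scales close to Nyquist
  for (method in c("full", "overlap_save")) {
    W <- cwt(x, sp, g, 1000, method = method)
    worst <- max(apply(W$coefs, 1, neg_freq_content))
    expect_lt(worst, 1e-10)
  }
})

test_that("ridges localize, and the transform is linear and shift-equivariant", {
  fs <- 1250
  n <- 6250
  t <- (0:(n - 1)) / fs
  x <- cos(2 * pi * 60 * t)
  sp <- morse_wavelet(3, 20)
  g <- make_scale_grid(10, 300, 16, sp, fs)
  W <- cwt(x, sp, g, fs)
  profile <- rowMeans(Mod(W$coefs))
  expect_identical(which.max(profile), which.min(abs(g$freqs_hz - 60)))

  set.seed(33)
  y <- rnorm(n)
  Wy <- cwt(y, sp, g, fs)
  Wmix <- cwt(2 * x - 0.5 * y, sp, g, fs)
  expect_lt(max(Mod(Wmix$coefs - (2 * W$coefs - 0.5 * Wy$coefs))),
            1e-10 * max(Mod(W$coefs)))

  # periodic boundary: circular shift commutes exactly
  sh <- c(501:n, 1:500)
  Wsh <- cwt(y[sh], sp, g, fs)
  expect_lt(max(Mod(Wsh$coefs - Wy$coefs[, sh])), 1e-10 * max(Mod(Wy$coefs)))
})

test_that("dry run, on-disk rows, and worker counts leave results unchanged", {
  set.seed(34)
  x <- rnorm(3000)
  sp <- morse_wavelet(3, 20)
  g <- make_scale_grid(10, 100, 8, sp, 1000)
  info <- cwt(x, sp, g, 1000, describe = TRUE)
  expect_identical(info$out_shape, c(length(g$scales), 3000))
  expect_identical(info$out_dtype, "complex128")
  expect_identical(info$bytes_required, length(g$scales) * 3000 * 16)

  ref <- cwt(x, sp, g, 1000, method = "overlap_save")
  st <- disk_store_create(tempfile(), info$out_shape, "complex128")
  cwt(x, sp, g, 1000, method = "overlap_save", out = st)
  expect_identical(as.matrix(st), ref$coefs)

  par2 <- cwt(x, sp, g, 1000, method = "overlap_save", n_workers = 2L)
  expect_identical(par2$coefs, ref$coefs)

  bad <- mem_store_create(c(2, 3000), "complex128")
  expect_error(cwt(x, sp, g, 1000, out = bad), "shape")
})
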