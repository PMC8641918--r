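test_that("DPSS tapers satisfy the energy and orthogonality contracts", {
  ts <- get_tapers(1024, 4, 1250)
  expect_identical(nrow(ts$tapers), 5L)    # floor(2*1024*4/1250) - 1
  # unit energy per taper
  expect_lt(max(abs(rowSums(ts$tapers^2) - 1)), 1e-10)
  # pairwise orthogonality
  gram <- ts$tapers %*% t(ts$tapers)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  # concentrations strictly decreasing, leader near-perfect for NW >= 2
  expect_true(all(diff(ts$concentrations) < 0))
  expect_gt(ts$concentrations[1], 0.99)
  expect_true(all(ts$concentrations > 0 & ts$concentrations <= 1))
  expect_error(get_tapers(1024, 700, 1250), "fs/2")
  expect_warning(get_tapers(256, 4, 1250, n_tapers = 4), "concentrated")
})

test_that("tridiagonal route matches the dense concentration eigenproblem", {
  for (n in c(64, 256)) {
    L <- 5L
    w_hz <- 4 * 1250 / n              # time-bandwidth product NW = 4
    ts <- get_tapers(n, w_hz, 1250, n_tapers = L)
    dense <- oracle_dpss_dense(n, w_hz, 1250, L)
    for (l in seq_len(L)) {
      u <- dense$vectors[, l]
      v <- ts$tapers[l, ]
      if (sum(u * v) < 0) u <- -u
      expect_lt(max(abs(u - v)), 1e-8)
    }
    expect_equal(ts$concentrations, dense$values, tolerance = 1e-8)
  }
})

test_that("white-noise level, Parseval consistency, and 1/L variance reduction", {
  fs <- 1250
  n <- 2048
  sigma <- 1.5
  n_seeds <- 100
  ts_multi <- get_tapers(n, 10, fs, n_tapers = 8)
  ts_one <- get_tapers(n, 10, fs, n_tapers = 1)
  psd_multi <- psd_one <- NULL
  for (s in seq_len(n_seeds)) {
    set.seed(1000 + s)
    x <- rnorm(n, sd = sigma)
    psd_multi <- rbind(psd_multi, mtm_spectrum(x, 10, fs, tapers = ts_multi)$psd)
    psd_one <- rbind(psd_one, mtm_spectrum(x, 10, fs, tapers = ts_one)$psd)
  }
  interior <- 30:(ncol(psd_multi) - 30)   # avoid DC/Nyquist edge bins
  # one-sided white level 2*sigma^2/fs
  expect_equal(mean(psd_multi[, interior]), 2 * sigma^2 / fs,
               tolerance = 0.05)
  # total one-sided power integrates back to the variance
  tot <- mean(rowSums(psd_multi) * fs / 2048)
  expect_equal(tot, sigma^2, tolerance = 0.05)
  # averaging L orthogonal estimators divides the per-bin variance by ~L
  ratio <- mean(apply(psd_multi[, interior], 2, var)) /
           mean(apply(psd_one[, interior], 2, var))
  expect_equal(ratio, 1 / 8, tolerance = 0.25)
  # psd is nonnegative and zero input maps to zero
  expect_true(all(psd_multi >= 0))
  expect_equal(mtm_spectrum(numeric(512), 10, fs)$psd, numeric(257))
})

test_that("tones localize at the right bin with ~2W support", {
  fs <- 1250
  n <- 4096
  t <- (0:(n - 1)) / fs
  res <- mtm_spectrum(cos(2 * pi * 200 * t), 10, fs)
  peak <- res$freqs_hz[which.max(res$psd)]
  # the W-wide smoothing flattens the peak; locate it well inside W
  expect_lt(abs(peak - 200), 3)
  # half-power support approximately the 2W smoothing window
  half <- res$freqs_hz[res$psd >= max(res$psd) / 2]
  width <- diff(range(half))
  expect_gt(width, 10)
  expect_lt(width, 35)
})

test_that("spectrogram windowing arithmetic and shift invariance", {
  fs <- 1250
  x <- rep(1.7, 4000)
  sg <- mtm_spectrogram(x, 10, fs, nperseg = 625, noverlap = 312)
  expect_identical(ncol(sg$coefs), as.integer(1 + floor((4000 - 625) / 313)))
  # constant input: every column identical to the single-window spectrum
  ref <- mtm_spectrum(x[1:625], 10, fs)$psd
  for (k in seq_len(ncol(sg$coefs)))
    expect_equal(sg$coefs[, k], ref, tolerance = 1e-12)
  expect_equal(sg$times_s[1], (625 - 1) / 2 / fs)
  expect_equal(diff(sg$times_s)[1], 313 / fs)

  # two-tone switch: column argmax moves across the boundary
  n <- 8192
  t <- (0:(n - 1)) / fs
  x2 <- c(cos(2 * pi * 200 * t[1:(n / 2)]), cos(2 * pi * 50 * t[(n / 2 + 1):n]))
  sg2 <- mtm_spectrogram(x2, 10, fs, nperseg = 1024, noverlap = 512)
  fmax <- sg2$freqs_hz[apply(sg2$coefs, 2, which.max)]
  expect_lt(max(abs(fmax[1:3] - 200)), 10)
  expect_lt(max(abs(tail(fmax, 3) - 50)), 10)
  expect_error(mtm_spectrogram(x, 10, fs, nperseg = 5000, noverlap = 0),
               "exceeds")
})
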