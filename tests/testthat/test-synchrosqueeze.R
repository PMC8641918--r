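test_that("time-derivative pipeline is consistent with finite differences", {
  fs <- 1000
  n <- 4000
  t <- (0:(n - 1)) / fs
  sp <- morse_wavelet(3, 20)
  g <- make_scale_grid(10, 100, 8, sp, fs)

  # constant input has (numerically) zero derivative everywhere
  dc <- cwt_time_derivative(rep(2, n), sp, g, fs)
  x <- cos(2 * pi * 30 * t)
  dW <- cwt_time_derivative(x, sp, g, fs)
  expect_lt(max(Mod(dc$coefs)), 1e-9 * max(Mod(dW$coefs)))

  # derivative of the CWT ~ CWT of the (circular central) finite difference
  dx <- (x[c(2:n, 1)] - x[c(n, 1:(n - 1))]) * fs / 2
  Wdx <- cwt(dx, sp, g, fs)
  srow <- which.min(abs(g$freqs_hz - 30))
  interior <- 500:3500
  expect_lt(rel_err(dW$coefs[srow, interior], Wdx$coefs[srow, interior]),
            0.01)

  # linearity in the input
  set.seed(41)
  y <- rnorm(n)
  dY <- cwt_time_derivative(y, sp, g, fs)
  dMix <- cwt_time_derivative(3 * x + y, sp, g, fs)
  expect_lt(max(Mod(dMix$coefs - (3 * dW$coefs + dY$coefs))),
            1e-10 * max(Mod(dW$coefs)))
})

test_that("phase transform recovers tone frequency and ignores scaling", {
  fs <- 1000
  n <- 4000
  t <- (0:(n - 1)) / fs
  sp <- morse_wavelet(3, 20)
  g <- make_scale_grid(10, 100, 8, sp, fs)
  # 40 Hz is an integer number of cycles here, so the coefficient rows
  # are exact complex exponentials and omega_f = 40 at every valid point
  x <- cos(2 * pi * 40 * t)
  W <- cwt(x, sp, g, fs)
  dW <- cwt_time_derivative(x, sp, g, fs)
  # scales within an octave of the tone: the coefficient rows are pure
  # 40 Hz exponentials there (farther scales sink below the fp noise
  # floor of the transform and carry no usable phase)
  near <- which.min(abs(g$freqs_hz - 40))
  for (srow in near + (-4:4)) {
    pt <- phase_transform(W$coefs[srow, ], dW$coefs[srow, ])
    expect_equal(median(pt, na.rm = TRUE), 40, tolerance = 1e-6)
  }
  srow <- near
  pt <- phase_transform(W$coefs[srow, ], dW$coefs[srow, ])
  expect_lt(max(abs(pt - 40), na.rm = TRUE), 0.5)
  # invariant under real rescaling of W (both rows scale together)
  pt2 <- phase_transform(-2.5 * W$coefs[srow, ], -2.5 * dW$coefs[srow, ])
  expect_equal(pt2, pt)
  # an all-zero row is entirely unmapped
  expect_true(all(is.na(phase_transform(complex(100), complex(100)))))
})

test_that("accumulation conserves mapped CWT mass per column exactly", {
  fs <- 1000
  set.seed(42)
  sig <- make_tones(c(25, 97), c(1, 0.8), fs, 4, noise_sd = 0.3, seed = 5)
  sp <- morse_wavelet(3, 20)
  g <- make_scale_grid(10, 300, 10, sp, fs)
  ss <- wsst(sig$samples, fs, sp, g)
  W <- cwt(sig$samples, sp, g, fs)
  dW <- cwt_time_derivative(sig$samples, sp, g, fs)
  omega_f <- phase_transform(W$coefs, dW$coefs, 1e-8)
  edges <- ss$bin_edges_hz
  mapped <- !is.na(omega_f) & omega_f >= edges[1] &
            omega_f < edges[length(edges)]
  for (col in c(100, 1000, 2000, 3900)) {
    lhs <- sum(ss$coefs[, col])
    rhs <- sum(W$coefs[mapped[, col], col])
    expect_lt(Mod(lhs - rhs), 1e-10 * max(Mod(rhs), 1e-12))
  }
  # bin edges strictly increasing and centered on the grid
  expect_true(all(diff(edges) > 0))
  expect_identical(ss$bin_freqs_hz, g$freqs_hz)
})

test_that("tones concentrate into narrow disjoint ridges sharper than the CWT", {
  fs <- 1000
  sp <- morse_wavelet(3, 20)
  g <- make_scale_grid(10, 300, 10, sp, fs)
  tone <- make_tones(97, 1, fs, 4)
  ss <- wsst(tone$samples, fs, sp, g)
  W <- cwt(tone$samples, sp, g, fs)
  ib <- findInterval(97, ss$bin_edges_hz)
  interior <- seq(500, 3500, by = 250)
  for (col in interior) {
    mass <- Mod(ss$coefs[, col])
    expect_gt(sum(mass[(ib - 1):(ib + 1)]) / sum(mass), 0.90)
    # squeezed support is narrower than the CWT column support
    n_sst <- sum(mass > 0.1 * max(mass))
    n_cwt <- sum(Mod(W$coefs[, col]) > 0.1 * max(Mod(W$coefs[, col])))
    expect_lt(n_sst, n_cwt)
  }
  # reassignment only moves mass along frequency: time axis untouched
  expect_identical(ss$times_s, W$times_s)
  expect_identical(ncol(ss$coefs), ncol(W$coefs))

  # two well-separated tones occupy two disjoint ridges
  two <- make_tones(c(8, 200), c(1, 1), fs, 4)
  g2 <- make_scale_grid(4, 300, 10, sp, fs)   # grid spans both tones
  ss2 <- wsst(two$samples, fs, sp, g2)
  i8 <- findInterval(8, ss2$bin_edges_hz)
  i200 <- findInterval(200, ss2$bin_edges_hz)
  col_mass <- rowMeans(Mod(ss2$coefs[, 500:3500]))
  near <- unique(pmax(1, pmin(length(col_mass),
                              c(i8 + (-2:2), i200 + (-2:2)))))
  expect_lt(sum(col_mass[-near]) / sum(col_mass), 0.05)

  # backend independence: blockwise CWT gives the same squeezed picture
  ss_ols <- wsst(tone$samples, fs, sp, g, method = "overlap_save")
  expect_lt(max(Mod(ss_ols$coefs - ss$coefs)),
            1e-7 * max(Mod(ss$coefs)))
})
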