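test_that("lowpass prototype matches its closed form and limits", {
  # center tap is the w0/pi limit of sin(w0 n)/(pi n)
  set.seed(11)
  for (i in 1:5) {
    f1 <- runif(1, 1, 100)
    f2 <- f1 + runif(1, 0.5, 50)
    fs <- 625
    if (f2 >= fs / 2) next
    h <- lowpass_prototype(f1, f2, fs, p = sample(1:4, 1), n_taps = 101)
    expect_equal(h[51], pi * (f1 + f2) / fs / pi, tolerance = 1e-12)
  }
  # degenerate zero-width transition: ideal sinc low-pass
  h <- lowpass_prototype(100, 100, 1000, p = 2, n_taps = 201)
  n <- -100:100
  w0 <- 2 * pi * 100 / 1000
  ideal <- ifelse(n == 0, w0 / pi, sin(w0 * n) / (pi * n))
  expect_equal(h, ideal, tolerance = 1e-14)

  # term-by-term scalar evaluation at random offsets
  h <- lowpass_prototype(6, 10, 1250, p = 2, n_taps = 1001)
  set.seed(42)
  idx <- sample(1001, 20)
  w0 <- 2 * pi * 8 / 1250
  dw <- 2 * pi * 4 / 1250
  for (i in idx) {
    n <- i - 501
    expected <- if (n == 0) w0 / pi else {
      xs <- dw * n / 4  # 2p = 4
      sin(w0 * n) / (pi * n) * (sin(xs) / xs)^2
    }
    expect_equal(h[i], expected, tolerance = 1e-13)
  }
  expect_error(lowpass_prototype(6, 10, 1250, 2, 100), "odd")
  expect_error(filter_spec(list(c(10, 6)), c(0, 1), 1250), "f1 < f2")
})

test_that("designed filters are exactly linear phase with integer delay", {
  specs <- list(
    filter_spec(list(c(4, 6), c(10, 12)), c(0, 1, 0), 1250, 2, 501),
    filter_spec(list(c(50, 60)), c(1, 0), 1000, 3, 251),
    filter_spec(list(c(5, 10), c(40, 50), c(90, 100)), c(0, 1, 0.5, 0.25),
                500, 1, 401))
  for (sp in specs) {
    fir <- design_fir(sp)
    expect_equal(fir$taps, rev(fir$taps), tolerance = 1e-12)
    expect_identical(group_delay(fir) %% 1, 0)
  }
  expect_error(filter_spec(list(c(4, 6)), c(0, 1, 0), 1250), "one more")
})

test_that("multiband composition hits band gains and transition midpoints", {
  # transition midpoints sit at the mean of adjacent gains: -6.02 dB for
  # a full 0 <-> 1 step
  fir <- design_fir(filter_spec(list(c(4, 6), c(10, 12)), c(0, 1, 0),
                                1250, 2, 12501))
  mids <- 20 * log10(Mod(frequency_response(fir, c(5, 11))))
  expect_equal(mids, c(-6.0206, -6.0206), tolerance = 0.02)

  # arbitrary-gain staircase: flat-band interiors within 2% of request
  fir2 <- design_fir(filter_spec(list(c(20, 30), c(60, 70), c(100, 110)),
                                 c(0, 1, 0.5, 0), 500, 2, 4001))
  gain_at <- function(f) Mod(frequency_response(fir2, f))
  expect_lt(max(gain_at(seq(1, 10, 1))), 0.02)
  expect_equal(gain_at(seq(40, 50, 1)), rep(1, 11), tolerance = 0.02)
  expect_equal(gain_at(seq(80, 90, 1)), rep(0.5, 11), tolerance = 0.02)
  expect_lt(max(gain_at(seq(120, 249, 1))), 0.02)

  # equal gains everywhere telescope to a pure scaled impulse
  fir3 <- design_fir(filter_spec(list(c(10, 20), c(50, 60)), c(0.7, 0.7, 0.7),
                                 500, 2, 101))
  delta <- numeric(101)
  delta[51] <- 0.7
  expect_equal(fir3$taps, delta, tolerance = 1e-12)

  # larger spline power steepens the roll-off: stop-band energy within
  # one transition width of the edge is non-increasing in p
  energies <- vapply(1:4, function(p) {
    h <- lowpass_prototype(45, 55, 500, p, 1001)
    f <- seq(55, 65, 0.25)
    sum(Mod(oracle_dtft(h, f, 500))^2)
  }, numeric(1))
  expect_true(all(diff(energies) <= 1e-10))
})

test_that("tap-count search meets the measured attenuation and is monotone", {
  m60 <- estimate_taps(4, 1250, p = 2, atten_db = 60)
  # verify against a direct response evaluation of the canonical design
  dw <- 4
  f1 <- (1250 / 2 - dw) / 2
  h <- lowpass_prototype(f1, f1 + dw, 1250, 2, m60)
  f_stop <- seq(f1 + dw + dw / 2, 624, length.out = 400)
  expect_lt(20 * log10(max(Mod(oracle_dtft(h, f_stop, 1250)))), -60)

  expect_gte(estimate_taps(2, 1250, p = 2, atten_db = 60), m60)
  expect_identical(estimate_taps(4, 1250, p = 2, atten_db = 0), 3L)
  expect_error(estimate_taps(4, 1250, 2, atten_db = 300, max_taps = 2^12),
               "unreachable")
})

test_that("frequency response equals the brute-force DTFT", {
  set.seed(7)
  taps <- rnorm(31)
  fir <- structure(list(taps = taps, fs = 1000, group_delay_samples = 15,
                        spec = NULL), class = "fir_filter")
  freqs <- runif(50, 0, 500)
  expect_equal(frequency_response(fir, freqs), oracle_dtft(taps, freqs, 1000),
               tolerance = 1e-10)

  # unit impulse has unit response everywhere
  dirac <- c(1)
  expect_equal(frequency_response(dirac, c(0, 123.4, 500), fs = 1000),
               rep(1 + 0i, 3))

  # linear phase: unwrapped passband phase slope is -group_delay*2*pi/fs
  fir <- design_fir(filter_spec(list(c(100, 120)), c(1, 0), 1000, 2, 201))
  f <- seq(5, 50, 1)
  ph <- signal::unwrap(Arg(frequency_response(fir, f)))
  slope <- unname(coef(lm(ph ~ f))[2])
  expect_equal(slope, -group_delay(fir) * 2 * pi / 1000, tolerance = 1e-6)

  expect_error(frequency_response(fir, 501), "fs/2")
})
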