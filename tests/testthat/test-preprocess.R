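make_series <- function(data, wl, fs = 1) intensity_series(data, wl, fs)

test_that("attenuation conversion follows log10(I0/I) and is invertible", {
  a <- array(c(1e5, 1e4, 2e5, 5e4), c(1, 2, 2))
  I <- make_series(a, c(760, 820))
  A <- intensity_to_attenuation(I, I0 = 1e5)
  expect_equal(A$data[1, 1, 1], 0)
  expect_equal(A$data[1, 2, 1], 1)
  # doubling intensity lowers attenuation by log10(2) everywhere
  A2 <- intensity_to_attenuation(make_series(2 * a, c(760, 820)), I0 = 1e5)
  expect_equal(A2$data, A$data - log10(2), tolerance = 1e-12)
  # round trip to relative precision 1e-12
  I2 <- attenuation_to_intensity(A)
  expect_equal(I2$data, I$data, tolerance = 1e-12)
  expect_error(intensity_series(array(c(1, -1), c(1, 1, 2)), 800),
               "strictly positive")
})

test_that("band-pass rejects DC, keeps in-band and removes out-of-band sine", {
  fs <- 1; n <- 400
  t <- seq_len(n) - 1
  const <- attenuation_series(array(3, c(1, 1, n)), 800, fs)
  out <- bandpass(const)
  expect_equal(max(abs(out$data)), 0)

  # oracle: squared magnitude of the same Butterworth transfer function
  # (forward-backward application squares the magnitude), evaluated on the
  # unit circle
  gain_at <- function(f_hz) {
    filt <- signal::butter(5, c(0.01, 0.25) / (fs / 2), type = "pass")
    z <- exp(-1i * 2 * pi * f_hz / fs)
    k <- seq_along(filt$b) - 1
    Mod(sum(filt$b * z^k) / sum(filt$a * z^k))^2
  }
  # in-band sinusoid (0.1 Hz): amplitude preserved within 5% of the oracle
  inband <- bandpass(attenuation_series(array(sin(2 * pi * 0.1 * t),
                                              c(1, 1, n)), 800, fs))
  amp <- sqrt(2 * mean(inband$data[1, 1, 101:300]^2))  # RMS amplitude
  expect_equal(amp, gain_at(0.1), tolerance = 0.05)
  # out-of-band sinusoid (0.4 Hz): oracle response is tiny and the measured
  # amplitude is attenuated below 10% of the input
  expect_lt(gain_at(0.4), 1e-4)
  expect_lt(max(abs(bandpass(attenuation_series(
    array(sin(2 * pi * 0.4 * t), c(1, 1, n)), 800, fs))$data[1, 1, 100:300])),
    0.1)
  # output mean ~ 0 (DC removed)
  expect_lt(abs(mean(inband$data)), 1e-2)
  expect_error(bandpass(const, low_hz = 0.2, high_hz = 0.6), "invalid")
})

test_that("block averaging yields one 40-sample epoch and averages across epochs", {
  fs <- 1
  par <- paradigm()
  ep <- sin(2 * pi * seq(0, 39) / 40) + 2          # one 40-s epoch shape
  x <- rep(ep, 10)
  s <- attenuation_series(array(x, c(1, 1, 400)), 800, fs)
  out <- block_average(s, par)
  expect_identical(dim(out$data)[3], 40L)
  # identical epochs: output equals the single re-zeroed epoch
  expect_equal(out$data[1, 1, ], ep - ep[1], tolerance = 1e-12)
  # re-zeroing switchable
  raw <- block_average(s, par, rezero = FALSE)
  expect_equal(raw$data[1, 1, ], ep, tolerance = 1e-12)
  expect_error(block_average(s, paradigm(onsets_s = seq(0, 540, 60),
                                         n_epochs = 10)), "past the recording")
})

test_that("block averaging reduces independent noise variance about tenfold", {
  # Monte-Carlo oracle: variance of the mean of 10 independent epochs
  set.seed(101)
  par <- paradigm()
  ratios <- replicate(50, {
    noise <- rnorm(400)
    s <- attenuation_series(array(noise, c(1, 1, 400)), 800, 1)
    out <- block_average(s, par, rezero = FALSE)
    var(out$data[1, 1, ]) / var(noise)
  })
  expect_equal(mean(ratios), 1 / 10, tolerance = 0.3)
})

test_that("filtering and averaging commute with channel-wise scaling", {
  set.seed(41)
  a <- array(rnorm(2 * 2 * 400), c(2, 2, 400))
  s <- attenuation_series(a, c(760, 820), 1)
  s3 <- attenuation_series(3 * a, c(760, 820), 1)
  expect_equal(bandpass(s3)$data, 3 * bandpass(s)$data, tolerance = 1e-8)
  expect_equal(block_average(s3, paradigm())$data,
               3 * block_average(s, paradigm())$data, tolerance = 1e-12)
})

test_that("wavelength selection picks nearest samples on the 17-point grid", {
  wl <- seq(730, 910, by = 1)
  nt <- 5
  a <- array(rep(wl, each = 2), c(2, length(wl), nt))
  s <- attenuation_series(a, wl, 1)
  sel <- select_wavelengths(s)
  expect_identical(length(sel$wavelengths_nm), 17L)
  expect_equal(sel$wavelengths_nm, seq(740, 900, 10))
  expect_equal(sel$data[1, , 1], seq(740, 900, 10))  # value == wavelength
  # nearest-sample rule with a fractional grid point
  sel2 <- select_wavelengths(s, 745.4)
  expect_equal(sel2$data[1, 1, 1], 745)
  # identity when the grid equals the measured axis
  expect_equal(select_wavelengths(s, wl)$data, s$data)
  expect_error(select_wavelengths(s, 920), "outside measured range")
})

test_that("channel time-series survive a CSV round trip", {
  set.seed(3)
  a <- array(abs(rnorm(2 * 3 * 4)) + 1, c(2, 3, 4))
  s <- intensity_series(a, c(740, 800, 860), sample_rate = 2)
  f <- tempfile(fileext = ".csv")
  write_series_csv(s, f)
  r <- read_series_csv(f)
  expect_equal(r$data, s$data, tolerance = 1e-12)
  expect_equal(r$wavelengths_nm, s$wavelengths_nm)
  expect_equal(r$sample_rate, 2)
  unlink(f)
})
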