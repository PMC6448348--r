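fs <- 1000
tt <- (0:999) / fs

test_that("hilbert attributes of tones", {
  x <- cos(2 * pi * 10 * tt)
  a <- hilbert_attributes(x, fs)
  interior <- edge_mask(1000, 0.05)
  expect_true(all(abs(a$amplitude[interior] - 1) < 0.02))
  expect_true(all(abs(a$frequency[interior] - 10) < 0.1))
  # phase at a sample-aligned peak of the cosine is ~0
  expect_lt(abs(a$phase[201]), 0.01)  # t = 0.2 s, 2 full cycles

  s <- hilbert_attributes(sin(2 * pi * 10 * tt), fs)
  dphi <- circ_distance(a$phase[interior], s$phase[interior])
  expect_equal(mean(dphi), pi / 2, tolerance = 0.01)
  expect_lt(sd(dphi), 0.01)

  expect_error(hilbert_attributes(rep(1, 100), fs), "constant")
})

test_that("instantaneous frequency of an IMF is positive away from edges", {
  set.seed(3)
  x <- tone(9, fs) + 0.6 * tone(23, fs, phase = 1) + 0.1 * rnorm(1000)
  dec <- emd_decompose(x, fs = fs)
  w <- which.max(rowSums(dec$imfs^2))
  a <- hilbert_attributes(dec$imfs[w, ], fs)
  expect_true(all(a$frequency[edge_mask(1000, 0.05)] > 0))
})

test_that("FIR bandpass: passband, stopband, linearity, zero phase", {
  x10 <- tone(10, fs)
  yp <- fir_bandpass(x10, default_bands()$alpha, fs, pad = TRUE)
  expect_gt(sum(yp^2) / sum(x10^2), 0.9)
  ys <- fir_bandpass(x10, default_bands()$beta2, fs, pad = TRUE)
  expect_lt(sum(ys^2) / sum(x10^2), 0.01)

  set.seed(4)
  a <- rnorm(2000); b <- rnorm(2000)
  bd <- default_bands()$beta1
  lhs <- fir_bandpass(2 * a + 3 * b, bd, fs)
  rhs <- 2 * fir_bandpass(a, bd, fs) + 3 * fir_bandpass(b, bd, fs)
  expect_lt(max(abs(lhs - rhs)), 1e-9)

  # zero phase: cross-correlation peak of filtered in-band tone at lag 0
  xin <- tone(18, fs, duration = 2)
  yf <- fir_bandpass(xin, bd, fs)
  cc <- ccf(yf, xin, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(fir_bandpass(rnorm(100), default_bands()$theta, fs),
               "zero-pad")
})

test_that("preprocessing: window length, line-noise attenuation, DC removal", {
  set.seed(5)
  fs_raw <- 5000
  n_raw <- 2.2 * fs_raw
  traw <- -1.6 + (0:(n_raw - 1)) / fs_raw
  sig <- sin(2 * pi * 11 * traw)
  raw <- sensor_epoch(rbind(sig + 0.5 * sin(2 * pi * 60 * traw) + 4,
                            sig), fs_raw, onset = -1.6)
  out <- preprocess_epoch(raw)
  expect_equal(ncol(out$data), 478)
  expect_equal(out$fs, 1000)

  # 60 Hz contamination attenuated as the filter-response oracle predicts
  # (forward-backward 5th-order Butterworth: |H|^2 at each frequency)
  bf <- signal::butter(5, c(1, 45) / 500, type = "pass")
  Hof <- function(f) {
    z <- exp(-1i * 2 * pi * f / 1000)
    abs(sum(bf$b * z^(0:(length(bf$b) - 1))) /
          sum(bf$a * z^(0:(length(bf$a) - 1))))^2
  }
  att_pred_db <- -20 * log10(Hof(60) / Hof(11))
  # amplitude estimates by least squares on the output window
  tw <- (0:477) / 1000
  amp_at <- function(y, f) {
    fit <- lm(y ~ cos(2 * pi * f * tw) + sin(2 * pi * f * tw))
    sqrt(sum(coef(fit)[2:3]^2))
  }
  a11 <- amp_at(out$data[1, ], 11)
  a60 <- amp_at(out$data[1, ], 60)
  att_meas_db <- -20 * log10((a60 / a11) / 0.5)  # input ratio 0.5
  expect_gt(att_meas_db, 20)
  expect_lt(abs(att_meas_db - att_pred_db), 5)

  # DC offset of 4 is strongly reduced by the 1 Hz highpass edge (full
  # rejection needs a window longer than the ~160 ms highpass time
  # constant, so a short epoch retains a residual)
  expect_lt(abs(mean(out$data[1, ])), 0.5 * 4)

  short <- sensor_epoch(matrix(rnorm(2 * 100), 2), 1000, onset = -0.1)
  expect_error(preprocess_epoch(short), "window")
})
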