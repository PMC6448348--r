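fs <- 1000
t1 <- (0:999) / fs

test_that("extrema detection: tones, ramps, plateaus", {
  ex <- find_extrema(sin(2 * pi * 4 * t1))
  expect_length(ex$maxima, 4)
  expect_length(ex$minima, 4)
  expect_false(ex$monotone)

  expect_true(find_extrema(seq(0, 1, length.out = 100))$monotone)

  plat <- find_extrema(c(0, 1, 1, 0))
  expect_equal(plat$maxima, 2L)  # plateau midpoint
  expect_length(plat$minima, 0)

  # indices strictly increasing
  ex2 <- find_extrema(sin(2 * pi * 7 * t1) + 0.2 * sin(2 * pi * 31 * t1))
  expect_true(all(diff(ex2$maxima) > 0))
  expect_true(all(diff(ex2$minima) > 0))
})

test_that("envelopes: symmetry, offset equivariance, odd symmetry", {
  A <- 2.5
  x <- A * sin(2 * pi * 8 * t1)
  env <- envelopes(x)
  interior <- 100:900
  expect_lt(max(abs(env$local_mean[interior])), 0.05 * A)
  expect_equal(env$local_mean, (env$upper + env$lower) / 2)

  env_off <- envelopes(x + 3)
  expect_lt(max(abs(env_off$local_mean[interior] - 3)), 0.05 * A)

  env_neg <- envelopes(-x)
  expect_equal(env_neg$upper, -env$lower, tolerance = 1e-12)
  expect_equal(env_neg$lower, -env$upper, tolerance = 1e-12)

  expect_error(envelopes(seq(0, 1, length.out = 50)), "maxima|minima")
})

test_that("sifting: tones are fixed points, homogeneity, mode ordering", {
  x <- sin(2 * pi * 10 * t1)
  s <- sift(x)
  expect_gt(cor(s$imf, x), 0.999)
  expect_equal(s$imf + s$residual_input, x, tolerance = 1e-12)

  y <- sin(2 * pi * 4 * t1) + sin(2 * pi * 18 * t1)
  s1 <- sift(y)
  s2 <- sift(2 * y)
  expect_equal(s2$imf, 2 * s1$imf, tolerance = 1e-9)
  expect_equal(spectral_peak(s1$imf, fs), 18)

  expect_error(sift(seq_len(100) / 10), "monotone")
})

test_that("emd reconstruction is exact and modes land in the right bands", {
  y <- sin(2 * pi * 4 * t1) + 0.7 * sin(2 * pi * 18 * t1 + 1)
  dec <- emd_decompose(y, fs = fs)
  recon <- colSums(dec$imfs) + dec$residual
  expect_lt(max(abs(recon - y)), 1e-10 * max(abs(y)))

  peaks <- vapply(seq_len(nrow(dec$imfs)),
                  function(w) spectral_peak(dec$imfs[w, ], fs), numeric(1))
  expect_true(any(peaks >= 3.5 & peaks <= 4.5))
  expect_true(any(peaks >= 17.5 & peaks <= 18.5))

  # constant input: no IMFs, residual carries everything
  const <- emd_decompose(rep(2, 1000), fs = fs)
  expect_equal(nrow(const$imfs), 0)
  expect_equal(const$residual, rep(2, 1000))
})

test_that("amplitude equivariance and single-tone energy concentration", {
  set.seed(7)
  y <- sin(2 * pi * 6 * t1 + 0.3) + 0.5 * sin(2 * pi * 25 * t1)
  d1 <- emd_decompose(y, fs = fs)
  d2 <- emd_decompose(3 * y, fs = fs)
  expect_equal(nrow(d1$imfs), nrow(d2$imfs))
  expect_equal(d2$imfs, 3 * d1$imfs, tolerance = 1e-9)

  x <- sin(2 * pi * 10 * t1)
  dx <- emd_decompose(x, fs = fs)
  energies <- rowSums(dx$imfs^2)
  expect_gt(max(energies) / sum(x^2), 0.99)

  # successive IMFs slow down (mean instantaneous frequency non-increasing)
  mix <- sin(2 * pi * 5 * t1) + sin(2 * pi * 21 * t1 + 2)
  dm <- emd_decompose(mix, fs = fs)
  keep <- rowSums(dm$imfs^2) > 0.01 * sum(mix^2)
  cent <- vapply(which(keep), function(w) spectral_centroid(dm$imfs[w, ], fs),
                 numeric(1))
  expect_true(all(diff(cent) <= 2))
})

test_that("is_imf matches the two conditions", {
  expect_true(is_imf(sin(2 * pi * 10 * t1)))
  expect_false(is_imf(seq(0, 1, length.out = 1000)))
  expect_false(is_imf(sin(2 * pi * 10 * t1) + 5))
})
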