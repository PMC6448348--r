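fs <- 1000
tt <- (0:999) / fs

test_that("direction vectors: unit norm, determinism, 2-D spacing", {
  d <- direction_vectors(5, 16, seed = 1)
  expect_equal(dim(unclass(d)), c(16, 5))
  expect_true(all(abs(sqrt(rowSums(unclass(d)^2)) - 1) < 1e-12))
  expect_identical(unclass(direction_vectors(5, 16, seed = 1)), unclass(d))

  # n = 2: equally spaced angles, mean gap 2*pi/K (brute-force angles)
  d2 <- unclass(direction_vectors(2, 64, seed = 3))
  ang <- sort(atan2(d2[, 2], d2[, 1]))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  expect_equal(mean(gaps), 2 * pi / 64, tolerance = 1e-9)
  expect_lt(max(abs(gaps - 2 * pi / 64)), 1e-9)

  expect_error(direction_vectors(1, 8), "univariate")
  expect_warning(direction_vectors(8, 4, seed = 1), "K < n")
})

test_that("multivariate local mean: symmetry and shift equivariance", {
  x <- sin(2 * pi * 8 * tt)
  X <- rbind(x, x, x)
  dirs <- direction_vectors(3, 16, seed = 2)
  m <- multivariate_mean(X, dirs)
  expect_lt(max(abs(m[, 100:900])), 0.05)

  shift <- c(1, -2, 0.5)
  m2 <- multivariate_mean(X + shift, dirs)
  expect_equal(unclass(m2), unclass(m) + shift, tolerance = 1e-9,
               ignore_attr = TRUE)

  expect_error(multivariate_mean(matrix(x, 1), direction_vectors(2, 8)),
               "univariate|channels")
  Xtrend <- rbind(seq_len(100), seq_len(100) * 2)
  expect_error(suppressWarnings(
    multivariate_mean(Xtrend, direction_vectors(2, 8, seed = 1))), "trend")
})

test_that("MEMD: per-channel reconstruction, alignment, homogeneity", {
  set.seed(11)
  base <- sin(2 * pi * 4 * tt) + sin(2 * pi * 18 * tt + 0.5)
  X <- rbind(base, sin(2 * pi * 4 * tt + 0.2) + sin(2 * pi * 18 * tt))
  dec <- memd_decompose(X, K = 16, seed = 4)
  recon <- apply(dec$imfs, c(2, 3), sum) + dec$residual
  expect_lt(max(abs(recon - X)), 1e-10 * max(abs(X)))

  # dominant frequencies of each mode agree across channels
  for (w in seq_len(dim(dec$imfs)[1])) {
    e1 <- sum(dec$imfs[w, 1, ]^2); e2 <- sum(dec$imfs[w, 2, ]^2)
    if (min(e1, e2) > 0.05 * sum(base^2)) {
      p1 <- spectral_peak(dec$imfs[w, 1, ], fs)
      p2 <- spectral_peak(dec$imfs[w, 2, ], fs)
      expect_lt(abs(p1 - p2), 0.5 + 1e-9)
    }
  }

  dec2 <- memd_decompose(2 * X, K = 16, seed = 4)
  expect_equal(dec2$imfs, 2 * dec$imfs, tolerance = 1e-9)
})

test_that("NA-MEMD discards noise channels and concentrates tone energy", {
  x <- sin(2 * pi * 10 * tt)
  dec <- na_memd(x, n_noise = 12, seed = 5, fs = fs)
  expect_equal(dim(dec$imfs)[2], 1)            # only the data channel
  expect_true(all(dec$channel_roles == "data"))
  energies <- apply(dec$imfs[, 1, , drop = FALSE], 1, function(v) sum(v^2))
  expect_gt(max(energies) / sum(x^2), 0.9)

  expect_error(na_memd(x, noise_scale = 0), "noise_scale")
})

test_that("quasi-dyadic filterbank on white noise", {
  # log2 spectral centroids of successive noise IMFs fall by ~1 per level
  set.seed(21)
  steps <- c()
  for (r in 1:20) {
    x <- rnorm(512)
    dec <- emd_decompose(x, fs = 512)
    keep <- rowSums(dec$imfs^2) > 1e-3 * sum(x^2)
    cents <- vapply(which(keep),
                    function(w) spectral_centroid(dec$imfs[w, ], 512),
                    numeric(1))
    steps <- c(steps, -diff(log2(cents)))
  }
  expect_gt(mean(steps), 0.6)
  expect_lt(mean(steps), 1.4)
})

test_that("band power integrates the periodogram over the band", {
  x <- tone(10, fs)
  expect_gt(band_power(x, default_bands()$alpha, fs) /
              band_power(x, band("all", 0.5, 499), fs), 0.95)
  expect_lt(band_power(x, default_bands()$theta, fs) /
              band_power(x, band("all", 0.5, 499), fs), 0.05)
  expect_equal(band_power(numeric(1000), default_bands()$alpha, fs), 0)
  expect_error(band_power(x, band("bad", 400, 600), fs), "Nyquist")
})

test_that("band IMF selection: argmax band power, ties to lower index", {
  iset <- structure(list(imfs = rbind(tone(20, fs), tone(10, fs)),
                         residual = numeric(1000), fs = fs),
                    class = "imf_set")
  sel <- select_band_imfs(iset, default_bands(), fs)
  expect_equal(unname(sel[["alpha"]]), 2L)
  expect_equal(unname(sel[["beta1"]]), 1L)

  single <- structure(list(imfs = rbind(tone(10, fs)),
                           residual = numeric(1000), fs = fs),
                      class = "imf_set")
  expect_true(all(select_band_imfs(single, default_bands(), fs) == 1L))

  dup <- structure(list(imfs = rbind(tone(10, fs), tone(10, fs)),
                        residual = numeric(1000), fs = fs),
                   class = "imf_set")
  expect_equal(unname(select_band_imfs(dup, default_bands(), fs)[["alpha"]]),
               1L)  # tie -> lower (faster) index
})

test_that("median band IMF: single realization identity, permutation
           invariance, tone recovery", {
  x <- tone(10, fs)
  one <- median_band_imf(x, fs = fs, n_realizations = 1, seed = 9)
  d1 <- na_memd(x, seed = 9 + 1, fs = fs)
  sel <- select_band_imfs(d1, default_bands(), fs)
  expect_equal(one$alpha$series[1, ], d1$imfs[sel["alpha", 1], 1, ])

  med <- median_band_imf(x, fs = fs, n_realizations = 5, seed = 9)
  expect_gt(cor(med$alpha$series[1, ], x), 0.95)
})
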