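lf <- small_leadfield()

test_that("forward projection: one-hot, zero, linearity", {
  D <- ncol(lf$L)
  S <- matrix(0, D, 10); S[5, ] <- sin(1:10)
  expect_equal(apply_forward(lf, S, noise_std = 0), lf$L[, 5] %o% sin(1:10))
  expect_equal(apply_forward(lf, matrix(0, D, 4), noise_std = 0),
               matrix(0, nrow(lf$L), 4))
  S2 <- matrix(rnorm(D * 10), D)
  expect_equal(apply_forward(lf, S + 2 * S2, noise_std = 0),
               apply_forward(lf, S, noise_std = 0) +
                 2 * apply_forward(lf, S2, noise_std = 0),
               tolerance = 1e-9)
  expect_error(apply_forward(lf, matrix(0, D + 1, 4)), "vertices")
})

test_that("REST equals the explicit pseudoinverse composition and is
           idempotent", {
  set.seed(10)
  Y <- matrix(rnorm(nrow(lf$L) * 30), nrow(lf$L))
  H <- diag(nrow(Y)) - 1 / nrow(Y)
  Lavg <- H %*% lf$L
  sv <- svd(Lavg)
  r <- sum(sv$d > max(dim(Lavg)) * max(sv$d) * .Machine$double.eps)
  Pi <- sv$v[, 1:r] %*% (t(sv$u[, 1:r]) / sv$d[1:r])
  oracle <- lf$L %*% Pi %*% (H %*% Y)
  expect_equal(rest_transform(Y, lf), oracle, tolerance = 1e-10)

  Yr <- rest_transform(Y, lf)
  expect_equal(rest_transform(Yr, lf), Yr, tolerance = 1e-6)

  # linear in Y
  Y2 <- matrix(rnorm(length(Y)), nrow(Y))
  expect_equal(rest_transform(Y + 3 * Y2, lf),
               rest_transform(Y, lf) + 3 * rest_transform(Y2, lf),
               tolerance = 1e-9)
})

test_that("REST recovers reference-free potentials of focal sources", {
  lf61 <- make_spherical_leadfield(61, 500, seed = 2)
  set.seed(11)
  up <- which(lf61$geometry$vertex_positions[, 3] > 0.01)
  errs <- replicate(20, {
    sv <- sample(up, 2)
    S <- matrix(0, 500, 60); S[sv, ] <- matrix(rnorm(120), 2)
    Yc <- lf61$L %*% S
    Yr <- rest_transform(sweep(Yc, 2, colMeans(Yc)), lf61)
    norm(Yr - Yc, "F") / norm(Yc, "F")
  })
  expect_lt(median(errs), 0.05)
})

test_that("inverse solver: identity-leadfield limit", {
  D <- 16
  # identity gain; uncorrelated prior; fixed vanishing noise hyperparameter
  set.seed(99)
  lid <- structure(list(L = diag(D),
                        geometry = geometry(matrix(rnorm(D * 3), D),
                                            matrix(rnorm(D * 3), D),
                                            matrix(rep(c(1, 0, 0), D), D,
                                                   byrow = TRUE),
                                            1:2)),
                   class = "leadfield")
  set.seed(12)
  Y <- matrix(rnorm(D * 40), D)
  est <- suppressWarnings(
    solve_inverse(Y, lid, inverse_config(prior_width = 0,
                                         noise_var = 1e-10 * mean(Y^2))))
  expect_lt(norm(est$S - Y, "F") / norm(Y, "F"), 0.01)
})

test_that("free-energy trace is non-decreasing and scaling is equivariant", {
  set.seed(13)
  D <- ncol(lf$L)
  S <- matrix(0, D, 50); S[11, ] <- sin((1:50) / 3)
  Y <- lf$L %*% S
  Y <- Y + matrix(rnorm(length(Y), sd = 0.3 * sd(Y)), nrow(Y))
  est <- suppressWarnings(solve_inverse(Y, lf))
  fe <- est$free_energy
  expect_true(all(diff(fe) >= -1e-8 * (abs(fe[1]) + 1)))

  est2 <- suppressWarnings(solve_inverse(5 * Y, lf))
  expect_equal(est2$S, 5 * est$S, tolerance = 0.02)
})

test_that("planted source is localized within 2 cm at 10 dB SNR", {
  lfl <- make_spherical_leadfield(32, 600, seed = 3)
  op <- make_inverse_operator(lfl, inverse_config())
  up <- which(lfl$geometry$vertex_positions[, 3] > 0.01)
  set.seed(14)
  hits <- 0
  for (r in 1:10) {
    svx <- sample(up, 1)
    S <- matrix(0, 600, 300)
    S[svx, ] <- sin(2 * pi * 10 * (0:299) / 500)
    Y <- lfl$L %*% S
    noise <- matrix(rnorm(length(Y)), nrow(Y))
    Y <- Y + noise / sd(noise) * sd(Y) / 10^(10 / 20)
    est <- suppressWarnings(solve_inverse(Y, op))
    expect_true(all(diff(est$free_energy) >=
                      -1e-8 * (abs(est$free_energy[1]) + 1)))
    pk <- which.max(rowMeans(est$S^2))
    derr <- sqrt(sum((lfl$geometry$vertex_positions[pk, ] -
                        lfl$geometry$vertex_positions[svx, ])^2))
    hits <- hits + (derr <= 0.02)
  }
  expect_gte(hits, 9)
})

test_that("ROI extraction ranks by power with deterministic ties", {
  S <- matrix(1, 10, 20)
  S[4, ] <- 5; S[7, ] <- 3
  roi <- c(2, 4, 7, 9)
  out <- extract_roi_sources(S, roi, 2)
  expect_equal(out$vertices, c(4, 7))
  expect_equal(out$series[1, ], S[4, ])

  one <- extract_roi_sources(S, roi = 9, n_sources = 1)
  expect_equal(one$vertices, 9)

  expect_warning(all3 <- extract_roi_sources(S, c(1, 2, 3), 4), "ROI size")
  expect_equal(nrow(all3$series), 3)
  expect_error(extract_roi_sources(S, integer(0)), "empty")
})

test_that("nearest sensors by distance with index tie-breaks", {
  g <- lf$geometry
  i <- 7
  expect_equal(nearest_sensors(g, g$sensor_positions[i, ], 1), i)
  allidx <- nearest_sensors(g, c(0, 0, 0.2), nrow(g$sensor_positions))
  expect_setequal(allidx, seq_len(nrow(g$sensor_positions)))
  d <- sqrt(rowSums(sweep(g$sensor_positions, 2, c(0, 0, 0.2))^2))
  expect_equal(allidx, order(d, seq_along(d)))
})
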