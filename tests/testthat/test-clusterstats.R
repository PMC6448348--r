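# shared synthetic phase/response construction
make_null_data <- function(Nt, T, seed) {
  set.seed(seed)
  list(phases = matrix(runif(Nt * T, -pi, pi), Nt, T), z = rnorm(Nt))
}

test_that("1D cluster test finds a planted phase-response dependence", {
  set.seed(31)
  Nt <- 60; T <- 300
  phases <- matrix(runif(Nt * T, -pi, pi), Nt, T)
  z <- cos(phases[, 150]) + 0.3 * rnorm(Nt)  # dependence at samples 100-200
  for (s in 100:200) phases[, s] <- phases[, 150]
  res <- cluster_permutation_1d(phases, z, n_perm = 500, seed = 1)
  sig <- res$clusters[res$clusters$significant, ]
  expect_gt(nrow(sig), 0)
  expect_true(any(sig$start <= 200 & sig$end >= 100))
})

test_that("1D cluster test is deterministic for a fixed seed", {
  d <- make_null_data(40, 120, 5)
  r1 <- cluster_permutation_1d(d$phases, d$z, n_perm = 200, seed = 7)
  r2 <- cluster_permutation_1d(d$phases, d$z, n_perm = 200, seed = 7)
  expect_identical(r1$clusters, r2$clusters)
  expect_identical(r1$null_max, r2$null_max)
})

test_that("1D cluster members are exactly the supra-threshold runs", {
  d <- make_null_data(50, 200, 8)
  res <- cluster_permutation_1d(d$phases, d$z, n_perm = 300, seed = 2)
  supra <- which(res$t > res$threshold)
  members <- unlist(lapply(seq_len(nrow(res$clusters)), function(i)
    res$clusters$start[i]:res$clusters$end[i]))
  expect_setequal(members, supra)
})

test_that("p-values stabilize with many permutations", {
  d <- make_null_data(40, 150, 9)
  set.seed(1)
  d$z <- cos(d$phases[, 75]) + 0.8 * rnorm(40)
  d$phases[, 70:80] <- d$phases[, 75]
  r1 <- cluster_permutation_1d(d$phases, d$z, n_perm = 2000, seed = 3)
  r2 <- cluster_permutation_1d(d$phases, d$z, n_perm = 2000, seed = 4)
  if (nrow(r1$clusters) > 0 && nrow(r2$clusters) > 0) {
    i1 <- which.max(r1$clusters$stat)
    i2 <- which.max(r2$clusters$stat)
    expect_lt(abs(r1$clusters$p[i1] - r2$clusters$p[i2]), 0.02)
  }
})

test_that("sensor adjacency is symmetric with an empty diagonal", {
  lf <- small_leadfield()
  A <- sensor_adjacency(lf$geometry$sensor_positions)
  expect_true(isSymmetric(A))
  expect_true(all(!diag(A)))
  expect_true(any(A))
})

test_that("2D cluster test: planted sensor effect stays local; disconnected
           adjacency reduces to per-sensor 1D", {
  set.seed(41)
  N <- 6; Nt <- 50; T <- 80
  ph <- array(runif(N * Nt * T, -pi, pi), dim = c(N, Nt, T))
  z <- cos(ph[2, , 40]) + 0.3 * rnorm(Nt)
  for (s in 30:50) ph[2, , s] <- ph[2, , 40]
  A <- matrix(FALSE, N, N)
  A[cbind(1:5, 2:6)] <- TRUE; A <- A | t(A)
  res <- cluster_permutation_2d(ph, z, A, n_perm = 300, seed = 5)
  sig <- Filter(function(cl) cl$significant, res$clusters)
  expect_gt(length(sig), 0)
  sensors_hit <- unique(unlist(lapply(sig, function(cl) cl$members[, 1])))
  expect_true(all(sensors_hit %in% c(1, 2, 3)))  # sensor 2 and neighbors

  # isolated sensors: clusters never span sensors
  A0 <- matrix(FALSE, N, N)
  expect_warning(cluster_permutation_2d(ph, z, A0, n_perm = 10, seed = 5),
                 "isolated")
  res0 <- suppressWarnings(
    cluster_permutation_2d(ph, z, A0, n_perm = 300, seed = 5))
  for (cl in res0$clusters)
    expect_equal(length(unique(cl$members[, 1])), 1)
  # and the per-sensor t-map matches the 1D computation
  r1d <- cluster_permutation_1d(ph[2, , ], z, n_perm = 300, seed = 5)
  expect_equal(res0$t[2, ], r1d$t, tolerance = 1e-12)
})
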