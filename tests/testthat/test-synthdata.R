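lf <- small_leadfield()
sv <- default_soi_vertex(lf)

test_that("spherical leadfield construction contract", {
  expect_equal(dim(lf$L), c(16, 200))
  expect_true(all(is.finite(lf$L)))
  expect_true(all(colSums(abs(lf$L)) > 0))
  expect_gt(length(lf$geometry$roi_vertices), 3)

  lf2 <- make_spherical_leadfield(16, 200, seed = 1)
  expect_identical(lf$L, lf2$L)  # bit-identical for a fixed seed

  expect_error(make_spherical_leadfield(3, 100), "n_sensors")
  expect_error(make_spherical_leadfield(16, 10), "n_vertices")

  # a unit source at vertex d projects exactly to column d
  d <- 17
  S <- matrix(0, 200, 5); S[d, ] <- 1
  expect_equal(apply_forward(lf, S, noise_std = 0),
               lf$L[, d] %o% rep(1, 5))
})

test_that("SOI components: 1/f amplitudes, sample counts, spectral peaks", {
  cfg <- simulation_config(soi_vertex = sv, fs = 1000, seed = 2)
  soi <- make_soi(cfg, trial_seed = 11)
  expect_equal(dim(soi$components), c(3, 1000))
  # amplitude ratio forced by the 1/f law
  expect_equal(soi$amplitudes[1] / soi$amplitudes[3], 27.5 / 10.1,
               tolerance = 1e-12)
  # component 2 peaks near its 18 Hz center
  expect_gte(spectral_peak(soi$components[2, ], 1000), 17.5)
  expect_lte(spectral_peak(soi$components[2, ], 1000), 18.5)
  # instantaneous frequency confined to center +/- jitter
  for (j in 1:3)
    expect_true(all(abs(soi$freqs[j, ] - cfg$soi_center_freqs[j]) <= 0.5 + 1e-9))
  # phases wrapped and monotone (positive instantaneous frequency)
  expect_true(all(soi$phases > -pi & soi$phases <= pi))
  expect_true(all(soi$freqs > 0))

  expect_warning(make_soi(simulation_config(soi_vertex = sv,
                                            soi_center_freqs = c(10, 10.5),
                                            seed = 1), 1),
                 "overlap")
})

test_that("zero jitter gives a pure sinusoid at the center bin", {
  cfg <- simulation_config(soi_vertex = sv, freq_jitter = 0, fs = 1000,
                           seed = 3)
  soi <- make_soi(cfg, trial_seed = 5)
  for (j in 1:3) {
    fpeak <- spectral_peak(soi$components[j, ], 1000)
    expect_equal(fpeak, round(cfg$soi_center_freqs[j]))  # nearest 1 Hz bin
  }
})

test_that("distractors: narrowband confinement, broadband confinement", {
  cfg_nb <- simulation_config(soi_vertex = sv,
                              distractor_spec = list(list(vertex = 3,
                                                          center = 14)),
                              fs = 1000, seed = 4)
  d <- make_distractors(cfg_nb, 21)
  expect_gt(spectral_mass_frac(d[1, ], 1000, 13, 15), 0.95)

  cfg_bb <- simulation_config(soi_vertex = sv,
                              distractor_spec = list(list(vertex = 3,
                                                          band = c(4, 30))),
                              fs = 1000, seed = 4)
  db <- make_distractors(cfg_bb, 21)
  expect_gt(spectral_mass_frac(db[1, ], 1000, 4, 30), 0.95)

  cfg_empty <- simulation_config(soi_vertex = sv, fs = 1000, seed = 4)
  expect_error(make_distractors(cfg_empty, 1), "empty")
})

test_that("distractor placement resolves requested distances", {
  set.seed(9)
  v <- distractor_placements(lf, sv, c(0.03, 0.05), seed = 2)
  d <- sqrt(rowSums((lf$geometry$vertex_positions[v, , drop = FALSE] -
                     matrix(lf$geometry$vertex_positions[sv, ], 2, 3,
                            byrow = TRUE))^2))
  # matched to the nearest vertex of a jittered target; grid spacing bounds
  # the error
  expect_lt(abs(d[1] - 0.03), 0.012)
  expect_lt(abs(d[2] - 0.05), 0.012)
  expect_warning(distractor_placements(lf, sv, 10, seed = 1), "extent")
})

test_that("assembled trials satisfy the SNR contract exactly", {
  for (snr in c(-10, 0, 20)) {
    cfg <- simulation_config(soi_vertex = sv,
                             distractor_spec = list(list(vertex = 3,
                                                         center = 14)),
                             snr_db = snr, n_trials = 2, fs = 500, seed = 6)
    tr <- assemble_trials(lf, cfg)
    for (k in 1:2) {
      noise <- tr$epochs[[k]] - tr$ground_truth[[k]]$clean
      expect_equal(measure_snr(tr$ground_truth[[k]]$clean, noise), snr,
                   tolerance = 1e-9)
    }
  }
})

test_that("trial generation is reproducible and extends without reshuffling", {
  cfg <- simulation_config(soi_vertex = sv, n_trials = 3, fs = 500, seed = 8)
  t1 <- assemble_trials(lf, cfg)
  t2 <- assemble_trials(lf, cfg)
  expect_identical(t1$epochs, t2$epochs)
  expect_false(identical(t1$epochs[[1]], t1$epochs[[2]]))

  cfg5 <- simulation_config(soi_vertex = sv, n_trials = 5, fs = 500, seed = 8)
  t5 <- assemble_trials(lf, cfg5)
  expect_identical(t5$epochs[1:3], t1$epochs)
})
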