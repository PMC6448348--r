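#' Wrap angles to (-pi, pi]
#'
#' @param x angles in radians.
#' @return wrapped angles.
#' @export
wrap_pi <- function(x) -((pi - x) %% (2 * pi) - pi)

#' Simulation configuration
#'
#' Study design for generating multichannel trials: a source of interest
#' (SOI) that is the sum of three frequency-jittered oscillations with
#' amplitudes following the 1/frequency power law, one or more distractor
#' sources, projection through a leadfield and white sensor noise at a
#' target SNR. Defaults encode the simulated study conditions: center
#' frequencies 10.1, 18 and 27.5 Hz with +/-0.5 Hz jitter, 1-second trials.
#'
#' @param soi_vertex vertex index carrying the SOI.
#' @param distractor_spec list of distractors, each a list with `vertex` and
#'   either `center` (narrowband, Hz) or `band` (length-2 Hz range,
#'   broadband).
#' @param soi_center_freqs SOI component center frequencies in Hz.
#' @param freq_jitter maximal instantaneous-frequency excursion in Hz.
#' @param snr_db target signal-to-noise ratio in dB (clean projected signal
#'   std over noise std, pooled over sensors and samples).
#' @param n_trials number of trials.
#' @param fs sampling rate in Hz.
#' @param duration trial length in seconds; `duration * fs` must be integer.
#' @param seed master seed; each trial gets an independent substream so that
#'   changing `n_trials` does not reshuffle earlier trials.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(soi_vertex, distractor_spec = list(),
                              soi_center_freqs = c(10.1, 18, 27.5),
                              freq_jitter = 0.5, snr_db = 0, n_trials = 1L,
                              fs = 1000, duration = 1, seed = 1L) {
  stopifnot(is.finite(snr_db), n_trials >= 1, fs > 0, duration > 0)
  T <- duration * fs
  if (abs(T - round(T)) > 1e-9) stop("duration * fs must be an integer")
  stopifnot(soi_vertex >= 1)
  for (d in distractor_spec) {
    if (is.null(d$vertex)) stop("each distractor needs a vertex")
    if (is.null(d$center) && is.null(d$band))
      stop("each distractor needs a center frequency or a band")
  }
  structure(list(soi_vertex = as.integer(soi_vertex),
                 soi_center_freqs = soi_center_freqs,
                 freq_jitter = freq_jitter,
                 distractor_spec = distractor_spec,
                 snr_db = snr_db, n_trials = as.integer(n_trials),
                 fs = fs, duration = duration, T = as.integer(round(T)),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Smooth frequency-modulation trajectory: low-pass-smoothed Gaussian walk,
# scaled and clipped to +/- jitter Hz.
smooth_jitter_track <- function(T, fs, jitter) {
  if (jitter <= 0) return(numeric(T))
  walk <- cumsum(stats::rnorm(T))
  # Gaussian smoothing by FFT convolution (kernel sd ~ fs/8 samples)
  ksd <- max(2, round(fs / 8))
  half <- 3 * ksd
  kern <- stats::dnorm(seq(-half, half), sd = ksd)
  kern <- kern / sum(kern)
  padded <- c(rep(walk[1], half), walk, rep(walk[T], half))
  sm <- stats::convolve(padded, rev(kern), type = "filter")
  sm <- sm - mean(sm)
  s <- stats::sd(sm)
  if (s > 0) sm <- sm / s * (jitter / 2)
  pmin(pmax(sm, -jitter), jitter)
}

# single narrowband oscillation: random start phase, smoothly jittered
# instantaneous frequency integrated into phase
narrowband_component <- function(T, fs, center, jitter, amplitude) {
  f_inst <- center + smooth_jitter_track(T, fs, jitter)
  phase_unwrapped <- stats::runif(1, -pi, pi) + 2 * pi * cumsum(f_inst) / fs
  list(series = amplitude * cos(phase_unwrapped),
       phase = wrap_pi(phase_unwrapped),
       phase_unwrapped = phase_unwrapped,
       freq = f_inst, amplitude = amplitude)
}

#' Generate the source-of-interest components for one trial
#'
#' Three zero-mean narrowband oscillations whose instantaneous frequency
#' stays within `center +/- freq_jitter` Hz and whose amplitudes scale as
#' 1/center-frequency. The jitter is a smoothed, clipped Gaussian walk; the
#' phase is the cumulative integral of the instantaneous frequency, and the
#' ground-truth phase/frequency trajectories are stored alongside the
#' series.
#'
#' @param config a [simulation_config()].
#' @param trial_seed integer seed for this trial.
#' @return list with `components` (3 x T), `phases` (3 x T, wrapped to
#'   (-pi, pi]), `freqs` (3 x T, Hz) and `amplitudes`.
#' @export
make_soi <- function(config, trial_seed) {
  stopifnot(inherits(config, "simulation_config"))
  fc <- config$soi_center_freqs
  if (length(fc) >= 2 && min(diff(sort(fc))) < 2 * config$freq_jitter)
    warning("SOI center frequencies closer than twice the jitter: ",
            "component bands overlap")
  set.seed(as.integer(trial_seed))
  T <- config$T
  amp <- min(fc) / fc  # 1/f amplitude law, normalized to the slowest
  comps <- matrix(0, length(fc), T)
  phases <- matrix(0, length(fc), T)
  freqs <- matrix(0, length(fc), T)
  for (j in seq_along(fc)) {
    cm <- narrowband_component(T, config$fs, fc[j], config$freq_jitter,
                               amp[j])
    comps[j, ] <- cm$series
    phases[j, ] <- cm$phase
    freqs[j, ] <- cm$freq
  }
  list(components = comps, phases = phases, freqs = freqs, amplitudes = amp)
}

#' Generate distractor source time series for one trial
#'
#' Narrowband distractors are single frequency-jittered oscillations with
#' the same 1/frequency amplitude law as the SOI components; broadband
#' distractors are white noise FIR-filtered to the requested band, scaled to
#' the expected standard deviation of the summed SOI so the interference is
#' comparable in strength.
#'
#' @param config a [simulation_config()] with non-empty `distractor_spec`.
#' @param trial_seed integer seed for this trial.
#' @return matrix with one row per distractor.
#' @export
make_distractors <- function(config, trial_seed) {
  stopifnot(inherits(config, "simulation_config"))
  spec <- config$distractor_spec
  if (length(spec) == 0) stop("distractor_spec is empty")
  set.seed(as.integer(trial_seed))
  T <- config$T
  fs <- config$fs
  soi_amp <- min(config$soi_center_freqs) / config$soi_center_freqs
  soi_sd <- sqrt(sum(soi_amp^2 / 2))  # expected sd of the summed SOI
  out <- matrix(0, length(spec), T)
  for (i in seq_along(spec)) {
    d <- spec[[i]]
    if (!is.null(d$center)) {
      amp <- min(config$soi_center_freqs) / d$center
      out[i, ] <- narrowband_component(T, fs, d$center, config$freq_jitter,
                                       amp)$series
    } else {
      b <- d$band
      stopifnot(length(b) == 2, b[1] > 0, b[2] > b[1], b[2] < fs / 2)
      w <- stats::rnorm(T + 512)
      h <- signal::fir2(256,
                        c(0, b[1] * 0.8, b[1], b[2], min(b[2] * 1.2, fs / 2 * 0.99),
                          fs / 2) / (fs / 2),
                        c(0, 0, 1, 1, 0, 0),
                        window = signal::hamming(257))
      filt <- signal::filtfilt(as.numeric(h), 1, w)
      filt <- filt[257:(256 + T)]
      out[i, ] <- filt / stats::sd(filt) * soi_sd
    }
  }
  out
}

#' Resolve distractor placements at requested distances from the SOI
#'
#' Maps requested straight-line (chord) distances from the SOI vertex to the
#' nearest available vertices on the cortical sphere, with the requested
#' distance jittered by up to `jitter_m` before matching so that repeated
#' calls with different seeds give different placements. Distances exceeding
#' the source-space extent fall back to the farthest feasible vertex with a
#' warning.
#'
#' @param lf a [make_spherical_leadfield()] result (or any `leadfield`).
#' @param soi_vertex SOI vertex index.
#' @param distances requested chord distances in meters.
#' @param jitter_m maximal distance jitter in meters (default 1 mm).
#' @param seed integer seed.
#' @return integer vertex indices, one per requested distance.
#' @export
distractor_placements <- function(lf, soi_vertex, distances,
                                  jitter_m = 0.001, seed = 1L) {
  stopifnot(inherits(lf, "leadfield"))
  V <- lf$geometry$vertex_positions
  set.seed(as.integer(seed))
  d_all <- sqrt(rowSums(sweep(V, 2, V[soi_vertex, ])^2))
  vapply(distances, function(target) {
    tj <- target + stats::runif(1, -jitter_m, jitter_m)
    if (tj > max(d_all)) {
      warning("requested distance ", signif(target, 3),
              " m exceeds source-space extent; using farthest vertex")
      tj <- max(d_all)
    }
    cand <- abs(d_all - tj)
    cand[soi_vertex] <- Inf
    which.min(cand)
  }, integer(1))
}

#' Pooled SNR of a clean/noise pair in dB
#'
#' `20 * log10(sd(clean) / sd(noise))` with standard deviations pooled over
#' all sensors and samples.
#'
#' @param clean,noise numeric matrices/vectors of equal size.
#' @return scalar dB value.
#' @export
measure_snr <- function(clean, noise) {
  20 * log10(stats::sd(as.vector(clean)) / stats::sd(as.vector(noise)))
}

#' Assemble noisy multichannel trials
#'
#' Per trial, projects the SOI and distractor sources through the leadfield
#' and adds i.i.d. Gaussian sensor noise scaled so that the realized pooled
#' SNR equals `config$snr_db` exactly for that trial. Ground truth
#' (components, phases, instantaneous frequencies, distractor series, clean
#' projection) is retained per trial. The master seed spawns per-trial
#' substreams, so regenerating with the same seed is bit-exact and adding
#' trials does not change earlier ones.
#'
#' @param lf a `leadfield`.
#' @param config a [simulation_config()] whose vertices are valid for `lf`.
#' @return list of class `trial_set`: `epochs` (list of N x T matrices),
#'   `ground_truth` (list per trial), `config`, `fs`.
#' @export
assemble_trials <- function(lf, config) {
  stopifnot(inherits(lf, "leadfield"), inherits(config, "simulation_config"))
  L <- lf$L
  D <- ncol(L)
  verts <- c(config$soi_vertex,
             vapply(config$distractor_spec, function(d) d$vertex, numeric(1)))
  if (any(verts < 1 | verts > D)) stop("configured vertex out of range")
  set.seed(config$seed)
  trial_seeds <- sample.int(2^31 - 10, config$n_trials, replace = TRUE)
  N <- nrow(L)
  T <- config$T
  epochs <- vector("list", config$n_trials)
  gt <- vector("list", config$n_trials)
  for (tr in seq_len(config$n_trials)) {
    ts <- trial_seeds[tr]
    soi <- make_soi(config, ts)
    clean <- L[, config$soi_vertex] %o% colSums(soi$components)
    distr <- NULL
    if (length(config$distractor_spec)) {
      distr <- make_distractors(config, ts + 1L)
      for (i in seq_along(config$distractor_spec))
        clean <- clean +
          L[, config$distractor_spec[[i]]$vertex] %o% distr[i, ]
    }
    sd_clean <- stats::sd(as.vector(clean))
    if (sd_clean == 0)
      stop("clean projected signal has zero power; SNR undefined")
    set.seed(ts + 2L)
    eps <- matrix(stats::rnorm(N * T), N, T)
    eps <- eps / stats::sd(as.vector(eps)) * sd_clean / 10^(config$snr_db / 20)
    epochs[[tr]] <- clean + eps
    gt[[tr]] <- list(components = soi$components, phases = soi$phases,
                     freqs = soi$freqs, distractors = distr, clean = clean)
  }
  structure(list(epochs = epochs, ground_truth = gt, config = config,
                 fs = config$fs),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat("<trial_set> ", length(x$epochs), " trials, ",
      nrow(x$epochs[[1]]), " sensors x ", ncol(x$epochs[[1]]),
      " samples, SNR ", x$config$snr_db, " dB\n", sep = "")
  invisible(x)
}
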