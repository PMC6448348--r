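#' Sensor epoch container
#'
#' @param data N x T numeric matrix (channels x samples).
#' @param fs sampling rate in Hz.
#' @param onset time of the first sample relative to the stimulus, seconds
#'   (negative for prestimulus data).
#' @return list of class `sensor_epoch`.
#' @export
sensor_epoch <- function(data, fs, onset = 0) {
  data <- as.matrix(data)
  stopifnot(all(is.finite(data)), fs > 0)
  structure(list(data = data, fs = fs, onset = onset),
            class = "sensor_epoch")
}

# unwrap phase: remove 2*pi jumps
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d))
}

# analytic signal via FFT
analytic_signal <- function(x) {
  T <- length(x)
  X <- stats::fft(x)
  h <- numeric(T)
  if (T %% 2 == 0) {
    h[1] <- 1; h[T / 2 + 1] <- 1; h[2:(T / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((T + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / T
}

#' Instantaneous amplitude, phase and frequency via the Hilbert transform
#'
#' Amplitude and phase are the magnitude and angle of the analytic signal;
#' frequency is the centered-difference derivative of the unwrapped phase
#' divided by 2*pi, with the first/last samples copied from their
#' neighbors. Meaningful for zero-mean narrowband inputs such as IMFs; a
#' warning is issued when the DC offset exceeds 1% of the standard
#' deviation.
#'
#' @param c numeric vector.
#' @param fs sampling rate in Hz.
#' @return list of class `inst_attributes` with `amplitude` (>= 0), `phase`
#'   (radians in (-pi, pi]) and `frequency` (Hz).
#' @export
hilbert_attributes <- function(c, fs) {
  stopifnot(is.numeric(c), all(is.finite(c)), fs > 0)
  s <- stats::sd(c)
  if (s == 0) stop("constant input: instantaneous phase undefined")
  if (abs(mean(c)) > 0.01 * s)
    warning("input has a DC offset above 1% of its std; ",
            "instantaneous attributes may be biased")
  a <- analytic_signal(c)
  phase <- Arg(a)
  up <- unwrap_phase(phase)
  T <- length(c)
  freq <- numeric(T)
  freq[2:(T - 1)] <- (up[3:T] - up[1:(T - 2)]) * fs / (4 * pi)
  freq[1] <- freq[2]
  freq[T] <- freq[T - 1]
  structure(list(amplitude = Mod(a), phase = wrap_pi(phase), frequency = freq),
            class = "inst_attributes")
}

# order rule: three cycles of the low cutoff, forced odd (odd tap count
# keeps the design linear-phase type I)
fir_order <- function(lo, fs) {
  ord <- ceiling(3 * fs / lo)
  if (ord %% 2 == 0) ord <- ord + 1
  ord
}

# least-squares linear-phase (type I) FIR: desired amplitude is 1 on
# [lo, hi] with linear ramps over the transition zones, fit on a dense
# frequency grid in the cosine basis
fir_ls_design <- function(ntaps, f_edges, fs) {
  M <- (ntaps - 1) / 2
  G <- 16L * ntaps
  wg <- seq(0, pi, length.out = G)
  fg <- wg * fs / (2 * pi)
  D <- numeric(G)
  lo1 <- f_edges[1]; lo2 <- f_edges[2]; hi1 <- f_edges[3]; hi2 <- f_edges[4]
  D[fg >= lo2 & fg <= hi1] <- 1
  ramp_up <- fg > lo1 & fg < lo2
  D[ramp_up] <- (fg[ramp_up] - lo1) / (lo2 - lo1)
  ramp_dn <- fg > hi1 & fg < hi2
  D[ramp_dn] <- (hi2 - fg[ramp_dn]) / (hi2 - hi1)
  B <- cos(outer(wg, 0:M))
  a <- qr.solve(B, D)
  h <- c(rev(a[-1] / 2), a[1], a[-1] / 2)
  h
}

#' Zero-phase FIR bandpass comparator
#'
#' Least-squares linear-phase FIR with transition bands 20% of each cutoff
#' and `ceiling(3 * fs / lo)` taps (forced odd), applied forward and
#' backward (zero phase). For signals shorter than three filter lengths an
#' error advises zero-padding; with `pad = TRUE` the signal is symmetrically
#' zero-padded before filtering and cropped afterwards.
#'
#' @param x numeric vector.
#' @param band a [band()] within Nyquist.
#' @param fs sampling rate in Hz.
#' @param pad zero-pad short signals instead of failing.
#' @return filtered vector, same length as `x`.
#' @export
fir_bandpass <- function(x, band, fs, pad = FALSE) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (band$hi >= fs / 2) stop("band upper edge must be below Nyquist")
  ord <- fir_order(band$lo, fs)
  T <- length(x)
  npad <- 0L
  if (T < 3 * ord) {
    if (!pad)
      stop("signal (", T, " samples) shorter than 3x filter order (",
           3 * ord, "); zero-pad the signal (pad = TRUE)")
    npad <- ceiling((3 * ord - T) / 2) + ord
    x <- c(numeric(npad), x, numeric(npad))
  }
  tw <- 0.2
  nyq <- fs / 2
  h <- fir_ls_design(ord, c(band$lo * (1 - tw), band$lo, band$hi,
                            min(band$hi * (1 + tw), nyq * 0.999)), fs)
  y <- signal::filtfilt(h, 1, x)
  if (npad > 0) y <- y[(npad + 1):(npad + T)]
  y
}

#' Preprocess a raw epoch
#'
#' Standard conditioning chain for stimulus-locked EEG epochs: downsample to
#' 1000 Hz (anti-aliased polyphase resampling), crop the prestimulus window
#' [-500, -22) ms (left-closed, right-open: 478 samples), symmetrically
#' zero-pad to 2479 samples, bandpass [1, 45] Hz with a 5th-order
#' Butterworth applied forward and backward, and remove the padding.
#'
#' @param raw a [sensor_epoch()] with `fs >= 1000` covering at least the
#'   crop window.
#' @return a [sensor_epoch()] at 1000 Hz with 478 samples and onset -0.5 s.
#' @export
preprocess_epoch <- function(raw) {
  stopifnot(inherits(raw, "sensor_epoch"))
  if (raw$fs < 1000) stop("raw sampling rate must be >= 1000 Hz")
  X <- raw$data
  fs <- raw$fs
  if (fs > 1000) {
    g <- gcd_int(1000L, as.integer(round(fs)))
    X <- t(apply(X, 1, function(ch)
      signal::resample(ch, 1000L / g, as.integer(round(fs)) / g)))
    fs <- 1000
  }
  T <- ncol(X)
  times <- raw$onset + (seq_len(T) - 1) / fs
  keep <- which(times >= -0.5 - 1e-9 & times < -0.022 - 1e-9)
  if (length(keep) < 478)
    stop("epoch does not cover the [-500, -22) ms window")
  keep <- keep[seq_len(478)]
  X <- X[, keep, drop = FALSE]
  pre <- floor((2479 - 478) / 2)
  post <- 2479 - 478 - pre
  Xp <- cbind(matrix(0, nrow(X), pre), X, matrix(0, nrow(X), post))
  bf <- signal::butter(5, c(1, 45) / (fs / 2), type = "pass")
  for (i in seq_len(nrow(Xp)))
    Xp[i, ] <- signal::filtfilt(bf, Xp[i, ])
  sensor_epoch(Xp[, (pre + 1):(pre + 478), drop = FALSE], fs, onset = -0.5)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Edge-exclusion mask
#'
#' Logical mask excluding `frac` of the samples at each end, where EMD and
#' phase estimates are least reliable.
#'
#' @param T number of samples.
#' @param frac fraction excluded per side (default 5%).
#' @return logical vector of length `T`.
#' @export
edge_mask <- function(T, frac = 0.05) {
  k <- ceiling(T * frac)
  m <- rep(TRUE, T)
  if (k > 0) {
    m[seq_len(k)] <- FALSE
    m[(T - k + 1):T] <- FALSE
  }
  m
}
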