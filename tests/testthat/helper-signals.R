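# shared fixtures: tones, mixtures, spectral peak oracle

tone <- function(freq, fs = 1000, duration = 1, phase = 0, amp = 1) {
  amp * cos(2 * pi * freq * (0:(duration * fs - 1)) / fs + phase)
}

# periodogram peak frequency (one-sided), independent oracle for dominant
# frequency checks
spectral_peak <- function(x, fs) {
  T <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(T) - 1) * fs / T
  half <- f < fs / 2
  f[half][which.max(p[half])]
}

# fraction of periodogram mass inside [lo, hi]
spectral_mass_frac <- function(x, fs, lo, hi) {
  T <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(T) - 1) * fs / T
  half <- f <= fs / 2
  sum(p[half & f >= lo & f <= hi]) / sum(p[half])
}

# spectral centroid in Hz
spectral_centroid <- function(x, fs) {
  T <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(T) - 1) * fs / T
  half <- f > 0 & f < fs / 2
  sum(f[half] * p[half]) / sum(p[half])
}

small_leadfield <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_spherical_leadfield(16, 200, seed = 1)
    cache
  }
})
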