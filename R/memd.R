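#' Frequency band definition
#'
#' @param name band label.
#' @param lo,hi band edges in Hz, `0 < lo < hi`.
#' @return list of class `band`.
#' @export
band <- function(name, lo, hi) {
  stopifnot(is.character(name), length(name) == 1, lo > 0, hi > lo)
  structure(list(name = name, lo = lo, hi = hi), class = "band")
}

#' Canonical EEG analysis bands
#'
#' theta 4-8 Hz, alpha 8-14 Hz, beta1 14-22 Hz and beta2 22-30 Hz.
#'
#' @return named list of [band()] objects.
#' @export
default_bands <- function() {
  list(theta = band("theta", 4, 8),
       alpha = band("alpha", 8, 14),
       beta1 = band("beta1", 14, 22),
       beta2 = band("beta2", 22, 30))
}

# van der Corput radical inverse in the given base
radical_inverse <- function(i, base) {
  out <- numeric(length(i))
  f <- 1 / base
  i <- as.integer(i)
  while (any(i > 0)) {
    out <- out + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  out
}

#' Projection direction set on the unit hypersphere
#'
#' K low-discrepancy direction vectors on the unit (n-1)-sphere, used to
#' define envelopes of an n-channel signal. Points come from a Hammersley
#' sequence (first coordinate `(i - 1/2)/K`, remaining coordinates radical
#' inverses in successive prime bases) with a seed-derived Cranley-Patterson
#' shift, pushed to the sphere through the inverse-normal map. For n = 2 the
#' directions are exactly equally spaced angles (rotated by the seed), the
#' usual bivariate choice.
#'
#' @param n signal dimension (>= 2; univariate signals use [emd_decompose()]).
#' @param K number of directions.
#' @param seed integer; fixes the shift/rotation so direction sets are
#'   reproducible.
#' @return K x n matrix with unit-norm rows, class `direction_set`.
#' @export
direction_vectors <- function(n, K, seed = 0L) {
  if (n < 2) stop("n must be >= 2; use the univariate EMD for single channels")
  stopifnot(K >= 1)
  if (K < n) warning("K < n directions: envelope estimate may be poor")
  set.seed(as.integer(seed))
  if (n == 2) {
    ang <- 2 * pi * ((seq_len(K) - 1) / K + stats::runif(1))
    V <- cbind(cos(ang), sin(ang))
  } else {
    primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53,
                59, 61, 67, 71, 73, 79, 83, 89, 97, 101, 103, 107, 109, 113)
    if (n - 1 > length(primes))
      primes <- c(primes, seq(127, by = 2, length.out = n - 1 - length(primes)))
    U <- matrix(0, K, n)
    U[, 1] <- (seq_len(K) - 0.5) / K
    for (j in 2:n) U[, j] <- radical_inverse(seq_len(K), primes[j - 1])
    shift <- stats::runif(n)
    U <- (U + matrix(shift, K, n, byrow = TRUE)) %% 1
    U <- pmin(pmax(U, 1e-7), 1 - 1e-7)
    V <- matrix(stats::qnorm(U), K, n)
    V <- V / sqrt(rowSums(V^2))
  }
  structure(V, class = c("direction_set", "matrix"))
}

#' Multivariate local mean over K projections
#'
#' For each direction the n-channel signal is projected, the projection's
#' extrema are located in time, and all channels are spline-interpolated at
#' those times (with mirrored edges) to form multivariate upper and lower
#' envelopes; the local mean averages them over directions. Directions whose
#' projection is monotone are skipped with a warning; if every direction is
#' skipped the signal is a trend and an error is raised.
#'
#' @param X n x T numeric matrix, n >= 2.
#' @param dirs a [direction_vectors()] set with matching n.
#' @return n x T local-mean matrix with attribute `n_directions_used`.
#' @export
multivariate_mean <- function(X, dirs) {
  X <- as.matrix(X)
  if (nrow(X) < 2)
    stop("X must have >= 2 channels; use the univariate envelope path")
  stopifnot(ncol(dirs) == nrow(X))
  r <- cpp_local_mean_multi(X, unclass(dirs))
  if (!r$ok) stop("all projections are monotone: trend signal")
  if (r$n_directions_used < nrow(dirs))
    warning(nrow(dirs) - r$n_directions_used,
            " projection(s) monotone and skipped")
  structure(r$mean, n_directions_used = r$n_directions_used)
}

#' Multivariate empirical mode decomposition
#'
#' MEMD over K hypersphere projections. Sifting uses only the envelope-mean
#' stopping criterion (the extrema-count condition is not well defined for
#' multichannel signals and is not imposed). IMF indices are aligned across
#' channels by construction, and each channel is reconstructed exactly by
#' the sum of its IMFs plus the residual.
#'
#' @param X n x T matrix (n >= 2).
#' @param K number of projection directions (default 16).
#' @param stop a [sift_control()].
#' @param max_imfs maximum number of IMFs.
#' @param seed seed for the direction set.
#' @param fs sampling rate in Hz (optional, carried along).
#' @param channel_roles character vector `"data"`/`"noise"` per channel.
#' @return object of class `mv_imf_set`: list with `imfs` (W x n x T array),
#'   `residual` (n x T), `fs`, `channel_roles`.
#' @export
memd_decompose <- function(X, K = 16L, stop = sift_control(), max_imfs = 12L,
                           seed = 0L, fs = NULL, channel_roles = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("X must have >= 2 channels; use emd_decompose()")
  stopifnot(all(is.finite(X)), max_imfs >= 1)
  if (is.null(channel_roles)) channel_roles <- rep("data", n)
  stopifnot(length(channel_roles) == n)
  dirs <- direction_vectors(n, K, seed)
  r <- cpp_memd(X, unclass(dirs), as.integer(max_imfs), stop$sd_low,
                stop$sd_high, stop$tol_frac, stop$max_iter)
  W <- length(r$imfs)
  imfs <- array(0, dim = c(W, n, ncol(X)))
  for (w in seq_len(W)) imfs[w, , ] <- r$imfs[[w]]
  structure(list(imfs = imfs, residual = r$residual, fs = fs,
                 channel_roles = channel_roles),
            class = "mv_imf_set")
}

#' @export
print.mv_imf_set <- function(x, ...) {
  cat("<mv_imf_set> ", dim(x$imfs)[1], " IMFs x ", dim(x$imfs)[2],
      " channels, T = ", dim(x$imfs)[3], "\n", sep = "")
  invisible(x)
}

#' Noise-assisted multivariate EMD
#'
#' Appends `n_noise` white-Gaussian channels (at `noise_scale` times the
#' pooled data standard deviation) to the data channels and runs
#' [memd_decompose()] on the composite signal. The broadband noise drives
#' the decomposition toward its quasi-dyadic filterbank behavior, aligning
#' data IMFs with octave-like sub-bands and mitigating mode mixing. IMFs
#' belonging to the noise channels are discarded; only data-channel IMFs are
#' returned.
#'
#' @param X_data n_d x T matrix (or vector for a single channel).
#' @param n_noise number of appended noise channels (default 12).
#' @param noise_scale noise amplitude as a fraction of pooled data std.
#' @param K projection directions.
#' @param stop a [sift_control()].
#' @param max_imfs maximum number of IMFs.
#' @param seed seed for both the noise realization and the direction set.
#' @param fs sampling rate (optional).
#' @return `mv_imf_set` restricted to the data channels.
#' @export
na_memd <- function(X_data, n_noise = 12L, noise_scale = 1.0, K = 16L,
                    stop = sift_control(), max_imfs = 12L, seed = 1L,
                    fs = NULL) {
  if (is.null(dim(X_data))) X_data <- matrix(X_data, nrow = 1)
  X_data <- as.matrix(X_data)
  if (noise_scale <= 0) stop("noise_scale must be positive")
  stopifnot(n_noise >= 1)
  n_d <- nrow(X_data)
  T <- ncol(X_data)
  set.seed(as.integer(seed))
  sd_pool <- stats::sd(as.vector(X_data))
  if (sd_pool == 0) stop("data channels are constant")
  noise <- matrix(stats::rnorm(n_noise * T, sd = noise_scale * sd_pool),
                  nrow = n_noise)
  comp <- rbind(X_data, noise)
  roles <- c(rep("data", n_d), rep("noise", n_noise))
  dec <- memd_decompose(comp, K = K, stop = stop, max_imfs = max_imfs,
                        seed = seed, fs = fs, channel_roles = roles)
  keep <- which(dec$channel_roles == "data")
  structure(list(imfs = dec$imfs[, keep, , drop = FALSE],
                 residual = dec$residual[keep, , drop = FALSE],
                 fs = fs, channel_roles = rep("data", n_d)),
            class = "mv_imf_set")
}

#' Band power of a component
#'
#' Integral of the raw (rectangular-window) periodogram over `[lo, hi]`.
#'
#' @param c numeric vector.
#' @param band a [band()].
#' @param fs sampling rate in Hz; the band must lie below Nyquist.
#' @return scalar power.
#' @export
band_power <- function(c, band, fs) {
  stopifnot(is.numeric(c), all(is.finite(c)))
  if (band$hi >= fs / 2) stop("band upper edge must be below Nyquist (fs/2)")
  T <- length(c)
  spec <- Mod(stats::fft(c))^2 / T
  freqs <- (seq_len(T) - 1) * fs / T
  sel <- freqs >= band$lo & freqs <= band$hi & freqs <= fs / 2
  sum(spec[sel])
}

#' Select the dominant IMF per frequency band
#'
#' For each band, the index of the IMF with the highest band power; ties are
#' broken toward the lower (faster) IMF index. For multivariate sets the
#' selection is made per channel.
#'
#' @param imfset an `imf_set` or `mv_imf_set`.
#' @param bands list of [band()] objects.
#' @param fs sampling rate in Hz.
#' @return for `imf_set`, a named integer vector (one index per band); for
#'   `mv_imf_set`, a bands x channels integer matrix.
#' @export
select_band_imfs <- function(imfset, bands, fs) {
  if (inherits(imfset, "imf_set")) {
    W <- nrow(imfset$imfs)
    stopifnot(W >= 1)
    sel <- vapply(bands, function(b) {
      pw <- vapply(seq_len(W), function(w) band_power(imfset$imfs[w, ], b, fs),
                   numeric(1))
      which.max(pw)  # first maximum = lower index on ties
    }, integer(1))
    names(sel) <- vapply(bands, `[[`, character(1), "name")
    return(sel)
  }
  stopifnot(inherits(imfset, "mv_imf_set"))
  W <- dim(imfset$imfs)[1]
  n <- dim(imfset$imfs)[2]
  stopifnot(W >= 1)
  sel <- matrix(0L, length(bands), n,
                dimnames = list(vapply(bands, `[[`, character(1), "name"),
                                NULL))
  for (ch in seq_len(n)) {
    for (bi in seq_along(bands)) {
      pw <- vapply(seq_len(W),
                   function(w) band_power(imfset$imfs[w, ch, ], bands[[bi]], fs),
                   numeric(1))
      sel[bi, ch] <- which.max(pw)
    }
  }
  sel
}

#' Median band IMF over noise realizations
#'
#' Runs [na_memd()] `n_realizations` times with independent noise, selects
#' the dominant IMF per band (per data channel) in each realization, and
#' reduces to the sample-wise median across realizations. The median damps
#' leakage from any single noise realization into the data-channel IMFs.
#'
#' @param X_data n_d x T matrix or vector.
#' @param bands list of [band()] objects.
#' @param fs sampling rate in Hz.
#' @param n_realizations number of independent noise realizations.
#' @param seed master seed; realization r uses `seed + r`.
#' @inheritParams na_memd
#' @return named list (one entry per band), each of class `band_imf`: list
#'   with `band`, `series` (n_d x T median), and `selections` (realizations
#'   x channels matrix of chosen IMF indices).
#' @export
median_band_imf <- function(X_data, bands = default_bands(), fs,
                            n_realizations = 30L, n_noise = 12L,
                            noise_scale = 1.0, K = 16L,
                            stop = sift_control(), max_imfs = 12L,
                            seed = 1L) {
  if (is.null(dim(X_data))) X_data <- matrix(X_data, nrow = 1)
  X_data <- as.matrix(X_data)
  stopifnot(n_realizations >= 1)
  n_d <- nrow(X_data)
  T <- ncol(X_data)
  nb <- length(bands)
  # store per realization: bands x channels x T
  acc <- array(NA_real_, dim = c(n_realizations, nb, n_d, T))
  sels <- array(NA_integer_, dim = c(n_realizations, nb, n_d))
  for (r in seq_len(n_realizations)) {
    dec <- na_memd(X_data, n_noise = n_noise, noise_scale = noise_scale,
                   K = K, stop = stop, max_imfs = max_imfs,
                   seed = as.integer(seed) + r, fs = fs)
    sel <- select_band_imfs(dec, bands, fs)
    for (bi in seq_len(nb)) for (ch in seq_len(n_d)) {
      acc[r, bi, ch, ] <- dec$imfs[sel[bi, ch], ch, ]
      sels[r, bi, ch] <- sel[bi, ch]
    }
  }
  out <- vector("list", nb)
  names(out) <- vapply(bands, `[[`, character(1), "name")
  for (bi in seq_len(nb)) {
    med <- matrix(0, n_d, T)
    for (ch in seq_len(n_d))
      med[ch, ] <- apply(acc[, bi, ch, , drop = FALSE], 4, stats::median)
    out[[bi]] <- structure(list(band = bands[[bi]], series = med,
                                selections = sels[, bi, , drop = TRUE]),
                           class = "band_imf")
  }
  out
}
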