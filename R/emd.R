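#' Sifting control parameters
#'
#' Stopping rule for the sifting iteration, in the three-threshold style of
#' Rilling, Flandrin and Goncalves: sifting of a candidate component stops
#' once the envelope-mean-to-envelope-amplitude ratio `|m|/a` is below
#' `sd_low` on at least a fraction `1 - tol_frac` of samples and below
#' `sd_high` everywhere. Univariate sifting additionally requires the
#' zero-crossing/extrema count condition (see [is_imf()]).
#'
#' @param sd_low lower ratio threshold that most samples must satisfy.
#' @param sd_high hard ratio cap that every sample must satisfy.
#' @param tol_frac fraction of samples allowed to exceed `sd_low`.
#' @param max_iter hard cap on sifting iterations per component.
#' @return a list of class `sift_control`.
#' @export
sift_control <- function(sd_low = 0.05, sd_high = 0.5, tol_frac = 0.05,
                         max_iter = 100L) {
  stopifnot(sd_low > 0, sd_high > sd_low, tol_frac > 0, tol_frac < 1,
            max_iter >= 1)
  structure(list(sd_low = sd_low, sd_high = sd_high, tol_frac = tol_frac,
                 max_iter = as.integer(max_iter)),
            class = "sift_control")
}

#' Locate local extrema of a signal
#'
#' Strict local minima and maxima; a flat plateau contributes the index of
#' its midpoint. Endpoints are never extrema. A signal with fewer than two
#' minima or two maxima is flagged as monotone/trend, which terminates
#' decomposition downstream.
#'
#' @param x numeric vector (length >= 3).
#' @return list with integer vectors `minima` and `maxima` (1-based,
#'   increasing) and a logical `monotone`.
#' @export
find_extrema <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 3, all(is.finite(x)))
  ex <- cpp_find_extrema(x)
  minima <- ex$minima + 1L
  maxima <- ex$maxima + 1L
  list(minima = minima, maxima = maxima,
       monotone = length(minima) < 2L || length(maxima) < 2L)
}

#' Upper/lower spline envelopes and local mean
#'
#' Natural cubic splines through the local maxima (upper) and minima (lower),
#' with the two edge-nearest extrema mirrored about each signal end before
#' fitting so that the spline does not diverge at the borders. The local mean
#' is the sample-wise average of the two envelopes.
#'
#' @param x numeric vector.
#' @return list with `upper`, `lower` and `local_mean`, each of length
#'   `length(x)`.
#' @export
envelopes <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 3, all(is.finite(x)))
  env <- cpp_envelopes(x)
  if (!env$ok) {
    side <- if (env$n_max < 2) "maxima" else "minima"
    stop("cannot build envelopes: fewer than 2 ", side, " in the signal")
  }
  list(upper = as.numeric(env$upper), lower = as.numeric(env$lower),
       local_mean = as.numeric(env$mean))
}

#' Extract one intrinsic mode function by sifting
#'
#' Repeatedly subtracts the envelope local mean from the signal until the
#' stopping rule in `stop` and the IMF count condition hold, or `max_iter`
#' is reached (in which case the current candidate is returned with a
#' warning).
#'
#' @param x numeric vector, not monotone.
#' @param stop a [sift_control()] object.
#' @return list with `imf`, `residual_input` (`x - imf`), `converged` and
#'   `iters`.
#' @export
sift <- function(x, stop = sift_control()) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  ex <- find_extrema(x)
  if (ex$monotone) stop("signal is monotone/trend; nothing to sift")
  r <- cpp_sift(x, stop$sd_low, stop$sd_high, stop$tol_frac,
                stop$max_iter, TRUE)
  if (!r$converged)
    warning("sifting did not converge within ", stop$max_iter,
            " iterations; returning current candidate")
  list(imf = as.numeric(r$imf), residual_input = x - as.numeric(r$imf),
       converged = r$converged, iters = r$iters)
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) plus a trend
#' residual by iterated sifting: each extracted IMF is subtracted and the
#' sifting restarts on the remainder, until the remainder is monotone or
#' `max_imfs` components have been extracted. The IMFs are ordered fast to
#' slow and reconstruct the input exactly (`colSums(imfs) + residual == x`
#' up to floating point).
#'
#' @param x numeric vector.
#' @param max_imfs maximum number of IMFs to extract.
#' @param stop a [sift_control()] object.
#' @param fs sampling rate in Hz, carried along for downstream analysis.
#' @return an object of class `imf_set`: list with `imfs` (W x T matrix,
#'   possibly 0 rows), `residual` (length T) and `fs`.
#' @export
emd_decompose <- function(x, max_imfs = 12L, stop = sift_control(), fs = NULL) {
  stopifnot(is.numeric(x), length(x) >= 8, all(is.finite(x)), max_imfs >= 1)
  r <- cpp_emd(x, as.integer(max_imfs), stop$sd_low, stop$sd_high,
               stop$tol_frac, stop$max_iter)
  structure(list(imfs = r$imfs, residual = as.numeric(r$residual), fs = fs),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat("<imf_set> ", nrow(x$imfs), " IMFs, T = ", length(x$residual),
      if (!is.null(x$fs)) paste0(", fs = ", x$fs, " Hz"), "\n", sep = "")
  invisible(x)
}

#' Test the two intrinsic-mode-function conditions
#'
#' A component is an IMF when (1) the number of zero crossings and the number
#' of extrema differ by at most one, and (2) the mean of the upper and lower
#' envelopes is (numerically) zero. Condition (2) is operationalized as the
#' ratio `|envelope mean| / envelope amplitude` being below `10 * tol`
#' everywhere and below `tol` on at least 95% of samples.
#'
#' @param c numeric vector.
#' @param tol ratio tolerance operationalizing "envelope mean is zero".
#' @return logical.
#' @export
is_imf <- function(c, tol = 0.05) {
  stopifnot(is.numeric(c), all(is.finite(c)))
  if (length(c) < 3) return(FALSE)
  ex <- cpp_find_extrema(c)
  n_ext <- length(ex$minima) + length(ex$maxima)
  if (length(ex$minima) < 2 || length(ex$maxima) < 2) return(FALSE)
  if (abs(cpp_zero_crossings(c) - n_ext) > 1) return(FALSE)
  env <- cpp_envelopes(c)
  m <- abs(env$mean)
  a <- pmax(abs(env$upper - env$lower) / 2, 1e-12 * max(abs(c)))
  sx <- m / a
  mean(sx > tol) <= 0.05 && max(sx) < 10 * tol
}
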