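#' Circular-linear correlation
#'
#' Correlation in `[0, 1]` between an angular variable and a linear response:
#' `rho = sqrt((r_zc^2 + r_zs^2 - 2 r_zc r_zs r_cs) / (1 - r_cs^2))`, where
#' `r_zc`, `r_zs` are Pearson correlations of the response with `cos(phi)`
#' and `sin(phi)` and `r_cs` correlates `cos(phi)` with `sin(phi)`. This
#' equals the multiple correlation coefficient of regressing the response on
#' `[cos(phi), sin(phi)]`. Degenerate inputs (constant response, or phases
#' whose cosine or sine is constant) are undefined and return `NA` with a
#' warning, distinct from a true zero correlation.
#'
#' @param phi phase vector in radians (length >= 3).
#' @param z response vector of the same length (e.g., MEP amplitudes, mV).
#' @return scalar in `[0, 1]`, or `NA` when undefined.
#' @export
circ_lin_corr <- function(phi, z) {
  stopifnot(length(phi) == length(z), length(z) >= 3,
            all(is.finite(phi)), all(is.finite(z)))
  cx <- cos(phi); sx <- sin(phi)
  if (stats::sd(z) == 0 || stats::sd(cx) == 0 || stats::sd(sx) == 0) {
    warning("degenerate input: circular-linear correlation undefined")
    return(NA_real_)
  }
  r1 <- stats::cor(z, cx)
  r2 <- stats::cor(z, sx)
  rr <- stats::cor(cx, sx)
  rho2 <- (r1^2 + r2^2 - 2 * r1 * r2 * rr) / (1 - rr^2)
  sqrt(min(max(rho2, 0), 1))
}

#' Circular distance between angles
#'
#' Angle of `exp(1i * (phi - psi))`, elementwise with recycling; the result
#' wraps into `(-pi, pi]`.
#'
#' @param phi,psi angles in radians.
#' @return wrapped differences in radians.
#' @export
circ_distance <- function(phi, psi) {
  d <- atan2(sin(phi - psi), cos(phi - psi))
  d[d <= -pi] <- pi
  d
}

#' Compare estimated against true instantaneous attributes
#'
#' The three extraction-quality metrics: mean absolute circular phase
#' deviation (radians), mean absolute instantaneous-frequency deviation
#' (Hz), and the Pearson correlation of the time series. A fraction
#' `edge_margin` of samples at each end is excluded, where decomposition and
#' phase estimation are least reliable.
#'
#' @param est_attrs,true_attrs [hilbert_attributes()]-style lists with
#'   `phase` and `frequency`.
#' @param est_series,true_series the component time series themselves.
#' @param edge_margin fraction of samples excluded per side.
#' @return list of class `eval_metrics` with `phase_deviation` (in `[0,
#'   pi]`), `frequency_deviation` and `temporal_correlation` (in `[-1, 1]`).
#' @export
evaluate_estimate <- function(est_attrs, true_attrs, est_series, true_series,
                              edge_margin = 0.05) {
  T <- length(est_series)
  stopifnot(length(true_series) == T, length(est_attrs$phase) == T,
            length(true_attrs$phase) == T)
  m <- edge_mask(T, edge_margin)
  if (!any(m)) stop("edge margin excludes every sample")
  structure(list(
    phase_deviation = mean(abs(circ_distance(est_attrs$phase[m],
                                             true_attrs$phase[m]))),
    frequency_deviation = mean(abs(est_attrs$frequency[m] -
                                     true_attrs$frequency[m])),
    temporal_correlation = stats::cor(est_series[m], true_series[m])),
    class = "eval_metrics")
}
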