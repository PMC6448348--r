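# Vectorized circular-linear correlation of one response against phase
# columns; returns rho(t) for the observed response and, optionally, for
# permuted responses (columns of Zperm). Degenerate columns give NA.
circ_lin_trace <- function(Phi, z, Zperm = NULL) {
  Nt <- nrow(Phi)
  C <- cos(Phi); S <- sin(Phi)
  csd <- apply(C, 2, stats::sd)
  ssd <- apply(S, 2, stats::sd)
  ok <- csd > 0 & ssd > 0 & stats::sd(z) > 0
  Cs <- scale(C); Ss <- scale(S)
  Cs[, !ok] <- 0; Ss[, !ok] <- 0
  Cs[is.na(Cs)] <- 0; Ss[is.na(Ss)] <- 0
  rr <- colSums(Cs * Ss) / (Nt - 1)
  denom <- pmax(1 - rr^2, 1e-12)
  zs <- as.vector(scale(z))
  rho_of <- function(zcol) {
    r1 <- as.vector(crossprod(Cs, zcol)) / (Nt - 1)
    r2 <- as.vector(crossprod(Ss, zcol)) / (Nt - 1)
    rho2 <- (r1^2 + r2^2 - 2 * r1 * r2 * rr) / denom
    sqrt(pmin(pmax(rho2, 0), 1))
  }
  rho <- rho_of(zs)
  rho[!ok] <- NA_real_
  out <- list(rho = rho, ok = ok)
  if (!is.null(Zperm)) {
    R1 <- crossprod(Cs, Zperm) / (Nt - 1)   # T x P
    R2 <- crossprod(Ss, Zperm) / (Nt - 1)
    rho2 <- (R1^2 + R2^2 - 2 * R1 * R2 * rr) / denom
    RP <- sqrt(pmin(pmax(rho2, 0), 1))
    RP[!ok, ] <- NA_real_
    out$rho_perm <- RP
  }
  out
}

# maximal contiguous runs of a logical vector -> data.frame(start, end)
supra_runs <- function(mask) {
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

max_cluster_sum <- function(tvec, thresh) {
  runs <- supra_runs(tvec > thresh)
  if (nrow(runs) == 0) return(0)
  max(vapply(seq_len(nrow(runs)),
             function(i) sum(tvec[runs$start[i]:runs$end[i]]), numeric(1)))
}

#' Temporal (1D) cluster permutation test of phase-response correlation
#'
#' Links the per-trial phase at each time sample to a scalar behavioral
#' response with the circular-linear correlation, and controls for multiple
#' comparisons across time by cluster permutation: the response is randomly
#' permuted across trials `n_perm` times (phases fixed; the same
#' permutations are shared by all samples, as required for valid
#' maximum-statistic control); each sample's observed correlation is
#' converted into a one-sided t-like score against its permutation null
#' (observed minus null mean over null standard deviation); samples whose
#' score exceeds the t quantile at `1 - alpha` (df `n_perm - 1`) are joined
#' into maximal contiguous clusters scored by the sum of member scores; and
#' each cluster's p-value is the fraction of permutations whose own maximum
#' cluster score reaches it. Clusters with p < 0.05 are flagged significant.
#'
#' @param phases Nt x T phase matrix, radians.
#' @param z length-Nt response vector.
#' @param n_perm number of permutations (default 1000).
#' @param alpha cluster-forming significance level (per sample, one-sided).
#' @param seed permutation seed.
#' @return object of class `cluster_result`: data frame `clusters`
#'   (`start`, `end` in samples, `stat`, `p`, `significant`), plus `rho`,
#'   `t`, `threshold`, `null_max`, and the call parameters.
#' @export
cluster_permutation_1d <- function(phases, z, n_perm = 1000L, alpha = 0.05,
                                   seed = 1L) {
  phases <- as.matrix(phases)
  Nt <- nrow(phases)
  stopifnot(length(z) == Nt)
  if (Nt < 10) warning("fewer than 10 trials: permutation null is coarse")
  set.seed(as.integer(seed))
  perm <- replicate(n_perm, sample.int(Nt))
  zs <- as.vector(scale(z))
  Zperm <- matrix(zs[perm], Nt, n_perm)
  tr <- circ_lin_trace(phases, z, Zperm)
  if (all(!tr$ok)) {
    warning("correlation degenerate at every sample; empty result")
    return(structure(list(clusters = data.frame(start = integer(0),
                                                end = integer(0),
                                                stat = numeric(0),
                                                p = numeric(0),
                                                significant = logical(0)),
                          rho = tr$rho, t = rep(NA_real_, ncol(phases)),
                          threshold = NA_real_, null_max = numeric(0),
                          n_perm = n_perm, alpha = alpha, seed = seed),
                     class = "cluster_result"))
  }
  mu <- rowMeans(tr$rho_perm)
  sdv <- sqrt(pmax(rowSums((tr$rho_perm - mu)^2) / (n_perm - 1), 0))
  sdv <- pmax(sdv, 1e-12)
  t_obs <- (tr$rho - mu) / sdv
  t_perm <- (tr$rho_perm - mu) / sdv
  thresh <- stats::qt(1 - alpha, df = n_perm - 1)
  runs <- supra_runs(t_obs > thresh)
  stats_obs <- vapply(seq_len(nrow(runs)), function(i)
    sum(t_obs[runs$start[i]:runs$end[i]]), numeric(1))
  t_perm[is.na(t_perm)] <- NaN
  null_max <- as.vector(cpp_max_cluster_sums(t_perm, thresh))
  pvals <- vapply(stats_obs, function(s) mean(null_max >= s), numeric(1))
  clusters <- data.frame(start = runs$start, end = runs$end,
                         stat = stats_obs, p = pvals,
                         significant = pvals < 0.05)
  structure(list(clusters = clusters, rho = tr$rho, t = t_obs,
                 threshold = thresh, null_max = null_max,
                 n_perm = n_perm, alpha = alpha, seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  n_sig <- sum(x$clusters$significant)
  cat("<cluster_result> ", nrow(x$clusters), " cluster(s), ", n_sig,
      " significant (", x$n_perm, " permutations)\n", sep = "")
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Sensor adjacency graph by distance
#'
#' Connects sensor pairs closer than `mult` times the median
#' nearest-neighbor distance -- the usual "neighbours by distance" rule for
#' EEG montages.
#'
#' @param positions N x 3 sensor positions.
#' @param mult distance multiplier.
#' @return N x N logical adjacency matrix (symmetric, empty diagonal).
#' @export
sensor_adjacency <- function(positions, mult = 1.5) {
  positions <- as.matrix(positions)
  Dm <- as.matrix(stats::dist(positions))
  diag(Dm) <- Inf
  nn <- apply(Dm, 1, min)
  thr <- mult * stats::median(nn)
  A <- Dm <= thr
  diag(A) <- FALSE
  A | t(A)
}

# connected components over supra-threshold (sensor, time) nodes;
# neighbors: same sensor adjacent time, adjacent sensor same time
label_components_2d <- function(mask, adjacency) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list())
  key <- (idx[, 1] - 1L) * ncol(mask) + idx[, 2]
  lut <- integer(nrow(mask) * ncol(mask))
  lut[key] <- seq_len(nrow(idx))
  parent <- seq_len(nrow(idx))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  neighbors <- lapply(seq_len(nrow(adjacency)), function(s) which(adjacency[s, ]))
  for (n in seq_len(nrow(idx))) {
    s <- idx[n, 1]; t <- idx[n, 2]
    if (t > 1 && mask[s, t - 1]) union2(n, lut[(s - 1L) * ncol(mask) + t - 1L])
    for (s2 in neighbors[[s]])
      if (s2 < s && mask[s2, t]) union2(n, lut[(s2 - 1L) * ncol(mask) + t])
  }
  roots <- vapply(seq_len(nrow(idx)), find, integer(1))
  split(seq_len(nrow(idx)), roots) |>
    lapply(function(members) idx[members, , drop = FALSE])
}

#' Sensor-by-time (2D) cluster permutation test
#'
#' As [cluster_permutation_1d()], but over all sensors simultaneously:
#' supra-threshold (sensor, time) samples are clustered with connectivity
#' between temporally adjacent samples of the same sensor and spatially
#' adjacent sensors at the same time. Also reports the temporally summed
#' squared correlation per sensor (the usual topography summary).
#'
#' @param phases_per_sensor N x Nt x T array of phases.
#' @param z length-Nt response vector.
#' @param adjacency N x N symmetric logical sensor adjacency (e.g.,
#'   [sensor_adjacency()]); an empty matrix treats sensors as isolated (with
#'   a warning).
#' @param n_perm,alpha,seed as in [cluster_permutation_1d()].
#' @return object of class `cluster_result_2d`: `clusters` (list with
#'   `members` ((sensor, time) matrix), `stat`, `p`, `significant`),
#'   `rho` and `t` (N x T), `summed_sq_rho` per sensor, `threshold`.
#' @export
cluster_permutation_2d <- function(phases_per_sensor, z, adjacency,
                                   n_perm = 1000L, alpha = 0.05, seed = 1L) {
  dms <- dim(phases_per_sensor)
  stopifnot(length(dms) == 3)
  N <- dms[1]; Nt <- dms[2]; T <- dms[3]
  stopifnot(length(z) == Nt, nrow(adjacency) == N, ncol(adjacency) == N)
  if (!isTRUE(all.equal(adjacency, t(adjacency))))
    stop("adjacency must be symmetric")
  if (!any(adjacency))
    warning("empty adjacency: sensors treated as isolated")
  set.seed(as.integer(seed))
  perm <- replicate(n_perm, sample.int(Nt))
  zs <- as.vector(scale(z))
  Zperm <- matrix(zs[perm], Nt, n_perm)
  t_obs <- matrix(NA_real_, N, T)
  rho_obs <- matrix(NA_real_, N, T)
  t_perm <- array(NA_real_, dim = c(N, T, n_perm))
  for (s in seq_len(N)) {
    tr <- circ_lin_trace(phases_per_sensor[s, , ], z, Zperm)
    mu <- rowMeans(tr$rho_perm)
    sdv <- pmax(apply(tr$rho_perm, 1, stats::sd), 1e-12)
    rho_obs[s, ] <- tr$rho
    t_obs[s, ] <- (tr$rho - mu) / sdv
    t_perm[s, , ] <- (tr$rho_perm - mu) / sdv
  }
  thresh <- stats::qt(1 - alpha, df = n_perm - 1)
  obs_mask <- !is.na(t_obs) & t_obs > thresh
  comps <- label_components_2d(obs_mask, adjacency)
  stats_obs <- vapply(comps, function(m) sum(t_obs[m]), numeric(1))
  null_max <- vapply(seq_len(n_perm), function(p) {
    tp <- t_perm[, , p]
    msk <- !is.na(tp) & tp > thresh
    cm <- label_components_2d(msk, adjacency)
    if (length(cm) == 0) 0 else max(vapply(cm, function(m) sum(tp[m]),
                                           numeric(1)))
  }, numeric(1))
  pvals <- vapply(stats_obs, function(s) mean(null_max >= s), numeric(1))
  clusters <- lapply(seq_along(comps), function(i)
    list(members = comps[[i]], stat = stats_obs[i], p = pvals[i],
         significant = pvals[i] < 0.05))
  structure(list(clusters = clusters, rho = rho_obs, t = t_obs,
                 summed_sq_rho = rowSums(rho_obs^2, na.rm = TRUE),
                 threshold = thresh, null_max = null_max,
                 n_perm = n_perm, alpha = alpha, seed = seed),
            class = "cluster_result_2d")
}
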