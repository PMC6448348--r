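#' Sensor/source geometry container
#'
#' @param sensor_positions N x 3 matrix of sensor coordinates (meters).
#' @param vertex_positions D x 3 matrix of source-space vertex coordinates
#'   (meters), D >= N.
#' @param vertex_orientations D x 3 matrix of unit dipole orientation
#'   vectors.
#' @param roi_vertices integer indices into the vertices marking the region
#'   of interest (the motor-cortex analogue).
#' @return list of class `geometry`.
#' @export
geometry <- function(sensor_positions, vertex_positions, vertex_orientations,
                     roi_vertices = integer(0)) {
  sensor_positions <- as.matrix(sensor_positions)
  vertex_positions <- as.matrix(vertex_positions)
  vertex_orientations <- as.matrix(vertex_orientations)
  N <- nrow(sensor_positions)
  D <- nrow(vertex_positions)
  stopifnot(ncol(sensor_positions) == 3, ncol(vertex_positions) == 3,
            ncol(vertex_orientations) == 3,
            nrow(vertex_orientations) == D, N >= 4, D >= N)
  nrm <- sqrt(rowSums(vertex_orientations^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("vertex orientations must be unit vectors")
  roi_vertices <- as.integer(roi_vertices)
  if (length(roi_vertices) &&
      (min(roi_vertices) < 1 || max(roi_vertices) > D))
    stop("roi_vertices out of range")
  structure(list(sensor_positions = sensor_positions,
                 vertex_positions = vertex_positions,
                 vertex_orientations = vertex_orientations,
                 roi_vertices = roi_vertices),
            class = "geometry")
}

# Fibonacci lattice: n quasi-uniform points on the unit sphere
# (hemisphere = TRUE restricts to z > 0).
fibonacci_points <- function(n, hemisphere = FALSE) {
  i <- seq_len(n) - 0.5
  z <- if (hemisphere) i / n else 1 - 2 * i / n
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Expansion coefficients of the scalp-surface potential for a dipole at
# scaled radius beta inside three concentric shells. Works in units of the
# outer radius; per harmonic order a 5x5 system imposes potential and
# current continuity at the two inner interfaces and zero current at the
# scalp. Returns the surface coefficient per order for a unit source term.
shell_series <- function(n_terms, rho1, rho2, sigma) {
  out <- numeric(n_terms)
  for (n in seq_len(n_terms)) {
    M <- matrix(0, 5, 5)
    rhs <- numeric(5)
    # unknowns: A1, A2, B2, A3, B3 (potential = A rho^n + B rho^-(n+1))
    # continuity of potential at rho1
    M[1, ] <- c(rho1^n, -rho1^n, -rho1^(-(n + 1)), 0, 0)
    rhs[1] <- -rho1^(-(n + 1))
    # continuity of radial current at rho1
    M[2, ] <- c(sigma[1] * n * rho1^(n - 1),
                -sigma[2] * n * rho1^(n - 1),
                sigma[2] * (n + 1) * rho1^(-(n + 2)), 0, 0)
    rhs[2] <- sigma[1] * (n + 1) * rho1^(-(n + 2))
    # continuity of potential at rho2
    M[3, ] <- c(0, rho2^n, rho2^(-(n + 1)), -rho2^n, -rho2^(-(n + 1)))
    # continuity of radial current at rho2
    M[4, ] <- c(0, sigma[2] * n * rho2^(n - 1),
                -sigma[2] * (n + 1) * rho2^(-(n + 2)),
                -sigma[3] * n * rho2^(n - 1),
                sigma[3] * (n + 1) * rho2^(-(n + 2)))
    # no current through the scalp surface (rho = 1)
    M[5, ] <- c(0, 0, 0, n, -(n + 1))
    sol <- solve(M, rhs)
    out[n] <- sol[4] + sol[5]  # A3 + B3 at rho = 1
  }
  out
}

#' Synthetic spherical leadfield
#'
#' Quasi-equidistant sensors on the upper hemisphere of a scalp sphere,
#' quasi-uniform source vertices on an inner cortical sphere with radial
#' dipole orientations, and gains from a three-concentric-spheres (brain /
#' skull / scalp) analytic dipole model evaluated by Legendre series. A
#' region of interest emulating the precentral-gyrus patch under the
#' stimulation site is marked on the cortical sphere. Deterministic for a
#' fixed seed (the seed controls small tangential jitter of sensors and
#' vertices so layouts are not perfectly symmetric).
#'
#' @param n_sensors number of sensors (>= 4).
#' @param n_vertices number of cortical vertices (>= n_sensors).
#' @param seed integer seed.
#' @param radii shell radii in meters (brain, skull, scalp).
#' @param conductivities shell conductivities in S/m.
#' @param cortex_radius radius of the source sphere (must be < radii[1]).
#' @param roi_radius chord radius (m) of the region of interest.
#' @param n_terms number of Legendre terms in the series.
#' @return list of class `leadfield`: `L` (N x D gain matrix, volts per unit
#'   dipole moment) and `geometry`.
#' @export
make_spherical_leadfield <- function(n_sensors, n_vertices, seed = 1L,
                                     radii = c(0.080, 0.086, 0.092),
                                     conductivities = c(0.33, 0.0042, 0.33),
                                     cortex_radius = 0.072,
                                     roi_radius = 0.025, n_terms = 60L) {
  if (n_sensors < 4) stop("n_sensors must be >= 4")
  if (n_vertices < n_sensors) stop("n_vertices must be >= n_sensors")
  stopifnot(cortex_radius < radii[1], all(diff(radii) > 0))
  set.seed(as.integer(seed))
  jitter_tangent <- function(P, sd_m, radius) {
    P <- P + matrix(stats::rnorm(length(P), sd = sd_m), nrow(P), 3)
    P / sqrt(rowSums(P^2)) * radius
  }
  sens <- jitter_tangent(fibonacci_points(n_sensors, hemisphere = TRUE) *
                           radii[3], 0.001, radii[3])
  verts <- jitter_tangent(fibonacci_points(n_vertices) * cortex_radius,
                          0.0005, cortex_radius)
  ori <- verts / cortex_radius  # radial, outward
  # ROI: cortical patch under a "hand knob"-like scalp site
  roi_dir <- c(0.45, 0.20, 0.87)
  roi_dir <- roi_dir / sqrt(sum(roi_dir^2))
  roi_center <- roi_dir * cortex_radius
  d_roi <- sqrt(rowSums(sweep(verts, 2, roi_center)^2))
  roi <- which(d_roi <= roi_radius)
  geom <- geometry(sens, verts, ori, roi)

  # gains: radial dipoles only need the zonal (P_n) series
  beta <- cortex_radius / radii[3]
  cn <- shell_series(n_terms, radii[1] / radii[3], radii[2] / radii[3],
                     conductivities)
  n_seq <- seq_len(n_terms)
  # source coefficient for a unit radial dipole at scaled radius beta
  src <- n_seq * beta^(n_seq - 1) / (4 * pi * conductivities[1] * radii[3]^2)
  coef <- cn * src
  cosG <- (sens / radii[3]) %*% t(verts / cortex_radius)  # N x D
  P_prev <- matrix(1, nrow(cosG), ncol(cosG))
  P_cur <- cosG
  L <- coef[1] * P_cur
  for (n in 2:n_terms) {
    P_next <- ((2 * n - 1) * cosG * P_cur - (n - 1) * P_prev) / n
    L <- L + coef[n] * P_next
    P_prev <- P_cur
    P_cur <- P_next
  }
  structure(list(L = L, geometry = geom), class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat("<leadfield> ", nrow(x$L), " sensors x ", ncol(x$L), " vertices, ",
      length(x$geometry$roi_vertices), " ROI vertices\n", sep = "")
  invisible(x)
}

#' Sensors nearest to a target position
#'
#' @param geom a [geometry()].
#' @param target_position length-3 position (meters).
#' @param m number of sensors to return (<= N).
#' @return integer sensor indices by ascending Euclidean distance; ties are
#'   broken toward the lower index.
#' @export
nearest_sensors <- function(geom, target_position, m = 1L) {
  stopifnot(inherits(geom, "geometry"), length(target_position) == 3,
            m <= nrow(geom$sensor_positions))
  d <- sqrt(rowSums(sweep(geom$sensor_positions, 2, target_position)^2))
  order(d, seq_along(d))[seq_len(m)]
}
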