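#' The eight method variants
#'
#' Sensor-level: `1_sensor` (NA-EMD of the sensor nearest the target),
#' `4_sensors` (NA-MEMD of the four nearest sensors, all four analyzed),
#' `1plus_sensors` (NA-MEMD of the four nearest sensors, only the nearest
#' one's IMFs analyzed). Source-level: `1_source`, `4_sources`,
#' `1plus_sources` -- the same three schemes applied to the highest-power
#' sources of the region of interest after REST and source localization.
#' Comparators: `bandpass` (zero-phase FIR filtering of the top-power ROI
#' source) and `emd_sl` (NA-EMD per electrode, then source localization of
#' the per-electrode band IMFs).
#'
#' @return character vector of variant names.
#' @export
method_variants <- function() {
  c("1_sensor", "4_sensors", "1plus_sensors",
    "1_source", "4_sources", "1plus_sources",
    "bandpass", "emd_sl")
}

#' Pipeline configuration
#'
#' @param n_realizations NA-MEMD noise realizations per decomposition.
#' @param n_noise appended noise channels.
#' @param noise_scale noise amplitude as a fraction of the data std.
#' @param K projection directions.
#' @param max_imfs maximum IMFs per decomposition.
#' @param stop a [sift_control()].
#' @param bands list of [band()] objects.
#' @param inverse an [inverse_config()].
#' @param edge_margin edge fraction excluded from metrics.
#' @param condition_band length-2 Hz range for the zero-phase 5th-order
#'   Butterworth applied to every epoch before analysis (the standard
#'   conditioning chain); `NULL` disables.
#' @param seed master seed for decomposition noise.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_realizations = 30L, n_noise = 12L,
                            noise_scale = 1.0, K = 16L, max_imfs = 12L,
                            stop = sift_control(), bands = default_bands(),
                            inverse = inverse_config(), edge_margin = 0.05,
                            condition_band = c(1, 45), seed = 1L) {
  structure(list(n_realizations = as.integer(n_realizations),
                 n_noise = as.integer(n_noise), noise_scale = noise_scale,
                 K = as.integer(K), max_imfs = as.integer(max_imfs),
                 stop = stop, bands = bands, inverse = inverse,
                 edge_margin = edge_margin, condition_band = condition_band,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Default SOI vertex: the ROI vertex nearest the ROI centroid
#'
#' @param lf a `leadfield` with a non-empty ROI.
#' @return vertex index.
#' @export
default_soi_vertex <- function(lf) {
  roi <- lf$geometry$roi_vertices
  stopifnot(length(roi) > 0)
  P <- lf$geometry$vertex_positions[roi, , drop = FALSE]
  ctr <- colMeans(P)
  roi[which.min(rowSums(sweep(P, 2, ctr)^2))]
}

# scalp-level target above a vertex (for nearest-sensor selection)
scalp_target <- function(lf, vertex) {
  p <- lf$geometry$vertex_positions[vertex, ]
  r_s <- mean(sqrt(rowSums(lf$geometry$sensor_positions^2)))
  p / sqrt(sum(p^2)) * r_s
}

decompose_channels <- function(X, fs, cfg, seed) {
  median_band_imf(X, bands = cfg$bands, fs = fs,
                  n_realizations = cfg$n_realizations, n_noise = cfg$n_noise,
                  noise_scale = cfg$noise_scale, K = cfg$K, stop = cfg$stop,
                  max_imfs = cfg$max_imfs, seed = seed)
}

# band-keyed list of (n_analyzed x T) matrices -> attach Hilbert attributes
with_attributes <- function(band_series, fs) {
  attrs <- lapply(band_series, function(M)
    lapply(seq_len(nrow(M)), function(i) hilbert_attributes(M[i, ], fs)))
  list(series = band_series, attrs = attrs)
}

#' Run one method variant over epoched trials
#'
#' Sensor variants decompose raw sensor series; source variants run
#' REST, source localization and ROI extraction before decomposition;
#' `bandpass` filters the top-power ROI source; `emd_sl` decomposes every
#' electrode and source-localizes the per-electrode band IMFs. The hidden
#' variant `"truth"` (simulated trial sets only) injects the ground-truth
#' components, as a pipeline identity check.
#'
#' @param trials a `trial_set` (or list of N x T matrices with `fs` given
#'   via `cfg$fs`).
#' @param lf the `leadfield` (required for source variants and sensor
#'   geometry).
#' @param variant one of [method_variants()].
#' @param cfg a [pipeline_config()].
#' @param target_position length-3 target for nearest-sensor selection;
#'   defaults to the scalp point above the SOI vertex for simulated trials.
#' @param roi ROI vertex indices; defaults to the leadfield's ROI.
#' @param fs sampling rate, taken from `trials` when it is a `trial_set`.
#' @return list (one element per trial) with `series` (band-keyed list of
#'   n x T matrices) and `attrs` (band-keyed per-channel
#'   [hilbert_attributes()]).
#' @export
run_variant <- function(trials, lf, variant, cfg = pipeline_config(),
                        target_position = NULL, roi = NULL, fs = NULL) {
  known <- c(method_variants(), "truth")
  if (!variant %in% known)
    stop("unknown variant '", variant, "'; expected one of: ",
         paste(method_variants(), collapse = ", "))
  gt <- NULL
  if (inherits(trials, "trial_set")) {
    fs <- trials$fs
    gt <- trials$ground_truth
    soi_vertex <- trials$config$soi_vertex
    epochs <- trials$epochs
  } else {
    epochs <- trials
    if (is.null(fs)) stop("fs must be given for plain epoch lists")
    soi_vertex <- NULL
  }
  source_like <- variant %in% c("1_source", "4_sources", "1plus_sources",
                                "bandpass", "emd_sl")
  if (source_like && is.null(lf)) stop("source variants require a leadfield")
  if (is.null(roi) && !is.null(lf)) roi <- lf$geometry$roi_vertices
  if (is.null(target_position) && !is.null(lf) && !is.null(soi_vertex))
    target_position <- scalp_target(lf, soi_vertex)
  op <- if (source_like) {
    if (!is.null(attr(lf, "inverse_operator"))) attr(lf, "inverse_operator")
    else make_inverse_operator(lf, cfg$inverse)
  } else NULL
  band_names <- vapply(cfg$bands, `[[`, character(1), "name")
  bfilt <- NULL
  if (!is.null(cfg$condition_band) && variant != "truth") {
    if (cfg$condition_band[2] < fs / 2)
      bfilt <- signal::butter(5, cfg$condition_band / (fs / 2), type = "pass")
  }

  out <- vector("list", length(epochs))
  for (tr in seq_along(epochs)) {
    Y <- epochs[[tr]]
    if (!is.null(bfilt))
      Y <- t(apply(Y, 1, function(ch) signal::filtfilt(bfilt, ch)))
    seed_tr <- cfg$seed + 1009L * tr
    res <- switch(variant,
      "truth" = {
        if (is.null(gt)) stop("'truth' variant needs a simulated trial_set")
        comp <- gt[[tr]]$components
        centers <- trials$config$soi_center_freqs
        series <- lapply(cfg$bands, function(b) {
          j <- which(centers >= b$lo & centers < b$hi)
          if (length(j) == 0) matrix(0, 1, ncol(comp)) else
            comp[j[1], , drop = FALSE]
        })
        names(series) <- band_names
        list(series = series,
             attrs = lapply(seq_along(cfg$bands), function(bi) {
               b <- cfg$bands[[bi]]
               j <- which(centers >= b$lo & centers < b$hi)
               if (length(j) == 0) list(NULL) else
                 list(list(amplitude = abs(comp[j[1], ]),
                           phase = gt[[tr]]$phases[j[1], ],
                           frequency = gt[[tr]]$freqs[j[1], ]))
             }) |> stats::setNames(band_names))
      },
      "1_sensor" = ,
      "4_sensors" = ,
      "1plus_sensors" = {
        if (is.null(target_position))
          stop("sensor variants need a target position")
        n_ch <- if (variant == "1_sensor") 1L else 4L
        chans <- nearest_sensors(lf$geometry, target_position, n_ch)
        med <- decompose_channels(Y[chans, , drop = FALSE], fs, cfg, seed_tr)
        keep <- if (variant == "4_sensors") seq_len(n_ch) else 1L
        series <- lapply(med, function(b) b$series[keep, , drop = FALSE])
        with_attributes(series, fs)
      },
      "1_source" = ,
      "4_sources" = ,
      "1plus_sources" = {
        est <- solve_inverse(rest_transform(Y, lf), op)
        n_src <- if (variant == "1_source") 1L else 4L
        src <- extract_roi_sources(est, roi, n_src)
        med <- decompose_channels(src$series, fs, cfg, seed_tr)
        keep <- if (variant == "4_sources") seq_len(nrow(src$series)) else 1L
        series <- lapply(med, function(b) b$series[keep, , drop = FALSE])
        with_attributes(series, fs)
      },
      "bandpass" = {
        est <- solve_inverse(rest_transform(Y, lf), op)
        x <- extract_roi_sources(est, roi, 1L)$series[1, ]
        series <- lapply(cfg$bands, function(b)
          matrix(fir_bandpass(x, b, fs, pad = TRUE), nrow = 1))
        names(series) <- band_names
        with_attributes(series, fs)
      },
      "emd_sl" = {
        N <- nrow(Y)
        per_band <- lapply(cfg$bands, function(b) matrix(0, N, ncol(Y)))
        names(per_band) <- band_names
        for (i in seq_len(N)) {
          med <- decompose_channels(Y[i, , drop = FALSE], fs, cfg,
                                    seed_tr + 101L * i)
          for (bn in band_names) per_band[[bn]][i, ] <- med[[bn]]$series[1, ]
        }
        series <- lapply(per_band, function(M) {
          est <- solve_inverse(M, op)
          extract_roi_sources(est, roi, 1L)$series
        })
        with_attributes(series, fs)
      })
    out[[tr]] <- res
  }
  out
}

# metrics of one variant result against ground truth, averaged over the SOI
# components (component j is compared within the band containing its center
# frequency) and over the analyzed channels
variant_metrics <- function(res_trial, gt_trial, centers, bands, fs,
                            edge_margin) {
  band_names <- vapply(bands, `[[`, character(1), "name")
  per_comp <- lapply(seq_along(centers), function(j) {
    bi <- which(vapply(bands, function(b) centers[j] >= b$lo &&
                         centers[j] < b$hi, logical(1)))
    if (length(bi) == 0) return(NULL)
    bn <- band_names[bi[1]]
    truth_attr <- list(phase = gt_trial$phases[j, ],
                       frequency = gt_trial$freqs[j, ])
    M <- res_trial$series[[bn]]
    ms <- lapply(seq_len(nrow(M)), function(ch)
      evaluate_estimate(res_trial$attrs[[bn]][[ch]], truth_attr,
                        M[ch, ], gt_trial$components[j, ],
                        edge_margin = edge_margin))
    c(phase_deviation = mean(vapply(ms, `[[`, numeric(1), "phase_deviation")),
      frequency_deviation = mean(vapply(ms, `[[`, numeric(1),
                                        "frequency_deviation")),
      temporal_correlation = mean(vapply(ms, `[[`, numeric(1),
                                         "temporal_correlation")))
  })
  per_comp <- per_comp[!vapply(per_comp, is.null, logical(1))]
  colMeans(do.call(rbind, per_comp))
}

#' Simulation evaluation across method variants
#'
#' For each scenario and repetition, generates one simulated trial, runs the
#' requested variants, and scores each against ground truth (phase
#' deviation, frequency deviation, temporal correlation, averaged over the
#' three SOI components). Repetitions vary the planted frequencies, jitter
#' trajectories, distractor placement and noise; narrowband distractor
#' center frequencies are recycled across repetitions so sweeps are covered
#' evenly. Pairwise two-sided t-tests over repetitions compare variants.
#'
#' @param lf a `leadfield`.
#' @param scenarios list of scenario definitions: each a list with `name`,
#'   `snr_db`, `distractor_distances` (m), and either `distractor_centers`
#'   (Hz, recycled over repetitions) or `distractor_band` (length-2 Hz).
#' @param variants subset of [method_variants()] (plus `"truth"`).
#' @param n_reps repetitions per scenario.
#' @param cfg a [pipeline_config()].
#' @param soi_vertex SOI vertex; defaults to [default_soi_vertex()].
#' @param fs sampling rate of the simulated trials in Hz.
#' @param snr_db_grid optional per-repetition SNR values recycled across
#'   repetitions (overrides the scenario's single `snr_db`), emulating an
#'   SNR sweep averaged in the report.
#' @return data frame of class `table1_report` (scenario x variant means)
#'   with attributes `per_rep` (repetition-level metrics) and `pairwise`
#'   (t-test p-values per metric and scenario).
#' @export
evaluate_simulation <- function(lf, scenarios, variants = method_variants(),
                                n_reps = 20L, cfg = pipeline_config(),
                                soi_vertex = NULL, fs = 1000,
                                snr_db_grid = NULL) {
  if (is.null(soi_vertex)) soi_vertex <- default_soi_vertex(lf)
  # factor the inverse operator once; every variant/repetition reuses it
  attr(lf, "inverse_operator") <- make_inverse_operator(lf, cfg$inverse)
  per_rep <- list()
  for (sc in scenarios) {
    stopifnot(!is.null(sc$name), !is.null(sc$snr_db))
    for (r in seq_len(n_reps)) {
      rep_seed <- cfg$seed + 7919L * r
      dvert <- distractor_placements(lf, soi_vertex,
                                     sc$distractor_distances,
                                     seed = rep_seed)
      dspec <- lapply(seq_along(dvert), function(i) {
        if (!is.null(sc$distractor_centers)) {
          k <- (r - 1L) %% length(sc$distractor_centers) + 1L
          list(vertex = dvert[i], center = sc$distractor_centers[k])
        } else list(vertex = dvert[i], band = sc$distractor_band)
      })
      snr <- if (!is.null(snr_db_grid))
        snr_db_grid[(r - 1L) %% length(snr_db_grid) + 1L] else sc$snr_db
      config <- simulation_config(soi_vertex = soi_vertex,
                                  distractor_spec = dspec,
                                  snr_db = snr, n_trials = 1L,
                                  fs = fs, seed = rep_seed)
      trials <- assemble_trials(lf, config)
      for (v in variants) {
        res <- run_variant(trials, lf, v, cfg)
        m <- variant_metrics(res[[1]], trials$ground_truth[[1]],
                             config$soi_center_freqs, cfg$bands, trials$fs,
                             cfg$edge_margin)
        per_rep[[length(per_rep) + 1L]] <-
          data.frame(scenario = sc$name, variant = v, rep = r,
                     phase_deviation = m[["phase_deviation"]],
                     frequency_deviation = m[["frequency_deviation"]],
                     temporal_correlation = m[["temporal_correlation"]])
      }
    }
  }
  per_rep <- do.call(rbind, per_rep)
  rownames(per_rep) <- NULL
  agg <- stats::aggregate(
    per_rep[, c("phase_deviation", "frequency_deviation",
                "temporal_correlation")],
    by = per_rep[, c("scenario", "variant")], FUN = mean)
  # pairwise two-sided t-tests per scenario and metric
  pw <- list()
  for (scn in unique(per_rep$scenario)) {
    sub <- per_rep[per_rep$scenario == scn, ]
    vs <- unique(sub$variant)
    if (length(vs) < 2) next
    for (metric in c("phase_deviation", "frequency_deviation",
                     "temporal_correlation")) {
      cmb <- utils::combn(vs, 2)
      for (i in seq_len(ncol(cmb))) {
        a <- sub[sub$variant == cmb[1, i], metric]
        b <- sub[sub$variant == cmb[2, i], metric]
        p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
        pw[[length(pw) + 1L]] <- data.frame(
          scenario = scn, metric = metric, variant_a = cmb[1, i],
          variant_b = cmb[2, i], p = p)
      }
    }
  }
  structure(agg, per_rep = per_rep,
            pairwise = if (length(pw)) do.call(rbind, pw) else NULL,
            class = c("table1_report", class(agg)))
}

#' Phase-to-response analysis of epoched trials
#'
#' Optional response-based trial filtering (amplitude cap, removal of the
#' `drop_median_k` trials nearest the median response), per-trial band IMF
#' extraction via the chosen variant, Hilbert phase, and a temporal cluster
#' permutation test per frequency band linking phase to the response.
#'
#' @param epochs list of N x T matrices, or [sensor_epoch()] objects (set
#'   `preprocess = TRUE` for raw epochs needing the standard conditioning
#'   chain).
#' @param mep per-trial response vector, same length as `epochs`.
#' @param lf a `leadfield`.
#' @param roi ROI vertices (defaults to the leadfield's).
#' @param cfg a [pipeline_config()].
#' @param variant decomposition variant (default `1_source`).
#' @param target_position sensor-selection target for sensor variants.
#' @param mep_cap drop trials with response above this value (default Inf).
#' @param drop_median_k drop this many trials nearest the median response.
#' @param preprocess apply [preprocess_epoch()] to each epoch first.
#' @param fs sampling rate of plain-matrix epochs.
#' @param n_perm,alpha permutation-test parameters.
#' @return list of class `phase_response_result`: per-band `cluster_result`
#'   in `clusters`, per-band Nt x T `phases`, `rho` traces, `kept` trial
#'   indices.
#' @export
run_experimental_analysis <- function(epochs, mep, lf, roi = NULL,
                                      cfg = pipeline_config(),
                                      variant = "1_source",
                                      target_position = NULL,
                                      mep_cap = Inf, drop_median_k = 0L,
                                      preprocess = FALSE, fs = NULL,
                                      n_perm = 1000L, alpha = 0.05) {
  if (inherits(epochs, "trial_set")) { fs <- epochs$fs; epochs <- epochs$epochs }
  if (length(epochs) != length(mep))
    stop("mep length (", length(mep), ") does not match trial count (",
         length(epochs), ")")
  if (preprocess) {
    epochs <- lapply(epochs, function(e) preprocess_epoch(e))
    fs <- epochs[[1]]$fs
  }
  if (inherits(epochs[[1]], "sensor_epoch")) {
    fs <- epochs[[1]]$fs
    epochs <- lapply(epochs, `[[`, "data")
  }
  if (is.null(fs)) stop("fs must be known")
  keep <- which(mep <= mep_cap)
  if (drop_median_k > 0) {
    md <- stats::median(mep[keep])
    ord <- order(abs(mep[keep] - md), seq_along(keep))
    keep <- sort(keep[-ord[seq_len(min(drop_median_k, length(keep)))]])
  }
  if (length(keep) < 3) stop("fewer than 3 trials remain after filtering")
  z <- mep[keep]
  res <- run_variant(epochs[keep], lf, variant, cfg,
                     target_position = target_position, roi = roi, fs = fs)
  band_names <- vapply(cfg$bands, `[[`, character(1), "name")
  T <- ncol(res[[1]]$series[[1]])
  phases <- lapply(band_names, function(bn)
    do.call(rbind, lapply(res, function(tr) tr$attrs[[bn]][[1]]$phase)))
  names(phases) <- band_names
  clusters <- lapply(seq_along(band_names), function(bi)
    cluster_permutation_1d(phases[[bi]], z, n_perm = n_perm, alpha = alpha,
                           seed = cfg$seed))
  names(clusters) <- band_names
  structure(list(clusters = clusters, phases = phases,
                 rho = lapply(clusters, `[[`, "rho"), kept = keep,
                 variant = variant, fs = fs),
            class = "phase_response_result")
}
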