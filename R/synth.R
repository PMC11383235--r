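#' Configuration of the synthetic replicate-scan generator
#'
#' Parameterises a ground-truth nucleus population and the degradation model
#' that turns it into replicate "scans": positional jitter, a global tissue
#' shift, detection drop-out, spurious small detections (the low-area
#' artifact mode seen at high resolution), and multiplicative measurement
#' noise on area and stain values. Defaults emulate one 220 x 220 micron ROI
#' of an H&E-stained lymph-node section analysed at 0.11 micron per pixel:
#' on the order of two thousand nuclei, right-skewed areas with mode near
#' 10 um^2 and mean near 13.5 um^2, and sub-micron inter-replicate jitter.
#'
#' @param roi_width_um,roi_height_um ROI dimensions in microns.
#' @param n_nuclei expected ground-truth nucleus count.
#' @param min_separation_um hard-core distance between nucleus centroids.
#' @param area_log_mean,area_log_sd lognormal parameters of true nucleus area
#'   (um^2). The defaults put the mode at ~10 um^2 and the mean at ~13.5.
#' @param stain_mean,stain_sd length-2 vectors (hematoxylin, eosin) of
#'   truncated-normal parameters for the true median stain values.
#' @param jitter_sd_um per-axis positional jitter sd of a replicate.
#' @param p_miss per-nucleus drop-out probability.
#' @param fp_rate_per_um2 intensity of spurious detections (per um^2).
#' @param fp_area_log_mean,fp_area_log_sd lognormal area parameters of the
#'   spurious detections; must describe areas smaller than real nuclei.
#' @param shift_um deterministic global translation `c(dx, dy)` applied to a
#'   replicate (tissue placement shift between scans).
#' @param meas_log_sd sd of multiplicative measurement noise on the log of
#'   area and stain values.
#' @param area_scale multiplicative factor on measured area (resolution
#'   emulation; >= 1 at coarser pixels).
#' @param p_detect_scale multiplier on the detection probability (resolution
#'   emulation; <= 1 at coarser pixels).
#' @param seed seed for ground-truth generation (replicates take their own).
#' @return a `synthetic_scan_config` list.
#' @export
synthetic_scan_config <- function(roi_width_um = 220, roi_height_um = 220,
                                  n_nuclei = 1800, min_separation_um = 3,
                                  area_log_mean = 2.5, area_log_sd = 0.45,
                                  stain_mean = c(hema = 0.55, eosin = 0.25),
                                  stain_sd = c(hema = 0.12, eosin = 0.06),
                                  jitter_sd_um = 0.3, p_miss = 0.03,
                                  fp_rate_per_um2 = 0.002,
                                  fp_area_log_mean = 1.5, fp_area_log_sd = 0.35,
                                  shift_um = c(0, 0), meas_log_sd = 0.05,
                                  area_scale = 1, p_detect_scale = 1,
                                  seed = NULL) {
  cfg <- list(roi_width_um = roi_width_um, roi_height_um = roi_height_um,
              n_nuclei = as.integer(n_nuclei),
              min_separation_um = min_separation_um,
              area_log_mean = area_log_mean, area_log_sd = area_log_sd,
              stain_mean = stain_mean, stain_sd = stain_sd,
              jitter_sd_um = jitter_sd_um, p_miss = p_miss,
              fp_rate_per_um2 = fp_rate_per_um2,
              fp_area_log_mean = fp_area_log_mean,
              fp_area_log_sd = fp_area_log_sd,
              shift_um = as.double(shift_um), meas_log_sd = meas_log_sd,
              area_scale = area_scale, p_detect_scale = p_detect_scale,
              seed = seed)
  validate_synth_config(cfg)
  structure(cfg, class = "synthetic_scan_config")
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    if (roi_width_um <= 0 || roi_height_um <= 0)
      stop_domain("ROI dimensions must be positive")
    if (n_nuclei < 0) stop_domain("n_nuclei must be >= 0")
    if (min_separation_um < 0) stop_domain("min_separation_um must be >= 0")
    for (p in c(p_miss, p_detect_scale))
      if (p < 0 || p > 1) stop_domain("probabilities must lie in [0, 1]")
    for (s in c(area_log_sd, fp_area_log_sd, jitter_sd_um, meas_log_sd,
                stain_sd))
      if (s < 0) stop_domain("standard deviations must be >= 0")
    if (fp_rate_per_um2 < 0) stop_domain("fp_rate_per_um2 must be >= 0")
    if (fp_area_log_mean >= area_log_mean)
      stop_domain("artifact areas must be smaller than nucleus areas ",
                  "(fp_area_log_mean < area_log_mean)")
    if (length(shift_um) != 2L) stop_domain("shift_um must have length 2")
    if (area_scale <= 0) stop_domain("area_scale must be > 0")
  })
  invisible(cfg)
}

# Positive truncated-normal draws by resampling the negative tail.
rtruncnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a ground-truth nucleus population
#'
#' Places `n_nuclei` centroids in the ROI by sequential dart throwing under a
#' hard-core constraint (every pair at least `min_separation_um` apart), then
#' draws true areas from the configured lognormal and true stain medians from
#' positive truncated normals. Deterministic under the config seed.
#'
#' @param cfg a [synthetic_scan_config()].
#' @param attempt_budget maximum number of darts, as a multiple of
#'   `n_nuclei`; exhausted budget raises an infeasibility error reporting how
#'   many nuclei were placed.
#' @return a `ground_truth` object: data frame `nuclei` (columns as in
#'   [detection_set()] records) and `roi_bounds`.
#' @export
generate_ground_truth <- function(cfg, attempt_budget = 100) {
  validate_synth_config(cfg)
  n <- cfg$n_nuclei
  bounds <- c(x_min = 0, y_min = 0, x_max = cfg$roi_width_um,
              y_max = cfg$roi_height_um)
  if (n == 0L) {
    gt <- list(nuclei = data.frame(id = character(), x_um = numeric(),
                                   y_um = numeric(), area_um2 = numeric(),
                                   hema_median = numeric(),
                                   eosin_median = numeric()),
               roi_bounds = bounds, min_separation_um = cfg$min_separation_um)
    return(structure(gt, class = "ground_truth"))
  }
  with_seed(cfg$seed, {
    xs <- ys <- numeric(n)
    placed <- 0L
    budget <- attempt_budget * n
    d2min <- cfg$min_separation_um^2
    while (placed < n && budget > 0L) {
      budget <- budget - 1L
      px <- stats::runif(1, 0, cfg$roi_width_um)
      py <- stats::runif(1, 0, cfg$roi_height_um)
      if (placed == 0L ||
          min((xs[seq_len(placed)] - px)^2 + (ys[seq_len(placed)] - py)^2) >= d2min) {
        placed <- placed + 1L
        xs[placed] <- px
        ys[placed] <- py
      }
    }
    if (placed < n)
      stop_domain("hard-core placement infeasible: placed ", placed, " of ",
                  n, " nuclei within the attempt budget")
    area <- stats::rlnorm(n, cfg$area_log_mean, cfg$area_log_sd)
    hema <- rtruncnorm_pos(n, cfg$stain_mean[[1]], cfg$stain_sd[[1]])
    eosin <- rtruncnorm_pos(n, cfg$stain_mean[[2]], cfg$stain_sd[[2]])
    nuclei <- data.frame(id = paste0("t", seq_len(n)), x_um = xs, y_um = ys,
                         area_um2 = area, hema_median = hema,
                         eosin_median = eosin)
    structure(list(nuclei = nuclei, roi_bounds = bounds,
                   min_separation_um = cfg$min_separation_um),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d nuclei in [%g x %g] um ROI (hard core %g um)\n",
              nrow(x$nuclei), x$roi_bounds["x_max"] - x$roi_bounds["x_min"],
              x$roi_bounds["y_max"] - x$roi_bounds["y_min"],
              x$min_separation_um))
  invisible(x)
}

#' Simulate one replicate scan of a ground truth
#'
#' Applies the degradation model: each true nucleus is retained with
#' probability `(1 - p_miss) * p_detect_scale`; retained centroids are
#' translated by `shift_um` and jittered per axis with sd `jitter_sd_um`;
#' measured area is `true area * area_scale * exp(N(0, meas_log_sd^2))` and
#' stain medians are perturbed multiplicatively the same way; spurious
#' detections arrive as a Poisson process of intensity `fp_rate_per_um2`
#' with small lognormal areas and slightly hematoxylin-rich stains
#' (color-intensive specks). Detections pushed outside the ROI bounds are
#' dropped from the detection set but recorded as `"outside"` in the
#' correspondence map.
#'
#' @param truth a [generate_ground_truth()] result.
#' @param cfg the generating [synthetic_scan_config()].
#' @param replicate_seed seed of this replicate's degradation draws.
#' @param scan_id,roi_id labels for the emitted detection set.
#' @param pixel_size_um pixel size tag for the emitted set.
#' @return list with `detections` (a `detection_set`) and `map`, a data frame
#'   with columns `true_id`, `det_id` and `status` (`detected`, `missed`,
#'   `outside`, or `spurious` rows with `true_id = NA`).
#' @export
simulate_scan <- function(truth, cfg, replicate_seed = NULL,
                          scan_id = "sim", roi_id = "roi",
                          pixel_size_um = 0.11) {
  stopifnot(inherits(truth, "ground_truth"))
  validate_synth_config(cfg)
  b <- truth$roi_bounds
  with_seed(replicate_seed, {
    tn <- truth$nuclei
    n <- nrow(tn)
    p_keep <- (1 - cfg$p_miss) * cfg$p_detect_scale
    kept <- if (n) stats::runif(n) < p_keep else logical(0)
    k <- sum(kept)
    x <- tn$x_um[kept] + cfg$shift_um[1] +
      if (cfg$jitter_sd_um > 0) stats::rnorm(k, 0, cfg$jitter_sd_um) else 0
    y <- tn$y_um[kept] + cfg$shift_um[2] +
      if (cfg$jitter_sd_um > 0) stats::rnorm(k, 0, cfg$jitter_sd_um) else 0
    noise <- function(m) if (cfg$meas_log_sd > 0)
      m * exp(stats::rnorm(length(m), 0, cfg$meas_log_sd)) else m
    area <- noise(tn$area_um2[kept] * cfg$area_scale)
    hema <- noise(tn$hema_median[kept])
    eosin <- noise(tn$eosin_median[kept])
    det_id <- paste0("d", seq_len(k))

    n_fp <- stats::rpois(1, cfg$fp_rate_per_um2 *
                           (b["x_max"] - b["x_min"]) * (b["y_max"] - b["y_min"]))
    fp <- NULL
    if (n_fp > 0) {
      fp <- data.frame(id = paste0("fp", seq_len(n_fp)),
                       x_um = stats::runif(n_fp, b["x_min"], b["x_max"]),
                       y_um = stats::runif(n_fp, b["y_min"], b["y_max"]),
                       area_um2 = stats::rlnorm(n_fp, cfg$fp_area_log_mean,
                                                cfg$fp_area_log_sd) * cfg$area_scale,
                       hema_median = rtruncnorm_pos(n_fp, 1.3 * cfg$stain_mean[[1]],
                                                    cfg$stain_sd[[1]]),
                       eosin_median = rtruncnorm_pos(n_fp, cfg$stain_mean[[2]],
                                                     cfg$stain_sd[[2]]))
    }

    inside <- x >= b["x_min"] & x <= b["x_max"] &
      y >= b["y_min"] & y <= b["y_max"]
    status <- rep("missed", n)
    status[kept] <- ifelse(inside, "detected", "outside")
    map_det <- rep(NA_character_, n)
    map_det[kept][inside] <- det_id[inside]
    map <- data.frame(true_id = tn$id, det_id = map_det, status = status)

    rec <- data.frame(id = det_id[inside], x_um = x[inside], y_um = y[inside],
                      area_um2 = area[inside], hema_median = hema[inside],
                      eosin_median = eosin[inside])
    if (!is.null(fp)) {
      rec <- rbind(rec, fp)
      map <- rbind(map, data.frame(true_id = NA_character_, det_id = fp$id,
                                   status = "spurious"))
    }
    ds <- detection_set(rec, b, pixel_size_um, scan_id, roi_id)
    list(detections = ds, map = map)
  })
}

#' Simulate a series of replicate scans from one ground truth
#'
#' Mirrors a set of technical replicates of one physical sample: one seed
#' stream generates the truth, a derived seed per replicate generates its
#' degradation, so replicates of the same truth are exchangeable.
#'
#' @param cfg a [synthetic_scan_config()] (its `seed` drives the truth).
#' @param n_replicates number of replicate scans.
#' @param scan_prefix label prefix; replicate `i` is `<prefix><i>`.
#' @inheritParams simulate_scan
#' @return list with `truth` and `replicates` (each a [simulate_scan()]
#'   result).
#' @export
simulate_replicates <- function(cfg, n_replicates = 3, scan_prefix = "scan",
                                roi_id = "roi", pixel_size_um = 0.11) {
  truth <- generate_ground_truth(cfg)
  reps <- lapply(seq_len(n_replicates), function(i) {
    simulate_scan(truth, cfg, replicate_seed = derive_seed(cfg$seed, i),
                  scan_id = paste0(scan_prefix, i), roi_id = roi_id,
                  pixel_size_um = pixel_size_um)
  })
  names(reps) <- paste0(scan_prefix, seq_len(n_replicates))
  list(truth = truth, replicates = reps)
}

#' Default resolution-emulation lookup
#'
#' Coarser pixels merge boundary pixels into the detected object and miss
#' small nuclei, so measured areas grow and detection probability falls as
#' the pixel size doubles; the low-area artifact mode (spurious
#' color-intensive specks) appears only at the native resolution.
#'
#' @return data frame with columns `pixel_size_um`, `area_scale`,
#'   `p_detect_scale`, `fp_scale`.
#' @export
resolution_scales <- function() {
  data.frame(pixel_size_um = c(0.11, 0.22, 0.44),
             area_scale = c(1, 1.2, 1.5),
             p_detect_scale = c(1, 0.9, 0.8),
             fp_scale = c(1, 0, 0))
}

#' Simulate the same scan at several analysis resolutions
#'
#' Re-applies the degradation model per resolution with the configured
#' monotone scales (area up, detection probability down as pixels coarsen).
#'
#' @param truth a [generate_ground_truth()] result.
#' @param cfg base [synthetic_scan_config()].
#' @param resolutions pixel sizes (um/px) to emulate; each must appear in
#'   `scales`.
#' @param scales lookup data frame as in [resolution_scales()].
#' @param replicate_seed seed shared by all resolutions. Sharing the seed
#'   couples the draws (common random numbers), so the retained nucleus sets
#'   are nested across decreasing detection probability and a single
#'   resolution with unit scales reproduces [simulate_scan()] exactly.
#' @param scan_id label for the emitted sets.
#' @return named list of [simulate_scan()] results, one per resolution,
#'   each tagged with its `pixel_size_um`.
#' @export
resolution_series <- function(truth, cfg, resolutions = c(0.11, 0.22, 0.44),
                              scales = resolution_scales(),
                              replicate_seed = NULL, scan_id = "sim") {
  if (!length(resolutions) || any(resolutions <= 0))
    stop_domain("resolutions must be a non-empty positive vector")
  out <- vector("list", length(resolutions))
  for (i in seq_along(resolutions)) {
    r <- resolutions[i]
    row <- which(abs(scales$pixel_size_um - r) < 1e-12)
    if (!length(row))
      stop_domain("no configured scales for resolution ", r, " um/px")
    cfg_r <- cfg
    cfg_r$area_scale <- cfg$area_scale * scales$area_scale[row]
    cfg_r$p_detect_scale <- cfg$p_detect_scale * scales$p_detect_scale[row]
    cfg_r$fp_rate_per_um2 <- cfg$fp_rate_per_um2 * scales$fp_scale[row]
    out[[i]] <- simulate_scan(truth, cfg_r, replicate_seed = replicate_seed,
                              scan_id = scan_id, pixel_size_um = r)
  }
  names(out) <- paste0("px", resolutions)
  out
}
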