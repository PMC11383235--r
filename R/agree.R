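#' Agreement-analysis configuration
#'
#' Parameters of the ratio-scale Bland-Altman summary: which quantiles form
#' the limits of agreement (LOAs), and how the bootstrap percentile
#' confidence intervals are built.
#'
#' @param lower_q,upper_q LOA quantiles of the log-ratio differences
#'   (defaults 0.025 and 0.975, chosen over mean +/- 1.96 SD limits because
#'   log-ratios of nucleus measurements need not be normal).
#' @param n_boot bootstrap resamples (default 2000).
#' @param ci_level level of the percentile confidence intervals.
#' @param seed bootstrap seed.
#' @return an `agreement_config` list.
#' @export
agreement_config <- function(lower_q = 0.025, upper_q = 0.975,
                             n_boot = 2000, ci_level = 0.95, seed = NULL) {
  if (!(lower_q > 0 && lower_q < upper_q && upper_q < 1))
    stop_domain("need 0 < lower_q < upper_q < 1")
  if (n_boot < 1) stop_domain("n_boot must be >= 1")
  if (!(ci_level > 0 && ci_level < 1))
    stop_domain("ci_level must lie in (0, 1)")
  structure(list(lower_q = lower_q, upper_q = upper_q,
                 n_boot = as.integer(n_boot), ci_level = ci_level,
                 seed = seed),
            class = "agreement_config")
}

# Median and LOA quantiles of log-differences, back-transformed to ratio
# percentages. Quantiles use linear interpolation between order statistics
# (type 7).
loa_stats <- function(d, lower_q, upper_q) {
  100 * exp(c(median = stats::median(d),
              lower = unname(stats::quantile(d, lower_q, type = 7)),
              upper = unname(stats::quantile(d, upper_q, type = 7))))
}

#' Ratio-scale Bland-Altman agreement of a matched measurement
#'
#' Per-nucleus measurements such as area are heteroscedastic between
#' replicate scans (differences grow with magnitude), so agreement is
#' assessed on ratios: each matched pair contributes
#' `d_i = ln(v_A_i) - ln(v_B_i)`, and the median plus the `lower_q`/`upper_q`
#' quantiles of the `d_i` are back-transformed as `100 * exp(.)`, giving a
#' median ratio and limits of agreement in percent (100% = perfect
#' agreement). Confidence intervals for all three statistics are bootstrap
#' percentile intervals over resampled pairs.
#'
#' @param v_A,v_B strictly positive measurement vectors of equal length,
#'   ordered so element `i` of each belongs to the same matched pair.
#' @param cfg an [agreement_config()].
#' @param feature label carried into the result (e.g. `"area"`).
#' @return an object of class `loa` with fields `feature`, `n_pairs`,
#'   `median_ratio_pct`, `loa_lower_pct`, `loa_upper_pct`, `ci` (3 x 2
#'   matrix of bootstrap CIs), and the log-differences `log_diff`.
#' @export
log_ratio_agreement <- function(v_A, v_B, cfg = agreement_config(),
                                feature = "value") {
  if (length(v_A) != length(v_B))
    stop_domain("v_A and v_B must have equal length")
  n <- length(v_A)
  if (n < 2L) stop_domain("need at least 2 matched pairs")
  bad <- which(!is.finite(v_A) | !is.finite(v_B) | v_A <= 0 | v_B <= 0)
  if (length(bad))
    stop_domain("non-positive or non-finite value in pair ", bad[1L],
                " (ratios require strictly positive measurements)")
  d <- log(v_A) - log(v_B)
  est <- loa_stats(d, cfg$lower_q, cfg$upper_q)

  boot <- with_seed(cfg$seed, {
    idx <- matrix(sample.int(n, n * cfg$n_boot, replace = TRUE),
                  nrow = n, ncol = cfg$n_boot)
    apply(idx, 2L, function(i) loa_stats(d[i], cfg$lower_q, cfg$upper_q))
  })
  alpha <- 1 - cfg$ci_level
  ci <- t(apply(boot, 1L, stats::quantile,
                probs = c(alpha / 2, 1 - alpha / 2), type = 7))
  colnames(ci) <- c("ci_low", "ci_high")
  rownames(ci) <- c("median", "loa_lower", "loa_upper")

  structure(list(feature = feature, n_pairs = n,
                 median_ratio_pct = est[["median"]],
                 loa_lower_pct = est[["lower"]],
                 loa_upper_pct = est[["upper"]],
                 ci = ci, log_diff = d, config = cfg),
            class = "loa")
}

#' @export
print.loa <- function(x, ...) {
  cat(sprintf("Ratio-scale agreement of %s (%d matched pairs)\n",
              x$feature, x$n_pairs))
  cat(sprintf("  median ratio %s%% (95%% CI %s-%s)\n",
              fmt_pct(x$median_ratio_pct),
              fmt_pct(x$ci["median", 1]), fmt_pct(x$ci["median", 2])))
  cat(sprintf("  LOA %s%% (CI %s-%s) to %s%% (CI %s-%s)\n",
              fmt_pct(x$loa_lower_pct),
              fmt_pct(x$ci["loa_lower", 1]), fmt_pct(x$ci["loa_lower", 2]),
              fmt_pct(x$loa_upper_pct),
              fmt_pct(x$ci["loa_upper", 1]), fmt_pct(x$ci["loa_upper", 2])))
  if (x$loa_lower_pct > 100 || x$loa_upper_pct < 100)
    cat("  note: the LOA interval excludes 100% (systematic shift)\n")
  invisible(x)
}

#' @export
coef.loa <- function(object, ...) {
  c(median_ratio_pct = object$median_ratio_pct,
    loa_lower_pct = object$loa_lower_pct,
    loa_upper_pct = object$loa_upper_pct)
}

#' Bland-Altman ratio plot
#'
#' Plots each matched pair's ratio (percent, log-scaled axis) against the
#' geometric mean of the two measurements, with the median ratio and the
#' limits of agreement as horizontal lines.
#'
#' @param x an `loa` object.
#' @param v_A,v_B the paired measurements (to recover the pair means); if
#'   omitted, ratios are plotted against pair index.
#' @param ... passed to [graphics::plot()].
#' @export
plot.loa <- function(x, v_A = NULL, v_B = NULL, ...) {
  ratio <- 100 * exp(x$log_diff)
  if (!is.null(v_A) && !is.null(v_B)) {
    gm <- sqrt(v_A * v_B)
    graphics::plot(gm, ratio, log = "y", xlab = "pair geometric mean",
                   ylab = "ratio A/B (%)",
                   main = paste("Agreement of", x$feature), ...)
  } else {
    graphics::plot(seq_along(ratio), ratio, log = "y", xlab = "pair",
                   ylab = "ratio A/B (%)",
                   main = paste("Agreement of", x$feature), ...)
  }
  graphics::abline(h = c(x$median_ratio_pct, x$loa_lower_pct,
                         x$loa_upper_pct),
                   lty = c(1, 2, 2), col = "firebrick")
  graphics::abline(h = 100, lty = 3, col = "grey40")
  invisible(x)
}

#' Bootstrap percentile confidence interval
#'
#' Resamples the data with replacement `n_boot` times, recomputes the
#' statistic on each resample, and returns the `alpha/2` and `1 - alpha/2`
#' percentiles of the bootstrap distribution. Deterministic under a fixed
#' seed.
#'
#' @param values numeric sample (non-empty).
#' @param statistic `"median"` or `"quantile"`.
#' @param q the probability when `statistic = "quantile"`.
#' @param cfg an [agreement_config()] supplying `n_boot`, `ci_level`, `seed`.
#' @return numeric `c(lower, upper)`.
#' @export
bootstrap_percentile_ci <- function(values, statistic = c("median", "quantile"),
                                    q = 0.5, cfg = agreement_config()) {
  statistic <- match.arg(statistic)
  if (!length(values)) stop_domain("empty sample")
  stat_fun <- if (statistic == "median") stats::median else
    function(x) unname(stats::quantile(x, q, type = 7))
  n <- length(values)
  with_seed(cfg$seed, {
    idx <- matrix(sample.int(n, n * cfg$n_boot, replace = TRUE),
                  nrow = n, ncol = cfg$n_boot)
    reps <- apply(idx, 2L, function(i) stat_fun(values[i]))
    alpha <- 1 - cfg$ci_level
    unname(stats::quantile(reps, c(alpha / 2, 1 - alpha / 2), type = 7))
  })
}

#' Percentages of manually reviewed detection categories
#'
#' A manual review of algorithmic detections sorts them into correct
#' detections, detections that are not a nucleus (false detections),
#' nuclei the algorithm missed, and detections with incorrect (under- or
#' over-) segmentation that the reviewers replaced with corrected
#' annotations. This converts the raw counts into the usual percentages of
#' the total detection count; the incorrectly segmented detections are also
#' expressed as a fraction of the corrected annotations they cover (how many
#' true nuclei the flagged detections represent).
#'
#' @param n_total total algorithmic detections reviewed.
#' @param n_false detections deemed not a nucleus.
#' @param n_missed nuclei found manually but missed by the algorithm.
#' @param n_incorrect detections with incorrect segmentation.
#' @param n_corrected manual annotations replacing the incorrect detections.
#' @return a `categorization_percentages` list with `false_pct`,
#'   `missed_pct`, `incorrect_pct`, `correct_pct` and
#'   `detected_fraction_of_true_pct` (unrounded; the print method shows 2
#'   decimals, the detected fraction also as an integer).
#' @export
categorization_percentages <- function(n_total, n_false = 0, n_missed = 0,
                                       n_incorrect = 0, n_corrected = NA) {
  counts <- c(n_total, n_false, n_missed, n_incorrect)
  if (any(counts < 0)) stop_domain("counts must be >= 0")
  if (n_false + n_incorrect > n_total)
    stop_domain("false + incorrectly segmented detections exceed the total")
  if (n_total <= 0) stop_domain("percentage undefined: n_total must be > 0")
  frac <- if (!is.na(n_corrected)) {
    if (n_corrected <= 0)
      stop_domain("percentage undefined: n_corrected must be > 0")
    100 * n_incorrect / n_corrected
  } else NA_real_
  structure(list(false_pct = 100 * n_false / n_total,
                 missed_pct = 100 * n_missed / n_total,
                 incorrect_pct = 100 * n_incorrect / n_total,
                 correct_pct = 100 * (n_total - n_false - n_incorrect) / n_total,
                 detected_fraction_of_true_pct = frac),
            class = "categorization_percentages")
}

#' @export
print.categorization_percentages <- function(x, ...) {
  cat(sprintf("false detections %s%%, missed %s%%, incorrect segmentation %s%%, correct %s%%\n",
              fmt_pct(x$false_pct), fmt_pct(x$missed_pct),
              fmt_pct(x$incorrect_pct), fmt_pct(x$correct_pct)))
  if (!is.na(x$detected_fraction_of_true_pct))
    cat(sprintf("flagged detections cover %s%% (~%d%%) of the true nuclei they represent\n",
                fmt_pct(x$detected_fraction_of_true_pct),
                round(x$detected_fraction_of_true_pct)))
  invisible(x)
}

#' Descriptive summary of one detection set
#'
#' Count, sample mean and standard deviation (n - 1 denominator) of nucleus
#' area, per-stain mean and median, and an area histogram over half-open
#' bins `[k w, (k+1) w)`.
#'
#' @param ds a `detection_set`.
#' @param bin_width_um2 histogram bin width in um^2.
#' @return a `density_summary` list; an empty set yields `n_detections = 0`
#'   with `NA` moments and `moments_defined = FALSE`.
#' @export
density_summary <- function(ds, bin_width_um2 = 2) {
  stopifnot(inherits(ds, "detection_set"))
  if (bin_width_um2 <= 0) stop_domain("bin width must be > 0")
  rec <- ds$records
  n <- nrow(rec)
  if (n == 0L) {
    return(structure(list(scan_id = ds$scan_id, n_detections = 0L,
                          moments_defined = FALSE,
                          mean_area = NA_real_, sd_area = NA_real_,
                          mean_hema = NA_real_, median_hema = NA_real_,
                          mean_eosin = NA_real_, median_eosin = NA_real_,
                          area_histogram = data.frame(bin_start = numeric(),
                                                      bin_end = numeric(),
                                                      count = integer())),
                     class = "density_summary"))
  }
  k <- floor(rec$area_um2 / bin_width_um2)
  tab <- table(k)
  hist <- data.frame(bin_start = as.numeric(names(tab)) * bin_width_um2,
                     bin_end = (as.numeric(names(tab)) + 1) * bin_width_um2,
                     count = as.integer(tab))
  structure(list(scan_id = ds$scan_id, n_detections = n,
                 moments_defined = n >= 2L,
                 mean_area = mean(rec$area_um2),
                 sd_area = if (n >= 2L) stats::sd(rec$area_um2) else NA_real_,
                 mean_hema = mean(rec$hema_median),
                 median_hema = stats::median(rec$hema_median),
                 mean_eosin = mean(rec$eosin_median),
                 median_eosin = stats::median(rec$eosin_median),
                 area_histogram = hist),
            class = "density_summary")
}

#' @export
print.density_summary <- function(x, ...) {
  cat(sprintf("Scan '%s': %d detections", x$scan_id, x$n_detections))
  if (x$moments_defined)
    cat(sprintf(", area %.2f +/- %.2f um^2", x$mean_area, x$sd_area))
  cat("\n")
  invisible(x)
}

#' Benchmark comparison of two independent manual annotation sets
#'
#' Runs the matching algorithm on two observers' annotations of the same
#' regions; the resulting matched percentage serves as the reference line
#' that replicate-scan comparisons are judged against.
#'
#' @param manual_A,manual_B `detection_set`s of the two annotation sets.
#' @param mcfg a [match_config()].
#' @return a `matching_percentages` object with attribute
#'   `benchmark = TRUE`; degenerate inputs (one empty side) yield 0%
#'   matched without error.
#' @export
benchmark_compare <- function(manual_A, manual_B, mcfg = match_config()) {
  if (!nrow(manual_A$records) || !nrow(manual_B$records)) {
    m <- structure(list(pairs = data.frame(id_A = character(),
                                           id_B = character(),
                                           distance_um = numeric(),
                                           round = integer()),
                        unmatched_A = manual_A$records$id,
                        unmatched_B = manual_B$records$id,
                        edged_out_A = character(), edged_out_B = character(),
                        transform = list(type = "none"),
                        n_A = nrow(manual_A$records),
                        n_B = nrow(manual_B$records),
                        scan_A = manual_A$scan_id, scan_B = manual_B$scan_id,
                        config = mcfg), class = "nucleus_match")
  } else {
    m <- match_patterns(manual_A, manual_B, mcfg)
  }
  p <- matching_percentages(m)
  attr(p, "benchmark") <- TRUE
  p
}
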