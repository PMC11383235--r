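#' Extract matched measurement pairs
#'
#' Joins a feature column of the two detection sets along the matched id
#' pairs, in pair order.
#'
#' @param m a [match_patterns()] result on `A` vs `B`.
#' @param A,B the compared `detection_set`s.
#' @param feature one of `"area_um2"`, `"hema_median"`, `"eosin_median"`.
#' @return data frame with columns `id_A`, `id_B`, `v_A`, `v_B`.
#' @export
matched_feature_pairs <- function(m, A, B, feature = "area_um2") {
  stopifnot(feature %in% c("area_um2", "hema_median", "eosin_median"))
  ia <- match(m$pairs$id_A, A$records$id)
  ib <- match(m$pairs$id_B, B$records$id)
  data.frame(id_A = m$pairs$id_A, id_B = m$pairs$id_B,
             v_A = A$records[[feature]][ia], v_B = B$records[[feature]][ib])
}

#' Define a replicate-scan comparison study
#'
#' A study is a set of scan settings, each with at least two replicate
#' detection sets of the same ROI; every unordered replicate pair within a
#' setting is compared (for three replicates: 1 vs 2, 1 vs 3, 2 vs 3).
#' Optionally each replicate is also compared to a designated reference
#' setting's first replicate, and a pair of independent manual annotation
#' sets provides a benchmark matching percentage.
#'
#' @param settings named list; each element a list of `detection_set`
#'   replicates (>= 2).
#' @param match_cfg a [match_config()].
#' @param agree_cfg an [agreement_config()].
#' @param features measurement columns to run agreement on.
#' @param reference_setting optional name of a setting used as reference
#'   standard.
#' @param benchmark optional list of two manual `detection_set`s.
#' @return a validated `study_design` list.
#' @export
study_design <- function(settings, match_cfg = match_config(),
                         agree_cfg = agreement_config(),
                         features = c("area_um2", "hema_median", "eosin_median"),
                         reference_setting = NULL, benchmark = NULL) {
  if (length(settings) && is.null(names(settings)))
    names(settings) <- paste0("S", seq_along(settings))
  for (nm in names(settings)) {
    reps <- settings[[nm]]
    if (length(reps) < 2L)
      stop_domain("setting '", nm, "' has ", length(reps),
                  " replicate(s); pairwise comparison needs at least 2")
    for (r in reps) stopifnot(inherits(r, "detection_set"))
  }
  if (!is.null(reference_setting) && !reference_setting %in% names(settings))
    stop_domain("reference_setting '", reference_setting,
                "' names no existing setting")
  if (!is.null(benchmark)) {
    stopifnot(length(benchmark) == 2L)
    for (b in benchmark) stopifnot(inherits(b, "detection_set"))
  }
  structure(list(settings = settings, match_cfg = match_cfg,
                 agree_cfg = agree_cfg, features = features,
                 reference_setting = reference_setting,
                 benchmark = benchmark),
            class = "study_design")
}

same_roi <- function(a, b) {
  isTRUE(all.equal(unname(a$roi_bounds), unname(b$roi_bounds), tolerance = 1e-9))
}

compare_pair <- function(A, B, design, setting, pair_label) {
  if (!same_roi(A, B))
    stop_domain("mixed ROI geometries in comparison ", setting, " ", pair_label)
  m <- match_patterns(A, B, design$match_cfg)
  p <- matching_percentages(m)
  loa <- lapply(design$features, function(f) {
    fp <- matched_feature_pairs(m, A, B, f)
    if (nrow(fp) < 2L || anyNA(fp$v_A) || anyNA(fp$v_B)) return(NULL)
    log_ratio_agreement(fp$v_A, fp$v_B, design$agree_cfg, feature = f)
  })
  names(loa) <- design$features
  list(match = m, percentages = p, loa = loa[!vapply(loa, is.null, TRUE)])
}

#' Run a replicate-scan comparison study
#'
#' Executes every within-setting pairwise comparison in the fixed order
#' (1 vs 2, 1 vs 3, 2 vs 3, ...): alignment, matching, matched/unmatched/
#' edged-out percentages, and per-feature ratio-scale agreement. If the
#' design names a reference setting, each replicate of every other setting
#' is additionally compared to the reference's first replicate; a benchmark
#' annotation pair, if given, is compared once. Deterministic given the
#' configured seeds.
#'
#' @param design a [study_design()].
#' @return a `scan_study` object: data frames `comparisons` (percentages per
#'   comparison, pooled and per side) and `loa_table` (per feature:
#'   estimates and bootstrap CIs), list `details` of `nucleus_match`
#'   results, `densities` per scan, optional `benchmark`, and `metadata`.
#' @export
run_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  comp_rows <- list()
  loa_rows <- list()
  details <- list()

  add_comparison <- function(kind, setting, label, A, B) {
    res <- compare_pair(A, B, design, setting, label)
    p <- res$percentages
    key <- paste(kind, setting, label, sep = ":")
    details[[key]] <<- res$match
    comp_rows[[key]] <<- data.frame(
      kind = kind, setting = setting, comparison = label,
      n_A = p$n_A, n_B = p$n_B, n_pairs = p$n_pairs,
      matched_pct = p$matched_pct, unmatched_pct = p$unmatched_pct,
      edged_out_pct = p$edged_out_pct,
      matched_pct_A = p$per_side["A", "matched_pct"],
      matched_pct_B = p$per_side["B", "matched_pct"])
    for (f in names(res$loa)) {
      l <- res$loa[[f]]
      loa_rows[[paste(key, f)]] <<- data.frame(
        kind = kind, setting = setting, comparison = label, feature = f,
        n_pairs = l$n_pairs, median_ratio_pct = l$median_ratio_pct,
        loa_lower_pct = l$loa_lower_pct, loa_upper_pct = l$loa_upper_pct,
        median_ci_low = l$ci["median", 1], median_ci_high = l$ci["median", 2],
        loa_lower_ci_low = l$ci["loa_lower", 1],
        loa_lower_ci_high = l$ci["loa_lower", 2],
        loa_upper_ci_low = l$ci["loa_upper", 1],
        loa_upper_ci_high = l$ci["loa_upper", 2],
        excludes_100 = l$loa_lower_pct > 100 || l$loa_upper_pct < 100)
    }
  }

  for (setting in names(design$settings)) {
    reps <- design$settings[[setting]]
    r <- length(reps)
    for (i in seq_len(r - 1L)) for (j in seq.int(i + 1L, r)) {
      add_comparison("within", setting, sprintf("%dv%d", i, j),
                     reps[[i]], reps[[j]])
    }
  }
  if (!is.null(design$reference_setting)) {
    ref <- design$settings[[design$reference_setting]][[1L]]
    for (setting in setdiff(names(design$settings), design$reference_setting)) {
      reps <- design$settings[[setting]]
      for (i in seq_along(reps)) {
        add_comparison("reference", setting, sprintf("ref_v%d", i),
                       ref, reps[[i]])
      }
    }
  }

  benchmark <- if (!is.null(design$benchmark))
    benchmark_compare(design$benchmark[[1L]], design$benchmark[[2L]],
                      design$match_cfg)

  densities <- list()
  for (setting in names(design$settings)) {
    for (ds in design$settings[[setting]]) {
      densities[[paste(setting, ds$scan_id, sep = ":")]] <- density_summary(ds)
    }
  }

  empty_comp <- data.frame(kind = character(), setting = character(),
                           comparison = character(), n_A = integer(),
                           n_B = integer(), n_pairs = integer(),
                           matched_pct = numeric(), unmatched_pct = numeric(),
                           edged_out_pct = numeric(),
                           matched_pct_A = numeric(),
                           matched_pct_B = numeric())
  structure(list(
    comparisons = if (length(comp_rows))
      do.call(rbind, c(comp_rows, make.row.names = FALSE)) else empty_comp,
    loa_table = if (length(loa_rows))
      do.call(rbind, c(loa_rows, make.row.names = FALSE)) else NULL,
    details = details, densities = densities, benchmark = benchmark,
    metadata = list(
      n_settings = length(design$settings),
      features = design$features,
      match_cfg = unclass(design$match_cfg),
      agree_cfg = unclass(design$agree_cfg),
      reference_setting = design$reference_setting,
      package_version = as.character(utils::packageVersion("replicascan")))),
    class = "scan_study")
}

#' @export
print.scan_study <- function(x, ...) {
  nw <- sum(x$comparisons$kind == "within")
  cat(sprintf("Replicate-scan study: %d setting(s), %d within-setting comparison(s)\n",
              x$metadata$n_settings, nw))
  if (nw) {
    w <- x$comparisons[x$comparisons$kind == "within", ]
    agg <- stats::aggregate(matched_pct ~ setting, data = w, FUN = mean)
    for (k in seq_len(nrow(agg)))
      cat(sprintf("  %s: mean matched %s%%\n", agg$setting[k],
                  fmt_pct(agg$matched_pct[k])))
  }
  if (!is.null(x$benchmark))
    cat(sprintf("  benchmark (manual vs manual): matched %s%%\n",
                fmt_pct(x$benchmark$matched_pct)))
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits the per-comparison percentage table, the per-feature LOA table
#' with bootstrap CIs, per-scan density summaries (all TSV), and a
#' machine-readable JSON summary including run metadata for provenance.
#' Rerunning with identical inputs and seeds reproduces the JSON byte for
#' byte.
#'
#' @param study a [run_study()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
render_report <- function(study, dir) {
  stopifnot(inherits(study, "scan_study"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2L) != 0L)
    stop_format("cannot write to output directory '", dir, "'")
  paths <- character()
  tsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (nrow(study$comparisons)) tsv(study$comparisons, "comparisons.tsv")
  if (!is.null(study$loa_table)) tsv(study$loa_table, "agreement_loa.tsv")
  if (length(study$densities)) {
    dens <- do.call(rbind, lapply(names(study$densities), function(k) {
      d <- study$densities[[k]]
      data.frame(scan = k, n_detections = d$n_detections,
                 mean_area = d$mean_area, sd_area = d$sd_area,
                 mean_hema = d$mean_hema, mean_eosin = d$mean_eosin)
    }))
    tsv(dens, "densities.tsv")
  }
  summary <- list(metadata = study$metadata,
                  comparisons = study$comparisons,
                  loa = study$loa_table,
                  benchmark = if (!is.null(study$benchmark))
                    unclass(study$benchmark)[c("matched_pct", "unmatched_pct",
                                               "edged_out_pct")])
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' Simulate a full multi-setting study
#'
#' Convenience wrapper generating, per setting, one ground truth and `n_rep`
#' degraded replicate scans from a base configuration; setting-specific
#' overrides model, e.g., settings of different jitter or drop-out.
#'
#' @param base_cfg a [synthetic_scan_config()]; its seed drives everything.
#' @param settings named list of per-setting override lists (may be empty
#'   lists for identical conditions).
#' @param n_rep replicates per setting.
#' @return named list of replicate `detection_set` lists, directly usable as
#'   the `settings` argument of [study_design()].
#' @export
simulate_study_settings <- function(base_cfg, settings, n_rep = 3) {
  out <- vector("list", length(settings))
  names(out) <- names(settings)
  for (k in seq_along(settings)) {
    cfg <- base_cfg
    for (field in names(settings[[k]])) cfg[[field]] <- settings[[k]][[field]]
    cfg$seed <- derive_seed(base_cfg$seed, 7919L * k)
    sim <- simulate_replicates(cfg, n_replicates = n_rep,
                               scan_prefix = paste0(names(out)[k], "_scan"))
    out[[k]] <- lapply(sim$replicates, `[[`, "detections")
  }
  out
}
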