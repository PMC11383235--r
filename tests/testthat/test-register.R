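no_align <- match_config(align_mode = "none")

test_that("translation estimation recovers constructed shifts", {
  cfg <- synthetic_scan_config(n_nuclei = 300, min_separation_um = 3,
                               seed = 41)
  gt <- generate_ground_truth(cfg)
  A <- point_set(gt$nuclei$id, gt$nuclei$x_um, gt$nuclei$y_um,
                 roi = c(0, 0, 220, 220))
  # identity
  expect_equal(estimate_translation(A, A), c(0, 0), tolerance = 1e-12)
  # exact translation: shifting B by the estimate restores A's frame
  B <- point_set(gt$nuclei$id, gt$nuclei$x_um + 0.5, gt$nuclei$y_um - 0.3,
                 roi = c(0, 0, 221, 220))
  expect_equal(estimate_translation(A, B), c(-0.5, 0.3), tolerance = 1e-9)
})

test_that("translation estimation is robust to jitter", {
  cfg <- synthetic_scan_config(n_nuclei = 500, min_separation_um = 3,
                               roi_width_um = 300, roi_height_um = 300,
                               seed = 42)
  gt <- generate_ground_truth(cfg)
  set.seed(43)
  A <- point_set(gt$nuclei$id, gt$nuclei$x_um, gt$nuclei$y_um,
                 roi = c(0, 0, 300, 300))
  B <- point_set(gt$nuclei$id,
                 gt$nuclei$x_um + 1 + rnorm(500, 0, 0.1),
                 gt$nuclei$y_um + 1 + rnorm(500, 0, 0.1),
                 roi = c(-2, -2, 302, 302))
  sh <- estimate_translation(A, B)
  expect_lt(max(abs(sh - c(-1, -1))), 0.05)
})

test_that("alignment failure is reported when patterns share no window", {
  A <- point_set("a1", 5, 5, roi = c(0, 0, 100, 100))
  B <- point_set("b1", 95, 95, roi = c(0, 0, 100, 100))
  expect_error(estimate_translation(A, B), "alignment failure")
})

test_that("affine estimation recovers constructed transforms", {
  # identity
  set.seed(31)
  x <- runif(50, 0, 200); y <- runif(50, 0, 200)
  tr <- estimate_affine(data.frame(x_A = x, y_A = y, x_B = x, y_B = y))
  expect_equal(tr$matrix, diag(2), tolerance = 1e-10)
  expect_equal(tr$translation, c(0, 0), tolerance = 1e-8)
  # known rotation + scale + shift, noise free
  th <- 5 * pi / 180
  M <- 1.01 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  t0 <- c(3, -2)
  xa <- M[1, 1] * x + M[1, 2] * y + t0[1]
  ya <- M[2, 1] * x + M[2, 2] * y + t0[2]
  tr2 <- estimate_affine(data.frame(x_A = xa, y_A = ya, x_B = x, y_B = y))
  expect_equal(tr2$matrix, M, tolerance = 1e-8)
  expect_equal(tr2$translation, t0, tolerance = 1e-8)
  # noisy pairs: residual RMS near the theoretical sd * sqrt(2)
  set.seed(32)
  n <- 200
  xb <- runif(n, 0, 200); yb <- runif(n, 0, 200)
  tr3 <- estimate_affine(data.frame(x_A = xb + rnorm(n, 0, 0.1),
                                    y_A = yb + rnorm(n, 0, 0.1),
                                    x_B = xb, y_B = yb))
  expect_equal(tr3$residual_rms, 0.1 * sqrt(2), tolerance = 0.2)
  # degenerate geometry
  expect_error(estimate_affine(data.frame(x_A = 1:2, y_A = 1:2,
                                          x_B = 1:2, y_B = 1:2)),
               "non-collinear")
  expect_error(estimate_affine(data.frame(x_A = 1:5, y_A = 2 * (1:5),
                                          x_B = 1:5, y_B = 2 * (1:5))),
               "non-collinear")
})

test_that("identical patterns match completely at distance zero", {
  inst <- random_instance(1)
  m <- match_patterns(inst$A, inst$A, no_align)
  expect_equal(nrow(m$pairs), nrow(inst$A$records))
  expect_true(all(m$pairs$distance_um == 0))
  expect_length(m$unmatched_A, 0)
  expect_length(m$edged_out_A, 0)
})

test_that("conflict resolution follows the smallest-distance rule", {
  # both a1 and a2 want b1; a1 is closer and wins, a2 finds nothing after
  A <- point_set(c("a1", "a2"), c(0, 0), c(0, 3))
  B <- point_set("b1", 0, 1, scan_id = "B")
  m <- match_patterns(A, B, no_align)
  expect_equal(m$pairs$id_A, "a1")
  expect_equal(m$pairs$id_B, "b1")
  expect_equal(m$pairs$distance_um, 1)
  expect_equal(m$pairs$round, 1L)
  expect_equal(m$unmatched_A, "a2")
  expect_length(m$unmatched_B, 0)
})

test_that("losers of round one are rematched in round two", {
  A <- point_set(c("a1", "a2"), c(0, 0), c(0, 1))
  B <- point_set(c("b1", "b2"), c(0, 0), c(0.4, 2), scan_id = "B")
  m <- match_patterns(A, B, no_align)
  p <- canon_pairs(m$pairs)
  expect_equal(p$id_A, c("a1", "a2"))
  expect_equal(p$id_B, c("b1", "b2"))
  expect_equal(p$round, c(1L, 2L))
  expect_equal(sort(m$pairs$distance_um), c(0.4, 1.0))
})

test_that("the matcher agrees with a brute-force oracle on random instances", {
  mismatches <- 0L
  for (seed in 1:400) {
    inst <- random_instance(seed)
    m <- match_patterns(inst$A, inst$B, no_align)
    o <- oracle_match(inst$A$records$id, inst$A$records$x_um,
                      inst$A$records$y_um, inst$B$records$id,
                      inst$B$records$x_um, inst$B$records$y_um)
    if (!identical(canon_pairs(m$pairs), canon_pairs(o$pairs)))
      mismatches <- mismatches + 1L
    # one-to-one and window-diagonal bound
    expect_false(anyDuplicated(m$pairs$id_A) > 0)
    expect_false(anyDuplicated(m$pairs$id_B) > 0)
    if (nrow(m$pairs))
      expect_lte(max(m$pairs$distance_um), 5 * sqrt(2) + 1e-9)
  }
  expect_equal(mismatches, 0L)
})

test_that("matching is near-symmetric under argument swap without alignment", {
  # the greedy A-proposes scheme is not exactly direction-free: a conflict
  # loser's second-round choice can differ between directions, so a rare
  # pair (order 1 in 10^3 on replicate-like patterns) may swap partners.
  # The pair sets must still agree almost everywhere, and exactly for
  # clearly separated patterns.
  tot <- 0L
  asym <- 0L
  for (seed in 101:115) {
    inst <- random_instance(seed)
    mab <- match_patterns(inst$A, inst$B, no_align)
    mba <- match_patterns(inst$B, inst$A, no_align)
    ab <- sort(paste(mab$pairs$id_A, mab$pairs$id_B))
    ba <- sort(paste(mba$pairs$id_B, mba$pairs$id_A))
    tot <- tot + length(ab)
    asym <- asym + length(setdiff(ab, ba))
  }
  expect_lt(asym / tot, 0.05)
  # planted replicate with jitter far below the hard-core spacing: exact
  cfg <- synthetic_scan_config(n_nuclei = 300, min_separation_um = 4,
                               jitter_sd_um = 0.2, p_miss = 0,
                               fp_rate_per_um2 = 0, seed = 91)
  sim <- simulate_replicates(cfg, 2)
  A <- sim$replicates[[1]]$detections
  B <- sim$replicates[[2]]$detections
  mab <- match_patterns(A, B, no_align)
  mba <- match_patterns(B, A, no_align)
  expect_identical(sort(paste(mab$pairs$id_A, mab$pairs$id_B)),
                   sort(paste(mba$pairs$id_B, mba$pairs$id_A)))
})

test_that("exact distance ties break lexicographically", {
  # a1 equidistant from b1 and b2: picks b1; a2 then takes b2 in round 2
  A <- point_set(c("a1", "a2"), c(5, 5), c(5, 5.5))
  B <- point_set(c("b2", "b1"), c(6, 4), c(5, 5), scan_id = "B")
  m <- match_patterns(A, B, no_align)
  expect_equal(m$pairs$id_B[m$pairs$id_A == "a1"], "b1")
})

test_that("match categories partition each side", {
  for (seed in 201:210) {
    inst <- random_instance(seed)
    m <- match_patterns(inst$A, inst$B, no_align)
    expect_equal(nrow(m$pairs) + length(m$unmatched_A) + length(m$edged_out_A),
                 m$n_A)
    expect_equal(nrow(m$pairs) + length(m$unmatched_B) + length(m$edged_out_B),
                 m$n_B)
  }
})

test_that("leftovers outside the aligned ROI overlap are edged out", {
  # the tissue sat 3 um further right in scan B, so truth nuclei near A's
  # right edge were pushed out of B's ROI and have no counterpart; after
  # shift correction they fall outside the overlap rectangle
  cfg <- synthetic_scan_config(n_nuclei = 250, min_separation_um = 4,
                               seed = 61, p_miss = 0, fp_rate_per_um2 = 0,
                               jitter_sd_um = 0.05, shift_um = c(3, 0),
                               meas_log_sd = 0)
  gt <- generate_ground_truth(cfg)
  sim <- simulate_scan(gt, cfg, replicate_seed = 1)
  A <- point_set(gt$nuclei$id, gt$nuclei$x_um, gt$nuclei$y_um,
                 roi = c(0, 0, 220, 220))
  m <- match_patterns(A, sim$detections,
                      match_config(align_mode = "translation"))
  expect_equal(m$transform$type, "translation")
  expect_lt(max(abs(m$transform$shift - c(-3, 0))), 0.1)
  right_edge <- gt$nuclei$id[gt$nuclei$x_um > 217.4]
  expect_true(all(right_edge %in% m$edged_out_A))
  if (length(m$edged_out_A))
    expect_true(all(gt$nuclei$x_um[gt$nuclei$id %in% m$edged_out_A] > 216.5))
  expect_length(m$unmatched_A, 0)
  expect_equal(nrow(m$pairs) + length(m$edged_out_A), 250)
})

test_that("pooled percentages follow the documented arithmetic and sum to 100", {
  m <- list(pairs = data.frame(id_A = sprintf("a%02d", 1:90),
                               id_B = sprintf("b%02d", 1:90),
                               distance_um = 0, round = 1L),
            unmatched_A = sprintf("u%02d", 1:5),
            unmatched_B = sprintf("v%02d", 1:9),
            edged_out_A = character(), edged_out_B = character(),
            n_A = 95, n_B = 99)
  p <- matching_percentages(m)
  expect_equal(p$matched_pct, 100 * 180 / 194, tolerance = 1e-12)
  expect_equal(p$unmatched_pct, 100 * 14 / 194, tolerance = 1e-12)
  expect_equal(p$edged_out_pct, 0)
  expect_equal(p$matched_pct + p$unmatched_pct + p$edged_out_pct, 100,
               tolerance = 1e-9)
  expect_equal(p$per_side["A", "matched_pct"], 100 * 90 / 95)
  expect_error(matching_percentages(m, n_A = 0, n_B = 0), "undefined")
})

test_that("planted pairs are recovered from simulated replicates", {
  cfg <- synthetic_scan_config(n_nuclei = 350, min_separation_um = 4,
                               jitter_sd_um = 0.3, p_miss = 0,
                               fp_rate_per_um2 = 0, seed = 71)
  gt <- generate_ground_truth(cfg)
  sA <- simulate_scan(gt, cfg, replicate_seed = 1, scan_id = "A")
  sB <- simulate_scan(gt, cfg, replicate_seed = 2, scan_id = "B")
  m <- match_patterns(sA$detections, sB$detections, no_align)
  truth_pairs <- merge(sA$map[!is.na(sA$map$det_id), c("true_id", "det_id")],
                       sB$map[!is.na(sB$map$det_id), c("true_id", "det_id")],
                       by = "true_id")
  key_true <- paste(truth_pairs$det_id.x, truth_pairs$det_id.y)
  key_found <- paste(m$pairs$id_A, m$pairs$id_B)
  expect_true(all(key_found %in% key_true))
})

test_that("matched percentage degrades with drop-out", {
  mean_matched <- function(p_miss) {
    vals <- vapply(1:5, function(s) {
      cfg <- synthetic_scan_config(n_nuclei = 500, p_miss = p_miss,
                                   fp_rate_per_um2 = 0, seed = 300 + s)
      sim <- simulate_replicates(cfg, 2)
      m <- match_patterns(sim$replicates[[1]]$detections,
                          sim$replicates[[2]]$detections, no_align)
      matching_percentages(m)$matched_pct
    }, 0)
    mean(vals)
  }
  res <- vapply(c(0, 0.05, 0.1), mean_matched, 0)
  expect_true(all(diff(res) < 0))
})
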