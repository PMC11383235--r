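#' Matching configuration
#'
#' Controls the two-round conflict-resolving nearest-neighbour matcher and
#' the alignment applied before it. The search window is a square of side
#' `window_um` centred on each nucleus (a Chebyshev window: candidate
#' partners satisfy |dx| <= window_um/2 and |dy| <= window_um/2); the nearest
#' candidate by Euclidean distance is proposed. Nuclei left over after a
#' round are considered again in the next round, twice in total by default.
#'
#' @param window_um side length of the square search window (default 10 um).
#' @param n_rounds matching rounds (default 2); `converge = TRUE` instead
#'   repeats rounds until no new pair forms.
#' @param align_mode `"translation"` (iterative median-shift correction,
#'   the default for replicate comparisons), `"none"`, or `"affine"`
#'   (least-squares affine refit on provisionally matched pairs, for
#'   cross-setting ROI alignment).
#' @param align_max_iter iteration cap of the translation estimator.
#' @param align_tol_um stop when the incremental shift is smaller than this.
#' @param converge if `TRUE`, ignore `n_rounds` and iterate to stability.
#' @return a `match_config` list.
#' @export
match_config <- function(window_um = 10, n_rounds = 2,
                         align_mode = c("translation", "none", "affine"),
                         align_max_iter = 25, align_tol_um = 1e-3,
                         converge = FALSE) {
  align_mode <- match.arg(align_mode)
  if (!is_scalar_num(window_um) || window_um <= 0)
    stop_domain("window_um must be > 0")
  if (n_rounds < 1) stop_domain("n_rounds must be >= 1")
  structure(list(window_um = window_um, n_rounds = as.integer(n_rounds),
                 align_mode = align_mode,
                 align_max_iter = as.integer(align_max_iter),
                 align_tol_um = align_tol_um, converge = isTRUE(converge)),
            class = "match_config")
}

# For each point of (bx, by), the Euclidean-nearest point of (ax, ay) within
# the Chebyshev window half-width h. Returns index (NA when no candidate)
# and squared distance.
nn_within_window <- function(ax, ay, bx, by, h) {
  if (!length(ax) || !length(bx))
    return(list(idx = rep(NA_integer_, length(bx)),
                d2 = rep(NA_real_, length(bx))))
  dx <- outer(bx, ax, "-")
  dy <- outer(by, ay, "-")
  d2 <- dx * dx + dy * dy
  d2[abs(dx) > h | abs(dy) > h] <- Inf
  idx <- max.col(-d2, ties.method = "first")
  best <- d2[cbind(seq_along(bx), idx)]
  idx[!is.finite(best)] <- NA_integer_
  list(idx = idx, d2 = best)
}

#' Estimate the residual translation between two replicate detections
#'
#' Small placement shifts of the tissue between scans leave a global offset
#' between the two point patterns. This estimator shifts side B towards the
#' nearest neighbours of side A iteratively: at each iteration every B
#' nucleus looks up its Euclidean-nearest A nucleus within the square search
#' window, the component-wise median of the displacements is accumulated
#' into the shift, and iteration stops when the incremental shift magnitude
#' drops below `align_tol_um` or `align_max_iter` is reached.
#'
#' @param A,B `detection_set`s (B is the side being shifted).
#' @param cfg a [match_config()].
#' @return numeric `c(dx, dy)`: the total shift to add to B's coordinates to
#'   bring it into A's frame.
#' @export
estimate_translation <- function(A, B, cfg = match_config()) {
  stopifnot(inherits(A, "detection_set"), inherits(B, "detection_set"))
  if (!nrow(A$records) || !nrow(B$records))
    stop_domain("translation estimation needs non-empty detection sets")
  h <- cfg$window_um / 2
  ax <- A$records$x_um; ay <- A$records$y_um
  bx <- B$records$x_um; by <- B$records$y_um
  shift <- c(0, 0)
  for (it in seq_len(cfg$align_max_iter)) {
    nn <- nn_within_window(ax, ay, bx + shift[1], by + shift[2], h)
    ok <- !is.na(nn$idx)
    if (!any(ok)) {
      if (it == 1L)
        stop_domain("alignment failure: no within-window neighbours; ",
                    "use align_mode = \"none\" or enlarge the window")
      break
    }
    inc <- c(stats::median(ax[nn$idx[ok]] - (bx[ok] + shift[1])),
             stats::median(ay[nn$idx[ok]] - (by[ok] + shift[2])))
    shift <- shift + inc
    if (sqrt(sum(inc^2)) < cfg$align_tol_um) break
  }
  shift
}

#' Least-squares affine transform from matched point pairs
#'
#' Fits the 2 x 2 matrix `M` and translation `t` minimising the squared
#' residuals of `M %*% (x_B, y_B) + t` against `(x_A, y_A)`; used to align
#' ROIs across scan settings where a pure translation is not enough.
#'
#' @param pairs data frame with columns `x_A`, `y_A`, `x_B`, `y_B` (at least
#'   3 non-collinear pairs).
#' @return an `affine_transform`: list with `matrix` (2 x 2), `translation`
#'   (length 2) and `residual_rms`.
#' @export
estimate_affine <- function(pairs) {
  pairs <- as.data.frame(pairs)
  need <- c("x_A", "y_A", "x_B", "y_B")
  if (!all(need %in% names(pairs)))
    stop_format("pairs must have columns ", paste(need, collapse = ", "))
  n <- nrow(pairs)
  X <- cbind(1, pairs$x_B, pairs$y_B)
  if (n < 3L || qr(X)$rank < 3L)
    stop_domain("affine fit needs at least 3 non-collinear pairs")
  fit <- stats::lm.fit(X, cbind(pairs$x_A, pairs$y_A))
  cf <- unname(fit$coefficients)
  res <- fit$residuals
  structure(list(matrix = t(cf[2:3, , drop = FALSE]),
                 translation = as.numeric(cf[1, ]),
                 residual_rms = sqrt(mean(res^2) * 2)),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("Affine transform (B -> A frame):\n")
  cat(sprintf("  matrix      [%9.6f %9.6f; %9.6f %9.6f]\n",
              x$matrix[1, 1], x$matrix[1, 2], x$matrix[2, 1], x$matrix[2, 2]))
  cat(sprintf("  translation (%g, %g) um, residual RMS %.4g um\n",
              x$translation[1], x$translation[2], x$residual_rms))
  invisible(x)
}

apply_affine <- function(tr, x, y) {
  list(x = tr$matrix[1, 1] * x + tr$matrix[1, 2] * y + tr$translation[1],
       y = tr$matrix[2, 1] * x + tr$matrix[2, 2] * y + tr$translation[2])
}

# Rectangle intersection of two c(x_min, y_min, x_max, y_max) vectors;
# may be empty (max < min).
rect_intersection <- function(r1, r2) {
  c(x_min = max(r1[["x_min"]], r2[["x_min"]]),
    y_min = max(r1[["y_min"]], r2[["y_min"]]),
    x_max = min(r1[["x_max"]], r2[["x_max"]]),
    y_max = min(r1[["y_max"]], r2[["y_max"]]))
}

# Greedy conflict-resolving rounds on aligned coordinates. Points enter
# sorted by id so that which.min/first-tie rules realise the documented
# lexicographic tie-break.
match_rounds <- function(ids_A, ax, ay, ids_B, bx, by, h, n_rounds, converge) {
  ordA <- order(ids_A, method = "radix")
  ordB <- order(ids_B, method = "radix")
  ia <- ordA
  ib <- ordB
  pairs <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    if (!length(ia) || !length(ib)) break
    dx <- outer(ax[ia], bx[ib], "-")
    dy <- outer(ay[ia], by[ib], "-")
    d2 <- dx * dx + dy * dy
    d2[abs(dx) > h | abs(dy) > h] <- Inf
    # each remaining A proposes to its nearest remaining B (first = smallest
    # id_B among exact ties, columns being id-sorted)
    prop <- max.col(-d2, ties.method = "first")
    pd2 <- d2[cbind(seq_along(ia), prop)]
    has <- is.finite(pd2)
    if (!any(has)) break
    # each proposed-to B accepts the closest proposer; ties fall to the
    # smallest id_A because rows are id-sorted and order() is stable
    cand <- data.frame(a = seq_along(ia)[has], b = prop[has], d2 = pd2[has])
    cand <- cand[order(cand$d2, cand$a), ]
    win <- cand[!duplicated(cand$b), ]
    pairs[[round]] <- data.frame(id_A = ids_A[ia[win$a]],
                                 id_B = ids_B[ib[win$b]],
                                 distance_um = sqrt(win$d2),
                                 round = round)
    ia <- ia[-win$a]
    ib <- ib[-win$b]
    if (converge) {
      if (nrow(pairs[[round]]) == 0L) break
    } else if (round >= n_rounds) break
  }
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else
    data.frame(id_A = character(), id_B = character(),
               distance_um = numeric(), round = integer()),
    left_A = ids_A[ia], left_B = ids_B[ib])
}

#' Match nucleus detections between two replicate scans
#'
#' Treats each scan's nucleus centroids as a point pattern and pairs them
#' up: after the configured alignment is applied to side B, every unmatched
#' nucleus of A proposes to its Euclidean-nearest unmatched nucleus of B
#' within the square search window; when several propose to the same
#' nucleus, the pair with the smallest distance wins and the losers are
#' considered again in the next round (two rounds by default). Nuclei still
#' unpaired after the last round are `unmatched`, unless their aligned
#' position falls outside the overlap of the two aligned ROI rectangles, in
#' which case they are `edged-out` (no counterpart can exist there).
#'
#' Exact distance ties are broken by lexicographic id order so results are
#' reproducible.
#'
#' @param A,B `detection_set`s of the two scans on the same ROI.
#' @param cfg a [match_config()].
#' @return a `nucleus_match`: `pairs` (data frame `id_A`, `id_B`,
#'   `distance_um`, `round`), `unmatched_A/B`, `edged_out_A/B` (id vectors),
#'   `transform` (the alignment applied to B), `n_A`, `n_B`, and the config.
#' @export
match_patterns <- function(A, B, cfg = match_config()) {
  stopifnot(inherits(A, "detection_set"), inherits(B, "detection_set"))
  h <- cfg$window_um / 2
  ax <- A$records$x_um; ay <- A$records$y_um
  bx0 <- B$records$x_um; by0 <- B$records$y_um
  ids_A <- A$records$id; ids_B <- B$records$id

  transform <- list(type = "none")
  bx <- bx0; by <- by0
  bounds_B <- B$roi_bounds
  if (length(ax) && length(bx0) && cfg$align_mode != "none") {
    shift <- estimate_translation(A, B, cfg)
    bx <- bx0 + shift[1]; by <- by0 + shift[2]
    bounds_B <- B$roi_bounds + shift[c(1, 2, 1, 2)]
    transform <- list(type = "translation", shift = shift)
    if (cfg$align_mode == "affine") {
      prov <- match_rounds(ids_A, ax, ay, ids_B, bx, by, h,
                           cfg$n_rounds, cfg$converge)
      pr <- prov$pairs
      ib <- match(pr$id_B, ids_B)
      tr <- estimate_affine(data.frame(
        x_A = ax[match(pr$id_A, ids_A)], y_A = ay[match(pr$id_A, ids_A)],
        x_B = bx0[ib], y_B = by0[ib]))
      al <- apply_affine(tr, bx0, by0)
      bx <- al$x; by <- al$y
      corners <- apply_affine(tr,
                              B$roi_bounds[c("x_min", "x_max", "x_min", "x_max")],
                              B$roi_bounds[c("y_min", "y_min", "y_max", "y_max")])
      bounds_B <- c(x_min = min(corners$x), y_min = min(corners$y),
                    x_max = max(corners$x), y_max = max(corners$y))
      transform <- tr
    }
  }

  mr <- match_rounds(ids_A, ax, ay, ids_B, bx, by, h,
                     cfg$n_rounds, cfg$converge)

  overlap <- rect_intersection(A$roi_bounds, bounds_B)
  in_overlap <- function(x, y) {
    overlap[["x_max"]] >= overlap[["x_min"]] &
      overlap[["y_max"]] >= overlap[["y_min"]] &
      x >= overlap[["x_min"]] & x <= overlap[["x_max"]] &
      y >= overlap[["y_min"]] & y <= overlap[["y_max"]]
  }
  la <- match(mr$left_A, ids_A)
  lb <- match(mr$left_B, ids_B)
  edged_A <- mr$left_A[!in_overlap(ax[la], ay[la])]
  edged_B <- mr$left_B[!in_overlap(bx[lb], by[lb])]

  out <- structure(list(
    pairs = mr$pairs,
    unmatched_A = setdiff(mr$left_A, edged_A),
    unmatched_B = setdiff(mr$left_B, edged_B),
    edged_out_A = edged_A, edged_out_B = edged_B,
    transform = transform,
    n_A = length(ids_A), n_B = length(ids_B),
    scan_A = A$scan_id, scan_B = B$scan_id,
    config = cfg), class = "nucleus_match")
  validate_match(out, cfg)
  out
}

validate_match <- function(m, cfg) {
  if (anyDuplicated(m$pairs$id_A) || anyDuplicated(m$pairs$id_B))
    stop("internal error: matching is not one-to-one")
  lim <- (cfg$window_um / 2) * sqrt(2) + 1e-9
  if (nrow(m$pairs) && any(m$pairs$distance_um > lim))
    stop("internal error: pair distance exceeds the window diagonal")
  okA <- nrow(m$pairs) + length(m$unmatched_A) + length(m$edged_out_A) == m$n_A
  okB <- nrow(m$pairs) + length(m$unmatched_B) + length(m$edged_out_B) == m$n_B
  if (!okA || !okB) stop("internal error: match categories do not partition")
  invisible(m)
}

#' @export
print.nucleus_match <- function(x, ...) {
  cat(sprintf("Nucleus match %s vs %s: %d pairs (n_A = %d, n_B = %d)\n",
              x$scan_A, x$scan_B, nrow(x$pairs), x$n_A, x$n_B))
  if (identical(x$transform$type, "translation"))
    cat(sprintf("  alignment shift applied to B: (%.3f, %.3f) um\n",
                x$transform$shift[1], x$transform$shift[2]))
  p <- matching_percentages(x)
  cat(sprintf("  matched %s%%, unmatched %s%%, edged-out %s%% (pooled)\n",
              fmt_pct(p$matched_pct), fmt_pct(p$unmatched_pct),
              fmt_pct(p$edged_out_pct)))
  invisible(x)
}

#' @export
summary.nucleus_match <- function(object, ...) {
  p <- matching_percentages(object)
  print(object)
  if (nrow(object$pairs)) {
    q <- stats::quantile(object$pairs$distance_um, c(0.5, 0.95))
    cat(sprintf("  pair distance: median %.3f um, 95th pct %.3f um\n",
                q[1], q[2]))
    cat(sprintf("  rounds: %s\n",
                paste(sprintf("round %d: %d", sort(unique(object$pairs$round)),
                              table(object$pairs$round)), collapse = ", ")))
  }
  invisible(p)
}

#' Matched / unmatched / edged-out percentages
#'
#' Summarises a pairwise scan comparison as percentages of the whole batch.
#' The pooled convention uses both sides' nuclei as the denominator
#' (`matched_pct = 100 * 2 |pairs| / (n_A + n_B)`), so the three pooled
#' percentages sum to 100 exactly; per-side percentages are also reported.
#'
#' @param m a [match_patterns()] result.
#' @param n_A,n_B side totals (defaults taken from `m`).
#' @return a `matching_percentages` list: `matched_pct`, `unmatched_pct`,
#'   `edged_out_pct` (pooled) and `per_side`, a 2-row data frame.
#' @export
matching_percentages <- function(m, n_A = m$n_A, n_B = m$n_B) {
  if (n_A + n_B == 0)
    stop_domain("percentages undefined: no nuclei on either side")
  np <- nrow(m$pairs)
  uA <- length(m$unmatched_A); uB <- length(m$unmatched_B)
  eA <- length(m$edged_out_A); eB <- length(m$edged_out_B)
  tot <- n_A + n_B
  side <- function(n, u, e) if (n > 0)
    c(matched_pct = 100 * np / n, unmatched_pct = 100 * u / n,
      edged_out_pct = 100 * e / n) else
        c(matched_pct = NA_real_, unmatched_pct = NA_real_,
          edged_out_pct = NA_real_)
  per_side <- rbind(A = side(n_A, uA, eA), B = side(n_B, uB, eB))
  structure(list(matched_pct = 100 * 2 * np / tot,
                 unmatched_pct = 100 * (uA + uB) / tot,
                 edged_out_pct = 100 * (eA + eB) / tot,
                 n_pairs = np, n_A = n_A, n_B = n_B,
                 per_side = as.data.frame(per_side)),
            class = "matching_percentages")
}

#' @export
print.matching_percentages <- function(x, ...) {
  cat(sprintf("matched %s%%  unmatched %s%%  edged-out %s%%  (pooled, %d pairs)\n",
              fmt_pct(x$matched_pct), fmt_pct(x$unmatched_pct),
              fmt_pct(x$edged_out_pct), x$n_pairs))
  invisible(x)
}
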