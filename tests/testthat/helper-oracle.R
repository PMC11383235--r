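# Independent brute-force re-implementation of the two-round
# conflict-resolving matcher, written as plain nested loops so it shares no
# code path with the package's vectorised matcher. Proposals go A -> B to
# the Euclidean-nearest free B nucleus within the Chebyshev window; each B
# accepts the closest proposer; exact ties fall to the lexicographically
# smallest id.
oracle_match <- function(ids_A, ax, ay, ids_B, bx, by,
                         window = 10, n_rounds = 2) {
  h <- window / 2
  freeA <- seq_along(ax)
  freeB <- seq_along(bx)
  pairs <- NULL
  for (r in seq_len(n_rounds)) {
    props <- list()
    for (i in freeA) {
      best_j <- NA_integer_
      best_d <- Inf
      for (j in freeB) {
        if (abs(ax[i] - bx[j]) > h || abs(ay[i] - by[j]) > h) next
        d <- sqrt((ax[i] - bx[j])^2 + (ay[i] - by[j])^2)
        if (d < best_d ||
            (d == best_d && !is.na(best_j) && ids_B[j] < ids_B[best_j])) {
          best_d <- d
          best_j <- j
        }
      }
      if (!is.na(best_j))
        props[[length(props) + 1L]] <- list(i = i, j = best_j, d = best_d)
    }
    if (!length(props)) break
    for (t in unique(vapply(props, function(p) p$j, 0L))) {
      cand <- Filter(function(p) p$j == t, props)
      win <- cand[[1L]]
      for (p in cand[-1L]) {
        if (p$d < win$d || (p$d == win$d && ids_A[p$i] < ids_A[win$i]))
          win <- p
      }
      pairs <- rbind(pairs, data.frame(id_A = ids_A[win$i],
                                       id_B = ids_B[win$j],
                                       distance_um = win$d, round = r))
      freeA <- setdiff(freeA, win$i)
      freeB <- setdiff(freeB, win$j)
    }
  }
  if (is.null(pairs))
    pairs <- data.frame(id_A = character(), id_B = character(),
                        distance_um = numeric(), round = integer())
  list(pairs = pairs, left_A = ids_A[freeA], left_B = ids_B[freeB])
}

# Random point-pattern instance on a small ROI; zero-padded ids keep
# lexicographic order locale-independent.
random_instance <- function(seed, n_max = 30, roi = 40) {
  set.seed(seed)
  n_A <- sample.int(n_max, 1)
  n_B <- sample.int(n_max, 1)
  A <- detection_set(data.frame(id = sprintf("a%03d", seq_len(n_A)),
                                x_um = runif(n_A, 0, roi),
                                y_um = runif(n_A, 0, roi),
                                area_um2 = runif(n_A, 5, 30),
                                hema_median = runif(n_A, 0.2, 0.9),
                                eosin_median = runif(n_A, 0.1, 0.5)),
                     c(0, 0, roi, roi), 0.11, scan_id = "A")
  B <- detection_set(data.frame(id = sprintf("b%03d", seq_len(n_B)),
                                x_um = runif(n_B, 0, roi),
                                y_um = runif(n_B, 0, roi),
                                area_um2 = runif(n_B, 5, 30),
                                hema_median = runif(n_B, 0.2, 0.9),
                                eosin_median = runif(n_B, 0.1, 0.5)),
                     c(0, 0, roi, roi), 0.11, scan_id = "B")
  list(A = A, B = B)
}

# Sort pair tables into a canonical order for comparison.
canon_pairs <- function(p) {
  p <- p[order(p$id_A, method = "radix"), c("id_A", "id_B", "round")]
  rownames(p) <- NULL
  p
}

# Small deterministic detection set from explicit coordinates.
point_set <- function(ids, x, y, roi = c(0, 0, 100, 100), scan_id = "S") {
  detection_set(data.frame(id = ids, x_um = x, y_um = y,
                           area_um2 = rep(10, length(x)),
                           hema_median = rep(0.5, length(x)),
                           eosin_median = rep(0.2, length(x))),
                roi, 0.11, scan_id = scan_id)
}
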