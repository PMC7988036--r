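# extract rate values and validity from a rate_map or a numeric vector
map_values <- function(m) {
  if (inherits(m, "rate_map")) {
    v <- as.numeric(m$rate)
    v[as.logical(m$empty)] <- NA
    v
  } else as.numeric(m)
}

#' Pearson correlation between two rate maps
#'
#' Computed over bins visited in both maps. Returns `NA` ("no value") when
#' neither map has a peak above `min_peak` Hz or when fewer than
#' `min_bins` common visited bins exist, so silent or barely-sampled map
#' pairs never enter the correlation analyses.
#'
#' @param a,b [rate_map()]s on the same grid, or numeric vectors of rates
#'   with `NA` at unvisited bins.
#' @param min_peak Minimum peak rate (Hz) required of at least one map.
#' @param min_bins Minimum number of common visited bins.
#' @return Pearson r, or `NA`.
#' @export
map_correlation <- function(a, b, min_peak = 1, min_bins = 10) {
  va <- map_values(a); vb <- map_values(b)
  if (length(va) != length(vb)) stop("maps are on different grids")
  ok <- is.finite(va) & is.finite(vb)
  if (sum(ok) < min_bins) return(NA_real_)
  pa <- suppressWarnings(max(va[ok]))
  pb <- suppressWarnings(max(vb[ok]))
  if (!(pa > min_peak || pb > min_peak)) return(NA_real_)
  if (stats::sd(va[ok]) == 0 || stats::sd(vb[ok]) == 0) return(NA_real_)
  stats::cor(va[ok], vb[ok])
}

#' Fuhs rate-remapping metric
#'
#' `sum|f1 - f2| / sum(|f1| + |f2|)` over the common visited bins, after
#' zero-normalizing each map by subtracting its own mean. The metric is 0
#' for identical fields (up to an additive offset) and approaches 1 when
#' maps differ spatially or in rate; it is symmetric and scale-free.
#'
#' @inheritParams map_correlation
#' @return Value in `[0, 1]`, or `NA` when both maps are constant on the
#'   common support.
#' @export
fuhs_metric <- function(a, b, min_bins = 10) {
  va <- map_values(a); vb <- map_values(b)
  if (length(va) != length(vb)) stop("maps are on different grids")
  ok <- is.finite(va) & is.finite(vb)
  if (sum(ok) < min_bins) return(NA_real_)
  f1 <- va[ok] - mean(va[ok])
  f2 <- vb[ok] - mean(vb[ok])
  den <- sum(abs(f1) + abs(f2))
  if (den == 0) return(NA_real_)
  sum(abs(f1 - f2)) / den
}

#' Session-by-session correlation structure of a population
#'
#' Per-cell Pearson correlations between the whole-maze maps of every
#' session pair, the cell-averaged 5 x 5 matrix, the O1-O2 versus O2-C1
#' contrast (same time separation, with versus without a connectivity
#' change), and the correlation versus session-separation curve.
#'
#' @param maps_by_cell List per cell of 5 session [rate_map()]s (or rate
#'   vectors), in session order O1, O2, C1, C2, O3.
#' @return List: `mean_matrix`, `per_cell` (data.frame `cell`, `s1`, `s2`,
#'   `r`, `separation`), `contrast` (per-cell O1-O2 and O2-C1 values),
#'   `separation` (mean r per separation 0-3).
#' @export
session_correlation_analysis <- function(maps_by_cell) {
  labs <- c("O1", "O2", "C1", "C2", "O3")
  rows <- list()
  for (ci in seq_along(maps_by_cell)) {
    maps <- maps_by_cell[[ci]]
    for (i in 1:4) for (j in (i + 1):5) {
      rows[[length(rows) + 1L]] <- data.frame(
        cell = ci, s1 = labs[i], s2 = labs[j],
        r = map_correlation(maps[[i]], maps[[j]]),
        separation = j - i - 1L)
    }
  }
  per_cell <- do.call(rbind, rows)
  mat <- matrix(NA_real_, 5, 5, dimnames = list(labs, labs))
  diag(mat) <- 1
  agg <- stats::aggregate(r ~ s1 + s2, per_cell, mean, na.rm = TRUE,
                          na.action = NULL)
  for (k in seq_len(nrow(agg))) {
    mat[agg$s1[k], agg$s2[k]] <- agg$r[k]
    mat[agg$s2[k], agg$s1[k]] <- agg$r[k]
  }
  o1o2 <- per_cell$r[per_cell$s1 == "O1" & per_cell$s2 == "O2"]
  o2c1 <- per_cell$r[per_cell$s1 == "O2" & per_cell$s2 == "C1"]
  sep <- stats::aggregate(r ~ separation, per_cell, mean, na.rm = TRUE,
                          na.action = NULL)
  list(mean_matrix = mat, per_cell = per_cell,
       contrast = data.frame(cell = seq_along(maps_by_cell),
                             o1_o2 = o1o2, o2_c1 = o2c1),
       separation = sep)
}

#' Doorway-level correlation analysis
#'
#' Correlations restricted to the 25 cm doorway regions, split into the
#' "closed/control" door sides (locked in C1/C2; in One-Way sequences each
#' door contributes one side to each group) versus "open" sides, for the
#' O1-O2 baseline and the O2-C1 change. Per-door-side correlations are
#' averaged so that every cell contributes exactly one value per group and
#' transition.
#'
#' @param doorway_by_cell List per cell; each element a list per session of
#'   named doorway rate-value lists as produced by
#'   [box_and_doorway_maps()]`$doorway` (keys `"<door>|<side>"`).
#' @param protocol A [session_protocol()].
#' @return data.frame: `cell`, `transition` (`"O1-O2"`/`"O2-C1"`),
#'   `group`, `r` (one row per cell x transition x group).
#' @export
doorway_correlation_analysis <- function(doorway_by_cell, protocol) {
  cc <- locked_door_sides(protocol)
  cc_key <- paste0(cc$door, "|", cc$side)
  transitions <- list("O1-O2" = c(1L, 2L), "O2-C1" = c(2L, 3L))
  rows <- list()
  for (ci in seq_along(doorway_by_cell)) {
    sess <- doorway_by_cell[[ci]]
    keys <- names(sess[[1]])
    for (tn in names(transitions)) {
      ij <- transitions[[tn]]
      rs <- vapply(keys, function(k)
        map_correlation(sess[[ij[1]]][[k]]$rate, sess[[ij[2]]][[k]]$rate),
        numeric(1))
      grp <- ifelse(keys %in% cc_key, "closed_control", "open")
      for (g in c("closed_control", "open")) {
        v <- rs[grp == g]
        rows[[length(rows) + 1L]] <- data.frame(
          cell = ci, transition = tn, group = g,
          r = if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
      }
    }
  }
  do.call(rbind, rows)
}

#' Shuffle-classified individual remapping
#'
#' For each place cell, the map correlation at each of the four
#' consecutive-session transitions (O1-O2, O2-C1, C1-C2, C2-O3) is
#' compared against a null built by correlating the maps of *different*
#' cells recorded in the same sequence across the same transition (1000
#' random pairings per sequence, pooled across sequences with more than 10
#' simultaneous place cells). A cell remaps at a transition when its
#' correlation falls below the shuffle's significance bound, and is
#' stable when it falls above the opposite bound.
#'
#' The significance bound defaults to the shuffle's 5th percentile (a cell
#' must look *less* similar across sessions than random cell pairings
#' rarely do); `bound = "above_95"` instead flags cells below the 95th
#' percentile, the literal wording of some descriptions of the procedure,
#' under which remapping would be the norm rather than the exception.
#'
#' @param sequences List of sequences; each a list per cell of 5 session
#'   maps ([rate_map()]s or rate vectors).
#' @param n Shuffle pairings per sequence and transition.
#' @param seed Optional seed.
#' @param min_cells Minimum simultaneous cells for a sequence to
#'   contribute (strictly more than 10 by default).
#' @param bound `"below_5"` (default) or `"above_95"`.
#' @return List: `profiles` (data.frame `sequence`, `cell`, `r1`..`r4`,
#'   `remap1`..`remap4`, `stable1`..`stable4`, `pattern` 0-15),
#'   `histogram` (counts of the 16 patterns), `thresholds` (per
#'   transition), `shuffles` (list of 4 pooled distributions).
#' @export
classify_individual_remapping <- function(sequences, n = 1000, seed = NULL,
                                          min_cells = 10,
                                          bound = c("below_5", "above_95")) {
  bound <- match.arg(bound)
  if (!is.null(seed)) set.seed(seed)
  qual <- vapply(sequences, function(sq) length(sq) > min_cells, logical(1))
  if (!any(qual)) stop("no sequence with more than ", min_cells,
                       " simultaneously recorded place cells")
  sequences <- sequences[qual]
  shuffles <- vector("list", 4)
  for (tr in 1:4) {
    pool <- numeric(0)
    for (sq in sequences) {
      nc <- length(sq)
      i <- sample.int(nc, n, replace = TRUE)
      j <- sample.int(nc - 1L, n, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)  # distinct-cell pairs
      rs <- vapply(seq_len(n), function(k)
        map_correlation(sq[[i[k]]][[tr]], sq[[j[k]]][[tr + 1L]]), numeric(1))
      pool <- c(pool, rs[!is.na(rs)])
    }
    shuffles[[tr]] <- pool
  }
  lo <- vapply(shuffles, stats::quantile, numeric(1), probs = 0.05,
               names = FALSE)
  hi <- vapply(shuffles, stats::quantile, numeric(1), probs = 0.95,
               names = FALSE)
  remap_thr <- if (bound == "below_5") lo else hi
  rows <- list()
  for (qi in seq_along(sequences)) {
    sq <- sequences[[qi]]
    for (ci in seq_along(sq)) {
      r <- vapply(1:4, function(tr)
        map_correlation(sq[[ci]][[tr]], sq[[ci]][[tr + 1L]]), numeric(1))
      remap <- r < remap_thr
      stable <- r > hi
      pattern <- if (anyNA(remap)) NA_integer_
                 else sum(2L^(3:0) * as.integer(remap))
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = qi, cell = ci,
        r1 = r[1], r2 = r[2], r3 = r[3], r4 = r[4],
        remap1 = remap[1], remap2 = remap[2], remap3 = remap[3],
        remap4 = remap[4],
        stable1 = stable[1], stable2 = stable[2], stable3 = stable[3],
        stable4 = stable[4], pattern = pattern)
    }
  }
  profiles <- do.call(rbind, rows)
  histogram <- tabulate(profiles$pattern + 1L, nbins = 16L)
  names(histogram) <- vapply(0:15, function(p)
    paste(as.integer(intToBits(p))[4:1], collapse = ""), character(1))
  list(profiles = profiles, histogram = histogram,
       thresholds = remap_thr, stable_threshold = hi, shuffles = shuffles)
}

#' Cross-box correlation analysis of one session
#'
#' Per cell, the mean Pearson correlation over all six box pairs
#' (box-specific maps compared bin-by-bin in shared box coordinates,
#' without rotation), split into the four adjacent and two diagonal pairs.
#'
#' @param box_maps_by_cell List per cell of named box-map lists
#'   (`A`,`B`,`C`,`D`; [rate_map()]s or rate vectors) for one session.
#' @return List: `per_pair` (data.frame `cell`, `box1`, `box2`,
#'   `adjacency`, `r`), `per_cell` (mean r per cell), `adjacent_mean`,
#'   `diagonal_mean`.
#' @export
cross_box_analysis <- function(box_maps_by_cell) {
  pairs <- data.frame(
    box1 = c("A", "B", "C", "D", "A", "B"),
    box2 = c("B", "C", "D", "A", "C", "D"),
    adjacency = c(rep("adjacent", 4), rep("diagonal", 2)))
  rows <- list()
  for (ci in seq_along(box_maps_by_cell)) {
    bm <- box_maps_by_cell[[ci]]
    for (k in seq_len(nrow(pairs))) {
      rows[[length(rows) + 1L]] <- data.frame(
        cell = ci, box1 = pairs$box1[k], box2 = pairs$box2[k],
        adjacency = pairs$adjacency[k],
        r = map_correlation(bm[[pairs$box1[k]]], bm[[pairs$box2[k]]]))
    }
  }
  per_pair <- do.call(rbind, rows)
  per_cell <- stats::aggregate(r ~ cell, per_pair, mean, na.rm = TRUE,
                               na.action = NULL)
  list(per_pair = per_pair, per_cell = per_cell,
       adjacent_mean = mean(per_pair$r[per_pair$adjacency == "adjacent"],
                            na.rm = TRUE),
       diagonal_mean = mean(per_pair$r[per_pair$adjacency == "diagonal"],
                            na.rm = TRUE))
}

#' Repetition shuffle for cross-box correlations
#'
#' Builds the cross-box correlation distribution expected if every cell
#' repeated one field template in `k` of the four boxes. For each cell a
#' random compartment is chosen and duplicated into `k - 1` other
#' compartments using that compartment's maps from *different sessions*
#' (the same compartment sampled in different sessions approximates
#' sampling the same field in different compartments); the remaining
#' compartments keep their session-O1 maps. The mean pairwise box
#' correlation is then computed exactly as for the data.
#'
#' @param box_maps_by_cell_session List per cell, then per session (5),
#'   of named box-map lists.
#' @param k Number of compartments sharing the duplicated field (2-4).
#' @param seed Optional seed.
#' @return Numeric vector, one shuffled mean cross-box correlation per
#'   cell.
#' @export
repetition_shuffle <- function(box_maps_by_cell_session, k, seed = NULL) {
  stopifnot(k %in% 2:4)
  if (!is.null(seed)) set.seed(seed)
  boxes <- c("A", "B", "C", "D")
  pairs <- utils::combn(4, 2)
  vapply(box_maps_by_cell_session, function(cell_sessions) {
    n_sess <- length(cell_sessions)
    if (n_sess < 2) stop("repetition shuffle needs at least 2 sessions per cell")
    src <- sample(boxes, 1)
    targets <- sample(setdiff(boxes, src), k - 1)
    donor_sessions <- sample(setdiff(seq_len(n_sess), 1L),
                             k - 1, replace = n_sess - 1 < k - 1)
    maps <- cell_sessions[[1]][boxes]
    for (m in seq_along(targets))
      maps[[targets[m]]] <- cell_sessions[[donor_sessions[m]]][[src]]
    rs <- apply(pairs, 2, function(pr)
      map_correlation(maps[[pr[1]]], maps[[pr[2]]]))
    mean(rs, na.rm = TRUE)
  }, numeric(1))
}

#' Foraging versus goal-directed stability
#'
#' Per session, each cell's foraging map is correlated with its own
#' goal-directed map; the population is judged *stable* across behavioral
#' modes when the median observed correlation exceeds the 95th percentile
#' of a shuffle that pairs the foraging map of one cell with the
#' goal-directed map of a different, same-session cell.
#'
#' @param foraging_by_cell,goal_by_cell Lists per cell of the session's
#'   foraging and goal-directed maps.
#' @param n Shuffle pairings.
#' @param seed Optional seed.
#' @return List: `observed` (per-cell r), `median`, `threshold` (shuffle
#'   95th percentile), `stable` (logical), `shuffle`.
#' @export
foraging_vs_goal_remapping <- function(foraging_by_cell, goal_by_cell,
                                       n = 1000, seed = NULL) {
  stopifnot(length(foraging_by_cell) == length(goal_by_cell))
  if (!is.null(seed)) set.seed(seed)
  nc <- length(foraging_by_cell)
  observed <- vapply(seq_len(nc), function(ci)
    map_correlation(foraging_by_cell[[ci]], goal_by_cell[[ci]]), numeric(1))
  i <- sample.int(nc, n, replace = TRUE)
  j <- sample.int(nc - 1L, n, replace = TRUE)
  j <- ifelse(j >= i, j + 1L, j)
  shuffle <- vapply(seq_len(n), function(k)
    map_correlation(foraging_by_cell[[i[k]]], goal_by_cell[[j[k]]]),
    numeric(1))
  shuffle <- shuffle[!is.na(shuffle)]
  thr <- stats::quantile(shuffle, 0.95, names = FALSE)
  med <- stats::median(observed, na.rm = TRUE)
  list(observed = observed, median = med, threshold = thr,
       stable = med > thr, shuffle = shuffle)
}
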