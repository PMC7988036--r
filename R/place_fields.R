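# connected-component labeling of a logical matrix (4- or 8-connectivity)
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  if (connectivity == 8) {
    off <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    off <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      i <- (p - 1L) %% nx + 1L
      j <- (p - 1L) %/% nx + 1L
      ni <- i + off[, 1]; nj <- j + off[, 2]
      ok <- ni >= 1 & ni <= nx & nj >= 1 & nj <= ny
      q <- (nj[ok] - 1L) * nx + ni[ok]
      q <- q[mask[q] & lab[q] == 0L]
      lab[q] <- cur
      queue <- c(queue, q)
    }
  }
  lab
}

#' Detect place fields in a rate map
#'
#' The map is thresholded at a fraction (default 20%) of its maximum;
#' connected supra-threshold regions (8-connectivity by default) with at
#' least `min_bins` bins and an in-region peak above `min_peak` Hz are
#' accepted as place fields. For each field the area (bin count), the
#' rate-weighted centroid, the convex hull of its bin centers and the mean
#' in-field rate are extracted.
#'
#' @param rm A foraging [rate_map()].
#' @param threshold_frac Fraction of the map maximum used as threshold.
#' @param min_bins Minimum field area in bins.
#' @param min_peak Minimum in-field peak rate (Hz).
#' @param connectivity 8 (default) or 4.
#' @return Object of class `place_field_set`: `fields` data.frame (`id`,
#'   `area`, `cx`, `cy`, `peak`, `mean_rate`, `nearest_door`, `door_dist`),
#'   plus per-field bin index lists and hull polygons, and the grid.
#' @export
detect_fields <- function(rm, threshold_frac = 0.2, min_bins = 9,
                          min_peak = 1, connectivity = 8) {
  stopifnot(inherits(rm, "rate_map"))
  geom_doors <- NULL
  rate <- rm$rate
  rate[rm$empty] <- NA
  mx <- suppressWarnings(max(rate, na.rm = TRUE))
  empty_set <- structure(list(
    fields = data.frame(id = integer(0), area = integer(0), cx = numeric(0),
                        cy = numeric(0), peak = numeric(0),
                        mean_rate = numeric(0)),
    bins = list(), hulls = list(), grid = rm$grid),
    class = "place_field_set")
  if (!is.finite(mx) || mx <= 0) return(empty_set)
  above <- !is.na(rate) & rate >= threshold_frac * mx
  lab <- label_components(above, connectivity)
  ids <- setdiff(unique(as.integer(lab)), 0L)
  g <- rm$grid
  rows <- list(); bins <- list(); hulls <- list()
  for (k in ids) {
    idx <- which(lab == k)
    if (length(idx) < min_bins) next
    if (max(rate[idx]) <= min_peak) next
    i <- (idx - 1L) %% g$nx + 1L
    j <- (idx - 1L) %/% g$nx + 1L
    bx <- g$x0 + (i - 0.5) * g$bin
    by <- g$y0 + (j - 0.5) * g$bin
    w <- rate[idx] / sum(rate[idx])
    hull_i <- grDevices::chull(bx, by)
    rows[[length(rows) + 1L]] <- data.frame(
      id = length(rows) + 1L, area = length(idx),
      cx = sum(w * bx), cy = sum(w * by),
      peak = max(rate[idx]), mean_rate = mean(rate[idx]))
    bins[[length(bins) + 1L]] <- cbind(i = i, j = j)
    hulls[[length(hulls) + 1L]] <- cbind(x = bx[hull_i], y = by[hull_i])
  }
  if (!length(rows)) return(empty_set)
  fields <- do.call(rbind, rows)
  structure(list(fields = fields, bins = bins, hulls = hulls, grid = g),
            class = "place_field_set")
}

#' @export
print.place_field_set <- function(x, ...) {
  cat(sprintf("place_field_set: %d field(s)\n", nrow(x$fields)))
  if (nrow(x$fields)) print(x$fields)
  invisible(x)
}

#' Annotate fields with their nearest door
#' @param pfs A [detect_fields()] result.
#' @param geometry A [maze_geometry()].
#' @return The field table with `nearest_door` and `door_dist` columns.
#' @export
fields_near_doors <- function(pfs, geometry = maze_geometry()) {
  f <- pfs$fields
  if (!nrow(f)) return(cbind(f, nearest_door = character(0),
                             door_dist = numeric(0)))
  d <- geometry$doors
  dist <- outer(seq_len(nrow(f)), seq_len(nrow(d)), Vectorize(function(a, b)
    sqrt((f$cx[a] - d$cx[b])^2 + (f$cy[a] - d$cy[b])^2)))
  f$nearest_door <- d$door[max.col(-dist)]
  f$door_dist <- apply(dist, 1, min)
  f
}

#' Bridge index of a field across a door
#'
#' `1 - |a - b| / (a + b)` where `a` and `b` are the field's bin counts on
#' the two sides of the infinite line through the door center along the
#' door axis: 0 when the field lies entirely on one side, 1 when its area
#' splits evenly. Bins exactly on the line (possible only for grids whose
#' bin centers can hit it) count half to each side. The field's convex
#' hull is also projected onto the axis perpendicular to the door, giving
#' the extent limits and the centroid along that axis.
#'
#' @param pfs A [detect_fields()] result.
#' @param field_id Field id within `pfs`.
#' @param door Door id.
#' @param geometry A [maze_geometry()].
#' @return List: `bridge_index`, `a`, `b`, `extent` (projection min/max),
#'   `centroid_perp` (weighted centroid along the perpendicular axis).
#' @export
bridge_index <- function(pfs, field_id, door, geometry = maze_geometry()) {
  d <- geometry$doors[geometry$doors$door == door, ]
  if (nrow(d) != 1) stop("unknown door: ", door)
  bins <- pfs$bins[[field_id]]
  g <- pfs$grid
  bx <- g$x0 + (bins[, "i"] - 0.5) * g$bin
  by <- g$y0 + (bins[, "j"] - 0.5) * g$bin
  v <- if (d$axis == "vertical") bx - d$cx else by - d$cy
  a <- sum(v < 0) + sum(v == 0) / 2
  b <- sum(v > 0) + sum(v == 0) / 2
  if (a + b == 0) stop("field has no bins; bridge index undefined")
  hull <- pfs$hulls[[field_id]]
  proj <- if (d$axis == "vertical") hull[, "x"] else hull[, "y"]
  f <- pfs$fields[pfs$fields$id == field_id, ]
  centroid_perp <- if (d$axis == "vertical") f$cx else f$cy
  list(bridge_index = 1 - abs(a - b) / (a + b), a = a, b = b,
       extent = range(proj), centroid_perp = centroid_perp)
}

# nearest test-area point among doors / dummy doors / box centers;
# points farther than `radius` from all test points get NA
nearest_test_area <- function(x, y, geometry, radius = 25) {
  pts <- rbind(
    data.frame(kind = "door", px = geometry$doors$cx, py = geometry$doors$cy),
    data.frame(kind = "dummy", px = geometry$dummy_doors$cx,
               py = geometry$dummy_doors$cy),
    data.frame(kind = "center", px = geometry$centers[, 1],
               py = geometry$centers[, 2]))
  d2 <- outer(x, pts$px, "-")^2 + outer(y, pts$py, "-")^2
  nearest <- max.col(-d2)
  kind <- pts$kind[nearest]
  kind[sqrt(d2[cbind(seq_along(x), nearest)]) > radius] <- NA
  kind
}

#' Door-overrepresentation tests for place fields
#'
#' Two chi-square analyses per session, with Holm-Bonferroni correction
#' across sessions. (i) *Locked vs open doors*: the number of fields with
#' centroid within 25 cm of the locked door (One-Way: on the locked side
#' of each door) against the average around open doors (open sides),
#' tested against a 50/50 split. (ii) *Doors vs dummy doors vs box
#' centers*: observed field counts per test area against expectations
#' proportional to the surviving dwell surface — bins of the median dwell
#' map (across sessions) above 0.01 s, each assigned to its nearest test
#' point within 25 cm.
#'
#' @param field_tables Named list (session -> data.frame with `cx`, `cy`)
#'   of field centroids per session.
#' @param dwell_maps Named list of raw dwell matrices on a common
#'   whole-maze grid (one per session).
#' @param grid The [map_grid()] of the dwell maps.
#' @param protocol A [session_protocol()].
#' @param radius Test-area radius in cm.
#' @param dwell_min Median-dwell threshold (s) for a bin to count as
#'   surveyed surface.
#' @return List: `locked_vs_open` (per-session data.frame with counts and
#'   corrected p), `areas` (per-session observed/expected per category and
#'   corrected p).
#' @export
overrepresentation_tests <- function(field_tables, dwell_maps, grid, protocol,
                                     radius = 25, dwell_min = 0.01) {
  if (!sum(vapply(field_tables, nrow, integer(1))))
    stop("no fields to test")
  geom <- protocol$geometry
  d <- geom$doors
  cc <- locked_door_sides(protocol)
  # (i) locked vs open
  lv <- lapply(names(field_tables), function(s) {
    f <- field_tables[[s]]
    if (!nrow(f)) return(NULL)
    per_side <- function(door, side) {
      pred <- door_region(geom, door,
                          radius, side = if (protocol$sequence == "one_way")
                            side else NULL)
      sum(pred(f$cx, f$cy))
    }
    if (protocol$sequence == "closed_door") {
      n_locked <- per_side(protocol$locked_door, NA)
      open_doors <- setdiff(d$door, protocol$locked_door)
      n_open <- mean(vapply(open_doors, per_side, numeric(1), side = NA))
    } else {
      locked_n <- vapply(seq_len(nrow(cc)), function(i)
        per_side(cc$door[i], cc$side[i]), numeric(1))
      all_sides <- rbind(data.frame(door = d$door, side = d$box1),
                         data.frame(door = d$door, side = d$box2))
      open_sides <- all_sides[!paste(all_sides$door, all_sides$side) %in%
                                paste(cc$door, cc$side), ]
      open_n <- vapply(seq_len(nrow(open_sides)), function(i)
        per_side(open_sides$door[i], open_sides$side[i]), numeric(1))
      n_locked <- mean(locked_n)
      n_open <- mean(open_n)
    }
    tot <- n_locked + n_open
    p <- if (tot > 0)
      chi2_expected_proportions(c(n_locked, n_open),
                                c(tot / 2, tot / 2))$p_value else NA
    data.frame(session = s, n_locked = n_locked, n_open = n_open,
               p_raw = p)
  })
  lv <- do.call(rbind, lv)
  ok <- !is.na(lv$p_raw)
  lv$p_corrected <- NA_real_
  lv$p_corrected[ok] <- holm_bonferroni(lv$p_raw[ok])
  # (ii) doors vs dummies vs centers against dwell surface
  med_dwell <- apply(simplify2array(dwell_maps), c(1, 2), stats::median)
  surv <- med_dwell >= dwell_min & grid$mask
  idx <- which(surv)
  bx <- grid$x0 + ((idx - 1L) %% grid$nx) * grid$bin + grid$bin / 2
  by <- grid$y0 + ((idx - 1L) %/% grid$nx) * grid$bin + grid$bin / 2
  surf_kind <- nearest_test_area(bx, by, geom, radius)
  surf <- table(factor(surf_kind, levels = c("door", "dummy", "center")))
  areas <- lapply(names(field_tables), function(s) {
    f <- field_tables[[s]]
    if (!nrow(f)) return(NULL)
    kind <- nearest_test_area(f$cx, f$cy, geom, radius)
    obs <- table(factor(kind, levels = c("door", "dummy", "center")))
    N <- sum(obs)
    if (N == 0 || sum(surf) == 0) return(NULL)
    expd <- as.numeric(surf) / sum(surf) * N
    p <- if (all(expd > 0))
      chi2_expected_proportions(as.numeric(obs), expd)$p_value else NA
    data.frame(session = s, category = names(surf),
               observed = as.numeric(obs), expected = expd, p_raw = p)
  })
  areas <- do.call(rbind, areas)
  if (!is.null(areas)) {
    per_sess <- !duplicated(areas$session)
    corr <- holm_bonferroni(areas$p_raw[per_sess])
    areas$p_corrected <- corr[match(areas$session, areas$session[per_sess])]
  }
  list(locked_vs_open = lv, areas = areas)
}

#' Track fields across sessions
#'
#' Pools field centroids from all sessions and clusters them with k-means,
#' choosing the number of clusters by gap-statistic evaluation over
#' 1..N (N = the largest number of fields seen in one session). Reports
#' per-cluster centroid shifts between consecutive sessions (shifts above
#' 60 cm — a box side — are excluded as identity errors) and the mean and
#' SD of each door's distance to its closest fields (16 per door, or 8 per
#' side for One-Way sequences), grouped into changed versus unchanged
#' doors.
#'
#' @param field_tables Named list (session -> data.frame `cx`, `cy`).
#' @param protocol A [session_protocol()].
#' @param max_shift Exclusion threshold for between-session shifts (cm).
#' @param n_closest Fields per door used in the distance statistics
#'   (16 for Closed-Door, 8 per side for One-Way).
#' @param gap_B Reference draws for the gap statistic.
#' @param seed Optional seed (k-means restarts and gap references).
#' @return List: `k` (chosen clusters), `assignments`, `shifts`
#'   (data.frame `cluster`, `from`, `to`, `shift_cm`), `door_distance`
#'   (data.frame `door`, `side`, `group`, `mean_cm`, `sd_cm`).
#' @export
track_fields <- function(field_tables, protocol, max_shift = 60,
                         n_closest = NULL, gap_B = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cent <- do.call(rbind, lapply(names(field_tables), function(s) {
    f <- field_tables[[s]]
    if (!nrow(f)) return(NULL)
    data.frame(session = s, cx = f$cx, cy = f$cy)
  }))
  if (is.null(cent) || nrow(cent) < 2) stop("need at least 2 fields to track")
  N <- max(vapply(field_tables, nrow, integer(1)))
  X <- as.matrix(cent[, c("cx", "cy")])
  if (N >= 2 && nrow(unique(X)) > N) {
    gap <- cluster::clusGap(X, FUNcluster = function(x, k)
      stats::kmeans(x, k, nstart = 50, iter.max = 50),
      K.max = max(2, N), B = gap_B, verbose = FALSE)
    k <- cluster::maxSE(gap$Tab[, "gap"], gap$Tab[, "SE.sim"],
                        method = "firstSEmax")
  } else {
    k <- max(1, min(N, nrow(unique(X))))
  }
  cl <- if (k > 1) stats::kmeans(X, k, nstart = 50, iter.max = 50)$cluster
        else rep(1L, nrow(X))
  cent$cluster <- cl
  sess_order <- names(field_tables)
  shifts <- list()
  for (g in sort(unique(cl))) {
    sub <- cent[cent$cluster == g, ]
    for (i in seq_len(length(sess_order) - 1)) {
      a <- sub[sub$session == sess_order[i], ]
      b <- sub[sub$session == sess_order[i + 1], ]
      if (nrow(a) && nrow(b)) {
        sh <- sqrt((mean(a$cx) - mean(b$cx))^2 + (mean(a$cy) - mean(b$cy))^2)
        shifts[[length(shifts) + 1L]] <- data.frame(
          cluster = g, from = sess_order[i], to = sess_order[i + 1],
          shift_cm = sh, excluded = sh > max_shift)
      }
    }
  }
  shifts <- if (length(shifts)) do.call(rbind, shifts) else NULL
  # door-distance statistics
  geom <- protocol$geometry
  d <- geom$doors
  cc <- locked_door_sides(protocol)
  one_way <- protocol$sequence == "one_way"
  if (is.null(n_closest)) n_closest <- if (one_way) 8 else 16
  dd <- list()
  side_list <- if (one_way) {
    rbind(data.frame(door = d$door, side = d$box1),
          data.frame(door = d$door, side = d$box2))
  } else data.frame(door = d$door, side = NA)
  for (i in seq_len(nrow(side_list))) {
    door <- side_list$door[i]; side <- side_list$side[i]
    k_d <- match(door, d$door)
    dist <- sqrt((cent$cx - d$cx[k_d])^2 + (cent$cy - d$cy[k_d])^2)
    if (one_way) {
      cen_b <- geom$centers[side, ]
      v <- if (d$axis[k_d] == "vertical") (cent$cx - d$cx[k_d]) *
             sign(cen_b[[1]] - d$cx[k_d])
           else (cent$cy - d$cy[k_d]) * sign(cen_b[[2]] - d$cy[k_d])
      dist <- dist[v >= 0]
    }
    dist <- sort(dist)[seq_len(min(n_closest, length(dist)))]
    changed <- if (one_way) paste(door, side) %in% paste(cc$door, cc$side)
               else door == protocol$locked_door
    dd[[i]] <- data.frame(door = door, side = side,
                          group = if (changed) "changed" else "unchanged",
                          mean_cm = mean(dist), sd_cm = stats::sd(dist),
                          n = length(dist))
  }
  list(k = k, assignments = cent, shifts = shifts,
       door_distance = do.call(rbind, dd))
}
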