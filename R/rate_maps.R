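#' Map grid over the maze footprint
#'
#' Square-bin grid anchored to the maze geometry (not to the data extent),
#' so maps from different sessions are directly comparable bin-by-bin.
#' Element `[i, j]` of a map covers
#' `x in [x0 + (i-1)*bin, x0 + i*bin)`, `y in [y0 + (j-1)*bin, y0 + j*bin)`.
#'
#' @param geometry A [maze_geometry()].
#' @param bin Bin side in cm (default 2).
#' @param box Optional box label: grid over that box's minimum enclosing
#'   rectangle instead of the whole maze.
#' @return List of class `map_grid`: `bin`, `x0`, `y0`, `nx`, `ny`, and
#'   `mask`, a logical `nx x ny` matrix marking bins whose centers lie in
#'   an accessible region (box or door unit).
#' @export
map_grid <- function(geometry = maze_geometry(), bin = 2, box = NULL) {
  if (is.null(box)) {
    x0 <- 0; y0 <- 0
    nx <- ceiling(geometry$extent / bin); ny <- nx
  } else {
    o <- geometry$origins[box, ]
    x0 <- o[[1]]; y0 <- o[[2]]
    nx <- ceiling(geometry$box_side / bin); ny <- nx
  }
  cx <- x0 + (seq_len(nx) - 0.5) * bin
  cy <- y0 + (seq_len(ny) - 0.5) * bin
  pts <- expand.grid(x = cx, y = cy)
  if (is.null(box)) {
    reg <- assign_region(pts$x, pts$y, geometry, outside = "na")
    mask <- matrix(!is.na(reg$label), nx, ny)
  } else {
    mask <- matrix(TRUE, nx, ny)
  }
  structure(list(bin = bin, x0 = x0, y0 = y0, nx = nx, ny = ny,
                 mask = mask, box = box),
            class = "map_grid")
}

gauss_kernel_1d <- function(sigma = 2.5, size = 9) {
  half <- (size - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  g / sum(g)
}

band_matrix <- function(n, g) {
  half <- (length(g) - 1) / 2
  B <- matrix(0, n, n)
  for (k in -half:half) {
    idx <- seq_len(n)
    j <- idx + k
    ok <- j >= 1 & j <= n
    B[cbind(idx[ok], j[ok])] <- g[k + half + 1]
  }
  B
}

#' Mask-renormalized Gaussian smoothing of a map
#'
#' Separable 2-D Gaussian filter in which bins outside `mask` contribute
#' nothing and the kernel is renormalized over the in-mask support, so rates
#' are not dragged down at walls or at the edge of the visited area.
#'
#' @param mat Numeric matrix; values outside `mask` are ignored.
#' @param mask Logical matrix of valid bins.
#' @param sigma Kernel standard deviation in bins.
#' @param size Kernel support in bins (size x size).
#' @return Smoothed matrix; `NA` outside the mask.
#' @export
smooth_map <- function(mat, mask, sigma = 2.5, size = 9) {
  stopifnot(all(dim(mat) == dim(mask)))
  g <- gauss_kernel_1d(sigma, size)
  Bx <- band_matrix(nrow(mat), g)
  By <- band_matrix(ncol(mat), g)
  M <- mask * 1
  X <- mat
  X[!mask] <- 0
  num <- Bx %*% X %*% By
  den <- Bx %*% M %*% By
  out <- num / den
  out[!mask | den == 0] <- NA
  out
}

#' Occupancy, spike and firing-rate maps
#'
#' Bivariate histograms of position (dwell time) and spike counts on a
#' geometry-anchored grid, after removing samples slower than the speed
#' threshold and optionally restricting to one behavioral mode. Spike and
#' dwell maps are smoothed separately (mask-renormalized Gaussian,
#' `sigma = 2.5` bins on a 9 x 9 support) and then divided; bins occupied
#' for less than `dwell_floor` seconds are flagged empty (`NA`).
#'
#' Each spike is attached to the tracking sample covering its time, so the
#' unsmoothed spike-map total equals the number of spikes surviving the
#' filters.
#'
#' @param trajectory data.frame with columns `t`, `x`, `y` (uniform 50 Hz
#'   tracking).
#' @param spikes Numeric vector of spike times (s), sorted.
#' @param grid A [map_grid()].
#' @param mode Behavior filter: `"all"`, `"foraging"` or `"goal_directed"`;
#'   requires `mode_labels` unless `"all"`.
#' @param mode_labels Optional character vector, one label per tracking
#'   sample (from [segment_behavior()]).
#' @param speed_threshold Minimum running speed in cm/s (samples below are
#'   removed; default 5).
#' @param dwell_floor Seconds below which a bin counts as unvisited.
#' @param sigma,kernel_size Smoothing parameters in bins.
#' @param smooth Set `FALSE` to skip smoothing (raw maps only).
#' @param keep_samples Optional precomputed logical filter (one per
#'   tracking sample) replacing the speed/mode filtering — useful when
#'   many cells share one trajectory.
#' @return Object of class `rate_map`: matrices `rate`, `dwell`, `spikes`
#'   (raw), `dwell_s`, `spikes_s` (smoothed), the `grid`, an `empty` mask,
#'   and counts/parameters.
#' @export
rate_map <- function(trajectory, spikes, grid,
                     mode = c("all", "foraging", "goal_directed"),
                     mode_labels = NULL, speed_threshold = 5,
                     dwell_floor = 0.05, sigma = 2.5, kernel_size = 9,
                     smooth = TRUE, keep_samples = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "map_grid"),
            all(c("t", "x", "y") %in% names(trajectory)))
  n <- nrow(trajectory)
  dt <- c(diff(trajectory$t), stats::median(diff(trajectory$t)))
  if (is.null(keep_samples)) {
    keep <- rep(TRUE, n)
    if (speed_threshold > 0)
      keep <- keep & compute_speed(trajectory) >= speed_threshold
    if (mode != "all") {
      if (is.null(mode_labels))
        stop("mode_labels required for a behavior-filtered map")
      stopifnot(length(mode_labels) == n)
      keep <- keep & mode_labels == mode
    }
  } else {
    stopifnot(length(keep_samples) == n)
    keep <- keep_samples
  }
  ix <- floor((trajectory$x - grid$x0) / grid$bin) + 1L
  iy <- floor((trajectory$y - grid$y0) / grid$bin) + 1L
  inb <- ix >= 1 & ix <= grid$nx & iy >= 1 & iy <= grid$ny
  keep_s <- keep & inb
  flat <- (iy - 1L) * grid$nx + ix
  nb <- grid$nx * grid$ny
  dwell <- matrix(0, grid$nx, grid$ny)
  if (any(keep_s)) {
    if (diff(range(dt)) < 1e-9) {
      dwell[] <- tabulate(flat[keep_s], nbins = nb) * dt[1]
    } else {
      tab <- rowsum(dt[keep_s], flat[keep_s])
      dwell[as.integer(rownames(tab))] <- tab
    }
  }
  spk <- matrix(0, grid$nx, grid$ny)
  n_spk <- 0L
  if (length(spikes)) {
    si <- findInterval(spikes, trajectory$t)
    si[si == 0] <- 1L
    ok <- keep_s[si]
    n_spk <- sum(ok)
    if (n_spk) spk[] <- tabulate(flat[si[ok]], nbins = nb)
  }
  if (sum(dwell) == 0)
    warning("no samples survive the filters; map is empty")
  if (smooth) {
    dwell_s <- smooth_map(dwell, grid$mask, sigma, kernel_size)
    spikes_s <- smooth_map(spk, grid$mask, sigma, kernel_size)
  } else {
    dwell_s <- dwell; spikes_s <- spk
    dwell_s[!grid$mask] <- NA; spikes_s[!grid$mask] <- NA
  }
  empty <- dwell < dwell_floor | !grid$mask
  rate <- spikes_s / dwell_s
  rate[empty | !is.finite(rate)] <- NA
  structure(list(rate = rate, dwell = dwell, spikes = spk,
                 dwell_s = dwell_s, spikes_s = spikes_s,
                 empty = empty, grid = grid, n_spikes = n_spk,
                 mode = mode, speed_threshold = speed_threshold,
                 dwell_floor = dwell_floor,
                 sigma = sigma, kernel_size = kernel_size),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("rate_map (%s): %d x %d bins of %g cm, %d spikes, peak %.2f Hz\n",
              x$mode, x$grid$nx, x$grid$ny, x$grid$bin, x$n_spikes,
              peak_rate(x)))
  invisible(x)
}

#' @export
plot.rate_map <- function(x, main = NULL, ...) {
  z <- x$rate
  graphics::image(seq_len(x$grid$nx) * x$grid$bin + x$grid$x0 - x$grid$bin / 2,
                  seq_len(x$grid$ny) * x$grid$bin + x$grid$y0 - x$grid$bin / 2,
                  z, asp = 1, xlab = "x (cm)", ylab = "y (cm)",
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = main %||% sprintf("peak %.1f Hz", peak_rate(x)), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Peak firing rate of a map (max over visited bins)
#' @param rm A [rate_map()].
#' @return Peak rate in Hz (0 for an all-empty map).
#' @export
peak_rate <- function(rm) {
  v <- rm$rate[!rm$empty]
  v <- v[is.finite(v)]
  if (!length(v)) 0 else max(v)
}

#' Per-box and per-doorway rate maps
#'
#' Maps for each box are built on that box's own grid and smoothed
#' separately, so smoothing never mixes data across the door gaps. The
#' 25 cm doorway sub-maps used by the doorway correlation analyses are
#' extracted from these box maps, one per door side (door x adjacent box).
#'
#' @inheritParams rate_map
#' @param geometry A [maze_geometry()].
#' @param doorway_radius Radius of the doorway regions in cm.
#' @return List with `box_maps` (named list of [rate_map()]s) and
#'   `doorway` — a named list keyed `"<door>|<side>"`, each holding the
#'   rate values of the box-map bins within the doorway region plus the
#'   logical selection used.
#' @export
box_and_doorway_maps <- function(trajectory, spikes, geometry = maze_geometry(),
                                 mode = "all", mode_labels = NULL,
                                 speed_threshold = 5, doorway_radius = 25,
                                 ...) {
  box_maps <- list()
  for (b in geometry$boxes) {
    g <- map_grid(geometry, box = b)
    box_maps[[b]] <- rate_map(trajectory, spikes, g, mode = mode,
                              mode_labels = mode_labels,
                              speed_threshold = speed_threshold, ...)
  }
  doorway <- list()
  d <- geometry$doors
  for (i in seq_len(nrow(d))) {
    for (side in c(d$box1[i], d$box2[i])) {
      rm_b <- box_maps[[side]]
      sel <- doorway_bin_mask(rm_b$grid, geometry, d$door[i], doorway_radius)
      doorway[[paste0(d$door[i], "|", side)]] <-
        list(door = d$door[i], side = side,
             rate = rm_b$rate[sel], sel = sel)
    }
  }
  list(box_maps = box_maps, doorway = doorway)
}

#' Logical bin mask of a doorway region on a grid
#' @param grid A [map_grid()].
#' @param geometry A [maze_geometry()].
#' @param door Door id.
#' @param radius Radius in cm.
#' @param side Optional box label for a half-disk (see [door_region()]).
#' @return Logical matrix with the grid's dimensions.
#' @export
doorway_bin_mask <- function(grid, geometry, door, radius = 25, side = NULL) {
  pred <- door_region(geometry, door, radius, side)
  cx <- grid$x0 + (seq_len(grid$nx) - 0.5) * grid$bin
  cy <- grid$y0 + (seq_len(grid$ny) - 0.5) * grid$bin
  outer(cx, cy, function(x, y) pred(x, y)) & grid$mask
}

#' Skaggs spatial information rate (bits/s)
#'
#' `SI = sum_i p_i * lambda_i * log2(lambda_i / lambda)` over visited bins,
#' with `p_i` the occupancy probability, `lambda_i` the bin firing rate and
#' `lambda` the occupancy-weighted mean rate. Bins with zero rate contribute
#' nothing. Occupancy is taken from the smoothed dwell map, matching the
#' smoothed rates.
#'
#' @param rm A [rate_map()], or a numeric rate vector if `dwell` is given.
#' @param dwell Optional dwell (occupancy) vector matching `rm`.
#' @return Spatial information in bits/s; 0 (with attribute `silent`) when
#'   the overall mean rate is 0.
#' @export
spatial_information <- function(rm, dwell = NULL) {
  if (inherits(rm, "rate_map")) {
    ok <- !rm$empty & is.finite(rm$rate) & is.finite(rm$dwell_s)
    lambda <- rm$rate[ok]
    occ <- rm$dwell_s[ok]
  } else {
    stopifnot(!is.null(dwell), length(rm) == length(dwell))
    ok <- is.finite(rm) & is.finite(dwell) & dwell > 0
    lambda <- rm[ok]; occ <- dwell[ok]
  }
  if (!length(occ) || sum(occ) == 0) stop("no visited bins")
  p <- occ / sum(occ)
  lbar <- sum(p * lambda)
  if (lbar == 0) return(structure(0, silent = TRUE))
  pos <- lambda > 0
  sum(p[pos] * lambda[pos] * log2(lambda[pos] / lbar))
}

#' Spike-shift shuffle significance of spatial information
#'
#' The spike train is circularly time-shifted by draws uniform on
#' `[20 s, duration - 20 s]`, which preserves spike count and inter-spike
#' structure while decoupling spikes from position; the rate map and its
#' spatial information are recomputed for each shift. A cell is significant
#' when the observed information exceeds the chosen percentile of the
#' shuffle distribution.
#'
#' @inheritParams rate_map
#' @param duration Session duration in s (> 40).
#' @param n Number of shuffles (default 100).
#' @param seed Optional integer seed.
#' @param percentile Significance percentile (default 95).
#' @return List of class `spatial_info_result`: `observed`, `shuffles`,
#'   `threshold`, `significant`.
#' @export
spike_shift_shuffle <- function(trajectory, spikes, grid, duration,
                                n = 100, seed = NULL, percentile = 95,
                                mode = "all", mode_labels = NULL,
                                speed_threshold = 5, ...) {
  if (duration <= 40) stop("session must be longer than 40 s for 20 s shifts")
  if (!is.null(seed)) set.seed(seed)
  observed <- spatial_information(
    rate_map(trajectory, spikes, grid, mode = mode, mode_labels = mode_labels,
             speed_threshold = speed_threshold, ...))
  shifts <- stats::runif(n, 20, duration - 20)
  shuffles <- vapply(shifts, function(s) {
    sh <- sort((spikes + s) %% duration)
    spatial_information(
      rate_map(trajectory, sh, grid, mode = mode, mode_labels = mode_labels,
               speed_threshold = speed_threshold, ...))
  }, numeric(1))
  thr <- stats::quantile(shuffles, percentile / 100, names = FALSE)
  structure(list(observed = observed, shuffles = shuffles, threshold = thr,
                 significant = observed > thr, n = n),
            class = "spatial_info_result")
}

#' Putative place-cell classification
#'
#' A unit is a putative place cell if its mean rate exceeds 0.1 Hz in at
#' least two sessions and, in its highest-rate session: (1) mean rate in
#' (0.1, 5) Hz, (2) spatial information > 0.5 bits/s, (3) information above
#' the spike-shift shuffle bound, and (4) waveform width (peak to trough)
#' > 300 microseconds.
#'
#' @param session_rates Mean firing rate (Hz) per session.
#' @param si Spatial information (bits/s) per session.
#' @param si_significant Logical per session: information above the shuffle
#'   bound.
#' @param width_us Waveform width in microseconds (highest-rate session).
#' @param rate_min,rate_max,si_min,width_min,min_active_sessions Thresholds.
#' @return List: `place_cell` (logical), `best_session` (index),
#'   `reasons` (character, failed criteria).
#' @export
classify_place_cell <- function(session_rates, si, si_significant, width_us,
                                rate_min = 0.1, rate_max = 5, si_min = 0.5,
                                width_min = 300, min_active_sessions = 2) {
  stopifnot(length(si) == length(session_rates),
            length(si_significant) == length(session_rates))
  best <- which.max(session_rates)
  reasons <- character(0)
  if (sum(session_rates > rate_min, na.rm = TRUE) < min_active_sessions)
    reasons <- c(reasons, "active_sessions")
  if (!(session_rates[best] > rate_min)) reasons <- c(reasons, "rate_floor")
  if (!(session_rates[best] < rate_max)) reasons <- c(reasons, "rate_ceiling")
  if (!(si[best] > si_min)) reasons <- c(reasons, "spatial_information")
  if (!isTRUE(si_significant[best])) reasons <- c(reasons, "shuffle")
  if (!(width_us > width_min)) reasons <- c(reasons, "waveform_width")
  list(place_cell = length(reasons) == 0, best_session = best,
       reasons = reasons)
}
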