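# Small independent oracles used across tests.

# Enumerate all directed paths of length <= max_len over the open door
# edges of a connectivity state; return the minimum hop count origin->goal.
brute_force_hops <- function(state, origin, goal, max_len = 4) {
  d <- state$geometry$doors
  edges <- rbind(
    data.frame(from = d$box1, to = d$box2, open = !state$locks[, "fwd"]),
    data.frame(from = d$box2, to = d$box1, open = !state$locks[, "rev"])
  )
  edges <- edges[edges$open, c("from", "to")]
  if (origin == goal) return(0L)
  best <- Inf
  walk <- function(node, depth) {
    if (depth > max_len || depth >= best) return()
    nxt <- edges$to[edges$from == node]
    for (v in nxt) {
      if (v == goal) best <<- min(best, depth + 1L)
      else walk(v, depth + 1L)
    }
  }
  walk(origin, 0L)
  best
}

# Direct evaluation of the Skaggs information-rate formula from raw
# occupancy and rate vectors (loop form, independent of map machinery).
skaggs_oracle <- function(p, lambda) {
  lbar <- sum(p * lambda)
  if (lbar == 0) return(0)
  s <- 0
  for (i in seq_along(p)) {
    if (lambda[i] > 0) s <- s + p[i] * lambda[i] * log2(lambda[i] / lbar)
  }
  s
}

# Tiny deterministic trajectory: constant-speed sweep through given points.
path_trajectory <- function(pts, speed = 10, rate = 50) {
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  tt <- c(0, cumsum(seg / speed))
  t_out <- seq(0, max(tt), by = 1 / rate)
  data.frame(t = t_out,
             x = stats::approx(tt, pts[, 1], t_out)$y,
             y = stats::approx(tt, pts[, 2], t_out)$y)
}

# Minimal rate_map stand-in for tests that construct maps analytically.
fake_rate_map <- function(rate, grid = NULL, dwell = NULL) {
  if (is.null(grid)) {
    grid <- structure(list(bin = 2, x0 = 0, y0 = 0,
                           nx = nrow(rate), ny = ncol(rate),
                           mask = matrix(TRUE, nrow(rate), ncol(rate)),
                           box = NULL), class = "map_grid")
  }
  empty <- !is.finite(rate)
  if (is.null(dwell)) dwell <- matrix(1, nrow(rate), ncol(rate))
  structure(list(rate = rate, dwell = dwell, spikes = rate,
                 dwell_s = dwell, spikes_s = rate, empty = empty,
                 grid = grid, n_spikes = sum(rate, na.rm = TRUE),
                 mode = "all", speed_threshold = 0, dwell_floor = 0,
                 sigma = 2.5, kernel_size = 9), class = "rate_map")
}

# Gaussian-bump rate matrix on a grid, in cm coordinates.
gaussian_map <- function(grid, cx, cy, peak = 5, sigma = 8) {
  bx <- grid$x0 + (seq_len(grid$nx) - 0.5) * grid$bin
  by <- grid$y0 + (seq_len(grid$ny) - 0.5) * grid$bin
  m <- outer(bx, by, function(x, y)
    peak * exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2)))
  m[!grid$mask] <- NA
  m
}

# Small deterministic simulated dataset shared by the slower tests.
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_cells = 18, session_minutes = 8,
                        protocol = session_protocol("closed_door",
                                                    locked_door = "A-B",
                                                    seed = 2))
      cache <<- simulate_sequence(cfg, seed = 42)
    }
    cache
  }
})
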