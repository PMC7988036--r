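#' Simulation configuration
#'
#' Parameters of the synthetic session generator. Defaults emulate the
#' study conditions: 50 Hz tracking, 23 min sessions of 12 bell-cued trials
#' following the goal list, slow circuitous foraging alternating with fast
#' direct goal-directed runs, and place cells firing as inhomogeneous
#' Poisson processes from planted Gaussian fields.
#'
#' @param n_cells Number of simulated cells.
#' @param tracking_rate Position samples per second.
#' @param session_minutes Session duration in minutes.
#' @param forage_speed,goal_speed Speed ranges (cm/s) for the two modes.
#' @param fields_per_cell_probs Probabilities of 1..4 fields for
#'   non-repeating cells.
#' @param field_sigma Gaussian field width (sd, cm).
#' @param peak_rate Range of field peak rates (Hz).
#' @param fraction_repeating Fraction of cells repeating one field template
#'   across `repeat_k` boxes (independent fields fill their remaining
#'   boxes, so repetition rides on top of an otherwise box-unique map).
#' @param repeat_k Number of boxes a repeating cell repeats in (2-4).
#' @param one_field_per_box Force every non-repeating cell to carry exactly
#'   one independent field in each box (used for matched shuffle-reference
#'   populations; default `FALSE`).
#' @param fraction_connectivity_remapping Fraction of cells drawing a new
#'   map at the O2 -> C1 connectivity change.
#' @param drift_centroid_sd Per-session random-walk jitter of field centers
#'   (cm); models slow across-session drift.
#' @param drift_rate_sd Per-session multiplicative (log-scale) rate noise.
#' @param push_avoidance_learning Probability that one push on a locked
#'   door side teaches the agent to avoid that side.
#' @param spontaneous_push_rate Exploratory door pushes per minute of
#'   foraging.
#' @param protocol A [session_protocol()].
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_cells = 50, tracking_rate = 50, session_minutes = 23,
                       forage_speed = c(6, 16), goal_speed = c(30, 60),
                       fields_per_cell_probs = c(0.30, 0.35, 0.20, 0.15),
                       field_sigma = 8, peak_rate = c(3, 10),
                       fraction_repeating = 0.1, repeat_k = 2,
                       one_field_per_box = FALSE,
                       fraction_connectivity_remapping = 0,
                       drift_centroid_sd = 1, drift_rate_sd = 0.1,
                       push_avoidance_learning = 0.6,
                       spontaneous_push_rate = 0.8,
                       protocol = session_protocol("closed_door", seed = 1)) {
  stopifnot(session_minutes > 0, n_cells >= 1,
            fraction_repeating >= 0, fraction_repeating <= 1,
            fraction_connectivity_remapping >= 0,
            fraction_connectivity_remapping <= 1,
            repeat_k %in% 2:4, all(peak_rate >= 0),
            push_avoidance_learning >= 0, push_avoidance_learning <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# box label of arbitrary points; door-gap points go to the nearest box
point_box <- function(x, y, geometry) {
  assign_region(x, y, geometry, outside = "na")$box
}

#' Planted ground-truth cells
#'
#' Draws per-cell true rate functions (sums of planar Gaussians confined to
#' their box) for all five sessions. A configured fraction of cells repeat
#' one field template across `repeat_k` boxes; a fraction remap to a fresh
#' map at the connectivity change (O2 -> C1); the rest are stable up to the
#' configured random-walk drift.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return List of class `ground_truth`; element `cells` holds one record
#'   per cell with per-session field tables (`box`, `cx`, `cy`, `sigma`,
#'   `peak`), `repeat_k` (0 for non-repeating), `remap_o2_c1` flag,
#'   `remap_flags` (4 transitions) and a synthetic waveform width.
#' @export
make_ground_truth <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geom <- config$protocol$geometry
  margin <- 6
  s <- geom$box_side
  draw_fields <- function(n_fields, box = NULL) {
    if (is.null(box)) box <- sample(geom$boxes, n_fields, replace = TRUE)
    o <- geom$origins[box, , drop = FALSE]
    data.frame(box = box,
               cx = o[, 1] + stats::runif(n_fields, margin, s - margin),
               cy = o[, 2] + stats::runif(n_fields, margin, s - margin),
               sigma = config$field_sigma,
               peak = stats::runif(n_fields, config$peak_rate[1],
                                   config$peak_rate[2]),
               stringsAsFactors = FALSE)
  }
  cells <- lapply(seq_len(config$n_cells), function(ci) {
    repeating <- stats::runif(1) < config$fraction_repeating
    if (repeating) {
      k <- config$repeat_k
      boxes <- sample(geom$boxes, k)
      off <- stats::runif(2, margin, s - margin)
      peak <- stats::runif(1, config$peak_rate[1], config$peak_rate[2])
      base <- data.frame(box = boxes,
                         cx = geom$origins[boxes, 1] + off[1],
                         cy = geom$origins[boxes, 2] + off[2],
                         sigma = config$field_sigma, peak = peak,
                         stringsAsFactors = FALSE)
      rest <- setdiff(geom$boxes, boxes)
      if (length(rest))  # box-unique fields alongside the repeated one
        base <- rbind(base, draw_fields(length(rest), box = rest))
    } else {
      k <- 0L
      if (config$one_field_per_box) {
        base <- draw_fields(4L, box = geom$boxes)
      } else {
        nf <- sample(seq_along(config$fields_per_cell_probs), 1,
                     prob = config$fields_per_cell_probs)
        base <- draw_fields(nf)
      }
    }
    remap <- stats::runif(1) < config$fraction_connectivity_remapping
    remap_fields <- if (remap) draw_fields(nrow(base)) else NULL
    sessions <- vector("list", 5)
    cur <- base
    for (si in 1:5) {
      if (si == 3 && remap) cur <- remap_fields
      if (si > 1) {
        cur$cx <- cur$cx + stats::rnorm(nrow(cur), 0, config$drift_centroid_sd)
        cur$cy <- cur$cy + stats::rnorm(nrow(cur), 0, config$drift_centroid_sd)
        cur$peak <- cur$peak * exp(stats::rnorm(nrow(cur), 0,
                                                config$drift_rate_sd))
      }
      sessions[[si]] <- cur
    }
    list(cell = ci, repeat_k = k, remap_o2_c1 = remap,
         remap_flags = c(FALSE, remap, FALSE, FALSE),
         width_us = stats::runif(1, 320, 450),
         sessions = sessions)
  })
  structure(list(cells = cells, config = config), class = "ground_truth")
}

#' True firing-rate function of a cell in a session
#'
#' Sum of planar Gaussians; each field contributes only inside its own box
#' (walls bound fields), with door-gap positions attached to the nearest
#' box.
#'
#' @param truth A [make_ground_truth()] result.
#' @param cell Cell index.
#' @param session Session index 1-5.
#' @param geometry The maze geometry.
#' @return Vectorized `function(x, y)` returning rates in Hz.
#' @export
truth_rate_fn <- function(truth, cell, session,
                          geometry = truth$config$protocol$geometry) {
  f <- truth$cells[[cell]]$sessions[[session]]
  function(x, y) {
    pb <- point_box(x, y, geometry)
    r <- numeric(length(x))
    for (i in seq_len(nrow(f))) {
      sel <- !is.na(pb) & pb == f$box[i]
      if (any(sel))
        r[sel] <- r[sel] + f$peak[i] *
          exp(-((x[sel] - f$cx[i])^2 + (y[sel] - f$cy[i])^2) /
                (2 * f$sigma[i]^2))
    }
    r
  }
}

# ---- agent movement primitives --------------------------------------------

# straight leg from `from` toward `to` at roughly `speed`, with small
# lateral jitter; returns a matrix of positions (one row per 20 ms sample)
leg_samples <- function(from, to, speed, dt, jitter = 0.8) {
  d <- sqrt(sum((to - from)^2))
  n <- max(1L, ceiling(d / (speed * dt)))
  frac <- seq_len(n) / n
  x <- from[1] + (to[1] - from[1]) * frac
  y <- from[2] + (to[2] - from[2]) * frac
  if (n > 2) {
    # one smooth lateral bow per leg keeps sample-to-sample speed realistic
    perp <- c(-(to[2] - from[2]), to[1] - from[1]) / max(d, 1e-9)
    amp <- stats::rnorm(1, 0, jitter * 2) * sin(frac * pi)
    x <- x + perp[1] * amp
    y <- y + perp[2] * amp
  }
  cbind(x, y)
}

clamp_box <- function(p, box, geometry, margin = 1.5) {
  o <- geometry$origins[box, ]
  s <- geometry$box_side
  c(min(max(p[1], o[[1]] + margin), o[[1]] + s - margin),
    min(max(p[2], o[[2]] + margin), o[[2]] + s - margin))
}

# entry/exit staging points just inside each box beside a door
door_approach <- function(geometry, door, box, inset = 6) {
  d <- geometry$doors[geometry$doors$door == door, ]
  cen <- geometry$centers[box, ]
  dir <- c(sign(cen[[1]] - d$cx), sign(cen[[2]] - d$cy))
  c(d$cx, d$cy) + dir * (geometry$door_size / 2 + inset)
}

#' Simulate one session of behavior
#'
#' A waypoint agent performs the 12-trial task under a session's lock
#' state: at each bell it runs a near-shortest-path route to the goal box
#' (planning on its *believed* connectivity, so a naive agent pushes locked
#' doors and learns to avoid them with probability
#' `push_avoidance_learning` per failed push), then forages in the goal box
#' with uniformly drawn waypoints until the next trial. Exploratory pushes
#' occur during foraging at a configurable rate, avoiding sides the agent
#' believes locked. Locked doors are never crossed.
#'
#' @param config A [sim_config()].
#' @param state A [connectivity_state()].
#' @param start_box Box the agent starts in.
#' @param belief Logical 4 x 2 matrix of door sides the agent believes
#'   locked (same layout as `state$locks`); defaults to all-open (naive).
#' @param seed Optional seed.
#' @return List: `trajectory` (`t`, `x`, `y`), `events` (`bells`,
#'   `pushes`), `mode_truth` (generator's own mode label per sample),
#'   `duration` (s), `end_box` and the updated `belief`.
#' @export
simulate_session <- function(config, state, start_box = NULL, belief = NULL,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geom <- config$protocol$geometry
  goals <- config$protocol$goal_list
  dt <- 1 / config$tracking_rate
  T_total <- config$session_minutes * 60
  trial_dur <- T_total / length(goals)
  if (is.null(start_box))
    start_box <- sample(setdiff(geom$boxes, goals[1]), 1)
  if (is.null(belief))
    belief <- matrix(FALSE, 4, 2,
                     dimnames = dimnames(state$locks))
  if (start_box == goals[1])
    start_box <- sample(setdiff(geom$boxes, goals[1]), 1)
  believed_state <- function() {
    st <- state
    st$locks <- belief  # the agent plans on what it believes, not the truth
    st
  }
  side_cols <- function(door, from) {
    d <- geom$doors[geom$doors$door == door, ]
    if (d$box1 == from) "fwd" else "rev"
  }
  xs <- numeric(0); ys <- numeric(0); md <- character(0)
  pos <- unname(geom$centers[start_box, ])
  box <- start_box
  n_samp <- 0L
  bells <- data.frame(t = numeric(0), goal = character(0))
  pushes <- data.frame(t = numeric(0), door = character(0),
                       side = character(0), crossed = logical(0))
  add <- function(mat, mode) {
    xs <<- c(xs, mat[, 1]); ys <<- c(ys, mat[, 2])
    md <<- c(md, rep(mode, nrow(mat)))
    n_samp <<- n_samp + nrow(mat)
    pos <<- c(mat[nrow(mat), 1], mat[nrow(mat), 2])
  }
  now <- function() n_samp * dt
  rspeed <- function(rng) stats::runif(1, rng[1], rng[2])
  clamp_rect <- function(seg, b, margin = 1) {
    o <- geom$origins[b, ]
    seg[, 1] <- pmin(pmax(seg[, 1], o[[1]] + margin),
                     o[[1]] + geom$box_side - margin)
    seg[, 2] <- pmin(pmax(seg[, 2], o[[2]] + margin),
                     o[[2]] + geom$box_side - margin)
    seg
  }
  clamp_corridor <- function(seg, door, half = 6) {
    d <- geom$doors[geom$doors$door == door, ]
    if (d$axis == "vertical") {
      seg[, 2] <- pmin(pmax(seg[, 2], d$cy - half), d$cy + half)
    } else {
      seg[, 1] <- pmin(pmax(seg[, 1], d$cx - half), d$cx + half)
    }
    seg
  }
  go_through_door <- function(door) {
    # approach, push, and (if unlocked) cross into the adjacent box
    other <- setdiff(unlist(geom$doors[geom$doors$door == door,
                                       c("box1", "box2")]), box)
    appr <- door_approach(geom, door, box)
    add(clamp_rect(leg_samples(pos, appr, rspeed(config$goal_speed), dt),
                   box), "goal_directed")
    dcen <- unlist(geom$doors[geom$doors$door == door, c("cx", "cy")])
    add(clamp_corridor(leg_samples(pos, dcen, rspeed(config$goal_speed) * 0.6,
                                   dt), door), "goal_directed")
    col <- side_cols(door, box)
    locked <- state$locks[door, col]
    pushes[nrow(pushes) + 1L, ] <<- list(now(), door, box, !locked)
    if (locked) {
      if (stats::runif(1) < config$push_avoidance_learning)
        belief[door, col] <<- TRUE
      add(clamp_corridor(leg_samples(pos, door_approach(geom, door, box),
                                     rspeed(config$goal_speed) * 0.6, dt),
                         door), "goal_directed")
      return(FALSE)
    }
    belief[door, col] <<- FALSE  # a successful cross proves the side open
    exitp <- door_approach(geom, door, other)
    add(clamp_corridor(leg_samples(pos, exitp, rspeed(config$goal_speed) * 0.7,
                                   dt), door), "goal_directed")
    box <<- other
    TRUE
  }
  goto_box <- function(goal) {
    tries <- 0L
    while (box != goal && tries < 12L) {
      tries <- tries + 1L
      sp <- shortest_door_path(believed_state(), box, goal)
      if (!is.finite(sp$hops) || sp$hops == 0) {
        sp <- shortest_door_path(state, box, goal)  # belief dead end
      }
      if (!length(sp$doors)) break
      go_through_door(sp$doors[1])
    }
  }
  forage_until <- function(t_end, current_goal) {
    push_p <- config$spontaneous_push_rate / 60  # per second
    while (now() < t_end) {
      o <- geom$origins[box, ]
      wp <- c(stats::runif(1, o[[1]] + 4, o[[1]] + geom$box_side - 4),
              stats::runif(1, o[[2]] + 4, o[[2]] + geom$box_side - 4))
      sp <- rspeed(config$forage_speed)
      seg <- leg_samples(pos, wp, sp, dt, jitter = 1.5)
      # truncate at t_end
      n_left <- floor((t_end - now()) / dt)
      if (n_left <= 0) break
      if (nrow(seg) > n_left) seg <- seg[seq_len(n_left), , drop = FALSE]
      seg[, 1] <- pmin(pmax(seg[, 1], o[[1]] + 1), o[[1]] + geom$box_side - 1)
      seg[, 2] <- pmin(pmax(seg[, 2], o[[2]] + 1), o[[2]] + geom$box_side - 1)
      add(seg, "foraging")
      leg_time <- nrow(seg) * dt
      if (stats::runif(1) < push_p * leg_time) {
        d <- geom$doors
        cand <- which(d$box1 == box | d$box2 == box)
        w <- vapply(cand, function(i) {
          col <- if (d$box1[i] == box) "fwd" else "rev"
          if (belief[d$door[i], col]) 0.05 else 1
        }, numeric(1))
        i <- cand[sample.int(length(cand), 1, prob = w)]
        dcen <- c(d$cx[i], d$cy[i])
        n_left <- floor((t_end - now()) / dt)
        seg2 <- leg_samples(pos, door_approach(geom, d$door[i], box, 2),
                            rspeed(config$forage_speed), dt)
        o2 <- geom$origins[box, ]
        seg2[, 1] <- pmin(pmax(seg2[, 1], o2[[1]] + 1),
                          o2[[1]] + geom$box_side - 1)
        seg2[, 2] <- pmin(pmax(seg2[, 2], o2[[2]] + 1),
                          o2[[2]] + geom$box_side - 1)
        if (nrow(seg2) > n_left) seg2 <- seg2[seq_len(n_left), , drop = FALSE]
        if (nrow(seg2)) add(seg2, "foraging")
        col <- if (d$box1[i] == box) "fwd" else "rev"
        locked <- state$locks[d$door[i], col]
        pushes[nrow(pushes) + 1L, ] <<- list(now(), d$door[i], box, FALSE)
        if (locked && stats::runif(1) < config$push_avoidance_learning)
          belief[d$door[i], col] <<- TRUE
      }
    }
  }
  # brief settling walk before the first bell
  forage_until(2, NULL)
  for (k in seq_along(goals)) {
    bells[nrow(bells) + 1L, ] <- list(now(), goals[k])
    goto_box(goals[k])
    t_end <- if (k < length(goals)) k * trial_dur else T_total
    forage_until(max(t_end, now()), goals[k])
  }
  n <- length(xs)
  trajectory <- data.frame(t = seq_len(n) * dt - dt, x = xs, y = ys)
  duration <- n * dt
  bells$t <- pmin(bells$t, duration - dt)
  list(trajectory = trajectory,
       events = list(bells = bells, pushes = pushes),
       mode_truth = md, duration = duration,
       end_box = box, belief = belief)
}

#' Inhomogeneous-Poisson spike simulation by thinning
#'
#' Candidate spikes are drawn from a homogeneous Poisson process at the
#' rate ceiling and kept with probability `rate(x(t), y(t)) / ceiling`,
#' with position linearly interpolated between tracking samples.
#'
#' @param trajectory data.frame `t`, `x`, `y`.
#' @param rate_fn Vectorized `function(x, y)` giving the true rate (Hz).
#' @param lambda_max Rate ceiling (Hz); must dominate `rate_fn`.
#' @param seed Optional seed.
#' @return Sorted numeric vector of spike times in s.
#' @export
simulate_spikes <- function(trajectory, rate_fn, lambda_max, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(lambda_max >= 0)
  T_total <- trajectory$t[nrow(trajectory)]
  if (lambda_max == 0 || T_total <= 0) return(numeric(0))
  n_cand <- stats::rpois(1, lambda_max * T_total)
  if (n_cand == 0) return(numeric(0))
  tc <- sort(stats::runif(n_cand, 0, T_total))
  xc <- stats::approx(trajectory$t, trajectory$x, tc, rule = 2)$y
  yc <- stats::approx(trajectory$t, trajectory$y, tc, rule = 2)$y
  lam <- rate_fn(xc, yc)
  if (any(lam > lambda_max + 1e-9))
    stop("rate_fn exceeds lambda_max; thinning would be biased")
  tc[stats::runif(n_cand) < lam / lambda_max]
}

#' Simulate a full five-session recording sequence
#'
#' Ground truth, behavior and spikes for all five sessions of the
#' configured protocol. The agent's door-lock beliefs persist across
#' sessions, so avoidance learned in C1/C2 carries into O3.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the single source of randomness.
#' @return Object of class `fourrooms_dataset`: `config`, `protocol`,
#'   `truth`, `sessions` (per session: trajectory, events, mode_truth,
#'   duration) and `spikes` (per session, a list of per-cell spike-time
#'   vectors).
#' @export
simulate_sequence <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  truth <- make_ground_truth(config)
  geom <- config$protocol$geometry
  belief <- NULL
  start_box <- NULL
  sessions <- list()
  spikes <- list()
  labs <- names(config$protocol$states)
  for (si in seq_along(labs)) {
    st <- config$protocol$states[[si]]
    ses <- simulate_session(config, st, start_box = start_box,
                            belief = belief)
    belief <- ses$belief
    start_box <- ses$end_box
    sessions[[labs[si]]] <- ses[c("trajectory", "events", "mode_truth",
                                  "duration")]
    spikes[[labs[si]]] <- lapply(seq_len(config$n_cells), function(ci) {
      f <- truth$cells[[ci]]$sessions[[si]]
      lam_max <- sum(f$peak) + 0.5
      simulate_spikes(ses$trajectory, truth_rate_fn(truth, ci, si, geom),
                      lam_max)
    })
  }
  structure(list(config = config, protocol = config$protocol, truth = truth,
                 sessions = sessions, spikes = spikes, seed = seed),
            class = "fourrooms_dataset")
}

#' @export
print.fourrooms_dataset <- function(x, ...) {
  cat(sprintf("fourrooms_dataset: %s sequence, %d sessions, %d cells, seed %s\n",
              x$protocol$sequence, length(x$sessions), x$config$n_cells,
              format(x$seed)))
  invisible(x)
}

#' Synthetic biphasic mean waveform
#'
#' Two-parameter template (peak-to-trough width and amplitude) used to
#' exercise the waveform-width quality checks on simulated cells.
#'
#' @param width_us Peak-to-trough time in microseconds.
#' @param amplitude Peak amplitude (arbitrary units).
#' @param n_samples Samples per waveform.
#' @param sample_us Microseconds per sample.
#' @return Numeric vector waveform.
#' @export
synth_waveform <- function(width_us, amplitude = 100, n_samples = 50,
                           sample_us = 1e6 / 48000) {
  t_us <- (seq_len(n_samples) - 1) * sample_us
  t_peak <- 150
  t_trough <- t_peak + width_us
  amplitude * (exp(-(t_us - t_peak)^2 / (2 * 50^2)) -
                 0.7 * exp(-(t_us - t_trough)^2 / (2 * 90^2)))
}
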