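#' Instantaneous running speed
#'
#' Forward-difference speed per tracking sample: distance to the next
#' sample divided by the time elapsed. The last sample copies the previous
#' value so the result has one speed per sample.
#'
#' @param trajectory data.frame with `t`, `x`, `y`.
#' @return Numeric vector of speeds in cm/s.
#' @export
compute_speed <- function(trajectory) {
  stopifnot(nrow(trajectory) >= 2)
  dt <- diff(trajectory$t)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  v <- sqrt(diff(trajectory$x)^2 + diff(trajectory$y)^2) / dt
  c(v, v[length(v)])
}

# Box label per sample with door-gap samples attached to the box the animal
# most recently occupied (leading door samples fall back to nearest box).
sample_boxes <- function(trajectory, geometry) {
  reg <- assign_region(trajectory$x, trajectory$y, geometry)
  box <- reg$box
  if (any(reg$in_door)) {
    lab <- ifelse(reg$in_door, NA, reg$box)
    idx <- cumsum(!is.na(lab))
    filled <- c(NA, lab[!is.na(lab)])[idx + 1L]
    box <- ifelse(is.na(filled), reg$box, filled)
  }
  box
}

#' Door crossings recovered from the trajectory
#'
#' A crossing is a transition of the per-sample box label (door-gap samples
#' attached to the preceding box) between two adjacent boxes.
#'
#' @param trajectory data.frame with `t`, `x`, `y`.
#' @param geometry A [maze_geometry()].
#' @return data.frame `t`, `door`, `from`, `to` (possibly 0 rows).
#' @export
door_crossings <- function(trajectory, geometry = maze_geometry()) {
  box <- sample_boxes(trajectory, geometry)
  ch <- which(box[-1] != box[-length(box)]) + 1L
  if (!length(ch))
    return(data.frame(t = numeric(0), door = character(0),
                      from = character(0), to = character(0)))
  out <- data.frame(t = trajectory$t[ch],
                    from = box[ch - 1L], to = box[ch],
                    stringsAsFactors = FALSE)
  out$door <- mapply(function(u, v) door_between(geometry, u, v),
                     out$from, out$to)
  out <- out[!is.na(out$door), c("t", "door", "from", "to")]
  rownames(out) <- NULL
  out
}

# Path length over non-overlapping 1 s windows anchored at the start of the
# index range: displacement across each window (remainder window included).
windowed_path_length <- function(trajectory, idx, window_s = 1) {
  if (length(idx) < 2) return(0)
  t0 <- trajectory$t[idx[1]]
  w <- floor((trajectory$t[idx] - t0) / window_s)
  bnd <- c(idx[!duplicated(w)], idx[length(idx)])
  sum(sqrt(diff(trajectory$x[bnd])^2 + diff(trajectory$y[bnd])^2))
}

# Fraction of a 10 x 10 grid over one box with > 1 position sample.
box_coverage <- function(trajectory, idx, box, geometry, nbin = 10,
                         min_samples = 2) {
  if (!length(idx)) return(0)
  o <- geometry$origins[box, ]
  w <- geometry$box_side / nbin
  ix <- pmin(pmax(floor((trajectory$x[idx] - o[[1]]) / w), 0), nbin - 1)
  iy <- pmin(pmax(floor((trajectory$y[idx] - o[[2]]) / w), 0), nbin - 1)
  counts <- tabulate(iy * nbin + ix + 1L, nbins = nbin * nbin)
  mean(counts >= min_samples)
}

#' Segment behavior into foraging and goal-directed epochs
#'
#' Visits are maximal runs of the per-sample box label. A visit is
#' *foraging* when its path length exceeds 120 cm (summed over
#' non-overlapping 1 s windows) and it covers more than 20% of the box area
#' (10 x 10 unsmoothed grid, bins with more than one sample). All other
#' samples are *goal-directed*, and additionally any sample within 1 s of a
#' door crossing or from 2 s before to 1 s after a door push is goal-
#' directed regardless of its visit's label.
#'
#' @param trajectory data.frame `t`, `x`, `y`.
#' @param events Event log: list with `pushes` (data.frame `t`, `door`,
#'   `side`, `crossed`); may be NULL when no pushes were recorded.
#' @param geometry A [maze_geometry()].
#' @param path_min Foraging path-length threshold (cm).
#' @param coverage_min Foraging coverage threshold (fraction of box bins).
#' @return List: `visits` data.frame (`box`, `t_start`, `t_end`,
#'   `path_cm`, `coverage`, `mode`) and `mode` — one label
#'   (`"foraging"`/`"goal_directed"`) per tracking sample.
#' @export
segment_behavior <- function(trajectory, events = NULL,
                             geometry = maze_geometry(),
                             path_min = 120, coverage_min = 0.20) {
  box <- sample_boxes(trajectory, geometry)
  r <- rle(box)
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  visits <- data.frame(box = r$values,
                       t_start = trajectory$t[starts],
                       t_end = trajectory$t[ends],
                       path_cm = NA_real_, coverage = NA_real_,
                       stringsAsFactors = FALSE)
  mode <- rep("goal_directed", nrow(trajectory))
  for (i in seq_len(nrow(visits))) {
    idx <- starts[i]:ends[i]
    visits$path_cm[i] <- windowed_path_length(trajectory, idx)
    visits$coverage[i] <- box_coverage(trajectory, idx, visits$box[i], geometry)
    if (visits$path_cm[i] > path_min && visits$coverage[i] > coverage_min)
      mode[idx] <- "foraging"
  }
  visits$mode <- ifelse(visits$path_cm > path_min &
                          visits$coverage > coverage_min,
                        "foraging", "goal_directed")
  # goal-directed overrides around door crossings and pushes
  tt <- trajectory$t
  cross <- door_crossings(trajectory, geometry)
  for (tc in cross$t) mode[tt >= tc - 1 & tt <= tc + 1] <- "goal_directed"
  if (!is.null(events) && !is.null(events$pushes) && nrow(events$pushes))
    for (tp in events$pushes$t)
      mode[tt >= tp - 2 & tt <= tp + 1] <- "goal_directed"
  list(visits = visits, mode = mode)
}

#' Correct manually flagged behavioral events
#'
#' Bell events are never altered, but trials where the animal was already
#' in the rewarded box when the bell rang are rejected. A recorded door
#' push that was impossible given the animal's position (the push side is
#' not the box the animal occupied) is replaced by the first door the
#' animal actually moved through after the bell; trials missing a first
#' push entirely are filled the same way.
#'
#' @param events List with `bells` (data.frame `t`, `goal`) and `pushes`
#'   (data.frame `t`, `door`, `side`, `crossed`).
#' @param trajectory data.frame `t`, `x`, `y`.
#' @param geometry A [maze_geometry()].
#' @return List: cleaned `events` (with `start_box` added to `bells`),
#'   `rejected` (integer trial indices) and `corrections` (character log).
#' @export
clean_event_flags <- function(events, trajectory, geometry = maze_geometry()) {
  bells <- events$bells[order(events$bells$t), , drop = FALSE]
  pushes <- events$pushes
  box <- sample_boxes(trajectory, geometry)
  at_bell <- box[pmax(findInterval(bells$t, trajectory$t), 1L)]
  bells$start_box <- at_bell
  rejected <- which(at_bell == bells$goal)
  crossings <- door_crossings(trajectory, geometry)
  corrections <- character(0)
  if (!is.null(pushes) && nrow(pushes)) {
    at_push <- box[pmax(findInterval(pushes$t, trajectory$t), 1L)]
    # a push is plausible when the animal was beside that door; the side
    # flag itself is not position-checked (the paper corrects doors only)
    adj <- vapply(seq_len(nrow(pushes)), function(i) {
      d <- geometry$doors[geometry$doors$door == pushes$door[i], ]
      nrow(d) == 1 && at_push[i] %in% c(d$box1, d$box2)
    }, logical(1))
    bad <- which(!adj)
    for (i in bad) {
      # replace with the first door crossed after the covering bell
      b <- findInterval(pushes$t[i], bells$t)
      t_from <- if (b >= 1) bells$t[b] else trajectory$t[1]
      nxt <- crossings[crossings$t >= t_from, , drop = FALSE]
      if (nrow(nxt)) {
        corrections <- c(corrections, sprintf(
          "push %d: door %s impossible from box %s; replaced with %s",
          i, pushes$door[i], at_push[i], nxt$door[1]))
        pushes$door[i] <- nxt$door[1]
        pushes$side[i] <- nxt$from[1]
        pushes$t[i] <- nxt$t[1]
        pushes$crossed[i] <- TRUE
      }
    }
  }
  # fill trials with no recorded push using the first door crossed
  trial_end <- c(bells$t[-1], Inf)
  for (k in seq_len(nrow(bells))) {
    if (k %in% rejected) next
    has_push <- !is.null(pushes) && nrow(pushes) &&
      any(pushes$t >= bells$t[k] & pushes$t < trial_end[k])
    if (!has_push) {
      nxt <- crossings[crossings$t >= bells$t[k] &
                         crossings$t < trial_end[k], , drop = FALSE]
      if (nrow(nxt)) {
        fill <- data.frame(t = nxt$t[1], door = nxt$door[1],
                           side = nxt$from[1], crossed = TRUE)
        pushes <- rbind(pushes, fill)
        corrections <- c(corrections,
                         sprintf("trial %d: missing push filled with %s",
                                 k, nxt$door[1]))
      }
    }
  }
  if (!is.null(pushes) && nrow(pushes))
    pushes <- pushes[order(pushes$t), , drop = FALSE]
  rownames(pushes) <- NULL
  list(events = list(bells = bells, pushes = pushes),
       rejected = rejected, corrections = corrections)
}

#' Normalized door-push rates
#'
#' Pushes per door side per minute, grouped into the "closed/control" door
#' sides (those locked — or later locked — under the sequence's lock plan)
#' versus the "open" sides, per session and optionally per session quarter.
#'
#' @param pushes_by_session Named list (`O1`..`O3`) of push data.frames
#'   (`t`, `door`, `side`, `crossed`).
#' @param protocol A [session_protocol()].
#' @param durations Named numeric, session durations in minutes.
#' @param quarters Split each session into four equal time quarters.
#' @return data.frame: `session`, `quarter` (NA when not split), `door`,
#'   `side`, `group`, `pushes`, `minutes`, `rate`.
#' @export
push_rate_analysis <- function(pushes_by_session, protocol, durations,
                               quarters = FALSE) {
  if (any(durations <= 0)) stop("session durations must be positive")
  cc <- locked_door_sides(protocol)
  cc_key <- paste(cc$door, cc$side)
  d <- protocol$geometry$doors
  sides <- rbind(data.frame(door = d$door, side = d$box1),
                 data.frame(door = d$door, side = d$box2))
  out <- list()
  for (s in names(pushes_by_session)) {
    p <- pushes_by_session[[s]]
    dur_min <- durations[[s]]
    qs <- if (quarters) 1:4 else NA
    for (q in qs) {
      if (quarters) {
        lo <- (q - 1) * dur_min * 60 / 4
        hi <- q * dur_min * 60 / 4
        pq <- p[p$t >= lo & p$t < hi, , drop = FALSE]
        mins <- dur_min / 4
      } else {
        pq <- p; mins <- dur_min
      }
      cnt <- vapply(seq_len(nrow(sides)), function(i)
        sum(pq$door == sides$door[i] & pq$side == sides$side[i]),
        numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        session = s, quarter = q, door = sides$door, side = sides$side,
        group = ifelse(paste(sides$door, sides$side) %in% cc_key,
                       "closed_control", "open"),
        pushes = cnt, minutes = mins, rate = cnt / mins)
    }
  }
  do.call(rbind, out)
}

#' Bell-response metrics
#'
#' Mean running speed in the second before versus after each bell, and the
#' latency from each bell to the next door push, compared against latencies
#' to uniformly drawn random time points (as many as there are real pushes,
#' redrawn `n_shuffles` times).
#'
#' @param trajectory data.frame `t`, `x`, `y`.
#' @param events List with `bells` and `pushes`.
#' @param duration Session duration in s.
#' @param n_shuffles Shuffle repetitions (default 1000).
#' @param seed Optional seed.
#' @return List: `speeds` (per bell: `pre`, `post`; bells in the final
#'   second omitted), `latency` (per bell, NA when no later push) and
#'   `shuffle_latency` (vector pooled over repetitions).
#' @export
bell_response_metrics <- function(trajectory, events, duration,
                                  n_shuffles = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- compute_speed(trajectory)
  tt <- trajectory$t
  bells <- events$bells
  keep <- bells$t <= duration - 1
  speeds <- data.frame(
    t = bells$t[keep],
    pre = vapply(bells$t[keep], function(b)
      mean(v[tt >= b - 1 & tt < b]), numeric(1)),
    post = vapply(bells$t[keep], function(b)
      mean(v[tt > b & tt <= b + 1]), numeric(1)))
  pt <- sort(events$pushes$t)
  latency <- vapply(bells$t, function(b) {
    nxt <- pt[pt > b]
    if (length(nxt)) nxt[1] - b else NA_real_
  }, numeric(1))
  n_push <- length(pt)
  shuffle <- numeric(0)
  if (n_push > 0 && n_shuffles > 0) {
    shuffle <- unlist(lapply(seq_len(n_shuffles), function(i) {
      rt <- sort(stats::runif(n_push, 0, duration))
      vapply(bells$t, function(b) {
        nxt <- rt[rt > b]
        if (length(nxt)) nxt[1] - b else NA_real_
      }, numeric(1))
    }))
    shuffle <- shuffle[!is.na(shuffle)]
  }
  list(speeds = speeds,
       latency = data.frame(t = bells$t, latency = latency),
       shuffle_latency = shuffle)
}

#' Assemble per-trial choice records
#'
#' One row per bell: the session, the box the animal occupied at the bell,
#' the goal, the first door push after the bell (before the next bell) and
#' the first box foraged in after the bell.
#'
#' @param session Session label.
#' @param events Cleaned event log (see [clean_event_flags()]; `bells`
#'   must carry `start_box`).
#' @param visits Visit table from [segment_behavior()].
#' @param rejected Trial indices to drop (bells rung in the goal box).
#' @return data.frame `session`, `trial`, `start_box`, `goal`,
#'   `first_push_door`, `first_forage_box`.
#' @export
build_trials <- function(session, events, visits, rejected = integer(0)) {
  bells <- events$bells
  pushes <- events$pushes
  t_end <- c(bells$t[-1], Inf)
  rows <- lapply(seq_len(nrow(bells)), function(k) {
    if (k %in% rejected) return(NULL)
    fp <- NA_character_
    if (!is.null(pushes) && nrow(pushes)) {
      w <- which(pushes$t >= bells$t[k] & pushes$t < t_end[k])
      if (length(w)) fp <- pushes$door[w[1]]
    }
    fv <- visits[visits$mode == "foraging" & visits$t_start > bells$t[k] &
                   visits$t_start < t_end[k], , drop = FALSE]
    data.frame(session = session, trial = k,
               start_box = bells$start_box[k], goal = bells$goal[k],
               first_push_door = fp,
               first_forage_box = if (nrow(fv)) fv$box[1] else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' First-choice accuracy after the bell
#'
#' Scores (i) whether the first door push of each trial lies on an optimal
#' path to the goal given the session's connectivity (stratified by
#' start-goal door distance; trials at distance 2 in all-open sessions are
#' discarded because both doors are optimal) and (ii) whether the first box
#' foraged in was the goal. Chance levels — 1/2 for door choices and 1/3
#' for box choices (the start box is excluded) — are reported alongside.
#'
#' @param trials data.frame from [build_trials()] (rows may pool sessions).
#' @param protocol A [session_protocol()].
#' @return List: `doors` (per session x distance: `n`, `n_optimal`,
#'   `proportion`, `chance`), `foraging` (`n`, `n_correct`, `proportion`,
#'   `chance`), `dropped` (character log).
#' @export
first_choice_accuracy <- function(trials, protocol) {
  dropped <- character(0)
  rows <- list()
  forage_n <- 0L; forage_ok <- 0L
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    st <- protocol$states[[tr$session]]
    sp <- shortest_door_path(st, tr$start_box, tr$goal)
    dist <- sp$hops
    if (is.na(tr$first_push_door) && is.na(tr$first_forage_box)) {
      dropped <- c(dropped, sprintf("trial %s/%d: no push and no foraging",
                                    tr$session, tr$trial))
      next
    }
    open_session <- !st$session %in% c("C1", "C2")
    score_door <- !is.na(tr$first_push_door) &&
      !(open_session && dist == 2)   # both doors optimal: uninformative
    if (score_door) {
      rows[[length(rows) + 1L]] <- data.frame(
        session = tr$session, distance = dist,
        optimal = tr$first_push_door %in% sp$first_doors)
    }
    if (!is.na(tr$first_forage_box)) {
      forage_n <- forage_n + 1L
      forage_ok <- forage_ok + (tr$first_forage_box == tr$goal)
    }
  }
  doors <- NULL
  if (length(rows)) {
    sc <- do.call(rbind, rows)
    agg <- stats::aggregate(optimal ~ session + distance, sc,
                            function(z) c(n = length(z), ok = sum(z)))
    doors <- data.frame(session = agg$session, distance = agg$distance,
                        n = agg$optimal[, "n"],
                        n_optimal = agg$optimal[, "ok"])
    doors$proportion <- doors$n_optimal / doors$n
    doors$chance <- 0.5
  }
  list(doors = doors,
       foraging = data.frame(n = forage_n, n_correct = forage_ok,
                             proportion = if (forage_n) forage_ok / forage_n
                                          else NA_real_,
                             chance = 1 / 3),
       dropped = dropped)
}
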