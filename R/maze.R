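#' Four-room maze geometry
#'
#' Builds the physical layout of the four-room apparatus: four square boxes
#' arranged in a 2x2 grid, separated by a gap equal to the depth of the door
#' units, with one pushable door at the midpoint of each shared wall and two
#' "dummy" doors appended to the outer walls of every box.
#'
#' Coordinate frame: origin at the outer lower-left corner of the assembled
#' maze, axes in cm, y pointing up. Box labels are `A` (upper-left), `B`
#' (upper-right), `C` (lower-right) and `D` (lower-left). With the defaults
#' (60 cm boxes, 16 cm door units) the overall footprint is 136 x 136 cm.
#'
#' @param box_side Side length of each box in cm.
#' @param door_size Side length of the square door unit in cm; also the gap
#'   between adjacent boxes.
#' @param wall_height Wall height in cm (metadata only; no 3-D geometry).
#' @return An object of class `maze_geometry`: a list with box origins and
#'   centers, the internal door table (`doors`), the external dummy-door
#'   table (`dummy_doors`) and the footprint extent.
#' @examples
#' geom <- maze_geometry()
#' geom$doors
#' @export
maze_geometry <- function(box_side = 60, door_size = 16, wall_height = 20) {
  stopifnot(box_side > 0, door_size > 0)
  s <- box_side
  g <- door_size
  ext <- 2 * s + g
  origins <- rbind(
    A = c(0,     s + g),
    B = c(s + g, s + g),
    C = c(s + g, 0),
    D = c(0,     0)
  )
  colnames(origins) <- c("x", "y")
  centers <- origins + s / 2
  h <- s / 2
  # axis = orientation of the door panel ("vertical" panels join
  # horizontally adjacent boxes); crossing direction is perpendicular to it
  doors <- data.frame(
    door = c("A-B", "B-C", "C-D", "D-A"),
    cx   = c(s + g / 2, s + g + h,  s + g / 2, h),
    cy   = c(s + g + h, s + g / 2,  h,         s + g / 2),
    axis = c("vertical", "horizontal", "vertical", "horizontal"),
    box1 = c("A", "B", "C", "D"),
    box2 = c("B", "C", "D", "A"),
    stringsAsFactors = FALSE
  )
  dummy_doors <- data.frame(
    door = c("A-left", "A-top", "B-top", "B-right",
             "C-right", "C-bottom", "D-bottom", "D-left"),
    cx = c(0, h, s + g + h, ext, ext, s + g + h, h, 0),
    cy = c(s + g + h, ext, ext, s + g + h, h, 0, 0, h),
    box = c("A", "A", "B", "B", "C", "C", "D", "D"),
    stringsAsFactors = FALSE
  )
  geom <- list(
    box_side = s, door_size = g, wall_height = wall_height,
    extent = ext, boxes = rownames(origins),
    origins = origins, centers = centers,
    doors = doors, dummy_doors = dummy_doors
  )
  class(geom) <- "maze_geometry"
  geom
}

#' @export
print.maze_geometry <- function(x, ...) {
  cat(sprintf("Four-room maze: %g cm boxes, %g cm door units, %g x %g cm footprint\n",
              x$box_side, x$door_size, x$extent, x$extent))
  cat("Boxes:", paste(x$boxes, collapse = " "),
      " Doors:", paste(x$doors$door, collapse = " "), "\n")
  invisible(x)
}

#' Per-direction door-lock state of a session
#'
#' A session's connectivity is the set of directed box-to-box crossings that
#' are possible. In `O` sessions all doors open both ways (8 directed edges).
#' In the Closed-Door sequence, sessions `C1`/`C2` have one door locked in
#' both directions (6 edges); in the One-Way sequence all four doors are
#' locked in one direction, leaving a single directed cycle (4 edges).
#'
#' @param session One of `"O1","O2","C1","C2","O3"`.
#' @param sequence `"closed_door"` or `"one_way"`.
#' @param locked_door Door locked in C sessions of a Closed-Door sequence
#'   (one of `"A-B","B-C","C-D","D-A"`).
#' @param cycle Direction of the open cycle in One-Way C sessions: `"cw"`
#'   keeps A->B->C->D->A open, `"ccw"` the reverse.
#' @param geometry A [maze_geometry()].
#' @return Object of class `connectivity_state`: session label, sequence
#'   type, and a 4 x 2 logical lock matrix (rows = doors, columns `fwd`
#'   (box1->box2) and `rev`).
#' @examples
#' st <- connectivity_state("C1", "one_way")
#' st$locks
#' @export
connectivity_state <- function(session = c("O1", "O2", "C1", "C2", "O3"),
                               sequence = c("closed_door", "one_way"),
                               locked_door = "A-B", cycle = c("cw", "ccw"),
                               geometry = maze_geometry()) {
  session <- match.arg(session)
  sequence <- match.arg(sequence)
  cycle <- match.arg(cycle)
  doors <- geometry$doors$door
  locks <- matrix(FALSE, nrow = 4, ncol = 2,
                  dimnames = list(doors, c("fwd", "rev")))
  if (session %in% c("C1", "C2")) {
    if (sequence == "closed_door") {
      stopifnot(locked_door %in% doors)
      locks[locked_door, ] <- TRUE
    } else {
      # door table is oriented along the cycle A->B->C->D->A
      if (cycle == "cw") locks[, "rev"] <- TRUE else locks[, "fwd"] <- TRUE
    }
  }
  structure(list(session = session, sequence = sequence,
                 locked_door = if (sequence == "closed_door") locked_door else NA,
                 cycle = if (sequence == "one_way") cycle else NA,
                 locks = locks, geometry = geometry),
            class = "connectivity_state")
}

#' @export
print.connectivity_state <- function(x, ...) {
  n <- sum(!x$locks)
  cat(sprintf("Session %s (%s): %d open directed door crossings\n",
              x$session, x$sequence, n))
  invisible(x)
}

#' Directed connectivity graph of a session
#'
#' One node per box; a directed edge (u, v) is present iff the door between
#' u and v can be pushed open in the u -> v direction.
#'
#' @param state A [connectivity_state()].
#' @return An [igraph::igraph] directed graph whose edges carry the door id
#'   in edge attribute `door`.
#' @export
connectivity_graph <- function(state) {
  stopifnot(inherits(state, "connectivity_state"))
  d <- state$geometry$doors
  from <- c(d$box1, d$box2)
  to <- c(d$box2, d$box1)
  door <- c(d$door, d$door)
  open <- c(!state$locks[, "fwd"], !state$locks[, "rev"])
  igraph::graph_from_data_frame(
    data.frame(from = from[open], to = to[open], door = door[open]),
    directed = TRUE,
    vertices = state$geometry$boxes
  )
}

#' Shortest door path between boxes
#'
#' Minimum number of door crossings needed to move from `origin` to `goal`
#' under a session's lock state, one door sequence realizing it, and the set
#' of first doors that lie on *any* optimal path (used to score first pushes
#' after a bell).
#'
#' @param state A [connectivity_state()].
#' @param origin,goal Box labels.
#' @return List with `hops` (integer, `Inf` if unreachable), `doors`
#'   (character, one optimal door sequence) and `first_doors` (character,
#'   doors starting any optimal path).
#' @examples
#' st <- connectivity_state("O1", "closed_door")
#' shortest_door_path(st, "A", "B")$hops  # 1
#' @export
shortest_door_path <- function(state, origin, goal) {
  boxes <- state$geometry$boxes
  stopifnot(origin %in% boxes, goal %in% boxes)
  if (origin == goal) {
    return(list(hops = 0L, doors = character(0), first_doors = character(0)))
  }
  gr <- connectivity_graph(state)
  sp <- suppressWarnings(
    igraph::all_shortest_paths(gr, from = origin, to = goal, mode = "out"))
  if (length(sp$res) == 0) {
    return(list(hops = Inf, doors = character(0), first_doors = character(0)))
  }
  path_doors <- lapply(sp$res, function(p) {
    v <- igraph::as_ids(p)
    vapply(seq_len(length(v) - 1L), function(i)
      door_between(state$geometry, v[i], v[i + 1L]), character(1))
  })
  list(hops = length(path_doors[[1]]),
       doors = path_doors[[1]],
       first_doors = sort(unique(vapply(path_doors, `[`, character(1), 1L))))
}

#' Door joining two adjacent boxes
#' @param geometry A [maze_geometry()].
#' @param u,v Box labels.
#' @return Door id, or `NA` if the boxes are not adjacent.
#' @export
door_between <- function(geometry, u, v) {
  d <- geometry$doors
  hit <- (d$box1 == u & d$box2 == v) | (d$box1 == v & d$box2 == u)
  if (!any(hit)) return(NA_character_)
  d$door[hit]
}

# accessible door-unit passage squares (16x16, centered on each door)
door_cells <- function(geometry) {
  h <- geometry$door_size / 2
  d <- geometry$doors
  data.frame(door = d$door,
             x0 = d$cx - h, x1 = d$cx + h,
             y0 = d$cy - h, y1 = d$cy + h,
             stringsAsFactors = FALSE)
}

#' Assign points to boxes, quadrants and door gaps
#'
#' Each box is split into 2x2 quadrants around its centroid, giving 16
#' quadrants across the maze. Boundaries are half-open with the left/bottom
#' side inclusive, so a point exactly at a centroid falls in the upper-right
#' quadrant. Quadrant numbering is fixed: `(box_index - 1) * 4 + sub`, box
#' order A, B, C, D, and sub-quadrant 1 = lower-left, 2 = lower-right,
#' 3 = upper-left, 4 = upper-right.
#'
#' Points inside a door unit get `label = "door:<id>"`; their quadrant
#' (needed as decoding ground truth) uses the nearest box centroid.
#'
#' @param x,y Coordinates in cm (vectorized).
#' @param geometry A [maze_geometry()].
#' @param outside `"error"` to fail on points outside the footprint,
#'   `"na"` to return NA rows.
#' @return data.frame with `label` (box, `door:*`), `box` (box label; for
#'   door points the nearest box), `quadrant` (1-16) and `in_door` flag.
#' @export
assign_region <- function(x, y, geometry = maze_geometry(),
                          outside = c("error", "na")) {
  outside <- match.arg(outside)
  stopifnot(length(x) == length(y))
  s <- geometry$box_side
  n <- length(x)
  box <- rep(NA_character_, n)
  for (b in geometry$boxes) {
    o <- geometry$origins[b, ]
    hit <- x >= o[1] & x < o[1] + s & y >= o[2] & y < o[2] + s
    box[hit] <- b
  }
  dc <- door_cells(geometry)
  in_door <- rep(FALSE, n)
  door_lab <- rep(NA_character_, n)
  miss <- is.na(box)
  if (any(miss)) {
    for (k in seq_len(nrow(dc))) {
      hit <- miss & x >= dc$x0[k] & x < dc$x1[k] & y >= dc$y0[k] & y < dc$y1[k]
      in_door[hit] <- TRUE
      door_lab[hit] <- dc$door[k]
    }
  }
  bad <- is.na(box) & !in_door
  if (any(bad)) {
    if (outside == "error")
      stop(sum(bad), " point(s) outside the maze footprint")
  }
  # nearest box centroid for door-gap (and tolerated outside) points
  need <- is.na(box) & !bad
  if (any(need)) {
    cen <- geometry$centers
    d2 <- outer(x[need], cen[, 1], "-")^2 + outer(y[need], cen[, 2], "-")^2
    box[need] <- geometry$boxes[max.col(-d2)]
  }
  quadrant <- rep(NA_integer_, n)
  ok <- !is.na(box)
  if (any(ok)) {
    bi <- match(box[ok], geometry$boxes)
    cx <- geometry$centers[bi, 1]
    cy <- geometry$centers[bi, 2]
    sub <- 1L + (x[ok] >= cx) + 2L * (y[ok] >= cy)
    quadrant[ok] <- (bi - 1L) * 4L + sub
  }
  label <- ifelse(in_door, paste0("door:", door_lab), box)
  data.frame(label = label, box = box, quadrant = quadrant,
             in_door = in_door, stringsAsFactors = FALSE)
}

#' Doorway region predicate
#'
#' Points (or map bins) within a Euclidean radius of a door's center;
#' optionally restricted to the half-disk on the side of one adjacent box,
#' as used for the per-side One-Way analyses.
#'
#' @param geometry A [maze_geometry()].
#' @param door Door id (internal door) or dummy-door id.
#' @param radius Radius in cm (default 25, the doorway analysis radius).
#' @param side Optional box label selecting the half-disk on that box's side
#'   of the door line (internal doors only).
#' @return A predicate `function(x, y)` returning a logical vector.
#' @export
door_region <- function(geometry, door, radius = 25, side = NULL) {
  stopifnot(radius >= 0)
  d <- geometry$doors
  i <- match(door, d$door)
  if (is.na(i)) {
    dd <- geometry$dummy_doors
    j <- match(door, dd$door)
    if (is.na(j)) stop("unknown door: ", door)
    cx <- dd$cx[j]; cy <- dd$cy[j]; axis <- NA; b1 <- NA
  } else {
    cx <- d$cx[i]; cy <- d$cy[i]; axis <- d$axis[i]; b1 <- d$box1[i]
  }
  side_sign <- NULL
  if (!is.null(side)) {
    if (is.na(axis)) stop("side half-disks are defined for internal doors only")
    cen <- geometry$centers[side, ]
    if (axis == "vertical") {
      side_sign <- sign(cen[1] - cx); coord <- "x"
    } else {
      side_sign <- sign(cen[2] - cy); coord <- "y"
    }
    if (side_sign == 0) stop("box ", side, " is not beside door ", door)
  }
  function(x, y) {
    inside <- (x - cx)^2 + (y - cy)^2 <= radius^2
    if (!is.null(side_sign)) {
      v <- if (coord == "x") x - cx else y - cy
      inside <- inside & (sign(v) == side_sign | v == 0)
    }
    inside
  }
}

#' Pseudo-random goal list
#'
#' Twelve goals built from three random permutations of the four boxes, so
#' each box is used exactly three times and all four boxes are used before
#' any repeats. Block joins that would repeat a box on consecutive trials
#' are rejected and redrawn.
#'
#' @param seed Optional integer seed.
#' @param geometry A [maze_geometry()].
#' @return Character vector of 12 box labels.
#' @export
make_goal_list <- function(seed = NULL, geometry = maze_geometry()) {
  if (!is.null(seed)) set.seed(seed)
  boxes <- geometry$boxes
  out <- sample(boxes)
  while (length(out) < 12) {
    blk <- sample(boxes)
    if (blk[1] != out[length(out)]) out <- c(out, blk)
  }
  out
}

#' Five-session protocol of a recording sequence
#'
#' The study day: two baseline sessions with all doors open (`O1`, `O2`),
#' two test sessions with altered connectivity (`C1`, `C2`), and a final
#' reopened session (`O3`), all using the same 12-goal list.
#'
#' @inheritParams connectivity_state
#' @param goal_list Optional character vector of 12 box labels; generated
#'   with [make_goal_list()] when omitted.
#' @param seed Seed for goal-list generation.
#' @return Object of class `session_protocol`: sequence type, a named list
#'   of five [connectivity_state()]s and the goal list.
#' @export
session_protocol <- function(sequence = c("closed_door", "one_way"),
                             locked_door = "A-B", cycle = c("cw", "ccw"),
                             goal_list = NULL, seed = NULL,
                             geometry = maze_geometry()) {
  sequence <- match.arg(sequence)
  cycle <- match.arg(cycle)
  if (is.null(goal_list)) goal_list <- make_goal_list(seed, geometry)
  stopifnot(length(goal_list) == 12,
            all(table(factor(goal_list, levels = geometry$boxes)) == 3))
  for (b in 0:2) {
    blk <- goal_list[b * 4 + 1:4]
    if (anyDuplicated(blk))
      stop("goal list must use all four boxes before repeating one")
  }
  labs <- c("O1", "O2", "C1", "C2", "O3")
  states <- lapply(labs, connectivity_state, sequence = sequence,
                   locked_door = locked_door, cycle = cycle,
                   geometry = geometry)
  names(states) <- labs
  structure(list(sequence = sequence, states = states,
                 goal_list = goal_list,
                 locked_door = if (sequence == "closed_door") locked_door else NA,
                 cycle = if (sequence == "one_way") cycle else NA,
                 geometry = geometry),
            class = "session_protocol")
}

#' @export
print.session_protocol <- function(x, ...) {
  cat(sprintf("Session protocol (%s): O1 O2 C1 C2 O3\n", x$sequence))
  cat("Goal list:", paste(x$goal_list, collapse = " "), "\n")
  invisible(x)
}

#' Doors locked (or later locked) under a protocol
#'
#' For Closed-Door sequences: the locked door, both sides. For One-Way
#' sequences: the locked *side* (approach box) of every door. These door
#' sides form the "closed/control" group of the doorway analyses; all other
#' door sides are the "open" group.
#'
#' @param protocol A [session_protocol()].
#' @return data.frame with columns `door` and `side` (approach box) for the
#'   closed/control group.
#' @export
locked_door_sides <- function(protocol) {
  d <- protocol$geometry$doors
  st <- protocol$states[["C1"]]
  out <- data.frame(door = character(0), side = character(0))
  for (i in seq_len(nrow(d))) {
    if (st$locks[d$door[i], "fwd"])
      out <- rbind(out, data.frame(door = d$door[i], side = d$box1[i]))
    if (st$locks[d$door[i], "rev"])
      out <- rbind(out, data.frame(door = d$door[i], side = d$box2[i]))
  }
  out
}
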