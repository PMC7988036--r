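geom <- maze_geometry()

test_that("geometry invariants: tiling, door placement, center-door distance", {
  expect_equal(geom$extent, 136)
  # boxes tile a 2x2 grid with a door-sized gap
  expect_equal(unname(geom$origins["B", "x"] - geom$origins["A", "x"]), 76)
  expect_equal(unname(geom$origins["A", "y"] - geom$origins["D", "y"]), 76)
  # each internal door center sits at the midpoint of the shared wall
  for (i in seq_len(nrow(geom$doors))) {
    d <- geom$doors[i, ]
    c1 <- geom$centers[d$box1, ]
    c2 <- geom$centers[d$box2, ]
    expect_equal(c(d$cx, d$cy), unname((c1 + c2) / 2))
  }
  # nearest door is farther than the 25 cm doorway radius from box centers
  dist_cd <- outer(seq_len(4), seq_len(nrow(geom$doors)),
                   Vectorize(function(b, k)
                     sqrt((geom$centers[b, 1] - geom$doors$cx[k])^2 +
                          (geom$centers[b, 2] - geom$doors$cy[k])^2)))
  expect_true(all(dist_cd > 25))
  # adjacent 25 cm door disks are disjoint
  dd <- as.matrix(dist(cbind(geom$doors$cx, geom$doors$cy)))
  expect_true(all(dd[upper.tri(dd)] > 50))
})

test_that("connectivity graphs have the expected directed edge counts", {
  g_open <- connectivity_graph(connectivity_state("O1", "closed_door"))
  expect_equal(igraph::ecount(g_open), 8)
  g_cd <- connectivity_graph(connectivity_state("C1", "closed_door", locked_door = "B-C"))
  expect_equal(igraph::ecount(g_cd), 6)
  g_ow <- connectivity_graph(connectivity_state("C1", "one_way"))
  expect_equal(igraph::ecount(g_ow), 4)
  # one-way state is a single directed cycle visiting all four boxes
  expect_true(all(igraph::degree(g_ow, mode = "out") == 1))
  expect_true(all(igraph::degree(g_ow, mode = "in") == 1))
  expect_true(igraph::is_connected(g_ow, mode = "strong"))
})

test_that("all-open graph respects the 4-fold layout symmetry", {
  g <- connectivity_graph(connectivity_state("O2", "closed_door"))
  rot <- c(A = "B", B = "C", C = "D", D = "A")
  el <- igraph::as_edgelist(g)
  el_rot <- cbind(rot[el[, 1]], rot[el[, 2]])
  key <- function(m) sort(paste(m[, 1], m[, 2]))
  expect_equal(key(el_rot), key(el))
})

test_that("shortest door paths match the paper's worked cases", {
  open <- connectivity_state("O1", "closed_door")
  expect_equal(shortest_door_path(open, "A", "B")$hops, 1)
  expect_equal(shortest_door_path(open, "A", "A")$hops, 0)
  locked <- connectivity_state("C1", "closed_door", locked_door = "A-B")
  expect_equal(shortest_door_path(locked, "A", "B")$hops, 3)
  expect_equal(shortest_door_path(locked, "A", "B")$doors, c("D-A", "C-D", "B-C"))
  # one-way cycle: with the flow 1 hop, against the flow 3
  ow <- connectivity_state("C1", "one_way", cycle = "cw")
  expect_equal(shortest_door_path(ow, "A", "B")$hops, 1)
  expect_equal(shortest_door_path(ow, "B", "A")$hops, 3)
  # diagonal boxes all-open: two optimal first doors
  sp <- shortest_door_path(open, "A", "C")
  expect_equal(sp$hops, 2)
  expect_equal(sp$first_doors, c("A-B", "D-A"))
})

test_that("shortest paths equal brute-force enumeration for every state/pair", {
  states <- c(
    lapply(c("O1", "C1"), connectivity_state, sequence = "closed_door", locked_door = "A-B"),
    lapply(c("C1", "C2"), connectivity_state, sequence = "closed_door", locked_door = "C-D"),
    list(connectivity_state("C1", "one_way", cycle = "cw"),
         connectivity_state("C2", "one_way", cycle = "ccw"))
  )
  for (st in states) {
    for (o in geom$boxes) for (g2 in geom$boxes) {
      expect_equal(shortest_door_path(st, o, g2)$hops,
                   brute_force_hops(st, o, g2),
                   info = paste(st$session, st$sequence, o, g2))
    }
  }
})

test_that("region assignment partitions the footprint and obeys tie rules", {
  # every accessible point maps to exactly one label, quadrants 1-16
  set.seed(7)
  xs <- runif(4000, 0, 136)
  ys <- runif(4000, 0, 136)
  reg <- assign_region(xs, ys, geom, outside = "na")
  inside <- !is.na(reg$label)
  expect_true(all(reg$quadrant[inside] %in% 1:16))
  # box centroid + (-1,-1) lands in that box's lower-left quadrant
  for (b in seq_along(geom$boxes)) {
    cen <- geom$centers[b, ]
    r <- assign_region(cen[1] - 1, cen[2] - 1, geom)
    expect_equal(r$quadrant, (b - 1) * 4 + 1)
    # exact centroid: upper-right by the half-open convention
    r2 <- assign_region(cen[1], cen[2], geom)
    expect_equal(r2$quadrant, (b - 1) * 4 + 4)
  }
  # door-gap point: door label, quadrant from nearest box centroid
  d <- geom$doors[1, ]  # A-B
  r3 <- assign_region(d$cx - 2, d$cy + 1, geom)
  expect_equal(r3$label, "door:A-B")
  expect_equal(r3$box, "A")
  expect_error(assign_region(70, 70, geom), "outside")
})

test_that("door regions: radius geometry and half-disk sides", {
  pred <- door_region(geom, "A-B", radius = 25)
  # excludes all box centers
  expect_false(any(pred(geom$centers[, 1], geom$centers[, 2])))
  expect_true(pred(geom$doors$cx[1], geom$doors$cy[1]))
  # half-disk on the A side only takes points left of the door line
  predA <- door_region(geom, "A-B", radius = 25, side = "A")
  expect_true(predA(60, 106))
  expect_false(predA(76, 106))
  # zero radius keeps only the center
  pred0 <- door_region(geom, "A-B", radius = 0)
  expect_true(pred0(68, 106))
  expect_false(pred0(68.5, 106))
})

test_that("goal lists satisfy the protocol constraints", {
  for (s in 1:5) {
    gl <- make_goal_list(seed = s)
    expect_equal(length(gl), 12)
    expect_true(all(table(gl) == 3))
    for (b in 0:2) expect_false(anyDuplicated(gl[b * 4 + 1:4]) > 0)
    expect_false(any(gl[-1] == gl[-12]))  # no immediate repeats
  }
  pr <- session_protocol("one_way", seed = 1)
  expect_equal(names(pr$states), c("O1", "O2", "C1", "C2", "O3"))
  expect_equal(nrow(locked_door_sides(pr)), 4)  # one side per door
  pr2 <- session_protocol("closed_door", locked_door = "B-C", seed = 1)
  expect_equal(locked_door_sides(pr2)$side, c("B", "C"))
})
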