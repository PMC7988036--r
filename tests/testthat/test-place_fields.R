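geom <- maze_geometry()
grid <- map_grid(geom)

test_that("connected-component labeling respects the connectivity choice", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- m[2, 2] <- m[3, 3] <- TRUE   # diagonal chain
  lab8 <- fourrooms:::label_components(m, 8)
  expect_equal(length(setdiff(unique(as.integer(lab8)), 0L)), 1)
  lab4 <- fourrooms:::label_components(m, 4)
  expect_equal(length(setdiff(unique(as.integer(lab4)), 0L)), 3)
})

test_that("field detection: thresholds, size and peak rules", {
  # flat sub-1 Hz map: no field (peak rule)
  flat <- fake_rate_map(matrix(0.5, 40, 40))
  expect_equal(nrow(detect_fields(flat)$fields), 0)
  # one planted Gaussian bump: exactly one field, centroid within 2 bins
  g <- map_grid(geom, box = "D")
  bump <- fake_rate_map(gaussian_map(g, 24, 38, peak = 5, sigma = 8), g)
  pf <- detect_fields(bump)
  expect_equal(nrow(pf$fields), 1)
  expect_lt(sqrt((pf$fields$cx - 24)^2 + (pf$fields$cy - 38)^2), 4)
  expect_gte(pf$fields$area, 9)
  # an 8-bin supra-threshold region is rejected
  m <- matrix(0, 30, 30)
  m[10:13, 10:11] <- 5   # 8 bins
  expect_equal(nrow(detect_fields(fake_rate_map(m))$fields), 0)
  m[10:13, 10:12] <- 5   # 12 bins
  expect_equal(nrow(detect_fields(fake_rate_map(m))$fields), 1)
})

test_that("field detection is scale-invariant and translation-equivariant", {
  g <- map_grid(geom, box = "D")
  base <- gaussian_map(g, 24, 38, peak = 5, sigma = 8)
  pf1 <- detect_fields(fake_rate_map(base, g))
  pf2 <- detect_fields(fake_rate_map(base * 3.7, g))
  expect_equal(pf1$fields$area, pf2$fields$area)
  expect_equal(pf1$fields$cx, pf2$fields$cx)
  # translate by 2 whole bins (4 cm)
  sh <- gaussian_map(g, 24 + 4, 38 + 4, peak = 5, sigma = 8)
  pf3 <- detect_fields(fake_rate_map(sh, g))
  expect_equal(pf3$fields$cx, pf1$fields$cx + 4, tolerance = 0.3)
  expect_equal(pf3$fields$cy, pf1$fields$cy + 4, tolerance = 0.3)
})

test_that("bridge index: fixed points, symmetry, scale invariance", {
  # synthetic field bins around door A-B (center x = 68, vertical line)
  make_pfs <- function(bins_xy) {
    g <- grid
    i <- round((bins_xy[, 1] - 1) / 2) + 1
    j <- round((bins_xy[, 2] - 1) / 2) + 1
    structure(list(
      fields = data.frame(id = 1L, area = nrow(bins_xy),
                          cx = mean(bins_xy[, 1]), cy = mean(bins_xy[, 2]),
                          peak = 5, mean_rate = 3),
      bins = list(cbind(i = i, j = j)),
      hulls = list(cbind(x = bins_xy[, 1], y = bins_xy[, 2])),
      grid = g), class = "place_field_set")
  }
  # 12 bins entirely on the A side -> 0
  left <- cbind(rep(seq(55, 61, 2), 3), rep(c(102, 104, 106), each = 4))
  b0 <- bridge_index(make_pfs(left), 1, "A-B", geom)
  expect_equal(b0$bridge_index, 0)
  expect_equal(b0$a + b0$b, 12)
  # equal split -> 1
  both <- rbind(left, cbind(left[, 1] + 16, left[, 2]))
  b1 <- bridge_index(make_pfs(both), 1, "A-B", geom)
  expect_equal(b1$bridge_index, 1)
  # a = 30, b = 10 -> 0.5; symmetric under mirroring
  a30 <- cbind(rep(seq(49, 67, 2), 3), rep(c(102, 104, 106), each = 10))
  b10 <- cbind(rep(seq(77, 85, 2), 2), rep(c(102, 104), each = 5))
  bi <- bridge_index(make_pfs(rbind(a30, b10)), 1, "A-B", geom)
  expect_equal(bi$a, 30); expect_equal(bi$b, 10)
  expect_equal(bi$bridge_index, 0.5)
  mir <- cbind(2 * 68 - rbind(a30, b10)[, 1], rbind(a30, b10)[, 2])
  bi_m <- bridge_index(make_pfs(mir), 1, "A-B", geom)
  expect_equal(bi_m$bridge_index, bi$bridge_index)
  # hull projection limits on the perpendicular (x) axis
  expect_equal(b1$extent, range(both[, 1]))
})

test_that("overrepresentation: conservation, null and planted alternatives", {
  proto <- session_protocol("closed_door", locked_door = "A-B", seed = 1)
  dwell <- matrix(1, grid$nx, grid$ny)
  dwell[!grid$mask] <- 0
  dwells <- list(O1 = dwell, O2 = dwell, C1 = dwell, C2 = dwell, O3 = dwell)
  # uniform fields over the accessible surface: expectations sum to N,
  # and no category is flagged after correction
  set.seed(31)
  idx <- which(grid$mask)
  uni <- lapply(1:5, function(s) {
    pick <- sample(idx, 160)
    data.frame(cx = ((pick - 1) %% grid$nx) * 2 + 1,
               cy = ((pick - 1) %/% grid$nx) * 2 + 1)
  })
  names(uni) <- names(dwells)
  ov <- overrepresentation_tests(uni, dwells, grid, proto)
  for (s in unique(ov$areas$session)) {
    sub <- ov$areas[ov$areas$session == s, ]
    expect_equal(sum(sub$expected), sum(sub$observed), tolerance = 1e-9)
  }
  expect_true(all(ov$areas$p_corrected > 0.05, na.rm = TRUE))
  # all fields planted at doors: the door category becomes significant
  d <- geom$doors
  at_doors <- lapply(1:5, function(s)
    data.frame(cx = rep(d$cx, 10) + rnorm(40, 0, 3),
               cy = rep(d$cy, 10) + rnorm(40, 0, 3)))
  names(at_doors) <- names(dwells)
  ov2 <- overrepresentation_tests(at_doors, dwells, grid, proto)
  expect_true(all(ov2$areas$p_corrected < 0.05))
  expect_error(overrepresentation_tests(
    lapply(uni, function(x) x[0, ]), dwells, grid, proto), "no fields")
})

test_that("field tracking recovers planted drift and excludes teleports", {
  proto <- session_protocol("closed_door", locked_door = "A-B", seed = 1)
  # three field clusters, drifting 5 cm per session in a fixed direction
  anchors <- rbind(c(20, 20), c(100, 100), c(110, 25))
  tabs <- lapply(0:4, function(s)
    data.frame(cx = anchors[, 1] + 5 * s * 0.7071,
               cy = anchors[, 2] + 5 * s * 0.7071))
  names(tabs) <- c("O1", "O2", "C1", "C2", "O3")
  tk <- track_fields(tabs, proto, gap_B = 20, seed = 5)
  expect_equal(tk$k, 3)
  expect_equal(mean(tk$shifts$shift_cm), 5, tolerance = 2)
  expect_false(any(tk$shifts$excluded))
  # identical centroids across sessions: zero shifts
  same <- lapply(1:5, function(s) data.frame(cx = anchors[, 1],
                                             cy = anchors[, 2]))
  names(same) <- names(tabs)
  tk0 <- track_fields(same, proto, gap_B = 20, seed = 5)
  expect_true(all(tk0$shifts$shift_cm < 1e-9))
  # a 70 cm teleport is flagged as excluded
  tele <- same
  tele$O2 <- data.frame(cx = anchors[, 1] + 70, cy = anchors[, 2])
  tk1 <- track_fields(tele, proto, gap_B = 20, seed = 5)
  expect_true(any(tk1$shifts$excluded))
  expect_error(track_fields(list(O1 = same$O1[0, ], O2 = same$O2[0, ]),
                            proto), "at least 2")
  # door-distance table covers every door with group labels
  expect_equal(sort(unique(tk$door_distance$group)),
               c("changed", "unchanged"))
  expect_equal(nrow(tk$door_distance), 4)
})
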