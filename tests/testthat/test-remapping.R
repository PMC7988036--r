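set.seed(100)
rand_map <- function(n = 80, peak = 5) {
  v <- runif(n) * peak
  v
}

test_that("map correlation: identity, no-value rules, hand case", {
  v <- rand_map()
  expect_equal(map_correlation(v, v), 1)
  # neither map peaks above 1 Hz -> no value
  expect_true(is.na(map_correlation(v * 0.1, v * 0.15)))
  # one peak above 1 Hz suffices
  expect_false(is.na(map_correlation(v, v * 0.01)))
  # fewer than 10 common visited bins -> no value
  v2 <- v; v2[1:75] <- NA
  expect_true(is.na(map_correlation(v, v2)))
  # hand case on a two-bin map (bin floor relaxed)
  expect_equal(map_correlation(c(1, 2), c(2, 1), min_bins = 2), -1)
  expect_error(map_correlation(v, v[-1]), "different grids")
})

test_that("Fuhs metric: fixed points, bounds, symmetry, offset invariance", {
  v <- rand_map()
  expect_equal(fuhs_metric(v, v), 0)
  expect_equal(fuhs_metric(c(1, 0), c(0, 1), min_bins = 2), 1)
  expect_equal(fuhs_metric(v, v + 2.5), 0, tolerance = 1e-12)
  set.seed(7)
  for (i in 1:30) {
    a <- rand_map(); b <- rand_map()
    f <- fuhs_metric(a, b)
    expect_gte(f, 0); expect_lte(f, 1)
    expect_equal(f, fuhs_metric(b, a), tolerance = 1e-12)
    expect_equal(f, fuhs_metric(a + 3, b - 1), tolerance = 1e-10)
  }
  # zero only when maps agree up to an additive constant
  a <- rand_map(); b <- a + rnorm(80, 0, 0.5)
  expect_gt(fuhs_metric(a, b), 0)
  expect_true(is.na(fuhs_metric(rep(2, 20), rep(5, 20))))
})

make_cell_maps <- function(n_cells, drift = 0, remap_at = NULL, n_bins = 120,
                           peak = 6) {
  lapply(seq_len(n_cells), function(ci) {
    base <- runif(n_bins) * peak
    cur <- base
    lapply(1:5, function(si) {
      if (!is.null(remap_at) && si == 3 && ci %in% remap_at)
        cur <<- runif(n_bins) * peak
      if (si > 1 && drift > 0) cur <<- cur + rnorm(n_bins, 0, drift)
      pmax(cur, 0)
    })
  })
}

test_that("session correlations: drift-free, drifting and remapping regimes", {
  set.seed(8)
  flat <- make_cell_maps(25, drift = 0)
  sc <- session_correlation_analysis(flat)
  expect_true(all(abs(sc$separation$r - 1) < 1e-9))
  expect_equal(unname(sc$mean_matrix["O1", "O2"]), 1)
  drift <- make_cell_maps(25, drift = 0.8)
  scd <- session_correlation_analysis(drift)
  expect_true(all(diff(scd$separation$r) < 0))  # decays with separation
  planted <- make_cell_maps(40, drift = 0.2, remap_at = 1:20)
  scp <- session_correlation_analysis(planted)
  expect_lt(mean(scp$contrast$o2_c1, na.rm = TRUE),
            mean(scp$contrast$o1_o2, na.rm = TRUE) - 0.2)
})

test_that("individual remapping: pattern encoding and planted detection", {
  set.seed(9)
  # stable population with one planted remapper at O2->C1; under the
  # literal below-95th-percentile bound the remapper is flagged
  maps <- make_cell_maps(30, drift = 0.3, remap_at = 1)
  out <- classify_individual_remapping(list(maps), n = 400, seed = 2,
                                       bound = "above_95")
  expect_equal(nrow(out$profiles), 30)
  expect_true(out$profiles$remap2[1])          # planted transition flagged
  expect_equal(out$profiles$pattern[1], 4)     # (F,T,F,F) encodes to 4
  expect_equal(sum(out$histogram), 30)
  expect_length(out$shuffles, 4)
  # a small sequence does not qualify
  expect_error(classify_individual_remapping(list(maps[1:5])), "more than 10")
  # stable cells sit above the stability bound most of the time
  stable_rate <- mean(as.matrix(out$profiles[-1, paste0("stable", 1:4)]))
  expect_gt(stable_rate, 0.8)
  # the conservative default (below the shuffle's 5th percentile) flags
  # essentially nothing in a stable population
  out5 <- classify_individual_remapping(list(maps[-1]), n = 400, seed = 2)
  flags <- as.matrix(out5$profiles[, paste0("remap", 1:4)])
  expect_lt(mean(flags, na.rm = TRUE), 0.05)
})

test_that("doorway analysis contributes one value per cell and group", {
  proto <- session_protocol("closed_door", locked_door = "A-B", seed = 1)
  keys <- paste0(proto$geometry$doors$door, "|",
                 rep(c(proto$geometry$doors$box1, proto$geometry$doors$box2),
                     each = 0))
  keys <- c(paste0(proto$geometry$doors$door, "|", proto$geometry$doors$box1),
            paste0(proto$geometry$doors$door, "|", proto$geometry$doors$box2))
  set.seed(10)
  mk_cell <- function(local_remap) {
    base <- lapply(keys, function(k) runif(40) * 5)
    names(base) <- keys
    lapply(1:5, function(si) {
      m <- base
      if (local_remap && si >= 3) {
        for (k in c("A-B|A", "A-B|B")) m[[k]] <- runif(40) * 5
      }
      lapply(m, function(v) list(rate = v))
    })
  }
  cells <- lapply(1:12, function(i) mk_cell(local_remap = TRUE))
  dw <- doorway_correlation_analysis(cells, proto)
  expect_equal(nrow(dw), 12 * 2 * 2)
  expect_true(all(table(dw$cell, dw$group) == 2))
  base_cc <- dw$r[dw$transition == "O1-O2" & dw$group == "closed_control"]
  chg_cc <- dw$r[dw$transition == "O2-C1" & dw$group == "closed_control"]
  chg_open <- dw$r[dw$transition == "O2-C1" & dw$group == "open"]
  expect_lt(mean(chg_cc), mean(chg_open) - 0.3)   # local remap at locked door
  expect_gt(mean(base_cc), 0.99)                  # baseline stable
})

test_that("cross-box analysis: pair counts, repetition and independence", {
  boxes <- c("A", "B", "C", "D")
  set.seed(11)
  # perfect 4-box repetition: all pairwise correlations are 1
  rep_cell <- local({
    m <- runif(60) * 5
    stats::setNames(lapply(boxes, function(b) m + rnorm(60, 0, 1e-6)), boxes)
  })
  # independent maps per box
  ind_cells <- lapply(1:30, function(i)
    stats::setNames(lapply(boxes, function(b) runif(60) * 5), boxes))
  cb <- cross_box_analysis(c(list(rep_cell), ind_cells))
  expect_equal(sum(cb$per_pair$cell == 1), 6)   # C(4,2) pairs per cell
  expect_gt(cb$per_cell$r[1], 0.999)
  expect_lt(abs(stats::median(cb$per_cell$r[-1])), 0.15)
  # brute-force oracle for the repeating cell
  prs <- utils::combn(4, 2)
  oracle <- mean(apply(prs, 2, function(p)
    stats::cor(rep_cell[[p[1]]], rep_cell[[p[2]]])))
  expect_equal(cb$per_cell$r[1], oracle, tolerance = 1e-9)
})

test_that("repetition shuffle concentrates near 1 for drift-free k = 4", {
  boxes <- c("A", "B", "C", "D")
  set.seed(12)
  cells <- lapply(1:25, function(i) {
    per_box <- stats::setNames(lapply(boxes, function(b) runif(60) * 5),
                               boxes)
    lapply(1:5, function(si) per_box)  # identical across sessions
  })
  sh4 <- repetition_shuffle(cells, k = 4, seed = 3)
  expect_true(all(sh4 > 0.999))
  sh2 <- repetition_shuffle(cells, k = 2, seed = 3)
  # k = 2: exactly one repeated pair of the six
  expect_equal(mean(sh2), mean(sh4) / 6, tolerance = 0.1)
  expect_error(repetition_shuffle(list(list(cells[[1]][[1]])), k = 2),
               "2 sessions")
})

test_that("foraging vs goal-directed stability verdict", {
  set.seed(13)
  shared <- lapply(1:20, function(i) runif(100) * 6)
  noisy <- lapply(shared, function(v) pmax(v + rnorm(100, 0, 0.5), 0))
  same <- foraging_vs_goal_remapping(shared, noisy, n = 400, seed = 1)
  expect_true(same$stable)
  diff_maps <- lapply(1:20, function(i) runif(100) * 6)
  other <- foraging_vs_goal_remapping(shared, diff_maps, n = 400, seed = 1)
  expect_false(other$stable)
})
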