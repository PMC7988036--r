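geom <- maze_geometry()

test_that("speed computation matches a brute-force oracle", {
  tr0 <- data.frame(t = seq(0, 5, 0.02), x = 30, y = 30)
  expect_true(all(compute_speed(tr0) == 0))
  tr1 <- data.frame(t = seq(0, 5, 0.02), x = 10 + 10 * seq(0, 5, 0.02), y = 30)
  expect_equal(compute_speed(tr1), rep(10, nrow(tr1)), tolerance = 1e-9)
  set.seed(1)
  tr2 <- data.frame(t = cumsum(runif(50, 0.01, 0.05)),
                    x = cumsum(rnorm(50)), y = cumsum(rnorm(50)))
  v <- compute_speed(tr2)
  for (i in seq_len(49)) {
    d <- sqrt((tr2$x[i + 1] - tr2$x[i])^2 + (tr2$y[i + 1] - tr2$y[i])^2)
    expect_equal(v[i], d / (tr2$t[i + 1] - tr2$t[i]), tolerance = 1e-12)
  }
  expect_equal(v[50], v[49])
  bad <- data.frame(t = c(0, 1, 1), x = 1:3, y = 1:3)
  expect_error(compute_speed(bad), "increasing")
})

test_that("visit classification follows the path and coverage thresholds", {
  # high-coverage wandering visit in box D -> foraging
  set.seed(4)
  pts <- cbind(runif(30, 5, 55), runif(30, 5, 55))
  tr_f <- path_trajectory(pts, speed = 12)
  seg_f <- segment_behavior(tr_f, NULL, geom)
  expect_equal(nrow(seg_f$visits), 1)
  expect_gt(seg_f$visits$path_cm, 200)
  expect_gt(seg_f$visits$coverage, 0.20)
  expect_equal(seg_f$visits$mode, "foraging")
  # short direct pass (60 cm) -> goal-directed
  tr_g <- path_trajectory(rbind(c(10, 30), c(50, 30)), speed = 20)
  seg_g <- segment_behavior(tr_g, NULL, geom)
  expect_equal(seg_g$visits$mode, "goal_directed")
  expect_lt(seg_g$visits$path_cm, 120)
  # a push overrides visit labels from 2 s before to 1 s after
  push <- list(pushes = data.frame(t = 15, door = "C-D", side = "D",
                                   crossed = FALSE))
  seg_p <- segment_behavior(tr_f, push, geom)
  tt <- tr_f$t
  expect_true(all(seg_p$mode[tt >= 13 & tt <= 16] == "goal_directed"))
  expect_true(any(seg_p$mode[tt < 12.5] == "foraging"))
})

test_that("classification is invariant to translating the maze frame", {
  set.seed(9)
  pts <- cbind(runif(25, 5, 55), runif(25, 5, 55))
  tr <- path_trajectory(pts, speed = 12)
  g2 <- maze_geometry()
  seg1 <- segment_behavior(tr, NULL, geom)
  tr2 <- transform(tr, x = x + 76, y = y + 76)  # same offsets in box B
  seg2 <- segment_behavior(tr2, NULL, geom)
  expect_equal(seg1$visits$path_cm, seg2$visits$path_cm, tolerance = 1e-9)
  expect_equal(seg1$visits$coverage, seg2$visits$coverage)
  expect_equal(seg1$visits$mode, seg2$visits$mode)
})

test_that("event cleaning rejects, replaces and fills as specified", {
  # trajectory: forage in D, cross D-A into A
  pts_d <- cbind(runif(12, 5, 50), runif(12, 5, 50))
  tr <- path_trajectory(rbind(pts_d, c(30, 55), c(30, 68), c(30, 80),
                              c(30, 100)), speed = 15)
  dur <- max(tr$t)
  cross <- door_crossings(tr, geom)
  expect_equal(cross$door, "D-A")
  t_bell <- 1
  ev <- list(bells = data.frame(t = t_bell, goal = "A"),
             pushes = data.frame(t = cross$t[1], door = "B-C", side = "B",
                                 crossed = TRUE))
  cl <- clean_event_flags(ev, tr, geom)
  # bell rang while the rat was in D (not the goal): kept
  expect_length(cl$rejected, 0)
  # impossible push (B-C from box D) replaced by the real crossing
  expect_equal(cl$events$pushes$door[1], "D-A")
  expect_equal(cl$events$pushes$side[1], "D")
  # bell in the goal box -> rejected
  ev2 <- list(bells = data.frame(t = t_bell, goal = "D"), pushes = NULL)
  cl2 <- clean_event_flags(ev2, tr, geom)
  expect_equal(cl2$rejected, 1L)
  # missing push filled with first crossed door
  ev3 <- list(bells = data.frame(t = t_bell, goal = "A"),
              pushes = data.frame(t = numeric(0), door = character(0),
                                  side = character(0), crossed = logical(0)))
  cl3 <- clean_event_flags(ev3, tr, geom)
  expect_equal(cl3$events$pushes$door, "D-A")
  # a clean log passes through unchanged (idempotence)
  cl4 <- clean_event_flags(cl$events, tr, geom)
  expect_equal(cl4$events$pushes, cl$events$pushes)
  expect_length(cl4$corrections, 0)
})

test_that("push rates normalize by duration and group by lock plan", {
  proto <- session_protocol("closed_door", locked_door = "A-B", seed = 1)
  empty <- data.frame(t = numeric(0), door = character(0),
                      side = character(0), crossed = logical(0))
  pr0 <- push_rate_analysis(list(O1 = empty), proto, c(O1 = 10))
  expect_true(all(pr0$rate == 0))
  expect_equal(sort(unique(pr0$group)), c("closed_control", "open"))
  expect_equal(sum(pr0$group == "closed_control"), 2)  # two sides of A-B
  p <- data.frame(t = c(10, 100, 200), door = c("A-B", "A-B", "C-D"),
                  side = c("A", "B", "C"), crossed = TRUE)
  pr1 <- push_rate_analysis(list(C1 = p), proto, c(C1 = 10))
  # doubling duration with proportional pushes leaves rates unchanged
  p2 <- rbind(p, transform(p, t = t + 600))
  pr2 <- push_rate_analysis(list(C1 = p2), proto, c(C1 = 20))
  expect_equal(pr1$rate, pr2$rate)
  expect_error(push_rate_analysis(list(C1 = p), proto, c(C1 = 0)), "positive")
  # learned simulated agent pushes locked sides less in C1
  ds <- small_dataset()
  pushes <- lapply(ds$sessions, function(s) s$events$pushes)
  durs <- vapply(ds$sessions, function(s) s$duration / 60, numeric(1))
  pr <- push_rate_analysis(pushes, ds$protocol, durs)
  c1 <- pr[pr$session == "C1", ]
  expect_lt(mean(c1$rate[c1$group == "closed_control"]),
            mean(c1$rate[c1$group == "open"]))
})

test_that("bell metrics: speed change, latency and the shuffle oracle", {
  # stationary agent: pre equals post
  tr0 <- data.frame(t = seq(0, 60, 0.02), x = 30, y = 30)
  ev0 <- list(bells = data.frame(t = c(10, 30), goal = "A"),
              pushes = data.frame(t = c(12, 33), door = "D-A", side = "D",
                                  crossed = TRUE))
  bm0 <- bell_response_metrics(tr0, ev0, 60, n_shuffles = 50, seed = 1)
  expect_equal(bm0$speeds$pre, bm0$speeds$post)
  expect_equal(bm0$latency$latency, c(2, 3))
  # bell in the final second is omitted from the speed metric
  ev1 <- list(bells = data.frame(t = c(10, 59.5), goal = "A"),
              pushes = ev0$pushes)
  bm1 <- bell_response_metrics(tr0, ev1, 60, n_shuffles = 0)
  expect_equal(nrow(bm1$speeds), 1)
  # sprint-on-bell simulated agent accelerates after every bell
  ds <- small_dataset()
  s <- ds$sessions$O1
  bm <- bell_response_metrics(s$trajectory, s$events, s$duration,
                              n_shuffles = 0)
  expect_gt(mean(bm$speeds$post - bm$speeds$pre), 5)
  # order-statistics oracle: expected latency from t = 0 to the nearest of
  # N uniform points on [0, T] is T / (N + 1)
  T_len <- 500; N <- 9
  tr2 <- data.frame(t = seq(0, T_len, 0.1), x = 30, y = 30)
  ev2 <- list(bells = data.frame(t = 0, goal = "A"),
              pushes = data.frame(t = sort(runif(N, 0, T_len)),
                                  door = "D-A", side = "D", crossed = TRUE))
  bm2 <- bell_response_metrics(tr2, ev2, T_len, n_shuffles = 3000, seed = 2)
  expect_equal(mean(bm2$shuffle_latency), T_len / (N + 1), tolerance = 0.05)
})

test_that("first-choice scoring: optimal agents, chance agents, exclusions", {
  proto <- session_protocol("closed_door", locked_door = "A-B", seed = 1)
  # always-optimal synthetic agent scores 1.0 in all strata
  set.seed(12)
  boxes <- proto$geometry$boxes
  rows <- lapply(1:80, function(i) {
    s <- sample(c("O1", "C1"), 1)
    st <- proto$states[[s]]
    start <- sample(boxes, 1)
    goal <- sample(setdiff(boxes, start), 1)
    sp <- shortest_door_path(st, start, goal)
    data.frame(session = s, trial = i, start_box = start, goal = goal,
               first_push_door = sp$first_doors[1], first_forage_box = goal)
  })
  fc <- first_choice_accuracy(do.call(rbind, rows), proto)
  expect_true(all(fc$doors$proportion == 1))
  expect_equal(fc$foraging$proportion, 1)
  # distance-2 all-open trials are excluded from the door denominator
  tr2 <- data.frame(session = "O1", trial = 1, start_box = "A", goal = "C",
                    first_push_door = "A-B", first_forage_box = NA)
  fc2 <- first_choice_accuracy(tr2, proto)
  expect_null(fc2$doors)
  expect_equal(fc2$foraging$n, 0)
  # trials with neither push nor foraging are dropped with a log entry
  tr3 <- data.frame(session = "O1", trial = 1, start_box = "A", goal = "B",
                    first_push_door = NA, first_forage_box = NA)
  fc3 <- first_choice_accuracy(tr3, proto)
  expect_length(fc3$dropped, 1)
  # a uniform-random box chooser sits at the 1/3 chance level
  set.seed(13)
  n <- 3000
  start <- sample(boxes, n, replace = TRUE)
  goal <- vapply(start, function(b) sample(setdiff(boxes, b), 1), "")
  choice <- vapply(start, function(b) sample(setdiff(boxes, b), 1), "")
  trials <- data.frame(session = "O1", trial = seq_len(n), start_box = start,
                       goal = goal, first_push_door = NA,
                       first_forage_box = choice)
  fc4 <- first_choice_accuracy(trials, proto)
  expect_equal(fc4$foraging$proportion, 1 / 3, tolerance = 0.05)
})
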