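test_that("generated protocols satisfy every training constraint", {
  set.seed(1001)
  for (i in 1:5) {
    p <- generate_protocol(maze, "build_up")
    expect_true(validate_protocol(p, maze))
    for (se in p$sessions) {
      expect_true(all(maze$dist[cbind(se$starts, se$goal)] >= 2L))
      expect_gte(mean(maze$npaths[cbind(se$starts, se$goal)] == 1), 0.6)
      expect_true(all(maze$dist[cbind(se$starts[-31], se$starts[-1])] >= 2L))
    }
    firsts <- vapply(p$sessions, function(s) s$starts[1L], 0L)
    lasts <- vapply(p$sessions, function(s) s$starts[31L], 0L)
    expect_false(any(firsts[-1] == firsts[-3] | firsts[-1] == lasts[-3]))
  }
  set.seed(1002)
  a <- generate_protocol(maze, "location_update")
  set.seed(1002)
  b <- generate_protocol(maze, "location_update")
  expect_identical(protocol_specs(a), protocol_specs(b))
})

test_that("the protocol validator catches constraint violations", {
  set.seed(1003)
  p <- generate_protocol(maze, "build_up")
  broken <- p
  # plant a start adjacent to the goal (< 2 choice points away)
  near <- maze$adj[[p$goal]][1L]
  broken$sessions[[1L]]$starts[5L] <- near
  expect_error(validate_protocol(broken, maze), "closer than 2")
  broken2 <- p
  broken2$sessions[[2L]]$starts[1L] <- p$sessions[[1L]]$starts[1L]
  expect_error(validate_protocol(broken2, maze), "repeats previous")
})

test_that("barrier updates remove 1-3 gangways and reroute geodesics", {
  set.seed(1004)
  p <- generate_protocol(maze, "barrier_update")
  expect_true(nrow(p$barriers) %in% 1:3)
  eff <- build_hexmaze(barrier_edges = p$barriers)
  expect_true(igraph::is_connected(eff$graph))
  expect_true(validate_protocol(p, maze))
  # at least half the eligible starts see a different geodesic set
  eligible <- which(maze$dist[, p$goal] >= 2L)
  changed <- vapply(eligible, function(s)
    !identical(optimal_path_set_exact(eff, s, p$goal)$nodes,
               optimal_path_set_exact(maze, s, p$goal)$nodes), TRUE)
  expect_gte(mean(changed), 0.5)
})

test_that("goal placement is counterbalanced across generated animals", {
  set.seed(1005)
  sched <- ground_truth_schedule("build_up", F_by_bin = rep(1, 4))
  d <- generate_dataset(maze, generate_protocol(maze, "build_up",
                                                goal_ring = "outer"),
                        sched, n_animals = 8L)
  rings <- vapply(d$protocols, `[[`, "", "goal_ring")
  expect_equal(sum(rings == "inner"), 2L)
  expect_equal(length(d$trials), 8L * 3L * 31L)
})

test_that("ground-truth schedules drive the navigator per bin", {
  set.seed(1006)
  p <- generate_protocol(maze, "build_up", trials_per_session = 4L)
  allseeing <- ground_truth_schedule("build_up", F_by_bin = rep(100, 4))
  d <- generate_dataset(maze, p, allseeing)
  expect_true(all(metrics_table(d$trials, maze)$rtl == 1))
  expect_error(generate_dataset(maze, p, allseeing[-1, ]), "does not cover")
  # rising foresight shifts RTL toward 1 across bins
  set.seed(1007)
  d2 <- generate_dataset(maze, generate_protocol(maze, "build_up"),
                         learning_schedule(), n_animals = 6L)
  mt <- metrics_table(d2$trials, maze)
  med <- tapply(mt$log_rtl, mt$bin, stats::median)
  expect_gt(med[["t2_11"]], med[["t22_31"]])
})

test_that("generated datasets round-trip through the CSV dialect", {
  set.seed(1008)
  p <- generate_protocol(maze, "build_up", trials_per_session = 5L)
  d <- generate_dataset(maze, p, ground_truth_schedule("build_up",
                                                       F_by_bin = rep(1, 4)))
  tmp <- tempfile(fileext = ".csv")
  write_trajectories(d$trials, tmp)
  back <- read_trajectories(tmp, graph = maze)
  expect_equal(as.data.frame(back), as.data.frame(d$trials),
               ignore_attr = TRUE)
})
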