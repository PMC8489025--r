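test_that("relative trial length counts edges against the geodesic", {
  # geodesic trial scores exactly 1 (log10 = 0)
  m <- relative_trial_length(trajectory(c(1, 2, 3, 4), graph = maze), maze)
  expect_equal(m$rtl, 1)
  expect_equal(m$log_rtl, 0)
  expect_equal(m$max_dfop, 0L)
  # twice the geodesic length (d = 2, 4 edges walked)
  m2 <- relative_trial_length(trajectory(c(7, 1, 2, 10, 9), goal = 9,
                                         graph = maze), maze)
  expect_equal(m2$rtl, 2)
  # hand-counted 9-step walk to a goal 3 edges away
  w <- trajectory(c(8, 7, 1, 2, 3, 4, 5, 6, 22, 23), goal = 23, graph = maze)
  expect_equal(graph_distance(maze, 8, 23), 3L)
  m3 <- relative_trial_length(w, maze)
  expect_equal(m3$rtl, 3)
  expect_equal(m3$path_steps, 9L)
  # ring occupancy partitions exactly
  expect_equal(m3$outer_fraction, mean(maze$ring[w$nodes] == "outer"))
  degen <- structure(list(nodes = c(3L, 2L, 3L), goal = 3L, animal_id = "x",
                          condition = "build_up", session = 1L, trial = 1L,
                          completed = TRUE), class = "trajectory")
  expect_error(relative_trial_length(degen, maze), "degenerate")
  expect_error(relative_trial_length(trajectory(c(1, 2), goal = 13,
                                                completed = FALSE), maze),
               "incomplete")
})

test_that("dfop series equals the brute-force distance to enumerated geodesics", {
  expect_equal(dfop_series(trajectory(c(1, 2, 3, 4), graph = maze), maze),
               rep(0L, 4L))
  # one-node detour off a unique geodesic contributes a single 1
  det <- suppressWarnings(trajectory(c(8, 9, 10, 2, 10, 11), goal = 11,
                                     graph = maze))
  expect_equal(dfop_series(det, maze), c(0L, 0L, 0L, 1L, 0L, 0L))
  # arbitrary simulated trajectories against the enumeration oracle
  set.seed(601)
  sims <- simulate_dataset(maze, data.frame(start = c(1, 9, 17),
                                            goal = c(14, 3, 6)),
                           sim_params(0, 0.5), n_reps = 3L)
  for (t in sims) {
    geo_nodes <- sort(unique(unlist(enum_geodesics(maze$adj, t$nodes[1L],
                                                   t$goal))))
    oracle <- vapply(t$nodes, function(v) min(maze$dist[v, geo_nodes]), 0L)
    expect_identical(dfop_series(t, maze), oracle)
    expect_equal(max(oracle), relative_trial_length(t, maze)$max_dfop)
  }
})

test_that("dfop profiles average, pad and bound correctly", {
  geo <- list(trajectory(c(1, 2, 3, 4), graph = maze),
              trajectory(c(7, 8, 9, 10), graph = maze))
  flat <- dfop_profile(geo, maze, horizon = 3L)
  expect_equal(flat$mean, rep(0, 4L))
  # a single trial reproduces its own series
  w <- trajectory(c(8, 7, 1, 2, 3, 4, 5, 6, 22, 23), goal = 23, graph = maze)
  prof1 <- dfop_profile(list(w), maze, horizon = 9L)
  expect_equal(prof1$mean, as.numeric(dfop_series(w, maze)))
  # padding keeps n constant; without it n decays after short trials end
  both <- c(geo, list(w))
  padded <- dfop_profile(both, maze, horizon = 9L, pad = TRUE)
  expect_true(all(padded$n == 3L))
  expect_equal(padded$mean[1L], 0)
  unpadded <- dfop_profile(both, maze, horizon = 9L, pad = FALSE)
  expect_equal(unpadded$n[9], 1L)
  expect_error(dfop_profile(list(), maze), "empty")
  # simulated memoryless group shows the rise-then-fall bump
  set.seed(602)
  grp <- simulate_dataset(maze, data.frame(start = 1, goal = 15),
                          sim_params(0, 0), n_reps = 60L)
  bump <- dfop_profile(grp, maze)
  expect_gt(max(bump$mean), 0)
  expect_lt(which.max(bump$mean), nrow(bump)) # peak strictly inside
})

test_that("optimal-trial probability counts RTL below threshold", {
  geo <- list(trajectory(c(1, 2, 3, 4), graph = maze),
              trajectory(c(7, 8, 9, 10), graph = maze))
  set.seed(603)
  expect_equal(optimal_trial_probability(geo, maze)$prob, 1)
  long <- trajectory(c(8, 7, 1, 2, 3, 4, 5, 6, 22, 23), goal = 23,
                     graph = maze)
  expect_equal(optimal_trial_probability(list(long), maze)$prob, 0)
  mix <- optimal_trial_probability(c(geo, list(long)), maze)
  expect_equal(mix$prob, 2 / 3)
  expect_gte(mix$sd, 0)
})

test_that("goal shuffling recomputes RTL toward surrogate goals", {
  trials <- list(
    trajectory(c(1, 2, 3), goal = 3, graph = maze),
    trajectory(c(7, 8, 9, 10), goal = 10, graph = maze),
    trajectory(c(14, 15, 16), goal = 16, graph = maze))
  # identity permutation leaves metrics unchanged
  id <- gl_shuffle(trials, maze, perm = 1:3)
  expect_equal(id$rtl, metrics_table(trials, maze)$rtl)
  # surrogate goal = first intermediate node, one edge from the start:
  # sub-trajectory has one step, distance is one edge, so rtl = 1
  pair <- list(trajectory(c(1, 2, 3), goal = 3, graph = maze),
               trajectory(c(7, 1, 2), goal = 2, graph = maze))
  got <- gl_shuffle(pair, maze, perm = c(2, 1))
  expect_equal(got$surrogate_goal, c(2L, 3L))
  expect_equal(got$rtl[1L], 1)
  # absent surrogate goal falls back to the default RTL of 10
  expect_equal(got$rtl[2L], 10)
  far <- gl_shuffle(list(trajectory(c(1, 2, 3), goal = 3, graph = maze),
                         trajectory(c(19, 20, 21), goal = 21, graph = maze)),
                    maze, perm = 2:1)
  expect_equal(far$rtl, c(10, 10))
  expect_error(gl_shuffle(pair[1], maze), "at least two")
})

test_that("node crossings equal a naive scan", {
  w <- trajectory(c(8, 7, 1, 2, 3, 4, 5, 6, 22, 23), goal = 23, graph = maze)
  counts <- node_crossings(w, c(1, 8, 20))
  expect_identical(unname(counts), c(1L, 1L, 0L))
  expect_gte(node_crossings(w, w$nodes[1L])[[1L]], 1L)
  set.seed(604)
  t <- simulate_trial(maze, 2, 18, sim_params(0, 0))
  for (v in c(2, 18, 11))
    expect_equal(node_crossings(t, v)[[1L]], sum(t$nodes == v))
})

test_that("bootstrap summaries are seeded and match an independent loop", {
  expect_equal(bootstrap_summary(rep(3.5, 20))$sd, 0)
  set.seed(605)
  x <- rexp(40)
  set.seed(606)
  got <- bootstrap_summary(x, n_boot = 50L)
  set.seed(606)
  means <- numeric(50L)
  for (b in 1:50) means[b] <- mean(sample(x, replace = TRUE))
  expect_equal(got$mean, mean(means))
  expect_equal(got$sd, sd(means))
  expect_lt(abs(got$mean - mean(x)), 4 * sd(x) / sqrt(length(x)))
  expect_error(bootstrap_summary(numeric(0)), "empty")
})
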