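test_that("two-sample KS distance matches a hand-enumerated CDF sweep", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$statistic, 1)
  # x = {1,2,3}, y = {2,3,4}: |F_x - F_y| peaks at 1/3
  expect_equal(ks_two_sample(c(1, 2, 3), c(2, 3, 4))$statistic, 1 / 3)
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
  # internal sorted-sweep D agrees with stats::ks.test on tied data
  set.seed(901)
  for (i in 1:20) {
    x <- sample(seq(1, 3, by = 0.25), 40, replace = TRUE)
    y <- sample(seq(1, 4, by = 0.25), 70, replace = TRUE)
    expect_equal(hexnav:::.ks_D_sorted(sort(x), sort(y)),
                 unname(suppressWarnings(stats::ks.test(x, y))$statistic))
  }
})

test_that("strategy fit recovers the generating foresight on a small grid", {
  set.seed(902)
  spec <- cohort_first_trials(maze, n_animals = 20L)
  obs <- simulate_dataset(maze, spec[, c("start", "goal")],
                          sim_params(0, 1.0), n_reps = 10L)
  fit <- fit_strategy(obs, maze, grid_eta = c(0, 0.05, 0.1),
                      grid_F = seq(0, 2, by = 0.25), n_reps = 10L)
  expect_s3_class(fit, "strategy_fit")
  expect_equal(fit$best$eta, 0)
  expect_lte(abs(fit$best$F - 1.0), 0.25)
  expect_true(all(fit$grid$ks_rtl >= 0 & fit$grid$ks_rtl <= 1, na.rm = TRUE))
  expect_equal(coef(fit), c(eta = fit$best$eta, F = fit$best$F))
  # held-out statistics match at the recovered pair
  expect_true(all(fit$validation$p_value[fit$validation$statistic !=
                                           "rtl"] > 0.05))
})

test_that("purely geodesic observations push foresight to the grid maximum", {
  geo <- lapply(1:60, function(i) {
    st <- c(3, 8, 12, 15, 20, 24)[(i %% 6) + 1]
    gl <- c(16, 21, 2, 6, 9, 13)[(i %% 6) + 1]
    path <- igraph::shortest_paths(maze$graph, st, gl)$vpath[[1]]
    trajectory(as.integer(path), goal = gl, graph = maze)
  })
  set.seed(903)
  fit <- fit_strategy(geo, maze, grid_eta = 0, grid_F = seq(0, 2, by = 0.5),
                      n_reps = 20L)
  expect_equal(fit$best$F, 2)
})

test_that("bootstrap refits give a spread of best-fit parameters", {
  set.seed(904)
  spec <- cohort_first_trials(maze, n_animals = 12L)
  obs <- simulate_dataset(maze, spec[, c("start", "goal")],
                          sim_params(0, 0.5), n_reps = 5L)
  fit <- fit_strategy(obs, maze, grid_eta = c(0, 0.1),
                      grid_F = seq(0, 1.5, by = 0.25), n_reps = 5L,
                      n_boot = 15L)
  expect_equal(nrow(fit$boot), 15L)
  expect_true(all(fit$boot$F %in% seq(0, 1.5, by = 0.25)))
  expect_lte(abs(stats::median(fit$boot$F) - 0.5), 0.5)
})

test_that("foresight trajectory orders groups and excludes undersized ones", {
  set.seed(905)
  sched <- ground_truth_schedule("build_up", F_by_bin = c(0, 0.5, 1.0, 1.5),
                                 n_sessions = 1L)
  d <- generate_dataset(maze,
                        lapply(1:10, function(a) generate_protocol(
                          maze, "build_up", n_sessions = 1L,
                          goal_ring = if (a %% 4 == 0) "inner" else "outer")),
                        sched, n_animals = 10L)
  expect_warning(
    ft <- foresight_trajectory(d$trials, maze, n_boot = 5L,
                               grid_eta = c(0, 0.1),
                               grid_F = seq(0, 2, by = 0.25), n_reps = 25L),
    "excluded")
  # the 10-trial first bin is dropped; the three 100-trial bins survive
  expect_equal(nrow(ft$groups), 3L)
  expect_equal(ft$groups$bin, c("t2_11", "t12_21", "t22_31"))
  # foresight rises monotonically along the learning schedule
  expect_true(all(diff(ft$groups$F) > 0))
  # identical groups are statistically indistinguishable
  b <- ft$fits[[1L]]$boot$F
  expect_gt(ks_two_sample(b, b)$p_value, 0.1)
})

test_that("a memoryless schedule is recovered as eta = 0, F = 0 everywhere", {
  set.seed(906)
  sched <- ground_truth_schedule("build_up", F_by_bin = rep(0, 4),
                                 n_sessions = 1L)
  d <- generate_dataset(maze,
                        lapply(1:6, function(a) generate_protocol(
                          maze, "build_up", n_sessions = 1L,
                          goal_ring = if (a %% 4 == 0) "inner" else "outer")),
                        sched, n_animals = 6L)
  mt <- metrics_table(d$trials, maze)
  mt <- mt[mt$bin != "first", ]
  ft <- foresight_trajectory(mt, maze, n_boot = 0L, grid_eta = c(0, 0.1),
                             grid_F = seq(0, 1, by = 0.25), n_reps = 20L)
  expect_true(all(ft$groups$eta == 0))
  expect_true(all(ft$groups$F <= 0.25))
})
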