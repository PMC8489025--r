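test_that("maze satisfies every structural invariant of the HexMaze", {
  g <- maze
  deg <- igraph::degree(g$graph)
  expect_equal(igraph::vcount(g$graph), 24L)
  expect_equal(igraph::ecount(g$graph), 30L)
  expect_equal(sum(deg == 2L), 12L)
  expect_equal(sum(deg == 3L), 12L)
  expect_equal(sum(g$ring == "inner"), 6L)
  expect_equal(sum(g$ring == "outer"), 18L)
  # inner ring is a 6-cycle of three-way choice points
  inner <- which(g$ring == "inner")
  expect_true(all(deg[inner] == 3L))
  sub_i <- igraph::induced_subgraph(g$graph, inner)
  expect_true(all(igraph::degree(sub_i) == 2L) && igraph::is_connected(sub_i))
  # outer ring is an 18-cycle
  sub_o <- igraph::induced_subgraph(g$graph, which(g$ring == "outer"))
  expect_true(all(igraph::degree(sub_o) == 2L) && igraph::is_connected(sub_o))
  expect_true(igraph::bipartite_mapping(g$graph)$res)
  # physical layout: every gangway is one edge length long
  elen <- sqrt(rowSums((g$coords[g$edges[, 1], ] - g$coords[g$edges[, 2], ])^2))
  expect_equal(elen, rep(36.3, 30), tolerance = 1e-6)
})

test_that("graph_distance agrees exactly with a brute-force BFS oracle", {
  d_oracle <- t(vapply(1:24, function(s) bfs_dist(maze$adj, s), integer(24L)))
  expect_identical(maze$dist, d_oracle)
  expect_equal(graph_distance(maze, 5, 5), 0L)
  expect_equal(graph_distance(maze, 1, 7), 1L)
  expect_equal(max(d_oracle), max(maze$dist)) # diameter from the oracle
  # symmetry and triangle inequality over all triples through node 1
  expect_identical(maze$dist, t(maze$dist))
  for (v in 1:24)
    expect_true(all(outer(maze$dist[, v], maze$dist[v, ], "+") >= maze$dist))
  expect_error(graph_distance(maze, 1, 25), "unknown node")
})

test_that("exact geodesic sets equal the union of enumerated shortest paths", {
  for (s in 1:24) for (t in 1:24) {
    ops <- optimal_path_set_exact(maze, s, t)
    paths <- enum_geodesics(maze$adj, s, t)
    expect_identical(ops$nodes, sort(unique(unlist(paths))))
    expect_equal(ops$distance, length(paths[[1L]]) - 1L)
    # membership criterion: d(s,v) + d(v,t) == d(s,t)
    expect_true(all(maze$dist[s, ops$nodes] + maze$dist[ops$nodes, t] ==
                      ops$distance))
  }
  expect_identical(optimal_path_set_exact(maze, 1, 7)$nodes, c(1L, 7L))
  one <- optimal_path_set_exact(maze, 9, 9)
  expect_identical(one$nodes, 9L)
  expect_identical(one$distance, 0L)
})

test_that("noisy-weight geodesic sets converge to the exact sets", {
  set.seed(401)
  mism <- 0L
  total <- 0L
  for (s in 1:24) for (t in setdiff(1:24, s)) {
    noisy <- optimal_path_set_noisy(maze, s, t, n_reps = 200L)
    exact <- optimal_path_set_exact(maze, s, t)
    total <- total + 1L
    if (!identical(noisy$nodes, exact$nodes)) mism <- mism + 1L
  }
  expect_equal(total, 552L)
  expect_lt(mism / total, 0.01)

  set.seed(402)
  # a single repetition yields one geodesic: d+1 nodes, all inside the set
  one <- optimal_path_set_noisy(maze, 1, 14, n_reps = 1L)
  exact <- optimal_path_set_exact(maze, 1, 14)
  expect_equal(length(one$nodes), exact$distance + 1L)
  expect_true(all(one$nodes %in% exact$nodes))
  # unique-geodesic pair equals the exact set at any n_reps
  expect_equal(maze$npaths[8, 11], 1)
  expect_identical(optimal_path_set_noisy(maze, 8, 11, n_reps = 2L)$nodes,
                   optimal_path_set_exact(maze, 8, 11)$nodes)
  expect_error(optimal_path_set_noisy(maze, 1, 4, noise_scale = 0.1),
               "noise_scale")
})

test_that("barriers remove edges but must leave the maze connected", {
  gb <- build_hexmaze(barrier_edges = c(1, 2))
  expect_equal(igraph::ecount(gb$graph), 29L)
  expect_true(igraph::is_connected(gb$graph))
  expect_gt(graph_distance(gb, 1, 2), 1L)
  expect_equal(nrow(gb$removed_edges), 1L)
  # removing every gangway at node 8 isolates it
  expect_error(build_hexmaze(barrier_edges = rbind(c(7, 8), c(8, 9))),
               "disconnects")
  expect_error(build_hexmaze(barrier_edges = c(1, 3)), "not existing")
})

test_that("maze serialization round-trips and the loader validates", {
  tmp <- tempfile(fileext = ".edges")
  write_maze(maze, tmp)
  g2 <- read_maze(tmp)
  expect_identical(g2$edges, maze$edges)
  expect_identical(g2$ring, maze$ring)
  expect_identical(g2$dist, maze$dist)
  gb <- build_hexmaze(barrier_edges = c(5, 19))
  tmpb <- tempfile(fileext = ".edges")
  write_maze(gb, tmpb)
  expect_identical(read_maze(tmpb)$removed_edges, gb$removed_edges)
  # tampered edge list is rejected
  lines <- readLines(tmp)
  writeLines(lines[-1], tmp)
  expect_error(read_maze(tmp), "does not match")
})
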