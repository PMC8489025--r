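#' Construct the HexMaze graph
#'
#' Builds the 24-node, 30-edge HexMaze: six hexagonal corridor modules
#' tessellated around a central hexagonal circuit ("seven-hexagon flower").
#' Nodes 1--6 form the inner ring (the central 6-cycle, all three-way choice
#' points); nodes 7--24 form the outer ring (an 18-cycle) counter-clockwise,
#' with node 7 the outer end of the gangway leaving inner node 1. Each inner
#' node i is joined radially to outer node `7 + 3*(i-1)`. Without barriers
#' the graph has twelve two-way and twelve three-way choice points, spaced
#' one gangway (36.3 cm centre-to-centre) apart.
#'
#' Barriers are modelled purely as edge removals; construction fails if a
#' barrier set disconnects the maze.
#'
#' @param barrier_edges optional set of edges to remove: a two-column
#'   matrix/data.frame of node pairs, or a single length-2 vector. Each pair
#'   must be an existing gangway.
#' @param edge_cm physical gangway length in cm (plot coordinates only; all
#'   analysis distances are in edges).
#' @return An object of class `"hexmaze"`: a list with the igraph `graph`,
#'   the `edges` matrix, per-node `ring` labels (`"inner"`/`"outer"`),
#'   planar `coords` (cm), `removed_edges`, the all-pairs geodesic `dist`
#'   matrix (edges), the geodesic-count matrix `npaths`, and the adjacency
#'   list `adj`.
#' @examples
#' g <- build_hexmaze()
#' igraph::vcount(g$graph)   # 24
#' igraph::ecount(g$graph)   # 30
#' gb <- build_hexmaze(barrier_edges = c(1, 2))
#' @export
build_hexmaze <- function(barrier_edges = NULL, edge_cm = 36.3) {
  geo <- .hexmaze_geometry(edge_cm)
  edges <- geo$edges
  removed <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("u", "v")))
  if (!is.null(barrier_edges)) {
    removed <- .normalize_edges(barrier_edges)
    key_all <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    key_rm <- paste(pmin(removed[, 1], removed[, 2]), pmax(removed[, 1], removed[, 2]))
    if (anyDuplicated(key_rm))
      stop("duplicate barrier edges: ", paste(key_rm[duplicated(key_rm)], collapse = ", "))
    missing <- !(key_rm %in% key_all)
    if (any(missing))
      stop("barrier edges are not existing gangways: ",
           paste(key_rm[missing], collapse = "; "))
    edges <- edges[!(key_all %in% key_rm), , drop = FALSE]
  }
  gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(gr) < 24L) # removal can drop isolated vertex ids entirely
    gr <- igraph::add_vertices(gr, 24L - igraph::vcount(gr))
  if (!igraph::is_connected(gr)) {
    rm_str <- paste(sprintf("%d-%d", removed[, 1], removed[, 2]), collapse = ", ")
    stop("barrier set disconnects the maze (offending edges: ", rm_str, ")")
  }
  dist <- igraph::distances(gr)
  storage.mode(dist) <- "integer"
  dimnames(dist) <- NULL
  adj <- lapply(seq_len(24L), function(v) as.integer(igraph::neighbors(gr, v)))
  maze <- structure(list(
    graph = gr,
    edges = edges,
    ring = geo$ring,
    coords = geo$coords,
    removed_edges = removed,
    dist = dist,
    npaths = .count_geodesics(adj, dist),
    adj = adj,
    edge_cm = edge_cm
  ), class = "hexmaze")
  if (is.null(barrier_edges)) .assert_hexmaze_invariants(maze)
  maze
}

# Vertex geometry of the seven-hexagon flower; numbering by ring and angle.
.hexmaze_geometry <- function(edge_cm) {
  s <- edge_cm
  centers <- rbind(c(0, 0), t(vapply(0:5, function(k)
    sqrt(3) * s * c(cos(pi / 6 + k * pi / 3), sin(pi / 6 + k * pi / 3)),
    numeric(2))))
  verts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    t(vapply(0:5, function(j) centers[i, ] + s * c(cos(j * pi / 3), sin(j * pi / 3)),
             numeric(2)))))
  verts <- round(verts, 6)
  verts <- verts[!duplicated(verts), , drop = FALSE]
  stopifnot(nrow(verts) == 24L)
  r <- sqrt(rowSums(verts^2))
  ang <- atan2(verts[, 2], verts[, 1]) %% (2 * pi)
  inner <- which(abs(r - s) < 1e-3)
  outer <- setdiff(seq_len(24L), inner)
  ord <- c(inner[order(ang[inner])], outer[order(ang[outer])])
  coords <- verts[ord, , drop = FALSE]
  dimnames(coords) <- list(NULL, c("x", "y"))
  d <- as.matrix(stats::dist(coords))
  edges <- which(abs(d - s) < 1e-3 & upper.tri(d), arr.ind = TRUE)
  edges <- unname(cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2])))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  list(coords = coords,
       edges = edges,
       ring = rep(c("inner", "outer"), c(6L, 18L)))
}

.normalize_edges <- function(e) {
  if (is.data.frame(e)) e <- as.matrix(e)
  if (is.vector(e) && length(e) == 2L) e <- matrix(e, 1L, 2L)
  if (!is.matrix(e) || ncol(e) != 2L)
    stop("edges must be a two-column matrix of node pairs")
  storage.mode(e) <- "integer"
  .check_nodes(c(e))
  if (any(e[, 1] == e[, 2])) stop("self-loop edge given")
  dimnames(e) <- list(NULL, c("u", "v"))
  e
}

.check_nodes <- function(v) {
  bad <- !(v %in% 1:24)
  if (any(bad)) stop("unknown node(s): ", paste(unique(v[bad]), collapse = ", "))
  invisible(v)
}

.assert_hexmaze_invariants <- function(m) {
  deg <- igraph::degree(m$graph)
  stopifnot(
    igraph::vcount(m$graph) == 24L,
    igraph::ecount(m$graph) == 30L,
    sum(deg == 2L) == 12L, sum(deg == 3L) == 12L,
    all(deg[m$ring == "inner"] == 3L),
    igraph::is_connected(m$graph),
    igraph::bipartite_mapping(m$graph)$res
  )
  invisible(m)
}

# Geodesic counts between all node pairs by BFS order accumulation.
.count_geodesics <- function(adj, dist) {
  n <- length(adj)
  np <- matrix(0, n, n)
  for (s in seq_len(n)) {
    cnt <- numeric(n)
    cnt[s] <- 1
    for (v in order(dist[s, ])[-1L]) {
      pred <- adj[[v]][dist[s, adj[[v]]] == dist[s, v] - 1L]
      cnt[v] <- sum(cnt[pred])
    }
    np[s, ] <- cnt
  }
  np
}

#' @export
print.hexmaze <- function(x, ...) {
  cat("HexMaze graph: ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " gangways", sep = "")
  if (nrow(x$removed_edges))
    cat(" (", nrow(x$removed_edges), " removed by barriers)", sep = "")
  cat("\n  inner ring: nodes ", paste(which(x$ring == "inner"), collapse = ", "),
      "\n  diameter: ", max(x$dist), " edges\n", sep = "")
  invisible(x)
}

#' Plot the HexMaze
#'
#' Draws the maze in its physical planar layout (cm); barrier-removed
#' gangways are dashed.
#'
#' @param x a [build_hexmaze()] object.
#' @param node_labels draw node numbers?
#' @param ... passed to [graphics::plot()].
#' @export
plot.hexmaze <- function(x, node_labels = TRUE, ...) {
  co <- x$coords
  graphics::plot(co, type = "n", asp = 1, xlab = "x (cm)", ylab = "y (cm)", ...)
  apply(x$edges, 1L, function(e)
    graphics::segments(co[e[1], 1], co[e[1], 2], co[e[2], 1], co[e[2], 2], col = "grey40"))
  if (nrow(x$removed_edges))
    apply(x$removed_edges, 1L, function(e)
      graphics::segments(co[e[1], 1], co[e[1], 2], co[e[2], 1], co[e[2], 2],
                         col = "red", lty = 3))
  cols <- ifelse(x$ring == "inner", "tomato", "steelblue")
  graphics::points(co, pch = 21, bg = cols, cex = if (node_labels) 2.2 else 1.2)
  if (node_labels) graphics::text(co, labels = seq_len(24L), cex = 0.6)
  invisible(x)
}

#' Geodesic distance between maze nodes
#'
#' Breadth-first shortest-path length in edges on the (possibly barriered)
#' maze graph. Vectorized over `a` and `b`.
#'
#' @param g a [build_hexmaze()] object.
#' @param a,b node labels in 1..24.
#' @return integer distance(s) in edges.
#' @examples
#' g <- build_hexmaze()
#' graph_distance(g, 1, 1)  # 0
#' graph_distance(g, 1, 7)  # 1
#' @export
graph_distance <- function(g, a, b) {
  stopifnot(inherits(g, "hexmaze"))
  .check_nodes(c(a, b))
  g$dist[cbind(a, b)]
}

#' Exact geodesic node set between two nodes
#'
#' All nodes lying on at least one shortest `start` to `goal` path,
#' enumerated exactly by the bidirectional BFS criterion
#' `d(start, v) + d(v, goal) == d(start, goal)`.
#'
#' @param g a [build_hexmaze()] object.
#' @param start,goal node labels.
#' @return An object of class `"optimal_path_set"`: list with `start`,
#'   `goal`, `nodes` (sorted) and `distance` (edges).
#' @examples
#' g <- build_hexmaze()
#' optimal_path_set_exact(g, 1, 4)$nodes
#' @export
optimal_path_set_exact <- function(g, start, goal) {
  stopifnot(inherits(g, "hexmaze"))
  .check_nodes(c(start, goal))
  d <- g$dist[start, goal]
  nodes <- which(g$dist[start, ] + g$dist[, goal] == d)
  structure(list(start = start, goal = goal, nodes = as.integer(nodes),
                 distance = as.integer(d)),
            class = "optimal_path_set")
}

#' Geodesic node set via noisy edge weights
#'
#' The shortest path is recomputed `n_reps` times on edge weights
#' `1 + Uniform(0, noise_scale)`; in the presence of multiple equal-length
#' geodesics the noise selects one of them at random, and the union of the
#' selected paths converges to the exact geodesic set. Kept as a validation
#' mode for [optimal_path_set_exact()].
#'
#' @inheritParams optimal_path_set_exact
#' @param n_reps number of independent noisy repetitions (>= 1).
#' @param noise_scale upper bound of the uniform noise; must be smaller than
#'   1/(number of edges) so noise can never change which paths are geodesics.
#' @return An `"optimal_path_set"` (see [optimal_path_set_exact()]).
#' @export
optimal_path_set_noisy <- function(g, start, goal, n_reps = 100L,
                                   noise_scale = 1e-3) {
  stopifnot(inherits(g, "hexmaze"), n_reps >= 1L)
  .check_nodes(c(start, goal))
  m <- nrow(g$edges)
  if (noise_scale <= 0 || noise_scale >= 1 / m)
    stop("noise_scale must lie in (0, 1/", m, ") so the geodesic set is preserved")
  nodes <- integer(0)
  for (i in seq_len(n_reps)) {
    w <- 1 + stats::runif(m, 0, noise_scale)
    p <- igraph::shortest_paths(g$graph, from = start, to = goal,
                                weights = w, output = "vpath")$vpath[[1L]]
    nodes <- union(nodes, as.integer(p))
  }
  structure(list(start = start, goal = goal, nodes = sort(as.integer(nodes)),
                 distance = g$dist[start, goal]),
            class = "optimal_path_set")
}

# Per-node distance to the nearest member of the geodesic set of (start, goal):
# length-24 integer vector, the DFOP lookup for that pair.
.dfop_distances <- function(g, start, goal) {
  ops <- optimal_path_set_exact(g, start, goal)
  as.integer(apply(g$dist[, ops$nodes, drop = FALSE], 1L, min))
}

#' Write / read a maze to an edge-list file with JSON sidecar
#'
#' The edge list holds one `"u v"` pair per line; the sidecar stores ring
#' labels, planar coordinates and barrier-removed edges. The loader rebuilds
#' the maze and validates the structural invariants.
#'
#' @param g a [build_hexmaze()] object.
#' @param edge_file path of the edge-list text file.
#' @param meta_file path of the JSON sidecar (default: `edge_file` + ".json").
#' @return `write_maze` returns `g` invisibly; `read_maze` returns a
#'   `"hexmaze"` object.
#' @export
write_maze <- function(g, edge_file, meta_file = paste0(edge_file, ".json")) {
  stopifnot(inherits(g, "hexmaze"))
  writeLines(sprintf("%d %d", g$edges[, 1], g$edges[, 2]), edge_file)
  meta <- list(ring = g$ring, coords = unname(g$coords),
               removed_edges = unname(g$removed_edges), edge_cm = g$edge_cm)
  jsonlite::write_json(meta, meta_file, auto_unbox = TRUE, digits = NA)
  invisible(g)
}

#' @rdname write_maze
#' @export
read_maze <- function(edge_file, meta_file = paste0(edge_file, ".json")) {
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  removed <- if (length(meta$removed_edges)) {
    matrix(as.integer(meta$removed_edges), ncol = 2)
  } else NULL
  g <- build_hexmaze(barrier_edges = removed,
                     edge_cm = if (is.null(meta$edge_cm)) 36.3 else meta$edge_cm)
  ed <- utils::read.table(edge_file, col.names = c("u", "v"))
  key_file <- sort(paste(pmin(ed$u, ed$v), pmax(ed$u, ed$v)))
  key_built <- sort(paste(g$edges[, 1], g$edges[, 2]))
  if (!identical(key_file, key_built))
    stop("edge list in ", edge_file, " does not match the HexMaze topology")
  if (!identical(unname(meta$ring), g$ring))
    stop("ring labels in ", meta_file, " are inconsistent with the maze")
  g
}
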