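# Shared fixture and independent brute-force oracles.

maze <- build_hexmaze()

# Breadth-first distances from s, written independently of the package.
bfs_dist <- function(adj, s) {
  n <- length(adj)
  d <- rep(NA_integer_, n)
  d[s] <- 0L
  queue <- s
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (w in adj[[v]]) if (is.na(d[w])) {
      d[w] <- d[v] + 1L
      queue <- c(queue, w)
    }
  }
  d
}

# Depth-first enumeration of every shortest s -> t path; returns the list of
# paths (node vectors).
enum_geodesics <- function(adj, s, t) {
  dt <- bfs_dist(adj, t)
  paths <- list()
  walk <- function(v, acc) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- acc
      return(invisible())
    }
    for (w in adj[[v]]) if (!is.na(dt[w]) && dt[w] == dt[v] - 1L)
      walk(w, c(acc, w))
  }
  walk(s, s)
  paths
}

# Start-goal specs of a multi-animal cohort: first trials pooled across
# animals, goals counterbalanced (every fourth animal inner ring).
cohort_first_trials <- function(g, n_animals = 25L, sessions = 2L) {
  protos <- lapply(seq_len(n_animals), function(a) generate_protocol(
    g, "build_up", trials_per_session = sessions,
    goal_ring = if (a %% 4L == 0L) "inner" else "outer"))
  do.call(rbind, lapply(protos, function(p) {
    ps <- protocol_specs(p)
    ps[ps$trial == 1L, ]
  }))
}
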