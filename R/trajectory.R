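#' Maze trajectory with trial metadata
#'
#' A trajectory is the ordered sequence of maze nodes visited during one
#' trial, together with the trial metadata used for grouping. Consecutive
#' nodes must be adjacent on the maze; simulator-generated data never
#' reverse (node t+1 differs from node t-1), while real tracking data may
#' — the constructor then warns but does not reject. A completed trial ends
#' at the goal node and does not visit it earlier.
#'
#' @param nodes integer vector of visited nodes (first entry is the start).
#' @param goal the goal (rewarded) node; defaults to the last node.
#' @param animal_id animal label.
#' @param condition one of `"build_up"`, `"location_update"`,
#'   `"barrier_update"`.
#' @param session session number (1..3 in the experimental protocol).
#' @param trial 1-based trial index within the session.
#' @param completed did the trial end at the goal? Defaults to
#'   `nodes[length(nodes)] == goal`.
#' @param graph optional [build_hexmaze()] object; when given, adjacency and
#'   reversal checks are run against it.
#' @return An object of class `"trajectory"`.
#' @examples
#' g <- build_hexmaze()
#' t <- trajectory(c(1, 7, 8, 9, 2), goal = 2, graph = g)
#' @export
trajectory <- function(nodes, goal = nodes[length(nodes)], animal_id = "a1",
                       condition = "build_up", session = 1L, trial = 1L,
                       completed = NULL, graph = NULL) {
  nodes <- as.integer(nodes)
  if (length(nodes) < 1L) stop("trajectory must visit at least one node")
  .check_nodes(c(nodes, goal))
  condition <- match.arg(condition,
                         c("build_up", "location_update", "barrier_update"))
  if (is.null(completed)) completed <- nodes[length(nodes)] == goal
  if (!is.null(graph)) .validate_steps(nodes, graph)
  if (completed) {
    hit <- which(nodes == goal)
    if (!length(hit) || hit[1L] != length(nodes))
      stop("completed trajectory must end at the goal and not visit it earlier")
  }
  structure(list(nodes = nodes, goal = as.integer(goal),
                 animal_id = as.character(animal_id), condition = condition,
                 session = as.integer(session), trial = as.integer(trial),
                 completed = isTRUE(completed)),
            class = "trajectory")
}

.validate_steps <- function(nodes, graph, where = "trajectory") {
  if (length(nodes) >= 2L) {
    a <- nodes[-length(nodes)]
    b <- nodes[-1L]
    bad <- which(graph$dist[cbind(a, b)] != 1L)
    if (length(bad))
      stop(where, ": non-adjacent consecutive nodes at step(s) ",
           paste(bad, collapse = ", "), " (", paste0(a[bad], "->", b[bad],
           collapse = ", "), ")")
  }
  if (length(nodes) >= 3L &&
      any(nodes[-(1:2)] == nodes[seq_len(length(nodes) - 2L)]))
    warning(where, ": immediate reversal present (allowed for real data)")
  invisible(nodes)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory [%s %s s%d t%d] goal %d, %d steps, %s\n",
              x$animal_id, x$condition, x$session, x$trial, x$goal,
              length(x$nodes) - 1L,
              if (x$completed) "completed" else "censored"))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(animal_id = x$animal_id, condition = x$condition,
             session = x$session, trial = x$trial,
             step = seq_along(x$nodes) - 1L, node = x$nodes, goal = x$goal,
             stringsAsFactors = FALSE)
}

#' Trial-bin label used throughout the analysis
#'
#' Within each session, statistics are computed for the first trial alone
#' and then for trials in groups of ten up to trial 31: bins `"first"`
#' (trial 1), `"t2_11"`, `"t12_21"`, `"t22_31"`. Trials beyond 31 are
#' excluded (`NA`).
#'
#' @param trial integer trial index (1-based), vectorized.
#' @return factor with levels `first`, `t2_11`, `t12_21`, `t22_31`.
#' @examples
#' trial_bin(c(1, 2, 11, 12, 31, 32))
#' @export
trial_bin <- function(trial) {
  lev <- c("first", "t2_11", "t12_21", "t22_31")
  idx <- findInterval(trial, c(1L, 2L, 12L, 22L, 32L))
  idx[trial < 1L | trial > 31L] <- NA_integer_
  factor(lev[idx], levels = lev)
}

#' Read / write trajectory datasets as CSV
#'
#' The CSV dialect has one row per visited node with mandatory header
#' `animal_id, condition, session, trial, step, node` (steps 0-based) and an
#' optional `goal` column (constant per trial; when absent the goal is taken
#' to be the last node of each trial). `write_trajectories` always writes
#' the `goal` column so censored trials round-trip losslessly. The reader
#' validates node labels and, when a maze is supplied, step adjacency,
#' reporting offending file rows by number.
#'
#' @param path CSV file path.
#' @param graph optional [build_hexmaze()] object used for validation.
#' @return `read_trajectories` returns a list of [trajectory()] objects
#'   (class `"trajectory_set"`); `write_trajectories` returns `path`
#'   invisibly.
#' @export
read_trajectories <- function(path, graph = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "condition", "session", "trial", "step", "node")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed trajectory CSV: missing column(s) ", paste(miss, collapse = ", "))
  if (!nrow(df)) {
    warning("empty trajectory file: ", path)
    return(structure(list(), class = "trajectory_set"))
  }
  if (anyNA(df[need])) {
    bad <- which(rowSums(is.na(df[need])) > 0) + 1L
    stop("malformed rows (missing values) at file line(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  bad_node <- which(!(df$node %in% 1:24))
  if (length(bad_node))
    stop("unknown node label at file line(s): ",
         paste(utils::head(bad_node + 1L, 10L), collapse = ", "))
  key <- paste(df$animal_id, df$condition, df$session, df$trial, sep = "\r")
  rows <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  out <- lapply(rows, function(idx) {
    idx <- idx[order(df$step[idx])]
    nodes <- df$node[idx]
    if (!is.null(graph)) {
      a <- nodes[-length(nodes)]
      b <- nodes[-1L]
      bad <- which(graph$dist[cbind(a, b)] != 1L)
      if (length(bad)) # report the row where the non-adjacent arrival lands
        stop("non-adjacent consecutive nodes at file line(s) ",
             paste(idx[bad + 1L] + 1L, collapse = ", "), " (",
             paste0(a[bad], "->", b[bad], collapse = ", "), ")")
      if (length(nodes) >= 3L &&
          any(nodes[-(1:2)] == nodes[seq_len(length(nodes) - 2L)]))
        warning("immediate reversal in trial starting at file line ",
                idx[1L] + 1L, " (allowed for real data)")
    }
    goal <- if ("goal" %in% names(df)) df$goal[idx[1L]] else nodes[length(nodes)]
    trajectory(nodes, goal = goal, animal_id = df$animal_id[idx[1L]],
               condition = df$condition[idx[1L]], session = df$session[idx[1L]],
               trial = df$trial[idx[1L]])
  })
  structure(unname(out), class = "trajectory_set")
}

#' @param trials a list of [trajectory()] objects.
#' @rdname read_trajectories
#' @export
write_trajectories <- function(trials, path) {
  stopifnot(length(trials) > 0L)
  df <- do.call(rbind, lapply(trials, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("trajectory set:", length(x), "trials\n")
  if (length(x)) {
    tab <- table(condition = vapply(x, `[[`, "", "condition"),
                 session = vapply(x, `[[`, 0L, "session"))
    print(tab)
  }
  invisible(x)
}

#' @export
as.data.frame.trajectory_set <- function(x, ...) {
  do.call(rbind, lapply(x, as.data.frame))
}
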