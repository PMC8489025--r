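#' Relative trial length and companion trial metrics
#'
#' The relative trial length (RTL) is the length of the path taken by the
#' animal divided by the length of the shortest start-to-goal path. Length
#' is counted in edges traversed (so a geodesic trial scores exactly
#' RTL = 1 and log10 RTL = 0). The same pass also returns the maximal
#' distance from the optimal path (max DFOP), the fraction of node visits
#' on the outer ring, and the raw step count.
#'
#' Only the prefix up to the first goal arrival is scored.
#'
#' @param t a [trajectory()]; must be completed.
#' @param g a [build_hexmaze()] object.
#' @return An object of class `"trial_metrics"`: list with `rtl`,
#'   `log_rtl` (log10), `max_dfop` (edges), `outer_fraction`, `path_steps`
#'   and `distance` (shortest-path length).
#' @examples
#' g <- build_hexmaze()
#' relative_trial_length(trajectory(c(1, 7, 8, 9, 2), graph = g), g)$rtl
#' @export
relative_trial_length <- function(t, g) {
  stopifnot(inherits(t, "trajectory"), inherits(g, "hexmaze"))
  start <- t$nodes[1L]
  if (start == t$goal)
    stop("degenerate trial: start equals goal, RTL undefined")
  if (!t$completed)
    stop("incomplete (censored) trajectory: RTL undefined outside surrogate mode")
  pos <- match(t$goal, t$nodes)
  prefix <- t$nodes[seq_len(pos)]
  d <- g$dist[start, t$goal]
  steps <- pos - 1L
  series <- .dfop_distances(g, start, t$goal)[prefix]
  structure(list(rtl = steps / d, log_rtl = log10(steps / d),
                 max_dfop = max(series),
                 outer_fraction = mean(g$ring[prefix] == "outer"),
                 path_steps = steps, distance = as.integer(d)),
            class = "trial_metrics")
}

#' @export
print.trial_metrics <- function(x, ...) {
  cat(sprintf("RTL %.3f (log10 %.3f), %d steps / distance %d, max DFOP %d, outer %.2f\n",
              x$rtl, x$log_rtl, x$path_steps, x$distance, x$max_dfop,
              x$outer_fraction))
  invisible(x)
}

#' Per-trial metrics table for a dataset
#'
#' Applies [relative_trial_length()] to every completed trial and binds the
#' results with the trial metadata and [trial_bin()] label. Censored trials
#' are dropped (with a message giving the count).
#'
#' @param trials list of [trajectory()] objects.
#' @param g a [build_hexmaze()] object.
#' @return a data.frame, one row per completed trial.
#' @export
metrics_table <- function(trials, g) {
  cens <- !vapply(trials, `[[`, TRUE, "completed")
  if (any(cens)) {
    message(sum(cens), " censored trial(s) excluded from metrics")
    trials <- trials[!cens]
  }
  stopifnot(length(trials) > 0L)
  rows <- lapply(trials, function(t) {
    m <- relative_trial_length(t, g)
    data.frame(animal_id = t$animal_id, condition = t$condition,
               session = t$session, trial = t$trial,
               bin = as.character(trial_bin(t$trial)),
               start = t$nodes[1L], goal = t$goal, distance = m$distance,
               path_steps = m$path_steps, rtl = m$rtl, log_rtl = m$log_rtl,
               max_dfop = m$max_dfop, outer_fraction = m$outer_fraction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Distance-from-optimal-path series of a trajectory
#'
#' For each visited node, the graph distance to the nearest node belonging
#' to any shortest start-to-goal path (the exact geodesic set of
#' [optimal_path_set_exact()]). The first entry is always 0 (the start lies
#' on the optimal path) and, for completed trials, so is the last.
#'
#' @inheritParams relative_trial_length
#' @return integer vector, one entry per visited node.
#' @export
dfop_series <- function(t, g) {
  stopifnot(inherits(t, "trajectory"), inherits(g, "hexmaze"))
  .dfop_distances(g, t$nodes[1L], t$goal)[t$nodes]
}

#' Average DFOP profile of a trial group
#'
#' Per-step mean, SD and trial count of the DFOP series across a group of
#' trials, the "bump" profile whose rise and decay summarize how far and
#' for how long trajectories stray from the optimal path. With
#' `pad = TRUE` (default) completed trials contribute DFOP 0 after goal
#' arrival up to the horizon: the goal lies on the optimal path, so the
#' distance-0 continuation is the natural extension.
#'
#' @param trials nonempty list of [trajectory()] objects (one trial group).
#' @param g a [build_hexmaze()] object.
#' @param horizon last step index `H` of the profile; default is the 95th
#'   percentile of the group's trial step counts.
#' @param pad zero-pad completed trials after goal arrival?
#' @return class `"dfop_profile"`: a data.frame with columns `step`
#'   (0..H), `mean`, `sd`, `n`.
#' @export
dfop_profile <- function(trials, g, horizon = NULL, pad = TRUE) {
  if (!length(trials)) stop("empty trial group")
  series <- lapply(trials, dfop_series, g = g)
  steps <- vapply(series, length, 0L) - 1L
  if (is.null(horizon))
    horizon <- as.integer(ceiling(stats::quantile(steps, 0.95, names = FALSE)))
  completed <- vapply(trials, `[[`, TRUE, "completed")
  mat <- vapply(seq_along(series), function(i) {
    s <- series[[i]]
    if (length(s) < horizon + 1L) {
      fill <- if (pad && completed[i]) 0L else NA_integer_
      s <- c(s, rep(fill, horizon + 1L - length(s)))
    }
    as.numeric(s[seq_len(horizon + 1L)])
  }, numeric(horizon + 1L))
  mat <- matrix(mat, nrow = horizon + 1L)
  out <- data.frame(step = 0:horizon,
                    mean = rowMeans(mat, na.rm = TRUE),
                    sd = apply(mat, 1L, stats::sd, na.rm = TRUE),
                    n = rowSums(!is.na(mat)))
  structure(out, class = c("dfop_profile", "data.frame"),
            horizon = horizon, pad = pad)
}

#' @export
plot.dfop_profile <- function(x, ...) {
  graphics::plot(x$step, x$mean, type = "l", lwd = 2, col = "steelblue",
                 xlab = "step", ylab = "distance from optimal path (edges)", ...)
  se <- x$sd / sqrt(pmax(x$n, 1L))
  graphics::arrows(x$step, x$mean - se, x$step, x$mean + se, angle = 90,
                   code = 3, length = 0.02, col = "grey60")
  invisible(x)
}

#' Probability of an optimal trial
#'
#' Fraction of completed trials with RTL below `threshold` (default 1.5,
#' the "optimal trial" criterion), with a bootstrap SD.
#'
#' @inheritParams dfop_profile
#' @param threshold RTL cutoff.
#' @param n_boot bootstrap resamples for the SD.
#' @return list with `prob`, `sd`, `n`, `threshold`.
#' @export
optimal_trial_probability <- function(trials, g, threshold = 1.5, n_boot = 50L) {
  rtl <- metrics_table(trials, g)$rtl
  hit <- rtl < threshold
  bs <- vapply(seq_len(n_boot), function(i)
    mean(sample(hit, replace = TRUE)), numeric(1L))
  list(prob = mean(hit), sd = stats::sd(bs), n = length(hit),
       threshold = threshold)
}

#' Goal-location shuffle surrogate
#'
#' Tests the specificity of RTL trends for goal-directed behavior: goal
#' labels are randomly permuted (without replacement) across the trials of
#' a block, and the RTL is recomputed toward the surrogate goal using the
#' sub-trajectory up to its first occurrence. If the surrogate goal is
#' never visited, the trial is assigned a default RTL of 10. If the
#' surrogate goal coincides with the trial's start node the surrogate RTL
#' is undefined and reported as `NA`.
#'
#' @inheritParams dfop_profile
#' @param perm optional explicit permutation of `seq_along(trials)`;
#'   default is a uniformly random permutation.
#' @param rtl_absent RTL assigned when the surrogate goal is not visited.
#' @return data.frame with one row per trial: metadata, `surrogate_goal`,
#'   `rtl`, `log_rtl`.
#' @export
gl_shuffle <- function(trials, g, perm = NULL, rtl_absent = 10) {
  if (length(trials) < 2L) stop("need at least two trials to shuffle goals")
  goals <- vapply(trials, `[[`, 0L, "goal")
  if (is.null(perm)) perm <- sample.int(length(trials))
  stopifnot(length(perm) == length(trials), !anyDuplicated(perm))
  sg <- goals[perm]
  rows <- lapply(seq_along(trials), function(i) {
    t <- trials[[i]]
    start <- t$nodes[1L]
    rtl <- if (sg[i] == start) {
      NA_real_
    } else {
      pos <- match(sg[i], t$nodes)
      if (is.na(pos)) rtl_absent else (pos - 1L) / g$dist[start, sg[i]]
    }
    data.frame(animal_id = t$animal_id, condition = t$condition,
               session = t$session, trial = t$trial, goal = t$goal,
               surrogate_goal = sg[i], rtl = rtl, log_rtl = log10(rtl),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Node-visit counts along a trajectory
#'
#' Number of times each queried node occurs in the visited-node sequence
#' (used e.g. to score crossings of current and previous goal locations).
#'
#' @param t a [trajectory()].
#' @param nodes nodes to count.
#' @return named integer vector of counts.
#' @export
node_crossings <- function(t, nodes) {
  stopifnot(inherits(t, "trajectory"))
  .check_nodes(nodes)
  counts <- vapply(nodes, function(v) sum(t$nodes == v), 0L)
  stats::setNames(counts, nodes)
}

#' Bootstrap mean and SD of a sample
#'
#' Mean and SD of the distribution of resampled means over `n_boot`
#' resamples with replacement; reproducible under [set.seed()].
#'
#' @param values nonempty numeric vector.
#' @param n_boot number of bootstrap resamples.
#' @return list with `mean`, `sd`, `n_boot`.
#' @export
bootstrap_summary <- function(values, n_boot = 50L) {
  if (!length(values)) stop("empty input to bootstrap_summary")
  bs <- vapply(seq_len(n_boot), function(i)
    mean(sample(values, replace = TRUE)), numeric(1L))
  list(mean = mean(bs), sd = stats::sd(bs), n_boot = n_boot)
}
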