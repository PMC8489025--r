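#' Navigation-model parameters
#'
#' The generative navigator has two behavioral parameters: `eta`, the
#' per-step probability of initiating a diagonal run toward a random
#' outer-ring node at distance >= 3 (committing to a shortest path there),
#' and `foresight` (`F`), the mean of the exponential distribution of the
#' distance at which the agent detects the goal and switches to a direct
#' geodesic run. `F = 0` is an agent with no memory of the goal location:
#' it only ends a trial by walking over the goal.
#'
#' @param eta diagonal-run probability per step, in `[0, 1]`.
#' @param foresight mean goal-detection distance in edges, `>= 0`.
#' @param max_steps censoring cap on the number of steps (must exceed the
#'   maze diameter).
#' @return class `"sim_params"` list.
#' @examples
#' sim_params(eta = 0.02, foresight = 1.5)
#' @export
sim_params <- function(eta = 0, foresight = 0, max_steps = 5000L) {
  if (length(eta) != 1L || eta < 0 || eta > 1)
    stop("eta must be a probability in [0, 1]")
  if (length(foresight) != 1L || foresight < 0)
    stop("foresight must be non-negative")
  if (max_steps < 10L)
    stop("max_steps must exceed the maze diameter")
  structure(list(eta = eta, foresight = foresight,
                 max_steps = as.integer(max_steps)),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("navigator parameters: eta = %g, foresight F = %g, max_steps = %d\n",
              x$eta, x$foresight, x$max_steps))
  invisible(x)
}

#' Exponential-foresight goal detection
#'
#' At distance `d` from the goal, a draw `x ~ Exponential(mean = F)` is
#' taken and the goal is detected when `d < x`, so the detection
#' probability is `exp(-d / F)`. With `F = 0` detection never occurs at
#' positive distance.
#'
#' @param d distance(s) to the goal in edges, `>= 0`.
#' @param foresight the mean detection distance `F >= 0`.
#' @return logical vector: was a direct goal run triggered?
#' @examples
#' set.seed(1); mean(foresight_triggered(rep(2, 1000), 2))  # ~ exp(-1)
#' @export
foresight_triggered <- function(d, foresight) {
  if (any(d < 0)) stop("distances must be non-negative")
  if (length(foresight) != 1L || foresight < 0)
    stop("foresight must be non-negative")
  if (foresight == 0) return(rep(FALSE, length(d)))
  d < stats::rexp(length(d), rate = 1 / foresight)
}

#' Simulate one navigation trial
#'
#' At every step the virtual mouse moves to an adjacent node; immediate
#' reversals are not allowed (the previous node is excluded from the
#' choice, except that all neighbors are available at the start). On every
#' node arrival (including the start and during diagonal runs) the
#' foresight check runs first; if triggered, the agent appends a geodesic
#' to the goal (sampled uniformly among all geodesics) and the trial ends.
#' The no-reversal rule also binds goal runs and diagonal runs: a run whose
#' only shortest path would immediately re-enter the previous node is not
#' started at that step (the trigger can fire again on later arrivals).
#' Otherwise, in search mode a diagonal run is initiated with probability
#' `eta`; in run mode the stored geodesic is followed, and search resumes
#' at the target. The trial ends when the goal is first reached, or is
#' censored at `max_steps`.
#'
#' @param g a [build_hexmaze()] object.
#' @param start,goal distinct maze nodes.
#' @param params a [sim_params()] object.
#' @param ... metadata passed to [trajectory()] (`animal_id`, `condition`,
#'   `session`, `trial`).
#' @return a [trajectory()]; `$completed` is `FALSE` for censored runs.
#' @examples
#' g <- build_hexmaze()
#' set.seed(7)
#' simulate_trial(g, 1, 13, sim_params(foresight = 100))  # direct geodesic
#' @export
simulate_trial <- function(g, start, goal, params = sim_params(), ...) {
  stopifnot(inherits(g, "hexmaze"), inherits(params, "sim_params"))
  .check_nodes(c(start, goal))
  if (start == goal) stop("degenerate trial: start equals goal")
  res <- sim_trial_cpp(g$adj, g$dist, g$npaths, g$ring == "outer",
                       start, goal, params$eta, params$foresight,
                       params$max_steps)
  trajectory(as.integer(res), goal = goal,
             completed = attr(res, "completed"), ...)
}

#' Simulate a dataset of navigation trials
#'
#' Runs `n_reps` independent simulations for every start--goal spec (the
#' augmentation used when comparing model and experiment: each experimental
#' trial contributes `n_reps` simulated runs).
#'
#' @param g a [build_hexmaze()] object.
#' @param trial_specs data.frame with columns `start` and `goal` (optional
#'   `animal_id`, `condition`, `session`, `trial` are propagated).
#' @param params a [sim_params()] object.
#' @param n_reps simulated runs per spec.
#' @return list of [trajectory()] objects (class `"trajectory_set"`),
#'   of length `nrow(trial_specs) * n_reps`.
#' @export
simulate_dataset <- function(g, trial_specs, params = sim_params(),
                             n_reps = 50L) {
  stopifnot(inherits(g, "hexmaze"), inherits(params, "sim_params"),
            nrow(trial_specs) > 0L)
  .check_nodes(c(trial_specs$start, trial_specs$goal))
  if (any(trial_specs$start == trial_specs$goal))
    stop("degenerate trial spec: start equals goal")
  res <- sim_dataset_cpp(g$adj, g$dist, g$npaths, g$ring == "outer",
                         as.integer(trial_specs$start),
                         as.integer(trial_specs$goal),
                         as.integer(n_reps), params$eta, params$foresight,
                         params$max_steps)
  meta <- function(col, default) {
    if (col %in% names(trial_specs)) trial_specs[[col]] else default
  }
  an <- meta("animal_id", "sim")
  cond <- meta("condition", "build_up")
  sess <- meta("session", 1L)
  tri <- meta("trial", seq_len(nrow(trial_specs)))
  out <- lapply(seq_along(res$nodes), function(k) {
    i <- res$spec[k]
    r <- k - (i - 1L) * n_reps
    id <- rep(an, length.out = nrow(trial_specs))[i]
    if (n_reps > 1L) id <- sprintf("%s_r%02d", id, r) # keep rep trials distinct
    trajectory(res$nodes[[k]], goal = trial_specs$goal[i],
               completed = res$completed[k],
               animal_id = id,
               condition = rep(cond, length.out = nrow(trial_specs))[i],
               session = rep(sess, length.out = nrow(trial_specs))[i],
               trial = rep(tri, length.out = nrow(trial_specs))[i])
  })
  structure(out, class = "trajectory_set")
}
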