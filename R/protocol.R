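#' Generate an experiment-shaped trial protocol
#'
#' Produces goal and start locations for one animal and one condition
#' (three sessions, up to 31 analyzed trials each) under the behavioral
#' training constraints: start locations do not repeat in subsequent
#' trials; start locations are at least two choice points away from each
#' other and from the goal; at least 60% of trials in a session admit a
#' single shortest path; and the first start of a session differs from the
#' first and last starts of the previous session. Goals are placed on the
#' inner ring with probability 1/4 (the counterbalancing used across
#' animals), on the outer ring otherwise. For the `barrier_update`
#' condition 1--3 gangways are removed such that the maze stays connected
#' and the goal's geodesic set changes from at least half of the eligible
#' start nodes.
#'
#' Generation is by rejection sampling (deterministic under [set.seed()]),
#' with a bounded number of attempts per session.
#'
#' @param g a barrier-free [build_hexmaze()] object.
#' @param condition `"build_up"`, `"location_update"` or `"barrier_update"`.
#' @param n_sessions sessions in the condition.
#' @param trials_per_session trials per session (<= 31 are analyzed).
#' @param goal optional fixed goal node; default: sampled by ring.
#' @param goal_ring optionally force `"inner"` or `"outer"` goal placement.
#' @param n_barriers number of removed gangways for `barrier_update`
#'   (default: drawn from 1--3).
#' @param max_attempts rejection-sampling cap per session.
#' @return class `"protocol"`: list with `condition`, `goal`, `barriers`
#'   and `sessions` (per session: `goal`, `starts`, `barriers`).
#' @examples
#' g <- build_hexmaze()
#' set.seed(11)
#' p <- generate_protocol(g, "build_up")
#' validate_protocol(p, g)
#' @export
generate_protocol <- function(g, condition = c("build_up", "location_update",
                                               "barrier_update"),
                              n_sessions = 3L, trials_per_session = 31L,
                              goal = NULL, goal_ring = NULL, n_barriers = NULL,
                              max_attempts = 1e4L) {
  stopifnot(inherits(g, "hexmaze"), nrow(g$removed_edges) == 0L)
  condition <- match.arg(condition)
  if (is.null(goal)) {
    if (is.null(goal_ring))
      goal_ring <- if (stats::runif(1) < 0.25) "inner" else "outer"
    goal <- sample(which(g$ring == goal_ring), 1L)
  } else {
    .check_nodes(goal)
    goal_ring <- g$ring[goal]
  }
  barriers <- NULL
  eff <- g
  if (condition == "barrier_update") {
    barriers <- .sample_barriers(g, goal, n_barriers, max_attempts)
    eff <- build_hexmaze(barrier_edges = barriers, edge_cm = g$edge_cm)
  }
  eligible <- which(eff$dist[, goal] >= 2L)
  sessions <- vector("list", n_sessions)
  prev_first <- prev_last <- NA_integer_
  for (s in seq_len(n_sessions)) {
    starts <- NULL
    for (attempt in seq_len(max_attempts)) {
      cand <- .sample_session_starts(eff, goal, eligible, trials_per_session,
                                     prev_first, prev_last)
      if (is.null(cand)) next
      if (mean(eff$npaths[cbind(cand, goal)] == 1) >= 0.6) { starts <- cand; break }
    }
    if (is.null(starts))
      stop("protocol generation failed for session ", s, " after ",
           max_attempts, " attempts (constraints unsatisfiable with goal ",
           goal, ")")
    sessions[[s]] <- list(goal = goal, starts = starts, barriers = barriers)
    prev_first <- starts[1L]
    prev_last <- starts[length(starts)]
  }
  structure(list(condition = condition, goal = goal, goal_ring = goal_ring,
                 barriers = barriers, sessions = sessions,
                 trials_per_session = as.integer(trials_per_session)),
            class = "protocol")
}

# One candidate start sequence; NULL if the sequential draw dead-ends.
.sample_session_starts <- function(eff, goal, eligible, n, prev_first,
                                   prev_last) {
  starts <- integer(n)
  for (t in seq_len(n)) {
    pool <- eligible
    if (t == 1L) {
      pool <- setdiff(pool, c(prev_first, prev_last))
    } else {
      pool <- pool[eff$dist[pool, starts[t - 1L]] >= 2L]
    }
    if (!length(pool)) return(NULL)
    starts[t] <- pool[sample.int(length(pool), 1L)]
  }
  starts
}

.sample_barriers <- function(g, goal, n_barriers, max_attempts) {
  eligible <- which(g$dist[, goal] >= 2L)
  base_sets <- lapply(eligible, function(s) optimal_path_set_exact(g, s, goal)$nodes)
  for (attempt in seq_len(max_attempts)) {
    k <- if (is.null(n_barriers)) sample(1:3, 1L) else as.integer(n_barriers)
    idx <- sample.int(nrow(g$edges), k)
    cand <- g$edges[idx, , drop = FALSE]
    eff <- tryCatch(build_hexmaze(barrier_edges = cand, edge_cm = g$edge_cm),
                    error = function(e) NULL)
    if (is.null(eff)) next
    if (any(eff$dist[eligible, goal] < 2L)) next # keep all starts eligible
    changed <- vapply(seq_along(eligible), function(i)
      !identical(optimal_path_set_exact(eff, eligible[i], goal)$nodes,
                 base_sets[[i]]), logical(1L))
    if (mean(changed) >= 0.5) return(cand)
  }
  stop("no barrier set satisfying the constraints found in ", max_attempts,
       " attempts")
}

#' Check a protocol against the training constraints
#'
#' Verifies every invariant of [generate_protocol()]; errors with the list
#' of violations if any fails.
#'
#' @param p a [generate_protocol()] object.
#' @param g the barrier-free maze it was generated on.
#' @return `TRUE` invisibly.
#' @export
validate_protocol <- function(p, g) {
  stopifnot(inherits(p, "protocol"), inherits(g, "hexmaze"))
  eff <- if (is.null(p$barriers)) g else
    build_hexmaze(barrier_edges = p$barriers, edge_cm = g$edge_cm)
  bad <- character(0)
  prev_first <- prev_last <- NA_integer_
  for (s in seq_along(p$sessions)) {
    se <- p$sessions[[s]]
    st <- se$starts
    if (any(st == se$goal))
      bad <- c(bad, sprintf("session %d: start equals goal", s))
    if (any(eff$dist[cbind(st, se$goal)] < 2L))
      bad <- c(bad, sprintf("session %d: start closer than 2 choice points to goal", s))
    if (length(st) > 1L) {
      dd <- eff$dist[cbind(st[-length(st)], st[-1L])]
      if (any(dd < 2L))
        bad <- c(bad, sprintf("session %d: consecutive starts closer than 2", s))
    }
    if (mean(eff$npaths[cbind(st, se$goal)] == 1) < 0.6)
      bad <- c(bad, sprintf("session %d: fewer than 60%% unique-geodesic trials", s))
    if (!is.na(prev_first) && st[1L] %in% c(prev_first, prev_last))
      bad <- c(bad, sprintf("session %d: first start repeats previous session's first/last", s))
    prev_first <- st[1L]
    prev_last <- st[length(st)]
  }
  if (length(bad)) stop("protocol violates constraints:\n  ",
                        paste(bad, collapse = "\n  "))
  invisible(TRUE)
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("%s protocol: goal %d (%s ring), %d sessions x %d trials",
              x$condition, x$goal, x$goal_ring, length(x$sessions),
              x$trials_per_session))
  if (!is.null(x$barriers))
    cat(", barriers: ", paste(sprintf("%d-%d", x$barriers[, 1],
                                      x$barriers[, 2]), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Trial specs of a protocol as a data.frame
#'
#' @param p a [generate_protocol()] object.
#' @return data.frame with `condition`, `session`, `trial`, `bin`, `start`,
#'   `goal`.
#' @export
protocol_specs <- function(p) {
  stopifnot(inherits(p, "protocol"))
  do.call(rbind, lapply(seq_along(p$sessions), function(s) {
    se <- p$sessions[[s]]
    data.frame(condition = p$condition, session = s,
               trial = seq_along(se$starts),
               bin = as.character(trial_bin(seq_along(se$starts))),
               start = se$starts, goal = se$goal, stringsAsFactors = FALSE)
  }))
}

#' Ground-truth parameter schedule per trial bin
#'
#' Encodes the `(eta, F)` values driving the generative navigator in each
#' (session, bin) cell of a condition, the "learning scenario" used for
#' parameter-recovery experiments.
#'
#' @param condition condition label.
#' @param F_by_bin foresight values: a length-4 vector (applied to every
#'   session, bins `first`, `t2_11`, `t12_21`, `t22_31`) or an
#'   `n_sessions x 4` matrix.
#' @param eta_by_bin diagonal-run probabilities, recycled the same way.
#' @param n_sessions number of sessions.
#' @return data.frame with `condition`, `session`, `bin`, `eta`, `foresight`.
#' @examples
#' ground_truth_schedule("build_up", F_by_bin = c(0, 0.5, 1, 1.5))
#' @export
ground_truth_schedule <- function(condition = "build_up",
                                  F_by_bin = c(0, 0.5, 1, 1.5),
                                  eta_by_bin = 0, n_sessions = 3L) {
  bins <- levels(trial_bin(1L))
  Fm <- if (is.matrix(F_by_bin)) F_by_bin else
    matrix(F_by_bin, n_sessions, 4L, byrow = TRUE)
  Em <- if (is.matrix(eta_by_bin)) eta_by_bin else
    matrix(eta_by_bin, n_sessions, 4L, byrow = TRUE)
  stopifnot(nrow(Fm) == n_sessions, ncol(Fm) == 4L,
            all(Fm >= 0), all(Em >= 0 & Em <= 1))
  data.frame(condition = condition,
             session = rep(seq_len(n_sessions), each = 4L),
             bin = rep(bins, n_sessions),
             eta = as.vector(t(Em)), foresight = as.vector(t(Fm)),
             stringsAsFactors = FALSE)
}

#' A build-up-like learning schedule
#'
#' Foresight rising within and across sessions while staying at or below 2
#' (the range observed for fitted animal behavior), with `eta = 0`
#' throughout: the scenario used to emulate build-up learning.
#'
#' @param condition condition label.
#' @return a [ground_truth_schedule()] data.frame.
#' @export
learning_schedule <- function(condition = "build_up") {
  ground_truth_schedule(condition,
                        F_by_bin = rbind(c(0, 0.5, 1.0, 1.25),
                                         c(0.75, 1.25, 1.5, 1.75),
                                         c(1.0, 1.5, 1.75, 2.0)))
}

#' Generate a ground-truth trajectory dataset
#'
#' Simulates every trial of one or more protocols with the navigator at the
#' `(eta, F)` of the trial's (condition, session, bin) cell in the
#' schedule, labeling trajectories with the full trial metadata. When a
#' single protocol is given and `n_animals > 1`, additional protocols are
#' generated with goals counterbalanced so every fourth animal has an
#' inner-ring goal.
#'
#' @param g a barrier-free [build_hexmaze()] object.
#' @param protocol a [generate_protocol()] object, or a list of them (one
#'   per animal).
#' @param schedule a [ground_truth_schedule()] covering all (session, bin)
#'   cells of the protocol condition.
#' @param n_animals number of animals.
#' @param max_steps censoring cap per simulated trial.
#' @return list with `trials` (a `"trajectory_set"`), `truth` (the
#'   schedule) and `protocols`.
#' @examples
#' g <- build_hexmaze()
#' set.seed(3)
#' p <- generate_protocol(g, "build_up", trials_per_session = 5)
#' d <- generate_dataset(g, p, ground_truth_schedule(), n_animals = 2)
#' length(d$trials)
#' @export
generate_dataset <- function(g, protocol, schedule, n_animals = 1L,
                             max_steps = 5000L) {
  stopifnot(inherits(g, "hexmaze"))
  protos <- if (inherits(protocol, "protocol")) list(protocol) else protocol
  stopifnot(all(vapply(protos, inherits, TRUE, "protocol")))
  while (length(protos) < n_animals) {
    k <- length(protos) + 1L
    protos[[k]] <- generate_protocol(
      g, protos[[1L]]$condition,
      trials_per_session = protos[[1L]]$trials_per_session,
      goal_ring = if (k %% 4L == 0L) "inner" else "outer")
  }
  trials <- list()
  for (a in seq_len(n_animals)) {
    p <- protos[[a]]
    eff <- if (is.null(p$barriers)) g else
      build_hexmaze(barrier_edges = p$barriers, edge_cm = g$edge_cm)
    spec <- protocol_specs(p)
    for (i in seq_len(nrow(spec))) {
      cell <- schedule[schedule$condition == spec$condition[i] &
                         schedule$session == spec$session[i] &
                         schedule$bin == spec$bin[i], , drop = FALSE]
      if (nrow(cell) != 1L)
        stop("schedule does not cover (", spec$condition[i], ", session ",
             spec$session[i], ", bin ", spec$bin[i], ")")
      trials[[length(trials) + 1L]] <- simulate_trial(
        eff, spec$start[i], spec$goal[i],
        sim_params(eta = cell$eta, foresight = cell$foresight,
                   max_steps = max_steps),
        animal_id = sprintf("sim%02d", a), condition = spec$condition[i],
        session = spec$session[i], trial = spec$trial[i])
    }
  }
  list(trials = structure(trials, class = "trajectory_set"),
       truth = schedule, protocols = protos)
}
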