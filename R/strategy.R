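#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Sup-norm distance between the empirical CDFs of two samples with the
#' asymptotic p-value, the distance measure used both as fitting objective
#' and as effect size. Significance claims require the sample-size ratio
#' `n*m/(n+m) >= 50`.
#'
#' @param x,y nonempty numeric samples.
#' @return list with `statistic` (the KS D), `p_value`, and `n_eff`
#'   (`n*m/(n+m)`).
#' @examples
#' ks_two_sample(1:3, 2:4)$statistic
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample in KS comparison")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  n <- as.numeric(length(x))
  m <- as.numeric(length(y))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n_eff = n * m / (n + m))
}

# KS D for presorted samples: ECDFs compared at every sample point.
.ks_D_sorted <- function(xs, ys) {
  v <- c(xs, ys)
  max(abs(findInterval(v, xs) / length(xs) - findInterval(v, ys) / length(ys)))
}

#' Fit the navigation model to observed trials by KS-distance minimization
#'
#' For every `(eta, F)` pair on the grid, `n_reps` trials are simulated for
#' each observed trial's start--goal pair and the two-sample KS distance
#' between simulated and observed RTL distributions is computed; the
#' best-fitting pair minimizes this distance. Because the KS surface is
#' evaluated by Monte Carlo and is nearly flat along `eta` (diagonal runs
#' change the RTL distribution only weakly), the minimizer is selected by a
#' parsimony rule rather than a raw argmin: with the tolerance
#' `0.5 * sqrt(1/n_obs + 1/n_sim)` (about two asymptotic SDs of the
#' two-sample KS statistic), the smallest `F` whose profile minimum over
#' `eta` lies within the tolerance of the grid minimum is chosen first, and
#' then the smallest `eta` within the tolerance of that profile minimum.
#' This resolves exact and statistical ties toward the simpler strategy and
#' keeps the weakly identified `eta` from wandering along the flat axis of
#' the objective. The same simulated runs also give KS surfaces
#' for the two held-out validation statistics, maximal DFOP and
#' outer-ring fraction; at the best pair the model is re-simulated and the
#' validation statistics are compared with p-values.
#'
#' With `n_boot > 0` the observed trial set is resampled with replacement
#' and the KS surface re-evaluated (against the same simulated samples) to
#' give a bootstrap distribution of the best-fit parameters.
#'
#' @param observed list of completed [trajectory()] objects sharing a trial
#'   group, or a [metrics_table()] data.frame.
#' @param g a [build_hexmaze()] object.
#' @param grid_eta,grid_F parameter grids searched.
#' @param n_reps simulated runs per observed trial and grid point.
#' @param max_steps censoring cap per simulated run.
#' @param n_boot bootstrap resamples of the observed trials (0 = none).
#' @return class `"strategy_fit"`: list with the KS `grid` (one row per
#'   `(eta, F)` with `ks_rtl`, `ks_maxdfop`, `ks_ring`), the `best` pair,
#'   `p_value` and `effect_size` (RTL KS at the best pair, re-simulated),
#'   `validation` (held-out KS tests), `n_obs`, `n_eff`, and `boot`
#'   (bootstrap best-fit parameters, if requested).
#' @examples
#' \dontrun{
#' g <- build_hexmaze()
#' obs <- simulate_dataset(g, data.frame(start = 1:5 * 2, goal = 15),
#'                         sim_params(foresight = 1), n_reps = 20)
#' fit <- fit_strategy(obs, g, grid_F = seq(0, 2, 0.5))
#' coef(fit)
#' }
#' @export
fit_strategy <- function(observed, g, grid_eta = seq(0, 0.20, by = 0.02),
                         grid_F = seq(0, 4, by = 0.1), n_reps = 50L,
                         max_steps = 5000L, n_boot = 0L) {
  stopifnot(inherits(g, "hexmaze"), length(grid_eta) > 0L, length(grid_F) > 0L)
  mt <- if (is.data.frame(observed)) observed else metrics_table(observed, g)
  n_obs <- nrow(mt)
  if (n_obs < 2L) stop("need at least two observed trials")

  key <- paste(mt$start, mt$goal)
  pairs <- mt[!duplicated(key), c("start", "goal")]
  mult <- as.integer(table(factor(key, levels = unique(key))))
  dfop <- lapply(seq_len(nrow(pairs)), function(i)
    as.numeric(.dfop_distances(g, pairs$start[i], pairs$goal[i])))

  grid <- expand.grid(eta = sort(unique(grid_eta)), F = sort(unique(grid_F)),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$F, grid$eta), , drop = FALSE]
  rownames(grid) <- NULL

  obs <- list(rtl = sort(mt$rtl), max_dfop = sort(mt$max_dfop),
              ring = sort(mt$outer_fraction))
  boot_sorted <- if (n_boot > 0L) {
    lapply(seq_len(n_boot), function(b)
      sort(mt$rtl[sample.int(n_obs, replace = TRUE)]))
  } else NULL

  np <- nrow(grid)
  ks_rtl <- ks_mx <- ks_rg <- cens <- nsim <- numeric(np)
  boot_D <- if (n_boot > 0L) matrix(NA_real_, np, n_boot) else NULL
  outer_ring <- g$ring == "outer"
  for (i in seq_len(np)) {
    st <- sim_stats_cpp(g$adj, g$dist, g$npaths, outer_ring,
                        as.integer(pairs$start), as.integer(pairs$goal),
                        mult * as.integer(n_reps), dfop,
                        grid$eta[i], grid$F[i], as.integer(max_steps))
    comp <- st[, "completed"] == 1
    cens[i] <- sum(!comp)
    nsim[i] <- sum(comp)
    if (nsim[i] < n_obs) { # censoring-dominated grid point: no usable KS
      ks_rtl[i] <- ks_mx[i] <- ks_rg[i] <- NA_real_
      next
    }
    rtl_s <- sort(st[comp, "rtl"])
    ks_rtl[i] <- .ks_D_sorted(obs$rtl, rtl_s)
    ks_mx[i] <- .ks_D_sorted(obs$max_dfop, sort(st[comp, "max_dfop"]))
    ks_rg[i] <- .ks_D_sorted(obs$ring, sort(st[comp, "outer_fraction"]))
    if (n_boot > 0L)
      boot_D[i, ] <- vapply(boot_sorted, .ks_D_sorted, numeric(1L), ys = rtl_s)
  }
  if (all(is.na(ks_rtl)))
    stop("strategy fit failed: censoring dominates simulations at every grid point")

  # two-stage parsimony rule; grid rows are sorted by (F, eta). The eta
  # stage uses a stricter evidence bar (2x) because eta shifts the RTL
  # distribution only weakly and would otherwise absorb Monte-Carlo noise.
  one_se <- 0.5 * sqrt(1 / n_obs + 1 / stats::median(nsim))
  f_levels <- sort(unique(grid$F))
  fi <- match(grid$F, f_levels)
  pick_best <- function(D) {
    Dmin <- min(D, na.rm = TRUE)
    prof <- vapply(seq_along(f_levels), function(l)
      min(D[fi == l], na.rm = TRUE), numeric(1L))
    lev <- which(prof <= Dmin + one_se)[1L]
    rows <- which(fi == lev) # eta-ascending within one F
    rows[which(D[rows] <= prof[lev] + 2 * one_se)[1L]]
  }
  best_i <- pick_best(ks_rtl)
  best <- list(eta = grid$eta[best_i], F = grid$F[best_i])

  # held-out validation at the best pair, freshly simulated
  st <- sim_stats_cpp(g$adj, g$dist, g$npaths, outer_ring,
                      as.integer(pairs$start), as.integer(pairs$goal),
                      mult * as.integer(n_reps), dfop,
                      best$eta, best$F, as.integer(max_steps))
  comp <- st[, "completed"] == 1
  v_rtl <- ks_two_sample(mt$rtl, st[comp, "rtl"])
  v_mx <- ks_two_sample(mt$max_dfop, st[comp, "max_dfop"])
  v_rg <- ks_two_sample(mt$outer_fraction, st[comp, "outer_fraction"])
  validation <- data.frame(
    statistic = c("rtl", "max_dfop", "outer_fraction"),
    D = c(v_rtl$statistic, v_mx$statistic, v_rg$statistic),
    p_value = c(v_rtl$p_value, v_mx$p_value, v_rg$p_value))

  boot <- if (n_boot > 0L) {
    bi <- apply(boot_D, 2L, pick_best)
    data.frame(eta = grid$eta[bi], F = grid$F[bi])
  } else NULL

  structure(list(
    grid = cbind(grid, ks_rtl = ks_rtl, ks_maxdfop = ks_mx, ks_ring = ks_rg,
                 n_sim = nsim, censored = cens),
    best = best, best_index = best_i, best_ks = ks_rtl[best_i],
    min_ks = min(ks_rtl, na.rm = TRUE), one_se = one_se,
    p_value = v_rtl$p_value, effect_size = v_rtl$statistic,
    validation = validation, n_obs = n_obs, n_eff = v_rtl$n_eff,
    n_reps = as.integer(n_reps), boot = boot, observed = mt,
    pairs = pairs, maze = g, call = match.call()
  ), class = "strategy_fit")
}

#' @export
print.strategy_fit <- function(x, ...) {
  cat("Navigation-model fit by KS-distance minimization on RTL\n")
  cat(sprintf("  observed trials: %d (n_eff %.1f); %d runs/trial/grid point\n",
              x$n_obs, x$n_eff, x$n_reps))
  cat(sprintf("  best fit (one-SE parsimony): eta = %g, foresight F = %g\n",
              x$best$eta, x$best$F))
  cat(sprintf("  RTL KS at best: D = %.4f (grid min %.4f, one SE %.4f), p = %.3g\n",
              x$effect_size, x$min_ks, x$one_se, x$p_value))
  if (!is.null(x$boot))
    cat(sprintf("  bootstrap (n=%d): F mean %.3g, sd %.3g\n",
                nrow(x$boot), mean(x$boot$F), stats::sd(x$boot$F)))
  invisible(x)
}

#' @export
summary.strategy_fit <- function(object, ...) {
  print(object)
  cat("  held-out validation at best pair:\n")
  v <- object$validation
  for (i in seq_len(nrow(v)))
    cat(sprintf("    %-15s D = %.4f, p = %.3g\n", v$statistic[i], v$D[i],
                v$p_value[i]))
  invisible(object)
}

#' @export
coef.strategy_fit <- function(object, ...) {
  c(eta = object$best$eta, F = object$best$F)
}

#' Plot KS-distance profiles of a strategy fit
#'
#' KS distance between simulated and observed RTL distributions as a
#' function of foresight, one curve per `eta`; the best-fit point is
#' marked with a triangle.
#'
#' @param x a [fit_strategy()] object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.strategy_fit <- function(x, ...) {
  gr <- x$grid
  etas <- sort(unique(gr$eta))
  fs <- sort(unique(gr$F))
  m <- matrix(NA_real_, length(fs), length(etas))
  m[cbind(match(gr$F, fs), match(gr$eta, etas))] <- gr$ks_rtl
  graphics::matplot(fs, m, type = "l", lty = 1,
                    col = grDevices::hcl.colors(max(2L, length(etas)), "viridis"),
                    xlab = "foresight F", ylab = "KS distance (RTL)", ...)
  graphics::points(x$best$F, x$best_ks, pch = 17, col = "red", cex = 1.4)
  invisible(x)
}

#' @param object a [fit_strategy()] object.
#' @param nsim simulated runs per observed trial.
#' @param seed optional seed passed to [set.seed()].
#' @rdname fit_strategy
#' @export
simulate.strategy_fit <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  simulate_dataset(object$maze, object$observed[, c("start", "goal")],
                   sim_params(eta = object$best$eta, foresight = object$best$F),
                   n_reps = nsim)
}

#' Best-fit navigation strategy per trial group
#'
#' Groups a dataset by (condition, session, trial bin), fits the navigation
#' model to every group of sufficient effective size, and reports the
#' best-fit `(eta, F)` with a bootstrap spread; the time course of the
#' fitted foresight measures the accumulation of goal knowledge across
#' learning. Groups with `n_eff < min_n_eff` are excluded with a warning.
#' Between-group comparisons can be made with [ks_two_sample()] on the
#' bootstrap foresight distributions of two groups.
#'
#' @param trials list of [trajectory()] objects, or a [metrics_table()].
#' @param g a [build_hexmaze()] object.
#' @param n_boot bootstrap resamples per group.
#' @param min_n_eff minimum `n*m/(n+m)` for a group to be fitted.
#' @param ... passed to [fit_strategy()] (`grid_eta`, `grid_F`, `n_reps`...).
#' @return class `"foresight_trajectory"`: list with `groups` (one row per
#'   fitted group: `condition`, `session`, `bin`, `n`, `eta`, `F`,
#'   `F_boot_mean`, `F_boot_sd`) and `fits` (the underlying
#'   [fit_strategy()] objects, named `condition.session.bin`).
#' @export
foresight_trajectory <- function(trials, g, n_boot = 50L, min_n_eff = 50,
                                 ...) {
  mt <- if (is.data.frame(trials)) trials else metrics_table(trials, g)
  mt <- mt[!is.na(mt$bin), , drop = FALSE]
  keys <- unique(mt[, c("condition", "session", "bin")])
  keys <- keys[order(keys$condition, keys$session,
                     match(keys$bin, levels(trial_bin(1L)))), , drop = FALSE]
  fits <- list()
  rows <- list()
  dots <- list(...)
  n_reps <- if (is.null(dots$n_reps)) 50L else dots$n_reps
  for (i in seq_len(nrow(keys))) {
    sub <- mt[mt$condition == keys$condition[i] & mt$session == keys$session[i] &
                mt$bin == keys$bin[i], , drop = FALSE]
    n <- nrow(sub)
    n_eff <- n * n * n_reps / (n + n * n_reps)
    label <- paste(keys$condition[i], keys$session[i], keys$bin[i], sep = ".")
    if (n_eff < min_n_eff) {
      warning("group ", label, " excluded: effective sample size ",
              round(n_eff, 1), " < ", min_n_eff)
      next
    }
    fit <- fit_strategy(sub, g, n_boot = n_boot, ...)
    fits[[label]] <- fit
    rows[[label]] <- data.frame(
      condition = keys$condition[i], session = keys$session[i],
      bin = keys$bin[i], n = n, eta = fit$best$eta, F = fit$best$F,
      F_boot_mean = if (n_boot > 0L) mean(fit$boot$F) else NA_real_,
      F_boot_sd = if (n_boot > 0L) stats::sd(fit$boot$F) else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (!length(fits)) stop("no group reaches the minimum effective sample size")
  structure(list(groups = do.call(rbind, c(rows, make.row.names = FALSE)),
                 fits = fits, n_boot = n_boot),
            class = "foresight_trajectory")
}

#' @export
print.foresight_trajectory <- function(x, ...) {
  cat("Best-fit navigation strategy per trial group\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' @export
plot.foresight_trajectory <- function(x, ...) {
  gr <- x$groups
  idx <- seq_len(nrow(gr))
  graphics::plot(idx, gr$F, type = "b", pch = 16, xaxt = "n",
                 xlab = "trial group", ylab = "best-fit foresight F", ...)
  if (!all(is.na(gr$F_boot_sd)))
    graphics::arrows(idx, gr$F - gr$F_boot_sd, idx, gr$F + gr$F_boot_sd,
                     angle = 90, code = 3, length = 0.03, col = "grey50")
  graphics::axis(1, at = idx, labels = paste0("s", gr$session, ".", gr$bin),
                 las = 2, cex.axis = 0.7)
  invisible(x)
}
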