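#' Normalized difference-of-Gaussians curve
#'
#' The DFOP bump profile is parametrized as
#' `g(x) = A * (exp(-x^2 / (2*L1^2)) - exp(-x^2 / (2*L2^2))) / Z`
#' with `L1 > L2 > 0`, where the Gaussians are unit-amplitude (not
#' densities: the density form would be negative at 0 for `L1 > L2`,
#' contradicting the bump rising from 0) and `Z` is the maximum of the
#' bracketed difference over `x >= 0`, so that `g(0) = 0` and
#' `max g = A`. `A` is the peak stray (edges), `L1` the descending and
#' `L2` the ascending length scale (steps). `Z` is computed numerically on
#' a 0.01-step grid over `[0, 3*L1]`.
#'
#' @param x step values (>= 0).
#' @param A peak height, `A >= 0`.
#' @param L1,L2 descending/ascending length scales, `L1 > L2 > 0`.
#' @param z_step grid resolution for the normalization constant.
#' @return numeric curve values.
#' @examples
#' dog_curve(0:20, A = 2, L1 = 8, L2 = 2)
#' @export
dog_curve <- function(x, A, L1, L2, z_step = 0.01) {
  if (!(L2 > 0 && L1 > L2))
    stop("invalid length scales: need L1 > L2 > 0 (curve would be non-positive)")
  if (A < 0) stop("peak height A must be non-negative")
  A * (exp(-x^2 / (2 * L1^2)) - exp(-x^2 / (2 * L2^2))) / .dog_z(L1, L2, z_step)
}

.dog_z <- function(L1, L2, z_step = 0.01) {
  grid <- seq(0, 3 * L1, by = z_step)
  max(exp(-grid^2 / (2 * L1^2)) - exp(-grid^2 / (2 * L2^2)))
}

#' Fit the difference-of-Gaussians model to a DFOP profile
#'
#' Bounded least squares on the profile means via Levenberg-Marquardt
#' ([minpack.lm::nls.lm]), with the constraint `L1 > L2` enforced by the
#' parametrization `L1 = L2 + delta`, `delta > 0`, and `n_starts` random
#' restarts (seeded through the caller's RNG). An all-zero profile is
#' returned as a degenerate fit with `A = 0`. When the trial list and maze
#' are supplied, `n_boot` bootstrap refits on resampled trial sets give
#' parameter spreads.
#'
#' @param profile a [dfop_profile()] (any data.frame with `step`, `mean`
#'   and `n` columns works).
#' @param n_starts number of optimizer restarts.
#' @param z_step grid resolution of the normalization constant.
#' @param trials,g optional trial list and maze enabling the bootstrap.
#' @param n_boot number of bootstrap resamples of the trial set (0 = none).
#' @return class `"dog_fit"`: list with `A`, `L1`, `L2`, `Z`,
#'   `peak_step` (argmax of the fitted curve), `rss`, `degenerate`,
#'   `fitted`, the input `profile`, and (optionally) `boot`, a data.frame
#'   of bootstrap parameter estimates.
#' @examples
#' prof <- data.frame(step = 0:25, mean = dog_curve(0:25, 2, 8, 2), n = 30)
#' coef(fit_dog(prof))
#' @export
fit_dog <- function(profile, n_starts = 10L, z_step = 0.01,
                    trials = NULL, g = NULL, n_boot = 0L) {
  x <- profile$step[profile$n >= 1L]
  y <- profile$mean[profile$n >= 1L]
  if (length(x) < 5L) stop("profile must have at least 5 steps with n >= 1")
  fit <- .fit_dog_core(x, y, n_starts, z_step)
  fit$profile <- profile
  if (n_boot > 0L) {
    if (is.null(trials) || is.null(g))
      stop("bootstrap refits need the trial list and the maze")
    horizon <- attr(profile, "horizon")
    pad <- attr(profile, "pad")
    boot <- lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(trials), replace = TRUE)
      prof_b <- dfop_profile(trials[idx], g, horizon = horizon,
                             pad = if (is.null(pad)) TRUE else pad)
      fb <- .fit_dog_core(prof_b$step[prof_b$n >= 1L],
                          prof_b$mean[prof_b$n >= 1L], n_starts, z_step)
      data.frame(A = fb$A, L1 = fb$L1, L2 = fb$L2)
    })
    fit$boot <- do.call(rbind, boot)
  }
  fit
}

.fit_dog_core <- function(x, y, n_starts = 10L, z_step = 0.01) {
  if (max(y) < 1e-6) {
    # flat profile: no bump to fit, report the lower-bound scales
    return(structure(list(A = 0, L1 = 1.05, L2 = 1, Z = .dog_z(1.05, 1, z_step),
                          peak_step = 0, rss = sum(y^2), degenerate = TRUE,
                          fitted = rep(0, length(x)), converged = TRUE),
                     class = "dog_fit"))
  }
  resid_fn <- function(p) y - dog_curve(x, p[1L], p[2L] + p[3L], p[2L], z_step)
  xmax <- x[which.max(y)]
  starts <- rbind(
    c(max(y), max(0.5, xmax / 2), max(1, 1.5 * xmax)),
    cbind(max(y) * stats::runif(n_starts - 1L, 0.5, 2),
          stats::runif(n_starts - 1L, 0.3, 5),
          stats::runif(n_starts - 1L, 0.5, 25)))
  lower <- c(0, 0.1, 0.05)
  upper <- c(Inf, 100, 500)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-8, ptol = 1e-8, maxiter = 500L)),
      error = function(e) NULL)
    if (is.null(f)) next
    rss <- sum(f$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = f$par, rss = rss)
  }
  if (is.null(best)) stop("difference-of-Gaussians fit failed from all starts")
  A <- best$par[1L]; L2 <- best$par[2L]; L1 <- L2 + best$par[3L]
  grid <- seq(0, 3 * L1, by = z_step)
  structure(list(A = A, L1 = L1, L2 = L2, Z = .dog_z(L1, L2, z_step),
                 peak_step = grid[which.max(dog_curve(grid, A, L1, L2, z_step))],
                 rss = best$rss, degenerate = A <= 1e-6,
                 fitted = dog_curve(x, A, L1, L2, z_step), converged = TRUE),
            class = "dog_fit")
}

#' @export
print.dog_fit <- function(x, digits = 4L, ...) {
  cat("Difference-of-Gaussians DFOP fit",
      if (x$degenerate) " [degenerate: flat profile]", "\n", sep = "")
  cat(sprintf("  peak height A   = %.*g edges\n", digits, x$A))
  cat(sprintf("  descending  L1  = %.*g steps\n", digits, x$L1))
  cat(sprintf("  ascending   L2  = %.*g steps\n", digits, x$L2))
  cat(sprintf("  peak at step %.*g, RSS %.*g\n", digits, x$peak_step,
              digits, x$rss))
  if (!is.null(x$boot))
    cat(sprintf("  bootstrap SD (n=%d): A %.3g, L1 %.3g, L2 %.3g\n",
                nrow(x$boot), stats::sd(x$boot$A), stats::sd(x$boot$L1),
                stats::sd(x$boot$L2)))
  invisible(x)
}

#' @export
coef.dog_fit <- function(object, ...) {
  c(A = object$A, L1 = object$L1, L2 = object$L2)
}

#' @export
predict.dog_fit <- function(object, steps = NULL, ...) {
  if (is.null(steps)) steps <- object$profile$step
  if (object$degenerate) return(rep(0, length(steps)))
  dog_curve(steps, object$A, object$L1, object$L2)
}

#' @export
residuals.dog_fit <- function(object, ...) {
  keep <- object$profile$n >= 1L
  object$profile$mean[keep] - predict(object, object$profile$step[keep])
}

#' @export
plot.dog_fit <- function(x, ...) {
  p <- x$profile
  graphics::plot(p$step, p$mean, pch = 16, col = "grey40", xlab = "step",
                 ylab = "distance from optimal path (edges)", ...)
  grid <- seq(0, max(p$step), length.out = 200L)
  graphics::lines(grid, predict(x, grid), col = "tomato", lwd = 2)
  invisible(x)
}

#' @export
summary.dog_fit <- function(object, ...) {
  out <- c(coef(object), Z = object$Z, peak_step = object$peak_step,
           rss = object$rss)
  print(object)
  invisible(out)
}
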