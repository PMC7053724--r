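#' Morris one-at-a-time trajectories
#'
#' Generates `r` random trajectories through the unit hypercube on a
#' `levels`-point grid: each trajectory starts from a random grid point
#' and changes one randomly chosen coordinate at a time by +/- `delta`,
#' visiting p + 1 points that all stay inside \[0, 1\].
#'
#' @param p number of parameters.
#' @param r number of trajectories (>= 2 for dispersion estimates).
#' @param levels number of grid levels (default 4).
#' @param delta elementary step in rescaled coordinates; default
#'   `levels / (2 * (levels - 1))`, the classic choice (2/3 for 4 levels).
#' @param seed integer seed for reproducibility.
#' @return list of r matrices, each (p + 1) x p, plus attributes `delta`
#'   and `moves` (per-trajectory data.frame of changed index and signed
#'   step).
#' @export
morris_trajectories <- function(p, r, levels = 4, delta = NULL, seed = 1) {
  stopifnot(p >= 1, r >= 1, levels >= 2)
  if (is.null(delta)) delta <- levels / (2 * (levels - 1))
  if (delta <= 0 || delta >= 1) stop("delta must lie in (0, 1)")
  grid <- seq(0, 1, length.out = levels)
  starts <- grid[grid <= 1 - delta + 1e-12]
  if (!length(starts))
    stop("infeasible delta/levels combination: no room for a step")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lapply(seq_len(r), function(i) {
    x <- sample(starts, p, replace = TRUE)
    ord <- sample.int(p)
    pts <- matrix(NA_real_, p + 1, p)
    pts[1, ] <- x
    moves <- data.frame(index = ord, step = NA_real_)
    for (s in seq_len(p)) {
      j <- ord[s]
      dir <- sample(c(-1, 1), 1)
      if (x[j] + dir * delta < -1e-12 || x[j] + dir * delta > 1 + 1e-12)
        dir <- -dir
      x[j] <- min(1, max(0, x[j] + dir * delta))
      moves$step[s] <- dir * delta
      pts[s + 1, ] <- x
    }
    attr(pts, "moves") <- moves
    pts
  })
}

#' Elementary effect of one parameter
#'
#' `EE* = |Y(X) - Y(X with X_j + delta)| / delta` for a pair of model
#' evaluations differing only in parameter j.  The signed version
#' (without the absolute value) is retained internally for the dispersion
#' estimate.
#'
#' @param y_before,y_after model outputs at the two points.
#' @param delta signed step applied to the parameter.
#' @return signed elementary effect (take `abs()` for EE*).
#' @export
elementary_effect <- function(y_before, y_after, delta) {
  if (delta == 0) stop("delta must be nonzero")
  (y_after - y_before) / delta
}

#' Summary statistics of elementary effects
#'
#' For each parameter: `mu_star` = mean of |EE|, `sigma` = standard
#' deviation of the elementary effects, and the Euclidean distance
#' `D = sqrt(mu_star^2 + sigma^2)` in the (mu*, sigma) plane used for the
#' global importance ranking.
#'
#' @param ee matrix of elementary effects, r rows x p columns (signed).
#' @param abs_sigma if `TRUE`, sigma is computed over |EE| instead of the
#'   signed effects (the literal reading when effects are stored as
#'   magnitudes); default `FALSE`, the standard revised-Morris convention.
#' @return object of class `morris_screen`: data.frame with `parameter`,
#'   `mu_star`, `sigma`, `D`, `rank` (1 = most influential), sorted by
#'   decreasing D.
#' @export
morris_stats <- function(ee, abs_sigma = FALSE) {
  stopifnot(is.matrix(ee), nrow(ee) >= 2)
  mu_star <- colMeans(abs(ee))
  sigma <- apply(if (abs_sigma) abs(ee) else ee, 2, stats::sd)
  D <- sqrt(mu_star^2 + sigma^2)
  out <- data.frame(
    parameter = colnames(ee) %||% paste0("x", seq_along(mu_star)),
    mu_star = mu_star, sigma = sigma, D = D, row.names = NULL
  )
  out$rank <- rank(-out$D, ties.method = "first")
  out <- out[order(out$rank), ]
  class(out) <- c("morris_screen", "data.frame")
  out
}

#' Morris elementary-effects screening of an arbitrary function
#'
#' Runs the full screening: trajectory generation in rescaled \[0, 1\]
#' coordinates, mapping to physical ranges (`nominal` +/- `range_frac`),
#' model evaluation at every trajectory point, and the mu*/sigma/D
#' summary.  Evaluations that return `NA`/`NaN` invalidate their
#' trajectory (it is dropped with a message).
#'
#' @param fn function taking a named numeric vector of physical parameter
#'   values and returning a scalar output.
#' @param nominal named numeric vector of nominal parameter values.
#' @param range_frac half-width of each range as a fraction of nominal
#'   (default 0.30).
#' @param r number of trajectories.
#' @param levels,delta,seed see [morris_trajectories()].
#' @param abs_sigma see [morris_stats()].
#' @return a `morris_screen` (see [morris_stats()]), with attributes
#'   `n_eval` and `n_dropped`.
#' @export
morris_screen <- function(fn, nominal, range_frac = 0.30, r = 10,
                          levels = 4, delta = NULL, seed = 1,
                          abs_sigma = FALSE) {
  p <- length(nominal)
  stopifnot(p >= 1, r >= 2, !is.null(names(nominal)))
  trajs <- morris_trajectories(p, r, levels, delta, seed)
  to_phys <- function(u) nominal * (1 + range_frac * (2 * u - 1))
  ee_rows <- list(); n_eval <- 0L; dropped <- 0L
  for (tr in trajs) {
    moves <- attr(tr, "moves")
    ys <- apply(tr, 1, function(u) fn(to_phys(u)))
    n_eval <- n_eval + nrow(tr)
    if (any(!is.finite(ys))) { dropped <- dropped + 1L; next }
    ee <- rep(NA_real_, p)
    for (s in seq_len(p))
      ee[moves$index[s]] <- elementary_effect(ys[s], ys[s + 1],
                                              moves$step[s])
    ee_rows[[length(ee_rows) + 1L]] <- ee
  }
  if (dropped)
    message(dropped, " trajectory(ies) dropped due to failed evaluations")
  if (length(ee_rows) < 2)
    stop("fewer than 2 valid trajectories; cannot estimate dispersion")
  ee <- do.call(rbind, ee_rows)
  colnames(ee) <- names(nominal)
  out <- morris_stats(ee, abs_sigma)
  attr(out, "n_eval") <- n_eval
  attr(out, "n_dropped") <- dropped
  out
}

#' Rank cardiovascular model parameters by influence on the gradient
#'
#' Morris screening of the closed-loop model output
#' `dP = max(P_LV) - Pao_sys` (the transvalvular gradient) over the
#' identified parameter subsets X_LV and X_art plus the aortic
#' `A_eff_max`, each varied +/- 30% around nominal.  In the nominal AS
#' configuration the aortic effective area dominates the ranking, with LV
#' elastance parameters (E_es_lv, alpha_2) among the leaders.
#'
#' @param ps nominal [cvs_params()] parameter set.
#' @param r number of trajectories (default 10).
#' @param range_frac range half-width (default 0.30).
#' @param beats,dt simulation settings per evaluation.
#' @param extra named character vector of additional dotted parameter
#'   paths to screen; default adds the aortic effective area.
#' @param ... passed to [morris_screen()].
#' @return a `morris_screen` ranking.
#' @export
rank_cvs_parameters <- function(ps, r = 10, range_frac = 0.30,
                                beats = 8, dt = 0.002,
                                extra = c(A_eff_max = "valves.aortic.A_eff_max"),
                                ...) {
  view <- c(param_view("both"), extra)
  nominal <- view_values(ps, view)
  fn <- function(x) {
    psx <- apply_view(ps, x, view)
    sim <- tryCatch(
      cvs_simulate(psx, beats = beats, dt = dt, warn = FALSE),
      error = function(e) NULL)
    if (is.null(sim)) return(NA_real_)
    pressure_gradient(sim)
  }
  morris_screen(fn, nominal, range_frac = range_frac, r = r, ...)
}

#' @export
print.morris_screen <- function(x, n = 10, ...) {
  cat("Morris elementary-effects screening\n")
  if (!is.null(attr(x, "n_eval")))
    cat(sprintf("  %d model evaluations, %d trajectories dropped\n",
                attr(x, "n_eval"), attr(x, "n_dropped")))
  print.data.frame(utils::head(as.data.frame(x), n), digits = 3,
                   row.names = FALSE)
  invisible(x)
}

#' Plot a Morris screening in the mu*-sigma plane
#' @param x a `morris_screen`.
#' @param n label the n top-ranked parameters.
#' @param ... ignored.
#' @export
plot.morris_screen <- function(x, n = 8, ...) {
  graphics::plot(x$mu_star, x$sigma, pch = 19,
                 xlab = expression(mu * "*"), ylab = expression(sigma))
  top <- head(x[order(x$rank), ], n)
  graphics::text(top$mu_star, top$sigma, top$parameter, pos = 3, cex = 0.7)
  invisible(x)
}
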