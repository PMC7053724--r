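#' Segmental strain set
#'
#' Container for speckle-tracking-style longitudinal strain: K segmental
#' traces on one uniform time grid, plus the valve event times bounding
#' the work phases.
#'
#' @param time uniform time grid (s).
#' @param strain numeric matrix (or data.frame) with one column per
#'   segment, strain in % (negative = shortening).
#' @param events named list or vector with `MVC`, `AVO`, `AVC`, `MVO`
#'   times (s) inside the grid, satisfying MVC < AVC < MVO.
#' @return object of class `strain_set`.
#' @export
strain_set <- function(time, strain, events) {
  strain <- as.matrix(strain)
  if (nrow(strain) != length(time))
    stop("strain traces must share the time grid")
  ev <- as.list(events)
  for (nm in c("MVC", "AVO", "AVC", "MVO"))
    if (is.null(ev[[nm]])) stop("missing event time: ", nm)
  if (!(ev$MVC < ev$AVC && ev$AVC < ev$MVO))
    stop("event times must satisfy MVC < AVC < MVO")
  if (ev$MVC < min(time) || ev$MVO > max(time))
    stop("event times outside the strain time grid")
  if (is.null(colnames(strain)))
    colnames(strain) <- paste0("seg", seq_len(ncol(strain)))
  structure(list(time = time, strain = strain,
                 events = ev[c("MVC", "AVO", "AVC", "MVO")]),
            class = "strain_set")
}

#' Instantaneous myocardial power of one segment
#'
#' Strain rate (central differences on the uniform grid, one-sided at the
#' ends) multiplied by the instantaneous LV pressure:
#' power(t) = d(eps)/dt x P_LV(t), in mmHg %/s.
#'
#' @param time uniform grid (s).
#' @param strain one segmental strain trace (%).
#' @param pressure LV pressure on the same grid (mmHg).
#' @param smooth if `TRUE`, the strain trace is smoothed with a
#'   Savitzky-Golay quadratic filter (window `sg_window`) before
#'   differentiation; default is the transparent unsmoothed estimator.
#' @param sg_window odd window length for the optional smoother.
#' @return power trace (mmHg %/s).
#' @export
instantaneous_power <- function(time, strain, pressure,
                                smooth = FALSE, sg_window = 9) {
  n <- length(time)
  if (length(strain) != n || length(pressure) != n)
    stop("strain and pressure must be aligned on the same grid")
  dt <- diff(time)
  if (max(dt) - min(dt) > 1e-9 * max(dt))
    stop("time grid must be uniform")
  if (smooth) strain <- sgolay_smooth(strain, sg_window)
  rate <- c(strain[2] - strain[1],
            (strain[3:n] - strain[1:(n - 2)]) / 2,
            strain[n] - strain[n - 1]) / dt[1]
  rate * pressure
}

# quadratic Savitzky-Golay smoothing by local least squares
sgolay_smooth <- function(x, window = 9) {
  stopifnot(window %% 2 == 1, window >= 5)
  h <- (window - 1) / 2
  z <- -h:h
  X <- cbind(1, z, z^2)
  w <- (solve(crossprod(X)) %*% t(X))[1, ]   # center-point weights
  n <- length(x)
  xp <- c(rep(x[1], h), x, rep(x[n], h))
  as.numeric(stats::filter(xp, rev(w), sides = 2))[(h + 1):(h + n)]
}

#' Cumulative segmental work
#'
#' Integrates the power trace from mitral valve closure up to each time
#' point of the cycle (trapezoidal rule), yielding the running work
#' w(t) = int_MVC^t power dtau for t in \[MVC, MVO\].
#'
#' @param time uniform grid (s).
#' @param power power trace (mmHg %/s).
#' @param MVC,MVO phase boundaries (s), inside the grid.
#' @return list with `time` (grid restricted to \[MVC, MVO\]) and `w`
#'   (cumulative work, mmHg %).
#' @export
segmental_work <- function(time, power, MVC, MVO) {
  if (MVC >= MVO) stop("need MVC < MVO")
  if (MVC < min(time) || MVO > max(time)) stop("events outside grid")
  w <- which(time >= MVC - 1e-12 & time <= MVO + 1e-12)
  tt <- time[w]; pp <- power[w]
  dw <- c(0, diff(tt) * (head(pp, -1) + tail(pp, -1)) / 2)
  list(time = tt, w = cumsum(dw))
}

#' Decompose a work trace into constructive/wasted components
#'
#' Within the systolic phase S (MVC to AVC) and the isovolumic relaxation
#' phase IVR (AVC to MVO), the cumulative work trace is partitioned into
#' maximal monotone runs; `Wp` sums the increments of ascending runs and
#' `Wn` the magnitudes of descending runs.  Successive differences within
#' a dead-band of 1e-12 are treated as run continuation.
#'
#' @param time grid of the work trace (s), spanning MVC to MVO.
#' @param w cumulative work trace (mmHg %).
#' @param AVC aortic valve closure time (s), strictly inside the trace.
#' @return named numeric vector `Wp_S`, `Wn_S`, `Wp_IVR`, `Wn_IVR`
#'   (all >= 0, mmHg %).
#' @export
decompose_work <- function(time, w, AVC) {
  if (any(!is.finite(w))) stop("non-finite work samples")
  if (AVC <= min(time) || AVC >= max(time))
    stop("AVC must lie strictly inside the trace")
  i_avc <- which.min(abs(time - AVC))
  pn <- function(x) {
    d <- diff(x)
    d[abs(d) <= 1e-12] <- 0
    c(p = sum(d[d > 0]), n = -sum(d[d < 0]))
  }
  s <- pn(w[1:i_avc]); r <- pn(w[i_avc:length(w)])
  c(Wp_S = s[["p"]], Wn_S = s[["n"]], Wp_IVR = r[["p"]], Wn_IVR = r[["n"]])
}

#' Global myocardial work indices
#'
#' Means over segments of the per-phase components:
#' GCW = mean(Wp_S + Wn_IVR): shortening during systole plus lengthening
#' during isovolumic relaxation (energy effective for ejection);
#' GWW = mean(Wn_S + Wp_IVR): systolic stretch plus IVR shortening
#' (wasted energy); GWE = GCW / (GCW + GWW).
#'
#' @param components matrix or data.frame with columns `Wp_S`, `Wn_S`,
#'   `Wp_IVR`, `Wn_IVR`, one row per segment (all non-negative).
#' @return list with `GCW`, `GWW` (mmHg %) and `GWE` (dimensionless;
#'   `NA` with attribute `"undefined"` when GCW + GWW = 0).
#' @export
global_indices <- function(components) {
  components <- as.data.frame(components)
  cols <- c("Wp_S", "Wn_S", "Wp_IVR", "Wn_IVR")
  stopifnot(nrow(components) >= 1, all(cols %in% names(components)))
  if (any(!is.finite(as.matrix(components[cols]))))
    stop("non-finite components")
  GCW <- mean(components$Wp_S + components$Wn_IVR)
  GWW <- mean(components$Wn_S + components$Wp_IVR)
  if (GCW + GWW == 0) {
    GWE <- NA_real_
    attr(GWE, "undefined") <- TRUE
  } else GWE <- GCW / (GCW + GWW)
  list(GCW = GCW, GWW = GWW, GWE = GWE)
}

#' Pressure-strain myocardial work indices
#'
#' End-to-end computation of segmental and global myocardial work from a
#' strain set and an LV pressure trace: per segment, power = strain rate x
#' pressure, integrated from MVC; the cumulative work is decomposed into
#' ascending/descending runs per phase and averaged into GCW, GWW and GWE.
#'
#' The cumulative work trace follows the clinical pressure-strain
#' convention in which shortening against pressure counts as positive
#' (ascending) work: w_k(t) = -int power dtau.  With this orientation a
#' synchronously shortening ventricle accumulates its systolic work in
#' `Wp_S` (constructive) and its isovolumic-relaxation lengthening in
#' `Wn_IVR`, so GWW = 0 and GWE = 1 in the ideal synchronous case.
#'
#' @param ss a [strain_set()].
#' @param pressure LV pressure (mmHg) sampled on `pressure_time`.
#' @param pressure_time time grid of `pressure` (defaults to the strain
#'   grid; otherwise the pressure is linearly resampled onto it).
#' @param smooth,sg_window see [instantaneous_power()].
#' @return object of class `work_indices`: list with `segment`
#'   (data.frame of per-segment components), `GCW`, `GWW`, `GWE`, `K`.
#' @export
#' @examples
#' t <- seq(0, 0.8, by = 0.01)
#' eps <- -15 * sin(pi * pmin(t, 0.6) / 0.6)
#' ss <- strain_set(t, cbind(s1 = eps),
#'                  list(MVC = 0.05, AVO = 0.1, AVC = 0.45, MVO = 0.7))
#' myocardial_work(ss, pressure = rep(100, length(t)))
myocardial_work <- function(ss, pressure, pressure_time = ss$time,
                            smooth = FALSE, sg_window = 9) {
  stopifnot(inherits(ss, "strain_set"))
  if (!isTRUE(all.equal(pressure_time, ss$time))) {
    pressure <- stats::approx(pressure_time, pressure, xout = ss$time,
                              rule = 2)$y
  } else if (length(pressure) != length(ss$time))
    stop("pressure and strain grids are misaligned")
  ev <- ss$events
  comp <- t(apply(ss$strain, 2, function(eps) {
    pw <- instantaneous_power(ss$time, eps, pressure, smooth, sg_window)
    # shortening-positive orientation of the cumulative work trace
    wk <- segmental_work(ss$time, -pw, ev$MVC, ev$MVO)
    decompose_work(wk$time, wk$w, ev$AVC)
  }))
  seg <- data.frame(segment = colnames(ss$strain), comp,
                    row.names = NULL, check.names = FALSE)
  gi <- global_indices(seg)
  structure(c(list(segment = seg, K = ncol(ss$strain)), gi),
            class = "work_indices")
}

#' @export
print.work_indices <- function(x, ...) {
  cat(sprintf("Myocardial work indices (%d segments)\n", x$K))
  cat(sprintf("  GCW = %.1f mmHg%%   GWW = %.1f mmHg%%   GWE = %s\n",
              x$GCW, x$GWW,
              if (is.na(x$GWE)) "undefined" else sprintf("%.3f", x$GWE)))
  invisible(x)
}
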