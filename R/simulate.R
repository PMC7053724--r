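#' Simulate the closed-loop cardiovascular model
#'
#' Assembles the conduction network, chamber laws, valve dynamics and
#' circulation into one stiff ODE system and integrates it beat by beat.
#' The conduction automata are simulated first (event-driven, exact); their
#' activation instants set the periodic driver clocks of the four cardiac
#' chambers.  The 18 continuous states (10 chamber volumes, 4 x (flow,
#' opening fraction)) are integrated with `deSolve::lsoda` against the
#' compiled right-hand side, and sampled on a uniform grid.
#'
#' Periodic steady state is declared when the beat-to-beat change of both
#' the LV pressure maximum and the stroke volume falls below `steady_tol`
#' (relative); the analysis beat is always the last complete beat.
#'
#' @param ps a [cvs_params()] parameter set.
#' @param beats number of beats to integrate (>= 1; default 15, enough for
#'   convergence from the packaged initial conditions).
#' @param dt output sampling step (s); default 1 ms.
#' @param rtol,atol solver tolerances.
#' @param warn warn if the run has not reached periodic steady state.
#' @return object of class `cvs_sim` with components
#'   \describe{
#'     \item{ts}{data.frame: `time`, volumes `V_*`, valve states
#'       `Q_*`/`xi_*`, pressures `P_*`.}
#'     \item{events}{list: `qrs` times and per-beat valve events
#'       (MVC/AVO/AVC/MVO).}
#'     \item{derived}{`Pao_sys`, `Pao_dias`, `max_plv`, `dP` (transvalvular
#'       gradient), `sv` (stroke volume), over the analysis beat.}
#'     \item{converged}{logical steady-state flag.}
#'   }
#' @seealso [pressure_gradient()], [detect_valve_events()],
#'   [lv_pressure_cycle()]
#' @export
#' @examples
#' \donttest{
#' sim <- cvs_simulate(cvs_params(), beats = 12)
#' sim$derived$max_plv   # ~120 mmHg for the healthy nominal run
#' }
cvs_simulate <- function(ps, beats = 15, dt = 0.001,
                         rtol = 1e-6, atol = 1e-8, warn = TRUE) {
  stopifnot(inherits(ps, "cvs_params"), beats >= 1)
  T <- ps$T
  sched <- run_conduction(ps$electrical, duration = (beats + 1) * T)
  offsets <- activation_offsets(sched)
  parms <- pack_parms(ps, offsets)
  y0 <- initial_state(ps)
  t_end <- offsets[["lv"]] + beats * T
  times <- seq(0, t_end, by = dt)
  pn <- c("P_lv", "P_la", "P_rv", "P_ra", "P_ao", "P_sa", "P_sv", "P_vc",
          "P_pa", "P_pv")
  out <- deSolve::lsoda(y0, times, func = "cvs_derivs", parms = parms,
                        dllname = "cvwork", initfunc = "cvs_init",
                        nout = 10, outnames = pn,
                        rtol = rtol, atol = atol, maxsteps = 20000)
  if (anyNA(out))
    stop("integration failure: NaN in state (diagnostics: last t = ",
         max(out[stats::complete.cases(out), "time"]), ")")
  ts <- as.data.frame(out)
  qrs <- sched$qrs[sched$qrs + T <= t_end + dt / 2]

  # per-beat summaries over windows [qrs_k, qrs_k + T]
  nb <- length(qrs)
  max_plv_b <- sv_b <- numeric(nb)
  for (k in seq_len(nb)) {
    w <- ts$time >= qrs[k] - dt / 2 & ts$time <= qrs[k] + T + dt / 2
    max_plv_b[k] <- max(ts$P_lv[w])
    sv_b[k] <- max(ts$V_lv[w]) - min(ts$V_lv[w])
  }
  converged <- FALSE
  if (nb >= 2) {
    rel <- function(a, b) abs(a - b) / max(abs(b), 1e-9)
    converged <- rel(max_plv_b[nb], max_plv_b[nb - 1]) < 0.005 &&
      rel(sv_b[nb], sv_b[nb - 1]) < 0.005
  }
  if (!converged && warn)
    warning("periodic steady state not reached after ", beats,
            " beats; analysis beat may be transient")

  t0 <- qrs[nb]; t1 <- qrs[nb] + T
  w <- ts$time >= t0 - dt / 2 & ts$time <= t1 + dt / 2
  derived <- list(
    Pao_sys = max(ts$P_ao[w]), Pao_dias = min(ts$P_ao[w]),
    max_plv = max(ts$P_lv[w]), sv = sv_b[nb]
  )
  derived$dP <- derived$max_plv - derived$Pao_sys

  sim <- structure(list(
    ts = ts, events = list(qrs = qrs), derived = derived,
    converged = converged, beats = beats, dt = dt, T = T,
    offsets = offsets, params = ps, analysis_window = c(t0, t1)
  ), class = "cvs_sim")
  sim$events$valves <- detect_valve_events(sim)
  sim
}

#' Transvalvular pressure gradient of a simulation
#'
#' `dP = max(P_LV) - Pao_sys` over the analysis beat: the model output used
#' for sensitivity screening and the hallmark of aortic stenosis severity.
#'
#' @param sim a `cvs_sim` object.
#' @return gradient in mmHg.
#' @export
pressure_gradient <- function(sim) {
  stopifnot(inherits(sim, "cvs_sim"))
  sim$derived$dP
}

#' Detect valve events per beat
#'
#' Opening (upward) and closing (downward) crossings of the valve opening
#' fraction through `threshold`, reported per beat as mitral valve closure
#' (MVC), aortic valve opening (AVO) and closure (AVC), and mitral valve
#' opening (MVO).  Crossing times are linearly interpolated between output
#' samples.
#'
#' @param sim a `cvs_sim` object.
#' @param threshold opening-fraction threshold (default 0.05).
#' @return data.frame with columns `beat`, `MVC`, `AVO`, `AVC`, `MVO`
#'   (times in s; `NA` with a `missing_events` attribute if a valve never
#'   opens or closes within a beat).
#' @export
detect_valve_events <- function(sim, threshold = 0.05) {
  stopifnot(inherits(sim, "cvs_sim"))
  ts <- sim$ts
  qrs <- sim$events$qrs
  T <- sim$T
  cross <- function(tt, x, dir, lo, hi) {
    w <- which(tt >= lo & tt <= hi)
    if (length(w) < 2) return(NA_real_)
    xx <- x[w]; ttw <- tt[w]
    d <- diff(xx >= threshold)
    i <- if (dir == "up") which(d == 1) else which(d == -1)
    if (!length(i)) return(NA_real_)
    i <- i[1]
    # linear interpolation of the crossing instant
    x0 <- xx[i]; x1 <- xx[i + 1]
    ttw[i] + (threshold - x0) / (x1 - x0) * (ttw[i + 1] - ttw[i])
  }
  res <- lapply(seq_along(qrs), function(k) {
    # mitral closure can precede the QRS by a few ms (end of the atrial
    # kick), so the search window starts slightly before it
    lo <- qrs[k] - 0.1 * T; hi <- qrs[k] + 0.9 * T
    mvc <- cross(ts$time, ts$xi_mv, "down", lo, qrs[k] + 0.4 * T)
    avo <- cross(ts$time, ts$xi_av, "up", if (is.na(mvc)) lo else mvc, hi)
    avc <- cross(ts$time, ts$xi_av, "down", if (is.na(avo)) lo else avo, hi)
    mvo <- cross(ts$time, ts$xi_mv, "up", if (is.na(avc)) lo else avc, hi)
    c(beat = k, MVC = mvc, AVO = avo, AVC = avc, MVO = mvo)
  })
  ev <- as.data.frame(do.call(rbind, res))
  if (anyNA(ev[-1]))
    attr(ev, "missing_events") <- TRUE
  ev
}

#' LV pressure over the analysis beat
#'
#' Samples the simulated LV pressure at times `t_e` after the QRS of the
#' analysis (last) beat, by linear interpolation on the output grid.  This
#' is the model counterpart of a catheter trace synchronised on the QRS.
#'
#' @param sim a `cvs_sim` object.
#' @param t_e times since QRS (s); defaults to the full beat at the output
#'   step.
#' @return numeric vector of pressures (mmHg).
#' @export
lv_pressure_cycle <- function(sim, t_e = NULL) {
  stopifnot(inherits(sim, "cvs_sim"))
  t0 <- sim$analysis_window[1]
  if (is.null(t_e)) t_e <- seq(0, sim$T, by = sim$dt)
  stats::approx(sim$ts$time, sim$ts$P_lv, xout = t0 + t_e, rule = 2)$y
}

#' Pure-R right-hand side of the assembled model
#'
#' Reference implementation composing the module-level laws
#' ([ventricle_pressure()], [atrial_pressure()], [vessel_pressure()],
#' [valve_derivatives()], [resistive_flow()], [volume_derivatives()]).
#' It mirrors the compiled right-hand side exactly and is used as the
#' independent cross-check in the test suite; simulation itself always
#' runs the compiled version.
#'
#' @param t time (s).
#' @param y state vector in simulator order (see [cvs_simulate()]).
#' @param ps a [cvs_params()] object.
#' @param offsets named driver offsets (`lv`, `rv`, `la`, `ra`).
#' @return list: `dy` (derivatives) and `pressures`.
#' @export
cvs_rhs_r <- function(t, y, ps, offsets) {
  T <- ps$T
  tau <- function(off) { x <- (t - off) %% T; x }
  e_lv <- driver_double_hill(tau(offsets[["lv"]]), ps$lv, T)
  e_rv <- driver_double_hill(tau(offsets[["rv"]]), ps$rv, T)
  P <- c(
    lv = ventricle_pressure(y[["V_lv"]], NULL, ps$lv, T, e = e_lv),
    la = atrial_pressure(y[["V_la"]], tau(offsets[["la"]]), ps$la),
    rv = ventricle_pressure(y[["V_rv"]], NULL, ps$rv, T, e = e_rv),
    ra = atrial_pressure(y[["V_ra"]], tau(offsets[["ra"]]), ps$ra),
    ao = vessel_pressure(y[["V_ao"]], ps$circulation$E_ao, ps$circulation$Vd_ao),
    sa = vessel_pressure(y[["V_sa"]], ps$circulation$E_sa, ps$circulation$Vd_sa),
    sv = vessel_pressure(y[["V_sv"]], ps$circulation$E_sv, ps$circulation$Vd_sv),
    vc = vessel_pressure(y[["V_vc"]], ps$circulation$E_vc, ps$circulation$Vd_vc),
    pa = vessel_pressure(y[["V_pa"]], ps$circulation$E_pa, ps$circulation$Vd_pa),
    pv = vessel_pressure(y[["V_pv"]], ps$circulation$E_pv, ps$circulation$Vd_pv)
  )
  vd <- function(valve, dP, Q, xi)
    valve_derivatives(dP, list(Q = Q, xi = xi), ps$valves[[valve]], ps$rho)
  mv <- vd("mitral", P[["la"]] - P[["lv"]], y[["Q_mv"]], y[["xi_mv"]])
  av <- vd("aortic", P[["lv"]] - P[["ao"]], y[["Q_av"]], y[["xi_av"]])
  tv <- vd("tricuspid", P[["ra"]] - P[["rv"]], y[["Q_tv"]], y[["xi_tv"]])
  pu <- vd("pulmonary", P[["rv"]] - P[["pa"]], y[["Q_pu"]], y[["xi_pu"]])
  circ <- ps$circulation
  flows <- c(
    Q_mv = y[["Q_mv"]], Q_av = y[["Q_av"]],
    q_ao_sa = resistive_flow(P[["ao"]], P[["sa"]], circ$R_ao),
    q_sa_sv = resistive_flow(P[["sa"]], P[["sv"]], circ$R_sys),
    q_sv_vc = resistive_flow(P[["sv"]], P[["vc"]], circ$R_vc),
    q_vc_ra = resistive_flow(P[["vc"]], P[["ra"]], circ$R_ra),
    Q_tv = y[["Q_tv"]], Q_pu = y[["Q_pu"]],
    q_pa_pv = resistive_flow(P[["pa"]], P[["pv"]], circ$R_pul),
    q_pv_la = resistive_flow(P[["pv"]], P[["la"]], circ$R_pv)
  )
  dV <- volume_derivatives(flows)
  dy <- c(
    V_lv = dV[["lv"]], V_la = dV[["la"]], V_rv = dV[["rv"]], V_ra = dV[["ra"]],
    V_ao = dV[["ao"]], V_sa = dV[["sa"]], V_sv = dV[["sv"]], V_vc = dV[["vc"]],
    V_pa = dV[["pa"]], V_pv = dV[["pv"]],
    Q_mv = mv$dQ, xi_mv = mv$dxi, Q_av = av$dQ, xi_av = av$dxi,
    Q_tv = tv$dQ, xi_tv = tv$dxi, Q_pu = pu$dQ, xi_pu = pu$dxi
  )
  list(dy = dy, pressures = P)
}

#' @export
print.cvs_sim <- function(x, ...) {
  d <- x$derived
  cat("Closed-loop cardiovascular simulation\n")
  cat(sprintf("  %d beats, T = %.3f s, output step %.0f ms%s\n",
              x$beats, x$T, x$dt * 1000,
              if (x$converged) "" else "  [NOT converged]"))
  cat(sprintf("  analysis beat: max P_LV = %.1f mmHg, aortic %.1f/%.1f mmHg\n",
              d$max_plv, d$Pao_sys, d$Pao_dias))
  cat(sprintf("  transvalvular gradient dP = %.1f mmHg, stroke volume %.1f mL\n",
              d$dP, d$sv))
  invisible(x)
}

#' @export
summary.cvs_sim <- function(object, ...) {
  vol_cols <- grep("^V_", names(object$ts), value = TRUE)
  tot <- rowSums(object$ts[vol_cols])
  out <- c(object$derived,
           list(volume_drift = (max(tot) - min(tot)) / tot[1],
                converged = object$converged))
  class(out) <- "summary.cvs_sim"
  out
}

#' @export
print.summary.cvs_sim <- function(x, ...) {
  cat(sprintf("max P_LV  %8.2f mmHg\nPao_sys   %8.2f mmHg\nPao_dias  %8.2f mmHg\n",
              x$max_plv, x$Pao_sys, x$Pao_dias))
  cat(sprintf("dP        %8.2f mmHg\nSV        %8.2f mL\n", x$dP, x$sv))
  cat(sprintf("volume drift %.2e (relative), converged: %s\n",
              x$volume_drift, x$converged))
  invisible(x)
}

#' Plot simulated hemodynamics
#'
#' Two panels over the last beats: LV/aortic/LA pressures, and valve
#' opening fractions.
#'
#' @param x a `cvs_sim` object.
#' @param beats how many trailing beats to show.
#' @param ... ignored.
#' @export
plot.cvs_sim <- function(x, beats = 3, ...) {
  ts <- x$ts
  t1 <- max(ts$time); t0 <- max(0, t1 - beats * x$T)
  w <- ts$time >= t0
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(ts$time[w], ts$P_lv[w], type = "l", col = "firebrick",
                 xlab = "time (s)", ylab = "pressure (mmHg)",
                 ylim = range(ts$P_lv[w], ts$P_ao[w], ts$P_la[w]))
  graphics::lines(ts$time[w], ts$P_ao[w], col = "navy")
  graphics::lines(ts$time[w], ts$P_la[w], col = "darkgreen")
  graphics::legend("topright", c("LV", "aorta", "LA"), lty = 1, bty = "n",
                   col = c("firebrick", "navy", "darkgreen"))
  graphics::plot(ts$time[w], ts$xi_av[w], type = "l", col = "navy",
                 xlab = "time (s)", ylab = "valve opening", ylim = c(0, 1))
  graphics::lines(ts$time[w], ts$xi_mv[w], col = "darkgreen")
  graphics::legend("topright", c("aortic", "mitral"), lty = 1, bty = "n",
                   col = c("navy", "darkgreen"))
  invisible(x)
}
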