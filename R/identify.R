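#' Identification cost functions
#'
#' Step 1 compares the full simulated LV pressure cycle plus the aortic
#' systolic/diastolic values with the measurements:
#' `J_step1 = J_PLV + J_Pao_sys + J_Pao_dias`, where `J_PLV` is the mean
#' absolute error between the experimental and simulated LV traces over
#' one cycle (both synchronised on the QRS) and the aortic terms are
#' absolute errors of the extrema.  Step 2 uses only the non-invasive
#' aortic terms: `J_step2 = J_Pao_sys + J_Pao_dias`.
#'
#' @param sim a `cvs_sim` simulated with the patient's cycle length.
#' @param record a [patient_record()].
#' @return list of class `cost_breakdown`: `J_PLV`, `J_Pao_sys`,
#'   `J_Pao_dias`, `J_step1`, `J_step2` (all mmHg, >= 0).
#' @export
cost_breakdown <- function(sim, record) {
  plv_model <- lv_pressure_cycle(sim, record$time)
  j_plv <- mean(abs(record$plv - plv_model))
  j_sys <- abs(record$pao_sys - sim$derived$Pao_sys)
  j_dias <- abs(record$pao_dias - sim$derived$Pao_dias)
  structure(list(J_PLV = j_plv, J_Pao_sys = j_sys, J_Pao_dias = j_dias,
                 J_step1 = j_plv + j_sys + j_dias,
                 J_step2 = j_sys + j_dias),
            class = "cost_breakdown")
}

#' @rdname cost_breakdown
#' @export
cost_step1 <- function(sim, record) cost_breakdown(sim, record)$J_step1

#' @rdname cost_breakdown
#' @export
cost_step2 <- function(sim, record) cost_breakdown(sim, record)$J_step2

#' Change the heart period of a parameter set
#'
#' Updates `T`, rebuilds the conduction network for the new pacing period
#' and keeps every other parameter unchanged.
#'
#' @param ps a [cvs_params()] object.
#' @param T new heart period (s).
#' @return modified parameter set.
#' @export
set_heart_period <- function(ps, T) {
  stopifnot(T > 0.2)
  ps$T <- T
  ps$electrical <- standard_conduction_network(T)
  validate_params(ps)
  ps
}

# nominal parameter set adapted to one patient: cycle length from the
# record, aortic effective area clamped to the measured AVA
patient_nominal <- function(record, ps = cvs_params()) {
  ps <- set_heart_period(ps, record$t_c)
  ps <- ps_set(ps, "valves.aortic.A_eff_max", record$ava)
  ps_set(ps, "valves.aortic.A_eff_min", 0.001 * record$ava)
}

# simulate one candidate parameter vector for one patient; identification
# runs use slightly relaxed solver tolerances (the costs are means and
# extrema, insensitive at that level) for speed
simulate_candidate <- function(x, view, base_ps, beats, dt,
                               rtol = 1e-5, atol = 1e-6) {
  ps <- apply_view(base_ps, x, view)
  cvs_simulate(ps, beats = beats, dt = dt, rtol = rtol, atol = atol,
               warn = FALSE)
}

#' Step-1 identification for one training patient
#'
#' Jointly identifies the ventricular (`X_LV`) and circulatory (`X_art`)
#' parameters by evolutionary minimisation of `J_step1`, with bounds
#' +/- `range_frac` around nominal values and the aortic effective area
#' fixed to the patient's AVA.
#'
#' @param record a [patient_record()] with an LV pressure trace.
#' @param ps nominal parameter set used as the identification centre.
#' @param control EA settings ([ea_control()]).
#' @param range_frac bound half-width (default 0.30, the sensitivity
#'   convention).
#' @param beats,dt per-evaluation simulation settings.
#' @param seed EA seed.
#' @return object of class `cvs_fit`: `par` (best `X_LV`/`X_art`
#'   values), `value`, `history`, `breakdown` (cost components at the
#'   optimum), `sim` (best simulation), `view`, `record_id`, `step`.
#' @export
fit_step1 <- function(record, ps = cvs_params(), control = ea_control(),
                      range_frac = 0.30, beats = 8, dt = 0.002,
                      rtol = 1e-5, atol = 1e-6, seed = 1) {
  view <- param_view("both")
  base <- patient_nominal(record, ps)
  nominal <- view_values(base, view)
  b <- relative_bounds(nominal, range_frac)
  fn <- function(x) cost_step1(simulate_candidate(x, view, base, beats, dt,
                                                  rtol, atol),
                               record)
  ea <- ea_minimize(fn, b$lower, b$upper, control = control, seed = seed)
  best_sim <- simulate_candidate(ea$par, view, base, beats, dt, rtol, atol)
  structure(list(par = ea$par, value = ea$value, history = ea$history,
                 evals = ea$evals,
                 breakdown = cost_breakdown(best_sim, record),
                 sim = best_sim, view = view, base = base,
                 record_id = record$id, step = 1L),
            class = "cvs_fit")
}

#' Step-2 identification for one test patient
#'
#' With the ventricular parameters frozen at the training-set average
#' `xlv_bar`, identifies only the circulatory subset `X_art` from the
#' non-invasive observables (aortic systolic/diastolic pressures; AVA
#' fixes the aortic valve area), then predicts the full LV pressure
#' curve.
#'
#' @param record a [patient_record()]; only its non-invasive fields enter
#'   the cost.
#' @param xlv_bar named numeric vector of averaged ventricular
#'   parameters (names as in `param_view("X_LV")`).
#' @inheritParams fit_step1
#' @return a `cvs_fit` (step = 2) whose `sim` carries the estimated LV
#'   pressure.
#' @export
fit_step2 <- function(record, xlv_bar, ps = cvs_params(),
                      control = ea_control(), range_frac = 0.30,
                      beats = 8, dt = 0.002, rtol = 1e-5, atol = 1e-6,
                      seed = 1) {
  view <- param_view("X_art")
  base <- patient_nominal(record, ps)
  base <- apply_view(base, xlv_bar, param_view("X_LV"))
  nominal <- view_values(base, view)
  b <- relative_bounds(nominal, range_frac)
  fn <- function(x) cost_step2(simulate_candidate(x, view, base, beats, dt,
                                                  rtol, atol),
                               record)
  ea <- ea_minimize(fn, b$lower, b$upper, control = control, seed = seed)
  best_sim <- simulate_candidate(ea$par, view, base, beats, dt, rtol, atol)
  structure(list(par = ea$par, value = ea$value, history = ea$history,
                 evals = ea$evals,
                 breakdown = cost_breakdown(best_sim, record),
                 sim = best_sim, view = view, base = base,
                 record_id = record$id, step = 2L),
            class = "cvs_fit")
}

#' @export
print.cvs_fit <- function(x, ...) {
  cat(sprintf("Step-%d identification of patient %s\n", x$step, x$record_id))
  cat(sprintf("  best cost %.4g mmHg after %d evaluations\n",
              x$value, x$evals))
  b <- x$breakdown
  cat(sprintf("  J_PLV %.3g  J_Pao_sys %.3g  J_Pao_dias %.3g\n",
              b$J_PLV, b$J_Pao_sys, b$J_Pao_dias))
  invisible(x)
}

#' @export
coef.cvs_fit <- function(object, ...) object$par

#' Predicted LV pressure of a fitted patient model
#'
#' @param object a `cvs_fit`.
#' @param t_e times since QRS (s); default the record grid used in the
#'   fit's simulation step.
#' @param ... ignored.
#' @return numeric vector of LV pressures (mmHg).
#' @export
predict.cvs_fit <- function(object, t_e = NULL, ...) {
  lv_pressure_cycle(object$sim, t_e)
}

#' Step 1 over a training set
#'
#' Runs [fit_step1()] on every training patient and averages the
#' ventricular estimates into `xlv_bar = mean(X_LV*)` (element-wise).
#' Patients whose identification fails are dropped from the average with
#' a message.
#'
#' @param records list of [patient_record()]s.
#' @param ... passed to [fit_step1()].
#' @param seed base seed; patient p uses `seed + p`.
#' @return list with `fits` (per patient) and `xlv_bar`.
#' @export
run_step1 <- function(records, ..., seed = 1) {
  fits <- list()
  for (p in seq_along(records)) {
    f <- tryCatch(fit_step1(records[[p]], ..., seed = seed + p),
                  error = function(e) {
                    message("step-1 failure for patient ",
                            records[[p]]$id, ": ", conditionMessage(e))
                    NULL
                  })
    if (!is.null(f)) fits[[records[[p]]$id]] <- f
  }
  if (!length(fits)) stop("no training patient could be identified")
  xlv_names <- names(param_view("X_LV"))
  xlv_bar <- colMeans(do.call(rbind,
                              lapply(fits, function(f) f$par[xlv_names])))
  list(fits = fits, xlv_bar = xlv_bar)
}

#' Step 2 over a test set
#'
#' @param records list of test [patient_record()]s.
#' @param xlv_bar averaged ventricular parameters from [run_step1()].
#' @param ... passed to [fit_step2()].
#' @param seed base seed.
#' @return named list of `cvs_fit`s.
#' @export
run_step2 <- function(records, xlv_bar, ..., seed = 1) {
  fits <- list()
  for (p in seq_along(records)) {
    f <- tryCatch(fit_step2(records[[p]], xlv_bar, ..., seed = seed + p),
                  error = function(e) {
                    message("step-2 failure for patient ",
                            records[[p]]$id, ": ", conditionMessage(e))
                    NULL
                  })
    if (!is.null(f)) fits[[records[[p]]$id]] <- f
  }
  fits
}

#' Monte-Carlo cross-validated two-step identification
#'
#' Repeats `N` times: split the cohort randomly into training and test
#' halves, identify `{X_LV, X_art}` per training patient (step 1, from
#' the invasive LV trace), freeze the ventricular average `xlv_bar`, and
#' identify `X_art` per test patient from the non-invasive observables
#' (step 2).  Each time a patient lands in a test set, its LV pressure
#' curve is estimated and pressure-strain work indices are computed from
#' it; per-patient markers are the arithmetic means over those
#' iterations.
#'
#' @param records list of [patient_record()]s (cohort size >= 2).
#' @param N number of Monte-Carlo realisations.
#' @param ps nominal parameter set.
#' @param control1,control2 EA settings for steps 1 and 2.
#' @param range_frac identification bound half-width.
#' @param beats,dt per-evaluation simulation settings.
#' @param seed master seed; the split of realisation n and all EA seeds
#'   derive from it.
#' @param smooth_strain smooth strain before differentiation in the work
#'   computation.
#' @return object of class `cvs_mccv`: list with `markers` (per-patient
#'   data.frame of averaged GCW/GWW/GWE and mean e%), `fits2` (all
#'   step-2 fits), `xlv_bars` (per-realisation), `splits`.
#' @export
mc_cross_validate <- function(records, N = 10, ps = cvs_params(),
                              control1 = ea_control(),
                              control2 = ea_control(),
                              range_frac = 0.30, beats = 8, dt = 0.002,
                              seed = 1, smooth_strain = FALSE) {
  n <- length(records)
  stopifnot(n >= 2, N >= 1)
  ids <- vapply(records, `[[`, "", "id")
  acc <- setNames(lapply(ids, function(i)
    list(GCW = numeric(), GWW = numeric(), GWE = numeric(),
         e_pct = numeric())), ids)
  splits <- list(); fits2 <- list(); xlv_bars <- list()
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  for (it in seq_len(N)) {
    set.seed(seed * 100L + it)
    train_idx <- sort(sample.int(n, floor(n / 2)))
    test_idx <- setdiff(seq_len(n), train_idx)
    splits[[it]] <- list(train = ids[train_idx], test = ids[test_idx])
    s1 <- run_step1(records[train_idx], ps = ps, control = control1,
                    range_frac = range_frac, beats = beats, dt = dt,
                    seed = seed * 1000L + it * 50L)
    xlv_bars[[it]] <- s1$xlv_bar
    s2 <- run_step2(records[test_idx], s1$xlv_bar, ps = ps,
                    control = control2, range_frac = range_frac,
                    beats = beats, dt = dt,
                    seed = seed * 1000L + it * 50L + 25L)
    for (id in names(s2)) {
      f <- s2[[id]]
      rec <- records[[match(id, ids)]]
      ss <- rec$strain
      plv_model <- lv_pressure_cycle(f$sim, ss$time)
      wi <- myocardial_work(ss, plv_model, smooth = smooth_strain)
      e_pct <- total_relative_error(
        rec$plv, lv_pressure_cycle(f$sim, rec$time),
        rec$pao_sys, f$sim$derived$Pao_sys,
        rec$pao_dias, f$sim$derived$Pao_dias)
      acc[[id]]$GCW <- c(acc[[id]]$GCW, wi$GCW)
      acc[[id]]$GWW <- c(acc[[id]]$GWW, wi$GWW)
      acc[[id]]$GWE <- c(acc[[id]]$GWE, wi$GWE)
      acc[[id]]$e_pct <- c(acc[[id]]$e_pct, e_pct)
      fits2[[paste0(id, "_it", it)]] <- f
    }
  }
  never <- ids[vapply(acc, function(a) length(a$GCW) == 0, TRUE)]
  if (length(never))
    warning("patient(s) never in a test set: ",
            paste(never, collapse = ", "), " (increase N)")
  markers <- do.call(rbind, lapply(ids, function(id) {
    a <- acc[[id]]
    data.frame(id = id, n_test = length(a$GCW),
               GCW = mean(a$GCW), GWW = mean(a$GWW), GWE = mean(a$GWE),
               e_pct = mean(a$e_pct))
  }))
  structure(list(markers = markers, fits2 = fits2, xlv_bars = xlv_bars,
                 splits = splits, N = N),
            class = "cvs_mccv")
}

#' @export
print.cvs_mccv <- function(x, ...) {
  cat(sprintf("Monte-Carlo cross-validated identification (%d realisations)\n",
              x$N))
  print.data.frame(x$markers, digits = 3, row.names = FALSE)
  invisible(x)
}
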