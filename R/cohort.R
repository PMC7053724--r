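#' Observation noise settings for virtual patients
#'
#' Defaults emulate the clinical acquisition chain: a fluid-filled
#' catheter LV trace resampled at 200 Hz with ~1 mmHg additive noise,
#' cuff-grade systolic/diastolic aortic readings (~2 mmHg), an
#' echocardiographic AVA taken as exact, and speckle-tracking strain at
#' 100 Hz with a small additive error.
#'
#' @param plv_sd LV pressure noise SD (mmHg).
#' @param pao_sd aortic systolic/diastolic reading noise SD (mmHg).
#' @param ava_sd AVA measurement noise SD (cm2).
#' @param strain_sd segmental strain noise SD (%).
#' @param plv_rate,strain_rate sampling rates (Hz).
#' @return list of settings.
#' @export
noise_control <- function(plv_sd = 1, pao_sd = 2, ava_sd = 0,
                          strain_sd = 0.05, plv_rate = 200,
                          strain_rate = 100) {
  list(plv_sd = plv_sd, pao_sd = pao_sd, ava_sd = ava_sd,
       strain_sd = strain_sd, plv_rate = plv_rate,
       strain_rate = strain_rate)
}

#' Patient record (observables of one patient)
#'
#' The observable data of one (real or virtual) patient: an LV pressure
#' trace over one cycle synchronised on the QRS, systolic/diastolic
#' aortic pressure values, the aortic valve area, and the segmental
#' strain set with valve event times.
#'
#' @param id patient identifier.
#' @param time time grid of the LV trace, seconds since QRS.
#' @param plv LV pressure trace (mmHg).
#' @param pao_sys,pao_dias aortic pressures (mmHg), `pao_sys > pao_dias > 0`.
#' @param ava aortic valve area (cm2), > 0.
#' @param strain a [strain_set()] (times in the same QRS-anchored frame).
#' @param t_c cycle duration (s); defaults to the trace span.
#' @return object of class `patient_record`.
#' @export
patient_record <- function(id, time, plv, pao_sys, pao_dias, ava, strain,
                           t_c = max(time)) {
  stopifnot(length(time) == length(plv), t_c > 0)
  if (!(pao_sys > pao_dias && pao_dias > 0))
    stop("need pao_sys > pao_dias > 0")
  if (ava <= 0) stop("AVA must be > 0")
  stopifnot(inherits(strain, "strain_set"))
  structure(list(id = id, time = time, plv = plv, pao_sys = pao_sys,
                 pao_dias = pao_dias, ava = ava, strain = strain,
                 t_c = t_c),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("Patient %s: T_c = %.2f s, Pao %.0f/%.0f mmHg, AVA %.2f cm2, %d strain segments\n",
              x$id, x$t_c, x$pao_sys, x$pao_dias, x$ava,
              ncol(x$strain$strain)))
  invisible(x)
}

#' Sample one virtual aortic-stenosis patient
#'
#' Draws a ground-truth parameter set around the nominal model (each
#' identified parameter jittered by a uniform +/- `jitter` factor), fixes
#' the aortic `A_eff_max` to the sampled AVA, simulates to periodic
#' steady state, and derives noisy observables.  Draws whose simulation
#' fails or does not converge are resampled (bounded retries).
#'
#' @param seed integer seed (drives the parameter draw and all noise).
#' @param ava aortic valve area (cm2); if `NULL`, drawn uniformly from
#'   `severity_range`.
#' @param severity_range AVA sampling range (cm2); the default covers
#'   severe stenosis.
#' @param jitter uniform relative half-width of the truth draw for the
#'   identified parameters (in \[0, 0.3\]).
#' @param t_range heart-period sampling range (s).
#' @param K number of strain segments.
#' @param noise a [noise_control()] list.
#' @param dyssynchrony optional list `list(n = , tau = )`: apply a time
#'   shift of `tau` seconds to `n` randomly chosen segments (default
#'   none; segments contract synchronously).
#' @param beats,dt simulation settings for the truth run.
#' @param max_retry resampling attempts on failure.
#' @return object of class `virtual_patient`: list with `id`, `truth`
#'   (the full `cvs_params`), `ava`, `sim` (the hidden truth
#'   `cvs_sim`), and `record` (the observable [patient_record()]).
#' @export
sample_patient <- function(seed, ava = NULL, severity_range = c(0.6, 1.0),
                           jitter = 0.15, t_range = c(0.8, 1.1), K = 18,
                           noise = noise_control(), dyssynchrony = NULL,
                           beats = 12, dt = 0.002, max_retry = 5) {
  stopifnot(jitter >= 0, jitter <= 0.3)
  for (attempt in 0:max_retry) {
    sd_i <- (seed * 131L + attempt) %% 2147483647L
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(sd_i)
    T_c <- round(runif(1, t_range[1], t_range[2]), 2)
    ava_i <- if (is.null(ava)) runif(1, severity_range[1], severity_range[2]) else ava
    view <- param_view("both")
    ps <- cvs_params(T = T_c)
    nom <- view_values(ps, view)
    truth_vals <- nom * (1 + runif(length(nom), -jitter, jitter))
    ps <- apply_view(ps, truth_vals, view)
    ps <- ps_set(ps, "valves.aortic.A_eff_max", ava_i)
    ps <- ps_set(ps, "valves.aortic.A_eff_min", 0.001 * ava_i)
    sim <- tryCatch(cvs_simulate(ps, beats = beats, dt = dt, warn = FALSE),
                    error = function(e) NULL)
    noise_seed <- sd_i + 1L
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    if (!is.null(sim) && sim$converged) {
      vp <- structure(list(id = paste0("vp", seed), truth = ps,
                           ava = ava_i, sim = sim, record = NULL),
                      class = "virtual_patient")
      vp$record <- degrade_to_observables(vp, noise, K = K,
                                          dyssynchrony = dyssynchrony,
                                          seed = noise_seed)
      return(vp)
    }
  }
  stop("non-physiological draw: simulation failed after ", max_retry,
       " retries (seed ", seed, ")")
}

#' Degrade a virtual patient's truth into noisy observables
#'
#' Applies the measurement model: the true LV pressure of the analysis
#' beat is resampled at the catheter rate plus Gaussian noise; aortic
#' systolic/diastolic values are the true extrema plus reading noise
#' (clipped to keep sys > dias); AVA optionally noised; strain traces via
#' [synth_strain()].
#'
#' @param vp a `virtual_patient` with a simulated truth.
#' @param noise a [noise_control()] list.
#' @param K number of strain segments.
#' @param dyssynchrony see [sample_patient()].
#' @param seed seed for the noise draws.
#' @return a [patient_record()].
#' @export
degrade_to_observables <- function(vp, noise = noise_control(), K = 18,
                                   dyssynchrony = NULL, seed = 1) {
  sim <- vp$sim
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  T_c <- sim$T
  t_e <- seq(0, T_c, by = 1 / noise$plv_rate)
  plv <- lv_pressure_cycle(sim, t_e) + rnorm(length(t_e), 0, noise$plv_sd)
  d <- sim$derived
  pao_sys <- d$Pao_sys + rnorm(1, 0, noise$pao_sd)
  pao_dias <- d$Pao_dias + rnorm(1, 0, noise$pao_sd)
  if (pao_dias >= pao_sys) {         # enforce the record invariant
    mid <- (pao_sys + pao_dias) / 2
    pao_sys <- mid + 1; pao_dias <- mid - 1
  }
  pao_dias <- max(pao_dias, 1)
  ava <- max(vp$ava + rnorm(1, 0, noise$ava_sd), 0.1)
  ss <- synth_strain(vp, K = K, dyssynchrony = dyssynchrony,
                     noise_sd = noise$strain_sd,
                     rate = noise$strain_rate)
  patient_record(id = vp$id, time = t_e, plv = plv, pao_sys = pao_sys,
                 pao_dias = pao_dias, ava = ava, strain = ss, t_c = T_c)
}

#' Synthetic segmental strain from the true LV volume
#'
#' The lumped model has no regional mechanics, so segmental longitudinal
#' strain is synthesised from the true LV volume trace under a
#' self-similar geometry assumption:
#' \deqn{\epsilon_{base}(t) = 100\,\left[(V(t)/V(MVC))^{1/3} - 1\right],}
#' which yields physiological magnitudes (about -15 to -20% at end
#' systole).  Segment k applies an amplitude scale `s_k` (uniform 0.9 to
#' 1.1), an optional dyssynchronous time shift, and additive noise.
#' Valve events are copied from the truth simulation.
#'
#' @inheritParams degrade_to_observables
#' @param noise_sd additive strain noise SD (%).
#' @param rate strain sampling rate (Hz).
#' @param scales optional explicit amplitude scales (length K).
#' @param shifts optional explicit per-segment time shifts (s).
#' @return a [strain_set()], times anchored at the QRS of the analysis
#'   beat.
#' @export
synth_strain <- function(vp, K = 18, dyssynchrony = NULL, noise_sd = 0.05,
                         rate = 100, scales = NULL, shifts = NULL,
                         seed = NULL) {
  stopifnot(K >= 1)
  if (!is.null(seed)) set.seed(seed)
  sim <- vp$sim
  T_c <- sim$T
  t0 <- sim$analysis_window[1]
  tt <- seq(0, T_c, by = 1 / rate)
  V <- stats::approx(sim$ts$time, sim$ts$V_lv, xout = t0 + tt, rule = 2)$y
  ev_row <- sim$events$valves[nrow(sim$events$valves), ]
  # mitral closure may fall a few ms before the QRS anchor; clamp to the
  # start of the observed cycle
  ev <- list(MVC = max(ev_row$MVC - t0, 0), AVO = ev_row$AVO - t0,
             AVC = ev_row$AVC - t0, MVO = min(ev_row$MVO - t0, T_c))
  v_mvc <- stats::approx(tt, V, xout = max(ev$MVC, 0), rule = 2)$y
  eps_base <- 100 * ((V / v_mvc)^(1 / 3) - 1)
  if (is.null(scales)) scales <- runif(K, 0.9, 1.1)
  if (is.null(shifts)) {
    shifts <- rep(0, K)
    if (!is.null(dyssynchrony)) {
      idx <- sample.int(K, min(dyssynchrony$n, K))
      shifts[idx] <- dyssynchrony$tau
    }
  }
  strain <- sapply(seq_len(K), function(k) {
    e <- stats::approx(tt + shifts[k], eps_base, xout = tt, rule = 2)$y
    scales[k] * e + rnorm(length(tt), 0, noise_sd)
  })
  colnames(strain) <- paste0("seg", seq_len(K))
  strain_set(tt, strain, ev)
}

#' Generate a virtual aortic-stenosis cohort
#'
#' Default mirrors the structure of a severe-AS catheterisation cohort:
#' `n = 12` patients, all but one with AVA <= 1.0 cm2 (severe), one
#' moderate (AVA in 1.0 to 1.5 cm2).  Fully reproducible from the master
#' seed.
#'
#' @param n cohort size.
#' @param seed master seed; per-patient seeds are derived from it.
#' @param n_moderate number of moderate-AS patients.
#' @param ... passed to [sample_patient()].
#' @return object of class `virtual_cohort`: list of `virtual_patient`s.
#' @export
synth_cohort <- function(n = 12, seed = 1, n_moderate = 1, ...) {
  stopifnot(n >= 1, n_moderate <= n)
  patients <- lapply(seq_len(n), function(i) {
    rng <- if (i <= n - n_moderate) c(0.6, 1.0) else c(1.0, 1.5)
    vp <- sample_patient(seed = seed * 1000L + i, severity_range = rng, ...)
    vp$id <- sprintf("vp%02d", i)
    vp$record$id <- vp$id
    vp
  })
  structure(patients, class = "virtual_cohort")
}

#' @export
print.virtual_cohort <- function(x, ...) {
  cat(sprintf("Virtual AS cohort: %d patients\n", length(x)))
  for (vp in x)
    cat(sprintf("  %s  AVA %.2f cm2, T_c %.2f s, dP %.1f mmHg\n",
                vp$id, vp$ava, vp$sim$T, vp$sim$derived$dP))
  invisible(x)
}

#' Records of a virtual cohort
#' @param cohort a `virtual_cohort`.
#' @return list of [patient_record()]s.
#' @export
cohort_records <- function(cohort) lapply(cohort, `[[`, "record")

# ---- plain-text cohort I/O --------------------------------------------

#' Write / read a patient record as delimited text
#'
#' One directory per patient: `plv.csv` (time_s, pressure_mmhg),
#' `obs.json` (pao_sys, pao_dias, ava_cm2, t_c), `strain.csv` (time_s +
#' one column per segment, %), `events.json` (MVC/AVO/AVC/MVO, s).
#'
#' @param record a [patient_record()].
#' @param dir directory to write into (created if needed).
#' @return `write_patient` the directory, invisibly; `read_patient` a
#'   [patient_record()].
#' @export
write_patient <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(time_s = record$time,
                              pressure_mmhg = record$plv),
                   file.path(dir, "plv.csv"), row.names = FALSE)
  jsonlite::write_json(list(id = record$id, pao_sys = record$pao_sys,
                            pao_dias = record$pao_dias,
                            ava_cm2 = record$ava, t_c = record$t_c),
                       file.path(dir, "obs.json"), auto_unbox = TRUE,
                       digits = NA)
  ss <- record$strain
  utils::write.csv(data.frame(time_s = ss$time, ss$strain,
                              check.names = FALSE),
                   file.path(dir, "strain.csv"), row.names = FALSE)
  jsonlite::write_json(ss$events, file.path(dir, "events.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_patient
#' @export
read_patient <- function(dir) {
  plv <- utils::read.csv(file.path(dir, "plv.csv"))
  obs <- jsonlite::read_json(file.path(dir, "obs.json"))
  sdf <- utils::read.csv(file.path(dir, "strain.csv"), check.names = FALSE)
  ev <- jsonlite::read_json(file.path(dir, "events.json"))
  ss <- strain_set(sdf$time_s, as.matrix(sdf[-1]), ev)
  patient_record(id = obs$id %||% basename(dir), time = plv$time_s,
                 plv = plv$pressure_mmhg, pao_sys = obs$pao_sys,
                 pao_dias = obs$pao_dias, ava = obs$ava_cm2,
                 strain = ss, t_c = obs$t_c)
}

#' @rdname write_patient
#' @param cohort a `virtual_cohort` or list of records.
#' @param path cohort directory; one subdirectory per patient.
#' @export
write_cohort <- function(cohort, path) {
  recs <- if (inherits(cohort, "virtual_cohort")) cohort_records(cohort)
          else cohort
  for (r in recs) write_patient(r, file.path(path, r$id))
  invisible(path)
}

#' @rdname write_patient
#' @export
read_cohort <- function(path) {
  dirs <- list.dirs(path, recursive = FALSE)
  lapply(dirs, read_patient)
}
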