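#' Load and validate a run configuration
#'
#' Reads a JSON or YAML configuration, rejects unknown keys, fills
#' defaults and returns a resolved configuration.  Recognised top-level
#' keys:
#' \describe{
#'   \item{T}{heart period (s).}
#'   \item{params}{named list of dotted parameter overrides applied via
#'     [cvs_params()], e.g. `valves.aortic.A_eff_max: 0.75`.}
#'   \item{solver}{`beats`, `dt`, `rtol`, `atol`.}
#'   \item{ea}{arguments of [ea_control()].}
#'   \item{morris}{`r`, `levels`, `range_frac`.}
#'   \item{cohort}{`n`, `jitter`, `K`, `n_moderate`.}
#'   \item{seed}{master seed (mandatory for stochastic commands).}
#' }
#'
#' @param path file path (`.json`, `.yaml` or `.yml`).
#' @return list of class `run_config` with elements `params`
#'   (a [cvs_params()]), `solver`, `ea`, `morris`, `cohort`, `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw)) raw <- list()
  known <- c("T", "params", "solver", "ea", "morris", "cohort", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  sub_known <- list(solver = c("beats", "dt", "rtol", "atol"),
                    morris = c("r", "levels", "range_frac"),
                    cohort = c("n", "jitter", "K", "n_moderate"))
  for (s in names(sub_known)) {
    bad <- setdiff(names(raw[[s]]), sub_known[[s]])
    if (length(bad))
      stop("unknown key(s) under '", s, "': ", paste(bad, collapse = ", "))
  }
  T <- raw$T %||% 1.0
  overrides <- raw$params %||% list()
  ps <- do.call(cvs_params, c(overrides, list(T = T)))
  solver <- utils::modifyList(list(beats = 15, dt = 0.001,
                                   rtol = 1e-6, atol = 1e-8),
                              raw$solver %||% list())
  ea <- do.call(ea_control, raw$ea %||% list())
  morris <- utils::modifyList(list(r = 10, levels = 4, range_frac = 0.30),
                              raw$morris %||% list())
  cohort <- utils::modifyList(list(n = 12, jitter = 0.15, K = 18,
                                   n_moderate = 1),
                              raw$cohort %||% list())
  structure(list(params = ps, solver = solver, ea = ea, morris = morris,
                 cohort = cohort, seed = raw$seed),
            class = "run_config")
}

#' Serialise a resolved configuration next to the outputs
#'
#' Writes the fully-resolved configuration (all defaults filled) as JSON
#' for provenance; loading the written file reproduces the resolved
#' settings.
#'
#' @param cfg a `run_config`.
#' @param path output file (`.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  ps <- cfg$params
  flat <- function(prefix, x) {
    out <- list()
    for (nm in names(x)) {
      v <- x[[nm]]
      key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
      if (is.list(v)) out <- c(out, flat(key, v))
      else out[[key]] <- v
    }
    out
  }
  params <- c(flat("lv", ps$lv), flat("rv", ps$rv), flat("la", ps$la),
              flat("ra", ps$ra), flat("valves", lapply(ps$valves, unclass)),
              flat("circulation", ps$circulation), flat("init", ps$init),
              list(rho = ps$rho))
  jsonlite::write_json(list(T = ps$T, params = params, solver = cfg$solver,
                            ea = cfg$ea[setdiff(names(cfg$ea), "init")],
                            morris = cfg$morris, cohort = cfg$cohort,
                            seed = cfg$seed),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Export a simulation as delimited text
#'
#' Writes the sampled time series as CSV (one column per state and
#' pressure signal) and the event markers (QRS, per-beat MVC/AVO/AVC/MVO)
#' as a JSON sidecar.
#'
#' @param sim a `cvs_sim`.
#' @param csv output CSV path.
#' @param events_json optional JSON sidecar path (default: alongside
#'   `csv`).
#' @return `csv`, invisibly.
#' @export
export_simulation <- function(sim, csv,
                              events_json = sub("\\.csv$", "_events.json",
                                                csv)) {
  utils::write.csv(sim$ts, csv, row.names = FALSE)
  jsonlite::write_json(
    list(qrs = sim$events$qrs, valves = sim$events$valves,
         derived = sim$derived, converged = sim$converged),
    events_json, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(csv)
}
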