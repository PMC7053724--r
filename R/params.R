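#' Model parameter set
#'
#' Builds the full parameter set of the closed-loop cardiovascular model:
#' cardiac conduction network timings, ventricular and atrial chamber laws,
#' the four heart valves, and the systemic/pulmonary circulation.  Defaults
#' describe a resting healthy adult (heart period 1 s, aortic valve area
#' 2.5 cm2) and are calibrated so that the nominal simulation reproduces a
#' systolic left-ventricular pressure of about 120 mmHg with aortic pressure
#' cycling between roughly 50 and 120 mmHg; reducing the aortic
#' `A_eff_max` to stenotic values (around 0.75 cm2) reproduces the
#' transvalvular gradient of severe aortic stenosis.
#'
#' Units are mmHg, mL and s throughout; valve geometry is in cm/cm2 and
#' blood density in g/cm3, converted internally once (see
#' [bernoulli_coefficients()]).
#'
#' @param ... named overrides. Each name is a dotted path into the nested
#'   parameter list, e.g. `lv.E_es = 3`, `valves.aortic.A_eff_max = 0.75`,
#'   `circulation.R_sys = 1.1`. Whole sublists may also be replaced with
#'   lists.
#' @param T heart period in seconds (sets the conduction network cycle and
#'   all driver clocks).
#'
#' @return An object of class `cvs_params`: a nested named list with
#'   components `T`, `electrical`, `lv`, `rv`, `la`, `ra`, `valves`
#'   (mitral/aortic/tricuspid/pulmonary), `circulation`, and `init`
#'   (initial pressures used to distribute blood volume at t = 0).
#' @seealso [cvs_simulate()], [param_view()] for the identified parameter
#'   subsets `X_LV` and `X_art`.
#' @export
#' @examples
#' ps <- cvs_params()
#' ps_as <- cvs_params(valves.aortic.A_eff_max = 0.75)
cvs_params <- function(..., T = 1.0) {
  stopifnot(is.numeric(T), length(T) == 1L, T > 0)
  ps <- default_params(T)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all overrides must be named")
    for (nm in names(dots)) ps <- ps_set(ps, nm, dots[[nm]])
  }
  validate_params(ps)
  ps
}

default_params <- function(T = 1.0) {
  hill <- list(a1 = 0.303, a2 = 0.508, n1 = 1.32, n2 = 21.9)
  ps <- list(
    T = T,
    electrical = standard_conduction_network(T),
    lv = c(list(E_es = 3.4, V_d = 10, P_0 = 0.9, lambda = 0.022, V_0 = 10), hill),
    rv = c(list(E_es = 0.7, V_d = 5, P_0 = 0.35, lambda = 0.023, V_0 = 5), hill),
    la = list(E_max = 0.40, E_min = 0.15, V_d = 10, B = 300, C = 0.10),
    ra = list(E_max = 0.30, E_min = 0.12, V_d = 10, B = 300, C = 0.10),
    rho = 1.06,  # g/cm3
    valves = list(
      mitral    = valve_params(A_eff_max = 4.0, l_eff = 1.8, K_vo = 30, K_vc = 40),
      aortic    = valve_params(A_eff_max = 2.5, l_eff = 1.5, K_vo = 20, K_vc = 25),
      tricuspid = valve_params(A_eff_max = 5.0, l_eff = 1.8, K_vo = 30, K_vc = 40),
      pulmonary = valve_params(A_eff_max = 3.0, l_eff = 1.5, K_vo = 20, K_vc = 25)
    ),
    circulation = list(
      E_ao = 2.40, Vd_ao = 50,
      E_sa = 3.00, Vd_sa = 200,
      E_sv = 0.018, Vd_sv = 800,
      E_vc = 0.012, Vd_vc = 300,
      E_pa = 0.45, Vd_pa = 20,
      E_pv = 0.045, Vd_pv = 100,
      R_ao = 0.03, R_sys = 0.90, R_vc = 0.05,
      R_ra = 0.025, R_pul = 0.08, R_pv = 0.035,
      total_volume = 3000
    ),
    # initial pressures (mmHg) from which starting volumes are distributed
    init = list(lv = 8, la = 8, rv = 4, ra = 4, ao = 75, sa = 70,
                sv = 10, vc = 4.5, pa = 15, pv = 8)
  )
  class(ps) <- "cvs_params"
  ps
}

#' Valve parameter block
#'
#' @param A_eff_max maximal effective orifice area (cm2). For the aortic
#'   valve this is the quantity fixed to the echocardiographic AVA during
#'   patient-specific identification.
#' @param A_eff_min minimal (closed) effective area (cm2); defaults to
#'   0.1% of `A_eff_max`, a negligible leakage that keeps the Bernoulli
#'   resistance finite.
#' @param l_eff effective length of the valve (cm).
#' @param K_vo,K_vc opening and closing rate constants (1/(mmHg s)).
#' @return named list of class `valve_params`.
#' @export
valve_params <- function(A_eff_max, A_eff_min = 0.001 * A_eff_max,
                         l_eff = 1.5, K_vo = 20, K_vc = 25) {
  stopifnot(A_eff_max > A_eff_min, A_eff_min >= 0, l_eff > 0,
            K_vo > 0, K_vc > 0)
  structure(list(A_eff_max = A_eff_max, A_eff_min = A_eff_min,
                 l_eff = l_eff, K_vo = K_vo, K_vc = K_vc),
            class = "valve_params")
}

validate_params <- function(ps) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid parameters: ", msg)
  chk(ps$T > 0, "T must be > 0")
  for (v in c("lv", "rv")) {
    b <- ps[[v]]
    chk(b$E_es > 0, paste0(v, ".E_es must be > 0"))
    chk(b$lambda > 0, paste0(v, ".lambda must be > 0"))
    chk(b$P_0 > 0, paste0(v, ".P_0 must be > 0"))
    chk(b$n1 >= 1 && b$n2 >= 1, paste0(v, ": n1, n2 must be >= 1"))
    chk(b$a1 > 0 && b$a1 < 1.5 && b$a2 > 0 && b$a2 < 1.5,
        paste0(v, ": a1, a2 must lie in (0, 1.5)"))
  }
  for (a in c("la", "ra")) {
    b <- ps[[a]]
    chk(b$E_max >= b$E_min && b$E_min > 0, paste0(a, ": need E_max >= E_min > 0"))
    chk(b$B > 0, paste0(a, ".B must be > 0"))
    chk(b$C >= 0 && b$C < ps$T, paste0(a, ".C must lie in [0, T)"))
  }
  for (v in names(ps$valves)) {
    b <- ps$valves[[v]]
    chk(b$A_eff_max > b$A_eff_min && b$A_eff_min >= 0,
        paste0("valve ", v, ": need A_eff_max > A_eff_min >= 0"))
  }
  circ <- ps$circulation
  en <- grep("^E_", names(circ), value = TRUE)
  rn <- grep("^R_", names(circ), value = TRUE)
  chk(all(unlist(circ[en]) > 0), "all vessel elastances must be > 0")
  chk(all(unlist(circ[rn]) > 0), "all resistances must be > 0")
  chk(ps$rho > 0, "rho must be > 0")
  invisible(ps)
}

#' @export
print.cvs_params <- function(x, ...) {
  cat("Closed-loop cardiovascular model parameters\n")
  cat(sprintf("  heart period T = %.3f s (HR %.0f bpm)\n", x$T, 60 / x$T))
  cat(sprintf("  LV: E_es = %.2f mmHg/mL, lambda = %.3f 1/mL, P_0 = %.2f mmHg\n",
              x$lv$E_es, x$lv$lambda, x$lv$P_0))
  cat(sprintf("  aortic valve A_eff_max = %.2f cm2\n",
              x$valves$aortic$A_eff_max))
  cat(sprintf("  R_sys = %.2f mmHg s/mL, E_ao = %.2f mmHg/mL\n",
              x$circulation$R_sys, x$circulation$E_ao))
  invisible(x)
}

# ---- dotted-path access -----------------------------------------------

#' Get or set a parameter by dotted path
#'
#' @param ps a `cvs_params` object.
#' @param path character scalar such as `"lv.E_es"` or
#'   `"valves.aortic.A_eff_max"`.
#' @param value replacement value.
#' @return `ps_get` returns the value; `ps_set` the modified object.
#' @export
ps_get <- function(ps, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  out <- ps
  for (k in keys) {
    if (is.null(out[[k]])) stop("unknown parameter path: ", path)
    out <- out[[k]]
  }
  out
}

#' @rdname ps_get
#' @export
ps_set <- function(ps, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(node, keys) {
    k <- keys[[1]]
    if (!k %in% names(node) && !identical(k, "electrical"))
      stop("unknown parameter path component: ", k)
    if (length(keys) == 1L) node[[k]] <- value
    else node[[k]] <- rec(node[[k]], keys[-1])
    node
  }
  out <- rec(ps, keys)
  class(out) <- class(ps)
  out
}

# ---- identified parameter views ---------------------------------------

#' Identified parameter subsets X_LV and X_art
#'
#' The ventricular subset `X_LV` = \{E_es_lv, lambda_lv, P_0_lv, alpha_1,
#' alpha_2, n_1, n_2\} and the circulatory subset `X_art` = \{E_ao, E_vc,
#' E_sa, E_sv, Vd_ao, Vd_vc, Vd_sa, Vd_sv, R_ao, R_sys, R_vc\} are the
#' parameters retained for patient-specific estimation after sensitivity
#' screening; the remaining constants stay at nominal values.
#'
#' @param which `"X_LV"`, `"X_art"`, or `"both"`.
#' @return named character vector mapping identified-parameter names to
#'   dotted paths into a `cvs_params` object.
#' @export
param_view <- function(which = c("both", "X_LV", "X_art")) {
  which <- match.arg(which)
  xlv <- c(E_es_lv = "lv.E_es", lambda_lv = "lv.lambda", P_0_lv = "lv.P_0",
           alpha_1 = "lv.a1", alpha_2 = "lv.a2", n_1 = "lv.n1", n_2 = "lv.n2")
  xart <- c(E_ao = "circulation.E_ao", E_vc = "circulation.E_vc",
            E_sa = "circulation.E_sa", E_sv = "circulation.E_sv",
            Vd_ao = "circulation.Vd_ao", Vd_vc = "circulation.Vd_vc",
            Vd_sa = "circulation.Vd_sa", Vd_sv = "circulation.Vd_sv",
            R_ao = "circulation.R_ao", R_sys = "circulation.R_sys",
            R_vc = "circulation.R_vc")
  switch(which, X_LV = xlv, X_art = xart, both = c(xlv, xart))
}

#' Extract the numeric values of a parameter view
#' @param ps a `cvs_params` object.
#' @param view named character vector of dotted paths (see [param_view()]).
#' @return named numeric vector.
#' @export
view_values <- function(ps, view = param_view()) {
  vapply(view, function(p) as.numeric(ps_get(ps, p)), numeric(1))
}

#' Apply numeric values of a view back into a parameter set
#' @inheritParams view_values
#' @param values named numeric vector; names must be a subset of
#'   `names(view)`.
#' @return modified `cvs_params` object.
#' @export
apply_view <- function(ps, values, view = param_view()) {
  for (nm in names(values)) {
    if (!nm %in% names(view)) stop("not in view: ", nm)
    ps <- ps_set(ps, view[[nm]], as.numeric(values[[nm]]))
  }
  ps
}

#' Symmetric relative bounds around nominal values
#' @param nominal named numeric vector.
#' @param frac half-width as a fraction of the nominal value (default 0.30,
#'   the same convention used for the sensitivity ranges).
#' @return list with `lower` and `upper` named vectors.
#' @export
relative_bounds <- function(nominal, frac = 0.30) {
  stopifnot(frac >= 0)
  half <- abs(nominal) * frac
  list(lower = nominal - half, upper = nominal + half)
}

# ---- packing for the compiled right-hand side -------------------------

MMHG_PER_CGS <- 1333.22  # dyn/cm2 per mmHg

vblock <- function(b) c(b$E_es, b$V_d, b$P_0, b$lambda, b$V_0,
                        hill_norm_k(b), b$a1, b$a2, b$n1, b$n2)

pack_parms <- function(ps, offsets) {
  ab <- function(b) c(b$E_max, b$E_min, b$V_d, b$B, b$C)
  vv <- function(b) c(b$A_eff_max, b$A_eff_min, b$l_eff, b$K_vo, b$K_vc)
  circ <- ps$circulation
  c(ps$T,
    offsets[c("lv", "rv", "la", "ra")],
    vblock(ps$lv), vblock(ps$rv),
    ab(ps$la), ab(ps$ra),
    ps$rho / MMHG_PER_CGS,
    vv(ps$valves$mitral), vv(ps$valves$aortic),
    vv(ps$valves$tricuspid), vv(ps$valves$pulmonary),
    circ$E_ao, circ$Vd_ao, circ$E_sa, circ$Vd_sa, circ$E_sv, circ$Vd_sv,
    circ$E_vc, circ$Vd_vc, circ$E_pa, circ$Vd_pa, circ$E_pv, circ$Vd_pv,
    circ$R_ao, circ$R_sys, circ$R_vc, circ$R_ra, circ$R_pul, circ$R_pv)
}

# Initial state: cardiac chambers start from target filling pressures
# (ventricles on the EDPVR, atria at minimal elastance); the remaining
# blood volume is distributed over the vessel chambers on top of their
# unstressed volumes, proportionally to nominal stressed volumes implied
# by the initial pressures.  Total blood volume is thus exactly
# circulation$total_volume, and unstressed-volume changes trade against
# stressed (pressure-generating) volume as they do physiologically.
initial_state <- function(ps) {
  ini <- ps$init
  inv_edpvr <- function(P, b) b$V_0 + log(P / b$P_0 + 1) / b$lambda
  circ <- ps$circulation
  heart <- c(
    V_lv = inv_edpvr(ini$lv, ps$lv),
    V_la = ps$la$V_d + ini$la / ps$la$E_min,
    V_rv = inv_edpvr(ini$rv, ps$rv),
    V_ra = ps$ra$V_d + ini$ra / ps$ra$E_min
  )
  vessels <- c("ao", "sa", "sv", "vc", "pa", "pv")
  vd <- vapply(vessels, function(v) circ[[paste0("Vd_", v)]], 0)
  stressed <- vapply(vessels, function(v)
    ini[[v]] / circ[[paste0("E_", v)]], 0)
  budget <- circ$total_volume - sum(heart) - sum(vd)
  if (budget <= 0.05 * sum(stressed))
    stop("total blood volume too small for the unstressed volumes")
  kappa <- budget / sum(stressed)
  vv <- vd + kappa * stressed
  c(heart,
    V_ao = vv[["ao"]], V_sa = vv[["sa"]], V_sv = vv[["sv"]],
    V_vc = vv[["vc"]], V_pa = vv[["pa"]], V_pv = vv[["pv"]],
    Q_mv = 0, xi_mv = 0, Q_av = 0, xi_av = 0,
    Q_tv = 0, xi_tv = 0, Q_pu = 0, xi_pu = 0)
}
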