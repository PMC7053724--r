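#' Effective valve orifice area
#'
#' Linear interpolation between the closed and open effective areas by the
#' opening fraction xi: `A_eff = (A_eff_max - A_eff_min) xi + A_eff_min`.
#'
#' @param xi opening fraction in \[0, 1\] (vectorised).
#' @param params a [valve_params()] block.
#' @return effective area (cm2).
#' @export
effective_area <- function(xi, params) {
  if (any(xi < 0 | xi > 1)) stop("xi must lie in [0, 1]")
  (params$A_eff_max - params$A_eff_min) * xi + params$A_eff_min
}

#' Bernoulli resistance and blood inertance of a valve
#'
#' From the instantaneous effective area:
#' \deqn{B = \rho / (2 A_{eff}^2), \qquad L = \rho l_{eff} / A_{eff}.}
#' With rho in g/cm3, areas in cm2, lengths in cm and flow in mL/s these
#' come out in CGS pressure units (dyn/cm2); a single division by
#' 1333.22 dyn/cm2 per mmHg converts them to mmHg s2/mL2 and mmHg s2/mL,
#' the units used by the pressure equations.  The conversion happens here
#' and nowhere else.
#'
#' @param A_eff effective area (cm2), > 0.
#' @param params valve block (for `l_eff`).
#' @param rho blood density (g/cm3), default 1.06.
#' @return list with `B` (mmHg s2/mL2) and `L` (mmHg s2/mL).
#' @export
bernoulli_coefficients <- function(A_eff, params, rho = 1.06) {
  if (any(A_eff <= 0)) stop("A_eff must be > 0")
  rc <- rho / MMHG_PER_CGS
  list(B = rc / (2 * A_eff^2), L = rc * params$l_eff / A_eff)
}

#' Valve state derivatives
#'
#' The transvalvular flow obeys a Bernoulli law with inertance,
#' \deqn{dQ/dt = (\Delta P - B Q |Q|) / L,}
#' and the opening fraction follows first-order pressure-driven dynamics,
#' \deqn{d\xi/dt = (1-\xi) K_{vo} \Delta P \ \mathrm{if}\ \Delta P > 0,
#'   \qquad \xi K_{vc} \Delta P \ \mathrm{otherwise}.}
#' Both xi = 0 and xi = 1 are invariant manifolds, so xi stays in \[0, 1\]
#' along any trajectory.
#'
#' @param dP pressure gradient upstream minus downstream (mmHg).
#' @param state list or numeric vector with `Q` (mL/s) and `xi`.
#' @param params a [valve_params()] block.
#' @param rho blood density (g/cm3).
#' @return list with `dQ` and `dxi`.
#' @export
valve_derivatives <- function(dP, state, params, rho = 1.06) {
  Q <- state$Q %||% state[["Q"]]
  xi <- state$xi %||% state[["xi"]]
  stopifnot(xi >= 0, xi <= 1)
  A <- effective_area(xi, params)
  bl <- bernoulli_coefficients(A, params, rho)
  dQ <- (dP - bl$B * Q * abs(Q)) / bl$L
  dxi <- if (dP > 0) (1 - xi) * params$K_vo * dP else xi * params$K_vc * dP
  list(dQ = dQ, dxi = dxi)
}
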