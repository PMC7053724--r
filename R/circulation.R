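#' Vessel chamber pressure
#'
#' Arterial and venous compartments follow a linear elastance law
#' `P = E (V - V_d)`.
#'
#' @param V volume (mL), >= 0.
#' @param E elastance (mmHg/mL).
#' @param V_d unstressed volume (mL).
#' @return pressure (mmHg).
#' @export
vessel_pressure <- function(V, E, V_d) {
  stopifnot(all(V >= 0))
  E * (V - V_d)
}

#' Resistive inter-chamber flow
#'
#' Signed Ohmic flow `Q = (P_up - P_down) / R`; pure resistances have no
#' diode behaviour (valves do).
#'
#' @param P_up,P_down pressures (mmHg).
#' @param R resistance (mmHg s/mL), > 0.
#' @return flow (mL/s).
#' @export
resistive_flow <- function(P_up, P_down, R) {
  if (any(R <= 0)) stop("R must be > 0")
  (P_up - P_down) / R
}

#' Closed-loop flow topology
#'
#' Edge list of the circulation: each row carries a named flow from one
#' chamber to the next.  Chamber names follow the closed-loop layout
#' LV -> ao -> sa -> sv -> vc -> RA -> RV -> pa -> pv -> LA -> LV, with the
#' four valves at the cardiac interfaces.
#'
#' @return data.frame with columns `flow`, `from`, `to`.
#' @export
cvs_topology <- function() {
  data.frame(
    flow = c("Q_mv", "Q_av", "q_ao_sa", "q_sa_sv", "q_sv_vc", "q_vc_ra",
             "Q_tv", "Q_pu", "q_pa_pv", "q_pv_la"),
    from = c("la", "lv", "ao", "sa", "sv", "vc", "ra", "rv", "pa", "pv"),
    to   = c("lv", "ao", "sa", "sv", "vc", "ra", "rv", "pa", "pv", "la"),
    stringsAsFactors = FALSE
  )
}

#' Volume derivatives from a set of flows
#'
#' Conservation bookkeeping: `dV_i/dt` is the sum of inflows minus the sum
#' of outflows of chamber i.  By construction the derivatives sum to zero
#' (closed loop, no sources or sinks).
#'
#' @param flows named numeric vector of flows (mL/s); names must match the
#'   `flow` column of `topology`.
#' @param topology edge list as returned by [cvs_topology()].
#' @return named numeric vector `dV/dt` per chamber.
#' @export
volume_derivatives <- function(flows, topology = cvs_topology()) {
  missing <- setdiff(topology$flow, names(flows))
  if (length(missing))
    stop("flows missing from topology: ", paste(missing, collapse = ", "))
  chambers <- unique(c(topology$from, topology$to))
  dV <- setNames(rep(0, length(chambers)), chambers)
  for (i in seq_len(nrow(topology))) {
    q <- flows[[topology$flow[i]]]
    dV[topology$from[i]] <- dV[topology$from[i]] - q
    dV[topology$to[i]] <- dV[topology$to[i]] + q
  }
  dV
}
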