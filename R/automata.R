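#' Cardiac conduction as a network of timed automata
#'
#' The electrical activity of the heart is described by seven coupled
#' finite-state automata: sinoatrial node (NSA), right and left atria
#' (RA, LA), atrioventricular node (NAV), upper bundle of His (UH) and the
#' two ventricles (RV, LV).  Each automaton cycles through slow diastolic
#' depolarisation (SDD), upstroke depolarisation (UDP), absolute refractory
#' (ARP) and relative refractory (RRP) phases; at the end of UDP it is
#' "activated" and stimulates its downstream neighbours after a conduction
#' delay.  Only pacemaker automata (by default the NSA) traverse SDD
#' spontaneously; the others wait in SDD until stimulated.  Activation
#' instants of the LV automaton serve as QRS fiducials and reset the
#' mechanical driver clocks of the chambers.
#'
#' @param name automaton label.
#' @param SDD,UDP,ARP,RRP phase durations in seconds (`SDD = Inf` for a
#'   non-pacemaker at rest).
#' @param neighbors named numeric vector of conduction delays (s) to
#'   downstream automata.
#' @param pacemaker logical; if `TRUE` the automaton self-cycles.
#' @return list of class `automaton_spec`.
#' @export
automaton_spec <- function(name, SDD, UDP, ARP, RRP,
                           neighbors = numeric(), pacemaker = FALSE) {
  durs <- c(SDD = SDD, UDP = UDP, ARP = ARP, RRP = RRP)
  if (any(durs < 0, na.rm = TRUE)) stop("phase durations must be >= 0")
  if (length(neighbors) && any(neighbors < 0))
    stop("conduction delays must be >= 0")
  structure(list(name = name, SDD = SDD, UDP = UDP, ARP = ARP, RRP = RRP,
                 neighbors = neighbors, pacemaker = pacemaker),
            class = "automaton_spec")
}

#' Standard seven-automaton conduction network
#'
#' NSA paces with period `T`; conduction runs NSA -> (RA, LA) and
#' NSA -> NAV -> UH -> (RV, LV).  Non-pacemaker SDD is infinite (no escape
#' rhythm).  For short cycle lengths the NSA refractory phases are scaled
#' down so the diastolic phase stays positive.
#'
#' @param T pacing period of the sinoatrial node (s).
#' @param nav_delay conduction delay NAV -> UH (s); the main knob for the
#'   atrioventricular delay.
#' @return named list of `automaton_spec` objects (class `conduction_network`).
#' @export
standard_conduction_network <- function(T = 1.0, nav_delay = 0.07) {
  stopifnot(T > 0.2)
  udp <- 0.05; arp <- 0.25; rrp <- 0.15
  sdd <- T - (udp + arp + rrp)
  if (sdd < 0.05 * T) {           # fast pacing: shrink refractoriness
    sc <- (T * 0.95) / (udp + arp + rrp)
    udp <- udp * sc; arp <- arp * sc; rrp <- rrp * sc
    sdd <- T - (udp + arp + rrp)
  }
  # delays give the physiologic activation order
  # NSA < RA <= LA < NAV < UH < RV ~= LV, with atria ~0.15 s before the
  # ventricles (PR-like interval)
  net <- list(
    NSA = automaton_spec("NSA", sdd, udp, arp, rrp,
                         c(RA = 0.0, LA = 0.01, NAV = 0.03), pacemaker = TRUE),
    RA  = automaton_spec("RA", Inf, 0.05, 0.20, 0.05),
    LA  = automaton_spec("LA", Inf, 0.05, 0.20, 0.05),
    NAV = automaton_spec("NAV", Inf, 0.05, 0.25, 0.05, c(UH = nav_delay)),
    UH  = automaton_spec("UH", Inf, 0.02, 0.25, 0.05,
                         c(RV = 0.01, LV = 0.01)),
    RV  = automaton_spec("RV", Inf, 0.03, 0.25, 0.10),
    LV  = automaton_spec("LV", Inf, 0.03, 0.25, 0.10)
  )
  structure(net, class = "conduction_network", period = T)
}

#' Advance one automaton over a time step
#'
#' Pure transition function of the four-phase automaton.  Stimulation
#' arriving during SDD or RRP truncates the phase and starts UDP;
#' stimulation during ARP (and during UDP itself) is ignored.  An
#' `"activation"` event is emitted when UDP completes.
#'
#' @param state list with `phase` (one of `"SDD"`, `"UDP"`, `"ARP"`,
#'   `"RRP"`), `elapsed` (s in current phase) and `spec`
#'   (an [automaton_spec()]).
#' @param stim logical: stimulation arriving at the start of this step.
#' @param dt step length (s), must be > 0.
#' @return list with updated `state` and `events` (character vector,
#'   possibly containing `"activation"`).
#' @export
step_automaton <- function(state, stim = FALSE, dt) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  phases <- c("SDD", "UDP", "ARP", "RRP")
  stopifnot(state$phase %in% phases)
  spec <- state$spec
  events <- character()
  if (isTRUE(stim) && state$phase %in% c("SDD", "RRP")) {
    state$phase <- "UDP"; state$elapsed <- 0
  }
  remaining <- dt
  repeat {
    dur <- spec[[state$phase]]
    left <- dur - state$elapsed
    if (remaining < left || !is.finite(left)) {
      state$elapsed <- state$elapsed + remaining
      break
    }
    remaining <- remaining - left
    if (state$phase == "UDP") events <- c(events, "activation")
    nxt <- phases[match(state$phase, phases) %% 4L + 1L]
    # non-pacemakers rest in SDD until stimulated
    if (nxt == "SDD" && !isTRUE(spec$pacemaker) && !is.finite(spec$SDD)) {
      state$phase <- "SDD"; state$elapsed <- 0
      break
    }
    state$phase <- nxt; state$elapsed <- 0
  }
  list(state = state, events = events)
}

#' Run the conduction network
#'
#' Event-driven simulation of the coupled automata: exact activation times,
#' no time discretisation.  Stimulations arriving during ARP are dropped;
#' arriving during SDD or RRP they trigger an immediate upstroke.
#'
#' @param network a `conduction_network` (see
#'   [standard_conduction_network()]).
#' @param duration simulated time span (s), > 0.
#' @return object of class `activation_schedule`: list with `activations`
#'   (named list of activation-time vectors per automaton), `qrs`
#'   (LV activation times), and `period` (pacemaker period).
#' @export
run_conduction <- function(network, duration) {
  stopifnot(duration > 0)
  nms <- names(network)
  for (a in network) {
    bad <- setdiff(names(a$neighbors), nms)
    if (length(bad)) stop("missing neighbor automata: ",
                          paste(bad, collapse = ", "))
  }
  phase <- setNames(rep("SDD", length(network)), nms)
  # pacemakers start at the beginning of UDP so the first beat is immediate
  t_end <- setNames(rep(Inf, length(network)), nms)
  elaps0 <- 0
  for (nm in nms) {
    sp <- network[[nm]]
    if (isTRUE(sp$pacemaker)) { phase[nm] <- "UDP"; t_end[nm] <- sp$UDP }
  }
  stim_q <- data.frame(time = numeric(), target = character())
  act <- setNames(vector("list", length(network)), nms)
  guard <- 0L
  guard_max <- 1000L * (length(network) + 1L) * ceiling(duration + 1)
  phases <- c("SDD", "UDP", "ARP", "RRP")
  repeat {
    t_next <- min(t_end)
    t_stim <- if (nrow(stim_q)) min(stim_q$time) else Inf
    t_now <- min(t_next, t_stim)
    if (!is.finite(t_now) || t_now > duration) break
    guard <- guard + 1L
    if (guard > guard_max)
      stop("conduction network does not settle (zero-delay loop?)")
    if (t_stim <= t_next) {          # deliver one stimulation
      i <- which.min(stim_q$time)
      tgt <- stim_q$target[i]
      stim_q <- stim_q[-i, , drop = FALSE]
      if (phase[tgt] %in% c("SDD", "RRP")) {
        sp <- network[[tgt]]
        phase[tgt] <- "UDP"
        t_end[tgt] <- t_now + sp$UDP
        if (sp$UDP == 0 && length(sp$neighbors) == 0)
          t_end[tgt] <- t_now  # degenerate, handled below
      }
      next
    }
    nm <- nms[which.min(t_end)]      # phase completion
    sp <- network[[nm]]
    ph <- phase[nm]
    if (ph == "UDP") {               # activation: stimulate neighbors
      act[[nm]] <- c(act[[nm]], t_now)
      if (length(sp$neighbors))
        stim_q <- rbind(stim_q,
                        data.frame(time = t_now + unname(sp$neighbors),
                                   target = names(sp$neighbors)))
    }
    nxt <- phases[match(ph, phases) %% 4L + 1L]
    phase[nm] <- nxt
    dur <- sp[[nxt]]
    t_end[nm] <- if (is.finite(dur)) t_now + dur else Inf
  }
  structure(list(activations = act, qrs = act$LV %||% numeric(),
                 period = attr(network, "period")),
            class = "activation_schedule")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' QRS fiducial times of a schedule
#'
#' The QRS marker is the activation instant of the LV automaton; it is the
#' t = 0 reference used to synchronise simulated and measured signals.
#'
#' @param schedule an `activation_schedule`.
#' @return numeric vector of QRS times (s), possibly empty.
#' @export
qrs_times <- function(schedule) {
  stopifnot(inherits(schedule, "activation_schedule"))
  schedule$qrs
}

# driver clock offsets for the continuous model: first activation of each
# mechanically driven chamber, taken modulo the pacing period
activation_offsets <- function(schedule) {
  T <- schedule$period
  get1 <- function(nm) {
    a <- schedule$activations[[nm]]
    if (is.null(a) || !length(a)) stop("automaton never activates: ", nm)
    a[1] %% T
  }
  c(lv = get1("LV"), rv = get1("RV"), la = get1("LA"), ra = get1("RA"))
}
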