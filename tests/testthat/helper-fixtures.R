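# Shared fixtures: small simulations are expensive enough to cache per
# test run.

healthy_sim <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- cvs_simulate(cvs_params(), beats = 12,
                                           dt = 0.002, warn = FALSE)
    val
  }
})

as_sim <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- cvs_simulate(cvs_params(valves.aortic.A_eff_max = 0.75),
                           beats = 12, dt = 0.002, warn = FALSE)
    val
  }
})

# brute-force monotone-run decomposition oracle: explicit segmentation
# into maximal ascending/descending runs, then summed increments
run_decomposition_oracle <- function(w) {
  d <- diff(w)
  d[abs(d) <= 1e-12] <- 0
  wp <- 0; wn <- 0
  run_sign <- 0; run_sum <- 0
  flush <- function() {
    if (run_sign > 0) wp <<- wp + run_sum
    if (run_sign < 0) wn <<- wn + abs(run_sum)
  }
  for (x in d) {
    s <- sign(x)
    if (s == 0) next
    if (s != run_sign) { flush(); run_sign <- s; run_sum <- 0 }
    run_sum <- run_sum + x
  }
  flush()
  c(p = wp, n = wn)
}

# minimal stand-in simulation carrying a prescribed LV cycle and aortic
# extrema, for testing the cost functions in isolation
fake_sim <- function(t_e, plv, pao_sys, pao_dias) {
  structure(list(
    ts = data.frame(time = t_e, P_lv = plv),
    derived = list(Pao_sys = pao_sys, Pao_dias = pao_dias,
                   max_plv = max(plv), sv = NA_real_,
                   dP = max(plv) - pao_sys),
    analysis_window = c(min(t_e), max(t_e)),
    T = max(t_e) - min(t_e), dt = diff(t_e[1:2]),
    events = list(qrs = min(t_e))
  ), class = "cvs_sim")
}

# quick synthetic patient record with a prescribed trace (no simulation)
toy_record <- function(t_e = seq(0, 0.75, by = 0.25),
                       plv = c(0, 10, 20, 10),
                       pao_sys = 100, pao_dias = 50, ava = 0.8) {
  n <- length(t_e)
  ss <- strain_set(seq(0, 1, length.out = 21),
                   cbind(seg1 = -10 * sin(pi * seq(0, 1, length.out = 21))),
                   list(MVC = 0.05, AVO = 0.1, AVC = 0.5, MVO = 0.8))
  patient_record("toy", t_e, plv, pao_sys, pao_dias, ava, ss,
                 t_c = max(t_e))
}
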