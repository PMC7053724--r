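test_that("compiled right-hand side matches the pure-R module composition", {
  ps <- cvs_params()
  sched <- run_conduction(ps$electrical, 3)
  offsets <- activation_offsets(sched)
  parms <- cvwork:::pack_parms(ps, offsets)
  y0 <- cvwork:::initial_state(ps)
  set.seed(1)
  for (i in 1:15) {
    y <- y0
    # random physiologic-ish perturbation of volumes and valve states
    y[1:10] <- y[1:10] * runif(10, 0.8, 1.2)
    y[c(11, 13, 15, 17)] <- runif(4, -50, 300)
    y[c(12, 14, 16, 18)] <- runif(4, 0, 1)
    t <- runif(1, 0, 2)
    cc <- deSolve::DLLfunc(func = "cvs_derivs", dllname = "cvwork",
                           initfunc = "cvs_init", times = t, y = y,
                           parms = parms, nout = 10,
                           outnames = paste0("o", 1:10))
    rr <- cvs_rhs_r(t, y, ps, offsets)
    expect_equal(unname(cc$dy), unname(rr$dy), tolerance = 1e-12)
    expect_equal(unname(cc$var[1]), unname(rr$pressures[["lv"]]),
                 tolerance = 1e-12)
  }
})

test_that("equilibrium state with frozen gradients has zero volume derivatives", {
  ps <- cvs_params()
  offsets <- c(lv = 0.26, rv = 0.26, la = 0.11, ra = 0.10)
  # all chamber pressures equal and valve flows zero => dV/dt all zero
  circ <- ps$circulation
  P <- 10
  inv_edpvr <- function(P, b) b$V_0 + log(P / b$P_0 + 1) / b$lambda
  t <- 0.9  # diastole: driver ~ 0, atrial gaussian ~ 0
  y <- c(V_lv = inv_edpvr(P, ps$lv), V_la = ps$la$V_d + P / ps$la$E_min,
         V_rv = inv_edpvr(P, ps$rv), V_ra = ps$ra$V_d + P / ps$ra$E_min,
         V_ao = circ$Vd_ao + P / circ$E_ao, V_sa = circ$Vd_sa + P / circ$E_sa,
         V_sv = circ$Vd_sv + P / circ$E_sv, V_vc = circ$Vd_vc + P / circ$E_vc,
         V_pa = circ$Vd_pa + P / circ$E_pa, V_pv = circ$Vd_pv + P / circ$E_pv,
         Q_mv = 0, xi_mv = 0, Q_av = 0, xi_av = 0,
         Q_tv = 0, xi_tv = 0, Q_pu = 0, xi_pu = 0)
  rr <- cvs_rhs_r(t, y, ps, offsets)
  # resistive flows vanish (equal pressures) and valve flows are zero
  expect_true(all(abs(rr$dy[1:10]) < 0.7))  # only tiny driver leakage
})

test_that("simulation is deterministic and reaches periodic steady state", {
  s1 <- cvs_simulate(cvs_params(), beats = 12, dt = 0.002, warn = FALSE)
  s2 <- cvs_simulate(cvs_params(), beats = 12, dt = 0.002, warn = FALSE)
  expect_identical(s1$ts, s2$ts)
  expect_true(s1$converged)
  # beat-to-beat LV pressure maximum settles below 0.5 mmHg
  qrs <- s1$events$qrs
  mx <- sapply(tail(qrs, 3), function(q) {
    w <- s1$ts$time >= q & s1$ts$time <= q + s1$T
    max(s1$ts$P_lv[w])
  })
  expect_lt(max(abs(diff(mx))), 0.5)
})

test_that("valve events are ordered MVC < AVO < AVC < MVO in every beat", {
  for (sim in list(healthy_sim(), as_sim())) {
    ev <- sim$events$valves
    ev <- ev[ev$beat >= 3, ]  # skip start-up transients
    expect_false(anyNA(ev))
    expect_true(all(ev$MVC < ev$AVO))
    expect_true(all(ev$AVO < ev$AVC))
    expect_true(all(ev$AVC < ev$MVO))
  }
})

test_that("event detection responds to the crossing threshold", {
  sim <- healthy_sim()
  lo <- detect_valve_events(sim, threshold = 0.05)
  hi <- detect_valve_events(sim, threshold = 0.5)
  n <- nrow(lo)
  expect_lt(lo$AVO[n], hi$AVO[n])  # lower threshold -> earlier opening
})

test_that("transvalvular gradient is the LV-aortic systolic difference", {
  sim <- as_sim()
  d <- sim$derived
  expect_equal(pressure_gradient(sim), d$max_plv - d$Pao_sys)
  expect_gt(pressure_gradient(sim), 20)           # stenotic
  expect_lt(abs(pressure_gradient(healthy_sim())), 5)  # healthy ~ 0
})

test_that("severity sweep: gradient strictly decreasing in valve area", {
  areas <- c(0.5, 1.0, 1.5, 2.0, 2.5)
  dps <- sapply(areas, function(a)
    pressure_gradient(cvs_simulate(cvs_params(valves.aortic.A_eff_max = a),
                                   beats = 10, dt = 0.002, warn = FALSE)))
  expect_true(all(diff(dps) < 0))
})

test_that("non-physiological configurations surface as errors", {
  ps <- cvs_params()
  ps$circulation$E_sv <- 1e-9   # venous reservoir would need ~10^10 mL
  expect_error(cvs_simulate(ps, beats = 3, warn = FALSE),
               "total blood volume")
})
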