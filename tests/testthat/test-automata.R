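test_that("automaton phase transitions follow the state diagram", {
  spec <- automaton_spec("X", SDD = 0.4, UDP = 0.1, ARP = 0.2, RRP = 0.1,
                         pacemaker = TRUE)
  st <- list(phase = "SDD", elapsed = 0, spec = spec)
  # SDD elapses -> UDP
  r <- step_automaton(st, stim = FALSE, dt = 0.4)
  expect_identical(r$state$phase, "UDP")
  expect_length(r$events, 0)
  # UDP completion emits the activation and enters ARP
  r2 <- step_automaton(r$state, stim = FALSE, dt = 0.1)
  expect_identical(r2$state$phase, "ARP")
  expect_identical(r2$events, "activation")
  # stimulation during ARP is ignored
  r3 <- step_automaton(r2$state, stim = TRUE, dt = 0.05)
  expect_identical(r3$state$phase, "ARP")
  expect_length(r3$events, 0)
  # stimulation during SDD truncates it
  st_sdd <- list(phase = "SDD", elapsed = 0.1, spec = spec)
  r4 <- step_automaton(st_sdd, stim = TRUE, dt = 0.01)
  expect_identical(r4$state$phase, "UDP")
  expect_error(step_automaton(st, stim = FALSE, dt = -0.1), "dt")
})

test_that("pacemaker period equals the sum of its phase durations", {
  spec <- automaton_spec("P", SDD = 0.5, UDP = 0.1, ARP = 0.25, RRP = 0.15,
                         pacemaker = TRUE)
  net <- structure(list(P = spec), class = "conduction_network", period = 1)
  # walk a single pacemaker automaton for 3 s in small steps
  st <- list(phase = "SDD", elapsed = 0, spec = spec)
  acts <- c()
  t <- 0; dt <- 0.001
  while (t < 3.2) {
    r <- step_automaton(st, stim = FALSE, dt = dt)
    st <- r$state; t <- t + dt
    if (length(r$events)) acts <- c(acts, t)
  }
  expect_equal(length(acts), 3)   # activations near 0.6, 1.6, 2.6: period 1
  expect_equal(diff(acts), rep(1.0, 2), tolerance = 0.01)
})

test_that("standard network activates in physiological order, periodically", {
  net <- standard_conduction_network(1)
  sc <- run_conduction(net, duration = 5)
  first <- vapply(sc$activations, function(a) a[1], 0)
  expect_lt(first[["NSA"]], first[["RA"]])
  expect_lte(first[["RA"]], first[["LA"]])
  expect_lt(first[["LA"]], first[["NAV"]])
  expect_lt(first[["NAV"]], first[["UH"]])
  expect_lt(first[["UH"]], first[["RV"]])
  expect_equal(first[["RV"]], first[["LV"]], tolerance = 0.02)
  # 5 LV activations spaced by the pacing period
  expect_length(sc$qrs, 5)
  expect_equal(diff(sc$qrs), rep(1, 4), tolerance = 1e-9)
  # per-automaton times strictly increasing, no double-firing within ARP
  for (nm in names(sc$activations)) {
    a <- sc$activations[[nm]]
    expect_true(all(diff(a) > net[[nm]]$ARP))
  }
})

test_that("conduction delays are additive and the schedule deterministic", {
  base <- run_conduction(standard_conduction_network(1), 4)
  slow <- run_conduction(standard_conduction_network(1, nav_delay = 0.07 + 0.08), 4)
  expect_equal(slow$activations$LV, base$activations$LV + 0.08)
  expect_identical(slow$activations$NSA, base$activations$NSA)
  again <- run_conduction(standard_conduction_network(1), 4)
  expect_identical(base$activations, again$activations)
})

test_that("qrs_times returns LV markers and handles empty schedules", {
  sc <- run_conduction(standard_conduction_network(1), 3)
  expect_identical(qrs_times(sc), sc$activations$LV)
  empty <- structure(list(activations = list(), qrs = numeric(), period = 1),
                     class = "activation_schedule")
  expect_identical(qrs_times(empty), numeric())
})

test_that("malformed networks are rejected", {
  bad <- standard_conduction_network(1)
  bad$NAV$neighbors <- c(XX = 0.05)
  expect_error(run_conduction(bad, 2), "missing neighbor")
  expect_error(automaton_spec("A", -1, 0.1, 0.1, 0.1), "durations")
})
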