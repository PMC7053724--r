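test_that("cost functions match hand arithmetic on toy traces", {
  rec <- toy_record(plv = c(0, 10, 20, 10))
  sim_eq <- fake_sim(rec$time, rec$plv, 100, 50)
  b <- cost_breakdown(sim_eq, rec)
  expect_equal(b$J_step1, 0)
  expect_equal(b$J_step2, 0)
  # constant +5 mmHg offset on the LV trace, aortic exact
  sim_off <- fake_sim(rec$time, rec$plv + 5, 100, 50)
  expect_equal(cost_step1(sim_off, rec), 5)
  # toy example: model [0,12,18,10], aortic errors 3 and 2
  sim_toy <- fake_sim(rec$time, c(0, 12, 18, 10), 103, 48)
  bt <- cost_breakdown(sim_toy, rec)
  expect_equal(bt$J_PLV, 1)       # mean |0,2,2,0|
  expect_equal(bt$J_Pao_sys, 3)
  expect_equal(bt$J_Pao_dias, 2)
  expect_equal(bt$J_step1, 6)
  expect_equal(bt$J_step2, 5)
})

test_that("step-2 cost ignores the LV pressure trace", {
  rec <- toy_record()
  sim <- fake_sim(rec$time, c(5, 8, 9, 2), 104, 46)
  rec2 <- rec; rec2$plv <- rec$plv + rnorm(4, 0, 10)
  expect_equal(cost_step2(sim, rec), cost_step2(sim, rec2))
  expect_equal(cost_step2(sim, rec), 4 + 4)
})

test_that("noise-free step-1 identification recovers the pressure curve", {
  # virtual patient generated by the model itself; modest jitter
  vp <- sample_patient(seed = 11, jitter = 0.12,
                       noise = noise_control(plv_sd = 0, pao_sd = 0,
                                             strain_sd = 0))
  rec <- vp$record
  fit <- fit_step1(rec, control = ea_control(pop = 30, generations = 25,
                                             stall = 25, polish = TRUE,
                                             polish_maxit = 400),
                   beats = 12, dt = 0.002, rtol = 1e-6, atol = 1e-8,
                   seed = 3)
  plv_model <- predict(fit, rec$time)
  e <- total_relative_error(rec$plv, plv_model,
                            rec$pao_sys, fit$sim$derived$Pao_sys,
                            rec$pao_dias, fit$sim$derived$Pao_dias)
  r2 <- regression_agreement(rec$plv, plv_model)$r_squared
  expect_lt(e, 2)
  expect_gt(r2, 0.99)
  # contractility recovered within 10% of the hidden truth
  truth <- view_values(vp$truth, param_view("X_LV"))
  expect_lt(abs(coef(fit)[["E_es_lv"]] - truth[["E_es_lv"]]) /
              truth[["E_es_lv"]], 0.10)
})

test_that("training average and matched-ventricle step 2 behave as specified", {
  nf <- noise_control(plv_sd = 0, pao_sd = 0, strain_sd = 0)
  # two identical patients: the X_LV average equals each individual fit
  vp <- sample_patient(seed = 8, ava = 0.85, jitter = 0, noise = nf)
  recs <- list(vp$record, vp$record)
  recs[[1]]$id <- "a"; recs[[2]]$id <- "b"
  ctrl <- ea_control(pop = 14, generations = 8, stall = 8,
                     polish = TRUE, polish_maxit = 120)
  s1 <- run_step1(recs, control = ctrl, beats = 7, dt = 0.0025, seed = 5)
  # both patients identical, identical seeds would give identical fits;
  # seeds differ per patient so compare the average against members
  xa <- s1$fits$a$par[names(param_view("X_LV"))]
  xb <- s1$fits$b$par[names(param_view("X_LV"))]
  expect_equal(s1$xlv_bar, (xa + xb) / 2)
  # a test patient whose truth X_LV equals the frozen values: step 2
  # recovers the LV pressure maximum within 5%
  f2 <- fit_step2(vp$record, view_values(vp$truth, param_view("X_LV")),
                  control = ctrl, beats = 7, dt = 0.0025, seed = 9)
  expect_lt(abs(f2$sim$derived$max_plv - vp$sim$derived$max_plv) /
              vp$sim$derived$max_plv, 0.05)
  expect_lt(f2$value, 1.5)   # aortic observables nearly matched
})

test_that("a reduced AVA raises the estimated gradient in step 2", {
  nf <- noise_control(plv_sd = 0, pao_sd = 0, strain_sd = 0)
  vp <- sample_patient(seed = 14, ava = 1.0, jitter = 0, noise = nf)
  xlv <- view_values(vp$truth, param_view("X_LV"))
  ctrl <- ea_control(pop = 10, generations = 6, stall = 6)
  rec_half <- vp$record; rec_half$ava <- 0.5
  f_full <- fit_step2(vp$record, xlv, control = ctrl, beats = 6,
                      dt = 0.0025, seed = 2)
  f_half <- fit_step2(rec_half, xlv, control = ctrl, beats = 6,
                      dt = 0.0025, seed = 2)
  expect_gt(pressure_gradient(f_half$sim), pressure_gradient(f_full$sim))
})

test_that("Monte-Carlo cross-validation splits halve the cohort reproducibly", {
  nf <- noise_control(plv_sd = 0.5, pao_sd = 1, strain_sd = 0.02)
  ch <- synth_cohort(n = 4, seed = 3, jitter = 0.1, K = 4, noise = nf)
  recs <- cohort_records(ch)
  ctrl <- ea_control(pop = 8, generations = 4, stall = 4)
  mc <- suppressWarnings(
    mc_cross_validate(recs, N = 2, control1 = ctrl, control2 = ctrl,
                      beats = 6, dt = 0.0025, seed = 6))
  for (sp in mc$splits) {
    expect_length(sp$train, 2)
    expect_length(sp$test, 2)
    expect_length(intersect(sp$train, sp$test), 0)
  }
  expect_equal(nrow(mc$markers), 4)
  # markers averaged over test appearances only
  expect_equal(sum(mc$markers$n_test), 2 * 2)
  mc2 <- suppressWarnings(
    mc_cross_validate(recs, N = 2, control1 = ctrl, control2 = ctrl,
                      beats = 6, dt = 0.0025, seed = 6))
  expect_identical(mc$splits, mc2$splits)
  expect_equal(mc$markers, mc2$markers)
})
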