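test_that("virtual patients are reproducible and anchored to the truth", {
  vp1 <- sample_patient(seed = 21, jitter = 0.1)
  vp2 <- sample_patient(seed = 21, jitter = 0.1)
  expect_identical(vp1$record$plv, vp2$record$plv)
  expect_identical(view_values(vp1$truth, param_view()),
                   view_values(vp2$truth, param_view()))
  # AVA in the record equals the aortic effective area of the truth
  expect_equal(vp1$record$ava,
               ps_get(vp1$truth, "valves.aortic.A_eff_max"))
})

test_that("zero jitter and zero noise reproduce the nominal model exactly", {
  vp <- sample_patient(seed = 4, ava = 0.8, jitter = 0,
                       noise = noise_control(plv_sd = 0, pao_sd = 0,
                                             strain_sd = 0))
  nom <- cvs_params(T = vp$sim$T)
  expect_equal(view_values(vp$truth, param_view()),
               view_values(nom, param_view()))
  expect_equal(vp$record$ava, 0.8)
  # observables equal the truth readings
  expect_equal(vp$record$pao_sys, vp$sim$derived$Pao_sys)
  expect_equal(vp$record$pao_dias, vp$sim$derived$Pao_dias)
  expect_equal(vp$record$plv, lv_pressure_cycle(vp$sim, vp$record$time),
               tolerance = 1e-12)
})

test_that("degradation noise has the configured dispersion", {
  vp <- sample_patient(seed = 4, ava = 0.8, jitter = 0)
  # many repeated degradations of the same truth: Pao_sys error SD ~ 2
  errs <- sapply(1:300, function(i) {
    r <- degrade_to_observables(vp, noise_control(pao_sd = 2), seed = i)
    r$pao_sys - vp$sim$derived$Pao_sys
  })
  expect_equal(sd(errs), 2, tolerance = 0.25)
  # record invariants hold after noise
  for (i in 1:20) {
    r <- degrade_to_observables(vp, noise_control(pao_sd = 30), seed = i)
    expect_gt(r$pao_sys, r$pao_dias)
    expect_gt(r$pao_dias, 0)
  }
})

test_that("severity drives the transvalvular gradient", {
  vs <- sample_patient(seed = 10, ava = 0.75, jitter = 0)
  vm <- sample_patient(seed = 10, ava = 2.5, jitter = 0)
  expect_gt(pressure_gradient(vs$sim), pressure_gradient(vm$sim))
})

test_that("synthetic strain has physiologic shape; dyssynchrony raises GWW", {
  nf <- noise_control(plv_sd = 0, pao_sd = 0, strain_sd = 0)
  vp <- sample_patient(seed = 31, ava = 0.8, jitter = 0, noise = nf, K = 6)
  ss <- vp$record$strain
  expect_equal(ncol(ss$strain), 6)
  # near zero at MVC, minimum during ejection, magnitude 10-30%
  expect_lt(abs(ss$strain[1, 1]), 1)
  expect_lt(min(ss$strain), -10)
  expect_gt(min(ss$strain), -35)
  w0 <- myocardial_work(ss, vp$record$plv, pressure_time = vp$record$time)
  expect_lt(w0$GWW / w0$GCW, 0.01)     # synchronous: GWW ~ 0
  expect_gt(w0$GWE, 0.99)
  vpd <- sample_patient(seed = 31, ava = 0.8, jitter = 0, noise = nf, K = 6,
                        dyssynchrony = list(n = 3, tau = 0.06))
  wd <- myocardial_work(vpd$record$strain, vpd$record$plv,
                        pressure_time = vpd$record$time)
  expect_gt(wd$GWW, w0$GWW)
})

test_that("cohort generation mirrors the study design and round-trips to text", {
  ch <- synth_cohort(n = 4, seed = 2, n_moderate = 1, K = 4)
  expect_length(ch, 4)
  avas <- vapply(ch, `[[`, 0, "ava")
  expect_true(all(avas[1:3] <= 1.0))
  expect_gt(avas[4], 1.0)
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  back <- read_cohort(dir)
  expect_length(back, 4)
  ids <- vapply(back, `[[`, "", "id")
  for (vp in ch) {
    r0 <- vp$record
    r1 <- back[[match(vp$id, ids)]]
    expect_equal(r1$plv, r0$plv, tolerance = 1e-12)
    expect_equal(r1$pao_sys, r0$pao_sys)
    expect_equal(r1$ava, r0$ava)
    expect_equal(unclass(r1$strain$strain), unclass(r0$strain$strain),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(r1$strain$events, r0$strain$events, tolerance = 1e-12)
  }
})

test_that("patient record invariants are enforced", {
  ss <- strain_set(seq(0, 1, 0.1), cbind(a = rnorm(11)),
                   list(MVC = 0.1, AVO = 0.2, AVC = 0.5, MVO = 0.8))
  expect_error(patient_record("x", 0:1, c(1, 2), 80, 90, 1, ss), "pao_sys")
  expect_error(patient_record("x", 0:1, c(1, 2), 90, 80, -1, ss), "AVA")
  expect_error(strain_set(seq(0, 1, 0.1), cbind(a = rnorm(11)),
                          list(MVC = 0.5, AVO = 0.2, AVC = 0.3, MVO = 0.8)),
               "MVC < AVC")
})
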