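test_that("instantaneous power is the strain-rate pressure product", {
  t <- seq(0, 0.3, by = 0.01)
  # linear strain: -20% over 0.3 s at constant 100 mmHg
  eps <- seq(0, -20, length.out = length(t))
  p <- rep(100, length(t))
  pw <- instantaneous_power(t, eps, p)
  expect_equal(pw, rep(-20 / 0.3 * 100, length(t)), tolerance = 1e-9)
  expect_equal(instantaneous_power(t, rep(-5, length(t)), p),
               rep(0, length(t)))
  expect_equal(instantaneous_power(t, eps, rep(0, length(t))),
               rep(0, length(t)))
  expect_error(instantaneous_power(t, eps[-1], p), "aligned")
})

test_that("segmental work integrates power over MVC..MVO", {
  t <- seq(0, 1, by = 0.005)
  expect_equal(segmental_work(t, rep(0, length(t)), 0.1, 0.8)$w,
               rep(0, length(which(t >= 0.1 & t <= 0.8))))
  # constant power p over duration d accumulates p*d
  wk <- segmental_work(t, rep(40, length(t)), 0.1, 0.6)
  expect_equal(tail(wk$w, 1), 40 * 0.5, tolerance = 1e-9)
  # a full sine period integrates to ~ 0
  pw <- sin(2 * pi * (t - 0.1) / 0.5)
  wk2 <- segmental_work(t, pw, 0.1, 0.6)
  expect_lt(abs(tail(wk2$w, 1)), 1e-3)
  expect_error(segmental_work(t, pw, 0.5, 0.2), "MVC")
  expect_error(segmental_work(t, pw, -0.5, 0.6), "outside")
})

test_that("monotone-run decomposition matches the spec examples", {
  # S-phase run boundaries [0, 5, 3, 8]: Wp = 5 + 5, Wn = 2
  tt <- seq(0, 1, length.out = 13)
  w <- c(approx(c(0, 0.25, 0.5, 0.75), c(0, 5, 3, 8), xout = tt[tt <= 0.75])$y,
         approx(c(0.75, 1), c(8, 6), xout = tt[tt > 0.75])$y)
  d <- decompose_work(tt, w, AVC = 0.75)
  expect_equal(d[["Wp_S"]], 10)
  expect_equal(d[["Wn_S"]], 2)
  expect_equal(d[["Wp_IVR"]], 0)
  expect_equal(d[["Wn_IVR"]], 2)
  # flat trace: all four components zero
  expect_equal(unname(decompose_work(tt, rep(1, 13), 0.5)), rep(0, 4))
  # monotone S ascending / IVR descending: single-run case
  w2 <- c(seq(0, 6, length.out = 7), seq(6, 2, length.out = 6)[-1])
  d2 <- decompose_work(tt[1:12], w2, AVC = tt[7])
  expect_equal(d2[["Wn_S"]], 0)
  expect_equal(d2[["Wp_IVR"]], 0)
  expect_error(decompose_work(tt, c(w[-1], NaN), 0.5), "non-finite")
})

test_that("decomposition agrees with the brute-force run oracle on random traces", {
  set.seed(7)
  for (i in 1:1000) {
    n <- sample(6:40, 1)
    tt <- seq(0, 1, length.out = n)
    w <- cumsum(rnorm(n))
    i_avc <- sample(2:(n - 1), 1)
    d <- decompose_work(tt, w, AVC = tt[i_avc])
    os <- run_decomposition_oracle(w[1:i_avc])
    oi <- run_decomposition_oracle(w[i_avc:n])
    expect_equal(d[["Wp_S"]], os[["p"]])
    expect_equal(d[["Wn_S"]], os[["n"]])
    expect_equal(d[["Wp_IVR"]], oi[["p"]])
    expect_equal(d[["Wn_IVR"]], oi[["n"]])
    # telescoping identity per phase
    expect_equal(d[["Wp_S"]] - d[["Wn_S"]], w[i_avc] - w[1])
    expect_equal(d[["Wp_IVR"]] - d[["Wn_IVR"]], w[n] - w[i_avc])
  }
})

test_that("time reversal swaps ascending and descending totals", {
  set.seed(11)
  w <- cumsum(rnorm(25))
  tt <- seq(0, 1, length.out = 25)
  f <- decompose_work(tt, w, AVC = tt[13])
  r <- decompose_work(tt, rev(w), AVC = tt[13])
  expect_equal(f[["Wp_S"]], r[["Wn_IVR"]])
  expect_equal(f[["Wn_S"]], r[["Wp_IVR"]])
})

test_that("global indices follow Eqs and the efficiency identity", {
  one <- data.frame(Wp_S = 1500, Wn_S = 150, Wp_IVR = 0, Wn_IVR = 0)
  gi <- global_indices(one)
  expect_equal(gi$GCW, 1500)
  expect_equal(gi$GWW, 150)
  expect_equal(gi$GWE, 1500 / 1650)
  # identical segments: global equals per-segment
  many <- one[rep(1, 6), ]
  expect_equal(global_indices(many), gi)
  # degenerate: zero total work -> flagged undefined efficiency
  z <- global_indices(data.frame(Wp_S = 0, Wn_S = 0, Wp_IVR = 0, Wn_IVR = 0))
  expect_true(is.na(z$GWE))
  expect_true(isTRUE(attr(z$GWE, "undefined")))
})

test_that("GWE is invariant to uniform pressure rescaling", {
  t <- seq(0, 0.9, by = 0.01)
  set.seed(3)
  eps <- sapply(1:4, function(k)
    -15 * sin(pi * pmin(t, 0.6) / 0.6) + cumsum(rnorm(length(t), 0, 0.05)))
  ss <- strain_set(t, eps, list(MVC = 0.03, AVO = 0.08, AVC = 0.5, MVO = 0.75))
  p <- 60 + 60 * sin(pi * pmin(t, 0.65) / 0.65)
  w1 <- myocardial_work(ss, p)
  w2 <- myocardial_work(ss, 3.7 * p)
  expect_equal(w2$GCW, 3.7 * w1$GCW, tolerance = 1e-9)
  expect_equal(w2$GWE, w1$GWE, tolerance = 1e-9)
  expect_equal(w1$GWE, w1$GCW / (w1$GCW + w1$GWW))
})

test_that("synchronously shortening segments yield pure constructive work", {
  # monotone shortening during S against positive pressure, recovery after
  t <- seq(0, 0.8, by = 0.005)
  base <- ifelse(t <= 0.45, -18 * t / 0.45,
                 ifelse(t <= 0.65, -18 + 18 * (t - 0.45) / 0.2, 0))
  ss <- strain_set(t, cbind(a = base, b = 0.9 * base, c = 1.1 * base),
                   list(MVC = 0, AVO = 0.05, AVC = 0.45, MVO = 0.65))
  p <- 30 + 100 * sin(pi * pmin(t, 0.6) / 0.6)^2
  wi <- myocardial_work(ss, p)
  expect_equal(wi$GWW, 0, tolerance = 1e-9)
  expect_equal(wi$GWE, 1, tolerance = 1e-9)
  expect_gt(wi$GCW, 0)
})
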