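test_that("trajectories have the one-at-a-time structure and are reproducible", {
  p <- 6; r <- 5
  tr <- morris_trajectories(p, r, seed = 3)
  expect_length(tr, r)
  for (m in tr) {
    expect_equal(dim(m), c(p + 1, p))
    expect_true(all(m >= 0 & m <= 1))
    for (s in seq_len(p)) {
      d <- m[s + 1, ] - m[s, ]
      expect_equal(sum(d != 0), 1)                 # one coordinate moves
      expect_equal(abs(d[d != 0]), 2 / 3)          # by delta
    }
    # every coordinate moves exactly once over the trajectory
    expect_setequal(attr(m, "moves")$index, seq_len(p))
  }
  expect_identical(morris_trajectories(p, r, seed = 3), tr)
  expect_error(morris_trajectories(3, 2, levels = 2, delta = 1.5), "delta")
})

test_that("elementary effects are exact for linear and quadratic outputs", {
  # linear with coefficient a: EE = a regardless of location or step
  expect_equal(elementary_effect(3 * 0.2, 3 * 0.7, 0.5), 3)
  expect_equal(elementary_effect(5, 5, 0.25), 0)
  # quadratic x^2 at x = 1, delta = 0.5: |1 - 2.25|/0.5 = 2.5
  expect_equal(abs(elementary_effect(1, 2.25, 0.5)), 2.5)
  expect_error(elementary_effect(1, 2, 0), "delta")
})

test_that("mu*, sigma and D statistics follow their definitions", {
  ee <- matrix(c(2, 2, 2, 1, -1, 3), ncol = 2)
  ms <- morris_stats(ee)
  expect_equal(ms$mu_star[ms$parameter == "x1"], 2)
  expect_equal(ms$sigma[ms$parameter == "x1"], 0)
  expect_equal(ms$D[ms$parameter == "x1"], 2)
  # 3-4-5 triangle: signed EEs with mean|EE| = 3 and sd = 4
  ee2 <- cbind(a = c(3 - 4 / sqrt(2), 3 + 4 / sqrt(2)), b = c(1, 1))
  ms2 <- morris_stats(ee2)
  i <- which(ms2$parameter == "a")
  expect_equal(ms2$sigma[i], 4)
  expect_equal(ms2$D[i], sqrt(ms2$mu_star[i]^2 + 16))
  expect_equal(ms2$D, sqrt(ms2$mu_star^2 + ms2$sigma^2))
})

test_that("linear-model oracle: mu* = |a| (rescaled), sigma = 0, ranking by |a|", {
  a <- c(x1 = 4, x2 = -9, x3 = 0.5, x4 = 2)
  nominal <- c(x1 = 1, x2 = 1, x3 = 1, x4 = 1)
  fn <- function(x) sum(a * x)
  ms <- morris_screen(fn, nominal, range_frac = 0.3, r = 6, seed = 5)
  # physical step per unit of rescaled coordinate: 2 * 0.3 * nominal
  expected_mu <- abs(a) * 0.6
  got <- setNames(ms$mu_star, ms$parameter)[names(a)]
  expect_equal(got, expected_mu, tolerance = 1e-10)
  expect_true(all(ms$sigma < 1e-10))
  expect_identical(ms$parameter[1:2], c("x2", "x1"))
  # D ordering invariant to positive output rescaling
  ms2 <- morris_screen(function(x) 37 * fn(x), nominal, range_frac = 0.3,
                       r = 6, seed = 5)
  expect_identical(ms$parameter, ms2$parameter)
})

test_that("degenerate ranges: only the varied parameter has nonzero D", {
  nominal <- c(a = 2, b = 3, c = 4)
  fn <- function(x) x[["a"]]^2 + x[["b"]] + x[["c"]]
  # zero-width ranges for b and c are emulated by a function ignoring them
  ms <- morris_screen(function(x) x[["a"]]^2, nominal, r = 4, seed = 2)
  expect_gt(ms$D[ms$parameter == "a"], 0)
  expect_equal(ms$D[ms$parameter == "b"], 0)
  expect_equal(ms$D[ms$parameter == "c"], 0)
})

test_that("failed evaluations drop their trajectory with a message", {
  nominal <- c(u = 1, v = 1)
  cnt <- 0
  fn <- function(x) { cnt <<- cnt + 1; if (cnt == 2) NaN else sum(x) }
  expect_message(ms <- morris_screen(fn, nominal, r = 4, seed = 9),
                 "dropped")
  expect_equal(attr(ms, "n_dropped"), 1L)
})
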