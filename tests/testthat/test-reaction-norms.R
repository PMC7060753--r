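test_that("logistic curve matches hand-evaluated closed form", {
  # 1/(1 + exp((30.39 - 28)/(-0.41))) evaluated by independent arithmetic
  expect_equal(sr_logistic(28, P = 30.39, S = -0.41), 0.9971,
               tolerance = 1e-4)
  expect_equal(sr_logistic(30.39, P = 30.39, S = -0.41), 0.5)
  # slope at P is 1/(4S)
  h <- 1e-6
  slope <- (sr_logistic(30 + h, 30, -0.41) - sr_logistic(30 - h, 30, -0.41)) /
    (2 * h)
  expect_equal(slope, 1 / (4 * -0.41), tolerance = 1e-4)
  # saturation limits for a falling norm
  expect_equal(sr_logistic(c(-1e3, 1e3), P = 30, S = -0.4), c(1, 0))
  expect_error(sr_logistic(30, 30, 0), "S = 0")
})

test_that("flexit agrees with the naive direct-arithmetic oracle", {
  cases <- list(
    c(P = 30.57, S = -0.79, K1 = -1.72, K2 = 5),
    c(P = 30, S = -0.4, K1 = 2, K2 = -3),
    c(P = 29, S = 0.5, K1 = 0.3, K2 = 1.4),
    c(P = 31, S = -1.2, K1 = -8, K2 = 12)
  )
  tt <- seq(24, 38, by = 0.25)
  for (cs in cases) {
    expect_equal(
      sr_flexit(tt, cs["P"], cs["S"], cs["K1"], cs["K2"]),
      naive_flexit(tt, cs["P"], cs["S"], cs["K1"], cs["K2"]),
      tolerance = 1e-9
    )
  }
  # the published asymmetric fit: smooth male-side transition, value checked
  # against the oracle at a hand-picked temperature below the pivotal one
  v <- sr_flexit(29, 30.57, -0.79, -1.72, 200)
  expect_equal(v, naive_flexit(29, 30.57, -0.79, -1.72, 200),
               tolerance = 1e-9)
  expect_gt(v, 0.5)
  expect_lt(v, 1)
})

test_that("flexit survives extreme K without overflow and stays monotone", {
  tt <- seq(20, 40, by = 0.05)
  for (K2 in c(200, 900)) {
    f <- sr_flexit(tt, 30.57, -0.79, -1.72, K2)
    expect_true(all(is.finite(f)))
    expect_true(all(f >= 0 & f <= 1))
    expect_true(all(diff(f) <= 1e-12))  # non-increasing for S < 0
  }
  set.seed(71)
  for (i in 1:25) {
    P <- runif(1, 27, 33); S <- -runif(1, 0.05, 1.5)
    K1 <- runif(1, -50, 50); K2 <- runif(1, -50, 50)
    f <- sr_flexit(tt, P, S, K1, K2)
    expect_true(all(is.finite(f)) && all(f >= 0 & f <= 1))
    expect_true(all(diff(f) <= 1e-9))
  }
})

test_that("flexit is continuous at P and across the K ~ 0 guard", {
  eps <- 1e-9
  for (cs in list(c(-1.72, 200), c(2, 3), c(-0.5, -0.5))) {
    lo <- sr_flexit(30 - eps, 30, -0.6, cs[1], cs[2])
    hi <- sr_flexit(30 + eps, 30, -0.6, cs[1], cs[2])
    expect_equal(lo, 0.5, tolerance = 1e-6)
    expect_equal(hi, 0.5, tolerance = 1e-6)
  }
  expect_equal(sr_flexit(30, 30, -0.6, 1, 1), 0.5)
  tt <- seq(25, 35, 0.5)
  expect_equal(sr_flexit(tt, 30, -0.6, 0, 0),
               sr_flexit(tt, 30, -0.6, 1e-9, 1e-9), tolerance = 1e-6)
  expect_equal(sr_flexit(tt, 30, -0.6, 5e-10, 2e-10),
               sr_flexit(tt, 30, -0.6, 1e-9, 1e-9), tolerance = 1e-6)
})

test_that("flexit with K1 = K2 = 1 reduces to the logistic under S conversion", {
  tt <- seq(20, 40, by = 0.01)
  for (S_log in c(-0.41, -0.37, 0.3, -1.5)) {
    expect_equal(
      sr_flexit(tt, 30.4, 1 / (4 * S_log), 1, 1),
      sr_logistic(tt, 30.4, S_log),
      tolerance = 1e-9
    )
  }
  pl <- tsd_params("logistic", P = 30.4, S = -0.41)
  pf <- as_flexit_params(pl)
  expect_equal(sex_ratio(tt, pf), sex_ratio(tt, pl), tolerance = 1e-9)
})

test_that("TRT closed forms equal bisection inversion of the curves", {
  specs <- list(
    tsd_params("logistic", P = 30.46, S = -0.37),
    tsd_params("logistic", P = 29, S = 0.6),
    tsd_params("flexit", P = 30.57, S = -0.79, K1 = -1.72, K2 = 200),
    tsd_params("flexit", P = 30, S = -0.3, K1 = 2.5, K2 = -1.2)
  )
  for (ps in specs) {
    for (l in c(0.05, 0.025, 0.2)) {
      res <- trt(ps, l)
      f <- function(x) sex_ratio(x, ps)
      t1 <- bisect_crossing(f, l)
      t2 <- bisect_crossing(f, 1 - l)
      expect_equal(res$trt, abs(t1 - t2), tolerance = 1e-6)
      expect_equal(sort(c(res$lower, res$upper)), sort(c(t1, t2)),
                   tolerance = 1e-6)
    }
  }
})

test_that("TRT closed-form values and limits behave as published", {
  # |S * K_l| with K_l = |2 ln(l/(1-l))|: 0.37 * 2 ln 19 = 2.1789
  expect_equal(trt(tsd_params("logistic", P = 30.46, S = -0.37))$trt,
               2.178885, tolerance = 1e-5)
  # flexit at K1 = K2 = 1 equals the logistic TRT under the S conversion
  expect_equal(
    trt(tsd_params("flexit", P = 30, S = 1 / (4 * -0.37), K1 = 1, K2 = 1))$trt,
    trt(tsd_params("logistic", P = 30, S = -0.37))$trt,
    tolerance = 1e-9
  )
  # limits collapse onto the pivotal temperature as l -> 0.5
  expect_lt(trt(tsd_params("logistic", P = 30, S = -0.4), l = 0.4999)$trt,
            1e-3)
  expect_error(trt(tsd_params("logistic", P = 30, S = -0.4), l = 0.7),
               "between 0 and 0.5")
  expect_error(trt(tsd_params("logistic", P = 30, S = -0.4), l = 0))
})

test_that("parameter containers validate and convert", {
  expect_error(tsd_params("logistic", P = 30, S = -0.4, K1 = 1), "flexit")
  expect_error(tsd_params("flexit", P = 30, S = -0.4), "four")
  expect_error(tsd_params("logistic", P = Inf, S = -0.4), "finite")
  p <- tsd_params("flexit", P = 30, S = -0.4, K1 = 2, K2 = -1)
  expect_identical(as_tsd_params(as.list(p)), p)
  expect_error(as_flexit_params(tsd_params("logistic", P = 30, S = 0)))
})
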