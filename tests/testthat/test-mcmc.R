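test_that("default priors follow the published specification", {
  pr <- tsd_priors("logistic")
  expect_equal(pr$parameter, c("P", "S"))
  expect_equal(pr$density, c("dunif", "dunif"))
  expect_equal(pr$min, c(25, -2))
  expect_equal(pr$max, c(35, 2))
  expect_equal(pr$sd_prop, c(2, 0.5))

  fit <- fit_tsd(filter_tsd(olive_ridley(rmu = "East Pacific")), "logistic")
  prm <- tsd_priors("logistic", fit)
  expect_equal(prm$density, c("dnorm", "dnorm"))
  expect_equal(prm$prior1, unname(fit$estimate), tolerance = 1e-10)
  expect_equal(prm$prior2, c(2, 1))
  expect_equal(prm$init, unname(fit$estimate), tolerance = 1e-10)
  expect_true(attr(prm, "from_mle"))

  prf <- tsd_priors("flexit")
  expect_equal(prf$min, c(25, -2, -500, -500))
  expect_equal(prf$max, c(35, 2, 500, 500))
})

test_that("chains are reproducible, respect support, and adapt towards 0.234", {
  d <- filter_tsd(olive_ridley(rmu = "East Pacific"))
  m1 <- fit_tsd_mcmc(d, "logistic", n_iter = 12000, seed = 17)
  m2 <- fit_tsd_mcmc(d, "logistic", n_iter = 12000, seed = 17)
  expect_identical(m1$chain, m2$chain)
  expect_true(all(m1$chain[, "P"] >= 25 & m1$chain[, "P"] <= 35))
  expect_true(all(m1$chain[, "S"] >= -2 & m1$chain[, "S"] <= 2))
  expect_equal(mean(m1$acceptance_post), 0.234, tolerance = 0.05 / 0.234)
  expect_lt(m1$burn_in, 100)  # started from the MLE
})

test_that("the sampler recovers an analytic beta-binomial posterior", {
  # one incubation at the pivotal temperature with a flat prior on the sex
  # ratio: holding S fixed is impossible, so instead check via a fit where
  # the curve value at the single temperature is a smooth monotone map of P.
  # Simpler and exact: a single group at t with uniform P prior induces a
  # posterior on sr(t; P, S0). Compare the posterior of sr against the
  # conjugate Beta(M + 1, F + 1) truncated to the reachable range.
  one <- make_groups(30, 14, 6)
  pr <- tsd_priors("logistic")
  pr$init <- c(30, -0.5)
  pr$min <- c(10, -0.5)   # S held fixed by a point support
  pr$max <- c(50, -0.5)
  pr$density <- c("dunif", "dnorm")
  pr$prior1 <- c(10, -0.5)
  pr$prior2 <- c(50, 1e-6)
  # with S fixed at -0.5, sr(30) = 1/(1 + exp(2 (30 - P))) and a flat P
  # prior maps by change of variables (|dP/dsr| = 1/(2 sr (1-sr))) to a
  # posterior on sr proportional to sr^(M-1) (1-sr)^(F-1): Beta(M, F).
  m <- fit_tsd_mcmc(one, "logistic", priors = pr, n_iter = 60000,
                    burn_in = 5000, seed = 23)
  sr_draws <- sr_logistic(30, tsdnorm:::post_burnin(m)[, "P"], -0.5)
  qs <- quantile(sr_draws, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  expect_equal(qs, qbeta(c(0.1, 0.25, 0.5, 0.75, 0.9), 14, 6),
               tolerance = 0.02)
})

test_that("an uninformative dataset returns the prior and warns", {
  empty <- make_groups(numeric(0), integer(0), integer(0))
  pr <- tsd_priors("logistic")
  m <- fit_tsd_mcmc(empty, "logistic", priors = pr, n_iter = 40000,
                    burn_in = 2000, seed = 31)
  ch <- tsdnorm:::post_burnin(m)
  # posterior indistinguishable from the uniform prior on P
  ks <- suppressWarnings(
    stats::ks.test(ch[, "P"], "punif", 25, 35)
  )
  expect_lt(ks$statistic[[1]], 0.03)     # close to uniform
  ov <- prior_posterior_overlap(m)
  expect_true(all(ov$overlap > 0.9))
  expect_warning(tidy(m), "caution")
})

test_that("posterior summaries include the derived TRT and handle degeneracy", {
  d <- filter_tsd(olive_ridley(rmu = "East Pacific"))
  m <- fit_tsd_mcmc(d, "logistic", n_iter = 15000, seed = 7)
  td <- suppressWarnings(tidy(m))
  expect_equal(td$term, c("P", "S", "TRT"))
  # TRT row is the transform of the S draws, not an independent quantity
  ch <- tsdnorm:::post_burnin(m)
  expect_equal(unname(td$mean[td$term == "TRT"]),
               mean(abs(ch[, "S"]) * 2 * log(19)), tolerance = 1e-10)
  expect_true(all(td$q0.025 <= td$q0.5 & td$q0.5 <= td$q0.975))

  degen <- m
  degen$chain <- matrix(rep(c(30.4, -0.4), each = 50), 50, 2,
                        dimnames = list(NULL, c("P", "S")))
  degen$burn_in <- 10
  td2 <- suppressWarnings(tidy(degen))
  expect_equal(unname(td2$sd), rep(0, 3))
  expect_equal(td2$q0.025, td2$q0.975, ignore_attr = TRUE)
})

test_that("credibility intervals cover the truth at the nominal rate", {
  truth <- tsd_params("logistic", P = 30, S = -0.4)
  hits <- vapply(1:40, function(r) {
    sim <- simulate_tsd(seq(27.5, 32.5, length.out = 8), 40, truth,
                        seed = 5000 + r)
    m <- fit_tsd_mcmc(sim, "logistic", n_iter = 6000, seed = r)
    ch <- tsdnorm:::post_burnin(m)
    q <- quantile(ch[, "P"], c(0.025, 0.975), names = FALSE)
    q[1] <= 30 && 30 <= q[2]
  }, logical(1))
  expect_gte(mean(hits), 0.85)   # ~95% nominal, 40 replicates
  expect_lte(mean(hits), 1.0)
})

test_that("invalid starting points and burn-in are rejected", {
  d <- filter_tsd(olive_ridley(country = "Brazil"))
  pr <- tsd_priors("logistic")
  pr$init <- c(50, -0.3)
  expect_error(fit_tsd_mcmc(d, "logistic", priors = pr, n_iter = 100),
               "support")
  expect_error(fit_tsd_mcmc(d, "logistic", n_iter = 100, burn_in = 100),
               "burn_in")
})
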