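test_that("deviance is the likelihood gap to the saturated model", {
  d <- filter_tsd(olive_ridley(country = "Costa Rica"))
  fit <- fit_tsd(d, "logistic")
  g <- gof_deviance(fit)
  # pure consistency identity with the package's own likelihood routine
  sat_nll <- -sum(dbinom(d$males, d$males + d$females,
                         d$males / (d$males + d$females), log = TRUE))
  expect_equal(g$deviance, 2 * (fit$neg_log_lik - sat_nll), tolerance = 1e-8)
  expect_equal(g$df, nrow(d) - 2)
  expect_equal(g$p_chi2, pchisq(g$deviance, g$df, lower.tail = FALSE))

  # a saturated-equivalent fit has deviance zero
  perfect <- make_groups(c(28, 30, 32), c(10, 5, 0), c(0, 5, 10))
  gp <- gof_deviance(suppressWarnings(fit_tsd(perfect, "logistic")))
  expect_equal(gp$deviance, 0, tolerance = 1e-4)
})

test_that("published global deviance and chi-squared tail are reproduced", {
  fit <- fit_tsd(filter_tsd(olive_ridley()), "logistic")
  g <- gof_deviance(fit)
  expect_equal(g$deviance, 45.68, tolerance = 0.001)
  expect_equal(g$df, 38)
  expect_equal(g$p_chi2, 0.183117, tolerance = 0.001)
})

test_that("simulated null deviances behave like a parametric bootstrap", {
  # chi-squared limit: with generous counts the null deviance mean is near df
  d <- simulate_tsd(seq(27, 33, length.out = 12), 400,
                    tsd_params("logistic", P = 30, S = -0.6), seed = 2)
  fit <- fit_tsd(d, "logistic")
  g <- gof_null_deviance(fit, n_rep = 300, seed = 4)
  expect_equal(mean(g$null_deviances), g$df, tolerance = 0.25)
  expect_true(g$p_random >= 0 && g$p_random <= 1)
  expect_equal(g$n_failed, 0)

  # p_random is roughly uniform when the data really come from the model
  ps <- vapply(1:24, function(r) {
    sim <- simulate_tsd(seq(27, 33, length.out = 10), 25,
                        tsd_params("logistic", P = 30, S = -0.5),
                        seed = 1000 + r)
    f <- suppressWarnings(fit_tsd(sim, "logistic"))
    gof_null_deviance(f, n_rep = 59, seed = r)$p_random
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("AICc table reproduces the published model comparison", {
  d <- filter_tsd(olive_ridley())
  tab <- compare_models(logistic = fit_tsd(d, "logistic"),
                        flexit = fit_tsd(d, "flexit"))
  expect_equal(tab$AICc[tab$model == "logistic"], 69.52, tolerance = 0.002)
  expect_equal(tab$AICc[tab$model == "flexit"], 62.6, tolerance = 0.002)
  expect_equal(sum(tab$weight), 1)
  expect_equal(tab$weight[tab$model == "flexit"], 0.97, tolerance = 0.011)
  expect_equal(tab$delta_AICc[which.min(tab$AICc)], 0)
})

test_that("information-criterion weights have the elementary properties", {
  d <- filter_tsd(olive_ridley(country = "Brazil"))
  fit <- fit_tsd(d, "logistic")
  # single model: weight one
  expect_equal(compare_models(fit)$weight, 1)
  # two identical models: weights half and half
  tab <- compare_models(a = fit, b = fit)
  expect_equal(tab$weight, c(0.5, 0.5))
  # weights depend only on criterion differences: a common -lnL shift
  # (e.g. dropping the binomial-coefficient constants) leaves them unchanged
  fit2 <- fit
  fit2$neg_log_lik <- fit$neg_log_lik + 7
  fit3 <- suppressWarnings(fit_tsd(d, "flexit"))
  fit4 <- fit3
  fit4$neg_log_lik <- fit3$neg_log_lik + 7
  expect_equal(compare_models(a = fit, b = fit3)$weight,
               compare_models(a = fit2, b = fit4)$weight, tolerance = 1e-10)
  # AICc undefined when n - p - 1 <= 0 is flagged
  tiny <- compare_models(fit, n = 3)
  expect_false(tiny$aicc_defined)
})

test_that("grouped-vs-separated comparison uses distinct-temperature sample sizes", {
  cr <- filter_tsd(olive_ridley(country = "Costa Rica"))
  mx <- filter_tsd(olive_ridley(country = "Mexico"))
  cmp <- suppressWarnings(
    compare_datasets(list(`Costa Rica` = cr, Mexico = mx))
  )
  expect_equal(cmp$n, c(15, 19))  # pooled distinct; per-dataset distinct sum
  expect_equal(cmp$BIC,
               2 * cmp$neg_log_lik + cmp$p * log(cmp$n), tolerance = 1e-10)
  expect_equal(sum(cmp$w_value), 1)
  expect_equal(cmp$hypothesis[which.max(cmp$w_value)], "grouped")

  # two identical copies: grouped always wins (penalty-only difference)
  cmp2 <- compare_datasets(list(a = cr, b = cr))
  expect_equal(cmp2$hypothesis[which.min(cmp2$BIC)], "grouped")
  # identical copies: grouped and separated likelihoods coincide, so only
  # the parameter penalty separates the hypotheses
  expect_equal(cmp2$neg_log_lik[2], cmp2$neg_log_lik[1], tolerance = 1e-4)
  expect_equal(cmp2$delta_BIC[2], 4 * log(cmp2$n[2]) - 2 * log(cmp2$n[1]),
               tolerance = 1e-3)

  # worldwide: separate reaction norms per management unit are favoured
  d <- filter_tsd(olive_ridley())
  world <- suppressWarnings(compare_datasets(split(d, d$rmu)))
  expect_equal(world$n, c(30, 33))
  expect_equal(world$hypothesis[which.max(world$w_value)], "separated")
  expect_equal(world$BIC[world$hypothesis == "grouped"], 71.99,
               tolerance = 0.001)
  expect_equal(world$w_value[world$hypothesis == "separated"], 0.97,
               tolerance = 0.05 / 0.97)
})
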