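#' Default prior specification for a reaction-norm family
#'
#' One row per parameter with the fields the sampler understands: `density`
#' (`"dnorm"` or `"dunif"`), its two parameters `prior1`/`prior2` (mean/sd
#' for the normal, min/max for the uniform), hard support bounds
#' `min`/`max`, the chain's starting value `init`, and the initial proposal
#' standard deviation `sd_prop`.
#'
#' The hard support is P in \[25, 35\] degC, S in \[-2, 2\] and K in
#' \[-500, 500\]. When a maximum-likelihood fit is supplied the priors are
#' Gaussian, centred on the estimates with deliberately wide standard
#' deviations (2 degC for P, 1 for S, 100 for K) so the data, not the prior,
#' drive the posterior, and the chain starts at the estimates (a burn-in of
#' around 10 then suffices). Without a fit the priors are uniform over the
#' support. Initial proposal standard deviations are 2 for P and 0.5 for S,
#' K1 and K2; they are tuned during the adaptation phase.
#'
#' @param family `"logistic"` or `"flexit"`.
#' @param mle Optional [fit_tsd()] result used to centre the priors.
#' @return A tibble of class `"tsd_priors"`, one row per parameter, with an
#'   attribute `from_mle`.
#' @examples
#' tsd_priors("logistic")
#' tsd_priors("logistic", fit_tsd(filter_tsd(olive_ridley()), "logistic"))
#' @export
tsd_priors <- function(family = c("logistic", "flexit"), mle = NULL) {
  family <- match.arg(family)
  nm <- param_names(family)
  support <- list(P = c(25, 35), S = c(-2, 2),
                  K1 = c(-500, 500), K2 = c(-500, 500))
  prior_sd <- c(P = 2, S = 1, K1 = 100, K2 = 100)
  sd_prop <- c(P = 2, S = 0.5, K1 = 0.5, K2 = 0.5)
  from_mle <- !is.null(mle)
  if (from_mle) {
    stopifnot(inherits(mle, "tsd_fit"))
    if (mle$family != family) {
      abort("`mle` was fitted with a different family than requested.")
    }
  }
  rows <- lapply(nm, function(p) {
    lo <- support[[p]][1]; hi <- support[[p]][2]
    if (from_mle) {
      ctr <- min(max(mle$estimate[[p]], lo), hi)
      tibble(parameter = p, density = "dnorm",
             prior1 = ctr, prior2 = prior_sd[[p]],
             min = lo, max = hi, init = ctr, sd_prop = sd_prop[[p]])
    } else {
      tibble(parameter = p, density = "dunif",
             prior1 = lo, prior2 = hi,
             min = lo, max = hi, init = (lo + hi) / 2, sd_prop = sd_prop[[p]])
    }
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("tsd_priors", class(out)), from_mle = from_mle)
}

log_prior_fun <- function(priors) {
  dens <- priors$density
  p1 <- priors$prior1
  p2 <- priors$prior2
  function(x, j) {
    if (dens[j] == "dnorm") {
      dnorm(x, p1[j], p2[j], log = TRUE)
    } else {
      dunif(x, p1[j], p2[j], log = TRUE)
    }
  }
}

#' Bayesian reaction-norm fit by adaptive Metropolis-Hastings
#'
#' Component-wise Gaussian random-walk Metropolis-Hastings on the binomial
#' log-likelihood plus log-prior. Each parameter is updated in turn with a
#' normal proposal; proposals outside the prior's hard support are rejected
#' outright. During the adaptation phase (the first
#' `min(10000, n_iter / 2)` iterations) proposal standard deviations are
#' rescaled after every batch of 100 iterations by
#' `exp(kappa * (acc - 0.234))` with `kappa = 1 / sqrt(batch)` — a
#' Robbins-Monro scheme steering each component's acceptance rate towards
#' the optimal 0.234 — and are frozen afterwards, so the summarised part of
#' the chain is Markovian.
#'
#' Unlike the maximum-likelihood route, datasets without any mixed-sex
#' group — even all-male or all-female data — are accepted: the posterior
#' then simply reflects the prior where the likelihood is uninformative,
#' which is exactly the credibility statement such data support.
#'
#' @param data An incubation tibble (may have no mixed-sex groups).
#' @param family `"logistic"` or `"flexit"`.
#' @param priors A [tsd_priors()] tibble; defaults to priors centred on the
#'   maximum-likelihood fit when one is obtainable, else uniform priors.
#' @param n_iter Total iterations (default 100,000).
#' @param burn_in Iterations discarded before summarising. Defaults to 10
#'   for MLE-centred priors and 10,000 otherwise.
#' @param seed Integer seed; fixed seed gives a bit-identical chain.
#' @param adapt Tune proposal standard deviations? (Default `TRUE`.)
#' @param thin Keep every `thin`-th iteration (default 1, no thinning).
#' @return An object of class `"tsd_mcmc"`: the chain (matrix of kept
#'   states), log-posterior trace, overall and post-adaptation acceptance
#'   rates, per-parameter tuned proposal sds, burn-in, seed, priors, family
#'   and data. Supports [tidy()], [glance()], `print()` and [autoplot()].
#' @examples
#' \donttest{
#' d <- filter_tsd(olive_ridley(rmu = "East Pacific"))
#' post <- fit_tsd_mcmc(d, "logistic", n_iter = 20000, seed = 1)
#' tidy(post)
#' }
#' @export
fit_tsd_mcmc <- function(data, family = c("logistic", "flexit"),
                         priors = NULL, n_iter = 100000, burn_in = NULL,
                         seed = NULL, adapt = TRUE, thin = 1) {
  family <- match.arg(family)
  validate_tsd(data)
  data <- complete_tsd(data)
  if (is.null(priors)) {
    mle <- tryCatch(fit_tsd(data, family, hessian = FALSE),
                    error = function(e) NULL)
    priors <- suppressWarnings(tsd_priors(family, mle))
  }
  stopifnot(all(param_names(family) == priors$parameter))
  k <- nrow(priors)
  init <- priors$init
  if (any(init < priors$min | init > priors$max)) {
    abort("Initial value outside the prior support.")
  }
  lpr <- log_prior_fun(priors)
  lp0 <- sum(vapply(seq_len(k), function(j) lpr(init[j], j), numeric(1)))
  if (!is.finite(lp0)) abort("Initial value has zero prior probability.")
  if (is.null(burn_in)) {
    burn_in <- if (isTRUE(attr(priors, "from_mle"))) 10 else 10000
  }
  if (burn_in >= n_iter) abort("`burn_in` must be smaller than `n_iter`.")
  nll <- nll_closure(data, family)
  adapt_n <- if (adapt) min(10000, floor(n_iter / 2)) else 0

  run_chain <- function() {
    x <- init
    cur_ll <- -nll(x)
    cur_lp <- vapply(seq_len(k), function(j) lpr(x[j], j), numeric(1))
    sds <- priors$sd_prop
    lo <- priors$min; hi <- priors$max
    chain <- matrix(NA_real_, ceiling(n_iter / thin), k)
    lp_trace <- numeric(ceiling(n_iter / thin))
    acc <- acc_post <- integer(k)
    n_post <- 0L
    batch_acc <- integer(k)
    batch <- 0L
    kept <- 0L
    for (i in seq_len(n_iter)) {
      for (j in seq_len(k)) {
        prop <- x[j] + rnorm(1, 0, sds[j])
        if (prop < lo[j] || prop > hi[j]) next
        lp_prop <- lpr(prop, j)
        xp <- x; xp[j] <- prop
        ll_prop <- -nll(xp)
        # la may be +Inf (escaping a zero-likelihood state) or -Inf
        # (proposal has zero posterior); only NaN (-Inf vs -Inf) is skipped
        la <- (ll_prop + lp_prop) - (cur_ll + cur_lp[j])
        if (!is.na(la) && log(runif(1)) < la) {
          x <- xp; cur_ll <- ll_prop; cur_lp[j] <- lp_prop
          acc[j] <- acc[j] + 1L
          batch_acc[j] <- batch_acc[j] + 1L
          if (i > adapt_n) acc_post[j] <- acc_post[j] + 1L
        }
      }
      if (i > adapt_n) n_post <- n_post + 1L
      if (adapt && i <= adapt_n && i %% 100 == 0) {
        batch <- batch + 1L
        rate <- batch_acc / 100
        sds <- sds * exp((rate - 0.234) / sqrt(batch))
        batch_acc <- integer(k)
      }
      if (i %% thin == 0) {
        kept <- kept + 1L
        chain[kept, ] <- x
        lp_trace[kept] <- cur_ll + sum(cur_lp)
      }
    }
    list(chain = chain[seq_len(kept), , drop = FALSE],
         lp = lp_trace[seq_len(kept)],
         acceptance = acc / n_iter,
         acceptance_post = if (n_post > 0) acc_post / n_post else NA_real_,
         sds = sds)
  }
  res <- if (is.null(seed)) run_chain() else withr::with_seed(seed, run_chain())
  colnames(res$chain) <- priors$parameter
  structure(
    list(
      family = family,
      chain = res$chain,
      log_posterior = res$lp,
      acceptance = res$acceptance,
      acceptance_post = res$acceptance_post,
      proposal_sd = setNames(res$sds, priors$parameter),
      n_iter = n_iter,
      adapt_n = adapt_n,
      burn_in = burn_in,
      thin = thin,
      seed = seed,
      priors = priors,
      data = data
    ),
    class = "tsd_mcmc"
  )
}

post_burnin <- function(x) {
  keep <- floor(x$burn_in / x$thin)
  if (keep >= nrow(x$chain)) abort("Burn-in leaves no samples to summarise.")
  x$chain[(keep + 1):nrow(x$chain), , drop = FALSE]
}

#' Posterior summaries including the derived TRT
#'
#' Summaries are computed on the post-burn-in samples only. The transitional
#' range of temperatures is evaluated at *every* retained parameter vector,
#' so its posterior honours all parameter correlations; its quantiles need
#' no distributional assumption. The posterior standard deviation of a
#' parameter is the standard error of its estimate.
#'
#' @param x A [fit_tsd_mcmc()] result.
#' @param l TRT limit (see [trt()]).
#' @param probs Quantiles to report.
#' @param ... Unused.
#' @return A tibble with one row per parameter plus one for `TRT`:
#'   `term`, `mean`, `sd` and one column per quantile.
#' @export
tidy.tsd_mcmc <- function(x, l = 0.05, probs = c(0.025, 0.5, 0.975), ...) {
  ch <- post_burnin(x)
  tw <- trt_width(x$family, ch[, "P"], ch[, "S"],
                  K1 = if (x$family == "flexit") ch[, "K1"],
                  K2 = if (x$family == "flexit") ch[, "K2"], l = l)
  vals <- cbind(ch, TRT = tw)
  qs <- t(apply(vals, 2, quantile, probs = probs, names = FALSE))
  colnames(qs) <- paste0("q", probs)
  ov <- prior_posterior_overlap(x)
  if (any(ov$overlap > 0.9)) {
    warn(paste(
      "Posterior of",
      paste(ov$parameter[ov$overlap > 0.9], collapse = ", "),
      "is close to its prior: the data carry little information about it;",
      "use these results with caution."
    ))
  }
  dplyr::bind_cols(
    tibble(term = colnames(vals),
           mean = colMeans(vals),
           sd = apply(vals, 2, sd)),
    as_tibble(as.data.frame(qs))
  )
}

#' @describeIn fit_tsd_mcmc one-row summary: iteration counts, burn-in,
#'   overall and post-adaptation acceptance rates, maximum prior-posterior
#'   overlap.
#' @param x A `tsd_mcmc` object.
#' @param ... Unused.
#' @export
glance.tsd_mcmc <- function(x, ...) {
  tibble(
    family = x$family,
    n_iter = x$n_iter,
    burn_in = x$burn_in,
    thin = x$thin,
    acceptance = mean(x$acceptance),
    acceptance_post = mean(x$acceptance_post),
    max_prior_overlap = max(prior_posterior_overlap(x)$overlap)
  )
}

#' Overlap between prior and posterior distributions
#'
#' Overlap coefficient (shared probability mass on a 101-bin histogram over
#' the prior support) between each parameter's prior and its post-burn-in
#' posterior. Values near 1 mean the data did not update the prior: results
#' for that parameter reflect the prior, not the observations, and should be
#' used with caution.
#'
#' @param x A [fit_tsd_mcmc()] result.
#' @return A tibble with columns `parameter`, `overlap` in \[0, 1\].
#' @export
prior_posterior_overlap <- function(x) {
  stopifnot(inherits(x, "tsd_mcmc"))
  ch <- post_burnin(x)
  pr <- x$priors
  ov <- vapply(seq_len(nrow(pr)), function(j) {
    breaks <- seq(pr$min[j], pr$max[j], length.out = 102)
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
    w <- diff(breaks)
    prior_mass <- if (pr$density[j] == "dnorm") {
      m <- dnorm(mids, pr$prior1[j], pr$prior2[j]) * w
      m / sum(m)
    } else {
      rep(1 / length(mids), length(mids))
    }
    h <- hist(pmin(pmax(ch[, j], pr$min[j]), pr$max[j]),
              breaks = breaks, plot = FALSE)
    post_mass <- h$counts / sum(h$counts)
    sum(pmin(prior_mass, post_mass))
  }, numeric(1))
  tibble(parameter = pr$parameter, overlap = ov)
}

#' @export
print.tsd_mcmc <- function(x, ...) {
  cat(sprintf(
    "<tsd_mcmc: %s, %d iterations (burn-in %d, thin %d)>\n",
    x$family, x$n_iter, x$burn_in, x$thin
  ))
  cat(sprintf("Acceptance rate %.3f (post-adaptation %.3f)\n",
              mean(x$acceptance), mean(x$acceptance_post)))
  print(suppressWarnings(tidy(x)), digits = 4)
  invisible(x)
}

#' Trace and posterior-density plot for an MCMC fit
#'
#' @param object A `tsd_mcmc` object.
#' @param ... Unused.
#' @return A ggplot object: one facet per parameter, trace on the iteration
#'   axis.
#' @export
autoplot.tsd_mcmc <- function(object, ...) {
  ch <- as.data.frame(object$chain)
  ch$iteration <- seq_len(nrow(ch)) * object$thin
  long <- tidyr::pivot_longer(ch, -"iteration",
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = object$burn_in, linetype = "dotted") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Iteration", y = NULL)
}

#' Export an MCMC chain as a tibble
#'
#' One row per kept iteration with the parameter values and log-posterior;
#' convenient for CSV export or external diagnostics.
#'
#' @param x A [fit_tsd_mcmc()] result.
#' @param ... Unused.
#' @return A tibble with `iteration`, one column per parameter, and
#'   `log_posterior`.
#' @export
as_tibble.tsd_mcmc <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$chain))
  dplyr::bind_cols(
    tibble(iteration = seq_len(nrow(out)) * x$thin),
    out,
    tibble(log_posterior = x$log_posterior)
  )
}
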