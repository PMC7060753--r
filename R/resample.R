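#' Resample parameters from the asymptotic covariance
#'
#' Draws parameter vectors from a multivariate normal centred at the maximum
#' likelihood estimates with the Hessian-derived covariance (Cholesky
#' factorisation; an eigenvalue factorisation is used when the covariance is
#' not positive definite). Draws that flip the sign of `S` — which would
#' reverse the whole sex-determination pattern — or, for flexit fits, the
#' sign of `K1 - 1` or `K2 - 1`, are discarded and logged.
#'
#' Note that this sign-coherence screening *artificially narrows* the
#' resulting confidence intervals, because the most divergent draws are
#' exactly the ones removed. When the rejection rate is substantial the
#' Bayesian sampler ([fit_tsd_mcmc()]) is the sound alternative; a warning
#' says so when more than 90% of draws are rejected. Screening can be
#' switched off (`screen = FALSE`) to quantify its effect.
#'
#' @param fit A [fit_tsd()] result with a valid covariance.
#' @param n Number of draws requested (default 10,000).
#' @param seed Integer seed; draws are bit-reproducible given a seed.
#' @param screen Apply the sign-coherence rules? Default `TRUE`.
#' @return A tibble of retained draws (one column per parameter) of class
#'   `"tsd_draws"`, with attributes `n_requested`, `n_retained`,
#'   `rejections` (named counts per rule), `seed`, and the generating `fit`.
#' @examples
#' fit <- fit_tsd(filter_tsd(olive_ridley()), "logistic")
#' draws <- resample_fit(fit, n = 2000, seed = 1)
#' attr(draws, "n_retained")
#' @export
resample_fit <- function(fit, n = 10000, seed = NULL, screen = TRUE) {
  stopifnot(inherits(fit, "tsd_fit"))
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    abort("`n` must be a positive count.")
  }
  if (is.null(fit[["vcov"]])) {
    abort("The fit carries no covariance; rerun `fit_tsd()` with hessian = TRUE.")
  }
  n <- as.integer(n)
  est <- fit$estimate
  k <- length(est)
  V <- fit[["vcov"]]
  draw_fun <- function() {
    Z <- matrix(rnorm(n * k), n, k)
    R <- tryCatch(chol(V), error = function(e) NULL)
    X <- if (!is.null(R)) {
      Z %*% R
    } else if (all(abs(V) < .Machine$double.eps)) {
      matrix(0, n, k)
    } else {
      e <- eigen(V, symmetric = TRUE)
      lam <- pmax(e$values, 0)
      Z %*% (t(e$vectors) * sqrt(lam))
    }
    sweep(X, 2, est, "+")
  }
  X <- if (is.null(seed)) draw_fun() else withr::with_seed(seed, draw_fun())
  colnames(X) <- names(est)

  rejections <- c()
  keep <- rep(TRUE, n)
  if (screen) {
    bad_s <- sign(X[, "S"]) != sign(est[["S"]])
    rejections <- c(rejections, S_sign_flip = sum(bad_s))
    keep <- keep & !bad_s
    if (fit$family == "flexit") {
      bad_k1 <- sign(X[, "K1"] - 1) != sign(est[["K1"]] - 1)
      bad_k2 <- sign(X[, "K2"] - 1) != sign(est[["K2"]] - 1)
      rejections <- c(rejections,
                      K1_minus_1_sign_flip = sum(bad_k1 & !bad_s),
                      K2_minus_1_sign_flip = sum(bad_k2 & !bad_s & !bad_k1))
      keep <- keep & !bad_k1 & !bad_k2
    }
  }
  retained <- as_tibble(as.data.frame(X[keep, , drop = FALSE]))
  if (screen && sum(keep) < 0.1 * n) {
    warn(paste(
      "More than 90% of resampled parameter vectors violated the",
      "sign-coherence rules; the screened interval is unreliable.",
      "Use the Bayesian sampler `fit_tsd_mcmc()` instead."
    ))
  }
  structure(retained,
            class = c("tsd_draws", class(retained)),
            n_requested = n,
            n_retained = sum(keep),
            rejections = rejections,
            seed = seed,
            fit = fit)
}

draws_or_default <- function(fit, draws, seed) {
  if (is.null(draws)) resample_fit(fit, seed = seed) else draws
}

#' Pointwise confidence band for the fitted sex-ratio curve
#'
#' Evaluates the reaction norm at every retained parameter draw and returns
#' per-temperature quantiles of the resulting curves.
#'
#' @param fit A [fit_tsd()] result.
#' @param draws A [resample_fit()] result; generated on the fly (with
#'   `seed`) when omitted.
#' @param temperatures Vector of temperatures (degC) at which to evaluate.
#' @param level Coverage of the band (default 0.95).
#' @param seed Seed used only when `draws` is omitted.
#' @return A tibble with columns `temperature`, `lower`, `median`, `upper`;
#'   the band is contained in \[0, 1\] and contains the median curve.
#' @export
ci_curve <- function(fit, draws = NULL, temperatures, level = 0.95,
                     seed = NULL) {
  stopifnot(inherits(fit, "tsd_fit"))
  draws <- draws_or_default(fit, draws, seed)
  if (!nrow(draws)) abort("No retained draws to summarise.")
  a <- (1 - level) / 2
  M <- as.matrix(draws)
  curves <- vapply(seq_len(nrow(M)), function(i) {
    sex_ratio(temperatures, params_from_vector(fit$family, M[i, ]))
  }, numeric(length(temperatures)))
  curves <- matrix(curves, nrow = length(temperatures))
  qs <- apply(curves, 1, quantile, probs = c(a, 0.5, 1 - a), names = FALSE)
  tibble(temperature = temperatures,
         lower = qs[1, ], median = qs[2, ], upper = qs[3, ])
}

#' Resampled intervals for the pivotal temperature and the TRT
#'
#' Computes the transitional range of temperatures for every retained draw
#' and summarises `P` and `TRT` by quantiles.
#'
#' @param fit A [fit_tsd()] result.
#' @param draws A [resample_fit()] result; generated on the fly when omitted.
#' @param l TRT limit (see [trt()]).
#' @param probs Quantiles to report.
#' @param seed Seed used only when `draws` is omitted.
#' @return A tibble with one row per quantity (`P`, `TRT`) and one column
#'   per requested quantile (named `q0.025` etc.).
#' @examples
#' fit <- fit_tsd(filter_tsd(olive_ridley(rmu = "East Pacific")), "logistic")
#' ci_derived(fit, resample_fit(fit, n = 5000, seed = 42))
#' @export
ci_derived <- function(fit, draws = NULL, l = 0.05,
                       probs = c(0.025, 0.5, 0.975), seed = NULL) {
  stopifnot(inherits(fit, "tsd_fit"))
  draws <- draws_or_default(fit, draws, seed)
  if (!nrow(draws)) abort("No retained draws to summarise.")
  tw <- trt_width(fit$family, draws$P, draws$S,
                  K1 = draws$K1, K2 = draws$K2, l = l)
  out <- rbind(
    quantile(draws$P, probs, names = FALSE),
    quantile(tw, probs, names = FALSE)
  )
  colnames(out) <- paste0("q", probs)
  dplyr::bind_cols(tibble(quantity = c("P", "TRT")),
                   as_tibble(as.data.frame(out)))
}

#' Delta-method intervals are deliberately not provided
#'
#' The delta method presumes the estimator is (asymptotically) normal. The
#' shape parameter `S` of a reaction norm has a truncated sampling
#' distribution — a sign change reverses the entire pattern — so the
#' assumption fails exactly where intervals matter. Use [resample_fit()]
#' with [ci_derived()], or the Bayesian sampler [fit_tsd_mcmc()].
#'
#' @param ... Ignored.
#' @export
delta_method <- function(...) {
  abort(paste(
    "The delta method is not implemented: it assumes untruncated normality",
    "of the estimators, which fails for the sign-constrained shape",
    "parameter S. Use resample_fit()/ci_derived() or fit_tsd_mcmc()."
  ))
}
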