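aicc_value <- function(neg_log_lik, p, n) {
  aic <- 2 * neg_log_lik + 2 * p
  if (n - p - 1 <= 0) return(NA_real_)
  aic + 2 * p * (p + 1) / (n - p - 1)
}

#' Goodness of fit by deviance against the saturated model
#'
#' The deviance is `D = 2 (ln L_S - ln L_M)` where the saturated model
#' replaces each group's fitted sex ratio by its observed proportion (one
#' parameter per listed group; groups without sexed embryos are skipped).
#' `D` is asymptotically chi-squared with `n_groups - p` degrees of freedom,
#' but with the small per-group counts typical of incubation studies that
#' approximation can be poor — see [gof_null_deviance()] for the simulated
#' alternative.
#'
#' @param fit A [fit_tsd()] result.
#' @return An object of class `"tsd_gof"`: a list with `deviance`, `df`,
#'   `p_chi2` (and `NA` placeholders for the simulated-null fields).
#' @examples
#' gof_deviance(fit_tsd(filter_tsd(olive_ridley()), "logistic"))
#' @export
gof_deviance <- function(fit) {
  stopifnot(inherits(fit, "tsd_fit"))
  p <- length(fit$estimate)
  df <- fit$n_groups - p
  if (df < 0) abort("More parameters than incubation groups: deviance undefined.")
  D <- max(0, 2 * (saturated_loglik(fit$data) + fit$neg_log_lik))
  structure(
    list(deviance = D, df = df, p_chi2 = pchisq(D, df, lower.tail = FALSE),
         p_random = NA_real_, null_deviances = NULL, n_rep = 0L,
         seed = NULL, n_failed = 0L),
    class = "tsd_gof"
  )
}

#' Goodness of fit by a simulated null-deviance distribution
#'
#' Parametric bootstrap of the deviance: each replicate redraws the male
#' count of every group from a binomial with the group's egg number and the
#' *fitted* sex ratio at its temperature, refits the same model family, and
#' records the replicate's deviance. The reported `p_random` is the fraction
#' of null deviances at least as large as the observed one (`>=` in the tail
#' count). This keeps the experimental design — the same temperatures and
#' the same number of eggs per temperature — and so remains valid where the
#' chi-squared approximation breaks down.
#'
#' @param fit A [fit_tsd()] result.
#' @param n_rep Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; replicate generators are derived
#'   deterministically from it.
#' @return A `"tsd_gof"` object as in [gof_deviance()], with `p_random`,
#'   the vector of `null_deviances`, `n_rep` and the count of failed
#'   replicate refits filled in. More than 10% refit failures triggers a
#'   warning.
#' @examples
#' \donttest{
#' fit <- fit_tsd(filter_tsd(olive_ridley(country = "Costa Rica")), "logistic")
#' gof_null_deviance(fit, n_rep = 200, seed = 1)
#' }
#' @export
gof_null_deviance <- function(fit, n_rep = 1000, seed = NULL) {
  stopifnot(inherits(fit, "tsd_fit"))
  base <- gof_deviance(fit)
  data <- fit$data
  n <- data$males + data$females
  p_fit <- clamp_p(sex_ratio(data$temperature, fit$params))
  family <- fit$family
  b <- default_bounds(family)
  start <- fit$estimate

  one_rep <- function(r) {
    sim <- data
    sim$males <- rbinom(length(n), n, p_fit)
    sim$females <- n - sim$males
    obj <- nll_closure(sim, family)
    o <- tryCatch(
      optim(start, obj, method = "L-BFGS-B", lower = b$lower, upper = b$upper,
            control = list(factr = 1e2, maxit = 2000)),
      error = function(e) NULL
    )
    if (is.null(o) || !is.finite(o$value)) return(NA_real_)
    max(0, 2 * (saturated_loglik(sim) + o$value))
  }
  runner <- function() vapply(seq_len(n_rep), one_rep, numeric(1))
  nulls <- if (is.null(seed)) runner() else withr::with_seed(seed, runner())
  failed <- sum(is.na(nulls))
  if (failed > 0.1 * n_rep) {
    warn(sprintf("%d of %d null-deviance refits failed.", failed, n_rep))
  }
  ok <- nulls[!is.na(nulls)]
  base$p_random <- mean(ok >= base$deviance)
  base$null_deviances <- ok
  base$n_rep <- as.integer(n_rep)
  base$seed <- seed
  base$n_failed <- as.integer(failed)
  base
}

#' @export
print.tsd_gof <- function(x, ...) {
  cat(sprintf("Deviance %.3f on %d df; chi-squared p = %.4f\n",
              x$deviance, x$df, x$p_chi2))
  if (!is.na(x$p_random)) {
    cat(sprintf("Simulated-null p = %.3f (%d replicates, %d failed)\n",
                x$p_random, x$n_rep, x$n_failed))
  }
  invisible(x)
}

#' @export
tidy.tsd_gof <- function(x, ...) {
  tibble(deviance = x$deviance, df = x$df, p_chi2 = x$p_chi2,
         p_random = x$p_random, n_rep = x$n_rep)
}

#' Compare fitted models by AICc and Akaike weights
#'
#' Builds the information-criterion table for a set of models fitted to the
#' *same* dataset: `AIC = 2(-ln L) + 2p`, the small-sample correction
#' `AICc = AIC + 2p(p+1)/(n-p-1)`, differences to the best model, and
#' Akaike weights `exp(-delta/2)` normalised to sum to one. The sample size
#' `n` entering the correction is the number of incubation groups as listed
#' in the dataset (not the number of distinct temperatures).
#'
#' @param ... Two or more [fit_tsd()] results on the same data, optionally
#'   named (names become the `model` column).
#' @param n Override for the AICc sample size; defaults to the common group
#'   count of the fits.
#' @return A tibble with columns `model`, `p`, `neg_log_lik`, `AIC`,
#'   `AICc`, `delta_AICc`, `weight`, `n`; `NA` AICc (when `n - p - 1 <= 0`)
#'   is flagged by the `aicc_defined` column.
#' @examples
#' d <- filter_tsd(olive_ridley())
#' compare_models(logistic = fit_tsd(d, "logistic"),
#'                flexit = fit_tsd(d, "flexit"))
#' @export
compare_models <- function(..., n = NULL) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) && !inherits(fits[[1]], "tsd_fit")) {
    fits <- fits[[1]]
  }
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1), "tsd_fit")))
  labels <- names(fits) %||% rep("", length(fits))
  labels[labels == ""] <- vapply(fits[labels == ""], function(f) f$family,
                                 character(1))
  sizes <- vapply(fits, function(f) f$n_groups, numeric(1))
  if (is.null(n)) {
    if (length(unique(sizes)) != 1L) {
      abort("The fits use different group counts; supply `n` explicitly.")
    }
    n <- sizes[1]
  }
  n_aicc <- n
  tab <- tibble(
    model = labels,
    p = vapply(fits, function(f) length(f$estimate), numeric(1)),
    neg_log_lik = vapply(fits, function(f) f$neg_log_lik, numeric(1)),
    n = n_aicc
  )
  tab$AIC <- 2 * tab$neg_log_lik + 2 * tab$p
  tab$AICc <- vapply(seq_len(nrow(tab)), function(i) {
    aicc_value(tab$neg_log_lik[i], tab$p[i], n_aicc)
  }, numeric(1))
  tab$aicc_defined <- !is.na(tab$AICc)
  crit <- ifelse(tab$aicc_defined, tab$AICc, tab$AIC)
  tab$delta_AICc <- crit - min(crit)
  w <- exp(-tab$delta_AICc / 2)
  tab$weight <- w / sum(w)
  tab[, c("model", "p", "neg_log_lik", "AIC", "AICc", "delta_AICc",
          "weight", "n", "aicc_defined")]
}

#' Grouped versus separated dataset comparison by BIC weight (w-value)
#'
#' Tests whether a collection of datasets is better described by a single
#' reaction norm (one set of `p` parameters fitted to the pooled data) or by
#' one norm per dataset (`k * p` parameters, log-likelihoods summed). Since
#' the true hypothesis is one of the two, BIC (`-2 ln L + p ln n`) is used
#' rather than AICc, and the BIC weights — termed *w-values* — give the
#' probability of each hypothesis.
#'
#' The BIC sample size follows the distinct-temperature convention: `n` is
#' the number of distinct incubation temperatures (duplicates pooled via
#' [merge_temperatures()]) — over the pooled data for the grouped
#' hypothesis, and summed per dataset for the separated one. Set
#' `n_convention = "groups"` to use listed group counts instead.
#'
#' @param datasets A named list of two or more incubation tibbles.
#' @param family Model family fitted throughout (default `"logistic"`).
#' @param n_convention `"distinct_temperatures"` (default) or `"groups"`.
#' @return An object of class `"tsd_bic_comparison"`: a tibble with rows
#'   `grouped` and `separated` and columns `hypothesis`, `neg_log_lik`, `p`,
#'   `n`, `BIC`, `delta_BIC`, `w_value`, carrying the individual fits as
#'   attributes.
#' @examples
#' compare_datasets(list(
#'   `Costa Rica` = filter_tsd(olive_ridley(country = "Costa Rica")),
#'   Mexico = filter_tsd(olive_ridley(country = "Mexico"))
#' ))
#' @export
compare_datasets <- function(datasets, family = "logistic",
                             n_convention = c("distinct_temperatures",
                                              "groups")) {
  n_convention <- match.arg(n_convention)
  stopifnot(is.list(datasets), length(datasets) >= 2)
  labels <- names(datasets) %||% paste0("dataset", seq_along(datasets))
  pooled <- dplyr::bind_rows(lapply(datasets, function(d) {
    complete_tsd(d)[, intersect(tsd_core_cols, names(complete_tsd(d)))]
  }))
  grouped_fit <- fit_tsd(pooled, family)
  sep_fits <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    sep_fits[[i]] <- tryCatch(fit_tsd(datasets[[i]], family),
                              error = function(e) e)
  }
  bad <- vapply(sep_fits, inherits, logical(1), "error")
  if (any(bad)) {
    abort(sprintf(
      "Separate fit failed for dataset(s): %s. First error: %s",
      paste(labels[bad], collapse = ", "),
      conditionMessage(sep_fits[which(bad)[1]][[1]])
    ))
  }
  names(sep_fits) <- labels
  size <- function(d) {
    if (n_convention == "groups") nrow(d) else n_distinct_temperatures(d)
  }
  p <- length(param_names(family))
  tab <- tibble(
    hypothesis = c("grouped", "separated"),
    neg_log_lik = c(grouped_fit$neg_log_lik,
                    sum(vapply(sep_fits, function(f) f$neg_log_lik,
                               numeric(1)))),
    p = c(p, p * length(datasets)),
    n = c(size(pooled), sum(vapply(datasets, size, numeric(1))))
  )
  tab$BIC <- 2 * tab$neg_log_lik + tab$p * log(tab$n)
  tab$delta_BIC <- tab$BIC - min(tab$BIC)
  w <- exp(-tab$delta_BIC / 2)
  tab$w_value <- w / sum(w)
  structure(tab, class = c("tsd_bic_comparison", class(tab)),
            grouped_fit = grouped_fit, separate_fits = sep_fits)
}

#' @export
print.tsd_bic_comparison <- function(x, ...) {
  cat("Grouped vs separated reaction norms (BIC weights / w-values)\n")
  NextMethod()
  best <- x$hypothesis[which.min(x$BIC)]
  cat(sprintf("Favoured hypothesis: %s (w-value %.3f)\n",
              best, max(x$w_value)))
  invisible(x)
}
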