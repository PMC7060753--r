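# Probability clamp: keeps log-likelihoods finite when a fitted curve
# saturates at 0/1 while a group still holds the opposite sex.
clamp_p <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Negative binomial log-likelihood of a dataset under a reaction norm
#'
#' Each incubation group contributes a binomial term: observing `M` males
#' among `M + F` sexed embryos at temperature `t` has likelihood
#' `choose(M+F, M) * p^M * (1-p)^F` with `p` the model sex ratio at `t`.
#' The binomial coefficient is included, groups are summed exactly as listed
#' (duplicate temperatures are *not* pooled), and intersexes never enter the
#' counts. Groups without sexed embryos contribute nothing.
#'
#' @param data An incubation tibble (see [read_tsd()]).
#' @param params A [tsd_params()] object.
#' @return The negative log-likelihood, a single finite number.
#' @examples
#' d <- filter_tsd(olive_ridley())
#' neg_loglik(d, tsd_params("logistic", P = 30.39, S = -0.41))
#' @export
neg_loglik <- function(data, params) {
  validate_tsd(data)
  data <- complete_tsd(data)
  n <- data$males + data$females
  if (!any(n >= 1)) abort("The dataset holds no sexed embryos.")
  p <- clamp_p(sex_ratio(data$temperature, params))
  -sum(dbinom(data$males, n, p, log = TRUE))
}

# log-likelihood of the saturated model: one fitted proportion per group,
# equal to the observed proportion. Groups with no sexed embryos are skipped.
saturated_loglik <- function(data) {
  data <- complete_tsd(data)
  n <- data$males + data$females
  keep <- n > 0
  p <- data$males[keep] / n[keep]
  sum(dbinom(data$males[keep], n[keep], p, log = TRUE))
}

# fast closure used by optimisers and the MCMC sampler: avoids repeated
# validation and tibble access inside tight loops
nll_closure <- function(data, family) {
  tt <- data$temperature
  M <- data$males
  n <- data$males + data$females
  if (family == "logistic") {
    function(x) {
      if (x[2] == 0) return(Inf)
      p <- clamp_p(1 / (1 + exp((x[1] - tt) / x[2])))
      -sum(dbinom(M, n, p, log = TRUE))
    }
  } else {
    function(x) {
      p <- clamp_p(sr_flexit(tt, x[1], x[2], x[3], x[4]))
      v <- -sum(dbinom(M, n, p, log = TRUE))
      if (!is.finite(v)) Inf else v
    }
  }
}
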