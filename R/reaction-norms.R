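# log(|exp(z) - 1|), stable for |z| small and z large
log_expm1_abs <- function(z) {
  out <- numeric(length(z))
  pos <- z > 0
  out[pos] <- z[pos] + log1p(-exp(-z[pos]))
  out[!pos] <- log(-expm1(z[!pos]))
  out
}

# K values of magnitude below 1e-9 are replaced by 1e-9, sign preserved
# (the flexit form is undefined at K = 0)
guard_k <- function(K) {
  if (abs(K) < 1e-9) K <- if (K < 0) -1e-9 else 1e-9
  K
}

# slope-scaling term of each flexit branch: 2^(K-1) * S * K / (2^K - 1),
# written as S*K / (2*(1 - 2^-K)) so that large |K| cannot overflow
flexit_branch_slope <- function(S, K) S * K / (2 * (1 - 2^(-K)))

# log of base = 1 + (2^K - 1) * exp(u), computed in log space.
# For K > 0 the added term is positive (log-sum-exp); for K < 0 it lies in
# (-1, 0) and the base is clamped just above zero if a pathological
# parameter combination drives it non-positive.
flexit_log_base <- function(K, u) {
  lt <- log_expm1_abs(K * log(2)) + u
  if (K > 0) {
    ifelse(lt > 35, lt, log1p(exp(pmin(lt, 35))))
  } else {
    log1p(-exp(pmin(lt, -1e-17)))
  }
}

#' Logistic sex-ratio reaction norm
#'
#' Male relative frequency produced by a constant incubation at temperature
#' `t` under the symmetric logistic model
#' \deqn{sr(t) = (1 + \exp((P - t)/S))^{-1}.}
#' The curve equals 0.5 at `t = P` and its slope there is `1/(4S)`; with
#' `S < 0` it decreases with temperature (TSD Ia: males cool, females warm).
#'
#' @param t Vector of temperatures (degC).
#' @param P Pivotal temperature (degC).
#' @param S Shape parameter: one fourth of the inverse of the slope at `P`.
#'   Must be non-zero.
#' @return Vector of male frequencies in \[0, 1\].
#' @examples
#' sr_logistic(28:33, P = 30.4, S = -0.41)
#' @export
sr_logistic <- function(t, P, S) {
  if (S == 0) abort("S = 0 does not define a logistic reaction norm.")
  1 / (1 + exp((P - t) / S))
}

#' Flexit sex-ratio reaction norm
#'
#' Male relative frequency under the four-parameter asymmetric (flexit)
#' sigmoid. Below the pivotal temperature the curve is
#' \deqn{f(t) = (1 + (2^{K_1}-1) e^{4S_1(P-t)})^{-1/K_1}, \quad
#'       S_1 = 2^{K_1-1} S K_1 / (2^{K_1}-1),}
#' and at or above it
#' \deqn{f(t) = 1 - (1 + (2^{K_2}-1) e^{4S_2(t-P)})^{-1/K_2}, \quad
#'       S_2 = 2^{K_2-1} S K_2 / (2^{K_2}-1).}
#' Both branches give exactly 0.5 at `t = P`; `S` is the slope of the curve
#' there. `K1` and `K2` shape the lower and upper transitions independently.
#' `K` values with magnitude below `1e-9` are replaced by `1e-9` (sign
#' preserved). Evaluation is carried out in log space so that very large
#' `|K|` (the likelihood surface is often nearly flat in `K2`, and fitted
#' values in the hundreds occur) cannot overflow.
#'
#' @param t Vector of temperatures (degC).
#' @param P Pivotal temperature (degC).
#' @param S Slope of the curve at `P`.
#' @param K1,K2 Lower/upper asymptote shape parameters.
#' @return Vector of male frequencies in \[0, 1\].
#' @examples
#' sr_flexit(28:33, P = 30.6, S = -0.79, K1 = -1.72, K2 = 200)
#' @export
sr_flexit <- function(t, P, S, K1, K2) {
  if (!all(is.finite(c(P, S, K1, K2)))) {
    abort("Flexit parameters must all be finite.")
  }
  K1 <- guard_k(K1)
  K2 <- guard_k(K2)
  S1 <- flexit_branch_slope(S, K1)
  S2 <- flexit_branch_slope(S, K2)
  f <- numeric(length(t))
  lo <- t < P
  if (any(lo)) {
    f[lo] <- exp(-flexit_log_base(K1, 4 * S1 * (P - t[lo])) / K1)
  }
  if (any(!lo)) {
    f[!lo] <- 1 - exp(-flexit_log_base(K2, 4 * S2 * (t[!lo] - P)) / K2)
  }
  pmin(pmax(f, 0), 1)
}

#' Evaluate a reaction norm at given temperatures
#'
#' Dispatches to [sr_logistic()] or [sr_flexit()] according to the family
#' recorded in `params`.
#'
#' @param t Vector of temperatures (degC).
#' @param params A [tsd_params()] object.
#' @return Vector of male frequencies in \[0, 1\].
#' @export
sex_ratio <- function(t, params) {
  stopifnot(inherits(params, "tsd_params"))
  if (params$family == "logistic") {
    sr_logistic(t, params$P, params$S)
  } else {
    sr_flexit(t, params$P, params$S, params$K1, params$K2)
  }
}

#' Transitional range of temperatures
#'
#' Width (and bounding temperatures) of the range of constant incubation
#' temperatures producing mixed sex ratios, bounded by male frequencies `l`
#' and `1 - l`. The default `l = 0.05` defines the conventional 5%--95% TRT.
#'
#' For the logistic model the closed form is `TRT = |S * K_l|` with
#' `K_l = |2 ln(l / (1 - l))|`. For the flexit model the two crossing
#' temperatures are obtained by inverting each branch analytically:
#' \deqn{TRT = \frac{1}{4S_2}\ln\frac{(1/(1-l))^{K_2}-1}{2^{K_2}-1}
#'     + \frac{1}{4S_1}\ln\frac{(1/(1-l))^{K_1}-1}{2^{K_1}-1}.}
#' The width is reported as an absolute value (the signed expression is
#' negative for rising norms, i.e. `S > 0`).
#'
#' @param params A [tsd_params()] object with `S != 0`.
#' @param l Sex-ratio limit defining the range, in (0, 0.5).
#' @return A one-row tibble with columns `trt` (width, degC), `lower` and
#'   `upper` (temperatures where the curve crosses `l` and `1 - l`; `lower`
#'   is always the cooler bound).
#' @examples
#' trt(tsd_params("logistic", P = 30.46, S = -0.37))
#' @export
trt <- function(params, l = 0.05) {
  stopifnot(inherits(params, "tsd_params"))
  if (!is.numeric(l) || length(l) != 1L || l <= 0 || l >= 0.5) {
    abort("`l` must lie strictly between 0 and 0.5.")
  }
  if (params$S == 0) abort("TRT is undefined for S = 0.")
  if (params$family == "logistic") {
    half <- params$S * log((1 - l) / l)
    t_at_l <- params$P - half      # curve = l here when S < 0
    t_at_1ml <- params$P + half
  } else {
    K1 <- guard_k(params$K1)
    K2 <- guard_k(params$K2)
    S1 <- flexit_branch_slope(params$S, K1)
    S2 <- flexit_branch_slope(params$S, K2)
    la <- log(1 / (1 - l))
    # log[ ((1/(1-l))^K - 1) / (2^K - 1) ]; numerator and denominator share
    # the sign of K so the ratio is always positive
    lr1 <- log_expm1_abs(K1 * la) - log_expm1_abs(K1 * log(2))
    lr2 <- log_expm1_abs(K2 * la) - log_expm1_abs(K2 * log(2))
    t_at_1ml <- params$P - lr1 / (4 * S1)  # lower-branch crossing of 1 - l
    t_at_l <- params$P + lr2 / (4 * S2)    # upper-branch crossing of l
  }
  lohi <- sort(c(t_at_l, t_at_1ml))
  tibble(trt = lohi[2] - lohi[1], lower = lohi[1], upper = lohi[2])
}

# TRT width only, vectorised over parameter draws; used by the resampling
# and MCMC machinery where a per-draw tibble would be wasteful
trt_width <- function(family, P, S, K1 = NULL, K2 = NULL, l = 0.05) {
  if (family == "logistic") {
    abs(S * 2 * log(l / (1 - l)))
  } else {
    K1 <- vapply(K1, guard_k, numeric(1))
    K2 <- vapply(K2, guard_k, numeric(1))
    S1 <- flexit_branch_slope(S, K1)
    S2 <- flexit_branch_slope(S, K2)
    la <- log(1 / (1 - l))
    lr1 <- log_expm1_abs(K1 * la) - log_expm1_abs(K1 * log(2))
    lr2 <- log_expm1_abs(K2 * la) - log_expm1_abs(K2 * log(2))
    abs(lr2 / (4 * S2) + lr1 / (4 * S1))
  }
}
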