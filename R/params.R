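#' Reaction-norm parameter sets
#'
#' `tsd_params()` bundles the parameters of a sex-ratio thermal reaction norm
#' together with the model family they belong to. Two families are supported:
#'
#' * `"logistic"` — the symmetric sigmoid with pivotal temperature `P` (degC)
#'   and shape `S`, where `S` is one fourth of the inverse of the slope of the
#'   curve at `P`. Negative `S` gives the common pattern with males produced
#'   at low and females at high temperatures (TSD Ia).
#' * `"flexit"` — the four-parameter asymmetric sigmoid. `P` is again the
#'   pivotal temperature, `S` is the slope (first derivative) of the curve at
#'   `P`, and `K1`, `K2` shape the approach to the lower and upper asymptotes
#'   respectively (acute for positive values, obtuse for negative).
#'
#' Note that `S` does **not** mean the same thing in the two families. The
#' flexit model with `K1 = K2 = 1` is exactly the logistic model under the
#' conversion `S_flexit = 1 / (4 * S_logistic)`; use
#' [as_flexit_params()] to convert explicitly. No function in this package
#' converts silently.
#'
#' @param family `"logistic"` or `"flexit"`.
#' @param P Pivotal temperature in degC.
#' @param S Shape/slope parameter (see Details). Must be non-zero for the
#'   transitional range of temperatures to be defined.
#' @param K1,K2 Flexit asymptote shape parameters. Required for (and only
#'   allowed with) `family = "flexit"`. Values with magnitude below `1e-9`
#'   are replaced by `1e-9` (sign preserved) at evaluation time, since the
#'   flexit form is undefined at `K = 0`.
#'
#' @return An object of class `"tsd_params"`: a named list with elements
#'   `family`, `P`, `S` and, for flexit, `K1` and `K2`.
#' @examples
#' tsd_params("logistic", P = 30.4, S = -0.41)
#' tsd_params("flexit", P = 30.6, S = -0.79, K1 = -1.7, K2 = 200)
#' @export
tsd_params <- function(family = c("logistic", "flexit"), P, S,
                       K1 = NULL, K2 = NULL) {
  family <- match.arg(family)
  for (nm in c("P", "S")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm))
    }
  }
  if (family == "logistic") {
    if (!is.null(K1) || !is.null(K2)) {
      abort("`K1`/`K2` are flexit parameters; a logistic model has none.")
    }
    out <- list(family = family, P = P, S = S)
  } else {
    if (is.null(K1) || is.null(K2)) {
      abort("A flexit model needs all four parameters: P, S, K1, K2.")
    }
    if (!all(is.finite(c(K1, K2)))) abort("`K1` and `K2` must be finite.")
    out <- list(family = family, P = P, S = S, K1 = K1, K2 = K2)
  }
  structure(out, class = "tsd_params")
}

#' @export
print.tsd_params <- function(x, digits = 4, ...) {
  est <- unlist(x[setdiff(names(x), "family")])
  cat(sprintf("<tsd_params: %s>\n", x$family))
  print(round(est, digits))
  invisible(x)
}

#' @export
as.list.tsd_params <- function(x, ...) unclass(x)

#' Rebuild a parameter set from a plain list
#'
#' Inverse of `as.list()` on a `tsd_params` object; convenient when
#' parameters have round-tripped through JSON.
#'
#' @param x A named list with `family`, `P`, `S` and optionally `K1`, `K2`.
#' @return A `tsd_params` object.
#' @export
as_tsd_params <- function(x) {
  do.call(tsd_params, x[!vapply(x, is.null, logical(1))])
}

#' Convert logistic parameters to the equivalent flexit parameters
#'
#' The flexit family nests the logistic: with `K1 = K2 = 1` and
#' `S_flexit = 1 / (4 * S_logistic)` the two curves are identical at every
#' temperature. The conversion is exposed explicitly because `S` has a
#' different meaning in each family.
#'
#' @param params A logistic `tsd_params` object.
#' @return A flexit `tsd_params` object describing the same curve.
#' @examples
#' as_flexit_params(tsd_params("logistic", P = 30, S = -0.4))
#' @export
as_flexit_params <- function(params) {
  stopifnot(inherits(params, "tsd_params"))
  if (params$family == "flexit") return(params)
  if (params$S == 0) abort("Cannot convert a logistic model with S = 0.")
  tsd_params("flexit", P = params$P, S = 1 / (4 * params$S), K1 = 1, K2 = 1)
}

param_names <- function(family) {
  if (family == "logistic") c("P", "S") else c("P", "S", "K1", "K2")
}

params_from_vector <- function(family, x) {
  nm <- param_names(family)
  do.call(tsd_params, c(list(family = family), as.list(setNames(x, nm))))
}
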