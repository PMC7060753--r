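#' Simulate a binomial incubation dataset from a known reaction norm
#'
#' For each temperature `t_i` with `eggs_i` eggs, the male count is drawn as
#' `Binomial(eggs_i, sr(t_i))` under the supplied true reaction norm; the
#' remaining embryos are females. This is the same generator the
#' simulated-null deviance test uses, and the workhorse for power and
#' parameter-recovery studies. The truth is embedded in the result (as the
#' `truth` attribute and an `area = "synthetic"` label) so recovery can be
#' checked later.
#'
#' @param temperatures Vector of constant incubation temperatures (degC).
#' @param eggs Number of eggs per temperature; recycled to match.
#' @param params The true reaction norm, a [tsd_params()] object.
#' @param seed Integer seed; a fixed seed reproduces the dataset exactly.
#' @param label Value for the `area`/`rmu` label columns.
#' @return An incubation tibble (see [read_tsd()]) with attribute `truth`.
#' @examples
#' simulate_tsd(seq(27, 33, 1), 30,
#'              tsd_params("logistic", P = 30, S = -0.4), seed = 1)
#' @export
simulate_tsd <- function(temperatures, eggs, params, seed = NULL,
                         label = "synthetic") {
  stopifnot(inherits(params, "tsd_params"))
  if (!length(temperatures)) abort("`temperatures` must be non-empty.")
  eggs <- rep_len(eggs, length(temperatures))
  if (any(eggs < 0 | eggs != floor(eggs))) {
    abort("`eggs` must be non-negative integer counts.")
  }
  pr <- sex_ratio(temperatures, params)
  gen <- function() rbinom(length(temperatures), eggs, pr)
  males <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  out <- tibble(
    temperature = as.numeric(temperatures),
    amplitude = 0,
    males = males,
    females = eggs - males,
    intersexes = 0L,
    area = label,
    rmu = label
  )
  attr(out, "truth") <- params
  attr(out, "tsd_filters") <- list()
  out
}

#' Parameter-recovery study for the maximum-likelihood estimator
#'
#' Repeatedly simulates datasets from a known reaction norm on a fixed
#' design, refits by [fit_tsd()], and reports bias, root-mean-square error
#' and 95% (normal-theory) confidence-interval coverage for `P`, `S` and the
#' derived TRT. Each replicate draws from its own stream seeded
#' deterministically from the master seed, so individual replicates can be
#' reproduced in isolation.
#'
#' @param temperatures,eggs,params Design and truth, as in [simulate_tsd()].
#' @param n_rep Number of replicates.
#' @param seed Master integer seed.
#' @param l TRT limit (see [trt()]).
#' @param level Nominal confidence level for the coverage column.
#' @return A tibble with one row per quantity (`P`, `S`, `TRT`): `truth`,
#'   `bias`, `rmse`, `coverage`, `n_ok` (replicates whose fit succeeded).
#'   Zero replicates give an empty tibble.
#' @examples
#' \donttest{
#' parameter_recovery(seq(27, 33, length.out = 10), 50,
#'                    tsd_params("logistic", P = 30, S = -0.4),
#'                    n_rep = 20, seed = 1)
#' }
#' @export
parameter_recovery <- function(temperatures, eggs, params, n_rep,
                               seed = NULL, l = 0.05, level = 0.95) {
  stopifnot(inherits(params, "tsd_params"))
  if (n_rep == 0) {
    return(tibble(quantity = character(), truth = numeric(),
                  bias = numeric(), rmse = numeric(), coverage = numeric(),
                  n_ok = integer()))
  }
  z <- qnorm(1 - (1 - level) / 2)
  true_trt <- trt(params, l)$trt
  truth <- c(P = params$P, S = params$S, TRT = true_trt)
  seed <- seed %||% 0
  reps <- purrr::map(seq_len(n_rep), function(r) {
    sim <- simulate_tsd(temperatures, eggs, params,
                        seed = (seed + r) %% .Machine$integer.max)
    fit <- tryCatch(
      suppressWarnings(fit_tsd(sim, params$family)),
      error = function(e) NULL
    )
    if (is.null(fit) || is.null(fit$se)) return(NULL)
    est_trt <- trt(fit$params, l)$trt
    # TRT standard error by linear propagation of SE(S) for the logistic;
    # replicate-level resampling would be prohibitive inside a power study
    se_trt <- if (fit$family == "logistic") {
      abs(2 * log(l / (1 - l))) * fit$se[["S"]]
    } else {
      NA_real_
    }
    tibble(
      quantity = c("P", "S", "TRT"),
      estimate = c(fit$estimate[["P"]], fit$estimate[["S"]], est_trt),
      se = c(fit$se[["P"]], fit$se[["S"]], se_trt)
    )
  })
  reps <- purrr::compact(reps)
  if (!length(reps)) {
    warn("All replicate fits failed.")
    return(tibble(quantity = names(truth), truth = unname(truth),
                  bias = NA_real_, rmse = NA_real_, coverage = NA_real_,
                  n_ok = 0L))
  }
  all <- dplyr::bind_rows(reps)
  all$truth <- truth[all$quantity]
  all %>%
    group_by(.data$quantity) %>%
    summarise(
      truth = .data$truth[1],
      bias = mean(.data$estimate - .data$truth),
      rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
      coverage = mean(abs(.data$estimate - .data$truth) <= z * .data$se),
      n_ok = dplyr::n(),
      .groups = "drop"
    ) %>%
    arrange(match(.data$quantity, c("P", "S", "TRT")))
}
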