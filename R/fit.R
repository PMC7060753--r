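default_bounds <- function(family) {
  if (family == "logistic") {
    list(lower = c(P = 20, S = -2), upper = c(P = 40, S = 2))
  } else {
    list(lower = c(P = 20, S = -2, K1 = -1000, K2 = -1000),
         upper = c(P = 40, S = 2, K1 = 1000, K2 = 1000))
  }
}

# count temperatures with a mixed sex ratio (both sexes present)
n_mixed_groups <- function(data) {
  n <- data$males + data$females
  sum(data$males > 0 & data$females > 0 & n > 0)
}

logistic_starts <- function(data) {
  n <- data$males + data$females
  mixed <- data$males > 0 & data$females > 0
  P0 <- if (any(mixed)) {
    weighted.mean(data$temperature[mixed], n[mixed])
  } else {
    mean(range(data$temperature))
  }
  starts <- expand.grid(
    P = unique(c(P0, seq(min(data$temperature), max(data$temperature),
                         length.out = 5))),
    S = c(-0.1, -0.3, -1, 0.1, 0.3, 1)
  )
  lapply(seq_len(nrow(starts)), function(i) as.numeric(starts[i, ]))
}

flexit_starts <- function(data, seed_params) {
  base <- if (!is.null(seed_params)) {
    c(seed_params$P, 1 / (4 * seed_params$S), 1, 1)
  } else {
    c(mean(range(data$temperature)), -0.3, 1, 1)
  }
  ks <- expand.grid(K1 = c(-2, 1, 4), K2 = c(-2, 1, 4, 50))
  c(list(base),
    lapply(seq_len(nrow(ks)), function(i) {
      c(base[1], base[2], ks$K1[i], ks$K2[i])
    }))
}

run_starts <- function(obj, starts, lower, upper, max_optim = 8) {
  starts <- lapply(starts, function(s) pmin(pmax(s, lower), upper))
  # pre-screen: full optimisation only from the most promising starts
  vals <- vapply(starts, function(s) {
    v <- tryCatch(obj(s), error = function(e) Inf)
    if (is.finite(v)) v else Inf
  }, numeric(1))
  starts <- starts[order(vals)][seq_len(min(max_optim, length(starts)))]
  best <- NULL
  trace <- list()
  for (s in starts) {
    o <- tryCatch(
      optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(factr = 1e2, maxit = 2000)),
      error = function(e) NULL
    )
    if (is.null(o) || !is.finite(o$value)) next
    trace <- c(trace, list(c(start = list(s), value = o$value)))
    better <- is.null(best) ||
      o$value < best$value - 1e-8 ||
      (abs(o$value - best$value) <= 1e-8 &&
         sum(abs(o$par[-(1:2)])) < sum(abs(best$par[-(1:2)])))
    if (better) best <- o
  }
  converged <- FALSE
  if (!is.null(best)) {
    # polish from the incumbent; convergence is declared when another pass
    # cannot improve the objective beyond the 1e-8 tolerance
    polish <- tryCatch(
      optim(best$par, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(factr = 1e2, maxit = 2000)),
      error = function(e) NULL
    )
    if (!is.null(polish) && is.finite(polish$value) &&
        polish$value <= best$value) {
      converged <- best$value - polish$value < 1e-8 || polish$convergence == 0
      best <- polish
    } else {
      converged <- best$convergence == 0
    }
  }
  list(best = best, n_starts = length(starts), n_converged = length(trace),
       converged = converged)
}

#' Fit a sex-ratio reaction norm by maximum likelihood
#'
#' Minimises the negative binomial log-likelihood ([neg_loglik()]) over the
#' parameters of the chosen family using box-constrained quasi-Newton
#' optimisation (`optim`, method `"L-BFGS-B"`) from a grid of starting
#' points. For the flexit family a logistic fit is run first and seeds the
#' search at the equivalent flexit parameters (`K1 = K2 = 1`,
#' `S = 1/(4 S_logistic)`): the flexit likelihood is often nearly flat in
#' `K2`, and a good start matters more than optimizer polish. Ties between
#' starts are broken by the smaller `|K1| + |K2|`.
#'
#' Standard errors come from the inverse of the numerically differentiated
#' Hessian of the negative log-likelihood at the optimum (see
#' [hessian_covariance()]). Parameters whose coefficient of variation
#' `se / |estimate|` exceeds 1 are flagged: their sign is not established by
#' the data, and resampling-based intervals will be biased (the Bayesian
#' sampler, [fit_tsd_mcmc()], is preferable there).
#'
#' A dataset whose groups are all single-sex cannot pin down the parameters
#' (an infinity of curves share the maximal likelihood) and the fit is
#' refused with a pointer to the Bayesian route. Fewer mixed-sex
#' temperatures than parameters triggers a warning, not an error.
#'
#' @param data An incubation tibble (see [read_tsd()]; apply [filter_tsd()]
#'   first to exclude intersexes and high-amplitude incubations).
#' @param family `"logistic"` or `"flexit"`.
#' @param init Optional [tsd_params()] used as an additional starting point.
#' @param bounds Optional list with named numeric vectors `lower` and
#'   `upper` overriding the default parameter box
#'   (P in \[20, 40\], S in \[-2, 2\], K in \[-1000, 1000\]).
#' @param hessian Compute the Hessian-based covariance? (Default `TRUE`.)
#' @return An object of class `"tsd_fit"` with components `params`
#'   (a [tsd_params()]), `estimate` (named vector), `neg_log_lik`, `vcov`,
#'   `se`, `cv`, `n_groups`, `n_mixed`, `converged`, `boundary` (parameters
#'   sitting on a box bound), `vcov_singular` and the data used. Supports
#'   `coef()`, `vcov()`, `logLik()`, [tidy()], [glance()], `print()` and
#'   [autoplot()].
#' @examples
#' d <- filter_tsd(olive_ridley())
#' fit <- fit_tsd(d, "logistic")
#' tidy(fit)
#' glance(fit)
#' @export
fit_tsd <- function(data, family = c("logistic", "flexit"), init = NULL,
                    bounds = NULL, hessian = TRUE) {
  family <- match.arg(family)
  validate_tsd(data)
  data <- complete_tsd(data)
  n <- data$males + data$females
  if (!any(n >= 1)) abort("The dataset holds no sexed embryos; nothing to fit.")
  n_mixed <- n_mixed_groups(data)
  p_n <- length(param_names(family))
  if (n_mixed == 0) {
    abort(paste(
      "Every incubation group is single-sex: the maximum-likelihood fit is",
      "unidentifiable. Use the Bayesian sampler `fit_tsd_mcmc()` to obtain",
      "credibility intervals instead."
    ))
  }
  if (n_mixed < p_n) {
    warn(sprintf(
      paste("Only %d temperature(s) with a mixed sex ratio for %d parameters;",
            "standard errors will be large and possibly meaningless."),
      n_mixed, p_n
    ))
  }
  b <- default_bounds(family)
  if (!is.null(bounds)) b <- modifyList(b, bounds)
  obj <- nll_closure(data, family)

  seed_fit <- NULL
  if (family == "flexit") {
    seed_fit <- fit_tsd(data, "logistic", hessian = FALSE)
  }
  starts <- if (family == "logistic") {
    logistic_starts(data)
  } else {
    flexit_starts(data, seed_fit$params)
  }
  if (!is.null(init)) {
    stopifnot(inherits(init, "tsd_params"), init$family == family)
    starts <- c(list(unlist(init[param_names(family)])), starts)
  }
  res <- run_starts(obj, starts, b$lower, b$upper)
  if (is.null(res$best)) abort("No optimisation start converged.")
  est <- setNames(res$best$par, param_names(family))
  params <- params_from_vector(family, est)
  on_boundary <- param_names(family)[
    est <= b$lower + 1e-8 | est >= b$upper - 1e-8
  ]

  vc <- se <- cv <- NULL
  singular <- FALSE
  if (hessian) {
    hc <- hessian_covariance(data, params)
    vc <- hc$covariance
    singular <- hc$singular
    se <- sqrt(pmax(diag(vc), 0))
    cv <- se / abs(est)
    names(se) <- names(cv) <- names(est)
  }

  structure(
    list(
      family = family,
      params = params,
      estimate = est,
      neg_log_lik = res$best$value,
      vcov = vc,
      se = se,
      cv = cv,
      vcov_singular = singular,
      n_groups = nrow(data),
      n_mixed = n_mixed,
      converged = res$converged,
      boundary = on_boundary,
      n_starts = res$n_starts,
      data = data
    ),
    class = "tsd_fit"
  )
}

#' Hessian-based covariance of reaction-norm parameters
#'
#' Numerically differentiates the negative log-likelihood twice (central
#' differences, per-parameter relative step `1e-4`, with step halving when a
#' perturbed evaluation is not finite) and inverts the Hessian. When the
#' Hessian is not invertible — typical when the likelihood is flat in a
#' flexit `K` — the Moore-Penrose pseudo-inverse is returned and flagged.
#'
#' @param data An incubation tibble.
#' @param params Parameters at (or very near) the likelihood optimum.
#' @return A list with `covariance` (matrix), `hessian`, and `singular`
#'   (logical flag).
#' @export
hessian_covariance <- function(data, params) {
  stopifnot(inherits(params, "tsd_params"))
  validate_tsd(data)
  data <- complete_tsd(data)
  obj <- nll_closure(data, params$family)
  x <- unlist(params[param_names(params$family)])
  H <- num_hessian(obj, x)
  inv <- tryCatch(solve(H), error = function(e) NULL)
  singular <- is.null(inv)
  if (singular || any(!is.finite(inv))) {
    singular <- TRUE
    e <- eigen(H, symmetric = TRUE)
    pos <- e$values > max(abs(e$values)) * 1e-12
    inv <- e$vectors[, pos, drop = FALSE] %*%
      diag(1 / e$values[pos], sum(pos)) %*% t(e$vectors[, pos, drop = FALSE])
  }
  inv <- (inv + t(inv)) / 2
  dimnames(inv) <- list(names(x), names(x))
  list(covariance = inv, hessian = H, singular = singular)
}

# central-difference Hessian with per-parameter relative steps and step
# halving on non-finite entries
num_hessian <- function(f, x, rel_step = 1e-4, max_halvings = 10) {
  k <- length(x)
  h <- abs(x) * rel_step
  h[h == 0] <- rel_step
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      hi <- h[i]; hj <- h[j]
      for (try in seq_len(max_halvings)) {
        ei <- ej <- numeric(k)
        ei[i] <- hi; ej[j] <- hj
        v <- (f(x + ei + ej) - f(x + ei - ej) -
                f(x - ei + ej) + f(x - ei - ej)) / (4 * hi * hj)
        if (is.finite(v)) break
        hi <- hi / 2; hj <- hj / 2
      }
      H[i, j] <- H[j, i] <- v
    }
  }
  H
}

#' @export
print.tsd_fit <- function(x, ...) {
  cat(sprintf("<tsd_fit: %s, %d incubation groups (%d mixed-sex)>\n",
              x$family, x$n_groups, x$n_mixed))
  tab <- data.frame(estimate = round(x$estimate, 4))
  if (!is.null(x$se)) {
    tab$se <- round(x$se, 4)
    tab$cv <- round(x$cv, 3)
  }
  print(tab)
  cat(sprintf("-ln L = %.3f%s\n", x$neg_log_lik,
              if (!x$converged) " (optimizer did not report convergence)" else ""))
  if (length(x$boundary)) {
    cat("On box bound:", paste(x$boundary, collapse = ", "), "\n")
  }
  if (!is.null(x$cv) && any(x$cv > 1)) {
    cat("High-CV parameter(s):",
        paste(names(x$cv)[x$cv > 1], collapse = ", "),
        "- sign not established by the data.\n")
  }
  invisible(x)
}

#' @export
coef.tsd_fit <- function(object, ...) object$estimate

#' @export
vcov.tsd_fit <- function(object, ...) object[["vcov"]]

#' @export
logLik.tsd_fit <- function(object, ...) {
  structure(-object$neg_log_lik, df = length(object$estimate),
            nobs = object$n_groups, class = "logLik")
}

#' @describeIn fit_tsd one row per parameter: `term`, `estimate`,
#'   `std.error`, `cv`, `high.cv` flag.
#' @param x,object A `tsd_fit`.
#' @param ... Unused.
#' @export
tidy.tsd_fit <- function(x, ...) {
  tibble(
    term = names(x$estimate),
    estimate = unname(x$estimate),
    std.error = if (is.null(x$se)) NA_real_ else unname(x$se),
    cv = if (is.null(x$cv)) NA_real_ else unname(x$cv),
    high.cv = if (is.null(x$cv)) NA else unname(x$cv) > 1
  )
}

#' @describeIn fit_tsd one-row model summary: `neg_log_lik`, `AIC`, `AICc`,
#'   `deviance`, `df`, `p.value` (chi-squared tail), counts and convergence.
#' @export
glance.tsd_fit <- function(x, ...) {
  p <- length(x$estimate)
  gof <- gof_deviance(x)
  tibble(
    family = x$family,
    n_groups = x$n_groups,
    n_mixed = x$n_mixed,
    p = p,
    neg_log_lik = x$neg_log_lik,
    AIC = 2 * x$neg_log_lik + 2 * p,
    AICc = aicc_value(x$neg_log_lik, p, x$n_groups),
    deviance = gof$deviance,
    df = gof$df,
    p.value = gof$p_chi2,
    converged = x$converged
  )
}

#' Plot a fitted reaction norm over the data
#'
#' Draws the fitted sex-ratio curve, the observed per-group male frequencies
#' (point area proportional to group size), and optionally a resampled
#' confidence band.
#'
#' @param object A `tsd_fit`.
#' @param band Optional band tibble from [ci_curve()].
#' @param l TRT limit used to shade the transitional range.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tsd_fit <- function(object, band = NULL, l = 0.05, ...) {
  d <- object$data
  n <- d$males + d$females
  obs <- tibble(temperature = d$temperature, n = n,
                sr = ifelse(n > 0, d$males / n, NA_real_))
  grid <- tibble(temperature = seq(min(d$temperature) - 1,
                                   max(d$temperature) + 1, length.out = 300))
  grid$sr <- sex_ratio(grid$temperature, object$params)
  tr <- trt(object$params, l)
  gg <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$temperature, y = .data$sr)) +
    ggplot2::annotate("rect", xmin = tr$lower, xmax = tr$upper,
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::geom_line()
  if (!is.null(band)) {
    gg <- gg + ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$temperature, ymin = .data$lower,
                   ymax = .data$upper),
      inherit.aes = FALSE, alpha = 0.25
    )
  }
  gg +
    ggplot2::geom_point(data = obs,
                        ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::geom_vline(xintercept = object$estimate[["P"]],
                        linetype = "dotdash") +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "Constant incubation temperature (°C)",
                  y = "Male relative frequency",
                  size = "Sexed embryos") +
    ggplot2::coord_cartesian(ylim = c(0, 1))
}
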