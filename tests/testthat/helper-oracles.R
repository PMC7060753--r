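# Independent oracles: deliberately naive implementations used only to
# cross-check the package. They share no code with R/.

# flexit curve by direct arithmetic (no log-space); valid for moderate |K|
naive_flexit <- function(t, P, S, K1, K2) {
  vapply(t, function(x) {
    if (x < P) {
      S1 <- 2^(K1 - 1) * S * K1 / (2^K1 - 1)
      (1 + (2^K1 - 1) * exp(4 * S1 * (P - x)))^(-1 / K1)
    } else {
      S2 <- 2^(K2 - 1) * S * K2 / (2^K2 - 1)
      1 - (1 + (2^K2 - 1) * exp(4 * S2 * (x - P)))^(-1 / K2)
    }
  }, numeric(1))
}

# temperature at which a decreasing reaction norm crosses `target`, by
# bisection on a wide bracket
bisect_crossing <- function(f, target, lo = -50, hi = 120, tol = 1e-9) {
  stopifnot(sign(f(lo) - target) != sign(f(hi) - target))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sign(f(mid) - target) == sign(f(lo) - target)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# brute-force logistic MLE on a (P, S) grid
grid_search_logistic <- function(data, P_range, S_range, step = 0.01) {
  Ps <- seq(P_range[1], P_range[2], by = step)
  Ss <- seq(S_range[1], S_range[2], by = step)
  n <- data$males + data$females
  best <- c(P = NA, S = NA, nll = Inf)
  for (S in Ss) {
    if (S == 0) next
    for (P in Ps) {
      p <- 1 / (1 + exp((P - data$temperature) / S))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      v <- -sum(dbinom(data$males, n, p, log = TRUE))
      if (v < best["nll"]) best <- c(P = P, S = S, nll = v)
    }
  }
  best
}

make_groups <- function(temperature, males, females, ...) {
  tibble::tibble(temperature = temperature, males = males, females = females,
                 intersexes = 0L, amplitude = 0, ...)
}
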