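# Independent brute-force oracle for the piecewise first-order fit:
# lm()-based phase regressions and explicit loops over every admissible
# breakpoint placement. Deliberately naive; shares no code with the
# package implementation.

oracle_phase <- function(t, y, t0, a0 = NULL) {
  dt <- t - t0
  if (is.null(a0)) {
    f <- stats::lm(y ~ dt)
    k <- -unname(stats::coef(f)[2])
    if (is.na(k)) k <- 0
    if (k < 0) {
      k <- 0
      a <- mean(y)
    } else {
      a <- unname(stats::coef(f)[1])
    }
  } else {
    f <- stats::lm(I(a0 - y) ~ 0 + dt)
    k <- unname(stats::coef(f)[1])
    if (is.na(k) || k < 0) k <- 0
    a <- a0
  }
  list(k = k, a0 = a, sse = sum((y - (a - k * dt))^2))
}

oracle_piecewise <- function(t, c_t, n_phases, min_pts = 3) {
  y <- log(c_t)
  n <- length(t)
  cuts_list <- if (n_phases == 1) {
    list(integer(0))
  } else if (n_phases == 2) {
    lapply(min_pts:(n - min_pts), function(i) i)
  } else {
    out <- list()
    for (i in min_pts:(n - 2 * min_pts)) {
      for (j in (i + min_pts):(n - min_pts)) out[[length(out) + 1]] <- c(i, j)
    }
    out
  }
  best <- NULL
  for (cuts in cuts_list) {
    bounds <- c(0, cuts, n)
    a0 <- NULL
    t0 <- t[1]
    sse <- 0
    ks <- numeric(0)
    bps <- numeric(0)
    for (p in 1:n_phases) {
      idx <- (bounds[p] + 1):bounds[p + 1]
      f <- oracle_phase(t[idx], y[idx], t0, a0)
      sse <- sse + f$sse
      ks <- c(ks, f$k)
      if (p < n_phases) {
        tb <- t[bounds[p + 1]]
        a0 <- f$a0 - f$k * (tb - t0)
        t0 <- tb
        bps <- c(bps, tb)
      }
    }
    if (is.null(best) || sse < best$sse - 1e-15) {
      best <- list(sse = sse, ks = ks, breakpoints = bps,
                   rmse = sqrt(sse / n))
    }
  }
  best
}

# Random fit-ready test series: piecewise exponential with log-normal noise.
random_substrate <- function(n, sd = 0.05) {
  t <- sort(sample(0:60, n))
  k1 <- runif(1, 0.005, 0.08)
  k2 <- runif(1, 0.001, 0.05)
  brk <- t[sample(3:(n - 3), 1)]
  expo <- ifelse(t <= brk, k1 * t, k1 * brk + k2 * (t - brk))
  c_t <- 1500 * exp(-expo) * exp(rnorm(n, 0, sd))
  make_substrate(t, c_t, c0 = 1600)
}
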