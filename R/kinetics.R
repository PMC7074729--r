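# Stoichiometric substrate reconstruction and piecewise first-order fitting.
#
# Mineralization chemistry assumes a CH2 backbone: 2 CH2 + 3 O2 -> 2 CO2 +
# 2 H2O, i.e. 44 mg CO2 per 14 mg CH2 oxidised and 12 mg C per 14 mg CH2.
# Remaining substrate is reconstructed by the integral method from net
# cumulative CO2 and fitted with ln C_t = ln C_0 - k t, allowing separate
# rate constants over two or three contiguous temporal phases.

CO2_PER_CH2 <- 44 / 14   # mg CO2 evolved per mg CH2 mineralized
C_PER_CH2 <- 12 / 14     # mg carbon per mg CH2
C_PER_CO2 <- 12 / 44     # mg carbon per mg CO2

#' CO2 mass to mineralized hydrocarbon mass
#'
#' Inverts the mineralization stoichiometry: 44 mg of CO2 corresponds to
#' 14 mg of CH2-equivalent hydrocarbon oxidised.
#'
#' @param co2 CO2 mass in mg (non-negative; vectorised).
#' @return Mineralized CH2-equivalent mass in mg.
#' @examples
#' co2_to_mineralized(44)  # 14
#' @export
co2_to_mineralized <- function(co2) {
  if (any(co2 < 0)) stop("CO2 mass must be non-negative")
  co2 / CO2_PER_CH2
}

#' @rdname co2_to_mineralized
#' @param mineralized CH2-equivalent mass in mg.
#' @export
mineralized_to_co2 <- function(mineralized) {
  if (any(mineralized < 0)) stop("mineralized mass must be non-negative")
  mineralized * CO2_PER_CH2
}

#' Carbon content of a fuel dose
#'
#' Under the CH2 composition assumption a fuel is 12/14 carbon by mass:
#' the standard 2000 mg dose carries 1714 mg C (~1700 rounded to the
#' nearest hundred).
#'
#' @param fuel_mass Fuel mass in mg (vectorised).
#' @param c_fraction Carbon mass fraction; default `12/14`.
#' @return Carbon mass in mg.
#' @export
fuel_carbon <- function(fuel_mass, c_fraction = C_PER_CH2) {
  if (any(fuel_mass < 0)) stop("fuel mass must be non-negative")
  fuel_mass * c_fraction
}

#' Reconstruct the remaining-substrate trajectory from respiration
#'
#' The integral method: remaining contaminant at each sampling day is the
#' initial mass minus the CH2 equivalent of net cumulative CO2. Values are
#' clipped at a small positive floor so the log-linear fit is defined;
#' clipped points are flagged and excluded from fitting.
#'
#' @param resp A baseline-subtracted [respiration_series()].
#' @param c0 Initial contaminant mass in mg (> 0).
#' @param include_t0 Prepend the known anchor (day 0, `c0`)? Default TRUE;
#'   set FALSE to keep only the observed sampling days.
#' @param require_baseline Error if `resp` has not been baseline-subtracted
#'   (default TRUE; disable for soil-free setups with no meaningful
#'   control).
#' @return An object of class `substrate_series` with fields `days`, `c_t`,
#'   `c0`, `clipped`, `microcosm`.
#' @export
build_substrate_series <- function(resp, c0, include_t0 = TRUE,
                                   require_baseline = TRUE) {
  stopifnot(inherits(resp, "respiration_series"))
  if (!is.numeric(c0) || length(c0) != 1L || c0 <= 0) {
    stop("c0 must be a single positive mass (mg)")
  }
  if (require_baseline && !resp$baseline_subtracted) {
    stop("respiration series must be baseline-subtracted first ",
         "(or pass require_baseline = FALSE)")
  }
  days <- resp$days
  cum <- resp$cumulative_co2
  if (include_t0 && days[1] > 0) {
    days <- c(0, days)
    cum <- c(0, cum)
  }
  c_t <- c0 - co2_to_mineralized(cum)
  pos <- c_t[c_t > 0]
  floor_val <- max(1e-6 * c0, if (length(pos)) min(pos) * 1e-3 else 0)
  if (min(c_t) < -floor_val) {
    stop("stoichiometric overdraw: cumulative CO2 implies more substrate ",
         "mineralized than the initial mass c0 = ", c0,
         " mg; check c0 or baseline subtraction")
  }
  clipped <- c_t < floor_val
  c_t[clipped] <- floor_val
  structure(
    list(days = days, c_t = c_t, c0 = c0, clipped = clipped,
         microcosm = resp$microcosm),
    class = "substrate_series"
  )
}

#' @export
print.substrate_series <- function(x, ...) {
  id <- if (is.null(x$microcosm)) "?" else x$microcosm$id
  cat(sprintf(
    "<substrate_series> %s: C0 = %.1f mg, %d days, %.1f%% remaining at day %g%s\n",
    id, x$c0, length(x$days), 100 * x$c_t[length(x$c_t)] / x$c0,
    max(x$days),
    if (any(x$clipped)) sprintf(" (%d clipped)", sum(x$clipped)) else ""))
  invisible(x)
}

# One-phase first-order fit on (t, ln c). If log_c_start is NULL the
# intercept is free (ordinary least squares); otherwise the line is pinned
# to pass through (t0, log_c_start) and only the slope is estimated.
# Negative slopes in t (i.e. k < 0) are clamped to 0. SSE is reported in
# the requested objective space.
.phase_fit <- function(t, logc, cvals, t0, log_c_start = NULL,
                       objective = "log") {
  n <- length(t)
  dt <- t - t0
  if (objective == "log") {
    if (is.null(log_c_start)) {
      tb <- mean(dt)
      yb <- mean(logc)
      sxx <- sum((dt - tb)^2)
      slope <- if (sxx > 0) sum((dt - tb) * (logc - yb)) / sxx else 0
      k <- -slope
      clamped <- k < 0
      if (clamped) k <- 0
      a0 <- yb + k * tb            # intercept at t0 given the (clamped) k
      resid <- logc - (a0 - k * dt)
    } else {
      sxx <- sum(dt^2)
      k <- if (sxx > 0) sum(dt * (log_c_start - logc)) / sxx else 0
      clamped <- k < 0
      if (clamped) k <- 0
      a0 <- log_c_start
      resid <- logc - (a0 - k * dt)
    }
    list(k = k, log_c_start = a0, sse = sum(resid^2), n = n,
         clamped = clamped)
  } else {
    # linear-space RMSE: c = C_s exp(-k dt); C_s profiled analytically when
    # free, so a 1-D search over k suffices.
    sse_for <- function(k) {
      e <- exp(-k * dt)
      cs <- if (is.null(log_c_start)) {
        s2 <- sum(e^2)
        if (s2 > 0) sum(cvals * e) / s2 else mean(cvals)
      } else exp(log_c_start)
      sum((cvals - cs * e)^2)
    }
    opt <- stats::optimize(sse_for, c(0, 5), tol = 1e-10)
    k <- opt$minimum
    # boundary polish: a flat series should give exactly k = 0
    if (sse_for(0) <= opt$objective + 1e-12) k <- 0
    e <- exp(-k * dt)
    cs <- if (is.null(log_c_start)) {
      s2 <- sum(e^2)
      if (s2 > 0) sum(cvals * e) / s2 else mean(cvals)
    } else exp(log_c_start)
    list(k = k, log_c_start = log(cs), sse = sum((cvals - cs * e)^2),
         n = n, clamped = FALSE)
  }
}

# Extract the fit-ready points of a substrate series: clipped values are
# excluded (their magnitude is an artifact of the floor).
.fit_points <- function(s, t_start = NULL, t_end = NULL) {
  keep <- !s$clipped
  if (!is.null(t_start)) keep <- keep & s$days >= t_start - 1e-9
  if (!is.null(t_end)) keep <- keep & s$days <= t_end + 1e-9
  list(t = s$days[keep], c = s$c_t[keep])
}

#' Fit a single first-order phase
#'
#' Least-squares fit of `ln C_t = ln C_start - k (t - t_start)` over a
#' window of a substrate series. By default both the intercept and the
#' slope are estimated (closed-form log-linear regression); a fixed
#' starting mass can be imposed via `c_start`. Negative fitted slopes are
#' clamped to `k = 0` with a warning. The RMSE is reported in the chosen
#' objective space.
#'
#' @param s A [build_substrate_series()] result.
#' @param t_start,t_end Fit window in days; defaults to the full span.
#' @param objective `"log"` (default) minimises RMSE of ln C_t; `"linear"`
#'   minimises RMSE of C_t itself.
#' @param c_start Optional fixed substrate mass at `t_start` (mg); when
#'   given, only the slope is estimated.
#' @return List with elements `k` (per day), `rmse`, `c_start` (fitted or
#'   imposed mass at `t_start`), `t_start`, `t_end`, `n`, `clamped`.
#' @export
fit_single_phase <- function(s, t_start = NULL, t_end = NULL,
                             objective = c("log", "linear"),
                             c_start = NULL) {
  stopifnot(inherits(s, "substrate_series"))
  objective <- match.arg(objective)
  if (is.null(t_start)) t_start <- min(s$days)
  if (is.null(t_end)) t_end <- max(s$days)
  pts <- .fit_points(s, t_start, t_end)
  if (length(pts$t) < 3L) {
    stop("need at least 3 unclipped points in [", t_start, ", ", t_end,
         "] to fit a phase; have ", length(pts$t))
  }
  if (any(pts$c <= 0)) stop("non-positive substrate values in fit window")
  fit <- .phase_fit(pts$t, log(pts$c), pts$c, t_start,
                    log_c_start = if (is.null(c_start)) NULL else log(c_start),
                    objective = objective)
  if (fit$clamped) {
    warning("fitted slope was negative (substrate apparently increasing); ",
            "k clamped to 0")
  }
  list(k = fit$k, rmse = sqrt(fit$sse / fit$n),
       c_start = exp(fit$log_c_start), t_start = t_start, t_end = t_end,
       n = fit$n, clamped = fit$clamped)
}

#' Piecewise first-order fit with exhaustive breakpoint search
#'
#' Fits 1 to 3 contiguous first-order phases to a substrate trajectory.
#' Breakpoints are restricted to observed sampling days; every admissible
#' placement with at least `min_points` points per phase is evaluated and
#' the one minimising total RMSE (in the chosen objective space) is
#' returned — a deterministic replacement for choosing phase lengths by
#' visual inspection. Substrate mass is forced continuous at breakpoints:
#' the first phase has a free intercept, and each later phase starts at the
#' previous phase's fitted value at the breakpoint. Ties are broken toward
#' the earliest breakpoints.
#'
#' @param s A [build_substrate_series()] result.
#' @param n_phases Number of phases, 1, 2 or 3.
#' @param min_points Minimum points per phase (default 3).
#' @param objective `"log"` (default) or `"linear"` RMSE space.
#' @return An object of class `piecewise_fit`: a list with `phases` (data
#'   frame of `phase`, `t_start`, `t_end`, `k`, `c_start`, `n_points`),
#'   `rmse` (total, over all fitted points), `n_phases`, `objective`,
#'   `breakpoints`, and `clamped` (any phase slope clamped to 0).
#' @export
fit_piecewise <- function(s, n_phases = 2, min_points = 3,
                          objective = c("log", "linear")) {
  stopifnot(inherits(s, "substrate_series"))
  objective <- match.arg(objective)
  n_phases <- as.integer(n_phases)
  if (is.na(n_phases) || n_phases < 1L || n_phases > 3L) {
    stop("n_phases must be 1, 2 or 3")
  }
  pts <- .fit_points(s)
  t <- pts$t
  cv <- pts$c
  n <- length(t)
  if (n < n_phases * min_points) {
    stop("series too short for ", n_phases, " phases: need at least ",
         n_phases * min_points, " unclipped points, have ", n)
  }
  y <- log(cv)

  eval_placement <- function(cuts) {
    # cuts: point indices ending each non-final phase
    bounds <- c(0L, cuts, n)
    sse <- 0
    log_cs <- NULL  # imposed start for phases after the first
    t0 <- t[1]
    rows <- vector("list", n_phases)
    clamped <- FALSE
    for (p in seq_len(n_phases)) {
      idx <- (bounds[p] + 1L):bounds[p + 1L]
      fit <- .phase_fit(t[idx], y[idx], cv[idx], t0,
                        log_c_start = log_cs, objective = objective)
      sse <- sse + fit$sse
      clamped <- clamped || fit$clamped
      t_end <- if (p < n_phases) t[bounds[p + 1L]] else t[n]
      rows[[p]] <- data.frame(
        phase = p, t_start = t0, t_end = t_end, k = fit$k,
        c_start = exp(fit$log_c_start), n_points = fit$n
      )
      if (p < n_phases) {
        # continuity: next phase starts at this phase's fitted endpoint
        log_cs <- fit$log_c_start - fit$k * (t_end - t0)
        t0 <- t_end
      }
    }
    list(sse = sse, phases = do.call(rbind, rows), clamped = clamped)
  }

  placements <- if (n_phases == 1L) {
    list(integer(0))
  } else if (n_phases == 2L) {
    lapply(seq(min_points, n - min_points), function(i) i)
  } else {
    out <- list()
    for (i in seq(min_points, n - 2L * min_points)) {
      for (j in seq(i + min_points, n - min_points)) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
    out
  }

  best <- NULL
  for (cuts in placements) {
    res <- eval_placement(as.integer(cuts))
    if (is.null(best) || res$sse < best$sse - 1e-15) best <- res
  }
  if (best$clamped) {
    warning("one or more phase slopes were negative and clamped to k = 0")
  }
  structure(
    list(phases = best$phases, rmse = sqrt(best$sse / n),
         n_phases = n_phases, objective = objective,
         breakpoints = best$phases$t_end[-n_phases],
         clamped = best$clamped, microcosm = s$microcosm),
    class = "piecewise_fit"
  )
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf("<piecewise_fit> %d phase(s), %s-space RMSE %.4g\n",
              x$n_phases, x$objective, x$rmse))
  print(x$phases, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.piecewise_fit <- function(x, ...) {
  df <- x$phases
  df$microcosm_id <- if (is.null(x$microcosm)) NA_character_ else x$microcosm$id
  df$n_phases <- x$n_phases
  df$rmse <- x$rmse
  df[, c("microcosm_id", "n_phases", "phase", "t_start", "t_end", "k",
         "c_start", "n_points", "rmse")]
}

#' Per-fuel summary of replicate rate constants
#'
#' Arithmetic mean and standard error of the whole-window first-order rate
#' constant across replicates, by fuel. With a single replicate the SE is
#' undefined and reported as `NA` with `se_defined = FALSE`.
#'
#' @param k Numeric vector of per-replicate rate constants (per day).
#' @param fuel Fuel label for each element of `k`.
#' @return Data frame with `fuel`, `n`, `mean_k`, `se_k`, `se_defined`.
#' @export
summarize_k <- function(k, fuel) {
  if (length(k) == 0L) stop("no rate constants to summarise")
  if (length(k) != length(fuel)) stop("k and fuel lengths differ")
  groups <- split(as.numeric(k), as.character(fuel))
  out <- do.call(rbind, lapply(names(groups), function(f) {
    v <- groups[[f]]
    data.frame(
      fuel = f, n = length(v), mean_k = mean(v),
      se_k = if (length(v) >= 2L) standard_error(v) else NA_real_,
      se_defined = length(v) >= 2L,
      stringsAsFactors = FALSE
    )
  }))
  out[order(out$fuel), , drop = FALSE]
}
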