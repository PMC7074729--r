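# Alkaline-trap respirometry: titration -> CO2, baseline subtraction,
# accumulation, daily-rate summaries.

#' Controlled vocabularies for microcosm metadata
#'
#' `fuel_levels()` returns the recognised fuel treatments: conventional
#' diesel, heating diesel (HTG), Fischer-Tropsch synthetic diesel
#' (SYNTROLEUM), a 20% fish-biodiesel blend (B20), pure fish biodiesel
#' (B100), and the no-fuel CONTROL. `setup_levels()` returns the physical
#' configurations: a soil bed dosed at the surface (SOIL_BED), or a grid
#' suspended in the headspace above neat fuel, with or without a small
#' amount of soil on the grid (GRID_WITH_SOIL, GRID_NO_SOIL).
#'
#' @return Character vector of allowed level names.
#' @export
fuel_levels <- function() {
  c("DIESEL", "HTG", "SYNTROLEUM", "B20", "B100", "CONTROL")
}

#' @rdname fuel_levels
#' @export
setup_levels <- function() {
  c("SOIL_BED", "GRID_WITH_SOIL", "GRID_NO_SOIL")
}

#' Describe one experimental microcosm
#'
#' A microcosm is one sealed incubation jar: a fuel treatment applied to a
#' soil bed (or placed below a suspended grid), with a nitrogen amendment
#' and a replicate index. The spec carries everything needed downstream:
#' the fuel dose enters the initial-substrate computation and the setup
#' decides which control series forms the respiration baseline.
#'
#' @param id Unique microcosm identifier (single string).
#' @param fuel One of [fuel_levels()].
#' @param fuel_mass Fuel dose in mg; must be 0 exactly for CONTROL and
#'   positive otherwise.
#' @param soil_mass Soil mass in g (0 allowed, e.g. grid-no-soil setups).
#' @param n_added Nitrogen amendment in mg N.
#' @param setup One of [setup_levels()].
#' @param replicate Positive integer replicate index.
#' @param temperature Incubation temperature in degrees C.
#' @return An object of class `microcosm_spec`.
#' @examples
#' microcosm_spec("d1", "DIESEL", fuel_mass = 2000, soil_mass = 1000)
#' @export
microcosm_spec <- function(id, fuel, fuel_mass = 2000, soil_mass = 1000,
                           n_added = 300, setup = "SOIL_BED",
                           replicate = 1L, temperature = 20) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("'id' must be a single non-empty string")
  }
  fuel <- match.arg(toupper(fuel), fuel_levels())
  setup <- match.arg(toupper(setup), setup_levels())
  stopifnot(is.numeric(fuel_mass), length(fuel_mass) == 1L, fuel_mass >= 0,
            is.numeric(soil_mass), length(soil_mass) == 1L,
            is.numeric(n_added), length(n_added) == 1L, n_added >= 0,
            is.numeric(temperature), length(temperature) == 1L)
  if (soil_mass < 0) stop("soil_mass must be >= 0")
  if ((fuel == "CONTROL") != (fuel_mass == 0)) {
    stop("fuel_mass must be 0 if and only if fuel is CONTROL (microcosm '",
         id, "')")
  }
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L) stop("replicate must be >= 1")
  structure(
    list(id = id, fuel = fuel, fuel_mass = fuel_mass, soil_mass = soil_mass,
         n_added = n_added, setup = setup, replicate = replicate,
         temperature = temperature),
    class = "microcosm_spec"
  )
}

#' @export
print.microcosm_spec <- function(x, ...) {
  cat(sprintf(
    "<microcosm_spec> %s: %s %g mg on %g g soil (%s, rep %d, %g mg N, %g C)\n",
    x$id, x$fuel, x$fuel_mass, x$soil_mass, x$setup, x$replicate,
    x$n_added, x$temperature))
  invisible(x)
}

#' Convert a trap back-titration to trapped CO2 mass
#'
#' Evolved CO2 is captured in NaOH; after precipitating the carbonate with
#' BaCl2, the residual NaOH is back-titrated with acid. The difference
#' between the blank-trap and sample-trap titrant volumes, times the
#' titrant normality, gives milliequivalents of CO2 absorbed; at 22 mg CO2
#' per meq this yields the trapped mass.
#'
#' @param blank_ml Titrant volume (mL) required for the unexposed blank trap.
#' @param sample_ml Titrant volume (mL) required for the sample trap; must
#'   not exceed `blank_ml`.
#' @param normality Titrant normality in eq/L (> 0).
#' @param mg_per_meq Mass of CO2 per milliequivalent of NaOH consumed;
#'   default 22 (= 44 g/mol over 2 eq/mol).
#' @param day Optional sampling day(s), used only to label error messages.
#' @return CO2 mass in mg (vectorised over the inputs).
#' @examples
#' titration_to_co2(10, 5, 1)     # 110 mg
#' titration_to_co2(8.2, 6, 0.5)  # 24.2 mg
#' @export
titration_to_co2 <- function(blank_ml, sample_ml, normality,
                             mg_per_meq = 22, day = NULL) {
  n <- max(length(blank_ml), length(sample_ml), length(normality))
  blank_ml <- rep_len(as.numeric(blank_ml), n)
  sample_ml <- rep_len(as.numeric(sample_ml), n)
  normality <- rep_len(as.numeric(normality), n)
  if (anyNA(blank_ml) || anyNA(sample_ml) || anyNA(normality)) {
    stop("titration volumes and normality must be non-missing numbers")
  }
  if (any(normality <= 0)) stop("titrant normality must be > 0")
  if (any(sample_ml < 0)) stop("sample titrant volume must be >= 0")
  bad <- sample_ml > blank_ml
  if (any(bad)) {
    lab <- if (is.null(day)) paste("index", which(bad)[1]) else {
      paste("day", rep_len(day, n)[which(bad)[1]])
    }
    stop("negative CO2: sample titrant volume exceeds blank volume (", lab,
         "); check trap records")
  }
  (blank_ml - sample_ml) * normality * mg_per_meq
}

#' Per-microcosm respiration time series
#'
#' Holds the daily (per-interval) net CO2 masses and their running sum for
#' one microcosm. Days are real numbers measured from fuel application
#' (day 0); each daily value is the CO2 trapped over the half-open interval
#' since the previous trap opening.
#'
#' @param days Strictly increasing sampling days.
#' @param daily_co2 CO2 trapped in each interval, mg; non-negative.
#' @param microcosm Optional [microcosm_spec()].
#' @param baseline_subtracted Has a control baseline been removed?
#' @param daily_co2_raw Unfloored daily values kept for audit (defaults to
#'   `daily_co2`); may be negative after baseline subtraction.
#' @param interpolated Logical flags marking days filled by interpolation.
#' @return An object of class `respiration_series` with fields `days`,
#'   `daily_co2`, `cumulative_co2`, `daily_co2_raw`, `baseline_subtracted`,
#'   `interpolated`, `microcosm`.
#' @export
respiration_series <- function(days, daily_co2, microcosm = NULL,
                               baseline_subtracted = FALSE,
                               daily_co2_raw = daily_co2,
                               interpolated = rep(FALSE, length(days))) {
  days <- as.numeric(days)
  daily_co2 <- as.numeric(daily_co2)
  if (length(days) == 0L) stop("empty respiration series")
  if (length(days) != length(daily_co2)) {
    stop("days and daily_co2 lengths differ")
  }
  if (anyNA(days) || anyNA(daily_co2)) stop("missing values in series")
  if (any(diff(days) <= 0)) stop("days must be strictly increasing")
  if (any(days < 0)) stop("days must be >= 0")
  if (any(daily_co2 < 0)) stop("daily_co2 must be >= 0 (raw values go in daily_co2_raw)")
  if (!is.null(microcosm) && !inherits(microcosm, "microcosm_spec")) {
    stop("microcosm must be a microcosm_spec or NULL")
  }
  structure(
    list(days = days, daily_co2 = daily_co2,
         cumulative_co2 = cumsum(daily_co2),
         daily_co2_raw = as.numeric(daily_co2_raw),
         baseline_subtracted = isTRUE(baseline_subtracted),
         interpolated = as.logical(interpolated),
         microcosm = microcosm),
    class = "respiration_series"
  )
}

#' @export
print.respiration_series <- function(x, ...) {
  id <- if (is.null(x$microcosm)) "?" else x$microcosm$id
  cat(sprintf(
    "<respiration_series> %s: %d days (%g..%g), total %.1f mg CO2%s\n",
    id, length(x$days), min(x$days), max(x$days),
    x$cumulative_co2[length(x$cumulative_co2)],
    if (x$baseline_subtracted) ", baseline-subtracted" else ""))
  invisible(x)
}

#' @export
as.data.frame.respiration_series <- function(x, ...) {
  data.frame(
    microcosm_id = if (is.null(x$microcosm)) NA_character_ else x$microcosm$id,
    day = x$days,
    daily_co2_mg = x$daily_co2,
    cumulative_co2_mg = x$cumulative_co2,
    baseline_subtracted = x$baseline_subtracted,
    interpolated = x$interpolated,
    stringsAsFactors = FALSE
  )
}

#' Build a respiration series from raw titration records
#'
#' @param records Data frame with columns `day`, `blank_volume_ml`,
#'   `sample_volume_ml`, `normality` (one row per trap reading).
#' @param microcosm Optional [microcosm_spec()].
#' @inheritParams titration_to_co2
#' @return A [respiration_series()].
#' @export
resp_from_titration <- function(records, microcosm = NULL, mg_per_meq = 22) {
  need <- c("day", "blank_volume_ml", "sample_volume_ml", "normality")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("titration records missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(records) == 0L) stop("no titration records")
  records <- records[order(records$day), , drop = FALSE]
  if (anyDuplicated(records$day)) {
    stop("duplicate titration records for day(s) ",
         paste(unique(records$day[duplicated(records$day)]), collapse = ", "))
  }
  co2 <- titration_to_co2(records$blank_volume_ml, records$sample_volume_ml,
                          records$normality, mg_per_meq = mg_per_meq,
                          day = records$day)
  respiration_series(records$day, co2, microcosm = microcosm)
}

# Cumulative CO2 as a function of time, anchored at (0, 0): cumulative
# production is measured from dosing, so the curve passes through the origin
# when the first trap reading is after day 0. Interpolation only; no
# extrapolation beyond the observed span.
.cum_lookup <- function(series, at) {
  d <- series$days
  cc <- series$cumulative_co2
  if (d[1] > 0) {
    d <- c(0, d)
    cc <- c(0, cc)
  }
  if (any(at < d[1] - 1e-9) || any(at > d[length(d)] + 1e-9)) {
    stop("requested day(s) outside observed span [", d[1], ", ",
         d[length(d)], "]; extrapolation is not supported")
  }
  stats::approx(d, cc, xout = at, ties = "ordered")$y
}

#' Align a respiration series onto a new day grid
#'
#' Cumulative CO2 is interpolated linearly at the requested days (within the
#' observed span only) and daily values recomputed as interval differences.
#' Days not present in the original grid are flagged `interpolated`.
#'
#' @param series A [respiration_series()].
#' @param days Strictly increasing target days within the observed span.
#' @return A [respiration_series()] on the new grid.
#' @export
align_series <- function(series, days) {
  stopifnot(inherits(series, "respiration_series"))
  days <- as.numeric(days)
  if (length(days) == 0L || any(diff(days) <= 0)) {
    stop("target days must be non-empty and strictly increasing")
  }
  cum_new <- .cum_lookup(series, days)
  daily <- diff(c(0, cum_new))
  daily <- pmax(daily, 0)  # guards tiny negative rounding from approx()
  respiration_series(
    days, daily, microcosm = series$microcosm,
    baseline_subtracted = series$baseline_subtracted,
    interpolated = !(days %in% series$days)
  )
}

#' Subtract a control baseline from a sample respiration series
#'
#' Uncontaminated-control respiration is taken as the soil background and
#' removed day by day from the fuel-treated series. Net daily values are
#' floored at zero (a control out-gassing more than a sample carries no
#' kinetic information); the unfloored differences are retained in
#' `daily_co2_raw` for audit. The cumulative series is recomputed from the
#' floored dailies.
#'
#' @param sample,control [respiration_series()] objects on the same day
#'   grid (use `align = TRUE` to interpolate the control onto the sample
#'   grid first).
#' @param align Interpolate the control onto the sample's days before
#'   subtracting.
#' @return A baseline-subtracted [respiration_series()].
#' @export
subtract_baseline <- function(sample, control, align = FALSE) {
  stopifnot(inherits(sample, "respiration_series"),
            inherits(control, "respiration_series"))
  if (align) control <- align_series(control, sample$days)
  if (length(sample$days) != length(control$days) ||
      any(abs(sample$days - control$days) > 1e-9)) {
    miss_c <- setdiff(sample$days, control$days)
    miss_s <- setdiff(control$days, sample$days)
    stop("day grids differ between sample and control",
         if (length(miss_c)) paste0("; days missing from control: ",
                                    paste(miss_c, collapse = ", ")),
         if (length(miss_s)) paste0("; days missing from sample: ",
                                    paste(miss_s, collapse = ", ")))
  }
  raw <- sample$daily_co2 - control$daily_co2
  respiration_series(
    sample$days, pmax(raw, 0), microcosm = sample$microcosm,
    baseline_subtracted = TRUE, daily_co2_raw = raw,
    interpolated = sample$interpolated | control$interpolated
  )
}

#' Recompute the cumulative CO2 of a series
#'
#' The running sum of the daily values; the last element equals total net
#' CO2 production. Constructors maintain this invariant already, so this is
#' mainly useful after manual edits to `daily_co2`.
#'
#' @param series A [respiration_series()].
#' @return The series with `cumulative_co2` recomputed.
#' @export
accumulate <- function(series) {
  stopifnot(inherits(series, "respiration_series"))
  series$cumulative_co2 <- cumsum(series$daily_co2)
  series
}

#' Average daily CO2 production over a window
#'
#' Total net CO2 evolved in `(from, to]` divided by the window length in
#' days. Endpoints inside the observed span may fall between trap readings;
#' cumulative CO2 is then interpolated linearly.
#'
#' @param series A [respiration_series()].
#' @param from,to Window bounds in days; default the full observed span
#'   starting at day 0.
#' @return Mean daily rate in mg CO2 per day.
#' @export
average_daily_rate <- function(series, from = NULL, to = NULL) {
  stopifnot(inherits(series, "respiration_series"))
  if (is.null(from)) from <- min(0, series$days[1])
  if (is.null(to)) to <- max(series$days)
  if (!(to > from)) stop("empty window: 'to' must exceed 'from'")
  bounds <- .cum_lookup(series, c(from, to))
  (bounds[2] - bounds[1]) / (to - from)
}

#' Average several respiration series day by day
#'
#' All series must share one day grid (align first if not). Used to pool
#' replicate jars or control replicates into a mean series.
#'
#' @param series_list List of [respiration_series()] on a common grid.
#' @return A [respiration_series()] of day-wise mean daily values.
#' @export
average_series <- function(series_list) {
  if (length(series_list) == 0L) stop("no series to average")
  stopifnot(all(vapply(series_list, inherits, TRUE, "respiration_series")))
  days <- series_list[[1]]$days
  for (s in series_list[-1]) {
    if (length(s$days) != length(days) || any(abs(s$days - days) > 1e-9)) {
      stop("series are not on a common day grid; align_series() first")
    }
  }
  daily <- rowMeans(vapply(series_list, function(s) s$daily_co2,
                           numeric(length(days))))
  interp <- Reduce(`|`, lapply(series_list, function(s) s$interpolated))
  respiration_series(
    days, daily, microcosm = series_list[[1]]$microcosm,
    baseline_subtracted = all(vapply(series_list,
                                     function(s) s$baseline_subtracted, TRUE)),
    interpolated = interp
  )
}

#' Nitrogen amendment arithmetic
#'
#' Mass of nitrogen applied per kg of dry soil when a fertiliser solution of
#' given concentration and volume is scattered over a soil bed. The study
#' design applies 10 mL of a 30 mg N/mL solution to 1 kg sand, i.e.
#' 300 mg N/kg.
#'
#' @param conc_mg_per_ml Solution concentration, mg N per mL.
#' @param volume_ml Volume applied, mL.
#' @param soil_kg Dry soil mass receiving the amendment, kg.
#' @return mg N per kg dry soil.
#' @examples
#' nitrogen_amendment(30, 10, 1)  # 300
#' @export
nitrogen_amendment <- function(conc_mg_per_ml, volume_ml, soil_kg = 1) {
  stopifnot(conc_mg_per_ml >= 0, volume_ml >= 0, soil_kg > 0)
  conc_mg_per_ml * volume_ml / soil_kg
}
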