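# Fixtures are built in code; nothing is read from disk.

# Substrate series assembled directly from a known trajectory (bypasses the
# respirometry layer so kinetics can be tested in isolation).
make_substrate <- function(days, c_t, c0 = max(c_t)) {
  structure(
    list(days = days, c_t = c_t, c0 = c0,
         clipped = rep(FALSE, length(days)), microcosm = NULL),
    class = "substrate_series"
  )
}

# Noiseless piecewise-exponential trajectory: flat for lag_days, then
# consecutive (duration, k) segments; evaluated at integer days 0..days.
make_decay <- function(c0, lag_days, segs, days) {
  t <- 0:days
  tt <- pmax(0, t - lag_days)
  expo <- numeric(length(t))
  for (s in segs) {
    used <- pmin(tt, s[1])
    expo <- expo + s[2] * used
    tt <- tt - used
  }
  list(days = t, c_t = c0 * exp(-expo))
}

make_series <- function(daily, days = seq_along(daily), ...) {
  respiration_series(days, daily, ...)
}
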