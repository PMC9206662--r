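# Shared fixtures, memoised so expensive model states are computed once per
# test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

cached_spinup <- function(mode = "permian") {
  memo(paste0("spinup_", mode), spin_up(default_params(mode)))
}

cached_run <- function(dynamic_rw = TRUE) {
  key <- paste0("run_", dynamic_rw)
  memo(key, run_scenario(cached_spinup("permian"), extinction_scenario(),
    dynamic_rw = dynamic_rw
  ))
}

# Independent bisection root finder on pH in [2, 12] for the alkalinity
# balance, used as the oracle for the carbonate solver (deliberately naive:
# plain interval halving on the pH axis).
bisect_ph_oracle <- function(dic, ta, temperature = 25, salinity = 35,
                             borate = TRUE, water = TRUE, iter = 60) {
  cn <- carbonate_constants(temperature, salinity)
  resid <- function(ph) {
    h <- 10^(-ph) * 1000 / siclimate:::RHO_SW # mol/L -> mol/kg
    siclimate:::alk_of_h(h, dic / siclimate:::RHO_SW, cn, borate, water) -
      ta / siclimate:::RHO_SW
  }
  lo <- 2
  hi <- 12
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (resid(lo) * resid(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Manual sort-based quantile (type-1 inverse CDF), independent of
# stats::quantile, for checking distribution summaries.
manual_quantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  vapply(p, function(pp) xs[max(1, ceiling(pp * n))], numeric(1))
}

# Minimal stand-in run for filter tests: only times/temp_anomaly are needed.
fake_run <- function(times, anomaly) {
  list(times = times, temp_anomaly = anomaly)
}
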