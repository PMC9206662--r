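## Monte Carlo parameter ensembles, temperature-target filtering, and
## ensemble summaries.

#' Default Monte Carlo sampling ranges
#'
#' The shipped parameter ranges for the end-Permian ensembles: carbon release
#' 30,000-55,000 Pg C over 0.8e5-2.4e5 yr, climate sensitivity 2-5 deg C per
#' doubling, weathering exponents n_si 0.2-0.5 and n_carb 0.1-0.3, modern
#' biogenic silica constant 2.7e14-3.2e14 (Permian 1e10-7e13, log scale),
#' biogenic clay proportionality 0.022-0.099, extinction-interval clay-law
#' offset 1-7, exponents r_si and r_H 1-6, Alk:Si 0.17-6 (pre-extinction 1-2),
#' abiotic silica onset 0.6-0.9 mol m^-3, full-extinction duration 2-7 Myr and
#' recovery 1-6 Myr. Each entry is `(min, max, scale)` with scale `"linear"`
#' or `"log"` (uniform on the stated scale).
#'
#' @param mode `"permian"` (default) or `"modern"` (modern k_bsi window).
#' @return Named list of class `frw_ranges`.
#' @export
default_ranges <- function(mode = c("permian", "modern")) {
  mode <- match.arg(mode)
  rng <- function(min, max, scale = "linear") list(min = min, max = max,
                                                   scale = scale)
  r <- list(
    carbon_mass = rng(30000, 55000),
    release_duration = rng(0.8e5, 2.4e5),
    climate_sensitivity = rng(2, 5),
    n_si = rng(0.2, 0.5),
    n_carb = rng(0.1, 0.3),
    k_bsi = if (mode == "modern") rng(2.7e14, 3.2e14) else
      rng(1e10, 7e13, "log"),
    rw_bsi_ratio = rng(0.022, 0.099),
    alk_si = rng(1, 2),
    r_h = rng(1, 2),
    pco2c = rng(140, 1000),
    isi_threshold = rng(0.6, 0.9),
    full_duration = rng(2e6, 7e6),
    recovery_duration = rng(1e6, 6e6),
    o = rng(1, 7),
    ext_r_si = rng(1, 6),
    ext_r_h = rng(1, 6),
    ext_alk_si = rng(0.17, 6)
  )
  structure(r, class = "frw_ranges")
}

#' Draw Monte Carlo parameter samples
#'
#' Independent uniform draws on the stated scale of each range entry,
#' reproducible under `seed`.
#'
#' @param ranges Ranges from [default_ranges()] (or a like-shaped list).
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Data frame with one row per draw and one column per parameter.
#' @export
sample_parameters <- function(ranges, n, seed = 1) {
  stopifnot(n >= 1)
  for (key in names(ranges)) {
    r <- ranges[[key]]
    if (!is.list(r) || is.null(r$min) || is.null(r$max) || r$min > r$max ||
      !r$scale %in% c("linear", "log")) {
      stop("invalid sampling range for parameter: ", key)
    }
    if (r$scale == "log" && r$min <= 0) {
      stop("log-scale range requires positive bounds: ", key)
    }
  }
  set.seed(seed)
  draws <- lapply(names(ranges), function(key) {
    r <- ranges[[key]]
    u <- stats::runif(n)
    if (r$scale == "log") {
      exp(log(r$min) + u * (log(r$max) - log(r$min)))
    } else {
      r$min + u * (r$max - r$min)
    }
  })
  names(draws) <- names(ranges)
  out <- as.data.frame(draws)
  out$draw <- seq_len(n)
  out
}

## Split a draw row into parameter overrides and scenario overrides. The
## clay-law offset `o` is a run-level property of the integrated clay
## assemblage: one sampled value serves both the background (spin-up) and the
## extinction interval.
draw_to_config <- function(draw, p, scenario_template) {
  pn <- intersect(names(draw), names(p))
  p[pn] <- as.list(draw[pn])
  sn <- intersect(names(draw), names(scenario_template))
  scenario_template[sn] <- as.list(draw[sn])
  if (!is.null(draw$o)) {
    p$rw_offset_o <- draw$o
    scenario_template$ext_o <- draw$o
  }
  list(p = p, scenario = scenario_template)
}

#' Run a Monte Carlo ensemble
#'
#' For each parameter draw, spins the model up and (if the spin-up passes the
#' background pCO2 acceptance window) runs the extinction scenario. Rejected
#' spin-ups are redrawn (fresh parameters from the same ranges, seeded
#' deterministically from `seed` and the draw index) up to `max_redraws`
#' times, so results are bit-identical regardless of scheduling.
#'
#' @param draws Draw table from [sample_parameters()].
#' @param p Base parameter set.
#' @param scenario_template Scenario whose sampled fields are overridden per
#'   draw.
#' @param dynamic_rw Passed to [run_scenario()].
#' @param ranges Ranges used for redraws (defaults to [default_ranges()]).
#' @param seed Master seed for redraw streams.
#' @param max_redraws Redraw attempts per draw before recording a failure.
#' @param t_end Optional end time for each run.
#' @param progress Print one line per completed run.
#' @return List of class `frw_ensemble`: `runs` (list of `frw_run`),
#'   `accepted_draws` (data frame of the parameter values actually run),
#'   `n_spinups` (total spin-up attempts), `failures` (indices with no
#'   accepted spin-up).
#' @export
run_ensemble <- function(draws, p = default_params("permian"),
                         scenario_template = extinction_scenario(),
                         dynamic_rw = TRUE, ranges = default_ranges(),
                         seed = 1, max_redraws = 30, t_end = NULL,
                         progress = FALSE) {
  runs <- vector("list", nrow(draws))
  used <- vector("list", nrow(draws))
  n_spinups <- 0
  failures <- integer(0)
  for (i in seq_len(nrow(draws))) {
    row <- draws[i, , drop = FALSE]
    ok <- FALSE
    for (attempt in 0:max_redraws) {
      if (attempt > 0) {
        ## deterministic redraw stream per (seed, draw index, attempt)
        sub_seed <- (seed * 1000003L + i * 1009L + attempt * 7L) %% 2147483647L
        row <- sample_parameters(ranges, 1, seed = sub_seed)
        row$draw <- draws$draw[i]
      }
      cfg <- draw_to_config(as.list(row[1, ]), p, scenario_template)
      st <- suppressWarnings(spin_up(cfg$p))
      n_spinups <- n_spinups + 1
      if (st$accepted) {
        ## individual run failures are recorded, not fatal
        run <- tryCatch(
          run_scenario(st, cfg$scenario, cfg$p,
            dynamic_rw = dynamic_rw, t_end = t_end
          ),
          error = function(e) {
            warning(sprintf("run for draw %d failed: %s", i,
                            conditionMessage(e)))
            NULL
          }
        )
        if (!is.null(run)) {
          runs[[i]] <- run
          row$spinup_pco2 <- st$pco2
          row$redraws <- attempt
          used[[i]] <- row
          ok <- TRUE
          break
        }
      }
    }
    if (!ok) failures <- c(failures, i)
    if (progress) {
      cat(sprintf(
        "draw %d/%d: %s after %d spin-up attempt(s)\n", i, nrow(draws),
        if (ok) "accepted" else "FAILED", attempt + 1
      ))
    }
  }
  keep <- !vapply(runs, is.null, logical(1))
  out <- list(
    runs = runs[keep],
    accepted_draws = do.call(rbind, used[keep]),
    n_spinups = n_spinups,
    failures = failures
  )
  class(out) <- "frw_ensemble"
  out
}

#' @export
print.frw_ensemble <- function(x, ...) {
  cat(sprintf(
    "<frw_ensemble> %d runs (%d spin-up attempts, %d failures)\n",
    length(x$runs), x$n_spinups, length(x$failures)
  ))
  invisible(x)
}

#' Temperature-target curve for ensemble filtering
#'
#' @param times Model times (yr), strictly increasing.
#' @param mean_anomaly Target mean anomaly (deg C) at `times`.
#' @param tol_temp Acceptance half-width in temperature (default 4 deg C).
#' @param tol_time Acceptance half-width in time (default 4e5 yr).
#' @return List of class `frw_target`.
#' @export
temperature_target <- function(times, mean_anomaly, tol_temp = 4,
                               tol_time = 4e5) {
  stopifnot(
    length(times) == length(mean_anomaly), all(diff(times) > 0),
    tol_temp > 0, tol_time > 0
  )
  structure(
    list(times = times, mean_anomaly = mean_anomaly,
         tol_temp = tol_temp, tol_time = tol_time),
    class = "frw_target"
  )
}

#' Filter ensemble runs against a temperature target
#'
#' A run passes if, for every target point, some model output time within
#' `tol_time` of the target time has an anomaly within `tol_temp` of the
#' target mean. The trace records the first violated target point of each
#' rejected run.
#'
#' @param ens A `frw_ensemble` (or plain list of `frw_run`).
#' @param target A `frw_target` from [temperature_target()].
#' @return List with `accepted` (indices), `trace` (data frame: run, pass,
#'   first failed target time), and `runs` (the accepted `frw_run` objects).
#' @export
filter_by_temperature <- function(ens, target) {
  runs <- if (inherits(ens, "frw_ensemble")) ens$runs else ens
  pass <- logical(length(runs))
  first_fail <- rep(NA_real_, length(runs))
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    ok <- TRUE
    for (j in seq_along(target$times)) {
      win <- abs(r$times - target$times[j]) <= target$tol_time
      if (!any(win) ||
        !any(abs(r$temp_anomaly[win] - target$mean_anomaly[j]) <=
          target$tol_temp)) {
        ok <- FALSE
        first_fail[i] <- target$times[j]
        break
      }
    }
    pass[i] <- ok
  }
  list(
    accepted = which(pass),
    trace = data.frame(run = seq_along(runs), pass = pass,
                       first_fail_time = first_fail),
    runs = runs[pass]
  )
}

#' Summarise an ensemble of runs
#'
#' Per-time median and central 68% / 95% quantile envelopes for the main
#' output variables, interpolated onto a common time grid, plus the
#' success-frequency of runs by full-extinction duration when a filter trace
#' is supplied.
#'
#' @param runs List of `frw_run` objects (e.g. `filter_by_temperature()$runs`).
#' @param variables Character vector of variables to summarise; any column of
#'   the run `states`/`fluxes` tables plus `"temp_anomaly"`, `"f_rw_ma"`,
#'   `"residence_norm"`.
#' @param grid Common time grid (default: times of the first run).
#' @return List of class `frw_summary`: `envelopes` (long data frame with
#'   time, variable, q025, q16, q50, q84, q975) and `n_runs`.
#' @export
summarize_ensemble <- function(runs,
                               variables = c("temp_anomaly", "f_rw_ma",
                                             "residence_norm", "pco2",
                                             "f_rw", "f_isi"),
                               grid = NULL) {
  if (length(runs) == 0) {
    return(structure(list(envelopes = NULL, n_runs = 0, empty = TRUE),
                     class = "frw_summary"))
  }
  if (is.null(grid)) grid <- runs[[1]]$times
  get_var <- function(r, v) {
    if (v %in% names(r)) return(r[[v]])
    if (v %in% names(r$states)) return(r$states[[v]])
    if (v %in% names(r$fluxes)) return(r$fluxes[[v]])
    stop("unknown run variable: ", v)
  }
  rows <- list()
  for (v in variables) {
    mat <- vapply(runs, function(r) {
      stats::approx(r$times, get_var(r, v), xout = grid, rule = 2)$y
    }, numeric(length(grid)))
    qs <- apply(mat, 1, stats::quantile,
      probs = c(0.025, 0.16, 0.5, 0.84, 0.975), na.rm = TRUE
    )
    rows[[v]] <- data.frame(
      time = grid, variable = v,
      q025 = qs[1, ], q16 = qs[2, ], q50 = qs[3, ], q84 = qs[4, ],
      q975 = qs[5, ]
    )
  }
  structure(
    list(envelopes = do.call(rbind, rows), n_runs = length(runs),
         empty = FALSE),
    class = "frw_summary"
  )
}

#' @export
print.frw_summary <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("<frw_summary> empty (no accepted runs)\n")
  } else {
    cat(sprintf(
      "<frw_summary> %d runs, %d variables on %d time points\n", x$n_runs,
      length(unique(x$envelopes$variable)), length(unique(x$envelopes$time))
    ))
  }
  invisible(x)
}

#' Success frequency by full-extinction duration
#'
#' Fraction of runs passing the temperature filter, binned by the
#' full-extinction duration of their scenario.
#'
#' @param ens A `frw_ensemble`.
#' @param filter_result Result of [filter_by_temperature()] on `ens`.
#' @param breaks Duration bin edges (yr).
#' @return Data frame with bin, n, n_pass, frequency.
#' @export
success_by_duration <- function(ens, filter_result,
                                breaks = seq(2e6, 7e6, by = 1e6)) {
  dur <- vapply(ens$runs, function(r) r$scenario$full_duration, numeric(1))
  bin <- cut(dur, breaks, include.lowest = TRUE)
  pass <- filter_result$trace$pass
  out <- data.frame(
    bin = levels(bin),
    n = as.integer(table(bin)),
    n_pass = vapply(levels(bin), function(b) sum(pass[bin == b]), numeric(1))
  )
  out$frequency <- ifelse(out$n > 0, out$n_pass / out$n, NA_real_)
  rownames(out) <- NULL
  out
}
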