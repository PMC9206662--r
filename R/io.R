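## Configuration files, result serialisation, and run manifests.
##
## Config files are flat YAML with three optional sections: `params`
## (entries of default_params()), `scenario` (entries of
## extinction_scenario()), and `ranges` (per-parameter min/max/scale).
## Unknown keys are rejected by name; an empty or absent section means the
## pinned defaults.

#' Load a model configuration file
#'
#' @param path YAML file path (missing sections fall back to defaults). An
#'   empty file yields the full default configuration.
#' @param mode Mode for the parameter defaults.
#' @param allow_out_of_range Accept parameter values outside the default
#'   sampling ranges with a warning instead of rejecting them silently
#'   (out-of-range values always warn).
#' @return List with `params`, `scenario`, `ranges`.
#' @export
load_config <- function(path, mode = "permian", allow_out_of_range = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad_sections <- setdiff(names(raw), c("params", "scenario", "ranges"))
  if (length(bad_sections) > 0) {
    stop("unknown config section(s): ", paste(bad_sections, collapse = ", "))
  }
  p <- default_params(mode)
  if (!is.null(raw$params)) {
    p <- do.call(update_params, c(list(p), raw$params))
  }
  scen <- extinction_scenario()
  if (!is.null(raw$scenario)) {
    bad <- setdiff(names(raw$scenario), names(scen))
    if (length(bad) > 0) {
      stop("unknown scenario key(s): ", paste(bad, collapse = ", "))
    }
    scen <- do.call(extinction_scenario,
                    utils::modifyList(unclass(scen)[setdiff(names(scen),
                                                            names(raw$scenario))],
                                      raw$scenario))
  }
  ranges <- default_ranges(if (mode == "modern") "modern" else "permian")
  if (!is.null(raw$ranges)) {
    bad <- setdiff(names(raw$ranges), names(ranges))
    if (length(bad) > 0) {
      stop("unknown range key(s): ", paste(bad, collapse = ", "))
    }
    for (k in names(raw$ranges)) {
      entry <- utils::modifyList(ranges[[k]], raw$ranges[[k]])
      ranges[[k]] <- entry
    }
  }
  ## range check: sampled parameters supplied as scalars outside the
  ## documented ranges are flagged
  for (k in intersect(names(p), names(ranges))) {
    v <- p[[k]]
    r <- ranges[[k]]
    if (is.numeric(v) && (v < r$min || v > r$max)) {
      msg <- sprintf(
        "parameter %s = %g is outside its documented range [%g, %g]",
        k, v, r$min, r$max
      )
      if (allow_out_of_range) warning(msg) else stop(msg)
    }
  }
  list(params = p, scenario = scen, ranges = ranges)
}

#' Save a configuration file
#'
#' Writes `params`, `scenario` and `ranges` sections; `load_config()` on the
#' result reproduces the input.
#'
#' @param config List as returned by [load_config()].
#' @param path Output YAML path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(
    list(
      params = unclass(config$params),
      scenario = unclass(config$scenario),
      ranges = lapply(unclass(config$ranges), unclass)
    ),
    path,
    precision = 15
  )
  invisible(path)
}

#' Write a model run to CSV with a JSON manifest sidecar
#'
#' Serialises the state and flux time series of a run to one CSV (one row per
#' output time, full precision) and writes `<path>.json` containing the
#' parameters, scenario, seed, package version, and the md5 digest of the
#' CSV. Re-reading with [read_results()] reproduces the arrays exactly.
#'
#' @param run A `frw_run` from [run_scenario()].
#' @param path Output CSV path.
#' @param seed Seed recorded in the manifest (optional).
#' @return Invisibly, the manifest list.
#' @export
write_results <- function(run, path, seed = NULL) {
  stopifnot(inherits(run, "frw_run"))
  tab <- cbind(
    run$states,
    run$fluxes[, setdiff(names(run$fluxes), c("time")), drop = FALSE],
    temp_anomaly = run$temp_anomaly,
    f_rw_ma = run$f_rw_ma,
    residence_norm = run$residence_norm
  )
  utils::write.csv(format(tab, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  manifest <- list(
    created = format(Sys.time(), tz = "UTC"),
    package_version = as.character(utils::packageVersion("siclimate")),
    seed = seed,
    dynamic_rw = run$dynamic_rw,
    spinup_pco2 = run$spinup_pco2,
    parameters = unclass(run$p),
    scenario = unclass(run$scenario),
    files = list(list(path = basename(path),
                      md5 = unname(tools::md5sum(path))))
  )
  jsonlite::write_json(manifest, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Read back a run CSV with manifest verification
#'
#' @param path CSV written by [write_results()].
#' @param verify Check the md5 digest recorded in the sidecar (default TRUE);
#'   a mismatch (tampered or truncated file) is an error.
#' @return List with `table` (data frame) and `manifest`.
#' @export
read_results <- function(path, verify = TRUE) {
  manifest_path <- paste0(path, ".json")
  manifest <- NULL
  if (file.exists(manifest_path)) {
    manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    if (verify) {
      rec <- manifest$files$md5[manifest$files$path == basename(path)]
      now <- unname(tools::md5sum(path))
      if (length(rec) == 1 && !identical(rec, now)) {
        stop("digest mismatch for ", path, ": file differs from manifest")
      }
    }
  } else if (verify) {
    warning("no manifest sidecar found for ", path)
  }
  list(table = utils::read.csv(path), manifest = manifest)
}

#' Read a temperature-target CSV
#'
#' Two-column format `time_yr, temp_anomaly_C`.
#'
#' @param path CSV path.
#' @param tol_temp,tol_time Filter tolerances to attach.
#' @return A `frw_target`.
#' @export
read_target_csv <- function(path, tol_temp = 4, tol_time = 4e5) {
  tab <- utils::read.csv(path)
  need <- c("time_yr", "temp_anomaly_C")
  if (!all(need %in% names(tab))) {
    stop("target CSV must have columns: ", paste(need, collapse = ", "))
  }
  temperature_target(tab$time_yr, tab$temp_anomaly_C, tol_temp, tol_time)
}

#' Write a temperature target as CSV
#'
#' @param target A `frw_target`.
#' @param path Output path.
#' @export
write_target_csv <- function(target, path) {
  utils::write.csv(
    data.frame(time_yr = target$times, temp_anomaly_C = target$mean_anomaly),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
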