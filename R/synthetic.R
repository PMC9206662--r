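## Synthetic-data generators.
##
## The real study inputs (the SST proxy compilation, section mineralogy, the
## chert-occurrence compilation) are not shipped; these generators emulate
## their structure so every downstream stage can be exercised end to end.
## Everything is a pure function of its arguments and seed. Outputs are
## labelled synthetic.

#' Synthetic sea-surface-temperature target curve
#'
#' Piecewise-linear anomaly emulating the end-Permian trend: zero before
#' onset, a rapid rise of `rise_magnitude` (> 10 deg C) over `rise_duration`,
#' a plateau of `plateau_duration` (~5 Myr), and a linear decline back to
#' zero, sampled at `n_points` with optional Gaussian noise.
#'
#' @param rise_magnitude Plateau anomaly (deg C), default +12.
#' @param rise_duration Duration of the rise (yr), default 1.5e5.
#' @param plateau_duration Plateau length (yr), default 5e6.
#' @param decline_duration Decline length (yr), default 2e6.
#' @param t_onset Onset model time (yr), default 5e6 (matching the scenario).
#' @param t_end Last sampled time (yr).
#' @param n_points Number of samples.
#' @param noise_sd Gaussian noise s.d. (deg C), default 0.
#' @param tol_temp,tol_time Filter tolerances stored on the target.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return A `frw_target` (see [temperature_target()]) with an extra
#'   `synthetic = TRUE` flag and the noiseless curve in `true_anomaly`.
#' @export
make_sst_target <- function(rise_magnitude = 12, rise_duration = 1.5e5,
                            plateau_duration = 5e6, decline_duration = 2e6,
                            t_onset = 5e6, t_end = 14e6, n_points = 40,
                            noise_sd = 0, tol_temp = 4, tol_time = 4e5,
                            seed = 1) {
  stopifnot(rise_duration > 0, plateau_duration > 0, decline_duration > 0,
            noise_sd >= 0, n_points >= 2)
  times <- seq(0, t_end, length.out = n_points)
  knots_t <- c(
    0, t_onset, t_onset + rise_duration,
    t_onset + rise_duration + plateau_duration,
    t_onset + rise_duration + plateau_duration + decline_duration, t_end
  )
  knots_v <- c(0, 0, rise_magnitude, rise_magnitude, 0, 0)
  keep <- !duplicated(knots_t) & knots_t <= t_end
  anomaly <- stats::approx(knots_t[keep], knots_v[keep], xout = times,
                           rule = 2)$y
  noisy <- anomaly
  if (noise_sd > 0) {
    set.seed(seed)
    noisy <- anomaly + stats::rnorm(n_points, 0, noise_sd)
  }
  tgt <- temperature_target(times, noisy, tol_temp, tol_time)
  tgt$true_anomaly <- anomaly
  tgt$synthetic <- TRUE
  tgt
}

#' Synthetic mineral-abundance table
#'
#' Builds a two-interval (pre/post extinction) mineral table whose recomputed
#' sediment authigenic ratios land in the requested ranges before noise. Each
#' sample carries quartz, a random split of the cation-bearing clays, an
#' independent kaolinite fraction (to exercise the exclusion logic), and an
#' inert remainder.
#'
#' @param pre_frw_range,post_frw_range Target `f_rw_s` ranges within `[0, 1]`.
#' @param n_pre,n_post Samples per interval.
#' @param noise_sd S.d. of multiplicative abundance noise (0 = exact).
#' @param section_id Section label.
#' @param seed Integer seed.
#' @return Long-format mineral table (see [section_frw_profile()]).
#' @export
make_mineral_table <- function(pre_frw_range = c(0, 0.15),
                               post_frw_range = c(0.15, 0.55),
                               n_pre = 15, n_post = 15, noise_sd = 0,
                               section_id = "synthetic", seed = 1) {
  stopifnot(
    all(pre_frw_range >= 0 & pre_frw_range <= 1),
    all(post_frw_range >= 0 & post_frw_range <= 1), noise_sd >= 0
  )
  set.seed(seed)
  clay_names <- MINERALS$cation_clays
  one_sample <- function(h, interval, frw) {
    ## clay + quartz budget of 0.7, split to produce the requested ratio
    budget <- 0.7
    clays_total <- frw * budget
    quartz <- budget - clays_total
    split <- stats::runif(length(clay_names))
    split <- split / sum(split)
    kaolinite <- stats::runif(1, 0, 0.15)
    other <- max(0, 1 - budget - kaolinite)
    m <- c("quartz", clay_names, "kaolinite", "other")
    w <- c(quartz, clays_total * split, kaolinite, other)
    if (noise_sd > 0) {
      w <- w * exp(stats::rnorm(length(w), 0, noise_sd))
    }
    data.frame(
      section_id = section_id, height = h, interval = interval,
      mineral = m, weight_fraction = w
    )
  }
  pre_frw <- stats::runif(n_pre, pre_frw_range[1], pre_frw_range[2])
  post_frw <- stats::runif(n_post, post_frw_range[1], post_frw_range[2])
  rows <- c(
    lapply(seq_len(n_pre), function(i) {
      one_sample(i, "pre", pre_frw[i])
    }),
    lapply(seq_len(n_post), function(i) {
      one_sample(n_pre + i, "post", post_frw[i])
    })
  )
  do.call(rbind, rows)
}

#' Synthetic chert-occurrence records
#'
#' Emulates the Early Triassic chert gap: sites bear chert in the pre-gap
#' bins, lose it during the gap bins, and recover at a bin that depends on
#' paleolatitude band (high-latitude sites recover earlier by default,
#' low-latitude recovery is delayed to ~Spathian-Anisian).
#'
#' @param n_sites Number of sites (default 36).
#' @param gap_bins Age bins forming the gap.
#' @param recovery_bin_by_latitude Named list mapping latitude band
#'   (`"0-30"`, `"30-60"`, `"60-90"`) to the recovery age bin.
#' @param p_chert_background Probability a site bears chert outside the gap.
#' @param seed Integer seed.
#' @return Chert record data frame (one row per site per age bin).
#' @export
make_chert_records <- function(n_sites = 36,
                               gap_bins = c("Griesbachian", "Dienerian",
                                            "Smithian"),
                               recovery_bin_by_latitude = list(
                                 "0-30" = "Anisian", "30-60" = "Anisian",
                                 "60-90" = "Spathian"
                               ),
                               p_chert_background = 0.9, seed = 1) {
  stopifnot(n_sites >= 1, all(gap_bins %in% AGE_BINS))
  set.seed(seed)
  lats <- stats::runif(n_sites, 0, 72)
  lith <- sample(c("siliciclastic", "carbonate", "mixed"), n_sites,
                 replace = TRUE)
  band <- as.character(cut(lats, c(0, 30, 60, 90),
    labels = c("0-30", "30-60", "60-90"), include.lowest = TRUE
  ))
  bin_index <- stats::setNames(seq_along(AGE_BINS), AGE_BINS)
  rows <- lapply(seq_len(n_sites), function(i) {
    recovery <- recovery_bin_by_latitude[[band[i]]]
    do.call(rbind, lapply(AGE_BINS, function(b) {
      in_gap <- b %in% gap_bins ||
        (bin_index[b] > max(bin_index[gap_bins]) &
           bin_index[b] < bin_index[recovery])
      bearing <- !in_gap && stats::runif(1) < p_chert_background
      type <- if (bearing) {
        paste(sample(c("biogenic", "nodule", "replacement"),
                     sample(1:2, 1)), collapse = ";")
      } else "none"
      data.frame(
        site_id = sprintf("site%02d", i), age_bin = b, lithology = lith[i],
        paleolat_deg = lats[i], chert_types = type
      )
    }))
  })
  do.call(rbind, rows)
}

#' Default parameter-range and scenario fixture
#'
#' The shipped study conditions: the Monte Carlo sampling ranges (carbon
#' release 30,000-55,000 Pg C, release duration 0.8e5-2.4e5 yr, climate
#' sensitivity 2-5 deg C per doubling, and the clay-law/extinction ranges)
#' together with the default extinction scenario and the synthetic SST
#' target.
#'
#' @return List with `ranges` (a `frw_ranges`), `scenario` (a
#'   `frw_scenario`), and `target` (a `frw_target`).
#' @export
default_fixture <- function() {
  list(
    ranges = default_ranges("permian"),
    scenario = extinction_scenario(),
    target = make_sst_target()
  )
}
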