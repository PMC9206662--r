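## Sediment-expressed authigenic ratio from mineral abundances, and chert
## occurrence tabulation.
##
## Mineral tables are long-format data frames with columns
##   section_id, height, interval ("pre"/"post"), mineral, weight_fraction
## where mineral is one of the documented vocabulary. Chert tables have
##   site_id, age_bin, lithology, paleolat_deg, chert_types
## (chert_types a ";"-separated subset of biogenic/nodule/replacement/none).

#' Mineral vocabulary for abundance tables
#'
#' Cation-bearing clays (berthierine/chamosite, glauconite, Fe-smectite,
#' Fe-illite) consume alkalinity when they form and therefore count as
#' reverse-weathering products; kaolinite bears no interlayer cations and is
#' excluded, as are quartz (the denominator) and accessory phases.
#' @export
MINERALS <- list(
  cation_clays = c("berthierine_chamosite", "glauconite", "fe_smectite",
                   "fe_illite"),
  excluded = c("kaolinite", "pyrite", "other"),
  all = c("quartz", "pyrite", "berthierine_chamosite", "glauconite",
          "fe_smectite", "fe_illite", "kaolinite", "other")
)

#' Ordered age-bin vocabulary for chert records
#' @export
AGE_BINS <- c(
  "Changhsingian", "Griesbachian", "Dienerian", "Smithian", "Spathian",
  "Anisian", "Ladinian"
)

## Validate a mineral table; returns it invisibly or stops.
validate_mineral_table <- function(tab, tol = 0.02) {
  need <- c("section_id", "height", "interval", "mineral", "weight_fraction")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("mineral table lacks column(s): ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(tab$mineral), MINERALS$all)
  if (length(bad) > 0) {
    stop("unknown mineral name(s): ", paste(bad, collapse = ", "))
  }
  if (any(tab$weight_fraction < 0)) stop("negative weight fractions")
  sums <- tapply(tab$weight_fraction,
                 interaction(tab$section_id, tab$height, drop = TRUE), sum)
  if (any(sums > 1 + tol)) {
    stop("per-sample weight fractions exceed 1 beyond tolerance")
  }
  invisible(tab)
}

#' Sediment-expressed authigenic ratio from mineral abundances
#'
#' `f_rw_s = sum(cation-bearing clays) / (sum(cation-bearing clays) + quartz)`
#' for one sample; kaolinite and other non-cation phases are excluded from
#' both numerator and denominator, so the ratio is invariant to dilution by
#' excluded phases and to overall rescaling of the abundances. An optional
#' per-mineral silica weight table reweights each phase by its Si content.
#'
#' @param minerals Character vector of mineral names for one sample.
#' @param weight_fraction Numeric weight fractions matching `minerals`.
#' @param si_weights Optional named numeric vector of per-mineral Si weights
#'   (e.g. mol Si per gram); phases absent from the table default to 1.
#' @return Ratio in `[0, 1]`, or `NA` with a warning when neither quartz nor
#'   cation-bearing clays are present.
#' @export
f_rw_s_from_minerals <- function(minerals, weight_fraction,
                                 si_weights = NULL) {
  stopifnot(length(minerals) == length(weight_fraction),
            all(weight_fraction >= 0))
  w <- weight_fraction
  if (!is.null(si_weights)) {
    sw <- si_weights[minerals]
    sw[is.na(sw)] <- 1
    w <- w * sw
  }
  clays <- sum(w[minerals %in% MINERALS$cation_clays])
  quartz <- sum(w[minerals == "quartz"])
  if (clays + quartz <= 0) {
    warning("no cation-bearing clays or quartz in sample; f_rw_s undefined")
    return(NA_real_)
  }
  clays / (clays + quartz)
}

#' Stratigraphic profile of the sediment authigenic ratio
#'
#' Computes `f_rw_s` per sample (grouped by section and height), sorted by
#' height within section, plus the min-max range per pre/post interval label.
#'
#' @param tab Long-format mineral table (see [MINERALS] for the vocabulary).
#' @param si_weights Optional per-mineral Si weights, passed through.
#' @return List with `profile` (data frame: section_id, height, interval,
#'   f_rw_s) and `interval_ranges` (data frame: interval, n, min, max).
#' @export
section_frw_profile <- function(tab, si_weights = NULL) {
  validate_mineral_table(tab)
  key <- interaction(tab$section_id, tab$height, drop = TRUE)
  rows <- lapply(split(tab, key), function(g) {
    data.frame(
      section_id = g$section_id[1], height = g$height[1],
      interval = g$interval[1],
      f_rw_s = f_rw_s_from_minerals(g$mineral, g$weight_fraction, si_weights)
    )
  })
  profile <- do.call(rbind, rows)
  profile <- profile[order(profile$section_id, profile$height), ]
  rownames(profile) <- NULL
  ok <- !is.na(profile$f_rw_s)
  rng <- lapply(split(profile[ok, ], profile$interval[ok]), function(g) {
    data.frame(interval = g$interval[1], n = nrow(g),
               min = min(g$f_rw_s), max = max(g$f_rw_s))
  })
  interval_ranges <- do.call(rbind, rng)
  rownames(interval_ranges) <- NULL
  list(profile = profile, interval_ranges = interval_ranges)
}

## Split a ";"-separated chert_types field into a character vector.
split_chert_types <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  lapply(out, trimws)
}

#' Fraction of sites bearing chert per age bin
#'
#' For each age bin (and optional grouping by lithology, paleolatitude band
#' 0-30/30-60/60-90, or chert type) reports the fraction of distinct sites
#' with any chert (or the selected type), together with the site count per
#' bin. A site counts once per bin regardless of how many beds bear chert.
#'
#' @param records Chert record data frame (site_id, age_bin, lithology,
#'   paleolat_deg, chert_types).
#' @param grouping `"none"`, `"lithology"`, `"latitude_band"`, or `"type"`.
#' @return Data frame with age_bin (ordered), optional group column,
#'   n_sites, n_chert, f_chert (`NA` where a bin has no sites).
#' @export
chert_fraction <- function(records,
                           grouping = c("none", "lithology", "latitude_band",
                                        "type")) {
  grouping <- match.arg(grouping)
  stopifnot(all(records$age_bin %in% AGE_BINS),
            all(records$paleolat_deg >= 0 & records$paleolat_deg <= 90))
  types <- split_chert_types(records$chert_types)
  has_chert_any <- vapply(types, function(z) any(z != "none" & z != ""),
                          logical(1))
  records$lat_band <- cut(records$paleolat_deg, c(0, 30, 60, 90),
    labels = c("0-30", "30-60", "60-90"), include.lowest = TRUE
  )

  tab_one <- function(rec, has, group_value = NULL, group_name = NULL) {
    out <- lapply(AGE_BINS, function(b) {
      sel <- rec$age_bin == b
      sites <- unique(rec$site_id[sel])
      chert_sites <- unique(rec$site_id[sel & has])
      data.frame(
        age_bin = b, n_sites = length(sites), n_chert = length(chert_sites),
        f_chert = if (length(sites) > 0) {
          length(chert_sites) / length(sites)
        } else NA_real_
      )
    })
    out <- do.call(rbind, out)
    if (!is.null(group_name)) {
      out[[group_name]] <- group_value
      out <- out[, c("age_bin", group_name, "n_sites", "n_chert", "f_chert")]
    }
    out
  }

  if (grouping == "none") {
    res <- tab_one(records, has_chert_any)
  } else if (grouping == "lithology") {
    res <- do.call(rbind, lapply(unique(records$lithology), function(g) {
      sel <- records$lithology == g
      tab_one(records[sel, ], has_chert_any[sel], g, "lithology")
    }))
  } else if (grouping == "latitude_band") {
    res <- do.call(rbind, lapply(levels(records$lat_band), function(g) {
      sel <- records$lat_band == g
      tab_one(records[sel, ], has_chert_any[sel], g, "latitude_band")
    }))
  } else {
    all_types <- c("biogenic", "nodule", "replacement")
    res <- do.call(rbind, lapply(all_types, function(g) {
      has <- vapply(types, function(z) g %in% z, logical(1))
      tab_one(records, has, g, "chert_type")
    }))
  }
  res$age_bin <- factor(res$age_bin, levels = AGE_BINS, ordered = TRUE)
  rownames(res) <- NULL
  res
}
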