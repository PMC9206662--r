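## Model parameters and configuration.
##
## A ParameterSet is a flat named list; `default_params()` gives the pinned
## defaults for the modern calibration or the pre-extinction (Permian)
## background. Fluxes are carried in Tmol yr^-1 at the parameter level and
## converted to mol yr^-1 inside the integrator.

#' Unit conversions pinned in configuration
#'
#' `mol_per_ppm`: atmospheric carbon mass per ppm of CO2 (1 ppm = 1.77e14 mol
#' C). `tmol_per_pg_c`: 1 Pg C = 83.33 Tmol C (12 g mol^-1).
#' @export
UNITS <- list(mol_per_ppm = 1.77e14, tmol_per_pg_c = 1000 / 12)

#' Default model parameter set
#'
#' Returns the full pinned configuration for the coupled carbon-silica model.
#' `mode = "modern"` is the present-day calibration (reproducing the modern
#' marine silica budget: riverine 8.1, reverse weathering ~4.7 and biogenic
#' silica sediment export ~90 Tmol yr^-1); `mode = "permian"` is the
#' pre-extinction background with weaker biological silica uptake.
#'
#' @param mode `"modern"` or `"permian"`.
#' @return A named list of class `frw_params`.
#' @export
default_params <- function(mode = c("modern", "permian")) {
  mode <- match.arg(mode)
  p <- list(
    mode = mode,

    ## --- geometry -----------------------------------------------------------
    ocean_area = 3.61e14,       # m^2
    surface_depth = 100,        # m
    ocean_volume = 1.34e18,     # m^3 total
    mixing_rate = 4.5e15,       # m^3 yr^-1 surface<->deep exchange
    piston_velocity = 1825,     # m yr^-1 (~0.2 m/hr gas exchange)

    ## --- climate / chemistry ------------------------------------------------
    climate_sensitivity = 3,    # deg C per doubling
    t_surface_ref = 18,         # deg C at pco2 = pco2c
    t_deep_offset = 14,         # deg C below surface, floored at 2 C
    salinity = 35,
    calcium = 10.28e-3,         # mol kg^-1
    borate = TRUE,

    ## --- carbon fluxes (Tmol yr^-1) ----------------------------------------
    f_vc = 5,                   # background volcanic degassing
    f_carbw0 = 10,              # carbonate weathering at pco2 = pco2c
    pco2c = 140,                # ppm, weathering reference pCO2
    n_si = 0.2,                 # silicate weathering exponent
    n_carb = 0.1,               # carbonate weathering exponent
    f_orgb = 10,                # organic carbon burial = terrestrial org weathering
    f_pump = 800,               # organic carbon export at 100 m (remineralised at depth)
    b_carb = 10,                # biogenic carbonate export (burial)
    k_inorg_carb = 0.9,         # inorganic carbonate burial scale
    n_inorg_carb = 1.7,         # (omega_calcite - 1) exponent

    ## --- carbon isotopes (per mil) -----------------------------------------
    d13c_volc = -5,
    d13c_carbw = 2,
    d13c_orgw = -28,
    eps_org = -25,              # organic matter vs surface DIC
    d13c_release = -15,         # volcanic pulse carbon

    ## --- silica fluxes (Tmol Si yr^-1) -------------------------------------
    quartz_fraction = 0.19,     # terrestrial SiO2 weathering vs silicate flux
    f_dust = 0.5,
    f_hyd = 1.2,
    f_gw = 1.0,
    f_mssw = 0.65,

    ## --- biogenic silica (Michaelis-Menten + opal dissolution) -------------
    k_bsi = 3.2e14,             # mol yr^-1 proportionality constant
    vmax = 1.74,
    km = 74.48,                 # uM
    sigma_sol = 0.9,            # mM, opal-A solubility
    rho_surface_deep = 5.5,     # dissolution exponent, water column
    rho_sediment = 0.4,         # dissolution exponent, sediment return

    ## --- reverse weathering (authigenic clay) ------------------------------
    rw_bsi_ratio = 4.7 / 90.2,  # modern F_rw / F_bSi_sed
    rw_offset_o = 1,
    r_x = 1, x_conc = 1,
    r_si = 3, r_h = 1,
    si_o = 0.123,               # mM
    h_o = 1.9e-5,               # mM
    alk_si = 0.3,
    rw_box = "deep",            # box supplying [Si], [H+] for the clay law

    ## --- inorganic silica ---------------------------------------------------
    isi_threshold = 0.9,        # mol m^-3 (surface [Si] below which F_iSi = 0)
    isi_exponent = 1.1
  )
  if (mode == "permian") {
    p$t_surface_ref <- 21
    p$pco2c <- 140
    p$n_si <- 0.4
    p$n_carb <- 0.2
    p$k_bsi <- 5e13
    p$r_si <- 1
    p$r_h <- 2
    p$alk_si <- 1
    p$isi_threshold <- 0.75
  }
  structure(p, class = "frw_params")
}

#' @export
print.frw_params <- function(x, ...) {
  cat(sprintf(
    "<frw_params> mode=%s, pco2c=%g ppm, n_si=%g, alk_si=%g, k_bsi=%.3g\n",
    x$mode, x$pco2c, x$n_si, x$alk_si, x$k_bsi
  ))
  invisible(x)
}

#' Override entries of a parameter set
#'
#' @param p A parameter set from [default_params()].
#' @param ... Named replacements; names must already exist in `p`.
#' @return The modified parameter set.
#' @export
update_params <- function(p, ...) {
  upd <- list(...)
  if (length(upd) == 0) return(p)
  bad <- setdiff(names(upd), names(p))
  if (length(bad) > 0) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  }
  p[names(upd)] <- upd
  p
}

## Derived geometry helper.
geometry <- function(p) {
  vs <- p$surface_depth * p$ocean_area
  list(
    v_surface = vs,
    v_deep = p$ocean_volume - vs,
    area = p$ocean_area
  )
}
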