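## Carbon and silica flux parameterisations.
##
## All laws take and return Tmol yr^-1 except biogenic silica production and
## dissolution, which work in mol yr^-1 (the scale of k_bsi); conversion
## happens in the integrator. Removal laws clamp to zero beyond their
## thresholds (opal solubility, clay saturation offset, abiotic silica onset),
## so every flux is nonnegative and continuous at the threshold.

#' Silicate weathering flux
#'
#' Power law in atmospheric pCO2: `F = F0 * (pCO2 / pCO2c)^n_si`, with the
#' background flux `F0` equal to the background volcanic degassing rate so
#' that, absent reverse weathering, steady state sits at `pCO2 = pCO2c`.
#'
#' @param pco2 Atmospheric pCO2 (ppm).
#' @param p Parameter set ([default_params()]).
#' @return Flux in Tmol Si yr^-1.
#' @export
silicate_weathering <- function(pco2, p) {
  stopifnot(all(pco2 > 0))
  p$f_vc * (pco2 / p$pco2c)^p$n_si
}

#' Carbonate weathering flux
#'
#' `F = F0_carbw * (pCO2 / pCO2c)^n_carb` (Tmol C yr^-1).
#'
#' @inheritParams silicate_weathering
#' @export
carbonate_weathering <- function(pco2, p) {
  stopifnot(all(pco2 > 0))
  p$f_carbw0 * (pco2 / p$pco2c)^p$n_carb
}

#' Terrestrial quartz (SiO2) weathering flux
#'
#' A fixed fraction (default 19%) of the silicate weathering flux, delivering
#' dissolved silica but no alkalinity (congruent SiO2 dissolution).
#'
#' @param f_silw Silicate weathering flux (Tmol Si yr^-1).
#' @param quartz_fraction Fraction of the silicate flux (default 0.19).
#' @export
quartz_weathering <- function(f_silw, quartz_fraction = 0.19) {
  stopifnot(all(f_silw >= 0))
  quartz_fraction * f_silw
}

#' Biogenic silica production
#'
#' Michaelis-Menten kinetics in surface dissolved silica:
#' `F = k_bsi * Vmax * [Si]_uM / (Km + [Si]_uM)` with `[Si]` supplied in mM
#' and converted to uM internally (factor 1000).
#'
#' @param si_surface Surface dissolved silica (mM == mol m^-3).
#' @param p Parameter set.
#' @return Flux in mol Si yr^-1.
#' @export
bsi_production <- function(si_surface, p) {
  stopifnot(all(si_surface >= 0))
  si_um <- si_surface * 1000
  p$k_bsi * p$vmax * si_um / (p$km + si_um)
}

#' Biogenic silica dissolution
#'
#' A fraction `(1 - [Si]/sigma)^rho` of the incoming opal flux redissolves in
#' the receiving reservoir, clamped to zero at and above the opal-A solubility
#' `sigma` (0.9 mM).
#'
#' @param f_in Incoming biogenic silica flux (any flux unit; output matches).
#' @param si_box Dissolved silica of the receiving box (mM).
#' @param rho Dissolution exponent (5.5 water column, 0.4 sediment return).
#' @param p Parameter set (supplies `sigma_sol`).
#' @export
bsi_dissolution <- function(f_in, si_box, rho, p) {
  stopifnot(all(f_in >= 0))
  u <- pmax(0, 1 - si_box / p$sigma_sol)
  f_in * u^rho
}

#' Authigenic clay saturation index
#'
#' `Omega_rw = IAP / Ksp` with `IAP = [X]^r_x [Si]^r_si / [H+]^r_H` and the
#' solubility product evaluated at the calibration point
#' (`[Si]_o`, `[H+]_o`, `[X]_o = 1`). Equal to 1 exactly at the calibration
#' point for any exponents.
#'
#' @param si Dissolved silica (mM).
#' @param h Hydrogen ion concentration (mM).
#' @param p Parameter set.
#' @param r_si,r_h Optional exponent overrides (default from `p`).
#' @export
rw_saturation <- function(si, h, p, r_si = p$r_si, r_h = p$r_h) {
  stopifnot(all(si > 0), all(h > 0))
  iap <- p$x_conc^p$r_x * si^r_si / h^r_h
  ksp <- 1^p$r_x * p$si_o^r_si / p$h_o^r_h
  iap / ksp
}

#' Reverse weathering (authigenic clay) silica flux
#'
#' `F_rw = (beta + alpha) * (Omega_rw - o)`, clamped to zero when the
#' saturation index does not exceed the offset `o`. The abiotic
#' proportionality `alpha` is the sum of the constant silica inputs
#' (`F_vc + F_hyd + F_dust + F_mssw + F_gw`); the biogenic term
#' `beta = F_bSi_sed * rw_bsi_ratio` ties clay formation to the biogenic
#' silica flux reaching the sediment.
#'
#' @param si,h Dissolved silica and [H+] of the sediment-interface box (mM).
#' @param f_bsi_sed Biogenic silica export to sediment (Tmol yr^-1).
#' @param p Parameter set.
#' @param o,r_si,r_h,rw_bsi_ratio Optional overrides of the clay-law
#'   parameters (used for phased extinction-interval values).
#' @return Flux in Tmol Si yr^-1.
#' @export
reverse_weathering <- function(si, h, f_bsi_sed, p, o = p$rw_offset_o,
                               r_si = p$r_si, r_h = p$r_h,
                               rw_bsi_ratio = p$rw_bsi_ratio) {
  stopifnot(all(f_bsi_sed >= 0))
  omega <- rw_saturation(si, h, p, r_si = r_si, r_h = r_h)
  (rw_proportionality(f_bsi_sed, p, rw_bsi_ratio)) * pmax(0, omega - o)
}

## beta + alpha of the clay and abiotic silica laws (Tmol yr^-1).
rw_proportionality <- function(f_bsi_sed, p, rw_bsi_ratio = p$rw_bsi_ratio) {
  alpha <- p$f_vc + p$f_hyd + p$f_dust + p$f_mssw + p$f_gw
  f_bsi_sed * rw_bsi_ratio + alpha
}

#' Inorganic (abiotic) silica precipitation flux
#'
#' `F_iSi = (beta + alpha) * ([Si]_ssw / d - 1)^1.1` above the onset
#' concentration `d` (`isi_threshold`), zero below it.
#'
#' @param si_surface Surface dissolved silica (mM).
#' @param f_bsi_sed Biogenic silica export to sediment (Tmol yr^-1).
#' @param p Parameter set.
#' @param rw_bsi_ratio Optional override of the biogenic proportionality.
#' @return Flux in Tmol Si yr^-1.
#' @export
inorganic_si <- function(si_surface, f_bsi_sed, p,
                         rw_bsi_ratio = p$rw_bsi_ratio) {
  stopifnot(all(si_surface >= 0), all(f_bsi_sed >= 0))
  s <- pmax(0, si_surface / p$isi_threshold - 1)
  rw_proportionality(f_bsi_sed, p, rw_bsi_ratio) * s^p$isi_exponent
}

#' Alkalinity consumption by reverse weathering
#'
#' Clay formation consumes `Alk:Si` mol-equivalents of alkalinity per mol of
#' silica taken up, with DIC unchanged: this shifts the carbonate speciation
#' toward CO2 and is the mechanism by which authigenic clay formation recycles
#' carbon within the ocean-atmosphere system.
#'
#' @param f_rw Reverse weathering silica flux (Tmol Si yr^-1).
#' @param alk_si Alkalinity:silica consumption ratio.
#' @return Alkalinity flux removed (Tmol-eq yr^-1).
#' @export
rw_alkalinity_consumption <- function(f_rw, alk_si) {
  stopifnot(all(f_rw >= 0))
  alk_si * f_rw
}
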