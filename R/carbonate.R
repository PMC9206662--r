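## Seawater carbonate chemistry for the two-box ocean.
##
## Alkalinity closure is the carbonate + borate + water balance solved on the
## total pH scale, with constants from the standard T,S fits pinned below.
## Concentrations enter in mol m^-3 and are converted internally to mol kg^-1
## with a fixed seawater density.

#' Seawater density used for mol m^-3 <-> mol kg^-1 conversion (kg m^-3)
#' @keywords internal
RHO_SW <- 1027

#' Equilibrium constants for the seawater CO2 system
#'
#' Temperature- and salinity-dependent dissociation constants on the total pH
#' scale (mol kg^-1): `k0` CO2 solubility (mol kg^-1 atm^-1, Weiss-type fit),
#' `k1`, `k2` carbonic acid (Lueker-type fit), `kb` boric acid (Dickson-type
#' fit), `kw` water, plus the total borate concentration `bt` scaled to
#' salinity, and the calcite stoichiometric solubility product `ksp_calcite`.
#'
#' @param temperature Temperature in degrees Celsius.
#' @param salinity Salinity (psu).
#' @return Named list of constants.
#' @export
carbonate_constants <- function(temperature, salinity = 35) {
  tk <- temperature + 273.15
  s <- salinity
  lntk <- log(tk)

  ## CO2 solubility (mol kg^-1 atm^-1)
  lnk0 <- -60.2409 + 93.4517 * (100 / tk) + 23.3585 * log(tk / 100) +
    s * (0.023517 - 0.023656 * (tk / 100) + 0.0047036 * (tk / 100)^2)
  k0 <- exp(lnk0)

  ## K1, K2 (total scale, mol kg^-1)
  pk1 <- 3633.86 / tk - 61.2172 + 9.6777 * lntk - 0.011555 * s + 0.0001152 * s^2
  pk2 <- 471.78 / tk + 25.929 - 3.16967 * lntk - 0.01781 * s + 0.0001122 * s^2
  k1 <- 10^(-pk1)
  k2 <- 10^(-pk2)

  ## Boric acid (total scale)
  lnkb <- (-8966.9 - 2890.53 * sqrt(s) - 77.942 * s + 1.728 * s^1.5 -
    0.0996 * s^2) / tk +
    148.0248 + 137.1942 * sqrt(s) + 1.62142 * s -
    (24.4344 + 25.085 * sqrt(s) + 0.2474 * s) * lntk +
    0.053105 * sqrt(s) * tk
  kb <- exp(lnkb)

  ## Water (total scale)
  lnkw <- 148.9652 - 13847.26 / tk - 23.6521 * lntk +
    (118.67 / tk - 5.977 + 1.0495 * lntk) * sqrt(s) - 0.01615 * s
  kw <- exp(lnkw)

  ## Calcite solubility (Mucci-type fit, mol^2 kg^-2)
  logksp <- -171.9065 - 0.077993 * tk + 2839.319 / tk + 71.595 * log10(tk) +
    (-0.77712 + 0.0028426 * tk + 178.34 / tk) * sqrt(s) -
    0.07711 * s + 0.0041249 * s^1.5
  ksp <- 10^logksp

  list(
    k0 = k0, k1 = k1, k2 = k2, kb = kb, kw = kw,
    bt = 4.157e-4 * s / 35, ksp_calcite = ksp
  )
}

## Total alkalinity (mol kg^-1) implied by [H+] (mol kg^-1) and DIC (mol kg^-1).
## Vectorised over h.
alk_of_h <- function(h, dic_kg, cn, borate = TRUE, water = TRUE) {
  den <- h * h + cn$k1 * h + cn$k1 * cn$k2
  alk <- dic_kg * cn$k1 * (h + 2 * cn$k2) / den
  if (borate) alk <- alk + cn$bt * cn$kb / (cn$kb + h)
  if (water) alk <- alk + cn$kw / h - h
  alk
}

#' Solve the seawater carbonate system from DIC and total alkalinity
#'
#' Finds the unique hydrogen-ion concentration in pH 2-12 at which the
#' alkalinity balance (carbonate + borate + water contributions) is consistent
#' with the supplied DIC, then returns the full speciation. Reconstructing TA
#' from the returned species reproduces the input to better than 1e-8 relative.
#'
#' @param dic Dissolved inorganic carbon (mol m^-3).
#' @param ta Total alkalinity (mol-eq m^-3).
#' @param temperature Temperature (deg C), in `[0, 60]`.
#' @param salinity Salinity (psu).
#' @param calcium Calcium concentration (mol kg^-1) used for the calcite
#'   saturation state; default is the modern value 10.28 mmol kg^-1.
#' @param borate,water Include the borate / water self-ionisation terms in the
#'   alkalinity balance (both on by default).
#' @return An object of class `carb_speciation`: list with `ph` (total scale),
#'   `h_conc` ([H+] in mM, i.e. mmol per litre), `co2aq`, `hco3`, `co3`
#'   (mol m^-3), `omega_calcite`, `pco2` (ppm at equilibrium with the water),
#'   and the constants used.
#' @export
solve_carbonate_system <- function(dic, ta, temperature = 20, salinity = 35,
                                   calcium = 10.28e-3,
                                   borate = TRUE, water = TRUE) {
  stopifnot(dic > 0, ta > 0, temperature >= 0, temperature <= 60)
  cn <- carbonate_constants(temperature, salinity)
  dic_kg <- dic / RHO_SW
  ta_kg <- ta / RHO_SW

  f <- function(h) alk_of_h(h, dic_kg, cn, borate, water) - ta_kg
  h_lo <- 10^-12
  h_hi <- 10^-2
  if (f(h_hi) * f(h_lo) > 0) {
    stop(sprintf(
      "degenerate carbonate chemistry: no root in pH [2, 12] for dic=%g, ta=%g",
      dic, ta
    ))
  }
  ## bisection on pH then Newton polish on h for the 1e-8 round trip
  root <- stats::uniroot(f, c(h_lo, h_hi), tol = 1e-20)
  h <- root$root
  for (i in 1:4) {
    dh <- h * 1e-7
    fp <- (f(h + dh) - f(h - dh)) / (2 * dh)
    step <- f(h) / fp
    if (!is.finite(step)) break
    h <- h - step
    if (h <= 0) {
      h <- root$root
      break
    }
  }
  speciate_from_h(h, dic, temperature, salinity, calcium, cn)
}

## Build a carb_speciation object from a known [H+] (mol kg^-1).
speciate_from_h <- function(h, dic, temperature, salinity, calcium, cn) {
  dic_kg <- dic / RHO_SW
  den <- h * h + cn$k1 * h + cn$k1 * cn$k2
  co2aq <- dic_kg * h * h / den
  hco3 <- dic_kg * cn$k1 * h / den
  co3 <- dic_kg * cn$k1 * cn$k2 / den
  out <- list(
    ph = -log10(h * RHO_SW / 1000), # [H+] mol/kg -> mol/L via density
    h_conc = h * RHO_SW,            # mol kg^-1 -> mol m^-3 == mmol/L (mM)
    co2aq = co2aq * RHO_SW,
    hco3 = hco3 * RHO_SW,
    co3 = co3 * RHO_SW,
    omega_calcite = calcium * co3 / cn$ksp_calcite,
    pco2 = co2aq / cn$k0 * 1e6, # atm -> ppm (uatm)
    temperature = temperature,
    salinity = salinity,
    constants = cn
  )
  class(out) <- "carb_speciation"
  out
}

#' @export
print.carb_speciation <- function(x, ...) {
  cat(sprintf(
    "carbonate speciation: pH %.4f, pCO2 %.1f ppm, omega_calcite %.2f\n",
    x$ph, x$pco2, x$omega_calcite
  ))
  invisible(x)
}

#' Air-sea CO2 exchange flux
#'
#' Linear gas-exchange law: flux is proportional to the partial-pressure
#' difference between the atmosphere and the surface-water equilibrium value.
#'
#' @param pco2_atm Atmospheric pCO2 (ppm).
#' @param speciation_surface Surface-water speciation from
#'   [solve_carbonate_system()] (supplies equilibrium pCO2 and the solubility).
#' @param piston_velocity Gas transfer (piston) velocity (m yr^-1).
#' @param area Exchange area (m^2).
#' @return Carbon flux in mol C yr^-1, positive into the ocean.
#' @export
air_sea_co2_exchange <- function(pco2_atm, speciation_surface,
                                 piston_velocity = 1825, area = 3.61e14) {
  stopifnot(piston_velocity > 0, area > 0)
  k0_m3 <- speciation_surface$constants$k0 * RHO_SW # mol m^-3 atm^-1
  piston_velocity * area * k0_m3 * 1e-6 * (pco2_atm - speciation_surface$pco2)
}

## Carbon isotope fractionation factors for air-sea exchange (per mil epsilons,
## linear fits in temperature after the standard inorganic-carbon compilation).
eps_co2aq_gas <- function(t) 0.0049 * t - 1.31
eps_hco3_gas <- function(t) -0.1141 * t + 10.78
eps_co3_gas <- function(t) -0.052 * t + 7.22
EPS_KINETIC <- -0.88

## Equilibrium DIC-gas fractionation, speciation-weighted.
eps_dic_gas <- function(spec) {
  t <- spec$temperature
  dic <- spec$co2aq + spec$hco3 + spec$co3
  (spec$co2aq * eps_co2aq_gas(t) + spec$hco3 * eps_hco3_gas(t) +
    spec$co3 * eps_co3_gas(t)) / dic
}

#' Air-sea 13C exchange flux
#'
#' Gross invasion/evasion fluxes of 13C across the air-sea interface with
#' kinetic and temperature-dependent equilibrium fractionation, in the LOSCAR
#' convention: the net 13C flux vanishes when the system is at joint chemical
#' and isotopic equilibrium (surface DIC offset from the atmosphere by the
#' equilibrium DIC-gas fractionation).
#'
#' @param atm_d13c Atmospheric delta-13C (per mil).
#' @param surface_d13c Surface DIC delta-13C (per mil).
#' @param speciation Surface speciation from [solve_carbonate_system()].
#' @param pco2_atm Atmospheric pCO2 (ppm).
#' @param piston_velocity Piston velocity (m yr^-1).
#' @param area Exchange area (m^2).
#' @param fractionation If `FALSE` all fractionation factors are set to 1.
#' @return List with `net13` (net 13C-equivalent delta-weighted flux in
#'   mol-permil yr^-1, positive into the ocean), and the gross `invasion` and
#'   `evasion` carbon fluxes (mol yr^-1).
#' @export
air_sea_13c_exchange <- function(atm_d13c, surface_d13c, speciation, pco2_atm,
                                 piston_velocity = 1825, area = 3.61e14,
                                 fractionation = TRUE) {
  k0_m3 <- speciation$constants$k0 * RHO_SW
  kg <- piston_velocity * area * k0_m3 * 1e-6
  f_inv <- kg * pco2_atm
  f_ev <- kg * speciation$pco2
  if (fractionation) {
    e_k <- EPS_KINETIC
    e_aq <- eps_co2aq_gas(speciation$temperature)
    e_dic <- eps_dic_gas(speciation)
  } else {
    e_k <- e_aq <- e_dic <- 0
  }
  ## ratios r = 1 + d/1000; net 13C flux in delta-mass (mol-permil) units
  a_k <- 1 + e_k / 1000
  a_aq <- 1 + e_aq / 1000
  a_dic <- 1 + e_dic / 1000
  r_atm <- 1 + atm_d13c / 1000
  r_dic <- 1 + surface_d13c / 1000
  net_r <- a_k * a_aq * (f_inv * r_atm - f_ev * r_dic / a_dic)
  net12 <- f_inv - f_ev
  list(net13 = 1000 * (net_r - net12), invasion = f_inv, evasion = f_ev)
}

#' Equilibrium warming from a pCO2 change
#'
#' `delta_T = S * log2(pCO2 / pCO2_background)`: the climate sensitivity `S` is
#' the equilibrium warming per doubling of pCO2, so the anomaly is exactly
#' additive over successive doublings.
#'
#' @param pco2 Atmospheric pCO2 (ppm).
#' @param pco2_background Reference pCO2 (ppm).
#' @param climate_sensitivity Warming per doubling (deg C).
#' @return Temperature anomaly (deg C).
#' @export
temperature_anomaly <- function(pco2, pco2_background, climate_sensitivity = 3) {
  stopifnot(all(pco2 > 0), pco2_background > 0)
  climate_sensitivity * log2(pco2 / pco2_background)
}
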