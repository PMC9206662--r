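## Time integration of the coupled carbon-silica system.
##
## State vector (concentration units so magnitudes stay O(1)):
##   pco2                 atmospheric pCO2 (ppm)
##   dic_s, ta_s, si_s    surface box (mol m^-3 / mol-eq m^-3)
##   dic_d, ta_d, si_d    deep box
##   i_atm, i_s, i_d      delta-mass isotope tracers (value * d13C)
##   c_in, c_out          cumulative carbon input/output (mol), for the
##   si_in, si_out        conservation diagnostics; silicon likewise
##
## Fluxes are evaluated in Tmol yr^-1 and converted to mol yr^-1 (1e12).

STATE_NAMES <- c(
  "pco2", "dic_s", "ta_s", "si_s", "dic_d", "ta_d", "si_d",
  "i_atm", "i_s", "i_d", "c_in", "c_out", "si_in", "si_out"
)

#' Extinction scenario description
#'
#' Timing and forcing of the three-phase mass-extinction experiment: carbon
#' release begins at `t_onset` together with the extinction initiation ramp
#' (linear, `initiation_duration`), followed by the full-extinction interval
#' (`full_duration`, biogenic deposition suppressed) and a linear recovery
#' (`recovery_duration`). The volcanic pulse is a boxcar of `carbon_mass` Pg C
#' spread over `release_duration` years on top of background degassing.
#' Extinction-interval overrides of the clay-law parameters (`ext_o`,
#' `ext_r_si`, `ext_r_h`, `ext_alk_si`), of the biogenic silica constant
#' (`ext_k_bsi`) and of biogenic carbonate export (`ext_carb_factor`) are
#' phased in linearly with the extinction ramps.
#'
#' @param t_onset Model time of release/extinction onset (yr).
#' @param initiation_duration,full_duration,recovery_duration Phase lengths (yr).
#' @param carbon_mass Released carbon (Pg C).
#' @param release_duration Length of the release boxcar (yr).
#' @param release_d13c delta-13C of released carbon (per mil).
#' @param ext_o,ext_r_si,ext_r_h,ext_alk_si Full-extinction clay-law values.
#' @param ext_k_bsi Full-extinction biogenic silica proportionality constant.
#' @param ext_carb_factor Full-extinction biogenic carbonate export factor.
#' @return List of class `frw_scenario`.
#' @export
extinction_scenario <- function(t_onset = 5e6,
                                initiation_duration = 1e5,
                                full_duration = 5e6,
                                recovery_duration = 2e6,
                                carbon_mass = 42500,
                                release_duration = 1.5e5,
                                release_d13c = -15,
                                ext_o = 1,
                                ext_r_si = 1,
                                ext_r_h = 1,
                                ext_alk_si = 2,
                                ext_k_bsi = 0,
                                ext_carb_factor = 0) {
  s <- as.list(environment())
  stopifnot(
    s$initiation_duration > 0, s$full_duration > 0, s$recovery_duration > 0,
    s$release_duration > 0, s$carbon_mass >= 0,
    s$ext_carb_factor >= 0, s$ext_carb_factor <= 1
  )
  class(s) <- "frw_scenario"
  s
}

#' Extinction phase factor
#'
#' Scales biogenic deposition between background (1) and full extinction (0):
#' 1 before onset, linear ramp to 0 over the initiation phase, 0 through the
#' full-extinction interval, linear ramp back to 1 over the recovery phase.
#'
#' @param t Model time (yr), vectorised.
#' @param s Scenario from [extinction_scenario()].
#' @return Factor in `[0, 1]`.
#' @export
phase_factor <- function(t, s) {
  t1 <- s$t_onset
  t2 <- t1 + s$initiation_duration
  t3 <- t2 + s$full_duration
  t4 <- t3 + s$recovery_duration
  out <- rep(1, length(t))
  ramp_down <- t >= t1 & t < t2
  out[ramp_down] <- 1 - (t[ramp_down] - t1) / s$initiation_duration
  out[t >= t2 & t < t3] <- 0
  ramp_up <- t >= t3 & t < t4
  out[ramp_up] <- (t[ramp_up] - t3) / s$recovery_duration
  out
}

#' Solid-Earth carbon degassing rate
#'
#' Background volcanic degassing plus a boxcar pulse of height
#' `carbon_mass / release_duration` (converted at 1 Pg C = 83.33 Tmol C)
#' during the release interval.
#'
#' @param t Model time (yr), vectorised.
#' @param s Scenario.
#' @param f_vc_background Background degassing (Tmol C yr^-1).
#' @return Total degassing (Tmol C yr^-1).
#' @export
degassing_rate <- function(t, s, f_vc_background = 5) {
  pulse <- s$carbon_mass * UNITS$tmol_per_pg_c / s$release_duration
  f_vc_background +
    ifelse(t >= s$t_onset & t < s$t_onset + s$release_duration, pulse, 0)
}

## Fast Newton solve for [H+] (mol kg^-1) from DIC/TA (mol kg^-1), warm start.
solve_h_fast <- function(dic_kg, ta_kg, cn, h0 = 1e-8, borate = TRUE) {
  h <- if (is.null(h0)) 1e-8 else h0
  for (i in 1:50) {
    den <- h * h + cn$k1 * h + cn$k1 * cn$k2
    carb <- dic_kg * cn$k1 * (h + 2 * cn$k2) / den
    bor <- if (borate) cn$bt * cn$kb / (cn$kb + h) else 0
    f <- carb + bor + cn$kw / h - h - ta_kg
    if (abs(f) < 1e-12 * ta_kg) return(h)
    dcarb <- dic_kg * cn$k1 * (den - (h + 2 * cn$k2) * (2 * h + cn$k1)) / den^2
    dbor <- if (borate) -cn$bt * cn$kb / (cn$kb + h)^2 else 0
    df <- dcarb + dbor - cn$kw / h^2 - 1
    hn <- h - f / df
    if (!is.finite(hn) || hn <= 1e-13 || hn > 1e-1) break
    h <- hn
  }
  ## robust fallback
  f2 <- function(hh) alk_of_h(hh, dic_kg, cn, borate = borate) - ta_kg
  lo <- 1e-14
  hi <- 1
  if (f2(lo) * f2(hi) > 0) {
    stop(sprintf(
      "carbonate chemistry out of range: no [H+] root for dic=%g, ta=%g mol/kg",
      dic_kg, ta_kg
    ))
  }
  stats::uniroot(f2, c(lo, hi), tol = 1e-20)$root
}

## Evaluate every flux and state derivative at (t, y).
## Returns list(deriv = named vector, fluxes = named list of Tmol yr^-1 values
## plus diagnostics). `cache` is an environment holding warm-start [H+].
## The flux arithmetic here is inlined (no calls into the exported flux-law
## wrappers) for integrator speed; test-simulator.R asserts that the two
## evaluation routes agree.
model_step <- function(t, y, p, scen, dynamic_rw, frozen, cache) {
  g <- cache$g
  if (is.null(g)) g <- cache$g <- geometry(p)
  pco2 <- max(y[["pco2"]], 1e-3)
  si_s <- max(y[["si_s"]], 1e-9)
  si_d <- max(y[["si_d"]], 1e-9)
  d13_atm <- y[["i_atm"]] / pco2
  d13_s <- y[["i_s"]] / y[["dic_s"]]
  d13_d <- y[["i_d"]] / y[["dic_d"]]

  phi <- phase_factor(t, scen)
  o_t <- phi * p$rw_offset_o + (1 - phi) * scen$ext_o
  r_si_t <- phi * p$r_si + (1 - phi) * scen$ext_r_si
  r_h_t <- phi * p$r_h + (1 - phi) * scen$ext_r_h
  alk_si_t <- phi * p$alk_si + (1 - phi) * scen$ext_alk_si
  k_bsi_t <- phi * p$k_bsi + (1 - phi) * scen$ext_k_bsi
  carb_fac <- phi + (1 - phi) * scen$ext_carb_factor

  ## temperatures and carbonate chemistry
  t_s <- p$t_surface_ref + p$climate_sensitivity * log2(pco2 / p$pco2c)
  t_s <- min(max(t_s, 0.5), 59.5)
  t_d <- min(max(t_s - p$t_deep_offset, 2), 59.5)
  cn_s <- carbonate_constants(t_s, p$salinity)
  cn_d <- carbonate_constants(t_d, p$salinity)
  h_s <- solve_h_fast(y[["dic_s"]] / RHO_SW, y[["ta_s"]] / RHO_SW, cn_s,
    h0 = cache$h_s, borate = p$borate
  )
  h_d <- solve_h_fast(y[["dic_d"]] / RHO_SW, y[["ta_d"]] / RHO_SW, cn_d,
    h0 = cache$h_d, borate = p$borate
  )
  cache$h_s <- h_s
  cache$h_d <- h_d
  spec_s <- speciate_from_h(h_s, y[["dic_s"]], t_s, p$salinity, p$calcium, cn_s)
  spec_d <- speciate_from_h(h_d, y[["dic_d"]], t_d, p$salinity, p$calcium, cn_d)

  ## --- carbon fluxes (Tmol yr^-1) ------------------------------------------
  f_degas <- p$f_vc +
    (if (t >= scen$t_onset && t < scen$t_onset + scen$release_duration) {
      scen$carbon_mass * UNITS$tmol_per_pg_c / scen$release_duration
    } else 0)
  f_pulse <- f_degas - p$f_vc
  f_silw <- p$f_vc * (pco2 / p$pco2c)^p$n_si
  f_q <- p$quartz_fraction * f_silw
  f_carbw <- p$f_carbw0 * (pco2 / p$pco2c)^p$n_carb
  f_cb_bio <- p$b_carb * carb_fac
  f_cb_inorg <- p$k_inorg_carb * max(spec_s$omega_calcite - 1, 0)^p$n_inorg_carb
  f_cb <- f_cb_bio + f_cb_inorg
  airsea <- p$piston_velocity * g$area * cn_s$k0 * RHO_SW * 1e-6 *
    (pco2 - spec_s$pco2)

  ## --- silica fluxes --------------------------------------------------------
  si_um <- si_s * 1000
  p_bsi <- k_bsi_t * p$vmax * si_um / (p$km + si_um) # mol/yr
  u_s <- max(0, 1 - si_s / p$sigma_sol)
  u_d <- max(0, 1 - si_d / p$sigma_sol)
  d_s <- p_bsi * u_s^p$rho_surface_deep
  e_sd <- p_bsi - d_s
  d_d <- e_sd * u_d^p$rho_surface_deep
  f_sed <- e_sd - d_d
  d_sed <- f_sed * u_d^p$rho_sediment
  bsi_burial <- f_sed - d_sed
  f_sed_t <- f_sed / 1e12

  alpha <- p$f_vc + p$f_hyd + p$f_dust + p$f_mssw + p$f_gw
  beta_alpha <- f_sed_t * p$rw_bsi_ratio + alpha
  if (dynamic_rw) {
    if (p$rw_box == "deep") {
      si_rw <- si_d
      h_rw <- h_d * RHO_SW
    } else {
      si_rw <- si_s
      h_rw <- h_s * RHO_SW
    }
    omega <- (si_rw^r_si_t / h_rw^r_h_t) / (p$si_o^r_si_t / p$h_o^r_h_t)
    f_rw <- beta_alpha * max(0, omega - o_t)
    alk_cons <- alk_si_t * f_rw
  } else {
    f_rw <- frozen$f_rw
    alk_cons <- frozen$alk_cons
  }
  f_isi <- beta_alpha * max(0, si_s / p$isi_threshold - 1)^p$isi_exponent

  ## --- isotope flux deltas --------------------------------------------------
  d13_org <- d13_s + p$eps_org * (1 + d13_s / 1000)
  as13 <- air_sea_13c_exchange(d13_atm, d13_s, spec_s, pco2,
    p$piston_velocity, g$area
  )

  ## --- mass balances (mol yr^-1) -------------------------------------------
  T <- 1e12
  datm <- (f_degas + p$f_orgb - 2 * f_silw - f_carbw) * T - airsea
  ddic_s <- airsea + (2 * f_silw + 2 * f_carbw - f_cb - p$f_pump) * T +
    p$mixing_rate * (y[["dic_d"]] - y[["dic_s"]])
  dta_s <- (2 * f_silw + 2 * f_carbw - 2 * f_cb) * T +
    p$mixing_rate * (y[["ta_d"]] - y[["ta_s"]]) -
    (if (p$rw_box == "surface") alk_cons * T else 0)
  dsi_s <- (f_silw + f_q + p$f_dust - f_isi) * T - e_sd +
    p$mixing_rate * (si_d - si_s)
  ddic_d <- (p$f_pump - p$f_orgb) * T +
    p$mixing_rate * (y[["dic_s"]] - y[["dic_d"]])
  dta_d <- p$mixing_rate * (y[["ta_s"]] - y[["ta_d"]]) -
    (if (p$rw_box == "deep") alk_cons * T else 0)
  dsi_d <- (p$f_hyd + p$f_gw + p$f_mssw - f_rw) * T + d_d + d_sed +
    p$mixing_rate * (si_s - si_d)

  di_atm <- (p$f_vc * p$d13c_volc + f_pulse * scen$release_d13c +
    p$f_orgb * p$d13c_orgw -
    (2 * f_silw + f_carbw) * d13_atm) * T - as13$net13
  di_s <- as13$net13 + (2 * f_silw * d13_atm +
    f_carbw * (d13_atm + p$d13c_carbw) -
    f_cb * d13_s - p$f_pump * d13_org) * T +
    p$mixing_rate * (y[["dic_d"]] * d13_d - y[["dic_s"]] * d13_s)
  di_d <- (p$f_pump - p$f_orgb) * T * d13_org +
    p$mixing_rate * (y[["dic_s"]] * d13_s - y[["dic_d"]] * d13_d)

  deriv <- c(
    datm / UNITS$mol_per_ppm,
    ddic_s / g$v_surface, dta_s / g$v_surface, dsi_s / g$v_surface,
    ddic_d / g$v_deep, dta_d / g$v_deep, dsi_d / g$v_deep,
    di_atm / UNITS$mol_per_ppm,
    di_s / g$v_surface, di_d / g$v_deep,
    (f_degas + p$f_orgb + f_carbw) * T,      # carbon inputs
    (f_cb + p$f_orgb) * T,                   # carbon outputs
    (f_silw + f_q + p$f_dust + p$f_hyd + p$f_gw + p$f_mssw) * T,
    (f_rw + f_isi) * T + bsi_burial
  )
  names(deriv) <- STATE_NAMES

  fluxes <- list(
    phi = phi, degassing = f_degas, f_silw = f_silw, f_quartz = f_q,
    f_carbw = f_carbw, f_cb = f_cb, f_cb_bio = f_cb_bio,
    f_cb_inorg = f_cb_inorg,
    f_bsi_prod = p_bsi / 1e12, f_bsi_export = e_sd / 1e12,
    f_bsi_sed = f_sed_t, f_bsi_burial = bsi_burial / 1e12,
    f_rw = f_rw, f_isi = f_isi, alk_cons = alk_cons,
    omega_calcite_s = spec_s$omega_calcite,
    ph_s = spec_s$ph, ph_d = spec_d$ph,
    t_surface = t_s, d13c_s = d13_s, d13c_atm = d13_atm,
    alk_si_t = alk_si_t, o_t = o_t
  )
  list(deriv = deriv, fluxes = fluxes)
}

## deSolve-facing RHS.
rhs_ode <- function(t, y, parms) {
  st <- model_step(
    t, y, parms$p, parms$scen, parms$dynamic_rw, parms$frozen, parms$cache
  )
  list(st$deriv)
}

## A do-nothing scenario for spin-up (phase factor 1, no pulse everywhere).
quiet_scenario <- function() {
  extinction_scenario(t_onset = 1e18, carbon_mass = 0)
}

default_state0 <- function(p) {
  y0 <- c(
    pco2 = p$pco2c * 1.5, dic_s = 1.9, ta_s = 2.1, si_s = 0.1,
    dic_d = 2.1, ta_d = 2.1, si_d = 0.15,
    i_atm = 0, i_s = 0, i_d = 0, c_in = 0, c_out = 0, si_in = 0, si_out = 0
  )
  y0
}

ode_tols <- function() {
  atol <- c(
    pco2 = 1e-5, dic_s = 1e-8, ta_s = 1e-8, si_s = 1e-9,
    dic_d = 1e-8, ta_d = 1e-8, si_d = 1e-9,
    i_atm = 1e-4, i_s = 1e-7, i_d = 1e-7,
    c_in = 1, c_out = 1, si_in = 1, si_out = 1
  )
  list(rtol = 1e-8, atol = atol)
}

#' Spin the model up to an unforced steady state
#'
#' Integrates the coupled system under constant forcing until the largest
#' relative tracer drift over 1e4 years falls below `tol` (default 1e-6). In
#' `"permian"` mode the converged state is accepted only if the equilibrium
#' pCO2 lies within `pco2_window` (default 300-1000 ppm); callers running
#' Monte Carlo ensembles redraw parameters when `accepted` is `FALSE`.
#'
#' @param p Parameter set from [default_params()].
#' @param tol Relative drift tolerance per 1e4 yr.
#' @param max_time Maximum spin-up time (yr) before flagging non-convergence.
#' @param pco2_window Acceptance window (ppm) applied in permian mode.
#' @return Object of class `frw_state`: the steady state vector `y`, the
#'   equilibrium `pco2`, a `fluxes` snapshot, the background carbon residence
#'   time `residence_bg` (yr), `accepted` and `converged` flags, and the final
#'   relative `drift`.
#' @export
spin_up <- function(p, tol = 1e-6, max_time = 4e8,
                    pco2_window = c(300, 1000)) {
  scen <- quiet_scenario()
  cache <- new.env(parent = emptyenv())
  cache$h_s <- 1e-8
  cache$h_d <- 1e-8
  parms <- list(p = p, scen = scen, dynamic_rw = TRUE, frozen = NULL,
                cache = cache)
  tl <- ode_tols()
  core <- STATE_NAMES[1:10]
  drift_of <- function(y) {
    d <- model_step(0, y, p, scen, TRUE, NULL, cache)$deriv
    max(abs(d[core]) * 1e4 / pmax(abs(y[core]), 1e-6))
  }

  ## damped Newton on the 10 core tendencies; fast path for ensemble redraws
  newton_polish <- function(y) {
    resid <- function(yc) {
      yy <- y
      yy[core] <- yc
      model_step(0, yy, p, scen, TRUE, NULL, cache)$deriv[core]
    }
    yc <- y[core]
    f <- resid(yc)
    scale <- pmax(abs(yc), 1e-4)
    for (it in 1:40) {
      if (any(!is.finite(f))) return(NULL)
      if (max(abs(f) * 1e4 / scale) < tol / 10) {
        y[core] <- yc
        return(y)
      }
      jac <- matrix(0, 10, 10)
      for (j in 1:10) {
        dy <- pmax(abs(yc[j]), 1e-4) * 1e-7
        yp <- yc
        yp[j] <- yc[j] + dy
        jac[, j] <- (resid(yp) - f) / dy
      }
      step <- tryCatch(solve(jac, -f), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      lam <- 1
      repeat {
        yn <- yc + lam * step
        if (all(yn[1:7] > 0)) {
          fn <- tryCatch(resid(yn), error = function(e) rep(NaN, 10))
          if (all(is.finite(fn)) && max(abs(fn) / scale) <=
            max(abs(f) / scale)) break
        }
        lam <- lam / 2
        if (lam < 1e-4) return(NULL)
      }
      yc <- yn
      f <- fn
      scale <- pmax(abs(yc), 1e-4)
    }
    NULL
  }

  ## the transient approach only needs to land in the Newton basin, so it is
  ## integrated at relaxed tolerance; the steady state itself is pinned by the
  ## Newton polish and the drift criterion, not by the ODE error control
  y <- default_state0(p)
  t_now <- 0
  window <- 2e6
  converged <- FALSE
  drift <- Inf
  chem_failed <- FALSE
  tryCatch(
    while (t_now < max_time) {
      sol <- deSolve::lsoda(y, c(t_now, t_now + window), rhs_ode, parms,
        rtol = 1e-5, atol = tl$atol * 1e3, maxsteps = 100000
      )
      y <- sol[nrow(sol), 1 + seq_along(y)]
      names(y) <- STATE_NAMES
      t_now <- t_now + window
      window <- min(window * 2, 5e7)
      drift <- drift_of(y)
      if (drift < tol) {
        converged <- TRUE
        break
      }
      if (drift < 1e2) { # close enough for Newton to take over
        yn <- newton_polish(y)
        if (!is.null(yn)) {
          y <- yn
          drift <- drift_of(y)
          if (drift < tol) {
            converged <- TRUE
            break
          }
        }
      }
    },
    error = function(e) {
      ## runaway chemistry (e.g. alkalinity driven negative by extreme clay
      ## parameters): the configuration is reported as a failed, rejected
      ## spin-up rather than an exception
      chem_failed <<- TRUE
    }
  )
  if (chem_failed) {
    out <- list(
      y = y, p = p, pco2 = NA_real_, fluxes = NULL, residence_bg = NA_real_,
      accepted = FALSE, converged = FALSE, drift = Inf
    )
    class(out) <- "frw_state"
    warning("spin-up abandoned: carbonate chemistry left the physical range")
    return(out)
  }
  y[c("c_in", "c_out", "si_in", "si_out")] <- 0
  st <- model_step(t_now, y, p, scen, TRUE, NULL, cache)
  fl <- st$fluxes
  g <- geometry(p)
  total_c <- y[["pco2"]] * UNITS$mol_per_ppm +
    y[["dic_s"]] * g$v_surface + y[["dic_d"]] * g$v_deep
  residence_bg <- total_c / ((fl$f_cb + p$f_orgb) * 1e12)
  accepted <- converged &&
    (p$mode != "permian" ||
      (y[["pco2"]] >= pco2_window[1] && y[["pco2"]] <= pco2_window[2]))
  if (!converged) {
    warning(sprintf(
      "spin-up did not converge within %g yr (relative drift %.3g per 1e4 yr)",
      max_time, drift
    ))
  }
  out <- list(
    y = y, p = p, pco2 = unname(y[["pco2"]]), fluxes = fl,
    residence_bg = unname(residence_bg),
    accepted = accepted, converged = converged, drift = unname(drift)
  )
  class(out) <- "frw_state"
  out
}

#' @export
print.frw_state <- function(x, ...) {
  if (is.null(x$fluxes)) {
    cat("<frw_state> failed spin-up (not converged)\n")
  } else {
    cat(sprintf(
      "<frw_state> pCO2 %.1f ppm, F_rw %.2f, F_bSi_sed %.2f Tmol/yr, accepted=%s\n",
      x$pco2, x$fluxes$f_rw, x$fluxes$f_bsi_sed, x$accepted
    ))
  }
  invisible(x)
}

## Output time grid: coarse before onset, fine across onset, then regular.
scenario_times <- function(scen, t_end) {
  t1 <- scen$t_onset
  fine_end <- min(t1 + 6e5, t_end)
  tt <- c(
    seq(0, min(t1, t_end), by = 1e5),
    if (t1 < t_end) seq(t1, fine_end, by = 5e3),
    if (fine_end < t_end) seq(fine_end, t_end, by = 2.5e4),
    t_end
  )
  sort(unique(pmin(tt, t_end)))
}

#' Run a forced extinction scenario
#'
#' Integrates the coupled system from a spun-up background state through the
#' carbon release and extinction phases. With `dynamic_rw = TRUE` the
#' authigenic clay flux responds to evolving silica and pH (and the
#' extinction-interval clay-law overrides are phased in); with
#' `dynamic_rw = FALSE` the clay flux and its alkalinity consumption are
#' frozen at their spin-up values.
#'
#' @param state0 Background state from [spin_up()].
#' @param scenario Scenario from [extinction_scenario()].
#' @param p Parameter set (defaults to the one stored in `state0`).
#' @param dynamic_rw Logical: dynamic (TRUE) or frozen (FALSE) clay formation.
#' @param t_end End of integration (yr); default runs 5 Myr past the recovery.
#' @return Object of class `frw_run`: `times`, a `states` data frame, a
#'   `fluxes` data frame, `temp_anomaly` (deg C relative to the background),
#'   `f_rw_ma`, `residence_norm`, `spinup_pco2`, `accepted_spinup`, and a
#'   `conservation` list with the relative carbon/silicon closure errors.
#' @export
run_scenario <- function(state0, scenario, p = state0$p, dynamic_rw = TRUE,
                         t_end = NULL) {
  stopifnot(inherits(state0, "frw_state"), inherits(scenario, "frw_scenario"))
  if (is.null(t_end)) {
    t_end <- scenario$t_onset + scenario$initiation_duration +
      scenario$full_duration + scenario$recovery_duration + 5e6
  }
  frozen <- list(
    f_rw = state0$fluxes$f_rw,
    alk_cons = state0$fluxes$alk_cons
  )
  cache <- new.env(parent = emptyenv())
  cache$h_s <- 1e-8
  cache$h_d <- 1e-8
  parms <- list(p = p, scen = scenario, dynamic_rw = dynamic_rw,
                frozen = frozen, cache = cache)
  tl <- ode_tols()
  times <- scenario_times(scenario, t_end)

  ## integrate piecewise between forcing breakpoints so lsoda never steps
  ## across a discontinuity
  brk <- with(scenario, c(
    t_onset, t_onset + release_duration, t_onset + initiation_duration,
    t_onset + initiation_duration + full_duration,
    t_onset + initiation_duration + full_duration + recovery_duration
  ))
  brk <- sort(unique(brk[brk > 0 & brk < t_end]))
  edges <- c(0, brk, t_end)
  y <- state0$y
  y[c("c_in", "c_out", "si_in", "si_out")] <- 0
  rows <- list()
  for (i in seq_len(length(edges) - 1)) {
    seg <- sort(unique(c(
      edges[i], times[times > edges[i] & times < edges[i + 1]], edges[i + 1]
    )))
    ## integrate the segment, resuming (a bounded number of times) if the
    ## step limit is hit before the segment end: sharp threshold crossings
    ## (opal saturation, abiotic-silica onset) can transiently force very
    ## small steps
    seg_rows <- list()
    attempt <- 0
    repeat {
      sol <- suppressWarnings(deSolve::lsoda(y, seg, rhs_ode, parms,
        rtol = tl$rtol, atol = tl$atol, maxsteps = 25000, hmax = 1e5
      ))
      reached <- sol[nrow(sol), 1]
      done <- attr(sol, "istate")[1] >= 0 ||
        reached >= seg[length(seg)] - 1e-9
      keep_rows <- sol[sol[, 1] < reached, , drop = FALSE]
      seg_rows[[length(seg_rows) + 1]] <- keep_rows
      y <- sol[nrow(sol), 1 + seq_along(y)]
      names(y) <- STATE_NAMES
      if (done) break
      attempt <- attempt + 1
      if (attempt > 8 || nrow(sol) < 2) {
        stop(sprintf(
          "integrator failure in segment [%g, %g] near t=%g; last state: %s",
          edges[i], edges[i + 1], reached,
          paste(sprintf("%s=%.4g", STATE_NAMES, y), collapse = ", ")
        ))
      }
      seg <- c(reached, seg[seg > reached])
    }
    rows[[i]] <- do.call(rbind, seg_rows)
    names(y) <- STATE_NAMES
  }
  out <- rbind(do.call(rbind, rows), c(t_end, y))
  colnames(out) <- c("time", STATE_NAMES)
  states <- as.data.frame(out)

  ## diagnostics per output row
  smat <- as.matrix(states[, STATE_NAMES])
  fx <- lapply(seq_len(nrow(smat)), function(i) {
    yi <- smat[i, ]
    unlist(model_step(states$time[i], yi, p, scenario, dynamic_rw, frozen,
                      cache)$fluxes)
  })
  fluxes <- as.data.frame(do.call(rbind, fx))
  fluxes$time <- states$time

  g <- geometry(p)
  total_c <- states$pco2 * UNITS$mol_per_ppm +
    states$dic_s * g$v_surface + states$dic_d * g$v_deep
  total_si <- states$si_s * g$v_surface + states$si_d * g$v_deep
  res <- total_c / ((fluxes$f_cb + p$f_orgb) * 1e12) / state0$residence_bg
  removal <- fluxes$f_rw + fluxes$f_bsi_burial + fluxes$f_isi
  f_rw_ma <- ifelse(removal > 0, fluxes$f_rw / removal, NA_real_)

  cons_c <- (total_c - total_c[1]) - (states$c_in - states$c_out)
  cons_si <- (total_si - total_si[1]) - (states$si_in - states$si_out)
  conservation <- list(
    carbon_rel = max(abs(cons_c)) / total_c[1],
    silicon_rel = max(abs(cons_si)) / total_si[1]
  )

  run <- list(
    times = states$time,
    states = states,
    fluxes = fluxes,
    temp_anomaly = temperature_anomaly(
      states$pco2, state0$pco2, p$climate_sensitivity
    ),
    f_rw_ma = f_rw_ma,
    residence_norm = res,
    spinup_pco2 = state0$pco2,
    accepted_spinup = state0$accepted,
    dynamic_rw = dynamic_rw,
    scenario = scenario,
    p = p,
    conservation = conservation
  )
  class(run) <- "frw_run"
  run
}

#' @export
print.frw_run <- function(x, ...) {
  cat(sprintf(
    "<frw_run> %d samples over %.1f Myr, %s clay formation\n",
    length(x$times), max(x$times) / 1e6,
    if (x$dynamic_rw) "dynamic" else "frozen"
  ))
  cat(sprintf(
    "  peak warming %.1f C, peak f_rw_ma %.2f, peak residence x%.1f\n",
    max(x$temp_anomaly), max(x$f_rw_ma, na.rm = TRUE), max(x$residence_norm)
  ))
  invisible(x)
}

#' Authigenic fraction of total silica removal
#'
#' `f_rw_ma = F_rw / (F_rw + F_bSi_burial + F_iSi)`: the share of total silica
#' removal sequestered as authigenic clay.
#'
#' @param f_rw,f_bsi_burial,f_isi Removal fluxes (same units), vectorised.
#' @return Ratio in `[0, 1]`; `NA` where all removal fluxes are zero.
#' @export
f_rw_ma <- function(f_rw, f_bsi_burial, f_isi) {
  stopifnot(all(f_rw >= 0), all(f_bsi_burial >= 0), all(f_isi >= 0))
  tot <- f_rw + f_bsi_burial + f_isi
  ifelse(tot > 0, f_rw / tot, NA_real_)
}

#' Normalised ocean-atmosphere carbon residence time
#'
#' Reservoir size over total carbon burial flux, normalised to the background
#' (pre-event) value.
#'
#' @param total_carbon Ocean + atmosphere carbon (mol).
#' @param burial_flux Total carbon burial (mol yr^-1).
#' @param background_value Background residence time (yr).
#' @return Dimensionless fold-change; `NA` where burial is zero.
#' @export
residence_time_norm <- function(total_carbon, burial_flux, background_value) {
  stopifnot(background_value > 0)
  ifelse(burial_flux > 0, total_carbon / burial_flux / background_value,
    NA_real_
  )
}

#' Duration of sustained warming in a run
#'
#' Total model time (yr) after scenario onset during which the temperature
#' anomaly meets or exceeds `threshold`; the plateau-length diagnostic used to
#' contrast frozen- and dynamic-clay runs.
#'
#' @param run A `frw_run`.
#' @param threshold Anomaly threshold (deg C).
#' @return Duration in years.
#' @export
warm_duration <- function(run, threshold = 8) {
  t <- run$times
  keep <- t >= run$scenario$t_onset
  t <- t[keep]
  warm <- run$temp_anomaly[keep] >= threshold
  if (length(t) < 2) return(0)
  dt <- diff(t)
  sum(dt * (warm[-length(warm)] & warm[-1]))
}
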