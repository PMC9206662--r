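# Scenario machinery, spin-up, conservation, and the contrast between
# frozen and dynamic clay formation.

test_that("phase factor ramps linearly through the three extinction phases", {
  s <- extinction_scenario(
    t_onset = 5e6, initiation_duration = 1e5,
    full_duration = 4e6, recovery_duration = 2e6
  )
  expect_equal(phase_factor(c(0, 1e6, 4.99e6), s), rep(1, 3))
  expect_equal(phase_factor(5e6 + 5e4, s), 0.5)
  expect_equal(phase_factor(c(5.1e6, 7e6, 9.09e6), s), rep(0, 3))
  expect_equal(phase_factor(9.1e6 + 1e6, s), 0.5)
  expect_equal(phase_factor(12e6, s), 1)
})

test_that("degassing converts released mass correctly and conserves it", {
  s <- extinction_scenario(carbon_mass = 48000, release_duration = 1e5)
  # 48,000 Pg over 1e5 yr at 83.33 Tmol/Pg -> 40 Tmol/yr above background
  expect_equal(degassing_rate(5e6 + 5e4, s, 5), 5 + 40, tolerance = 1e-4)
  expect_equal(degassing_rate(4.9e6, s, 5), 5)
  expect_equal(degassing_rate(5.2e6, s, 5), 5)
  tt <- seq(0, 2e7, by = 50) # resolves the boxcar
  excess <- sum(degassing_rate(tt, s, 5) - 5) * 50 # Tmol
  expect_equal(excess / UNITS$tmol_per_pg_c, 48000, tolerance = 1e-3)
})

test_that("the integrator's inlined flux arithmetic matches the public
           flux laws", {
  p <- default_params("permian")
  st <- cached_spinup("permian")
  cache <- new.env()
  ms <- siclimate:::model_step(0, st$y, p, siclimate:::quiet_scenario(),
                               TRUE, NULL, cache)$fluxes
  expect_equal(ms$f_silw, silicate_weathering(st$y[["pco2"]], p))
  expect_equal(ms$f_quartz, quartz_weathering(ms$f_silw, p$quartz_fraction))
  expect_equal(ms$f_carbw, carbonate_weathering(st$y[["pco2"]], p))
  expect_equal(ms$f_bsi_prod * 1e12, bsi_production(st$y[["si_s"]], p))
  spec_d <- solve_carbonate_system(
    st$y[["dic_d"]], st$y[["ta_d"]],
    max(ms$t_surface - p$t_deep_offset, 2), p$salinity
  )
  expect_equal(
    ms$f_rw,
    reverse_weathering(st$y[["si_d"]], spec_d$h_conc, ms$f_bsi_sed, p),
    tolerance = 1e-9
  )
  expect_equal(ms$f_isi, inorganic_si(st$y[["si_s"]], ms$f_bsi_sed, p))
})

test_that("spin-up reaches a genuine steady state (further integration
           leaves tracers unchanged)", {
  st <- cached_spinup("permian")
  expect_true(st$converged)
  expect_lt(st$drift, 1e-6)
  # integrate 1 Myr beyond the detected steady state
  run <- run_scenario(st, siclimate:::quiet_scenario(), t_end = 1e6)
  core <- siclimate:::STATE_NAMES[1:7]
  for (v in core) {
    expect_lt(
      max(abs(run$states[[v]] - st$y[[v]])) / abs(st$y[[v]]), 1e-6
    )
  }
  # d13C tendencies also vanish at the unforced steady state
  expect_lt(diff(range(run$fluxes$d13c_s)), 1e-4)
})

test_that("permian spin-ups outside the 300-1000 ppm window are flagged for
           redraw", {
  st <- spin_up(update_params(default_params("permian"), alk_si = 2,
                              k_bsi = 1e12))
  expect_false(st$accepted)
  expect_gt(st$pco2, 1000)
  expect_true(cached_spinup("permian")$accepted)
})

test_that("a zero-perturbation scenario reproduces the steady state for
           all time", {
  st <- cached_spinup("permian")
  p <- st$p
  quiet <- extinction_scenario(
    t_onset = 2e6, carbon_mass = 0,
    ext_o = p$rw_offset_o, ext_r_si = p$r_si, ext_r_h = p$r_h,
    ext_alk_si = p$alk_si, ext_k_bsi = p$k_bsi, ext_carb_factor = 1
  )
  run <- run_scenario(st, quiet, t_end = 8e6)
  expect_lt(max(abs(run$temp_anomaly)), 1e-3)
  expect_lt(max(abs(run$states$pco2 - st$pco2)) / st$pco2, 1e-5)
})

test_that("carbon and silicon are conserved through a forced run", {
  r2 <- cached_run(TRUE)
  expect_lt(r2$conservation$carbon_rel, 1e-6)
  expect_lt(r2$conservation$silicon_rel, 1e-6)
  r1 <- cached_run(FALSE)
  expect_lt(r1$conservation$carbon_rel, 1e-6)
  expect_lt(r1$conservation$silicon_rel, 1e-6)
})

test_that("with frozen clay formation the warming is transient, while
           dynamic clay formation sustains a multi-Myr plateau", {
  r1 <- cached_run(FALSE)
  r2 <- cached_run(TRUE)
  # identical volcanic forcing
  expect_equal(r1$scenario$carbon_mass, r2$scenario$carbon_mass)
  # frozen: peak warming decays on the silicate-weathering timescale
  peak_t1 <- r1$times[which.max(r1$temp_anomaly)]
  after <- r1$times >= peak_t1 + 2e6
  expect_lt(max(r1$temp_anomaly[after]), 0.25 * max(r1$temp_anomaly))
  expect_lt(warm_duration(r1, 8), 1e6)
  # dynamic: plateau of at least 4 Myr above +8 C
  expect_gt(warm_duration(r2, 8), 4e6)
  expect_gt(warm_duration(r2, 8), 4 * max(warm_duration(r1, 8), 1))
})

test_that("surface dissolved silica rises quickly after extinction onset and
           clay and abiotic silica fluxes rise to a new plateau", {
  r2 <- cached_run(TRUE)
  onset <- r2$scenario$t_onset
  si0 <- r2$states$si_s[r2$times == onset]
  risen <- r2$times[r2$states$si_s > si0 * 1.5 & r2$times > onset]
  expect_lt(min(risen) - onset, 1e5) # rise initiates well within 1e5 yr
  # plateau values well above background
  plateau <- r2$times > onset + 3e6 & r2$times < onset + 5e6
  pre <- r2$times < onset
  expect_gt(mean(r2$fluxes$f_rw[plateau]), 1.5 * mean(r2$fluxes$f_rw[pre]))
  expect_gt(mean(r2$fluxes$f_isi[plateau]), 1)
  expect_lt(mean(r2$fluxes$f_isi[pre]), 1e-6)
})

test_that("the carbon residence time rises severalfold in the dynamic run
           but not in the frozen run", {
  r2 <- cached_run(TRUE)
  r1 <- cached_run(FALSE)
  onset <- r2$scenario$t_onset
  plateau <- r2$times > onset + 3e6 & r2$times < onset + 5e6
  expect_gt(mean(r2$residence_norm[plateau]), 2)
  expect_lt(mean(r1$residence_norm[r1$times > onset + 3e6 &
                                     r1$times < onset + 5e6]), 1.5)
  # normalisation: background value is 1
  expect_equal(r2$residence_norm[1], 1, tolerance = 1e-3)
})

test_that("f_rw_ma is the authigenic share of total silica removal", {
  expect_equal(f_rw_ma(0, 10, 5), 0)
  expect_equal(f_rw_ma(5, 10, 5), 0.25)
  expect_equal(f_rw_ma(5, 0, 0), 1)
  expect_true(is.na(f_rw_ma(0, 0, 0)))
  r2 <- cached_run(TRUE)
  expect_true(all(r2$f_rw_ma >= 0 & r2$f_rw_ma <= 1, na.rm = TRUE))
})

test_that("residence time normalisation behaves as a ratio of reservoir to
           export", {
  expect_equal(residence_time_norm(100, 10, 10), 1)
  expect_equal(residence_time_norm(200, 10, 10), 2)
  expect_true(is.na(residence_time_norm(100, 0, 10)))
})

test_that("delta-13C records a negative excursion during the release and
           recovers", {
  r2 <- cached_run(TRUE)
  onset <- r2$scenario$t_onset
  pre <- r2$fluxes$d13c_s[r2$times == onset]
  during <- r2$times > onset & r2$times < onset + 3e5
  expect_lt(min(r2$fluxes$d13c_s[during]), pre - 1.5)
  late <- r2$times > onset + 4e6
  expect_gt(mean(r2$fluxes$d13c_s[late]), min(r2$fluxes$d13c_s[during]) + 1)
})
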