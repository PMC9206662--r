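# Seawater carbonate chemistry: solver correctness, oracle agreement,
# air-sea exchange, and the climate law.

test_that("speciation round-trips DIC and TA to 1e-8 relative", {
  set.seed(11)
  for (i in 1:50) {
    dic <- runif(1, 0.8, 4)
    ta <- dic * runif(1, 0.85, 1.3)
    tc <- runif(1, 2, 35)
    s <- solve_carbonate_system(dic, ta, tc, 35)
    expect_equal(s$co2aq + s$hco3 + s$co3, dic, tolerance = 1e-8)
    ta_back <- siclimate:::alk_of_h(
      s$h_conc / siclimate:::RHO_SW, dic / siclimate:::RHO_SW, s$constants
    ) * siclimate:::RHO_SW
    expect_lt(abs(ta_back - ta) / ta, 1e-8)
    expect_equal(s$ph, -log10(s$h_conc / 1000))
    expect_gt(s$omega_calcite, 0)
  }
})

test_that("with borate and water terms disabled, carbonate alkalinity alone
           balances TA", {
  s <- solve_carbonate_system(2, 2, 25, 35, borate = FALSE, water = FALSE)
  expect_equal(s$hco3 + 2 * s$co3, 2, tolerance = 1e-8)
})

test_that("solver agrees with an independent pH bisection oracle", {
  # frozen value computed with bisect_ph_oracle(2.0, 2.3, 25, 35), an
  # interval-halving search written before the Newton solver
  s <- solve_carbonate_system(2.0, 2.3, 25, 35)
  expect_equal(s$ph, bisect_ph_oracle(2.0, 2.3, 25, 35), tolerance = 1e-9)
  expect_equal(s$ph, 8.0301896, tolerance = 1e-6)
})

test_that("solver matches a brute-force pH grid search on random states", {
  set.seed(7)
  ph_grid <- seq(2, 12, length.out = 1e6)
  h_grid <- 10^(-ph_grid) * 1000 / siclimate:::RHO_SW
  for (i in 1:100) {
    dic <- runif(1, 1, 3.5)
    ta <- dic * runif(1, 0.9, 1.25)
    tc <- runif(1, 2, 35)
    cn <- carbonate_constants(tc, 35)
    resid <- abs(siclimate:::alk_of_h(h_grid, dic / siclimate:::RHO_SW, cn) -
      ta / siclimate:::RHO_SW)
    ph_bf <- ph_grid[which.min(resid)]
    s <- solve_carbonate_system(dic, ta, tc, 35)
    expect_lt(abs(s$ph - ph_bf), 2e-5) # grid resolution 1e-5
  }
})

test_that("pH is monotone in TA (rising) and DIC (falling)", {
  tas <- seq(2.0, 2.6, by = 0.1)
  phs <- vapply(tas, function(ta) solve_carbonate_system(2, ta, 20)$ph,
                numeric(1))
  expect_true(all(diff(phs) > 0))
  dics <- seq(1.6, 2.2, by = 0.1)
  phs <- vapply(dics, function(d) solve_carbonate_system(d, 2.4, 20)$ph,
                numeric(1))
  expect_true(all(diff(phs) < 0))
})

test_that("strongly alkaline water becomes carbonate-dominated with
           vanishing CO2(aq)", {
  tas <- c(2.6, 3.0, 3.4, 3.8)
  co2 <- vapply(tas, function(ta) solve_carbonate_system(2, ta, 20)$co2aq,
                numeric(1))
  expect_true(all(diff(co2) < 0))
  s <- solve_carbonate_system(2, 3.9, 20)
  expect_gt(s$co3, s$co2aq * 100)
})

test_that("degenerate chemistry is reported with the offending inputs", {
  expect_error(
    solve_carbonate_system(2, 100, 25),
    "degenerate.*dic=2.*ta=100"
  )
})

test_that("air-sea CO2 flux is zero at equilibrium and linear in the
           disequilibrium", {
  s <- solve_carbonate_system(2, 2.3, 25)
  expect_equal(air_sea_co2_exchange(s$pco2, s), 0)
  f1 <- air_sea_co2_exchange(s$pco2 + 50, s)
  f2 <- air_sea_co2_exchange(s$pco2 + 100, s)
  expect_equal(f2, 2 * f1, tolerance = 1e-12)
  expect_gt(f1, 0) # into the ocean when the atmosphere is supersaturated
})

test_that("air-sea CO2 flux matches the hand-evaluated linear law", {
  s <- solve_carbonate_system(2, 2.3, 25)
  dpco2 <- 100
  f <- air_sea_co2_exchange(s$pco2 + dpco2, s,
    piston_velocity = 3e4, area = 3.61e14
  )
  by_hand <- 3e4 * 3.61e14 * s$constants$k0 * siclimate:::RHO_SW * 1e-6 * 100
  expect_equal(f, by_hand, tolerance = 1e-12)
})

test_that("net 13C air-sea flux vanishes at joint chemical and isotopic
           equilibrium", {
  s <- solve_carbonate_system(2, 2.3, 25)
  eps <- siclimate:::eps_dic_gas(s)
  d_atm <- -6
  # isotopic equilibrium: r_dic = alpha_dic_gas * r_atm
  d_dic <- (1 + d_atm / 1000) * (1 + eps / 1000) * 1000 - 1000
  ex <- air_sea_13c_exchange(d_atm, d_dic, s, pco2_atm = s$pco2)
  expect_equal(ex$net13, 0, tolerance = 1e-8 * ex$invasion)
})

test_that("with fractionation disabled the 13C flux reduces to the carbon
           flux times the isotope ratio", {
  s <- solve_carbonate_system(2, 2.3, 25)
  d <- -6
  ex <- air_sea_13c_exchange(d, d, s, pco2_atm = s$pco2 + 80,
                             fractionation = FALSE)
  net12 <- air_sea_co2_exchange(s$pco2 + 80, s)
  expect_equal(ex$net13, net12 * d, tolerance = 1e-9 * abs(net12 * d))
})

test_that("steady-state surface-minus-atmosphere d13C offset matches the
           closed-form two-reservoir equilibrium", {
  # two reservoirs exchanging only via air-sea: at equilibrium the DIC is
  # offset from the atmosphere by the speciation-weighted eps_DIC-gas(T)
  s <- solve_carbonate_system(2, 2.3, 25)
  eps <- siclimate:::eps_dic_gas(s)
  d_atm <- -7
  offset <- uniroot(function(dd) {
    air_sea_13c_exchange(d_atm, d_atm + dd, s, pco2_atm = s$pco2)$net13
  }, c(0, 15))$root
  expect_equal(offset, eps * (1 + d_atm / 1000), tolerance = 1e-4)
  expect_gt(offset, 7) # ~8 per mil enrichment of DIC at 25 C
  expect_lt(offset, 10)
})

test_that("temperature anomaly follows the doubling law and is additive", {
  expect_equal(temperature_anomaly(280, 280, 3), 0)
  expect_equal(temperature_anomaly(560, 280, 3), 3)
  expect_equal(temperature_anomaly(4 * 140, 140, 2.5), 5)
  s <- 3.7
  a <- temperature_anomaly(500, 280, s)
  b <- temperature_anomaly(1000, 500, s)
  expect_equal(a + b, temperature_anomaly(1000, 280, s), tolerance = 1e-12)
})
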