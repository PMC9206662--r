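# Monte Carlo sampling, the temperature filter, and ensemble summaries.

test_that("parameter sampling is reproducible, in-bounds, and uniform on the
           stated scale", {
  rng <- default_ranges("permian")
  d1 <- sample_parameters(rng, 500, seed = 99)
  d2 <- sample_parameters(rng, 500, seed = 99)
  expect_identical(d1, d2)
  for (key in names(rng)) {
    expect_true(all(d1[[key]] >= rng[[key]]$min & d1[[key]] <= rng[[key]]$max),
                info = key)
  }
  # headline uniformity check at n = 1e4: KS test should not reject
  big <- sample_parameters(rng, 1e4, seed = 3)
  u_lin <- (big$alk_si - 1) / (2 - 1)
  expect_gt(stats::ks.test(u_lin, "punif")$p.value, 0.01)
  u_log <- (log(big$k_bsi) - log(1e10)) / (log(7e13) - log(1e10))
  expect_gt(stats::ks.test(u_log, "punif")$p.value, 0.01)
})

test_that("invalid sampling ranges are rejected by name", {
  rng <- default_ranges()
  rng$alk_si$min <- 10 # min > max
  expect_error(sample_parameters(rng, 5), "alk_si")
  rng <- default_ranges()
  rng$k_bsi$min <- -1 # log scale needs positive bounds
  expect_error(sample_parameters(rng, 5), "k_bsi")
})

test_that("the sampled clay-law offset applies to both spin-up and
           extinction interval", {
  cfg <- siclimate:::draw_to_config(
    list(o = 4.5, n_si = 0.3), default_params("permian"),
    extinction_scenario()
  )
  expect_equal(cfg$p$rw_offset_o, 4.5)
  expect_equal(cfg$scenario$ext_o, 4.5)
  expect_equal(cfg$p$n_si, 0.3)
})

test_that("temperature filter accepts matching runs and rejects offset
           runs", {
  tgt <- make_sst_target()
  tt <- seq(0, 14e6, by = 5e4)
  truth <- approx(tgt$times, tgt$mean_anomaly, xout = tt, rule = 2)$y
  runs <- list(
    fake_run(tt, truth), # identical to target
    fake_run(tt, truth + 5), # offset beyond +-4 C everywhere
    fake_run(tt, truth + 3.5) # inside the band
  )
  res <- filter_by_temperature(runs, tgt)
  expect_equal(res$accepted, c(1L, 3L))
  expect_false(res$trace$pass[2])
  expect_equal(res$trace$first_fail_time[2], tgt$times[1])
})

test_that("the filter is monotone in its tolerances", {
  set.seed(21)
  tgt <- make_sst_target()
  tt <- seq(0, 14e6, by = 1e5)
  truth <- approx(tgt$times, tgt$mean_anomaly, xout = tt, rule = 2)$y
  runs <- lapply(1:40, function(i) {
    fake_run(tt, truth + rnorm(1, 0, 3) + rnorm(length(tt), 0, 1.5))
  })
  base <- filter_by_temperature(runs, tgt)$accepted
  wider_t <- temperature_target(tgt$times, tgt$mean_anomaly,
                                tol_temp = 6, tol_time = tgt$tol_time)
  wider_w <- temperature_target(tgt$times, tgt$mean_anomaly,
                                tol_temp = tgt$tol_temp, tol_time = 8e5)
  expect_true(all(base %in% filter_by_temperature(runs, wider_t)$accepted))
  expect_true(all(base %in% filter_by_temperature(runs, wider_w)$accepted))
})

test_that("ensemble summaries match a direct quantile oracle and collapse
           for a single run", {
  set.seed(5)
  tt <- seq(0, 1e6, by = 1e5)
  runs <- lapply(1:25, function(i) {
    r <- list(
      times = tt, temp_anomaly = rnorm(1, 5, 2) + 0 * tt,
      f_rw_ma = rep(runif(1), length(tt)),
      residence_norm = rep(1, length(tt))
    )
    r
  })
  s <- summarize_ensemble(runs, variables = "temp_anomaly", grid = tt)
  vals <- vapply(runs, function(r) r$temp_anomaly[1], numeric(1))
  env1 <- s$envelopes[s$envelopes$time == tt[1], ]
  expect_equal(env1$q50, unname(stats::quantile(vals, 0.5)))
  expect_equal(env1$q16, unname(stats::quantile(vals, 0.16)))
  # bands nest: 68% within 95%
  expect_true(all(s$envelopes$q025 <= s$envelopes$q16))
  expect_true(all(s$envelopes$q84 <= s$envelopes$q975))
  # independent sort-based oracle
  expect_equal(env1$q975, manual_quantile(vals, 0.975),
               tolerance = diff(range(vals)) * 0.08)
  s1 <- summarize_ensemble(runs[1], variables = "temp_anomaly", grid = tt)
  expect_equal(s1$envelopes$q025, s1$envelopes$q975)
  expect_equal(s1$envelopes$q50, rep(runs[[1]]$temp_anomaly[1], length(tt)))
})

test_that("an empty accepted set yields an explicit empty summary", {
  s <- summarize_ensemble(list())
  expect_true(s$empty)
  expect_equal(s$n_runs, 0)
})

test_that("a small ensemble runs deterministically end to end with shared
           scenario timing", {
  # narrow ranges around an accepted background keep this smoke test quick
  rng <- default_ranges("permian")
  rng$k_bsi <- list(min = 4e13, max = 6e13, scale = "log")
  rng$pco2c <- list(min = 140, max = 160, scale = "linear")
  rng$alk_si <- list(min = 1, max = 1.2, scale = "linear")
  rng$n_si <- list(min = 0.35, max = 0.45, scale = "linear")
  rng$o <- list(min = 1, max = 2, scale = "linear")
  rng$full_duration <- list(min = 4e6, max = 5e6, scale = "linear")
  draws <- sample_parameters(rng, 2, seed = 17)
  ens_a <- run_ensemble(draws, ranges = rng, seed = 17, t_end = 11e6)
  ens_b <- run_ensemble(draws, ranges = rng, seed = 17, t_end = 11e6)
  expect_equal(length(ens_a$runs), 2)
  expect_identical(
    lapply(ens_a$runs, function(r) r$states),
    lapply(ens_b$runs, function(r) r$states)
  )
  expect_true(all(vapply(ens_a$runs, function(r) r$scenario$t_onset,
                         numeric(1)) == 5e6))
  expect_true(all(vapply(ens_a$runs, function(r) r$accepted_spinup,
                         logical(1))))
  expect_gte(ens_a$n_spinups, 2)
  # success-by-duration bookkeeping runs on the result
  flt <- filter_by_temperature(ens_a, make_sst_target())
  sbd <- success_by_duration(ens_a, flt)
  expect_equal(sum(sbd$n), 2)
})
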