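test_that("generators are deterministic functions of (parameters, seed)", {
  a <- simulate_frr_transient(0.4, 1, 380, 0.22, noise_sd = 0.01, seed = 9)
  b <- simulate_frr_transient(0.4, 1, 380, 0.22, noise_sd = 0.01, seed = 9)
  expect_identical(a$fluorescence, b$fluorescence)
  c2 <- simulate_frr_transient(0.4, 1, 380, 0.22, noise_sd = 0.01, seed = 10)
  expect_false(identical(a$fluorescence, c2$fluorescence))

  p1 <- simulate_pam_protocol(0.4, 1, 1.4, 0.14, noise_sd = 0.01, seed = 9)
  p2 <- simulate_pam_protocol(0.4, 1, 1.4, 0.14, noise_sd = 0.01, seed = 9)
  expect_identical(p1$data, p2$data)

  o1 <- simulate_oxygen_trace(30, 6, 5, noise_sd = 0.05, seed = 9)
  o2 <- simulate_oxygen_trace(30, 6, 5, noise_sd = 0.05, seed = 9)
  expect_identical(o1$o2, o2$o2)

  e1 <- simulate_pe_experiment(2.97, 0.09, noise_cv = 0.05, seed = 9)
  e2 <- simulate_pe_experiment(2.97, 0.09, noise_cv = 0.05, seed = 9)
  expect_identical(e1$p, e2$p)

  sc <- diel_scenario(list(x = list(baseline = 10, peak_mult = 2,
                                    depression = 0.7)),
                      noise_sd = 0.02, seed = 9)
  sch <- make_irradiance_schedule("half-sine", 500, 12)
  expect_identical(simulate_diel_experiment(sc, sch)$value,
                   simulate_diel_experiment(sc, sch)$value)
})

test_that("generators do not disturb the global RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_frr_transient(0.4, 1, 380, 0.22, noise_sd = 0.01, seed = 1))
  invisible(simulate_pe_experiment(2.97, 0.09, noise_cv = 0.05, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("zero-noise transients equal the forward model; zero dose stays at Fo", {
  doses <- rep(1e-4, 100)
  tr <- simulate_frr_transient(0.4, 1, 380, 0.22, flashlet_doses = doses)
  expect_identical(tr$fluorescence, frr_forward(0.4, 1, 380, 0.22, doses))
  tr0 <- simulate_frr_transient(0.4, 1, 380, 0.22,
                                flashlet_doses = rep(0, 20))
  expect_equal(tr0$fluorescence, rep(0.4, 20))
  expect_error(simulate_frr_transient(1, 0.4, 380, 0.22), "fo < fm")
  expect_error(simulate_frr_transient(0.4, 1, 380, 1), "\\[0, 1\\)")
})

test_that("PAM generator encodes the NPQ and PhiPSII targets in its landmarks", {
  tr <- simulate_pam_protocol(0.4, 1.2, npq_true = 1.4, phi_true = 0.14)
  truth <- attr(tr, "truth")
  expect_equal(truth$fm_prime, 0.5) # 1.2 / (1 + 1.4)
  # npq_true = 0 leaves Fm' = Fm
  tr0 <- simulate_pam_protocol(0.4, 1.2, npq_true = 0, phi_true = 0.1)
  expect_equal(attr(tr0, "truth")$fm_prime, 1.2)
  # quenching so strong that Ft would exceed Fm' is rejected
  expect_error(simulate_pam_protocol(0.6, 1.2, npq_true = 3, phi_true = 0.1),
               "inconsistent")
})

test_that("oxygen generator encodes the stated slopes", {
  tr <- simulate_oxygen_trace(30, 6, chl = 5)
  light <- tr[tr$phase == "light", ]
  dark <- tr[tr$segment == 1, ]
  light_slope <- unname(coef(lm(o2 ~ time, light))["time"])
  dark_slope <- unname(coef(lm(o2 ~ time, dark))["time"])
  expect_equal(light_slope, (30 - 6) * 5 / 3600)
  expect_equal(dark_slope, -6 * 5 / 3600)
  # rd = 0: flat dark segments
  tr0 <- simulate_oxygen_trace(30, 0, chl = 5)
  expect_equal(diff(range(tr0$o2[tr0$phase == "dark" & tr0$segment == 1])), 0)
  expect_error(simulate_oxygen_trace(30, 6, 5,
                                     segment_plan = data.frame(phase = character(0),
                                                               duration = numeric(0))),
               "non-empty")
})

test_that("P-E generator hits the tanh mean and saturates", {
  d <- simulate_pe_experiment(2.97, 0.09, e_grid = c(0, 1500))
  expect_equal(d$p[1], 0)
  expect_equal(d$p[2], 2.97, tolerance = 0.01) # tanh(45.4) ~ 1
  # lognormal noise is unit-mean: large-sample average stays on the curve
  dn <- simulate_pe_experiment(2.97, 0.09, e_grid = rep(1500, 4000),
                               noise_cv = 0.2, seed = 2)
  expect_equal(mean(dn$p), 2.97, tolerance = 0.02)
})

test_that("diel generator honours its scenario invariants", {
  sch <- make_irradiance_schedule("half-sine", 500, 12)
  sc <- diel_scenario(list(x = list(baseline = 10, peak_mult = 3,
                                    depression = 0.6)))
  d <- simulate_diel_experiment(sc, sch)
  expect_true(all(d$irradiance == irradiance_at(sch, d$time)))
  expect_equal(max(d$value), 30)            # baseline * peak_mult
  expect_equal(d$value[d$time == 0], 10)    # baseline at light onset
  expect_equal(d$value[d$time == 6], 0.6 * 30) # depressed midday
  expect_equal(unique(d$value[d$time > 12]), 10) # night baseline
  expect_error(diel_scenario(list(x = list(baseline = 10, depression = 0))),
               "depression")
  expect_error(diel_scenario(list(x = list(baseline = 10, peak_mult = -1))),
               "peak_mult")
})
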