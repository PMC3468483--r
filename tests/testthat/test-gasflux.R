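make_trace <- function(light_slope, dark_slope, chl = 5, dur = c(120, 300, 300),
                       noise_sd = 0, seed = NULL) {
  # piecewise-linear dark/light/dark trace built directly (independent of
  # the package generator)
  t1 <- seq(0, dur[1] - 1); t2 <- seq(0, dur[2] - 1); t3 <- seq(0, dur[3] - 1)
  o1 <- 250 + dark_slope * t1
  o2 <- o1[length(o1)] + dark_slope + light_slope * t2
  o3 <- o2[length(o2)] + light_slope + dark_slope * t3
  o2v <- c(o1, o2, o3)
  if (noise_sd > 0) {
    o2v <- o2v + withr::with_seed(seed, rnorm(length(o2v), 0, noise_sd))
  }
  oxygen_trace(seq_along(o2v) - 1, o2v,
               rep(c("dark", "light", "dark"), times = dur), chl)
}

test_that("segment slopes are recovered exactly on clean traces", {
  tr <- make_trace(0.01, -0.002)
  expect_equal(fit_segment_slope(tr, 2)$slope, 0.01)
  expect_equal(fit_segment_slope(tr, 1)$slope, -0.002)
  expect_equal(fit_segment_slope(tr, 2, method = "theil-sen")$slope, 0.01)
  expect_error(fit_segment_slope(tr, 9), "segment")
})

test_that("noisy slopes land within 3 standard errors of truth", {
  tr <- make_trace(0.01, -0.002, noise_sd = 0.05, seed = 3)
  s <- fit_segment_slope(tr, 2)
  expect_lt(abs(s$slope - 0.01), 3 * s$se)
})

test_that("Theil-Sen shrugs off a single outlier", {
  tr <- make_trace(0.01, -0.002)
  o2 <- tr$o2
  o2[300] <- o2[300] + 5 # gross outlier mid-light
  tr2 <- oxygen_trace(tr$time, o2, tr$phase, attr(tr, "chl"))
  s <- fit_segment_slope(tr2, 2, method = "theil-sen")
  expect_equal(s$slope, 0.01, tolerance = 0.01)
})

test_that("gross photosynthesis adds dark respiration back onto the net slope", {
  # light +2.0 umol L-1 min-1, dark -0.5, chl 5 -> Ag = 2.5 * 60 / 5 = 30
  expect_equal(gross_photosynthesis(2 / 60, -0.5 / 60, 5), 30)
  expect_equal(gross_photosynthesis(0.01, 0, 5), 0.01 * 3600 / 5)
  expect_equal(gross_photosynthesis(0, 0, 5), 0)
  expect_error(gross_photosynthesis(0.01, -0.002, 0), "chl")
})

test_that("gas rates round-trip the oxygen generator and ignore O2 offsets", {
  tr <- simulate_oxygen_trace(30, 6, chl = 5)
  gr <- gas_rates(tr)
  expect_equal(gr$ag, 30, tolerance = 1e-9)
  expect_equal(gr$rd, 6, tolerance = 1e-9)
  # absolute offset leaves slopes, hence rates, unchanged
  shifted <- oxygen_trace(tr$time, tr$o2 + 80, tr$phase, attr(tr, "chl"))
  expect_equal(gas_rates(shifted)$ag, gr$ag)
  # zero respiration gives a flat dark slope
  gr0 <- gas_rates(simulate_oxygen_trace(30, 0, chl = 5))
  expect_equal(gr0$rd, 0, tolerance = 1e-12)
})

test_that("post-illumination uptake burst is detected with rate and duration", {
  tr <- simulate_oxygen_trace(30, 6, chl = 5,
                              post_illumination_burst = list(factor = 3,
                                                             duration = 60))
  b <- detect_post_illumination_uptake(tr)
  expect_false(is.null(b))
  expect_equal(b$rate, 18, tolerance = 1e-6)       # 3 x steady uptake
  expect_lt(abs(b$duration - 60), 20)
  expect_equal(b$steady_rate, 6, tolerance = 1e-6)
  # constant dark slope: nothing detected
  expect_null(detect_post_illumination_uptake(simulate_oxygen_trace(30, 6, 5)))
  # sub-threshold burst: nothing detected
  weak <- simulate_oxygen_trace(30, 6, chl = 5,
                                post_illumination_burst = list(factor = 1.3,
                                                               duration = 60))
  expect_null(detect_post_illumination_uptake(weak))
  # burst detection survives electrode noise
  noisy <- simulate_oxygen_trace(30, 6, chl = 5, noise_sd = 0.02, seed = 5,
                                 post_illumination_burst = list(factor = 3,
                                                                duration = 60))
  bn <- detect_post_illumination_uptake(noisy)
  expect_false(is.null(bn))
  expect_equal(bn$rate, 18, tolerance = 0.1)
  expect_lt(abs(bn$duration - 60), 20)
  # no transition at all
  dark_only <- simulate_oxygen_trace(30, 6, chl = 5,
                                     segment_plan = data.frame(
                                       phase = "dark", duration = 300))
  expect_error(detect_post_illumination_uptake(dark_only), "transition")
})

test_that("carbon fixation rate reproduces the hand-computed example", {
  r <- carbon_fixation_rate(5200, 200, 1e6, dic = 2000, chl = 5,
                            incubation = 0.667)
  expect_equal(r$p_umol, 5000 / 1e6 * 2000 * 1.05 / (5 * 0.667))
  expect_equal(r$p_umol, 3.149, tolerance = 1e-3)
  expect_equal(r$p_mg, r$p_umol * 12.011e-3)
  # zero fixation when sample equals background
  expect_equal(carbon_fixation_rate(200, 200, 1e6, 2000, 5, 0.667)$p_umol, 0)
  # linear in excess DPM and DIC; halves when incubation doubles
  r2 <- carbon_fixation_rate(10200, 200, 1e6, 2000, 5, 0.667)
  expect_equal(r2$p_umol, 2 * r$p_umol)
  r3 <- carbon_fixation_rate(5200, 200, 1e6, 4000, 5, 0.667)
  expect_equal(r3$p_umol, 2 * r$p_umol)
  r4 <- carbon_fixation_rate(5200, 200, 1e6, 2000, 5, 2 * 0.667)
  expect_equal(r4$p_umol, r$p_umol / 2)
  expect_error(carbon_fixation_rate(5200, 200, 100, 2000, 5, 0.667),
               "dpm_total")
})

test_that("tanh curve fitting recovers noiseless parameters exactly", {
  d <- simulate_pe_experiment(2.97, 0.09)
  fit <- fit_pe_curve(d$e, d$p)
  expect_true(fit$converged)
  expect_equal(fit$pmax, 2.97, tolerance = 1e-6)
  expect_equal(fit$alpha, 0.09, tolerance = 1e-6)
  expect_equal(fit$ek, 33, tolerance = 1e-6)
  expect_equal(fit$pmax_umol, 2.97 / 12.011e-3, tolerance = 1e-6)
  # model properties: initial slope alpha, saturation at Pmax
  expect_equal(fit$pmax * tanh(fit$alpha * 1e-6 / fit$pmax) / 1e-6, fit$alpha,
               tolerance = 1e-6)
  expect_equal(fit$pmax * tanh(fit$alpha * 1e5 / fit$pmax), fit$pmax)
})

test_that("median Pmax bias stays under 3% at 5% lognormal noise", {
  pmax_hat <- vapply(1:50, function(s) {
    d <- simulate_pe_experiment(2.97, 0.09, noise_cv = 0.05, seed = s)
    fit_pe_curve(d$e, d$p)$pmax
  }, numeric(1))
  expect_lt(abs(stats::median(pmax_hat) - 2.97) / 2.97, 0.03)
})

test_that("sub-saturating P-E data are flagged, not silently extrapolated", {
  e <- c(2, 5, 10, 20, 30) # all below Ek = 33
  p <- 2.97 * tanh(0.09 * e / 2.97)
  fit <- fit_pe_curve(e, p)
  expect_identical(fit$flag, "Pmax unconstrained")
  expect_error(fit_pe_curve(c(10, 10, 20), c(1, 1, 2)), "4 distinct")
})

test_that("light-saturation index and photosynthetic quotient are plain ratios", {
  expect_equal(ek(2.97, 0.09), 33)
  expect_equal(ek(1, 0.5), 2)
  expect_lt(ek(1, 1e6), 1e-5) # alpha -> Inf drives Ek -> 0
  expect_error(ek(1, 0), "division")
  expect_equal(photosynthetic_quotient(338, 248), 338 / 248)
  expect_equal(photosynthetic_quotient(338, 248), 1.36, tolerance = 5e-3)
  expect_equal(photosynthetic_quotient(386, 306), 1.26, tolerance = 5e-3)
  expect_equal(photosynthetic_quotient(100, 100), 1)
  expect_error(photosynthetic_quotient(100, 0), "division")
})
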