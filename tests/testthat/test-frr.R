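test_that("forward model matches the p = 0 Poisson closed form", {
  doses <- rep(1e-4, 100)
  f <- frr_forward(0.4, 1.0, sigma = 380, p = 0, flashlet_doses = doses)
  x <- cumsum(doses)
  expect_equal(f, 0.4 + 0.6 * (1 - exp(-380 * x)), tolerance = 1e-4)
  # frozen spot value at cumulative dose 0.01 photons A-2
  expect_equal(f[100], 0.4 + 0.6 * (1 - exp(-3.8)), tolerance = 1e-4)
})

test_that("forward model agrees with the implicit closed form at p > 0", {
  doses <- rep(1e-4, 100)
  for (p in c(0.1, 0.22, 0.37, 0.6)) {
    got <- frr_forward(0.4, 1.0, 380, p, doses)
    want <- frr_yield_implicit(0.4, 1.0, 380, p, cumsum(doses))
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("forward model saturates, is monotone, and stays in [Fo, Fm]", {
  doses <- rep(5e-4, 200) # heavy total dose: sigma X = 38
  f <- frr_forward(0.4, 1.0, 380, 0.22, doses)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0.4 & f <= 1.0))
  expect_equal(f[200], 1.0, tolerance = 1e-6) # saturation limit
  expect_equal(frr_forward(0.4, 1.0, 380, 0.22, rep(0, 20)), rep(0.4, 20))
  expect_error(frr_forward(1.0, 0.4, 380, 0.22, doses), "fo < fm")
  expect_error(frr_forward(0.4, 1.0, 380, 1, doses), "\\[0, 1\\)")
})

test_that("noiseless transients are recovered to 1e-6 relative error", {
  tr <- simulate_frr_transient(0.4, 1.0, sigma = 380, p = 0.22)
  fit <- fit_frr(tr)
  expect_true(fit$converged)
  expect_equal(fit$fo, 0.4, tolerance = 1e-6)
  expect_equal(fit$fm, 1.0, tolerance = 1e-6)
  expect_equal(fit$sigma_psii, 380, tolerance = 1e-6)
  expect_equal(fit$p, 0.22, tolerance = 1e-6)
  # low-light acclimated parameter set
  fit2 <- fit_frr(simulate_frr_transient(0.39, 1.0, sigma = 307, p = 0.37))
  expect_equal(fit2$sigma_psii, 307, tolerance = 1e-6)
  expect_equal(fit2$p, 0.37, tolerance = 1e-6)
})

test_that("connectivity is identifiable: p = 0 data fits to p <= 0.02", {
  tr <- simulate_frr_transient(0.4, 1.0, sigma = 380, p = 0)
  fit <- fit_frr(tr)
  expect_true(fit$converged)
  expect_lte(fit$p, 0.02)
})

test_that("fit objective at truth is a local minimum on noiseless data", {
  doses <- rep(1e-4, 100)
  y <- frr_forward(0.4, 1.0, 380, 0.22, doses)
  rss <- function(fo, fm, sigma, p) {
    sum((y - frr_forward(fo, fm, sigma, p, doses))^2)
  }
  base <- rss(0.4, 1.0, 380, 0.22)
  expect_lte(base, rss(0.41, 1.0, 380, 0.22))
  expect_lte(base, rss(0.4, 0.98, 380, 0.22))
  expect_lte(base, rss(0.4, 1.0, 395, 0.22))
  expect_lte(base, rss(0.4, 1.0, 380, 0.27))
})

test_that("sigma and p recovery bias stays below 2% at 0.5% noise", {
  n_seeds <- 100
  sig <- numeric(n_seeds); pp <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    tr <- simulate_frr_transient(0.4, 1.0, sigma = 380, p = 0.22,
                                 noise_sd = 0.005, seed = s)
    fit <- fit_frr(tr)
    sig[s] <- fit$sigma_psii; pp[s] <- fit$p
  }
  expect_lt(abs(mean(sig) - 380) / 380, 0.02)
  expect_lt(abs(mean(pp) - 0.22) / 0.22, 0.02)
})

test_that("flat transients are rejected as carrying no variable fluorescence", {
  flat <- frr_transient(rep(1e-4, 50), rep(0.4, 50) + 1e-6 * sin(1:50))
  expect_error(fit_frr(flat), "no variable fluorescence")
})

test_that("electron transport rate follows the sigma (Fq'/Fv')/(Fv/Fm) E form", {
  # hand-tracked units: 3.8e-18 m2 * (480e-6 * 6.022e23) photons m-2 s-1 * 0.5/0.52
  want <- 3.8e-18 * (480e-6 * 6.022e23) * (0.5 / 0.52)
  got <- compute_etr(380, 0.5, 0.52, 480)
  expect_equal(got$per_rc, want, tolerance = 1e-12)
  expect_equal(got$per_rc, 1056.2, tolerance = 1e-4)
  # linear in E; zero at E = 0
  expect_equal(compute_etr(380, 0.5, 0.52, 960)$per_rc, 2 * got$per_rc)
  expect_equal(compute_etr(380, 0.5, 0.52, 0)$per_rc, 0)
  # per-chl twin: per-RC rate scaled by RC per mg chl and per hour
  rc_per_mg <- 0.002 * (1e-3 / 893.5) * 6.022e23
  expect_equal(got$per_chl, want * rc_per_mg / 6.022e23 * 1e6 * 3600,
               tolerance = 1e-12)
  expect_error(compute_etr(380, 0.5, 0, 480), "division")
})

test_that("a*_PSII combines sigma, unit size and Fv'/Fm' correctly", {
  rc_per_mg <- 0.002 * (1e-3 / 893.5) * 6.022e23 # RC per mg chl a
  expect_equal(compute_apsii(380, 0.5), 3.8e-18 * rc_per_mg / 0.5,
               tolerance = 1e-12)
  expect_equal(compute_apsii(380, 0.5), 0.0102, tolerance = 1e-2)
  expect_equal(compute_apsii(380, 1), 3.8e-18 * rc_per_mg) # unit denominator
  expect_equal(compute_apsii(0, 0.5), 0)
  expect_error(compute_apsii(380, 0), "division")
  # plausible inputs give values in the 1e-3..1e-1 m2/mg range
  expect_true(compute_apsii(307, 0.32) > 1e-3 && compute_apsii(307, 0.32) < 1e-1)
})
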