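test_that("quench parameters follow the standard definitions", {
  # Fo = 0.39 Fm gives the low-light Fv/Fm of 0.61
  q <- quench_params(quench_markers(fo = 0.39, fm = 1, ft = 0.5, fm_prime = 0.7))
  expect_equal(q$fv_fm, 0.61)
  # Fm 1.2, Fm' 0.5 gives NPQ = 1.4
  q2 <- quench_params(quench_markers(fo = 0.3, fm = 1.2, ft = 0.35,
                                     fm_prime = 0.5))
  expect_equal(q2$npq, 1.4)
  expect_equal(q2$phi_psii, (0.5 - 0.35) / 0.5)
  # no quenching: NPQ = 0 and Fo' = Fo
  q3 <- quench_params(quench_markers(fo = 0.39, fm = 1, ft = 0.6, fm_prime = 1))
  expect_equal(q3$npq, 0)
  expect_equal(q3$fo_prime, 0.39)
  expect_equal(q3$one_minus_qp, 1 - q3$qp)
})

test_that("PhiPSII = qP * Fv'/Fm' holds to 1e-12 for any valid marker set", {
  for (m in random_marker_sets(50)) {
    q <- quench_params(m)
    fvp_fmp <- (m$fm_prime - q$fo_prime) / m$fm_prime
    expect_equal(q$phi_psii, q$qp * fvp_fmp, tolerance = 1e-12)
    expect_gte(q$npq, 0)
    expect_true(q$qp >= 0 && q$qp <= 1)
  }
})

test_that("Fm' above Fm is flagged, not fatal", {
  q <- quench_params(quench_markers(fo = 0.3, fm = 1, ft = 0.8, fm_prime = 1.1))
  expect_true(q$fm_prime_exceeds_fm)
  expect_lt(q$npq, 0)
})

test_that("Fo' estimator reproduces hand values and is monotone in Fm'", {
  expect_equal(estimate_fo_prime(0.39, 0.61, 0.7), 0.39 / (0.61 + 0.39 / 0.7))
  expect_equal(estimate_fo_prime(0.39, 0.61, 0.7), 0.334, tolerance = 1e-3)
  # identity at no quenching: Fm' = Fm recovers Fo
  expect_equal(estimate_fo_prime(0.39, 0.61, 1), 0.39)
  # Fo' decreases as quenching deepens (Fm' decreases)
  fmp <- seq(1, 0.3, by = -0.1)
  fop <- vapply(fmp, function(f) estimate_fo_prime(0.39, 0.61, f), numeric(1))
  expect_true(all(diff(fop) < 0))
  expect_true(all(fop <= fmp))
})

test_that("NPQ recovery fraction interpolates and clamps", {
  tt <- c(0, 60, 120, 180, 300)
  expect_equal(npq_recovery_fraction(tt, c(1, 0.7, 0.5, 0.35, 0.3)), 0.65)
  expect_equal(npq_recovery_fraction(tt, rep(0.8, 5)), 0)   # no decay
  expect_equal(npq_recovery_fraction(tt, c(1, 0.4, 0.1, 0, 0)), 1) # full decay
  expect_equal(npq_recovery_fraction(tt, c(1, 0.9, 0.8, 0.7, 0.6), 90), 0.15)
  expect_error(npq_recovery_fraction(tt, c(0, 0.1, 0.2, 0.2, 0.2)), "zero")
})

test_that("marker extraction from a simulated PAM trace is exact when noiseless", {
  tr <- simulate_pam_protocol(0.4, 1.2, npq_true = 1.4, phi_true = 0.14)
  q <- quench_params(extract_quench_markers(tr))
  expect_equal(q$npq, 1.4)
  expect_equal(q$phi_psii, 0.14)
  expect_equal(q$fv_fm, (1.2 - 0.4) / 1.2)
  # light-adapted maximum equals fm / (1 + NPQ)
  m <- extract_quench_markers(tr)
  expect_equal(m$fm_prime, 1.2 / (1 + 1.4))
})

test_that("marker extraction tolerates instrument noise", {
  tr <- simulate_pam_protocol(0.4, 1.2, npq_true = 1.4, phi_true = 0.14,
                              noise_sd = 0.005, seed = 11)
  q <- quench_params(extract_quench_markers(tr))
  expect_equal(q$npq, 1.4, tolerance = 0.05)
  # the pulse-apex maximum is positively biased under noise, which inflates
  # small quantum yields; check on an absolute scale
  expect_lt(abs(q$phi_psii - 0.14), 0.03)
})

test_that("spectrum normalisation pins the reference to 1 and is idempotent", {
  sp <- two_gaussian_spectrum()
  norm <- normalize_spectrum(sp, 690)
  expect_equal(stats::approx(norm$wavelength, norm$intensity, 690)$y, 1)
  twice <- normalize_spectrum(norm, 690)
  expect_equal(twice$intensity, norm$intensity)
  # scale invariance and shape preservation
  scaled <- emission_spectrum(sp$wavelength, sp$intensity * 37)
  expect_equal(normalize_spectrum(scaled, 690)$intensity, norm$intensity)
  i1 <- which.min(abs(sp$wavelength - 685))
  i2 <- which.min(abs(sp$wavelength - 710))
  expect_equal(norm$intensity[i1] / norm$intensity[i2],
               sp$intensity[i1] / sp$intensity[i2])
  expect_error(normalize_spectrum(emission_spectrum(600:700, c(0, rep(1, 100))),
                                  600), "zero intensity")
})

test_that("peak location resolves single and double peaks with sub-nm accuracy", {
  wl <- seq(650, 760, by = 0.5)
  single <- emission_spectrum(wl, exp(-(wl - 690)^2 / (2 * 5^2)))
  pk <- locate_emission_peaks(single)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$wavelength, 690, tolerance = 0.5)
  expect_identical(pk$type, "peak")

  two <- two_gaussian_spectrum(685, 710, h2 = 0.2)
  pk2 <- locate_emission_peaks(two, min_prominence = 0.05)
  peaks <- pk2[pk2$type == "peak", ]
  expect_equal(nrow(peaks), 2)
  expect_equal(sort(peaks$wavelength), c(685, 710), tolerance = 0.6)

  ramp <- emission_spectrum(wl, seq(0, 1, length.out = length(wl)))
  expect_equal(nrow(locate_emission_peaks(ramp)), 0)
})

test_that("shoulders on a flank are detected via curvature", {
  # dominant 690 nm band with a weak red-shifted shoulder near 712 nm that
  # never forms a strict maximum
  wl <- seq(650, 780, by = 0.5)
  y <- exp(-(wl - 690)^2 / (2 * 9^2)) + 0.25 * exp(-(wl - 712)^2 / (2 * 7^2))
  sp <- emission_spectrum(wl, y)
  feats <- locate_emission_peaks(sp, min_prominence = 0.05)
  expect_true(any(feats$type == "peak" & abs(feats$wavelength - 690) < 1.5))
  sh <- feats[feats$type == "shoulder", ]
  expect_true(any(abs(sh$wavelength - 712) < 3))
})
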