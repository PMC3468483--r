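# Independent oracles used against the package's own code paths.

# Closed-fraction solution of the connectivity induction model, obtained by
# separating variables: p*C - (1-p)*log(1-C) = sigma*(1-p)*X, solved for C
# by bisection. Independent of the package's Runge-Kutta integrator.
closed_fraction_implicit <- function(sigma, p, cumulative_dose) {
  vapply(cumulative_dose, function(x) {
    if (x == 0) return(0)
    stats::uniroot(function(C) p * C - (1 - p) * log(1 - C) - sigma * (1 - p) * x,
                   interval = c(0, 1 - 1e-13), tol = 1e-14)$root
  }, numeric(1))
}

frr_yield_implicit <- function(fo, fm, sigma, p, cumulative_dose) {
  cc <- closed_fraction_implicit(sigma, p, cumulative_dose)
  q <- cc * (1 - p) / (1 - p * cc)
  fo + (fm - fo) * q
}

# Signed polygon area by the shoelace formula (counterclockwise positive).
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

# Two-Gaussian emission spectrum fixture.
two_gaussian_spectrum <- function(mu1 = 685, mu2 = 710, h2 = 0.2,
                                  sd1 = 6, sd2 = 6,
                                  wl = seq(650, 760, by = 0.5)) {
  emission_spectrum(wl, exp(-(wl - mu1)^2 / (2 * sd1^2)) +
                      h2 * exp(-(wl - mu2)^2 / (2 * sd2^2)))
}

# Random but internally consistent quench marker sets under a fixed seed.
random_marker_sets <- function(n, seed = 42) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      fm <- runif(1, 0.5, 2)
      fo <- fm * runif(1, 0.2, 0.6)
      fm_prime <- fm / (1 + runif(1, 0, 2.5))
      # keep Ft physically consistent: between the implied Fo' and Fm'
      fo_prime <- estimate_fo_prime(fo, (fm - fo) / fm, fm_prime)
      ft <- fo_prime + runif(1, 0.05, 0.95) * (fm_prime - fo_prime)
      quench_markers(fo = fo, fm = fm, ft = ft, fm_prime = fm_prime)
    })
  })
}
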