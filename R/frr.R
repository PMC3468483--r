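#' Single-turnover fluorescence induction forward model
#'
#' Advances the fraction of closed PSII reaction centers, C, along a train
#' of single-turnover flashlets following the connectivity-aware induction
#' model of Kolber, Prasil and Falkowski:
#' \deqn{dC/dX = \sigma (1 - C)(1 - p) / (1 - pC)}
#' with X the cumulative excitation dose (photons A^-2), \eqn{\sigma} the
#' effective PSII absorption cross-section (A^2) and p the inter-unit
#' connectivity. The observed fluorescence yield is
#' \deqn{F = F_o + (F_m - F_o) \, C (1 - p) / (1 - pC).}
#' Integration is 4th-order Runge-Kutta per flashlet with sub-stepping so
#' that no step advances C by more than about 0.01.
#'
#' @param fo,fm Minimal and maximal fluorescence yield (relative units),
#'   `0 <= fo < fm`.
#' @param sigma Effective PSII cross-section, A^2 (> 0).
#' @param p Connectivity, in `[0, 1)`.
#' @param flashlet_doses Per-flashlet excitation doses, photons A^-2
#'   (non-negative). Yields are reported at the cumulative dose reached
#'   after each flashlet.
#' @return Numeric vector of fluorescence yields, one per flashlet, bounded
#'   in `[fo, fm]` and non-decreasing for non-negative doses.
#' @examples
#' doses <- rep(1e-4, 100)
#' f <- frr_forward(0.4, 1.0, sigma = 380, p = 0.22, flashlet_doses = doses)
#' @export
frr_forward <- function(fo, fm, sigma, p, flashlet_doses) {
  .assert(.is_num(fo) && .is_num(fm) && fo >= 0 && fo < fm,
          "need 0 <= fo < fm")
  .assert(.is_num(sigma) && sigma > 0, "sigma must be > 0")
  .assert(.is_num(p) && p >= 0 && p < 1, "connectivity p must lie in [0, 1)")
  .assert(is.numeric(flashlet_doses) && all(is.finite(flashlet_doses)) &&
            all(flashlet_doses >= 0), "flashlet doses must be non-negative")
  cc <- .frr_closed_fraction(sigma, p, flashlet_doses)
  q <- cc * (1 - p) / (1 - p * cc)
  fo + (fm - fo) * q
}

## RK4 integration of dC/dX = sigma (1-C)(1-p)/(1-pC); returns C after each
## flashlet. Unchecked: also used inside the fit residual where the
## optimizer may probe edge values.
.frr_closed_fraction <- function(sigma, p, flashlet_doses) {
  n <- length(flashlet_doses)
  out <- numeric(n)
  cc <- 0
  one_m_p <- 1 - p
  for (i in seq_len(n)) {
    dx <- flashlet_doses[i]
    if (dx > 0) {
      nsub <- max(1L, ceiling(sigma * dx / 0.01))
      h <- dx / nsub
      for (k in seq_len(nsub)) {
        k1 <- sigma * (1 - cc) * one_m_p / (1 - p * cc)
        c2 <- cc + h / 2 * k1
        k2 <- sigma * (1 - c2) * one_m_p / (1 - p * c2)
        c3 <- cc + h / 2 * k2
        k3 <- sigma * (1 - c3) * one_m_p / (1 - p * c3)
        c4 <- cc + h * k3
        k4 <- sigma * (1 - c4) * one_m_p / (1 - p * c4)
        cc <- cc + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        if (cc > 1 - 1e-12) cc <- 1 - 1e-12
      }
    }
    out[i] <- cc
  }
  out
}

#' Construct an FRR transient
#'
#' @param dose Per-flashlet excitation dose, photons A^-2.
#' @param fluorescence Measured yield, relative units.
#' @return A data.frame of class `frr_transient` with columns `flashlet`,
#'   `dose`, `cumulative_dose`, `fluorescence`.
#' @export
frr_transient <- function(dose, fluorescence) {
  .assert(is.numeric(dose) && is.numeric(fluorescence) &&
            length(dose) == length(fluorescence),
          "dose and fluorescence must be numeric vectors of equal length")
  .assert(length(dose) >= 10, "an FRR transient needs at least 10 flashlets")
  .assert(all(is.finite(dose)) && all(dose >= 0), "doses must be finite and >= 0")
  .assert(all(is.finite(fluorescence)), "fluorescence yields must be finite")
  out <- data.frame(flashlet = seq_along(dose), dose = dose,
                    cumulative_dose = cumsum(dose), fluorescence = fluorescence)
  class(out) <- c("frr_transient", "data.frame")
  out
}

#' Fit the connectivity-aware induction model to an FRR transient
#'
#' Least-squares estimation of (Fo, Fm, sigma_PSII, p) by
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]). Starting values: Fo = mean
#' of the first 3 yields, Fm = mean of the last 5, sigma from the early
#' log-linear slope assuming p = 0, p = 0.3. Connectivity is bounded in
#' `[0, 0.99]`.
#'
#' @param transient An [frr_transient()] (or data.frame with `dose` and
#'   `fluorescence` columns).
#' @param init Optional named list overriding any of the starting values
#'   `fo`, `fm`, `sigma`, `p`.
#' @param lower,upper Optional bound vectors, order `(fo, fm, sigma, p)`.
#' @return An object of class `frr_fit`: list with `fo`, `fm`, `sigma_psii`
#'   (A^2), `p`, `fv_fm`, `rss`, `converged`, `flag` (`NA` or
#'   `"no variable fluorescence"`), and `n`.
#' @details A transient whose total relative fluorescence rise is below 5%
#'   carries no usable variable fluorescence and is rejected with an error;
#'   a fitted `fv_fm < 0.05` is flagged rather than rejected.
#'   Non-convergence is reported via `converged = FALSE`, never silently.
#' @export
fit_frr <- function(transient, init = NULL, lower = NULL, upper = NULL) {
  if (!inherits(transient, "frr_transient")) {
    .assert(is.data.frame(transient) &&
              all(c("dose", "fluorescence") %in% names(transient)),
            "transient must be an frr_transient or have dose/fluorescence columns")
    transient <- frr_transient(transient$dose, transient$fluorescence)
  }
  y <- transient$fluorescence
  doses <- transient$dose
  xc <- transient$cumulative_dose

  if ((max(y) - min(y)) < 0.05 * max(abs(y))) {
    stop("no variable fluorescence", call. = FALSE)
  }

  fo0 <- mean(y[1:3])
  fm0 <- mean(utils::tail(y, 5))
  ## early slope, p = 0 Poisson limit: C = 1 - exp(-sigma X)
  early <- which((y - fo0) / (fm0 - fo0) < 0.8 & xc > 0)
  if (length(early) < 3) early <- seq_len(min(5L, length(y)))
  cc_early <- pmin(pmax((y[early] - fo0) / (fm0 - fo0), 1e-6), 1 - 1e-6)
  sigma0 <- stats::median(-log(1 - cc_early) / xc[early])
  if (!is.finite(sigma0) || sigma0 <= 0) sigma0 <- 1 / max(xc)
  start <- list(fo = fo0, fm = fm0, sigma = sigma0, p = 0.3)
  if (!is.null(init)) start[names(init)] <- init

  if (is.null(lower)) lower <- c(0, 0, 1e-8, 0)
  if (is.null(upper)) upper <- c(Inf, Inf, Inf, 0.99)

  resid_fn <- function(par) {
    cc <- .frr_closed_fraction(par[3], par[4], doses)
    q <- cc * (1 - par[4]) / (1 - par[4] * cc)
    y - (par[1] + (par[2] - par[1]) * q)
  }
  fit <- minpack.lm::nls.lm(
    par = unlist(start), lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  par <- fit$par
  fv_fm <- (par[["fm"]] - par[["fo"]]) / par[["fm"]]
  flag <- if (fv_fm < 0.05) "no variable fluorescence" else NA_character_
  structure(
    list(fo = par[["fo"]], fm = par[["fm"]], sigma_psii = par[["sigma"]],
         p = par[["p"]], fv_fm = fv_fm, rss = sum(fit$fvec^2),
         converged = fit$info %in% 1:4, flag = flag, n = length(y)),
    class = "frr_fit"
  )
}

#' @export
print.frr_fit <- function(x, ...) {
  cat("<frr_fit>\n")
  cat(sprintf("  Fo = %.4g, Fm = %.4g (Fv/Fm = %.3f)\n", x$fo, x$fm, x$fv_fm))
  cat(sprintf("  sigma_PSII = %.4g A2, p = %.4g\n", x$sigma_psii, x$p))
  cat(sprintf("  rss = %.3g over %d flashlets; converged: %s\n",
              x$rss, x$n, x$converged))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' PSII electron transport rate from FRR parameters
#'
#' \eqn{ETR_{PSII} = \sigma_{PSII} (F_q'/F_v')/(F_v/F_m) E}: the per-center
#' electron transport rate obtained from the cross-section, the ratio of
#' light- to dark-adapted quantum yields, and the incident irradiance.
#' The per-reaction-center rate (electrons RC^-1 s^-1) follows directly
#' from converting sigma to m^2 and E to photons m^-2 s^-1; the
#' chlorophyll-normalised twin (umol electrons mg chl a^-1 h^-1) uses the
#' photosynthetic unit size `rc_per_chl` (mol RC per mol chl a) and the
#' chl a molar mass.
#'
#' @param sigma_psii Effective PSII cross-section, A^2.
#' @param fq_over_fv_prime Ratio Fq'/Fv' (dimensionless, >= 0).
#' @param fv_over_fm Dark-adapted Fv/Fm (> 0).
#' @param e Irradiance, umol photons m^-2 s^-1 (>= 0).
#' @param rc_per_chl Photosynthetic unit size, mol RC (mol chl a)^-1;
#'   default 0.002.
#' @param chl_molar_mass Chl a molar mass, g mol^-1; default 893.5.
#' @return List with `per_rc` (electrons RC^-1 s^-1) and `per_chl`
#'   (umol electrons mg chl a^-1 h^-1).
#' @examples
#' compute_etr(380, 0.5, 0.52, 480)$per_rc # ~1056 electrons RC-1 s-1
#' @export
compute_etr <- function(sigma_psii, fq_over_fv_prime, fv_over_fm, e,
                        rc_per_chl = 0.002, chl_molar_mass = CHL_A_MOLAR_MASS) {
  .assert(.is_num(sigma_psii) && sigma_psii >= 0, "sigma_psii must be >= 0")
  .assert(.is_num(fq_over_fv_prime) && fq_over_fv_prime >= 0,
          "fq_over_fv_prime must be >= 0")
  .assert(.is_num(fv_over_fm), "fv_over_fm must be a single number")
  if (fv_over_fm <= 0) stop("division by zero: fv_over_fm must be > 0", call. = FALSE)
  .assert(.is_num(e) && e >= 0, "irradiance e must be >= 0")
  photons <- e * 1e-6 * AVOGADRO # photons m^-2 s^-1
  per_rc <- sigma_psii * A2_TO_M2 * photons * fq_over_fv_prime / fv_over_fm
  ## electrons RC^-1 s^-1 == mol e- (mol RC)^-1 s^-1; scale to per mg chl, h
  per_chl <- per_rc * rc_per_chl / chl_molar_mass * 1e-3 * 1e6 * 3600
  list(per_rc = per_rc, per_chl = per_chl)
}

#' Chlorophyll-specific PSII absorption coefficient
#'
#' \eqn{a^*_{PSII} = \sigma_{PSII} (RC_{PSII}/chl\,a) / (F_v'/F_m')} with the
#' unit size expressed per mg chl a:
#' `rc_per_mg = rc_per_chl * (1e-3 / chl_molar_mass) * N_A`.
#'
#' @inheritParams compute_etr
#' @param fv_prime_over_fm_prime Light-adapted Fv'/Fm', in `(0, 1]`.
#' @return a*_PSII in m^2 (mg chl a)^-1.
#' @examples
#' compute_apsii(380, 0.5) # ~0.0102 m2 per mg chl a
#' @export
compute_apsii <- function(sigma_psii, fv_prime_over_fm_prime,
                          rc_per_chl = 0.002,
                          chl_molar_mass = CHL_A_MOLAR_MASS) {
  .assert(.is_num(sigma_psii) && sigma_psii >= 0, "sigma_psii must be >= 0")
  .assert(.is_num(fv_prime_over_fm_prime), "fv_prime_over_fm_prime must be a single number")
  if (fv_prime_over_fm_prime <= 0) {
    stop("division by zero: fv_prime_over_fm_prime must be > 0", call. = FALSE)
  }
  .assert(fv_prime_over_fm_prime <= 1, "fv_prime_over_fm_prime must lie in (0, 1]")
  rc_per_mg <- rc_per_chl * (1e-3 / chl_molar_mass) * AVOGADRO
  sigma_psii * A2_TO_M2 * rc_per_mg / fv_prime_over_fm_prime
}
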