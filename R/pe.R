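#' Carbon fixation rate from 14C scintillation counts
#'
#' Standard small-volume 14C incubation calculation (Lewis-Smith / JGOFS
#' convention): the fraction of the added label fixed, scaled by the
#' dissolved inorganic carbon pool and the 1.05 isotope-discrimination
#' factor, normalised to chlorophyll and incubation time:
#' \deqn{P = \frac{(DPM_{sample} - DPM_{background})}{DPM_{total}}
#'   \cdot \frac{DIC \cdot 1.05}{chl \cdot t}}
#' in umol C mg chl a^-1 h^-1, with the mg C twin obtained via the molar
#' mass of carbon (12.011 g mol^-1).
#'
#' @param dpm_sample,dpm_background,dpm_total Disintegrations min^-1
#'   (vectorised); `dpm_total > dpm_background >= 0`.
#' @param dic Dissolved inorganic carbon, umol C L^-1.
#' @param chl mg chl a L^-1 (> 0).
#' @param incubation Incubation time, h (> 0).
#' @param discrimination Isotope discrimination factor (default 1.05).
#' @return data.frame with `p_umol` (umol C mg chl a^-1 h^-1) and `p_mg`
#'   (mg C mg chl a^-1 h^-1).
#' @examples
#' carbon_fixation_rate(5200, 200, 1e6, dic = 2000, chl = 5,
#'                      incubation = 0.667)
#' @export
carbon_fixation_rate <- function(dpm_sample, dpm_background, dpm_total,
                                 dic, chl, incubation, discrimination = 1.05) {
  .assert(is.numeric(dpm_sample) && is.numeric(dpm_background) &&
            is.numeric(dpm_total), "DPM inputs must be numeric")
  .assert(all(dpm_background >= 0), "background DPM must be >= 0")
  if (any(dpm_total <= dpm_background)) {
    stop("dpm_total must exceed dpm_background", call. = FALSE)
  }
  .assert(all(dic > 0), "DIC must be > 0")
  .assert(all(chl > 0), "chl must be > 0")
  .assert(all(incubation > 0), "incubation time must be > 0")
  .assert(.is_num(discrimination) && discrimination > 0,
          "discrimination factor must be > 0")
  p_umol <- (dpm_sample - dpm_background) / dpm_total * dic * discrimination /
    (chl * incubation)
  data.frame(p_umol = p_umol, p_mg = p_umol * C_MOLAR_MASS * 1e-3)
}

#' Fit a Jassby-Platt photosynthesis-irradiance curve
#'
#' Least-squares fit of \eqn{P = P_{max} \tanh(\alpha E / P_{max})} by
#' Levenberg-Marquardt. The light-saturation index Ek = Pmax/alpha is
#' attached. When the measured irradiances do not reach saturation
#' (max(E) below about 1.5 Ek) the fitted Pmax is extrapolation, and the
#' result is flagged `"Pmax unconstrained"`.
#'
#' @param e Irradiance, umol photons m^-2 s^-1 (at least 4 distinct values).
#' @param p Photosynthetic rate, mg C mg chl a^-1 h^-1 (same length as `e`).
#' @return Object of class `pe_fit`: list with `pmax` (mg C mg chl a^-1
#'   h^-1), `pmax_umol` (umol C twin), `alpha` (mg C mg chl a^-1 h^-1 per
#'   umol photons m^-2 s^-1), `ek` (umol photons m^-2 s^-1), `rss`,
#'   `converged`, `flag`, `n`.
#' @examples
#' e <- c(5, 10, 25, 50, 100, 250, 500, 1000, 1500)
#' p <- 2.97 * tanh(0.09 * e / 2.97)
#' fit_pe_curve(e, p)
#' @export
fit_pe_curve <- function(e, p) {
  if (is.data.frame(e)) {
    .assert(all(c("e", "p") %in% names(e)), "data.frame input needs columns e and p")
    p <- e$p; e <- e$e
  }
  .assert(is.numeric(e) && is.numeric(p) && length(e) == length(p),
          "e and p must be numeric vectors of equal length")
  .assert(all(is.finite(e)) && all(e >= 0), "irradiances must be finite and >= 0")
  .assert(length(unique(e)) >= 4, "need at least 4 distinct irradiances")

  pmax0 <- max(p)
  low <- e > 0 & e <= stats::quantile(e[e > 0], 1 / 3)
  alpha0 <- if (sum(low) >= 2) {
    unname(stats::coef(stats::lm(p[low] ~ 0 + e[low])))
  } else {
    max(p[e > 0] / e[e > 0])
  }
  if (!is.finite(alpha0) || alpha0 <= 0) alpha0 <- pmax0 / max(e)

  resid_fn <- function(par) p - par[1] * tanh(par[2] * e / par[1])
  fit <- minpack.lm::nls.lm(
    par = c(pmax = pmax0, alpha = alpha0),
    lower = c(1e-12, 1e-12), upper = c(Inf, Inf), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  pmax_hat <- fit$par[["pmax"]]
  alpha_hat <- fit$par[["alpha"]]
  ek_hat <- ek(pmax_hat, alpha_hat)
  flag <- if (max(e) < 1.5 * ek_hat) "Pmax unconstrained" else NA_character_
  structure(
    list(pmax = pmax_hat, pmax_umol = mgC_to_umolC(pmax_hat),
         alpha = alpha_hat, ek = ek_hat, rss = sum(fit$fvec^2),
         converged = fit$info %in% 1:4, flag = flag, n = length(e)),
    class = "pe_fit"
  )
}

#' @export
print.pe_fit <- function(x, ...) {
  cat("<pe_fit>\n")
  cat(sprintf("  Pmax = %.4g mg C mg chl-1 h-1 (%.4g umol C)\n",
              x$pmax, x$pmax_umol))
  cat(sprintf("  alpha = %.4g, Ek = %.4g umol photons m-2 s-1\n",
              x$alpha, x$ek))
  cat(sprintf("  rss = %.3g over %d points; converged: %s\n",
              x$rss, x$n, x$converged))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Light-saturation index
#'
#' `Ek = Pmax / alpha`, the irradiance at which the initial slope of a
#' Jassby-Platt curve intersects the saturated rate.
#'
#' @param pmax Maximum photosynthetic rate.
#' @param alpha Initial slope (same rate units per umol photons m^-2 s^-1).
#' @return Ek in umol photons m^-2 s^-1.
#' @examples
#' ek(2.97, 0.09) # 33
#' @export
ek <- function(pmax, alpha) {
  .assert(is.numeric(pmax) && is.numeric(alpha), "pmax and alpha must be numeric")
  if (any(alpha == 0)) stop("division by zero: alpha must be non-zero", call. = FALSE)
  pmax / alpha
}

#' Photosynthetic quotient
#'
#' Molar ratio of gross O2 evolution to carbon fixation, both on the same
#' normalisation basis (e.g. umol mg chl a^-1 h^-1). Values near 1 indicate
#' balanced carbohydrate synthesis; below 1 suggest photorespiration, near
#' 2 nitrate-supported or lipid-directed metabolism.
#'
#' @param ag_molar_o2 Gross O2 evolution, umol O2 mg chl a^-1 h^-1 (> 0).
#' @param pmax_molar_c Carbon fixation, umol C mg chl a^-1 h^-1 (> 0).
#' @return Dimensionless PQ.
#' @examples
#' photosynthetic_quotient(338, 248) # 1.36
#' @export
photosynthetic_quotient <- function(ag_molar_o2, pmax_molar_c) {
  .assert(is.numeric(ag_molar_o2) && is.numeric(pmax_molar_c),
          "rates must be numeric")
  if (any(pmax_molar_c <= 0)) stop("division by zero: carbon rate must be > 0",
                                   call. = FALSE)
  .assert(all(ag_molar_o2 > 0), "O2 rate must be > 0")
  ag_molar_o2 / pmax_molar_c
}
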