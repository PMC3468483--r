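#' Specific growth rate between two census points
#'
#' `mu = (ln c - ln c0) / (t - t0)` in day^-1.
#'
#' @param c0,c Cell concentrations (cells mL^-1, > 0) at times `t0 < t`.
#' @param t0,t Times in days.
#' @return Growth rate, day^-1.
#' @examples
#' growth_rate(1e6, 2e6, 0, 1) # ln 2
#' @export
growth_rate <- function(c0, c, t0, t) {
  .assert(is.numeric(c0) && is.numeric(c) && all(c0 > 0) && all(c > 0),
          "cell concentrations must be > 0")
  .assert(all(t > t0), "t must exceed t0")
  (log(c) - log(c0)) / (t - t0)
}

#' Pooled growth rate from a census series with dilutions
#'
#' Semi-continuous cultures are periodically diluted back into the working
#' band; intervals spanning a dilution reset carry no growth information.
#' The pooled rate sums log-growth over all between-dilution intervals and
#' divides by their total duration, recovering the underlying exponential
#' rate exactly when growth is exponential between resets.
#'
#' @param records data.frame with columns `t` (days, strictly increasing),
#'   `c` (cells mL^-1, > 0), `dilution_flag` (logical; `TRUE` marks a
#'   census taken immediately after a dilution reset).
#' @return Pooled growth rate, day^-1.
#' @export
growth_rate_series <- function(records) {
  .assert(is.data.frame(records) &&
            all(c("t", "c", "dilution_flag") %in% names(records)),
          "records must have columns t, c, dilution_flag")
  .assert(!is.unsorted(records$t, strictly = TRUE), "t must be strictly increasing")
  .assert(all(records$c > 0), "cell concentrations must be > 0")
  n <- nrow(records)
  .assert(n >= 2, "need at least two census points")
  keep <- !records$dilution_flag[-1] # interval i-1 -> i unusable if i is a reset
  dlogc <- diff(log(records$c))[keep]
  dt <- diff(records$t)[keep]
  .assert(length(dt) > 0, "no between-dilution intervals in series")
  sum(dlogc) / sum(dt)
}

#' Cell volume from Coulter diameter
#'
#' Cells are modelled as spheres: `V = (pi/6) d^3`.
#'
#' @param diameter Equivalent spherical diameter, um (> 0).
#' @return Volume in um^3.
#' @examples
#' cell_volume(6.87) # 169.8 um3
#' @export
cell_volume <- function(diameter) {
  .assert(is.numeric(diameter) && all(diameter > 0), "diameter must be > 0")
  pi / 6 * diameter^3
}

#' Intracellular density of a cell quota
#'
#' @param quota_pg Per-cell quota, pg cell^-1 (>= 0).
#' @param volume_um3 Cell volume, um^3 (> 0).
#' @param unit Output unit: `"fg"` (fg um^-3, default - the conventional
#'   scale for pigments) or `"pg"` (pg um^-3).
#' @return Density in the requested unit.
#' @examples
#' cellular_density(0.60, cell_volume(6.87)) # 3.5 fg chl a um-3
#' @export
cellular_density <- function(quota_pg, volume_um3, unit = c("fg", "pg")) {
  unit <- match.arg(unit)
  .assert(is.numeric(quota_pg) && all(quota_pg >= 0), "quota must be >= 0")
  if (any(volume_um3 <= 0)) stop("cell volume must be > 0", call. = FALSE)
  d <- quota_pg / volume_um3
  if (unit == "fg") d * 1000 else d
}

#' Molar C:N ratio from mass quotas
#'
#' `(C/12.011) / (N/14.007)`, mol:mol.
#'
#' @param c_quota_pg Carbon quota, pg cell^-1.
#' @param n_quota_pg Nitrogen quota, pg cell^-1 (> 0).
#' @return Molar C:N.
#' @examples
#' cn_molar_ratio(32, 4.18) # 8.9
#' @export
cn_molar_ratio <- function(c_quota_pg, n_quota_pg) {
  .assert(is.numeric(c_quota_pg) && all(c_quota_pg >= 0), "C quota must be >= 0")
  if (any(n_quota_pg <= 0)) stop("N quota must be > 0", call. = FALSE)
  (c_quota_pg / C_MOLAR_MASS) / (n_quota_pg / N_MOLAR_MASS)
}

#' Percent change of a treatment relative to a reference
#'
#' @param reference Reference value (> 0).
#' @param treatment Treatment value.
#' @return `100 * (treatment - reference) / reference`, unrounded; rounding
#'   is a report-level formatting choice, never applied to stored values.
#' @examples
#' percent_change(0.87, 1.11) # 27.6 -> prints as 28%
#' @export
percent_change <- function(reference, treatment) {
  if (any(reference <= 0)) stop("reference must be > 0", call. = FALSE)
  100 * (treatment - reference) / reference
}

#' Convert a molar carbon rate to a mass rate
#'
#' @param rate_umol Rate in umol C (per any basis).
#' @return Rate in mg C: `rate_umol * 12.011e-3`.
#' @examples
#' umolC_to_mgC(306) # 3.67 mg C
#' @export
umolC_to_mgC <- function(rate_umol) {
  .assert(is.numeric(rate_umol) && all(rate_umol >= 0), "rate must be >= 0")
  rate_umol * C_MOLAR_MASS * 1e-3
}

#' @rdname umolC_to_mgC
#' @param rate_mg Rate in mg C.
#' @export
mgC_to_umolC <- function(rate_mg) {
  .assert(is.numeric(rate_mg) && all(rate_mg >= 0), "rate must be >= 0")
  rate_mg / (C_MOLAR_MASS * 1e-3)
}

#' Per-treatment summary of a cell-composition table
#'
#' Emits a compact per-treatment physiology summary from a composition
#' table: spherical cell volume, intracellular C, N and chl a densities,
#' and the molar C:N ratio.
#'
#' @param composition data.frame with columns `treatment`, `diameter_um`,
#'   `c_quota_pg`, `n_quota_pg`, `chl_quota_pg`.
#' @return data.frame, one row per treatment.
#' @export
composition_summary <- function(composition) {
  needed <- c("treatment", "diameter_um", "c_quota_pg", "n_quota_pg",
              "chl_quota_pg")
  .assert(is.data.frame(composition) && all(needed %in% names(composition)),
          paste("composition needs columns:", paste(needed, collapse = ", ")))
  vol <- cell_volume(composition$diameter_um)
  data.frame(
    treatment = composition$treatment,
    volume_um3 = vol,
    c_density_pg_um3 = cellular_density(composition$c_quota_pg, vol, "pg"),
    n_density_pg_um3 = cellular_density(composition$n_quota_pg, vol, "pg"),
    chl_density_fg_um3 = cellular_density(composition$chl_quota_pg, vol, "fg"),
    cn_molar = cn_molar_ratio(composition$c_quota_pg, composition$n_quota_pg)
  )
}
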