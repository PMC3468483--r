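#' PAM protocol landmarks
#'
#' Bundle the fluorescence landmarks of a standard quenching protocol:
#' dark-adapted minimal (Fo) and maximal (Fm) yields, the steady-state
#' yield under actinic light (Ft), the light-adapted maximum from a
#' saturating pulse (Fm'), and optionally the light-adapted minimum (Fo').
#' When Fo' is not measured it is estimated downstream (see
#' [estimate_fo_prime()]).
#'
#' @param fo,fm Dark-adapted minimal and maximal yields, `0 < fo <= fm`.
#' @param ft Steady-state yield in the light, `ft <= fm_prime`.
#' @param fm_prime Light-adapted maximal yield. `fm_prime > fm` is
#'   physically unexpected and is flagged downstream, not rejected.
#' @param fo_prime Optional measured light-adapted minimal yield.
#' @return An object of class `quench_markers`.
#' @export
quench_markers <- function(fo, fm, ft, fm_prime, fo_prime = NULL) {
  .assert(.is_num(fo) && .is_num(fm) && fo > 0 && fo <= fm,
          "need 0 < fo <= fm")
  .assert(.is_num(ft) && .is_num(fm_prime), "ft and fm_prime must be single numbers")
  .assert(ft <= fm_prime, "ft must not exceed fm_prime")
  if (!is.null(fo_prime)) {
    .assert(.is_num(fo_prime) && fo_prime > 0 && fo_prime <= fm_prime,
            "measured fo_prime must lie in (0, fm_prime]")
  }
  structure(list(fo = fo, fm = fm, ft = ft, fm_prime = fm_prime,
                 fo_prime = fo_prime),
            class = "quench_markers")
}

#' Quenching parameters from protocol landmarks
#'
#' Computes the standard chlorophyll-fluorescence quenching quantities:
#' \itemize{
#'   \item `fv_fm`  = (Fm - Fo)/Fm, maximum quantum yield of PSII
#'   \item `phi_psii` = (Fm' - Ft)/Fm', effective quantum yield (Genty)
#'   \item `qp` = (Fm' - Ft)/(Fm' - Fo'), photochemical quenching
#'   \item `npq` = (Fm - Fm')/Fm', non-photochemical quenching
#'   \item `one_minus_qp` = 1 - qP, PSII excitation pressure
#' }
#' The identity `phi_psii = qp * (Fm' - Fo')/Fm'` holds algebraically for
#' any Fo'. If Fo' was not measured it is estimated with
#' [estimate_fo_prime()].
#'
#' @param markers A [quench_markers()] object.
#' @return One-row data.frame with the five parameters plus `fo_prime`,
#'   `fo_prime_estimated`, and `fm_prime_exceeds_fm` (flag, not an error).
#' @examples
#' m <- quench_markers(fo = 0.39, fm = 1, ft = 0.55, fm_prime = 0.7)
#' quench_params(m)
#' @export
quench_params <- function(markers) {
  stopifnot(inherits(markers, "quench_markers"))
  fo <- markers$fo; fm <- markers$fm
  ft <- markers$ft; fmp <- markers$fm_prime
  if (fm == 0) stop("division by zero in Fv/Fm: Fm is 0", call. = FALSE)
  if (fmp == 0) stop("division by zero in NPQ/PhiPSII: Fm' is 0", call. = FALSE)
  fv_fm <- (fm - fo) / fm
  estimated <- is.null(markers$fo_prime)
  fop <- if (estimated) estimate_fo_prime(fo, fv_fm, fmp) else markers$fo_prime
  if (fmp == fop) stop("division by zero in qP: Fm' equals Fo'", call. = FALSE)
  out <- data.frame(
    fv_fm = fv_fm,
    phi_psii = (fmp - ft) / fmp,
    qp = (fmp - ft) / (fmp - fop),
    npq = (fm - fmp) / fmp,
    fo_prime = fop,
    fo_prime_estimated = estimated,
    fm_prime_exceeds_fm = fmp > fm
  )
  out$one_minus_qp <- 1 - out$qp
  out[c("fv_fm", "phi_psii", "qp", "one_minus_qp", "npq",
        "fo_prime", "fo_prime_estimated", "fm_prime_exceeds_fm")]
}

#' Estimate the light-adapted minimal fluorescence Fo'
#'
#' Oxborough-Baker estimator, used when Fo' is not measured directly
#' (e.g. no far-red post-actinic determination):
#' \deqn{F_o' = F_o / (F_v/F_m + F_o/F_m').}
#' At Fm' = Fm (no quenching) this reduces algebraically to Fo.
#'
#' @param fo Dark-adapted minimal yield (> 0).
#' @param fv_fm Dark-adapted Fv/Fm, in (0, 1).
#' @param fm_prime Light-adapted maximal yield (> 0).
#' @return Estimated Fo' (guaranteed <= fm_prime for consistent inputs).
#' @examples
#' estimate_fo_prime(0.39, 0.61, 0.7) # 0.334
#' @export
estimate_fo_prime <- function(fo, fv_fm, fm_prime) {
  .assert(.is_num(fo) && fo > 0, "fo must be > 0")
  .assert(.is_num(fv_fm) && fv_fm > 0 && fv_fm < 1, "fv_fm must lie in (0, 1)")
  .assert(.is_num(fm_prime) && fm_prime > 0, "fm_prime must be > 0")
  denom <- fv_fm + fo / fm_prime
  if (denom <= 0) stop("non-positive denominator in Fo' estimate", call. = FALSE)
  fo / denom
}

#' Fraction of NPQ relaxing within a time window
#'
#' Dark-relaxation capacity of non-photochemical quenching: the relative
#' NPQ decline from light-off to `t_window`,
#' `(NPQ(0) - NPQ(t_window)) / NPQ(0)`, clamped to `[0, 1]`. NPQ at the
#' window boundary is obtained by linear interpolation.
#'
#' @param time Seconds since light-off (first element must be 0).
#' @param npq NPQ values at `time`.
#' @param t_window Window length in seconds (default 180 s = 3 min).
#' @return Recovered fraction in `[0, 1]`.
#' @export
npq_recovery_fraction <- function(time, npq, t_window = 180) {
  .assert(is.numeric(time) && is.numeric(npq) && length(time) == length(npq),
          "time and npq must be numeric vectors of equal length")
  .assert(length(time) >= 2 && time[1] == 0 && !is.unsorted(time, strictly = TRUE),
          "series must start at light-off (time 0) and be strictly increasing")
  .assert(.is_num(t_window) && t_window > 0, "t_window must be > 0")
  .assert(t_window <= max(time), "t_window lies beyond the measured series")
  npq0 <- npq[1]
  if (npq0 == 0) stop("NPQ at light-off is zero: recovery fraction undefined",
                      call. = FALSE)
  npq_t <- stats::approx(time, npq, xout = t_window)$y
  min(max((npq0 - npq_t) / npq0, 0), 1)
}
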