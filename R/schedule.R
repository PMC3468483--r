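#' Define a daily irradiance schedule
#'
#' Growth-light regimes are either continuous ("constant") or a half-sine
#' light:dark cycle in which irradiance rises from zero at light onset to a
#' midday peak and back to zero at the end of the photoperiod,
#' `E(t) = peak * sin(pi * t / photoperiod)`, mimicking computer-controlled
#' "sinusoidal" lamp programs. The schedule is periodic with a 24 h day and
#' time is expressed in decimal hours since light onset.
#'
#' @param mode `"constant"` or `"half-sine"`.
#' @param level_or_peak Irradiance in umol photons m^-2 s^-1: the constant
#'   level, or the midday peak of the half-sine.
#' @param photoperiod Hours of light per 24 h day. Constant mode is
#'   continuous light and must have `photoperiod = 24`.
#' @return An object of class `irradiance_schedule`.
#' @examples
#' hl <- make_irradiance_schedule("constant", 200)
#' sinus <- make_irradiance_schedule("half-sine", 500, photoperiod = 12)
#' irradiance_at(sinus, c(0, 6, 12, 18))
#' @export
make_irradiance_schedule <- function(mode = c("constant", "half-sine"),
                                     level_or_peak,
                                     photoperiod = if (mode == "constant") 24 else 12) {
  mode <- match.arg(mode)
  .assert(.is_num(level_or_peak) && level_or_peak >= 0,
          "irradiance must be a single non-negative number")
  .assert(.is_num(photoperiod) && photoperiod > 0 && photoperiod <= 24,
          "photoperiod must lie in (0, 24] hours")
  if (mode == "constant") {
    .assert(photoperiod == 24, "constant mode means continuous light: photoperiod must be 24 h")
  }
  structure(
    list(mode = mode, level = level_or_peak, photoperiod = photoperiod,
         day_length = 24),
    class = "irradiance_schedule"
  )
}

#' Evaluate a schedule at times of day
#'
#' @param schedule An [make_irradiance_schedule()] object.
#' @param t Hours since light onset (vectorised); reduced modulo 24.
#' @return Irradiance in umol photons m^-2 s^-1.
#' @export
irradiance_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "irradiance_schedule"))
  tm <- t %% schedule$day_length
  if (schedule$mode == "constant") {
    rep(schedule$level, length(t))
  } else {
    ifelse(tm < schedule$photoperiod,
           schedule$level * sin(pi * tm / schedule$photoperiod),
           0)
  }
}

#' Daily photon dose of a light schedule
#'
#' Integrates irradiance over one 24 h day and converts to
#' mol photons m^-2 d^-1. Constant schedules use the analytic product; the
#' half-sine is integrated numerically (its analytic value
#' `(2/pi) * peak * photoperiod` is used as a cross-check in the tests).
#'
#' @param schedule An [make_irradiance_schedule()] object.
#' @return Dose in mol photons m^-2 d^-1.
#' @examples
#' daily_photon_dose(make_irradiance_schedule("constant", 200)) # 17.28
#' @export
daily_photon_dose <- function(schedule) {
  stopifnot(inherits(schedule, "irradiance_schedule"))
  if (schedule$mode == "constant") {
    return(schedule$level * 86400 * 1e-6)
  }
  sec_per_hour <- 3600
  f <- function(th) irradiance_at(schedule, th) * sec_per_hour * 1e-6
  stats::integrate(f, 0, schedule$photoperiod, rel.tol = 1e-10)$value
}

#' @export
print.irradiance_schedule <- function(x, ...) {
  cat(sprintf("<irradiance_schedule> %s, %g umol photons m-2 s-1%s, photoperiod %g h\n",
              x$mode, x$level, if (x$mode == "half-sine") " (peak)" else "",
              x$photoperiod))
  cat(sprintf("  daily photon dose: %.4g mol photons m-2 d-1\n",
              daily_photon_dose(x)))
  invisible(x)
}
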