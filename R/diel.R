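#' Construct a diel series
#'
#' @param time Hours since light onset, in `[0, 24)`.
#' @param parameter Parameter name per record.
#' @param value Parameter value.
#' @param irradiance Irradiance at each timestamp, umol photons m^-2 s^-1.
#' @return data.frame of class `diel_series`.
#' @export
diel_series <- function(time, parameter, value, irradiance) {
  .assert(is.numeric(time) && all(time >= 0) && all(time < 24),
          "timestamps must lie in [0, 24) hours")
  if (length(parameter) == 1) parameter <- rep(parameter, length(time))
  .assert(length(parameter) == length(time) && length(value) == length(time) &&
            length(irradiance) == length(time),
          "all columns must have equal length")
  .assert(all(irradiance >= 0), "irradiance must be >= 0")
  out <- data.frame(time = time, parameter = as.character(parameter),
                    value = value, irradiance = irradiance)
  class(out) <- c("diel_series", "data.frame")
  out
}

.single_parameter <- function(series, parameter) {
  .assert(is.data.frame(series) &&
            all(c("time", "parameter", "value", "irradiance") %in% names(series)),
          "series must have time/parameter/value/irradiance columns")
  pars <- unique(series$parameter)
  if (is.null(parameter)) {
    .assert(length(pars) == 1,
            "series holds several parameters; pick one with `parameter=`")
    parameter <- pars
  }
  .assert(parameter %in% pars, sprintf("parameter '%s' not in series", parameter))
  s <- series[series$parameter == parameter, , drop = FALSE]
  s[order(s$time), , drop = FALSE]
}

#' Morning/afternoon hysteresis of a diel parameter
#'
#' Quantifies the asymmetric response of a parameter to the same
#' irradiance in the rising (morning) versus falling (afternoon) light
#' phase. Samples within the photoperiod are split at the irradiance
#' maximum (the boundary sample counts as morning) and binned by
#' irradiance in bins of `bin_frac` times the peak irradiance. For each
#' bin populated in both phases the relative asymmetry is
#' `delta = (v_am - v_pm) / v_am`, using the bin medians (robust to the
#' single boundary sample); the index is the mean `delta` over matched
#' bins. The loop area is the signed integral of `v dE` around the closed
#' daily trajectory in the (E, v) plane: zero for a time-symmetric series.
#'
#' @param series A [diel_series()] (or compatible data.frame) covering both
#'   rising and falling light phases.
#' @param parameter Parameter name; may be omitted for single-parameter
#'   series.
#' @param bin_frac Irradiance bin width as a fraction of the peak
#'   (default 0.1).
#' @return Object of class `hysteresis_result`: list with `index`,
#'   `loop_area`, `n_bins`, and a `bins` data.frame
#'   (`e_lo`, `e_hi`, `v_am`, `v_pm`, `delta`).
#' @export
hysteresis_index <- function(series, parameter = NULL, bin_frac = 0.1) {
  s <- .single_parameter(series, parameter)
  .assert(.is_num(bin_frac) && bin_frac > 0 && bin_frac <= 1,
          "bin_frac must lie in (0, 1]")
  lit <- s[s$irradiance > 0, , drop = FALSE]
  .assert(nrow(lit) >= 4, "too few samples within the photoperiod")
  e_peak <- max(lit$irradiance)
  t_peak <- lit$time[which.max(lit$irradiance)]
  morning <- lit$time <= t_peak
  .assert(any(morning) && any(!morning),
          "series must cover both rising and falling light phases")

  edges <- seq(0, e_peak, by = bin_frac * e_peak)
  if (max(edges) < e_peak) edges <- c(edges, e_peak)
  bin <- cut(lit$irradiance, edges, include.lowest = TRUE, labels = FALSE)

  rows <- lapply(sort(unique(bin)), function(b) {
    am <- lit$value[bin == b & morning]
    pm <- lit$value[bin == b & !morning]
    if (length(am) == 0 || length(pm) == 0) return(NULL)
    v_am <- stats::median(am)
    v_pm <- stats::median(pm)
    data.frame(e_lo = edges[b], e_hi = edges[b + 1], v_am = v_am, v_pm = v_pm,
               delta = (v_am - v_pm) / v_am)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0) {
    stop("no irradiance bin is populated in both phases", call. = FALSE)
  }

  ## signed loop integral of v dE around the closed (E, v) trajectory
  e_path <- c(lit$irradiance, lit$irradiance[1])
  v_path <- c(lit$value, lit$value[1])
  loop_area <- sum(diff(e_path) * (v_path[-length(v_path)] + v_path[-1]) / 2)

  structure(list(index = mean(rows$delta), loop_area = loop_area,
                 n_bins = nrow(rows), bins = rows),
            class = "hysteresis_result")
}

#' @export
print.hysteresis_result <- function(x, ...) {
  cat(sprintf("<hysteresis_result> index = %.4g over %d matched bins; loop area = %.4g\n",
              x$index, x$n_bins, x$loop_area))
  invisible(x)
}

#' Midday depression of a diel parameter
#'
#' Ratio of the value at midday (the sample nearest the irradiance peak)
#' to the maximum value observed up to and including midday. 1 for a
#' series that is still rising at midday; below 1 when the parameter has
#' already dropped from its mid-morning maximum.
#'
#' @inheritParams hysteresis_index
#' @return Depression ratio, typically in `(0, 1]`.
#' @export
midday_depression <- function(series, parameter = NULL) {
  s <- .single_parameter(series, parameter)
  lit <- s[s$irradiance > 0, , drop = FALSE]
  .assert(nrow(lit) >= 2, "too few samples within the photoperiod")
  t_peak <- lit$time[which.max(lit$irradiance)]
  i_mid <- which.min(abs(s$time - t_peak))
  v_mid <- s$value[i_mid]
  pre <- s$value[s$time <= s$time[i_mid] & s$irradiance > 0]
  .assert(length(pre) >= 1, "missing morning samples before midday")
  v_mid / max(pre)
}
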