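#' Construct an oxygen-electrode trace
#'
#' @param time Seconds, strictly increasing.
#' @param o2 Dissolved oxygen, umol O2 L^-1.
#' @param phase Character vector of `"dark"`/`"light"` labels per sample;
#'   consecutive runs of the same label form numbered segments.
#' @param chl Chlorophyll a concentration in the chamber, mg chl a L^-1 (> 0).
#' @return A data.frame of class `oxygen_trace` with columns `time`, `o2`,
#'   `phase`, `segment`, and a `chl` attribute. Each segment must contain
#'   at least 5 samples.
#' @export
oxygen_trace <- function(time, o2, phase, chl) {
  .assert(is.numeric(time) && is.numeric(o2) && length(time) == length(o2),
          "time and o2 must be numeric vectors of equal length")
  .assert(!is.unsorted(time, strictly = TRUE), "time must be strictly increasing")
  .assert(length(phase) == length(time) && all(phase %in% c("dark", "light")),
          "phase must be 'dark'/'light' per sample")
  .assert(.is_num(chl) && chl > 0, "chl must be a single positive number")
  runs <- rle(phase)
  segment <- rep(seq_along(runs$lengths), runs$lengths)
  .assert(all(runs$lengths >= 5), "each dark/light segment needs >= 5 samples")
  out <- data.frame(time = time, o2 = o2, phase = phase, segment = segment)
  attr(out, "chl") <- chl
  class(out) <- c("oxygen_trace", "data.frame")
  out
}

#' Oxygen slope of one trace segment
#'
#' Ordinary least-squares slope of `o2 ~ time` over one labelled segment,
#' in umol O2 L^-1 s^-1, with its standard error. Five seconds are trimmed
#' from each segment edge (when enough samples remain) to avoid
#' light/dark transition artifacts. A Theil-Sen variant (median of all
#' pairwise slopes) is available for outlier-contaminated traces.
#'
#' @param trace An [oxygen_trace()].
#' @param segment Segment number (see the trace's `segment` column).
#' @param method `"ols"` or `"theil-sen"`.
#' @param trim Seconds trimmed from each segment edge (default 5; reduced
#'   automatically if fewer than 5 samples would remain).
#' @return List with `slope`, `se` (`NA` for Theil-Sen), `n`, `phase`.
#' @export
fit_segment_slope <- function(trace, segment, method = c("ols", "theil-sen"),
                              trim = 5) {
  stopifnot(inherits(trace, "oxygen_trace"))
  method <- match.arg(method)
  seg <- trace[trace$segment == segment, , drop = FALSE]
  .assert(nrow(seg) >= 5, sprintf("segment %s has fewer than 5 points", segment))
  t0 <- min(seg$time); t1 <- max(seg$time)
  keep <- seg$time >= t0 + trim & seg$time <= t1 - trim
  if (sum(keep) >= 5) seg <- seg[keep, , drop = FALSE]
  if (method == "ols") {
    fit <- stats::lm(o2 ~ time, data = seg)
    ## noiseless traces trigger lm's "essentially perfect fit" warning
    cf <- suppressWarnings(summary(fit)$coefficients)
    list(slope = unname(cf["time", "Estimate"]),
         se = unname(cf["time", "Std. Error"]),
         n = nrow(seg), phase = seg$phase[1])
  } else {
    list(slope = .theil_sen(seg$time, seg$o2), se = NA_real_,
         n = nrow(seg), phase = seg$phase[1])
  }
}

## Median of all pairwise slopes.
.theil_sen <- function(x, y) {
  n <- length(x)
  ij <- utils::combn(n, 2)
  stats::median((y[ij[2, ]] - y[ij[1, ]]) / (x[ij[2, ]] - x[ij[1, ]]))
}

#' Gross photosynthesis from light and dark slopes
#'
#' The gross O2 evolution rate is the light-phase net slope plus the
#' magnitude of the dark respiratory slope, normalised to chlorophyll:
#' `Ag = (light_slope + |dark_slope|) * 3600 / chl` in
#' umol O2 mg chl a^-1 h^-1, with slopes in umol O2 L^-1 s^-1 and chl in
#' mg chl a L^-1. Being slope-based, Ag is invariant to the trace's
#' absolute O2 offset.
#'
#' @param light_slope Net O2 slope in the light, umol O2 L^-1 s^-1.
#' @param dark_slope O2 slope in the dark (typically negative).
#' @param chl mg chl a L^-1 (> 0).
#' @return Ag, umol O2 mg chl a^-1 h^-1.
#' @export
gross_photosynthesis <- function(light_slope, dark_slope, chl) {
  .assert(.is_num(light_slope) && .is_num(dark_slope), "slopes must be single numbers")
  if (!.is_num(chl) || chl <= 0) stop("chl must be > 0", call. = FALSE)
  (light_slope + abs(dark_slope)) * 3600 / chl
}

#' Chlorophyll-normalised gas-exchange rates from a full trace
#'
#' Fits the light-segment slope and the steady dark slope (the second half
#' of the dark segment following the light exposure, so that any transient
#' post-illumination burst does not contaminate respiration), then derives
#' gross photosynthesis Ag and dark respiration Rd.
#'
#' @param trace An [oxygen_trace()] containing at least one light segment;
#'   the dark segment after the light exposure is preferred for Rd.
#' @param method Slope estimator, passed to [fit_segment_slope()].
#' @return Object of class `gas_rates`: list with `ag`, `rd`
#'   (umol O2 mg chl a^-1 h^-1, rd positive), `light_slope`, `dark_slope`,
#'   `flag` (set when rates come out physically negative).
#' @export
gas_rates <- function(trace, method = "ols") {
  stopifnot(inherits(trace, "oxygen_trace"))
  chl <- attr(trace, "chl")
  segs <- unique(trace$segment)
  phases <- vapply(segs, function(s) trace$phase[trace$segment == s][1], "")
  light_seg <- segs[phases == "light"]
  .assert(length(light_seg) >= 1, "trace has no light segment")
  light_seg <- light_seg[1]
  dark_after <- segs[phases == "dark" & segs > light_seg]
  dark_seg <- if (length(dark_after)) dark_after[1] else segs[phases == "dark"][1]
  .assert(length(dark_seg) == 1 && !is.na(dark_seg), "trace has no dark segment")

  light <- fit_segment_slope(trace, light_seg, method = method)
  ## steady respiration: second half of the dark segment
  dseg <- trace[trace$segment == dark_seg, , drop = FALSE]
  tmid <- min(dseg$time) + diff(range(dseg$time)) / 2
  steady <- dseg[dseg$time >= tmid, , drop = FALSE]
  if (nrow(steady) < 5) steady <- dseg
  dark_slope <- if (method == "ols") {
    unname(stats::coef(stats::lm(o2 ~ time, data = steady))["time"])
  } else {
    .theil_sen(steady$time, steady$o2)
  }

  ag <- gross_photosynthesis(light$slope, dark_slope, chl)
  rd <- -dark_slope * 3600 / chl
  flag <- if (ag < 0 || rd < 0) "negative rate: check trace" else NA_character_
  structure(list(ag = ag, rd = rd, light_slope = light$slope,
                 light_slope_se = light$se, dark_slope = dark_slope,
                 chl = chl, flag = flag),
            class = "gas_rates")
}

#' @export
print.gas_rates <- function(x, ...) {
  cat(sprintf("<gas_rates> Ag = %.3g, Rd = %.3g umol O2 mg chl-1 h-1\n",
              x$ag, x$rd))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Detect transiently enhanced post-illumination O2 uptake
#'
#' After a light-to-dark transition some cells show a brief burst of O2
#' consumption (a chlororespiration-like signature) before settling to
#' steady dark respiration. The dark segment following the first
#' light-to-dark transition is fitted with a continuous two-segment
#' piecewise-linear model over a grid of candidate breakpoints; the
#' early slope is reported as a burst when its uptake rate exceeds the
#' steady rate by at least `factor`.
#'
#' @param trace An [oxygen_trace()] with a light-to-dark transition
#'   followed by at least 60 s of dark.
#' @param factor Detection threshold: early uptake must be at least this
#'   multiple of steady uptake (default 1.5).
#' @param max_burst Longest burst considered, s (default 180).
#' @return `NULL` when no enhancement is detected, otherwise a list with
#'   `rate` (burst uptake, umol O2 mg chl a^-1 h^-1), `duration` (s),
#'   `steady_rate` (same units) and `ratio`.
#' @export
detect_post_illumination_uptake <- function(trace, factor = 1.5,
                                            max_burst = 180) {
  stopifnot(inherits(trace, "oxygen_trace"))
  chl <- attr(trace, "chl")
  segs <- unique(trace$segment)
  phases <- vapply(segs, function(s) trace$phase[trace$segment == s][1], "")
  trans <- which(phases[-length(phases)] == "light" & phases[-1] == "dark")
  if (length(trans) == 0) stop("no light-to-dark transition in trace", call. = FALSE)
  dark_seg <- segs[trans[1] + 1]
  dseg <- trace[trace$segment == dark_seg, , drop = FALSE]
  t0 <- min(dseg$time)
  .assert(diff(range(dseg$time)) >= 60,
          "need at least 60 s of dark after the transition")

  tt <- dseg$time - t0
  o2 <- dseg$o2
  ## candidate breakpoints: keep >= 5 points on each side
  cand <- tt[tt >= tt[5] & tt <= min(max_burst, tt[length(tt) - 4])]
  .assert(length(cand) >= 1, "dark segment too short for breakpoint search")
  best <- NULL
  for (bp in cand) {
    x2 <- pmax(tt - bp, 0)
    fit <- stats::lm(o2 ~ tt + x2)
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(rss = rss, bp = bp, slope1 = unname(cf["tt"]),
                   slope2 = unname(cf["tt"]) + unname(cf["x2"]))
    }
  }
  rate1 <- -best$slope1 * 3600 / chl
  rate2 <- -best$slope2 * 3600 / chl
  if (rate1 <= 0 || rate2 < 0) return(NULL)
  ratio <- if (rate2 > 0) rate1 / rate2 else Inf
  if (ratio < factor) return(NULL)
  list(rate = rate1, duration = best$bp, steady_rate = rate2, ratio = ratio)
}
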