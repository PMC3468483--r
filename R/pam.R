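#' Construct a PAM fluorescence trace
#'
#' A saturating-pulse quenching protocol trace: continuous fluorescence
#' samples plus a table of timed event windows naming the protocol
#' landmarks. At minimum a trace must contain a dark Fo window, a dark
#' saturating pulse (Fm) and a light saturating pulse (Fm') so that NPQ can
#' be computed.
#'
#' @param time Sample times, s, strictly increasing.
#' @param fluorescence Yields, relative units.
#' @param events data.frame with columns `event`, `start`, `end` (s).
#'   Recognised events: `fo_window`, `fm_pulse`, `actinic`, `ft_window`,
#'   `fmprime_pulse`, `post_actinic`.
#' @return An object of class `pam_trace`.
#' @export
pam_trace <- function(time, fluorescence, events) {
  .assert(is.numeric(time) && is.numeric(fluorescence) &&
            length(time) == length(fluorescence),
          "time and fluorescence must be numeric vectors of equal length")
  .assert(!is.unsorted(time, strictly = TRUE), "time must be strictly increasing")
  .assert(is.data.frame(events) &&
            all(c("event", "start", "end") %in% names(events)),
          "events must be a data.frame with event/start/end columns")
  .assert(all(events$end >= events$start), "event windows must have end >= start")
  .assert(!is.unsorted(events$start), "event windows must be ordered in time")
  needed <- c("fo_window", "fm_pulse", "fmprime_pulse")
  .assert(all(needed %in% events$event),
          "trace needs fo_window, fm_pulse and fmprime_pulse events")
  structure(list(data = data.frame(time = time, fluorescence = fluorescence),
                 events = events),
            class = "pam_trace")
}

.event_values <- function(trace, event_name) {
  ev <- trace$events[trace$events$event == event_name, , drop = FALSE]
  if (nrow(ev) == 0) return(numeric(0))
  d <- trace$data
  sel <- d$time >= ev$start[1] & d$time <= ev$end[1]
  d$fluorescence[sel]
}

#' Extract quenching landmarks from a PAM trace
#'
#' Noise-robust landmark extraction: Fo is the median of the dark window,
#' pulse apexes (Fm, Fm') are the maximum over their pulse windows, and Ft
#' is the median of the steady-state window at the end of the actinic
#' phase (the dedicated `ft_window` if present, otherwise the last 10 s
#' before the light pulse).
#'
#' @param trace A [pam_trace()].
#' @return A [quench_markers()] object.
#' @export
extract_quench_markers <- function(trace) {
  stopifnot(inherits(trace, "pam_trace"))
  fo <- stats::median(.event_values(trace, "fo_window"))
  fm <- max(.event_values(trace, "fm_pulse"))
  fmp_vals <- .event_values(trace, "fmprime_pulse")
  fm_prime <- max(fmp_vals)
  ft_vals <- .event_values(trace, "ft_window")
  if (length(ft_vals) == 0) {
    pulse_start <- trace$events$start[trace$events$event == "fmprime_pulse"][1]
    d <- trace$data
    sel <- d$time >= pulse_start - 10 & d$time < pulse_start
    ft_vals <- d$fluorescence[sel]
  }
  .assert(length(ft_vals) > 0, "no steady-state Ft samples before the light pulse")
  ft <- stats::median(ft_vals)
  quench_markers(fo = fo, fm = fm, ft = min(ft, fm_prime), fm_prime = fm_prime)
}

#' @export
print.pam_trace <- function(x, ...) {
  cat(sprintf("<pam_trace> %d samples over %.0f s; events: %s\n",
              nrow(x$data), diff(range(x$data$time)),
              paste(x$events$event, collapse = ", ")))
  invisible(x)
}
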