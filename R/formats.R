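#' Write an analysis input object to its canonical file form
#'
#' Dispatches on the object class and emits the matching
#' [write_phys_table()] kind, recording any generator ground truth (and
#' seed) from the `truth` attribute in the header so simulated files are
#' self-describing.
#'
#' @param x An [frr_transient()], [pam_trace()], [oxygen_trace()],
#'   `pe_data`, `diel_series`, or growth records data.frame.
#' @param path Output file path.
#' @param ... Unused.
#' @return `path`, invisibly.
#' @export
write_phys_input <- function(x, path, ...) UseMethod("write_phys_input")

.truth_params <- function(x, extra = list()) {
  tr <- attr(x, "truth")
  if (inherits(tr, "diel_scenario")) {
    flat <- list(noise_sd = tr$noise_sd, ramp_frac = tr$ramp_frac,
                 seed = tr$seed)
    for (nm in names(tr$parameters)) {
      sp <- tr$parameters[[nm]]
      flat[[paste0(nm, ".baseline")]] <- sp$baseline
      flat[[paste0(nm, ".peak_mult")]] <- sp$peak_mult
      flat[[paste0(nm, ".depression")]] <- sp$depression
      flat[[paste0(nm, ".lag")]] <- sp$lag
    }
    tr <- flat
  }
  if (is.null(tr)) tr <- list()
  utils::modifyList(tr[!vapply(tr, is.list, logical(1))], extra)
}

#' @export
write_phys_input.frr_transient <- function(x, path, ...) {
  write_phys_table(x, path, "frr_transient", params = .truth_params(x))
}

#' @export
write_phys_input.pam_trace <- function(x, path, ...) {
  d <- x$data
  d$event <- ""
  ## narrow windows (pulses, steady-state Ft) take precedence where they
  ## overlap wider phase windows
  x$events <- x$events[order(x$events$end - x$events$start), , drop = FALSE]
  for (i in seq_len(nrow(x$events))) {
    sel <- d$time >= x$events$start[i] & d$time <= x$events$end[i]
    d$event[sel & d$event == ""] <- x$events$event[i]
  }
  write_phys_table(d, path, "pam_trace", params = .truth_params(x))
}

#' @export
write_phys_input.oxygen_trace <- function(x, path, ...) {
  write_phys_table(as.data.frame(x), path, "oxygen_trace",
                   params = .truth_params(x, list(chl = attr(x, "chl"))))
}

#' @export
write_phys_input.pe_data <- function(x, path, ...) {
  write_phys_table(as.data.frame(x), path, "pe_table",
                   params = .truth_params(x))
}

#' @export
write_phys_input.diel_series <- function(x, path, ...) {
  write_phys_table(as.data.frame(x), path, "diel_series",
                   params = .truth_params(x))
}

#' @export
write_phys_input.data.frame <- function(x, path, ...) {
  .assert(all(c("t", "c", "dilution_flag") %in% names(x)),
          "plain data.frame inputs must be growth records (t, c, dilution_flag)")
  write_phys_table(x, path, "growth", params = .truth_params(x))
}

#' Read an analysis input file back into its object form
#'
#' Inverse of [write_phys_input()]: detects the kind from the header and
#' rebuilds the matching object (including event windows for PAM traces
#' and the chlorophyll attribute for oxygen traces).
#'
#' @param path File written by [write_phys_input()]/[write_phys_table()].
#' @param kind Optional expected kind (error if the file declares another).
#' @return The reconstructed object; header parameters stay attached as
#'   the `params` attribute.
#' @export
read_phys_input <- function(path, kind = NULL) {
  tab <- read_phys_table(path, kind = kind)
  params <- attr(tab, "params")
  kind <- attr(tab, "kind")
  out <- switch(
    kind,
    frr_transient = frr_transient(tab$dose, tab$fluorescence),
    pam_trace = {
      ev_rows <- tab[tab$event != "", , drop = FALSE]
      .assert(nrow(ev_rows) > 0, "PAM file has no event labels")
      agg <- do.call(rbind, lapply(split(ev_rows, ev_rows$event), function(d) {
        data.frame(event = d$event[1], start = min(d$time), end = max(d$time))
      }))
      agg <- agg[order(agg$start), , drop = FALSE]
      pam_trace(tab$time, tab$fluorescence, agg)
    },
    oxygen_trace = {
      .assert(!is.null(params$chl), "oxygen file header lacks 'param chl'")
      oxygen_trace(tab$time, tab$o2, tab$phase, chl = params$chl)
    },
    pe_table = {
      out <- data.frame(e = tab$e, p = tab$p)
      class(out) <- c("pe_data", "data.frame")
      out
    },
    diel_series = diel_series(tab$time, tab$parameter, tab$value,
                              tab$irradiance),
    growth = data.frame(t = tab$t, c = tab$c,
                        dilution_flag = as.logical(tab$dilution_flag)),
    composition = tab,
    stop("unsupported kind: ", kind)
  )
  attr(out, "params") <- params
  attr(out, "kind") <- kind
  out
}
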