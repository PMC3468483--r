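## Registered file kinds: required columns and their unit strings. Files
## are comma-separated UTF-8 with a comment header recording the kind, the
## column units, and any generator parameters (including the seed).

.schemas <- list(
  frr_transient = c(flashlet = "index", dose = "photons A-2",
                    fluorescence = "relative"),
  pam_trace = c(time = "s", fluorescence = "relative", event = "label"),
  oxygen_trace = c(time = "s", o2 = "umol O2 L-1", phase = "label"),
  pe_table = c(e = "umol photons m-2 s-1", p = "mg C mg chl a-1 h-1"),
  growth = c(t = "day", c = "cells mL-1", dilution_flag = "logical"),
  diel_series = c(time = "h", parameter = "label", value = "as declared",
                  irradiance = "umol photons m-2 s-1"),
  composition = c(treatment = "label", diameter_um = "um",
                  c_quota_pg = "pg cell-1", n_quota_pg = "pg cell-1",
                  chl_quota_pg = "pg cell-1")
)

#' Write a typed delimited-text table
#'
#' Emits the canonical on-disk form of each data kind: `#`-prefixed header
#' lines carrying the kind, the column units, and any parameters (e.g. the
#' generator ground truth and seed), followed by a CSV body. Written files
#' round-trip losslessly through [read_phys_table()].
#'
#' @param x data.frame whose columns include the schema of `kind`.
#' @param path Output file path.
#' @param kind One of `"frr_transient"`, `"pam_trace"`, `"oxygen_trace"`,
#'   `"pe_table"`, `"growth"`, `"diel_series"`, `"composition"`.
#' @param params Optional named list recorded in the header (scalars only).
#' @return `path`, invisibly.
#' @export
write_phys_table <- function(x, path, kind, params = NULL) {
  .assert(kind %in% names(.schemas),
          paste("unknown kind; use one of:", paste(names(.schemas), collapse = ", ")))
  schema <- .schemas[[kind]]
  missing_cols <- setdiff(names(schema), names(x))
  .assert(length(missing_cols) == 0,
          paste("missing columns for", kind, ":", paste(missing_cols, collapse = ", ")))
  x <- as.data.frame(x)[names(schema)]
  header <- c(
    sprintf("# phytophys: %s", kind),
    sprintf("# units: %s", paste(sprintf("%s=%s", names(schema), schema),
                                 collapse = "; "))
  )
  if (!is.null(params)) {
    keep <- !vapply(params, is.null, logical(1))
    params <- params[keep]
    flat <- vapply(params, function(v) paste(format(v, digits = 17), collapse = ","),
                   character(1))
    header <- c(header, sprintf("# param %s: %s", names(flat), flat))
  }
  ## serialise doubles at full precision so files round-trip losslessly
  for (col in names(x)) {
    if (is.double(x[[col]])) x[[col]] <- sprintf("%.17g", x[[col]])
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(x, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a typed delimited-text table
#'
#' Strictly validates the header against the declared schema: the kind
#' line must match, every schema column must be present (by name, order
#' free), and the recorded units must equal the schema's units. Violations
#' raise named errors with the offending header line number.
#'
#' @param path File written by [write_phys_table()] (or hand-built to the
#'   same layout).
#' @param kind Expected kind; `NULL` accepts whatever the file declares.
#' @return data.frame with schema columns first; header parameters are
#'   attached as the `params` attribute and the kind as `kind`.
#' @export
read_phys_table <- function(path, kind = NULL) {
  .assert(file.exists(path), paste("file not found:", path))
  lines <- readLines(path, encoding = "UTF-8")
  hdr_idx <- grep("^#", lines)
  .assert(length(hdr_idx) >= 2 && identical(hdr_idx, seq_along(hdr_idx)),
          "malformed file: expected a leading '#' header block")
  header <- lines[hdr_idx]

  kind_line <- grep("^# phytophys:", header)
  .assert(length(kind_line) == 1, "header line 1: missing '# phytophys: <kind>'")
  file_kind <- trimws(sub("^# phytophys:", "", header[kind_line]))
  if (!is.null(kind) && !identical(file_kind, kind)) {
    stop(sprintf("line %d: file is kind '%s', expected '%s'",
                 kind_line, file_kind, kind), call. = FALSE)
  }
  .assert(file_kind %in% names(.schemas),
          sprintf("line %d: unknown kind '%s'", kind_line, file_kind))
  schema <- .schemas[[file_kind]]

  units_line <- grep("^# units:", header)
  .assert(length(units_line) == 1, "missing '# units:' header line")
  declared <- strsplit(trimws(sub("^# units:", "", header[units_line])), ";\\s*")[[1]]
  declared_units <- sub("^[^=]*=", "", declared)
  names(declared_units) <- sub("=.*$", "", declared)
  for (col in names(schema)) {
    if (is.na(declared_units[col]) || declared_units[col] != schema[col]) {
      stop(sprintf("line %d: column '%s' must declare units '%s'",
                   units_line, col, schema[col]), call. = FALSE)
    }
  }

  params <- list()
  for (pl in grep("^# param ", header, value = TRUE)) {
    key <- sub("^# param ([^:]+):.*$", "\\1", pl)
    val <- trimws(sub("^# param [^:]+:", "", pl))
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    params[[key]] <- if (anyNA(num)) val else num
  }

  body <- utils::read.csv(text = paste(lines[-hdr_idx], collapse = "\n"),
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(schema), names(body))
  if (length(missing_cols)) {
    stop(sprintf("line %d: missing column(s) %s for kind '%s'",
                 length(header) + 1, paste(missing_cols, collapse = ", "),
                 file_kind), call. = FALSE)
  }
  body <- body[c(names(schema), setdiff(names(body), names(schema)))]
  attr(body, "params") <- params
  attr(body, "kind") <- file_kind
  body
}

#' Build a validated run configuration
#'
#' Central knobs of the analysis chain, with the documented defaults:
#' isotope discrimination 1.05, photosynthetic unit size 0.002 mol RC per
#' mol chl a, chl a molar mass 893.5 g mol^-1, carbon molar mass
#' 12.011 g mol^-1. Unknown keys are rejected so that config typos cannot
#' silently change an analysis.
#'
#' @param ... Overrides for: `seed`, `discrimination`, `rc_per_chl`,
#'   `chl_molar_mass`, `c_molar_mass`, `report_digits`,
#'   `burst_factor`, `hysteresis_bin_frac`.
#' @return List of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(seed = 1L, discrimination = 1.05, rc_per_chl = 0.002,
                   chl_molar_mass = CHL_A_MOLAR_MASS,
                   c_molar_mass = C_MOLAR_MASS, report_digits = 4,
                   burst_factor = 1.5, hysteresis_bin_frac = 0.1)
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(defaults))
  .assert(length(unknown) == 0,
          paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, over)
  for (key in c("discrimination", "rc_per_chl", "chl_molar_mass",
                "c_molar_mass", "burst_factor", "hysteresis_bin_frac")) {
    .assert(.is_num(cfg[[key]]) && cfg[[key]] > 0,
            paste("config constant", key, "must be positive"))
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file of key-value pairs (see [run_config()] for keys).
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  .assert(file.exists(path), paste("config file not found:", path))
  run_config(yaml::read_yaml(path))
}
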