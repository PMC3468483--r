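#' Construct a fluorescence emission spectrum
#'
#' @param wavelength Wavelengths in nm, strictly increasing.
#' @param intensity Non-negative intensities, relative units.
#' @param temperature `"RT"` (room temperature) or `"77K"`.
#' @return A data.frame of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelength, intensity, temperature = c("RT", "77K")) {
  temperature <- match.arg(temperature)
  .assert(is.numeric(wavelength) && is.numeric(intensity) &&
            length(wavelength) == length(intensity),
          "wavelength and intensity must be numeric vectors of equal length")
  .assert(!is.unsorted(wavelength, strictly = TRUE),
          "wavelengths must be strictly increasing")
  .assert(all(is.finite(intensity)) && all(intensity >= 0),
          "intensities must be finite and >= 0")
  out <- data.frame(wavelength = wavelength, intensity = intensity)
  attr(out, "temperature") <- temperature
  class(out) <- c("emission_spectrum", "data.frame")
  out
}

#' Normalise an emission spectrum to a reference wavelength
#'
#' Divides intensities by the (interpolated) intensity at the reference
#' wavelength so that the spectrum equals 1 there, preserving all shape
#' ratios. 77K chlorophyll spectra are conventionally normalised at 690 nm;
#' `reference = "max"` normalises at the spectrum maximum instead. The
#' operation is idempotent and scale-invariant.
#'
#' @param spectrum An [emission_spectrum()].
#' @param reference Reference wavelength in nm (must lie inside the
#'   measured range), or `"max"`.
#' @return The normalised `emission_spectrum`.
#' @export
normalize_spectrum <- function(spectrum, reference = 690) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  wl <- spectrum$wavelength
  if (identical(reference, "max")) {
    ref_val <- max(spectrum$intensity)
  } else {
    .assert(.is_num(reference), "reference must be a wavelength or \"max\"")
    .assert(reference >= min(wl) && reference <= max(wl),
            "reference wavelength outside the measured range")
    ref_val <- stats::approx(wl, spectrum$intensity, xout = reference)$y
  }
  if (ref_val <= 0) stop("zero intensity at the reference wavelength",
                         call. = FALSE)
  out <- emission_spectrum(wl, spectrum$intensity / ref_val,
                           attr(spectrum, "temperature"))
  out
}

#' Locate emission peaks and shoulders
#'
#' Finds local maxima above a prominence threshold, refining each position
#' by parabolic interpolation through the three samples around the maximum
#' (sub-sample wavelength resolution). Shoulders - bands that modulate a
#' flank without forming a strict maximum, such as red-shifted antenna
#' emission near 710-712 nm - are detected as interior local minima of the
#' second derivative (negative-curvature pockets) away from reported peaks.
#'
#' @param spectrum An [emission_spectrum()] with at least 5 points.
#' @param min_prominence Minimum peak prominence, same units as intensity
#'   (default 0.05; spectra are typically normalised first).
#' @param shoulders Also report shoulders? Default `TRUE`.
#' @param min_separation Minimum distance (nm) between a shoulder and a
#'   reported peak (default 5 nm).
#' @return data.frame with columns `wavelength`, `height` (relative to the
#'   spectrum maximum), `type` (`"peak"` or `"shoulder"`); zero rows for a
#'   flat or monotone spectrum.
#' @export
locate_emission_peaks <- function(spectrum, min_prominence = 0.05,
                                  shoulders = TRUE, min_separation = 5) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  wl <- spectrum$wavelength
  y <- spectrum$intensity
  n <- length(y)
  .assert(n >= 5, "need at least 5 spectral points")
  .assert(.is_num(min_prominence) && min_prominence >= 0,
          "min_prominence must be >= 0")
  ymax <- max(y)
  empty <- data.frame(wavelength = numeric(0), height = numeric(0),
                      type = character(0))
  if (ymax <= 0 || diff(range(y)) == 0) return(empty)

  ## strict interior local maxima
  idx <- which(diff(sign(diff(y))) == -2) + 1L
  keep <- vapply(idx, function(i) .prominence(y, i) >= min_prominence,
                 logical(1))
  idx <- idx[keep]
  res <- lapply(idx, function(i) .parabolic_vertex(wl, y, i))
  peaks <- if (length(res)) {
    data.frame(wavelength = vapply(res, `[[`, 0, "x"),
               height = vapply(res, `[[`, 0, "y") / ymax,
               type = "peak")
  } else empty

  if (shoulders) {
    d2 <- .second_derivative(wl, y)
    ## interior local minima of curvature that are genuinely negative
    cand <- which(diff(sign(diff(d2))) == 2) + 1L
    cand <- cand[d2[cand] < -1e-8 * ymax]
    if (length(peaks$wavelength)) {
      near_peak <- vapply(cand, function(i) {
        any(abs(wl[i] - peaks$wavelength) < min_separation)
      }, logical(1))
      cand <- cand[!near_peak]
    }
    if (length(cand)) {
      sh <- data.frame(wavelength = wl[cand], height = y[cand] / ymax,
                       type = "shoulder")
      peaks <- rbind(peaks, sh)
    }
  }
  peaks[order(peaks$wavelength), , drop = FALSE]
}

## Topographic prominence of the local maximum at index i: height above the
## higher of the two minima separating it from higher terrain (or the edge).
.prominence <- function(y, i) {
  left <- y[seq_len(i - 1)]
  right <- y[seq(i + 1, length(y))]
  higher_l <- which(left > y[i])
  base_l <- if (length(higher_l)) min(left[seq(max(higher_l), i - 1)]) else min(left)
  higher_r <- which(right > y[i])
  base_r <- if (length(higher_r)) min(right[seq_len(min(higher_r))]) else min(right)
  y[i] - max(base_l, base_r)
}

## Vertex of the parabola through (x,y) at i-1, i, i+1.
.parabolic_vertex <- function(x, y, i) {
  x0 <- x[i - 1]; x1 <- x[i]; x2 <- x[i + 1]
  y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
  denom <- (x0 - x1) * (x0 - x2) * (x1 - x2)
  a <- (x2 * (y1 - y0) + x1 * (y0 - y2) + x0 * (y2 - y1)) / denom
  b <- (x2^2 * (y0 - y1) + x1^2 * (y2 - y0) + x0^2 * (y1 - y2)) / denom
  if (a >= 0) return(list(x = x1, y = y1)) # degenerate; keep the sample
  xv <- -b / (2 * a)
  cpar <- y1 - a * x1^2 - b * x1
  list(x = xv, y = a * xv^2 + b * xv + cpar)
}

## Central-difference second derivative on a (possibly uneven) grid.
.second_derivative <- function(x, y) {
  n <- length(y)
  d2 <- numeric(n)
  for (i in 2:(n - 1)) {
    h1 <- x[i] - x[i - 1]
    h2 <- x[i + 1] - x[i]
    d2[i] <- 2 * (h1 * y[i + 1] - (h1 + h2) * y[i] + h2 * y[i - 1]) /
      (h1 * h2 * (h1 + h2))
  }
  d2[1] <- d2[2]
  d2[n] <- d2[n - 1]
  d2
}
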