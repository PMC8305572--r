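#' 1D NMR spectrum container
#'
#' Bundles a processed (Fourier-transformed, phased, baseline-corrected)
#' one-dimensional NMR spectrum: a chemical-shift axis in ppm, strictly
#' decreasing with index (the conventional left-to-right NMR orientation),
#' and the matching real intensity vector. All downstream computation
#' (peak picking, fitting, integration) works in data-point units; the ppm
#' axis is carried along for reporting and region selection.
#'
#' Data-point indices are 0-based throughout the package: index 0 is the
#' highest-ppm (leftmost) point. Fractional positions, e.g. fitted peak
#' centers, use the same convention.
#'
#' @param ppm Numeric vector of chemical shifts in ppm, strictly
#'   monotonically decreasing.
#' @param intensity Numeric vector of intensities, same length as `ppm`.
#' @param sf_hz Spectrometer proton frequency in Hz (metadata, optional).
#' @param source Provenance string (file path, "synthetic", ...).
#' @param excluded Optional logical vector marking points excluded from
#'   peak detection and error computation (e.g. a removed water region).
#'   Defaults to all `FALSE`.
#'
#' @return An object of class `spectrum1d`: a list with elements `ppm`,
#'   `intensity`, `n_points`, `sf_hz`, `source`, `excluded`.
#' @examples
#' s <- spectrum1d(ppm = seq(10, 0.5, length.out = 64), intensity = rnorm(64)^2)
#' s
#' @export
spectrum1d <- function(ppm, intensity, sf_hz = NA_real_, source = "memory",
                       excluded = NULL) {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  n <- length(ppm)
  if (length(intensity) != n) {
    stop("`ppm` and `intensity` must have the same length", call. = FALSE)
  }
  if (n <= 3L) {
    stop("a spectrum needs more than 3 data points", call. = FALSE)
  }
  if (anyNA(ppm) || any(!is.finite(ppm))) {
    stop("`ppm` contains non-finite values", call. = FALSE)
  }
  if (anyNA(intensity) || any(!is.finite(intensity))) {
    stop("`intensity` contains non-finite values", call. = FALSE)
  }
  if (any(diff(ppm) >= 0)) {
    stop("`ppm` must be strictly monotonically decreasing", call. = FALSE)
  }
  if (is.null(excluded)) {
    excluded <- logical(n)
  } else {
    excluded <- as.logical(excluded)
    if (length(excluded) != n || anyNA(excluded)) {
      stop("`excluded` must be a logical vector matching the spectrum length",
           call. = FALSE)
    }
  }
  structure(
    list(ppm = ppm, intensity = intensity, n_points = n,
         sf_hz = as.numeric(sf_hz)[1], source = as.character(source)[1],
         excluded = excluded),
    class = "spectrum1d"
  )
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d> %d points, %.4f .. %.4f ppm\n",
              x$n_points, x$ppm[1], x$ppm[x$n_points]))
  if (is.finite(x$sf_hz)) {
    cat(sprintf("  spectrometer frequency: %.2f MHz\n", x$sf_hz / 1e6))
  }
  if (any(x$excluded)) {
    cat(sprintf("  excluded points: %d\n", sum(x$excluded)))
  }
  cat(sprintf("  source: %s\n", x$source))
  invisible(x)
}

#' Test for the spectrum class
#' @param x Object to test.
#' @return `TRUE` if `x` is a `spectrum1d`.
#' @export
is_spectrum1d <- function(x) inherits(x, "spectrum1d")

# Mean ppm spacing per data point (> 0; axis is decreasing).
ppm_step <- function(spectrum) {
  (spectrum$ppm[1] - spectrum$ppm[spectrum$n_points]) / (spectrum$n_points - 1)
}

#' Convert between 0-based data-point positions and ppm
#'
#' Positions may be fractional (fitted peak centers). The conversion uses
#' the spectrum's uniform grid: `ppm = ppm[0] - x * step`.
#'
#' @param spectrum A [spectrum1d()] object.
#' @param x_pts Numeric vector of 0-based data-point positions.
#' @return `pts_to_ppm()`: ppm values; `ppm_to_pts()`: 0-based positions.
#' @export
pts_to_ppm <- function(spectrum, x_pts) {
  spectrum$ppm[1] - x_pts * ppm_step(spectrum)
}

#' @rdname pts_to_ppm
#' @param ppm Numeric vector of chemical shifts in ppm.
#' @export
ppm_to_pts <- function(spectrum, ppm) {
  (spectrum$ppm[1] - ppm) / ppm_step(spectrum)
}

# Indices (1-based, for internal vector access) of points whose ppm lies
# inside the closed interval `region` (length-2 numeric, any order).
region_indices <- function(spectrum, region) {
  region <- sort(as.numeric(region))
  which(spectrum$ppm >= region[1] & spectrum$ppm <= region[2])
}
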