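#' Blank the residual water artifact
#'
#' Sets intensities inside the given ppm interval to zero and flags the
#' points as excluded, so that peak detection and error computation skip
#' them. Points are flagged rather than deleted: index arithmetic and the
#' upper integration border of the closed-form integral stay consistent
#' with the original grid.
#'
#' There is no default region: the water position depends on field,
#' temperature and lock solvent, so it is a required user input.
#'
#' @param spectrum A [spectrum1d()] object.
#' @param region Length-2 numeric ppm interval (any order).
#' @return The spectrum with the region zeroed and flagged.
#' @export
remove_water <- function(spectrum, region) {
  stopifnot(is_spectrum1d(spectrum))
  region <- sort(as.numeric(region))
  if (length(region) != 2L || anyNA(region)) {
    stop("`region` must be a length-2 numeric ppm interval", call. = FALSE)
  }
  rng <- range(spectrum$ppm)
  if (region[2] < rng[1] || region[1] > rng[2]) {
    stop("water region lies entirely outside the spectrum", call. = FALSE)
  }
  idx <- region_indices(spectrum, region)
  spectrum$intensity[idx] <- 0
  spectrum$excluded[idx] <- TRUE
  spectrum
}

#' Convert intensities to absolute values
#'
#' After phasing and baseline correction small negative excursions
#' remain; taking magnitudes guarantees the positivity the 3-point
#' Lorentzian solve requires. Idempotent.
#'
#' @param spectrum A [spectrum1d()] object.
#' @return The spectrum with `intensity = |intensity|`.
#' @export
absolute_value <- function(spectrum) {
  stopifnot(is_spectrum1d(spectrum))
  spectrum$intensity <- abs(spectrum$intensity)
  spectrum
}

#' Running-mean smoothing
#'
#' Each pass replaces every intensity by the mean of itself and its
#' `half_width` neighbors on either side (a "2,5-mean" smoothing for
#' `half_width = 2`: a 5-point window, 2 per side). Windows are truncated
#' at the spectrum edges, i.e. the mean runs over the neighbors that
#' exist. Passes are applied sequentially. Smoothing suppresses noise
#' maxima that would otherwise seed spurious peak triplets.
#'
#' @param spectrum A [spectrum1d()] object or bare numeric vector.
#' @param half_width Neighbors per side (default 2).
#' @param passes Number of passes (default 2).
#' @return Same type as the input, smoothed.
#' @export
mean_smooth <- function(spectrum, half_width = 2, passes = 2) {
  half_width <- as.integer(half_width)
  passes <- as.integer(passes)
  if (half_width < 0L) stop("`half_width` must be >= 0", call. = FALSE)
  if (passes < 0L) stop("`passes` must be >= 0", call. = FALSE)
  if (is_spectrum1d(spectrum)) {
    y <- spectrum$intensity
  } else {
    y <- as.numeric(spectrum)
  }
  for (p in seq_len(passes)) y <- running_mean(y, half_width)
  if (is_spectrum1d(spectrum)) {
    spectrum$intensity <- y
    spectrum
  } else {
    y
  }
}

# One truncated-window running mean, O(n) via cumulative sums.
running_mean <- function(y, h) {
  if (h == 0L) return(y)
  n <- length(y)
  cs <- cumsum(c(0, y))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Standard preprocessing chain
#'
#' Water removal (optional), conversion to absolute values, then
#' repeated running-mean smoothing — the steps applied to an already
#' Fourier-transformed, phased and baseline-corrected spectrum before
#' deconvolution, in that order.
#'
#' @inheritParams mean_smooth
#' @param water_region ppm interval to blank, or `NULL` to skip (e.g.
#'   for synthetic spectra without a water artifact).
#' @return The preprocessed [spectrum1d()].
#' @export
preprocess <- function(spectrum, water_region = NULL, half_width = 2,
                       passes = 2) {
  stopifnot(is_spectrum1d(spectrum))
  if (!is.null(water_region)) {
    spectrum <- remove_water(spectrum, water_region)
  }
  spectrum <- absolute_value(spectrum)
  mean_smooth(spectrum, half_width = half_width, passes = passes)
}
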