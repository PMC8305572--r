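#' Discrete second derivative
#'
#' Central second difference in data-point units,
#' `y''[i] = y[i-1] - 2 y[i] + y[i+1]`, with the two endpoints set to 0.
#' Inflection points of the smoothed spectrum (sign changes of this
#' vector) delimit the curvature core of each peak.
#'
#' @param spectrum A [spectrum1d()] object or numeric vector of at least
#'   3 points.
#' @return Numeric vector, same length as the input.
#' @export
second_derivative <- function(spectrum) {
  y <- if (is_spectrum1d(spectrum)) spectrum$intensity else as.numeric(spectrum)
  n <- length(y)
  if (n < 3L) stop("need at least 3 points for a second derivative",
                   call. = FALSE)
  c(0, y[1:(n - 2L)] - 2 * y[2:(n - 1L)] + y[3:n], 0)
}

#' Curvature-based peak-triplet detection
#'
#' A data point `x` is a triplet center when `y''(x) < 0` and
#' `y''(x+1) > y''(x) <= y''(x-1)`, i.e. a local minimum of the second
#' derivative inside a region of negative curvature — a local maximum of
#' the spectrum, including shoulders of partly overlapped signals that
#' never form a maximum of the intensity itself. The left and right
#' triplet points are found by walking outward from the center to the
#' nearest second-derivative zero crossing, local maximum, or plateau
#' (two consecutive equal values within a 1e-12 relative tolerance).
#'
#' Triplets whose center lies in an excluded (water) region are dropped,
#' as are triplets whose flank walk reaches the spectrum edge or an
#' excluded point before any stopping criterion — such a triplet has no
#' complete 3-point system to solve.
#'
#' @param spectrum The (preprocessed) [spectrum1d()].
#' @param d2 Second derivative of `spectrum`; computed if missing.
#' @return A data frame of class `peak_triplets`, sorted by center, with
#'   0-based index columns `i_left`, `i_middle`, `i_right`, intensity
#'   columns `y_left`, `y_middle`, `y_right`, and a `score` column
#'   (filled by [score_and_filter()], `NA` here).
#' @export
detect_triplets <- function(spectrum, d2 = second_derivative(spectrum)) {
  stopifnot(is_spectrum1d(spectrum))
  n <- spectrum$n_points
  if (length(d2) != n) stop("`d2` length must match the spectrum",
                            call. = FALSE)
  i <- 2:(n - 1L)
  is_center <- d2[i] < 0 & d2[i + 1L] > d2[i] & d2[i] <= d2[i - 1L]
  centers <- i[is_center]
  centers <- centers[!spectrum$excluded[centers]]
  if (length(centers) == 0L) return(empty_triplets())

  excl <- spectrum$excluded
  left <- integer(length(centers))
  right <- integer(length(centers))
  for (k in seq_along(centers)) {
    left[k] <- walk_flank(d2, excl, centers[k], -1L)
    right[k] <- walk_flank(d2, excl, centers[k], +1L)
  }
  ok <- !is.na(left) & !is.na(right)
  centers <- centers[ok]; left <- left[ok]; right <- right[ok]
  if (length(centers) == 0L) return(empty_triplets())
  y <- spectrum$intensity
  structure(
    data.frame(
      i_left = left - 1L, i_middle = centers - 1L, i_right = right - 1L,
      y_left = y[left], y_middle = y[centers], y_right = y[right],
      d2_middle = d2[centers],
      score = NA_real_
    ),
    class = c("peak_triplets", "data.frame")
  )
}

empty_triplets <- function() {
  structure(
    data.frame(i_left = integer(), i_middle = integer(), i_right = integer(),
               y_left = numeric(), y_middle = numeric(), y_right = numeric(),
               d2_middle = numeric(), score = numeric()),
    class = c("peak_triplets", "data.frame")
  )
}

# Walk outward from center `c` in direction `dir` (+1 right / -1 left)
# until the second derivative crosses zero, attains a local maximum, or
# plateaus. Returns the 1-based stopping index, or NA if the spectrum
# edge or an excluded point is reached first.
walk_flank <- function(d2, excl, c, dir) {
  n <- length(d2)
  j <- c + dir
  while (j > 1L && j < n) {
    if (excl[j]) return(NA_integer_)
    if (d2[j] >= 0) return(j)                      # zero crossing
    prev <- j - dir
    nxt <- j + dir
    tol <- 1e-12 * max(abs(d2[j]), abs(d2[prev]), abs(d2[nxt]))
    if (abs(d2[j] - d2[nxt]) <= tol) return(j)     # plateau
    if (d2[j] > d2[prev] && d2[j] >= d2[nxt]) return(j)  # local max of d2
    j <- j + dir
  }
  NA_integer_  # fell off the spectrum edge
}

#' Noise filtering of peak triplets
#'
#' Scores every triplet and keeps it only if the score exceeds
#' `mean + delta * sd` of the same score statistic evaluated over a
#' user-declared signal-free noise region. `delta` is the user-set
#' signal-to-noise threshold multiple; it should be checked by visual
#' inspection of which triplets survive (see the package vignette).
#'
#' Two score statistics are available. `"curvature"` (the default)
#' scores a triplet by the negated second derivative at its center,
#' `-y''(i_middle)`, against the distribution of `-y''` over the noise
#' region. Curvature discriminates sharply: a genuine Lorentzian line of
#' height `h` has center curvature of order `2 h / lambda^2`, while
#' noise wiggles — including wiggles riding on the high-intensity tail
#' of a strong line — have curvature at the noise scale regardless of
#' the local intensity. `"intensity"` scores by the smoothed intensity
#' at the center against the noise-region intensities; it is the
#' simpler statistic but cannot reject spurious triplets sitting on the
#' tails of strong signals, where the intensity is far above the noise
#' floor, and those tail triplets bias the integrals of strong lines
#' downward in the subsequent height adjustment.
#'
#' The noise region must be signal-free; if it holds fewer than 30
#' points, or above-threshold centers remain inside it after filtering,
#' the function warns and proceeds, since the threshold is a user
#' responsibility.
#'
#' @param triplets Result of [detect_triplets()].
#' @param spectrum The same (preprocessed) spectrum the triplets came from.
#' @param delta Nonnegative threshold multiplier.
#' @param noise_region Length-2 ppm interval declared signal-free.
#' @param score Score statistic, `"curvature"` or `"intensity"`.
#' @return The surviving triplets (order preserved) with the `score`
#'   column filled; attributes `noise_mean`, `noise_sd` and `threshold`
#'   record the statistics used.
#' @export
score_and_filter <- function(triplets, spectrum, delta, noise_region,
                             score = c("curvature", "intensity")) {
  stopifnot(is_spectrum1d(spectrum))
  score <- match.arg(score)
  delta <- as.numeric(delta)
  if (length(delta) != 1L || is.na(delta) || delta < 0) {
    stop("`delta` must be a single nonnegative number", call. = FALSE)
  }
  idx <- region_indices(spectrum, noise_region)
  idx <- idx[!spectrum$excluded[idx]]
  if (length(idx) < 30L) {
    warning("noise region holds fewer than 30 points; ",
            "threshold statistics will be unstable", call. = FALSE)
  }
  if (score == "curvature") {
    d2 <- second_derivative(spectrum)
    noise <- -d2[idx]
    triplets$score <- -triplets$d2_middle
  } else {
    noise <- spectrum$intensity[idx]
    triplets$score <- triplets$y_middle
  }
  m <- mean(noise)
  s <- stats::sd(noise)
  threshold <- m + delta * s
  out <- triplets[triplets$score > threshold, , drop = FALSE]
  if (any((out$i_middle + 1L) %in% idx)) {
    warning("noise region contains above-threshold triplet centers; ",
            "it may not be signal-free", call. = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "noise_mean") <- m
  attr(out, "noise_sd") <- s
  attr(out, "threshold") <- threshold
  out
}

#' Equidistant bucket count for a ppm region
#'
#' Number of fixed-width buckets a region supports,
#' `floor((upper - lower) / width)`, the conventional comparison point
#' for deconvolution versus spectral binning. A 1e-9 relative tolerance
#' absorbs IEEE rounding when the ratio is an exact integer (e.g. a
#' 4.10 ppm region at 0.01 ppm is 410 buckets, not 409).
#'
#' @param region Length-2 ppm interval.
#' @param width Bucket width in ppm, > 0.
#' @return Integer bucket count.
#' @examples
#' count_buckets(c(0.50, 4.60), 0.01)  # 410
#' @export
count_buckets <- function(region, width) {
  region <- as.numeric(region)
  width <- as.numeric(width)
  if (length(region) != 2L || anyNA(region) || region[1] >= region[2]) {
    stop("`region` must be an interval with lower < upper", call. = FALSE)
  }
  if (length(width) != 1L || is.na(width) || width <= 0) {
    stop("`width` must be a positive number", call. = FALSE)
  }
  ratio <- (region[2] - region[1]) / width
  as.integer(floor(ratio + 1e-9 * max(1, ratio)))
}
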