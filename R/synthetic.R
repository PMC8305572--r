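#' Generate a synthetic 1D NMR spectrum with known ground truth
#'
#' Sums Lorentzian lines on a uniform decreasing ppm axis and optionally
#' adds i.i.d. Gaussian noise, emulating a processed 1H spectrum (128 k
#' real points over 14 to -2 ppm by default, typical of a 600 MHz
#' instrument). The true parameters are returned alongside so every
#' pipeline stage can be validated against ground truth.
#'
#' Peak amplitudes are specified in ppm units: each row of `peaks` gives
#' the Lorentzian scale `A` (full-line area `A * pi` in
#' intensity-times-ppm), the half width at half height `lambda_ppm`, and
#' the center `x0_ppm`. The returned truth table also carries the
#' equivalent data-point-unit parameters (`A_pts`, `lambda_pts`,
#' `x0_pts`) for direct comparison with fitted values.
#'
#' The noise model is additive Gaussian on the intensities; magnitude
#' spectra of real instruments have slightly heavier-tailed noise, which
#' this generator does not emulate.
#'
#' @param peaks Data frame with columns `A`, `lambda_ppm`, `x0_ppm`.
#' @param n_points Number of data points (default 131072, i.e. 128 k).
#' @param ppm_range Length-2 vector, first element the high-ppm edge
#'   (default `c(14, -2)`). Following the processed-data convention the
#'   axis starts at the high edge and the last point stops one step
#'   short of the low edge.
#' @param noise_sd Gaussian noise standard deviation relative to the
#'   maximum peak height of the noise-free spectrum (default 0).
#' @param seed Integer seed; when given, the spectrum is bit-identical
#'   across calls.
#' @param sf_hz Spectrometer frequency metadata (default 600 MHz).
#' @return A list: `spectrum` (a [spectrum1d()]) and `truth` (the peak
#'   table augmented with point-unit parameters and peak heights).
#' @examples
#' s <- synthetic_spectrum(data.frame(A = 1, lambda_ppm = 0.002, x0_ppm = 5),
#'                         n_points = 4096, ppm_range = c(10, 0), seed = 1)
#' max(s$spectrum$intensity) * s$truth$lambda_ppm  # ~ A
#' @export
synthetic_spectrum <- function(peaks, n_points = 131072,
                               ppm_range = c(14, -2), noise_sd = 0,
                               seed = NULL, sf_hz = 6e8) {
  stopifnot(is.data.frame(peaks),
            all(c("A", "lambda_ppm", "x0_ppm") %in% names(peaks)))
  n_points <- as.integer(n_points)
  if (n_points <= 3L) stop("`n_points` must exceed 3", call. = FALSE)
  hi <- ppm_range[1]; lo <- ppm_range[2]
  if (!(hi > lo)) stop("`ppm_range` must be (high, low)", call. = FALSE)
  if (any(peaks$lambda_ppm <= 0)) stop("all lambda must be > 0", call. = FALSE)
  if (any(peaks$x0_ppm >= hi | peaks$x0_ppm <= lo)) {
    stop("all peak centers must lie inside `ppm_range`", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)

  step <- (hi - lo) / n_points
  ppm <- hi - (0:(n_points - 1L)) * step
  y <- numeric(n_points)
  for (k in seq_len(nrow(peaks))) {
    lam <- peaks$lambda_ppm[k]
    y <- y + peaks$A[k] * lam / (lam^2 + (ppm - peaks$x0_ppm[k])^2)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (noise_sd > 0) {
    y <- y + stats::rnorm(n_points, sd = noise_sd * max(abs(y)))
  }
  truth <- peaks
  truth$height <- truth$A / truth$lambda_ppm
  truth$A_pts <- truth$A / step
  truth$lambda_pts <- truth$lambda_ppm / step
  truth$x0_pts <- (hi - truth$x0_ppm) / step
  list(spectrum = spectrum1d(ppm, y, sf_hz = sf_hz, source = "synthetic"),
       truth = truth)
}

#' Random peak table for simulation studies
#'
#' Draws peak positions uniformly inside a ppm window, half widths
#' uniformly from a realistic range (0.0005-0.003 ppm, roughly 0.3-1.8
#' Hz at 600 MHz), and areas log-uniformly over a given number of
#' decades, emulating the spread of metabolite signal intensities in a
#' biofluid spectrum.
#'
#' @param n Number of peaks.
#' @param ppm_window Length-2 interval for the centers (default
#'   `c(0.5, 9.5)`).
#' @param lambda_range Half-width range in ppm (default
#'   `c(0.0005, 0.003)`).
#' @param area_decades Orders of magnitude spanned by the areas
#'   (default 2).
#' @param seed Integer seed.
#' @return Data frame with columns `A`, `lambda_ppm`, `x0_ppm` for
#'   [synthetic_spectrum()].
#' @export
random_peak_table <- function(n, ppm_window = c(0.5, 9.5),
                              lambda_range = c(0.0005, 0.003),
                              area_decades = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  area <- 10^stats::runif(n, 0, area_decades)
  data.frame(
    A = area / pi,
    lambda_ppm = stats::runif(n, lambda_range[1], lambda_range[2]),
    x0_ppm = stats::runif(n, min(ppm_window), max(ppm_window))
  )
}

# The Latin-square design's ten metabolites: one representative singlet
# position each (ppm) and the number of contributing protons. TMAO is
# placed at 3.27 ppm: at 3.25 it would exactly overlap the betaine
# singlet, which no line-shape method can separate (a documented
# limitation), so the generator keeps the signals resolvable.
latin_square_metabolites <- function() {
  data.frame(
    name = c("alanine", "acetate", "citrate", "creatinine", "betaine",
             "TMAO", "taurine", "glycine", "ethanolamine", "histidine"),
    x0_ppm = c(1.48, 1.91, 2.56, 3.05, 3.25, 3.27, 3.41, 3.56, 3.81, 7.05),
    n_protons = c(3L, 3L, 4L, 3L, 9L, 9L, 2L, 2L, 2L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Synthetic Latin-square dilution series
#'
#' Emulates the classic validation design for NMR quantification: `n`
#' samples of `n` metabolites whose concentrations follow a cyclically
#' shifted geometric 2-fold dilution series, so each metabolite takes
#' each dilution level exactly once and the total concentration per
#' sample is constant. Every sample carries a constant-concentration
#' reference singlet (a TSP analogue at 0.0 ppm, 9 protons). Each
#' metabolite contributes one singlet whose area is proportional to
#' concentration times proton count.
#'
#' For `n = 10` and `base_conc = 1` the per-metabolite concentrations
#' span 1 down to 1/512 mmol/L.
#'
#' @param n_samples,n_metabolites Design size; must be equal and at most
#'   10 (the built-in singlet table).
#' @param base_conc Highest concentration level (mmol/L, default 1).
#' @param seed Integer seed; sample `s` uses `seed + s` for its noise.
#' @param n_points,ppm_range,sf_hz Passed to [synthetic_spectrum()].
#' @param lambda_ppm Common half width at half height (default 0.0015).
#' @param noise_sd Noise level relative to each sample's maximum peak
#'   height (default `2e-4`, a high-field signal-to-noise ratio of a few
#'   thousand).
#' @param reference_conc Reference concentration (default 1 mmol/L).
#' @return A list: `spectra` (list of [spectrum1d()]), `concentrations`
#'   (samples x metabolites matrix, mmol/L), `metabolites` (name,
#'   `x0_ppm`, `n_protons`), `reference` (list with `name`, `x0_ppm`,
#'   `n_protons`, `conc`), `lambda_ppm`.
#' @export
synthetic_latin_square <- function(n_samples = 10, n_metabolites = 10,
                                   base_conc = 1, seed = NULL,
                                   n_points = 131072, ppm_range = c(14, -2),
                                   lambda_ppm = 0.0015, noise_sd = 2e-4,
                                   reference_conc = 1, sf_hz = 6e8) {
  n_samples <- as.integer(n_samples)
  n_metabolites <- as.integer(n_metabolites)
  if (n_samples != n_metabolites) {
    stop("a Latin square needs n_samples == n_metabolites", call. = FALSE)
  }
  met <- latin_square_metabolites()
  if (n_metabolites < 1L || n_metabolites > nrow(met)) {
    stop(sprintf("`n_metabolites` must be between 1 and %d", nrow(met)),
         call. = FALSE)
  }
  met <- met[seq_len(n_metabolites), , drop = FALSE]
  n <- n_samples
  conc <- matrix(NA_real_, n, n,
                 dimnames = list(paste0("sample_", seq_len(n)), met$name))
  for (s in seq_len(n)) {
    for (m in seq_len(n)) {
      conc[s, m] <- base_conc * 2^(-((s + m - 2L) %% n))
    }
  }
  reference <- list(name = "TSP", x0_ppm = 0.0, n_protons = 9L,
                    conc = reference_conc)
  spectra <- vector("list", n)
  for (s in seq_len(n)) {
    peaks <- data.frame(
      A = c(conc[s, ] * met$n_protons, reference$conc * reference$n_protons) / pi,
      lambda_ppm = lambda_ppm,
      x0_ppm = c(met$x0_ppm, reference$x0_ppm)
    )
    spectra[[s]] <- synthetic_spectrum(
      peaks, n_points = n_points, ppm_range = ppm_range,
      noise_sd = noise_sd,
      seed = if (is.null(seed)) NULL else as.integer(seed) + s,
      sf_hz = sf_hz
    )$spectrum
  }
  list(spectra = spectra, concentrations = conc, metabolites = met,
       reference = reference, lambda_ppm = lambda_ppm)
}
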