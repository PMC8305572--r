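#' Closed-form integral of a fitted Lorentzian
#'
#' Area under `y(x) = A * lambda / (lambda^2 + (x - x0)^2)` from 0 to
#' the upper border `b`,
#' `A * (atan((b - x0) / lambda) - atan((0 - x0) / lambda))`,
#' with `b` the number of data points of the spectrum the peak was
#' fitted on, so the integral runs over the whole recorded axis in
#' data-point units. For a peak far from both borders this approaches
#' the full-line area `A * pi`. All arguments are vectorized.
#'
#' The lower border is fixed at 0 (the start of the spectrum); the
#' truncation error for peaks close to a spectrum edge is not corrected.
#'
#' @param A,lambda_pts,x0_pts Lorentzian parameters in data-point units.
#' @param b Upper integration border = `n_points`, > 0.
#' @return Integral value(s) in intensity-times-points units.
#' @examples
#' integrate_peak(1, 1, 5, 10)  # 2 * atan(5)
#' @export
integrate_peak <- function(A, lambda_pts, x0_pts, b) {
  if (any(b <= 0)) stop("integration border `b` must be > 0", call. = FALSE)
  if (any(lambda_pts <= 0)) stop("`lambda_pts` must be > 0", call. = FALSE)
  A * (atan((b - x0_pts) / lambda_pts) - atan((0 - x0_pts) / lambda_pts))
}

#' Convert signal integrals to concentrations via a reference signal
#'
#' Sums the closed-form integrals of the fitted peaks assigned to each
#' metabolite signal (a multiplet is the sum of its Lorentz components),
#' normalizes by the number of contributing protons, and scales by the
#' known concentration of an internal reference signal (e.g. TSP for
#' urine, formic acid for plasma):
#' `conc(m) = ref_conc * (I_m / n_m) / (I_ref / n_ref) * correction`.
#'
#' Because the result is a ratio of integrals on the same spectrum, the
#' ppm-per-point factor and any global intensity scale cancel; no unit
#' conversion is needed. The optional per-metabolite `correction_factor`
#' (default 1) accommodates known multiplicative biases such as
#' differential T1 relaxation between a metabolite and the reference.
#'
#' @param assignments Data frame with columns `metabolite`, `peak_ids`
#'   (integer vector in a list column, or a semicolon-separated string),
#'   `n_protons`, and optionally `correction_factor`.
#' @param peaks An `nmr_decon` result or a peak data frame with
#'   `peak_id` and `integral` columns.
#' @param reference A single-row assignment (list or data frame row)
#'   with `metabolite`, `peak_ids`, `n_protons` for the reference
#'   signal.
#' @param reference_conc Known reference concentration (mmol/L).
#' @return A data frame of class `quant_table`: `metabolite`,
#'   `summed_integral`, `n_protons`, `concentration`, `units`.
#' @export
quantify <- function(assignments, peaks, reference, reference_conc) {
  peak_df <- if (inherits(peaks, "nmr_decon")) peaks$peaks else peaks
  if (is.null(peak_df$peak_id) || is.null(peak_df$integral)) {
    stop("`peaks` must provide peak_id and integral columns", call. = FALSE)
  }
  reference_conc <- as.numeric(reference_conc)
  if (length(reference_conc) != 1L || is.na(reference_conc) ||
      reference_conc <= 0) {
    stop("`reference_conc` must be a single positive number", call. = FALSE)
  }

  summed <- function(ids, label) {
    ids <- parse_peak_ids(ids)
    if (length(ids) == 0L) {
      stop(sprintf("assignment '%s' lists no peaks", label), call. = FALSE)
    }
    pos <- match(ids, peak_df$peak_id)
    if (anyNA(pos)) {
      stop(sprintf("assignment '%s' references unknown peak id(s): %s",
                   label, paste(ids[is.na(pos)], collapse = ", ")),
           call. = FALSE)
    }
    sum(peak_df$integral[pos])
  }

  ref <- as.list(reference)
  i_ref <- summed(ref$peak_ids, ref$metabolite)
  if (i_ref <= 0) stop("reference integral must be > 0", call. = FALSE)
  ref_per_proton <- i_ref / as.numeric(ref$n_protons)

  n_m <- nrow(assignments)
  out <- data.frame(metabolite = character(n_m),
                    summed_integral = numeric(n_m),
                    n_protons = integer(n_m),
                    concentration = numeric(n_m),
                    units = character(n_m),
                    stringsAsFactors = FALSE)
  corr <- assignments$correction_factor
  if (is.null(corr)) corr <- rep(1, n_m)
  for (i in seq_len(n_m)) {
    im <- summed(assignments$peak_ids[[i]], assignments$metabolite[i])
    np <- as.numeric(assignments$n_protons[i])
    if (is.na(np) || np < 1) {
      stop("`n_protons` must be >= 1", call. = FALSE)
    }
    out$metabolite[i] <- assignments$metabolite[i]
    out$summed_integral[i] <- im
    out$n_protons[i] <- as.integer(np)
    out$concentration[i] <- reference_conc * (im / np) / ref_per_proton *
      corr[i]
    out$units[i] <- "mmol/L"
  }
  class(out) <- c("quant_table", "data.frame")
  out
}

# "1;3;5" or c(1,3,5) or list(c(1,3,5)) -> integer vector
parse_peak_ids <- function(ids) {
  if (is.list(ids)) ids <- ids[[1]]
  if (is.character(ids)) {
    ids <- unlist(strsplit(ids, "[;,]"))
    ids <- ids[nzchar(trimws(ids))]
  }
  as.integer(ids)
}

#' Match fitted peaks to expected signal positions
#'
#' Returns the `peak_id`s of all fitted Lorentzians whose centers lie
#' within `window` ppm of a given position — the components of one
#' signal (noise can split a line into close-lying components, and a
#' multiplet's lines are deliberately summed). Intended for building
#' [quantify()] assignments when the expected chemical shifts are known.
#'
#' @param peaks An `nmr_decon` result or peak data frame with `peak_id`
#'   and `x0_ppm`.
#' @param x0_ppm Expected signal position(s), ppm.
#' @param window Half-width of the matching window in ppm (default
#'   0.005).
#' @return For a single position, an integer vector of peak ids (empty
#'   if none); for several, a list of such vectors.
#' @export
match_peaks <- function(peaks, x0_ppm, window = 0.005) {
  pk <- if (inherits(peaks, "nmr_decon")) peaks$peaks else peaks
  out <- lapply(x0_ppm, function(x) pk$peak_id[abs(pk$x0_ppm - x) <= window])
  if (length(x0_ppm) == 1L) out[[1]] else out
}

#' Read a metabolite assignment table
#'
#' CSV with columns `metabolite`, `peak_ids` (semicolon-separated fitted
#' peak identifiers), `n_protons`, and optionally `correction_factor`.
#'
#' @param path CSV path.
#' @return Data frame suitable for [quantify()].
#' @export
read_assignments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "peak_ids", "n_protons")
  if (!all(need %in% names(df))) {
    stop("assignment table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$peak_ids <- as.character(df$peak_ids)
  df
}
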