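#' Read a Bruker processed 1D data set
#'
#' Reads the real processed spectrum (`1r` binary) and the `procs`
#' parameter file of a Bruker processed-data folder and reconstructs the
#' ppm axis from the stored offset, sweep width, spectrometer frequency
#' and size. Intensities are de-scaled by the stored power-of-two
#' exponent `NC_proc`. Only classic 32-bit integer data (`DTYPP = 0`) in
#' either endianness (`BYTORDP`) are supported; raw FIDs and 2D data are
#' out of scope.
#'
#' `path` may point either at the experiment folder (containing
#' `pdata/<proc_no>/`) or directly at the processed-data folder holding
#' `1r` and `procs`.
#'
#' The axis follows the Bruker convention
#' `ppm[i] = OFFSET - i * (SW_p / SF) / SI` for 0-based `i`, i.e. the
#' first point sits at the offset and the axis decreases.
#'
#' @param path Directory of a Bruker data set.
#' @param proc_no Processed-data number under `pdata/` (default 1).
#' @return A [spectrum1d()] object.
#' @seealso [write_bruker()] for writing the same dialect.
#' @examples
#' d <- tempfile()
#' s <- synthetic_spectrum(data.frame(A = 1, lambda_ppm = 0.1, x0_ppm = 5),
#'                         n_points = 256, ppm_range = c(10, 0))
#' write_bruker(s$spectrum, d)
#' read_bruker(d)
#' @export
read_bruker <- function(path, proc_no = 1) {
  pdir <- path
  if (!file.exists(file.path(pdir, "1r"))) {
    pdir <- file.path(path, "pdata", as.character(proc_no))
  }
  f_1r <- file.path(pdir, "1r")
  f_procs <- file.path(pdir, "procs")
  if (!file.exists(f_1r) || !file.exists(f_procs)) {
    stop(sprintf("'%s' is not a Bruker processed dataset (need 1r and procs)",
                 path), call. = FALSE)
  }
  p <- parse_procs(f_procs)
  for (key in c("OFFSET", "SW_p", "SF", "SI", "NC_proc")) {
    if (is.na(p[[key]])) {
      stop(sprintf("procs file is missing parameter %s", key), call. = FALSE)
    }
  }
  if (!is.na(p[["DTYPP"]]) && p[["DTYPP"]] != 0) {
    stop("only integer processed data (DTYPP = 0) are supported",
         call. = FALSE)
  }
  si <- as.integer(p[["SI"]])
  n_stored <- file.size(f_1r) / 4L
  if (n_stored != si) {
    stop(sprintf("1r holds %d points but procs declares SI = %d",
                 n_stored, si), call. = FALSE)
  }
  endian <- if (!is.na(p[["BYTORDP"]]) && p[["BYTORDP"]] == 1) "big" else "little"
  con <- file(f_1r, "rb")
  on.exit(close(con))
  raw <- readBin(con, what = "integer", n = si, size = 4L, endian = endian)
  intensity <- raw * 2^p[["NC_proc"]]
  sweep_ppm <- p[["SW_p"]] / p[["SF"]]  # SW_p in Hz, SF in MHz -> ppm
  ppm <- p[["OFFSET"]] - (0:(si - 1L)) * sweep_ppm / si
  spectrum1d(ppm, intensity, sf_hz = p[["SF"]] * 1e6,
             source = normalizePath(pdir))
}

# JCAMP-style "##$KEY= value" parameter file -> named numeric vector.
parse_procs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keys <- c("OFFSET", "SW_p", "SF", "SI", "NC_proc", "BYTORDP", "DTYPP")
  out <- stats::setNames(rep(NA_real_, length(keys)), keys)
  m <- regmatches(lines, regexec("^##\\$([A-Za-z_]+)=\\s*(\\S+)", lines))
  for (g in m) {
    if (length(g) == 3L && g[2] %in% keys) {
      out[[g[2]]] <- suppressWarnings(as.numeric(g[3]))
    }
  }
  out
}

#' Write a spectrum as a minimal Bruker processed data set
#'
#' Writes `pdata/<proc_no>/1r` (32-bit integers, little endian) and a
#' matching `procs` file. Intensities are scaled by a power-of-two
#' exponent `NC_proc` chosen so the largest magnitude fits comfortably in
#' the integer range; the quantization error is at most one integer unit
#' at that scale. Mainly intended for generating test fixtures that
#' exercise [read_bruker()].
#'
#' @param spectrum A [spectrum1d()] object (uniform ppm grid assumed).
#' @param path Target directory (created if needed).
#' @param proc_no Processed-data number (default 1).
#' @return Invisibly, the processed-data directory written.
#' @export
write_bruker <- function(spectrum, path, proc_no = 1) {
  stopifnot(is_spectrum1d(spectrum))
  pdir <- file.path(path, "pdata", as.character(proc_no))
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  y <- spectrum$intensity
  max_abs <- max(abs(y), 1e-300)
  # keep scaled magnitudes below 2^28
  nc <- max(ceiling(log2(max_abs / 2^28)), -64)
  ints <- as.integer(round(y / 2^nc))
  si <- spectrum$n_points
  step <- ppm_step(spectrum)
  sf_mhz <- if (is.finite(spectrum$sf_hz)) spectrum$sf_hz / 1e6 else 600
  sw_p <- step * si * sf_mhz  # Hz
  procs <- c(
    "##TITLE= Parameter file, nmrdecon synthetic fixture",
    sprintf("##$BYTORDP= 0"),
    sprintf("##$DTYPP= 0"),
    sprintf("##$NC_proc= %d", nc),
    sprintf("##$OFFSET= %.12g", spectrum$ppm[1]),
    sprintf("##$SF= %.12g", sf_mhz),
    sprintf("##$SI= %d", si),
    sprintf("##$SW_p= %.12g", sw_p),
    "##END="
  )
  writeLines(procs, file.path(pdir, "procs"))
  con <- file(file.path(pdir, "1r"), "wb")
  on.exit(close(con))
  writeBin(ints, con, size = 4L, endian = "little")
  invisible(pdir)
}

#' Read a two-column text spectrum
#'
#' Column 1 is the chemical shift in ppm, column 2 the intensity;
#' whitespace-, comma- or tab-delimited, rows in any order. Rows are
#' sorted to the standard decreasing-ppm orientation. Duplicate ppm
#' values and non-numeric cells are rejected.
#'
#' @param path File path.
#' @return A [spectrum1d()] object.
#' @export
read_xy <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: '%s'", path), call. = FALSE)
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          colClasses = "character",
                          strip.white = TRUE, comment.char = "#")
  if (ncol(df) < 2L) stop("expected two columns (ppm, intensity)", call. = FALSE)
  ppm <- suppressWarnings(as.numeric(df[[1]]))
  y <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(ppm) || anyNA(y)) {
    stop("non-numeric cells in spectrum file", call. = FALSE)
  }
  if (nrow(df) < 4L) {
    stop("a spectrum needs at least 4 rows", call. = FALSE)
  }
  if (anyDuplicated(ppm)) {
    stop("duplicate ppm values in spectrum file", call. = FALSE)
  }
  o <- order(ppm, decreasing = TRUE)
  spectrum1d(ppm[o], y[o], source = normalizePath(path))
}

#' Write a spectrum as two-column text
#'
#' Full-precision (17 significant digits) ppm/intensity pairs, one row
#' per point, so that `read_xy(write_xy(s))` round-trips exactly.
#'
#' @param spectrum A [spectrum1d()] object.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_xy <- function(spectrum, path) {
  stopifnot(is_spectrum1d(spectrum))
  writeLines(sprintf("%.17g %.17g", spectrum$ppm, spectrum$intensity), path)
  invisible(path)
}

#' Write a fitted peak table and run-metadata sidecar
#'
#' One CSV row per fitted Lorentzian: identifier, center and half width
#' at half height in ppm and in data-point units, scale factor `A`, the
#' closed-form integral, and the triplet indices the peak was solved
#' from. Numeric columns are written with 17 significant digits so a
#' re-read reproduces the fit to full double precision. A JSON sidecar
#' (`<path minus extension>_meta.json`) records the run parameters.
#'
#' @param result A deconvolution result from [deconvolve()], or a peak
#'   data frame of the same shape.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_peak_table <- function(result, path) {
  peaks <- if (inherits(result, "nmr_decon")) result$peaks else result
  cols <- c("peak_id", "x0_ppm", "lambda_ppm", "A", "lambda_pts", "x0_pts",
            "integral", "i_left", "i_middle", "i_right")
  header <- paste(cols, collapse = ",")
  if (is.null(peaks) || nrow(peaks) == 0L) {
    writeLines(header, path)
  } else {
    rows <- sprintf("%d,%.17g,%.17g,%.17g,%.17g,%.17g,%.17g,%d,%d,%d",
                    peaks$peak_id, peaks$x0_ppm, peaks$lambda_ppm, peaks$A,
                    peaks$lambda_pts, peaks$x0_pts, peaks$integral,
                    peaks$i_left, peaks$i_middle, peaks$i_right)
    writeLines(c(header, rows), path)
  }
  if (inherits(result, "nmr_decon")) {
    meta_path <- paste0(tools::file_path_sans_ext(path), "_meta.json")
    meta <- result$params
    meta$n_triplets_raw <- result$n_triplets_raw
    meta$n_peaks <- nrow(peaks)
    meta$mse_trace <- result$mse_trace
    meta$best_iteration <- result$best_iteration
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' Read a peak table written by [write_peak_table()]
#' @param path CSV path.
#' @return A data frame of fitted peaks.
#' @export
read_peak_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
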