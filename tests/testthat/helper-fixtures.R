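# Shared fixture builders. All fixtures are generated in code at test
# time; nothing binary is stored in the repository.

# Closed-form Lorentzian, written out independently of the package's
# lorentz_eval so oracle computations do not share its code path.
lorentz_ref <- function(x, A, lambda, x0) A * lambda / (lambda^2 + (x - x0)^2)

# Spectrum sampled on an n-point grid (0-based point units) from a peak
# table given in point units.
point_spectrum <- function(peak_tab, n, ppm_hi = 10, ppm_lo = 0.01) {
  x <- 0:(n - 1)
  y <- numeric(n)
  for (k in seq_len(nrow(peak_tab))) {
    y <- y + lorentz_ref(x, peak_tab$A[k], peak_tab$lambda[k], peak_tab$x0[k])
  }
  spectrum1d(seq(ppm_hi, ppm_lo, length.out = n), y)
}

# Minimal hand-written Bruker processed folder (independent of
# write_bruker) so the reader is tested against first principles.
make_bruker_fixture <- function(dir, ints, offset = 10, sweep_ppm = 10,
                                sf_mhz = 600, nc_proc = 0, bytordp = 0,
                                si = length(ints), write_procs = TRUE) {
  pdir <- file.path(dir, "pdata", "1")
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  if (write_procs) {
    writeLines(c(
      "##TITLE= test fixture",
      sprintf("##$BYTORDP= %d", bytordp),
      "##$DTYPP= 0",
      sprintf("##$NC_proc= %d", nc_proc),
      sprintf("##$OFFSET= %.10g", offset),
      sprintf("##$SF= %.10g", sf_mhz),
      sprintf("##$SI= %d", si),
      sprintf("##$SW_p= %.10g", sweep_ppm * sf_mhz),
      "##END="
    ), file.path(pdir, "procs"))
  }
  con <- file(file.path(pdir, "1r"), "wb")
  writeBin(as.integer(ints), con, size = 4L,
           endian = if (bytordp == 1) "big" else "little")
  close(con)
  dir
}

# Window-sum concentration estimates for a synthetic Latin-square
# design: every metabolite's concentration from the fitted peaks of
# every sample, relative to the TSP reference.
quantify_latin_square <- function(design, delta = 5,
                                  noise_region = c(10.5, 13.5),
                                  window = 0.005) {
  met <- design$metabolites
  n <- nrow(design$concentrations)
  est <- matrix(NA_real_, n, ncol(design$concentrations),
                dimnames = dimnames(design$concentrations))
  for (s in seq_len(n)) {
    fit <- suppressWarnings(
      deconvolve(design$spectra[[s]], delta = delta,
                 noise_region = noise_region, verbose = FALSE)
    )
    ref_ids <- match_peaks(fit, design$reference$x0_ppm, window)
    asg <- data.frame(metabolite = met$name, n_protons = met$n_protons)
    asg$peak_ids <- match_peaks(fit, met$x0_ppm, window)
    ok <- lengths(asg$peak_ids) > 0
    qt <- quantify(asg[ok, ], fit,
                   list(metabolite = design$reference$name,
                        peak_ids = list(ref_ids),
                        n_protons = design$reference$n_protons),
                   design$reference$conc)
    est[s, match(qt$metabolite, colnames(est))] <- qt$concentration
  }
  est
}
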