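# nmrdecon

Fully automated deconvolution of 1D ¹H NMR spectra into individual
Lorentzian lines, with closed-form integration and reference-based
quantification.

## The problem

One-dimensional proton NMR spectra of biofluids (urine, plasma) carry
signals from hundreds of metabolites on one axis, and the signals
overlap. Overlap breaks the two things a metabolomics workflow needs
most: assigning a signal to a compound, and measuring its area.
Reference-library fitting tools resolve overlap but only for compounds
in the library; fixed-width bucketing needs no library but cannot
separate co-resident signals at all. `nmrdecon` takes the third route:
it decomposes the measured spectrum into the individual lines
themselves, with no reference information, so every component — known
metabolite or unidentified feature — gets its own precise integral.

## The method

Every NMR signal is, to good approximation, a Lorentzian

```
y(x) = A·λ / (λ² + (x − x₀)²)
```

with area `A·π`, half width at half height `λ`, and center `x₀`. The
pipeline:

1. **Preprocess** an already Fourier-transformed, phased,
   baseline-corrected spectrum: blank the residual water region
   (optional), take absolute values, and apply a 5-point running mean
   twice ("2,5-mean smoothing") so noise cannot split curvature cores.
2. **Detect peak triplets** from the second derivative: a center is a
   local minimum of `y''` inside negative curvature — this finds
   shoulders of overlapped signals that never form an intensity
   maximum — and its two flank points are the nearest zero crossings,
   local maxima or plateaus of `y''`.
3. **Filter noise triplets** against a user-declared signal-free
   region: keep a triplet only if its center curvature exceeds
   `mean + δ·sd` of the curvature distribution there. δ is a user knob
   meant to be checked visually.
4. **Solve each triplet analytically**: three Lorentz equations in
   three unknowns reduce to an exact linear solve (positions shifted so
   the left point is zero, for numerical stability; `λ` taken as its
   absolute value).
5. **Adjust heights iteratively** (default 10 iterations): the measured
   intensity at every triplet point is apportioned among peaks in
   proportion to their current contributions and each system re-solved,
   which untangles overlapping lines; the iteration with the minimal
   deviation from the spectrum wins.
6. **Integrate and quantify**: each line's area follows in closed form,
   `A·(arctan((b−x₀)/λ) − arctan(−x₀/λ))`, and concentrations come from
   an internal reference signal (e.g. TSP) of known concentration, with
   proton-count normalization and optional relaxation correction.

A synthetic-spectrum generator (sums of Lorentzians with noise,
Latin-square dilution designs with ground truth) backs the entire test
suite. See the vignette in `vignettes/deconvolution-methods.Rmd` for
the full model description and design rationale.

## Worked example

Three synthetic lines — one reference singlet at 1.48 ppm and a pair at
1.910/1.913 ppm overlapping at twice their half width — with noise:

```r
library(nmrdecon)

peaks <- data.frame(A = c(2.0, 0.8, 0.5), lambda_ppm = 0.0015,
                    x0_ppm = c(1.48, 1.910, 1.913))
sim <- synthetic_spectrum(peaks, n_points = 131072, ppm_range = c(14, -2),
                          noise_sd = 5e-4, seed = 42)

fit <- deconvolve(sim$spectrum, delta = 8, noise_region = c(10.5, 13.5))
#> detected 36884 peak triplets
#> 3 triplets survive the noise filter (delta = 8)
#> best iteration 10 of 10, normalized MSE 8.73e-09

fit$peaks[, c("peak_id", "x0_ppm", "lambda_ppm", "A", "integral")]
#>   peak_id x0_ppm lambda_ppm     A integral
#> 1       1  1.913   0.001571  4145    13020
#> 2       2  1.910   0.001574  6675    20968
#> 3       3  1.480   0.001575 16775    52690
```

All three lines are recovered, including the two whose maxima are not
visually separated. Quantification against the 1.48 ppm signal treated
as a 3-proton reference at 1 mmol/L:

```r
asg <- data.frame(metabolite = c("acetate", "unknown"),
                  n_protons = c(3L, 2L))
asg$peak_ids <- match_peaks(fit, c(1.910, 1.913), window = 0.001)
quantify(asg, fit,
         reference = list(metabolite = "alanine",
                          peak_ids = list(match_peaks(fit, 1.48)),
                          n_protons = 3),
         reference_conc = 1.0)
#>   metabolite summed_integral n_protons concentration  units
#> 1    acetate           20968         3        0.3979 mmol/L
#> 2    unknown           13020         2        0.3707 mmol/L
```

The generated truth is 0.4000 and 0.3750 mmol/L: both overlapped lines
are quantified to within ~1 %.

A command-line front-end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "nmrdecon.R", package = "nmrdecon"))') \
    deconvolute --input pdata_dir/ --output peaks.csv \
    --delta 5 --noise-region 10.5,13.5 --water-region 4.6,4.9
```

Subcommands: `deconvolute`, `quantify`, `simulate`.

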