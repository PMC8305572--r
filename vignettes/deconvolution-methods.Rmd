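---
title: "Lorentzian deconvolution of 1D NMR spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lorentzian deconvolution of 1D NMR spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrdecon)
```

## The problem

A 1D ¹H NMR spectrum of a biofluid such as urine or plasma contains
hundreds to thousands of metabolite signals on a shared chemical-shift
axis. Every signal has, to good approximation, the natural NMR line
shape — a Lorentzian

$$y(x) = \frac{A\,\lambda}{\lambda^2 + (x - x_0)^2},$$

with scale factor $A$ (the full-line area is $A\pi$), half width at
half height $\lambda$, and center $x_0$. Because the lines are narrow
but heavy-tailed and the spectrum is crowded, neighboring signals
overlap, and naive approaches — picking intensity maxima, or integrating
fixed-width buckets — either miss shoulders entirely or lump several
metabolites into one number. `nmrdecon` decomposes the measured
spectrum into its individual Lorentzian components without any
reference-compound library, so that each component (known metabolite or
not) can be integrated separately and converted to a concentration
against an internal reference signal.

All fitting happens in data-point units (index 0 = highest ppm, the
conventional plot direction); the closed-form integral's upper border is
the number of data points, so point units keep detection, fitting and
integration consistent. Conversion to ppm happens only for reporting,
and concentration estimation is a ratio of integrals on the same
spectrum, so the ppm-per-point factor cancels.

## The pipeline

### Preprocessing

Input spectra are assumed Fourier-transformed, phased and
baseline-corrected (the package reads Bruker processed folders and
two-column text). Three further steps precede detection:

1. **Water blanking** (optional, `water_region`): intensities in the
   residual-water interval are set to zero and the points flagged, not
   deleted, so index arithmetic and integration borders stay on the
   original grid. Flagged points are skipped by detection and by the
   error metric. There is no default region — the water position
   depends on field and solvent, so it is the user's input.
2. **Absolute values**: magnitudes guarantee the positivity the
   three-point solve requires. The operation is idempotent; its one
   side effect is a small positive noise floor (the folded mean of the
   noise), which is why error values below are interpreted against the
   smoothed measured spectrum rather than an idealized baseline.
3. **2,5-mean smoothing** (`smooth_half_width = 2`, `smooth_passes =
   2`): each intensity is replaced by the mean of itself and two
   neighbors per side; the pass is applied twice. Windows truncate at
   the spectrum edges (the mean runs over the neighbors that exist),
   which avoids inventing phantom edge values. Smoothing exists to stop
   noise from splitting one curvature core into several detections; it
   is linear and never raises the global maximum. It also widens lines
   slightly — on clean synthetic data the fitted $\lambda$ comes out
   roughly 5–10 % above truth with the default two passes. For
   noise-free simulations use `smooth_passes = 0`; for quantification
   the widening largely cancels, because concentrations are ratios of
   integrals of lines with similar widths (see below).

### Curvature-based triplet detection

The second derivative is the discrete central difference
$y''_i = y_{i-1} - 2 y_i + y_{i+1}$ (endpoints set to 0). An index $x$
is a **triplet center** when

$$y''(x) < 0 \quad\text{and}\quad y''(x+1) > y''(x) \le y''(x-1),$$

i.e. a local minimum of the second derivative inside a region of
negative curvature. This catches genuine maxima *and* shoulders of
partly overlapped lines that never form an intensity maximum — two
equal lines only $1\lambda$ apart still produce two curvature minima.
The left and right triplet points are found by walking outward from the
center to the nearest zero crossing, local maximum, or plateau (two
consecutive equal values within a $10^{-12}$ relative tolerance) of the
second derivative. A walk that reaches the spectrum edge or an excluded
point first discards the triplet: a three-point system with a missing
flank cannot be solved. Two adjacent peaks may share a flank boundary
point; each system is solved independently, so the shared point is
harmless.

### Noise filtering: the threshold δ

Noise also produces curvature minima. Each triplet receives a score,
and survives if the score exceeds

$$\text{mean} + \delta \cdot \text{sd}$$

of the same statistic over a user-declared signal-free `noise_region`.
δ is deliberately a user-set knob: set it, deconvolve, and *look* at
which triplets survive (`plot()` on the result); raise δ until the
baseline is quiet but shoulders you believe in are still kept. A
warning is raised when surviving centers remain inside the declared
noise region — either δ is too low or the region is not signal-free.

The default score is the **negated second derivative at the center**,
compared against the distribution of $-y''$ over the noise region. A
real line of height $h$ has center curvature of order $2h/\lambda^2$;
a noise wiggle has curvature at the noise scale — *regardless of the
local intensity*. The distinction matters on the tails of strong
signals: an intensity-based score (available as `score = "intensity"`)
cannot reject spurious triplets there, because the tail intensity is
far above any noise-derived intensity threshold. In testing, such
tail triplets went on to siphon up to ~10 % of a strong line's height
through the height adjustment, scrambling integrals sample-to-sample;
with the curvature score the same spectra quantify to within 2 %. Both
scores are exposed; the curvature score is the default for exactly this
reason.

### The analytic three-point solve

The three triplet points give three Lorentz equations in the three
unknowns $(A, \lambda, x_0)$. Substituting $B = A\lambda$,
$u = \lambda^2 + x_0^2$, $v = x_0$ turns them into a linear system

$$B - y_p u + 2 y_p x_p v = y_p x_p^2, \qquad p \in \{l, m, r\},$$

solved exactly (no least squares, no starting values). Positions are
shifted so the left point sits at zero before solving and shifted back
after — at index ~10⁵ the raw system is badly scaled and the shift
removes that instability. Two guards handle real data: $\lambda$ is
taken as $|\lambda|$ (noise can push the solved $\lambda^2$ negative),
and a system whose determinant falls below $10^{-12}$ of its scale
(coincident points, non-positive intensities, collinear degeneracy) is
dropped with a warning at the initial solve, or keeps its previous
parameters mid-iteration so the error trace stays comparable.

Initial solves whose centers coincide within 1.5 data points are merged
before iterating (the strongest-curvature triplet wins). Noise on the
flat top of a line can tile one curvature core into several adjacent
triplets that each solve to numerically the same Lorentzian; reporting
the same line several times would double- to quadruple-count its area.
Lines genuinely closer than 1.5 grid points are below grid resolution,
so the merge cannot split resolvable signals.

### Iterative height adjustment

Each initial solve attributes the *full* measured intensity at its
three points to its own peak, so wherever peaks overlap the sum of the
initial curves overshoots the spectrum. Each iteration therefore
apportions the measured intensity at every triplet point among the
peaks in proportion to their current contributions,

$$\hat y_k(p) = y_{\mathrm{exp}}(p)\,\frac{L_k(p)}{S(p)},
\qquad S = \sum_j L_j,$$

and re-solves every three-point system from the adjusted intensities.
All peaks update simultaneously (order-independent, reproducible). An
isolated peak has $L_k = S$ at its own points and is a fixed point of
the scheme. If $S(p)$ is zero or the ratio non-finite, the previous
adjusted value is kept. After a fixed number of iterations (default
10) the parameter set with the minimal mean squared deviation from the
spectrum over the whole trace — initial fit included — is returned; no
early-stopping tolerance is introduced. On a clean two-line overlap
with centers $2\lambda$ apart the scheme contracts by roughly two
orders of magnitude in MSE per iteration.

### Error metrics: selection vs reporting

Two mean-squared-error variants appear, on purpose. Iteration
*selection* uses the plain MSE between the preprocessed spectrum and
the reconstruction on the measured intensity scale (excluded points
omitted) — the direct "deviation between the sum of computed curves
and the experimental spectrum". The *reported* figure of merit
(`normalized_mse()`, also stored as `normalized_mse` on the result)
first scales both vectors to a total integral of one (rectangle rule
in point units), which makes values comparable across spectra of
different absolute scales.

The two must not be conflated. The measured magnitude spectrum
contains an unmodeled positive noise floor (absolute values fold the
noise mean above zero), so its normalization constant is slightly
larger than the reconstruction's. Under integral normalization, an
*overshooting* fit — exactly what the initial independent solves
produce at overlaps — gets part of that discrepancy back for free, and
on sparse spectra the initial fit can score better than every adjusted
one, freezing the overlap overshoot. Selecting on the plain MSE
removes this artifact; the normalized value is then computed for the
selected reconstruction.

### Integration and quantification

Each fitted line is integrated in closed form over the recorded axis,

$$\int_0^b y(x)\,dx = A\left(\arctan\frac{b - x_0}{\lambda}
 - \arctan\frac{0 - x_0}{\lambda}\right),$$

with $b$ = number of data points. For a line far from both borders
this approaches $A\pi$; the truncation error of lines near an edge is
documented, not corrected. Concentrations follow from an internal
reference of known concentration (TSP for urine; formic acid for
plasma, which is not prone to protein binding):

$$c_m = c_{\mathrm{ref}}\cdot
\frac{I_m / n_m}{I_{\mathrm{ref}} / n_{\mathrm{ref}}}\cdot f_m,$$

where $I$ sums the integrals of the peaks assigned to the signal (a
multiplet is the sum of its components — `match_peaks()` collects
components within a ppm window), $n$ is the number of contributing
protons, and $f_m$ is an optional per-metabolite multiplicative
correction (default 1) for known biases such as differential $T_1$
relaxation against the reference. Global intensity rescaling cancels in
the ratio, as does the smoothing-induced line widening when analyte and
reference have similar widths.

## The synthetic-data generator

Every stage is validated against `synthetic_spectrum()`: sums of
Lorentzians on a 131072-point axis from 14 to −2 ppm (the processed
size of a typical 600 MHz ¹H spectrum) with additive i.i.d. Gaussian
noise scaled to the maximum peak height. Half widths default to
0.0005–0.003 ppm (≈0.3–1.8 Hz at 600 MHz) and areas span two orders of
magnitude in `random_peak_table()`, the spread seen across metabolite
signals in one biofluid spectrum. What the generator deliberately does
*not* emulate: J-coupling beyond user-supplied peak lists, baseline or
phase artifacts, and the heavier-than-Gaussian noise tails of magnitude
spectra. Tests passing on this generator therefore demonstrate the
correctness of the algorithm's mechanics, not robustness to every
artifact of real instruments.

`synthetic_latin_square()` reproduces the classic validation design
for quantification: 10 samples × 10 metabolites, concentrations
following a cyclically shifted geometric 2-fold dilution (each
metabolite takes each level exactly once; constant total per sample;
levels spanning 1 to 1/512 of `base_conc`), plus a constant TSP
reference singlet at 0.0 ppm in every sample. Singlet positions are the
design's real chemical shifts, with one change: TMAO sits at 3.27 ppm
rather than 3.25, because at 3.25 it would *exactly* overlap the
betaine singlet — a constellation no line-shape method can separate
and a documented limitation of the approach. The default noise level is
2 × 10⁻⁴ of the maximum peak height (a signal-to-noise ratio of a few
thousand, realistic for a cryoprobe); at that level the two to three
lowest dilution steps of some metabolites fall below any sensible
detection threshold, exactly as the lowest dilutions of weak analytes
do on real instruments, and drop out of the recovery regression as
non-detections rather than zeros.

## Numerical choices, in one place

- Discrete second derivative; endpoints 0. Plateau tolerance $10^{-12}$
  relative to the local second-derivative scale.
- Degeneracy threshold for the 3×3 solve: $|\det| < 10^{-12}$ of the
  row-norm product.
- Duplicate-center merge tolerance: 1.5 data points, strongest center
  curvature wins.
- Bucket counting uses `floor((upper - lower)/width)` with a $10^{-9}$
  relative guard so that an exact-ratio region (4.10 ppm at 0.01 ppm =
  410 buckets) is not floored to 409 by IEEE rounding.
- Iterations default to 10 with minimal-MSE selection over all 11
  parameter sets; `iterations = 0` returns the raw analytic solves.
- Seeds: every generator takes an explicit integer seed; the
  deconvolution itself is deterministic, and identical runs produce
  byte-identical output tables.

## Problem sizes used in the shipped validation

The test suite and the acceptance script regenerate everything from
code: full-scale 131072-point spectra with 400 random lines for the
reconstruction benchmark (normalized MSE ~10⁻¹¹ against a bound of
2 × 10⁻⁹), a 20-line clean spectrum for exact parameter recovery, the
lactate/threonine-style pair of overlapped doublets (inner components
$2\lambda$ apart) for shoulder resolution, and the 10 × 10 Latin
square for end-to-end quantification (slope within 2 % of unity,
R² ≥ 0.999 per metabolite). Oracle checks run the analytic solve and
the closed-form integral against substitution and adaptive quadrature
over 1000 random parameter draws each.

## Known limitations

- Exactly co-resonant signals (TMAO/betaine at 3.25 ppm) cannot be
  separated by line shape alone; reference-spectrum methods are needed
  there.
- Peaks whose flank walk hits the spectrum edge or a blanked region are
  discarded rather than half-fitted.
- The closed-form integral truncates at the recorded axis; lines within
  a few dozen $\lambda$ of an edge lose a visible fraction of $A\pi$.
- Smoothing widens lines; width-sensitive applications on clean data
  should reduce `smooth_passes`.
- $T_1$-relaxation differences against the reference are not modeled,
  only correctable via the per-metabolite factor.
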