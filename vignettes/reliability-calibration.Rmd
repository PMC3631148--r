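---
title: "Calibrated reliability bounds for SERS spectral demultiplexing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated reliability bounds for SERS spectral demultiplexing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multiplexed molecular diagnostics with SERS-coded nanoparticles read a
panel of biomarkers out of one Raman spectrum: each nanoparticle flavor
contributes its fingerprint spectrum in proportion to its concentration.
The quantities of diagnostic interest are the fitted flavor weights and,
more robustly in vivo, the ratios of targeted flavors to an untargeted
control flavor. Both are produced by a least-squares unmixing routine that
will always return *some* answer — including when noise and broadband
background have destroyed the information needed to support it. The
package's purpose is a decision rule: from one measurement, decide whether
its demultiplexed concentrations meet a user-chosen accuracy requirement
at a user-chosen confidence.

## Forward model and its assumptions

A measurement on a fixed wavenumber grid is modeled as

$$X = \sum_n c_n F_n + k B + \delta,$$

with flavor references $F_n$, a single broadband background reference $B$
scaled by $k$, and i.i.d. zero-mean Gaussian channel noise $\delta$. Three
assumptions are inherited from the physics: (1) backgrounds are spectrally
broadband, with no features as sharp as SERS peaks; (2) autofluorescence
enters only through its slowly varying long-wavelength tail; (3) all
stochastic noise sources (shot, readout, dark) are lumped into one
Gaussian term. There is deliberately no separate autofluorescence channel
and no signal-dependent (Poisson) noise option: the single lumped
background and noise term keep the error model analytically clean
(Gaussian weight errors under linear fitting), and the calibration indexes
everything by the *realized* spectral quality anyway, so mild departures
from these idealizations shift where a measurement lands on the
error-vs-SRI curve rather than invalidating the curve. Negative
intensities caused by noise are retained; clipping would bias the fit.

## Demultiplexing and the two quality metrics

`dcls_fit()` solves, by QR-based ordinary least squares,

$$S = \sum_n w_n F_n + kB + \sum_{m=0}^{3} a_m P_m + R .$$

The third-order polynomial baseline $P_m$ absorbs broadband content not
captured by $B$; it is evaluated on the axis affinely mapped to $[-1,1]$,
because raw wavenumber monomials up to cubic span nine orders of magnitude
and degrade conditioning. The fit is unconstrained: unconstrained OLS is
the standard DCLS reading, keeps single-flavor error distributions
symmetric, and makes the fitted weights unbiased. A nonnegative-weights
variant (`nonneg = TRUE`, active-set elimination on the flavor columns
only) exists for users who want it, but it is not the default precisely
because truncation at zero skews the error distributions the calibration
relies on.

Two scalar summaries of fit quality:

* **RFE** $= \lVert \hat S \rVert_2 / \lVert S\rVert_2$, the norm of the
  full reconstruction over the norm of the input. Since the reconstruction
  is an orthogonal projection, RFE lies in $[0,1]$, reaching 1 for a
  perfect fit. Its flaw: a dominant background is itself fit with high
  fidelity, pushing RFE toward 1 even when the particle weights are junk.
* **SRI** $= \lVert \sum_n w_n F_n \rVert_2 \,/\,
  \lVert S - (kB + \sum_m a_m P_m)\rVert_2$ — the same ratio restricted to
  particle content. The denominator (background/baseline-subtracted
  signal) decomposes orthogonally into the particle fit plus the residual,
  so SRI also lies in $[0,1]$ and, unlike RFE, is insensitive to the
  background magnitude. The denominator choice follows the defining intent
  of ignoring non-particle components; it is additionally the only choice
  that keeps the metric bounded by 1 under the projection algebra. Both
  metrics are clamped to $[0,1]$, warning if numerics stray beyond
  $10^{-9}$. When the background-subtracted signal has zero norm there is
  nothing to judge and `sri()` returns a no-signal sentinel (`NA` with
  attribute), which the workflow maps to its own verdict.

Per-flavor accuracy is the signed percent error; a mixture is summarized
by the **composite error**, the RMS of the per-flavor percent errors —
nonnegative by construction, which is what licenses a gamma model for its
distribution.

## Monte-Carlo calibration

The calibration answers: *given that a measurement realized SRI $s$, what
error should I expect at confidence $q$?* Because SRI is an output, not a
knob, `run_calibration()` sweeps the noise standard deviation over a
log-spaced grid, simulates replicates at each level, fits each one, and
records (realized SRI, error) pairs; `bin_by_sri()` then partitions them
into SRI bins (width 0.02 by default) regardless of which noise level
produced them — matching how the consumer of the table will use it, with
no knowledge of the true noise level.

Choices that matter here:

* **Grid density.** The default sweep has 100 log-spaced points from 1/100
  to 2× the RMS amplitude of the noiseless spectrum. Density is not
  cosmetic: with a coarse grid (say 25 points) each 0.02-wide SRI bin
  collects errors from only one or two discrete noise conditions, and the
  resulting within-bin mixture distribution is visibly non-gamma, which
  distorts the fitted percentiles. At 100 points each bin blends a
  near-continuum of conditions and the gamma fit is accurate.
* **Span.** 1/100 of the signal RMS yields near-perfect fits (SRI ≈ 1);
  2× yields noise-dominated fits (SRI ≈ 0.2); together they cover the SRI
  range a lookup table needs without wasting replicates far outside it.
* **Bin merging.** Bins holding fewer than `min_count` (default 200)
  samples merge with their neighbor, logged, so every fitted distribution
  has a stable sample size. Percentiles from fewer than ~200 samples draw
  a warning in `fit_distribution()`.
* **Error families.** Signed single-flavor errors are exactly Gaussian
  under this forward model (the weights are linear images of Gaussian
  noise), so the Gaussian family is fixed for one flavor; composite errors
  are nonnegative and gamma-fit by maximum likelihood
  (`fitdistrplus::fitdist`) with location fixed at zero. For mixtures the
  Gaussian log-likelihood is recorded alongside, making the family
  comparison testable.
* **The confidence bound.** For gamma (composite) errors, $e_{80}$ is the
  80th percentile of the fitted CDF. For Gaussian (signed) errors the
  bound is *central*: the $b$ with $P(|e|\le b) = q$. Central and
  one-sided-on-$|e|$ coincide for the zero-mean symmetric case this model
  produces; the central definition is kept because it remains meaningful
  if a user calibrates a biased scenario. An empirical-percentile mode
  exists as a cross-check and is what the validation tests use on held-out
  data.
* **Isotonic smoothing.** The binned $e_{80}$-vs-SRI curve is regularized
  to be non-increasing in SRI by isotonic regression (`stats::isoreg`) —
  the physically expected shape; raw values are kept alongside and any
  adjustment is logged.

## The minimum-SRI threshold and the decision rule

`min_sri_for_bound()` inverts the curve: the smallest SRI whose bound is
at or below the requested error. The crossing is located by linear
interpolation between bin centers and then **padded by half a bin width**.
The padding implements guarantee semantics — the threshold must *ensure*
the bound — since an unpadded crossing sits exactly where $e_{80}$ equals
the bound, and a measurement landing half a bin below the calibrated
center would violate it about half the time. The padding is configurable
(`margin`), never pushes past the highest calibrated bin, and is not
applied when the whole calibrated range already satisfies the bound. If
no calibrated bin satisfies the bound the function reports the criterion
as not achievable rather than extrapolating.

`build_reliability_table()` repeats the calibration per mixture ratio
(target concentration $r$, control fixed at 1) because the minimum SRI
depends strongly on the ratio: in an imbalanced mixture the abundant
flavor dominates both the spectrum and the SRI while the scarce flavor is
fit poorly, so the same SRI hides a larger composite error. Tables carry
full provenance — seed, replicate count, noise sweep, and an MD5 hash of
the library — and `assess()` refuses tables whose hash does not match the
library at hand.

`assess()` makes the decision with the *fitted* ratio (the truth being
unknown at assessment time): it selects the nearest calibrated table,
rejecting fitted ratios more than 25% beyond the calibrated grid edge as
out-of-calibration rather than extrapolating between tables that do not
exist. Verdicts are `accept`, `reject`, or `no-signal`, each with a
deterministic remediation hint (`advise()`): a low SRI suggests averaging
or longer integration; an out-of-range ratio suggests extending the
calibration grid. Each spectrum is assessed independently; no
multiple-measurement correction is applied.

## The synthetic library

Real instrument reference spectra are instrument- and lot-specific, so the
package ships a generator instead of data. `generate_flavor()` sums
Lorentzian lines — the canonical Raman lineshape — with seeded-random
centers, half-widths of 4–12 cm⁻¹, and amplitudes, normalized to unit
maximum; `generate_background()` produces a positive low-order polynomial
trend plus one broad Gaussian hump (minimum feature width 300 cm⁻¹,
roughly 25× the widest flavor peak, encoding the broadband-background
assumption), also unit-normalized. The default axis spans 800–1800 cm⁻¹ —
the Raman fingerprint region — in 1024 channels, a typical spectroscopic
CCD column count. Unit normalization makes concentrations and the
background scale dimensionless amplitudes, so `noise_sigma` is expressed
relative to unit peak height. One master seed derives per-flavor sub-seeds
counter-style, so extending a library appends flavors without reshuffling
existing ones; a library whose flavors draw too collinear (pairwise cosine
similarity above 0.95) regenerates the offending flavor from a perturbed
sub-seed, logged.

What the generator does *not* emulate: spectral overlap structure of any
particular commercial flavor set, wavelength-dependent detector response,
cosmic rays, wavenumber miscalibration, endogenous Raman features, or
signal-dependent noise. Passing tests therefore demonstrate that the
calibration machinery is statistically sound under the stated model — not
that any particular instrument achieves a particular minimum SRI. Every
quantitative threshold (e.g. the minimum SRI for 10% error at 80%
confidence) is library- and instrument-specific and must be recalibrated
per application; this is inherent to the method, not a limitation of the
implementation.

## Numerical choices and degenerate inputs

Least squares is solved via QR, never normal equations (the test suite
uses an explicit normal-equations solve as an independent oracle, agreeing
to $10^{-8}$ relative). Design condition numbers are computed by SVD and
reported; rank deficiency aborts with the collinear columns named; an
ill-conditioned but full-rank design warns and proceeds. Zero-norm input
spectra make RFE undefined (error); exact pure background yields the SRI
no-signal sentinel; a non-positive fitted control weight flags all ratios
unreliable rather than reporting a sign-flipped ratio. Seeds derive
through an affine map modulo $2^{31}-1$, exact in double arithmetic, so
every derived seed is a valid R seed and batches are reproducible
replicate-by-replicate, independent of batch size.

## Problem sizes

The shipped calibrations use 50,000 replicates for coverage
characterization, 20,000 per reliability table, and 5,000 pinned held-out
replicates for threshold validation, on the 1024-channel default library —
sizes at which per-bin percentile estimates are stable to a few tenths of
a percent and a full calibration completes in well under a minute on one
CPU, since all replicates of a noise level share a single QR
factorization. Unit tests use a 256-channel library and smaller batches.

## Known limitations

* The calibration transfers only to data generated by the same forward
  model; background shape mismatch beyond what the cubic baseline absorbs
  will bias weights without necessarily lowering SRI.
* Gamma is an approximation for composite errors of correlated,
  unequal-variance flavor errors; it is accurate here (coverage within a
  few tenths of a point at the 80th percentile) but heavier multiplexing
  with strong spectral overlap may warrant a refit diagnostic.
* Ratio-error calibration excludes replicates with non-positive fitted
  control weight (counted and reported); at very low SNR this truncation
  makes ratio tables optimistic in the extreme low-SRI bins that no
  sensible criterion would accept anyway.
* Tables interpolate only within their calibrated SRI and ratio ranges;
  criteria outside them are reported as not achievable by design.
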