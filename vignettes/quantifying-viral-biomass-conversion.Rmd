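---
title: "Quantifying giant-virus replication and biomass conversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying giant-virus replication and biomass conversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virionquant)
```

## The measurement problem

A giant DNA virus replicating inside an amoeba converts a sizeable share
of its host's carbonaceous biomass into virions.  virionquant implements
the quantitative chain that turns three kinds of raw measurements into a
biomass-conversion estimate:

1. **Water-window soft X-ray micrographs** of infected cells.  Between
   the carbon and oxygen K-edges, dry biomass absorbs roughly an order of
   magnitude more strongly than water, so hydrated, unstained cells show
   their carbon distribution directly.  Large ovoid virions
   (about 1.25 µm × 0.59 µm) are individually resolvable, countable, and
   their absorbance is measurable.
2. **End-point dilution titrations**: serial dilutions of a lysate across
   replicate wells, scored positive/negative, from which the infectious
   titre — and through bookkeeping, the burst size — is inferred.
3. **Thermogravimetric analysis (TGA)**: post-pyrolysis residual mass of
   virus and cell samples, a proxy for their relative carbon
   concentration.

Because no public micrograph set exists for this system, the package
ships a phantom generator that renders synthetic micrographs with exact
ground truth.  Every estimator in the pipeline can therefore be validated
end to end on data whose answer is known.

## Forward model: the optical phantom

`project_phantom()` is a parallel-beam line-integral model.  Each pixel's
transmitted intensity is

$$ I(x, y) = I_0(x, y)\, \exp\Big(-\sum_c \mu_c\, t_c(x, y)\Big), $$

where $t_c$ is the analytic chord length of the ray through component $c$
(cell ellipsoid, nucleus, water-filled vacuoles, arbitrarily oriented
prolate-spheroid virions) and $I_0$ is a 2D Gaussian illumination
profile.  The medium fills the remaining `ice_thickness` along the ray.
A component of dry-biomass volume fraction $\rho$ attenuates with
$\mu = \rho\,\mu_{\text{biomass}} + (1-\rho)\,\mu_{\text{water}}$.
Overlaps along a ray are resolved by material priority
virion > nucleus > vacuole > cell, implemented as clipped subtraction —
matter is mutually exclusive, so chord lengths must not be double
counted.  `render_micrograph()` adds the only noise source modelled:
Poisson shot noise at the configured flat field.

Key defaults (all in `inst/extdata/default_config.yaml`, none hard-coded):

| parameter | default | why |
|---|---|---|
| `mu_water` | 0.1309 µm⁻¹ | inverted from 27% transmission through 10 µm of medium |
| `mu_biomass` | 1.1 µm⁻¹ | order-of-magnitude water-window contrast of dry organic matter; only the µ ratio matters for fraction-recovery tests |
| flat field | 700 photons/pixel | typical 60-s exposure without sample |
| pixel pitch | 19.3 nm | laboratory full-field geometry (39.5 µm field of view) |
| cell | 30 × 25 × 4 µm ellipsoid | a flattened adhered amoeba; 4 µm is the typical cryo-fixed thickness |
| cell density | 0.14 | calibrated once so the mean in-cell expectation is ≈ 130 photons/pixel under the 700-photon flat field |
| virion | 1250 × 590 nm prolate spheroid | measured particle dimensions |

The 130 photons/pixel calibration is deliberately loose (the quoted
"typical sample" figure mixes cell and background pixels in unknown
proportion), and the generator's test asserts it only to ±20%.

What the phantom does **not** emulate: zone-plate PSF and partial
coherence, hollow-cone condenser geometry, chromatic aberration,
cryo-fixation artifacts, tomographic tilt.  Passing recovery tests show
the *estimators* are unbiased under projection + Poisson noise; they do
not certify performance on real micrographs, where background
normalisation is the dominant systematic.

## Counting virions and the two-part error

Marks (length, width, angle crosses) are trusted as given — the package
emulates the semi-manual workflow and does no pixel-based detection.  A
mark is a virion iff its length lies in [700, 1500] nm **and**
length/width ≥ 1.3, all bounds inclusive (the thresholds are stated
without strictness; inclusive is the conventional reading).

The per-cell uncertainty adds two error sources:

* **False positives**: the misclassification rate measured on
  non-infected control cells, scaled by the cell's total mark count.
* **Orientation loss**: a randomly oriented rod of length $L$ projects
  below a cutoff $c$ with probability $1-\sqrt{1-(c/L)^2}$ — about 30%
  for 1-µm particles at 700 nm (`orientation_miss_probability()`).

Counting is a thinning of the true population, so the undercount given
$n$ counted is estimated as $n\,p/(1-p)$ (unbiased inversion); the cruder
$n\,p$ reading is available as `miss_mode = "direct"` since the source
analysis does not say which was applied.

Two geometric subtleties the package makes explicit:

* For a **prolate spheroid** the projected length never falls below the
  width $W$, so the exact miss probability is the rod formula on reduced
  axes, $(\sqrt{L^2-W^2}, \sqrt{c^2-W^2})$ — `spheroid_miss_probability()`.
  For the default particle this is 10.4% rather than the rod formula's
  21% at the same cutoff; phantom-cohort count corrections use the exact
  form, while the rod formula remains the back-of-envelope quantity.
* With $W = 590$ nm the **ellipticity bound is the binding one**: a
  projection shorter than $1.3 \times 590 = 767$ nm fails classification
  even though it exceeds 700 nm.  `effective_min_projected_length()`
  returns this effective cutoff; sensitivity is 100% above it by
  construction, not above 700 nm.

## Absorbance and conversion estimates

`absorbance_map()` computes $-\ln(I/I_0)$ per pixel after estimating
$I_0$ by least-squares fitting a 2D Gaussian to background samples around
the cell (`fit_illumination()`, Levenberg–Marquardt, no constant offset
by default).  Numerical choices:

* **Background sampling**: 36 points on a ring 2–5 µm outside the mask
  (offsets cycling 2 / 3.5 / 5 µm).  Each sample averages a 5 × 5-pixel
  patch: an annulus of single noisy pixels leaves the amplitude/width
  pair ill-determined (a ridge in parameter space), and extrapolating the
  fitted peak to the cell centre amplifies that noise severely; patch
  means restore conditioning without changing the sampling geometry.
* **Smoothing**: separable Gaussian, σ = 1 pixel, kernel truncated at 4σ
  and renormalised, reflective boundaries; σ = 0 is an exact identity.
* **Medium compensation**: the fitted illumination is seen through the
  full medium layer, but the cell displaces ≈ 4 µm of it, so the
  illumination used over the cell is the fit × exp(µ_water · 4 µm) ≈ 1.688.
* **Water corrections**: absorbance is only ∝ biomass after discounting
  the water share — ×(1 − 0.15) for the cell, ×(1 − 0.03) for the much
  denser virions, read as proportional decreases.  The constants are
  config values taken at face value.

`conversion_estimates()` produces the two bracketing estimates: **high**
= absorbance summed over marked virion footprints (ellipse of each mark's
length × width at its angle) over cell total — an overestimate since
projection includes cell material above and below each virion; **low** =
count × typical single-virion absorbance over cell total, where the
typical value comes from reference images containing only the virus
(`typical_virion_absorbance()`).  The integrated absorbance of one virion
is orientation-invariant (it is µ × volume), which the tests verify.

**Conventions in recovery tests.**  The phantom declares its water and
biomass content explicitly, and its ground-truth fraction is defined on
*water-excess* absorbance (everything above the medium baseline).
Recovery tests therefore run the estimator with medium compensation off
and water corrections zero — the matching convention — while the
paper-facing convention (compensation + 15%/3%) is exercised by its own
tests on slab phantoms where its bias-removal claim is well defined.
End-to-end, for programmed fractions 0.02–0.20 at 700 photons/pixel, the
low estimate recovers truth with small relative bias (the acceptance
suite bounds it at 15% over 50-cell cohorts) and high ≥ low in ≥ 95% of
cells.

## Titration inference

At dilution $d_i$ each well receives a Poisson number of infectious
units with mean $\lambda_i = a\,d_i$; a well is positive with probability
$1 - e^{-\lambda_i}$.  `fit_titration()` maximises the binomial
log-likelihood

$$ \ell(a) = \sum_i k_i \ln(1 - e^{-a d_i}) - (n_i - k_i)\, a d_i, $$

which is strictly concave in $a$, by bounded 1-D optimisation in
$\log a$; the implementation is checked against a dense grid-search
oracle.  The 95% interval is the profile-likelihood set (deviance drop
3.84, bisection in $\log a$ to 10⁻⁶).  Maximum likelihood is the default
because "fitting the detection percentages" is ambiguous; a least-squares
option is retained (with a seeded parametric bootstrap for its interval,
and a coarse-grid basin search first, since the squared-error surface can
have shoulders for decade-spaced schedules).  All-positive steps above
and all-negative steps below the informative region are included when
present; a deeper all-negative step is mildly informative (it shifts
$\hat a$ by a few percent) but leaves the TCID50 bracket unchanged,
which is what the robustness test asserts.

TCID50 is the dilution of half detection, $\ln 2 / \hat a$ exactly.
Degenerate series (all positive, or no positives) are refused with
explicit errors rather than returning boundary estimates.

Converting $\hat a$ to a burst size requires bookkeeping the series
itself cannot supply — the dilution of well 0 relative to the undiluted
lysate, the inoculated volume per well, lysate volume, and producing-cell
count — so `burst_size()` demands an explicit `burst_bookkeeping()` and
transforms the interval endpoints linearly.  Published per-cell intervals
are not reproducible without the unprinted inoculum volume, so burst
arithmetic is validated by self-consistency: simulated titrations from a
known burst recover it within the profile interval at the nominal rate.

## TGA reduction and the conversion interval

`residual_fraction()` finds the post-pyrolysis plateau as the trailing
run of points whose local mass-loss rate stays below 10⁻⁴ per °C.  The
rate is estimated by linear regression over a sliding window spanning 10%
of the temperature range — a plain finite difference would let
measurement noise of realistic amplitude (σ ≈ 0.005) mask a true plateau.
The plateau must span at least the last 5% of the range; otherwise the
function raises "weight stabilization not achieved", mirroring the
experimental failure mode.  The generator's plateaus are recovered to
±0.01 across levels 0.1–0.9.

The closing arithmetic: virion volume = π/6 · L · W² (prolate spheroid;
1.25 × 0.59 µm gives 0.23 µm³), volume fraction = burst × V_virion /
V_cell with V_cell = 3000 µm³, and biomass conversion = volume fraction ×
carbon ratio.  The carbon ratio is kept unrounded internally (68/28 =
2.43); only paper-facing reports round percentages to integers, which
reproduces every printed interval (2–5%, 5–12%, and the 6–12% overlap
with the image-based 6–17%).  `interval_intersection()` treats the empty
intersection as a value, not an error.

## Pipeline, configuration, reproducibility

`run_pipeline()` chains phantom generation → counting → absorbance →
titration → biomass report.  All constants live in YAML configuration
(validated structurally on load; user files overlay the bundled
defaults); every stochastic stage takes an explicit integer seed, and all
randomness flows through a state-restoring seed wrapper, so identical
configurations produce byte-identical tabular outputs.  Every report
carries the md5 hash of its configuration.  Units are fixed per field:
nanometres for marks and pixel pitch, micrometres for phantom geometry
and volumes; converters are explicit.

Problem sizes used by the validation suite are chosen to keep the full
run inside a few minutes on one CPU: recovery cohorts use 16 × 14 × 4 µm
cells rasterised at 80 nm/pixel (the estimators are pitch-independent;
tests confirm integrals scale with pixel area), 50 cells per programmed
fraction, 500 replicate titrations for interval coverage, and 10⁶
orientation draws for the stereology checks.

## Known limitations

* Projection imaging fundamentally confounds the high estimate with cell
  material above and below virions; only tomography removes this.
* Real background normalisation error is the dominant systematic on real
  data and is only partially represented by the Gaussian-illumination
  model.
* Virions leaving the cell by exocytosis are invisible to mask-restricted
  counting, so late-time counts and conversions are lower bounds.
* The TGA carbon ratio assumes comparable pyrolysis behaviour of virus
  and host biomolecules and carries the residual-char approximation.
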