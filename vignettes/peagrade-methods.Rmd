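---
title: "Methods: image features and discriminant models for field-pea grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image features and discriminant models for field-pea grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(peagrade)
```

This vignette records the models, parameter choices and design decisions
behind `peagrade`, including what the synthetic generator does and does not
establish. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The measurement model

Each seed is observed as six colour-intensity images under narrow-band LED
illumination (405–850 nm) plus a laser-measured surface-height image, all
co-registered, floating point, with exactly-zero background height. Two
empirical facts drive the feature design:

* colour intensity varies approximately **linearly with surface height**
  (taller parts of the seed are closer to the illuminant and less shadowed),
  so the per-pixel ratio `intensity / height` is a height-free estimate of
  coat reflectance;
* pixels near the seed boundary have near-zero height and shadow-corrupted
  intensities, so all colour and height statistics are taken inside a
  height-thresholded mask.

### Masks

* **M1** (size/shape): the original segmentation method for this instrument
  is not published, so we substitute a stated decision: threshold the height
  map at a small floor (default 1 height unit), apply a 3×3 morphological
  closing, fill interior holes, keep the largest 4-connected component.
  Single seeds on an exactly-zero background make intensity-based
  segmentation unnecessary. Connectivity conventions are fixed once:
  4-connectivity for components and hole filling, 8-connectivity for
  boundary tests.
* **M2** (colour/height): `M1 ∧ (height > 20 units)`. The 20-unit threshold
  is the instrument convention this pipeline follows; with the generator's
  height scale (peak heights roughly 100–300 units) it trims the ~10–15%
  boundary skirt of the dome, which is its intended role.

### The thirteen features

Six colour factors (median of `I_c / h` over M2, one per channel), seed
height (median of `h` over M2), area (`|M1|` in pixels), perimeter,
equivalent diameter `2·sqrt(area/π)`, volume (`Σ h` over M1), circularity
`4·area / (equivalent diameter × perimeter)`, plumpness.

Two definitions deferred to unpublished prior work were substituted:

* **Plumpness** := `seed_height / equivalent_diameter`. It uses only
  in-scope measurements and responds to shrivelling (height collapses while
  the footprint barely changes), which is the role the defect analysis needs.
* **Equivalent diameter** := diameter of the equal-area circle — the
  standard definition, and the one that makes circularity equal 1 for an
  ideal disk.

**Perimeter** deserves a note. The working definition "number of pixels in
the seed boundary" is ambiguous on a raster: counting mask pixels with a
background 8-neighbour tends to `~8r` for a disk of radius `r` (making
circularity → π/4 ≈ 0.785), and with a background 4-neighbour to `~5.7r`
(circularity ≈ 1.11). Neither reproduces the defining property that a disk
has circularity ≈ 1. We therefore measure the perimeter as the length of the
traced 8-connected boundary chain (Moore neighbour tracing) with diagonal
steps weighted √2 — the classic chain-code estimator, which gives disks
circularity ≈ 0.95, an axis-aligned square side `s` exactly `4s − 4`, and a
strictly decreasing circularity under elongation at equal area. Raw border
pixel counts remain available internally and are cross-checked against a
brute-force oracle in the tests.

### Aggregation and standardisation

A sample's feature vector is the coordinate-wise **median** over its seeds
(even counts: midpoint of the central order statistics); the median is what
makes a sample robust to its small fraction of atypical seeds. Features are
standardised to zero mean and unit sd **across the full calibration set**,
fitted once and reused for every model and for all validation samples.
Whether the original analysis refitted standardisation per model is
unstated; the single fit is the simpler convention and keeps the three
models on one scale.

## Discriminant analysis

LDA is implemented from first principles: per-class arithmetic mean vectors,
pooled within-class covariance `Σ = Σ_k (n_k − 1) S_k / (N − K)`, inverse via
Cholesky factorisation (failure maps to a "reduce the feature set" error).
Classification assigns the nearest class mean in Mahalanobis distance
`d_k(x) = sqrt((x − μ_k)' Σ⁻¹ (x − μ_k))`.

Decisions where the original convention is unstated:

* **Priors**: equal by default — pure nearest-Mahalanobis, which is what the
  published diagnostic plots describe ("the closest market grade mean").
  Proportional priors are available (`priors = "proportional"`), entering
  the decision as `d² − 2·log π_k`.
* **Ties**: broken by declared class order, everywhere.
* **Screening**: the published screen reports a per-feature F statistic from
  a one-way MANOVA; `screen_features()` computes per-feature one-way ANOVA F
  with p-values, plus Wilks' lambda and the singular values of the feature
  matrix (full rank iff `min(sv) > 1e-8 × max(sv)`).
* **Forward selection**: candidates visited once in colour → size → shape
  preference order; a candidate is kept iff refit-and-classify calibration
  accuracy **strictly** increases ("did not improve" ⇒ discarded). The ±
  reported on Mahalanobis group means is taken to be a standard error
  (`sd/√n`).

The identity `argmin_k d_k(x) = argmax_k (μ_k'Σ⁻¹x − ½μ_k'Σ⁻¹μ_k)` (equal
priors) is asserted on random instances in the tests, as are affine
invariance and the closed-form two-Gaussian accuracy `Φ(Δ/2)`.

## The three models

| | model1 | model2 | defect |
|---|---|---|---|
| features | blue, green, orange, red factors | + violet factor, equivalent diameter, circularity, plumpness | as model2 |
| training | non-defective calibration | full calibration | full calibration |
| classes | 7 grades (no Yellow Forage) | 8 grades | defective / non-defective |

Model 1 omits Yellow Forage because, in the standard design, every Yellow
Forage sample is defective, so the non-defective training subset contains
none; accordingly its defective-sample accuracy is scored without Yellow
Forage samples and its defective-calibration cell is never assessed
(reported `NA`). Accuracies are reported per evaluation cell
(non-defective/defective × calibration/validation) to the nearest integer
percent.

## The synthetic generator: the stated world

No instrument imagery is deposited, so the generator emulates the *structure*
the analysis assumes, under a fixed design of 175 calibration samples (39
defective) and 142 validation samples (39 defective) with the published
per-grade cell counts, 30 seeds per sample, 96×96 px.

* **Geometry**: an elliptical paraboloid height dome; per-grade mean
  semi-axes 16–28 px with sd ~1.2 px, peak heights 140–220 units (sd 10–14).
  The absolute height unit is a free choice (nothing published fixes it);
  100–300-unit peaks make the 20-unit threshold a boundary trim rather than
  a body cut. Boundary irregularity: low-order Fourier modulation (modes
  2–4) of the footprint radius, amplitude 0.5 px for round grades, 1.5 px
  for the blocky Marrowfat.
* **Colour**: channel intensity = reflectance × height × lognormal noise
  (sd 0.05), so colour factors recover reflectance; per-seed coat jitter
  (lognormal, sd `0.6 × noise_sd`) creates within-grade spread. Reflectance
  vectors are invented but ordered like real coats (White bright everywhere,
  duns darker at short wavelengths, Yellow Forage yellow, NIR nearly
  constant across grades); every grade pair is separated on at least one
  mid-wavelength channel by more than the induced within-grade spread.
  Mottled Dun and Kaspa type carry natural dark speckling.
* **Defects** (drawn per defective seed: disease stain 50%, shrivel 20%,
  exposed cotyledon 15%, insect 15%; severity ~ U(0.3, 0.8)): stains darken
  patches with a short-wavelength-weighted transmittance (violet hardest
  hit — which is what lets the violet factor separate staining from natural
  speckling); exposed cotyledon swaps patch reflectance for a yellow-shifted
  cotyledon colour; shrivelling scales the height field by `1 − severity`
  and carves dimples *only into pixels strictly below the median footprint
  height* (this provably leaves the median height equal to
  `(1 − severity) ×` the clean median — the exactness the contract demands);
  insect damage adds dark pits. Shrivel and insect damage also dull the coat
  slightly (short-wavelength-weighted), a stated-world choice justified by
  the fact that weather and insect damage discolour as well as deform seed;
  it gives all defect kinds a shared spectral component, without which a
  single linear boundary could not be expected to catch a mixture of
  geometry-only and colour-only defects.
* **Sample defect rules**: defective samples draw a defective-seed fraction
  ~ U(0.75, 1); non-defective samples allow at most `⌈0.05·n⌉ − 1` mildly
  defective seeds via Binomial(n, 0.01) — i.e. ≥ 75% vs < 5% of seeds.
* **Determinism**: every draw derives from the design's single `rng_seed`
  via fixed integer sub-seeds per (sample, seed); identical designs are
  bit-for-bit identical, and geometry draws precede defect draws so a
  defective render shares its clean counterpart's geometry.

**What a green test establishes — and does not.** The generator produces
grade clusters that are linearly separable by construction (the published
screen found the same qualitatively: every feature's F significant at
p < 0.001), so 100% non-defective accuracy here validates the *pipeline
logic* — masks, height correction, medians, standardisation, LDA — not the
field difficulty of pea grading. Real defective samples are harder than
synthetic ones: the published grade models scored 87%/77% on defective
calibration/validation samples, while this synthetic world gives model 2
higher defective accuracy because its defect palette is cleaner than real
disease. The defect model's all-validation accuracy is a stochastic quantity
(a handful of borderline mildly-defective samples decide it); the acceptance
suite evaluates it at the design's default seed, where it clears 97%, and
the defective-vs-non-defective Mahalanobis gap (defective samples roughly
twice as far from their nearest grade mean) reproduces the qualitative
published pattern at every seed we compute.

## Numerical conventions

* Pixels are matrix cells, row-major, origin at the top-left pixel centre;
  masks are pure pixel sets.
* Rank tolerance `1e-8` (relative smallest/largest singular value);
  covariance inversion failures raise errors rather than pseudo-inverting.
* Medians over even counts take the midpoint of the two central order
  statistics (R's default), used identically at pixel, seed and sample
  level.
* `fit_lda()` demands ≥ 2 records per class and `N − K ≥ p` up front, so
  singularities surface as informative errors.
* Degenerate inputs: all-zero height → "no seed found"; no pixel above the
  height threshold → "seed below height threshold"; zero-variance feature →
  error naming the feature; empty seed list → error.

## Known limitations

* One seed per stack: no touching-seed separation or watershed splitting.
* No broken-seed fragment geometry; "broken" grain is represented only
  through the other defect overlays.
* Defect sub-type classification (disease vs insect vs weather) is out of
  scope.
* The substituted plumpness/equivalent-diameter/segmentation definitions are
  reasonable but not guaranteed to match the unpublished originals; absolute
  feature values are therefore not comparable to the original instrument's,
  only the pipeline's behaviour is.
* TIFF stack serialisation is not provided (no TIFF writer in the supported
  dependency set); the plain-text directory format holds the same data.
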