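---
title: "Dual geometric-morphometric pipelines for wing-based species identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual geometric-morphometric pipelines for wing-based species identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingmorph)
```

## The problem

Closely related horse fly species (*Tabanus*) are hard to tell apart from
external characters, yet identifying them matters: they are mechanical
vectors of livestock pathogens. Wing venation is species-specific and the
wing is nearly two-dimensional, which makes it ideal for quantitative
shape analysis. `wingmorph` implements the two standard, complementary
quantifications:

* **landmarks** — 21 homologous vein intersections and terminations per
  wing, coordinates in mm;
* **outlines** — the closed contour of the first submarginal cell,
  digitized as an ordered boundary polygon.

Each pipeline yields one *size* variable and a set of *shape* variables,
which enter a shared discriminant stack. The informative contrast is that
wing *shape* classifies specimens to species almost perfectly while wing
*size* alone performs near chance: size distributions of congeneric
species overlap broadly, shape does not.

## Landmark pipeline

**Centroid size.** `centroid_size()` is the square root of the summed
squared distances of the landmarks from their centroid — the standard
isometric size measure; it is invariant under rotation and translation and
scales linearly with the configuration.

**Generalized Procrustes analysis.** `gpa()` removes non-shape variation
by centring every configuration, scaling it to unit centroid size, and
iteratively rotating it onto an evolving consensus (the mean of the
aligned shapes, re-normalized each sweep) until the consensus
root-mean-square change drops below `tol = 1e-8` or 100 sweeps pass
(non-convergence is flagged, not fatal; in practice 3–5 sweeps suffice).
Rotations come from the standard SVD solution with reflections excluded —
all wings are digitized from the same (left) side, so a reflection would
be an artefact, and shape statistics are reflection-sensitive. Aligned
shapes are then projected orthogonally onto the tangent space at the
consensus so that ordinary multivariate statistics apply. Two numerical
consequences worth knowing: the unit-centroid-size property holds exactly
*before* tangent projection (projection perturbs norms by the square of
the shape spread, here ~10⁻³), and re-running the alignment on aligned
shapes is a no-op only with projection off — both are covered by tests in
exactly those terms.

**Repeatability.** Digitization error is quantified by
`procrustes_anova_repeatability()`: all replicates enter one GPA, and the
aligned coordinates are decomposed into among-specimen and
within-specimen sums of squares pooled over all landmark coordinates
(Goodall-style, rather than per-landmark ANOVA — the source analyses cite
the method without formulas, and pooled residuals are the convention for
Procrustes data). The reported statistic is the intraclass correlation
R = (MSₐ − MS_w)/(MSₐ + (m−1)MS_w), clamped to [0, 1]. Equal replication
is required; the estimate recovers a designed 9:1 variance ratio to
within ±0.05 at 200 specimens.

**Allometry.** `allometry_r2()` regresses the first discriminant factor
on centroid size and reports r². The generator can induce a known
allometric signal (`allometry_coef`) for validation; by default size and
shape are independent.

## Outline pipeline

`resample_contour()` places pseudo-landmarks at equal arc-length spacing
(300 by default) and normalizes orientation to counter-clockwise.
`efa()` computes elliptic Fourier coefficients from the piecewise-linear
chord-length parameterization; `efa_normalize()` applies first-harmonic
normalization — parameter origin moved to a major-axis vertex of the
first-harmonic ellipse, frame rotated onto that axis, all coefficients
divided by the semi-major magnitude — leaving a₁ = 1, b₁ = c₁ = 0 and
shape information in d₁ and the higher harmonics. Which of the two
major-axis vertices is chosen flips the sign of even harmonics; the
package resolves it intrinsically (first nonzero even-harmonic
coefficient positive) or, at dataset level (`efa_dataset()`), by aligning
every specimen to the first one via a dot-product sign check, so
conspecific coefficient vectors are directly comparable. Whether the
upstream tool the reference analyses used normalizes this way is not
documented; first-harmonic normalization is the assumption made here, and
it is the common one.

The size variable is the *raw digitized perimeter*, measured before
resampling. Defaults of 300 points and 20 harmonics retain ≥ 99.9% of
cumulative harmonic power on smooth quadrilateral-like cells
(`harmonic_power_cutoff()` lets you verify this on your own data).

Numerical caveats, both tested: the integral (Kuhl–Giardina-style)
coefficients are not the DFT, so full-harmonic reconstruction reproduces a
smooth 300-point contour to ~10⁻⁴ (not machine precision, and worse at
sharp corners); and chord-length parameterization of a true ellipse is not
the uniform-angle parameterization, so a 2:1 ellipse's first harmonic
recovers the semi-axes only to within ~10%.

## The discriminant stack

`shape_pca()` reduces either variable set to its leading principal
components — 24 (landmark) and 23 (outline) by default, matching the
reference analyses; no selection rule is implied, and both are
overridable. `discriminant_analysis()` computes canonical variates of the
between-species covariance against the pooled within-species covariance
(the standard CVA convention; the pooled choice also underlies
`mahalanobis_matrix()`). Singular pooled covariances are
ridge-regularized (λ = 10⁻⁸ × mean diagonal) with a warning.

`permutation_test()` compares every species pair with B = 1000 label
permutations within the pair by default, using the add-one estimator
p = (1 + #{permuted ≥ observed})/(B + 1) — so p ≥ 1/(B+1) — and declares
significance at the Bonferroni-corrected 0.05/#pairs.

`loo_classify_shape()` refits means and pooled covariance without each
specimen and assigns it to the nearest species by Mahalanobis distance
(ties, which essentially only occur in degenerate data, go to the first
species in label order and are counted). `loo_classify_size()` assigns by
univariate Gaussian likelihood under the held-out species mean and
variance, weighted by the species' relative frequency as prior — the
"maximum likelihood" size rule is not spelled out in the reference
analyses beyond its name, and this is the documented interpretation.
Zero within-species variance gets an epsilon floor (10⁻¹² × mean²).

**Chance adjustment.** Raw leave-one-out accuracy is corrected by the
proportional chance criterion: A_chance = Σ(nᵢ/N)², adjusted =
(A_obs − A_chance)/(1 − A_chance), reported as an integer percent
(half-up rounding). With the published group sizes this formula reproduces
all four published adjusted scores (97 and 27 for the landmark pipeline,
96 and 23 for the outline pipeline) from the published raw accuracies —
the key evidence that the implemented formula matches the one used. A flat
1/k correction would round to the same integers on these near-balanced
groups; Σpᵢ² is used because it respects unequal sample sizes.

## The synthetic generator

Real raw coordinates for the reference study are not deposited, so every
stage is validated against `generate_landmark_dataset()` /
`generate_contour_dataset()`. The defaults *are* the study design:

* 15 species; per-species sample sizes from the published Table of wing
  counts (N = 636 landmark, N = 633 outline);
* species mean centroid sizes 7.34–13.47 mm and cell perimeters
  9.27–16.92 mm (the published species means), log-normal size noise with
  cv = 0.05 (published SD/mean ratios are ≈ 0.04–0.07);
* species mean shapes are a fixed hand-placed 21-landmark wing template
  (coordinates arbitrary by construction) plus Gaussian offsets of
  0.006 shape units per coordinate; specimens add 0.005 within-species
  noise; replicate digitization noise defaults to 0.01 mm (≈ 0.001 shape
  units on a 9 mm wing); contours analogously perturb normalized Fourier
  coefficients (0.006 / 0.005). The between/within ratio was chosen analytically so
  expected pairwise Mahalanobis distances fall in the published 4–19
  range (E[D²] ≈ 2q·(b/w)² at q ≈ 24 retained PCs), not fitted to any
  test outcome;
* specimens are randomly rotated and translated, so alignment is
  genuinely exercised; contour draws that self-intersect are rejected and
  redrawn (max 100 tries).

What the generator does *not* emulate: allometric curvature of real
wings (only an optional linear coupling), landmark-specific error
structure (noise is isotropic and homoscedastic), digitization outliers,
and any phylogenetic correlation among species means. Passing the
end-to-end tests therefore shows the pipeline recovers *this* structure
— Gaussian clusters in shape space with overlapping sizes — at study
scale, not that real tabanid wings behave identically.

At these settings the full landmark pipeline yields shape LOO accuracy
above 90% with size LOO accuracy below 50% across seeds, reproducing the
published qualitative contrast; these are computed live in the test suite
(`test-acceptance.R`), never asserted as constants.

## Degenerate inputs and tie-breaks

* Fully coincident landmark configurations are rejected; collinear ones
  are allowed with a warning (rank-deficient but alignable).
* A circle has no defined major axis; its normalized harmonics degenerate
  to (1, 0, 0, ±1) and downstream shape variables carry no information —
  the quarter-turn candidate search in `efa_normalize()` keeps the
  operation well-defined even there.
* PCA retains at most the data rank, with a warning when asked for more.
* TPS ids written as `<species>_<id>` round-trip exactly; files with
  other conventions can supply labels explicitly.

## Problem sizes

Module tests run on small instances (tens of specimens); the end-to-end
checks use the full simulated study design (15 species, 636/633
specimens) — one landmark run takes a few seconds. Permutation tests
default to B = 1000 in analyses but use smaller B in tests, where only
estimator properties (bounds, null uniformity, detection at complete
separation) are at stake.

## Barcode utilities

`base_composition()` summarizes nucleotide composition of *cox*1 barcode
FASTA over unambiguous A/C/G/T positions, averaging per sequence
(equal weight) by default, with pooled-position averaging as an option —
the two conventions differ only when sequence lengths differ. The
deposited barcode accessions themselves are not bundled, so composition
checks in the test suite use sequences of constructed, known makeup.
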