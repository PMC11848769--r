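# wingmorph

Geometric morphometrics for insect wing species identification, built
around the two complementary pipelines used to separate morphologically
similar horse flies (*Tabanus*) by their wings:

* **Landmark pipeline** — 21 fixed anatomical landmarks per wing are
  aligned by generalized Procrustes analysis (GPA); size is the centroid
  size CS = √Σᵢ‖xᵢ − x̄‖², the standard isometric size measure.
* **Outline pipeline** — the closed contour of the first submarginal wing
  cell is resampled by arc length and decomposed into elliptic Fourier
  harmonics (aₙ, bₙ, cₙ, dₙ); first-harmonic normalization removes size,
  rotation and starting point; size is the cell perimeter.

Both feed the same statistical stack: shape PCA (24 PCs landmark / 23 PCs
outline by default), canonical discriminant analysis with a DF1/DF2 factor
map, pairwise Mahalanobis distances
D(i,j) = √((μᵢ−μⱼ)ᵀ S⁻¹ (μᵢ−μⱼ)) with S the pooled within-species
covariance, non-parametric permutation tests (1000 replicates,
Bonferroni-corrected), and validated (leave-one-out) classification —
Gaussian maximum likelihood with frequency priors for size, minimum
Mahalanobis distance for shape — reported with the chance-adjusted
accuracy (A − Σpᵢ²)/(1 − Σpᵢ²) under the proportional chance criterion.

Because raw wing coordinates for the reference study are not public, the
package ships a synthetic generator (`generate_landmark_dataset()`,
`generate_contour_dataset()`) that emulates the study design — 15 species,
the published sample sizes, centroid sizes of 7.3–13.5 mm, cell perimeters
of 9.3–16.9 mm — plus the published summary tables
(`tabanus_reference()`) for the arithmetic that *is* reproducible.

## Worked example

```r
library(wingmorph)

spec  <- synthetic_wing_spec(seed = 7)       # study-like 15-species design
wings <- generate_landmark_dataset(spec)
wings
#> wing_dataset: 636 specimens, 15 species
#>   landmarks: 636 records (21 per wing), contours: 0 records, unit: mm

res <- analyze_wing_data(wings, "landmark", permutation_B = 0)
res
#> wing_analysis (landmark pipeline): 636 specimens, 15 species
#>   DF1 = 19.4%, DF2 = 13.5%; allometry r^2 = 0.002
#>   size LOO:  36.79% (adjusted 32%)
#>   shape LOO: 100.00% (adjusted 100%)

round(res$mahalanobis[1:4, 1:4], 2)
#>       sp01  sp02  sp03  sp04
#> sp01  0.00 12.58 10.04 10.07
#> sp02 12.58  0.00 10.36 10.66
#> sp03 10.04 10.36  0.00 10.39
#> sp04 10.07 10.66 10.39  0.00
```

Shape separates the simulated species almost perfectly while size alone
stays near chance — the qualitative contrast the dual-pipeline design is
meant to expose (size distributions overlap heavily across species; shape
does not). `analyze_wing_data(..., out_dir = "reports")` writes the size
summary, Mahalanobis lower triangle and classification tables as CSV with
JSON twins. The chance adjustment is also available standalone:

```r
chance_adjust(0.9733, tabanus_reference()$n_landmark)
#> [1] 97
```

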