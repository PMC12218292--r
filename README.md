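# filamentr

Quantification of Rad51 recombinase structures in yeast nuclei, and NMR
mapping of the Rad51-binding region of an intrinsically disordered partner
domain.

After a DNA double-strand break, the Rad51 recombinase polymerises on
resected single-stranded DNA into a helical nucleofilament. In strains
expressing GFP-tagged Rad51, these filaments appear as elongated structures
in the nucleus, while stalled or partial assemblies appear as
diffraction-limited foci. `filamentr` turns cropped 3D image stacks of such
nuclei into a per-cell feature table and strain-level statistics:

1. **Segmentation** — filaments and foci are enhanced with a generalized
   Laplacian-of-Gaussian (GLoG) filter bank: anisotropic
   second-derivative-of-Gaussian ridge filters steered over 24 orientations
   and 3 scales tied to the single user parameter, the filament width
   (2 px = 130 nm at a 65 nm pixel), plus isotropic LoG blob filters for
   foci. Detections are thresholded with a robust z-score
   (median + k·MAD) and refined to the half-maximum footprint.
2. **Skeletonization** — masks are thinned to 1-px skeletons, spurious
   branches pruned, endpoints elongated to fit the mask, and
   Analyze-Skeleton-style features extracted (components, branches,
   junctions, endpoints, lengths with √2 diagonal steps).
3. **Classification** — each nucleus is assigned one of four categories:
   *Simple* (a unique unbranched skeleton), *Complex* (multiple or branched
   skeletons), *Foci* (no skeleton, ≥1 focus), *Nothing*. Lengths and total
   intensities are reported for Simple filaments only (complex shapes
   overestimate length); for multi-focus cells only the brightest focus is
   kept. Intensities are background-subtracted on raw images (median
   nuclear gray level) and normalized to the wild-type mean; strain mean
   focus intensities are classed bright / intermediate / dim at 80% / 20%
   of wild type.
4. **Statistics** — for each pair of strains, three binomial logistic
   regressions test feature–strain association, always adjusting for the
   experimental batch:

   ```
   condition ~ 1 + hasFilament + batch
   condition ~ 1 + filamentLength + filamentIntensity + batch
   condition ~ 1 + spotIntensity + batch
   ```

   Wald statistics t = estimate/SE are referred to a t distribution with
   residual degrees of freedom, and all p-values are corrected jointly with
   the Benjamini–Hochberg false discovery rate.
5. **NMR mapping** — from per-residue amide peak tables of a free and a
   partner-bound sample, the package computes the intensity ratio I/I0,
   the Cα chemical-shift index against sequence-corrected random-coil
   values (near-zero values flag disorder), and calls contiguous
   interacting regions as runs of attenuated residues.

A first-class synthetic-data module renders nucleus crops (Gaussian-tube
filaments and point foci over a diffuse nuclear background, PSF blur,
Poisson + read noise, per-batch intensity factors) and NMR titrations with
planted attenuation, so every stage can be validated against known ground
truth without any external data.

## Worked example

```r
library(filamentr)

# simulate a 4-strain experiment and quantify it end to end
out <- run_imaging_pipeline(list(
  seed = 31,
  simulate = list(n_cells = 25, n_batches = 3),
  statistics = list(pairs = list(c("WT", "mutA")))
))

dplyr::count(out$records, strain, category)
#> # A tibble: 15 × 3
#>    strain category     n
#>    <chr>  <chr>    <int>
#>  1 WT     Complex      3
#>  2 WT     Foci         5
#>  3 WT     Nothing      4
#>  4 WT     Simple      13
#>  5 mutA   Complex      2
#>  6 mutA   Foci        15
#>  7 mutA   Nothing      8
#>  ...

subset(out$tests, term == "has_filament",
       c(model_id, estimate, se, t, p, q, stars))
#> # A tibble: 1 × 7
#>   model_id term         estimate    se     t        p        q stars
#>   <chr>    <chr>           <dbl> <dbl> <dbl>    <dbl>    <dbl> <chr>
#> 1 M1       has_filament    -3.11 0.873 -3.57 0.000857 0.000857 ***
```

The record table carries one row per nucleus (`category`, `has_filament`,
`filament_length_px`, `filament_intensity`, `spot_intensity`); the test
table carries one row per tested coefficient with its FDR-adjusted q.
Here the filament-deficient mutant shows a strong negative `hasFilament`
association (log-odds −3.1, q < 0.001). The M3 comparison of this pair is
*flagged* rather than reported: with 25 cells per strain the mutant's
8-fold-dimmer foci separate the two strains perfectly, and the package
reports complete separation instead of a fabricated p-value.

For the NMR side:

```r
seq471 <- simulate_protein_sequence(471, seed = 4, no_pro_at = c(310, 395))
tt <- simulate_nmr_titration(seq471, region = c(310, 395),
                             attenuation = 0.2, noise_cv = 0.1, seed = 1)
call_interaction_region(intensity_ratio(tt$bound, tt$free))
#> # A tibble: 1 × 4
#>   start   end n_obs mean_ratio
#>   <int> <int> <int>      <dbl>
#> 1   310   395    80      0.200
```

`plot_category_proportions()`, `plot_intensity_distributions()`,
`plot_ratio_profile()` and `plot_secondary_shift()` give the standard
figures; `tidy()` / `glance()` work on fitted pair models. A thin CLI with
`simulate` / `quantify` / `stats` / `nmr` / `all` subcommands is installed
under `inst/cli/filamentr`.

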