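# sagisou

Lip morphometrics and microsatellite population genetics for the egret
flower, *Habenaria radiata* — a terrestrial orchid whose fringed lip
(labellum) resembles a white egret in flight, and whose small, fragmented
Japanese populations are of conservation concern.

The package implements the two analysis tracks such a population survey
needs, plus synthetic-data generators that make every stage testable
without field data:

* **Lip morphometrics.** A lip outline is decomposed into a central *body*
  and two *wings*. Seven factors are measured from vector contours and
  landmarks: whole-lip area and perimeter, the dissection index of the
  left wing (DI = perimeter / √area, minimized by a circle at 2√π), body
  length and width, wing length, the body–wing angle, and the serration
  (tooth) count of the left wing's fringed margin. Six of these are
  normalized by fixed maxima (DI 40, body length 30 mm, body width 10 mm,
  wing length 40 mm, angle 90°, serrations 50) into radar profiles for
  per-population comparison.
* **SSR population genetics.** From diploid microsatellite genotypes
  (allele = fragment size): per-locus and per-population observed
  heterozygosity *Ho*, Nei's unbiased expected heterozygosity
  *He* = (2n/(2n−1))(1 − Σp²), the fixation index
  *F* = 1 − H̄o/H̄e with a within-population permutation test, the
  conditional exact Hardy–Weinberg test (full enumeration or seeded
  Monte Carlo), and Chakraborty-style null-allele frequencies
  r = (He − Ho)/(He + Ho).
* **Trees.** Nei's standard genetic distance
  D = −ln(J_XY / √(J_X·J_Y)) between individuals or populations,
  neighbor-joining, locus-bootstrap supports, Newick export.
* **Admixture.** A Gibbs sampler for the standard admixture model
  (STRUCTURE-style, independent allele frequencies), ln P(D) per run
  estimated as mean − variance/2 of the likelihood trace, Evanno's
  ΔK = |L″(K)|/sd(K) for choosing the number of clusters, and exhaustive
  label alignment across runs.
* **Synthetic data.** Parametric "egret" lip contours with controllable
  dimensions, body–wing angle and tooth count, and SSR genotype datasets
  with known allele frequencies, inbreeding coefficients (F from −1 to 1),
  admixture proportions or clonal founder structure.
* **IO.** Genepop and STRUCTURE text formats (round-trip safe), CSV
  tables, and a seeded end-to-end pipeline (`run_pipeline()`).

## Worked example

```r
library(sagisou)

# a synthetic flower: 20 teeth on the left wing, 60 degree wing spread
ann <- generate_lip_contour(lip_shape_params(
  body_length = 15, body_width = 6, wing_radius = 20,
  body_wing_angle = 60, serration_count = 20, serration_amplitude = 0.5
))
measure_lip(ann)
#> # A tibble: 1 x 8
#>    area perimeter dissection_index body_length body_width wing_length angle serration_number
#>   <dbl>     <dbl>            <dbl>       <dbl>      <dbl>       <dbl> <dbl>            <int>
#> 1  735.      151.             5.08          15          6          20    60               20
```

The whole lip covers 735 mm² with a 151 mm outline; the left wing's
dissection index 5.08 sits above the circular minimum 2√π ≈ 3.54, as the
isoperimetric inequality demands — the serrated fan is moderately more
dissected than a disc. Dividing by the fixed maxima gives the radar
profile (DI 0.127, BL 0.5, BW 0.6, WL 0.5, A 0.667, Se 0.4).

```r
# eight populations at the field survey's sample sizes, then Table-1 output
sim <- simulate_genotypes(pop_sim_params(f_is_per_pop = 0.1, seed = 1))
population_table(sim$genotypes, reps = 999, seed = 1)
#> # A tibble: 8 x 7
#>   population     n he_mean ho_mean       f   f_p significant
#>   <chr>      <int>   <dbl>   <dbl>   <dbl> <dbl> <lgl>
#> 1 pop1           9   0.657   0.550 0.163   0.001 TRUE
#> 2 pop2           9   0.685   0.661 0.0345  0.485 FALSE
#> # ... 6 more rows: n tracks the input sample sizes (5-18); F is the
#> # heterozygote deficit relative to Hardy-Weinberg, here simulated at 0.1

# tree and admixture
tree <- bootstrap_tree(sim$genotypes, unit = "individual",
                       replicates = 1000, seed = 1, cap = 25)
write_newick(tree, "tree.nwk")
scan <- run_admixture_scan(sim$genotypes, k_values = 1:4, runs_per_k = 4,
                           burn_in = 2000, reps = 10000, seed = 1)
optimal_k(evanno_delta_k(scan))
```

`autoplot()` methods draw the radar charts, Evanno panels and stacked-bar
membership plots; `plot_tree()` renders the NJ tree with supports at or
above the display threshold (50% by default).

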