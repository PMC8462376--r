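# mycospat

Spatial ecology of paired soil and phylloplane fungal communities.

`mycospat` analyses paired-habitat, spatially explicit fungal metabarcoding
surveys: grid transects where the soil and the overhanging leaf surfaces
(the phylloplane) are swabbed at the *same* geographic points, yielding a
samples × OTUs table indexed by transect, habitat and within-transect
coordinates. It is written for microbial ecologists who want to ask, from
one OTU table:

* **Are the two habitats spatially coupled?** Same-location cross-habitat
  Bray–Curtis dissimilarities, `BC(x, y) = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ)`, are
  compared against a randomized-pairing null built from derangements
  (pairings with no same-location pair), with a Welch t-test at the
  whole-study and per-transect scales.
* **Which OTUs are habitat specialists or generalists?** Occurrence-based
  rules per transect: a generalist occurs more than once in each habitat; a
  specialist more than once and exclusively in one. Occupancy (occupied
  locations per transect, max 36 in the default design) is compared across
  class–habitat groups by pairwise Wilcoxon tests with Benjamini–Hochberg
  correction, and occupancy–abundance curves are fitted with a tricube
  local-polynomial smoother.
* **How large are individual OTUs' geographic ranges?** A one-sided Mantel
  screen flags spatially autocorrelated OTUs; their method-of-moments
  semivariograms `γ̂(h) = (1/2N(h)) Σ (zᵢ−zⱼ)²` are fitted with the
  zero-nugget exponential model `γ(h) = sill·(1 − exp(−h/a))` by bounded
  weighted least squares, and the effective range `3a` (lag at 95% of the
  sill) is reported, culled below 1 m and outlier-flagged above the
  transect diagonal.
* **What do distributions look like?** Ordinary kriging (global
  neighborhood, Lagrange unbiasedness constraint) produces paired
  soil/phylloplane prediction and standard-error surfaces, with a
  cross-habitat synchrony score per generalist OTU.

A first-class synthetic-data generator simulates the full survey design —
six 10 m × 40 m transects, 36 paired locations each, 432 samples — with
spatially autocorrelated Gaussian latent fields (exponential covariance,
Cholesky draws), tunable cross-habitat coupling, and known
specialist/generalist membership, so every inference stage is validated
against ground truth. The statistical kernel (Bray–Curtis, permanova,
Mantel, Wilcoxon, Welch/pooled t, Benjamini–Hochberg) is implemented in the
package and cross-checked in the tests against independent oracles and
vegan/stats.

## Worked example

```r
library(mycospat)

sim <- simulate_study(synthetic_params(coupling_rho = 0.8,
                                       detection_offset = 3, seed = 42))
sim$table
#> <spatial_otu_table> 432 samples x 120 OTUs (counts), 6 transect(s), habitats: soil, phylloplane

inter_habitat_test(sim$table, scale = "entire_study",
                   n_randomizations = 99, seed = 42)
#>    scale_label observed_mean_bc randomized_mean_bc t_statistic  p_value autocorrelated
#> 1 entire_study            0.789              0.871       -16.4 5.21e-40           TRUE

filt <- remove_singletons(sim$table)
cl <- classify_otus(filt)
table(cl$label)
#>             generalist phylloplane_specialist        soil_specialist
#>                    240                    240                    240

screen <- mantel_screen(filt, n_permutations = 199, seed = 42)
est <- estimate_ranges(filt, screen, cl, min_pairs = 5)
cull_and_flag(est)
#> <cull_result> 49 models: 17 culled (< min range), 0 outliers, 32 remaining
```

Reading the output: paired communities are *less* dissimilar (0.789) than
randomized pairings (0.871), so cross-habitat co-occurrence is spatially
autocorrelated, as expected with generalists coupled at ρ = 0.8. All 120
simulated OTUs are recovered in their generating class (40 OTUs × 6
transects = 240 labels per class). Of the 960 screened OTU–transect–habitat
candidates, 49 pass the Mantel screen at α = 0.05; 17 fitted ranges fall
below the 1 m cull and 32 survive, with a median effective range of 6.7 m.

`run_pipeline(pipeline_config(synthetic = synthetic_params(seed = 1)))`
runs every stage end to end and writes TSV outputs plus a JSON manifest;
`autoplot()` methods draw variograms, kriged surfaces and paired-map
panels, and `plot_occupancy_abundance()` the occupancy–abundance
relationship.

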