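# betadrivers

Which forces shape the composition of terrestrial arthropod
assemblages — the local flora, the surrounding land cover, climate,
plain geography, the abiotic conditions the vegetation integrates, or
direct trophic links to host plants? `betadrivers` is an R package for
ecologists who want to answer that question from presence–absence
survey data. It implements the full attribution workflow:

* **community assembly** — pooling sampling periods and surveys into
  binary site × taxon tables, subsetting by functional group or order,
  identification-confidence filtering, host-plant subsets of the flora;
* **dissimilarities** — Sørensen distances
  d = (b + c) / (2a + b + c) for assemblages, Euclidean distances for
  numeric predictors, max-value standardization for mixed-unit climate
  blocks;
* **dbRDA + variation partitioning** — distance-based redundancy
  analysis with the McArdle–Anderson trace-ratio R²,
  R²_adj = 1 − (1 − R²)(n − 1)/(n − m − 1) (Ezekiel), and exclusive
  fractions for 2–4 predictor sets via Möbius inversion over the subset
  lattice (negative fractions reported, never truncated);
* **Mantel permutation tests** — site-relabeling null, add-one
  one-sided p-values, batch mode for predictor inter-correlations;
* **Ellenberg indicator profiles** — per-site relative frequencies of
  light, temperature, continentality, moisture, soil-reaction and
  nutrient classes, with the standard missing-value exclusion rule;
* **host-plant randomization null** — does the host-plant subset of
  monophagous herbivores explain arthropod composition better than
  random plant subsets of equal size? (one-sample t-test against the
  observed value, z-score alongside);
* **a synthetic study generator** — niche-structured plants with
  indicator values, arthropods assembled from configurable driver
  mixtures (plants, land cover, climate, space, noise) with optional
  monophage–host dependencies, so the whole pipeline is testable with
  known truth.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects
have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(betadrivers)
library(dplyr)

sim  <- simulate_study(synthetic_config(monophage_fraction = 0.3, seed = 1))
herb <- subset_by_group(sim$arthropods, sim$traits, "herbivore")
d    <- sorensen_matrix(herb)

vp <- varpart(d, list(
  plants    = sorensen_matrix(sim$plants),
  landcover = euclidean_matrix(landcover_block(sim$sites)),
  climate   = euclidean_matrix(max_standardize(climate_block(sim$sites))),
  space     = euclidean_matrix(space_block(sim$sites))),
  max_axes = 8)
vp
#> Variation partitioning (4 sets: plants, landcover, climate, space; n = 60 sites)
#>   total adjusted R2 = 0.3489, residual = 0.6511
#>   independent fractions:
#>     plants       0.2138
#>     landcover    0.0318
#>     climate      0.0087
#>     space        0.0028
```

The four predictor sets together explain 34.9 % of the variation in
herbivore composition (adjusted R²). Plant species composition keeps
the largest unique share (0.21); land cover adds a small unique
fraction (0.03) on top of what it shares with the flora, while climate
and space contribute essentially nothing of their own — the pattern the
generator's default driver weights encode.

```r
prof <- indicator_frequency_matrix(sim$plants, sim$plant_attrs)
mantel_test(d, euclidean_matrix(single_indicator_block(prof, "T")),
            n_perm = 199, seed = 1)
#> Mantel test: r = 0.1601, p = 0.005 (199 permutations, n = 60)

hosts <- host_plant_subset(sim$plants, sim$plant_attrs, sim$traits)
nn <- random_subset_null(d, sim$plants, prof, hosts,
                         n_reps = 100, seed = 1)
summarize_null(nn) |>
  select(observed, null_mean, null_sd, t_statistic, p_value, stars)
#> # A tibble: 1 × 6
#>   observed null_mean null_sd t_statistic  p_value stars
#>      <dbl>     <dbl>   <dbl>       <dbl>    <dbl> <chr>
#> 1   0.0886    0.0737  0.0140       -10.6 4.61e-18 ***
```

Temperature-indicator distances correlate with herbivore turnover
(Mantel r = 0.16), and the host-plant subset explains more of the
herbivore composition (plant-unique adjusted R² = 0.089) than random
plant subsets of the same size (0.074 ± 0.014) — the monophage–host
dependencies built into this simulation are recovered.

`run_full_analysis()` chains all of these per arthropod group and
writes CSV/JSON tables plus a hashed run manifest; see the vignette
`vignettes/community-attribution.Rmd` for the model details and design
choices.

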