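# vignagap

Ecogeographic analysis and *ex situ* conservation gap assessment for crop
wild relatives, built around the *Vigna* genus (mung bean, cowpea and their
wild relatives).

Wild *Vigna* taxa are a key source of heat, drought and salinity tolerance
and of pest and disease resistance for legume breeding, but many are poorly
represented in genebanks. Deciding which taxa and which countries to
prioritise for collecting missions requires combining noisy occurrence
records, climate layers, greenhouse screening scores, literature reviews
and genebank inventories into one reproducible analysis. `vignagap` is that
analysis as a tested R package, aimed at genetic-resources scientists and
conservation planners:

- **Record cleaning** — five audited rules for georeferenced occurrence
  records: country-mismatch removal with a 10 arc-minute border buffer,
  relocation of near-shore points to the coastline, removal of
  country-centroid coordinates, per-taxon deduplication, and a per-taxon
  climate-outlier filter (values beyond `Q1 − 2.5·IQR` or `Q3 + 2.5·IQR`
  on ≥ 3 of the 19 bioclim variables). The composed pipeline is idempotent
  and every decision is logged with a reason.
- **Niche modelling** — a presence–background maximum-entropy model fit by
  convex optimisation: weights `w` minimise
  `−mean_pres(w·f) + log Σ_bg exp(w·f) + β‖w‖₁` over standardised linear +
  quadratic features, so that at the optimum
  `|E_P[f_j] − mean_pres(f_j)| ≤ β` for every feature (the maximum-entropy
  property). The protocol thins presences on a grid scaled to 10% of the
  longest inter-point distance, keeps 80%, samples 10× background from the
  buffered convex hull, averages three runs, thresholds at maximum
  sensitivity + specificity, and clips to the buffered hull.
- **Harshness classification** — one-way ANOVA on rank-transformed climate
  values with taxon as factor, Tukey HSD (Tukey–Kramer) pairwise
  comparisons, compact letter display, and three-tier groups for four harsh
  climates: permanently hot (BIO1), seasonally hot (BIO8), permanently dry
  (BIO12), seasonally dry (BIO16). Likert screening scores (1–5, best
  accession per taxon) merge into a six-column tolerance matrix.
- **Gap analysis** — per-taxon genebank categories (absent / < 10 / ≥ 10
  accessions), sampled and unconserved taxonomic-richness rasters,
  modelled-but-unreported gap rasters, and zonal priority-country rankings.
- **Synthetic study system** — a seeded generator for all six input classes
  (correlated climate layers, country tiles, niche-structured presences
  with a ledger of injected errors, inventories, screening and resistance
  tables), so the whole pipeline is testable with known ground truth.

## Worked example

```r
library(vignagap)

world <- simulate_world(world_spec(seed = 1))   # ~1000 records, 10 taxa
out <- run_pipeline(world, list(seed = 1, model_taxa = "Taxon_10"))

out$report$steps
#>                 step n_in n_removed n_modified n_out
#> 1   country_mismatch 1050        30          0  1020
#> 2 coastal_relocation 1020         0         10  1020
#> 3   centroid_removal 1020        20          0  1000
#> 4             dedupe 1000        50          0   950
#> 5   climate_outliers  950        19          0   931
```

Of 1050 raw records, 30 contradicted their passport country beyond the
border buffer, 10 near-shore points were repaired onto the coastline, 20
sat on country centroids, 50 were exact duplicates and 19 had outlier
climates — 931 records survive. The tolerance matrix combines the four
climate criteria with the two screening assays:

```r
head(out$tolerance[, 1:8], 5)
#>   taxon_id AMEANT TWETQ           AP        PWETQ  dehydration     salinity profile_count
#> 1 Taxon_01    low   low          low          low          low          low             0
#> 2 Taxon_02    low   low          low          low intermediate intermediate             0
#> 3 Taxon_03    low   low          low intermediate           nd           nd             0
#> 4 Taxon_04    low   low intermediate         high intermediate         high             2
#> 5 Taxon_05    low   low         high         high          low         high             3
```

`Taxon_05` is high for three of the six variables: it occurs in permanently
and seasonally dry climates and tolerated high salinity in the pot
experiments — the profile of a drought-adapted collecting priority.
Conservation status and biotic resistance summarise as:

```r
table(out$status$category)
#>   absent adequate     poor
#>        1        7        2
out$resistance_summary
#>   stressor n_evaluated n_resistant pct
#> 1 bruchids           9           8  89
#> 2      YMD           6           6 100
head(out$priorities, 3)
#>   country_code score rank
#> 1          C01   249    1
#> 2          C02   173    2
#> 3          C03    33    3
```

Three of ten taxa are absent from genebanks or hold fewer than ten
accessions; country `C01` accumulates the most modelled-but-unreported gap
richness and would head the collecting-mission list.

## Layout

- `R/` — implementation (I/O, synthetic worlds, cleaning, climate ops,
  niche model, classification, gap analysis, reporting)
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/vigna-ecogap-methods.Rmd` — the methods vignette
- `inst/scripts/vigna-ecogap.R` — thin CLI (`simulate`, `clean`, `run`)
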