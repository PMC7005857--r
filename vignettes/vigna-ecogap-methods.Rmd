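---
title: "Ecogeographic analysis and conservation gap assessment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecogeographic analysis and conservation gap assessment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`vignagap` implements a desk-scale ecogeographic pipeline for crop wild
relatives of the genus *Vigna*: cleaning of georeferenced presence records,
presence–background niche modelling, classification of taxa into
climate-harshness groups, integration of greenhouse screening scores and a
biotic-resistance literature table, and an *ex situ* conservation gap
analysis. Every stage runs on synthetic inputs with known ground truth, so
the whole pipeline is testable offline; the same functions accept real
occurrence tables, bioclim rasters and genebank inventories in the standard
text formats (CSV, ESRI ASCII grid, GeoJSON).

```{r, eval = FALSE}
library(vignagap)
world <- simulate_world(world_spec(seed = 1))
out <- run_pipeline(world, list(seed = 1, model_taxa = "Taxon_01"),
                    out_dir = "results")
```

# Record cleaning

Occurrence data aggregated from herbaria, genebank passport data and living
collections carry characteristic georeferencing errors. Five rules address
them, applied in a fixed order:

1. **Country mismatch.** A record whose passport country contradicts its
   projected location is removed, unless the point falls within a 10
   arc-minute buffer of the declared country's border. Records with no
   country code cannot be contradicted; they are kept and flagged.
2. **Coastal relocation.** Points in coastal waters within 10 arc-minutes of
   the coastline are moved to the nearest coastline point (their
   `georef_status` becomes `relocated_coast`). Because land masks are
   cell-aligned, a point exactly on the boundary would sit in a sea raster
   cell, so the relocated point is nudged 0.1 arc-minutes (about 185 m)
   towards the country centroid.
3. **Centroid removal.** Coordinates within 1 arc-minute of a country
   centroid are likely georeferenced at country precision and are removed.
   The tolerance is a package default; any value in arc-minutes can be set.
4. **Deduplication.** Within each taxon, records sharing coordinates rounded
   to 4 decimal places (about 11 m) collapse to one survivor — the smallest
   `record_id`, a deterministic choice.
5. **Climate outliers.** Per taxon, type-7 quartiles and
   `Q1 − 2.5·IQR, Q3 + 2.5·IQR` fences are computed for each of the 19
   bioclim variables over that taxon's records; a record violating the fence
   on three or more variables is removed. Taxa with fewer than 4 records
   are exempt (quartiles would be meaningless). Records on nodata cells are
   removed with their own reason.

The step order is a design decision: the country filter's buffer spares
near-shore points so that relocation can repair them, relocation must
precede climate extraction (a sea point has no climate), and deduplication
precedes the outlier filter so duplicated outliers do not distort their own
fences. The composed pipeline is idempotent — re-running it on its own
output removes nothing — and this is asserted in the test suite. Every
removal and modification is logged with a reason in a `cleaning_report`
whose step counts satisfy `n_in(k+1) = n_in(k) − n_removed(k)`.

All distances are great-circle (haversine) on a 6371-km sphere; arc-minute
buffers are angular distances (1 arc-minute ≈ 1853 m). Nearest-point
computations on polylines use a local equirectangular projection, which is
accurate to well under a metre at the arc-minute scales involved.

# Climate extraction and variable pruning

Raster cells are half-open, `[x0, x0 + res)` in both axes, with row 1 the
northernmost row and values referring to cell centres; a point on a shared
edge belongs to the cell whose origin it lies on. Records on nodata cells
are excluded and reported.

Collinearity among the 19 bioclim variables is pruned greedily: variables
are visited in a preferred order (BIO1..BIO19 by default, overridable with
an explicit list) and retained iff their absolute Pearson correlation with
every already-retained variable is at most 0.7. The result is maximal: no
dropped variable could be re-added without violating the bound, which the
tests verify exhaustively.

The four climate-harshness indicators are annual mean temperature (AMEANT =
BIO1, °C), mean temperature of the wettest quarter (TWETQ = BIO8, °C),
annual precipitation (AP = BIO12, mm) and precipitation of the wettest
quarter (PWETQ = BIO16, mm) — the standard bioclim codes for those
quantities.

# Niche model

The species distribution model is a presence–background maximum-entropy
(Maxent-type) model, implemented directly as the convex optimisation it is:
find weights `w` minimising

```
−mean_presence(w·f) + log Σ_background exp(w·f) + β‖w‖₁
```

where `f` are standardised linear and quadratic features of each retained
variable (centring and scaling computed from the background sample and
stored with the model). The optimum is the Gibbs distribution over
background cells that matches the presence feature means up to the box
constraint `|E_P[f_j] − mean_presence(f_j)| ≤ β` — the defining
maximum-entropy property, asserted after every fit. The solver is proximal
gradient descent with soft-thresholding and backtracking line search,
stopping when the KKT violation drops below 1e-8 (cap 5000 iterations;
non-convergence is an error, never a silent result). The default
regularisation `β = 0.05` is a conventional mild penalty for
presence–background models with a few dozen features. Quadratic features
make Gaussian-shaped niches exactly representable; hinge and product
features of the original Maxent tool are deliberately out of scope.

The modelling protocol per taxon:

1. **Spatial thinning.** A grid with cell size 10% of the longest
   inter-point great-circle distance (converted to degrees at the presences'
   mean latitude, grid origin aligned to the raster) retains one record per
   occupied cell, uniformly at random; then 80% of the survivors are
   subsampled. We read the published protocol's "80% of the randomly
   resampled records from grid cells" as exactly this two-stage scheme and
   record it as an interpretation.
2. **Background.** 10× as many background points as presences, drawn
   uniformly (with replacement) over the data cells whose centres fall in
   the convex hull of the presences buffered by 10% of the longest
   inter-point distance. The buffered hull is evaluated as a predicate
   (inside the hull, or within the buffer distance of its boundary) rather
   than as offset geometry.
3. **Averaging.** Three independent thin-and-fit runs; the continuous map is
   the cellwise mean of the run predictions, each normalised to [0, 1] by
   its maximum over the clip region.
4. **Thresholding.** The binary map uses the threshold maximising
   sensitivity + specificity, scanned over all observed scores of the
   averaged raster at the supplied presences versus the background sample,
   ties broken by the smallest threshold. Computing the threshold once on
   the averaged raster (rather than per run) is a determinism-motivated
   choice.
5. **Clipping.** Binary suitability outside the buffered hull is discarded,
   limiting extrapolation beyond the sampled range.

Taxa with fewer than 5 presence records are skipped and reported — the same
floor the ecogeographic classification uses. Model recovery is evaluated as
AUC of the (unclipped) averaged suitability for held-out presences against
all land cells; on planted synthetic niches (200 presences, 100×100 grid)
the suite requires AUC ≥ 0.9. Discrimination measured against the
hull-restricted training background is intrinsically capped much lower —
the hull hugs the niche — which is why the landscape-wide background is the
meaningful recovery yardstick.

# Harshness classification

Climate values at record locations are rank-transformed over the pooled
records (average ties), and a one-way ANOVA with taxon as the factor is
followed by Tukey HSD pairwise comparisons at α = 0.05 (`stats::TukeyHSD`,
which applies the Tukey–Kramer adjustment under unbalanced sizes). Ranking
makes the classification invariant to monotone transformations of the raw
variable and robust to its heavy tails.

A compact letter display is built with the insert-and-absorb algorithm; the
tests verify exhaustively that two taxa share a letter iff their comparison
is non-significant, and validate the letters against Tukey–Kramer p-values
recomputed independently from the studentized-range distribution. Group 1
(harsh) contains the taxa sharing a letter with the taxon of most extreme
mean rank — highest for the hot criteria, lowest for the dry ones; group 2
shares a letter with the most extreme taxon not already in group 1; group 3
is the remainder. The published analysis did not define group membership
under overlapping letters; this sharing rule is the package's
deterministic, testable operationalisation. Taxa with fewer than 5 records
are excluded and listed. Four variable/direction pairs define the harsh
climates: permanently hot (high BIO1), seasonally hot (high BIO8),
permanently dry (low BIO12), seasonally dry (low BIO16).

Screening scores integrate by the best (minimum) accession score per taxon
and assay on the 1–5 Likert scale: 1 → high tolerance, 2 → intermediate,
3–5 → low, unscreened → nd. Climate groups map 1/2/3 → high/intermediate/
low, with excluded taxa nd. The per-taxon count of "high" entries across
the six columns is the resilience profile.

# Gap analysis and reporting

Per-taxon genebank holdings (summed over institutes) classify as absent
(0), poor (1–9) or adequate (≥ 10 accessions); taxa in the taxonomy but not
in the accession table are absent. Sampled taxonomic richness counts
distinct taxa per grid cell, optionally filtered by record source
(herbarium versus genebank/living collection); unconserved richness
restricts to absent/poor taxa. The modelled gap raster counts, per cell,
taxa modelled suitable but with no record of any source in that cell.
Priority countries rank by the zonal sum of gap richness over cells whose
centres fall in the country polygon (mean and max are offered as
alternatives; the aggregation rule behind published priority lists is not
formalised anywhere, so the sum is this package's stated choice), ties
broken alphabetically.

Summary tables count evaluated, qualifying, screened, tolerant, reviewed
and resistant taxa per section and gene pool; a section or gene pool
qualifies for a criterion iff at least one member taxon qualifies, making
aggregation monotone. Percentages are rounded half-up to integers — the
rule consistent with published table arithmetic such as 9/77 → 12% — and
are always recomputable from the emitted counts.

# The synthetic study system

`world_spec()` defines a 20°×20° tropical extent at 12 arc-minutes (a
100×100 grid), six rectangular countries tiling a land block with sea
around it, and ten taxa. It emulates:

- **Climate.** BIO1 decreases with |latitude| (0.75 °C per degree, noise sd
  0.5 °C); BIO12 increases westwards (100 mm per degree, noise sd 60 mm).
  The 17 remaining layers are linear mixtures of the standardised parent
  gradient (temperature layers on BIO1, precipitation layers on BIO12) and
  iid noise, hitting target Pearson correlations chosen to echo real
  bioclim collinearity (e.g. 0.95 for warmest-quarter temperature).
  Parents are standardised over land cells so the targets hold on the cells
  the pipeline sees. Sea cells are nodata in all layers, as in real land
  masks.
- **Niches.** Gaussian suitability in (BIO1, BIO12) with breadths 1.5 °C
  and 150 mm — overlapping but separable; presences are drawn from land
  cells with probability ∝ exp(−Mahalanobis²/2) and jittered within their
  cell. Niche centres spread over 17–28 °C with precipitation centres
  rotated so the hottest and driest specialists are different taxa.
- **Record errors.** Default rates: 2% country mismatch, 2% offshore (half
  within the 10 arc-minute coastal buffer, half beyond — exercising both
  the relocation and the removal branch), 2% centroid, 5% duplicates, 2%
  climate outliers; every injection is ledgered with the original values,
  so cleaning precision and recall are computable exactly. Planted outliers
  are chosen against 4×IQR fences so they still violate the 2.5×IQR filter
  after their own injection shifts the quartiles. These rates are in the
  range reported for curated occurrence aggregates; 100 records per taxon
  gives the n = 1000 scale at which the suite requires ≥ 95% ledger
  recall.
- **Inventories.** About 7% of taxa absent from genebanks and 18% with
  fewer than 10 accessions (echoing the roughly one quarter of taxa found
  poorly conserved in genus-wide genebank reviews); screening scores with
  planted tolerance classes tied to the hottest and driest niches; a
  resistance table with 75% bruchid and 100% YMD resistance among evaluated
  taxa, the rates genus-wide legume reviews report.

One global seed drives everything; stage seeds derive from it via a fixed
linear-congruential map, so every generator is reproducible independently.

What the generator does **not** emulate: spatial autocorrelation beyond
smooth gradients, taxonomic misidentification, collection-effort bias
correlated with infrastructure, irregular country shapes, and
latitude-dependent cell areas. Passing tests therefore demonstrate
correctness of the algorithms under known ground truth, not performance on
real aggregated occurrence data.

# Numerical choices and degenerate inputs

- Quartiles are type 7 (linear interpolation), R's default, stated for
  reproducibility.
- The deduplication survivor and all ranking ties are resolved
  deterministically (smallest id; alphabetical country codes).
- Degenerate hulls (fewer than 3 distinct presence points) reduce to a
  distance buffer around the points; single-cell presence clusters yield a
  constant model (weights 0) whose binary map covers the cluster.
- Constant feature columns get unit scale (their features vanish);
  all-tied rank vectors short-circuit to "every taxon group 1" with a
  warning rather than a spurious ANOVA.
- Background sampling with a single eligible cell, identical presence and
  background distributions, and zero-signal fits (weights exactly 0) are
  all covered by tests.

# Problem sizes

The test suite and the acceptance script run on: the default 100×100 world
(~1000 records, 10 taxa) for cleaning and classification; a 50×50 world (4
taxa, 240 records) for pipeline-level tests; 200-presence niche models on
the 100×100 grid; and 200 replicates of the 3-taxon, n = 30 harshness
recovery experiment. These sizes keep any single check under a few seconds
while leaving the statistics well away from small-sample artefacts.

# Known limitations

- The maximum-entropy model uses linear + quadratic features only; strongly
  multimodal niches would need richer features.
- Compact-letter construction is exponential in the worst case; it is
  intended for the tens of taxa typical of genus-level analyses.
- Country polygons are treated as planar in lon/lat for point-in-polygon
  (distances, however, are spherical); at high latitudes a projected
  workflow would be preferable.
- The pipeline does not model detection bias or absence data; background
  points are pseudo-absences in the usual presence–background sense.
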