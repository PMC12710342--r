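# cyclevag

Longitudinal analysis of the vaginal microbiota over one menstrual cycle.

Healthy reproductive-age women are sampled once per cycle phase —
follicular (F), ovulatory (O), early luteal (EL), late luteal (LL) — with
16S taxa counts, serum sex hormones (17-beta estradiol, LH, FSH,
progesterone, prolactin) and technical covariates per swab. `cyclevag`
implements the full analysis such a design calls for, plus a synthetic
cohort generator with known ground truth so every stage is testable without
access to participant-level data:

* **Synthetic cohorts** — logistic-normal compositions per community state
  type (CST) regime, multinomial counts, cyclic hormone trajectories,
  configurable intraclass correlation (ICC), missingness, and injected
  visit/hormone effects (`cohortConfig()`, `simulateCohort()`).
* **QC and table handling** — read-count sample filters (input < 80,000,
  survived < 60,000, negative control > 500 reads), without-replacement
  rarefaction, rare-taxon filtering (≥5 reads in ≥2 samples), taxa
  relabelling with merge semantics.
* **Compositional transforms** — relative abundance, centered log-ratio
  (CLR) `clr_i = ln(x_i/g(x))`, strict prevalence/abundance taxa filter,
  and a cumulative 10-step covariate-residualisation ladder.
* **Diversity dynamics** — Shannon/Simpson, Bray-Curtis and Euclidean-on-CLR
  distances, PCoA with per-visit Kruskal-Wallis covariate screening and
  axis adjustment, PERMANOVA, Friedman tests, and the two beta-diversity
  comparison procedures: per-phase (paired across phases, Bonferroni over
  the 6 phase pairs) and self-vs-random (each woman's within-self distances
  against pseudo-women assembled from other women's phases).
* **Association models** — per-taxon random-intercept visit models
  `taxa_adj ~ visit_number + (1|woman)`, permutation empirical p-values
  (exact proportion of permuted p ≤ observed), BH-FDR, ICC
  `σ²_b/(σ²_b+σ²_e)`, 4-SD hormone outlier removal, consecutive-phase
  differences with rank-inverse-normal (`ordernorm`) transformation,
  per-transition difference models, and overall hormone models
  `hormone ~ visit_number + taxa_adj + (1|woman) + pregnancy_category`.
* **CST classification** — nearest-centroid assignment by Yue-Clayton
  similarity θ = Σxy/(Σx²+Σy²−Σxy) against a user-supplied centroid table,
  a 60%-dominance fallback rule, and longitudinal transition statistics.

See the vignette (`vignettes/cycle-dynamics.Rmd`) for the model details and
the design choices.

## Worked example

```r
library(cyclevag)

cfg    <- cohortConfig(nWomen = 61, seed = 1)
cohort <- simulateCohort(cfg)
cohort
#> CycleCohort: 219 samples, 25 taxa, 61 women
#>   samples per visit (F/O/EL/LL): 61/51/55/52
#>   simulated cohort with ground truth attached
```

244 possible (woman, visit) rows minus random missingness leaves 219
samples; visit 1 is never dropped. Classify samples against the generator's
regime centroids and check individuality:

```r
rel <- relativeAbundance(rareTaxaFilter(taxaCounts(cohort)))
table(assignCST(rel, generateCentroids(cfg))$cst)
#>  CST-I  CST-II CST-III  CST-IV   CST-V
#>     64      32      76      41       6

design <- sampleData(cohort)
adj <- residualizeTaxa(clrTransform(rel), design, modelId = 2L)
svr <- selfVsRandom(euclideanCLR(adj), design, seed = 1)
head(svr$tests, 3)
#>   replicate            p p_bonferroni  m
#> 1         1 1.665756e-21 1.665756e-20 10
#> 2         2 1.665756e-21 1.665756e-20 10
#> 3         3 1.665756e-21 1.665756e-20 10
```

CST-III (*L. iners*-dominated) is the most common state, and each woman's
microbiota is far more similar to itself across phases than to random
pseudo-women (all 10 replicate comparisons significant after Bonferroni) —
the individual-signature result. Taxon trajectories across visits, on
technical-covariate-adjusted CLR abundances:

```r
fitVisitModels(adj[, c("Lactobacillus_iners", "Lactobacillus_crispatus")],
               design)[, c("taxon", "beta", "se", "p", "q")]
#>                     taxon       beta         se          p          q
#> 1     Lactobacillus_iners -0.1223833 0.06678570 0.06688021 0.07362935
#> 2 Lactobacillus_crispatus  0.1061172 0.05931949 0.07362935 0.07362935
```

`beta` is the change in adjusted CLR abundance per visit; with no injected
effects neither species shows a significant trend, as expected. Injected
effects (via `visitEffects` / `hormoneEffects` in the config) are recovered
by the same machinery — the test suite quantifies this.

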