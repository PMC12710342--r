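---
title: "Modelling vaginal-microbiota dynamics over the menstrual cycle"
author: "cyclevag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling vaginal-microbiota dynamics over the menstrual cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclevag)
```

## The scientific setting

The vaginal microbiota of reproductive-age women is a low-diversity
ecosystem usually dominated by a single *Lactobacillus* species, and is
conventionally summarised by community state types (CSTs): CST-I
(*L. crispatus*-dominated), CST-II (*L. gasseri*), CST-III (*L. iners*),
CST-IV (a diverse anaerobe community), and CST-V (*L. jensenii*). A
short-term longitudinal design samples each woman once per menstrual-cycle
phase — follicular (F), ovulatory (O), early luteal (EL), late luteal (LL),
coded as visits 1–4 — together with serum levels of five sex hormones
(17-beta estradiol BES17, LH, FSH, progesterone PROG, prolactin PRL) and
technical covariates of the sequencing workflow.

The questions this package operationalises are: (i) does community
composition change across cycle phases, (ii) is a woman's microbiota more
similar to itself over time than to other women's (individual signature),
and (iii) are within-cycle changes in taxon abundance coupled to hormone
fluctuations? Because participant-level data from such cohorts cannot be
redistributed, the package ships a synthetic cohort generator with known
ground truth, so every stage of the analysis is testable end to end.

## The synthetic cohort generator

The generator is a logistic-normal/multinomial hierarchy. For woman $w$ at
visit $t$, the latent (CLR-scale) abundance of taxon $j$ is

$$ \ell_{wtj} = b_{r(w)j} + u_{wj} + \beta_j t + \sum_h \gamma_{hj}
   z_{wth} + \varepsilon_{wtj}, $$

where $r(w)$ is the woman's CST regime drawn from the configured regime
frequencies, $u_{wj} \sim N(0, \sigma_b^2)$ is a per-(woman, taxon) random
intercept, $\beta_j$ is an (optional) injected linear visit effect,
$\gamma_{hj}$ couples the taxon to the standardised deviation $z_{wth}$ of
hormone $h$ from its visit-specific population mean, and
$\varepsilon_{wtj} \sim N(0, \sigma_e^2)$. Compositions are
$\mathrm{softmax}(\ell_{wt\cdot})$ — the natural conjugate structure for a
CLR-based analysis — and counts are multinomial at a negative-binomial
library size. Hormone values are visit-profile means plus a woman-level
intercept and within-woman noise.

Key parameter choices (all exposed in `cohortConfig()`):

* **ICC target.** $\sigma_b^2$ is set from `iccTarget` via
  $\mathrm{ICC} = \sigma_b^2 / (\sigma_b^2 + \sigma_e^2)$; default 0.75,
  reflecting the strong within-woman stability such cohorts show. With
  `iccTarget = 0` the intercepts vanish.
* **Regime frequencies.** Defaults follow the sample-level CST frequencies
  reported for healthy Italian women (CST-III 38.2%, CST-I 31.6%, CST-IV
  14.1%, CST-II 12.7%, CST-V 3.3%); the printed values sum to 0.999, so the
  default renormalises them to sum exactly to 1.
* **Missingness.** `missingRate` is the overall expected fraction of
  missing (woman, visit) rows. The self-vs-random procedure anchors on each
  woman's first collection, so visit 1 is never dropped; visits 2–4 are
  dropped with probability `missingRate * 4/3`. The default 0.13 yields
  roughly 212 of 244 rows for a 61-woman cohort, matching the QC yield such
  a study reports.
* **Hormone profiles.** Arbitrary but fixed units per hormone; the defaults
  encode the cycle (BES17 and LH peak at the ovulatory visit, PROG in the
  luteal visits, PRL flat). Within-woman SDs are kept small relative to the
  means so that truncation at zero is negligible. Neither within-woman
  variances nor effect sizes are reported by longitudinal vaginal-microbiome
  studies in a reusable form, so these are free parameters, surfaced in the
  configuration rather than hard-coded.
* **Effect sizes for the recovery studies** were fixed at design time: a
  visit slope of 0.5 latent-CLR units per visit, a hormone coupling of
  −2 CLR units per within-visit hormone SD (a detectable-by-design effect of
  the kind the FDR-0.2 analyses report), and +1.5 for the
  progesterone–*L. crispatus* difference-model check.

All randomness flows from one master seed through hashed substreams, so
regenerating one component (e.g. hormones) never perturbs another, and
adding a taxon never changes another taxon's permutations.

### What the generator does and does not emulate

It reproduces the *structure* of such a cohort: per-woman compositional
regimes at realistic frequencies, high within-woman stability, cyclic
hormone trajectories, random missingness, multinomial count noise at
realistic sequencing depth, and configurable injected effects. It does not
emulate taxonomic misassignment, batch effects correlated with composition,
menses-associated perturbations (the study design excludes menses days),
zero-inflation beyond what the multinomial induces, or strain-level
variation. Passing tests therefore demonstrate that the *statistical
machinery* is correct and calibrated under the stated generative model —
not that the model captures every feature of real vaginal-microbiome data.

## Compositional pipeline

Counts → relative abundance → CLR, with the pseudocount defaulting to half
the smallest nonzero relative abundance of the table (recorded in the
output); the zero-handling of published pipelines is rarely stated, so this
is a logged, configurable parameter. Taxa enter the association models only
if prevalence strictly exceeds 20% *and* mean relative abundance strictly
exceeds 0.10% — both thresholds strict, matching the wording "prevalence
>20%". CLR values are residualised on a cumulative ten-step covariate
ladder (1: none; 2: + technical covariates Qubit_DNA, Qubit_Library,
Total_counts; 3–10: + Age, sex_less_than_two_days, Pregnancy_category,
Pill_use, Swab_after_feces, Bristol_stool_scale, Swab_morning_or_not,
WHR_ranges). Categorical covariates are treatment-coded with the most
frequent level as reference (the source analyses do not state their coding;
this choice is symmetric-by-frequency and logged).

## Diversity and the two beta-diversity procedures

Alpha diversity uses Shannon $H$ and Simpson reported as the complement
$D = 1 - \sum p_i^2$ (the common "Simpson diversity"; the raw concentration
is also emitted since the convention is ambiguous). Beta diversity is
Bray-Curtis on relative abundances and Euclidean distance on
covariate-adjusted CLR values.

**Per-phase procedure.** Each sample is summarised by the mean (or median)
of its distances to all other samples in the same phase; phases are
compared pairwise with Wilcoxon and t tests paired by woman, Bonferroni
over the six phase pairs. The aggregation unit (per sample, then paired by
woman) is one of several defensible readings of the procedure and is
recorded in the output.

**Self-vs-random procedure.** The Self distribution is each woman's mean
pairwise distance among her own collections. Each Random replicate builds,
per woman, a pseudo-woman from her visit-1 sample plus one sample per
remaining phase drawn from distinct other women, summarised the same way;
Self is compared to each replicate with an unpaired Wilcoxon test,
Bonferroni over replicates. Donor sampling is without replacement within a
pseudo-woman (the with/without-replacement convention is not stated in the
source design; without-replacement avoids degenerate pseudo-women).

A property worth knowing: the Self and Random groups *share samples* — the
focal woman's visit-1 swab sits in both her Self summary and her Random
summary, and each donor sample also contributes to its owner's Self
summary. On fully exchangeable synthetic data (single regime, `iccTarget =
0`) the calibration test in `test-acceptance.R` shows the procedure rejects
far *below* the nominal 5% level (about 0.5–1%). The test is therefore
conservative — it understates, never overstates, individual signatures — so
the strong separations it reports on high-ICC cohorts are trustworthy.
Note also that exchangeability requires a single regime: with mixed CST
regimes each woman's regime baseline already constitutes an individual
signature, and the procedure (correctly) rejects essentially always even at
`iccTarget = 0`.

PERMANOVA (via `vegan::adonis2`) permutes raw sample labels without strata;
it is applied to per-visit subsets, where within-woman dependence is absent
by construction. PCoA axes are screened per visit with Kruskal-Wallis tests
(continuous covariates binned by tertiles, configurable) and each axis is
adjusted only for covariates it associates with.

## Association models

**Visit models.** Per taxon, `taxa_adj ~ visit_number + (1|woman)` by REML,
visit numeric 1–4, fitted for any covariate-ladder step. P-values use the
normal approximation on $t = \hat\beta/\mathrm{SE}$ by default: the source
analyses relied on a Satterthwaite-style package without stating the
approximation numerically, and the permutation empirical p-value is the
calibrated quantity reported alongside (a Satterthwaite option is available
via lmerTest).

**Empirical p-values.** The taxon-abundance column is permuted across all
rows — deliberately breaking the repeated-measures structure, as the
procedure is defined — the model is refit, and the empirical p is the exact
proportion of permutation p-values at or below the observed one (0 is
attainable; the minimum positive value is 1/nPerm). For the visit models
the permuted column is the response, so `lme4::refit` reuses the model
structure; for the overall hormone models it is a predictor and each
permutation is a full refit. BH-FDR is applied to the asymptotic (not
empirical) p-values over the declared family, with the 0.2 threshold used
by the hormone analyses.

**ICC.** From the random-intercept model's variance components,
$\mathrm{ICC} = \sigma_b^2/(\sigma_b^2+\sigma_e^2)$. Fits where either
component collapses to the boundary are flagged singular and reported at
0 or 1.

**Difference models.** Hormone outliers beyond 4 SD from the pooled mean
(single pass, all visits pooled) are removed first; consecutive-phase
differences (gap pairs skipped) of both hormones and adjusted taxa are
rank-inverse-normal transformed ($\Phi^{-1}(r/(n+1))$, mid-ranks for ties)
and related per transition. Each woman contributes at most one observation
per transition, which makes a per-woman random intercept unidentifiable, so
the fit is OLS within transition, with woman-clustered robust SEs as an
option. This is the main place where the described model family ("mixed
models") and the data structure are in tension; both readings are
implemented and neither is claimed as the original computation.

**Overall hormone models.**
`hormone ~ visit_number + taxa_adj + (1|woman) + Pregnancy_category`, focal
coefficient on the adjusted taxon, with taxa-column permutation for the
empirical p (the permutation description is written for the visit models
and stated to carry over; permuting the taxa column is the adopted
reading).

## CST classification

The nearest-centroid core: compositions are harmonised onto the centroid
vocabulary (rename map, merge, renormalise; samples losing >50% of mass are
flagged unclassifiable), then assigned by maximal Yue-Clayton similarity
$\theta = \sum x_iy_i / (\sum x_i^2 + \sum y_i^2 - \sum x_iy_i)$. Published
reference centroids are an *input* (TSV; labels are free strings, so
subCSTs need no code change); the repository ships only synthetic regime
centroids from the generator. Ties — probability zero on real data — break
lexicographically with an explicit flag, for determinism. A dominance-rule
fallback labels I/II/III/V when the marker species strictly exceeds 60%,
else IV. Transition bookkeeping counts label changes between consecutive
available visits and classifies women as CH / CH+NA / NO CH / NO CH+NA.

## Numerical conventions and degenerate inputs

* Strict thresholds throughout (dominance > 0.60; prevalence > 20%; mean
  abundance > 0.10%; QC < 80,000 / < 60,000 / > 500) with boundary cases
  pinned by tests.
* Distance procedures use the add-one permutation rule
  $(1 + \#\{F_\pi \ge F\})/(1 + n_\pi)$; the association models use the
  exact-proportion rule, which their defining description states verbatim.
  The difference is intentional and documented per module.
* All-tied inputs (constant alpha diversity, identical samples, all-zero
  paired differences) return p = 1 rather than NaN: tied data carry no
  evidence of change.
* Degenerate fits (zero residual variance, zero-variance predictors,
  < 10 difference pairs) are flagged, not silently dropped.

## Problem sizes used by the checks

The calibration and recovery studies in the test suite use cohorts of
20–61 women (500–2,000 for distributional convergence checks), 100–200
simulation replicates, and 199–200 permutations — sizes chosen so the whole
suite documents the pipeline's statistical behaviour while remaining quick
to run. The reproducibility script (`scripts/acceptance.R`) regenerates
study-sized cohorts (61 women) and reports only quantities it computes at
run time.

## Known limitations

Count-space rarefaction stands in for read-level subsampling; the
generator's covariates are independent of composition (no confounding to
untangle); the per-phase aggregation unit and the Eq.-style difference
model's random effect are interpretive choices among defensible readings;
and the nearest-centroid classifier is validated against synthetic
centroids, so real-data CST assignments should be checked against the
published reference centroid set.
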