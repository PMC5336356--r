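---
title: "Syndromic mapping of multivariate TBI phenotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Syndromic mapping of multivariate TBI phenotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syndromap)
```

Traumatic brain injury (TBI) is clinically heterogeneous: imaging findings,
psychiatric sequelae and cognitive outcomes each capture a different facet of
the injury, and no single "gold standard" endpoint stratifies patients well.
`syndromap` implements a topological stratification pipeline for cohorts
described by standardized common data elements (CDEs): patients are compared
across all variables simultaneously, projected into a low-dimensional *lens*,
grouped into an overlapping-cover Mapper (reeb) graph whose connected regions
are candidate phenotypes, and candidate markers found this way are then
confirmed with an ordinary repeated-measures factorial GLM. This vignette
records the model, the tunable parameters, the numerical choices, and the
limits of what the bundled synthetic validation demonstrates.

## The distance: norm correlation over standardized CDEs

The default analysis set is 17 CDEs: ten binary CT findings (coded 0/1 with
1 = pathology present), the Marshall and Rotterdam CT grades (ordinal 1–6),
PTSD diagnosis (binary) with the PTSD Checklist civilian score (PCL, 17–85),
WAIS processing-speed index, and two CVLT verbal-learning z-scores. Because
these live on incompatible scales, each column is mean-centered and variance
normalized first (`standardize_columns()`); we use the population-SD
convention (divide by *N*) throughout, which cancels in every correlation and
is stated here only so the standardization oracle in the tests is
well-defined. Patient *i* and patient *j* are then compared by the
norm-correlation distance

$$d(i, j) \;=\; 1 - r(x'_i, x'_j),$$

the Pearson correlation $r$ being taken across the 17 standardized
coordinates of the two patient profiles. The distance is 0 for identical
profiles and 2 for sign-opposite profiles; it is *not* a metric (no triangle
inequality), which Mapper does not require.

Missing cells are imputed per column (median by default, configurable to
mean or to pairwise-complete correlation) *before* standardization, and
imputed cells are flagged. The source cohorts this pipeline targets observe
missingness almost exclusively in 6-month outcome variables; since the
handling used by the original analysis platform for such cells is not
public, exact reproduction of any particular published graph is explicitly
out of scope (see *Limitations*). A patient whose profile is constant across
all standardized coordinates has undefined correlation; such patients are
isolated at the maximal distance 2 with a warning rather than aborting the
run.

## The lens: two MDS coordinates by stress majorization

The lens maps patients to $\mathbb{R}^2$ from the distance matrix alone, by
minimizing the raw stress

$$f(Z) \;=\; \sum_{i<j}\bigl(d_{ij} - \lVert z_i - z_j \rVert_2\bigr)^2 .$$

`optimize_lens()` starts from the classical (Torgerson) MDS solution —
the double-centered eigendecomposition, via `stats::cmdscale()` — and
applies SMACOF majorization (Guttman transform) steps, which provably never
increase the stress. Defaults: `max_iter = 300`, `tol = 1e-6` on the
relative stress change. Hitting `max_iter` produces a warning, not an
error: on correlation-type distance matrices the objective is typically not
exactly realizable in 2-D and late iterations only polish the layout. Three
conventions remove the remaining indeterminacy so identical inputs give
byte-identical results:

* axes are ordered by sample variance (lens coordinate 1 = highest);
* each axis is sign-flipped so the patient with the largest absolute
  coordinate (lowest index on ties) is positive;
* each coordinate is Gower range-normalized to $[0, 1]$. A constant
  coordinate is pinned at 0.5 with a warning.

We read "Gower normalization" as range-scaling of the lens coordinates; the
alternative reading (range-scaling the input variables before MDS) is
redundant here because the inputs are already standardized and the
correlation is scale-free.

## The cover and graph

The cover of the unit lens square is controlled by `cover_config()`:
`resolution` (intervals per axis, default 30), `gain` (overlap multiplier,
default 3) and `equalize` (default `TRUE`). With equalization, each axis is
split at empirical quantile breakpoints so every base interval holds about
$n/\text{resolution}$ patients. Internally the equalized cover works in rank
(ECDF) space: base intervals have equal width there, and dilating each
interval about its center to `gain` times its width gives the exact
guarantees that neighboring intervals overlap by $1 - 1/\text{gain}$ of
their width and that *no point lies in more than `gain` intervals per axis*.
(Dilating variable-width value-space intervals directly does not bound the
multiplicity — a wide tail interval can swallow several narrow central
ones — which is why the rank-space construction was chosen.) Intervals are
half-open $[\text{lo}, \text{hi})$; quantile ties are broken by stable
patient order. Two-dimensional bins are Cartesian products, so a patient
lies in at most $\text{gain}^2$ bins.

Within each bin, patients are clustered by single linkage under the global
norm-correlation distance, cut at the left edge of the first empty bar in a
10-bar histogram of merge distances — the standard Mapper first-gap
heuristic; with no empty bar the bin stays one cluster. Every cluster
becomes a node; nodes sharing at least one patient are joined by an edge.
Per-node statistics (mean of each cohort variable over non-missing member
values) drive both coloring and node-level subgroup predicates. The whole
stage is deterministic: there is no randomness anywhere after the cohort is
fixed.

## Subgroup selection and enrichment

`select_subgroup()` picks nodes by a predicate over node statistics (e.g.
`gose_6m < 5 & ct_pathology == 0`, the default "poor 6-month recovery
without CT pathology" selection) or by explicit node ids. Because of cover
overlap a patient can sit in both selected and unselected nodes; such
patients are assigned to the subgroup and removed from the complement so
that the two-sample tests compare disjoint sets. Continuous variables are
tested with the two-sample Kolmogorov–Smirnov statistic (asymptotic p);
3-level genotype columns with the $R \times 2$ chi-square test of
independence without continuity correction, falling back to Fisher's exact
test when only two categories are observed. p-values are
Benjamini–Hochberg-adjusted within each family (categorical and continuous
separately); variables with too little data are flagged untestable and
excluded from the family rather than diluting it.

## The confirmatory GLM

The confirmatory stage mirrors the classical SPSS-style analysis: a
repeated-measures factorial GLM of GOS-E (Glasgow Outcome Scale-Extended,
1–8, treated as interval-scaled) on time (3 vs 6 months, within-subject),
CT pathology (2 levels) and genotype (3 levels), with Type III sums of
squares and $\alpha = 0.05$. With exactly two timepoints the
within-subject time-by-factor effects are algebraically identical to
between-subjects effects on the change score $\text{GOSE}_{6m} -
\text{GOSE}_{3m}$, so `repeated_measures_suite()` reports the full
factorial on three responses — the 3-month score, the 6-month score and the
change score — plus genotype-only models within each CT stratum. The
identity is asserted in the tests against an independent multivariate
repeated-measures implementation. Type III SS are computed by model
comparison under sum-to-zero contrasts (each term dropped last from the
full factorial), which is valid under imbalance; posthoc genotype contrasts
use Tukey–Kramer (studentized range with the harmonic adjustment for
unequal group sizes) on the stratum's mean-square error. Patients are
included listwise (non-missing GOS-E at both timepoints, CT status and
genotype); exclusions are logged. No multiplicity correction is applied
across the three response columns, matching the confirmatory convention
this stage mirrors; treat the three columns as one family if that matters
for your application.

## The synthetic cohort generator

`generate_cohort()` exists so the whole pipeline can be validated without
any restricted clinical data. It emulates the marginal structure of a
586-patient multicenter TBI cohort:

* **One latent severity factor** $s \sim N(0,1)$ per patient drives
  everything CT-related: the CT-positive class is $s$ above the
  $1-0.44$ quantile; each binary finding occurs only in the CT-positive
  class with probability $\operatorname{logit}^{-1}(a_v + s)$, the
  intercept $a_v$ calibrated by numerical integration so the *marginal*
  rate matches its target (e.g. subdural hematoma 0.26); Marshall and
  Rotterdam grades are quantile-mapped from noisy severity scores within
  the CT-positive class, with class distributions implying overall moments
  near 1.76 ± 1.10 and 2.45 ± 0.83.
* **PTSD and PCL.** PTSD risk is logistic in severity (slope 1.5),
  calibrated so the rate among patients observed at 6 months hits its
  target (0.24). The severity link makes PTSD-positive CT-negative patients
  rare outside the planted subgroup, which matches the cohorts this
  emulates, where that combination was uncommon. PCL is a PTSD-linked
  mixture of gamma components anchored at the checklist floor of 17
  (asymptomatic patients pile up near the minimum), with component moments
  solved so the cohort-level mean/SD land on 32.98/14.80 *including* the
  planted high-PCL slice.
* **Cognition.** WAIS and the two CVLT scores load negatively on severity
  (loading 0.35); the CVLT pair shares a memory factor (loading 0.6).
* **GOS-E.** Ordinal scores are rounded, clipped latent normals:
  $6.5 - 0.8 s$ at 3 months, plus a latent improvement of $+0.5$ by
  6 months for everyone except planted members.
* **The planted subgroup** is the ground truth for recovery tests: a
  fraction (default 0.20) of CT-negative patients who are PTSD-positive
  with high PCL (60 ± 6), *lose* 3.5 latent GOS-E points between 3 and
  6 months (landing near the "substantial dysfunction" range of 3–4), and
  draw one SNP (default PARP1) with heterozygote odds multiplied by 4.
  The decrement and odds ratio are the default effect sizes the acceptance
  simulations run at; the fraction was sized by a prospective power
  analysis so that the prescribed detection regime (top-ranked enrichment,
  BH q < 0.05 over six SNP tests) is statistically attainable — below
  roughly 55 members the 3-level chi-square cannot reach 90% power at this
  odds ratio regardless of how well the subgroup is recovered. Background
  marginals (PTSD rate, PCL moments) are compensated for the planted shift
  so cohort-level targets stay honest.
* **Genotypes** are independent across the six SNP columns (no linkage
  disequilibrium); defaults are the reference frequencies for PARP1
  (0.225/0.389/0.386) and Hardy–Weinberg frequencies at literature-typical
  allele frequencies for the ANKK1/COMT/DRD2 columns.
* **Missingness** is confined to the 6-month instruments: a patient-level
  loss-to-follow-up core (rate 248/586) hits PTSD/PCL/WAIS/CVLT together,
  with instrument-specific attrition on top to match the per-variable
  counts. Planted members keep complete 6-month data — the subgroup
  emulates patients who *were* observed at follow-up, which is the only way
  such a phenotype can be identified in real data. GOS-E and genotypes are
  complete by default; set `missing_rates` entries to emulate genotyping
  coverage.

What the generator does *not* emulate: linkage disequilibrium between SNPs,
informative (outcome-dependent) missingness, site effects, measurement
error models for the CT grades, and any dependence of PTSD on genotype.
Passing the synthetic validation therefore demonstrates that the pipeline's
machinery is correct and well-powered under a single-factor severity
structure — not that it will find every phenotype in real data.

## Problem sizes and numerical choices

The bundled validation runs at the emulated study scale, $n = 586$ with 17
variables: 100 replicate cohorts for subgroup recovery/enrichment (and 100
null cohorts for the false-positive rate), plus 100 + 100 simulations for
the confirmatory GLM's power and size; the acceptance script reports the
same quantities over 50 mapped cohorts and 100 + 100 GLM simulations.
Fixed numerical conventions worth knowing: population-SD standardization;
correlations clamped to $[-1, 1]$ before the distance; half-open cover
intervals with stable-rank tie-breaks; the 10-bar first-gap clustering
histogram spans the observed merge-distance range; Type III sums of squares
below $10^{-12} \times \max(\sum y^2, 1)$ are treated as exact zeros so
degenerate responses report $F = 0$; and the SMACOF loop stops early if
floating-point noise would ever make the stress rise.

## Limitations

* The published 434-node graph of the motivating study is not reproducible
  from public information: the platform's cover resampling ("millions" of
  cover perturbations), its clusterer, and its missing-data handling are
  proprietary. This package builds a single deterministic cover; the Mapper
  stage is validated by structural properties (partition/overlap bounds,
  coverage, edge semantics, determinism, severity separation), not by node
  counts.
* The enrichment stage tests the cohort's typed SNP columns only; it is not
  genome-wide machinery.
* GOS-E is modeled as interval-scaled in the GLM to mirror the classical
  analysis; an ordinal (proportional-odds) treatment is a deliberate
  non-goal here.
* An ensemble over perturbed covers (the natural reading of the platform's
  resampling) is left as a flagged extension point.
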