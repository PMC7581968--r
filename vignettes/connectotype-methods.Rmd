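---
title: "Connection-type analysis of structural connectomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connection-type analysis of structural connectomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectotype)
```

# Overview

`connectotype` implements an inference chain that links *where* in the white
matter at-risk Parkinson's patients lose structural connectivity to *which*
genes are preferentially expressed in the affected cortical territory, and to
the cell types those genes mark. The chain has five stages:

1. **Connectome model.** Subject-level weighted, undirected connectivity
   matrices over a fixed parcellation (default: 360 cortical regions, 180 per
   hemisphere, plus 19 subcortical regions). No threshold is ever applied to
   the weights: thresholding SIFT2-style streamline weights injects an
   arbitrary parameter, so all analyses work on the full weighted graph.
2. **Module partition and connection classes.** Cortical regions of a
   group-averaged connectome are partitioned into modules by consensus Louvain
   clustering; every connection is then classified as *interhemispheric*
   (left module to right module), *intrahemispheric* (two modules, one
   hemisphere), *intramodular* (within a module), or *subcortical-cortical*
   (a hemisphere's block of six deep grey structures — thalamus, caudate,
   putamen, pallidum, accumbens, ventral diencephalon — to an ipsilateral
   module). With 4 modules per hemisphere this yields
   `4*4 + 2*choose(4,2) + 8 + 8 = 44` classes.
3. **Loss scoring and group contrasts.** Per-class summed strengths are
   z-scored against controls and transformed as `loss = tanh(-z)`, a bounded
   score that is positive when strength is below the control mean. Patient
   groups are contrasted per class with a linear model (`strength ~ group +
   age + sex`), with Benjamini-Hochberg FDR over all classes.
4. **Imaging transcriptomics.** A per-region loss map (regional connection
   strength to a class's partner territory, z-scored, tanh-transformed,
   averaged over the target group) is regressed on a regions-by-genes
   expression matrix by partial least squares. Significance of the explained
   variance uses spatial spin permutations; gene-weight stability uses a
   regional bootstrap; FDR-surviving genes are ranked by weight, split into
   down- and upweighted lists.
5. **Enrichment.** Ranked gene lists are tested for expression-weighted
   cell-type enrichment (EWCE) with a covariate-matched bootstrap, and for
   hypergeometric overlap with disease-risk gene lists or annotation sets.

A synthetic-data generator emulates the full cohort-study design so that
every stage runs, and is validated, without any external download.

# The data model

A `parcellation` fixes the node universe: contiguous 0-based region ids,
hemisphere, cortical/subcortical class, and — for cortical regions — a
unit-norm centroid on the per-hemisphere sphere used by the spin test. A
`connectome` holds one subject's symmetric nonnegative matrix plus `group`,
`age` and `sex`. Loading symmetrises numerically-asymmetric input only below
an asymmetry of 1e-6 (averaging with the transpose) and refuses anything
larger, on the view that real asymmetry signals an upstream bug rather than
noise.

# Module partitioning

`louvain_consensus()` runs Louvain `n_runs` times (default 1000) at
resolution `gamma` (default 1.0), forms the co-assignment matrix across runs,
thresholds it at its off-diagonal mean, and re-clusters the thresholded
agreement graph until all runs agree (at most 20 iterations). The procedure
is deterministic given its seed. A disconnected cortical graph triggers a
warning and its components are partitioned separately.

Classification requires hemisphere-pure modules. On connectomes with strong
homotopic connectivity Louvain may merge mirrored territories across the
midline; `split_by_hemisphere()` cuts such modules at the midline, which is
the practical remedy used with real connectomes. The group average used for
partitioning is the arithmetic mean of the *control* matrices, consistent
with the control-referenced normalisation used everywhere else.

`random_partition_null()` rebuilds the negative control: a random graph with
the same node and edge count (weights shuffled from the observed ones) is
partitioned by Louvain, and those module allocations are applied to every
subject. Random modules ignore anatomy, so they mix hemispheres; the null
partition therefore carries an arbitrary balanced pseudo-hemisphere
assignment of modules (alternating by module size) so the four-kind
classification can be replicated under the null. This is deliberate: the
null asks what happens to class-level group differences when the class
boundaries stop aligning with anatomy.

# Loss scores and contrasts

The `tanh(-z)` transform maps the control-referenced z-score to a bounded
(-1, 1) loss score with higher values meaning greater loss. The sign
convention (negating z before the tanh) is what makes "loss" positive for
weakened connections. Classes with zero control variance are excluded with a
warning; at least three controls are required. Shapiro-Wilk normality of
per-class strengths is exposed as a diagnostic (`normality_screen()`), not a
gate.

Group contrasts default to a per-class fixed-effects model
(`strength ~ group + age + sex`). A mixed variant — per connection kind, a
per-class group effect with a subject random intercept shared across the
kind's classes — is available via `method = "mixed"` (requires lmerTest).
Both recover one t statistic per class; the fixed model is the default
because it is exactly reproducible without convergence concerns. Tests are
two-sided; FDR control is Benjamini-Hochberg at q < 0.05.

# Partial least squares and its nulls

`pls_fit()` implements univariate-response PLS (NIPALS). Gene weights are
unit-norm per component; region scores are mutually orthogonal, so the
response variance explained decomposes into per-component increments
`r2[k]`. The component used downstream is the one with the largest `r2` —
chosen by the data, never hard-coded; with real atlas data it is often a
later component, not the first. Each component is oriented so its region
scores correlate positively with the loss map, which pins down the reading of "upweighted"
(higher expression where loss is greater) and "downweighted". Expression is
z-scored per gene across regions before fitting. A response exactly
orthogonal to every gene yields a null fit with zero variance explained
rather than an error.

**Spin permutations.** `make_spins()` draws uniformly random rotations (QR of
a Gaussian matrix with sign fixing, determinant +1) of the cortical
centroids and matches original to rotated parcels by greedy one-to-one
nearest-neighbour assignment. Making the null map a *permutation* of the
observed one (rather than allowing duplicate assignments) keeps the gene-wise
null weights exchangeable with the observed ones. The mapped null maps
preserve spatial autocorrelation to within about 10% (Moran's I) at the
default 180-region resolution; preservation degrades at much coarser
resolutions because assignment error grows with parcel spacing.

**Null statistic.** The observed statistic is the chosen component's `r2`,
which is by construction the *maximum* over fitted components; each spin's
statistic is therefore also the maximum component `r2` of the refit on the
spun map. Matching the selection rule in the null is what keeps the
permutation p value calibrated (`p = (1 + #{null >= obs}) / (1 + n_perm)`).

**Bootstrap.** Regions are resampled with replacement and the model refit;
the component at the originally chosen index is aligned to the original by
the sign of the correlation between score vectors, removing the reflection
ambiguity of PLS components. `z = weight / SE` summarises weight stability.
Degenerate resamples (component collapse) are redrawn, at most 10 times.

**Gene ranking.** Each gene is tested against its own spin-null weight
distribution (two-sided via absolute value), BH-corrected across genes;
survivors are split by weight sign and ranked by absolute weight. The
`top_genes()` cut takes `floor(frac * n_survivors)` genes (default 20%, with
10/30/50% as robustness settings) — with 790 surviving genes the 20% cut is
158 genes.

# Enrichment

**EWCE.** Specificity of gene g for cell type c is g's mean expression in c
divided by the sum of those means across types (computing per-type means
first makes the statistic invariant to any single cell's library size). The
observed statistic is the mean specificity of the target list per type;
bootstrap lists are drawn within joint transcript-length-by-GC strata
(quintile-by-quintile bins) matching the target's per-stratum counts, so the
null respects both covariates. A stratum with fewer than twice the needed
candidates merges into its length-bin margin (finally the whole background)
with a warning. Defaults are 100,000 bootstrap lists; the test suite uses
10,000, where the `sd_from_mean` statistic is stable to within a few percent.

**Overlap tests.** Gene-list overlap uses the upper-tail hypergeometric
probability (including the observed count, so disjoint lists give p = 1).
Annotation enrichment applies the same test per set with BH correction
across sets — a plain hypergeometric+BH procedure, deliberately *not* a
reimplementation of the g:SCS correction used by the g:Profiler service;
outputs are labelled accordingly. Uncorrected p values are reported
alongside q because marginal overlaps (e.g. with disease-risk lists) are
often discussed uncorrected. The default background universe is the filtered
expression matrix's gene set.

# The synthetic-data generator

The generator's defaults define the emulated study conditions: 180 cortical
regions per hemisphere plus 19 subcortical regions; 4 modules per
hemisphere; 34 controls, 67 high visual performers, 33 low visual
performers; ages and sex ratios drawn from the reported group demographics;
and connection-strength attenuation in the low-performing group confined to
interhemispheric (20%) and subcortical-cortical (10%) connections.

Geometry drives the rest. Cortical centroids are Fibonacci lattices on two
offset unit spheres (modules are contiguous azimuthal sectors, hemisphere-
pure by construction); the deep grey structures cluster between and below the
hemispheres with a small lateral extent, as in anatomy. Base weights decay
exponentially with embedded distance and within-module connections get a
2-fold boost, so intramodular connections are short and strong while
interhemispheric and subcortical-cortical connections are long and weak —
reproducing the empirical ordering of connection lengths. Streamline lengths
are the embedded distances (50 mm per unit). Edge presence is Bernoulli with
a distance-decaying probability calibrated by root finding so the expected
density matches the 60% target.

Noise is multiplicative log-normal (weights stay nonnegative), with two
components: a global per-subject factor (sdlog 0.2, i.e. a between-subject
coefficient of variation of about 20% in total connection weight, of the
order reported for SIFT2-weighted connectomes) and independent per-edge
noise (sdlog 0.25). Two consequences matter for interpretation. First,
because the subject factor is shared across classes, the per-class group
tests are strongly correlated: the planted attenuation is either detected
across most interhemispheric classes or (rarely) washed out wholesale.
Second, the planted attenuation removes about 4% of total cortical weight,
and that global difference dilutes into *every* class of a random module
allocation; the negative control is quiet because the diluted shift stays
within noise, not because the group difference vanishes identically. Both
recovery rates (planted attenuation flagged with no intramodular false
positives; random-partition null quiet) sit near 0.92-0.95 under these
conditions — they are stochastic properties of the design, not certainties.

Expression maps are Gaussian random fields on the cortical sphere built by
von Mises-Fisher kernel smoothing of white noise (length-scale 0.3 rad;
Moran's I increases monotonically with the length-scale). Signal genes
(default 30 of 500) mix the standardised loss map into such a field with
weight 0.7, half positively and half negatively. Transcript lengths are
log-normal, GC content Beta-distributed. The cell-by-gene table boosts
signal-gene expression 25-fold in one designated cell type, putting their
specificity above 0.8 so cell-type recovery has a defined truth.

What the generator does *not* emulate: donor-level microarray structure,
right-hemisphere expression, spatially structured scanner artefacts,
head-motion confounds correlated with group, and gene-gene co-expression
beyond shared spatial smoothness. Passing tests therefore demonstrate that
the pipeline recovers what it is designed to recover under its own model
assumptions — not that those assumptions hold in any particular MRI cohort.

# Numerical choices and problem sizes

- Edge lengths for shortest paths are reciprocal weights (`1/w`), the
  standard strength-to-length mapping; unreachable pairs are `NA`.
- The Louvain consensus threshold is the co-assignment matrix's off-diagonal
  mean; consensus iterations cap at 20.
- Spin assignment cost is the great-circle angle; ties resolve by scan
  order, which cannot matter for distinct centroids.
- PLS stops extracting components when the weight norm collapses below
  1e-12 of the response scale.
- The replicate-based recovery properties are exercised at 60 regions per
  hemisphere with the full group sizes: per-class edge counts stay large
  enough to preserve the study-scale correlation structure of the noise,
  which much coarser layouts distort (intramodular classes with a dozen
  edges decorrelate and inflate false-positive rates purely as a
  downscaling artefact). Calibration suites use 200 replicates; recovery
  suites 100; the gene-ranking recovery runs once at the full default scale
  with 1000 spins and 200 bootstraps.

# Known limitations

- Parcel-matched spin nulls are slightly rougher than the observed map (the
  one-to-one assignment cannot be exact on a discrete lattice). When the
  response is exactly as smooth as the predictor fields — no measurement
  noise of its own — the roughening deflates every null fit and the test
  becomes anti-conservative. For responses carrying finite-cohort noise, as
  pipeline loss maps do, the calibration is nominal; surrogate-map nulls
  that match the variogram would be the remedy for noiseless smooth
  responses, and are out of scope here.
- The spin test assumes one sphere of centroids per modelled hemisphere;
  bilateral maps would need per-hemisphere rotations.
- The mixed-model contrast variant depends on lmerTest convergence and is
  not the default.
- EWCE stratification uses fixed quintile bins; very small backgrounds merge
  strata and weaken covariate control (a warning is emitted).
- The random-partition null's pseudo-hemisphere assignment is one of several
  defensible conventions; alternatives (e.g. majority-vote hemispheres)
  would change which mixed classes are enumerated but not the null's logic.

# A minimal worked run

```{r example, eval = FALSE}
cfg <- generator_config(n_regions_per_hemisphere = 60L, n_subcortical = 14L)
parc <- make_parcellation(cfg)
cohort <- make_cohort(cfg, parc, seed = 1)

classes <- enumerate_connection_classes(planted_partition(parc, cfg), parc)
strengths <- class_strength_table(cohort$connectomes, classes)
contrasts <- contrast_classes(strengths)          # pd_low vs pd_high
subset(contrasts, significant)

loss_map <- regional_loss(cohort$connectomes, parc, "interhemispheric")
expr <- make_expression(cfg, loss_map, parc, seed = 2)
fit <- pls_fit(expr$expression, loss_map, n_components = 5)
cen <- as.matrix(parc[parc$region_class == "cortical" &
                        parc$hemisphere == "left", c("x", "y", "z")])
spins <- make_spins(cen, n_perm = 1000, seed = 3)
sp <- spin_pvalue(fit, expr$expression, loss_map, spins)
boot <- bootstrap_weights(expr$expression, loss_map, fit,
                          n_boot = 200, seed = 4)
ranking <- rank_genes(fit, boot, sp)

spec <- build_specificity(expr$cell_by_gene, expr$cell_labels)
ewce(top_genes(ranking, "downweighted"), spec, expr$meta,
     n_boot = 10000, seed = 5)
```
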