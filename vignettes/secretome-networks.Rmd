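---
title: "Comparative secretomics and enzyme-class co-expression networks"
author: "secretomeNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative secretomics and enzyme-class co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretomeNet)
```

# The analysis

Saprophytic fungi degrade plant biomass by secreting large cocktails of
carbohydrate-active enzymes (CAZymes): glycoside hydrolases (GH),
carbohydrate esterases (CE), polysaccharide lyases (PL), auxiliary-activity
redox enzymes (AA, including lytic polysaccharide monooxygenases, LPMOs) and
carbohydrate-binding modules (CBMs). When several fungi are grown on several
carbon sources and their secretomes are quantified by label-free
mass-spectrometry (LFQ), two questions arise:

1. *What is secreted where?* — per-fungus composition tables and
   per-substrate detection counts.
2. *Which enzyme classes are deployed together?* — a co-expression network
   over enzyme classes rather than individual proteins, so that the answer
   generalizes across fungi that express different paralogs.

`secretomeNet` implements this pipeline end to end, starting from a
protein-by-sample LFQ intensity table (samples keyed
`fungus|substrate|replicate`), reduced annotation tables (dbCAN-style CAZy
families, MEROPS-style peptidase families, boolean calls from three
signal-peptide predictors) and a family-to-class map.

## Detection filtering

A protein enters the analysis for a fungus only if it was detected in at
least two of the three biological replicates on at least one carbon source.
Once a protein passes, it counts as *present* on every substrate with at
least one detected replicate — the single-replicate carry-over convention
used in per-substrate detection tables. `detectionFilter()` returns both
decisions; the threshold (`minReplicates = 2`) applies unchanged when a
design has fewer or more replicates.

## Normalization

Samples are placed on a common scale by log2 transformation followed by
subtraction of each sample's Tukey-biweight location, a robust average that
zeroes the influence of points beyond `c` (default 5) scaled median absolute
deviations. `tukeyBiweight()` iterates the re-weighted mean to convergence
(`epsilon = 1e-6`) from a median start with the scale fixed at the unscaled
MAD; `oneStep = TRUE` gives the classical one-step variant. When at least
half the values are tied (MAD 0) the median is returned. Because every step
is shift-equivariant, normalization is idempotent and self-centering: the
biweight of a normalized sample is 0 to within the convergence tolerance.
Missing (not detected) values remain missing; they are never imputed at this
stage so that replicate averages are not dragged toward a detection floor.

The pipeline filters before normalizing. The two orders differ only through
the set of values entering each sample's biweight; both are available by
calling `normalizeAbundance()` and `detectionFilter()` in either order.

## Annotation rules

* **Secretion consensus** (`consensusSecretion`): secreted iff at least two
  of the three predictor calls are positive. A missing predictor output is a
  "not secreted" vote — a predictor that returned nothing found no signal
  peptide. How a WoLF-PSORT-style score was thresholded into a boolean is
  the caller's responsibility; the reduced input format deliberately takes
  booleans.
* **Accounting category** (`assignCategory`): catalytic CAZy domain
  (GH/CE/PL/AA, with LPMO families AA9/11/13/14/16 flagged within AA) beats
  peptidase — in particular CE-and-peptidase proteins count as CE; then
  CBM-only; proteins with no CAZy/peptidase domain are *uncharacterized*
  unless their description names a function, in which case *other*. Among
  multiple catalytic domains the fixed order GH > CE > PL > AA decides,
  which keeps categories a partition of the protein set.
* **Class membership** (`classMembers`): enzyme-class sets may overlap —
  a family mapped to two classes (GH5: endoglucanase *and* endomannanase)
  or a multi-domain protein places the protein in every matching set.
  Subfamily tokens (`AA3_2`) match a subfamily-specific map row first and
  fall back to the base family, which is what separates cellobiose
  dehydrogenases (AA3_1) from other AA3 oxidoreductases. The shipped map
  (`defaultEnzymeClassMap()`) transcribes the standard lignocellulose
  deconstruction scheme and can be replaced by any two-column TSV.

## The class co-expression network

For each fungus, proteins kept by the filter form a weighted graph over the
15 replicate-level samples (5 substrates x 3 replicates). Missing entries
are first substituted with -10, below the lowest normalized value, so
absence itself is informative. The edge weight is
\(e_{vu} = |\mathrm{PCC}(v,u)|^\beta\) with \(\beta = 1\) by default — the
edge weight is literally the absolute Pearson correlation; \(\beta\) is
exposed for soft-thresholding behavior but no power selection is performed.
A zero-variance profile (e.g. all-substituted) has undefined correlation and
contributes edge weight 0.

The protein graph is collapsed onto the class sets
\(S_1, \dots, S_n\):

\[
C_{S_i S_j} = \frac{\sum_{v \in S_i} \sum_{u \in S_j} e_{vu}}{|S_i|\,|S_j|},
\]

the collective strength of the edges between two classes over the maximum
possible. For \(i = j\) both numerator and denominator are reduced by
\(|S_i|\) to remove the unit self-correlations, leaving the intra-class
coefficient undefined for singleton classes. Because the double sum runs
over sets that may share proteins, overlapping annotations are handled
without special cases.

The per-fungus class networks are averaged entry-wise (undefined entries
omitted; an entry defined in one fungus only is kept as is), giving one
consensus network whose node sizes are the summed class memberships. Node
*strength* — the sum of a class's defined incident weights, self-loop
counted once — ranks hub classes and is always reported from this full
pre-filter network.

For display, weights are discretized onto the integer 0–100 percent scale
(half-up rounding; weight 0 means no edge) and pruned with the marginal
likelihood filter: with total discretized weight \(T\) and integer strengths
\(k_i\), each of the \(T\) unit edges falls on the pair \((i,j)\) with
probability \(p_{ij} = k_i k_j / (2T^2)\) under a strength-preserving null,
so the observed weight is Binomial\((T, p_{ij})\) and an edge survives when
its upper-tail p-value is below \(\alpha = 0.05\). Self-loops are excluded
from the null and never filtered; they remain as node annotations. Averaging
happens on the continuous coefficients before the single discretization,
following the order of the processing chain.

## The synthetic study generator

Real deposited raw data is neither needed nor touched: `generateStudy()`
draws studies with the statistical structure the analysis assumes, so every
stage is testable offline.

* Log2 abundances: protein baseline \(b_p \sim N(\mu, \sigma^2)\) with
  \(\mu = 25\), \(\sigma = 2\) (raw log2-LFQ-like magnitudes), an additive
  induction effect of 4 log2 units (16-fold) for a protein's enzyme class on
  the substrates where that class is induced, and replicate noise with
  \(\sigma = 0.5\).
* Missingness: left-censoring at a hard detection threshold (default 23),
  reproducing the "not detected" pattern of LFQ tables; under the defaults
  this censors roughly 12% of entries and, since glucose induces nothing,
  concentrates missingness there.
* Design: 5 fungi x 5 substrates (bagasse, birch, spruce, cellulose,
  glucose) x 3 replicates, 200 proteins of which 48 belong to 8 enzyme
  classes (6 each). Two class pairs are *planted* as co-induced — identical
  induction patterns — while the remaining classes get distinct patterns;
  the glucose column is forced to zero induction, emulating catabolite
  repression of CAZymes on free sugar.
* Annotations: each class maps to one CAZy family; 10% of class proteins
  receive a second family (multi-domain proteins); background proteins are
  peptidases, CBM-only or uncharacterized; true secretion status (90% for
  class proteins, 30% for background) is passed through three predictors
  that each flip with probability 0.05.

One RNG stream seeded from the config drives everything, so a config is a
reproducible study and `writeFixtures()` emits byte-identical files.

What the generator does *not* emulate: peptide-level effects,
match-between-runs transfer, intensity-dependent variance, batch effects,
correlated predictor errors, or fungus-specific proteomes (all fungi share
one protein universe, like a fully orthologous set). Passing recovery tests
therefore shows the pipeline recovers planted class-level co-induction under
idealized LFQ-like noise and censoring — not that it is robust to every
artifact of real spectra.

## Numerical conventions

* Printed percentages and the percent discretization round half away from
  zero (`roundHalfUp`), since half-even rounding cannot reproduce printed
  summary tables (e.g. 25/45 = 55.6% printing as 56).
* Euclidean/UPGMA heat-map ordering (`hierarchicalOrder`) fills missing
  entries with the same -10 sentinel the network uses, a stated assumption
  rather than an inherited convention; distances are computed on the filled
  matrix only.
* Replicate Pearson correlations use pairwise-complete proteins and are
  undefined below 3 shared proteins.
* Heat-map color bounds [-5, 10] and profile display range [-4, 8] are
  recorded as metadata, not clamped into the values.

## Problem sizes used in validation

The shipped checks run: the brute-force collapse oracle on 1000 random
instances (up to 10 proteins, 4 overlapping classes), the exact
binomial-tail oracle on all 18,564 4-node integer-weight graphs with total
weight up to 12, the replicate-filter rule on all 64 detection patterns over
two substrates, and 100 independent synthetic studies at the default design
for planted-pair recovery (ROC-AUC of the averaged coefficient and MLF
survival at \(\alpha = 0.05\)). These sizes make every oracle exact or
exhaustive while keeping a full run in the order of a minute.

## Known limitations

* The adjacency is unsigned; anti-correlated expression is indistinguishable
  from co-expression by design choice (\(|PCC|\)).
* Whether a soft-thresholding power above 1 should be used is left to the
  caller; no power-selection diagnostic is provided.
* The MLF null treats discretized weights as exchangeable unit edges; with
  very small \(T\) the test is conservative.
* Genome-encoded per-class counts in the class-by-substrate table are user
  input (a family scan is out of scope), not computed.

# A worked example

```{r example, eval = FALSE}
library(secretomeNet)
bundle <- generateStudy(syntheticConfig(seed = 7))
out <- tempfile()
res <- runPipeline(list(input = list(synthetic = list(seed = 7))), out)
res$summary
nodeStrength(res$grand)
plantedPairs(bundle$truth)
```

The run directory contains the secretome summary, per-fungus
class-by-substrate tables, the ordered heat-map matrix, replicate QC,
edge significance, the filtered network in SIF + TSV and GraphML form, and
a manifest with the seed and every effective parameter.
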