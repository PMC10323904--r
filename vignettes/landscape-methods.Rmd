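---
title: "Methods: mapping a transcription factor's lncRNA landscape by recurrence"
author: "p53lncscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping a transcription factor's lncRNA landscape by recurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p53lncscape)
```

# The problem

Long non-coding RNAs (lncRNAs) are expressed in a strongly tissue- and
cell-type-specific manner, so any single perturbation experiment sees only a
slice of the p53-responsive lncRNA transcriptome, and most lncRNAs are too
lowly expressed to reach significance in any one dataset. The strategy
implemented here is recurrence: integrate many independent
differential-expression (DE) datasets and many independent ChIP-seq peak
sets, and trust what keeps coming back. On top of the recurrence layer, the
package classifies *how* p53 reaches each recurrent lncRNA — directly at the
promoter, through a bound enhancer, indirectly through the p21–DREAM/RB
repressive axis, or through a protein-coding host gene that physically
contains the lncRNA — and asks whether recurrently regulated gene sets
stratify cancer-patient survival.

# The recurrence expression score

For each gene and each DE dataset in the compendium, the input is a log2
fold-change and an FDR (a gene absent from a dataset's table was not
testable there). The score is a count, not a pooled effect:

$$\mathrm{score}(g) \;=\; \#\{d : \mathrm{FDR}_{gd} < \alpha,\ \mathrm{LFC}_{gd} > 0\}
\;-\; \#\{d : \mathrm{FDR}_{gd} < \alpha,\ \mathrm{LFC}_{gd} < 0\}$$

with $\alpha = 0.05$ by default. A gene must be testable in at least
`min_expressed = 3` datasets to be scored at all; below that it is dropped,
not reported as zero, because "no evidence" and "evidence of no recurrence"
are different things. The median log2 fold-change is computed over all
testable entries *regardless of significance*: a medium-sized median with few
significant calls is exactly the signature of a lowly expressed but
consistently responsive lncRNA, which is why the median is reported next to
the score rather than folded into it. Recurrent sets use inclusive cutoffs
(score ≥ 10 up, ≤ −10 down by default). Three deliberate edge rules:

* an entry with log2 fold-change exactly 0 and a significant FDR counts
  neither up nor down (its direction is undefined);
* significance calls may alternatively be supplied precomputed as a ternary
  `call` column, so published per-dataset calls can be reused verbatim;
* scoring is antisymmetric under global sign flip of the fold-changes — this
  is a tested invariant, not an accident.

# Binding-site recurrence

Peak compendia disagree about boundaries, so recurrence is defined per base.
All peak sets of one factor are partitioned (`multi_intersect()`) into
maximal segments over which the set of supporting datasets is constant —
peaks within one dataset are collapsed first, so support counts datasets,
never stacked peaks. `recurrent_sites()` keeps segments with support ≥ k and
merges book-ended survivors (`merge_gap = 0`; a configurable gap is
available). The alternative definition — counting reciprocal whole-peak
overlaps — was rejected because it makes the result depend on arbitrary peak
extents; the per-base partition is the natural meaning of a multi-way
interval intersection. Default thresholds follow the compendium sizes the
pipeline is built around: 5 of 28 datasets for p53, 4 of 9 for E2F4, 2 of 4
for p130/p107, 3 of 6 for RB. DREAM — the repressive complex whose key
DNA-binding components are E2F4 and p130/p107 — is located where both
factors recur: `dream_sites()` is the base-wise intersection of the two
recurrent sets. A precompiled published site set (e.g. a BED of recurrent
p53 sites) can be loaded in place of the computed one; both paths produce the
same container.

All internal coordinates are 0-based half-open. GTF input (1-based closed)
is converted on read; BED is taken as-is; chromosome-name dialects ("chr1"
vs "1") are normalized by an explicit style switch rather than guessed.

# Mechanism classification

A gene is a **direct** target when any recurrent p53 site overlaps, by at
least one base, a window of ±2500 bases around any of its transcription
start sites. "Within 2.5 kb" is read inclusively (|pos − TSS| ≤ 2500, so the
window is 5001 bases wide); TSSs are the deduplicated starts of all of the
gene's transcripts, windows are not merged, and whole-site overlap rather
than summit distance is used because summits are not available in published
site lists (a midpoint mode exists). An **enhancer-mediated** target has a
high-confidence ("elite") enhancer association whose enhancer overlaps a
recurrent p53 site, *and* no TSS-proximal site at any of its TSSs — direct
binding takes precedence, and the exclusion is gene-level (every TSS), the
stricter of the two possible readings. **DREAM** and **RB** targets use the
same machinery with ±1000-base windows, the established distance for these
repressor complexes. Direct/enhancer flags are evaluated on the recurrently
up-regulated set and DREAM/RB flags on the down-regulated set, mirroring the
activating and repressive arms of p53 signalling; an "all genes" scope is
available for exploration.

# Nested co-regulation

A lncRNA is **nested** when its full gene span lies inside a protein-coding
gene's span on the same chromosome and strand (overlap fraction of the
lncRNA = 1). Containment uses gene spans, not exon structure: intronic vs
UTR placement is a description, not a gate. Co-regulation is the Spearman
correlation of the two genes' log2 fold-change vectors over the datasets
where **both** are testable; at least 3 shared datasets are required, below
which the pair is flagged untestable rather than assigned a meaningless
statistic. "Significantly positively co-regulated" means ρ > 0 and
two-sided p < 0.05 (α configurable — the underlying studies display
per-pair p-values without fixing a level). P-values use the exact
permutation null below n = 10 without ties and the large-sample t
approximation otherwise, with average ranks on ties; the small-n exact path
is checked against a full permutation enumeration in the tests.

# Perturbation-dependence tests

All expression contrasts are two-sided unpaired Student's t-tests with
pooled variance on log2(TPM + 1) values. The log transform stabilizes the
variance of TPMs across the dynamic range (a raw-scale mode exists since the
choice is not forced by the data model). Zero pooled variance is handled
explicitly: equal means give t = 0, p = 1; unequal means give a degenerate
flag with p → 0.

**p21 dependence.** A gene is p21-dependent when (i) it is significantly
repressed by treatment in parental cells and (ii) the knockout fails to
repress it. "Failure" is not quantified in the underlying literature, so the
package adopts a two-branch rule exposed as configuration: the knockout
contrast is not significant at α, *or* its log2 repression magnitude is less
than half (`failure_fraction = 0.5`) of the parental magnitude. The same
classifier serves mediator dependence generally — e.g. an siRNA
knockdown series against a control — by relabelling the genotype arms.

**Pocket-protein predominance.** Across a depletion series (parental,
RB-depleted, p130/p107-depleted, triple-depleted), a detected gene
(mean parental-control TPM ≥ 1, configurable) with significant parental
repression is classified by where repression is lost: lost only upon RB
depletion → RB-predominant; lost only upon p130/p107 depletion →
DREAM-predominant; retained in both single depletions but lost in the
triple → cooperative. Any resolved call requires the triple depletion to
abolish repression — if removing all three pocket proteins leaves the
repression intact, the gene's repression is not pocket-protein-mediated and
the call is "unresolved". The classifier is a pure function of the
(direction, significance) truth table, verified by exhaustive enumeration of
all 16 repression patterns.

# Survival stratification

Each patient is scored for a gene set with a single-sample rank-weighted
running-sum enrichment statistic. Genes are ranked by expression per sample
(descending, average ranks on ties); walking down the ranking, the running
sum accumulates the difference between the weighted fraction of set members
seen (weight = ascending rank magnitude raised to α = 0.75, so the top gene
weighs N) and the unweighted fraction of non-members seen, and the score is
the sum over all positions. This concrete formula is fully specified here so
tests can pin it to a literal-summation oracle at 10⁻⁹; the exponent and the
cross-cohort range normalization (divide by max − min) are configuration.
Because the statistic depends on ranks only, it is invariant under any
strictly increasing per-sample transform — also a tested invariant.

Patients are split into score **tertiles** (low/medium/high). Ties are
broken by sample id for determinism; when n is not divisible by 3 the
remainder goes to low first, then high (10 patients → 4/3/3). The groups
enter a Cox proportional-hazards model (Efron tie handling) with age and sex
as confounders, reference level low; the group effect is tested with a
likelihood-ratio test against the age+sex-only model. Kaplan–Meier curves
are plotted per group with a cosmetic horizon (default day 5000) that never
alters the estimates. Splitting by p53 mutation status (any non-silent
somatic TP53 variant → mutant; the non-silent list is configurable because
no canonical filter exists) re-derives tertiles within each subcohort — the
subcohort, not the full cohort, is the population being stratified. Gene-set
overlaps (e.g. with proliferation-module lncRNA lists) use the two-sided
Fisher exact test over an explicit background universe.

# What the synthetic data emulates — and what it does not

The generators reproduce the *structure* of the study conditions: 44 DE
datasets with per-(gene, dataset) missingness (default 30%) emulating sparse
lncRNA detectability, planted up/down genes responding in a
`response_prob = 0.5` fraction of testable datasets with |log2FC| centred at
2, peak compendia of 28/9/4/6 sets with 80% detection, 10-base endpoint
jitter and rare decoys, nested lncRNA/host pairs whose host fold-changes
shadow the lncRNA's (noise sd 0.3), TPM experiments with 3 replicates and
4-fold planted effects, and cohorts of 600 patients with planted group
hazard ratios (1.5 and 2 vs low) and 30% censoring. Significance calls are
generated directly with the stated probabilities rather than via a count
model, because the pipeline consumes calls, not read counts — its
correctness does not depend on how an upstream DE model produced them.

What the generators do **not** emulate: correlated responsiveness across
datasets from the same lab or cell line (real compendia are not
independent draws), biotype-dependent detectability, peak-width biology,
overdispersed expression, or cancer-type heterogeneity in the cohort.
Passing the planted-recovery tests therefore demonstrates that the
*computations* are correct and well-calibrated under the stated noise model,
not that the thresholds are optimal for any particular real compendium.

Problem sizes in the test-suite and acceptance runs (2000-gene universes,
44 datasets, 100–600 patients, 100-seed Cox calibration loops) were chosen
as the smallest scales at which the stochastic properties under test are
stable; all generators accept larger sizes.

# Numerical and design choices

* Coordinates: one internal convention (0-based half-open), conversions only
  at I/O boundaries.
* Gene span = min/max over transcripts; TSS set from all transcripts of the
  gene (not only lncRNA-biotype transcripts within a gene).
* Tertile remainder rule favours low then high, keeping group sizes within
  one of each other.
* Score-table exclusion below `min_expressed` rather than zero-filling.
* Exact small-n permutation p-values where enumeration is feasible;
  standard approximations elsewhere.
* Degenerate inputs (zero-variance arms, constant enrichment scores, empty
  groups, event-free cohorts) produce flags, warnings or errors — never
  silent numbers.

# Known limitations

* Recurrence counts calls; it does not pool effect sizes, so a gene
  consistently but sub-significantly induced scores 0 (the median
  fold-change column is the intended lens for such genes).
* Enhancer-mediated classification is only as good as the enhancer:gene
  association table; no 3D-contact or co-accessibility evidence is used.
* Host-gene co-regulation is correlational; shared-promoter vs
  independent-initiation mechanisms are not distinguished.
* The survival module pools the cohort; per-cancer-type stratification is
  out of scope, and with tissue-specific lncRNAs a pooled hazard ratio can
  mask opposite type-specific effects.
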