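---
title: "Methods: chemogenomic fitness analysis with chemofit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemogenomic fitness analysis with chemofit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models, parameter
choices and numerical conventions, and of what the synthetic-data
generator does and does not establish about real screens.

## The data model

A chemogenomic screen grows a pool of barcoded deletion strains in a
chemical condition and reads out per-strain abundance. `chemofit`
works from the derived per-entry summaries, not the raw intensities: a
gene-by-condition matrix of log2-ratio fitness defects
(control/treatment, so a sensitive strain scores positive) and a
parallel matrix of one-sided P-values for sensitivity. The container,
`FitnessDataset`, extends `SummarizedExperiment` with assays `fd` and
`pval`; the column data maps each condition to its compound,
concentration label and timepoint, and a `zygosity` slot distinguishes
the heterozygous (HIP) assay — where a drug binding its target further
reduces the functional dosage of the one remaining copy and so
sensitizes the target's strain — from the homozygous (HOP) assay,
which reports genes buffering the target pathway.

Conventions fixed here, because the underlying quantities admit more
than one reading:

* P-values are interpreted as one-sided in the sensitivity direction.
* Significance calls use a strict inequality (P < 0.01 by default);
  an entry equal to the cutoff is not called, and a missing entry is
  never called.
* Replicate conditions of one compound collapse to the maximum
  fitness defect (greatest sensitivity); the retained P-value is the
  one paired with the selected score, so a collapsed cell remains a
  coherent (fd, P) record rather than a mix of the best fd and the
  best P.
* Missing measurements are explicit `NA`s in files (`NA` or empty
  cell) and in memory — never a sentinel number.

## Co-fitness and co-inhibition

Co-fitness is the similarity of two genes' fitness profiles across
conditions; co-inhibition is the Pearson correlation of two compounds'
profiles across strains. Four co-fitness metrics (Pearson, Spearman,
negated Euclidean distance, cosine of bits discretized at fd > 0.5)
over four score types (log2 ratio, per-condition z-score, P-value,
-log10 P) are provided so the metric choice can be audited; Pearson on
log2 ratios is the default and, on the package's own synthetic
benchmark, recovers reference-network edges with a higher
precision-coverage area than the binarized cosine — discretization
discards the informative part of sub-threshold responses.

Numerical conventions:

* All pairwise statistics are pairwise-complete, and a pair observed
  in fewer than `minOverlap` (default 10) shared conditions is
  reported missing rather than unstable.
* The significance threshold for "co-fit partners" is the mean plus
  three sample (n-1) standard deviations of all unordered off-diagonal
  pair scores. On the full published heterozygous dataset this rule
  gave 0.47; on synthetic data it is recomputed from the matrix at
  hand.
* Group comparisons (paralog pairs, within-complex pairs,
  essential-partner fractions) use Welch's unequal-variance t-test.
* Euclidean distances are stored negated so that "larger = more
  similar" holds for every metric, which keeps threshold sweeps and
  PR evaluation uniform.
* The z-score score type standardizes each condition across genes.

## Fingerprints, IDF and therapeutic classes

Compound structure enters as a binary substructure fingerprint, by
default 554 keys (matching the PubChem SMILES/SMARTS key range
327–880). Key semantics live outside the package: fingerprints are
consumed as precomputed bit matrices, so any dialect of the same width
can be supplied. Bits are weighted by inverse document frequency,
IDF(m) = ln(|C| / c_m) for the c_m carriers among |C| compounds, and
optionally re-binarized keeping only carried motifs with IDF strictly
above 2.5. The logarithm base is natural; rankings are base-invariant
and the threshold is a parameter, so other bases are reachable by
rescaling. Tanimoto (intersection over union of on-bits, defined as 0
for two empty bit sets) is the default similarity; Dice, Hamming,
cosine, Pearson, Spearman, Kendall, Euclidean and city-block are
available for the weighted forms.

Two compounds are co-therapeutic when any pair of their 7-character
WHO ATC codes shares the level-3 prefix, implemented as the first four
characters of the code (anatomical group, therapeutic subgroup,
pharmacological subgroup). The structure/therapy/co-inhibition
cross-tabulation counts pairs with positive co-inhibition and a shared
class, and reports the fraction lacking structural similarity
(Tanimoto < 0.2 by default) — on the published data, 74%
(heterozygous) and 90% (homozygous), figures that require the external
dataset and are therefore documentation, not test gates.

At desk scale one IDF artifact is worth knowing: with 10 families of 8
compounds in a library of 80, each family core motif has
IDF = ln(80/8) ≈ 2.30, below the 2.5 cutoff, so the binarized dialect
strips family cores. The learning features consequently use the raw
binary fingerprints.

## Conditionally essential complexes

A complex is conditionally essential when at least 80% (inclusive) of
its assayed members are significant in the condition; complexes with
fewer than two assayed members are dropped. The null model reassigns
assayed genes to complexes while preserving every complex's size:
sampling without replacement within a complex, independently across
complexes (which also tolerates overlapping catalogs), from the
assayed-gene universe — all genes measured in that condition,
including genes outside any complex, the least biased pool. Under this
scheme the significant-member count of a size-s complex is exactly
hypergeometric, so the implementation draws null counts with `rhyper`;
this is an exact realization of the reassignment null, verified in the
tests against a literal gene-shuffling simulation. The empirical
P-value uses the add-one estimator (1 + b)/(1 + N), which can never be
0 and makes "X exceeded in no permutation" correspond to P < 1e-4 at
N = 10,000. Family-wise control across conditions is Bonferroni
(per-condition 1e-4 over 418 conditions gives 0.04). The analysis is
intended for homozygous data, where a full deletion cleanly removes
the complex member; heterozygous dosage effects on complex
stoichiometry are out of scope. Integer thresholds are computed as
`ceiling(fraction * size - 1e-9)` to guard against binary
floating-point representations of 0.8 tipping a boundary case.

## The 20-feature target predictor

Positives are curated (gene, compound) interactions; balanced
negatives are a random bipartite graph on the same nodes with exactly
the positive degree sequence and no overlap with the positives, built
by a configuration-model draw repaired with seeded endpoint swaps
(bounded retries; infeasibility is an error, never silently relaxed).
Unbalanced negatives are all remaining node combinations. Features are
built from the replicate-collapsed heterozygous data; sentinel values
(missing fd 0, missing P 1, undefined set statistics 0) are flagged in
the table's metadata, and trees tolerate sentinels. The risk-ratio
feature is pair-specific by default — candidate motifs restricted to
the query compound's motif set, and within those to motifs or motif
pairs carried by at least one sensitizing compound — with a
gene-centric mode behind a switch, since the underlying definition is
gene-centric but the feature attaches to a pair. Secondary-ligand
features take the top ten co-inhibiting compounds by signed
correlation, ties broken by compound id, padding absent slots with 0.

The classifiers are built in the package rather than delegated: a
decision stump (single feature and threshold minimizing training
misclassification; its score for threshold sweeps is the selected
feature's polarity-oriented value) and a random forest of ten CART
trees grown on bootstrap resamples with Gini impurity, minimum leaf
size 2, growth to purity, and floor(sqrt(M)) + 1 candidate features
per node (5 for the full 20-feature table; the rounding of sqrt(M)+1
is fixed here as floor). The forest decision is the mode of tree
votes, its confidence the fraction of positive votes (multiples of
1/10; a 0.5 tie resolves negative). Evaluation is stratified ten-fold
cross-validation at the pair level, pooling held-out confidences into
a precision-recall sweep over every distinct score. Top predictions
pass five filters: a rich-medium phenotype (essential, or homozygous
defect at or above a cutoff), confidence >= 0.7, heterozygous log2
ratio >= 5, the compound not in the top promiscuity decile of
predicted-positive counts (the notion of "frequently predicted" is a
parameter), and reciprocal top-ten sensitivity ranks. The optical
density calibration for follow-up growth curves is the affine map
real = -1.0543 + 12.2716 x measured.

## Precision-coverage evaluation

PR curves sweep every distinct observed score (exact curve, not
binned); predicted = score at or above the threshold; missing scores
rank below every threshold and can only contribute false negatives.
The evaluation universe is restricted to pairs whose genes the score
matrix actually measured, so a dataset is not penalized for genes it
never assayed. The area under the precision-coverage curve is
trapezoidal over recall from 0 to the maximum achieved recall — the
first achieved point's precision extends back to recall 0, ties in
recall collapse to their best precision, and there is no extrapolation
to recall 1. Per-process evaluation assigns a gene pair to a process
when both genes carry the label and reports one area per process
(missing when a process has no reference edges in its universe).

## The synthetic generator: what it emulates and what it does not

`simulateChemogenomics()` generates, at desk scale (600 genes, 80
compounds, 2 conditions per compound by default; the published screens
were roughly ten times larger in each dimension), the structure the
analyses exploit:

* disjoint protein complexes (40, sizes 2–12) with one process label
  each (32 labels); the reference network is all within-complex pairs
  plus a 2% sample of within-process pairs;
* essentiality assigned complex-wise (probability 0.2), so essential
  genes co-cluster; paralog partners drawn within complexes (10% of
  genes);
* compound families (10) with disjoint six-motif fingerprint cores,
  3% background bits, and one ATC level-3 class per family;
* one target complex per family and one target gene within it: every
  compound of the family sensitizes that heterozygous strain by
  deltaTarget = 4.0 log2 units, while the module's members respond in
  the homozygous assay by deltaModule = 2.5;
* 15 multi-drug-resistance genes, each responding to a random 60% of
  compounds by 2.0 in both assays — real signal for the promiscuity
  features to penalize;
* i.i.d. Gaussian noise (SD 0.8) on the log2 scale, P-values as the
  upper normal tail of fd/SD, and 2% of entries masked missing.

Noise is Gaussian because the score types in use include z-scores and
no empirical noise model is part of the inputs; effect sizes are
tuning parameters of the benchmark, not claims about real screens.
Both assays share one gene set — in a real HOP collection essential
genes are absent — which keeps the heterozygous/homozygous comparison
on a common universe. Everything is bit-reproducible given the seed;
the orchestrator derives component seeds by fixed small offsets.

What passing tests on this generator establish is that each algorithm
recovers exactly the structure it targets when that structure is
present, with calibrated behavior under the null. What they do not
establish is performance on real screens, whose noise is heteroscedastic
and correlated, whose signals are weaker and overlapping, and whose
annotation is incomplete. Two concrete consequences show up in the
package's own acceptance checks and are left visible rather than
patched:

* The planted target effect is five noise SDs, so the collapsed log2
  ratio alone separates balanced training sets almost perfectly: the
  decision stump and the random forest both reach precision-coverage
  areas near 1 and the forest cannot demonstrate the strict advantage
  it shows on real data — its vote-fraction confidence is coarser
  (multiples of 1/10) than the stump's continuous ratio sweep, so
  saturated curves can even order the other way by a hair.
* The generated P-value is an exact monotone transform of the fitness
  defect within the planted model, so the `pvalue` feature duplicates
  `ratio` and single-feature ablation of `ratio` costs nothing —
  unlike real data, where P-values carry replicate-variance
  information of their own. Feature-importance conclusions from this
  benchmark are therefore about redundancy structure, not about which
  feature a real screen needs most.

Problem sizes used in the checked analyses: the default study (600 x
160 conditions) for metric selection and target recovery; a
200-condition null (100 compounds, all effects zero, 1,000
permutations per condition) for permutation-test calibration; 10,000
permutations per condition elsewhere; 100 regenerations for the
degree-preservation check. Conditionally essential complex counts on
the default study are 0 or 1 per condition — one responsive module per
compound family — so a count of 1 is always reachable under the null
and no condition is flagged at P < 1e-4; the published prevalence
figure (40% of conditions) arises from conditions sensitizing several
complexes at once and needs the external dataset.

## Known limitations

* Fingerprint key semantics (SMARTS matching) are out of scope;
  supply precomputed bit matrices. Structural findings depend on the
  dialect supplied.
* The balanced-negative sampler targets the exact degree sequence;
  for adversarial degree sequences close to uniqueness it reports
  infeasibility rather than approximating.
* Forest confidences are deliberately coarse (ten voting trees, per
  the model definition); downstream consumers needing finer ranking
  should use the feature table with their own scorer.
* The permutation screen treats conditions independently; no
  correlation structure between replicate conditions of one compound
  is modeled or exploited.
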