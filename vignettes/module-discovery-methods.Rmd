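---
title: "Discovering injury-specific co-expression modules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering injury-specific co-expression modules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxmodule)
```

## The problem

Toxicogenomics screens expose animals to many chemicals at several doses
and time points, profile organ transcriptomes, and record clinical
pathology, organ-weight, and histopathology findings for each exposure
*condition*. `toxmodule` asks: which groups of genes are coherently
co-expressed over subsets of those conditions, and which of those groups
activate specifically when a given injury endpoint (an *indicator*,
coded +1/0 per condition) is abnormal?  Such modules are candidate
molecular toxicity pathways, and their most representative genes are
candidate biomarker panels.

The pipeline runs entirely on a gene x condition matrix of log-ratio
Z-scores plus a condition x indicator label matrix, and every stage can
be exercised end to end on synthetic data with planted ground truth.

## Preprocessing

Per-condition log ratios are replicate-averaged treatment minus control
log2 expression.  Two gene filters follow: a present-call filter (keep
genes whose fraction of conditions with an all-replicate "Present" call
is at least 0.25) and a variance filter (keep the `ceiling(n/2)`
highest-variance genes).  The global Z transform then standardizes every
entry against the grand mean and grand standard deviation of the whole
matrix, so one unit means one global standard deviation of log-ratio
change.

Numerical choices:

* The grand standard deviation uses the **population** convention
  (divide by N).  The choice is arbitrary at matrix sizes of interest
  (the two conventions differ by a factor `sqrt(N/(N-1))`), but fixing
  it makes the transform exactly testable.
* The order of the two gene filters is not canonical; it is exposed as
  `preprocess_matrix(order =)` with present-call-first as the default.
* Rows are opaque gene/probe ids; no probe-to-gene collapsing is done,
  and missing values are rejected at load rather than imputed.

## Seed gene sets

The iterative signature algorithm needs starter gene sets.  Five
families are provided:

* **HC** — average-linkage hierarchical clustering of genes on `1 - r`
  Pearson distances, cut by a recursive hybrid rule (split a node when
  it is larger than `max_size`, or when the gap between its merge height
  and its children's heights is large and both children reach
  `min_size`; defaults 16–100).  This is a simplified rendering of
  dynamic hybrid tree cutting: exact equivalence to the published
  heuristic is not claimed, and planted-block recovery is the tested
  surface.
* **PPI** — ego networks (a protein plus its direct partners) of a
  protein-interaction network, scored per indicator by counting up- and
  down-regulated member genes and standardizing the counts against
  permutations of which conditions carry the positive label.  "Up/down
  regulated" is not canonical either; the definition used here is a
  mean Z over the positive conditions beyond `±reg_threshold`
  (default 1), monotone in signal and configurable.  Significance
  thresholds come from repeating the scoring on fully randomized labels
  and taking the 5th most extreme of 100 per-run extremes (an estimated
  maximum false-positive rate of 5%).
* **MAZ** — the top genes by mean |Z| over an indicator's positive
  conditions ("condition set" is read as the positive conditions, since
  the sets are built per indicator).
* **RAND** — uniform random sets, the null family.
* Precomputed sets (e.g. SVM-derived classifier signatures) load from
  GMT and are not retrained.

`expand_starters()` pads each seed with random genes, which is how a
few hundred seeds become thousands of starters for the saturation
analysis.

## The iterative signature algorithm

Given a gene set G, each condition scores the mean Z of G; conditions
more than `t_c` standard deviations from the mean score are *relevant*
and keep their signed scores `s^c`.  Each gene then scores the weighted
mean of its Z values over the relevant conditions, with weights `s^c`
normalized by `sum(|s^c|)` (the absolute-value normalization keeps gene
scores on the Z scale when conditions of both signs are present); genes
more than `t_g` standard deviations out are relevant and replace G.
The loop stops when neither the gene set nor the condition set changes
by more than 1% (symmetric difference over the union — the convergence
test compares **sets**, not scores, and applies to genes and conditions
jointly).  Defaults `t_c = 1.8`, `t_g = 3.5` follow the tuning regime
the method was published with (modules no larger than a typical
pathway, maximal indicator specificity and intra-module correlation).

Further choices that the algorithm definition leaves open:

* Thresholding is two-sided on both axes, so modules can mix up- and
  down-regulated genes; signs are carried in the scores.
* `max_iter = 100`; a trajectory that empties, oscillates past the cap,
  or shrinks below `min_genes = 5` returns no module.  The minimum size
  exists because a near-singleton gene set is a stable fixed point of
  the scoring loop on *any* matrix — one extreme gene selects its own
  extreme conditions — and carries no co-expression information; on
  pure noise these degenerate fixed points are essentially the only
  converged trajectories.
* Redundancy pruning is a greedy scan in descending robustness order
  dropping any module whose full-length gene-score vector correlates
  above `cor_limit = 0.9` with a retained one.
* Robustness of a module is
  `sqrt(sum over module cells |s^g(i) * s^c(c)|)`.  The robustness
  filter builds a signal-free null by permuting the entries of the
  matrix (value distribution kept, block structure destroyed), reruns
  the algorithm from random starters there, and keeps only modules
  strictly above the largest null robustness.  Running the null on the
  *observed* matrix instead is tempting but wrong: a random starter
  occasionally cascades onto a real module, which would set the
  threshold at the real modules' own robustness and delete them.
* Tie-breaks everywhere are lexicographic in gene/condition id.

`run_isa()` is the package's central fit; it returns a classed result
with `print`, `summary`, and `plot` (saturation curve) methods.

## Module evaluation

For module m and indicator p with positive conditions P:

* **Activation** `A(m, p)` — mean Z over member genes and P.  |A| > 1.5
  is carried as the significance convention (on the real data it marks
  the ~5% tails of the near-normal activation distribution; the
  threshold is a configurable default here, not recomputed).
* **Specificity** `S(m, p)` — mean |A(m, p) − A(m, q)| over the other
  indicators q; `S+` averages the per-indicator maxima over indicators.
  Indicators with no positive condition are dropped from the averages
  rather than zero-filled.
* **Intra-module correlation** `R(m, p)` — mean pairwise Pearson
  correlation of member genes across P, self-pairs excluded (they would
  only add a constant).  Undefined below two positive conditions or two
  non-constant genes; such values are reported missing.
* **Gene activation** `A(i, p)` — mean Z of one gene over P; module
  activation is exactly the mean of its members' gene activations, an
  identity the tests assert at 1e-12.
* **Center gene** — the member with the largest sum of correlations to
  its fellow members (self term 1), demoted to the next candidate while
  its mean Z over P is below the module mean.  The span of the
  correlation normalization is ambiguous in the source description;
  the default computes the correlations over the positive conditions
  only, and `span = "all"` normalizes each gene over all conditions
  while still accumulating over P.  Note the reselection rule can never
  exhaust the candidate list on finite data: the module mean is the
  average of the member means, so some member always reaches it.

## Cluster views, enrichment, signatures, validation

Modules and indicators are clustered by their activation patterns
(average linkage, `1 - r` distance, tree cut at height
`1 - cor_cutoff`, default cutoff 0.90, or at a requested cluster
count — the criterion behind any particular published indicator
grouping is not recoverable, so both cuts are supported).  Constant
activation vectors have no defined correlation and are assigned the
maximal distance 2, which makes them singletons.  The reduced
activation map averages activations within module-cluster x
indicator-cluster blocks, and indicator-cluster separation is
summarized by root-mean-square distances between its columns.

Pathway mapping tests each (module, pathway) pair with the one-sided
hypergeometric tail and admits a mapping only when the module is
activated beyond `a_thresh` for some indicator, the Bonferroni-corrected
p (family = all pairs tested in the run; the family is otherwise
unspecified) is below 0.05, and the overlap has at least 6 genes.  The
test universe defaults to all genes surviving preprocessing and is
configurable.

Three signature constructions are provided: all member genes of one
module with per-gene |activation| above threshold; the center genes of
every module activated for one indicator (shared center genes collapse
to one entry listing all source modules); and the union of the latter
over all indicators.  For the general panel a module activated by
several indicators may contribute a different center gene per
indicator; all are kept by default, with `per_module = TRUE` keeping
only the strongest recruitment per module.

External validation compares per-gene mean log-ratios ("fold changes")
between an internal and an external dataset by Pearson correlation, and
embeds external conditions restricted to the panel genes by classical
(Torgerson) multidimensional scaling; group separation is quantified by
the mean silhouette width of the given grouping on the embedding,
turning a visual claim into a number.

## The synthetic study design

`planted_design()` describes the ground truth; defaults are the
package's reference study conditions: **2,000 genes x 300 conditions,
8 disjoint modules of 30 genes x 25 conditions, mean block signal 3
against Normal(0, 1) background, alternating signs**.  This mirrors, at
desk scale, a liver-toxicogenomics Z-score matrix where module signal
sits about three background standard deviations out (comparable to the
|A| > 1.5 significance regime).  Signals are planted on the log-ratio
scale *before* global standardization, so the pipeline's own transform
is exercised.

Each block condition carries a response amplitude
`a_c ~ Normal(1, 0.3)` shared by the whole block (cell value
`sign * mu * a_c + Normal(0, 1)`).  This shared amplitude is essential,
not cosmetic: it is what makes block genes *co-expressed* — pairwise
correlation ≈ 0.45 across their positive conditions — rather than
merely mean-shifted.  A pure mean shift produces blocks whose genes are
uncorrelated across the positive conditions, and the intra-module
correlation metric would not distinguish recovered modules from random
gene sets.

Blocks are disjoint and regularly spaced; overlapping gene membership,
batch effects, probe-level noise, and realistic inter-gene correlation
of the background are not emulated, so passing tests demonstrate
correctness of the machinery and recoverability of clean planted
structure, not performance on real arrays.  Companion generators emit a
matched PPI network (one hub per block wired to all block genes plus
random background edges), pathway sets (each block plus distractors,
and random decoys), and external matrices whose per-gene mean
fold-changes are Gaussian mixtures tuned to a target correlation with
the internal fold-changes (per-condition replicate noise is expressed
in units of the fold-change spread so the delivered correlation stays
on target; the boundary values ±1 are accepted and exact).  Label
noise, when requested, flips each indicator label independently.

## Problem sizes in the test-suite and reports

The unit-test fixture scales the reference design down to 1,000 genes x
200 conditions with 4 modules of 25 genes x 20 conditions — the same
block-to-background proportions, chosen so that the default thresholds
separate signal from noise after variance filtering exactly as they do
at full size.  (Proportions matter: concentrating blocks into a much
smaller matrix inflates the spread of the gene scores until `t_g = 3.5`
rejects true block genes.)  End-to-end recovery checks, the
specificity/correlation comparison against size-matched random sets
(10 replicates), enrichment recovery (5 replicate designs), and the
validation-stage parameter recovery (20 replicates) all run at the full
reference design size; the whole suite completes in well under a
minute on one CPU.

## Known limitations

* The hybrid tree cut is a simplified re-derivation; published
  dynamic-tree-cut partitions will differ in detail.
* The robustness null is a single permutation ensemble; modules whose
  robustness sits just above the null maximum are kept without a
  formal error rate.
* Indicators are treated independently; correlated indicators inflate
  neither specificity denominators nor any multiplicity correction.
* All correlation machinery is Pearson; heavy-tailed expression noise
  would argue for rank-based variants, which are not provided.
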