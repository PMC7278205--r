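---
title: "Methods: supervised discretization and joint gene selection for stage prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: supervised discretization and joint gene selection for stage prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagesel)
```

# The modeling problem

The package predicts a binary tumor-stage label — early (AJCC pathologic
Stage I–II) versus late (Stage III–IV) — from bulk RNA-seq abundance
profiles on the RSEM/FPKM scale. Two properties of such data drive the
design. First, abundances are non-negative and heavy-tailed: a handful of
extreme values per gene can dominate a linear model fitted on the raw
scale. Second, genes are massively redundant: co-regulated genes carry
nearly identical information, and feeding them jointly to a classifier
dilutes significance and can flip coefficient signs.

The response is a two-part strategy: *supervised discretization* replaces
each gene by a small number of class-informed bins encoded by weight of
evidence, and a *joint selection chain* removes irrelevant and redundant
genes before a final significance-constrained logistic model fixes the
panel. Everything downstream of the train/test split is fitted on training
samples only.

# The pipeline, stage by stage

`stage_fit()` executes the stages in a fixed order; each stage can only
remove genes, and every elimination is recorded once in the provenance
table.

## Stratified split

Samples are partitioned 80/20, stratified by the four stage groups when
stage strings are available (falling back to the binary label). Each
stratum contributes its nearest-integer share of training samples; when a
stratum's share is an exact half, ties are rounded alternately up and down
in stratum order, so two equal strata at fraction 0.5 yield an exact
half/half split rather than both rounding the same way. The split is a
deterministic function of the labels and the seed — expression values play
no role, which is what makes the downstream leak-freedom test meaningful.

## FCBF stability selection

The fast correlation-based filter is run on *raw* training values:
discretization cuts are order statistics, so any monotone transform of the
abundances yields the same result, and no preprocessing choice can leak
into relevance estimation. Continuous genes are discretized by recursive
entropy minimization with the Fayyad–Irani MDL acceptance rule (base-2
entropies, as is conventional for that criterion); genes with no accepted
cut become single-valued and drop out of relevance ranking automatically.
Relevance and redundancy both use symmetric uncertainty
$SU(X,Y) = 2I(X;Y)/(H(X)+H(Y))$, computed with natural-log entropies (the
ratio is base-invariant).

A single FCBF pass is unstable under resampling, so the filter runs in 10
repeats of stratified 10-fold resampling: within a repeat, FCBF runs once
per fold-training split, and the repeat's subset is formed by a
configurable rule. How the ten fold-level selections collapse into one
subset per repeat is genuinely open; the package defaults to
*majority-of-folds* (selected in at least ⌈folds/2⌉ of the folds), with
`union` and `intersection` available, because majority voting is the least
sensitive to a single unlucky fold while still rewarding consistency. Genes
selected in at least 8 of the 10 repeats survive. With `min_count = 0` the
kept set is the set of genes *ever* selected, not the full gene universe —
a gene no run chose is never "kept by default".

## Chi-merge binning and WOE encoding

Surviving genes are discretized by Chi-merge: values start in 20
equal-frequency prebins (tied values are never split across a boundary) and
the adjacent pair with the smallest Pearson χ² on its 2 × 2 bin-by-class
table is merged repeatedly. A pair in which one class is absent from both
bins has χ² defined as 0 via the zero-expected-cell convention, so
class-uninformative boundaries always collapse first. Merging stops only
when three conditions hold simultaneously: all adjacent χ² exceed
`chi2_stop`, at most `max_bins` bins remain, and every bin holds at least
`min_bin_fraction` of the training samples. The stopping parameters are
nowhere pinned down by the method's origin, so the package adopts standard
credit-scoring practice: `chi2_stop = 3.841` (the 0.95 quantile of χ² with
1 df — merging continues while adjacent bins are statistically
indistinguishable at the 5 % level), `max_bins = 6`, and
`min_bin_fraction = 0.05` to keep per-bin WOE estimates stable. All three
surface in `stage_control()` and the serialized run report. Ties in the
merge statistic go to the leftmost pair; bins are half-open `(a, b]` with
unbounded outer bins, so every real value maps to exactly one bin at
prediction time. Genes whose largest bin exceeds a 90 % share (strict
inequality) are eliminated as effectively constant.

Bin *i* is encoded as $WOE_i = \ln\frac{E_i/E}{L_i/L}$ with early counts
$E_i$ and late counts $L_i$. A zero cell makes the log undefined; in that
case 0.5 is added to every bin cell while totals stay unsmoothed, which
keeps the formula exact on clean tables and bounded otherwise. Encoded
values are *not* clipped to the conventional [−3, 3] band — on realistic
cohorts they land there on their own, and the band is treated as an
empirical observation, not a contract. No monotonicity constraint is
imposed on WOE across bins.

## Information value, correlation, VIF

$IV = \sum_i (E_i/E - L_i/L)\,WOE_i$ scores each discretized gene; every
term is of the form $(a-b)\ln(a/b) \ge 0$. When smoothing was applied, the
smoothed numerators enter both factors so contributions stay non-negative.
Genes with IV < 0.1 are rejected ("lower than" is the rejection rule, so a
gene at exactly 0.1 survives); the conventional strength bands are 0.02 /
0.10 / 0.30.

Correlation filtering on the encoded training matrix processes violating
pairs (|r| > 0.7) in decreasing |r| — worst redundancy first — dropping the
lower-IV member and discarding the loser's remaining pairs. The processing
order for pairs sharing a gene is a design choice (only the pairwise rule
itself is canonical); the greedy descending-|r| order is deterministic and
attacks the strongest redundancy before it can influence weaker pairs. IV
ties break lexicographically. A gene in no violating pair is never dropped.

The variance inflation factor $VIF_i = 1/(1-R_i^2)$ is computed from QR
projections of each encoded gene on all others (with intercept); genes are
removed iteratively, worst first, while any VIF ≥ 10, with exact linear
dependence reported as infinite VIF and removed first.

## Stepwise logistic elimination

The final stage refits an unpenalized logistic model (positive class =
late) and removes one feature per iteration until every remaining feature
has Wald p ≤ 0.1 *and* a negative coefficient. The sign constraint follows
from the WOE orientation: positive encoded values mark early-enriched bins,
so any gene genuinely informative about late stage must enter with β < 0,
and a non-negative coefficient signals sign distortion rather than signal —
it therefore outranks a mere p-value violation in the removal order. Within
the same violation class the largest p-value goes first, ties
lexicographically. One-at-a-time removal (rather than dropping all
violators at once) was chosen because each refit redistributes
significance among correlated survivors; it also makes the elimination
trace exactly k rows for k removals. Perfect separation is detected by a
numerically zero residual deviance and, during selection, resolved by
removing the separating feature (logged with reason `"separation"`); the
classifier wrapper instead tolerates saturated fits, since a resampled fold
may separate even when the full training set does not.

## Classifiers and evaluation

The selected panel (WOE-encoded by default; a log2/z-score mode exists for
comparison arms) feeds five classifiers. The RBF-SVM is tuned by
stratified k-fold accuracy over γ ∈ 10^{−9,−7,…,3} (literal powers of ten)
and C ∈ 2^{−5,−3,…,15} (powers of two, the libsvm convention for a grid
written as integers); ties prefer the smaller cost, then the smaller γ.
MLP (single hidden layer, size 5, decay 0.1), random forest (500 trees) and
Gaussian naive Bayes use recorded library defaults with a fixed seed.
Evaluation uses the confusion matrix at a fixed operating point
(probability 0.5, decision value 0 — no operating point is tuned) plus the
rank-based AUC, which equals the trapezoidal area under the empirical ROC
and is invariant under monotone score transforms. Cross-validated metrics
are arithmetic means over stratified folds, each fold scored by a freshly
trained model.

# The synthetic cohort

`generate_cohort()` emulates exactly the structure the pipeline assumes:
log-normal marginals (per-gene baseline log2 means uniform on [2, 9],
log2-scale SD = `dispersion`, giving the heavy right tail typical of
RSEM data), informative genes whose log2 mean shifts by `effect_shift`
between classes (alternating direction), redundant genes built on the log
scale as $r z_{parent} + \sqrt{1-r^2}\,\varepsilon$ so the target Pearson
correlation holds without truncation, and pure-noise genes. The reference
conditions — 500 samples with 40 % late (matching the late-stage share of
a typical renal-carcinoma cohort), 15 informative genes with a one-unit
log2 shift, two redundant copies each, 2000 noise genes, dispersion 1 —
are the generator defaults and are what `scripts/acceptance.R` runs.

What the generator does *not* emulate: batch effects, library-size
variation, pathway-level correlation structure beyond the planted blocks,
zero inflation, or label noise in staging. Passing the recovery tests
therefore shows the chain correctly identifies location-shifted genes
against log-normal noise and resists planted redundancy — it does not
certify performance on real TCGA-scale data, where effect sizes are
smaller and correlation structure is pervasive.

# Numerical choices and degenerate inputs

* Constant genes: Chi-merge warns and returns a single-bin scheme; a
  single-bin table has IV 0 (warned) and is eliminated by the IV filter;
  constant *encoded* genes are dropped in correlation filtering with a
  warning.
* The expression writer emits 17 significant digits so write/read round
  trips are exact to 1e-12.
* Derived stage seeds are `(seed · 7919 + offset) mod (2^31 − 1)`, keeping
  every internal seed a valid 32-bit integer while decoupling the RNG
  streams of split, stability selection, tuning and cross-validation.
* Bin assignment of a value exactly equal to a cut goes to the left bin;
  values outside the training range map to the outer bins.
* `fcbf` breaks relevance ties lexicographically on gene name, making the
  output invariant to input column order.

# Problem sizes used by the test suite

Unit tests run the oracles on hundreds of randomized small instances
(n ≤ 15 for the Chi-merge merge-order oracle, n ≤ 30 for the MDL
discretizer, ≤ 10 features for the FCBF brute force) and the end-to-end
properties on a 200-sample, 72-gene cohort; the acceptance-level recovery
test runs the full reference cohort (500 × 2045) once with a tuned SVM.
These sizes were chosen so the whole suite completes in about a minute
while every code path — including the full stability-selection loop — is
exercised at realistic signal-to-noise ratios.

# Known limitations

* The unpenalized logistic stage requires more training samples than
  surviving genes; the chain upstream makes this hold in practice, but a
  pathological configuration (e.g. `fcbf_min_count = 0`) can violate it.
* The no-selection baseline arm cannot use unpenalized logistic regression
  when genes outnumber samples; it defaults to an untuned SVM.
* Stage strings outside "Stage I–IV" (substages like "Stage IIIa", stage X,
  discrepant records) are treated as missing, not parsed.
* The pipeline targets a binary endpoint; per-stage (four-class) prediction
  and survival endpoints are out of scope.
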