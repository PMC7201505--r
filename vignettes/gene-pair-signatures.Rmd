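---
title: "Rank-based gene-pair signatures: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based gene-pair signatures: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairsig)
```

## The problem and the model

Kawasaki disease (KD) presents like many childhood febrile infections
(FI), and expression-based diagnostics built on absolute intensities
transfer poorly between array platforms and normalization pipelines.
`pairsig` works entirely on *within-sample orderings*. The elementary
feature for genes $i, j$ in sample $x$ is the indicator
$I(x_i > x_j)$, with ties falling in the 0 branch. The score of an
oriented pair between two classes is the difference of class-conditional
indicator frequencies,

$$\Delta_{ij} = \lvert \hat{P}(X_i > X_j \mid \text{KD}) -
                \hat{P}(X_i > X_j \mid \text{FI}) \rvert \in [0, 1],$$

the classic top-scoring-pair (TSP) statistic. Because the indicator
depends only on the ordering of two measurements taken in the *same*
sample, every score and every classifier in the package is invariant
under strictly increasing transformations applied within a sample — the
property that makes a discovered panel portable across platforms, and
the property the test suite asserts explicitly.

One caveat is worth spelling out because it is easy to overclaim: the
Wilcoxon rank-sum *prefilter* (used only to make pair enumeration
tractable) compares one gene **across** samples, so it shares this
invariance only for transforms applied identically to every sample
(log, affine, global monotone maps). A sample-specific transform such as
replacing values by within-sample ranks leaves all pair indicators,
pair scores and classifier outputs unchanged, but can change which genes
pass the prefilter. The tests therefore assert full invariance for
fixed-pair scores and classifier predictions, and global-transform
invariance for the filtering stage.

## Discovery: stability selection over resampled cohorts

A single cohort ranking of $\binom{G}{2}$ pair scores is fragile; the
framework instead asks which pairs *recur*. Each of `n_runs` runs:

1. draws a stratified 80/20 train/test split (stratified on the
   three-way KD/DB/DV label so both infection subclasses are present in
   every training set — without this, step 2 would be undefined in some
   runs);
2. selects the top `top_m_per_comparison` (default 100) score pairs of
   KD vs DB and of KD vs DV among Wilcoxon-prefiltered genes (default
   100 genes: the 50 most up- and 50 most down-regulated). These two
   stage-1 selections are deliberately *not* gene-disjoint, so their
   union is a genuine ~200-pair restricted candidate set;
3. re-scores the union against KD vs FI and keeps the top `top_m_final`
   gene-disjoint pairs (descending $\Delta$, then descending
   $|\gamma|$ — the between-class difference in mean within-sample rank
   difference — then lexicographic ids, a fully deterministic order);
4. trains a k-TSP majority-vote classifier on that list and evaluates it
   on the held-out 20%.

The pairs of each run's classifier are counted; a pair's **repetition
rate** is count / `n_runs`, and pairs with rate strictly above 0.1 form
the top-ranked panel. Counting the full stage-3 candidate list instead is
available as `count_mode = "final_pairs"`; it recovers planted signal
too, but in our experiments it also promotes moderately-scored background
pairs that recur for free in every candidate list, so the classifier-pair
count is the default.

### Choosing k, and why ties go to the largest panel

Within each run, odd panel sizes $k \in \{1, 3, 5, 7, 9\}$ are compared
by apparent (training-data) balanced accuracy. When several sizes tie —
which happens systematically once pairs are strong, because a 3-pair
majority vote already classifies the training data perfectly — the tie
goes to the **largest** k. The classifier built in each run is not an end
in itself: its pair set is the stability-selection counting statistic.
A minimal-k rule freezes the count at the same two or three pairs every
run and starves equally-supported pairs of counts (we observed recovery
of only 5 of 7 planted pairs under a smallest-k rule, with the selected
k stuck at 3 in 83% of runs); among training-equivalent panels the
largest harvests the most evidence per run, and its majority vote also
has the lowest held-out variance. With this rule all planted pairs of
the reference cohort are counted in essentially every run.

Per-run seeds are derived from the master seed by run index (a fixed
draw of child seeds), so runs are individually reproducible and the
count multiset is invariant to run order.

## The TRGP classifier

The top-ranked gene-pair classifier over the first $N$ panel pairs gives
each pair the vote $p_{ij} = +1$ if $x_i > x_j$ and $-1$ otherwise
(a tie votes $-1$, the image of the indicator's 0 branch), and scores

$$s(x) = \frac{1}{N}\sum p_{ij} \in \Big\{\frac{2v - N}{N} : v = 0..N\Big\},$$

predicting KD exactly when $s(x) > 0$; a score of exactly 0 (possible
for even $N$) is called FI, keeping the rule strict. The panel size is
chosen by sweeping $N = 1..60$ on the evaluation cohort and taking the
smallest $N$ attaining the maximum balanced accuracy, with AUROC as
secondary tie-break — one defensible formalization of "best balanced
accuracy and AUROC"; parsimony favors the smallest panel because every
extra pair costs two qRT-PCR assays in a clinical follow-up.

## Permutation null

`shuffle_dataset()` permutes each gene row's values across samples
independently and then permutes the gene-id-to-row assignment, leaving
labels untouched: all gene–class association is destroyed while every
row's value multiset survives. (A pooled whole-matrix shuffle is offered
as an option; the default per-gene mode is the stricter null because it
also preserves per-row marginals.) `permutation_study()` contrasts
matched numbers of real and shuffled discovery runs, recording per run
the *top* (maximum) pair score of the final candidate list, the selected
k, and train/test AUROC; a two-sample Kolmogorov–Smirnov test compares
the real and null top-score samples. The top score per run is the
summary compared because it is the quantity a practitioner would read
off a discovery run; on the reference cohort real top scores sit near
0.95 against a null near 0.34, and null held-out AUROC hovers around
0.5 while real held-out AUROC stays near 1.

## Evaluation stack

Confusion metrics follow the usual conventions (sensitivity = KD recall,
specificity = FI recall, balanced accuracy their mean; precision is
reported as missing when no KD is called). AUROC is the Mann–Whitney
statistic (ties count ½), cross-checked in the tests against brute-force
pair counting; its 95% CI uses the DeLong variance (via pROC), collapsing
to the point estimate with a warning flag when the score distribution is
degenerate. Sensitivity/specificity/accuracy CIs use a 2,000-draw
stratified percentile bootstrap (seeded; resamples where a metric is
undefined are redrawn with a capped attempt count) — the CI method for
these quantities is a package choice, documented rather than asserted as
anyone else's. A coverage simulation in the tests shows ~93–95% empirical
coverage at 60 samples per class.

The LDA / linear-SVM / random-forest comparison harness trains each
family on the binary pair-indicator matrix (so all of them inherit rank
invariance), with stratified 10-fold CV over prefix sizes of a per-fold
importance ranking: absolute discriminant coefficients (LDA), absolute
linear weights (SVM), Gini importance (random forest). The family fits
delegate to MASS, e1071 and randomForest; the bespoke content is the
feature construction and the selection protocol.

## The synthetic cohort generator

`generate_cohort()` is the ground-truth test bed standing in for the
multi-cohort GEO data the method was designed for. Background genes are
class-independent Gaussians with gene-specific means
(`baseline_mean = 8`, `baseline_sd = 1`, a typical log2-intensity
regime), so any background pair has identical indicator probability in
both classes and population score 0. A planted pair draws its order
indicator Bernoulli($p_c$) per class and *enforces* it with an explicit
expression gap (default 1) on a shared baseline draw — ordering
probabilities are therefore exact by construction, not approximate via
mean shifts, and the planted population score is analytic:
$|p_{KD} - (n_{DB} p_{DB} + n_{DV} p_{DV})/(n_{DB}+n_{DV})|$. Ties never
occur (continuous baselines plus a positive gap); the tie rule is
exercised by separate hand-built fixtures. DB and DV get independent
flip probabilities so the two-branch restricted-pair stage is genuinely
exercised.

The reference conditions (`standard_cohort()`): 60 KD / 40 DB / 60 DV
samples, 200 genes of which 7 pairs are planted with flip probability
0.95 in KD and 0.05 in both infection subclasses. Tests and the
acceptance script run discovery at 200 resampling runs and the
permutation study at 50+50 runs — sizes at which every stage's behavior
is already unambiguous on this cohort — while the defaults expose the
full-scale settings (`n_runs = 10000`).

What the generator does *not* emulate: probe-level noise, saturation,
batch chemistry, class-correlated background structure, age or ethnicity
heterogeneity between cohorts, or label noise. Passing tests on this
cohort show the machinery is correct and the pipeline recovers planted
relative-ordering signal against an exchangeable background; they do not
show that real KD/FI cohorts contain such signal, nor how the panel
degrades under cohort heterogeneity.

## Interfaces and degenerate inputs

The package exposes the workflow as composable R functions returning
tibbles (with `tidy()`/`glance()`/`autoplot()` methods) rather than as a
shell tool; datasets travel as plain TSV (gene-keyed matrix + labels),
models as small JSON documents. Degenerate inputs fail loudly and early:
empty classes, unknown genes, classes that a split would empty, an empty
probe-collapsing result, single-class ROC input. Probe collapsing breaks
mean-intensity ties toward the lexicographically smallest probe id;
probe means are taken over all samples pooled (the source pipeline does
not restrict them to a class). Gene identifiers are opaque,
case-sensitive strings — no symbol aliasing is attempted.

## Known limitations

- Pair enumeration is restricted to the Wilcoxon-prefiltered gene set
  (default 100 genes, 4,950 pairs per comparison); exhaustive enumeration
  over ~16,000 genes is out of scope by design.
- The per-run k-selection rule (apparent balanced accuracy, largest k on
  ties) is one defensible choice among several the underlying method
  family admits; repetition rates of borderline pairs can shift under
  alternatives, which is why the counting mode is configurable.
- Repetition rates just above the 0.1 cutoff are cohort-realization
  dependent; on some reference-cohort draws a few background pairs graze
  0.10–0.13 while planted pairs sit at 1.0. The panel-size sweep is the
  second line of defense and reliably truncates to the planted prefix.
- DeLong CIs assume non-degenerate score distributions; heavily tied
  vote scores at tiny N can trip the degenerate path.
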