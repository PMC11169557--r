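---
title: "Methods: scaffold diversity, few-shot bioactivity models, and the model-selection zones"
author: "goldilocks package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scaffold diversity, few-shot bioactivity models, and the model-selection zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures the package implements,
the parameters that matter, the numerical conventions, and the design
choices that were genuinely open. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The problem

Given a single-target bioactivity dataset (SMILES plus potencies), which
model family should you train? Three families occupy different niches:

* **Few-shot prototypical classifiers (FSLC)** — shine when a task offers
  only a handful of labelled molecules, because the embedding is
  meta-learned across many related tasks and each new task only has to
  supply a support set.
* **Pre-trained transformers** — transfer general chemical knowledge and
  are insensitive to per-task dataset size; they pay off on mid-sized,
  structurally diverse sets.
* **Classical fingerprint models (SVC/SVR and kin)** — once data is
  plentiful, a task-specific kernel model beats both.

The package quantifies the two dataset covariates this decision turns on —
size and scaffold diversity — and provides the rule heuristic plus a
learned tree-sums selector mapping `(n, div)` to a family. The zone
boundaries are n < 50 (few-shot), 50–240 (transformer when diverse), and
n > 240 (classical).

## Scaffold diversity: CSFP and `div`

Every molecule is reduced to its Bemis–Murcko scaffold (ring systems plus
linkers; acyclic substituents removed). Scaffolds are sorted from most to
least frequent and the cumulative scaffold frequency plot (CSFP) records,
for the top fraction *x* of scaffolds, the fraction *y* of molecules they
cover. The diversity score is

$$\mathrm{div} = 2\,(1 - \mathrm{AUC}),$$

where AUC is the area under the CSFP.

**Step convention.** The AUC is computed with the upper-step rectangle rule
$\mathrm{AUC} = \sum_i y_i (x_i - x_{i-1})$, $x_0 = 0$: the curve jumps to
its level at the left edge of each scaffold's interval. This is the only
rectangle convention that reproduces both limiting anchors exactly: a
single-scaffold dataset covers the whole unit square (AUC = 1, div = 0),
and an all-unique dataset follows the diagonal from above
(AUC = (n+1)/2n, div = (n−1)/n → 1). A trapezoid rule cannot give div = 0
for one scaffold.

Two conventions worth knowing:

* **Acyclic molecules** share the single empty scaffold `""`. Treating
  each acyclic molecule as its own scaffold would inflate diversity;
  the shared-class reading matches what standard toolkits return.
* **Finite samples** are reported as-is: the all-unique value is
  (n−1)/n, not rescaled to 1. "Perfect diversity = 1" is the large-n
  limit.
* **Ties** between equally frequent scaffolds are ordered
  lexicographically purely so the curve is reproducible; the AUC is
  invariant to tie order.

A subtlety the test suite documents: *merging two arbitrary scaffold
classes can raise div* (merging counts {3,1} inside {4,3,1} yields the
more even {4,4}, and evenness is diversity). The monotone statement that
does hold, and is property-tested, is that merging the two most frequent
classes never increases div.

## Structure handling

SMILES parsing, canonicalization, InChIKeys, ECFP-style circular
fingerprints and MACCS keys are delegated to the OpenBabel toolchain
(ChemmineR/ChemmineOB in-process; fingerprints through the `obabel`
executable, whose per-call process boundary keeps long episodic runs at
constant memory). Circular fingerprints come as 4096-bit vectors and are
folded to the requested length by OR-ing halves. The Bemis–Murcko
scaffold is computed in the package: framework atoms are the 2-core of
the heavy-atom graph (iterated pruning of degree-1 atoms leaves exactly
the rings plus inter-ring linkers), plus atoms attached to that core by a
bond of order ≥ 2 — this retains exocyclic carbonyl-type atoms, matching
the convention of the common cheminformatics toolkits. Formal charges on
framework atoms are not preserved through scaffold extraction; for the
drug-like, salt-stripped inputs the curation layer produces this does not
arise.

Curation follows the standard ChEMBL-style pipeline: potencies are
converted to −log[M] (100 nM ↔ 7.0), duplicates are averaged by InChIKey
*after* unit conversion (the mean is taken on the log scale), activities
are binarized with the inclusive convention "potency ≤ threshold
concentration is active" (−log[M] ≥ 7 at 100 nM), and datasets failing
"at least 20 records" / "at least 20 per class" minima are dropped.
Splits floor each fraction target and give the remainder to the largest
fraction, so 70/5/25 on n = 100 is exactly 70/5/25.

## The synthetic-data generator

The generator is the package's study environment: chemically valid
datasets whose scaffold diversity is controlled *exactly* and whose
activity labels follow a planted, recoverable rule.

* **Scaffold library** — a deterministic enumeration of ring systems and
  linked ring pairs (6 linkers × ~20 rings), canonicalized, checked to be
  fixed points of the scaffold extractor, and checked to accept
  substituents; benzene is always first. Capacity exceeds 500.
* **Decoration** — each molecule is a library scaffold with an acyclic
  substituent prefixed at a ring position: one of 12 functional heads
  (methyl … carboxamide) times a linear alkyl spacer. Because every
  substituent is acyclic, the Murcko scaffold of each product equals its
  source scaffold, so the realized CSFP diversity equals the closed-form
  diversity of the requested count vector — a round-trip the tests check
  to machine precision.
* **Label rules** — `substructure` (default): active iff the substituent
  head belongs to a planted set of polar heads, so the signal is visible
  to any fingerprint model; `scaffold`: active iff the scaffold belongs
  to a planted subset — the right rule for studying generalization across
  scaffolds (a model that has never seen a scaffold cannot label it);
  `latent`: a thresholded linear score over substituent and scaffold
  features. Labels are then flipped independently with probability
  `noise_rate`.
* **Activities** — actives sit near 7.5 (≈30 nM) and inactives near 5.5
  (≈3 µM) with σ = 0.3 log-unit Gaussian noise, clipped to [3, 10]
  −log[M]; a plausible potency geometry for curated single-target sets.
* **Task families** — tasks share the grammar and scaffold library (a
  shared embedding space, as with a kinase family) but each task plants
  its own rule (a random half of the substituent heads), so labels
  transfer across tasks only through structure–activity signal.

What the generator deliberately does not emulate: real scaffold frequency
tails (unless `zipf_counts` is used), assay heterogeneity, activity
cliffs, or inter-task correlation of rules. Tests passing on this family
show the machinery is correct and that the qualitative zone structure
emerges; they do not certify effect sizes on real screening data.

## The few-shot classifier

The FSLC is a prototypical network over circular fingerprints (default
2048 bits, radius 5 — the radius is unusually large by classical QSAR
standards but is kept configurable):

1. **Embedding** `g'`: a two-layer rectified-linear network
   (2048 → 512 → 128 by default).
2. **Refinement** `g`: K = 3 iterations of a gated attention recurrence
   in the IterRefLSTM family. Per iteration, queries attend over the
   support set and the support attends over itself with scaled
   dot-product attention; each embedding is then updated as a
   sigmoid-gated convex combination of its current state and its
   attention read-out, with learned per-iteration gate vectors
   (initialized at logit 2, so refinement starts as a gentle
   perturbation). K = 0 recovers a plain prototypical network.
3. **Prototypes and classification**: class prototypes are the mean
   refined support embeddings; a query's class probability is the
   softmax of negative squared Euclidean distances to the prototypes.

**Training** is episodic: per episode a task is drawn, a support/query
split is sampled at one of the six standard compositions (10-10, 5-10,
1-10, 5-5, 1-5, 1-1 — cycled unless a single composition is requested),
and the query negative log-likelihood is minimized with Adam
(lr 10⁻³). All gradients, through the attention recurrence included, are
computed analytically and are verified against finite differences in the
test suite. Two numerical choices matter:

* **Gradient clipping** (global norm 5): one-support-active episodes have
  very high gradient variance and, unclipped, can destabilize
  mixed-composition training to the point of non-convergence.
* **Stopping**: the loss criterion (10⁻⁶) is applied to a 50-episode
  moving average rather than a single episode, because a lucky separable
  episode can hit any threshold; the episode cap (default 2000) is the
  practical stop on noisy families.

**Evaluation** resamples each test task (default 1000 episodes per task
and composition; the heavier acceptance experiment uses 200), scores the
query sets, averages each metric within a task and reports mean ± sd
across tasks — the layout used for few-shot benchmarking tables (ROC AUC,
average precision, F1, Cohen's κ, MCC).

**The SVC comparator.** The episodic SVC baseline is fit on each
episode's support set, works from the classical pipeline's own descriptor
(circular radius 3, 1024 bits), and by default scores queries by
*predicted class*. Hard-label scoring mirrors the reporting convention of
classification pipelines that compute all metrics from label predictions,
and it reproduces the characteristic micro-data failure: shown one active
and ten inactives, an SVC predicts (nearly) everything inactive and its
ROC AUC collapses to chance, while its continuous decision values would
still carry some ranking signal. The continuous variant is available
(`hard = FALSE`). Hyperparameters follow per-dataset tuning practice:
`episodic_svc_hypers()` selects C and γ for a task by support-only
cross-validated ROC AUC averaged over a batch of support draws, and the
choice is then held fixed during evaluation resampling; compositions too
small to fold (one support active) fall back to library defaults,
because there is nothing to tune on.

## Classical baselines

`nested_cv()` runs stratified outer folds (5 by default) with an inner
loop (5 folds) selecting hyperparameters by ROC AUC (classification) or
R² (regression). Defaults: radial-basis SVM with C ∈ {0.1, 1, 10, 100}
and γ ∈ {1/p, 0.01, 0.001}; kNN, random forest, and logistic regression
are available behind the same interface. For SVC, ranking metrics use the
decision values and reported probabilities come from a logistic
calibration fit on inner-fold decision values — calibration is fit
strictly inside the training side of each outer fold. Fingerprints
default to ECFP6-style (radius 3, 1024 bits). `import_external_scores()`
accepts per-molecule scores produced by any external model (for example a
fine-tuned transformer) and evaluates them with the same metrics;
transformer training itself is out of scope.

## The selector

`recommend_rule()` encodes the published-style heuristic: n < 50 → FSLC;
50 ≤ n ≤ 240 and div ≥ 0.5 → transformer; otherwise classical. The
boundaries are inclusive on the middle zone. The diversity cut for
"particularly diverse" mid-size datasets is not printed anywhere in the
source material; 0.5 is used because real single-target training sets
span roughly 0.52–0.74, and the parameter is exposed. The low-diversity
middle zone defaults to classical as the conservative choice.

`figs_fit()` is a greedy tree-sums (FIGS-family) meta-classifier: at most
`max_trees = 3` shallow trees grown greedily, where each step evaluates
every leaf of every tree — and the root of a potential new tree — for the
best squared-error split of the one-hot residuals (class indicators minus
the *other* trees' predictions), and commits the single best split
anywhere in the ensemble. Ties break toward the lowest feature index,
then the lowest threshold. Class probabilities are the softmax of the
summed leaf vectors; the one-vs-rest residual treatment with softmax
normalization is this package's multi-class reading, not a verbatim
reproduction of the original FIGS multi-class internals. With
`max_trees = 1` the procedure provably reduces to a single CART-style
tree (split choices are leaf-local, so greedy order does not matter); the
suite checks exact agreement with an independently written recursive
partitioner.

On grids labelled by the rule itself, the selector recovers the zones
with ≥ 95 % held-out accuracy and re-finds thresholds within ±20 % of 50
and 240 (`tests/testthat/test-acceptance.R`). The published selector's
real-data accuracy (trained on curated public kinase benchmarks) is not
reproducible offline and is out of the package's acceptance scope.

## Problem sizes used in the checks

The test suite and acceptance script run entirely on generated data at
sizes the package's own experiments use: tasks of 120 molecules over 24
scaffolds (noise 0.1) in families of 16 training and 14 test tasks; 1200
training episodes; 200 evaluation resamples per task and composition;
diversity property sweeps over 1000 random multisets; selector grids of
40 × 40 points. The zone-reproduction experiment checks that the FSLC
beats the episodic SVC by ≥ 0.05 mean ROC AUC at 1-10 shots (where the
hard-label SVC sits at chance) and that the gap closes below 0.05 at
10-10.

## Known limitations

* Scaffold extraction drops formal charges on framework atoms (rare in
  curated, salt-stripped input).
* The refinement recurrence is a faithful-in-contract but independent
  specification of the cited attention-refinement family; exact
  equations of the original are not reproduced.
* The generator's SAR is simpler than real screening data; effect sizes
  measured on it transfer qualitatively, not quantitatively.
* Training runs on a single CPU; the architecture is sized accordingly
  (1.2 M parameters).
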