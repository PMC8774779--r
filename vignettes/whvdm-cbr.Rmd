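---
title: "Case retrieval with a weighted heterogeneous value distance measure"
author: "cbrmatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case retrieval with a weighted heterogeneous value distance measure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbrmatch)
```

## The problem

Case-based reasoning supports a physician facing a new patient by
retrieving the most similar solved cases from a repository and presenting
their diagnoses, treatment plans and outcomes. Two things make this hard in
clinical data: the case attributes are *heterogeneous* — lab values are
continuous while stage, sex, or findings are discrete — and the attributes
are not equally *relevant*, so an unweighted distance lets irrelevant
fields drown the informative ones. `cbrmatch` addresses both with a
weighted heterogeneous value distance measure (WHVDM) and learns the
attribute weights from labeled cases with a genetic algorithm. Upstream of
retrieval, it builds the case base itself from semi-structured record text
and triages it by quality, readability and disease rarity.

## The distance

For cases t (target) and r (stored) sharing a schema of n attributes,

$$\mathrm{WHVDM}(t,r) = \sum_{i=1}^n w_i\, d_i^2(t,r), \qquad
  0 \le w_i \le 1,\ \ \sum_i w_i = 1 .$$

**Discrete attributes** use the value difference metric: two values are
close when they condition the class variable similarly. With
$p_v(a) = \Pr(y=a \mid x_i = v)$,

$$\mathrm{vdm}_i(t,r) = \sum_{a\in Y}\bigl(p_{x_{t,i}}(a)-p_{x_{r,i}}(a)\bigr)^2
  \cdot \sum_{a\in Y} p_{x_{t,i}}(a)^2 .$$

The trailing squared-probability factor is the package default
(`vdm_variant = "as_printed"`). It makes the component asymmetric in
(t, r) and is absent from the classic Stanfill–Waltz metric, so
`vdm_variant = "classic"` switches to the symmetric form
$\sum_a (\Delta p_a)^2$; both are exercised by the test suite. Identical
values are at distance 0 under either variant.

The conditional probabilities are estimated from the stored case base by
add-α counting,
$\hat p_v(a) = (\#\{x_i=v, y=a\} + \alpha)/(\#\{x_i=v\} + \alpha|Y|)$,
with α = 1 by default; a value never seen in the base degenerates to the
uniform distribution, which is also the α → ∞ limit. α = 0 reproduces raw
frequencies (used for the hand-enumerated oracle values in the tests).

**Continuous attributes** contribute the squared difference
$(x_{t,i}-x_{r,i})^2$ *after min–max normalization to [0, 1]* with
statistics taken from the reference base; target values outside the
training range are clipped. Without this the raw squared difference has
arbitrary units and dominates (or vanishes against) the VDM terms, whose
scale is bounded by the probability simplex. Constant attributes map to 0.

**Missing values** survive loading as an explicit sentinel and contribute
`missing_penalty` (default 1.0, the maximum possible normalized continuous
contribution) to $d_i^2$ whenever either side is missing: incomparability
is penalized rather than imputed or discarded.

Prediction is 1-NN — the class of $s(t)=\arg\min_r \mathrm{WHVDM}(t,r)$ —
because the weight-learning objective is defined through $s(t)$. Top-k
retrieval (`retrieve_top_k`) is presentation for the physician, not a
voting scheme; ties are broken by storage order, which makes every result
deterministic.

## Learning the weights

`learn_weights` maximizes the count of correctly predicted held-out cases
$\sum_{t\in T} I(y_t = y_{s(t)})$ over the weight simplex. Chromosomes are
non-negative gene vectors decoded by $w = g/\sum g$, so every individual is
feasible by construction and no repair step is needed. The defaults —
population 50, 100 generations, tournament selection of size 3, arithmetic
blend crossover at rate 0.9, additive Gaussian mutation (sd 0.05, rate 0.1)
clipped at zero, one elite — are conventional GA settings; the search stops
early when fitness is perfect, and elitism makes the best-so-far trace
monotone. The population is seeded from a flat Dirichlet plus one uniform
individual so the unweighted baseline is always in the gene pool. The
conditional-probability table and normalization map are computed from the
reference set only, never from T.

By default T is a stratified 30% holdout (leakage-safe); resubstitution is
possible by passing the reference set as T but inflates fitness. The
per-attribute component matrices between T and R are precomputed once, so
one fitness evaluation is a single matrix–vector product plus a row argmin;
this is what keeps a 50 × 100 GA run on a 400-case base in seconds.

**A caution on interpreting learned weights.** The influence of attribute i
on the metric is $w_i \times$ (typical magnitude of $d_i^2$), and those
magnitudes differ systematically: a well-separated discrete attribute's VDM
component can be several times larger than any normalized continuous
component. The fitness-optimal *nominal* weight on a dominant discrete
attribute is therefore small, and because the fitness count over a
~100-case holdout is nearly flat in the weights, the GA can also spend mass
exploiting holdout noise (selection bias). Consequently the learned weight
*mass* on truly informative attributes routinely stays well under what
their influence would suggest, even while GA-weighted accuracy clearly
beats uniform weights and the Euclidean baseline. The method-comparison
harness reports both the accuracies and the informative-attribute mass so
this effect is visible rather than hidden.

## Building the case base from text

The construction pipeline mirrors how semi-structured record text becomes
structured cases:

1. **Embedding** — characters (tokens) are looked up in a Z × d
   word-vector dictionary with an out-of-vocabulary fallback. The package
   ships a seeded random dictionary satisfying the lookup contract; a
   trained clinical dictionary drops in with the same shape.
2. **Segmentation fusion** — M classifiers each emit a per-character
   probability column over the BMES labels (Begin/Middle/End/Single).
   Columns are scaled by classifier weights, summed across the row, and
   the 4-vector is renormalized; the label is the argmax with ties broken
   in fixed B<M<E<S order. Fusion is invariant to scaling all weights by a
   positive constant, so fitted weights are reported with max 1.
3. **Decoding** — B…E runs and S singletons become words. Fused argmax
   sequences need not be well-formed, so malformed runs are repaired by
   opening a word at the first unopened character; the decoded words always
   concatenate back to the input exactly.
4. **Entity fusion** — per-word feature vectors (the column-normalized
   row-sums of the word's fused character vectors) go to N taggers emitting
   7-row probability columns over the clinical categories CL1–CL7 (patient
   information, time, disease, symptom, examination test, treatment plan,
   other); the same weight/sum/normalize/argmax procedure applies.
5. **Ensemble losses** — `Loss1` and `Loss2` are the mean fused probability
   mass missed on the gold segmentation and entity labels; the total
   `Loss = Loss1 + Loss2` is minimized over both weight sets by
   coordinate-wise scalar minimization on [0, 1] (round-robin
   `stats::optimize` passes until the improvement falls below 1e-6 or 50
   passes). The fused — not per-classifier — probability is used as the
   "true-label" probability, since that is the quantity the weights act on.
6. **Key data and merging** — named regular expressions capture numeric
   clinical indices (e.g. fasting blood glucose) in text order, and
   key data + tagged spans are merged per patient ID, last occurrence
   winning on duplicate index names (with a warning).

## Scoring and triage

`Score1 = 100·sigmoid(Σ aᵢxᵢ)` scores audit indices (x₁ knowledge
richness, x₂ curative effect / treatment time, …), `Score2` does the same
for readability indices (z₁ accuracy of wording, z₂ simplicity, …). The
×100 convention puts scores on the same 0–100 scale as the thresholds σ
and γ, which would otherwise be incomparable with a (0,1) sigmoid output.
The selection rule for well-known cases is applied to Score2 ≥ γ (reading
the alternative — re-thresholding Score1 — as a typographical slip, since
γ is introduced together with Score2). The index weights aᵢ, bᵢ are
configuration, not fitted: they encode institutional review policy. Two
reference audit-feature extractors ship as replaceable defaults: knowledge
richness as the fraction of the seven entity categories present, and a
key-data count. Rare-disease triage flags every case whose class relative
frequency is below ω ∈ (0, 1). Flags never remove cases; filtered bases
are flag subsets, so stage counts are monotone non-increasing.

Privacy masking (`mask_private_fields`) replaces identifier/text fields
with an irreversible token and provably cannot change retrieval, which
only reads attribute vectors and labels.

## Synthetic data: what it emulates and what it does not

The generators make every component testable without clinical data.

* `gen_case_base`: continuous informative attributes are class-shifted
  unit-variance Gaussians (shift = `separation`, default 2 — about a
  16% Bayes error for two classes on one attribute); discrete informative
  attributes put a class-linked majority mass on one of
  `disc_cardinality` values, interpolating from uniform at separation 0 to
  0.7 at the reference separation 2 so that separation is the single
  effect-size dial for both attribute kinds; noise attributes are
  class-independent. The default spec (400 cases, 2 classes, 1 + 1
  informative and 4 + 4 noise attributes) is the "standard noisy setting"
  used in the method comparison: it exercises both component formulas and
  is hard enough that unweighted distances visibly suffer. An optional
  planted label at a chosen frequency supports rare-triage tests.
* `gen_emr_corpus`: documents are sequences of category-tagged phrases of
  English tokens (tokens play the role of characters; the fusion math is
  script-agnostic). Simulated classifier columns put mass q on the gold
  row when uncorrupted and on a random wrong row otherwise, the remainder
  spread uniformly — so q = 1 recovers gold exactly and q = 1/k is exactly
  uniform, giving closed-form loss values (0.75 and 6/7) that the tests
  assert. Per-classifier fidelities enable the
  faithful-vs-noisy weight-fitting checks.
* `gen_rater_scores` interpolates between one shared ranking
  (agreement 1 → W = 1) and independent noise (agreement 0).

What passing these tests shows is that the machinery is correct under its
own assumptions: attribute independence given class, Gaussian/categorical
forms, uniform corruption, templated text. Real clinical data violate all
of these — correlated labs, non-stationary coding practice, segmentation
errors correlated across classifiers — so synthetic results bound
implementation correctness, not clinical performance.

## Numerical choices and degenerate inputs

* All argmax operations break ties by fixed row order (B<M<E<S,
  CL1<…<CL7) and retrieval by storage order: results are deterministic.
* Weight vectors are validated to the simplex within 1e-9; probability
  columns within 1e-9 of sum 1.
* Constant continuous attributes normalize to 0; an attribute with no
  observed values is an error rather than a guess.
* `k` larger than the base returns the whole base with a warning.
* Empty corpora flow through the pipeline to empty bases with zero counts.
* Kendall's W uses mean ranks for ties and the standard tie-corrected
  denominator $m^2(n^3-n) - m\sum_j T_j$; a constant rater without tie
  correction is an error (the uncorrected statistic is undefined there).
  The implementation is cross-checked against an independent one (vegan)
  to 1e-10 in the tests.

## Problem sizes

The shipped tests and the acceptance script run the method comparison at
400 cases × 10 attributes × 5 seeds with the default GA (50 × 100), the
metric oracles at 20–50 cases with exhaustive enumeration, triage at 1,000
cases, and fusion on corpora of 4–20 documents — sizes chosen so the whole
suite replays in about a minute while every code path, including the GA,
runs at its default settings.

## Known limitations

* The as-printed VDM variant is asymmetric; if a symmetric metric matters
  (e.g. for indexing structures), use the classic variant.
* 1-NN prediction has no probability calibration; the retrieval list, not
  a posterior, is the intended clinical artifact.
* Learned weights are relevance indicators only up to component scale (see
  the caution above); do not read them as feature importances.
* The GA fitness is evaluated on the same holdout used to select weights;
  for unbiased accuracy reporting, evaluate on a third split or fresh data.
* The text pipeline's classifiers/taggers are pluggable interfaces; the
  shipped ones are simulators and a seeded dictionary, not trained clinical
  models.
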