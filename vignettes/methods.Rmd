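---
title: "Models and methods behind dephos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dephos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dephos)
```

This vignette is the package's own account of its science: the statistical
model, the assumptions it rests on, the parameters that matter, what the
synthetic data generator does and does not emulate, and the design decisions
taken where the problem left genuine freedom.

## The prediction problem

Dephosphorylation is catalysed by protein phosphatases (PPs) acting on
phosphorylated serine, threonine or tyrosine residues. The prediction task
is binary classification at the residue level: given the sequence context of
an S/T/Y site, how likely is it to be a (phosphatase-specific)
dephosphorylation site? The central modelling assumption is that the local
flanking sequence carries the recognition signal — a 61-mer window (30
residues each side, `*`-padded past termini) is the unit of analysis.
Anything outside that window (3-D context, co-localization,
phosphorylation state dynamics) is invisible to the model, which is the
single biggest caveat on its predictions.

Serine and threonine sites are pooled into one residue class (`ST`) and
tyrosine sites form a second (`Y`); all models are trained per class,
reflecting the distinct enzymology of Ser/Thr- and Tyr-directed
phosphatases.

## The stacked ensemble

Each window is encoded ten ways (`list_encoders()`): a similarity score
against the known positive peptides computed with BLOSUM62 (the
nearest-exemplar feature, `GPS`), one-hot, k-spaced residue-pair
composition (`CKSAAP`, spacings 0–3), eight AAindex physicochemical
profiles, 10-bit overlapping-property flags, enhanced amino-acid composition
(window 5), BLOSUM row profiles, the five Sandberg z-scales, composition
descriptors over seven property splits (`CTDC`), and grouped composition
(`EGAAC`). The encoding alphabet has 21 symbols: the 20 amino acids plus one
shared slot for the unknown residue `X` and the terminal pad, which also
keeps the one-hot dimension at 61 × 21 and the transformer vocabulary at 21
(+ class token). The pad row and column of the substitution matrix are fixed
at zero so overhangs never contribute similarity.

Per feature, two base learners are trained: a feed-forward network (two
ReLU hidden layers of 128 and 32 units, dropout 0.3, Adam at 1e-3, batch
64) and a ridge logistic regression (glmnet, `alpha = 0`, unpenalized
intercept; sparse storage where the encoding is mostly zeros). Two compact
transformers consume the token stream directly: a bidirectional encoder
that classifies from a prepended class token with pad keys masked out of
attention, and a causal decoder that classifies from the final position.
Both use 2 layers, 4 heads and 32-dimensional embeddings with pre-norm RMS
normalization; the attention kernels are compiled (RcppArmadillo) and the
gradients are analytic, verified against numerical differentiation in the
test suite. The embedding width of 32 was chosen once so that the complete
22-model ensemble trains in about a minute per two thousand windows on one
CPU core; wider models are configurable through `tnn_config()`.

The 22 base probabilities form the stacking vector
`V = (D1..D10, P1..P10, B, G)` in the frozen registry order, and a logistic
meta-learner over V yields the final score. Two choices here depart from
the naive recipe, both standard stacking hygiene:

* the meta-learner is fitted on an internal stacking split (by default 25 %
  of the training rows that the base models never see), because in-sample
  base scores are overconfident exactly for the most overfit base models;
* its coefficients are constrained non-negative — every input is already a
  probability of the same event, and allowing sign flips only lets the
  ridge chase noise.

Score cutoffs (`high`/`medium`/`low`) are calibrated on training negatives
to false-positive rates of 2 %, 6 % and 10 %; the mapping is exposed in
`ensemble_config()`.

## The training cascade

Dephosphorylation only occurs at phosphosites, so training proceeds in
three steps:

1. **Pretrain** general phosphorylation ensembles per residue class
   (positives = known p-sites; negatives = all other same-class residues).
2. **Fine-tune to general dephosphorylation** in freeze-backbone mode: the
   pretrained base-model weights are left untouched; only the positive
   reference set of the similarity feature (with its z-scaler) and the
   meta-learner are refit on dephosphorylation data. A full-finetune mode
   that continues training the base weights is available via
   `train_plan(freeze_mode = "full-finetune")`.
3. **Phosphatase-specific predictors.** Site-specific PP–substrate records
   are clustered at three levels (group, family, individual enzyme), split
   by residue class, with distinct sites counted by (accession, position).
   Clusters with fewer than 3 distinct sites are excluded; 30 or more
   routes to transfer learning (per-iteration negative resampling at 1:10,
   k-fold cross-validation, best iterate kept, early stopping when the
   validation AUC stops improving); 3–29 routes to first-order
   meta-learning.

Negatives for dephosphorylation models are drawn from the same substrate
proteins as the positives. The default follows the broad reading (every
other same-class residue on those substrates); a stricter mode restricts
negatives to known phosphosites that are not dephosphorylation sites
(`negatives_from_psites = TRUE`), since dephosphorylation presupposes
phosphorylation. The two modes answer slightly different questions — "is
this residue a dephosphorylation site?" versus "given that it is
phosphorylated, is it removed by this enzyme?" — and the default favours
comparability with general site predictors.

## Few-shot meta-learning

For data-poor clusters, the neural components (the ten networks and two
transformers) are meta-trained across sibling clusters with first-order
MAML: each outer step samples tasks, adapts a copy of the initialization
for a few plain gradient-descent steps on the task's support split, and
applies the query-split gradient at the adapted parameters to the shared
initialization. The meta-update is a plain gradient step (default
`outer_lr = 0.02`, 10 outer steps); adaptive per-coordinate updates were
tried and rejected — they move flat coordinates as far as informative ones,
which at these weight scales destroys the pretrained networks. Second-order
MAML terms are not implemented; on these problem sizes the first-order
approximation is the standard choice.

After meta-training, the initialization is adapted on the target cluster's
support set and wrapped into a full ensemble: the similarity feature is
re-referenced on the support positives (its own closed-form "refit"), all
other scalers and the logistic base models stay frozen, and the
meta-learner is refit on the support stacking vectors. Freezing the
logistic base models in this route is a deliberate deviation from refitting
everything per task: ridge refits of 1200–1600-dimensional models on a
few-shot support yield stacking columns that are in-sample-perfect and
out-of-sample noise, and a meta-learner fit on them collapses. The
evaluation harness measures this route by leave-one-out over the cluster's
positives, each held-out positive scored against freshly resampled
negatives.

Two regimes of this comparison are worth knowing about, and the test suite
pins both. When the few-shot cluster's motif is strongly and cleanly
planted, the direct route (freeze-backbone fine-tune, i.e. re-referencing
the similarity feature on the support) is already near its ceiling — four
clean exemplars make an excellent nearest-exemplar classifier — and
meta-learning merely ties it. When the family signal is imperfect (the
generator's signal strength 0.7, so not every support exemplar carries the
motif), the exemplar-based route degrades sharply while the meta-trained
networks, which have seen the whole family across siblings, retain their
accuracy. The directional property test runs in the second regime; the
first is documented here rather than hidden.

## Evaluation machinery

AUC is computed in its Mann–Whitney form with the tie convention (ties
count one half); the ROC curve groups tied scores into single threshold
steps, and the identity between its trapezoidal area and the pairwise
statistic is asserted to 1e-12 across random score sets. Cross-validation
is stratified per class with fold sizes differing by at most one; the
headline number is the pooled AUC over concatenated held-out scores, with
per-fold AUCs also reported. For cross-validating the freeze-backbone
fine-tune, the nine static feature scores and the transformer scores do
not depend on the fold (those models are frozen), so they are computed
once; the similarity feature and the meta-learner are rebuilt inside every
fold so held-out scores stay leakage-free. The independent-test harness
refuses any overlap between held-out and training sites by (accession,
position). Cross-predictor specificity is summarized as a matrix whose
(i, j) entry is model i's AUC on model j's positives against model i's own
negatives; diagonal dominance is the operational definition of
phosphatase-specific recognition.

## Attribution and motif discovery

Shapley values are computed by exact coalition enumeration over the ±3
window positions around the site (128 coalitions; permutation sampling
takes over beyond 12 players), with absent positions filled in from
background windows. Local accuracy — attributions summing to the score
minus the background expectation — holds exactly for the enumerated case
and is asserted in the tests. The similarity feature's contribution is
attributed through the model like any other (the masked window is simply
rescored), not distributed by fiat.

For each block (upstream −3..−1, downstream +1..+3) and residue class, the
exact triplet of every positive site is tabulated: site frequency, mean
summed attribution, the correlation between the triplet's per-position
residue-frequency profile and the per-position mean-attribution profile
(with a pooled site-level correlation as a secondary column), and the
z-score of its mean attribution within the block. Both published filter
thresholds are strict inequalities: |PCC| > 0.2 and z > 0.15. A caution
the package wears openly: a three-point correlation is permissive, so the
selectivity of the combined filter comes largely from the attribution
z-score; the correlation filter mainly removes triplets whose profile
disagrees with the attribution profile.

Enrichment of curated motif patterns among passing triplets uses a
one-sided hypergeometric test with Benjamini–Hochberg correction. The
background is the set of distinct triplets observed at *all* candidate
sites, negatives included. A positives-only background is degenerate
whenever a motif saturates the positive set (nearly every positive triplet
carries it, so candidates cannot be enriched against themselves); the
all-sites background measures enrichment against the peptide space the
filters actually selected from. The pattern grammar supports literals,
`[..]` classes, the `x` wildcard and the `p[..]` site anchor; unanchored
patterns (docking motifs such as `RVxF`) are matched anywhere in the
window, and pads never match any token.

## The synthetic proteome generator

The generator emulates exactly the inputs the pipeline consumes: proteins
drawn from database-like amino-acid composition (not uniform, so
composition-sensitive encoders see realistic backgrounds), planted
phosphatase-specific sites whose motif is realised with a configurable
probability (`signal_strength`; 1 plants the motif at every site, 0 places
sites at random same-class residues), a hierarchical phosphatase taxonomy,
background phosphorylation at a configurable density, and the guarantee
that every dephosphorylation site is also a phosphosite. Anchored motifs
rewrite only the residues the pattern constrains; docking-style motifs are
written a few residues away from the site. The truth manifest records every
planted site.

What it does not emulate — and therefore what green tests do **not**
establish about real data: homologous substrate families and shared
evolutionary context, position-dependent composition around real
phosphosites (disorder bias), noisy or erroneous curation, mass-spec
detectability bias, and cooperative or overlapping motifs. Performance
numbers on synthetic cohorts characterise the machinery, not biological
accuracy.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately chosen desk
scales: the stacking benchmark uses ~2000 windows (180 planted sites at
signal 0.8 with 1:10 negatives) and the full ten-feature, 22-model
ensemble; cascade and motif properties use a reduced three-feature
configuration (`GPS`, one-hot, BLOSUM rows, no transformers) wherever the
property under test does not depend on the registry width. Feed-forward
epochs default to 10 (8 in the benchmark), transformer epochs to 6 (4 in
the benchmark). These are configuration defaults, not limits; all scale up
through `ensemble_config()`.

Other numerical decisions: ridge fits take a short geometric lambda path
down to the target penalty (cold-started coordinate descent at a single
small lambda on dense high-dimensional encodings converges poorly);
min-max feature scaling uses training-set statistics persisted with the
model, with the similarity score z-scaled instead (its scale depends on
the reference set size); degenerate variances anywhere (constant features,
zero attribution spread) fall back to zero rather than NaN; duplicate
windows are removed within each data split as redundancy control, and the
similarity score excludes identical windows from a query's own reference
(the leakage guard). All stochastic steps derive their streams from a
single integer seed, and RNG state is always restored, so any two runs with
the same seed are bit-identical.

## Known limitations

Sequence-window-only modelling; the exact identity of the nine selected
composition features in the original feature-selection sweep is not
public, so the registry here is a documented, configurable stand-in;
redundancy control is exact-window deduplication rather than
similarity-based clustering; the few-shot route keeps its logistic base
models frozen (see above); and the full-finetune mode restacks on
in-sample scores and should be used with data sizes that warrant it.
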