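# dephos

Protein phosphorylation is reversible: kinases attach phosphoryl groups and
protein phosphatases (PPs) remove them. While kinase-specific phosphorylation
site predictors are plentiful, predicting which sites a given *phosphatase*
dephosphorylates is much harder — experimentally verified site-specific
phosphatase–substrate relationships are scarce, and most phosphatases have
only a handful of known sites. `dephos` is an R implementation of a hybrid
learning framework for exactly this problem: predicting general and
phosphatase-specific dephosphorylation sites on S/T/Y residues of protein
sequences, built for researchers who study dephosphorylation signalling and
for methods developers who want a fully testable, simulation-backed
reference implementation.

## The model

Every candidate site is represented by its 61-mer peptide window (30
residues of flanking context on each side, `*`-padded at termini). Ten
sequence features encode each window — a substitution-matrix peptide
similarity score against the known positive peptides (the nearest-exemplar
"GPS" feature, BLOSUM62-based), one-hot, k-spaced residue-pair composition,
AAindex physicochemical profiles, 10-bit overlapping-property flags,
enhanced and grouped amino-acid composition, BLOSUM-row profiles, z-scales,
and composition descriptors. Each feature trains one feed-forward network
(D) and one ridge logistic model (P); two compact transformers — a
bidirectional encoder (B) and a causal decoder (G) — consume the raw token
stream. Their 22 probabilities form the stacking vector

    V = (D1, ..., D10, P1, ..., P10, B, G)

and a non-negative ridge logistic meta-learner over V produces the final
score. Training proceeds as a cascade: pretrain on general phosphorylation,
fine-tune to general dephosphorylation with the base models frozen, then
derive one predictor per phosphatase cluster (group / family / individual
enzyme) — by transfer learning when a cluster has ≥ 30 distinct sites, by
first-order model-agnostic meta-learning (MAML) over sibling clusters when
it has 3–29, skipping clusters below 3. Negatives are resampled at 1:10 per
iteration. Motif discovery runs Shapley-value attribution over the ±3
positions around predicted sites, filters triplets by |PCC| > 0.2 and
z-scored mean attribution > 0.15, and tests enrichment of curated
dephosphorylation motifs (e.g. `p[ST]P`, `LSPIxE`, `RVxF`) with a
hypergeometric test and Benjamini–Hochberg correction.

Because real curated site tables cannot ship with the package, a first-class
synthetic proteome generator plants configurable phosphatase-specific motifs
into background sequences; every pipeline stage is exercised and tested
against that generator's ground truth.

## Worked example

```r
library(dephos)

# simulate a proteome with two planted phosphatases and train the cascade
panel <- example_phosphatase_panel()[c(1, 4), ]   # p[ST]P and [ED]pY[ED]
panel$n_sites <- c(35L, 35L)
sim  <- generate_proteome(generator_spec(n_proteins = 40, phosphatases = panel, seed = 7))
cfg  <- ensemble_config(features = c("GPS", "onehot", "BLOSUMrow"), use_tnn = FALSE)
plan <- train_plan(iterations = 2, folds = 4, seed = 11)

pre <- pretrain_general(sim$proteins, sim$psites, config = cfg, plan = plan)
gen <- list()
for (rc in c("ST", "Y")) {
  sites <- unique(sim$sspsr[residue_class_of(sim$sspsr$residue) == rc,
                            c("accession", "position")])
  gen[[rc]] <- finetune_general_dephos(pre[[rc]], sim$proteins, sites, sim$psites, plan)
}
reg <- build_all_specific(gen, sim$sspsr, sim$taxonomy, sim$proteins, plan)
reg$manifest[, c("id", "route", "n_sites", "metric")]
#>                id    route n_sites    metric
#> 1 SerThr|group|ST transfer      35 0.8801633
#> 2     Tyr|group|Y transfer      35 0.9150757
#> 3  PPP1|family|ST transfer      35 0.8801633
#> 4   PTPN|family|Y transfer      35 0.9150757
#> 5  PP1A|single|ST transfer      35 0.8801633
#> 6   PTP1|single|Y transfer      35 0.9150757

head(predict_sites(sim$proteins[1:3, ], gen, reg, "medium", sim$sspsr), 3)
#>         ID Position Phosphatase Peptide     Score    Cutoff Source
#> 15 SYN0001       41     General SELYGTR 0.6440375 0.1414702   Pred
#> 19 SYN0001       41         Tyr SELYGTR 0.6440375 0.1414702   Pred
#> 23 SYN0001       41        PTPN SELYGTR 0.6440375 0.1414702   Pred
```

The `metric` column is each cluster model's pooled cross-validation AUC
(35 planted sites vs 1:10 resampled negatives, 4-fold). In the prediction
table, `Score` is the meta-learner probability, `Cutoff` the threshold
calibrated to the chosen false-positive rate on training negatives
(high/medium/low = 2 %/6 %/10 %), and `Source` is `Exp` when the site is in
the supplied experimental table.

A shell entry point wrapping the same functions is installed at
`inst/scripts/dephos` (`simulate`, `train`, `predict`, `evaluate`,
`motifs` subcommands).

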