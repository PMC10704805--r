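# pairppi

Stringent pair-input benchmarks and classifiers for protein-protein
interaction (PPI) prediction.

Sequence-based PPI prediction is a *pair-input* learning problem: every
example is a pair of proteins, and because each protein occurs in many
pairs, a naive random split leaks protein-level information from train to
test and inflates reported performance. `pairppi` implements the complete
workflow that guards against this:

* **Dataset construction** from curated interaction evidence: keep only
  evidence typed *direct interaction* or *physical association* with
  confidence (MIscore) ≥ 0.45; canonicalize unordered pairs; sample
  negatives at 1:10 by random pairing over a candidate pool purged of
  positive-set proteins and of their ≥ 40%-identity homologs, then
  redundancy-reduced at the same cutoff.
* **C1/C2/C3 partitioning** by held-out-protein membership (the
  Park-Marcotte scheme): C1 pairs have both proteins seen in training, C2
  exactly one, C3 none — C3 measures extrapolation to entirely novel
  proteins.
* **Symmetric pair encoding**: a pair is the Hadamard (elementwise)
  product of its two per-protein feature vectors, so prediction is
  order-invariant by construction. Feature sources plug in: amino-acid
  composition (20-dim), dipeptide composition (400-dim), or a loaded table
  of pre-computed protein-language-model embeddings (keyed TSV; a
  mean-pooling helper collapses per-residue matrices).
* **Classifier heads**: a 4-layer MLP (1024/512/128/16, ReLU, sigmoid
  output, binary cross-entropy, 40 epochs, Adam), a 100-tree random
  forest, and an RBF SVM (C = 1, variance-scaled gamma). A score ≥ 0.5 is
  called an interaction.
* **Imbalance-aware evaluation**: accuracy, specificity, precision,
  recall and MCC
  — MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)) —
  plus PR/ROC curves, AUPR (step-wise / average precision) and AUROC
  (trapezoidal). Under 1:10 imbalance the AUPR random floor is the
  prevalence, 1/11 ≈ 0.091.
* **A seeded synthetic interaction world** (latent bilinear ground truth,
  calibrated prevalence) so the whole pipeline is testable end-to-end
  without any download.

## Worked example

```r
library(pairppi)

# a synthetic world stands in for (interactome download + embedding extractor)
world <- synthetic_world(n_proteins = 120, n_positives = 100, seed = 3)
pairs <- sample_labeled_pairs(world, n_positives = 100, ratio = 12, seed = 3)

bench <- run_ppi_benchmark(pairs, world$embeddings, head = "mlp",
                           config = mlp_config(epochs = 10), seed = 5)
bench
#> Pair-input PPI benchmark run (head = mlp, seed = 5)
#>   C1: AUPR 0.8042 | AUROC 0.9626 (prevalence 0.0891)
#>   C2: AUPR 0.6694 | AUROC 0.9336 (prevalence 0.0909)
#>   C3: AUPR 0.5647 | AUROC 0.8516 (prevalence 0.0909)
```

Read: within-distribution pairs (C1) are easiest; pairs with one unseen
protein (C2) cost ~0.13 AUPR; pairs of two unseen proteins (C3) cost
another ~0.10 — the generalization gap that naive splits hide. All three
AUPRs sit far above the 0.091 random floor.

The evaluation suite also re-derives full confusion matrices from a
published recall/precision pair plus the test-set class sizes:

```r
counts <- reconstruct_confusion(0.589, 0.901, n_pos = 3404, n_neg = 34040)
classification_metrics(counts)
#> # A tibble: 1 × 6
#>   accuracy specificity precision recall   mcc     fpr
#>      <dbl>       <dbl>     <dbl>  <dbl> <dbl>   <dbl>
#> 1    0.957       0.994     0.901  0.589 0.708 0.00646
```

File-based entry points (`read_fasta()`, `read_evidence()`,
`filter_positives()`, `build_candidate_pool()`, `load_embeddings()`,
`write_split()`) cover the path from raw evidence files to benchmark
TSVs; `inst/scripts/pairppi-cli.R` wraps the same functions as a small
command-line tool (`simulate`, `split`, `train`, `predict`, `evaluate`).

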