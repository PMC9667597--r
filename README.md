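# ddiscl

Multi-type drug–drug interaction (DDI) prediction with supervised
contrastive learning, for computational pharmacologists and method
developers who need a tested, inspectable implementation of the
similarity-profile / attention-autoencoder / three-level-loss approach to
DDI type classification.

## What it does

Given per-drug binary descriptors (chemical substructures, targets,
enzymes, pathways) and a table of drug pairs labelled with one of C
interaction types, the package:

1. represents each drug by its **Jaccard similarity profile** — for each
   feature type, the vector of similarities
   `J(A,B) = |A∩B| / (|A|+|B|−|A∩B|)` to every drug in the dataset, blocks
   concatenated to a `T·n`-wide input;
2. encodes each drug with a **multi-head self-attention layer (residual)
   plus a two-layer autoencoder** (outputs DA1, DA2, DA3 at decreasing
   widths, and a reconstruction for the MSE term);
3. fuses a pair **across depths** — concatenations DA1+DB3, DA2+DB2,
   DA3+DB1 through per-scale fully connected layers — then reduces
   DA3, DB3, FD1–FD3 through attention and width-halving layers to the pair
   embedding **CFV**;
4. trains end-to-end under the **three-level loss**

   `Loss = l_MSE(x, x~) + l_con(CFV, y) + l_cla(y, y~)`

   where `l_con` is the supervised contrastive loss (cosine similarity,
   temperature τ = 0.05) pulling same-type pair embeddings together, and
   `l_cla` is label-smoothed cross-entropy (ε = 0.3) that switches to focal
   loss `−(1−p_t)^γ log p_t` (γ = 2) a third of the way through training;
5. evaluates under three 5-fold schemes — random over records (Task 1),
   cold-start with one (Task 2) or both (Task 3) drugs held out — with
   accuracy, micro AUPR/AUC, and macro F1/precision/recall.

A synthetic-data generator plants recoverable archetype-pair structure with
power-law class imbalance so the whole pipeline is verifiable without any
download. The forward/backward passes are hand-derived matrix code (no
deep-learning framework), pinned by finite-difference gradient checks in
the test suite. See `vignettes/ddiscl-methods.Rmd` for the full model
account and design decisions.

## Worked example

```r
library(ddiscl)

# benchmark-shaped synthetic data: ~57 drugs, 7 interaction types,
# 4 descriptor types, 5% label noise
cfg <- paper_shaped_preset("dataset1", scale = 0.1, seed = 1)
cfg$label_noise <- 0.05
syn  <- generate_synthetic(cfg)
prof <- build_similarity_profiles(syn$descriptors)
prof
#> <similarity_profile> 57 drugs x 228 (4 feature-type blocks:
#>  substructure, target, enzyme, pathway)

plan <- split_task1(syn$ddis, seed = 1)
fold <- plan$folds[[1]]
model <- ddi_train(prof, syn$ddis$records[fold$train, ],
                   toy_train_config(seed = 1),
                   toy_network_config(ncol(prof$matrix), syn$ddis$n_classes),
                   n_classes = syn$ddis$n_classes)

test <- syn$ddis$records[fold$test, ]
compute_metrics(test$label, ddi_predict(model, prof, test))
#> <metric_report> acc 0.9324  aupr 0.9083  auc 0.9621  f1 0.8822
#>  precision 0.9462  recall 0.8393

# how much of the planted signal was recovered (labels before noise)?
compute_metrics(syn$ground_truth$true_labels[fold$test],
                ddi_predict(model, prof, test))$f1
#> [1] 0.980998
```

The observed-label scores sit just under the 5% label-noise ceiling (a
perfect predictor scores ≈ 0.90 macro-F1 against noise-corrupted labels);
against the planted labels the model recovers the structure almost
perfectly. The embedding geometry the contrastive term is designed to
produce:

```r
g <- class_similarity_gap(pair_embeddings(model, prof, test), test$label)
round(unlist(g), 3)
#> intra inter   gap
#> 0.943 0.255 0.688
```

## Command line

```sh
Rscript inst/cli/ddiscl.R generate --preset dataset1 --scale 0.1 --seed 0 --out data/
Rscript inst/cli/ddiscl.R train    --descriptors data/ --ddis data/ddis.csv \
                                   --task 1 --fold 1 --toy --seed 0 --out runs/
Rscript inst/cli/ddiscl.R evaluate --descriptors data/ --ddis data/ddis.csv \
                                   --task 2 --toy --seed 0 --out runs/
Rscript inst/cli/ddiscl.R predict  --model runs/model_task1_fold1.json \
                                   --descriptors data/ --pairs pairs.csv --out preds.csv
```

Descriptors are one CSV per feature type (`drug_id` column plus binary
descriptor columns) or a single long-format CSV; DDI tables are
`drugA,drugB,label` CSVs. Upstream datasets shipped as SQLite databases can
be exported with `sqlite3 db.db ".mode csv" "SELECT ..."` into these forms.

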