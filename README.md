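# twincnn

Phenotypic drug response prediction on cancer cell line panels from
chemical structure and genomic profile. `twincnn` implements a twin
convolutional network: one 1D-CNN branch reads a drug as a one-hot
symbol-by-position grid built from its canonical SMILES string, a second
branch reads the cell line's binary genomic features (mutation states and
copy-number alterations), and a fully connected head regresses the
normalized IC50 of the pair. The package targets researchers studying
drug sensitivity screens in the style of the GDSC (Genomics of Drug
Sensitivity in Cancer) panel.

## The model

A drug's SMILES is tokenized (bracket atoms and two-letter halogens are
single symbols), one-hot encoded into an `n_symbols x max_len` binary
grid, left-aligned and space-padded. Each symbol row is one input
channel, so convolution slides along the molecule without mixing
chemical elements. Log-IC50 labels x are squashed into (0, 1) by

    y = 1 / (1 + exp(x)^(-0.1))

a strictly increasing logistic that the package can also invert to report
predictions on the log scale.

Both branches use the same stack — three layers of (convolution width 7,
stride 1; max pooling width 3, stride 3) with 40, 80, 60 channels and
length-preserving padding. An input of length 188 flattens to 420
dimensions and a 735-long feature vector to 1680; their concatenation
feeds three hidden layers of 1024 rectifier units with dropout 0.5 and a
logistic output. Training minimizes MSE with Adam and stops early when
validation RMSE has not improved for 10 epochs.

Around the model sits the full experimental harness: GDSC-style CSV
ingestion with the panel-cleansing rules, pair / drug-blind / cell-blind
/ tissue-blind split protocols with a leakage validator, R²/Pearson/RMSE
metrics with mean and top-quartile summaries over repetitions, encoding
perturbation studies (row shuffles, position rotations and shuffles),
feature-reduction and learning-curve experiments, and a seeded
synthetic-data generator with a planted structure–activity signal so the
whole pipeline runs without any external download.

## Worked example

Generate a synthetic screen, train the default architecture, and score
held-out pairs:

```r
library(twincnn)

syn   <- synthetic_interaction_table(synthetic_config(seed = 7))
tab   <- syn$table
print(tab)
#> <interaction_table> 60 drugs x 120 cells: 6101/7200 pairs known (84.7%),
#>   39.7% of known below max_conc

split <- pair_split(tab, fractions = c(0.8, 0.1, 0.1), seed = 7)
model <- build_model(length(syn$encoder$vocabulary$tokens),
                     syn$encoder$max_len, ncol(tab$cells$features),
                     seed = 7)
print(model)
#> <twin_cnn> drug branch 17ch x 40 -> 120 dims | cell branch 64 -> 180 dims |
#>   head 1024-1024-1024 | 2,525,849 parameters

fit   <- train_model(model, tab, split,
                     train_config(max_epochs = 5, learning_rate = 1e-3,
                                  seed = 7),
                     encoder = syn$encoder)
preds  <- predict(fit, split$test_pairs, tab, encoder = syn$encoder)
labels <- tab$values[cbind(match(split$test_pairs$drug_id, tab$drugs$drug_id),
                           match(split$test_pairs$cell_id, tab$cells$cell_id))]
evaluate_predictions(labels, preds)
#> <metrics_report> n=610  R2=0.9482  Rp=0.9817  RMSE=0.0151

head(denormalize_ic50(preds), 3)      # back on the natural-log IC50 scale
#> [1] -1.829990 -5.190204 -2.413146
```

After five epochs the network explains ~95% of the held-out variance of
the planted signal (R² 0.948, Pearson 0.982); RMSE is on the normalized
(0, 1) scale. `run_rediscovery()`, `run_predict_missing()`,
`run_perturbation()`, `run_feature_reduction()` and
`run_learning_curve()` wrap the repeated-evaluation experiments, and
`inst/cli/twincnn` exposes the same flows as shell subcommands
(`synthesize`, `summarize`, `split`, `experiment ...`).

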