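# Orchestration of the repeated-evaluation experiments. Every run_*
# function takes a loaded interaction table plus an encoder, derives one
# seed per repetition from the base seed (base + index - 1) so any single
# repetition can be re-run in isolation, and returns per-repetition
# metrics together with the mean / top-quartile summary.

fit_and_score <- function(table, split, encoder, drug_cfg, cell_cfg,
                          head_cfg, train_cfg, drug_onehot = NULL) {
  if (is.null(drug_onehot)) {
    drug_onehot <- encode_table_drugs(table, encoder)
  }
  model <- build_model(dim(drug_onehot)[1L], dim(drug_onehot)[2L],
                       ncol(table$cells$features),
                       drug_cfg, cell_cfg, head_cfg,
                       seed = train_cfg$seed)
  model <- train_model(model, table, split, train_cfg,
                       drug_onehot = drug_onehot)
  preds <- predict(model, split$test_pairs, table, drug_onehot = drug_onehot)
  labels <- table$values[cbind(match(split$test_pairs$drug_id,
                                     table$drugs$drug_id),
                               match(split$test_pairs$cell_id,
                                     table$cells$cell_id))]
  list(model = model, report = evaluate_predictions(labels, preds),
       predictions = preds, labels = labels)
}

rep_train_cfg <- function(train_cfg, seed) {
  train_cfg$seed <- as.integer(seed)
  train_cfg
}

env_fingerprint <- function() {
  list(r_version = R.version.string,
       platform = R.version$platform,
       package_version = as.character(utils::packageVersion("twincnn")))
}

write_run_outputs <- function(output_dir, config, reports, summary) {
  if (is.null(output_dir)) return(invisible(NULL))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  config$environment <- env_fingerprint()
  jsonlite::write_json(config, file.path(output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  utils::write.csv(reports_frame(reports),
                   file.path(output_dir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}

#' Rediscovery experiment: repeated pair-split evaluation
#'
#' Repeatedly splits the known pairs 80/10/10, trains a fresh model per
#' repetition (seed = `seed + repetition - 1`), and scores the held-out
#' pairs. This is the protocol under which the reference full-scale run
#' reaches mean R2 0.826 / Rp 0.909 over 50 repetitions on the GDSC
#' panel; shipped desk-scale profiles use fewer repetitions.
#'
#' @param table An [interaction_table()].
#' @param encoder An [encoder_config()] for the table's drugs.
#' @param repetitions Number of repetitions (default 5).
#' @param seed Base seed.
#' @param fractions Train/val/test fractions for [pair_split()].
#' @param drug_cfg,cell_cfg,head_cfg Architecture configurations.
#' @param train_cfg A [train_config()]; its seed is overridden per
#'   repetition.
#' @param output_dir Optional directory for config/metrics/summary files.
#' @return List with `reports` (one `metrics_report` per repetition),
#'   `metrics` (a `data.frame`), and `summary` (mean/top-quartile).
#' @export
run_rediscovery <- function(table, encoder, repetitions = 5L, seed = 1L,
                            fractions = c(0.8, 0.1, 0.1),
                            drug_cfg = branch_config(),
                            cell_cfg = branch_config(),
                            head_cfg = head_config(),
                            train_cfg = train_config(),
                            output_dir = NULL) {
  stopifnot(repetitions >= 1L)
  drug_onehot <- encode_table_drugs(table, encoder)
  reports <- vector("list", repetitions)
  for (i in seq_len(repetitions)) {
    rep_seed <- seed + i - 1L
    split <- pair_split(table, fractions, seed = rep_seed)
    fit <- fit_and_score(table, split, encoder, drug_cfg, cell_cfg,
                         head_cfg, rep_train_cfg(train_cfg, rep_seed),
                         drug_onehot = drug_onehot)
    reports[[i]] <- fit$report
  }
  summary <- summarize_repetitions(reports)
  write_run_outputs(output_dir,
                    list(experiment = "rediscovery", seed = seed,
                         repetitions = repetitions, fractions = fractions),
                    reports, summary)
  list(reports = reports, metrics = reports_frame(reports),
       summary = summary)
}

#' Blind-test experiment: repeated entity- or tissue-held-out evaluation
#'
#' Repeats an entity-blind (drug or cell) or tissue-blind evaluation,
#' resampling the held-out entities with a fresh seed per repetition
#' (seed = `seed + repetition - 1`), to probe generalization to drugs,
#' cell lines or tissues never seen in training. For the tissue protocol
#' each repetition holds out the same tissue and varies only the
#' train/validation shuffle.
#'
#' @inheritParams run_rediscovery
#' @param protocol `"drug_blind"`, `"cell_blind"` or `"tissue_blind"`.
#' @param n_test_entities Held-out entity count for the entity protocols
#'   (defaults to 10% of entities, rounded).
#' @param held_out_tissue Tissue name, required for `"tissue_blind"`.
#' @return As [run_rediscovery()].
#' @export
run_blind_test <- function(table, encoder,
                           protocol = c("drug_blind", "cell_blind",
                                        "tissue_blind"),
                           repetitions = 5L, seed = 1L,
                           n_test_entities = NULL, held_out_tissue = NULL,
                           drug_cfg = branch_config(),
                           cell_cfg = branch_config(),
                           head_cfg = head_config(),
                           train_cfg = train_config(),
                           output_dir = NULL) {
  protocol <- match.arg(protocol)
  drug_onehot <- encode_table_drugs(table, encoder)
  reports <- vector("list", repetitions)
  for (i in seq_len(repetitions)) {
    rep_seed <- seed + i - 1L
    split <- if (protocol == "tissue_blind") {
      if (is.null(held_out_tissue)) {
        stop("held_out_tissue is required for the tissue protocol")
      }
      tissue_blind_split(table, held_out_tissue, seed = rep_seed)
    } else {
      entity <- if (protocol == "drug_blind") "drug" else "cell"
      entity_blind_split(table, entity,
                         n_test_entities = n_test_entities,
                         test_fraction =
                           if (is.null(n_test_entities)) 0.1 else NULL,
                         seed = rep_seed)
    }
    validate_split(split, table)
    fit <- fit_and_score(table, split, encoder, drug_cfg, cell_cfg,
                         head_cfg, rep_train_cfg(train_cfg, rep_seed),
                         drug_onehot = drug_onehot)
    reports[[i]] <- fit$report
  }
  summary <- summarize_repetitions(reports)
  write_run_outputs(output_dir,
                    list(experiment = protocol, seed = seed,
                         repetitions = repetitions,
                         n_test_entities = n_test_entities,
                         held_out_tissue = held_out_tissue),
                    reports, summary)
  list(reports = reports, metrics = reports_frame(reports),
       summary = summary)
}

#' Predict the missing entries of an interaction table
#'
#' Trains on all known pairs (split 90/10 into training and validation),
#' then predicts every unmeasured (drug, cell) pair. Drugs are ranked by
#' the median of their predicted responses, and the number of missing
#' cell lines per drug is reported alongside — low-median drugs are the
#' candidates predicted most potent.
#'
#' @inheritParams run_rediscovery
#' @param val_fraction Fraction of known pairs used for validation.
#' @return List with `predictions` (per missing pair, including the
#'   denormalized log-IC50) and `per_drug` (median prediction, missing
#'   count, rank), or empty with a warning when nothing is missing.
#' @export
run_predict_missing <- function(table, encoder, seed = 1L,
                                val_fraction = 0.1,
                                drug_cfg = branch_config(),
                                cell_cfg = branch_config(),
                                head_cfg = head_config(),
                                train_cfg = train_config(),
                                output_dir = NULL) {
  missing_idx <- which(table$known == 0L, arr.ind = TRUE)
  if (nrow(missing_idx) == 0L) {
    warning("no missing pairs to predict")
    return(list(predictions = data.frame(), per_drug = data.frame()))
  }
  kp <- known_pairs(table)
  n <- nrow(kp)
  set.seed(seed)
  ord <- sample.int(n)
  n_val <- max(1L, floor(val_fraction * n))
  split <- new_split_spec(kp[ord[seq_len(n - n_val)], , drop = FALSE],
                          kp[ord[(n - n_val) + seq_len(n_val)], ,
                             drop = FALSE],
                          kp[0L, , drop = FALSE],
                          protocol = "pair", seed = seed,
                          params = list(val_fraction = val_fraction))
  drug_onehot <- encode_table_drugs(table, encoder)
  model <- build_model(dim(drug_onehot)[1L], dim(drug_onehot)[2L],
                       ncol(table$cells$features), drug_cfg, cell_cfg,
                       head_cfg, seed = seed)
  model <- train_model(model, table, split, rep_train_cfg(train_cfg, seed),
                       drug_onehot = drug_onehot)
  pairs <- data.frame(drug_id = table$drugs$drug_id[missing_idx[, 1L]],
                      cell_id = table$cells$cell_id[missing_idx[, 2L]],
                      stringsAsFactors = FALSE)
  preds <- predict(model, pairs, table, drug_onehot = drug_onehot)
  predictions <- cbind(pairs,
                       data.frame(pred = preds,
                                  pred_log_ic50 = denormalize_ic50(
                                    preds, table$alpha)))
  med <- tapply(predictions$pred, predictions$drug_id, stats::median)
  per_drug <- data.frame(drug_id = names(med),
                         median_pred = as.numeric(med),
                         n_missing_cells = as.integer(
                           table(predictions$drug_id)[names(med)]),
                         stringsAsFactors = FALSE)
  per_drug <- per_drug[order(per_drug$median_pred), , drop = FALSE]
  per_drug$rank <- seq_len(nrow(per_drug))
  rownames(per_drug) <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(predictions,
                     file.path(output_dir, "missing_predictions.csv"),
                     row.names = FALSE)
    utils::write.csv(per_drug, file.path(output_dir, "per_drug.csv"),
                     row.names = FALSE)
  }
  list(predictions = predictions, per_drug = per_drug, model = model)
}

#' Feature-count reduction experiment
#'
#' For each requested feature count k, subsamples k cell features
#' (seeded, without replacement), retrains on a pair split and records
#' the test metrics — tracing how performance degrades as the genomic
#' description of the cell lines is thinned.
#'
#' @inheritParams run_rediscovery
#' @param feature_counts Integer vector of feature counts to evaluate.
#' @return `data.frame` with one row per feature count and the test
#'   metrics.
#' @export
run_feature_reduction <- function(table, encoder, feature_counts,
                                  seed = 1L,
                                  drug_cfg = branch_config(),
                                  cell_cfg = branch_config(),
                                  head_cfg = head_config(),
                                  train_cfg = train_config(),
                                  output_dir = NULL) {
  nf <- ncol(table$cells$features)
  stopifnot(all(feature_counts >= 1L), all(feature_counts <= nf))
  rows <- vector("list", length(feature_counts))
  for (j in seq_along(feature_counts)) {
    k <- feature_counts[j]
    sub <- table
    if (k < nf) {
      set.seed(seed)
      keep <- sort(sample.int(nf, k))
      sub$cells$features <- table$cells$features[, keep, drop = FALSE]
    }
    split <- pair_split(sub, seed = seed)
    fit <- fit_and_score(sub, split, encoder, drug_cfg, cell_cfg,
                         head_cfg, rep_train_cfg(train_cfg, seed))
    rows[[j]] <- cbind(data.frame(n_features = k),
                       as.data.frame(fit$report))
  }
  curve <- do.call(rbind, rows)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(curve, file.path(output_dir, "feature_curve.csv"),
                     row.names = FALSE)
  }
  curve
}

#' Encoding perturbation experiment
#'
#' Applies one seeded perturbation to all drug one-hot encodings before
#' training and evaluation: shuffling the symbol rows, rotating the
#' position columns at a random cut, or shuffling the position columns.
#' Comparable scores across modes indicate the model exploits statistical
#' regularities of the encoding rather than its chemical reading.
#'
#' @inheritParams run_rediscovery
#' @param mode One of `"none"`, `"shuffle_rows"`, `"rotate_positions"`,
#'   `"shuffle_positions"`.
#' @return As [run_rediscovery()], plus the `mode` and perturbation
#'   parameters used.
#' @export
run_perturbation <- function(table, encoder,
                             mode = c("none", "shuffle_rows",
                                      "rotate_positions",
                                      "shuffle_positions"),
                             repetitions = 5L, seed = 1L,
                             fractions = c(0.8, 0.1, 0.1),
                             drug_cfg = branch_config(),
                             cell_cfg = branch_config(),
                             head_cfg = head_config(),
                             train_cfg = train_config(),
                             output_dir = NULL) {
  mode <- match.arg(mode)
  drug_onehot <- encode_table_drugs(table, encoder)
  set.seed(seed)
  pert <- switch(mode,
    none = list(),
    shuffle_rows = list(permutation = sample.int(dim(drug_onehot)[1L])),
    rotate_positions = list(cut = sample.int(dim(drug_onehot)[2L], 1L)),
    shuffle_positions = list(permutation = sample.int(dim(drug_onehot)[2L]))
  )
  drug_onehot <- switch(mode,
    none = drug_onehot,
    shuffle_rows = shuffle_symbol_rows(drug_onehot, pert$permutation),
    rotate_positions = rotate_positions(drug_onehot, pert$cut),
    shuffle_positions = shuffle_positions(drug_onehot, pert$permutation)
  )
  reports <- vector("list", repetitions)
  for (i in seq_len(repetitions)) {
    rep_seed <- seed + i - 1L
    split <- pair_split(table, fractions, seed = rep_seed)
    fit <- fit_and_score(table, split, encoder, drug_cfg, cell_cfg,
                         head_cfg, rep_train_cfg(train_cfg, rep_seed),
                         drug_onehot = drug_onehot)
    reports[[i]] <- fit$report
  }
  summary <- summarize_repetitions(reports)
  write_run_outputs(output_dir,
                    list(experiment = "perturbation", mode = mode,
                         seed = seed, repetitions = repetitions),
                    reports, summary)
  list(mode = mode, perturbation = pert, reports = reports,
       metrics = reports_frame(reports), summary = summary)
}

#' Learning-curve experiment
#'
#' Fixes one pair split, then for each training fraction subsamples the
#' training pairs (nested: smaller fractions are subsets of larger ones)
#' and retrains, recording test metrics per fraction. With
#' `include_max_conc = TRUE` the curve is traced a second time on the
#' table restricted to responses below the maximum screening
#' concentration, mirroring the comparison of all versus
#' experimentally-verified data.
#'
#' @inheritParams run_rediscovery
#' @param fractions_grid Numeric vector of training fractions in (0, 1].
#' @param include_max_conc Also trace the below-max_conc variant.
#' @return List of `data.frame` curves: `all`, and `max_conc` when
#'   requested.
#' @export
run_learning_curve <- function(table, encoder, fractions_grid = c(0.1, 0.5, 1),
                               seed = 1L, include_max_conc = FALSE,
                               drug_cfg = branch_config(),
                               cell_cfg = branch_config(),
                               head_cfg = head_config(),
                               train_cfg = train_config(),
                               output_dir = NULL) {
  stopifnot(all(fractions_grid > 0), all(fractions_grid <= 1))
  trace_one <- function(tab) {
    base <- pair_split(tab, seed = seed)
    rows <- lapply(fractions_grid, function(f) {
      split <- subsample_training(base, f, seed = seed)
      fit <- fit_and_score(tab, split, encoder, drug_cfg, cell_cfg,
                           head_cfg, rep_train_cfg(train_cfg, seed))
      cbind(data.frame(fraction = f,
                       n_train = nrow(split$train_pairs)),
            as.data.frame(fit$report))
    })
    do.call(rbind, rows)
  }
  out <- list(all = trace_one(table))
  if (include_max_conc) out$max_conc <- trace_one(max_conc_subset(table))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$all, file.path(output_dir, "learning_curve_all.csv"),
                     row.names = FALSE)
    if (include_max_conc) {
      utils::write.csv(out$max_conc,
                       file.path(output_dir, "learning_curve_max_conc.csv"),
                       row.names = FALSE)
    }
  }
  out
}
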