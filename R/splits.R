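new_split_spec <- function(train, val, test, protocol, seed, params = list()) {
  structure(list(train_pairs = train, val_pairs = val, test_pairs = test,
                 protocol = protocol, seed = seed, params = params),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> protocol=%s seed=%s  train=%d val=%d test=%d\n",
              x$protocol, format(x$seed), nrow(x$train_pairs),
              nrow(x$val_pairs), nrow(x$test_pairs)))
  invisible(x)
}

pair_key <- function(pairs) paste(pairs$drug_id, pairs$cell_id, sep = "\r")

#' Random pair-level split
#'
#' Shuffles the known (drug, cell) pairs with the given seed and
#' partitions them by the given fractions: validation and test sizes are
#' floored, the remainder goes to training. Drugs and cell lines may
#' appear on both sides — only the pairs are disjoint ("rediscovery"
#' protocol).
#'
#' @param table An [interaction_table()].
#' @param fractions Train/validation/test fractions summing to 1
#'   (default `c(0.8, 0.1, 0.1)`).
#' @param seed Integer seed.
#' @return A `split_spec`.
#' @export
pair_split <- function(table, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  kp <- known_pairs(table)
  n <- nrow(kp)
  n_val <- floor(fractions[2L] * n)
  n_test <- floor(fractions[3L] * n)
  n_train <- n - n_val - n_test
  if (n_train < 1L || n_val < 1L || n_test < 1L) {
    stop("configuration error: every partition must be non-empty")
  }
  set.seed(seed)
  ord <- sample.int(n)
  new_split_spec(kp[ord[seq_len(n_train)], , drop = FALSE],
                 kp[ord[n_train + seq_len(n_val)], , drop = FALSE],
                 kp[ord[n_train + n_val + seq_len(n_test)], , drop = FALSE],
                 protocol = "pair", seed = seed,
                 params = list(fractions = fractions))
}

#' Entity-blind split (drug-blind or cell-blind)
#'
#' Samples held-out entities whose every known pair goes to the test set;
#' the remaining pairs are split at the pair level into training and
#' validation. Held-out entities therefore never appear in training,
#' probing generalization to novel drugs (or cell lines). On the GDSC
#' panel the reference protocol holds out 23 of 223 drugs or 94 of 948
#' cell lines.
#'
#' @param table An [interaction_table()].
#' @param entity `"drug"` or `"cell"`.
#' @param n_test_entities Number of held-out entities. Exactly one of
#'   `n_test_entities` and `test_fraction` must be given.
#' @param test_fraction Alternative: fraction of entities to hold out
#'   (rounded to nearest).
#' @param inner_val_fraction Fraction of the remaining pairs used for
#'   validation (default 0.1).
#' @param seed Integer seed.
#' @return A `split_spec` with protocol `drug_blind` or `cell_blind`.
#' @export
entity_blind_split <- function(table, entity = c("drug", "cell"),
                               n_test_entities = NULL, test_fraction = NULL,
                               inner_val_fraction = 0.1, seed = 1L) {
  entity <- match.arg(entity)
  ids <- if (entity == "drug") table$drugs$drug_id else table$cells$cell_id
  if (is.null(n_test_entities)) {
    if (is.null(test_fraction)) {
      stop("give either n_test_entities or test_fraction")
    }
    n_test_entities <- round(test_fraction * length(ids))
  }
  n_test_entities <- as.integer(n_test_entities)
  if (n_test_entities < 1L || n_test_entities >= length(ids)) {
    stop(sprintf("n_test_entities must be in [1, %d)", length(ids)))
  }
  set.seed(seed)
  held <- sample(ids, n_test_entities)
  kp <- known_pairs(table)
  col <- if (entity == "drug") kp$drug_id else kp$cell_id
  in_test <- col %in% held
  test <- kp[in_test, , drop = FALSE]
  rest <- kp[!in_test, , drop = FALSE]
  n_rest <- nrow(rest)
  n_val <- floor(inner_val_fraction * n_rest)
  if (nrow(test) < 1L || n_val < 1L || n_rest - n_val < 1L) {
    stop("configuration error: every partition must be non-empty")
  }
  ord <- sample.int(n_rest)
  new_split_spec(rest[ord[seq_len(n_rest - n_val)], , drop = FALSE],
                 rest[ord[(n_rest - n_val) + seq_len(n_val)], , drop = FALSE],
                 test,
                 protocol = paste0(entity, "_blind"), seed = seed,
                 params = list(n_test_entities = n_test_entities,
                               held_out = held,
                               inner_val_fraction = inner_val_fraction))
}

#' Tissue-blind split
#'
#' Holds out every known pair whose cell line belongs to the given tissue
#' type; the remaining pairs are split into training and validation at
#' the pair level. Iterating over all tissue types yields a
#' leave-one-tissue-out evaluation.
#'
#' @param table An [interaction_table()].
#' @param held_out_tissue Tissue type present in the table.
#' @param inner_val_fraction Validation fraction of the remaining pairs.
#' @param seed Integer seed.
#' @return A `split_spec` with protocol `tissue_blind`.
#' @export
tissue_blind_split <- function(table, held_out_tissue,
                               inner_val_fraction = 0.1, seed = 1L) {
  tissues <- table$cells$tissue
  if (!held_out_tissue %in% tissues) {
    stop(sprintf("unknown tissue: %s", held_out_tissue))
  }
  held_cells <- table$cells$cell_id[tissues == held_out_tissue]
  kp <- known_pairs(table)
  in_test <- kp$cell_id %in% held_cells
  test <- kp[in_test, , drop = FALSE]
  rest <- kp[!in_test, , drop = FALSE]
  n_rest <- nrow(rest)
  n_val <- floor(inner_val_fraction * n_rest)
  if (nrow(test) < 1L || n_val < 1L || n_rest - n_val < 1L) {
    stop("configuration error: every partition must be non-empty")
  }
  set.seed(seed)
  ord <- sample.int(n_rest)
  new_split_spec(rest[ord[seq_len(n_rest - n_val)], , drop = FALSE],
                 rest[ord[(n_rest - n_val) + seq_len(n_val)], , drop = FALSE],
                 test,
                 protocol = "tissue_blind", seed = seed,
                 params = list(held_out_tissue = held_out_tissue,
                               inner_val_fraction = inner_val_fraction))
}

#' Subsample the training pairs of a split
#'
#' Reduces the training set to `round(fraction * n_train)` pairs by
#' seeded sampling without replacement; validation and test sets are
#' untouched. For a fixed seed the subsets are nested: the pairs kept at
#' a smaller fraction are a subset of those kept at any larger fraction,
#' which reduces variance along a learning curve.
#'
#' @param split A `split_spec`.
#' @param fraction Fraction in (0, 1].
#' @param seed Integer seed (defaults to the split's seed).
#' @return A `split_spec` with the reduced training set.
#' @export
subsample_training <- function(split, fraction, seed = split$seed) {
  stopifnot(inherits(split, "split_spec"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("'fraction' must be in (0, 1]")
  }
  if (fraction == 1) return(split)
  n <- nrow(split$train_pairs)
  n_keep <- round(fraction * n)
  if (n_keep < 1L) stop("resulting training set would be empty")
  set.seed(seed)
  ord <- sample.int(n)          # fixed per-seed ordering => nested subsets
  keep <- sort(ord[seq_len(n_keep)])
  split$train_pairs <- split$train_pairs[keep, , drop = FALSE]
  split$params$subsample_fraction <- fraction
  split
}

#' Validate a split against its table and protocol
#'
#' Checks that the three pair lists are pairwise disjoint, contain only
#' known pairs, and honor the protocol's leakage constraint (held-out
#' drugs, cells or tissues never occur in training or validation).
#' Raises an error naming the violated property; part of the public API
#' so leakage checks are available outside tests.
#'
#' @param split A `split_spec`.
#' @param table The [interaction_table()] the split was derived from.
#' @return `TRUE`, invisibly.
#' @export
validate_split <- function(split, table) {
  stopifnot(inherits(split, "split_spec"), inherits(table, "interaction_table"))
  ktr <- pair_key(split$train_pairs)
  kva <- pair_key(split$val_pairs)
  kte <- pair_key(split$test_pairs)
  if (anyDuplicated(c(ktr, kva, kte)) > 0L) {
    stop("split invalid: train/val/test pair lists are not disjoint")
  }
  kn <- pair_key(known_pairs(table))
  if (!all(c(ktr, kva, kte) %in% kn)) {
    stop("split invalid: split contains pairs not known in the table")
  }
  if (split$protocol %in% c("drug_blind", "cell_blind")) {
    col <- if (split$protocol == "drug_blind") "drug_id" else "cell_id"
    leak <- intersect(split$test_pairs[[col]],
                      c(split$train_pairs[[col]], split$val_pairs[[col]]))
    if (length(leak) > 0L) {
      stop(sprintf("split invalid: held-out %s leaked into train/val: %s",
                   col, paste(utils::head(leak, 5L), collapse = ", ")))
    }
  }
  if (split$protocol == "tissue_blind") {
    held <- split$params$held_out_tissue
    held_cells <- table$cells$cell_id[table$cells$tissue == held]
    leak <- intersect(held_cells,
                      c(split$train_pairs$cell_id, split$val_pairs$cell_id))
    if (length(leak) > 0L) {
      stop("split invalid: cells of the held-out tissue leaked into train/val")
    }
    if (!all(split$test_pairs$cell_id %in% held_cells)) {
      stop("split invalid: test set contains cells outside the held-out tissue")
    }
  }
  invisible(TRUE)
}

#' Serialize a split to JSON
#'
#' @param split A `split_spec`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_split_json <- function(split, path) {
  stopifnot(inherits(split, "split_spec"))
  jsonlite::write_json(
    list(protocol = split$protocol, seed = split$seed, params = split$params,
         train_pairs = split$train_pairs, val_pairs = split$val_pairs,
         test_pairs = split$test_pairs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a split written by [write_split_json()]
#'
#' @param path JSON file.
#' @return A `split_spec`.
#' @export
read_split_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_split_spec(as.data.frame(x$train_pairs), as.data.frame(x$val_pairs),
                 as.data.frame(x$test_pairs), x$protocol, x$seed,
                 as.list(x$params))
}
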