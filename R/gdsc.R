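# Rename file columns to the canonical schema. col_map is a named
# character vector: names are canonical column names, values the names
# used in the file.
apply_col_map <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  stopifnot(is.character(col_map), !is.null(names(col_map)))
  missing <- setdiff(unname(col_map), names(df))
  if (length(missing) > 0L) {
    stop(sprintf("schema error: mapped column(s) absent from file: %s",
                 paste(missing, collapse = ", ")))
  }
  names(df)[match(col_map, names(df))] <- names(col_map)
  df
}

#' Load and cleanse a drug list
#'
#' Reads a GDSC-style drug list (`drug_id,name`) and an offline
#' `drug_id -> canonical_smiles` mapping, removes duplicated drug ids
#' (keeping the first occurrence), drops drugs without a SMILES mapping
#' with a warning, and returns the records sorted by drug id. On the GDSC
#' export this reproduces the 265 -> 223 cleansing outcome given the
#' corresponding mapping file.
#'
#' @param path CSV with header columns `drug_id,name`.
#' @param smiles_map CSV with header columns `drug_id,canonical_smiles`.
#' @param col_map Optional named character vector renaming file columns
#'   to the canonical schema, e.g.
#'   `c(drug_id = "Drug ID", name = "Drug Name")` for a raw GDSC export.
#' @return `data.frame` with columns `drug_id`, `name`, `canonical_smiles`.
#' @export
load_drug_list <- function(path, smiles_map, col_map = NULL) {
  dl <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  dl <- apply_col_map(dl, col_map)
  req <- c("drug_id", "name")
  if (!all(req %in% names(dl))) {
    stop(sprintf("schema error: drug list must have columns %s",
                 paste(req, collapse = ", ")))
  }
  sm <- utils::read.csv(smiles_map, stringsAsFactors = FALSE)
  if (!all(c("drug_id", "canonical_smiles") %in% names(sm))) {
    stop("schema error: smiles map must have columns drug_id, canonical_smiles")
  }
  dl$drug_id <- as.character(dl$drug_id)
  sm$drug_id <- as.character(sm$drug_id)
  n_dup <- sum(duplicated(dl$drug_id))
  dl <- dl[!duplicated(dl$drug_id), , drop = FALSE]
  sm <- sm[!duplicated(sm$drug_id), , drop = FALSE]
  dl$canonical_smiles <- sm$canonical_smiles[match(dl$drug_id, sm$drug_id)]
  missing <- is.na(dl$canonical_smiles) | !nzchar(dl$canonical_smiles)
  if (any(missing)) {
    warning(sprintf("dropping %d drug(s) without a SMILES mapping: %s",
                    sum(missing),
                    paste(utils::head(dl$drug_id[missing], 10L),
                          collapse = ", ")))
    dl <- dl[!missing, , drop = FALSE]
  }
  if (nrow(dl) == 0L) stop("data error: no drugs left after cleansing")
  dl <- dl[order(dl$drug_id, method = "radix"), , drop = FALSE]
  rownames(dl) <- NULL
  attr(dl, "n_duplicates_removed") <- n_dup
  dl[, c("drug_id", "name", "canonical_smiles")]
}

#' Load and cleanse a cell-line feature table
#'
#' Reads binary genomic features (mutation states and copy-number
#' alterations) for a panel of cell lines, in either wide format
#' (`cell_id,tissue,<feature columns>`) or long format
#' (`cell_id,tissue,feature_name,value`); the dialect is autodetected from
#' the header. Cell lines with fewer than `required_features` defined
#' (non-missing) features are removed — the rule that trims the GDSC panel
#' from 990 to 948 lines at the full catalogue of 735 features.
#'
#' @param path Feature CSV.
#' @param required_features Minimum number of defined features a cell line
#'   must have to be retained. Defaults to the full catalogue size, i.e.
#'   only complete cell lines are kept.
#' @param feature_catalogue Optional character vector fixing the feature
#'   set and order; unknown feature names in the file raise a schema
#'   error. Defaults to the sorted feature names found in the file.
#' @param col_map Optional named character vector renaming file columns
#'   to the canonical schema (see [load_drug_list()]).
#' @return A `cell_line_set`: list with `cell_id`, `tissue` and a binary
#'   `features` matrix (cells x features).
#' @export
load_cell_lines <- function(path, required_features = NULL,
                            feature_catalogue = NULL, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df <- apply_col_map(df, col_map)
  if (!all(c("cell_id", "tissue") %in% names(df))) {
    stop("schema error: cell line table must have columns cell_id, tissue")
  }
  df$cell_id <- as.character(df$cell_id)
  if ("feature_name" %in% names(df)) {
    if (!"value" %in% names(df)) {
      stop("schema error: long format requires a 'value' column")
    }
    feats <- if (is.null(feature_catalogue)) {
      sort(unique(df$feature_name), method = "radix")
    } else feature_catalogue
    unknown <- setdiff(unique(df$feature_name), feats)
    if (length(unknown) > 0L) {
      stop(sprintf("schema error: unknown feature name(s): %s",
                   paste(utils::head(unknown, 5L), collapse = ", ")))
    }
    ids <- unique(df$cell_id)
    tissue <- df$tissue[match(ids, df$cell_id)]
    m <- matrix(NA_real_, nrow = length(ids), ncol = length(feats),
                dimnames = list(ids, feats))
    m[cbind(match(df$cell_id, ids), match(df$feature_name, feats))] <-
      df$value
  } else {
    featcols <- setdiff(names(df), c("cell_id", "tissue"))
    feats <- if (is.null(feature_catalogue)) {
      sort(featcols, method = "radix")
    } else feature_catalogue
    unknown <- setdiff(featcols, feats)
    if (length(unknown) > 0L) {
      stop(sprintf("schema error: unknown feature name(s): %s",
                   paste(utils::head(unknown, 5L), collapse = ", ")))
    }
    ids <- df$cell_id
    if (anyDuplicated(ids)) stop("data error: duplicated cell_id in wide table")
    tissue <- df$tissue
    m <- as.matrix(df[, intersect(feats, featcols), drop = FALSE])
    # columns absent from the file count as missing for every cell
    if (length(setdiff(feats, featcols)) > 0L) {
      extra <- matrix(NA_real_, nrow = nrow(m),
                      ncol = length(setdiff(feats, featcols)),
                      dimnames = list(NULL, setdiff(feats, featcols)))
      m <- cbind(m, extra)
    }
    m <- m[, feats, drop = FALSE]
    rownames(m) <- ids
  }
  if (is.null(required_features)) required_features <- length(feats)
  required_features <- as.integer(required_features)
  if (required_features < 1L) stop("'required_features' must be > 0")
  defined <- rowSums(!is.na(m))
  keep <- defined >= required_features   # strict "fewer than" removal rule
  ids <- ids[keep]
  tissue <- tissue[keep]
  m <- m[keep, , drop = FALSE]
  if (length(ids) == 0L) stop("data error: no cell lines left after cleansing")
  if (anyNA(m)) {
    warning("retained cell lines have missing feature values; setting to 0")
    m[is.na(m)] <- 0
  }
  if (!all(m %in% c(0, 1))) {
    stop("schema error: feature values must be binary (0/1)")
  }
  structure(list(cell_id = ids, tissue = tissue, features = m,
                 n_removed = sum(!keep)),
            class = "cell_line_set")
}

#' @export
print.cell_line_set <- function(x, ...) {
  cat(sprintf("<cell_line_set> %d cell lines x %d features, %d tissue type(s)\n",
              length(x$cell_id), ncol(x$features),
              length(unique(x$tissue))))
  invisible(x)
}

#' Normalize a log-IC50 value into (0, 1)
#'
#' GDSC stores IC50 as a natural-log value x; with y = exp(x) the map
#' y -> 1 / (1 + y^alpha) with alpha = -0.1 squashes the response into
#' (0, 1), i.e. a logistic in x with slope -alpha. The exponent -0.1
#' spreads typical IC50 magnitudes roughly uniformly over the interval.
#' The map is strictly increasing in x.
#'
#' @param x_log Numeric vector of natural-log IC50 values (finite).
#' @param alpha Exponent applied to y (default -0.1).
#' @return Values in (0, 1).
#' @examples
#' normalize_ic50(0)            # 0.5
#' normalize_ic50(log(1e-3))    # ~0.334
#' @export
normalize_ic50 <- function(x_log, alpha = -0.1) {
  if (!is.numeric(x_log) || any(!is.finite(x_log))) {
    stop("'x_log' must be finite numeric")
  }
  stats::plogis(-alpha * x_log)
}

#' Invert [normalize_ic50()]
#'
#' @param v Numeric vector strictly inside (0, 1).
#' @param alpha Exponent used during normalization.
#' @return Natural-log IC50 values.
#' @export
denormalize_ic50 <- function(v, alpha = -0.1) {
  if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0) || any(v >= 1)) {
    stop("domain error: 'v' must lie strictly in (0, 1)")
  }
  stats::qlogis(v) / (-alpha)
}

#' Construct an interaction table
#'
#' Low-level constructor assembling a drug x cell-line response matrix
#' with a missingness mask and a below-max_conc flag. Prefer
#' [build_interaction_table()] for loading from files.
#'
#' @param drugs Drug `data.frame` as from [load_drug_list()].
#' @param cells A `cell_line_set` as from [load_cell_lines()].
#' @param values Numeric matrix (drugs x cells) of normalized IC50; may be
#'   NA where unknown.
#' @param known Binary matrix, 1 where a response was measured.
#' @param below_max_conc Binary matrix, 1 where the response is below the
#'   maximum screening concentration (implies known).
#' @param alpha Normalization exponent recorded for later inversion.
#' @return An `interaction_table`.
#' @export
interaction_table <- function(drugs, cells, values, known, below_max_conc,
                              alpha = -0.1) {
  nd <- nrow(drugs); nc <- length(cells$cell_id)
  stopifnot(all(dim(values) == c(nd, nc)),
            all(dim(known) == c(nd, nc)),
            all(dim(below_max_conc) == c(nd, nc)))
  if (any(below_max_conc == 1 & known == 0)) {
    stop("below_max_conc flag set for an unknown pair")
  }
  defined <- values[known == 1]
  if (anyNA(defined) || any(defined <= 0) || any(defined >= 1)) {
    stop("known values must lie strictly in (0, 1)")
  }
  dimnames(values) <- dimnames(known) <- dimnames(below_max_conc) <-
    list(drugs$drug_id, cells$cell_id)
  structure(list(drugs = drugs, cells = cells, values = values,
                 known = known, below_max_conc = below_max_conc,
                 alpha = alpha),
            class = "interaction_table")
}

#' Build an interaction table from a long-format IC50 file
#'
#' Reads `drug_id,cell_id,log_ic50[,below_max_conc]`, discards rows that
#' reference drugs or cell lines dropped during cleansing, normalizes the
#' responses with [normalize_ic50()], and populates the known and
#' below-max_conc masks. Duplicate (drug, cell) rows are an error.
#'
#' @param drugs Output of [load_drug_list()].
#' @param cells Output of [load_cell_lines()].
#' @param ic50_path Long-format response CSV; `below_max_conc` defaults to
#'   1 when the column is absent.
#' @param alpha Normalization exponent (default -0.1).
#' @param col_map Optional named character vector renaming file columns
#'   to the canonical schema (see [load_drug_list()]).
#' @return An [interaction_table()].
#' @export
build_interaction_table <- function(drugs, cells, ic50_path, alpha = -0.1,
                                    col_map = NULL) {
  ic <- utils::read.csv(ic50_path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  ic <- apply_col_map(ic, col_map)
  req <- c("drug_id", "cell_id", "log_ic50")
  if (!all(req %in% names(ic))) {
    stop(sprintf("schema error: IC50 table must have columns %s",
                 paste(req, collapse = ", ")))
  }
  ic$drug_id <- as.character(ic$drug_id)
  ic$cell_id <- as.character(ic$cell_id)
  if (!"below_max_conc" %in% names(ic)) ic$below_max_conc <- 1L
  if (!all(ic$below_max_conc %in% c(0L, 1L))) {
    stop("schema error: below_max_conc must be 0/1")
  }
  dup <- duplicated(ic[, c("drug_id", "cell_id")])
  if (any(dup)) {
    first <- which(dup)[1L]
    stop(sprintf("data error: duplicate pair (%s, %s)",
                 ic$drug_id[first], ic$cell_id[first]))
  }
  keep <- ic$drug_id %in% drugs$drug_id & ic$cell_id %in% cells$cell_id
  ic <- ic[keep, , drop = FALSE]
  if (!is.numeric(ic$log_ic50) || any(!is.finite(ic$log_ic50))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(ic$log_ic50))))[1L]
    stop(sprintf("row error: unparseable log_ic50 for pair (%s, %s)",
                 ic$drug_id[bad], ic$cell_id[bad]))
  }
  nd <- nrow(drugs); nc <- length(cells$cell_id)
  values <- matrix(NA_real_, nd, nc)
  known <- matrix(0L, nd, nc)
  below <- matrix(0L, nd, nc)
  idx <- cbind(match(ic$drug_id, drugs$drug_id),
               match(ic$cell_id, cells$cell_id))
  values[idx] <- normalize_ic50(ic$log_ic50, alpha)
  known[idx] <- 1L
  below[idx] <- as.integer(ic$below_max_conc)
  interaction_table(drugs, cells, values, known, below, alpha)
}

#' Restrict an interaction table to responses below max_conc
#'
#' IC50 estimates above the maximum screening concentration are
#' extrapolated rather than experimentally verified; this subset keeps
#' only the verified responses by AND-ing the known mask with the
#' below-max_conc flag. Values are untouched.
#'
#' @param table An [interaction_table()].
#' @return An [interaction_table()] with the reduced known mask.
#' @export
max_conc_subset <- function(table) {
  stopifnot(inherits(table, "interaction_table"))
  if (is.null(table$below_max_conc)) {
    stop("configuration error: below_max_conc mask absent")
  }
  table$known <- table$known * table$below_max_conc
  table
}

#' Summarize an interaction table
#'
#' @param table An [interaction_table()].
#' @return List with drug/cell counts, total pair count, known-pair count
#'   and percentage, and below-max_conc count and percentage of known.
#' @export
interaction_summary <- function(table) {
  stopifnot(inherits(table, "interaction_table"))
  total <- length(table$known)
  n_known <- sum(table$known == 1L)
  n_below <- sum(table$below_max_conc == 1L & table$known == 1L)
  list(
    n_drugs = nrow(table$drugs),
    n_cells = length(table$cells$cell_id),
    total_pairs = total,
    n_known = n_known,
    pct_known = 100 * n_known / total,
    n_missing = total - n_known,
    n_below_max_conc = n_below,
    pct_below_max_conc = 100 * n_below / n_known
  )
}

#' @export
print.interaction_table <- function(x, ...) {
  s <- interaction_summary(x)
  cat(sprintf(paste0("<interaction_table> %d drugs x %d cells: ",
                     "%d/%d pairs known (%.1f%%), %.1f%% of known below max_conc\n"),
              s$n_drugs, s$n_cells, s$n_known, s$total_pairs,
              s$pct_known, s$pct_below_max_conc))
  invisible(x)
}

#' Known (drug, cell) pairs of a table
#'
#' @param table An [interaction_table()].
#' @return `data.frame` with `drug_id`, `cell_id` for every measured pair,
#'   in row-major table order.
#' @export
known_pairs <- function(table) {
  stopifnot(inherits(table, "interaction_table"))
  idx <- which(table$known == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(drug_id = table$drugs$drug_id[idx[, 1L]],
             cell_id = table$cells$cell_id[idx[, 2L]],
             stringsAsFactors = FALSE)
}

#' Serialize an interaction table to a directory
#'
#' Writes the drug list, cell lines, feature matrix, value matrix and
#' masks as CSV plus a JSON manifest with shapes, the normalization
#' exponent and per-file MD5 checksums. The write is deterministic: the
#' same table always produces byte-identical files.
#'
#' @param table An [interaction_table()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_interaction_table <- function(table, dir) {
  stopifnot(inherits(table, "interaction_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = TRUE)
  utils::write.csv(table$drugs, file.path(dir, "drugs.csv"), row.names = FALSE)
  utils::write.csv(data.frame(cell_id = table$cells$cell_id,
                              tissue = table$cells$tissue,
                              stringsAsFactors = FALSE),
                   file.path(dir, "cells.csv"), row.names = FALSE)
  wr(table$cells$features, "features.csv")
  wr(table$values, "values.csv")
  wr(table$known, "known.csv")
  wr(table$below_max_conc, "below_max_conc.csv")
  files <- c("drugs.csv", "cells.csv", "features.csv", "values.csv",
             "known.csv", "below_max_conc.csv")
  manifest <- list(
    n_drugs = nrow(table$drugs),
    n_cells = length(table$cells$cell_id),
    n_features = ncol(table$cells$features),
    n_known = sum(table$known == 1L),
    alpha = table$alpha,
    files = files,
    md5 = as.list(tools::md5sum(file.path(dir, files)))
  )
  names(manifest$md5) <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an interaction table written by [write_interaction_table()]
#'
#' Verifies the manifest checksums before loading.
#'
#' @param dir Directory produced by [write_interaction_table()].
#' @return An [interaction_table()].
#' @export
read_interaction_table <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  sums <- tools::md5sum(file.path(dir, manifest$files))
  names(sums) <- manifest$files
  bad <- manifest$files[unlist(manifest$md5[manifest$files]) != sums]
  if (length(bad) > 0L) {
    stop(sprintf("checksum mismatch for: %s", paste(bad, collapse = ", ")))
  }
  rd <- function(f, rn = TRUE) {
    x <- utils::read.csv(file.path(dir, f), check.names = FALSE,
                         row.names = if (rn) 1L else NULL)
    x
  }
  drugs <- utils::read.csv(file.path(dir, "drugs.csv"),
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  cellsdf <- utils::read.csv(file.path(dir, "cells.csv"),
                             stringsAsFactors = FALSE,
                             colClasses = "character")
  features <- as.matrix(rd("features.csv"))
  cells <- structure(list(cell_id = cellsdf$cell_id, tissue = cellsdf$tissue,
                          features = features, n_removed = 0L),
                     class = "cell_line_set")
  interaction_table(drugs, cells,
                    values = as.matrix(rd("values.csv")),
                    known = as.matrix(rd("known.csv")),
                    below_max_conc = as.matrix(rd("below_max_conc.csv")),
                    alpha = manifest$alpha)
}
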