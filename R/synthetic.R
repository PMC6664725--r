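default_token_alphabet <- function() {
  c("(", ")", "1", "2", "=", "#", "Br", "C", "Cl", "N", "O", "S",
    "c", "n", "[nH]", "[O-]")
}

default_motifs <- function() {
  list(c("N", "C", "=", "O"), c("Cl", "c", "1"), c("[nH]", "S"))
}

#' Configuration for the synthetic drug-response generator
#'
#' Describes a desk-scale corpus emulating a GDSC-style screen: random
#' SMILES-like token strings for drugs, random binary genomic feature
#' vectors for cell lines, and log-IC50 responses produced by a planted
#' structure-activity function. The deterministic part of the response is
#'
#' `baseline + sum_k motif_effects[k] * motif_k(drug)
#'  + sum_j feature_effects[j] * feature_j(cell)
#'  + interaction_strength * motif_1(drug) * feature_1(cell)`
#'
#' with Gaussian noise of standard deviation `noise_sd` added on the
#' natural-log IC50 scale before normalization. Motifs are short token
#' sequences planted into drug strings, so the signal is positional and
#' detectable by 1D convolution rather than by symbol composition alone.
#'
#' @param n_drugs,n_cells,n_features Corpus dimensions (default 60 drugs,
#'   120 cell lines, 64 binary features).
#' @param smiles_len_range Min/max token count of a drug string.
#' @param token_alphabet Tokens drug strings are drawn from; every token
#'   must round-trip through [tokenize_smiles()].
#' @param motifs List of token vectors planted as motifs.
#' @param motif_prob Probability that a given motif is planted in a drug.
#' @param motif_effects Per-motif additive effect on log-IC50.
#' @param feature_prob Bernoulli rate of the binary cell features.
#' @param feature_effects Per-feature additive effect; defaults to eight
#'   non-zero effects and zeros elsewhere.
#' @param interaction_strength Coefficient of the motif-1 x feature-1
#'   interaction term.
#' @param baseline Intercept of the response on the log scale.
#' @param noise_sd Gaussian noise standard deviation (log scale).
#' @param known_density Fraction of pairs with an observed response.
#' @param below_max_conc_prob Probability that an observed response is
#'   flagged as below the maximum screening concentration.
#' @param n_tissues Number of tissue labels assigned to cell lines.
#' @param seed Integer seed; the same configuration always generates
#'   byte-identical files.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(n_drugs = 60L, n_cells = 120L,
                             n_features = 64L,
                             smiles_len_range = c(20L, 40L),
                             token_alphabet = default_token_alphabet(),
                             motifs = default_motifs(),
                             motif_prob = 0.4,
                             motif_effects = c(-3, 2, -1.5),
                             feature_prob = 0.3,
                             feature_effects = NULL,
                             interaction_strength = 1,
                             baseline = 0,
                             noise_sd = 0.4,
                             known_density = 0.85,
                             below_max_conc_prob = 0.4,
                             n_tissues = 4L,
                             seed = 1L) {
  if (length(motifs) != length(motif_effects)) {
    stop("motifs and motif_effects must have equal length")
  }
  if (is.null(feature_effects)) {
    feature_effects <- numeric(n_features)
    nz <- min(8L, n_features)
    feature_effects[seq_len(nz)] <-
      c(2, -2, 1.5, -1.5, 1, -1, 0.5, -0.5)[seq_len(nz)]
  }
  if (length(feature_effects) != n_features) {
    stop("feature_effects must have length n_features")
  }
  if (known_density <= 0 || known_density > 1) {
    stop("known_density must be in (0, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  for (tok in token_alphabet) {
    if (!identical(tokenize_smiles(tok), tok)) {
      stop(sprintf("alphabet token %s does not tokenize to itself", tok))
    }
  }
  for (m in motifs) {
    if (!all(m %in% token_alphabet)) {
      stop("motifs must be composed of alphabet tokens")
    }
    if (length(m) > smiles_len_range[1L]) {
      stop("infeasible motif placement: motif longer than shortest drug")
    }
  }
  structure(list(n_drugs = as.integer(n_drugs),
                 n_cells = as.integer(n_cells),
                 n_features = as.integer(n_features),
                 smiles_len_range = as.integer(smiles_len_range),
                 token_alphabet = token_alphabet,
                 motifs = motifs, motif_prob = motif_prob,
                 motif_effects = motif_effects,
                 feature_prob = feature_prob,
                 feature_effects = feature_effects,
                 interaction_strength = interaction_strength,
                 baseline = baseline, noise_sd = noise_sd,
                 known_density = known_density,
                 below_max_conc_prob = below_max_conc_prob,
                 n_tissues = as.integer(n_tissues),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

motif_string <- function(m) paste(m, collapse = "")

motif_present <- function(config, smiles) {
  vapply(config$motifs,
         function(m) grepl(motif_string(m), smiles, fixed = TRUE),
         logical(1))
}

#' Noiseless response of the synthetic generative model
#'
#' Evaluates the deterministic part of the planted structure-activity
#' function for one drug (SMILES string) and one cell line (binary
#' feature vector). Motif presence is substring containment of the motif
#' token sequence — the same rule the generator uses — so the function
#' can score drugs whether or not a motif was explicitly planted.
#'
#' @param config A [synthetic_config()].
#' @param smiles Drug SMILES string.
#' @param features Binary feature vector of length `n_features`.
#' @return Noiseless log-IC50 value.
#' @export
ground_truth <- function(config, smiles, features) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(features) != config$n_features) {
    stop("unknown entity: feature vector length mismatch")
  }
  mp <- motif_present(config, smiles)
  as.numeric(config$baseline +
    sum(config$motif_effects * mp) +
    sum(config$feature_effects * features) +
    config$interaction_strength * mp[1L] * features[1L])
}

#' Generate a synthetic drug-response corpus
#'
#' Draws drugs, cell lines and responses under `config` and writes the
#' four CSV files consumed by the loading pipeline — `drug_list.csv`
#' (`drug_id,name`), `smiles_map.csv` (`drug_id,canonical_smiles`),
#' `cell_features.csv` (wide format) and `ic50.csv`
#' (`drug_id,cell_id,log_ic50,below_max_conc`) — plus `manifest.json`
#' recording the full configuration. Generation is seeded: the same
#' configuration produces byte-identical files.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if missing).
#' @return List with the file `paths`, the generated `drugs`, `cells`
#'   (feature matrix and tissues) and `ic50` data, invisibly usable
#'   in-memory.
#' @export
generate_synthetic <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nd <- config$n_drugs; nc <- config$n_cells; nf <- config$n_features

  drug_id <- sprintf("D%03d", seq_len(nd))
  lens <- sample(config$smiles_len_range[1L]:config$smiles_len_range[2L],
                 nd, replace = TRUE)
  planted <- matrix(stats::runif(nd * length(config$motifs)) <
                      config$motif_prob, nd, length(config$motifs))
  smiles <- character(nd)
  for (i in seq_len(nd)) {
    toks <- sample(config$token_alphabet, lens[i], replace = TRUE)
    for (k in seq_along(config$motifs)) {
      if (planted[i, k]) {
        m <- config$motifs[[k]]
        pos <- sample.int(lens[i] - length(m) + 1L, 1L)
        toks[pos:(pos + length(m) - 1L)] <- m
      }
    }
    smiles[i] <- paste(toks, collapse = "")
  }

  cell_id <- sprintf("CL%03d", seq_len(nc))
  tissue <- sample(paste0("tissue_", LETTERS[seq_len(config$n_tissues)]),
                   nc, replace = TRUE)
  feats <- matrix(as.integer(stats::runif(nc * nf) < config$feature_prob),
                  nc, nf, dimnames = list(cell_id,
                                          sprintf("feat_%03d", seq_len(nf))))

  mp <- matrix(unlist(lapply(smiles, function(s) motif_present(config, s))),
               nrow = nd, byrow = TRUE)
  gt <- config$baseline +
    matrix(as.vector(mp %*% config$motif_effects), nd, nc) +
    matrix(as.vector(feats %*% config$feature_effects), nd, nc,
           byrow = TRUE) +
    config$interaction_strength * (mp[, 1L] %o% unname(feats[, 1L]))
  x_log <- gt + matrix(stats::rnorm(nd * nc, sd = config$noise_sd), nd, nc)
  known <- matrix(stats::runif(nd * nc) < config$known_density, nd, nc)
  below <- matrix(stats::runif(nd * nc) < config$below_max_conc_prob,
                  nd, nc) & known

  idx <- which(known, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  ic50 <- data.frame(drug_id = drug_id[idx[, 1L]],
                     cell_id = cell_id[idx[, 2L]],
                     log_ic50 = x_log[idx],
                     below_max_conc = as.integer(below[idx]),
                     stringsAsFactors = FALSE)

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(drug_list = file.path(dir, "drug_list.csv"),
                smiles_map = file.path(dir, "smiles_map.csv"),
                cell_features = file.path(dir, "cell_features.csv"),
                ic50 = file.path(dir, "ic50.csv"),
                manifest = file.path(dir, "manifest.json"))
  utils::write.csv(data.frame(drug_id = drug_id, name = drug_id,
                              stringsAsFactors = FALSE),
                   paths$drug_list, row.names = FALSE)
  utils::write.csv(data.frame(drug_id = drug_id, canonical_smiles = smiles,
                              stringsAsFactors = FALSE),
                   paths$smiles_map, row.names = FALSE)
  utils::write.csv(cbind(data.frame(cell_id = cell_id, tissue = tissue,
                                    stringsAsFactors = FALSE),
                         as.data.frame(feats)),
                   paths$cell_features, row.names = FALSE)
  utils::write.csv(ic50, paths$ic50, row.names = FALSE)
  manifest <- unclass(config)
  manifest$motifs <- lapply(config$motifs, motif_string)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(paths = paths,
                 drugs = data.frame(drug_id = drug_id, name = drug_id,
                                    canonical_smiles = smiles,
                                    stringsAsFactors = FALSE),
                 tissue = tissue, features = feats, ic50 = ic50,
                 ground_truth = gt, config = config))
}

#' Generate a synthetic corpus and load it through the full pipeline
#'
#' Convenience wrapper: runs [generate_synthetic()], then feeds the files
#' through [load_drug_list()], [load_cell_lines()] and
#' [build_interaction_table()], and builds the matching
#' [encoder_config()] from the corpus vocabulary.
#'
#' @param config A [synthetic_config()].
#' @param dir Directory for the generated files (default: a fresh
#'   temporary directory).
#' @return List with `table` (an [interaction_table()]), `encoder`,
#'   `config` and the file `paths`.
#' @export
synthetic_interaction_table <- function(config = synthetic_config(),
                                        dir = tempfile("twincnn_syn_")) {
  gen <- generate_synthetic(config, dir)
  drugs <- load_drug_list(gen$paths$drug_list, gen$paths$smiles_map)
  cells <- load_cell_lines(gen$paths$cell_features)
  table <- build_interaction_table(drugs, cells, gen$paths$ic50)
  vocab <- build_vocabulary(drugs$canonical_smiles)
  max_len <- max(vapply(drugs$canonical_smiles,
                        function(s) length(tokenize_smiles(s)), integer(1)))
  list(table = table, encoder = encoder_config(vocab, max_len),
       config = config, paths = gen$paths)
}
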