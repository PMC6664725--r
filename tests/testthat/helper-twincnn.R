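# Shared desk-scale fixtures, built in code.

# Small planted-signal corpus exercising the whole pipeline quickly.
tiny_syn_config <- function(seed = 1L) {
  synthetic_config(n_drugs = 12L, n_cells = 18L, n_features = 16L,
                   smiles_len_range = c(8L, 14L), noise_sd = 0.3,
                   seed = seed)
}

tiny_branch <- function() {
  branch_config(conv_widths = c(3L, 3L), conv_strides = c(1L, 1L),
                channels = c(4L, 6L), pool_widths = c(2L, 2L),
                pool_strides = c(2L, 2L))
}

tiny_head <- function(dropout = 0.25) head_config(c(16L, 12L), dropout)

tiny_train <- function(seed = 1L, epochs = 3L, lr = 3e-3) {
  train_config(patience_epochs = 5L, max_epochs = epochs, batch_size = 32L,
               learning_rate = lr, seed = seed)
}

# Build an interaction table directly (no files) with seeded random
# responses; handy for split-protocol property tests.
toy_table <- function(n_drugs = 6L, n_cells = 8L, density = 1,
                      tissues = c("lung", "blood"), seed = 1L) {
  set.seed(seed)
  drugs <- data.frame(
    drug_id = sprintf("D%02d", seq_len(n_drugs)),
    name = sprintf("drug%02d", seq_len(n_drugs)),
    canonical_smiles = replicate(n_drugs, paste(
      sample(c("C", "N", "O", "="), 6, replace = TRUE), collapse = "")),
    stringsAsFactors = FALSE)
  feats <- matrix(rbinom(n_cells * 4L, 1L, 0.5), n_cells, 4L,
                  dimnames = list(sprintf("CL%02d", seq_len(n_cells)),
                                  sprintf("feat_%d", 1:4)))
  cells <- structure(list(cell_id = rownames(feats),
                          tissue = sample(tissues, n_cells, replace = TRUE),
                          features = feats, n_removed = 0L),
                     class = "cell_line_set")
  known <- matrix(as.integer(runif(n_drugs * n_cells) < density),
                  n_drugs, n_cells)
  values <- matrix(NA_real_, n_drugs, n_cells)
  values[known == 1L] <- plogis(rnorm(sum(known), sd = 2))
  below <- known * matrix(rbinom(n_drugs * n_cells, 1L, 0.5),
                          n_drugs, n_cells)
  interaction_table(drugs, cells, values, known, below)
}

# Random SMILES-like strings over the default synthetic alphabet.
random_smiles <- function(n, len_range = c(5L, 30L)) {
  alpha <- c("(", ")", "1", "2", "=", "#", "Br", "C", "Cl", "N", "O", "S",
             "c", "n", "[nH]", "[O-]", "[Au]")
  vapply(seq_len(n), function(i) {
    paste(sample(alpha, sample(len_range[1]:len_range[2], 1),
                 replace = TRUE), collapse = "")
  }, character(1))
}
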