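#' Convolutional branch configuration
#'
#' Defaults reproduce the reference stack: three layers of width-7,
#' stride-1 convolutions with 40, 80 and 60 channels, each followed by
#' width-3, stride-3 max pooling, with length-preserving (same) padding.
#'
#' @param conv_widths Integer vector of convolution widths.
#' @param conv_strides Integer vector of convolution strides.
#' @param channels Integer vector of output channels per layer.
#' @param pool_widths Integer vector of pooling widths.
#' @param pool_strides Integer vector of pooling strides.
#' @param padding_mode `"same"` (zero-padded convolutions, ceiling
#'   pooling) or `"valid"` (no padding, floor pooling).
#' @return A `branch_config`.
#' @export
branch_config <- function(conv_widths = c(7L, 7L, 7L),
                          conv_strides = c(1L, 1L, 1L),
                          channels = c(40L, 80L, 60L),
                          pool_widths = c(3L, 3L, 3L),
                          pool_strides = c(3L, 3L, 3L),
                          padding_mode = c("same", "valid")) {
  padding_mode <- match.arg(padding_mode)
  n <- length(channels)
  if (!all(lengths(list(conv_widths, conv_strides, pool_widths,
                        pool_strides)) == n)) {
    stop("all layer parameter vectors must have equal length")
  }
  if (any(c(conv_widths, conv_strides, channels, pool_widths,
            pool_strides) < 1L)) {
    stop("layer widths, strides and channel counts must be positive")
  }
  structure(list(conv_widths = as.integer(conv_widths),
                 conv_strides = as.integer(conv_strides),
                 channels = as.integer(channels),
                 pool_widths = as.integer(pool_widths),
                 pool_strides = as.integer(pool_strides),
                 padding_mode = padding_mode),
            class = "branch_config")
}

#' Regression head configuration
#'
#' @param hidden_sizes Integer vector of hidden layer widths (default
#'   three layers of 1024 rectifier units).
#' @param dropout Dropout probability in `[0, 1)` applied to hidden
#'   activations during training (default 0.5).
#' @return A `head_config`. The output activation is always logistic
#'   because the labels are normalized IC50 values in (0, 1).
#' @export
head_config <- function(hidden_sizes = c(1024L, 1024L, 1024L),
                        dropout = 0.5) {
  if (dropout < 0 || dropout >= 1) stop("'dropout' must be in [0, 1)")
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 dropout = dropout, output_activation = "logistic"),
            class = "head_config")
}

#' Training configuration
#'
#' Training minimizes mean squared error with Adam and stops early when
#' the validation RMSE has not decreased for `patience_epochs` epochs;
#' the parameters from the best-validation epoch are returned.
#'
#' @param patience_epochs Early-stopping patience (default 10).
#' @param max_epochs Hard epoch cap (default 500).
#' @param batch_size Minibatch size (default 128).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param seed Integer seed controlling shuffling and dropout.
#' @param optimizer_name Only `"adam"` is implemented.
#' @return A `train_config`.
#' @export
train_config <- function(patience_epochs = 10L, max_epochs = 500L,
                         batch_size = 128L, learning_rate = 1e-4,
                         seed = 1L, optimizer_name = "adam") {
  if (patience_epochs < 1L) stop("'patience_epochs' must be >= 1")
  if (!identical(optimizer_name, "adam")) {
    stop("unsupported optimizer: ", optimizer_name)
  }
  structure(list(patience_epochs = as.integer(patience_epochs),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 seed = as.integer(seed),
                 optimizer_name = optimizer_name),
            class = "train_config")
}

#' Flattened output dimensionality of a CNN branch
#'
#' Tracks the sequence length through every convolution/pooling layer of
#' the branch and returns length times last channel count. Under the
#' default stack with same padding, an input of length 188 (the SMILES
#' grid) maps 188 -> 63 -> 21 -> 7 and yields 7 x 60 = 420 dims, and an
#' input of length 735 (the cell feature vector) maps 735 -> 245 -> 82
#' -> 28 and yields 28 x 60 = 1680 dims.
#'
#' @param input_len Input sequence length.
#' @param cfg A [branch_config()].
#' @return Integer flattened dimension.
#' @examples
#' branch_output_dim(188)  # 420
#' branch_output_dim(735)  # 1680
#' @export
branch_output_dim <- function(input_len, cfg = branch_config()) {
  stopifnot(inherits(cfg, "branch_config"))
  L <- as.integer(input_len)
  if (is.na(L) || L < 1L) stop("'input_len' must be >= 1")
  same <- cfg$padding_mode == "same"
  for (i in seq_along(cfg$channels)) {
    pad <- if (same) same_pad(cfg$conv_widths[i]) else 0L
    L <- conv_out_len(L, cfg$conv_widths[i], cfg$conv_strides[i], pad)
    L <- pool_out_len(L, cfg$pool_widths[i], cfg$pool_strides[i],
                      ceil_mode = same)
  }
  L * cfg$channels[length(cfg$channels)]
}

init_conv <- function(Cout, Cin, k) {
  matrix(stats::rnorm(Cout * Cin * k, sd = sqrt(2 / (Cin * k))), Cout, Cin * k)
}

init_dense <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

init_branch_params <- function(prefix, Cin, cfg) {
  p <- list()
  for (i in seq_along(cfg$channels)) {
    Cout <- cfg$channels[i]
    p[[paste0(prefix, "_conv", i, "_W")]] <-
      init_conv(Cout, Cin, cfg$conv_widths[i])
    p[[paste0(prefix, "_conv", i, "_b")]] <- numeric(Cout)
    Cin <- Cout
  }
  p
}

#' Build a twin-CNN drug response model
#'
#' Two 1D convolutional branches — one over the drug one-hot grid (each
#' vocabulary row is an input channel), one over the binary cell feature
#' vector (a single channel) — whose flattened outputs are concatenated
#' and fed to a fully connected regression head with a logistic output,
#' so predictions live in (0, 1) like the normalized IC50 labels.
#' Weights use He initialization seeded for reproducibility.
#'
#' @param vocab_size Number of tokens (drug input channels).
#' @param max_len One-hot grid width.
#' @param n_cell_features Length of the cell feature vector.
#' @param drug_cfg,cell_cfg [branch_config()]s for the two branches.
#' @param head_cfg A [head_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `twin_cnn` model object.
#' @export
build_model <- function(vocab_size, max_len, n_cell_features,
                        drug_cfg = branch_config(),
                        cell_cfg = branch_config(),
                        head_cfg = head_config(), seed = 1L) {
  stopifnot(vocab_size >= 1L, max_len >= 1L, n_cell_features >= 1L)
  d_drug <- branch_output_dim(max_len, drug_cfg)
  d_cell <- branch_output_dim(n_cell_features, cell_cfg)
  set.seed(seed)
  params <- c(init_branch_params("drug", vocab_size, drug_cfg),
              init_branch_params("cell", 1L, cell_cfg))
  nin <- d_drug + d_cell
  for (i in seq_along(head_cfg$hidden_sizes)) {
    nout <- head_cfg$hidden_sizes[i]
    params[[paste0("fc", i, "_W")]] <- init_dense(nin, nout)
    params[[paste0("fc", i, "_b")]] <- numeric(nout)
    nin <- nout
  }
  # small output init keeps initial logits near 0 (predictions near 0.5),
  # away from the saturated tails of the logistic output
  params$out_W <- matrix(stats::rnorm(nin, sd = 1 / nin), nin, 1L)
  params$out_b <- 0
  structure(list(params = params, drug_cfg = drug_cfg, cell_cfg = cell_cfg,
                 head_cfg = head_cfg, vocab_size = as.integer(vocab_size),
                 max_len = as.integer(max_len),
                 n_cell_features = as.integer(n_cell_features),
                 d_drug = d_drug, d_cell = d_cell, seed = as.integer(seed)),
            class = "twin_cnn")
}

#' @export
print.twin_cnn <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(paste0("<twin_cnn> drug branch %dch x %d -> %d dims | ",
                     "cell branch %d -> %d dims | head %s | %s parameters\n"),
              x$vocab_size, x$max_len, x$d_drug, x$n_cell_features,
              x$d_cell, paste(x$head_cfg$hidden_sizes, collapse = "-"),
              format(n_par, big.mark = ",")))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs, best val RMSE %.5f at epoch %d\n",
                nrow(x$history), min(x$history$val_rmse), x$best_epoch))
  }
  invisible(x)
}

# Full forward pass. Xd: (V, L*B) matrix; Xc: (1, F*B) matrix.
model_forward <- function(model, Xd, Xc, B, train = FALSE) {
  fd <- branch_forward(Xd, model$max_len, B, model$params, "drug",
                       model$drug_cfg)
  fc <- branch_forward(Xc, model$n_cell_features, B, model$params, "cell",
                       model$cell_cfg)
  H <- cbind(fd$flat, fc$flat)
  hd <- head_forward(H, model$params, model$head_cfg, train = train)
  list(pred = hd$pred, drug = fd, cell = fc, head = hd)
}

model_backward <- function(model, fw, y) {
  B <- length(y)
  pred <- fw$pred
  # d/dz of mean((sigmoid(z) - y)^2)
  dz <- matrix((2 / B) * (pred - y) * pred * (1 - pred), B, 1L)
  hb <- head_backward(dz, model$params, model$head_cfg, fw$head)
  d_drug <- model$d_drug
  dH <- hb$dH_in
  g_drug <- branch_backward(dH[, seq_len(d_drug), drop = FALSE],
                            model$params, "drug", model$drug_cfg, fw$drug)
  g_cell <- branch_backward(dH[, d_drug + seq_len(model$d_cell),
                               drop = FALSE],
                            model$params, "cell", model$cell_cfg, fw$cell)
  c(hb$grads, g_drug, g_cell)
}

# Assemble (V, L*B) and (1, F*B) input matrices for a list of pair
# indices into the encoded drug array / cell feature matrix.
gather_inputs <- function(drug_onehot, cell_features, di, ci) {
  d <- dim(drug_onehot)
  B <- length(di)
  Xd <- matrix(drug_onehot[, , di, drop = FALSE], d[1L], d[2L] * B)
  Xc <- matrix(t(cell_features[ci, , drop = FALSE]), 1L,
               ncol(cell_features) * B)
  list(Xd = Xd, Xc = Xc, B = B)
}

predict_indices <- function(model, drug_onehot, cell_features, di, ci,
                            batch_size = 512L) {
  n <- length(di)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, n)
    inp <- gather_inputs(drug_onehot, cell_features, di[sel], ci[sel])
    out[sel] <- model_forward(model, inp$Xd, inp$Xc, inp$B,
                              train = FALSE)$pred
  }
  out
}

resolve_pairs <- function(pairs, table) {
  di <- match(pairs$drug_id, table$drugs$drug_id)
  ci <- match(pairs$cell_id, table$cells$cell_id)
  if (anyNA(di)) {
    stop(sprintf("lookup error: unknown drug id %s",
                 pairs$drug_id[which(is.na(di))[1L]]))
  }
  if (anyNA(ci)) {
    stop(sprintf("lookup error: unknown cell id %s",
                 pairs$cell_id[which(is.na(ci))[1L]]))
  }
  list(di = di, ci = ci)
}

encode_table_drugs <- function(table, encoder) {
  sm <- table$drugs$canonical_smiles
  names(sm) <- table$drugs$drug_id
  encode_corpus(sm, encoder)
}

#' Train a twin-CNN model
#'
#' Minibatch gradient descent (Adam) on the mean squared error over the
#' training pairs of `split`, with per-epoch validation RMSE controlling
#' early stopping: training stops once validation RMSE has not decreased
#' for `cfg$patience_epochs` consecutive epochs (or at `max_epochs`), and
#' the parameters from the best-validation epoch are kept. Dropout is
#' active only during training updates; validation uses the
#' deterministic network.
#'
#' @param model A `twin_cnn` from [build_model()].
#' @param table An [interaction_table()].
#' @param split A `split_spec` whose train and validation pairs are drawn
#'   from the known pairs of `table`.
#' @param cfg A [train_config()].
#' @param encoder The [encoder_config()] used to one-hot the drugs.
#'   Ignored when `drug_onehot` is supplied.
#' @param drug_onehot Optional pre-encoded (and possibly perturbed) drug
#'   array from [encode_corpus()], indexed by the table's drug ids.
#' @param verbose Print per-epoch RMSE.
#' @return The trained `twin_cnn`, carrying `$history` (a `data.frame`
#'   with `epoch`, `train_rmse`, `val_rmse`) and `$best_epoch`.
#' @export
train_model <- function(model, table, split, cfg = train_config(),
                        encoder = NULL, drug_onehot = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "twin_cnn"), inherits(table, "interaction_table"),
            inherits(split, "split_spec"), inherits(cfg, "train_config"))
  if (nrow(split$train_pairs) == 0L || nrow(split$val_pairs) == 0L) {
    stop("configuration error: empty training or validation set")
  }
  if (is.null(drug_onehot)) {
    if (is.null(encoder)) stop("give either 'encoder' or 'drug_onehot'")
    drug_onehot <- encode_table_drugs(table, encoder)
  }
  if (dim(drug_onehot)[1L] != model$vocab_size ||
      dim(drug_onehot)[2L] != model$max_len) {
    stop("drug encoding does not match the model's input dimensions")
  }
  feats <- table$cells$features
  tr <- resolve_pairs(split$train_pairs, table)
  va <- resolve_pairs(split$val_pairs, table)
  y_tr <- table$values[cbind(tr$di, tr$ci)]
  y_va <- table$values[cbind(va$di, va$ci)]
  n_tr <- length(y_tr)

  set.seed(cfg$seed)
  state <- adam_init(model$params)
  best_val <- Inf
  best_params <- model$params
  best_epoch <- 0L
  since_best <- 0L
  history <- vector("list", cfg$max_epochs)

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n_tr)
    sse <- 0
    for (start in seq(1L, n_tr, by = cfg$batch_size)) {
      sel <- ord[start:min(start + cfg$batch_size - 1L, n_tr)]
      inp <- gather_inputs(drug_onehot, feats, tr$di[sel], tr$ci[sel])
      fw <- model_forward(model, inp$Xd, inp$Xc, inp$B, train = TRUE)
      y <- y_tr[sel]
      sse <- sse + sum((fw$pred - y)^2)
      grads <- model_backward(model, fw, y)
      st <- adam_step(model$params, grads, state, cfg$learning_rate)
      model$params <- st$params
      state <- st$state
    }
    train_rmse <- sqrt(sse / n_tr)
    val_pred <- predict_indices(model, drug_onehot, feats, va$di, va$ci)
    val_rmse <- sqrt(mean((val_pred - y_va)^2))
    history[[epoch]] <- data.frame(epoch = epoch, train_rmse = train_rmse,
                                   val_rmse = val_rmse)
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      train_rmse, val_rmse))
    }
    if (val_rmse < best_val) {
      best_val <- val_rmse
      best_params <- model$params
      best_epoch <- epoch
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= cfg$patience_epochs) break
    }
  }
  model$params <- best_params
  model$history <- do.call(rbind, history[!vapply(history, is.null,
                                                  logical(1))])
  model$best_epoch <- best_epoch
  model
}

#' Predict normalized IC50 for drug-cell pairs
#'
#' Deterministic inference (dropout disabled); batch and single-pair
#' predictions agree to numerical precision.
#'
#' @param object A trained `twin_cnn`.
#' @param pairs `data.frame` with `drug_id`, `cell_id`.
#' @param table The [interaction_table()] providing drug SMILES and cell
#'   features; unknown ids raise a lookup error.
#' @param encoder [encoder_config()] used to encode the drugs (ignored
#'   when `drug_onehot` is given).
#' @param drug_onehot Optional pre-encoded drug array.
#' @param batch_size Inference batch size.
#' @param ... Unused.
#' @return Numeric vector of predictions in (0, 1).
#' @export
predict.twin_cnn <- function(object, pairs, table, encoder = NULL,
                             drug_onehot = NULL, batch_size = 512L, ...) {
  if (is.null(drug_onehot)) {
    if (is.null(encoder)) stop("give either 'encoder' or 'drug_onehot'")
    drug_onehot <- encode_table_drugs(table, encoder)
  }
  rp <- resolve_pairs(pairs, table)
  predict_indices(object, drug_onehot, table$cells$features, rp$di, rp$ci,
                  batch_size)
}

#' Drug embeddings from the last convolutional layer
#'
#' Returns the flattened activations of the drug branch's final
#' pooling layer — the representation the regression head consumes
#' (420-dimensional under the default configuration with a length-188
#' grid). Useful for projecting drugs into the learned feature space.
#'
#' @param model A trained `twin_cnn`.
#' @param drug_onehot 3D array from [encode_corpus()].
#' @return Matrix (drugs x embedding dims) with drug ids as rownames.
#' @export
embed_drugs <- function(model, drug_onehot) {
  stopifnot(length(dim(drug_onehot)) == 3L)
  d <- dim(drug_onehot)
  fd <- branch_forward(matrix(drug_onehot, d[1L], d[2L] * d[3L]),
                       d[2L], d[3L], model$params, "drug", model$drug_cfg)
  rownames(fd$flat) <- dimnames(drug_onehot)[[3L]]
  fd$flat
}

#' Cell-line embeddings from the last convolutional layer
#'
#' Flattened activations of the cell branch's final pooling layer
#' (1680-dimensional under the default configuration with 735 features).
#'
#' @param model A trained `twin_cnn`.
#' @param cell_features Binary matrix (cells x features).
#' @return Matrix (cells x embedding dims) with cell ids as rownames.
#' @export
embed_cells <- function(model, cell_features) {
  stopifnot(is.matrix(cell_features))
  Xc <- matrix(t(cell_features), 1L,
               ncol(cell_features) * nrow(cell_features))
  fc <- branch_forward(Xc, ncol(cell_features), nrow(cell_features),
                       model$params, "cell", model$cell_cfg)
  rownames(fc$flat) <- rownames(cell_features)
  fc$flat
}

#' Save a model checkpoint
#'
#' Writes the parameter arrays (RDS), a JSON manifest with the
#' architecture configuration, dimensions and seed, and the training
#' history as CSV when present.
#'
#' @param model A `twin_cnn`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "twin_cnn"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model$params, file.path(dir, "params.rds"))
  manifest <- list(
    drug_cfg = unclass(model$drug_cfg), cell_cfg = unclass(model$cell_cfg),
    head_cfg = unclass(model$head_cfg), vocab_size = model$vocab_size,
    max_len = model$max_len, n_cell_features = model$n_cell_features,
    seed = model$seed, best_epoch = model$best_epoch
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(model$history)) {
    utils::write.csv(model$history, file.path(dir, "history.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Load a model checkpoint written by [save_model()]
#'
#' @param dir Checkpoint directory.
#' @return A `twin_cnn`.
#' @export
load_model <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  bc <- function(x) branch_config(x$conv_widths, x$conv_strides, x$channels,
                                  x$pool_widths, x$pool_strides,
                                  x$padding_mode)
  model <- build_model(m$vocab_size, m$max_len, m$n_cell_features,
                       bc(m$drug_cfg), bc(m$cell_cfg),
                       head_config(m$head_cfg$hidden_sizes,
                                   m$head_cfg$dropout),
                       seed = m$seed)
  model$params <- readRDS(file.path(dir, "params.rds"))
  hist_path <- file.path(dir, "history.csv")
  if (file.exists(hist_path)) {
    model$history <- utils::read.csv(hist_path)
    model$best_epoch <- m$best_epoch
  }
  model
}
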