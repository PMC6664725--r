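test_that("branch output dims reproduce the reference architecture", {
  expect_identical(branch_output_dim(188L), 420L)
  expect_identical(branch_output_dim(735L), 1680L)
  expect_identical(
    branch_output_dim(188L, branch_config(padding_mode = "valid")), 240L)
  # single layer, length 3, pool stride 3 collapses to 1 x channels
  one <- branch_config(3L, 1L, 5L, 3L, 3L)
  expect_identical(branch_output_dim(3L, one), 5L)
  expect_error(branch_output_dim(2L, branch_config(padding_mode = "valid")),
               "architecture error")
})

test_that("branch_output_dim agrees with an actual forward pass", {
  # oracle: run the convolution/pooling stack on a random input and
  # measure the flattened width it produces
  set.seed(31)
  for (i in 1:100) {
    n_layers <- sample(1:3, 1)
    cfg <- branch_config(
      conv_widths = sample(c(3L, 5L, 7L), n_layers, replace = TRUE),
      conv_strides = rep(1L, n_layers),
      channels = sample(2:6, n_layers, replace = TRUE),
      pool_widths = sample(2:3, n_layers, replace = TRUE),
      pool_strides = sample(2:3, n_layers, replace = TRUE),
      padding_mode = sample(c("same", "valid"), 1))
    input_len <- sample(20:120, 1)
    claimed <- tryCatch(branch_output_dim(input_len, cfg),
                        error = function(e) NA_integer_)
    if (is.na(claimed)) next
    Cin <- sample(1:4, 1)
    params <- twincnn:::init_branch_params("p", Cin, cfg)
    fw <- twincnn:::branch_forward(
      matrix(rnorm(Cin * input_len * 2), Cin, input_len * 2),
      input_len, 2L, params, "p", cfg)
    expect_identical(ncol(fw$flat), claimed)
  }
})

test_that("model construction wires the two branches into the head", {
  m <- build_model(20L, 40L, 16L, tiny_branch(), tiny_branch(),
                   tiny_head(), seed = 1L)
  expect_identical(m$d_drug, branch_output_dim(40L, tiny_branch()))
  expect_identical(m$d_cell, branch_output_dim(16L, tiny_branch()))
  expect_identical(nrow(m$params$fc1_W), m$d_drug + m$d_cell)
  # default architecture head input is 420 + 1680 = 2100 wide
  md <- build_model(72L, 188L, 735L, seed = 1L)
  expect_identical(nrow(md$params$fc1_W), 2100L)
})

test_that("forward pass is deterministic, in range, batch-invariant", {
  set.seed(6)
  tab <- toy_table(n_drugs = 6L, n_cells = 8L, seed = 6L)
  enc <- encoder_config(build_vocabulary(tab$drugs$canonical_smiles), 8L)
  A <- encode_corpus(setNames(tab$drugs$canonical_smiles,
                              tab$drugs$drug_id), enc)
  m1 <- build_model(dim(A)[1], dim(A)[2], 4L, tiny_branch(), tiny_branch(),
                    tiny_head(), seed = 99L)
  m2 <- build_model(dim(A)[1], dim(A)[2], 4L, tiny_branch(), tiny_branch(),
                    tiny_head(), seed = 99L)
  pairs <- known_pairs(tab)[1:10, ]
  p1 <- predict(m1, pairs, tab, drug_onehot = A)
  p2 <- predict(m2, pairs, tab, drug_onehot = A)
  expect_identical(p1, p2)                    # same seed, same weights
  expect_true(all(p1 > 0 & p1 < 1))
  # batch vs single-pair inference agrees
  singles <- vapply(seq_len(10L), function(i) {
    predict(m1, pairs[i, ], tab, drug_onehot = A)
  }, numeric(1))
  expect_equal(singles, p1, tolerance = 1e-6)
  # repeated query of the same pair is identical
  expect_identical(predict(m1, pairs[c(1, 1), ], tab, drug_onehot = A),
                   p1[c(1, 1)])
  expect_true(all(is.finite(denormalize_ic50(p1))))
  expect_error(predict(m1, data.frame(drug_id = "zz", cell_id = "CL01"),
                       tab, drug_onehot = A), "lookup error")
})

test_that("backpropagation matches finite differences", {
  set.seed(42)
  V <- 5L; L <- 9L; Fn <- 7L; B <- 4L
  cfgb <- branch_config(c(3L, 3L), c(1L, 1L), c(3L, 4L), c(2L, 2L),
                        c(2L, 2L))
  m <- build_model(V, L, Fn, cfgb, cfgb, head_config(c(6L, 5L), 0),
                   seed = 7L)
  # keep pre-activations off the relu kink so the numeric derivative of
  # the piecewise-linear pieces is well defined
  for (nm in grep("_b$", names(m$params), value = TRUE)) {
    m$params[[nm]] <- m$params[[nm]] + rnorm(length(m$params[[nm]]),
                                             sd = 0.1)
  }
  Ad <- array(0, c(V, L, B))
  for (b in 1:B) for (j in 1:L) Ad[sample(V, 1), j, b] <- 1
  feats <- matrix(rbinom(Fn * B, 1, 0.5), B, Fn)
  inp <- twincnn:::gather_inputs(Ad, feats, 1:B, 1:B)
  y <- runif(B, 0.3, 0.7)
  fw <- twincnn:::model_forward(m, inp$Xd, inp$Xc, B, train = FALSE)
  gr <- twincnn:::model_backward(m, fw, y)
  loss <- function(params) {
    mm <- m; mm$params <- params
    mean((twincnn:::model_forward(mm, inp$Xd, inp$Xc, B, FALSE)$pred - y)^2)
  }
  eps <- 1e-6
  for (nm in names(m$params)) {
    idx <- sample(length(m$params[[nm]]), min(5L, length(m$params[[nm]])))
    for (i in idx) {
      p1 <- m$params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- m$params; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (loss(p1) - loss(p2)) / (2 * eps)
      expect_lt(abs(num - gr[[nm]][i]) /
                  max(1e-6, abs(num) + abs(gr[[nm]][i])), 1e-4)
    }
  }
})

test_that("training fits constant labels and stops on the best epoch", {
  syn <- synthetic_interaction_table(tiny_syn_config(seed = 2L))
  tab <- syn$table
  tab$values[tab$known == 1L] <- 0.5
  sp <- pair_split(tab, c(0.7, 0.15, 0.15), seed = 2L)
  m <- build_model(length(syn$encoder$vocabulary$tokens),
                   syn$encoder$max_len, ncol(tab$cells$features),
                   tiny_branch(), tiny_branch(), tiny_head(0),
                   seed = 2L)
  fit <- train_model(m, tab, sp, tiny_train(seed = 2L, epochs = 15L,
                                            lr = 1e-2),
                     encoder = syn$encoder)
  expect_lt(min(fit$history$val_rmse), 0.01)
  # returned parameters achieve the minimum recorded validation RMSE
  expect_equal(fit$history$val_rmse[fit$best_epoch],
               min(fit$history$val_rmse))
  va <- twincnn:::resolve_pairs(sp$val_pairs, tab)
  A <- twincnn:::encode_table_drugs(tab, syn$encoder)
  val_pred <- twincnn:::predict_indices(fit, A, tab$cells$features,
                                        va$di, va$ci)
  y_va <- tab$values[cbind(va$di, va$ci)]
  expect_equal(sqrt(mean((val_pred - y_va)^2)),
               min(fit$history$val_rmse), tolerance = 1e-12)
})

test_that("seeded training is reproducible", {
  syn <- synthetic_interaction_table(tiny_syn_config(seed = 3L))
  sp <- pair_split(syn$table, c(0.7, 0.15, 0.15), seed = 3L)
  mk <- function() {
    m <- build_model(length(syn$encoder$vocabulary$tokens),
                     syn$encoder$max_len,
                     ncol(syn$table$cells$features),
                     tiny_branch(), tiny_branch(), tiny_head(),
                     seed = 3L)
    train_model(m, syn$table, sp, tiny_train(seed = 3L, epochs = 3L),
                encoder = syn$encoder)
  }
  f1 <- mk(); f2 <- mk()
  expect_equal(f1$history, f2$history, tolerance = 1e-6)
  expect_equal(f1$params$fc1_W, f2$params$fc1_W, tolerance = 1e-6)
})

test_that("early stopping halts after patience epochs without progress", {
  syn <- synthetic_interaction_table(tiny_syn_config(seed = 4L))
  tab <- syn$table
  set.seed(1)
  # unlearnable labels: permuted across known pairs
  kn <- which(tab$known == 1L)
  tab$values[kn] <- tab$values[sample(kn)]
  sp <- pair_split(tab, c(0.7, 0.15, 0.15), seed = 4L)
  m <- build_model(length(syn$encoder$vocabulary$tokens),
                   syn$encoder$max_len, ncol(tab$cells$features),
                   tiny_branch(), tiny_branch(), tiny_head(),
                   seed = 4L)
  cfg <- train_config(patience_epochs = 3L, max_epochs = 50L,
                      batch_size = 32L, learning_rate = 1e-4, seed = 4L)
  fit <- train_model(m, tab, sp, cfg, encoder = syn$encoder)
  expect_lte(nrow(fit$history), 50L)
  expect_identical(nrow(fit$history), fit$best_epoch + 3L)
})

test_that("consistent channel relabeling leaves predictions unchanged", {
  # permuting the vocabulary rows of every input together with the
  # first-layer kernel slices is an exact symmetry of the network
  set.seed(12)
  tab <- toy_table(n_drugs = 6L, n_cells = 8L, seed = 12L)
  enc <- encoder_config(build_vocabulary(tab$drugs$canonical_smiles), 8L)
  A <- encode_corpus(setNames(tab$drugs$canonical_smiles,
                              tab$drugs$drug_id), enc)
  V <- dim(A)[1L]
  m <- build_model(V, dim(A)[2L], 4L, tiny_branch(), tiny_branch(),
                   tiny_head(), seed = 5L)
  pairs <- known_pairs(tab)[1:8, ]
  base <- predict(m, pairs, tab, drug_onehot = A)
  perm <- sample.int(V)
  A_perm <- shuffle_symbol_rows(A, perm)
  m_perm <- m
  k <- tiny_branch()$conv_widths[1L]
  W <- m$params$drug_conv1_W            # (Cout, V*k), channel-major blocks
  idx <- as.vector(outer(perm, (seq_len(k) - 1L) * V, "+"))
  m_perm$params$drug_conv1_W <- W[, idx, drop = FALSE]
  permuted <- predict(m_perm, pairs, tab, drug_onehot = A_perm)
  expect_equal(permuted, base, tolerance = 1e-12)
})

test_that("embeddings have the branch output width and are reproducible", {
  tab <- toy_table(n_drugs = 5L, n_cells = 6L, seed = 20L)
  enc <- encoder_config(build_vocabulary(tab$drugs$canonical_smiles), 8L)
  A <- encode_corpus(setNames(tab$drugs$canonical_smiles,
                              tab$drugs$drug_id), enc)
  m <- build_model(dim(A)[1L], dim(A)[2L], 4L, tiny_branch(),
                   tiny_branch(), tiny_head(), seed = 2L)
  ed <- embed_drugs(m, A)
  expect_identical(dim(ed), c(5L, branch_output_dim(8L, tiny_branch())))
  expect_identical(rownames(ed), tab$drugs$drug_id)
  ec <- embed_cells(m, tab$cells$features)
  expect_identical(dim(ec), c(6L, branch_output_dim(4L, tiny_branch())))
  # identical drugs get identical embeddings
  A2 <- A; A2[, , 2L] <- A[, , 1L]
  ed2 <- embed_drugs(m, A2)
  expect_identical(ed2[1L, ], unname(ed2[2L, ]))
})

test_that("checkpoints round-trip through save_model/load_model", {
  syn <- synthetic_interaction_table(tiny_syn_config(seed = 6L))
  sp <- pair_split(syn$table, c(0.7, 0.15, 0.15), seed = 6L)
  m <- build_model(length(syn$encoder$vocabulary$tokens),
                   syn$encoder$max_len, ncol(syn$table$cells$features),
                   tiny_branch(), tiny_branch(), tiny_head(), seed = 6L)
  fit <- train_model(m, syn$table, sp, tiny_train(seed = 6L, epochs = 2L),
                     encoder = syn$encoder)
  dir <- tempfile()
  save_model(fit, dir)
  back <- load_model(dir)
  pairs <- sp$test_pairs[1:5, ]
  expect_identical(predict(back, pairs, syn$table, encoder = syn$encoder),
                   predict(fit, pairs, syn$table, encoder = syn$encoder))
  expect_equal(back$history$val_rmse, fit$history$val_rmse)
})
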