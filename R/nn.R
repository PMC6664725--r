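# 1D CNN engine. Convolution = im2col gather (C++) + BLAS matmul; max
# pooling and the Adam update are C++ kernels. Tensors at the
# convolutional stage are (channels, length * batch) matrices with the
# length and batch extents carried alongside; dense stages use
# (batch, units) matrices. Each branch layer applies conv -> maxpool ->
# relu: pooling and relu commute (both monotone), and pooling first
# shrinks the relu and its mask threefold.

conv_out_len <- function(L, k, s, pad) {
  Lout <- floor((L + 2L * pad - k) / s) + 1L
  if (Lout < 1L) stop("architecture error: sequence length collapsed to 0")
  as.integer(Lout)
}

same_pad <- function(k) {
  if (k %% 2L == 0L) {
    stop("architecture error: same padding requires an odd convolution width")
  }
  (k - 1L) %/% 2L
}

pool_out_len <- function(L, w, s, ceil_mode) {
  if (ceil_mode) {
    max(1L, as.integer(ceiling((L - w) / s)) + 1L)
  } else {
    Lout <- floor((L - w) / s) + 1L
    if (Lout < 1L) stop("architecture error: sequence shorter than pool width")
    as.integer(Lout)
  }
}

# Column indices of the non-padding positions inside the padded layout.
interior_cols <- function(L, B, pad) {
  Lp <- L + 2L * pad
  as.vector(outer(pad + seq_len(L), (seq_len(B) - 1L) * Lp, "+"))
}

# X: (Cin, L*B) matrix.
conv1d_forward <- function(X, W, b, k, stride, pad, L, B) {
  Cin <- nrow(X)
  Lp <- L + 2L * pad
  if (pad > 0L) {
    Xp <- matrix(0, Cin, Lp * B)
    ic <- interior_cols(L, B, pad)
    Xp[, ic] <- X
  } else {
    Xp <- X
    ic <- NULL
  }
  Lout <- conv_out_len(L, k, stride, pad)
  starts <- (seq_len(Lout) - 1L) * as.integer(stride)
  idx_tb <- outer(starts, (seq_len(B) - 1L) * Lp, "+")       # Lout x B
  colidx <- outer(seq_len(k), as.vector(idx_tb), "+")        # k x (Lout*B)
  storage.mode(colidx) <- "integer"
  M <- cpp_im2col(Xp, colidx)
  Y <- W %*% M + b
  list(Y = Y, Lout = Lout,
       cache = list(M = M, colidx = colidx, Cin = Cin, ic = ic,
                    LpB = Lp * B))
}

conv1d_backward <- function(dY, W, cache) {
  dW <- tcrossprod(dY, cache$M)
  db <- rowSums(dY)
  dM <- crossprod(W, dY)                   # (Cin*k) x (Lout*B)
  dXp <- cpp_col2im_add(dM, cache$colidx, cache$Cin, cache$LpB)
  dX <- if (is.null(cache$ic)) dXp else dXp[, cache$ic, drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

# One CNN branch: (conv -> maxpool -> relu) per layer, then flatten.
branch_forward <- function(X, L, B, params, prefix, cfg) {
  n_layers <- length(cfg$channels)
  caches <- vector("list", n_layers)
  ceil_mode <- cfg$padding_mode == "same"
  for (i in seq_len(n_layers)) {
    k <- cfg$conv_widths[i]
    pad <- if (cfg$padding_mode == "same") same_pad(k) else 0L
    cv <- conv1d_forward(X, params[[paste0(prefix, "_conv", i, "_W")]],
                         params[[paste0(prefix, "_conv", i, "_b")]],
                         k, cfg$conv_strides[i], pad, L, B)
    Lpool <- pool_out_len(cv$Lout, cfg$pool_widths[i], cfg$pool_strides[i],
                          ceil_mode)
    pl <- cpp_maxpool(cv$Y, cv$Lout, B, cfg$pool_widths[i],
                      cfg$pool_strides[i], Lpool)
    A <- pmax(pl$Y, 0)
    caches[[i]] <- list(conv = cv$cache, conv_cols = ncol(cv$Y),
                        argmax = pl$argmax, relu_mask = pl$Y > 0)
    X <- A
    L <- Lpool
  }
  C_last <- cfg$channels[n_layers]
  flat <- t(matrix(X, C_last * L, B))          # (B, C*L)
  list(flat = flat, out_dim = C_last * L, caches = caches,
       C_last = C_last, L_last = L, B = B)
}

branch_backward <- function(dflat, params, prefix, cfg, fw) {
  dX <- matrix(t(dflat), fw$C_last, fw$L_last * fw$B)
  grads <- list()
  for (i in rev(seq_along(cfg$channels))) {
    cc <- fw$caches[[i]]
    dX <- dX * cc$relu_mask
    dX <- cpp_maxpool_bwd(dX, cc$argmax, cc$conv_cols)
    bk <- conv1d_backward(dX, params[[paste0(prefix, "_conv", i, "_W")]],
                          cc$conv)
    grads[[paste0(prefix, "_conv", i, "_W")]] <- bk$dW
    grads[[paste0(prefix, "_conv", i, "_b")]] <- bk$db
    dX <- bk$dX
  }
  grads
}

# Head: hidden dense+relu(+dropout) layers, then a logistic output unit.
head_forward <- function(H, params, head_cfg, train = FALSE) {
  n_h <- length(head_cfg$hidden_sizes)
  caches <- vector("list", n_h)
  for (i in seq_len(n_h)) {
    W <- params[[paste0("fc", i, "_W")]]
    b <- params[[paste0("fc", i, "_b")]]
    Z <- sweep(H %*% W, 2L, b, "+")
    A <- pmax(Z, 0)
    mask <- Z > 0
    drop_mask <- NULL
    if (train && head_cfg$dropout > 0) {
      keep <- 1 - head_cfg$dropout
      drop_mask <- matrix(
        (stats::runif(length(A)) < keep) / keep, nrow(A), ncol(A))
      A <- A * drop_mask
    }
    caches[[i]] <- list(H = H, relu_mask = mask, drop_mask = drop_mask)
    H <- A
  }
  z <- sweep(H %*% params$out_W, 2L, params$out_b, "+")
  pred <- stats::plogis(z)
  list(pred = as.vector(pred), z = z, H_last = H, caches = caches)
}

head_backward <- function(dz, params, head_cfg, fw) {
  grads <- list()
  grads$out_W <- crossprod(fw$H_last, dz)
  grads$out_b <- colSums(dz)
  dH <- tcrossprod(dz, params$out_W)
  for (i in rev(seq_along(head_cfg$hidden_sizes))) {
    cc <- fw$caches[[i]]
    if (!is.null(cc$drop_mask)) dH <- dH * cc$drop_mask
    dH <- dH * cc$relu_mask
    grads[[paste0("fc", i, "_W")]] <- crossprod(cc$H, dH)
    grads[[paste0("fc", i, "_b")]] <- colSums(dH)
    dH <- tcrossprod(dH, params[[paste0("fc", i, "_W")]])
  }
  list(grads = grads, dH_in = dH)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  # fold both bias corrections into a step size and a shifted epsilon
  lr_t <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  eps_t <- eps * sqrt(1 - beta2^state$t)
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    params[[nm]] <- cpp_adam(params[[nm]], state$m[[nm]], state$v[[nm]],
                             g, lr_t, eps_t, beta1, beta2)
  }
  list(params = params, state = state)
}
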