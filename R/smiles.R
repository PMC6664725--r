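#' Tokenize a SMILES string
#'
#' Splits a SMILES string into chemically meaningful symbols: bracket atoms
#' (`[...]`) are kept as single tokens, the two-letter organic-subset
#' halogens `Cl` and `Br` outside brackets are single tokens, and every
#' other character is its own token. Concatenating the returned tokens
#' reproduces the input exactly.
#'
#' Tokens are the unit over which the drug-branch convolution operates:
#' each distinct token becomes one row (channel) of the one-hot grid, so a
#' token must correspond to one chemical element or structural symbol.
#'
#' @param smiles A single non-empty SMILES string (assumed canonical).
#' @return Character vector of tokens.
#' @examples
#' tokenize_smiles("O=C=O")
#' tokenize_smiles("C(Cl)Br")
#' tokenize_smiles("[Au]C")
#' @export
tokenize_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    stop("'smiles' must be a single character string")
  }
  if (!nzchar(smiles)) stop("empty SMILES string")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  tokens <- character(n)
  nt <- 0L
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") {
        if (chars[j] == "[") {
          stop(sprintf("malformed SMILES: nested '[' at position %d", j))
        }
        j <- j + 1L
      }
      if (j > n) {
        stop(sprintf("malformed SMILES: unbalanced '[' at position %d", i))
      }
      nt <- nt + 1L
      tokens[nt] <- paste(chars[i:j], collapse = "")
      i <- j + 1L
    } else if (ch == "]") {
      stop(sprintf("malformed SMILES: unbalanced ']' at position %d", i))
    } else if (i < n &&
               ((ch == "C" && chars[i + 1L] == "l") ||
                (ch == "B" && chars[i + 1L] == "r"))) {
      nt <- nt + 1L
      tokens[nt] <- paste0(ch, chars[i + 1L])
      i <- i + 2L
    } else {
      nt <- nt + 1L
      tokens[nt] <- ch
      i <- i + 1L
    }
  }
  tokens[seq_len(nt)]
}

#' Padding token used for right-padding encoded SMILES
#'
#' A literal space. It always occupies its own vocabulary row so that
#' padded columns of the one-hot grid remain one-hot.
#' @export
padding_token <- function() " "

#' Build a token vocabulary from a SMILES corpus
#'
#' Tokenizes every string in the corpus, collects the distinct tokens,
#' adds the padding token, and orders them lexicographically (C locale) so
#' the vocabulary is deterministic for a given corpus. On the GDSC panel
#' of 223 drugs this yields 72 symbols; the count is corpus-dependent and
#' never hard-coded.
#'
#' @param corpus Character vector of SMILES strings.
#' @return A `token_vocabulary`: list with `tokens` (ordered character
#'   vector) and `index` (named integer vector mapping token to row).
#' @examples
#' build_vocabulary(c("[Au]C", "CCl"))
#' @export
build_vocabulary <- function(corpus) {
  if (!is.character(corpus) || length(corpus) == 0L) {
    stop("configuration error: corpus must be a non-empty character vector")
  }
  toks <- unique(unlist(lapply(corpus, tokenize_smiles), use.names = FALSE))
  toks <- sort(unique(c(toks, padding_token())), method = "radix")
  structure(
    list(tokens = toks,
         index = stats::setNames(seq_along(toks), toks)),
    class = "token_vocabulary"
  )
}

#' @export
print.token_vocabulary <- function(x, ...) {
  cat(sprintf("<token_vocabulary> %d tokens (incl. padding)\n",
              length(x$tokens)))
  cat("  ", paste(utils::head(x$tokens, 25L), collapse = " "),
      if (length(x$tokens) > 25L) "..." else "", "\n")
  invisible(x)
}

#' Encoder configuration
#'
#' Pairs a vocabulary with a fixed grid width `max_len`. Every drug is
#' encoded into a `n_tokens x max_len` matrix, left-aligned and
#' space-padded on the right; `max_len` must cover the longest tokenized
#' SMILES in the corpus (188 on the GDSC panel).
#'
#' @param vocabulary A `token_vocabulary`.
#' @param max_len Positive integer grid width (default 188).
#' @return An `encoder_config`.
#' @export
encoder_config <- function(vocabulary, max_len = 188L) {
  stopifnot(inherits(vocabulary, "token_vocabulary"))
  max_len <- as.integer(max_len)
  if (is.na(max_len) || max_len < 1L) stop("'max_len' must be >= 1")
  structure(list(vocabulary = vocabulary, max_len = max_len),
            class = "encoder_config")
}

#' @export
print.encoder_config <- function(x, ...) {
  cat(sprintf("<encoder_config> %d tokens x %d positions\n",
              length(x$vocabulary$tokens), x$max_len))
  invisible(x)
}

#' One-hot encode a SMILES string
#'
#' Produces the symbol-by-position binary grid: entry (i, j) is 1 iff
#' token i occupies position j. Positions beyond the tokenized length
#' activate the padding row, so every column sums to exactly 1.
#'
#' @param smiles A single SMILES string.
#' @param config An [encoder_config()].
#' @return Binary matrix of shape `(n_tokens, max_len)` with token
#'   rownames.
#' @examples
#' cfg <- encoder_config(build_vocabulary("CC"), max_len = 4)
#' encode_smiles("CC", cfg)
#' @export
encode_smiles <- function(smiles, config) {
  stopifnot(inherits(config, "encoder_config"))
  tokens <- tokenize_smiles(smiles)
  vocab <- config$vocabulary
  unknown <- setdiff(tokens, vocab$tokens)
  if (length(unknown) > 0L) {
    stop(sprintf("out-of-vocabulary token(s): %s",
                 paste(sQuote(unknown), collapse = ", ")))
  }
  L <- length(tokens)
  if (L > config$max_len) {
    stop(sprintf("tokenized length %d exceeds max_len %d", L, config$max_len))
  }
  V <- length(vocab$tokens)
  m <- matrix(0, nrow = V, ncol = config$max_len,
              dimnames = list(vocab$tokens, NULL))
  m[cbind(vocab$index[tokens], seq_len(L))] <- 1
  if (L < config$max_len) {
    m[vocab$index[[padding_token()]], (L + 1L):config$max_len] <- 1
  }
  m
}

#' Decode a one-hot matrix back to tokens
#'
#' Takes the argmax of each column and strips trailing padding; the result
#' equals `tokenize_smiles()` of the original string for any matrix
#' produced by [encode_smiles()].
#'
#' @param x One-hot matrix with token rownames.
#' @return Character vector of tokens (padding removed).
#' @export
decode_onehot <- function(x) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  toks <- rownames(x)[max.col(t(x), ties.method = "first")]
  keep <- length(toks)
  while (keep > 0L && toks[keep] == padding_token()) keep <- keep - 1L
  toks[seq_len(keep)]
}

#' Encode a corpus of drugs into a one-hot array
#'
#' @param smiles Named character vector of SMILES (names are drug ids).
#' @param config An [encoder_config()].
#' @return 3D array `(n_tokens, max_len, n_drugs)` with drug ids on the
#'   third dimension.
#' @export
encode_corpus <- function(smiles, config) {
  stopifnot(is.character(smiles), length(smiles) > 0L)
  ids <- names(smiles)
  if (is.null(ids)) ids <- as.character(seq_along(smiles))
  V <- length(config$vocabulary$tokens)
  out <- array(0, dim = c(V, config$max_len, length(smiles)),
               dimnames = list(config$vocabulary$tokens, NULL, ids))
  for (i in seq_along(smiles)) out[, , i] <- encode_smiles(smiles[[i]], config)
  out
}

# Apply a function over the drug slices of a 2D matrix or 3D array.
onehot_apply <- function(x, f) {
  nd <- length(dim(x))
  if (nd == 2L) return(f(x))
  if (nd == 3L) {
    out <- x
    for (i in seq_len(dim(x)[3L])) out[, , i] <- f(x[, , i])
    return(out)
  }
  stop("'x' must be a one-hot matrix or a 3D one-hot array")
}

check_permutation <- function(perm, n, what) {
  perm <- as.integer(perm)
  if (length(perm) != n || anyNA(perm) || !setequal(perm, seq_len(n))) {
    stop(sprintf("'permutation' must be a permutation of 1..%d (%s)", n, what))
  }
  perm
}

#' Shuffle the symbol rows of a one-hot encoding
#'
#' Row i of the output is row `permutation[i]` of the input while row
#' labels stay in place, i.e. the assignment of symbols to channels is
#' scrambled. Used to probe whether the model exploits symbol identity.
#'
#' @param x One-hot matrix or 3D array from [encode_corpus()].
#' @param permutation Integer permutation of the rows.
#' @return Perturbed object of the same shape.
#' @export
shuffle_symbol_rows <- function(x, permutation) {
  n <- dim(x)[1L]
  perm <- check_permutation(permutation, n, "rows")
  rn <- dimnames(x)[[1L]]
  onehot_apply(x, function(m) {
    out <- m[perm, , drop = FALSE]
    rownames(out) <- rn
    out
  })
}

#' Rotate the position columns of a one-hot encoding
#'
#' Cuts the position axis into two pieces at `cut` and swaps them: output
#' columns are input columns `cut+1..max_len` followed by `1..cut`.
#'
#' @param x One-hot matrix or 3D array.
#' @param cut Integer in `[0, max_len]`.
#' @return Perturbed object of the same shape.
#' @export
rotate_positions <- function(x, cut) {
  L <- dim(x)[2L]
  cut <- as.integer(cut)
  if (is.na(cut) || cut < 0L || cut > L) {
    stop(sprintf("'cut' must be in [0, %d]", L))
  }
  if (cut == 0L || cut == L) return(x)
  idx <- c((cut + 1L):L, seq_len(cut))
  onehot_apply(x, function(m) m[, idx, drop = FALSE])
}

#' Shuffle the position columns of a one-hot encoding
#'
#' Column j of the output is column `permutation[j]` of the input,
#' destroying positional (and hence structural) information while
#' preserving the symbol histogram.
#'
#' @param x One-hot matrix or 3D array.
#' @param permutation Integer permutation of the columns.
#' @return Perturbed object of the same shape.
#' @export
shuffle_positions <- function(x, permutation) {
  L <- dim(x)[2L]
  perm <- check_permutation(permutation, L, "columns")
  onehot_apply(x, function(m) m[, perm, drop = FALSE])
}

#' Write an encoded one-hot array to disk
#'
#' Stores the array as a flat binary vector of doubles (column-major)
#' next to a JSON sidecar recording dimensions, drug ids, vocabulary and
#' `max_len`, so the tensor can be reloaded or consumed by other tools.
#'
#' @param x 3D array from [encode_corpus()].
#' @param config The [encoder_config()] used to build `x`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_onehot_array <- function(x, config, dir) {
  stopifnot(length(dim(x)) == 3L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bin <- file.path(dir, "onehot.bin")
  con <- file(bin, "wb")
  on.exit(close(con))
  writeBin(as.vector(x), con, size = 8L, endian = "little")
  meta <- list(
    dims = dim(x),
    drug_ids = dimnames(x)[[3L]],
    tokens = config$vocabulary$tokens,
    max_len = config$max_len,
    dtype = "float64",
    order = "column-major"
  )
  jsonlite::write_json(meta, file.path(dir, "onehot.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an encoded one-hot array written by [write_onehot_array()]
#'
#' @param dir Directory containing `onehot.bin` and `onehot.json`.
#' @return List with `array` and `config` (a rebuilt [encoder_config()]).
#' @export
read_onehot_array <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "onehot.json"),
                              simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  con <- file(file.path(dir, "onehot.bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "double", n = prod(dims), size = 8L,
                  endian = "little")
  x <- array(vals, dim = dims,
             dimnames = list(meta$tokens, NULL, meta$drug_ids))
  vocab <- structure(
    list(tokens = meta$tokens,
         index = stats::setNames(seq_along(meta$tokens), meta$tokens)),
    class = "token_vocabulary"
  )
  list(array = x, config = encoder_config(vocab, meta$max_len))
}
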