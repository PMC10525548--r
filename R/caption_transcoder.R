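# The generative caption model: a transformer encoder block over image
# feature sequences and a transformer decoder block producing the token
# sequence, with greedy decoding.  Forward passes keep the intermediate
# activations needed by the analytic backward passes in transcoder_grad.R.

.SPECIALS <- c(PAD = 0L, START = 1L, END = 2L, UNK = 3L)

#' Build a vocabulary from captions
#'
#' Tokens are ordered by descending corpus frequency, ties broken
#' lexicographically, after four reserved specials with fixed indices:
#' PAD = 0, START = 1, END = 2, UNK = 3.  Unseen words at inference map
#' to UNK.
#'
#' @param captions list of character vectors (word sequences), or a
#'   character vector of space-separated captions.
#' @return an object of class `tricap_vocab`.
#' @export
build_vocabulary <- function(captions) {
  if (is.character(captions)) captions <- strsplit(captions, "[[:space:]]+")
  words <- unlist(captions, use.names = FALSE)
  words <- words[nzchar(words)]
  tab <- table(words)
  ord <- names(tab)[order(-as.integer(tab), names(tab))]
  specials <- c("<pad>", "<start>", "<end>", "<unk>")
  id_to_token <- c(specials, ord)
  token_to_id <- stats::setNames(seq_along(id_to_token) - 1L, id_to_token)
  structure(list(token_to_id = token_to_id, id_to_token = id_to_token,
                 size = length(id_to_token)),
            class = "tricap_vocab")
}

#' Encode words to token ids
#'
#' @param vocab a `tricap_vocab`.
#' @param words character vector.
#' @return integer vector of 0-based token ids; unknown words map to UNK.
#' @export
vocab_encode <- function(vocab, words) {
  ids <- unname(vocab$token_to_id[words])
  ids[is.na(ids)] <- .SPECIALS[["UNK"]]
  as.integer(ids)
}

#' Decode token ids to words
#'
#' @param vocab a `tricap_vocab`.
#' @param ids integer vector of 0-based token ids.
#' @return character vector of tokens (specials decode to their markers).
#' @export
vocab_decode <- function(vocab, ids) {
  stopifnot(all(ids >= 0), all(ids < vocab$size))
  vocab$id_to_token[ids + 1L]
}

#' Configure the caption transcoder
#'
#' @param embed_dim model width d (word embedding and attention width);
#'   must be divisible by `n_heads`.
#' @param n_heads number of attention heads.
#' @param ff_dim width of the decoder feed-forward layer.
#' @param max_len maximum token positions (>= 5: START + triple + END).
#' @param vocab_size vocabulary size including specials.
#' @param seed weight-initialization seed.
#' @return an object of class `tricap_config`.
#' @export
transcoder_config <- function(embed_dim = 128, n_heads = 2, ff_dim = 256,
                              max_len = 8, vocab_size, seed = 0) {
  stopifnot(embed_dim >= 1, n_heads >= 1, ff_dim >= 1, max_len >= 5,
            vocab_size >= 5)
  if (embed_dim %% n_heads != 0) {
    stop("embed_dim must be divisible by n_heads", call. = FALSE)
  }
  structure(list(embed_dim = as.integer(embed_dim),
                 n_heads = as.integer(n_heads),
                 ff_dim = as.integer(ff_dim),
                 max_len = as.integer(max_len),
                 vocab_size = as.integer(vocab_size),
                 seed = as.integer(seed)),
            class = "tricap_config")
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

attn_params <- function(d) {
  list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
       Wo = glorot(d, d), bq = numeric(d), bk = numeric(d),
       bv = numeric(d), bo = numeric(d))
}

#' Initialize a caption transcoder model
#'
#' Seeded Glorot-uniform weight initialization; layer-norm gains start at
#' 1, biases at 0.  The encoder has no positional encoding (it is
#' permutation-equivariant over feature tokens); the decoder uses learned
#' position embeddings.
#'
#' @param config a [transcoder_config()].
#' @param feature_dim channel dimension of the backbone feature tokens.
#' @param vocab optional `tricap_vocab` stored with the model.
#' @return an object of class `tricap_model`.
#' @export
transcoder_init <- function(config, feature_dim, vocab = NULL) {
  stopifnot(inherits(config, "tricap_config"))
  d <- config$embed_dim
  V <- config$vocab_size
  params <- with_seed(config$seed, {
    p <- list(
      enc_ln1_g = rep(1, feature_dim), enc_ln1_b = numeric(feature_dim),
      enc_Wd = glorot(feature_dim, d), enc_bd = numeric(d),
      enc_ln2_g = rep(1, d), enc_ln2_b = numeric(d),
      dec_Emb = matrix(rnorm(V * d, 0, 0.02), V, d),
      dec_Pos = matrix(rnorm(config$max_len * d, 0, 0.02), config$max_len, d),
      dec_ln1_g = rep(1, d), dec_ln1_b = numeric(d),
      dec_ln2_g = rep(1, d), dec_ln2_b = numeric(d),
      dec_f_W1 = glorot(d, config$ff_dim), dec_f_b1 = numeric(config$ff_dim),
      dec_f_W2 = glorot(config$ff_dim, d), dec_f_b2 = numeric(d),
      dec_ln3_g = rep(1, d), dec_ln3_b = numeric(d),
      dec_Wout = glorot(d, V), dec_bout = numeric(V)
    )
    for (blk in c("enc_a", "dec_s", "dec_c")) {
      ap <- attn_params(d)
      names(ap) <- paste0(blk, "_", names(ap))
      p <- c(p, ap)
    }
    p
  })
  structure(list(params = params, config = config,
                 feature_dim = as.integer(feature_dim), vocab = vocab),
            class = "tricap_model")
}

#' Number of trainable parameters
#'
#' @param model a `tricap_model`.
#' @return integer parameter count; a pure function of the configuration
#'   and feature dimension.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# --- primitive layers -----------------------------------------------------

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  s <- sqrt(rowMeans(xc^2) + eps)
  Xhat <- xc / s
  list(Y = sweep(sweep(Xhat, 2, g, `*`), 2, b, `+`), Xhat = Xhat, s = s)
}

softmax_rows <- function(S) {
  mx <- apply(S, 1, function(r) max(r[is.finite(r)]))
  E <- exp(S - mx)
  E[!is.finite(E)] <- 0
  E / pmax(rowSums(E), .Machine$double.xmin)
}

# Multi-head attention.  Qin: (Tq x d), Kin/Vin: (Tk x d).  `p` holds
# Wq,Wk,Wv,Wo and biases; causal=TRUE masks keys j > query i.
mha_fwd <- function(Qin, Kin, Vin, p, n_heads, causal = FALSE) {
  d <- ncol(p$Wq)
  dk <- d / n_heads
  Q <- sweep(Qin %*% p$Wq, 2, p$bq, `+`)
  K <- sweep(Kin %*% p$Wk, 2, p$bk, `+`)
  V <- sweep(Vin %*% p$Wv, 2, p$bv, `+`)
  H <- matrix(0, nrow(Qin), d)
  Ps <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dk)
    if (causal) S[upper.tri(S)] <- -Inf
    P <- softmax_rows(S)
    Ps[[h]] <- P
    H[, idx] <- P %*% V[, idx, drop = FALSE]
  }
  out <- sweep(H %*% p$Wo, 2, p$bo, `+`)
  list(out = out, Q = Q, K = K, V = V, P = Ps, H = H,
       Qin = Qin, Kin = Kin, Vin = Vin)
}

# --- encoder / decoder blocks --------------------------------------------

enc_slice <- function(params) {
  list(Wq = params$enc_a_Wq, Wk = params$enc_a_Wk, Wv = params$enc_a_Wv,
       Wo = params$enc_a_Wo, bq = params$enc_a_bq, bk = params$enc_a_bk,
       bv = params$enc_a_bv, bo = params$enc_a_bo)
}

encoder_fwd <- function(X, params, n_heads) {
  ln1 <- layernorm_fwd(X, params$enc_ln1_g, params$enc_ln1_b)
  pre <- sweep(ln1$Y %*% params$enc_Wd, 2, params$enc_bd, `+`)
  D <- pmax(pre, 0)
  mha <- mha_fwd(D, D, D, enc_slice(params), n_heads)
  R <- D + mha$out
  ln2 <- layernorm_fwd(R, params$enc_ln2_g, params$enc_ln2_b)
  list(E = ln2$Y, ln1 = ln1, pre = pre, D = D, mha = mha, R = R, ln2 = ln2,
       X = X)
}

dec_slice <- function(params, blk) {
  list(Wq = params[[paste0(blk, "_Wq")]], Wk = params[[paste0(blk, "_Wk")]],
       Wv = params[[paste0(blk, "_Wv")]], Wo = params[[paste0(blk, "_Wo")]],
       bq = params[[paste0(blk, "_bq")]], bk = params[[paste0(blk, "_bk")]],
       bv = params[[paste0(blk, "_bv")]], bo = params[[paste0(blk, "_bo")]])
}

decoder_fwd <- function(ids, E, params, n_heads) {
  L <- length(ids)
  rows <- ids + 1L
  Z0 <- params$dec_Emb[rows, , drop = FALSE] +
    params$dec_Pos[seq_len(L), , drop = FALSE]
  m1 <- mha_fwd(Z0, Z0, Z0, dec_slice(params, "dec_s"), n_heads,
                causal = TRUE)
  ln1 <- layernorm_fwd(Z0 + m1$out, params$dec_ln1_g, params$dec_ln1_b)
  Z1 <- ln1$Y
  m2 <- mha_fwd(Z1, E, E, dec_slice(params, "dec_c"), n_heads)
  ln2 <- layernorm_fwd(Z1 + m2$out, params$dec_ln2_g, params$dec_ln2_b)
  Z2 <- ln2$Y
  pre <- sweep(Z2 %*% params$dec_f_W1, 2, params$dec_f_b1, `+`)
  F1 <- pmax(pre, 0)
  F2 <- sweep(F1 %*% params$dec_f_W2, 2, params$dec_f_b2, `+`)
  ln3 <- layernorm_fwd(Z2 + F2, params$dec_ln3_g, params$dec_ln3_b)
  Z3 <- ln3$Y
  logits <- sweep(Z3 %*% params$dec_Wout, 2, params$dec_bout, `+`)
  probs <- softmax_rows(logits)
  list(probs = probs, logits = logits, ids = ids, Z0 = Z0, m1 = m1,
       ln1 = ln1, Z1 = Z1, m2 = m2, ln2 = ln2, Z2 = Z2, pre = pre, F1 = F1,
       F2 = F2, ln3 = ln3, Z3 = Z3, E = E)
}

#' Run the transformer encoder block
#'
#' Normalize, project through a ReLU dense layer to the model width,
#' multi-head self-attention, residual add, normalize.  The block carries
#' no positional encoding, so permuting the input tokens permutes the
#' output rows identically.
#'
#' @param features numeric matrix `(n_tokens, feature_dim)`.
#' @param model a `tricap_model`.
#' @return encoder state matrix `(n_tokens, embed_dim)`.
#' @export
encoder_block <- function(features, model) {
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  if (any(!is.finite(features))) {
    stop("encoder input must be finite", call. = FALSE)
  }
  stopifnot(ncol(features) == model$feature_dim)
  encoder_fwd(features, model$params, model$config$n_heads)$E
}

#' Run the transformer decoder block
#'
#' Token plus learned positional embedding, causally masked multi-head
#' self-attention, cross-attention over the encoder state, feed-forward,
#' and a softmax over the vocabulary at each position.  Position t of the
#' output depends only on tokens at positions <= t.
#'
#' @param tokens integer vector of 0-based token ids, length <= max_len.
#' @param encoder_state matrix from [encoder_block()].
#' @param model a `tricap_model`.
#' @return matrix `(length(tokens), vocab_size)`; each row sums to 1.
#' @export
decoder_block <- function(tokens, encoder_state, model) {
  tokens <- as.integer(tokens)
  if (any(tokens < 0 | tokens >= model$config$vocab_size)) {
    stop("token id out of range", call. = FALSE)
  }
  if (length(tokens) > model$config$max_len) {
    stop("sequence longer than max_len", call. = FALSE)
  }
  decoder_fwd(tokens, encoder_state, model$params, model$config$n_heads)$probs
}

#' Generate a caption by greedy decoding
#'
#' Starts from START and at each step appends the argmax token (ties go
#' to the lowest index); stops at END or when `max_len` positions are
#' filled.  Deterministic given the model weights.
#'
#' @param features feature matrix `(n_tokens, feature_dim)` for one
#'   image, or a precomputed encoder state with `encoded = TRUE`.
#' @param model a `tricap_model` (with a vocabulary attached).
#' @param max_len decoding cap; defaults to the model's `max_len`.
#' @param encoded set TRUE if `features` is already an encoder state.
#' @return character vector of generated words, specials removed; length
#'   is at most `max_len - 1`.
#' @export
generate_caption <- function(features, model, max_len = model$config$max_len,
                             encoded = FALSE) {
  stopifnot(!is.null(model$vocab))
  E <- if (encoded) features else encoder_block(features, model)
  ids <- .SPECIALS[["START"]]
  while (length(ids) < max_len) {
    probs <- decoder_fwd(ids, E, model$params, model$config$n_heads)$probs
    nxt <- which.max(probs[length(ids), ]) - 1L  # ties: lowest index
    if (nxt == .SPECIALS[["END"]]) break
    ids <- c(ids, nxt)
  }
  out <- ids[-1]
  out <- out[!out %in% .SPECIALS]
  vocab_decode(model$vocab, out)
}

#' Encode a caption as a fixed-length target sequence
#'
#' Builds START + words + END, padded with PAD to `max_len`.
#'
#' @param vocab a `tricap_vocab`.
#' @param words character vector of caption words.
#' @param max_len total sequence length.
#' @return integer vector of 0-based ids, length `max_len`.
#' @export
encode_caption <- function(vocab, words, max_len) {
  ids <- c(.SPECIALS[["START"]], vocab_encode(vocab, words),
           .SPECIALS[["END"]])
  if (length(ids) > max_len) stop("caption longer than max_len", call. = FALSE)
  c(ids, rep(.SPECIALS[["PAD"]], max_len - length(ids)))
}

# --- checkpointing --------------------------------------------------------

#' Save a model checkpoint
#'
#' Single-file JSON archive of weights, configuration and vocabulary,
#' with a versioned header.
#'
#' @param model a `tricap_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(
    format = "tricap-checkpoint", version = 1L,
    config = unclass(model$config), feature_dim = model$feature_dim,
    vocab = if (!is.null(model$vocab)) list(id_to_token = model$vocab$id_to_token),
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = length(p), data = as.numeric(p))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_checkpoint()].
#' @return a `tricap_model`.
#' @export
load_checkpoint <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "tricap-checkpoint")) {
    stop("not a tricap checkpoint: ", path, call. = FALSE)
  }
  cfg <- do.call(transcoder_config, x$config[c("embed_dim", "n_heads",
                                              "ff_dim", "max_len",
                                              "vocab_size", "seed")])
  vocab <- NULL
  if (!is.null(x$vocab)) {
    toks <- x$vocab$id_to_token
    vocab <- structure(list(
      token_to_id = stats::setNames(seq_along(toks) - 1L, toks),
      id_to_token = toks, size = length(toks)), class = "tricap_vocab")
  }
  params <- lapply(x$params, function(p) {
    if (length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  structure(list(params = params, config = cfg,
                 feature_dim = as.integer(x$feature_dim), vocab = vocab),
            class = "tricap_model")
}
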