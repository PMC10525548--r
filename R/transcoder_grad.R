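# Analytic backward passes for the transcoder.  Each *_bwd mirrors the
# cache layout of its forward in caption_transcoder.R; gradients are
# returned in the same named-list shape as the parameters.  Correctness
# is pinned by a central-finite-difference test.

layernorm_bwd <- function(dY, cache, g) {
  dXhat <- sweep(dY, 2, g, `*`)
  dX <- (dXhat - rowMeans(dXhat) - cache$Xhat * rowMeans(dXhat * cache$Xhat)) /
    cache$s
  list(dX = dX, dg = colSums(dY * cache$Xhat), db = colSums(dY))
}

mha_bwd <- function(dOut, cache, p, n_heads) {
  d <- ncol(p$Wq)
  dk <- d / n_heads
  dH <- dOut %*% t(p$Wo)
  dWo <- t(cache$H) %*% dOut
  dbo <- colSums(dOut)
  dQ <- matrix(0, nrow(cache$Q), d)
  dK <- matrix(0, nrow(cache$K), d)
  dV <- matrix(0, nrow(cache$V), d)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    P <- cache$P[[h]]
    Vh <- cache$V[, idx, drop = FALSE]
    dHh <- dH[, idx, drop = FALSE]
    dP <- dHh %*% t(Vh)
    dV[, idx] <- t(P) %*% dHh
    dS <- P * (dP - rowSums(dP * P))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dk)
    dK[, idx] <- t(dS) %*% cache$Q[, idx, drop = FALSE] / sqrt(dk)
  }
  list(dQin = dQ %*% t(p$Wq), dKin = dK %*% t(p$Wk), dVin = dV %*% t(p$Wv),
       dWq = t(cache$Qin) %*% dQ, dWk = t(cache$Kin) %*% dK,
       dWv = t(cache$Vin) %*% dV, dWo = dWo,
       dbq = colSums(dQ), dbk = colSums(dK), dbv = colSums(dV), dbo = dbo)
}

put_attn_grads <- function(grads, blk, mb) {
  for (nm in c("Wq", "Wk", "Wv", "Wo", "bq", "bk", "bv", "bo")) {
    key <- paste0(blk, "_", nm)
    grads[[key]] <- grads[[key]] + mb[[paste0("d", nm)]]
  }
  grads
}

encoder_bwd <- function(dE, fwd, params, n_heads, grads) {
  l2 <- layernorm_bwd(dE, fwd$ln2, params$enc_ln2_g)
  grads$enc_ln2_g <- grads$enc_ln2_g + l2$dg
  grads$enc_ln2_b <- grads$enc_ln2_b + l2$db
  dR <- l2$dX
  mb <- mha_bwd(dR, fwd$mha, enc_slice(params), n_heads)
  grads <- put_attn_grads(grads, "enc_a", mb)
  dD <- dR + mb$dQin + mb$dKin + mb$dVin
  dpre <- dD * (fwd$pre > 0)
  grads$enc_Wd <- grads$enc_Wd + t(fwd$ln1$Y) %*% dpre
  grads$enc_bd <- grads$enc_bd + colSums(dpre)
  dN1 <- dpre %*% t(params$enc_Wd)
  l1 <- layernorm_bwd(dN1, fwd$ln1, params$enc_ln1_g)
  grads$enc_ln1_g <- grads$enc_ln1_g + l1$dg
  grads$enc_ln1_b <- grads$enc_ln1_b + l1$db
  grads
}

decoder_bwd <- function(dLogits, fwd, params, n_heads, grads) {
  grads$dec_Wout <- grads$dec_Wout + t(fwd$Z3) %*% dLogits
  grads$dec_bout <- grads$dec_bout + colSums(dLogits)
  dZ3 <- dLogits %*% t(params$dec_Wout)
  l3 <- layernorm_bwd(dZ3, fwd$ln3, params$dec_ln3_g)
  grads$dec_ln3_g <- grads$dec_ln3_g + l3$dg
  grads$dec_ln3_b <- grads$dec_ln3_b + l3$db
  dR3 <- l3$dX
  dF2 <- dR3
  dF1 <- dF2 %*% t(params$dec_f_W2)
  grads$dec_f_W2 <- grads$dec_f_W2 + t(fwd$F1) %*% dF2
  grads$dec_f_b2 <- grads$dec_f_b2 + colSums(dF2)
  dpre <- dF1 * (fwd$pre > 0)
  grads$dec_f_W1 <- grads$dec_f_W1 + t(fwd$Z2) %*% dpre
  grads$dec_f_b1 <- grads$dec_f_b1 + colSums(dpre)
  dZ2 <- dR3 + dpre %*% t(params$dec_f_W1)
  l2 <- layernorm_bwd(dZ2, fwd$ln2, params$dec_ln2_g)
  grads$dec_ln2_g <- grads$dec_ln2_g + l2$dg
  grads$dec_ln2_b <- grads$dec_ln2_b + l2$db
  dR2 <- l2$dX
  mb2 <- mha_bwd(dR2, fwd$m2, dec_slice(params, "dec_c"), n_heads)
  grads <- put_attn_grads(grads, "dec_c", mb2)
  dE <- mb2$dKin + mb2$dVin
  dZ1 <- dR2 + mb2$dQin
  l1 <- layernorm_bwd(dZ1, fwd$ln1, params$dec_ln1_g)
  grads$dec_ln1_g <- grads$dec_ln1_g + l1$dg
  grads$dec_ln1_b <- grads$dec_ln1_b + l1$db
  dR1 <- l1$dX
  mb1 <- mha_bwd(dR1, fwd$m1, dec_slice(params, "dec_s"), n_heads)
  grads <- put_attn_grads(grads, "dec_s", mb1)
  dZ0 <- dR1 + mb1$dQin + mb1$dKin + mb1$dVin
  rows <- fwd$ids + 1L
  for (i in seq_along(rows)) {
    grads$dec_Emb[rows[i], ] <- grads$dec_Emb[rows[i], ] + dZ0[i, ]
  }
  L <- length(rows)
  grads$dec_Pos[seq_len(L), ] <- grads$dec_Pos[seq_len(L), , drop = FALSE] +
    dZ0
  list(grads = grads, dE = dE)
}

zero_grads <- function(params) {
  lapply(params, function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  })
}

# Loss, token accuracy and parameter gradients for one sample.
# `ids_in` are the decoder inputs, `targets` the shifted-by-one labels
# (both 0-based); PAD targets are masked out of loss and accuracy.
sample_loss_grads <- function(params, features, ids_in, targets, cfg,
                              grads = NULL, want_grads = TRUE) {
  n_heads <- cfg$n_heads
  ef <- encoder_fwd(features, params, n_heads)
  df <- decoder_fwd(ids_in, ef$E, params, n_heads)
  P <- df$probs
  valid <- targets != .SPECIALS[["PAD"]]
  n_valid <- sum(valid)
  cols <- targets + 1L
  picked <- P[cbind(seq_along(cols), cols)]
  eps <- 1e-12
  loss <- -sum(log(pmax(picked[valid], eps))) / max(n_valid, 1)
  pred <- max.col(P, ties.method = "first") - 1L
  n_correct <- sum(pred[valid] == targets[valid])
  if (!want_grads) {
    return(list(loss = loss, n_correct = n_correct, n_valid = n_valid))
  }
  dLogits <- P
  dLogits[cbind(seq_along(cols), cols)] <-
    dLogits[cbind(seq_along(cols), cols)] - 1
  dLogits[!valid, ] <- 0
  dLogits <- dLogits / max(n_valid, 1)
  if (is.null(grads)) grads <- zero_grads(params)
  db <- decoder_bwd(dLogits, df, params, n_heads, grads)
  grads <- encoder_bwd(db$dE, ef, params, n_heads, db$grads)
  list(loss = loss, n_correct = n_correct, n_valid = n_valid, grads = grads)
}
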