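# Training harness: sparse categorical cross-entropy, the optimizer menu
# (Adam, AdamW, Adadelta, Adafactor), the experiment grid runner, and
# per-family accuracy summaries.

#' Configure training
#'
#' @param optimizer one of `"adam"`, `"adamw"`, `"adadelta"`,
#'   `"adafactor"`.
#' @param learning_rate step size; `NULL` selects the optimizer's
#'   published default (adam/adamw 1e-3, adadelta 1.0, adafactor 1e-2).
#' @param batch_size minibatch size (gradients averaged over the batch).
#' @param max_epochs training epoch cap.
#' @param early_stop_patience stop after this many epochs without
#'   validation-loss improvement; 0 disables early stopping.
#' @param seed shuffling seed.
#' @return an object of class `tricap_train_config`.
#' @export
train_config <- function(optimizer = "adam", learning_rate = NULL,
                         batch_size = 16, max_epochs = 20,
                         early_stop_patience = 3, seed = 0) {
  opts <- c("adam", "adamw", "adadelta", "adafactor")
  if (!optimizer %in% opts) {
    stop("unknown optimizer: ", optimizer, " (expected one of ",
         paste(opts, collapse = ", "), ")", call. = FALSE)
  }
  if (is.null(learning_rate)) {
    learning_rate <- switch(optimizer, adam = 1e-3, adamw = 1e-3,
                            adadelta = 1.0, adafactor = 1e-2)
  }
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            early_stop_patience >= 0)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "tricap_train_config")
}

#' Sparse categorical cross-entropy
#'
#' Mean over positions of `-ln p[label]`, with integer (sparse) labels.
#' Positions whose label equals `pad` are excluded from the mean;
#' probabilities are clamped at a small epsilon before the log.
#'
#' @param probabilities numeric matrix, one row per position, columns over
#'   C classes; each row must sum to 1 (within tolerance).
#' @param labels integer vector of 0-based class indices, one per row.
#' @param pad optional label value to mask out (e.g. 0 for PAD).
#' @return non-negative scalar loss.
#' @examples
#' sparse_cce(matrix(0.25, 1, 4), 2)   # ln 4
#' @export
sparse_cce <- function(probabilities, labels, pad = NULL) {
  if (is.vector(probabilities)) probabilities <- matrix(probabilities, 1)
  labels <- as.integer(labels)
  C <- ncol(probabilities)
  if (any(labels < 0 | labels >= C)) {
    stop("label out of range [0, C)", call. = FALSE)
  }
  stopifnot(length(labels) == nrow(probabilities))
  if (any(abs(rowSums(probabilities) - 1) > 1e-4)) {
    stop("probability rows must sum to 1", call. = FALSE)
  }
  keep <- if (is.null(pad)) rep(TRUE, length(labels)) else labels != pad
  if (!any(keep)) return(0)
  p <- probabilities[cbind(which(keep), labels[keep] + 1L)]
  mean(-log(pmax(p, 1e-12)))
}

# --- optimizers -----------------------------------------------------------

optimizer_init <- function(config, params) {
  shape0 <- function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
                        else numeric(length(p))
  st <- switch(config$optimizer,
    adam = , adamw = list(m = lapply(params, shape0),
                          v = lapply(params, shape0)),
    adadelta = list(Eg = lapply(params, shape0),
                    Ed = lapply(params, shape0)),
    adafactor = list(V = lapply(params, function(p) {
      if (is.matrix(p)) list(R = numeric(nrow(p)), C = numeric(ncol(p)))
      else numeric(length(p))
    }))
  )
  st$t <- 0L
  st$config <- config
  st
}

optimizer_step <- function(state, params, grads) {
  cfg <- state$config
  lr <- cfg$learning_rate
  state$t <- state$t + 1L
  t <- state$t
  if (cfg$optimizer %in% c("adam", "adamw")) {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    for (k in names(params)) {
      g <- grads[[k]]
      state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * g
      state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * g^2
      mhat <- state$m[[k]] / (1 - b1^t)
      vhat <- state$v[[k]] / (1 - b2^t)
      upd <- lr * mhat / (sqrt(vhat) + eps)
      if (cfg$optimizer == "adamw") upd <- upd + lr * 0.004 * params[[k]]
      params[[k]] <- params[[k]] - upd
    }
  } else if (cfg$optimizer == "adadelta") {
    rho <- 0.95; eps <- 1e-6
    for (k in names(params)) {
      g <- grads[[k]]
      state$Eg[[k]] <- rho * state$Eg[[k]] + (1 - rho) * g^2
      dx <- -sqrt(state$Ed[[k]] + eps) / sqrt(state$Eg[[k]] + eps) * g
      state$Ed[[k]] <- rho * state$Ed[[k]] + (1 - rho) * dx^2
      params[[k]] <- params[[k]] + lr * dx
    }
  } else {  # adafactor: factored second moments + update clipping
    eps1 <- 1e-30; clip <- 1
    b2t <- 1 - t^(-0.8)
    for (k in names(params)) {
      g <- grads[[k]]
      if (is.matrix(g)) {
        st <- state$V[[k]]
        st$R <- b2t * st$R + (1 - b2t) * (rowMeans(g^2) + eps1)
        st$C <- b2t * st$C + (1 - b2t) * (colMeans(g^2) + eps1)
        state$V[[k]] <- st
        vhat <- outer(st$R, st$C) / mean(st$R)
      } else {
        state$V[[k]] <- b2t * state$V[[k]] + (1 - b2t) * (g^2 + eps1)
        vhat <- state$V[[k]]
      }
      u <- g / sqrt(vhat)
      rms_u <- sqrt(mean(u^2))
      if (is.finite(rms_u) && rms_u > clip) u <- u / rms_u
      params[[k]] <- params[[k]] - lr * u
    }
  }
  list(params = params, state = state)
}

# --- training -------------------------------------------------------------

eval_split <- function(params, feats, tok_in, tok_tgt, idx, cfg) {
  tot_loss <- 0; n_cor <- 0; n_val <- 0
  for (i in idx) {
    r <- sample_loss_grads(params, feats[i, , ], tok_in[i, ], tok_tgt[i, ],
                           cfg, want_grads = FALSE)
    tot_loss <- tot_loss + r$loss * r$n_valid
    n_cor <- n_cor + r$n_correct
    n_val <- n_val + r$n_valid
  }
  c(loss = tot_loss / max(n_val, 1), acc = n_cor / max(n_val, 1))
}

#' Train a caption transcoder
#'
#' Minimizes sparse categorical cross-entropy over non-PAD target
#' positions with the configured optimizer, stopping at `max_epochs` or
#' when the validation loss fails to improve for `early_stop_patience`
#' consecutive epochs.  Fully seeded and single-threaded: the same
#' configuration and seed reproduce the identical history.
#'
#' @param model an initialized `tricap_model`.
#' @param bundle a `tricap_features` bundle (or a plain
#'   `n x n_tokens x feature_dim` array).
#' @param targets integer matrix `n x max_len` of encoded target
#'   sequences (see [encode_caption()]), aligned with the bundle rows.
#' @param config a [train_config()].
#' @param val_bundle,val_targets optional held-out data monitored for
#'   early stopping; without them the training loss is monitored.
#' @return list with the trained `model` and a `history` data.frame
#'   (epoch, train_loss, train_acc, val_loss, val_acc).
#' @export
train <- function(model, bundle, targets, config,
                  val_bundle = NULL, val_targets = NULL) {
  stopifnot(inherits(config, "tricap_train_config"))
  feats <- if (inherits(bundle, "tricap_features")) bundle$features else bundle
  n <- dim(feats)[1]
  stopifnot(nrow(targets) == n)
  L <- ncol(targets)
  tok_in <- targets[, -L, drop = FALSE]
  tok_tgt <- targets[, -1, drop = FALSE]
  vfeats <- NULL
  if (!is.null(val_bundle)) {
    vfeats <- if (inherits(val_bundle, "tricap_features")) {
      val_bundle$features
    } else {
      val_bundle
    }
    vtok_in <- val_targets[, -L, drop = FALSE]
    vtok_tgt <- val_targets[, -1, drop = FALSE]
  }
  params <- model$params
  cfg <- model$config
  opt <- optimizer_init(config, params)
  hist <- vector("list", config$max_epochs)
  best <- Inf
  best_params <- params
  wait <- 0L
  epochs_run <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(config$seed * 1000L + epoch, sample.int(n))
    tot_loss <- 0; n_cor <- 0; n_val <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      batch <- ord[start:min(start + config$batch_size - 1, n)]
      grads <- zero_grads(params)
      for (i in batch) {
        r <- sample_loss_grads(params, feats[i, , ], tok_in[i, ],
                               tok_tgt[i, ], cfg, grads = grads)
        grads <- r$grads
        tot_loss <- tot_loss + r$loss * r$n_valid
        n_cor <- n_cor + r$n_correct
        n_val <- n_val + r$n_valid
      }
      grads <- lapply(grads, function(g) g / length(batch))
      stepped <- optimizer_step(opt, params, grads)
      params <- stepped$params
      opt <- stepped$state
    }
    train_loss <- tot_loss / max(n_val, 1)
    train_acc <- n_cor / max(n_val, 1)
    if (!is.null(vfeats)) {
      v <- eval_split(params, vfeats, vtok_in, vtok_tgt,
                      seq_len(dim(vfeats)[1]), cfg)
    } else {
      v <- c(loss = train_loss, acc = train_acc)
    }
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                train_acc = train_acc, val_loss = v[["loss"]],
                                val_acc = v[["acc"]])
    epochs_run <- epoch
    if (v[["loss"]] < best - 1e-6) {
      best <- v[["loss"]]
      best_params <- params
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (config$early_stop_patience > 0 &&
            wait >= config$early_stop_patience) {
        break
      }
    }
  }
  # keep the weights of the best monitored epoch, not the last one
  model$params <- best_params
  list(model = model,
       history = do.call(rbind, hist[seq_len(epochs_run)]))
}

#' Run an experiment grid
#'
#' Trains one model per combination of backbone, optimizer and the
#' TL/TR/IA switches on a curated synthetic corpus, and emits one
#' experiment record per cell in the standard column order.  Per-cell
#' failures are recorded (NA metrics), not fatal.
#'
#' @param manifest curated manifest with `split` and slot columns.
#' @param backbones character vector of backbone names.
#' @param optimizers character vector of optimizer names.
#' @param tl,tr,ia logical vectors of switch settings to cross.
#' @param model_config a [transcoder_config()] (vocab_size is replaced
#'   per run from the corpus vocabulary).
#' @param train_config a [train_config()] template; the optimizer field
#'   is overridden per cell.
#' @return data.frame of experiment records with columns
#'   `ID, CNN, OPTZ, TL, TR, IA, Loss, ACC, Epochs,
#'   Training Time (s), Test Time (s)`.
#' @export
run_grid <- function(manifest, backbones = "tiny_cnn",
                     optimizers = c("adam", "adamw", "adadelta", "adafactor"),
                     tl = FALSE, tr = FALSE, ia = c(FALSE, TRUE),
                     model_config = NULL, train_config = NULL) {
  grid <- expand.grid(ia = ia, tr = tr, tl = tl, optimizer = optimizers,
                      backbone = backbones, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0) stop("empty experiment grid", call. = FALSE)
  grid <- grid[, c("backbone", "optimizer", "tl", "tr", "ia")]
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    rec <- data.frame(ID = i, CNN = g$backbone, OPTZ = g$optimizer,
                      TL = as.integer(g$tl), TR = as.integer(g$tr),
                      IA = as.integer(g$ia), Loss = NA_real_,
                      ACC = NA_real_, Epochs = NA_integer_,
                      check.names = FALSE)
    rec[["Training Time (s)"]] <- NA_real_
    rec[["Test Time (s)"]] <- NA_real_
    res <- tryCatch({
      t0 <- proc.time()[["elapsed"]]
      fit <- fit_captioner(
        manifest,
        backbone = backbone_spec(g$backbone, pretrained = g$tl,
                                 trainable = g$tr),
        augment = if (g$ia) augment_spec(enabled = TRUE) else NULL,
        model_config = model_config, train_config = train_config,
        optimizer = g$optimizer)
      t1 <- proc.time()[["elapsed"]]
      ev <- eval_split(fit$model$params, fit$val$features, fit$val$tok_in,
                       fit$val$tok_tgt, seq_len(dim(fit$val$features)[1]),
                       fit$model$config)
      t2 <- proc.time()[["elapsed"]]
      h <- fit$history
      list(loss = ev[["loss"]], acc = ev[["acc"]], epochs = nrow(h),
           train_time = t1 - t0, test_time = t2 - t1)
    }, error = function(e) {
      warning("grid cell ", i, " failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      rec$Loss <- res$loss
      rec$ACC <- res$acc
      rec$Epochs <- res$epochs
      rec[["Training Time (s)"]] <- res$train_time
      rec[["Test Time (s)"]] <- res$test_time
    }
    rows[[i]] <- rec
  }
  do.call(rbind, rows)
}

#' Select the best experiment record
#'
#' The best model is the one with the highest accuracy.
#'
#' @param records experiment records with `ID` and `ACC` columns.
#' @return the single best row.
#' @export
best_record <- function(records) {
  stopifnot(nrow(records) > 0)
  records[which.max(records$ACC), , drop = FALSE]
}

#' Summarize a family of accuracies
#'
#' Arithmetic mean, population standard deviation (divisor n), range and
#' mean +/- sd of a vector of experiment accuracies.
#'
#' @param accuracies non-empty numeric vector.
#' @return one-row data.frame with columns `mu, sigma, Min, Max,
#'   mu-sigma, mu+sigma` (full precision; round for display).
#' @examples
#' family_summary(c(0.7, 0.9))  # mu 0.8, sigma 0.1
#' @export
family_summary <- function(accuracies) {
  if (length(accuracies) == 0 || any(!is.finite(accuracies))) {
    stop("accuracies must be a non-empty finite vector", call. = FALSE)
  }
  mu <- mean(accuracies)
  sigma <- sqrt(mean((accuracies - mu)^2))
  out <- data.frame(mu = mu, sigma = sigma, Min = min(accuracies),
                    Max = max(accuracies), check.names = FALSE)
  out[["mu-sigma"]] <- mu - sigma
  out[["mu+sigma"]] <- mu + sigma
  out
}

#' Summarize experiment families
#'
#' Applies [family_summary()] per backbone family plus a Global row, with
#' values rounded to 4 decimals as in the published summary table.
#'
#' @param records experiment records with `CNN` and `ACC` columns.
#' @return data.frame with columns `CNN, mu, sigma, Min, Max, mu-sigma,
#'   mu+sigma`.
#' @export
summarize_families <- function(records) {
  fams <- unique(records$CNN)
  rows <- lapply(c(fams, ".global"), function(f) {
    acc <- if (f == ".global") records$ACC else records$ACC[records$CNN == f]
    s <- family_summary(acc)
    cbind(data.frame(CNN = if (f == ".global") "Global" else f,
                     stringsAsFactors = FALSE), s)
  })
  out <- do.call(rbind, rows)
  num <- setdiff(names(out), "CNN")
  out[num] <- lapply(out[num], round_half_up, digits = 4)
  rownames(out) <- NULL
  out
}
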