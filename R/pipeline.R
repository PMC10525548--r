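# High-level pipeline: curated manifest -> features -> trained captioner.

#' Fit a captioner on a curated corpus
#'
#' Extracts features for the train and validation splits (augmentation,
#' when given, is applied to training images only), builds the
#' vocabulary from the training captions, initializes the transcoder and
#' trains it with validation-loss early stopping.
#'
#' @param manifest curated manifest with `split`, `path` and the slot
#'   columns.
#' @param backbone a [backbone_spec()]; default `tiny_cnn`.
#' @param augment optional [augment_spec()] for the training images.
#' @param model_config optional [transcoder_config()]; `vocab_size` is
#'   overridden from the corpus vocabulary.  Defaults to a compact
#'   configuration (embed_dim 64, 2 heads, ff_dim 128, max_len 8).
#' @param train_config optional [train_config()].
#' @param optimizer optional optimizer-name override.
#' @return list with `model` (vocabulary attached), `history`, the
#'   held-out `val` tensors, and the train/val manifests.
#' @export
fit_captioner <- function(manifest, backbone = backbone_spec("tiny_cnn"),
                          augment = NULL, model_config = NULL,
                          train_config = NULL, optimizer = NULL) {
  stopifnot("split" %in% names(manifest))
  tr_rows <- manifest[manifest$split == "train", , drop = FALSE]
  va_rows <- manifest[manifest$split == "val", , drop = FALSE]
  if (nrow(tr_rows) == 0) stop("no training rows in manifest", call. = FALSE)
  if (nrow(va_rows) == 0) va_rows <- tr_rows  # degenerate tiny corpora
  tr_feats <- extract_features(tr_rows, backbone, augment)
  va_feats <- extract_features(va_rows, backbone)

  vocab <- build_vocabulary(strsplit(tr_rows$caption, "[[:space:]]+"))
  if (is.null(model_config)) {
    model_config <- transcoder_config(embed_dim = 64, n_heads = 2,
                                      ff_dim = 128, max_len = 8,
                                      vocab_size = vocab$size)
  } else {
    model_config$vocab_size <- vocab$size
  }
  if (is.null(train_config)) train_config <- tricap::train_config()
  if (!is.null(optimizer)) {
    train_config <- tricap::train_config(
      optimizer = optimizer, batch_size = train_config$batch_size,
      max_epochs = train_config$max_epochs,
      early_stop_patience = train_config$early_stop_patience,
      seed = train_config$seed)
  }
  enc <- function(rows) {
    t(vapply(strsplit(rows$caption, "[[:space:]]+"),
             function(w) encode_caption(vocab, w, model_config$max_len),
             integer(model_config$max_len)))
  }
  tr_tok <- enc(tr_rows)
  va_tok <- enc(va_rows)
  model <- transcoder_init(model_config, dim(tr_feats$features)[3], vocab)
  fit <- train(model, tr_feats, tr_tok, train_config, va_feats, va_tok)
  L <- ncol(va_tok)
  list(model = fit$model, history = fit$history,
       val = list(features = va_feats$features,
                  tok_in = va_tok[, -L, drop = FALSE],
                  tok_tgt = va_tok[, -1, drop = FALSE],
                  manifest = va_rows),
       train_manifest = tr_rows, val_manifest = va_rows)
}
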