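# Shared builders for in-code fixtures.

# A tiny in-memory image set: n images per triple, rendered + noise,
# returned in the list form extract_features() accepts.
tiny_image_set <- function(triples, n_per_triple = 2, size = 32,
                           noise_sd = 0.02, seed = 1) {
  imgs <- list()
  ids <- character(0)
  k <- 0
  for (i in seq_len(nrow(triples))) {
    base <- tricap:::render_triple(triples$exam_type[i],
                                   triples$body_part[i],
                                   triples$problem[i], size, size)
    for (j in seq_len(n_per_triple)) {
      k <- k + 1
      noise <- tricap:::with_seed(seed + k,
                                  matrix(rnorm(size^2, 0, noise_sd),
                                         size, size))
      imgs[[k]] <- pmin(pmax(base + noise, 0), 1)
      ids <- c(ids, sprintf("im%03d", k))
    }
  }
  list(ids = ids, images = imgs)
}

three_triples <- function() {
  data.frame(exam_type = c("ct", "radiograph", "scan"),
             body_part = c("chest", "bone", "lung"),
             problem = c("tumor", "fracture", "nodule"),
             stringsAsFactors = FALSE)
}

# A small initialized transcoder for structural tests.
tiny_model <- function(seed = 0, vocab_words = c("ct", "chest", "tumor"),
                       embed_dim = 8, n_heads = 2, ff_dim = 12,
                       max_len = 6, feature_dim = 5) {
  vocab <- build_vocabulary(list(vocab_words))
  cfg <- transcoder_config(embed_dim = embed_dim, n_heads = n_heads,
                           ff_dim = ff_dim, max_len = max_len,
                           vocab_size = vocab$size, seed = seed)
  transcoder_init(cfg, feature_dim = feature_dim, vocab = vocab)
}

# Random slot confusion matrix with labels.
random_confusion <- function(k, max_count = 20) {
  m <- matrix(sample.int(max_count + 1, k * k, replace = TRUE) - 1L, k, k)
  dimnames(m) <- list(letters[seq_len(k)], letters[seq_len(k)])
  m
}

# Independent one-vs-rest 2x2 tabulation, written as plainly as possible:
# classify every (true, predicted) pair against one positive class.
brute_force_class_metrics <- function(m, class_idx) {
  k <- nrow(m)
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      n <- m[i, j]
      if (i == class_idx && j == class_idx) tp <- tp + n
      else if (i == class_idx) fn <- fn + n
      else if (j == class_idx) fp <- fp + n
      else tn <- tn + n
    }
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}
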