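test_that("sparse categorical cross-entropy matches closed forms", {
  onehot <- matrix(c(0, 1, 0, 0), 1)
  expect_equal(sparse_cce(onehot, 1L), 0, tolerance = 1e-10)
  expect_equal(sparse_cce(matrix(0.25, 1, 4), 2L), log(4), tolerance = 1e-12)
  p <- matrix(c(0.7, 0.1, 0.1, 0.1), 1)
  expect_equal(sparse_cce(p, 0L), -log(0.7), tolerance = 1e-12)
  expect_error(sparse_cce(p, 4L), "out of range")
  expect_error(sparse_cce(matrix(c(0.9, 0.3), 1), 0L), "sum to 1")

  # PAD masking: the masked first position does not enter the mean
  probs <- rbind(c(0.7, 0.1, 0.1, 0.1), c(0.25, 0.25, 0.25, 0.25))
  expect_equal(sparse_cce(probs, c(0L, 2L), pad = 0L),
               log(4), tolerance = 1e-12)
})

test_that("family summaries use the population standard deviation", {
  s <- family_summary(c(0.7, 0.9))
  expect_equal(s$mu, 0.8)
  expect_equal(s$sigma, 0.1)
  expect_equal(s[["mu-sigma"]], 0.7)
  expect_equal(s[["mu+sigma"]], 0.9)

  s1 <- family_summary(0.5)
  expect_equal(s1$mu, 0.5)
  expect_equal(s1$sigma, 0)
  expect_error(family_summary(numeric(0)), "non-empty")
})

test_that("family summary matches a brute-force oracle on random vectors", {
  withr::with_seed(21, {
    for (rep in 1:200) {
      x <- runif(sample(1:40, 1))
      s <- family_summary(x)
      mu <- sum(x) / length(x)
      sigma <- sqrt(sum((x - mu)^2) / length(x))
      expect_equal(s$mu, mu, tolerance = 1e-12)
      expect_equal(s$sigma, sigma, tolerance = 1e-12)
      expect_equal(s$Min, min(x))
      expect_equal(s$Max, max(x))
    }
  })
})

test_that("population and sample divisors differ on the printed accuracies", {
  acc <- load_fixture("densenet_acc")
  pop <- family_summary(acc)$sigma
  expect_equal(round(pop, 4), 0.0114)        # population divisor n
  expect_equal(round(sd(acc), 4), 0.0117)    # sample divisor would differ
})

test_that("every optimizer memorizes a single sample", {
  set <- tiny_image_set(three_triples()[1, ], n_per_triple = 1, seed = 2)
  fb <- extract_features(set, backbone_spec("tiny_cnn"))
  vocab <- build_vocabulary(list(c("ct", "chest", "tumor")))
  cfg <- transcoder_config(embed_dim = 16, n_heads = 2, ff_dim = 32,
                           max_len = 8, vocab_size = vocab$size, seed = 1)
  tgt <- matrix(encode_caption(vocab, c("ct", "chest", "tumor"), 8), 1)
  for (opt in c("adam", "adamw", "adadelta", "adafactor")) {
    model <- transcoder_init(cfg, feature_dim = dim(fb$features)[3], vocab)
    tc <- train_config(optimizer = opt, batch_size = 1, max_epochs = 200,
                       early_stop_patience = 0, seed = 1)
    fit <- train(model, fb, tgt, tc)
    final <- tail(fit$history$train_loss, 1)
    expect_lt(final, 0.05)
    # the memorized caption is generated exactly
    expect_identical(generate_caption(fb$features[1, , ], fit$model),
                     c("ct", "chest", "tumor"))
  }
})

test_that("training is deterministic given config and seed", {
  set <- tiny_image_set(three_triples(), n_per_triple = 2, seed = 6)
  fb <- extract_features(set, backbone_spec("tiny_cnn"))
  tri <- three_triples()
  caps <- rep(lapply(seq_len(3), function(i) unlist(tri[i, ], use.names = FALSE)),
              each = 2)
  vocab <- build_vocabulary(caps)
  cfg <- transcoder_config(embed_dim = 16, n_heads = 2, ff_dim = 32,
                           max_len = 8, vocab_size = vocab$size, seed = 4)
  tgt <- t(vapply(caps, function(w) encode_caption(vocab, w, 8), integer(8)))
  tc <- train_config(max_epochs = 5, early_stop_patience = 0, seed = 7)
  run <- function() {
    model <- transcoder_init(cfg, dim(fb$features)[3], vocab)
    train(model, fb, tgt, tc)$history
  }
  expect_identical(run(), run())
})

test_that("memorization loss is non-increasing after the initial epochs", {
  set <- tiny_image_set(three_triples()[1:2, ], n_per_triple = 1,
                        noise_sd = 0, seed = 8)
  fb <- extract_features(set, backbone_spec("tiny_cnn"))
  tri <- three_triples()
  caps <- lapply(1:2, function(i) unlist(tri[i, ], use.names = FALSE))
  vocab <- build_vocabulary(caps)
  cfg <- transcoder_config(embed_dim = 16, n_heads = 2, ff_dim = 32,
                           max_len = 8, vocab_size = vocab$size, seed = 2)
  tgt <- t(vapply(caps, function(w) encode_caption(vocab, w, 8), integer(8)))
  model <- transcoder_init(cfg, dim(fb$features)[3], vocab)
  fit <- train(model, fb, tgt,
               train_config(batch_size = 2, max_epochs = 40,
                            early_stop_patience = 0, seed = 3))
  loss <- fit$history$train_loss
  jumps <- diff(loss[5:length(loss)])
  expect_true(all(jumps <= 1e-3))
})

test_that("best-record selection maximizes accuracy", {
  rec <- data.frame(ID = 1:3, ACC = c(0.70, 0.76, 0.73))
  expect_equal(best_record(rec)$ID, 2)
  expect_error(best_record(rec[0, ]), "nrow")
})

test_that("the experiment grid emits one record per combination", {
  dir <- file.path(tempdir(), "synth_grid")
  unlink(dir, recursive = TRUE)
  man <- generate_corpus(synth_spec(three_triples(), n_per_triple = 5,
                                    image_size = c(32, 32), seed = 4), dir)
  man <- split_corpus(man, seed = 4)
  rec <- run_grid(man, optimizers = c("adam", "adadelta"), ia = FALSE,
                  model_config = transcoder_config(embed_dim = 16,
                                                   n_heads = 2, ff_dim = 32,
                                                   max_len = 8,
                                                   vocab_size = 5),
                  train_config = train_config(max_epochs = 2, seed = 1))
  expect_equal(nrow(rec), 2)
  expect_equal(names(rec), c("ID", "CNN", "OPTZ", "TL", "TR", "IA", "Loss",
                             "ACC", "Epochs", "Training Time (s)",
                             "Test Time (s)"))
  expect_true(all(rec$ACC >= 0 & rec$ACC <= 1))
  expect_true(all(rec$Epochs <= 2))
  expect_error(run_grid(man, optimizers = character(0)), "empty")
})

test_that("family summarization reproduces known values and rounds", {
  rec <- data.frame(CNN = rep(c("a", "b"), each = 2),
                    ACC = c(0.7, 0.9, 0.5, 0.5))
  s <- summarize_families(rec)
  expect_equal(s$CNN, c("a", "b", "Global"))
  expect_equal(s$mu, c(0.8, 0.5, 0.65))
  expect_equal(s$sigma[1], 0.1)
})
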