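test_that("token accuracy counts position-wise matches", {
  expect_equal(token_accuracy(list(c("a", "b", "c")), list(c("a", "b", "c"))),
               1.0)
  expect_equal(token_accuracy(list(c("x", "y", "z")), list(c("a", "b", "c"))),
               0.0)
  expect_equal(token_accuracy(list(c("ct", "lung", "tumor")),
                              list(c("ct", "chest", "tumor"))), 2 / 3)
  # short predictions are padded to the reference length
  expect_equal(token_accuracy(list("ct"), list(c("ct", "chest", "tumor"))),
               1 / 3)
  expect_error(token_accuracy(list(), list()), "non-empty")
  expect_error(token_accuracy(list("a"), list("a", "b")), "aligned")
})

test_that("F1 is the harmonic mean with undefined propagation", {
  expect_equal(f1_score(0.5, 0.5), 0.5)
  expect_equal(f1_score(0.71, 0.88), 2 * 0.71 * 0.88 / (0.71 + 0.88))
  expect_true(is.na(f1_score(0, 0)))
  expect_true(is.na(f1_score(NA, 0.5)))
  expect_true(is.na(f1_score(0.5, NA)))
})

test_that("BLEU-1 is clipped corpus-level unigram precision", {
  expect_equal(bleu1(list(c("a", "b", "c")), list(c("a", "b", "c"))), 1.0)
  expect_equal(bleu1(list(c("ct", "lung", "tumor")),
                     list(c("ct", "chest", "tumor"))), 2 / 3)
  # two 3-token predictions, 5 matched unigrams in total -> 5/6
  expect_equal(bleu1(list(c("a", "b", "c"), c("d", "e", "x")),
                     list(c("a", "b", "c"), c("d", "e", "f"))), 5 / 6)
  # repeated predicted words are clipped by the reference count
  expect_equal(bleu1(list(c("a", "a", "a")), list(c("a", "b", "c"))), 1 / 3)
  expect_error(bleu1(list(character(0)), list("a")), "undefined")
  # add-one smoothing keeps empty predictions finite
  expect_equal(bleu1(list(character(0)), list("a"), smooth = TRUE), 1)
  expect_equal(bleu1(list(c("a", "b", "x")), list(c("a", "b", "c")),
                     smooth = TRUE), 3 / 4)
})

test_that("synonym merging only affects the merged accuracy report", {
  preds <- list(c("xray", "chest", "cyst"))
  refs <- list(c("radiograph", "chest", "cystic"))
  expect_equal(token_accuracy(preds, refs), 1 / 3)
  expect_equal(token_accuracy(lapply(preds, apply_synonyms),
                              lapply(refs, apply_synonyms)), 1)
  expect_equal(apply_synonyms(c("tomography", "lung")), c("ct", "lung"))
})

test_that("token accuracy and BLEU-1 coincide on aligned slot triples", {
  # each slot draws from its own category vocabulary, so a predicted word
  # can only match the reference at its own position -- under which both
  # statistics reduce to matched/total
  slots <- list(c("ct", "scan", "xray"), c("chest", "lung", "bone"),
                c("tumor", "cyst", "nodule"))
  draw_triple <- function() vapply(slots, sample, "", size = 1)
  withr::with_seed(31, {
    for (rep in 1:25) {
      n <- sample(2:10, 1)
      refs <- replicate(n, draw_triple(), simplify = FALSE)
      preds <- lapply(refs, function(r) {
        swap <- runif(3) < 0.4
        for (k in which(swap)) r[k] <- sample(slots[[k]], 1)
        r
      })
      expect_equal(token_accuracy(preds, refs), bleu1(preds, refs))
    }
  })
})

test_that("slot confusion matrices tabulate true rows vs predicted columns", {
  cm <- build_slot_confusion(c("A", "B", "B"), c("A", "A", "B"))
  expect_equal(unname(cm), rbind(c(1L, 1L), c(0L, 1L)))
  expect_equal(rownames(cm), c("A", "B"))

  expect_equal(dim(build_slot_confusion(character(0), character(0))),
               c(0L, 0L))

  perfect <- build_slot_confusion(c("x", "y", "x"), c("x", "y", "x"))
  expect_true(all(perfect[upper.tri(perfect)] == 0) &&
                all(perfect[lower.tri(perfect)] == 0))

  # data.frame interface selects the slot column
  pred <- data.frame(exam_type = c("ct", "scan"), body_part = c("chest", "chest"),
                     problem = c("tumor", "cyst"))
  cm2 <- build_slot_confusion(pred, pred, "problem")
  expect_equal(sum(diag(cm2)), 2)

  # predicted-only labels are appended after true labels
  cm3 <- build_slot_confusion(c("zz", "aa"), c("aa", "aa"))
  expect_equal(rownames(cm3), c("aa", "zz"))
})

test_that("confusion metrics equal a brute-force one-vs-rest oracle", {
  withr::with_seed(17, {
    for (rep in 1:60) {
      k <- sample(2:7, 1)
      m <- random_confusion(k)
      met <- confusion_metrics(m)
      total <- sum(m)
      for (ci in seq_len(k)) {
        bf <- brute_force_class_metrics(m, ci)
        row <- met[ci, ]
        expect_equal(row$TP, unname(bf["TP"]))
        expect_equal(row$FP, unname(bf["FP"]))
        expect_equal(row$TN, unname(bf["TN"]))
        expect_equal(row$FN, unname(bf["FN"]))
        expect_equal(row$P, unname(bf["TP"] + bf["FN"]))
        expect_equal(row$N, unname(bf["FP"] + bf["TN"]))
        expect_equal(row$P + row$N, total)
        if (row$P > 0) expect_equal(row$TPR, unname(bf["TP"] / (bf["TP"] + bf["FN"])))
        expect_equal(row$ACC, unname((bf["TP"] + bf["TN"]) / total))
      }
      expect_equal(sum(met$TP), sum(diag(m)))
      expect_equal(sum(met$P), total)
    }
  })
})

test_that("undefined cells follow the dash conventions", {
  # class 'b' never predicted (PPV undefined), never correct (F1 undefined)
  m <- matrix(c(5L, 0L,
                2L, 0L), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  met <- confusion_metrics(m)
  expect_true(is.na(met$PPV[met$Class == "b"]))
  expect_true(is.na(met$F1[met$Class == "b"]))
  fmt <- format_metric_table(met)
  expect_equal(fmt$PPV[fmt$Class == "b"], "-")
  expect_equal(fmt$F1[fmt$Class == "b"], "-")
  # TP = 0 with FP > 0 prints PPV as 0.00, F1 still dashed
  m2 <- matrix(c(0L, 3L,
                 2L, 4L), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  f2 <- format_metric_table(confusion_metrics(m2))
  expect_equal(f2$PPV[f2$Class == "a"], "0.00")
  expect_equal(f2$F1[f2$Class == "a"], "-")
  expect_error(confusion_metrics(matrix(0, 2, 3)), "square")
})

test_that("rates round half away from zero at 2 decimals", {
  expect_equal(tricap:::round_half_up(0.125, 2), 0.13)
  expect_equal(tricap:::round_half_up(0.878, 2), 0.88)
  expect_equal(tricap:::round_half_up(0.004, 2), 0.00)
  m <- matrix(c(108L, 15L, 44L, 117L), 2, 2, byrow = TRUE,
              dimnames = list(c("pos", "neg"), c("pos", "neg")))
  fmt <- format_metric_table(confusion_metrics(m))
  expect_equal(fmt$TPR[1], "0.88")  # 108/123 = 0.878...
})

test_that("metric tables write and read back with dashes intact", {
  m <- load_fixture("exam_confusion")
  path <- tempfile(fileext = ".csv")
  write_metric_table(confusion_metrics(m), path)
  txt <- readLines(path)
  expect_equal(txt[1], "Class,P,N,TP,FP,TN,FN,TPR,TNR,PPV,NPV,ACC,F1")
  expect_true(any(grepl(",-$", txt)))
})
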