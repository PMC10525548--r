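test_that("keyword frequency index counts records and orders correctly", {
  expect_equal(nrow(compute_keyword_frequencies(list())), 0)

  idx <- compute_keyword_frequencies(list(c("a", "b"), "a", c("a", "c")))
  expect_equal(idx$keyword, c("a", "b", "c"))
  expect_equal(idx$frequency, c(3L, 1L, 1L))

  # ties broken lexicographically; duplicate within a record counts once
  idx <- compute_keyword_frequencies(list(c("zeta", "zeta", "alpha")))
  expect_equal(idx$keyword, c("alpha", "zeta"))
  expect_equal(idx$frequency, c(1L, 1L))
})

test_that("frequency index matches a brute-force count on random corpora", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      n <- sample(1:30, 1)
      records <- replicate(n, sample(letters[1:8], sample(1:5, 1)),
                           simplify = FALSE)
      idx <- compute_keyword_frequencies(records)
      for (kw in idx$keyword) {
        brute <- sum(vapply(records, function(r) kw %in% r, logical(1)))
        expect_identical(idx$frequency[idx$keyword == kw], brute)
      }
      expect_setequal(idx$keyword, unique(unlist(records)))
      expect_true(all(diff(idx$frequency) <= 0))
    }
  })
})

test_that("keyword-of-interest selection is strictly above threshold", {
  idx <- data.frame(keyword = c("ct", "chest", "tumor", "rare"),
                    frequency = c(501L, 500L, 777L, 3L))
  tpl <- list(exam_type = "ct", body_part = "chest", problem = "tumor")
  koi <- select_keywords_of_interest(idx, 500, tpl)
  expect_equal(koi$exam_type, "ct")      # 501 > 500 retained
  expect_equal(koi$body_part, character(0))  # 500 dropped (strict)
  expect_equal(koi$problem, "tumor")

  empty <- select_keywords_of_interest(
    data.frame(keyword = character(0), frequency = integer(0)), 500, tpl)
  expect_equal(lengths(empty), c(exam_type = 0L, body_part = 0L,
                                 problem = 0L))
})

test_that("triple enumeration is the ordered Cartesian product", {
  one <- enumerate_triples(list(exam_type = "ct", body_part = "chest",
                                problem = "tumor"))
  expect_equal(nrow(one), 1)

  none <- enumerate_triples(list(exam_type = "ct", body_part = character(0),
                                 problem = "tumor"))
  expect_equal(nrow(none), 0)

  # exhaustive size check for all small shapes
  for (ne in 1:3) for (nb in 1:3) for (np in 1:3) {
    tr <- enumerate_triples(list(exam_type = paste0("e", 1:ne),
                                 body_part = paste0("b", 1:nb),
                                 problem = paste0("p", 1:np)))
    expect_equal(nrow(tr), ne * nb * np)
  }

  # the built-in template has 14 x 31 x 24 keywords
  full <- enumerate_triples(default_category_template())
  expect_equal(nrow(full), 10416)
  # problem varies fastest, exam slowest
  expect_equal(full$exam_type[1], full$exam_type[2])
  expect_true(full$problem[1] != full$problem[2])
})

test_that("triple assignment requires exactly one keyword per category", {
  cats <- list(exam_type = c("ct", "scan"), body_part = "chest",
               problem = "tumor")
  expect_equal(unname(assign_triple(c("ct", "chest", "tumor", "other"), cats)),
               c("ct", "chest", "tumor"))
  expect_null(assign_triple(c("ct", "chest"), cats))          # missing slot
  expect_null(assign_triple(c("ct", "scan", "chest", "tumor"), cats))  # ambiguous
})

test_that("subclass selection keeps counts inside inclusive bounds", {
  groups <- list(t1 = paste0("i", 1:9), t2 = paste0("i", 1:10),
                 t3 = paste0("i", 1:80), t4 = paste0("i", 1:81))
  kept <- select_subclasses(groups, 10, 80)
  expect_setequal(names(kept), c("t2", "t3"))
  expect_length(select_subclasses(list(), 10, 80), 0)
  expect_true(all(lengths(kept) >= 10 & lengths(kept) <= 80))
})

test_that("split sizes follow the rounding rule", {
  man <- data.frame(id = seq_len(1419))
  s <- split_corpus(man, c(0.6, 0.2, 0.2), seed = 11)
  expect_equal(as.integer(table(s$split)[c("train", "val", "test")]),
               c(851L, 284L, 284L))

  s10 <- split_corpus(data.frame(id = 1:10), seed = 2)
  expect_equal(as.integer(table(s10$split)[c("train", "val", "test")]),
               c(6L, 2L, 2L))

  expect_error(split_corpus(man, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("splits are deterministic and partition the records", {
  man <- data.frame(id = sprintf("r%03d", 1:123))
  for (seed in 1:100) {
    a <- split_corpus(man, seed = seed)
    sets <- split(a$id, a$split)
    expect_equal(sort(unname(unlist(sets))), sort(man$id))
    expect_equal(sum(lengths(sets)), nrow(man))
    expect_true(length(intersect(sets$train, sets$val)) == 0)
    expect_true(length(intersect(sets$train, sets$test)) == 0)
    expect_true(length(intersect(sets$val, sets$test)) == 0)
  }
  expect_identical(split_corpus(man, seed = 42)$split,
                   split_corpus(man, seed = 42)$split)
})

test_that("curation pipeline filters, assigns and splits a toy corpus", {
  # 3 subclasses of sizes 12, 4, 15: the middle one violates min_size
  mk <- function(e, b, p, n, off) data.frame(
    id = sprintf("%s%03d", e, off + seq_len(n)),
    path = "none.png",
    caption = paste(e, b, p),
    keywords = paste(e, b, p, "noise", sep = ";"),
    stringsAsFactors = FALSE)
  man <- rbind(mk("ct", "chest", "tumor", 12, 0),
               mk("scan", "lung", "nodule", 4, 100),
               mk("radiograph", "bone", "fracture", 15, 200))
  cur <- curate_corpus(man, threshold = 0, min_size = 10, max_size = 80,
                       seed = 5)
  expect_equal(nrow(cur), 27)
  expect_false("scan" %in% cur$exam_type)
  expect_true(all(cur$split %in% c("train", "val", "test")))
  counts <- table(paste(cur$exam_type, cur$body_part, cur$problem))
  expect_true(all(counts >= 10 & counts <= 80))
})

test_that("ROCO-style per-split text files are read into a manifest", {
  caps <- tempfile(); kws <- tempfile()
  writeLines(c("img1\tCT of the chest showing a tumor",
               "img2\tradiograph of the hip"), caps)
  writeLines(c("img1\tct chest tumor", "img2\tradiograph hip fracture"), kws)
  m <- read_roco_corpus(caps, kws, image_dir = "imgs")
  expect_equal(nrow(m), 2)
  expect_equal(m$keywords[1], "ct;chest;tumor")
  expect_equal(m$path[2], file.path("imgs", "img2.png"))
})
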