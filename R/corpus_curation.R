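# Corpus curation: keyword frequency index, keywords of interest,
# triple enumeration, size-bounded subclass selection, 60/20/20 split.

#' Normalize a keyword token
#'
#' Lowercases and strips punctuation.  No stemming is applied: the keyword
#' lists used downstream already contain stemmed-looking forms ("pelvi",
#' "absces") which are treated as opaque tokens.
#'
#' @param x character vector of raw keywords.
#' @return character vector of normalized keywords.
#' @export
normalize_keyword <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:punct:]]", "", x)
}

#' Compute the keyword frequency index of a corpus
#'
#' Counts, for every distinct keyword, the number of records whose keyword
#' set contains it.  Keywords are case-normalized before counting and
#' deduplicated within a record, so the frequency is a record count.
#'
#' @param records a list of character vectors, one keyword set per record.
#' @return a data.frame with columns `keyword` and `frequency`, ordered by
#'   descending frequency with ties broken lexicographically.
#' @examples
#' compute_keyword_frequencies(list(c("a", "b"), "a", c("a", "c")))
#' @export
compute_keyword_frequencies <- function(records) {
  if (length(records) == 0) {
    return(data.frame(keyword = character(0), frequency = integer(0),
                      stringsAsFactors = FALSE))
  }
  kw <- unlist(lapply(records, function(r) unique(normalize_keyword(r))))
  kw <- kw[nzchar(kw)]
  tab <- table(kw)
  out <- data.frame(keyword = names(tab), frequency = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$keyword), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select keywords of interest above a frequency threshold
#'
#' Retains, within each category of a template, exactly the keywords whose
#' corpus frequency is strictly greater than `threshold`.  Keywords absent
#' from the template (uncategorizable) are discarded.
#'
#' @param index keyword frequency index from [compute_keyword_frequencies()].
#' @param threshold non-negative integer; a keyword is kept iff its
#'   frequency is `> threshold` (strict).
#' @param categories template: a named list with elements `exam_type`,
#'   `body_part`, `problem`, each a character vector of candidate keywords.
#'   Defaults to the built-in category template.
#' @return a named list (`exam_type`, `body_part`, `problem`) of retained
#'   keywords, template order preserved; the three lists are disjoint.
#' @export
select_keywords_of_interest <- function(index, threshold = 500,
                                        categories = default_category_template()) {
  stopifnot(threshold >= 0)
  keep <- index$keyword[index$frequency > threshold]
  out <- lapply(categories, function(k) k[k %in% keep])
  stopifnot(!anyDuplicated(unlist(out)))
  out
}

#' Built-in category template for keywords of interest
#'
#' The assignment of candidate keywords to the three slot categories
#' (exam type, body part, identified problem), as shipped in
#' `inst/extdata/table1.csv`.
#'
#' @return named list of three character vectors.
#' @export
default_category_template <- function() {
  t1 <- read.csv(extdata_path("table1.csv"), stringsAsFactors = FALSE)
  list(exam_type = t1$keyword[t1$category == "exam_type"],
       body_part = t1$keyword[t1$category == "body_part"],
       problem   = t1$keyword[t1$category == "problem"])
}

#' Enumerate all caption triples
#'
#' Cartesian product exam_type x body_part x problem, in deterministic
#' order: exam type varies slowest, problem fastest, each in the order
#' given by the category map.
#'
#' @param categories named list with `exam_type`, `body_part`, `problem`.
#' @return data.frame with columns `exam_type`, `body_part`, `problem`.
#' @export
enumerate_triples <- function(categories) {
  e <- categories$exam_type
  b <- categories$body_part
  p <- categories$problem
  if (length(e) == 0 || length(b) == 0 || length(p) == 0) {
    return(data.frame(exam_type = character(0), body_part = character(0),
                      problem = character(0), stringsAsFactors = FALSE))
  }
  g <- expand.grid(problem = p, body_part = b, exam_type = e,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- g[, c("exam_type", "body_part", "problem")]
  rownames(out) <- NULL
  out
}

#' Assign a caption triple to a record
#'
#' A record is assigned the triple (e, b, p) iff its keyword set contains
#' exactly one keyword from each of the three categories.  Records with a
#' missing slot, or matching two or more keywords in one category
#' (ambiguous), are excluded and get `NULL`.
#'
#' @param keywords character vector, the record's keyword set.
#' @param categories named list with `exam_type`, `body_part`, `problem`.
#' @return named character vector `c(exam_type=, body_part=, problem=)`,
#'   or `NULL` for unassignable records.
#' @export
assign_triple <- function(keywords, categories) {
  kw <- unique(normalize_keyword(keywords))
  hit <- lapply(categories[c("exam_type", "body_part", "problem")],
                function(k) kw[kw %in% k])
  if (any(lengths(hit) != 1L)) return(NULL)
  c(exam_type = hit$exam_type, body_part = hit$body_part,
    problem = hit$problem)
}

#' Filter subclasses by size
#'
#' Keeps exactly the triples whose image count lies in
#' `[min_size, max_size]`, boundaries inclusive.
#'
#' @param triple_to_images named list mapping a triple key to a character
#'   vector of image ids.
#' @param min_size,max_size inclusive size bounds (defaults 10 and 80).
#' @return the filtered named list.
#' @export
select_subclasses <- function(triple_to_images, min_size = 10, max_size = 80) {
  stopifnot(min_size <= max_size)
  n <- lengths(triple_to_images)
  triple_to_images[n >= min_size & n <= max_size]
}

#' Randomly split a corpus into train/validation/test
#'
#' Random permutation driven by `seed`; the validation and test sizes are
#' `round(frac * n)` (half away from zero) and training takes the
#' remainder, which reproduces 851/284/284 for n = 1419 at 60/20/20.
#'
#' @param manifest a corpus manifest data.frame (one row per image).
#' @param fractions numeric length 3 (train, val, test), summing to 1.
#' @param seed integer seed; same seed gives the identical assignment.
#' @return the manifest with a `split` column in
#'   `c("train", "val", "test")`.
#' @export
split_corpus <- function(manifest, fractions = c(0.6, 0.2, 0.2), seed = 0) {
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  n <- nrow(manifest)
  if (n == 0) stop("cannot split an empty manifest", call. = FALSE)
  n_val <- round_half_up(fractions[2] * n, 0)
  n_test <- round_half_up(fractions[3] * n, 0)
  n_train <- n - n_val - n_test
  stopifnot(n_train >= 0)
  perm <- with_seed(seed, sample.int(n))
  split <- character(n)
  split[perm[seq_len(n_train)]] <- "train"
  split[perm[n_train + seq_len(n_val)]] <- "val"
  split[perm[n_train + n_val + seq_len(n_test)]] <- "test"
  manifest$split <- split
  manifest
}

#' Curate a corpus end to end
#'
#' Runs the full dataset-selection algorithm on a manifest: keyword
#' frequency index, keyword-of-interest selection above `threshold`,
#' per-record triple assignment (exactly one keyword per category),
#' subclass size filtering, and the random split.
#'
#' @param manifest data.frame with at least `id` and `keywords`
#'   (`;`-separated) columns, as read by [read_manifest()].
#' @param categories category template (candidate keywords per slot).
#' @param threshold keyword frequency threshold (strict `>`).
#' @param min_size,max_size inclusive subclass size bounds.
#' @param fractions train/val/test fractions.
#' @param seed split seed.
#' @return the curated manifest: rows restricted to retained subclasses,
#'   with `exam_type`, `body_part`, `problem` and `split` columns added.
#' @export
curate_corpus <- function(manifest,
                          categories = default_category_template(),
                          threshold = 500, min_size = 10, max_size = 80,
                          fractions = c(0.6, 0.2, 0.2), seed = 0) {
  kw_sets <- strsplit(manifest$keywords, ";", fixed = TRUE)
  index <- compute_keyword_frequencies(kw_sets)
  koi <- select_keywords_of_interest(index, threshold, categories)
  triples <- lapply(kw_sets, assign_triple, categories = koi)
  has <- !vapply(triples, is.null, logical(1))
  m <- manifest[has, , drop = FALSE]
  tr <- do.call(rbind, triples[has])
  m$exam_type <- tr[, "exam_type"]
  m$body_part <- tr[, "body_part"]
  m$problem <- tr[, "problem"]
  key <- paste(m$exam_type, m$body_part, m$problem, sep = "|")
  groups <- split(m$id, key)
  kept <- select_subclasses(groups, min_size, max_size)
  m <- m[key %in% names(kept), , drop = FALSE]
  if (nrow(m) == 0) stop("no subclass satisfies the size bounds", call. = FALSE)
  rownames(m) <- NULL
  split_corpus(m, fractions, seed)
}

#' Read a corpus manifest CSV
#'
#' Layout: columns `id,path,caption,keywords` with `;`-separated keywords;
#' curated manifests additionally carry
#' `exam_type,body_part,problem,split`.
#'
#' @param path CSV file path.
#' @return manifest data.frame.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "path", "caption", "keywords")
  if (!all(req %in% names(m))) {
    stop("manifest must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(m$id)) stop("manifest ids must be unique", call. = FALSE)
  m
}

#' Write a corpus manifest CSV
#'
#' @param manifest manifest data.frame.
#' @param path output CSV file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a ROCO-style split from per-split text files
#'
#' The native layout pairs a captions file and a keywords file, each with
#' lines `<image id><TAB><text>`; keywords are whitespace-separated on
#' their line.  Records present in both files are returned.
#'
#' @param captions_file path to the captions file.
#' @param keywords_file path to the keywords file.
#' @param image_dir directory that holds `<id>.png` / `<id>.jpg` images;
#'   used to fill the `path` column (files need not exist yet).
#' @return manifest data.frame with columns `id,path,caption,keywords`.
#' @export
read_roco_corpus <- function(captions_file, keywords_file, image_dir = ".") {
  parse_kv <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    id <- sub("\t.*$", "", lines)
    val <- sub("^[^\t]*\t", "", lines)
    stats::setNames(val, id)
  }
  caps <- parse_kv(captions_file)
  kws <- parse_kv(keywords_file)
  ids <- intersect(names(caps), names(kws))
  data.frame(
    id = ids,
    path = file.path(image_dir, paste0(ids, ".png")),
    caption = unname(caps[ids]),
    keywords = vapply(strsplit(unname(kws[ids]), "[[:space:]]+"),
                      function(x) paste(x[nzchar(x)], collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
}
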