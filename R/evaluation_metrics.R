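# Slot-wise evaluation: token accuracy, F1, BLEU-1 unigram precision,
# confusion matrices and their one-vs-rest per-class metric tables.

#' Position-wise token accuracy
#'
#' Fraction of correctly generated words over all generated words:
#' each prediction is compared position by position against its
#' reference (padded to the reference length), and the counts are pooled
#' over the corpus.
#'
#' @param predictions list of character vectors (generated captions).
#' @param references aligned list of character vectors.
#' @return accuracy in [0, 1].
#' @examples
#' token_accuracy(list(c("ct", "lung", "tumor")),
#'                list(c("ct", "chest", "tumor")))  # 2/3
#' @export
token_accuracy <- function(predictions, references) {
  if (length(predictions) == 0 || length(predictions) != length(references)) {
    stop("predictions and references must be aligned and non-empty",
         call. = FALSE)
  }
  correct <- 0L
  total <- 0L
  for (i in seq_along(references)) {
    ref <- references[[i]]
    pred <- predictions[[i]]
    n <- length(ref)
    pred <- c(pred, rep("", n))[seq_len(n)]
    correct <- correct + sum(pred == ref)
    total <- total + n
  }
  correct / total
}

#' F1 score from precision and sensitivity
#'
#' Harmonic mean `2pr / (p + r)`.  Undefined (NA) when either input is
#' undefined or when `p + r = 0`; undefined cells are printed as dashes
#' in the metric tables.
#'
#' @param precision,sensitivity values in [0, 1], or NA for undefined.
#' @return the F1 score, or `NA` when undefined.
#' @export
f1_score <- function(precision, sensitivity) {
  ifelse(is.na(precision) | is.na(sensitivity) |
           (precision + sensitivity) == 0,
         NA_real_,
         2 * precision * sensitivity / (precision + sensitivity))
}

#' Corpus-level BLEU-1 unigram precision
#'
#' The number of correctly predicted unigrams (predicted counts clipped
#' by the reference counts, per pair) divided by the total number of
#' predicted unigrams, pooled over the corpus.  No brevity penalty and
#' no higher-order n-grams.  `smooth = TRUE` applies add-one smoothing
#' (one phantom match and one phantom prediction), for comparison with
#' smoothed BLEU implementations; the default is the unsmoothed ratio.
#'
#' @param predictions list of character vectors (generated captions).
#' @param references aligned list of character vectors.
#' @param smooth apply add-one smoothing (default FALSE).
#' @return BLEU-1 in [0, 1].
#' @export
bleu1 <- function(predictions, references, smooth = FALSE) {
  if (length(predictions) == 0 || length(predictions) != length(references)) {
    stop("predictions and references must be aligned and non-empty",
         call. = FALSE)
  }
  matched <- 0L
  predicted <- 0L
  for (i in seq_along(predictions)) {
    pred <- predictions[[i]]
    ref <- references[[i]]
    predicted <- predicted + length(pred)
    if (length(pred) == 0) next
    pt <- table(pred)
    rt <- table(ref)
    common <- intersect(names(pt), names(rt))
    matched <- matched + sum(pmin(pt[common], rt[common]))
  }
  if (smooth) return((matched + 1) / (predicted + 1))
  if (predicted == 0) {
    stop("no predicted unigrams; BLEU-1 undefined", call. = FALSE)
  }
  matched / predicted
}

#' Merge synonymous slot words
#'
#' Maps each token through a synonym table before scoring.  The default
#' table merges the pairs that the slot vocabularies treat as distinct
#' classes although they describe the same concept: xray/radiograph,
#' tomography/ct, cyst/cystic.  Confusion matrices and the standard
#' metrics never apply this merging; it exists for the optional
#' synonym-merged accuracy report.
#'
#' @param tokens character vector of words.
#' @param map named character vector `c(alias = canonical, ...)`.
#' @return tokens with aliases replaced by their canonical form.
#' @export
apply_synonyms <- function(tokens,
                           map = c(xray = "radiograph", tomography = "ct",
                                   cyst = "cystic")) {
  hit <- tokens %in% names(map)
  tokens[hit] <- unname(map[tokens[hit]])
  tokens
}

#' Build a slot confusion matrix
#'
#' Tabulates true vs predicted words for one caption slot.  Class labels
#' are the union of true and predicted slot words, ordered by true-class
#' frequency descending with lexicographic tie-break (predicted-only
#' labels come last); rows are true classes, columns predicted.
#'
#' @param predicted data.frame of predicted triples (columns `exam_type`,
#'   `body_part`, `problem`), or a character vector of slot words.
#' @param truth aligned data.frame of true triples, or character vector.
#' @param slot one of `"exam_type"`, `"body_part"`, `"problem"`; ignored
#'   when character vectors are given.
#' @return integer matrix with dimnames; grand total = number of pairs.
#' @export
build_slot_confusion <- function(predicted, truth,
                                 slot = c("exam_type", "body_part",
                                          "problem")) {
  if (is.data.frame(predicted) || is.data.frame(truth)) {
    slot <- match.arg(slot)
    predicted <- predicted[[slot]]
    truth <- truth[[slot]]
  }
  stopifnot(length(predicted) == length(truth))
  if (length(truth) == 0) {
    return(matrix(integer(0), 0, 0))
  }
  tf <- table(truth)
  true_labels <- names(tf)[order(-as.integer(tf), names(tf))]
  extra <- sort(setdiff(unique(predicted), true_labels))
  labels <- c(true_labels, extra)
  m <- table(factor(truth, levels = labels),
             factor(predicted, levels = labels))
  out <- matrix(as.integer(m), nrow(m), ncol(m),
                dimnames = list(labels, labels))
  out
}

#' Per-class metrics of a confusion matrix
#'
#' One-vs-rest reduction for every class of a square confusion matrix
#' (rows = true, columns = predicted): P, N, TP, FP, TN, FN and the
#' derived rates TPR, TNR, PPV, NPV, ACC, F1.  PPV is undefined (NA)
#' when TP + FP = 0, NPV when TN + FN = 0, and F1 follows
#' [f1_score()]'s undefined propagation (in particular F1 is undefined
#' whenever TP = 0).  Rates are returned at full precision; use
#' [format_metric_table()] for the printed 2-decimal form.
#'
#' @param m square numeric matrix (optionally with dimnames).
#' @return data.frame with columns
#'   `Class, P, N, TP, FP, TN, FN, TPR, TNR, PPV, NPV, ACC, F1`.
#' @export
confusion_metrics <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) {
    stop("confusion matrix must be square", call. = FALSE)
  }
  labels <- rownames(m) %||% as.character(seq_len(nrow(m)))
  total <- sum(m)
  TP <- diag(m)
  P <- rowSums(m)
  FN <- P - TP
  FP <- colSums(m) - TP
  TN <- total - TP - FN - FP
  N <- FP + TN
  safe_div <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  TPR <- safe_div(TP, P)
  TNR <- safe_div(TN, N)
  PPV <- safe_div(TP, TP + FP)
  NPV <- safe_div(TN, TN + FN)
  ACC <- safe_div(TP + TN, rep(total, length(TP)))
  F1 <- f1_score(PPV, TPR)
  data.frame(Class = labels, P = as.integer(P), N = as.integer(N),
             TP = as.integer(TP), FP = as.integer(FP), TN = as.integer(TN),
             FN = as.integer(FN), TPR = TPR, TNR = TNR, PPV = PPV,
             NPV = NPV, ACC = ACC, F1 = F1,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Format a metric table for printing
#'
#' Rounds the rate columns half away from zero to 2 decimals and renders
#' undefined cells as `"-"`, matching the published table conventions.
#'
#' @param metrics data.frame from [confusion_metrics()].
#' @return data.frame of character/integer columns ready for CSV output.
#' @export
format_metric_table <- function(metrics) {
  out <- metrics
  for (col in c("TPR", "TNR", "PPV", "NPV", "ACC", "F1")) {
    v <- metrics[[col]]
    out[[col]] <- ifelse(is.na(v), "-",
                         sprintf("%.2f", round_half_up(v, 2)))
  }
  out
}

#' Write a metric table CSV
#'
#' Header `Class,P,N,TP,FP,TN,FN,TPR,TNR,PPV,NPV,ACC,F1`, dashes for
#' undefined cells.
#'
#' @param metrics data.frame from [confusion_metrics()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(metrics, path) {
  write.csv(format_metric_table(metrics), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Evaluate generated captions slot-wise
#'
#' Generates a caption for every image in the bundle, compares against
#' the manifest's reference triples, and assembles the full evaluation:
#' token accuracy, BLEU-1, and per-slot confusion matrices with their
#' metric tables.
#'
#' @param model a trained `tricap_model`.
#' @param bundle `tricap_features` for the images to score.
#' @param manifest manifest rows aligned with the bundle (columns
#'   `exam_type`, `body_part`, `problem`).
#' @param synonyms optional synonym map (see [apply_synonyms()]); when
#'   given, an additional `token_accuracy_merged` is reported with both
#'   sides mapped through it.  Off by default; confusion matrices always
#'   keep synonyms distinct.
#' @return list with `predictions` (data.frame id/truth/predicted),
#'   `token_accuracy`, `bleu1`, `confusions` (list of 3 matrices) and
#'   `metrics` (list of 3 metric data.frames).
#' @export
evaluate_captioner <- function(model, bundle, manifest, synonyms = NULL) {
  stopifnot(inherits(bundle, "tricap_features"))
  n <- dim(bundle$features)[1]
  stopifnot(nrow(manifest) == n)
  preds <- vector("list", n)
  for (i in seq_len(n)) {
    preds[[i]] <- generate_caption(bundle$features[i, , ], model)
  }
  refs <- lapply(seq_len(n), function(i) {
    c(manifest$exam_type[i], manifest$body_part[i], manifest$problem[i])
  })
  slot_of <- function(x, k) if (length(x) >= k) x[k] else "<none>"
  pred_df <- data.frame(
    exam_type = vapply(preds, slot_of, "", 1),
    body_part = vapply(preds, slot_of, "", 2),
    problem = vapply(preds, slot_of, "", 3),
    stringsAsFactors = FALSE)
  true_df <- manifest[, c("exam_type", "body_part", "problem")]
  confusions <- lapply(c("exam_type", "body_part", "problem"),
                       function(s) build_slot_confusion(pred_df, true_df, s))
  names(confusions) <- c("exam_type", "body_part", "problem")
  out <- list(
    predictions = data.frame(
      id = bundle$image_ids,
      truth = vapply(refs, paste, "", collapse = " "),
      predicted = vapply(preds, paste, "", collapse = " "),
      stringsAsFactors = FALSE),
    token_accuracy = token_accuracy(preds, refs),
    bleu1 = bleu1(preds, refs),
    confusions = confusions,
    metrics = lapply(confusions, confusion_metrics))
  if (!is.null(synonyms)) {
    out$token_accuracy_merged <- token_accuracy(
      lapply(preds, apply_synonyms, map = synonyms),
      lapply(refs, apply_synonyms, map = synonyms))
  }
  out
}
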