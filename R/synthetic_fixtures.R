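# Synthetic corpus generator and machine-readable fixtures of the
# published result tables.

#' Specify a synthetic corpus
#'
#' @param triples data.frame with columns `exam_type`, `body_part`,
#'   `problem`; one subclass per row.  Defaults to the first three
#'   subclasses of the built-in selected-triples table.
#' @param n_per_triple images generated per triple (>= 1).
#' @param image_size integer `c(H, W)`, both >= 16.
#' @param noise_sd standard deviation of additive Gaussian pixel noise,
#'   in [0, 1] intensity units.
#' @param seed integer; the generator is fully deterministic given the
#'   spec, seed included.
#' @return an object of class `tricap_synth_spec`.
#' @export
synth_spec <- function(triples = NULL, n_per_triple = 10,
                       image_size = c(64, 64), noise_sd = 0.05, seed = 0) {
  if (is.null(triples)) {
    triples <- load_fixture("selected_triples")[1:3, c("exam_type", "body_part", "problem")]
  }
  stopifnot(n_per_triple >= 1, all(image_size >= 16),
            noise_sd >= 0,
            all(c("exam_type", "body_part", "problem") %in% names(triples)))
  structure(list(triples = triples, n_per_triple = as.integer(n_per_triple),
                 image_size = as.integer(image_size), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "tricap_synth_spec")
}

# Binary word-code patch: a g x g bit pattern derived from the word's
# hash, rendered at `scale` pixels per bit and stamped with its top-left
# corner at (y0, x0).
stamp_code <- function(img, code, y0, x0, g = 8L, scale = 2L) {
  bits <- ((code %/% (2^(0:(g * g - 1)))) %% 2) == 1
  patch <- matrix(as.numeric(bits), g, g)
  patch <- patch[rep(seq_len(g), each = scale), rep(seq_len(g), each = scale)]
  img[y0:(y0 + g * scale - 1), x0:(x0 + g * scale - 1)] <- patch
  img
}

# Render the deterministic content of one triple: the exam type selects a
# background texture (oriented sinusoidal grating), the body part a
# foreground shape (disk/square/diamond/ring, word-specific size), and
# the problem a marker glyph in the top-left corner.  Because hashed
# texture/shape parameters can nearly collide for arbitrary word pairs,
# each slot additionally stamps its word-code patch in its own corner
# (problem top-left, exam top-right, body part bottom-left), making every
# slot independently recoverable by construction.
render_triple <- function(exam_type, body_part, problem, H, W) {
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)

  ce <- word_code(exam_type)
  fx <- 1 + (ce %% 5)          # cycles across the image, 1..5
  fy <- 1 + ((ce %/% 5) %% 5)
  img <- 0.45 + 0.2 * sin(2 * pi * (fx * xx / W + fy * yy / H))

  cb <- word_code(body_part)
  shape <- cb %% 4L
  r <- (0.18 + 0.08 * ((cb %/% 4) %% 3)) * min(H, W)  # shape radius, px
  dy <- (yy - (H + 1) / 2) / r
  dx <- (xx - (W + 1) / 2) / r
  mask <- switch(shape + 1L,
    (dx^2 + dy^2) <= 1,                       # disk
    pmax(abs(dx), abs(dy)) <= 1,              # square
    (abs(dx) + abs(dy)) <= 1,                 # diamond
    (dx^2 + dy^2) <= 1 & (dx^2 + dy^2) >= 0.4 # ring
  )
  img[mask] <- img[mask] * 0.3 + 0.85

  side <- 16L  # rendered patch side, px (8 bits x 2 px)
  img <- stamp_code(img, word_code(problem), 2L, 2L)
  img <- stamp_code(img, ce, 2L, W - side - 1L)
  img <- stamp_code(img, cb, H - side - 1L, 2L)
  img
}

#' Generate a synthetic ROCO-like corpus
#'
#' Writes `nrow(triples) * n_per_triple` grayscale PNG images under
#' `out_dir/images/` plus `out_dir/manifest.csv`; each image's content
#' deterministically encodes its caption triple (texture = exam type,
#' shape = body part, corner glyph = problem) with additive pixel noise.
#' The sidecar manifest carries the triple as both caption and keywords.
#' Output is byte-identical for an identical spec.
#'
#' @param spec a [synth_spec()].
#' @param out_dir output directory (created if needed).
#' @return the manifest data.frame, invisibly written to
#'   `out_dir/manifest.csv`.
#' @export
generate_corpus <- function(spec, out_dir) {
  stopifnot(inherits(spec, "tricap_synth_spec"))
  img_dir <- file.path(out_dir, "images")
  ok <- dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir)) {
    stop("cannot create output directory: ", img_dir, call. = FALSE)
  }
  H <- spec$image_size[1]
  W <- spec$image_size[2]
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(spec$triples))) {
    tr <- spec$triples[i, ]
    base <- render_triple(tr$exam_type, tr$body_part, tr$problem, H, W)
    for (j in seq_len(spec$n_per_triple)) {
      k <- k + 1L
      id <- sprintf("img%05d", k)
      img <- base
      if (spec$noise_sd > 0) {
        noise <- with_seed(spec$seed * 100003L + k,
                           matrix(rnorm(H * W, 0, spec$noise_sd), H, W))
        img <- img + noise
      }
      img <- pmin(pmax(img, 0), 1)
      path <- file.path(img_dir, paste0(id, ".png"))
      png::writePNG(img, path)
      cap <- paste(tr$exam_type, tr$body_part, tr$problem)
      rows[[k]] <- data.frame(
        id = id, path = path, caption = cap,
        keywords = paste(tr$exam_type, tr$body_part, tr$problem, sep = ";"),
        exam_type = tr$exam_type, body_part = tr$body_part,
        problem = tr$problem, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}

#' Load a published-table fixture
#'
#' The package ships the printed result tables as CSV resources,
#' transcribed digit for digit.  Recognized names:
#' \describe{
#'   \item{`exam_confusion`, `body_confusion`, `problem_confusion`}{the
#'     three slot confusion matrices (integer matrix, rows = true class,
#'     columns = predicted class; grand total 284 each).}
#'   \item{`exam_metrics`, `body_metrics`, `problem_metrics`}{their
#'     printed 12-column per-class metric tables; undefined cells
#'     (printed as dashes) load as `NA`.}
#'   \item{`densenet_acc`}{numeric vector of the 24 printed accuracies of
#'     the DenseNet201 experiment family.}
#'   \item{`global_acc`}{numeric vector of all 192 printed accuracies.}
#'   \item{`family_summary`}{the printed per-family accuracy summary
#'     (mu, sigma, min, max, mu-sigma, mu+sigma).}
#'   \item{`grid_densenet201`, `grid_resnet152v2`, `grid_nasnetlarge`,
#'     `grid_vgg19`, `grid_xception`, `grid_inceptionv3`,
#'     `grid_inceptionresnetv2`, `grid_mobilenetv2`}{the full experiment
#'     record tables of one backbone family each.}
#'   \item{`grid_all`}{all 192 experiment records, stacked.}
#'   \item{`keywords_of_interest`}{category/keyword/frequency table.}
#'   \item{`selected_triples`}{the retained subclasses with image counts.}
#' }
#'
#' @param name fixture name (see above).
#' @return a matrix, data.frame or numeric vector depending on `name`.
#' @export
load_fixture <- function(name) {
  grid_files <- c(grid_densenet201 = "acc_table4.csv",
                  grid_resnet152v2 = "acc_table5.csv",
                  grid_nasnetlarge = "acc_table6.csv",
                  grid_vgg19 = "acc_table7.csv",
                  grid_xception = "acc_table8.csv",
                  grid_inceptionv3 = "acc_table9.csv",
                  grid_inceptionresnetv2 = "acc_table10.csv",
                  grid_mobilenetv2 = "acc_table11.csv")
  read_grid <- function(f) read.csv(extdata_path(f), check.names = FALSE,
                                    stringsAsFactors = FALSE)
  read_conf <- function(f) {
    d <- read.csv(extdata_path(f), check.names = FALSE,
                  stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1])
    storage.mode(m) <- "integer"
    rownames(m) <- d[[1]]
    stopifnot(nrow(m) == ncol(m))
    m
  }
  read_metrics <- function(f) {
    d <- read.csv(extdata_path(f), check.names = FALSE,
                  stringsAsFactors = FALSE, na.strings = "-")
    for (col in setdiff(names(d), "Class")) d[[col]] <- as.numeric(d[[col]])
    d
  }
  switch(name,
    exam_confusion = read_conf("table13.csv"),
    body_confusion = read_conf("table15.csv"),
    problem_confusion = read_conf("table17.csv"),
    exam_metrics = read_metrics("table14.csv"),
    body_metrics = read_metrics("table16.csv"),
    problem_metrics = read_metrics("table18.csv"),
    family_summary = read.csv(extdata_path("table3.csv"),
                              check.names = FALSE, stringsAsFactors = FALSE),
    densenet_acc = read_grid("acc_table4.csv")$ACC,
    global_acc = unlist(lapply(unname(grid_files),
                               function(f) read_grid(f)$ACC),
                        use.names = FALSE),
    grid_all = do.call(rbind, lapply(unname(grid_files), read_grid)),
    keywords_of_interest = read.csv(extdata_path("table1.csv"),
                                    stringsAsFactors = FALSE),
    selected_triples = read.csv(extdata_path("table2.csv"),
                                stringsAsFactors = FALSE),
    {
      if (name %in% names(grid_files)) {
        read_grid(grid_files[[name]])
      } else {
        stop("unknown fixture name: ", name, call. = FALSE)
      }
    }
  )
}
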