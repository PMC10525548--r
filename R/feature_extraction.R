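# Feature extraction: pluggable backbone registry with transfer-learning,
# fine-tuning and augmentation switches.  Images become fixed-shape
# feature sequences (n_tokens x feature_dim) for the attention encoder.

.backbone_menu <- list(
  mobilenetv2       = list(input_size = c(224, 224)),
  densenet201       = list(input_size = c(224, 224)),
  resnet152v2       = list(input_size = c(224, 224)),
  nasnetlarge       = list(input_size = c(331, 331)),
  vgg19             = list(input_size = c(224, 224)),
  xception          = list(input_size = c(299, 299)),
  inceptionv3       = list(input_size = c(299, 299)),
  inceptionresnetv2 = list(input_size = c(299, 299)),
  tiny_cnn          = list(input_size = c(32, 32))
)

#' Specify a feature-extraction backbone
#'
#' The menu covers the classical image-recognition families plus
#' `tiny_cnn`, a small seeded-random-weight convolutional network
#' (3 conv blocks) that runs without any downloaded weights and is the
#' backbone used by the test suite.
#'
#' @param name backbone identifier; one of mobilenetv2, densenet201,
#'   resnet152v2, nasnetlarge, vgg19, xception, inceptionv3,
#'   inceptionresnetv2, tiny_cnn.
#' @param pretrained use transfer-learning weights (TL flag).  Requires a
#'   locally provisioned weights file; never available for `tiny_cnn`.
#' @param trainable fine-tune backbone weights during training (TR flag).
#'   Carried as experiment metadata; `tiny_cnn` is always frozen.
#' @param input_size optional `c(H, W)` override.
#' @param seed seed for the random weights of `tiny_cnn`.
#' @return an object of class `tricap_backbone_spec`.
#' @export
backbone_spec <- function(name, pretrained = FALSE, trainable = FALSE,
                          input_size = NULL, seed = 0) {
  if (!name %in% names(.backbone_menu)) {
    stop("unknown backbone: ", name, call. = FALSE)
  }
  if (name == "tiny_cnn" && pretrained) {
    stop("tiny_cnn has no pretrained weights; set pretrained = FALSE",
         call. = FALSE)
  }
  structure(list(name = name, pretrained = pretrained, trainable = trainable,
                 input_size = input_size %||% .backbone_menu[[name]]$input_size,
                 seed = as.integer(seed)),
            class = "tricap_backbone_spec")
}

#' Specify seeded image augmentation
#'
#' @param enabled apply augmentation (IA flag).
#' @param max_rotation maximum absolute rotation, degrees.
#' @param max_zoom maximum zoom fraction in `[0, 1)`; the scale is drawn
#'   uniformly from `[1 - max_zoom, 1 + max_zoom]`.
#' @param mirror allow horizontal mirroring (probability 1/2).
#' @param seed base seed; combined with a per-draw seed in [augment()].
#' @return an object of class `tricap_augment_spec`.
#' @export
augment_spec <- function(enabled = TRUE, max_rotation = 15, max_zoom = 0.1,
                         mirror = TRUE, seed = 0) {
  stopifnot(max_rotation >= 0, max_zoom >= 0, max_zoom < 1)
  structure(list(enabled = enabled, max_rotation = max_rotation,
                 max_zoom = max_zoom, mirror = mirror, seed = as.integer(seed)),
            class = "tricap_augment_spec")
}

# Bilinear sampling of a 2D matrix at (possibly fractional) coordinates,
# clamped to the image border.
bilinear_sample <- function(img, ys, xs) {
  H <- nrow(img); W <- ncol(img)
  ys <- pmin(pmax(ys, 1), H); xs <- pmin(pmax(xs, 1), W)
  y0 <- floor(ys); x0 <- floor(xs)
  y1 <- pmin(y0 + 1, H); x1 <- pmin(x0 + 1, W)
  wy <- ys - y0; wx <- xs - x0
  v00 <- img[cbind(y0, x0)]; v01 <- img[cbind(y0, x1)]
  v10 <- img[cbind(y1, x0)]; v11 <- img[cbind(y1, x1)]
  (1 - wy) * ((1 - wx) * v00 + wx * v01) + wy * ((1 - wx) * v10 + wx * v11)
}

bilinear_resize <- function(img, H, W) {
  h <- nrow(img); w <- ncol(img)
  if (h == H && w == W) return(img)
  ys <- if (H == 1) (h + 1) / 2 else 1 + (seq_len(H) - 1) * (h - 1) / (H - 1)
  xs <- if (W == 1) (w + 1) / 2 else 1 + (seq_len(W) - 1) * (w - 1) / (W - 1)
  matrix(bilinear_sample(img, rep(ys, times = W), rep(xs, each = H)), H, W)
}

# Rotate by `theta` (radians) about the image center and scale by `zoom`,
# sampling the input bilinearly (inverse mapping); optional horizontal
# mirror.  theta = 0, zoom = 1, mirror = FALSE is the identity.
affine_transform <- function(img, theta = 0, zoom = 1, mirror = FALSE) {
  channels <- if (length(dim(img)) == 3) seq_len(dim(img)[3]) else 0
  one <- function(m) {
    H <- nrow(m); W <- ncol(m)
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    yy <- rep(seq_len(H), times = W) - cy
    xx <- rep(seq_len(W), each = H) - cx
    if (mirror) xx <- -xx
    ct <- cos(theta); st <- sin(theta)
    sy <- (ct * yy - st * xx) / zoom + cy
    sx <- (st * yy + ct * xx) / zoom + cx
    matrix(bilinear_sample(m, sy, sx), H, W)
  }
  if (identical(channels, 0)) return(one(img))
  out <- img
  for (c in channels) out[, , c] <- one(img[, , c])
  out
}

#' Preprocess an image for a backbone
#'
#' Resizes (bilinear) to the backbone input size, replicates a grayscale
#' channel to 3, and scales intensities to [0, 1] (inputs in 0..255 are
#' rescaled; inputs already in range pass through).  Deterministic.
#'
#' @param image numeric matrix (H x W) or array (H x W x C), C in 1 or 3.
#' @param input_size integer `c(H, W)`.
#' @return numeric array `input_size[1] x input_size[2] x 3` in [0, 1].
#' @export
preprocess <- function(image, input_size) {
  if (is.character(image)) image <- png::readPNG(image)
  if (!is.numeric(image)) stop("image must be numeric", call. = FALSE)
  if (max(image) > 1.5) image <- image / 255
  if (length(dim(image)) == 2) {
    image <- array(rep(image, 3), c(dim(image), 3))
  } else if (dim(image)[3] == 1) {
    image <- array(rep(image[, , 1], 3), c(dim(image)[1:2], 3))
  } else if (dim(image)[3] > 3) {
    image <- image[, , 1:3, drop = FALSE]  # drop alpha
  }
  H <- input_size[1]; W <- input_size[2]
  out <- array(0, c(H, W, 3))
  for (c in 1:3) out[, , c] <- bilinear_resize(image[, , c], H, W)
  out
}

#' Apply a seeded random augmentation draw
#'
#' Draws a rotation in `[-max_rotation, +max_rotation]` degrees, a zoom in
#' `[1 - max_zoom, 1 + max_zoom]`, and a mirror flip with probability 1/2,
#' all deterministically from `(spec$seed, draw_seed)`; the same pair
#' always yields identical output pixels.
#'
#' @param image numeric matrix or H x W x C array.
#' @param spec an [augment_spec()] with `enabled = TRUE`.
#' @param draw_seed integer identifying the draw (e.g. the image index).
#' @return the transformed image, same shape.
#' @export
augment <- function(image, spec, draw_seed = 0) {
  stopifnot(inherits(spec, "tricap_augment_spec"), isTRUE(spec$enabled))
  draws <- with_seed(spec$seed * 7919L + as.integer(draw_seed), runif(3))
  theta <- (2 * draws[1] - 1) * spec$max_rotation * pi / 180
  zoom <- 1 + (2 * draws[2] - 1) * spec$max_zoom
  mirror <- spec$mirror && draws[3] < 0.5
  affine_transform(image, theta, zoom, mirror)
}

# --- tiny_cnn -------------------------------------------------------------

# Seeded Glorot-uniform weights for the 3-block convnet:
# 3x3 conv (3->8) / ReLU / 2x2 mean pool, (8->16), (16->32).
# On a 32x32 input the output grid is 4x4x32 -> 16 tokens of dim 32.
tiny_cnn_weights <- function(seed = 0) {
  shapes <- list(c(3, 3, 3, 8), c(3, 3, 8, 16), c(3, 3, 16, 32))
  with_seed(seed, lapply(shapes, function(s) {
    fan_in <- s[1] * s[2] * s[3]
    fan_out <- s[1] * s[2] * s[4]
    lim <- sqrt(6 / (fan_in + fan_out))
    array(runif(prod(s), -lim, lim), s)
  }))
}

# Same-padding 3x3 convolution implemented by shift-and-add over the nine
# kernel offsets; x is H x W x Cin, w is 3 x 3 x Cin x Cout.
conv3x3 <- function(x, w) {
  H <- dim(x)[1]; W <- dim(x)[2]
  cin <- dim(w)[3]; cout <- dim(w)[4]
  xp <- array(0, c(H + 2, W + 2, cin))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  out <- array(0, c(H, W, cout))
  for (di in 0:2) for (dj in 0:2) {
    slab <- xp[di + seq_len(H), dj + seq_len(W), , drop = FALSE]
    # fold the Cin axis with the kernel slice: (H*W, Cin) %*% (Cin, Cout)
    m <- matrix(slab, H * W, cin) %*% matrix(w[di + 1, dj + 1, , ], cin, cout)
    out <- out + array(m, c(H, W, cout))
  }
  out
}

mean_pool2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  h <- H %/% 2; w <- W %/% 2
  x <- x[seq_len(2 * h), seq_len(2 * w), , drop = FALSE]
  (x[seq(1, 2 * h, 2), seq(1, 2 * w, 2), , drop = FALSE] +
   x[seq(2, 2 * h, 2), seq(1, 2 * w, 2), , drop = FALSE] +
   x[seq(1, 2 * h, 2), seq(2, 2 * w, 2), , drop = FALSE] +
   x[seq(2, 2 * h, 2), seq(2, 2 * w, 2), , drop = FALSE]) / 4
}

tiny_cnn_forward <- function(x, weights) {
  for (w in weights) {
    x <- conv3x3(x, w)
    x <- pmax(x, 0)
    x <- mean_pool2(x)
  }
  # flatten the final spatial grid to a token sequence
  matrix(x, dim(x)[1] * dim(x)[2], dim(x)[3])
}

#' Extract image features with a backbone
#'
#' Runs every image of the manifest through the backbone and returns the
#' activations of the final spatial grid, flattened to a token sequence of
#' shape `(n_tokens, feature_dim)` per image.  A frozen backbone is a pure
#' function: identical inputs give identical features.
#'
#' @param manifest manifest data.frame with `id` and `path` columns, or a
#'   list with elements `ids` and `images` (pre-loaded arrays) for
#'   in-memory use.
#' @param backbone a [backbone_spec()].  Only `tiny_cnn` runs without a
#'   provisioned weights file.
#' @param augment_spec optional [augment_spec()]; applied per image with
#'   `draw_seed` = image index when `enabled`.
#' @return an object of class `tricap_features`: list with `image_ids`
#'   and `features` (array `n_images x n_tokens x feature_dim`).
#' @export
extract_features <- function(manifest, backbone, augment_spec = NULL) {
  stopifnot(inherits(backbone, "tricap_backbone_spec"))
  if (backbone$pretrained) {
    stop("pretrained weights for '", backbone$name, "' are not bundled; ",
         "provision them offline and register a loader, or use ",
         "pretrained = FALSE", call. = FALSE)
  }
  if (backbone$name != "tiny_cnn") {
    stop("backbone '", backbone$name, "' requires externally provisioned ",
         "weights; 'tiny_cnn' is the self-contained backbone", call. = FALSE)
  }
  weights <- tiny_cnn_weights(backbone$seed)
  if (is.data.frame(manifest)) {
    ids <- manifest$id
    get_img <- function(i) png::readPNG(manifest$path[i])
  } else {
    ids <- manifest$ids
    get_img <- function(i) manifest$images[[i]]
  }
  n <- length(ids)
  feats <- NULL
  for (i in seq_len(n)) {
    img <- preprocess(get_img(i), backbone$input_size)
    if (!is.null(augment_spec) && isTRUE(augment_spec$enabled)) {
      img <- augment(img, augment_spec, draw_seed = i)
    }
    f <- tiny_cnn_forward(img, weights)
    if (is.null(feats)) feats <- array(0, c(n, nrow(f), ncol(f)))
    feats[i, , ] <- f
  }
  if (any(!is.finite(feats))) stop("non-finite features", call. = FALSE)
  structure(list(image_ids = ids, features = feats),
            class = "tricap_features")
}
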