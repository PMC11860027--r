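# Face-image pipeline: crop + bilinear normalization, CNN training and
# scoring, progressive multi-resolution training (scheme 1) and
# transfer/fine-tuning training (scheme 2).

#' Bilinear resize of an image array
#'
#' Corner-aligned bilinear interpolation: output pixel `i` (0-based) samples
#' source coordinate `i * (H - 1) / (out_h - 1)`. With matching sizes the
#' image is returned unchanged.
#'
#' @param img `H x W` matrix or `H x W x C` array of intensities.
#' @param out_h,out_w output dimensions (>= 1).
#' @return Resized matrix/array of the same channel count.
#' @export
bilinear_resize <- function(img, out_h, out_w) {
  was_matrix <- is.matrix(img)
  if (was_matrix) dim(img) <- c(dim(img), 1L)
  d <- dim(img); H <- d[1]; W <- d[2]; C <- d[3]
  src_r <- if (out_h == 1L) rep((H - 1) / 2, 1L) else
    (seq_len(out_h) - 1) * (H - 1) / (out_h - 1)
  src_c <- if (out_w == 1L) rep((W - 1) / 2, 1L) else
    (seq_len(out_w) - 1) * (W - 1) / (out_w - 1)
  r0 <- pmin(floor(src_r), H - 2); r0 <- pmax(r0, 0)
  c0 <- pmin(floor(src_c), W - 2); c0 <- pmax(c0, 0)
  if (H == 1L) r0 <- rep(0, out_h)
  if (W == 1L) c0 <- rep(0, out_w)
  fr <- src_r - r0; fc <- src_c - c0
  r1 <- pmin(r0 + 1, H - 1)
  c1 <- pmin(c0 + 1, W - 1)
  out <- array(0, c(out_h, out_w, C))
  wr <- matrix(1 - fr, out_h, out_w); wr2 <- matrix(fr, out_h, out_w)
  wc <- matrix(1 - fc, out_h, out_w, byrow = TRUE)
  wc2 <- matrix(fc, out_h, out_w, byrow = TRUE)
  for (ch in seq_len(C)) {
    p <- img[, , ch]
    out[, , ch] <-
      wr * wc * p[cbind(rep(r0 + 1, out_w), rep(c0 + 1, each = out_h))] +
      wr * wc2 * p[cbind(rep(r0 + 1, out_w), rep(c1 + 1, each = out_h))] +
      wr2 * wc * p[cbind(rep(r1 + 1, out_w), rep(c0 + 1, each = out_h))] +
      wr2 * wc2 * p[cbind(rep(r1 + 1, out_w), rep(c1 + 1, each = out_h))]
  }
  if (was_matrix && C == 1L) dim(out) <- c(out_h, out_w)
  out
}

#' Extract and normalize a face region
#'
#' Crops `image` to `box` (clipped to the image bounds) and resamples the
#' crop to `N x N` with corner-aligned bilinear interpolation — the
#' normalization step that precedes CNN feature extraction. The face detector
#' producing `box` is pluggable; the synthetic generator supplies ground-truth
#' boxes.
#'
#' @param image `H x W x 3` array, intensities in `[0, 1]` or `[0, 255]`.
#' @param box list or vector with elements `x`, `y`, `w`, `h` (1-based pixel
#'   units, `x` = column, `y` = row).
#' @param N output side length in pixels (>= 8).
#' @return `N x N x 3` array of class `painsense_face` with attributes `box`
#'   (the clipped box used) and `N`.
#' @export
normalize_face <- function(image, box, N) {
  if (N < 8) stop("argument error: N must be >= 8, got ", N)
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("image must be H x W x 3")
  box <- as.list(box)
  if (box$w <= 0 || box$h <= 0) stop("geometry error: box must have w, h > 0")
  x0 <- max(1, round(box$x)); y0 <- max(1, round(box$y))
  x1 <- min(d[2], round(box$x + box$w - 1))
  y1 <- min(d[1], round(box$y + box$h - 1))
  if (x0 > d[2] || y0 > d[1] || x1 < 1 || y1 < 1 || x0 > x1 || y0 > y1)
    stop("geometry error: box lies outside the image")
  crop <- image[y0:y1, x0:x1, , drop = FALSE]
  out <- bilinear_resize(crop, N, N)
  structure(out, box = c(x = x0, y = y0, w = x1 - x0 + 1, h = y1 - y0 + 1),
            N = N, class = "painsense_face")
}

# Stack a list of H x W x C arrays into an (n, H, W, C) batch.
stack_images <- function(images) {
  d <- dim(images[[1]])
  X <- vapply(images, function(im) {
    if (!identical(dim(im), d)) stop("configuration error: image shapes differ")
    unclass(im)
  }, FUN.VALUE = array(0, d))
  aperm(X, c(4, 1, 2, 3))
}

check_image_shape <- function(arch, X) {
  d <- dim(X)[-1]
  if (!identical(as.integer(d), arch$input_shape))
    stop("configuration error: images are ", paste(d, collapse = "x"),
         " but the architecture expects ",
         paste(arch$input_shape, collapse = "x"))
}

#' Train a face-image CNN
#'
#' Instantiates `arch` and trains it with Adam on softmax cross-entropy.
#' Images are scaled to `[0, 1]` if they arrive in `[0, 255]`.
#'
#' @param arch an [architecture_spec()] (e.g. [build_cnn_small()]).
#' @param images list of `H x W x 3` arrays matching `arch`'s input shape.
#' @param labels integer pain classes in `0 .. L-1` (or a factor).
#' @param epochs,batch_size,lr,seed training configuration. The default batch
#'   size of 16 is the value found best for the face nets.
#' @param freeze regex patterns of layer names to keep frozen.
#' @return A trained `painsense_model`.
#' @export
train_image_model <- function(arch, images, labels, epochs = 30L,
                              batch_size = 16L, lr = 1e-3, seed = 1L,
                              freeze = character(0)) {
  X <- stack_images(images)
  if (max(X) > 1.5) X <- X / 255
  check_image_shape(arch, X)
  model <- nn_init(arch, seed = seed)
  nn_train(model, X, labels, epochs = epochs, batch_size = batch_size,
           lr = lr, seed = seed, freeze = freeze)
}

#' Score images with a trained model
#'
#' @param model a trained `painsense_model`.
#' @param images list of image arrays matching the model's input shape.
#' @param sample_ids optional identifiers for the rows.
#' @return A [score_matrix()]: `n x L`, rows summing to 1.
#' @export
score_images <- function(model, images, sample_ids = NULL) {
  X <- stack_images(images)
  if (max(X) > 1.5) X <- X / 255
  check_image_shape(model$arch, X)
  probs <- nn_predict(model, X)
  score_matrix(probs,
               class_labels = paste0("class", seq_len(ncol(probs)) - 1L),
               sample_ids = sample_ids %||% paste0("s", seq_len(nrow(probs))))
}

#' Progressive multi-resolution training (scheme 1)
#'
#' Trains the same conv-block family at successively larger input
#' resolutions `k1 < k2 < ... < k`: the model is first trained at the lowest
#' resolution, then all resolution-independent weights (convolution and
#' batch-norm layers, plus dense layers whose fan-in is unchanged) are
#' transferred to the next-resolution model and training continues. The first
#' dense layer is re-initialized whenever the flatten length changes.
#'
#' @param arch_builder function `(input_size) -> architecture_spec`, e.g.
#'   `function(s) build_cnn_small(3, input_size = s)`.
#' @param images list of image arrays at any resolution; each is bilinearly
#'   resized to the stage resolution.
#' @param labels integer classes `0 .. L-1`.
#' @param resolutions strictly increasing integer vector of side lengths.
#' @param epochs_per_stage epochs at each resolution (scalar or vector).
#' @param batch_size,lr,seed as in [train_image_model()].
#' @return The final-stage trained model; `model$stage_log` holds a data
#'   frame (resolution, epochs, final training loss/accuracy, number of
#'   transferred layers).
#' @export
scheme1_progressive_train <- function(arch_builder, images, labels,
                                      resolutions, epochs_per_stage = 10L,
                                      batch_size = 16L, lr = 1e-3, seed = 1L) {
  resolutions <- as.integer(resolutions)
  if (length(resolutions) < 1L || is.unsorted(resolutions, strictly = TRUE))
    stop("argument error: resolutions must be strictly increasing")
  epochs_per_stage <- rep_len(epochs_per_stage, length(resolutions))
  prev <- NULL
  log_rows <- list()
  model <- NULL
  for (si in seq_along(resolutions)) {
    k <- resolutions[si]
    arch <- arch_builder(k)
    imgs_k <- lapply(images, bilinear_resize, out_h = k, out_w = k)
    model <- nn_init(arch, seed = seed + si - 1L)
    n_moved <- 0L
    if (!is.null(prev)) {
      model <- nn_transfer_weights(model, prev)
      n_moved <- length(attr(model, "transferred"))
    }
    X <- stack_images(imgs_k)
    if (max(X) > 1.5) X <- X / 255
    model <- nn_train(model, X, labels, epochs = epochs_per_stage[si],
                      batch_size = batch_size, lr = lr,
                      seed = seed + si - 1L)
    h <- model$history
    log_rows[[si]] <- data.frame(resolution = k,
                                 epochs = epochs_per_stage[si],
                                 loss = if (nrow(h)) h$loss[nrow(h)] else NA,
                                 acc = if (nrow(h)) h$acc[nrow(h)] else NA,
                                 transferred = n_moved)
    prev <- model
  }
  model$stage_log <- do.call(rbind, log_rows)
  model
}

#' Transfer learning with layer freezing (scheme 2)
#'
#' Either trains from scratch or warm-starts from a previously trained
#' model's weights, optionally freezing named layers so that only the
#' remaining layers are retrained (fine-tuning). Frozen layers are bit-exact
#' unchanged after training.
#'
#' @param arch an [architecture_spec()].
#' @param images,labels training data as in [train_image_model()].
#' @param mode `"from_scratch"` or `"warm_start"`.
#' @param init_model trained `painsense_model` supplying the warm start
#'   (required for `mode = "warm_start"`).
#' @param freeze regex patterns of layer names to freeze; each pattern must
#'   match at least one layer.
#' @param epochs,batch_size,lr,seed training configuration.
#' @return Trained model; `model$frozen_layers` records which layers were
#'   frozen.
#' @export
scheme2_transfer_train <- function(arch, images, labels,
                                   mode = c("from_scratch", "warm_start"),
                                   init_model = NULL, freeze = character(0),
                                   epochs = 10L, batch_size = 16L, lr = 1e-3,
                                   seed = 1L) {
  mode <- match.arg(mode)
  layer_names <- vapply(arch$layers, `[[`, character(1), "name")
  for (pat in freeze)
    if (!any(grepl(pat, layer_names)))
      stop("configuration error: freeze pattern '", pat,
           "' matches no layer")
  X <- stack_images(images)
  if (max(X) > 1.5) X <- X / 255
  check_image_shape(arch, X)
  model <- nn_init(arch, seed = seed)
  if (mode == "warm_start") {
    if (is.null(init_model))
      stop("configuration error: warm_start requires init_model")
    model <- nn_transfer_weights(model, init_model)
    if (!length(attr(model, "transferred")))
      stop("configuration error: init_model shares no compatible layers")
  }
  model <- nn_train(model, X, labels, epochs = epochs,
                    batch_size = batch_size, lr = lr, seed = seed,
                    freeze = freeze)
  model$frozen_layers <- layer_names[match_frozen(layer_names, freeze)]
  model
}

# ---- manifest I/O -----------------------------------------------------------

#' Read / write an image manifest
#'
#' Manifests are CSV files with columns `path,label[,x,y,w,h]`; images are
#' PNG files. `read_image_manifest` loads the images and returns them with
#' labels and (if present) face boxes.
#'
#' @param path manifest CSV path; image paths are resolved relative to it.
#' @return list with `images` (list of arrays), `labels` (integer), `boxes`
#'   (data frame or NULL), `manifest` (the parsed data frame).
#' @export
read_image_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("path", "label") %in% names(man)))
  base <- dirname(path)
  images <- lapply(man$path, function(p) {
    img <- png::readPNG(file.path(base, p))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    img[, , 1:3, drop = FALSE]
  })
  boxes <- if (all(c("x", "y", "w", "h") %in% names(man)))
    man[, c("x", "y", "w", "h")] else NULL
  list(images = images, labels = as.integer(man$label), boxes = boxes,
       manifest = man)
}
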