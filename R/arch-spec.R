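# ---- layer constructors -----------------------------------------------------

new_layer <- function(kind, name, ...) {
  structure(c(list(kind = kind, name = name), list(...)),
            class = "painsense_layer")
}

#' Layer specifications
#'
#' Constructors for the seven layer kinds used by the pain-sentiment CNNs:
#' 2-D convolution (3x3, stride 1, zero padding preserving the spatial size),
#' 2x2 max pooling (stride 2, valid, floor halving), batch normalization,
#' elementwise activation, dropout, flatten and dense (fully connected).
#'
#' @param filters,units positive integer; output channels (conv) or output
#'   units (dense).
#' @param kernel integer pair, convolution kernel size. Default `c(3, 3)`.
#' @param pool integer pair, pooling window (stride equals the window).
#' @param fun activation name, `"relu"` or `"softmax"`.
#' @param rate dropout fraction in (0, 1).
#' @param name optional layer name; auto-named inside [architecture_spec()]
#'   when empty.
#' @return A `painsense_layer` object.
#' @name layers
NULL

#' @rdname layers
#' @export
layer_conv <- function(filters, kernel = c(3L, 3L), name = NULL) {
  stopifnot(length(filters) == 1L, filters >= 1, length(kernel) == 2L)
  new_layer("conv2d", name, filters = as.integer(filters),
            kernel = as.integer(kernel))
}

#' @rdname layers
#' @export
layer_maxpool <- function(pool = c(2L, 2L), name = NULL) {
  stopifnot(length(pool) == 2L, all(pool >= 1))
  new_layer("maxpool2d", name, pool = as.integer(pool))
}

#' @rdname layers
#' @export
layer_batchnorm <- function(name = NULL) new_layer("batchnorm", name)

#' @rdname layers
#' @export
layer_activation <- function(fun = c("relu", "softmax"), name = NULL) {
  fun <- match.arg(fun)
  new_layer("activation", name, fun = fun)
}

#' @rdname layers
#' @export
layer_dropout <- function(rate = 0.25, name = NULL) {
  stopifnot(rate > 0, rate < 1)
  new_layer("dropout", name, rate = rate)
}

#' @rdname layers
#' @export
layer_flatten <- function(name = NULL) new_layer("flatten", name)

#' @rdname layers
#' @export
layer_dense <- function(units, name = NULL) {
  stopifnot(length(units) == 1L, units >= 1)
  new_layer("dense", name, units = as.integer(units))
}

# ---- architecture -----------------------------------------------------------

#' Declarative network architecture
#'
#' An `ArchitectureSpec` is an ordered list of layer specifications plus an
#' input shape and a class count. It is purely declarative: shapes and
#' parameter counts are derived analytically with [propagate_shapes()] and
#' [count_params()], and a trainable model is instantiated from it by
#' [train_image_model()] / [train_audio_model()].
#'
#' @param name architecture name.
#' @param input_shape integer `(H, W, C)` for image nets, or a single integer
#'   feature dimension `d` for vector-input nets.
#' @param layers list of [layers] objects. The final layers must be a dense
#'   layer with `num_classes` units followed by a softmax activation.
#' @param num_classes integer >= 2, the number of pain classes.
#' @return An object of class `painsense_arch`.
#' @export
architecture_spec <- function(name, input_shape, layers, num_classes) {
  num_classes <- as.integer(num_classes)
  if (num_classes < 2L)
    stop("num_classes must be >= 2, got ", num_classes)
  if (length(input_shape) == 1L) input_shape <- c(1L, 1L, as.integer(input_shape))
  stopifnot(length(input_shape) == 3L, all(input_shape >= 1))
  if (!all(vapply(layers, inherits, logical(1), "painsense_layer")))
    stop("layers must all be painsense_layer objects")
  # auto-name unnamed layers kind_k
  for (i in seq_along(layers)) {
    k <- layers[[i]]$kind
    if (is.null(layers[[i]]$name)) {
      n_prev <- sum(vapply(layers[seq_len(i - 1L)], function(l) l$kind == k,
                           logical(1)))
      layers[[i]]$name <- paste0(sub("2d$", "", k), "_", n_prev + 1L)
    }
  }
  nms <- vapply(layers, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate layer names: ",
                               paste(nms[duplicated(nms)], collapse = ", "))
  n <- length(layers)
  ok_head <- n >= 2L &&
    layers[[n]]$kind == "activation" && layers[[n]]$fun == "softmax" &&
    layers[[n - 1L]]$kind == "dense" && layers[[n - 1L]]$units == num_classes
  if (!ok_head)
    stop("architecture must end with dense(num_classes) + softmax")
  structure(list(name = name, input_shape = as.integer(input_shape),
                 layers = layers, num_classes = num_classes),
            class = "painsense_arch")
}

#' @export
print.painsense_arch <- function(x, ...) {
  cat(format_architecture(x), sep = "\n")
  invisible(x)
}

# ---- shape propagation ------------------------------------------------------

#' Propagate output shapes through an architecture
#'
#' Computes every layer's output shape analytically. Convolutions preserve the
#' spatial size (zero padding); 2x2 pooling halves it with floor; flatten
#' turns `(h, w, c)` into a vector of length `h * w * c`; dense layers require
#' a flattened input. An error is raised before any layer would produce a
#' spatial size of zero.
#'
#' @param arch a [architecture_spec()].
#' @return A `painsense_shapes` object: data frame of per-layer shapes with
#'   attribute `flatten_length` (the length entering the first dense layer,
#'   `NA` if the net has no flatten).
#' @export
propagate_shapes <- function(arch) {
  stopifnot(inherits(arch, "painsense_arch"))
  shp <- arch$input_shape          # c(h, w, c); after flatten: c(NA, NA, len)
  flat <- FALSE
  flatten_length <- NA_integer_
  rows <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    switch(l$kind,
      conv2d = {
        if (flat) stop("structural error: conv2d after flatten (layer '",
                       l$name, "')")
        shp[3] <- l$filters
      },
      maxpool2d = {
        if (flat) stop("structural error: maxpool2d after flatten (layer '",
                       l$name, "')")
        nh <- shp[1] %/% l$pool[1]
        nw <- shp[2] %/% l$pool[2]
        if (nh < 1L || nw < 1L)
          stop("shape error: layer '", l$name, "' would reduce spatial size ",
               shp[1], "x", shp[2], " to zero")
        shp[1:2] <- c(nh, nw)
      },
      flatten = {
        if (flat) stop("structural error: repeated flatten (layer '",
                       l$name, "')")
        flatten_length <- prod(shp)
        shp <- c(NA_integer_, NA_integer_, flatten_length)
        flat <- TRUE
      },
      dense = {
        if (!flat) stop("structural error: dense layer '", l$name,
                        "' requires a preceding flatten")
        shp[3] <- l$units
      },
      # batchnorm / activation / dropout preserve shape
      NULL)
    rows[[i]] <- data.frame(layer = l$name, kind = l$kind,
                            out_h = shp[1], out_w = shp[2], out_c = shp[3],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  structure(out, flatten_length = flatten_length,
            class = c("painsense_shapes", "data.frame"))
}

# ---- parameter accounting ---------------------------------------------------

#' Analytic parameter accounting
#'
#' Counts every layer's parameters from the architecture alone, with no model
#' instantiated: a `k x k` convolution from `C_in` to `C_out` channels has
#' `(k * k * C_in + 1) * C_out` parameters (the `+ 1` is the bias), a dense
#' layer `(n_in + 1) * n_out`, and batch normalization `4 * C` (scale and
#' shift trainable, moving mean and variance non-trainable: a `2C / 2C`
#' split). Pooling, activation, dropout and flatten contribute none.
#'
#' @param arch a [architecture_spec()].
#' @return A `painsense_params` object: per-layer data frame (`layer`, `kind`,
#'   `params`) with attributes `trainable`, `non_trainable` and `total`
#'   (`total = trainable + non_trainable`).
#' @export
count_params <- function(arch) {
  shapes <- propagate_shapes(arch)
  in_c <- arch$input_shape[3]
  in_len <- prod(arch$input_shape)
  params <- trainable <- non_trainable <- integer(length(arch$layers))
  prev_c <- in_c       # channels entering the current layer
  prev_len <- in_len   # vector length entering (post-flatten)
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    p <- tr <- nt <- 0
    if (l$kind == "conv2d") {
      p <- tr <- (prod(l$kernel) * prev_c + 1) * l$filters
    } else if (l$kind == "dense") {
      n_in <- if (i == 1L) prev_len else shapes$out_c[i - 1L]
      p <- tr <- (n_in + 1) * l$units
    } else if (l$kind == "batchnorm") {
      c_here <- if (i == 1L) prev_c else shapes$out_c[i - 1L]
      p <- 4 * c_here; tr <- 2 * c_here; nt <- 2 * c_here
    }
    params[i] <- p; trainable[i] <- tr; non_trainable[i] <- nt
    prev_c <- shapes$out_c[i]
  }
  out <- data.frame(layer = shapes$layer, kind = shapes$kind, params = params,
                    stringsAsFactors = FALSE)
  structure(out, trainable = sum(trainable), non_trainable = sum(non_trainable),
            total = sum(params), class = c("painsense_params", "data.frame"))
}

#' @export
print.painsense_params <- function(x, ...) {
  print.data.frame(x, ...)
  cat(sprintf("Total: %s (trainable %s, non-trainable %s)\n",
              format(attr(x, "total"), big.mark = ","),
              format(attr(x, "trainable"), big.mark = ","),
              format(attr(x, "non_trainable"), big.mark = ",")))
  invisible(x)
}

# ---- builders ---------------------------------------------------------------

conv_block <- function(block, filters, drop = 0.25) {
  pre <- paste0("block", block, "_")
  list(layer_conv(filters, name = paste0(pre, "conv")),
       layer_maxpool(name = paste0(pre, "pool")),
       layer_batchnorm(name = paste0(pre, "bn")),
       layer_activation("relu", name = paste0(pre, "relu")),
       layer_dropout(drop, name = paste0(pre, "drop")))
}

dense_head <- function(units, num_classes, drop = 0.5) {
  c(list(layer_flatten(name = "flatten"),
         layer_dense(units, name = "fc1"),
         layer_batchnorm(name = "fc1_bn"),
         layer_activation("relu", name = "fc1_relu"),
         layer_dropout(drop, name = "fc1_drop"),
         layer_dense(num_classes, name = "output"),
         layer_activation("softmax", name = "softmax")))
}

build_conv_family <- function(name, input_size, filters, fc_units, P,
                              conv_drop = 0.25, fc_drop = 0.5) {
  P <- as.integer(P)
  if (P < 2L) stop("class count P must be >= 2, got ", P)
  layers <- list()
  for (b in seq_along(filters))
    layers <- c(layers, conv_block(b, filters[b], conv_drop))
  layers <- c(layers, dense_head(fc_units, P, fc_drop))
  architecture_spec(name, c(input_size, input_size, 3L), layers, P)
}

#' Build the two face-image CNN architectures
#'
#' `build_cnn_a()` is the 128x128x3 network: seven conv blocks
#' (conv 3x3 -> maxpool 2x2 -> batch norm -> ReLU -> dropout) with 30, 60, 90,
#' 120, 120, 240 and 512 filters, a flatten, a 512-unit dense block, and a
#' `P`-class softmax head; 1,930,659 parameters at `P = 5`.
#' `build_cnn_b()` is the deeper 192x192x3 variant with filters 30, 60, 90,
#' 120, 240, 480 and 1024 and a 1024-unit dense block; 6,951,531 parameters at
#' `P = 5`. `build_cnn_small()` is a desk-scale member of the same family
#' (three conv blocks, 32x32 input) suitable for training on a single CPU in
#' seconds; it is the configuration the synthetic benchmark trains.
#'
#' @param P number of pain classes (>= 2).
#' @param input_size input image side length in pixels.
#' @param filters conv filter counts per block (`build_cnn_small` only).
#' @param fc_units width of the dense block (`build_cnn_small` only).
#' @param conv_drop,fc_drop dropout rates after conv blocks / the dense block.
#' @return An [architecture_spec()].
#' @examples
#' attr(count_params(build_cnn_a(5)), "total")  # 1930659
#' @export
build_cnn_a <- function(P, input_size = 128L, conv_drop = 0.25, fc_drop = 0.5) {
  build_conv_family("cnn_a", input_size, c(30L, 60L, 90L, 120L, 120L, 240L, 512L),
                    512L, P, conv_drop, fc_drop)
}

#' @rdname build_cnn_a
#' @export
build_cnn_b <- function(P, input_size = 192L, conv_drop = 0.25, fc_drop = 0.5) {
  build_conv_family("cnn_b", input_size, c(30L, 60L, 90L, 120L, 240L, 480L, 1024L),
                    1024L, P, conv_drop, fc_drop)
}

#' @rdname build_cnn_a
#' @export
build_cnn_small <- function(P, input_size = 32L, filters = c(12L, 24L, 48L),
                            fc_units = 48L, conv_drop = 0.1, fc_drop = 0.2) {
  build_conv_family("cnn_small", input_size, as.integer(filters),
                    as.integer(fc_units), P, conv_drop, fc_drop)
}

#' Build the dense audio classifier architecture
#'
#' A fully connected chain `d -> 512 -> 256 -> 128 -> num_classes`, each
#' hidden dense layer followed by batch normalization, ReLU and dropout.
#' Its total parameter count is `168,195 + (1 + d) * 512` at the default
#' three classes.
#'
#' @param d input feature dimension (>= 1); 352 for the MFCC+spectral bank,
#'   363 for all three blocks.
#' @param num_classes number of pain classes (default 3).
#' @param drop dropout rate after each hidden dense block.
#' @return An [architecture_spec()].
#' @examples
#' attr(count_params(build_audio_net(352)), "total")  # 348931
#' @export
build_audio_net <- function(d, num_classes = 3L, drop = 0.3) {
  d <- as.integer(d)
  if (d < 1L) stop("feature dimension d must be >= 1, got ", d)
  layers <- list(layer_flatten(name = "flatten"))
  widths <- c(512L, 256L, 128L)
  for (i in seq_along(widths)) {
    pre <- paste0("fc", i)
    layers <- c(layers, list(
      layer_dense(widths[i], name = pre),
      layer_batchnorm(name = paste0(pre, "_bn")),
      layer_activation("relu", name = paste0(pre, "_relu")),
      layer_dropout(drop, name = paste0(pre, "_drop"))))
  }
  layers <- c(layers, list(layer_dense(as.integer(num_classes), name = "output"),
                           layer_activation("softmax", name = "softmax")))
  architecture_spec("audio_net", d, layers, num_classes)
}

# ---- serialization and display ----------------------------------------------

#' Serialize an architecture to/from JSON
#'
#' @param arch a [architecture_spec()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @param json JSON string or file path produced by `arch_to_json`.
#' @return `arch_to_json`: JSON string (invisibly when written to `path`);
#'   `arch_from_json`: an [architecture_spec()].
#' @export
arch_to_json <- function(arch, path = NULL) {
  stopifnot(inherits(arch, "painsense_arch"))
  obj <- list(name = arch$name, input_shape = arch$input_shape,
              num_classes = arch$num_classes,
              layers = lapply(arch$layers, function(l) l[!vapply(l, is.null, TRUE)]))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname arch_to_json
#' @export
arch_from_json <- function(json) {
  if (length(json) == 1L && !grepl("\\{", json)) json <- paste(readLines(json),
                                                               collapse = "\n")
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  layers <- lapply(obj$layers, function(l) {
    switch(l$kind,
      conv2d = layer_conv(l$filters, unlist(l$kernel), name = l$name),
      maxpool2d = layer_maxpool(unlist(l$pool), name = l$name),
      batchnorm = layer_batchnorm(name = l$name),
      activation = layer_activation(l$fun, name = l$name),
      dropout = layer_dropout(l$rate, name = l$name),
      flatten = layer_flatten(name = l$name),
      dense = layer_dense(l$units, name = l$name),
      stop("unknown layer kind: ", l$kind))
  })
  architecture_spec(obj$name, unlist(obj$input_shape), layers, obj$num_classes)
}

#' Format or print an architecture's layer table
#'
#' Renders rows of (layer, output shape, parameter count) with a running
#' total, the layout of the printed network tables.
#'
#' @param arch an [architecture_spec()], or for [print_architecture()] one of
#'   the built-in names `"cnn_a"`, `"cnn_b"`, `"cnn_small"`, `"audio"`.
#' @param P class count for the image nets.
#' @param d feature dimension for the audio net.
#' @return `format_architecture`: character vector of table lines.
#'   `print_architecture`: the formatted lines, invisibly, after printing.
#' @export
format_architecture <- function(arch) {
  shp <- propagate_shapes(arch)
  cnt <- count_params(arch)
  shape_str <- ifelse(is.na(shp$out_h),
                      sprintf("(1, %d)", shp$out_c),
                      sprintf("(%d, %d, %d)", shp$out_h, shp$out_w, shp$out_c))
  lines <- sprintf("%-16s %-14s %12s", shp$layer, shape_str,
                   format(cnt$params, big.mark = ","))
  c(sprintf("%s  [input %s]", arch$name,
            paste(arch$input_shape, collapse = "x")),
    sprintf("%-16s %-14s %12s", "layer", "output shape", "parameters"),
    lines,
    sprintf("%-16s %-14s %12s", "total", "",
            format(attr(cnt, "total"), big.mark = ",")),
    sprintf("%-16s %-14s %12s", "trainable", "",
            format(attr(cnt, "trainable"), big.mark = ",")),
    sprintf("%-16s %-14s %12s", "non-trainable", "",
            format(attr(cnt, "non_trainable"), big.mark = ",")))
}

#' @rdname format_architecture
#' @export
print_architecture <- function(arch, P = 5L, d = 352L) {
  if (is.character(arch)) {
    arch <- switch(arch,
      cnn_a = build_cnn_a(P), cnn_b = build_cnn_b(P),
      cnn_small = build_cnn_small(P), audio = build_audio_net(d),
      stop("unknown architecture name: ", arch))
  }
  lines <- format_architecture(arch)
  cat(lines, sep = "\n")
  invisible(lines)
}
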