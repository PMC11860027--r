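# Minimal neural-network engine: conv2d (same padding) / maxpool / batchnorm /
# relu / dropout / flatten / dense, softmax cross-entropy loss, Adam updates.
# Data layout: images as (n, H, W, C) arrays, vectors as n x d matrices; all
# heavy work is BLAS matrix multiplication via im2col.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# ---- initialization ---------------------------------------------------------

#' Instantiate an untrained model from an architecture
#'
#' Allocates He-initialized weights for every parametric layer of `arch`.
#' The resulting object is what [train_image_model()] and
#' [train_audio_model()] train and what [score_images()] scores with.
#'
#' @param arch an [architecture_spec()].
#' @param seed integer seed for the weight initialization.
#' @return A `painsense_model`: list with elements `arch`, `params` (per-layer
#'   weight arrays) and `config`.
#' @export
nn_init <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "painsense_arch"))
  set.seed(seed)
  shapes <- propagate_shapes(arch)
  params <- vector("list", length(arch$layers))
  names(params) <- shapes$layer
  prev_c <- arch$input_shape[3]
  prev_len <- prod(arch$input_shape)
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    if (l$kind == "conv2d") {
      fan_in <- prod(l$kernel) * prev_c
      params[[i]] <- list(W = matrix(stats::rnorm(fan_in * l$filters,
                                                  sd = sqrt(2 / fan_in)),
                                     fan_in, l$filters),
                          b = numeric(l$filters))
    } else if (l$kind == "dense") {
      n_in <- if (i == 1L) prev_len else shapes$out_c[i - 1L]
      params[[i]] <- list(W = matrix(stats::rnorm(n_in * l$units,
                                                  sd = sqrt(2 / n_in)),
                                     n_in, l$units),
                          b = numeric(l$units))
    } else if (l$kind == "batchnorm") {
      c_here <- if (i == 1L) prev_c else shapes$out_c[i - 1L]
      params[[i]] <- list(gamma = rep(1, c_here), beta = numeric(c_here),
                          mmean = numeric(c_here), mvar = rep(1, c_here))
    }
    prev_c <- shapes$out_c[i]
  }
  structure(list(arch = arch, shapes = shapes, params = params,
                 config = list(seed = seed)),
            class = "painsense_model")
}

#' @export
print.painsense_model <- function(x, ...) {
  cnt <- nn_param_count(x)
  cat(sprintf("painsense_model '%s': %s parameters (%s trainable), %d classes\n",
              x$arch$name, format(cnt$total, big.mark = ","),
              format(cnt$trainable, big.mark = ","), x$arch$num_classes))
  if (!is.null(x$config$epochs))
    cat(sprintf("  trained %d epochs, batch %d, lr %g, seed %d\n",
                x$config$epochs, x$config$batch_size, x$config$lr,
                x$config$seed))
  invisible(x)
}

#' Count the variables actually held by an instantiated model
#'
#' Sums the lengths of every weight array the model stores; the independent
#' cross-check of the analytic [count_params()].
#'
#' @param model a `painsense_model`.
#' @return list with `trainable`, `non_trainable`, `total`.
#' @export
nn_param_count <- function(model) {
  tr <- nt <- 0L
  for (p in model$params) {
    if (is.null(p)) next
    for (nm in names(p)) {
      n <- length(p[[nm]])
      if (nm %in% c("mmean", "mvar")) nt <- nt + n else tr <- tr + n
    }
  }
  list(trainable = tr, non_trainable = nt, total = tr + nt)
}

# ---- layer forward/backward -------------------------------------------------

im2col <- function(x, kh, kw) {
  d <- dim(x); n <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  xp <- array(0, c(n, H + 2 * ph, W + 2 * pw, C))
  xp[, ph + seq_len(H), pw + seq_len(W), ] <- x
  cols <- matrix(0, n * H * W, kh * kw * C)
  k <- 0L
  for (dj in seq_len(kw) - 1L) for (di in seq_len(kh) - 1L) {
    sub <- xp[, di + seq_len(H), dj + seq_len(W), , drop = FALSE]
    dim(sub) <- c(n * H * W, C)
    cols[, k * C + seq_len(C)] <- sub
    k <- k + 1L
  }
  cols
}

col2im <- function(dcols, n, H, W, C, kh, kw) {
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  dxp <- array(0, c(n, H + 2 * ph, W + 2 * pw, C))
  k <- 0L
  for (dj in seq_len(kw) - 1L) for (di in seq_len(kh) - 1L) {
    sub <- dcols[, k * C + seq_len(C), drop = FALSE]
    dim(sub) <- c(n, H, W, C)
    dxp[, di + seq_len(H), dj + seq_len(W), ] <-
      dxp[, di + seq_len(H), dj + seq_len(W), , drop = FALSE] + sub
    k <- k + 1L
  }
  dxp[, ph + seq_len(H), pw + seq_len(W), , drop = FALSE]
}

fwd_conv <- function(x, p, l) {
  d <- dim(x)
  cols <- im2col(x, l$kernel[1], l$kernel[2])
  out <- cols %*% p$W
  out <- out + rep(p$b, each = nrow(out))
  dim(out) <- c(d[1], d[2], d[3], l$filters)
  list(out = out, cache = list(cols = cols, dims = d))
}

bwd_conv <- function(dout, p, l, cache) {
  d <- cache$dims
  doutm <- dout; dim(doutm) <- c(d[1] * d[2] * d[3], l$filters)
  dW <- crossprod(cache$cols, doutm)
  db <- colSums(doutm)
  dcols <- doutm %*% t(p$W)
  dx <- col2im(dcols, d[1], d[2], d[3], d[4], l$kernel[1], l$kernel[2])
  list(dx = dx, grads = list(W = dW, b = db))
}

fwd_maxpool <- function(x, l) {
  d <- dim(x); n <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  ph <- l$pool[1]; pw <- l$pool[2]
  Ho <- H %/% ph; Wo <- W %/% pw
  rows <- seq(1L, by = ph, length.out = Ho)
  cols <- seq(1L, by = pw, length.out = Wo)
  m <- NULL; idx <- NULL
  k <- 0L
  for (dj in seq_len(pw) - 1L) for (di in seq_len(ph) - 1L) {
    k <- k + 1L
    sub <- x[, rows + di, cols + dj, , drop = FALSE]
    if (k == 1L) { m <- sub; idx <- array(1L, dim(sub)) }
    else { upd <- sub > m; idx[upd] <- k; m[upd] <- sub[upd] }
  }
  list(out = m, cache = list(idx = idx, dims = d, Ho = Ho, Wo = Wo,
                             rows = rows, cols = cols, ph = ph, pw = pw))
}

bwd_maxpool <- function(dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  k <- 0L
  for (dj in seq_len(cache$pw) - 1L) for (di in seq_len(cache$ph) - 1L) {
    k <- k + 1L
    dsub <- dout * (cache$idx == k)
    dx[, cache$rows + di, cache$cols + dj, ] <- dsub
  }
  dx
}

as_bn_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  m <- x; dim(m) <- c(d[1] * d[2] * d[3], d[4])
  m
}

fwd_batchnorm <- function(x, p, training) {
  d <- dim(x)
  m <- as_bn_matrix(x)
  if (training) {
    mu <- colMeans(m)
    v <- colMeans(m * m) - mu^2
    new_stats <- list(mmean = BN_MOMENTUM * p$mmean + (1 - BN_MOMENTUM) * mu,
                      mvar = BN_MOMENTUM * p$mvar + (1 - BN_MOMENTUM) * v)
  } else {
    mu <- p$mmean; v <- p$mvar; new_stats <- NULL
  }
  inv_sd <- 1 / sqrt(v + BN_EPS)
  xhat <- (m - rep(mu, each = nrow(m))) * rep(inv_sd, each = nrow(m))
  out <- xhat * rep(p$gamma, each = nrow(m)) + rep(p$beta, each = nrow(m))
  dim(out) <- d
  list(out = out,
       cache = list(xhat = xhat, inv_sd = inv_sd, dims = d),
       new_stats = new_stats)
}

bwd_batchnorm <- function(dout, p, cache) {
  d <- cache$dims
  dm <- as_bn_matrix(dout)
  m_rows <- nrow(dm)
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  dxhat <- dm * rep(p$gamma, each = m_rows)
  dx <- (dxhat - rep(colMeans(dxhat), each = m_rows) -
           cache$xhat * rep(colMeans(dxhat * cache$xhat), each = m_rows)) *
    rep(cache$inv_sd, each = m_rows)
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

fwd_dropout <- function(x, l, training) {
  if (!training) return(list(out = x, cache = NULL))
  mask <- (stats::runif(length(x)) >= l$rate) / (1 - l$rate)
  dim(mask) <- dim(x)
  list(out = x * mask, cache = mask)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass through every layer. training toggles batch statistics and
# dropout; frozen batch-norm layers always use their moving statistics.
nn_forward <- function(model, x, training = FALSE, frozen = logical(0)) {
  layers <- model$arch$layers
  caches <- vector("list", length(layers))
  new_stats <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    p <- model$params[[i]]
    fr <- length(frozen) && frozen[i]
    r <- switch(l$kind,
      conv2d = fwd_conv(x, p, l),
      maxpool2d = fwd_maxpool(x, l),
      batchnorm = fwd_batchnorm(x, p, training && !fr),
      activation = {
        if (l$fun == "relu") list(out = pmax(x, 0), cache = x > 0)
        else list(out = softmax_rows(x), cache = NULL)  # softmax head
      },
      dropout = fwd_dropout(x, l, training),
      flatten = {
        d <- dim(x)
        out <- x; dim(out) <- c(d[1], prod(d[-1]))
        list(out = out, cache = d)
      },
      dense = list(out = x %*% p$W + rep(p$b, each = nrow(x)),
                   cache = x))
    x <- r$out
    caches[i] <- list(r$cache)   # keep NULL caches as elements
    if (!is.null(r$new_stats)) new_stats[[i]] <- r$new_stats
  }
  list(out = x, caches = caches, new_stats = new_stats)
}

# Backward pass from softmax cross-entropy. probs: n x L, y_onehot: n x L.
nn_backward <- function(model, fw, y_onehot) {
  layers <- model$arch$layers
  grads <- vector("list", length(layers))
  n <- nrow(y_onehot)
  dx <- (fw$out - y_onehot) / n   # grad wrt logits (softmax + CE combined)
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    p <- model$params[[i]]
    cache <- fw$caches[[i]]
    if (l$kind == "activation") {
      if (l$fun == "relu") dx <- dx * cache
      # softmax: combined with the loss; dx already holds dLoss/dlogits
    } else if (l$kind == "dense") {
      grads[[i]] <- list(W = crossprod(cache, dx), b = colSums(dx))
      dx <- dx %*% t(p$W)
    } else if (l$kind == "flatten") {
      dim(dx) <- cache
    } else if (l$kind == "dropout") {
      if (!is.null(cache)) dx <- dx * cache
    } else if (l$kind == "batchnorm") {
      r <- bwd_batchnorm(dx, p, cache)
      grads[[i]] <- r$grads; dx <- r$dx
    } else if (l$kind == "maxpool2d") {
      dx <- bwd_maxpool(dx, cache)
    } else if (l$kind == "conv2d") {
      r <- bwd_conv(dx, p, l, cache)
      grads[[i]] <- r$grads; dx <- r$dx
    }
  }
  grads
}

# ---- training ---------------------------------------------------------------

match_frozen <- function(layer_names, freeze) {
  if (!length(freeze)) return(rep(FALSE, length(layer_names)))
  Reduce(`|`, lapply(freeze, function(pat) grepl(pat, layer_names)))
}

#' Train a model with Adam on softmax cross-entropy
#'
#' Low-level trainer shared by the image and audio pipelines. Mini-batch
#' gradient descent with the Adam optimizer; batch normalization uses batch
#' statistics during training and moving averages at inference. Layers whose
#' names match a `freeze` pattern receive no updates (their batch-norm
#' statistics are also frozen).
#'
#' @param model a `painsense_model` from [nn_init()].
#' @param x input batch: `(n, H, W, C)` array or `n x d` matrix.
#' @param y integer class labels in `0 .. L-1` (or a factor).
#' @param epochs number of passes over the data; 0 returns the model unchanged.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate; `beta1`/`beta2` the moment decays.
#' @param seed RNG seed controlling shuffling and dropout.
#' @param freeze character vector of regular expressions matched against layer
#'   names; matching layers are not updated.
#' @param beta1,beta2 Adam moment decay rates.
#' @return The trained model, with a `history` data frame (epoch, mean
#'   cross-entropy loss, training accuracy) attached to `model$history`.
#' @export
nn_train <- function(model, x, y, epochs = 30L, batch_size = 16L, lr = 1e-3,
                     seed = 1L, freeze = character(0),
                     beta1 = 0.9, beta2 = 0.999) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  L <- model$arch$num_classes
  if (any(y < 0L | y >= L)) stop("labels must lie in 0 .. L-1")
  if (length(unique(y)) < 2L && epochs > 0L)
    stop("data error: training set contains a single class")
  n <- if (is.matrix(x)) nrow(x) else dim(x)[1]
  stopifnot(length(y) == n)
  frozen <- match_frozen(model$shapes$layer, freeze)
  set.seed(seed)
  onehot <- diag(L)[y + 1L, , drop = FALSE]
  # Adam state
  mstate <- vstate <- lapply(model$params, function(p)
    if (is.null(p)) NULL else lapply(p[setdiff(names(p), c("mmean", "mvar"))],
                                     function(w) array(0, dim(w) %||% length(w))))
  step <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        acc = numeric(0))
  eps <- 1e-8
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c(); correct <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      ix <- ord[start:min(start + batch_size - 1L, n)]
      xb <- if (is.matrix(x)) x[ix, , drop = FALSE] else
        x[ix, , , , drop = FALSE]
      yb <- onehot[ix, , drop = FALSE]
      fw <- nn_forward(model, xb, training = TRUE, frozen = frozen)
      probs <- fw$out
      losses <- c(losses, -mean(log(rowSums(probs * yb) + 1e-12)))
      correct <- correct + sum(max.col(probs) == max.col(yb))
      grads <- nn_backward(model, fw, yb)
      step <- step + 1L
      for (i in seq_along(grads)) {
        if (frozen[i]) next
        # refresh batch-norm moving statistics
        if (!is.null(fw$new_stats[[i]])) {
          model$params[[i]]$mmean <- fw$new_stats[[i]]$mmean
          model$params[[i]]$mvar <- fw$new_stats[[i]]$mvar
        }
        g <- grads[[i]]
        if (is.null(g)) next
        for (nm in names(g)) {
          mstate[[i]][[nm]] <- beta1 * mstate[[i]][[nm]] + (1 - beta1) * g[[nm]]
          vstate[[i]][[nm]] <- beta2 * vstate[[i]][[nm]] +
            (1 - beta2) * g[[nm]]^2
          mhat <- mstate[[i]][[nm]] / (1 - beta1^step)
          vhat <- vstate[[i]][[nm]] / (1 - beta2^step)
          model$params[[i]][[nm]] <- model$params[[i]][[nm]] -
            lr * mhat / (sqrt(vhat) + eps)
        }
      }
    }
    history <- rbind(history,
                     data.frame(epoch = ep, loss = mean(losses),
                                acc = correct / n))
  }
  model$history <- history
  model$config <- utils::modifyList(model$config,
                                    list(epochs = epochs,
                                         batch_size = batch_size, lr = lr,
                                         seed = seed, freeze = freeze))
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict class probabilities
#'
#' Runs the model in inference mode (moving batch-norm statistics, no
#' dropout); rows of the result sum to one.
#'
#' @param model a `painsense_model`.
#' @param x inputs in the model's layout.
#' @return `n x L` matrix of class probabilities.
#' @export
nn_predict <- function(model, x) {
  nn_forward(model, x, training = FALSE)$out
}

# ---- weight transfer --------------------------------------------------------

#' Copy compatible weights between models
#'
#' Transfers every parameter array whose layer name exists in both models and
#' whose dimensions agree; used by the progressive-resolution and
#' transfer-learning training schemes. Layers with incompatible shapes (for
#' example the first dense layer when the flatten length changed) keep the
#' destination's fresh initialization.
#'
#' @param to,from `painsense_model` objects.
#' @return `to`, with transferred weights; the names of the transferred layers
#'   are recorded in `attr(, "transferred")`.
#' @export
nn_transfer_weights <- function(to, from) {
  moved <- character(0)
  for (nm in intersect(names(to$params), names(from$params))) {
    pt <- to$params[[nm]]; pf <- from$params[[nm]]
    if (is.null(pt) || is.null(pf)) next
    ok <- all(vapply(names(pt), function(w)
      identical(dim(pt[[w]]) %||% length(pt[[w]]),
                dim(pf[[w]]) %||% length(pf[[w]])), logical(1)))
    if (ok) { to$params[[nm]] <- pf; moved <- c(moved, nm) }
  }
  attr(to, "transferred") <- moved
  to
}
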