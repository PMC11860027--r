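# Score-level fusion rules (product, sum, weighted sum) and decision-level
# majority voting over aligned classifier score matrices.

#' Classifier score matrix
#'
#' An `n x L` matrix of nonnegative per-class scores with class labels and
#' sample identifiers; the object every fusion rule operates on. Softmax
#' outputs have rows summing to one.
#'
#' @param scores numeric `n x L` matrix, no negative entries.
#' @param class_labels length-`L` class names.
#' @param sample_ids length-`n` sample identifiers.
#' @return A `painsense_scores` object (a matrix with `dimnames` set).
#' @export
score_matrix <- function(scores, class_labels = colnames(scores),
                         sample_ids = rownames(scores)) {
  scores <- as.matrix(scores)
  if (any(scores < 0)) stop("scores must be nonnegative")
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (is.null(class_labels))
    class_labels <- paste0("class", seq_len(ncol(scores)) - 1L)
  if (is.null(sample_ids))
    sample_ids <- paste0("s", seq_len(nrow(scores)))
  stopifnot(length(class_labels) == ncol(scores),
            length(sample_ids) == nrow(scores))
  dimnames(scores) <- list(as.character(sample_ids),
                           as.character(class_labels))
  class(scores) <- c("painsense_scores", "matrix", "array")
  scores
}

#' @export
print.painsense_scores <- function(x, ...) {
  cat(sprintf("score matrix: %d samples x %d classes\n", nrow(x), ncol(x)))
  print(utils::head(unclass(x), 6L), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

check_aligned <- function(l1, l2) {
  if (!identical(dim(l1), dim(l2)))
    stop("alignment error: score matrices have shapes ",
         paste(dim(l1), collapse = "x"), " and ",
         paste(dim(l2), collapse = "x"))
  if (!identical(colnames(l1), colnames(l2)))
    stop("alignment error: class labels differ")
  if (!identical(rownames(l1), rownames(l2)))
    stop("alignment error: sample ids differ")
}

#' Score-level fusion rules
#'
#' For two aligned score matrices `l1`, `l2` (same samples, same class
#' order): `product_fuse` returns the elementwise product `l1 * l2`,
#' `sum_fuse` the elementwise sum `l1 + l2`, and `weighted_sum_fuse` the
#' weighted sum `rho1 * l1 + rho2 * l2`. The predicted class is the row
#' argmax of the fused matrix.
#'
#' @param l1,l2 [score_matrix()] objects with identical shape, class labels
#'   and sample ids.
#' @param renormalize if `TRUE`, rescale each fused row to sum to one
#'   (default off; the argmax is unaffected).
#' @param weights a [fusion_weights()] or numeric pair `(rho1, rho2)`.
#' @return The fused [score_matrix()].
#' @name score_fusion
NULL

#' @rdname score_fusion
#' @export
product_fuse <- function(l1, l2, renormalize = FALSE) {
  check_aligned(l1, l2)
  out <- unclass(l1) * unclass(l2)
  if (renormalize) {
    rs <- rowSums(out)
    out[rs > 0, ] <- out[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  score_matrix(out, colnames(l1), rownames(l1))
}

#' @rdname score_fusion
#' @export
sum_fuse <- function(l1, l2, renormalize = FALSE) {
  check_aligned(l1, l2)
  out <- unclass(l1) + unclass(l2)
  if (renormalize) out <- out / rowSums(out)
  score_matrix(out, colnames(l1), rownames(l1))
}

#' @rdname score_fusion
#' @export
weighted_sum_fuse <- function(l1, l2, weights) {
  check_aligned(l1, l2)
  if (inherits(weights, "painsense_weights")) weights <- unlist(weights)
  if (length(weights) != 2L || any(weights < 0))
    stop("argument error: weights must be two nonnegative numbers")
  out <- weights[1] * unclass(l1) + weights[2] * unclass(l2)
  score_matrix(out, colnames(l1), rownames(l1))
}

#' Fusion weights from validation accuracies
#'
#' Normalizes the two weights to sum to one, proportional to each model's
#' validation accuracy, so that the better model receives the larger weight
#' (ties give 0.5/0.5). Both accuracies zero falls back to equal weights with
#' a warning.
#'
#' @param acc1,acc2 validation accuracies in `[0, 1]`.
#' @return A `painsense_weights` object: list `(rho1, rho2)`, summing to 1.
#' @export
choose_weights <- function(acc1, acc2) {
  stopifnot(acc1 >= 0, acc1 <= 1, acc2 >= 0, acc2 <= 1)
  if (acc1 + acc2 == 0) {
    warning("both accuracies are zero; falling back to equal weights")
    w <- c(0.5, 0.5)
  } else w <- c(acc1, acc2) / (acc1 + acc2)
  structure(list(rho1 = w[1], rho2 = w[2]), class = "painsense_weights")
}

#' @rdname choose_weights
#' @param rho1,rho2 nonnegative weights set directly.
#' @export
fusion_weights <- function(rho1, rho2) {
  if (rho1 < 0 || rho2 < 0) stop("argument error: weights must be nonnegative")
  structure(list(rho1 = rho1, rho2 = rho2), class = "painsense_weights")
}

#' Decision-level fusion by majority voting
#'
#' Each score matrix votes its per-row argmax; the plurality class wins.
#' Ties are broken by the highest posterior summed across the voting
#' matrices over the tied classes, then by the lowest class index — a fixed,
#' deterministic chain.
#'
#' @param score_matrices list of two or more aligned [score_matrix()] objects.
#' @return Integer vector of predicted class indices in `0 .. L-1`, named by
#'   sample id.
#' @export
majority_vote <- function(score_matrices) {
  if (length(score_matrices) < 2L)
    stop("majority_vote needs at least two score matrices")
  for (m in score_matrices[-1L]) check_aligned(score_matrices[[1L]], m)
  L <- ncol(score_matrices[[1L]])
  n <- nrow(score_matrices[[1L]])
  votes <- vapply(score_matrices, function(m) max.col(m, ties.method = "first"),
                  integer(n) + 0)
  votes <- matrix(votes, nrow = n)
  total <- Reduce(`+`, lapply(score_matrices, unclass))
  pred <- integer(n)
  for (i in seq_len(n)) {
    tab <- tabulate(votes[i, ], nbins = L)
    top <- which(tab == max(tab))
    if (length(top) > 1L) {
      post <- total[i, top]
      top <- top[post == max(post)]   # posterior tie-break
    }
    pred[i] <- min(top) - 1L          # lowest class index last
  }
  names(pred) <- rownames(score_matrices[[1L]])
  pred
}

#' Fuse paired multimodal scores and evaluate
#'
#' Aligns image-sample and audio-sample score matrices through a pairing
#' manifest (`image_id`, `audio_id`, `label`), fuses each pair with the
#' chosen rule, and scores the fused predictions against the shared labels.
#' When the two modalities use different class vocabularies a `class_map`
#' (named character vector, audio class -> image class) translates them.
#'
#' @param image_scores,audio_scores [score_matrix()] objects whose row names
#'   contain all paired ids.
#' @param pairing data frame with columns `image_id`, `audio_id`, `label`.
#' @param method `"majority"`, `"product"`, `"sum"` or `"weighted"`.
#' @param weights for `method = "weighted"`, a [fusion_weights()].
#' @param class_map optional named character vector mapping audio class
#'   labels onto image class labels.
#' @return An evaluation report (see [compute_metrics()]) with the fused
#'   predictions attached as `$predictions`.
#' @export
pair_and_fuse <- function(image_scores, audio_scores, pairing,
                          method = c("majority", "product", "sum", "weighted"),
                          weights = NULL, class_map = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("image_id", "audio_id", "label") %in% names(pairing)))
  miss_i <- setdiff(as.character(pairing$image_id), rownames(image_scores))
  miss_a <- setdiff(as.character(pairing$audio_id), rownames(audio_scores))
  if (length(miss_i) || length(miss_a))
    stop("alignment error: pairing refers to unknown samples: ",
         paste(c(miss_i, miss_a), collapse = ", "))
  au <- unclass(audio_scores)[as.character(pairing$audio_id), , drop = FALSE]
  if (!is.null(class_map)) {
    unmapped <- setdiff(colnames(au), names(class_map))
    if (length(unmapped))
      stop("mapping error: no image class for audio classes: ",
           paste(unmapped, collapse = ", "))
    colnames(au) <- unname(class_map[colnames(au)])
    au <- au[, colnames(image_scores), drop = FALSE]
  }
  im <- unclass(image_scores)[as.character(pairing$image_id), , drop = FALSE]
  ids <- paste0("pair", seq_len(nrow(pairing)))
  im <- score_matrix(im, colnames(image_scores), ids)
  au <- score_matrix(au, colnames(image_scores), ids)
  pred <- switch(method,
    majority = majority_vote(list(im, au)),
    product = max.col(product_fuse(im, au), ties.method = "first") - 1L,
    sum = max.col(sum_fuse(im, au), ties.method = "first") - 1L,
    weighted = {
      if (is.null(weights)) stop("argument error: weighted fusion needs weights")
      max.col(weighted_sum_fuse(im, au, weights), ties.method = "first") - 1L
    })
  rep <- compute_metrics(as.integer(pred), as.integer(pairing$label),
                         n_classes = ncol(image_scores))
  rep$predictions <- stats::setNames(as.integer(pred), ids)
  rep
}
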