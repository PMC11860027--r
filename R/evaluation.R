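# Evaluation protocols: stratified train/test splits, classification metrics
# in the mixed units of the reported tables (accuracy/precision/recall in %,
# F1 as a fraction), and the one-tailed two-sample t-test comparator.

#' Stratified train/test split
#'
#' Splits sample indices so that each class contributes
#' `round(train_fraction * class size)` training samples; deterministic under
#' `seed`. The 50-50 and 75-25 protocols are the two presets used throughout.
#'
#' @param labels vector of class labels (any type).
#' @param train_fraction fraction of each class used for training, in (0, 1).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.5, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("protocol error: train_fraction must be in (0, 1)")
  tab <- table(labels)
  if (any(tab < 2L))
    stop("protocol error: every class needs >= 2 samples; offending: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  set.seed(seed)
  train <- integer(0)
  for (cl in names(tab)) {
    ix <- which(labels == cl)
    n_tr <- round(train_fraction * length(ix))
    n_tr <- min(max(n_tr, 1L), length(ix) - 1L)  # both sides non-empty
    train <- c(train, sample(ix, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Classification metrics report
#'
#' Confusion matrix plus accuracy, macro-averaged precision and recall (all
#' in percent) and macro F1 (as a fraction), with per-class values attached.
#'
#' @param predictions,labels integer class indices `0 .. L-1` (or factors
#'   with identical levels), equal length and non-empty.
#' @param n_classes number of classes; inferred from the data when missing.
#' @return A `painsense_eval` list: `confusion`, `accuracy` (%), `precision`
#'   (%), `recall` (%), `f1` (fraction), `per_class` data frame, `n`.
#' @export
compute_metrics <- function(predictions, labels, n_classes = NULL) {
  if (length(predictions) != length(labels))
    stop("data error: predictions and labels differ in length")
  if (!length(labels)) stop("data error: empty prediction set")
  if (is.factor(predictions)) predictions <- as.integer(predictions) - 1L
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  L <- n_classes %||% (max(predictions, labels) + 1L)
  cm <- matrix(0L, L, L, dimnames = list(predicted = 0:(L - 1),
                                         actual = 0:(L - 1)))
  for (i in seq_along(labels))
    cm[predictions[i] + 1L, labels[i] + 1L] <- cm[predictions[i] + 1L,
                                                  labels[i] + 1L] + 1L
  n <- length(labels)
  tp <- diag(cm)
  pred_tot <- rowSums(cm)   # predicted as class c
  act_tot <- colSums(cm)    # truly class c
  prec_c <- ifelse(pred_tot > 0, tp / pred_tot, 0)
  rec_c <- ifelse(act_tot > 0, tp / act_tot, 0)
  f1_c <- ifelse(prec_c + rec_c > 0, 2 * prec_c * rec_c / (prec_c + rec_c), 0)
  structure(list(confusion = cm,
                 accuracy = 100 * sum(tp) / n,
                 precision = 100 * mean(prec_c),
                 recall = 100 * mean(rec_c),
                 f1 = mean(f1_c),
                 per_class = data.frame(class = 0:(L - 1),
                                        precision = prec_c, recall = rec_c,
                                        f1 = f1_c,
                                        support = as.integer(act_tot)),
                 n = n),
            class = "painsense_eval")
}

#' @export
print.painsense_eval <- function(x, ...) {
  cat(sprintf("n = %d  accuracy %.2f%%  precision %.2f%%  recall %.2f%%  F1 %.4f\n",
              x$n, x$accuracy, x$precision, x$recall, x$f1))
  cat("confusion (rows = predicted, cols = actual):\n")
  print(x$confusion)
  invisible(x)
}

#' One-tailed two-sample t-test (pooled variance)
#'
#' Tests `H0: mu_a <= mu_b` against `H1: mu_a > mu_b` with the Student
#' pooled-variance statistic on `df = n_a + n_b - 2` degrees of freedom; the
#' one-tailed p-value is the upper tail of the t distribution. `H0` is
#' rejected when `p < alpha`. With zero variance in both groups and equal
#' means the statistic is undefined and a no-decision flag is returned.
#'
#' @param a,b numeric performance values (each of length >= 2).
#' @param alpha significance level (default 0.05).
#' @param var_equal use the pooled (Student) variance; `FALSE` switches to
#'   the Welch statistic.
#' @return A `painsense_ttest` list: `mean_a`, `mean_b`, `sd_a`, `sd_b`, `t`,
#'   `df`, `p`, `alpha`, `reject` (logical, `NA` when undefined), `decision`
#'   (text).
#' @export
one_tailed_ttest <- function(a, b, alpha = 0.05, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("data error: each group needs >= 2 values")
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  if (se == 0) {
    if (ma == mb)
      return(structure(list(mean_a = ma, mean_b = mb, sd_a = sqrt(va),
                            sd_b = sqrt(vb), t = NA_real_, df = df,
                            p = NA_real_, alpha = alpha, reject = NA,
                            decision = "no decision: zero variance, equal means"),
                       class = "painsense_ttest"))
    tstat <- sign(ma - mb) * Inf
  } else tstat <- (ma - mb) / se
  p <- stats::pt(tstat, df, lower.tail = FALSE)
  reject <- is.finite(p) && p < alpha
  structure(list(mean_a = ma, mean_b = mb, sd_a = sqrt(va), sd_b = sqrt(vb),
                 t = tstat, df = df, p = p, alpha = alpha, reject = reject,
                 decision = if (reject) "H0 rejected: group A performs better"
                            else "H0 accepted"),
            class = "painsense_ttest")
}

#' @export
print.painsense_ttest <- function(x, ...) {
  cat(sprintf("one-tailed t-test: t = %.4f, df = %.6g, p = %.4g (alpha %.3g)\n%s\n",
              x$t, x$df, x$p, x$alpha, x$decision))
  invisible(x)
}
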