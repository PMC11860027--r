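# Audio classifier: the dense network over the handcrafted feature bank,
# plus the four classical baseline classifiers.

#' Train the dense audio classifier
#'
#' Standardizes the feature columns (z-score; the scaler is stored with the
#' model and re-applied at prediction), builds the `d -> 512 -> 256 -> 128 ->
#' L` architecture via [build_audio_net()] and trains it with Adam. The
#' default batch size 32 and 100 epochs are the configuration found optimal
#' for the audio model.
#'
#' @param features `n x d` numeric matrix (e.g. from
#'   [audio_feature_matrix()]).
#' @param labels integer classes `0 .. L-1` (or a factor).
#' @param num_classes class count; inferred from labels when missing.
#' @param epochs,batch_size,lr,seed training configuration.
#' @param drop dropout rate of the hidden blocks.
#' @return A trained `painsense_model` with a `$scaler` (column means/sds).
#' @export
train_audio_model <- function(features, labels, num_classes = NULL,
                              epochs = 100L, batch_size = 32L, lr = 1e-3,
                              seed = 1L, drop = 0.3) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop("data error: non-finite features")
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (length(unique(labels)) < 2L && epochs > 0L)
    stop("data error: training set contains a single class")
  L <- num_classes %||% (max(labels) + 1L)
  L <- max(L, 2L)
  mu <- colMeans(features)
  sd_ <- apply(features, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  X <- sweep(sweep(features, 2, mu), 2, sd_, "/")
  arch <- build_audio_net(ncol(X), num_classes = L, drop = drop)
  model <- nn_init(arch, seed = seed)
  model <- nn_train(model, X, labels, epochs = epochs,
                    batch_size = batch_size, lr = lr, seed = seed)
  model$scaler <- list(mean = mu, sd = sd_)
  model
}

#' Score audio feature vectors
#'
#' @param model model from [train_audio_model()].
#' @param features `n x d` matrix with the training dimensionality.
#' @param sample_ids optional row identifiers.
#' @return A [score_matrix()].
#' @export
score_audio <- function(model, features, sample_ids = NULL) {
  features <- as.matrix(features)
  d_expect <- model$arch$input_shape[3]
  if (ncol(features) != d_expect)
    stop("data error: features have d = ", ncol(features),
         " but the model expects ", d_expect)
  X <- sweep(sweep(features, 2, model$scaler$mean), 2, model$scaler$sd, "/")
  probs <- nn_predict(model, X)
  score_matrix(probs,
               class_labels = paste0("class", seq_len(ncol(probs)) - 1L),
               sample_ids = sample_ids %||% paste0("s", seq_len(nrow(probs))))
}

#' Classical baseline classifiers
#'
#' Fits the four standard baselines — decision tree (`rpart`), logistic
#' regression (`nnet::multinom`), k-nearest neighbours (`class::knn`,
#' `k = 5`) and a radial-kernel SVM (`e1071::svm`) — under one or more
#' stratified split protocols and reports accuracy, precision, recall and F1
#' for each classifier/protocol combination.
#'
#' @param features `n x d` feature matrix.
#' @param labels integer classes `0 .. L-1` (or a factor).
#' @param train_fractions split protocols (default the 50-50 and 75-25
#'   presets).
#' @param seed split seed.
#' @return Data frame with columns `classifier`, `protocol`, `accuracy`,
#'   `precision`, `recall` (percent) and `f1` (fraction); the full
#'   [compute_metrics()] reports are attached as attribute `reports`.
#' @export
baseline_classifiers <- function(features, labels,
                                 train_fractions = c(0.5, 0.75), seed = 1L) {
  features <- as.matrix(features)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (length(unique(labels)) < 2L)
    stop("data error: need >= 2 classes")
  y <- factor(labels)
  # drop constant columns (zero variance breaks scaling inside svm)
  keep <- apply(features, 2, stats::sd) > 0
  features <- features[, keep, drop = FALSE]
  rows <- list(); reports <- list()
  for (fr in train_fractions) {
    sp <- stratified_split(labels, train_fraction = fr, seed = seed)
    xtr <- features[sp$train, , drop = FALSE]
    xte <- features[sp$test, , drop = FALSE]
    ytr <- y[sp$train]; yte <- labels[sp$test]
    dtr <- data.frame(y = ytr, xtr)
    dte <- data.frame(xte)
    names(dte) <- names(dtr)[-1L]
    preds <- list(
      decision_tree = as.integer(as.character(stats::predict(
        rpart::rpart(y ~ ., dtr, method = "class"), dte, type = "class"))),
      logistic_regression = as.integer(as.character(stats::predict(
        nnet::multinom(y ~ ., dtr, trace = FALSE, MaxNWts = 1e5), dte))),
      knn = {
        mu <- colMeans(xtr)
        s <- pmax(apply(xtr, 2, stats::sd), 1e-8)
        as.integer(as.character(class::knn(
          sweep(sweep(xtr, 2, mu), 2, s, "/"),
          sweep(sweep(xte, 2, mu), 2, s, "/"), ytr, k = 5L)))
      },
      svm = as.integer(as.character(stats::predict(
        e1071::svm(y ~ ., dtr, kernel = "radial"), dte))))
    for (nm in names(preds)) {
      rep <- compute_metrics(preds[[nm]], yte, n_classes = nlevels(y))
      proto <- sprintf("%d-%d", round(100 * fr), round(100 * (1 - fr)))
      rows[[paste(nm, proto)]] <- data.frame(
        classifier = nm, protocol = proto, accuracy = rep$accuracy,
        precision = rep$precision, recall = rep$recall, f1 = rep$f1)
      reports[[paste(nm, proto)]] <- rep
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "reports") <- reports
  out
}
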