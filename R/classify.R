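#' Aggregate per-tensor features into one clip-level feature
#'
#' A clip yields one feature vector per stacked tensor; the clip-level
#' feature used for classification is their element-wise mean (default) or
#' sum.
#'
#' @param features list of equal-length numeric vectors, or a matrix with
#'   one feature per row.
#' @param mode `"mean"` or `"sum"`.
#' @return numeric vector of the common feature length.
#' @export
aggregate_clip_feature <- function(features, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  if (is.list(features)) {
    if (length(features) == 0L) stop("no features to aggregate", call. = FALSE)
    len <- unique(vapply(features, length, integer(1)))
    if (length(len) != 1L)
      stop("features have unequal lengths", call. = FALSE)
    features <- do.call(rbind, features)
  }
  if (nrow(features) == 0L) stop("no features to aggregate", call. = FALSE)
  if (mode == "mean") colMeans(features) else colSums(features)
}

#' Leave-one-subject-out folds
#'
#' One fold per distinct subject (in first-appearance order of the
#' manifest): the fold's test set is all clips of that subject, the
#' training set all remaining clips. Folds partition the dataset and no
#' subject ever appears on both sides of a fold.
#'
#' @param index a `dataset_index`.
#' @return list of folds, each a list with `subject`, `train` and `test`
#'   clip-id character vectors.
#' @export
loso_split <- function(index) {
  entries <- index$entries
  subjects <- unique(as.character(entries$subject))
  if (length(subjects) < 2L)
    stop("LOSO requires at least 2 subjects", call. = FALSE)
  lapply(subjects, function(s) {
    test <- entries$clip_id[entries$subject == s]
    list(subject = s,
         train = setdiff(entries$clip_id, test),
         test = test)
  })
}

#' Linear one-vs-rest SVM: fit on training features, predict test labels
#'
#' Features are standardized (zero mean, unit variance per dimension) using
#' training-fold statistics only; constant dimensions keep unit scale. One
#' binary linear SVM is fitted per class (class vs rest) and a test clip is
#' assigned the class with the largest decision value.
#'
#' @param train_x numeric matrix, one training clip per row.
#' @param train_y labels (character or factor) of the training clips.
#' @param test_x numeric matrix of test clips.
#' @param C soft-margin regularization constant (default 1).
#' @param standardize standardize features from train-fold statistics
#'   (default `TRUE`).
#' @return character vector of predicted labels for the rows of `test_x`.
#' @export
fit_predict_linear_svm <- function(train_x, train_y, test_x, C = 1,
                                   standardize = TRUE) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (nrow(train_x) == 0L) stop("empty training set", call. = FALSE)
  classes <- unique(as.character(train_y))
  if (length(classes) < 2L)
    stop("training fold contains a single class ('", classes,
         "'); cannot fit a classifier", call. = FALSE)
  if (standardize) {
    mu <- colMeans(train_x)
    sdv <- apply(train_x, 2L, stats::sd)
    sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
    train_x <- sweep(sweep(train_x, 2L, mu, "-"), 2L, sdv, "/")
    test_x <- sweep(sweep(test_x, 2L, mu, "-"), 2L, sdv, "/")
  }
  dec <- matrix(0, nrow(test_x), length(classes))
  for (ci in seq_along(classes)) {
    yk <- factor(ifelse(as.character(train_y) == classes[ci], "pos", "rest"),
                 levels = c("pos", "rest"))
    m <- e1071::svm(train_x, yk, kernel = "linear", cost = C, scale = FALSE)
    pr <- stats::predict(m, test_x, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # orient so positive means "pos" regardless of libsvm's internal order
    if (colnames(dv)[1] == "rest/pos") dv <- -dv
    dec[, ci] <- dv[, 1]
  }
  classes[max.col(dec, ties.method = "first")]
}

#' Confusion matrix over a fixed class ordering
#'
#' @param truth,pred character vectors of true and predicted labels.
#' @param class_names ordered class labels fixing the matrix axes.
#' @return integer `C x C` matrix, rows = true class, cols = predicted.
#' @export
confusion_matrix <- function(truth, pred, class_names = NULL) {
  class_names <- class_names %||% unique(c(as.character(truth),
                                           as.character(pred)))
  t_f <- factor(as.character(truth), levels = class_names)
  p_f <- factor(as.character(pred), levels = class_names)
  cm <- table(truth = t_f, predicted = p_f)
  matrix(as.integer(cm), length(class_names), length(class_names),
         dimnames = list(truth = class_names, predicted = class_names))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is the pooled fraction of correct predictions
#' (`sum(TP) / total`); per-class precision `P_i = TP_i / (TP_i + FP_i)`
#' and recall `R_i = TP_i / (TP_i + FN_i)` use the convention 0 when the
#' denominator is 0 (with a warning). Macro-F1 averages
#' `2 P_i R_i / (P_i + R_i)` over classes (terms with `P_i + R_i = 0`
#' contribute 0); macro-recall is the unweighted mean of `R_i`. The mean of
#' `P_i` is additionally reported as `macro_precision`.
#'
#' @param cm square integer confusion matrix, rows = true class.
#' @return a `metrics_report`: list with `accuracy`, `macro_f1`,
#'   `macro_recall`, `macro_precision` and a `per_class` data frame.
#' @export
compute_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (any(cm < 0)) stop("confusion counts must be non-negative", call. = FALSE)
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad))
      warning("zero denominator for ", what, " of class(es) ",
              paste(rownames(cm)[bad] %||% which(bad), collapse = ", "),
              "; reporting 0", call. = FALSE)
    ifelse(bad, 0, num / den)
  }
  P <- safe_div(tp, tp + fp, "precision")
  R <- safe_div(tp, tp + fn, "recall")
  f1 <- ifelse(P + R == 0, 0, 2 * P * R / (P + R))
  structure(list(
    accuracy = sum(tp) / total,
    macro_f1 = mean(f1),
    macro_recall = mean(R),
    macro_precision = mean(P),
    per_class = data.frame(class = rownames(cm) %||%
                             as.character(seq_len(nrow(cm))),
                           precision = as.numeric(P), recall = as.numeric(R),
                           f1 = as.numeric(f1), row.names = NULL)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | macro-F1 %.4f | macro-recall %.4f | macro-precision %.4f\n",
    x$accuracy, x$macro_f1, x$macro_recall, x$macro_precision))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}
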