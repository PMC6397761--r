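#' Wrap label vectors as a crisp prediction set
#'
#' Builds the same object [predict.miace_ovo()] returns from bare predicted
#' and true label vectors, with crisp 0/1 probabilities, so externally
#' produced classifications can be scored with [rank1_accuracy()],
#' [cross_entropy()], [soften()] and [confusion_matrix()].
#'
#' @param predicted character vector of predicted labels, one per crown.
#' @param truth character vector of true labels (same length).
#' @param classes label vocabulary; defaults to the union of both vectors.
#' @param bag_id optional crown identifiers.
#' @return A `miace_predictions` object.
#' @export
as_predictions <- function(predicted, truth, classes = NULL, bag_id = NULL) {
  stopifnot(length(predicted) == length(truth))
  n <- length(predicted)
  if (is.null(classes)) classes <- sort(unique(c(predicted, truth)))
  if (is.null(bag_id)) bag_id <- sprintf("crown%04d", seq_len(n))
  k <- match(predicted, classes)
  if (anyNA(k)) stop("predicted label outside the vocabulary")
  prob <- matrix(0, n, length(classes), dimnames = list(bag_id, classes))
  prob[cbind(seq_len(n), k)] <- 1
  structure(list(bag_id = bag_id, predicted = as.character(predicted),
                 votes = NULL, prob = prob, tie = rep(FALSE, n),
                 confidences = NULL, truth = as.character(truth),
                 classes = classes, level = "species", crisp = TRUE),
            class = "miace_predictions")
}

#' Confusion matrix of crown predictions
#'
#' Rows are ground-truth classes, columns predicted classes. Accepts either a
#' `miace_predictions` object (ground truth must be present for every bag) or
#' explicit truth/prediction vectors.
#'
#' @param x a `miace_predictions` object, or a character vector of true
#'   labels.
#' @param predicted character vector of predicted labels (when `x` is a
#'   vector).
#' @param classes ordered label vocabulary; defaults to the union of labels.
#' @return An integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(x, predicted = NULL, classes = NULL) {
  if (inherits(x, "miace_predictions")) {
    if (!all(nzchar(x$truth))) stop("ground truth missing for some bags")
    truth <- x$truth
    predicted <- x$predicted
    if (is.null(classes)) classes <- x$classes
  } else {
    truth <- as.character(x)
  }
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad))
    stop("label(s) outside the vocabulary: ", paste(bad, collapse = ", "))
  tf <- factor(truth, levels = classes)
  pf <- factor(predicted, levels = classes)
  m <- as.matrix(table(tf, pf))
  dimnames(m) <- list(truth = classes, predicted = classes)
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Rank-1 accuracy
#'
#' Fraction of crowns whose ground-truth class receives the highest assigned
#' probability. For crisp predictions this equals the diagonal sum of the
#' confusion matrix over the total. Probability ties on the argmax are
#' resolved to the stored predicted label (which already applied the voting
#' tie rule).
#'
#' @param x a `miace_predictions` object or a `confusion_matrix` (any square
#'   numeric matrix of truth-by-prediction counts works).
#' @param ... unused.
#' @return Fraction in `[0, 1]`.
#' @export
rank1_accuracy <- function(x, ...) UseMethod("rank1_accuracy")

#' @export
rank1_accuracy.miace_predictions <- function(x, ...) {
  if (!all(nzchar(x$truth))) stop("ground truth missing for some bags")
  top <- apply(x$prob, 1, max)
  hit <- vapply(seq_along(x$bag_id), function(i) {
    tied <- which(x$prob[i, ] == top[i])
    k <- if (length(tied) == 1L) tied else match(x$predicted[i], x$classes)
    x$classes[k] == x$truth[i]
  }, logical(1))
  mean(hit)
}

#' @export
rank1_accuracy.default <- function(x, ...) {
  m <- unclass(as.matrix(x))
  stopifnot(nrow(m) == ncol(m))
  sum(diag(m)) / sum(m)
}

#' Mean cross entropy of the true class
#'
#' `-(1/N) * sum_i log p_{i, g_i}`: the mean negative log probability
#' assigned to each crown's ground-truth class. Crisp (0/1) predictions give
#' infinite cross entropy as soon as one crown is wrong; apply [soften()]
#' first to obtain a finite score.
#'
#' @param x a `miace_predictions` object, or a probability matrix
#'   (bags x classes, rows summing to 1).
#' @param truth true labels (when `x` is a matrix); matched against
#'   `colnames(x)`.
#' @return Scalar cross entropy (nats).
#' @export
cross_entropy <- function(x, truth = NULL) {
  if (inherits(x, "miace_predictions")) {
    prob <- x$prob; truth <- x$truth; ids <- x$bag_id
  } else {
    prob <- as.matrix(x); ids <- rownames(prob)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(prob)))
  }
  if (!all(nzchar(truth))) stop("ground truth missing for some bags")
  k <- match(truth, colnames(prob))
  if (anyNA(k)) stop("true label outside the probability columns")
  p <- prob[cbind(seq_len(nrow(prob)), k)]
  if (any(p == 0))
    stop("zero probability on the true class for bag(s) ",
         paste(utils::head(ids[p == 0], 5), collapse = ", "),
         "; soften the predictions first (see soften())")
  -mean(log(p))
}

#' Per-class one-vs-rest metrics
#'
#' Reduces a confusion matrix to per-class TP/TN/FP/FN and reports accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)`, and F1 `2PR/(P+R)`. An empty
#' denominator (e.g. a class never predicted) yields 0 with the
#' corresponding `*_undefined` flag set, rather than NaN.
#'
#' @param cm a [confusion_matrix()] (or square count matrix with dimnames).
#' @return A data.frame with one row per class.
#' @export
per_class_metrics <- function(cm) {
  m <- unclass(as.matrix(cm))
  stopifnot(nrow(m) == ncol(m))
  classes <- rownames(m)
  total <- sum(m)
  out <- lapply(seq_along(classes), function(k) {
    TP <- m[k, k]
    FN <- sum(m[k, ]) - TP
    FP <- sum(m[, k]) - TP
    TN <- total - TP - FN - FP
    safe <- function(num, den) if (den == 0) c(0, TRUE) else c(num / den, FALSE)
    pr <- safe(TP, TP + FP)
    re <- safe(TP, TP + FN)
    f1 <- if (pr[1] + re[1] == 0) c(0, TRUE) else
      c(2 * pr[1] * re[1] / (pr[1] + re[1]), FALSE)
    sp <- safe(TN, TN + FP)
    data.frame(class = classes[k],
               accuracy = (TP + TN) / total,
               specificity = sp[1],
               precision = pr[1], recall = re[1], f1 = f1[1],
               precision_undefined = as.logical(pr[2]),
               recall_undefined = as.logical(re[2]),
               f1_undefined = as.logical(f1[2]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Epsilon-soften crisp class probabilities
#'
#' Replaces crisp 0/1 probabilities by `epsilon` for each non-predicted class
#' and `1 - (C-1) * epsilon` for the predicted class, so rows still sum to 1
#' and the cross entropy is finite even when some crowns are misclassified.
#'
#' @param preds a `miace_predictions` object with crisp probabilities.
#' @param epsilon scalar in `[0, 1/(C-1))`.
#' @return The predictions object with softened `prob`.
#' @seealso [optimal_epsilon()]
#' @export
soften <- function(preds, epsilon) {
  stopifnot(inherits(preds, "miace_predictions"))
  if (!isTRUE(preds$crisp)) stop("predictions are already softened")
  C <- length(preds$classes)
  if (epsilon < 0 || epsilon >= 1 / (C - 1))
    stop("epsilon must lie in [0, 1/(C-1))")
  if (epsilon == 0) return(preds)
  prob <- matrix(epsilon, nrow(preds$prob), C, dimnames = dimnames(preds$prob))
  prob[cbind(seq_len(nrow(prob)), match(preds$predicted, preds$classes))] <-
    1 - (C - 1) * epsilon
  preds$prob <- prob
  preds$crisp <- FALSE
  preds$epsilon <- epsilon
  preds
}

#' Optimal softening epsilon for crisp predictions
#'
#' For crisp predictions at rank-1 accuracy `a` over `C` classes, the
#' softened cross entropy is
#' `c(eps) = -[a * log(1 - (C-1) * eps) + (1 - a) * log(eps)]`,
#' which is convex on `(0, 1/(C-1))` with closed-form minimizer
#' `eps* = (1 - a) / (C - 1)`.
#'
#' @param accuracy rank-1 accuracy `a` in `[0, 1]`.
#' @param n_classes number of classes `C >= 2`.
#' @return The minimizing epsilon. `accuracy = 1` returns 0;
#'   `accuracy = 0` returns the upper end of the valid range with a warning.
#' @export
optimal_epsilon <- function(accuracy, n_classes) {
  stopifnot(n_classes >= 2, accuracy >= 0, accuracy <= 1)
  if (accuracy == 0) {
    warning("accuracy 0: epsilon at the upper end of its range")
    return(1 / (n_classes - 1))
  }
  (1 - accuracy) / (n_classes - 1)
}
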