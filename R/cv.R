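#' Repeated stratified two-fold cross-validation
#'
#' Splits the crowns of each class at random into two folds (bag-level,
#' never pixel-level, so no crown leaks between folds), trains a one-vs-one
#' model on each fold and predicts the other, and repeats the whole split
#' `repeats` times. Stratification keeps rare classes present in both folds.
#' Classes with fewer than 2 crowns cannot appear in both folds and are
#' excluded with a warning. Reported are the per-repeat confusion matrices
#' (each covering every retained crown once), their mean, and the mean
#' rank-1 accuracy.
#'
#' @param x a [bag_set].
#' @param level `"genus"` or `"species"`.
#' @param pairs_mode `"one"` or `"two"` (see [miace_ovo()]).
#' @param repeats number of repeated random splits (default 10).
#' @param seed integer seed controlling the splits and tie-breaking.
#' @param lambda,max_iter passed to [mi_ace()].
#' @return A list of class `miace_cv`: `mean_confusion`, `accuracy` (mean),
#'   `per_repeat_accuracy`, `confusions` (list), `classes`, `repeats`.
#' @export
crossval_ovo <- function(x, level = c("genus", "species"),
                         pairs_mode = c("one", "two"),
                         repeats = 10, seed = 1L,
                         lambda = 1e-6, max_iter = 1000) {
  level <- match.arg(level)
  pairs_mode <- match.arg(pairs_mode)
  labs <- x$bags[[level]]
  counts <- table(labs)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("excluding class(es) with fewer than 2 crowns from CV: ",
            paste(small, collapse = ", "))
    x <- subset_bags(x, !(labs %in% small))
    labs <- x$bags[[level]]
  }
  classes <- sort(unique(labs))
  if (length(classes) < 2L) stop("need at least 2 classes with >= 2 crowns")

  confusions <- vector("list", repeats)
  accs <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fold <- with_preserved_seed({
      set.seed(seed + r)
      f <- integer(n_bags(x))
      for (cl in classes) {
        idx <- which(labs == cl)
        half <- sample(idx, floor(length(idx) / 2))
        f[idx] <- 2L; f[half] <- 1L
      }
      f
    })
    cm <- matrix(0L, length(classes), length(classes),
                 dimnames = list(truth = classes, predicted = classes))
    for (fd in 1:2) {
      train <- subset_bags(x, fold != fd)
      test <- subset_bags(x, fold == fd)
      model <- miace_ovo(train, level = level, pairs_mode = pairs_mode,
                         lambda = lambda, max_iter = max_iter)
      pr <- predict(model, test, seed = seed + r)
      cm <- cm + unclass(confusion_matrix(pr$truth, pr$predicted, classes))
    }
    confusions[[r]] <- cm
    accs[r] <- sum(diag(cm)) / sum(cm)
  }
  structure(list(mean_confusion = Reduce(`+`, confusions) / repeats,
                 accuracy = mean(accs), per_repeat_accuracy = accs,
                 confusions = confusions, classes = classes,
                 repeats = repeats, level = level, pairs_mode = pairs_mode),
            class = "miace_cv")
}

#' @export
print.miace_cv <- function(x, ...) {
  cat(sprintf("%d-repeat stratified two-fold CV (%s level, mode '%s')\n",
              x$repeats, x$level, x$pairs_mode))
  cat(sprintf("mean rank-1 accuracy: %.4f (per-repeat sd %.4f)\n",
              x$accuracy, stats::sd(x$per_repeat_accuracy)))
  cat("mean confusion matrix:\n")
  print(round(x$mean_confusion, 2))
  invisible(x)
}
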