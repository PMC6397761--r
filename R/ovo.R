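#' Bag-level detection confidence
#'
#' The confidence of a crown under one pairwise classifier: the arithmetic
#' mean of the ACE statistic over all pixels in the bag. Aggregating at the
#' bag level before thresholding is what suppresses mislabeled pixels.
#'
#' @param bag numeric matrix of the bag's pixel spectra.
#' @param clf a `miace_binary` classifier (element of a [miace_ovo()] model)
#'   or a bare [mi_ace()] fit.
#' @return Scalar mean ACE statistic.
#' @export
bag_confidence <- function(bag, clf) {
  fit <- if (inherits(clf, "miace_binary")) clf$fit else clf
  bag <- as.matrix(bag)
  if (nrow(bag) < 1L) stop("empty bag")
  mean(ace_statistic(bag, fit))
}

#' Train a decision threshold on bag confidences
#'
#' Scans candidate thresholds placed half-way between every pair of
#' consecutive sorted confidence values (plus one below the minimum and one
#' above the maximum) and returns the candidate maximizing training
#' classification accuracy, where a bag is called target iff its confidence
#' strictly exceeds the threshold. Ties on accuracy are broken by the largest
#' margin to the nearest confidence, then by the smallest threshold.
#'
#' @param confidences numeric vector of bag confidences.
#' @param is_target logical vector, `TRUE` for target-class bags.
#' @return List with `threshold`, `accuracy`, and the scanned `candidates`.
#' @export
train_threshold <- function(confidences, is_target) {
  stopifnot(length(confidences) == length(is_target))
  is_target <- as.logical(is_target)
  if (!any(is_target) || all(is_target))
    stop("need at least one target and one non-target bag")
  z <- sort(unique(confidences))
  if (length(z) == 1L) {
    warning("all bag confidences identical; threshold degenerate")
    acc <- max(mean(is_target), mean(!is_target))
    return(list(threshold = z, accuracy = acc, candidates = z))
  }
  mids <- (z[-1] + z[-length(z)]) / 2
  span <- z[length(z)] - z[1]
  cand <- c(z[1] - span / 2, mids, z[length(z)] + span / 2)
  acc <- vapply(cand, function(tau)
    mean((confidences > tau) == is_target), numeric(1))
  best <- which(acc == max(acc))
  if (length(best) > 1L) {
    margin <- vapply(cand[best], function(tau) min(abs(confidences - tau)),
                     numeric(1))
    best <- best[margin == max(margin)]
    best <- best[which.min(cand[best])]
  }
  list(threshold = cand[best], accuracy = acc[best], candidates = cand)
}

#' One-vs-one MI-ACE multiclass classifier
#'
#' Trains a pairwise MI-ACE classifier for every pair of class labels at the
#' requested level and combines them by majority vote at prediction time.
#' For each ordered pair (target c1, background c2), the target signature is
#' fit with the c1 crowns as positive bags and the c2 crowns as negative
#' bags, the background model coming from the c2 pixels; the decision
#' threshold is then trained on the training-bag confidences. With
#' `pairs_mode = "one"` a single classifier per unordered pair is trained
#' (target = lexicographically first class, C(C-1)/2 classifiers); with
#' `"two"`, both orderings (C(C-1) classifiers), each casting one vote.
#'
#' With `hierarchical = TRUE` (genus level only), a species-level one-vs-one
#' model is additionally trained inside every genus that has at least two
#' species; single-species genera map directly to their species at
#' prediction time.
#'
#' @param x a [bag_set] of training crowns.
#' @param level `"genus"` or `"species"` — which label the classes come from.
#' @param pairs_mode `"one"` or `"two"` classifiers per pair.
#' @param hierarchical train genus model plus per-genus species sub-models.
#' @param lambda,max_iter passed to [mi_ace()].
#' @return An object of class `miace_ovo`: list with `classifiers` (named
#'   `"c1|c2"`), `classes`, `level`, `pairs_mode`, `wavelengths`, and
#'   `hierarchy` (`NULL`, or per-genus species name / sub-model).
#' @seealso [predict.miace_ovo()], [predict_hierarchical()]
#' @export
miace_ovo <- function(x, level = c("genus", "species"),
                      pairs_mode = c("one", "two"),
                      hierarchical = FALSE,
                      lambda = 1e-6, max_iter = 1000) {
  stopifnot(inherits(x, "bag_set"))
  level <- match.arg(level)
  pairs_mode <- match.arg(pairs_mode)
  classes <- class_vocabulary(x, level)
  if (length(classes) < 2L)
    stop("need at least 2 classes at the ", level, " level")
  nb <- table(factor(x$bags[[level]], levels = classes))
  if (any(nb == 0L))
    stop("class with zero bags: ", paste(names(nb)[nb == 0L], collapse = ", "))

  by_class <- bags_by_class(x, level)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  ordered_pairs <- if (pairs_mode == "one") pairs else
    c(pairs, lapply(pairs, rev))

  classifiers <- lapply(ordered_pairs, function(p) {
    c1 <- p[1]; c2 <- p[2]
    fit <- mi_ace(by_class[[c1]], by_class[[c2]],
                  lambda = lambda, max_iter = max_iter)
    conf1 <- vapply(by_class[[c1]], bag_confidence, numeric(1), clf = fit)
    conf2 <- vapply(by_class[[c2]], bag_confidence, numeric(1), clf = fit)
    th <- train_threshold(c(conf1, conf2),
                          c(rep(TRUE, length(conf1)), rep(FALSE, length(conf2))))
    structure(list(target_class = c1, background_class = c2, fit = fit,
                   threshold = th$threshold, training_accuracy = th$accuracy),
              class = "miace_binary")
  })
  names(classifiers) <- vapply(ordered_pairs, paste, "", collapse = "|")

  hierarchy <- NULL
  if (hierarchical) {
    if (level != "genus")
      stop("hierarchical training requires level = 'genus'")
    hierarchy <- lapply(classes, function(g) {
      sub <- subset_bags(x, x$bags$genus == g)
      sp <- class_vocabulary(sub, "species")
      if (length(sp) <= 1L) {
        if (length(sp) == 0L)
          stop("genus '", g, "' has no species labels")
        sp
      } else {
        miace_ovo(sub, level = "species", pairs_mode = pairs_mode,
                  lambda = lambda, max_iter = max_iter)
      }
    })
    names(hierarchy) <- classes
  }

  structure(list(classifiers = classifiers, classes = classes, level = level,
                 pairs_mode = pairs_mode, wavelengths = x$wavelengths,
                 hierarchy = hierarchy),
            class = "miace_ovo")
}

#' @export
print.miace_ovo <- function(x, ...) {
  cat(sprintf("one-vs-one MI-ACE model: %d classes (%s level), %d classifiers (mode '%s')\n",
              length(x$classes), x$level, length(x$classifiers), x$pairs_mode))
  cat("classes:", paste(x$classes, collapse = ", "), "\n")
  if (!is.null(x$hierarchy)) {
    nsub <- sum(vapply(x$hierarchy, inherits, TRUE, what = "miace_ovo"))
    cat(sprintf("hierarchy: %d genus -> species sub-model(s)\n", nsub))
  }
  invisible(x)
}

#' @export
summary.miace_ovo <- function(object, ...) {
  print(object)
  tab <- data.frame(
    target = vapply(object$classifiers, `[[`, "", "target_class"),
    background = vapply(object$classifiers, `[[`, "", "background_class"),
    objective = vapply(object$classifiers, function(c) c$fit$objective, 0),
    threshold = vapply(object$classifiers, `[[`, 0, "threshold"),
    train_acc = vapply(object$classifiers, `[[`, 0, "training_accuracy"),
    row.names = NULL)
  print(tab, digits = 4)
  invisible(tab)
}

# order-independent per-bag RNG stream for tie breaking
bag_tie_seed <- function(seed, bag_id) {
  h <- sum(utf8ToInt(bag_id) * seq_along(utf8ToInt(bag_id))) %% 1000003L
  (as.integer(seed) %% 1000003L) * 1009L %% 2147483647L + h
}

with_preserved_seed <- function(code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  force(code)
}

#' Predict crown classes by one-vs-one voting
#'
#' For every test crown and every pairwise classifier, the bag confidence
#' (mean ACE statistic over the crown's pixels) is compared with the trained
#' threshold: one vote goes to the target class if the confidence strictly
#' exceeds it, else to the background class. The crown is assigned the class
#' with the most votes. Vote ties are broken uniformly at random among the
#' tied classes using an order-independent stream derived from `seed` and
#' the crown id (so predictions are invariant to bag order); with
#' `tie_break = "margin"` the tied class with the largest mean signed margin
#' over its classifiers wins deterministically.
#'
#' Class probabilities are crisp (1 for the winner, 0 otherwise); see
#' [soften()] for epsilon-softening.
#'
#' @param object a [miace_ovo()] model.
#' @param newdata a [bag_set] on the model's band axis.
#' @param seed integer seed for tie breaking.
#' @param tie_break `"random"` or `"margin"`.
#' @param ... unused.
#' @return An object of class `miace_predictions`: list with `bag_id`,
#'   `predicted`, `votes` (bags x classes), `prob` (bags x classes, rows sum
#'   to 1), `tie` (logical), `confidences` (bags x classifiers), `truth`
#'   (from `newdata`'s labels, possibly empty strings), `classes`, `level`.
#' @export
predict.miace_ovo <- function(object, newdata, seed = 1L,
                              tie_break = c("random", "margin"), ...) {
  stopifnot(inherits(newdata, "bag_set"))
  tie_break <- match.arg(tie_break)
  if (!isTRUE(all.equal(object$wavelengths, newdata$wavelengths)))
    stop("band axis of newdata does not match the model")
  M <- n_bags(newdata)
  C <- length(object$classes)
  nc <- length(object$classifiers)
  votes <- matrix(0L, M, C, dimnames = list(newdata$bags$bag_id, object$classes))
  conf <- matrix(NA_real_, M, nc,
                 dimnames = list(newdata$bags$bag_id, names(object$classifiers)))
  margin_sum <- matrix(0, M, C, dimnames = dimnames(votes))

  for (k in seq_len(nc)) {
    clf <- object$classifiers[[k]]
    for (m in seq_len(M)) {
      z <- bag_confidence(bag_instances(newdata, m), clf)
      conf[m, k] <- z
      win <- if (z > clf$threshold) clf$target_class else clf$background_class
      votes[m, win] <- votes[m, win] + 1L
      margin_sum[m, clf$target_class] <- margin_sum[m, clf$target_class] +
        (z - clf$threshold)
      margin_sum[m, clf$background_class] <- margin_sum[m, clf$background_class] -
        (z - clf$threshold)
    }
  }

  predicted <- character(M)
  tie <- logical(M)
  for (m in seq_len(M)) {
    top <- which(votes[m, ] == max(votes[m, ]))
    if (length(top) == 1L) {
      predicted[m] <- object$classes[top]
    } else {
      tie[m] <- TRUE
      predicted[m] <- if (tie_break == "margin") {
        object$classes[top[which.max(margin_sum[m, top])]]
      } else {
        with_preserved_seed({
          set.seed(bag_tie_seed(seed, newdata$bags$bag_id[m]))
          object$classes[sample(top, 1L)]
        })
      }
    }
  }

  prob <- matrix(0, M, C, dimnames = dimnames(votes))
  prob[cbind(seq_len(M), match(predicted, object$classes))] <- 1

  structure(list(bag_id = newdata$bags$bag_id, predicted = predicted,
                 votes = votes, prob = prob, tie = tie, confidences = conf,
                 truth = newdata$bags[[object$level]],
                 classes = object$classes, level = object$level,
                 crisp = TRUE),
            class = "miace_predictions")
}

#' Hierarchical genus-then-species prediction
#'
#' Classifies each crown at the genus level first; crowns of a
#' single-species genus inherit that species automatically, crowns of a
#' multi-species genus are routed to that genus's species-level one-vs-one
#' sub-model.
#'
#' @param object a [miace_ovo()] model trained with `hierarchical = TRUE`.
#' @param newdata a [bag_set].
#' @param seed,tie_break as in [predict.miace_ovo()].
#' @return A `miace_predictions` object at the species level, with an extra
#'   `genus_predicted` element; `votes` are the genus-level votes.
#' @export
predict_hierarchical <- function(object, newdata, seed = 1L,
                                 tie_break = c("random", "margin")) {
  tie_break <- match.arg(tie_break)
  if (is.null(object$hierarchy))
    stop("model has no genus -> species hierarchy; train with hierarchical = TRUE")
  gp <- predict(object, newdata, seed = seed, tie_break = tie_break)
  M <- n_bags(newdata)
  species_classes <- sort(unique(unlist(lapply(object$hierarchy, function(h)
    if (inherits(h, "miace_ovo")) h$classes else h))))
  predicted <- character(M)
  tie <- gp$tie
  for (g in unique(gp$predicted)) {
    if (!g %in% names(object$hierarchy))
      stop("predicted genus '", g, "' missing from hierarchy")
    idx <- which(gp$predicted == g)
    h <- object$hierarchy[[g]]
    if (inherits(h, "miace_ovo")) {
      sub <- subset_bags(newdata, idx)
      sp <- predict(h, sub, seed = seed, tie_break = tie_break)
      predicted[idx[match(sp$bag_id, newdata$bags$bag_id[idx])]] <- sp$predicted
      tie[idx] <- tie[idx] | sp$tie[match(newdata$bags$bag_id[idx], sp$bag_id)]
    } else {
      predicted[idx] <- h
    }
  }
  prob <- matrix(0, M, length(species_classes),
                 dimnames = list(newdata$bags$bag_id, species_classes))
  prob[cbind(seq_len(M), match(predicted, species_classes))] <- 1
  structure(list(bag_id = newdata$bags$bag_id, predicted = predicted,
                 genus_predicted = gp$predicted, votes = gp$votes, prob = prob,
                 tie = tie, confidences = gp$confidences,
                 truth = newdata$bags$species, classes = species_classes,
                 level = "species", crisp = TRUE),
            class = "miace_predictions")
}

#' @export
print.miace_predictions <- function(x, ...) {
  cat(sprintf("miace_predictions: %d crowns over %d %s classes; %d tie(s)\n",
              length(x$bag_id), length(x$classes), x$level, sum(x$tie)))
  if (any(nzchar(x$truth)))
    cat(sprintf("rank-1 accuracy vs ground truth: %.4f\n", rank1_accuracy(x)))
  invisible(x)
}

#' @export
as.data.frame.miace_predictions <- function(x, ...) {
  df <- data.frame(bag_id = x$bag_id, predicted = x$predicted,
                   truth = x$truth, tie = x$tie, stringsAsFactors = FALSE)
  if (!is.null(x$genus_predicted)) df$genus_predicted <- x$genus_predicted
  cbind(df,
        stats::setNames(as.data.frame(x$votes), paste0("votes_", colnames(x$votes))),
        stats::setNames(as.data.frame(x$prob), paste0("p_", colnames(x$prob))))
}
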