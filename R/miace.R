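#' Fit a multiple-instance ACE target signature
#'
#' Estimates a discriminative target signature from positively and negatively
#' labeled bags of pixel spectra. Positive bags (crowns of the target class)
#' are assumed to contain at least one pixel carrying the target; negative
#' bags contain none. The signature maximizes the mean ACE detection
#' statistic of one selected instance per positive bag minus the mean ACE
#' statistic over all negative instances:
#'
#' \deqn{\frac{1}{N^+}\sum_{j: L_j=1} D_{ACE}(x_j^*, s) -
#'       \frac{1}{N^-}\sum_{j: L_j=0}\frac{1}{N_j^-}
#'       \sum_{x_i \in B_j^-} D_{ACE}(x_i, s)}
#'
#' Optimization alternates (a) selecting, per positive bag, the instance with
#' the largest ACE statistic under the current signature and (b) a
#' closed-form update: with selections fixed the objective is linear in the
#' whitened unit signature, so its maximizer is the normalized difference
#' between the mean selected positive direction and the mean negative
#' direction. The objective is non-decreasing across iterations and the
#' discrete selection state makes convergence exact: iteration stops when the
#' selected-instance set repeats, or at `max_iter`. Initialization evaluates
#' every positive instance as a candidate signature and starts from the best,
#' so the fit is deterministic.
#'
#' The background model (mean, covariance, eigensystem) is fit from the
#' negative-class pixels unless an explicit model is supplied.
#'
#' @param pos list of numeric matrices, one per positive bag (rows = pixels).
#' @param neg list of numeric matrices, one per negative bag.
#' @param lambda ridge weight for the background covariance
#'   (see [fit_background()]).
#' @param max_iter maximum number of alternating iterations (default 1000).
#' @param background optional pre-fit [fit_background()] model (e.g. a global
#'   background); by default the model is fit from `neg`.
#' @return An object of class `miace`: list with
#'   \describe{
#'     \item{s}{unit target signature in whitened space}
#'     \item{background}{the background model used}
#'     \item{objective}{final objective value}
#'     \item{objective_trace}{objective after initialization and after each
#'       signature update (non-decreasing)}
#'     \item{selected}{index of the selected instance in each positive bag}
#'     \item{n_iter}{number of alternating iterations run}
#'     \item{converged}{`TRUE` if selections stabilized before `max_iter`}
#'   }
#' @export
#' @examples
#' set.seed(1)
#' t <- c(3, 0, 0)
#' pos <- replicate(8, rbind(t + rnorm(3, sd = .1),
#'                           matrix(rnorm(9), 3)), simplify = FALSE)
#' neg <- replicate(8, matrix(rnorm(12), 4), simplify = FALSE)
#' fit <- mi_ace(pos, neg)
#' fit
mi_ace <- function(pos, neg, lambda = 1e-6, max_iter = 1000, background = NULL) {
  if (is.matrix(pos)) pos <- list(pos)
  if (is.matrix(neg)) neg <- list(neg)
  if (length(pos) < 1L || length(neg) < 1L)
    stop("need at least one positive and one negative bag")
  if (any(vapply(c(pos, neg), nrow, 1L) < 1L)) stop("empty bag")
  d <- ncol(pos[[1]])
  if (any(vapply(c(pos, neg), ncol, 1L) != d))
    stop("bags disagree on band count")

  bg <- if (is.null(background)) {
    fit_background(do.call(rbind, neg), lambda = lambda)
  } else background

  Wp <- lapply(pos, function(m) unit_rows(whiten(m, bg)))
  Wn <- lapply(neg, function(m) unit_rows(whiten(m, bg)))
  # mean over negative bags of the per-bag mean whitened unit direction
  m_neg <- Reduce(`+`, lapply(Wn, colMeans)) / length(Wn)

  obj_for <- function(s) {
    mean(vapply(Wp, function(m) max(m %*% s), numeric(1))) - sum(m_neg * s)
  }

  # initialization: best positive instance as candidate signature
  cand <- do.call(rbind, Wp)
  cand_obj <- vapply(seq_len(nrow(cand)), function(i) obj_for(cand[i, ]),
                     numeric(1))
  s <- cand[which.max(cand_obj), ]

  select <- function(s) {
    vapply(Wp, function(m) which.max(m %*% s), integer(1))  # ties: lowest index
  }

  sel <- select(s)
  trace <- obj_for(s)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    sel_mat <- do.call(rbind, Map(function(m, i) m[i, ], Wp, as.list(sel)))
    snew <- colMeans(sel_mat) - m_neg
    nrm <- sqrt(sum(snew^2))
    if (nrm == 0) break   # degenerate: positives indistinguishable from negatives
    s <- snew / nrm
    trace <- c(trace, obj_for(s))
    sel_new <- select(s)
    if (identical(sel_new, sel)) { converged <- TRUE; sel <- sel_new; break }
    sel <- sel_new
  }
  if (!converged)
    warning("mi_ace did not converge in ", max_iter, " iterations")

  structure(list(s = s, background = bg, objective = trace[length(trace)],
                 objective_trace = trace, selected = sel,
                 n_iter = iter, converged = converged, d = d),
            class = "miace")
}

#' Build an ACE detector from a known target signature
#'
#' Wraps a user-supplied target signature and background model into the same
#' object [mi_ace()] returns, so the ACE detector can be applied with a
#' library signature instead of a learned one.
#'
#' @param s numeric target signature. If `whitened = FALSE` (default) it is
#'   given in reflectance space and is whitened against `background` first;
#'   either way it is unit-normalized.
#' @param background a [fit_background()] model.
#' @param whitened is `s` already in whitened coordinates?
#' @return An object of class `miace`.
#' @export
miace_signature <- function(s, background, whitened = FALSE) {
  stopifnot(inherits(background, "background_model"))
  sw <- if (whitened) as.numeric(s) else
    drop(crossprod(sweep(background$U, 2, sqrt(background$D), "/"), s))
  nrm <- sqrt(sum(sw^2))
  if (nrm == 0) stop("signature has zero whitened norm")
  structure(list(s = sw / nrm, background = background, objective = NA_real_,
                 objective_trace = numeric(0), selected = integer(0),
                 n_iter = 0L, converged = TRUE, d = length(background$mean)),
            class = "miace")
}

#' ACE detection statistic
#'
#' The adaptive cosine estimator: the cosine between the whitened,
#' mean-subtracted spectrum and the whitened target signature,
#' `D_ACE(x, s) = <s_w, x_w / ||x_w||>` with `x_w = D^{-1/2} U' (x - mu_b)`.
#' Values lie in `[-1, 1]`. A pixel exactly equal to the background mean has
#' zero whitened norm; its statistic is defined as 0 with a warning.
#'
#' @param x numeric vector (one spectrum) or matrix (rows are spectra).
#' @param fit a fitted [mi_ace()] signature.
#' @return Scalar, or vector with one statistic per row of `x`.
#' @export
ace_statistic <- function(x, fit) {
  stopifnot(inherits(fit, "miace"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != fit$d) stop("dimension mismatch in ace_statistic()")
  xw <- whiten(x, fit$background)
  nrm <- sqrt(rowSums(xw^2))
  if (any(nrm == 0))
    warning("instance equal to the background mean; ACE statistic set to 0")
  out <- as.numeric(xw %*% fit$s)
  out[nrm > 0] <- out[nrm > 0] / nrm[nrm > 0]
  out[nrm == 0] <- 0
  out
}

#' Select the most target-like instance of a bag
#'
#' Returns the instance of a bag with the maximum ACE statistic under a
#' signature (ties broken by lowest instance index).
#'
#' @param bag numeric matrix of the bag's pixel spectra.
#' @param fit a fitted [mi_ace()] signature.
#' @return List with `index`, `statistic`, and `instance` (the row).
#' @export
select_instance <- function(bag, fit) {
  bag <- as.matrix(bag)
  if (nrow(bag) < 1L) stop("empty bag")
  st <- ace_statistic(bag, fit)
  i <- which.max(st)
  list(index = i, statistic = st[i], instance = bag[i, ])
}

#' Evaluate the MI-ACE objective for a signature
#'
#' Recomputes the bag-level objective (mean selected-positive statistic minus
#' mean over negative bags of their mean instance statistic) for a given
#' signature on given bags. Values lie in `[-2, 2]`.
#'
#' @param fit a fitted [mi_ace()] signature.
#' @param pos,neg lists of bag matrices (at least one of each).
#' @return Scalar objective value.
#' @export
miace_objective <- function(fit, pos, neg) {
  if (is.matrix(pos)) pos <- list(pos)
  if (is.matrix(neg)) neg <- list(neg)
  if (length(pos) < 1L || length(neg) < 1L)
    stop("need at least one positive and one negative bag")
  mean(vapply(pos, function(m) max(ace_statistic(m, fit)), numeric(1))) -
    mean(vapply(neg, function(m) mean(ace_statistic(m, fit)), numeric(1)))
}

#' @export
print.miace <- function(x, ...) {
  cat(sprintf("miace signature: d=%d, objective %.4f, %d iteration(s)%s\n",
              x$d, x$objective, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
summary.miace <- function(object, ...) {
  cat("MI-ACE target signature\n")
  cat(sprintf("  bands:        %d\n", object$d))
  cat(sprintf("  objective:    %.4f\n", object$objective))
  cat(sprintf("  iterations:   %d (%s)\n", object$n_iter,
              if (object$converged) "converged" else "max_iter reached"))
  cat(sprintf("  positive bags: %d; selected instance indices: %s\n",
              length(object$selected),
              paste(utils::head(object$selected, 10), collapse = " ")))
  invisible(object)
}

#' @export
#' @describeIn mi_ace the signature. `space = "whitened"` returns the unit
#'   signature the detector uses; `space = "original"` back-projects it to
#'   reflectance band space (`U D^{1/2} s`, unnormalized direction) for
#'   plotting against wavelength.
#' @param object,... method arguments.
#' @param space coordinate space for the returned signature.
coef.miace <- function(object, space = c("whitened", "original"), ...) {
  space <- match.arg(space)
  if (space == "whitened") return(object$s)
  drop(object$background$U %*% (sqrt(object$background$D) * object$s))
}

#' @export
plot.miace <- function(x, wavelengths = NULL, ...) {
  s <- coef(x, space = "original")
  xs <- if (is.null(wavelengths)) seq_along(s) else wavelengths
  xl <- if (is.null(wavelengths)) "band index" else "wavelength (nm)"
  plot(xs, s, type = "l", xlab = xl, ylab = "target signature (original space)",
       main = "MI-ACE discriminative signature", ...)
  abline(h = 0, lty = 3)
  invisible(x)
}
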