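#' Water absorption band intervals
#'
#' Default wavelength intervals (nm, closed at both ends) dominated by
#' atmospheric water absorption, where airborne reflectance is unusable and
#' is conventionally flagged with a sentinel value. Bands whose centers fall
#' inside these intervals are dropped, never imputed.
#'
#' @return A list of `c(low, high)` nm intervals.
#' @export
water_band_ranges <- function() {
  list(c(1345, 1430), c(1800, 1956), c(2482, 2512))
}

#' Remove water absorption bands
#'
#' Drops every band whose center wavelength falls inside one of the given
#' closed intervals, slicing all spectra and the band axis consistently. The
#' applied mask is attached as attribute `"band_mask"` (a list with
#' `excluded_ranges` and `kept_indices`).
#'
#' @param x a [bag_set].
#' @param ranges list of `c(low, high)` nm intervals; default
#'   [water_band_ranges()]. An empty list is the identity.
#' @return The filtered `bag_set` (hard error if no bands would remain).
#' @export
remove_water_bands <- function(x, ranges = water_band_ranges()) {
  stopifnot(inherits(x, "bag_set"))
  wl <- x$wavelengths
  drop <- rep(FALSE, length(wl))
  for (r in ranges) {
    if (length(r) != 2L || r[1] > r[2]) stop("each range must be c(low, high)")
    drop <- drop | (wl >= r[1] & wl <= r[2])
  }
  if (all(drop)) stop("band filtering would remove every band")
  kept <- which(!drop)
  out <- bag_set(x$spectra[, kept, drop = FALSE],
                 x$bags$bag_id[x$bag],
                 genus = x$bags$genus, species = x$bags$species,
                 wavelengths = wl[kept])
  attr(out, "band_mask") <- list(excluded_ranges = ranges, kept_indices = kept)
  out
}

#' Drop all crowns carrying a label
#'
#' Removes every bag labeled `label` at the given level, e.g. the OTHERS
#' crowns that no classifier is trained for. Dropping an absent label is a
#' no-op; dropping the only label empties the set with a warning.
#'
#' @param x a [bag_set].
#' @param label character label to drop.
#' @param level `"genus"` or `"species"`.
#' @return The filtered `bag_set`, or `NULL` (with a warning) if nothing
#'   remains.
#' @export
drop_label <- function(x, label, level = c("genus", "species")) {
  level <- match.arg(level)
  keep <- x$bags[[level]] != label
  if (all(keep)) return(x)
  if (!any(keep)) {
    warning(sprintf("dropping '%s' removed every bag", label))
    return(NULL)
  }
  subset_bags(x, keep)
}

#' Fit a background model
#'
#' Estimates the background mean and covariance from a set of pixel spectra
#' and stores the eigendecomposition used for whitening. The sample
#' covariance is ridge-regularized as `S + lambda * (tr(S)/d) * I` so that
#' classes with very few pixels (rank-deficient S) still yield a positive
#' definite model; when `tr(S) = 0` (degenerate constant input) the scale
#' falls back to 1 so the regularizer alone carries the model.
#'
#' @param x numeric matrix of background pixels (rows) or a [bag_set] whose
#'   pixels are all background.
#' @param lambda ridge weight relative to the mean eigenvalue scale
#'   (default `1e-6`).
#' @return An object of class `background_model`: list with `mean`, `cov`
#'   (regularized), `U` (eigenvectors, columns), `D` (eigenvalues,
#'   descending), `lambda`.
#' @export
fit_background <- function(x, lambda = 1e-6) {
  if (inherits(x, "bag_set")) x <- x$spectra
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 instances to fit a background")
  if (!all(is.finite(x))) stop("background instances contain non-finite values")
  mu <- colMeans(x)
  S <- stats::cov(x)
  d <- ncol(x)
  scale <- sum(diag(S)) / d
  if (scale <= 0) scale <- 1
  Sreg <- S + lambda * scale * diag(d)
  e <- eigen(Sreg, symmetric = TRUE)
  if (any(e$values <= 0))
    stop("background covariance not positive definite after regularization")
  structure(list(mean = mu, cov = Sreg, U = e$vectors, D = e$values,
                 lambda = lambda),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background_model: d=%d, eigenvalues [%.3g, %.3g], lambda=%g\n",
              length(x$mean), min(x$D), max(x$D), x$lambda))
  invisible(x)
}

#' Whiten spectra against a background model
#'
#' Applies the transform `D^{-1/2} U' (x - mu_b)` using the eigensystem of
#' the (regularized) background covariance. Under the background-generating
#' distribution the whitened covariance is the identity, which is what makes
#' the cosine detector adaptive to background correlation.
#'
#' @param x numeric vector (one spectrum) or matrix (rows are spectra).
#' @param bg a [fit_background()] model.
#' @return Whitened vector or matrix of the same shape.
#' @export
whiten <- function(x, bg) {
  stopifnot(inherits(bg, "background_model"))
  if (any(bg$D <= 0)) stop("background model has non-positive eigenvalues")
  W <- sweep(bg$U, 2, sqrt(bg$D), "/")   # U D^{-1/2}; whitening is t(W) %*% (x - mu)
  if (is.matrix(x)) {
    if (ncol(x) != length(bg$mean)) stop("dimension mismatch in whiten()")
    sweep(x, 2, bg$mean) %*% W
  } else {
    if (length(x) != length(bg$mean)) stop("dimension mismatch in whiten()")
    drop(crossprod(W, x - bg$mean))
  }
}

# rows scaled to unit length; zero rows stay zero
unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nz <- nrm > 0
  m[nz, ] <- m[nz, , drop = FALSE] / nrm[nz]
  m
}
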