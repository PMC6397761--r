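#' Bag-structured hyperspectral data
#'
#' A `bag_set` holds pixel spectra grouped into crowns (bags). Each crown
#' carries a genus label and a species label; every pixel (instance) is a
#' reflectance spectrum on a shared band axis. This is the multiple-instance
#' view of crown-labeled imagery: the crown label is trusted at the bag level
#' only, individual pixels may be mislabeled (shadow, ground, neighbours).
#'
#' @param spectra numeric matrix, one row per pixel, one column per band.
#' @param crown_id character vector (length `nrow(spectra)`) assigning each
#'   pixel to a crown. Rows of the same crown need not be contiguous but their
#'   original order is preserved within the bag.
#' @param genus character vector of genus codes, one per pixel (constant
#'   within a crown) or one per crown.
#' @param species character vector of species codes, same recycling rules as
#'   `genus`. An empty string marks a missing species label.
#' @param wavelengths numeric vector of band-center wavelengths in nm,
#'   strictly increasing, length `ncol(spectra)`.
#'
#' @return An object of class `bag_set`: a list with elements
#'   \describe{
#'     \item{spectra}{the instance matrix (N x d)}
#'     \item{bag}{integer index (length N) into `bags`}
#'     \item{bags}{data.frame with `bag_id`, `genus`, `species`, `n`}
#'     \item{wavelengths}{the band axis in nm}
#'   }
#' @export
#' @examples
#' x <- bag_set(matrix(runif(12), 3, 4), c("a", "a", "b"),
#'              genus = c("PI", "PI", "QU"), species = c("PIPA", "PIPA", "QULA"),
#'              wavelengths = c(400, 500, 600, 700))
#' x
bag_set <- function(spectra, crown_id, genus, species, wavelengths) {
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  n <- nrow(spectra)
  d <- ncol(spectra)
  if (n < 1L) stop("a bag_set needs at least one instance")
  if (length(wavelengths) != d)
    stop("length(wavelengths) must equal the number of spectral bands")
  wavelengths <- as.numeric(wavelengths)
  if (d > 1L && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (!all(is.finite(spectra)))
    stop("spectra contain non-finite values")
  crown_id <- as.character(crown_id)
  if (length(crown_id) != n) stop("crown_id must have one entry per instance")

  ids <- unique(crown_id)
  bag <- match(crown_id, ids)

  expand <- function(lab, what) {
    lab <- as.character(lab)
    if (length(lab) == length(ids)) return(lab)
    if (length(lab) == n) {
      per_bag <- vapply(seq_along(ids), function(j) {
        u <- unique(lab[bag == j])
        if (length(u) > 1L)
          stop(sprintf("crown '%s' has conflicting %s labels", ids[j], what))
        u
      }, character(1))
      return(per_bag)
    }
    stop(sprintf("%s must have one entry per instance or per crown", what))
  }
  genus <- expand(genus, "genus")
  species <- expand(species, "species")
  species[is.na(species)] <- ""

  bags <- data.frame(bag_id = ids, genus = genus, species = species,
                     n = as.integer(tabulate(bag, length(ids))),
                     stringsAsFactors = FALSE)
  structure(list(spectra = spectra, bag = bag, bags = bags,
                 wavelengths = wavelengths),
            class = "bag_set")
}

#' @export
print.bag_set <- function(x, ...) {
  cat(sprintf("bag_set: %d crowns, %d pixels, %d bands (%.0f-%.0f nm)\n",
              n_bags(x), n_instances(x), n_bands(x),
              min(x$wavelengths), max(x$wavelengths)))
  gt <- table(x$bags$genus)
  cat("genus counts:", paste(sprintf("%s=%d", names(gt), gt), collapse = ", "), "\n")
  if (any(nzchar(x$bags$species))) {
    st <- table(x$bags$species[nzchar(x$bags$species)])
    cat("species counts:", paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Bag-set dimensions
#'
#' @param x a `bag_set`.
#' @return Number of crowns, pixels, or bands respectively.
#' @export
n_bags <- function(x) nrow(x$bags)

#' @rdname n_bags
#' @export
n_instances <- function(x) nrow(x$spectra)

#' @rdname n_bags
#' @export
n_bands <- function(x) length(x$wavelengths)

#' Extract the instance matrix of one bag
#'
#' @param x a `bag_set`.
#' @param j bag index (integer) or `bag_id` (character).
#' @return Numeric matrix of that crown's pixel spectra, rows in original order.
#' @export
bag_instances <- function(x, j) {
  if (is.character(j)) j <- match(j, x$bags$bag_id)
  if (is.na(j) || j < 1L || j > n_bags(x)) stop("unknown bag")
  x$spectra[x$bag == j, , drop = FALSE]
}

#' Split a bag_set into per-class lists of instance matrices
#'
#' @param x a `bag_set`.
#' @param level `"genus"` or `"species"`.
#' @return Named list (one element per class label) of lists of per-bag
#'   instance matrices.
#' @export
bags_by_class <- function(x, level = c("genus", "species")) {
  level <- match.arg(level)
  labs <- x$bags[[level]]
  out <- lapply(unique(labs), function(cl) {
    idx <- which(labs == cl)
    stats::setNames(lapply(idx, function(j) bag_instances(x, j)),
                    x$bags$bag_id[idx])
  })
  names(out) <- unique(labs)
  out
}

#' Keep a subset of bags
#'
#' @param x a `bag_set`.
#' @param keep logical or integer index over bags.
#' @return A `bag_set` containing only the selected crowns (band axis
#'   unchanged), or `NULL`-like empty-set error if none remain.
#' @export
subset_bags <- function(x, keep) {
  if (is.logical(keep)) keep <- which(keep)
  keep <- sort(unique(as.integer(keep)))
  if (length(keep) == 0L) stop("subset_bags: no bags left")
  rows <- x$bag %in% keep
  bag_set(x$spectra[rows, , drop = FALSE],
          x$bags$bag_id[x$bag][rows],
          genus = x$bags$genus[keep],
          species = x$bags$species[keep],
          wavelengths = x$wavelengths)
}

#' Class vocabulary of a bag_set
#'
#' @param x a `bag_set`.
#' @param level `"genus"` or `"species"`.
#' @return Sorted character vector of distinct labels at that level
#'   (empty-string species labels are omitted).
#' @export
class_vocabulary <- function(x, level = c("genus", "species")) {
  level <- match.arg(level)
  v <- sort(unique(x$bags[[level]]))
  v[nzchar(v)]
}

all_equal_bagsets <- function(a, b, tol = 1e-8) {
  isTRUE(all.equal(a$wavelengths, b$wavelengths, tolerance = tol)) &&
    identical(a$bags$bag_id, b$bags$bag_id) &&
    identical(a$bags$genus, b$bags$genus) &&
    identical(a$bags$species, b$bags$species) &&
    identical(a$bag, b$bag) &&
    isTRUE(all.equal(a$spectra, b$spectra, tolerance = tol,
                     check.attributes = FALSE))
}
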