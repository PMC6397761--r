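#' Persist a one-vs-one model to a directory
#'
#' Writes a [miace_ovo()] model as plain JSON: a `manifest.json` with the
#' class vocabulary, level, pair mode, band axis and hierarchy layout, one
#' `classifier_<k>.json` per pairwise classifier (signature vector,
#' background mean/eigensystem, threshold, training accuracy), and a
#' `species_<genus>/` subdirectory per species sub-model. The schema is
#' self-contained; [read_miace_model()] is the inverse.
#'
#' @param model a `miace_ovo` model.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_miace_model <- function(model, dir) {
  stopifnot(inherits(model, "miace_ovo"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hier <- NULL
  if (!is.null(model$hierarchy)) {
    hier <- lapply(model$hierarchy, function(h) {
      if (inherits(h, "miace_ovo")) list(type = "submodel")
      else list(type = "species", species = h)
    })
  }
  manifest <- list(format = "miace_ovo/1", classes = model$classes,
                   level = model$level, pairs_mode = model$pairs_mode,
                   wavelengths = model$wavelengths,
                   n_classifiers = length(model$classifiers),
                   classifier_pairs = names(model$classifiers),
                   hierarchy = hier)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (k in seq_along(model$classifiers)) {
    clf <- model$classifiers[[k]]
    jsonlite::write_json(
      list(target_class = clf$target_class,
           background_class = clf$background_class,
           threshold = clf$threshold,
           training_accuracy = clf$training_accuracy,
           s = clf$fit$s, objective = clf$fit$objective,
           n_iter = clf$fit$n_iter, converged = clf$fit$converged,
           selected = clf$fit$selected, d = clf$fit$d,
           bg_mean = clf$fit$background$mean,
           bg_U = clf$fit$background$U, bg_D = clf$fit$background$D,
           bg_lambda = clf$fit$background$lambda),
      file.path(dir, sprintf("classifier_%03d.json", k)),
      auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(model$hierarchy)) {
    for (g in names(model$hierarchy)) {
      h <- model$hierarchy[[g]]
      if (inherits(h, "miace_ovo"))
        write_miace_model(h, file.path(dir, paste0("species_", g)))
    }
  }
  invisible(dir)
}

#' Load a one-vs-one model from a directory
#'
#' @param dir directory written by [write_miace_model()].
#' @return A `miace_ovo` model.
#' @export
read_miace_model <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  if (!identical(mf$format, "miace_ovo/1")) stop("not a miace_ovo model directory")
  classifiers <- lapply(seq_len(mf$n_classifiers), function(k) {
    j <- jsonlite::read_json(file.path(dir, sprintf("classifier_%03d.json", k)),
                             simplifyVector = TRUE)
    bg <- structure(list(mean = j$bg_mean,
                         cov = j$bg_U %*% (j$bg_D * t(j$bg_U)),
                         U = j$bg_U, D = j$bg_D, lambda = j$bg_lambda),
                    class = "background_model")
    fit <- structure(list(s = j$s, background = bg, objective = j$objective,
                          objective_trace = j$objective, selected = j$selected,
                          n_iter = j$n_iter, converged = j$converged, d = j$d),
                     class = "miace")
    structure(list(target_class = j$target_class,
                   background_class = j$background_class, fit = fit,
                   threshold = j$threshold,
                   training_accuracy = j$training_accuracy),
              class = "miace_binary")
  })
  names(classifiers) <- mf$classifier_pairs
  hierarchy <- NULL
  if (!is.null(mf$hierarchy) && length(mf$hierarchy)) {
    hierarchy <- lapply(names(mf$hierarchy), function(g) {
      h <- mf$hierarchy[[g]]
      if (identical(h$type, "submodel"))
        read_miace_model(file.path(dir, paste0("species_", g)))
      else h$species
    })
    names(hierarchy) <- names(mf$hierarchy)
  }
  structure(list(classifiers = classifiers, classes = mf$classes,
                 level = mf$level, pairs_mode = mf$pairs_mode,
                 wavelengths = mf$wavelengths, hierarchy = hierarchy),
            class = "miace_ovo")
}
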