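#' Read a crown instance table
#'
#' Reads the delimited per-pixel format used throughout the package: a CSV
#' with header `crown_id,genus,species,b<wavelength>,...`, one row per pixel.
#' The band axis is parsed from the header (`b` followed by the band-center
#' wavelength in nm), so no side-car file is needed.
#'
#' Rows with a missing crown id are rejected with a warning; a file whose
#' rows disagree on band count, or an empty file, is a hard error.
#'
#' @param path path to the CSV file.
#' @param label_columns names of the two label columns, genus first.
#' @return A [bag_set].
#' @export
read_instance_table <- function(path, label_columns = c("genus", "species")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = NA,
                    stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e)))
  if (nrow(df) == 0L) stop("empty instance table: ", path)
  need <- c("crown_id", label_columns)
  if (!all(need %in% names(df)))
    stop("instance table must have columns: ", paste(need, collapse = ", "))
  band_cols <- grep("^b[0-9.]+$", names(df), value = TRUE)
  if (length(band_cols) == 0L) stop("no band columns (b<wavelength_nm>) found")
  wl <- as.numeric(sub("^b", "", band_cols))
  o <- order(wl)
  band_cols <- band_cols[o]
  wl <- wl[o]

  cid <- as.character(df$crown_id)
  bad <- is.na(cid) | !nzchar(cid)
  if (any(bad)) {
    warning(sprintf("dropping %d row(s) with missing crown_id", sum(bad)))
    df <- df[!bad, , drop = FALSE]
    cid <- cid[!bad]
    if (nrow(df) == 0L) stop("no rows with a crown_id remain")
  }
  spectra <- as.matrix(df[, band_cols, drop = FALSE])
  if (!is.numeric(spectra) || anyNA(spectra))
    stop("non-numeric or missing reflectance values (inconsistent band count?)")
  sp <- as.character(df[[label_columns[2]]])
  sp[is.na(sp)] <- ""
  bag_set(spectra, cid,
          genus = as.character(df[[label_columns[1]]]),
          species = sp,
          wavelengths = wl)
}

#' Write a crown instance table
#'
#' Inverse of [read_instance_table()]: writes one row per pixel with the band
#' axis encoded in the header. `read_instance_table(write_instance_table(x))`
#' reproduces `x`, and writing the re-read set again is byte-identical.
#'
#' @param x a [bag_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_instance_table <- function(x, path) {
  stopifnot(inherits(x, "bag_set"))
  if (n_bands(x) == 0L) stop("cannot write a bag_set with an empty band axis")
  hdr <- c("crown_id", "genus", "species",
           paste0("b", format(x$wavelengths, trim = TRUE, scientific = FALSE)))
  vals <- apply(x$spectra, 1, function(r)
    paste(format(r, trim = TRUE, digits = 15, scientific = FALSE), collapse = ","))
  lines <- paste(x$bags$bag_id[x$bag], x$bags$genus[x$bag],
                 x$bags$species[x$bag], vals, sep = ",")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot open ", path, " for writing"))
  on.exit(close(con))
  writeLines(c(paste(hdr, collapse = ","), lines), con)
  invisible(path)
}
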