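#' Construct a mass spectrometry image
#'
#' In-memory container for one patient's pixel grid of centroided spectra.
#' Pixel coordinates are 0-based with `x` = column, `y` = row, origin
#' top-left.
#'
#' @param patient_id character scalar.
#' @param coords data.frame with integer columns `x`, `y`, one row per pixel;
#'   coordinates must be unique.
#' @param spectra list parallel to `coords`, each element
#'   `list(mz =, intensity =)` with `mz` strictly ascending and intensities
#'   non-negative.
#' @param mode `"processed"` (per-pixel peak lists) or `"continuous"` (all
#'   pixels share one m/z axis).
#' @param spatial_resolution pixel size in micrometres (metadata only).
#' @return object of class `msi_image`.
#' @export
msi_image <- function(patient_id, coords, spectra,
                      mode = c("processed", "continuous"),
                      spatial_resolution = NA_real_) {
  mode <- match.arg(mode)
  img <- structure(
    list(patient_id = as.character(patient_id),
         coords = data.frame(x = as.integer(coords$x), y = as.integer(coords$y)),
         spectra = spectra, mode = mode,
         spatial_resolution = spatial_resolution),
    class = "msi_image"
  )
  validate_msi_image(img)
  img
}

validate_msi_image <- function(img) {
  if (nrow(img$coords) != length(img$spectra)) {
    stop("coords and spectra must be parallel", call. = FALSE)
  }
  if (anyDuplicated(img$coords)) stop("pixel coordinates must be unique", call. = FALSE)
  for (i in seq_along(img$spectra)) {
    sp <- img$spectra[[i]]
    if (length(sp$mz) != length(sp$intensity)) {
      stop(sprintf("pixel (%d,%d): mz and intensity lengths differ",
                   img$coords$x[i], img$coords$y[i]), call. = FALSE)
    }
    if (length(sp$mz) > 1 && any(diff(sp$mz) <= 0)) {
      stop(sprintf("pixel (%d,%d): m/z values not strictly ascending",
                   img$coords$x[i], img$coords$y[i]), call. = FALSE)
    }
    if (any(sp$intensity < 0)) {
      stop(sprintf("pixel (%d,%d): negative intensity",
                   img$coords$x[i], img$coords$y[i]), call. = FALSE)
    }
  }
  if (img$mode == "continuous" && length(img$spectra) > 1) {
    ref <- img$spectra[[1]]$mz
    same <- vapply(img$spectra, function(s) {
      length(s$mz) == length(ref) && all(s$mz == ref)
    }, logical(1))
    if (!all(same)) stop("continuous mode requires a shared m/z axis", call. = FALSE)
  }
  invisible(img)
}

#' @export
print.msi_image <- function(x, ...) {
  cat(sprintf("MSI image '%s': %d pixels, %s mode\n",
              x$patient_id, nrow(x$coords), x$mode))
  invisible(x)
}

roi_labels <- c("background", "benign_tissue", "cancer_tissue")

#' Construct a region-of-interest label mask
#'
#' @param df data.frame with columns `x`, `y` (0-based pixel coordinates) and
#'   `label` (one of `background`, `benign_tissue`, `cancer_tissue`).
#' @return object of class `roi_mask` (a data.frame).
#' @export
roi_mask <- function(df) {
  if (!all(c("x", "y", "label") %in% names(df))) {
    stop("mask needs columns x, y, label", call. = FALSE)
  }
  bad <- setdiff(unique(df$label), roi_labels)
  if (length(bad)) {
    stop(sprintf("unknown ROI label(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(x = as.integer(df$x), y = as.integer(df$y),
                    label = as.character(df$label))
  class(out) <- c("roi_mask", "data.frame")
  out
}

#' Check a mask against an image
#'
#' Errors if any labelled pixel is absent from the image.
#'
#' @param img an `msi_image`.
#' @param mask an `roi_mask`.
#' @return the mask, invisibly.
#' @export
validate_mask <- function(img, mask) {
  key_img <- paste(img$coords$x, img$coords$y)
  key_msk <- paste(mask$x, mask$y)
  missing <- setdiff(key_msk, key_img)
  if (length(missing)) {
    stop(sprintf("mask for '%s' references %d pixel(s) absent from the image (e.g. %s)",
                 img$patient_id, length(missing), missing[1]), call. = FALSE)
  }
  invisible(mask)
}

#' Read / write ROI masks as TSV
#'
#' Plain tab-separated `(x, y, label)` with a comment header documenting the
#' coordinate convention (0-based, x = column, y = row, origin top-left).
#'
#' @param mask an `roi_mask`.
#' @param path file path.
#' @return `read_mask` returns an `roi_mask`; `write_mask` returns the path
#'   invisibly.
#' @export
write_mask <- function(mask, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# ROI mask: x = column, y = row, 0-based, origin top-left", con)
  utils::write.table(mask, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    return(roi_mask(data.frame(x = integer(0), y = integer(0), label = character(0))))
  }
  roi_mask(df)
}

#' Read / write the patient metadata table
#'
#' TSV with columns `patient_id`, `diagnosis`, `grade`, `stage`, `phenotype`;
#' unknown fields are written as empty strings. Benign patients must have no
#' grade or stage.
#'
#' @param meta data.frame of patient metadata.
#' @param path file path.
#' @return `read_metadata` returns the data.frame; `write_metadata` the path,
#'   invisibly.
#' @export
write_metadata <- function(meta, path) {
  out <- meta
  for (col in c("grade", "stage")) out[[col]][is.na(out[[col]])] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (col in c("grade", "stage")) {
    if (col %in% names(df)) df[[col]][df[[col]] == ""] <- NA_character_
  }
  if (anyDuplicated(df$patient_id)) stop("duplicate patient_id in metadata", call. = FALSE)
  bad <- df$diagnosis == "benign" & (!is.na(df$grade) | !is.na(df$stage))
  if (any(bad)) {
    stop(sprintf("benign patient '%s' carries grade/stage", df$patient_id[which(bad)[1]]),
         call. = FALSE)
  }
  df
}

#' Read / write a protein expression table as TSV
#'
#' Rows are patients (first column `patient_id`), remaining columns are
#' antibody identifiers.
#'
#' @param tab patients x proteins matrix (class `protein_table` accepted).
#' @param path file path.
#' @return `read_protein_table` returns a `protein_table` matrix.
#' @export
write_protein_table <- function(tab, path) {
  df <- data.frame(patient_id = rownames(tab), as.data.frame(unclass(tab)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_protein_table
#' @export
read_protein_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$patient_id
  if (anyDuplicated(colnames(m))) stop("duplicate protein names", call. = FALSE)
  if (!all(is.finite(m))) stop("protein table contains non-finite values", call. = FALSE)
  class(m) <- c("protein_table", "matrix", "array")
  m
}
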