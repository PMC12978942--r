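#' Image and summary file I/O
#'
#' Thin wrappers around the standard raster formats used by the pipeline:
#' multi-page TIFF for IHC channels (3 pages: UV1, UV2, B) and reflectance
#' stacks (31 pages, 500-800 nm in 10 nm steps), RGB PNG for eyeshine
#' photographs, and JSON for per-individual summaries. Intensities are
#' stored as 8-bit.
#'
#' @param section An `ihc_section`.
#' @param path Output file path.
#' @return The writers return `path` invisibly; the readers return the
#'   corresponding array or object.
#' @name ommatid-io
NULL

#' @rdname ommatid-io
#' @export
write_ihc_tiff <- function(section, path) {
  img <- if (inherits(section, "ihc_section")) section$image else section
  pages <- lapply(1:3, function(ch) img[, , ch] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname ommatid-io
#' @export
read_ihc_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 3L) stop("expected a 3-page (UV1, UV2, B) TIFF")
  img <- array(0, dim = c(dim(pages[[1]]), 3L))
  for (ch in 1:3) img[, , ch] <- round(pages[[ch]] * 255)
  img
}

#' @rdname ommatid-io
#' @param stack A `reflectance_stack`.
#' @export
write_reflectance_tiff <- function(stack, path) {
  planes <- if (inherits(stack, "reflectance_stack")) stack$planes else stack
  pages <- lapply(seq_len(dim(planes)[3]), function(p) planes[, , p] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname ommatid-io
#' @export
read_reflectance_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  planes <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (p in seq_along(pages)) planes[, , p] <- round(pages[[p]] * 255)
  structure(list(planes = planes, wavelengths = seq(500, 800, by = 10),
                 truth = NULL, omm_radius_px = NA_integer_),
            class = "reflectance_stack")
}

#' @rdname ommatid-io
#' @param image An `eyeshine_image`.
#' @export
write_eyeshine_png <- function(image, path) {
  img <- if (inherits(image, "eyeshine_image")) image$rgb else image
  png::writePNG(img / 255, path)
  invisible(path)
}

#' @rdname ommatid-io
#' @param dv_index Dorsoventral index to attach when reading an image.
#' @export
read_eyeshine_png <- function(path, dv_index = 0L) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
  structure(list(rgb = round(img * 255), dv_index = dv_index, spots = NULL),
            class = "eyeshine_image")
}

#' Write a per-individual IHC summary as JSON
#'
#' Records the mean class proportions, the consistency delta and the
#' kept/excluded status of a [section_consistency()] result.
#'
#' @param series A `section_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_section_summary <- function(series, path) {
  stopifnot(inherits(series, "section_series"))
  jsonlite::write_json(
    list(individual = series$individual,
         status = series$status,
         consistency_delta = series$consistency_delta,
         blue_fractions = series$blue_fractions,
         mean_proportions = as.list(series$mean_fractions)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
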