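#' Slide images and annotation maps
#'
#' A `slide_image` is an RGB raster stored as a numeric `height x width x 3`
#' array of intensities in `[0, 255]`, with microns-per-pixel (MPP) metadata
#' and an identifier. It is the unit the TSR pipeline scores. An
#' `annotation_map` is an integer label raster of identical geometry with the
#' coding 0 = unannotated/background, 1 = tumor, 2 = stroma, 3 = other,
#' 4 = adipose.
#'
#' @param pixels numeric `h x w x 3` array, intensities in `[0, 255]`.
#' @param mpp microns per pixel of the scan (default 0.5).
#' @param id slide identifier string.
#' @return A `slide_image` object.
#' @export
slide_image <- function(pixels, mpp = 0.5, id = "slide") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("slide pixels must be a height x width x 3 RGB array")
  }
  structure(pixels, mpp = mpp, slide_id = id, class = "slide_image")
}

#' @rdname slide_image
#' @param labels integer matrix (same geometry as the slide) with codes
#'   0 = unannotated/background, 1 = tumor, 2 = stroma, 3 = other, 4 = adipose.
#' @export
annotation_map <- function(labels, id = "slide") {
  labels <- as.matrix(labels)
  if (!all(labels %in% 0:4)) stop("annotation labels must be in 0..4")
  storage.mode(labels) <- "integer"
  structure(labels, slide_id = id, class = "annotation_map")
}

# canonical class order used everywhere (predictions, confusion matrices,
# tie-breaking); recorded in serialized models
TSR_CLASSES <- c("tumor", "stroma", "other")

# annotation codes for the three annotated classes
ANNOT_CODE <- c(tumor = 1L, stroma = 2L, other = 3L)

slide_dim <- function(slide) dim(slide)[1:2]

slide_id <- function(x) attr(x, "slide_id") %||% "slide"

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<slide_image '%s'> %d x %d px, %.2f microns/px, range [%.1f, %.1f]\n",
              slide_id(x), d[2], d[1], attr(x, "mpp") %||% NA_real_,
              min(x), max(x)))
  invisible(x)
}

#' @export
print.annotation_map <- function(x, ...) {
  tab <- table(factor(x, levels = 0:4,
                      labels = c("background", "tumor", "stroma", "other", "adipose")))
  cat(sprintf("<annotation_map '%s'> %d x %d px\n", slide_id(x), ncol(x), nrow(x)))
  print(tab)
  invisible(x)
}

#' Read and write slides and annotation maps as PNG
#'
#' Slides are stored as ordinary RGB PNG files; annotation maps as
#' single-channel 8-bit PNGs holding the raw label codes (0..4), so a label
#' PNG viewed in an image viewer is near-black by design.
#'
#' @param slide a `slide_image`.
#' @param path file path.
#' @return `read_slide_png` returns a `slide_image`; writers return the path
#'   invisibly.
#' @export
write_slide_png <- function(slide, path) {
  arr <- clip(unclass(slide), 0, 255) / 255
  png::writePNG(arr, target = path)
  invisible(path)
}

#' @rdname write_slide_png
#' @param mpp,id metadata attached to the slide on read.
#' @export
read_slide_png <- function(path, mpp = 0.5, id = sub("\\.png$", "", basename(path))) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L && dim(arr)[3] == 4L) arr <- arr[, , 1:3]  # drop alpha
  if (length(dim(arr)) != 3L) stop("not an RGB PNG: ", path)
  slide_image(arr * 255, mpp = mpp, id = id)
}

#' @rdname write_slide_png
#' @param annot an `annotation_map`.
#' @export
write_annotation_png <- function(annot, path) {
  png::writePNG(unclass(annot) / 255, target = path)
  invisible(path)
}

#' @rdname write_slide_png
#' @export
read_annotation_png <- function(path, id = sub("\\.png$", "", basename(path))) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  annotation_map(round(arr * 255), id = id)
}
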