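#' Patch sets
#'
#' A `patch_set` is the unit of exchange between the tiler, the stain
#' normalizer and the classifier: a collection of fixed-size RGB patches
#' with their window coordinates, slide provenance, tiling parameters, and
#' (in training mode) class labels.
#'
#' @param pixels list of `S x S x 3` numeric arrays (intensities 0..255), or
#'   `NULL` for a coordinates-only set.
#' @param windows data frame with columns `slide_id`, `x`, `y`, `size`
#'   (`x`, `y` are 0-based top-left corners of half-open windows).
#' @param labels factor over `c("tumor", "stroma", "other")`, or `NULL`
#'   (inference mode).
#' @param params list of tiling / generation parameters kept for provenance.
#' @return A `patch_set`.
#' @export
patch_set <- function(pixels, windows, labels = NULL, params = list()) {
  windows <- as.data.frame(windows)
  need <- c("slide_id", "x", "y", "size")
  if (!all(need %in% names(windows))) {
    stop("windows must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(windows[, need])) stop("patch windows must be unique")
  if (!is.null(pixels) && length(pixels) != nrow(windows)) {
    stop("pixels and windows disagree in length")
  }
  if (!is.null(labels)) {
    labels <- factor(as.character(labels), levels = TSR_CLASSES)
    if (anyNA(labels)) stop("labels must be tumor/stroma/other")
    if (length(labels) != nrow(windows)) stop("labels and windows disagree in length")
  }
  structure(list(pixels = pixels, windows = windows, labels = labels,
                 params = params),
            class = "patch_set")
}

#' @rdname patch_set
#' @param x a `patch_set`.
#' @export
n_patches <- function(x) nrow(x$windows)

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches of %d px, %s\n", n_patches(x),
              if (n_patches(x)) x$windows$size[1] else NA_integer_,
              if (is.null(x$labels)) "unlabeled" else "labeled"))
  if (!is.null(x$labels)) print(table(x$labels))
  invisible(x)
}

# subset a patch_set by index
patch_subset <- function(ps, idx) {
  patch_set(if (is.null(ps$pixels)) NULL else ps$pixels[idx],
            ps$windows[idx, , drop = FALSE],
            if (is.null(ps$labels)) NULL else ps$labels[idx],
            ps$params)
}

# concatenate patch_sets (labels must all be present or all absent)
patch_rbind <- function(...) {
  sets <- list(...)
  patch_set(
    do.call(c, lapply(sets, `[[`, "pixels")),
    do.call(rbind, lapply(sets, `[[`, "windows")),
    {
      labs <- lapply(sets, `[[`, "labels")
      if (all(vapply(labs, is.null, TRUE))) NULL else do.call(c, lapply(labs, as.character))
    },
    sets[[1]]$params)
}

#' Save / load a patch set as a directory of PNGs plus a CSV manifest
#'
#' The manifest (`manifest.csv`) records slide id, window coordinates, size
#' and label; each patch is written as `patch_<i>.png`.
#'
#' @param ps a `patch_set` with pixel data.
#' @param dir output directory (created if missing).
#' @export
write_patch_set <- function(ps, dir) {
  stopifnot(inherits(ps, "patch_set"), !is.null(ps$pixels))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- ps$windows
  man$label <- if (is.null(ps$labels)) NA_character_ else as.character(ps$labels)
  man$file <- sprintf("patch_%05d.png", seq_len(nrow(man)))
  for (i in seq_len(nrow(man))) {
    png::writePNG(clip(ps$pixels[[i]], 0, 255) / 255, file.path(dir, man$file[i]))
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_patch_set
#' @export
read_patch_set <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  pixels <- lapply(man$file, function(f) {
    a <- png::readPNG(file.path(dir, f))
    if (length(dim(a)) == 3L && dim(a)[3] == 4L) a <- a[, , 1:3]
    a * 255
  })
  labels <- if (all(is.na(man$label))) NULL else man$label
  patch_set(pixels, man[, c("slide_id", "x", "y", "size")], labels)
}
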