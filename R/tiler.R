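#' Enumerate sliding-window positions
#'
#' All `size x size` windows whose 0-based top-left corners lie on the
#' stride grid and that fit fully inside the image (partial windows at the
#' right/bottom edges are dropped, never padded). Windows are half-open,
#' `[x, x+size) x [y, y+size)`, returned in row-major order (x varies
#' fastest). The training regime uses `stride = size - overlap`
#' (224 - 64 = 160); the inference regime uses `stride = size` (no
#' overlap).
#'
#' @param width,height image size in pixels.
#' @param size window edge (default 224).
#' @param stride grid step in pixels (>= 1).
#' @return data frame with columns `x`, `y` (0-based corners).
#' @export
enumerate_windows <- function(width, height, size = 224, stride = size) {
  stopifnot(stride >= 1, size >= 1)
  if (size > width || size > height) {
    warning(sprintf("window size %d exceeds image %d x %d; no windows",
                    size, width, height))
    return(data.frame(x = integer(), y = integer()))
  }
  xs <- seq.int(0L, width - size, by = stride)
  ys <- seq.int(0L, height - size, by = stride)
  data.frame(x = rep(as.integer(xs), times = length(ys)),
             y = rep(as.integer(ys), each = length(xs)))
}

# extract one window from a slide array (x, y 0-based)
extract_window <- function(slide, x, y, size) {
  unclass(slide)[(y + 1L):(y + size), (x + 1L):(x + size), , drop = FALSE]
}

#' Tile an annotated slide for classifier training
#'
#' Sliding-window tiling of the training regime: overlapping windows
#' (stride `size - overlap`), a window kept only when the fraction of its
#' pixels carrying any annotation (tumor, stroma or other) reaches
#' `min_annotated` (inclusive: exactly 75% is kept), and each kept patch
#' labeled by the majority annotated class inside the window, ties broken
#' in the fixed class order tumor > stroma > other. With
#' `single_class = TRUE` the coverage test instead requires
#' `min_annotated` of the window to be one single class (sensitivity
#' variant).
#'
#' @param slide a [slide_image()].
#' @param annotation an [annotation_map()] aligned to the slide.
#' @param size patch edge (default 224).
#' @param overlap overlap between adjacent windows in pixels (default 64).
#' @param min_annotated inclusive annotated-coverage threshold
#'   (default 0.75).
#' @param single_class use the single-class coverage variant.
#' @param extract_pixels attach pixel data (set `FALSE` for a
#'   coordinates+labels-only scan).
#' @return a labeled [patch_set()].
#' @export
tile_training <- function(slide, annotation, size = 224, overlap = 64,
                          min_annotated = 0.75, single_class = FALSE,
                          extract_pixels = TRUE) {
  d <- slide_dim(slide)
  if (!all(dim(annotation) == d)) {
    stop("annotation map is not aligned to the slide")
  }
  stride <- size - overlap
  win <- enumerate_windows(d[2], d[1], size = size, stride = stride)
  lab <- unclass(annotation)
  cnt <- vapply(1:3, function(k) {
    window_sum(integral_image(lab == k), win$x, win$y, size)
  }, numeric(nrow(win)))
  cnt <- matrix(cnt, nrow = nrow(win))
  cover <- if (single_class) apply(cnt, 1L, max) else rowSums(cnt)
  keep <- cover / size^2 >= min_annotated
  win <- win[keep, , drop = FALSE]
  cnt <- cnt[keep, , drop = FALSE]
  labels <- TSR_CLASSES[max.col(cnt, ties.method = "first")]
  pixels <- if (extract_pixels) {
    lapply(seq_len(nrow(win)), function(i) {
      extract_window(slide, win$x[i], win$y[i], size)
    })
  } else NULL
  patch_set(pixels,
            data.frame(slide_id = rep(slide_id(slide), nrow(win)),
                       x = win$x, y = win$y,
                       size = rep(size, nrow(win))),
            labels = if (nrow(win)) labels else character(),
            params = list(mode = "train", size = size, overlap = overlap,
                          stride = stride, min_annotated = min_annotated,
                          single_class = single_class))
}

#' Tile a slide for TSR inference
#'
#' Non-overlapping grid tiling of the inference regime: a window is kept
#' when the tissue-mask coverage inside it reaches `min_tissue`
#' (inclusive). No labels are attached.
#'
#' @param slide a [slide_image()].
#' @param mask a `tissue_mask` (logical matrix) aligned to the slide.
#' @param size patch edge (default 224).
#' @param min_tissue inclusive tissue-coverage threshold (default 0.75).
#' @param extract_pixels attach pixel data.
#' @return an unlabeled [patch_set()].
#' @export
tile_inference <- function(slide, mask, size = 224, min_tissue = 0.75,
                           extract_pixels = TRUE) {
  d <- slide_dim(slide)
  if (!all(dim(mask) == d)) stop("tissue mask is not aligned to the slide")
  win <- enumerate_windows(d[2], d[1], size = size, stride = size)
  cov <- window_sum(integral_image(unclass(mask) * 1.0), win$x, win$y, size)
  keep <- cov / size^2 >= min_tissue
  win <- win[keep, , drop = FALSE]
  pixels <- if (extract_pixels) {
    lapply(seq_len(nrow(win)), function(i) {
      extract_window(slide, win$x[i], win$y[i], size)
    })
  } else NULL
  patch_set(pixels,
            data.frame(slide_id = rep(slide_id(slide), nrow(win)),
                       x = win$x, y = win$y,
                       size = rep(size, nrow(win))),
            labels = NULL,
            params = list(mode = "infer", size = size, stride = size,
                          min_tissue = min_tissue))
}
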