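#' Otsu threshold from a 256-bin histogram
#'
#' Returns the split point maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` over all 255 possible splits of a 256-bin
#' histogram; a threshold `t` puts bins `0..t` in the low class and
#' `t+1..255` in the high class. Ties are broken toward the lowest
#' maximizing index, so the result is deterministic.
#'
#' @param histogram numeric vector of 256 non-negative counts
#'   (bins 0..255).
#' @return integer threshold bin index in `0..254`.
#' @export
otsu_threshold <- function(histogram) {
  if (length(histogram) != 256L || any(histogram < 0)) {
    stop("histogram must be 256 non-negative counts")
  }
  if (sum(histogram > 0) < 2L) {
    stop(errorCondition("degenerate histogram: fewer than 2 nonempty bins",
                        class = c("tsr_degenerate_histogram", "error")))
  }
  p <- histogram / sum(histogram)
  bins <- 0:255
  w0 <- cumsum(p)[1:255]
  w1 <- 1 - w0
  m0 <- cumsum(p * bins)[1:255]
  mu_t <- sum(p * bins)
  # sigma_b^2(t) = w0 w1 (mu0 - mu1)^2 = (mu_t * w0 - m0)^2 / (w0 w1)
  denom <- w0 * w1
  sb <- ifelse(denom > 0, (mu_t * w0 - m0)^2 / denom, -Inf)
  as.integer(which.max(sb) - 1L)  # which.max takes the first (lowest) maximum
}

# 256-bin histogram of a matrix of values already scaled to [0, 255]
hist256 <- function(v) {
  tabulate(clip(floor(v), 0, 255) + 1L, nbins = 256L)
}

# HSV saturation of an RGB slide, scaled to 0..255
saturation_channel <- function(slide) {
  arr <- unclass(slide)
  mx <- pmax(arr[, , 1], arr[, , 2], arr[, , 3])
  mn <- pmin(arr[, , 1], arr[, , 2], arr[, , 3])
  s <- ifelse(mx > 0, (mx - mn) / mx, 0)
  s * 255
}

#' Build a binary tissue mask for a slide
#'
#' Thresholds a scalar channel of the slide with [otsu_threshold()] to
#' separate stained tissue from image background and adipose tissue, which
#' are both near-white. The default channel is HSV saturation (background
#' and adipose have low saturation, stained tissue high, so one threshold
#' removes both); grayscale is available, with tissue on the dark side.
#' A saturation floor guards the blank-slide case: if no pixel's saturation
#' exceeds `blank_floor`, the slide is treated as tissue-free and an
#' all-false mask is returned with a warning (Otsu on a pure-noise
#' histogram would otherwise split the noise).
#'
#' @param slide a [slide_image()] (RGB).
#' @param channel `"saturation"` (default) or `"grayscale"`.
#' @param min_object_px drop connected tissue components smaller than this
#'   many pixels (default 0 = no cleanup; uses EBImage when > 0).
#' @param blank_floor saturation floor in 0..255 units (default 20); only
#'   used for the saturation channel.
#' @return A `tissue_mask`: logical matrix (TRUE = tissue) with attributes
#'   `threshold` and `channel`.
#' @export
build_tissue_mask <- function(slide, channel = c("saturation", "grayscale"),
                              min_object_px = 0, blank_floor = 20) {
  channel <- match.arg(channel)
  d <- dim(slide)
  if (length(d) != 3L || d[3] != 3L) stop("slide must be RGB")
  v <- if (channel == "saturation") saturation_channel(slide)
       else (unclass(slide)[, , 1] + unclass(slide)[, , 2] + unclass(slide)[, , 3]) / 3
  blank <- FALSE
  thr <- NA_integer_
  if (channel == "saturation" && max(v) < blank_floor) {
    blank <- TRUE
  } else {
    thr <- tryCatch(otsu_threshold(hist256(v)),
                    tsr_degenerate_histogram = function(e) NA_integer_)
    if (is.na(thr)) blank <- TRUE
  }
  if (blank) {
    warning("blank slide: no tissue found, returning all-false mask")
    m <- matrix(FALSE, d[1], d[2])
  } else {
    m <- if (channel == "saturation") floor(v) > thr else floor(v) <= thr
  }
  if (min_object_px > 0 && any(m)) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("min_object_px > 0 requires the EBImage package")
    }
    cc <- EBImage::bwlabel(m)
    sizes <- tabulate(cc[cc > 0])
    m <- m & !(cc %in% which(sizes < min_object_px))
    dim(m) <- c(d[1], d[2])
  }
  structure(m, threshold = thr, channel = channel,
            slide_id = slide_id(slide), class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask '%s'> %d x %d px, %.1f%% tissue (channel %s, threshold %s)\n",
              attr(x, "slide_id") %||% "?", ncol(x), nrow(x), 100 * mean(x),
              attr(x, "channel"), format(attr(x, "threshold"))))
  invisible(x)
}

#' Write / read a tissue mask as an 8-bit PNG (0 = background, 255 = tissue)
#'
#' @param mask a `tissue_mask`.
#' @param path file path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(unclass(mask) * 1.0, target = path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  structure(arr > 0.5, class = "tissue_mask")
}
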