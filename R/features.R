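# Patch feature extraction for the compact classifier backbones.
#
# Each patch is summarized by stain-concentration and texture statistics
# computed against a fixed reference stain model: hematoxylin/eosin
# concentration distribution summaries, local gradient energy of each
# concentration field (separates nuclear speckle from smooth fibrous
# texture), the unstained (near-white) fraction, and global intensity /
# saturation. Patches must be stain-normalized with the same reference used
# at training time for these features to be comparable.

#' Summarize a patch as a stain/texture feature vector
#'
#' @param patch RGB array (`S x S x 3`, 0..255).
#' @param reference [stain_model()] used for the concentration decomposition.
#' @param I0 white intensity.
#' @return named numeric feature vector.
#' @export
extract_patch_features <- function(patch, reference = default_stain_model(),
                                   I0 = 255) {
  od <- rgb_to_od(patch, I0 = I0)
  conc <- solve_concentrations(od, reference)
  s <- dim(patch)[1]
  ch <- matrix(conc[, 1], s); ce <- matrix(conc[, 2], s)
  grad <- function(m) {
    (mean(abs(m[-1, ] - m[-nrow(m), ])) + mean(abs(m[, -1] - m[, -ncol(m)]))) / 2
  }
  q <- function(v) stats::quantile(v, c(0.1, 0.9), names = FALSE)
  qh <- q(ch); qe <- q(ce)
  od_norm <- sqrt(matrix(rowSums(od_pixels(od)^2), s))
  stained <- od_norm >= 0.15
  # per-pixel stain dominance among stained pixels: tracks the majority
  # tissue composition of mixed windows
  n_st <- max(sum(stained), 1L)
  c(h_mean = mean(ch), h_sd = stats::sd(ch), h_q10 = qh[1], h_q90 = qh[2],
    e_mean = mean(ce), e_sd = stats::sd(ce), e_q10 = qe[1], e_q90 = qe[2],
    h_median = stats::median(ch), e_median = stats::median(ce),
    h_grad = grad(ch), e_grad = grad(ce),
    white_frac = mean(od_norm < 0.15),
    h_dom_frac = sum(stained & (ch > ce + 0.15)) / n_st,
    e_dom_frac = sum(stained & (ce > ch + 0.15)) / n_st,
    intensity = mean(patch) / I0,
    saturation = mean(saturation_channel(patch)) / 255,
    h_share = mean(ch) / (mean(ch) + mean(ce) + 1e-8))
}

#' @rdname extract_patch_features
#' @param ps a [patch_set()] with pixel data.
#' @return `extract_features`: numeric matrix, one row per patch.
#' @export
extract_features <- function(ps, reference = default_stain_model(), I0 = 255) {
  stopifnot(inherits(ps, "patch_set"), !is.null(ps$pixels))
  t(vapply(ps$pixels, extract_patch_features,
           numeric(18), reference = reference, I0 = I0))
}

#' Generate patch features without materializing the patch corpus
#'
#' Streams the exact corpus of [make_patch_dataset()] — same seed, same
#' realizations — one patch at a time: render, optionally Macenko-normalize
#' to `reference`, extract features, discard the pixels. Peak memory is a
#' single patch instead of the whole corpus, which matters at study scale
#' (hundreds of 224 px patches per class). The returned features equal
#' `extract_features(normalize_patch_set(make_patch_dataset(...)))` to
#' machine precision.
#'
#' @inheritParams make_patch_dataset
#' @param reference reference [stain_model()] for normalization and
#'   feature extraction.
#' @param normalize Macenko-normalize each patch before featurizing
#'   (pass-through fallback on blank patches).
#' @return list with `X` (feature matrix, one row per patch) and `y`
#'   (factor of labels over tumor/stroma/other).
#' @export
stream_patch_features <- function(n_per_class, textures = texture_params(),
                                  stains = default_stain_model(), seed = 1L,
                                  size = 224, I0 = 255,
                                  mixed_fraction = 0.3, max_secondary = 0.25,
                                  reference = default_stain_model(),
                                  normalize = TRUE) {
  stopifnot(n_per_class >= 1)
  n_per_class <- as.integer(n_per_class)
  S <- stains$stain_matrix
  X <- matrix(NA_real_, 3L * n_per_class, 18L)
  y <- character(3L * n_per_class)
  with_seed(seed, {
    i <- 0L
    for (cl in TSR_CLASSES) {
      for (j in seq_len(n_per_class)) {
        i <- i + 1L
        p <- render_labeled_patch(cl, textures, S, size, I0,
                                  mixed_fraction, max_secondary)
        px <- p$pixels
        if (normalize) {
          px <- normalize_patch(px, reference = reference, I0 = I0,
                                fallback = "passthrough")
        }
        X[i, ] <- extract_patch_features(px, reference = reference, I0 = I0)
        y[i] <- cl
      }
    }
  })
  colnames(X) <- names(extract_patch_features(array(I0, c(4, 4, 3)),
                                              reference, I0))
  list(X = X, y = factor(y, levels = TSR_CLASSES))
}
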