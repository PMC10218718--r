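#' Tumor-stroma ratio from patch counts
#'
#' The TSR of a slide is the share of stroma among its stroma and tumor
#' patches, `TSR = n_stroma / (n_tumor + n_stroma)`. Patches classified as
#' *other* enter neither numerator nor denominator. A slide with no tumor
#' or stroma patches has no defined TSR and raises an error rather than
#' silently returning 0.
#'
#' @param n_stroma,n_tumor non-negative patch counts.
#' @return TSR as a fraction in `[0, 1]`.
#' @export
compute_tsr <- function(n_stroma, n_tumor) {
  stopifnot(n_stroma >= 0, n_tumor >= 0)
  if (n_stroma + n_tumor == 0) {
    stop(errorCondition("no tumor or stroma patches: TSR undefined",
                        class = c("tsr_no_tissue_patches", "error")))
  }
  n_stroma / (n_tumor + n_stroma)
}

#' Dichotomize a TSR percentage into stroma-high / stroma-low
#'
#' Strictly above the cutoff is stroma-high; at or below it is stroma-low
#' (so exactly 50% is stroma-low at the default cutoff). The cutoff is
#' configurable, e.g. to a cohort median.
#'
#' @param tsr_percent TSR value(s) in percent, in `[0, 100]`.
#' @param cutoff cutoff in percent (default 50).
#' @return factor with levels `stroma-low`, `stroma-high`.
#' @export
dichotomize <- function(tsr_percent, cutoff = 50) {
  if (any(is.na(tsr_percent)) || any(tsr_percent < 0 | tsr_percent > 100)) {
    stop("TSR percent values must be in [0, 100]")
  }
  factor(ifelse(tsr_percent > cutoff, "stroma-high", "stroma-low"),
         levels = c("stroma-low", "stroma-high"))
}

#' Estimate the TSR of one slide
#'
#' The full per-slide scoring composition: inference tiling of the tissue
#' mask (non-overlapping grid, coverage filter), Macenko normalization of
#' each kept patch to the model's stain reference (blank patches fall back
#' to pass-through with a warning and are still classified), classifier
#' prediction, and the patch-count TSR with its stroma-high/low
#' dichotomization.
#'
#' @param slide a [slide_image()].
#' @param mask a `tissue_mask` (built with [build_tissue_mask()] if
#'   omitted).
#' @param model a `tsr_classifier` or [oracle_classifier()].
#' @param size patch edge (default 224).
#' @param min_tissue inclusive tissue-coverage threshold (default 0.75).
#' @param reference stain reference; defaults to the model's own.
#' @param cutoff dichotomization cutoff in percent.
#' @param normalize stain-normalize patches before prediction (disable only
#'   when the classifier expects raw patches, e.g. the oracle).
#' @return a `tsr_result`: list with `slide_id`, `n_tumor`, `n_stroma`,
#'   `n_other`, `tsr` (fraction), `tsr_percent`, `stroma_class`, `cutoff`.
#' @export
estimate_slide_tsr <- function(slide, mask = NULL, model, size = 224,
                               min_tissue = 0.75,
                               reference = NULL, cutoff = 50,
                               normalize = !inherits(model, "tsr_oracle_classifier")) {
  if (is.null(mask)) mask <- build_tissue_mask(slide)
  reference <- reference %||% model$reference %||% default_stain_model()
  ps <- tile_inference(slide, mask, size = size, min_tissue = min_tissue)
  if (n_patches(ps) == 0L) {
    stop(errorCondition(
      sprintf("slide '%s': no patches pass the tissue filter", slide_id(slide)),
      class = c("tsr_no_tissue_patches", "error")))
  }
  if (normalize) {
    ps$pixels <- lapply(ps$pixels, normalize_patch, reference = reference,
                        fallback = "passthrough")
  }
  labels <- predict(model, ps, type = "class")
  n <- table(labels)
  n_tumor <- as.integer(n[["tumor"]]); n_stroma <- as.integer(n[["stroma"]])
  tsr <- tryCatch(compute_tsr(n_stroma, n_tumor),
                  tsr_no_tissue_patches = function(e) {
                    stop(errorCondition(
                      sprintf("slide '%s': %s", slide_id(slide), conditionMessage(e)),
                      class = class(e)))
                  })
  structure(list(slide_id = slide_id(slide),
                 n_tumor = n_tumor, n_stroma = n_stroma,
                 n_other = as.integer(n[["other"]]),
                 tsr = tsr, tsr_percent = 100 * tsr,
                 stroma_class = as.character(dichotomize(100 * tsr, cutoff)),
                 cutoff = cutoff),
            class = "tsr_result")
}

#' @export
print.tsr_result <- function(x, ...) {
  cat(sprintf("<tsr_result '%s'> TSR = %.1f%% (%s); tumor %d / stroma %d / other %d patches\n",
              x$slide_id, x$tsr_percent, x$stroma_class,
              x$n_tumor, x$n_stroma, x$n_other))
  invisible(x)
}

#' Collect per-slide TSR results into a table
#'
#' @param results list of `tsr_result` objects.
#' @return data frame with one row per slide (slide id, patch counts, TSR
#'   percent, stroma class).
#' @export
tsr_result_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(slide_id = r$slide_id, n_tumor = r$n_tumor,
               n_stroma = r$n_stroma, n_other = r$n_other,
               tsr_percent = r$tsr_percent, stroma_class = r$stroma_class)
  }))
}
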