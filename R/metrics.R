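#' Per-class classification report
#'
#' Confusion matrix (rows = true, columns = predicted, class order tumor /
#' stroma / other), overall accuracy, and per-class precision
#' `TP / (TP + FP)`, recall `TP / (TP + FN)` and `F1 = 2PR / (P + R)`.
#' A class with no predicted (respectively no true) instances gets
#' precision (recall) 0 together with a `zero_division` flag — never NaN.
#'
#' @param true_labels,pred_labels equal-length vectors over
#'   tumor/stroma/other.
#' @return a `class_report`: list with `confusion`, `accuracy`,
#'   `per_class` (data frame of precision/recall/F1/support),
#'   `zero_division` (classes where a 0 was substituted).
#' @export
classification_report <- function(true_labels, pred_labels) {
  y <- factor(as.character(true_labels), levels = TSR_CLASSES)
  p <- factor(as.character(pred_labels), levels = TSR_CLASSES)
  if (length(y) == 0L) stop("empty label vectors")
  if (length(y) != length(p)) stop("label vectors differ in length")
  if (anyNA(y) || anyNA(p)) stop("labels must be tumor/stroma/other")
  cm <- table(true = y, predicted = p)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  zd <- character(0)
  prec <- numeric(3); rec <- numeric(3)
  for (i in 1:3) {
    if (tp[i] + fp[i] == 0) { prec[i] <- 0; zd <- c(zd, paste0(TSR_CLASSES[i], ":precision")) }
    else prec[i] <- tp[i] / (tp[i] + fp[i])
    if (tp[i] + fn[i] == 0) { rec[i] <- 0; zd <- c(zd, paste0(TSR_CLASSES[i], ":recall")) }
    else rec[i] <- tp[i] / (tp[i] + fn[i])
  }
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(
    confusion = unclass(cm),
    accuracy = sum(tp) / length(y),
    per_class = data.frame(class = TSR_CLASSES, precision = prec,
                           recall = rec, f1 = f1,
                           support = as.integer(rowSums(cm))),
    zero_division = zd), class = "class_report")
}

#' @export
print.class_report <- function(x, ...) {
  cat(sprintf("<class_report> accuracy %.4f\n", x$accuracy))
  print(x$confusion)
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' F1 score from precision and recall
#'
#' @param precision,recall numeric vectors.
#' @return `2 * P * R / (P + R)` (0 where both are 0).
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Pearson correlation of predicted vs. true values
#'
#' Standard product-moment correlation; constant input is flagged as an
#' explicit error rather than returning NaN.
#'
#' @param pred,true equal-length numeric vectors, length >= 2.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(pred, true) {
  stopifnot(length(pred) == length(true))
  if (length(pred) < 2) stop("need at least 2 observations")
  if (stats::sd(pred) == 0 || stats::sd(true) == 0) {
    stop("zero variance: Pearson correlation undefined")
  }
  stats::cor(pred, true, method = "pearson")
}

#' Standard error of the estimate (SEE)
#'
#' Root-mean-square deviation of predictions from the true (reference)
#' values, `sqrt(sum((pred - true)^2) / n)`. For TSR evaluation the
#' reference is the visually assigned category value, so within a category
#' SEE^2 decomposes (up to the n vs n-1 convention) into squared bias plus
#' variance.
#'
#' @param pred,true equal-length numeric vectors, n >= 1.
#' @return non-negative SEE.
#' @export
see <- function(pred, true) {
  stopifnot(length(pred) == length(true))
  if (length(pred) == 0L) stop("empty vectors")
  sqrt(mean((pred - true)^2))
}

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement `p_e` from the raters' marginal products. When both
#' raters are constant and identical (`p_e = 1`), kappa is defined as 1 by
#' convention (with a warning).
#'
#' @param labels_a,labels_b equal-length vectors over two categories
#'   (e.g. stroma-high / stroma-low).
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  a <- as.character(labels_a); b <- as.character(labels_b)
  stopifnot(length(a) == length(b), length(a) >= 1)
  lev <- sort(unique(c(a, b)))
  if (length(lev) > 2) stop("cohens_kappa expects binary labels")
  a <- factor(a, levels = lev); b <- factor(b, levels = lev)
  tab <- table(a, b)
  n <- length(a)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - p_e < 1e-12) {
    warning("both raters constant and identical; kappa = 1 by convention")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Per-category evaluation of predicted TSR against visual categories
#'
#' True TSR values live on the visual scoring grid {10, 20, ..., 90}
#' percent. For each category the table reports the mean, median, SEE
#' (against the category value), standard deviation and n of the predicted
#' TSR values; overall it reports the Pearson correlation, the overall SEE
#' across all slides, and Cohen's kappa of the stroma-high/low
#' dichotomization at `cutoff`.
#'
#' @param pred_tsr predicted TSR values in percent.
#' @param true_tsr true category values, each in {10, 20, ..., 90}.
#' @param cutoff dichotomization cutoff in percent (default 50).
#' @param sd_denominator `"n-1"` (conventional sample standard deviation,
#'   default) or `"n"`.
#' @return a `tsr_eval_table`: list with `by_category` (data frame), `r`,
#'   `see_overall`, `kappa`, `n`, `cutoff`.
#' @export
tsr_eval_table <- function(pred_tsr, true_tsr, cutoff = 50,
                           sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  stopifnot(length(pred_tsr) == length(true_tsr))
  grid <- seq(10, 90, by = 10)
  off <- which(!true_tsr %in% grid)
  if (length(off)) {
    stop(sprintf("true TSR value off the 10..90 grid at position %d: %s",
                 off[1], format(true_tsr[off[1]])))
  }
  cats <- grid[grid %in% true_tsr]
  by_cat <- do.call(rbind, lapply(cats, function(g) {
    v <- pred_tsr[true_tsr == g]
    s <- stats::sd(v)
    if (sd_denominator == "n" && length(v) > 1) {
      s <- s * sqrt((length(v) - 1) / length(v))
    }
    if (length(v) == 1L) s <- 0
    data.frame(true_tsr = g, mean = mean(v), median = stats::median(v),
               see = see(v, rep(g, length(v))), std = s, n = length(v))
  }))
  structure(list(
    by_category = by_cat,
    r = pearson_r(pred_tsr, true_tsr),
    see_overall = see(pred_tsr, true_tsr),
    kappa = cohens_kappa(dichotomize(pred_tsr, cutoff),
                         dichotomize(true_tsr, cutoff)),
    n = length(pred_tsr), cutoff = cutoff), class = "tsr_eval_table")
}

#' @export
print.tsr_eval_table <- function(x, ...) {
  cat(sprintf("<tsr_eval_table> n = %d, r = %.3f, overall SEE = %.1f, kappa = %.3f (cutoff %g%%)\n",
              x$n, x$r, x$see_overall, x$kappa, x$cutoff))
  print(x$by_category, row.names = FALSE)
  invisible(x)
}
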