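# Independent brute-force oracles and small fixture builders used across
# the suite. Everything here is deliberately naive (double loops, direct
# formulas) and shares no code path with the implementation it checks.

# exhaustive Otsu: maximize w0*w1*(mu0-mu1)^2 over all 255 splits
bf_otsu <- function(h) {
  n <- sum(h)
  best <- -Inf; best_t <- NA_integer_
  for (t in 0:254) {
    lo <- h[1:(t + 1)]; hi <- h[(t + 2):256]
    w0 <- sum(lo) / n; w1 <- sum(hi) / n
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum((0:t) * lo) / sum(lo)
    mu1 <- sum(((t + 1):255) * hi) / sum(hi)
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best + 1e-12) { best <- v; best_t <- t }
  }
  best_t
}

# naive window enumeration by double loop
bf_windows <- function(width, height, size, stride) {
  out <- list()
  for (y in seq.int(0L, max(height - size, 0L), by = stride)) {
    for (x in seq.int(0L, max(width - size, 0L), by = stride)) {
      if (x + size <= width && y + size <= height) {
        out[[length(out) + 1L]] <- c(x = x, y = y)
      }
    }
  }
  if (!length(out)) return(data.frame(x = integer(), y = integer()))
  as.data.frame(do.call(rbind, out))
}

# naive coverage + majority-label scan of a label matrix
bf_tile_scan <- function(lab, size, stride, threshold, mode = c("annotated", "mask"),
                         mask = NULL) {
  mode <- match.arg(mode)
  win <- bf_windows(ncol(lab), nrow(lab), size, stride)
  keep <- logical(nrow(win)); label <- character(nrow(win))
  for (i in seq_len(nrow(win))) {
    sub <- lab[(win$y[i] + 1):(win$y[i] + size), (win$x[i] + 1):(win$x[i] + size)]
    if (mode == "annotated") {
      cnt <- c(sum(sub == 1), sum(sub == 2), sum(sub == 3))
      keep[i] <- sum(cnt) / size^2 >= threshold
      label[i] <- c("tumor", "stroma", "other")[which.max(cnt)]
    } else {
      subm <- mask[(win$y[i] + 1):(win$y[i] + size), (win$x[i] + 1):(win$x[i] + size)]
      keep[i] <- sum(subm) / size^2 >= threshold
    }
  }
  cbind(win, keep = keep, label = label)
}

# direct-formula metric oracles from label pairs
bf_class_metrics <- function(true, pred, cl) {
  tp <- sum(true == cl & pred == cl)
  fp <- sum(true != cl & pred == cl)
  fn <- sum(true == cl & pred != cl)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  c(precision = p, recall = r,
    f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
}

# OD point cloud with near-pure pixels of each stain plus mixtures, the
# composition Macenko estimation assumes; returns an RGB image array
render_stain_cloud <- function(sm, n = 6000, cmax = c(1, 1), seed = 1) {
  withr::with_seed(seed, {
    ch <- c(runif(n * 0.3, 0, 1), runif(n * 0.2, 0, 0.05), runif(n * 0.5, 0.05, 1)) * cmax[1]
    ce <- c(runif(n * 0.3, 0, 0.05), runif(n * 0.2, 0, 1), runif(n * 0.5, 0.05, 1)) * cmax[2]
    od <- cbind(ch, ce) %*% t(sm$stain_matrix)
    array(255 * 10^(-od), c(60, length(ch) / 60, 3))
  })
}

# random plausible H&E stain model: default vectors perturbed in OD space
random_stain_model <- function(seed) {
  withr::with_seed(seed, {
    S <- default_stain_model()$stain_matrix
    repeat {
      P <- pmax(S + matrix(rnorm(6, 0, 0.08), 3, 2), 0)
      if (all(colSums(P) > 0) &&
          P[3, 1] / sqrt(sum(P[, 1]^2)) > P[3, 2] / sqrt(sum(P[, 2]^2)) + 0.02) break
    }
    stain_model(P)
  })
}

max_stain_angle <- function(a, b) {
  max(stain_angle(a$stain_matrix[, 1], b$stain_matrix[, 1]),
      stain_angle(a$stain_matrix[, 2], b$stain_matrix[, 2]))
}

# small annotated synthetic slide for pipeline tests; 1120 px gives a few
# dozen training windows per slide at the default 224/64 tiling
make_dev_slide <- function(seed, stroma_fraction = 0.5, width = 1120,
                           other_fraction = 0.25) {
  lay <- random_slide_layout(width, width, stroma_fraction = stroma_fraction,
                             other_fraction = other_fraction, seed = seed,
                             id = sprintf("dev-%d", seed))
  ms <- make_slide(lay)
  list(slide = ms$slide, annotation = ms$ground_truth$annotation,
       ground_truth = ms$ground_truth)
}
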