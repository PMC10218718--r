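#' Stain models for H&E optical-density decomposition
#'
#' A `stain_model` holds the two H&E stain vectors as unit-norm columns of a
#' 3 x 2 matrix in optical-density (OD) space (column 1 = hematoxylin,
#' column 2 = eosin) together with per-stain robust maximum concentrations
#' (99th percentile of solved concentrations, OD units). Under the
#' Beer-Lambert law a pixel's OD vector is the stain matrix times its
#' per-stain concentrations, which is what makes stain estimation a
#' plane-fitting problem in OD space.
#'
#' @param stain_matrix numeric 3 x 2 matrix; columns are normalized to unit
#'   Euclidean norm, entries must be non-negative.
#' @param max_concentrations length-2 positive numeric (hematoxylin, eosin).
#' @return A `stain_model`.
#' @export
stain_model <- function(stain_matrix, max_concentrations = c(1, 1)) {
  S <- as.matrix(stain_matrix)
  if (!all(dim(S) == c(3L, 2L))) stop("stain_matrix must be 3 x 2")
  if (any(S < -1e-8)) stop("stain vectors must be non-negative in OD space")
  S <- pmax(S, 0)
  nrm <- sqrt(colSums(S^2))
  if (any(nrm == 0)) stop("stain vectors must be nonzero")
  S <- sweep(S, 2, nrm, "/")
  if (abs(det(crossprod(S))) < 1e-12) stop("stain vectors must be linearly independent")
  stopifnot(length(max_concentrations) == 2L, all(max_concentrations > 0))
  structure(list(stain_matrix = S,
                 max_concentrations = as.numeric(max_concentrations)),
            class = "stain_model")
}

#' @rdname stain_model
#' @details `default_stain_model()` returns the widely used reference H&E OD
#'   vectors, H = (0.65, 0.70, 0.29) and E = (0.07, 0.99, 0.11) (normalized),
#'   with the customary reference maximum concentrations (1.9705, 1.0308).
#' @export
default_stain_model <- function() {
  stain_model(cbind(h = c(0.65, 0.70, 0.29), e = c(0.07, 0.99, 0.11)),
              max_concentrations = c(1.9705, 1.0308))
}

#' @export
print.stain_model <- function(x, ...) {
  cat("<stain_model>\n")
  m <- round(x$stain_matrix, 4)
  dimnames(m) <- list(c("R", "G", "B"), c("hematoxylin", "eosin"))
  print(m)
  cat("max concentrations:", round(x$max_concentrations, 4), "\n")
  invisible(x)
}

#' @rdname stain_model
#' @param x a `stain_model`.
#' @param path JSON file path.
#' @export
write_stain_model <- function(x, path) {
  stopifnot(inherits(x, "stain_model"))
  jsonlite::write_json(list(stain_matrix = x$stain_matrix,
                            max_concentrations = x$max_concentrations),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname stain_model
#' @export
read_stain_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  stain_model(matrix(unlist(j$stain_matrix), 3, 2), j$max_concentrations)
}

#' Angular distance between stain vectors
#'
#' @param u,v numeric 3-vectors.
#' @return angle in degrees between `u` and `v`.
#' @export
stain_angle <- function(u, v) {
  cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(clip(cs, -1, 1)) * 180 / pi
}

#' Optical-density transform and its inverse
#'
#' Converts transmitted intensities to optical densities,
#' `OD = -log10(I / I0)`, the space in which Beer-Lambert stain mixing is
#' linear. Intensities are clipped to a floor of 1 unit so the transform is
#' finite; `od_to_rgb` inverts it up to that clipping.
#'
#' @param image numeric array (any shape; typically `h x w x 3` RGB) with
#'   values in `(0, I0]`.
#' @param I0 incident (white) intensity, default 255.
#' @return `rgb_to_od`: an array of the same shape of non-negative optical
#'   densities with attribute `I0`; `od_to_rgb`: intensities in `[1, I0]`.
#' @export
rgb_to_od <- function(image, I0 = 255) {
  if (is.array(image) && length(dim(image)) == 3L && dim(image)[3] != 3L) {
    stop("expected an RGB image (third dimension of size 3)")
  }
  od <- -log10(clip(unclass(image), 1, I0) / I0)
  attr(od, "I0") <- I0
  od
}

#' @rdname rgb_to_od
#' @param od optical-density array produced by `rgb_to_od`.
#' @export
od_to_rgb <- function(od, I0 = attr(od, "I0") %||% 255) {
  clip(I0 * 10^(-unclass(od)), 1, I0)
}

# flatten an OD array to an N x 3 matrix of pixels
od_pixels <- function(od) {
  d <- dim(od)
  if (is.null(d) || length(d) == 2L && d[2] == 3L) return(as.matrix(od))
  if (length(d) == 3L && d[3] == 3L) return(matrix(od, prod(d[1:2]), 3L))
  stop("cannot interpret optical-density input of dimension ",
       paste(d, collapse = " x "))
}

#' Estimate the H&E stain matrix of an image (Macenko)
#'
#' Implements Macenko stain estimation: pixels with optical density below
#' `beta` in every channel are discarded as unstained; the remaining OD point
#' cloud is projected onto the plane of its two leading principal directions;
#' the extreme stain directions are read off as the `alpha` and `100 - alpha`
#' percentiles of the projection angle; the hematoxylin column is the vector
#' with the heavier blue-channel OD loading. Robust maximum concentrations
#' are the 99th percentile of the concentrations solved against the
#' estimated matrix.
#'
#' @param od OD image from [rgb_to_od()] (or an N x 3 OD pixel matrix).
#' @param alpha angle percentile (default 1, i.e. 1st/99th percentiles).
#' @param beta OD threshold below which a pixel counts as unstained
#'   (default 0.15).
#' @param min_pixels minimum number of pixels that must survive the `beta`
#'   filter; below this the image is considered blank.
#' @param on_degenerate what to do when the OD cloud is essentially rank-1
#'   (a single pure stain): `"error"` or `"duplicate"` (return the leading
#'   direction in both columns, flagged via attribute `degenerate`).
#' @return A [stain_model()].
#' @export
estimate_stain_matrix <- function(od, alpha = 1, beta = 0.15,
                                  min_pixels = 50,
                                  on_degenerate = c("error", "duplicate")) {
  on_degenerate <- match.arg(on_degenerate)
  X <- od_pixels(od)
  # stained pixel = OD above beta in at least one channel
  Xh <- X[X[, 1] > beta | X[, 2] > beta | X[, 3] > beta, , drop = FALSE]
  if (nrow(Xh) < min_pixels) {
    stop(errorCondition(
      sprintf("insufficient tissue: %d stained pixels (need >= %d)",
              nrow(Xh), min_pixels),
      class = c("tsr_insufficient_tissue", "error")))
  }
  # leading plane of the (uncentered) OD cloud
  ev <- eigen(crossprod(Xh) / nrow(Xh), symmetric = TRUE)
  if (ev$values[2] < 1e-8 * max(ev$values[1], 1e-12)) {
    if (on_degenerate == "error") {
      stop(errorCondition("degenerate OD cloud: single stain (rank-1)",
                          class = c("tsr_single_stain", "error")))
    }
    v <- ev$vectors[, 1]
    if (sum(v) < 0) v <- -v
    S <- cbind(pmax(v, 0), pmax(v, 0))
    S[3, 2] <- S[3, 2] * 0.99  # nudge so columns are not exactly collinear
    sm <- stain_model(S, c(1, 1))
    attr(sm, "degenerate") <- TRUE
    return(sm)
  }
  V <- ev$vectors[, 1:2]
  # orient the basis so projections land in a consistent half-plane
  if (sum(V[, 1]) < 0) V[, 1] <- -V[, 1]
  proj <- Xh %*% V
  phi <- atan2(proj[, 2], proj[, 1])
  q <- stats::quantile(phi, c(alpha, 100 - alpha) / 100, names = FALSE)
  v1 <- V %*% c(cos(q[1]), sin(q[1]))
  v2 <- V %*% c(cos(q[2]), sin(q[2]))
  fix <- function(v) { if (sum(v) < 0) v <- -v; pmax(v, 0) }
  v1 <- fix(drop(v1)); v2 <- fix(drop(v2))
  # hematoxylin = the more blue-heavy OD vector; tie -> first principal angle
  S <- if (v1[3] / sqrt(sum(v1^2)) >= v2[3] / sqrt(sum(v2^2))) cbind(v1, v2) else cbind(v2, v1)
  sm <- stain_model(S, c(1, 1))
  conc <- solve_concentrations(X, sm)
  mx <- apply(conc, 2L, stats::quantile, probs = 0.99, names = FALSE)
  mx[mx <= 0] <- 1e-6
  sm$max_concentrations <- mx
  sm
}

#' Solve per-pixel stain concentrations
#'
#' Decomposes OD pixels into hematoxylin/eosin concentrations against a
#' stain model. The fast path is unconstrained least squares with negative
#' concentrations clipped to zero; `nonneg = TRUE` computes the exact
#' non-negative least-squares solution (closed form for two stains).
#'
#' @param od OD image or N x 3 OD pixel matrix.
#' @param model a [stain_model()].
#' @param nonneg use the exact non-negative solve.
#' @return N x 2 matrix of concentrations (columns hematoxylin, eosin).
#' @export
solve_concentrations <- function(od, model, nonneg = FALSE) {
  X <- od_pixels(od)
  S <- model$stain_matrix
  G <- crossprod(S)            # 2 x 2 Gram matrix
  C <- X %*% S %*% solve(G)    # unconstrained LS
  if (!nonneg) {
    C[C < 0] <- 0
    colnames(C) <- c("h", "e")
    return(C)
  }
  bad <- which(C[, 1] < 0 | C[, 2] < 0)
  if (length(bad)) {
    Xb <- X[bad, , drop = FALSE]
    # candidate single-stain fits on each edge of the feasible quadrant
    c1 <- pmax(Xb %*% S[, 1] / G[1, 1], 0)
    c2 <- pmax(Xb %*% S[, 2] / G[2, 2], 0)
    r1 <- rowSums((Xb - tcrossprod(c1, S[, 1]))^2)
    r2 <- rowSums((Xb - tcrossprod(c2, S[, 2]))^2)
    use1 <- r1 <= r2
    C[bad, 1] <- ifelse(use1, c1, 0)
    C[bad, 2] <- ifelse(use1, 0, c2)
  }
  colnames(C) <- c("h", "e")
  C
}

#' Macenko-normalize a patch to a reference stain model
#'
#' Estimates the patch's own stain matrix, solves its concentration maps,
#' rescales each stain's concentrations by the ratio of reference to source
#' robust maxima, and re-renders the patch through the reference stain
#' matrix. This collapses slide-to-slide stain variation onto one reference
#' appearance.
#'
#' @param patch RGB array (`h x w x 3`, intensities in `[0, I0]`).
#' @param reference reference [stain_model()].
#' @param alpha,beta Macenko parameters, see [estimate_stain_matrix()].
#' @param I0 white intensity (default 255).
#' @param nonneg exact non-negative concentration solve (slower).
#' @param fallback what to do when the patch has too little stained tissue
#'   to estimate stains: `"error"` propagates the condition,
#'   `"passthrough"` returns the patch unchanged with a warning.
#' @return normalized RGB array of the same shape.
#' @export
normalize_patch <- function(patch, reference = default_stain_model(),
                            alpha = 1, beta = 0.15, I0 = 255,
                            nonneg = FALSE,
                            fallback = c("error", "passthrough")) {
  fallback <- match.arg(fallback)
  d <- dim(patch)
  if (length(d) != 3L || d[3] != 3L) stop("patch must be an RGB array")
  od <- rgb_to_od(patch, I0 = I0)
  src <- tryCatch(estimate_stain_matrix(od, alpha = alpha, beta = beta),
                  tsr_insufficient_tissue = function(e) e,
                  tsr_single_stain = function(e) e)
  if (inherits(src, "error")) {
    if (fallback == "passthrough") {
      warning("stain normalization fell back to pass-through: ",
              conditionMessage(src))
      return(patch)
    }
    stop(src)
  }
  conc <- solve_concentrations(od, src, nonneg = nonneg)
  conc <- sweep(conc, 2L,
                reference$max_concentrations / src$max_concentrations, "*")
  od_new <- array(tcrossprod(conc, reference$stain_matrix), dim = d)
  out <- array(od_to_rgb(od_new, I0 = I0), dim = d)
  attributes(out)$dim <- d
  out
}
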