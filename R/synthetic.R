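#' Texture parameters for synthetic H&E tissue
#'
#' Controls the per-class appearance of synthetic slides. Each tissue class
#' gets hematoxylin/eosin concentration ranges (OD units) plus a
#' class-specific texture: tumor is rendered as dense hyperchromatic nuclear
#' blobs, stroma as oriented eosinophilic fibers, *other* as a smooth
#' heterogeneous mixture whose within-class variability is set by `mix`
#' (how uniform the *other* class is per slide is deliberately tunable).
#' Background and adipose are near-white (tiny concentrations) so a single
#' saturation-based Otsu mask removes both.
#'
#' @param tumor,stroma,other,adipose,background per-class parameter lists;
#'   any field supplied overrides the default.
#' @param noise_sd additive concentration noise (OD units), applied to every
#'   tissue pixel.
#' @return A `texture_params` object (nested list).
#' @export
texture_params <- function(tumor = list(), stroma = list(), other = list(),
                           adipose = list(), background = list(),
                           noise_sd = 0.03) {
  def <- list(
    tumor = list(h = c(0.65, 1.00), e = c(0.02, 0.42),
                 nuclear_density = 0.40, blob_radius = 6),
    stroma = list(h = c(0.02, 0.30), e = c(0.60, 0.95),
                  fiber_wavelength = 24, fiber_contrast = 0.35,
                  nuclear_density = 0.05, blob_radius = 4,
                  nuclei_h = c(0.55, 0.90)),
    other = list(h = c(0.35, 0.65), e = c(0.35, 0.65), mix = 48,
                 nuclear_density = 0.10, blob_radius = 4,
                 nuclei_h = c(0.55, 0.90)),
    adipose = list(h = c(0.002, 0.008), e = c(0.002, 0.010)),
    background = list(h = c(0.001, 0.004), e = c(0.001, 0.005))
  )
  tp <- def
  for (cl in names(def)) {
    ov <- get(cl)
    for (f in names(ov)) tp[[cl]][[f]] <- ov[[f]]
    if (any(unlist(tp[[cl]][c("h", "e")]) < 0)) {
      stop("concentration ranges must be non-negative")
    }
  }
  tp$noise_sd <- noise_sd
  structure(tp, class = "texture_params")
}

#' Synthetic slide layouts
#'
#' A layout is a canvas size plus an ordered list of regions painted onto a
#' background canvas; every pixel ends up with exactly one class. Region
#' specs: `list(class=, shape="rect", x0=, y0=, x1=, y1=)` (1-based,
#' inclusive), `list(class=, shape="disk", cx=, cy=, r=)`, or
#' `list(class=, shape="voronoi", n_seeds=, weights=c(tumor=, stroma=,
#' other=), x0=, y0=, x1=, y1=)` which fills the rectangle with Voronoi
#' cells whose classes are drawn from `weights`.
#'
#' @param width,height canvas size in pixels.
#' @param regions ordered list of region specs (see Details).
#' @param mpp microns per pixel (default 0.5, the resolution the pipeline
#'   assumes).
#' @param seed integer seed; all randomness in rendering this layout flows
#'   from it.
#' @param id slide identifier.
#' @return A `synth_layout`.
#' @export
synth_layout <- function(width, height, regions, mpp = 0.5, seed = 1L,
                         id = sprintf("synth-%d", seed)) {
  stopifnot(width >= 1, height >= 1, length(regions) >= 0)
  ok <- c("tumor", "stroma", "other", "adipose", "background")
  for (r in regions) {
    if (!r$class %in% ok) stop("unknown region class: ", r$class)
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 regions = regions, mpp = mpp, seed = as.integer(seed),
                 id = id),
            class = "synth_layout")
}

#' @rdname synth_layout
#' @param classes two classes for the left and right half.
#' @export
two_band_layout <- function(width, height, classes = c("tumor", "stroma"),
                            mpp = 0.5, seed = 1L,
                            id = sprintf("bands-%d", seed)) {
  half <- floor(width / 2)
  synth_layout(width, height, list(
    list(class = classes[1], shape = "rect", x0 = 1, y0 = 1, x1 = half, y1 = height),
    list(class = classes[2], shape = "rect", x0 = half + 1, y0 = 1, x1 = width, y1 = height)
  ), mpp = mpp, seed = seed, id = id)
}

#' @rdname synth_layout
#' @param stroma_fraction target stroma share among tumor + stroma tissue
#'   (the layout's nominal TSR; the exact patch-count TSR is computed from
#'   the rendered label map).
#' @param other_fraction share of Voronoi cells assigned to class *other*.
#' @param n_seeds number of Voronoi cells in the tissue area; the default
#'   (`NULL`) targets a mean cell diameter of about two patch widths so
#'   most windows are single-class, as tumor/stroma compartments are at
#'   this scale.
#' @param border white background margin (pixels) around the tissue.
#' @param n_adipose number of near-white adipose disks dropped on the tissue.
#' @export
random_slide_layout <- function(width, height, stroma_fraction,
                                other_fraction = 0.15, n_seeds = NULL,
                                border = 128, n_adipose = 3,
                                mpp = 0.5, seed = 1L,
                                id = sprintf("cohort-%d", seed)) {
  stopifnot(stroma_fraction >= 0, stroma_fraction <= 1)
  if (is.null(n_seeds)) {
    interior <- (width - 2 * border) * (height - 2 * border)
    n_seeds <- max(4L, as.integer(round(interior / 448^2)))
  }
  p_other <- other_fraction
  w <- c(tumor = (1 - p_other) * (1 - stroma_fraction),
         stroma = (1 - p_other) * stroma_fraction,
         other = p_other)
  regions <- list(list(class = "stroma", shape = "voronoi", n_seeds = n_seeds,
                       weights = w,
                       x0 = border + 1, y0 = border + 1,
                       x1 = width - border, y1 = height - border))
  if (n_adipose > 0) {
    rad <- round(min(width, height) / 14)
    ad <- with_seed(derive_seed(seed, "adipose"), {
      data.frame(cx = round(stats::runif(n_adipose, border + rad, width - border - rad)),
                 cy = round(stats::runif(n_adipose, border + rad, height - border - rad)),
                 r = round(stats::runif(n_adipose, rad / 2, rad)))
    })
    for (i in seq_len(n_adipose)) {
      regions[[length(regions) + 1L]] <-
        list(class = "adipose", shape = "disk",
             cx = ad$cx[i], cy = ad$cy[i], r = ad$r[i])
    }
  }
  synth_layout(width, height, regions, mpp = mpp, seed = seed, id = id)
}

#' Rasterize a layout into a label matrix
#'
#' @param layout a [synth_layout()].
#' @return integer `height x width` matrix with codes 0 = background,
#'   1 = tumor, 2 = stroma, 3 = other, 4 = adipose.
#' @export
layout_labels <- function(layout) {
  h <- layout$height; w <- layout$width
  lab <- matrix(0L, h, w)
  code <- c(background = 0L, tumor = 1L, stroma = 2L, other = 3L, adipose = 4L)
  for (ri in seq_along(layout$regions)) {
    r <- layout$regions[[ri]]
    cl <- code[[r$class]]
    if (r$shape == "rect") {
      lab[r$y0:r$y1, r$x0:r$x1] <- cl
    } else if (r$shape == "disk") {
      ys <- max(1, r$cy - r$r):min(h, r$cy + r$r)
      xs <- max(1, r$cx - r$r):min(w, r$cx + r$r)
      dy <- outer(ys - r$cy, rep(1, length(xs)))
      dx <- outer(rep(1, length(ys)), xs - r$cx)
      sub <- lab[ys, xs]
      sub[dy^2 + dx^2 <= r$r^2] <- cl
      lab[ys, xs] <- sub
    } else if (r$shape == "voronoi") {
      lab <- voronoi_fill(lab, r, layout$seed, ri)
    } else stop("unknown region shape: ", r$shape)
  }
  lab
}

# Fill a rectangle with Voronoi cells whose classes are drawn from weights.
voronoi_fill <- function(lab, r, seed, region_index) {
  with_seed(derive_seed(seed, paste0("voronoi-", region_index)), {
    k <- r$n_seeds
    sx <- stats::runif(k, r$x0, r$x1)
    sy <- stats::runif(k, r$y0, r$y1)
    w <- r$weights[c("tumor", "stroma", "other")]
    w[is.na(w)] <- 0
    cls <- sample(c(1L, 2L, 3L), k, replace = TRUE, prob = w)
    xs <- r$x0:r$x1; ys <- r$y0:r$y1
    px <- rep(xs, each = length(ys))
    py <- rep(ys, times = length(xs))
    best_d <- rep(Inf, length(px)); best_i <- rep(1L, length(px))
    for (i in seq_len(k)) {
      d <- (px - sx[i])^2 + (py - sy[i])^2
      upd <- d < best_d
      best_d[upd] <- d[upd]; best_i[upd] <- i
    }
    lab[ys, xs] <- matrix(cls[best_i], length(ys), length(xs))
    lab
  })
}

# --- texture field generation (all RNG is the caller's responsibility) ----

box_blur <- function(m, r) {
  if (r < 1) return(m)
  P <- integral_image(m)
  h <- nrow(m); w <- ncol(m)
  y1 <- pmax(seq_len(h) - r, 1L); y2 <- pmin(seq_len(h) + r, h)
  x1 <- pmax(seq_len(w) - r, 1L); x2 <- pmin(seq_len(w) + r, w)
  A <- P[y2 + 1L, x2 + 1L, drop = FALSE] - P[y1, x2 + 1L, drop = FALSE] -
    P[y2 + 1L, x1, drop = FALSE] + P[y1, x1, drop = FALSE]
  area <- outer(y2 - y1 + 1L, x2 - x1 + 1L)
  A / area
}

smooth_noise <- function(h, w, scale) {
  z <- box_blur(matrix(stats::rnorm(h * w), h, w), max(1L, as.integer(scale)))
  (z - mean(z)) / max(stats::sd(z), 1e-12)
}

# Render one labeled patch (RNG is the caller's responsibility). A
# mixed_fraction share of patches get a secondary-class band along a
# random direction covering < max_secondary of the area: the admixture a
# 75% coverage filter with majority labels admits.
render_labeled_patch <- function(cl, textures, S, size, I0,
                                 mixed_fraction, max_secondary) {
  code <- c(tumor = 1L, stroma = 2L, other = 3L)
  lab <- matrix(code[[cl]], size, size)
  if (stats::runif(1) < mixed_fraction) {
    sec <- sample(c(setdiff(1:3, code[[cl]]), 0L), 1L)
    frac <- stats::runif(1, 0.05, max_secondary)
    theta <- stats::runif(1, 0, pi)
    proj <- outer(seq_len(size) * sin(theta), rep(1, size)) +
      outer(rep(1, size), seq_len(size) * cos(theta))
    lab[proj <= stats::quantile(proj, frac)] <- sec
  }
  conc <- render_concentrations(lab, textures)
  od <- cbind(as.vector(conc$h), as.vector(conc$e)) %*% t(S)
  list(pixels = array(I0 * 10^(-od), dim = c(size, size, 3L)),
       conc = conc, label = cl)
}

# Sparse nuclear speckle for non-tumor tissue classes.
overlay_nuclei <- function(ch, idx, p, h, w) {
  if (is.null(p$nuclear_density) || p$nuclear_density <= 0) return(ch)
  z <- smooth_noise(h, w, p$blob_radius)
  nuc <- z > stats::quantile(z, 1 - p$nuclear_density)
  sel <- idx[nuc[idx]]
  if (length(sel)) ch[sel] <- stats::runif(length(sel), p$nuclei_h[1], p$nuclei_h[2])
  ch
}

# Per-class H/E concentration fields for one canvas. Returns list(h=, e=).
render_concentrations <- function(lab, tp) {
  h <- nrow(lab); w <- ncol(lab)
  ch <- matrix(0, h, w); ce <- matrix(0, h, w)
  mid <- function(rg) mean(rg)
  amp <- function(rg) diff(rg) / 2
  classes <- list(tumor = 1L, stroma = 2L, other = 3L, adipose = 4L, background = 0L)
  for (cl in names(classes)) {
    idx <- which(lab == classes[[cl]])
    if (!length(idx)) next
    p <- tp[[cl]]
    if (cl == "tumor") {
      # nuclear speckle: thresholded smooth noise at the target density
      z <- smooth_noise(h, w, p$blob_radius)
      nuc <- z > stats::quantile(z, 1 - p$nuclear_density)
      ch[idx] <- mid(p$h) - amp(p$h) + 2 * amp(p$h) * nuc[idx]
      ce[idx] <- mid(p$e) + amp(p$e) * 0.5 * smooth_noise(h, w, 8)[idx]
    } else if (cl == "stroma") {
      # oriented collagen fibers: sinusoid along a random direction, plus
      # sparse fibroblast nuclei that anchor the hematoxylin scale
      theta <- stats::runif(1, 0, pi)
      gx <- outer(rep(1, h), seq_len(w)); gy <- outer(seq_len(h), rep(1, w))
      phase <- 2 * pi * (gx * cos(theta) + gy * sin(theta)) / p$fiber_wavelength
      fib <- sin(phase + 2 * smooth_noise(h, w, 16))
      ce[idx] <- mid(p$e) + amp(p$e) * p$fiber_contrast * 2 * fib[idx]
      ch[idx] <- mid(p$h) + amp(p$h) * 0.5 * smooth_noise(h, w, 6)[idx]
      ch <- overlay_nuclei(ch, idx, p, h, w)
    } else if (cl == "other") {
      # heterogeneous mixture; `mix` is the correlation length in px;
      # scattered nuclei (lymphocytes, epithelium) on top
      z1 <- smooth_noise(h, w, p$mix); z2 <- smooth_noise(h, w, p$mix / 3)
      ch[idx] <- mid(p$h) + amp(p$h) * 0.7 * z1[idx]
      ce[idx] <- mid(p$e) + amp(p$e) * 0.7 * (0.5 * z1[idx] + 0.5 * z2[idx])
      ch <- overlay_nuclei(ch, idx, p, h, w)
    } else {  # adipose / background: near-white
      ch[idx] <- stats::runif(length(idx), p$h[1], p$h[2])
      ce[idx] <- stats::runif(length(idx), p$e[1], p$e[2])
    }
  }
  tissue <- lab %in% 1:3
  if (tp$noise_sd > 0 && any(tissue)) {
    n <- sum(tissue)
    ch[tissue] <- ch[tissue] + stats::rnorm(n, 0, tp$noise_sd)
    ce[tissue] <- ce[tissue] + stats::rnorm(n, 0, tp$noise_sd)
  }
  list(h = pmax(ch, 0), e = pmax(ce, 0))
}

#' Render a synthetic H&E slide with exact ground truth
#'
#' Renders per-class hematoxylin/eosin concentration fields for the layout's
#' label map and converts them to RGB by Beer-Lambert stain mixing,
#' `I = I0 * 10^(-S c)` per pixel with `S` the stain matrix. The returned
#' ground truth carries the exact annotation map, per-class pixel areas, the
#' generating stain model, per-class mean concentrations, and the expected
#' patch-count TSR under the inference tiling parameters (non-overlapping
#' grid, coverage threshold) alongside the pixel-area TSR — the two differ
#' at region boundaries, so both are reported.
#'
#' @param layout a [synth_layout()]; the canvas must fit at least one patch.
#' @param textures a [texture_params()].
#' @param stains generating [stain_model()].
#' @param I0 white intensity (default 255).
#' @param patch_size patch size used for the sizing check and the expected
#'   patch-count TSR (default 224).
#' @param min_coverage tissue-coverage threshold for the expected
#'   patch-count TSR (default 0.75).
#' @param keep_concentrations retain the full concentration fields in the
#'   ground truth (memory-heavy; useful for forward-model checks).
#' @return list with elements `slide` (a [slide_image()]) and
#'   `ground_truth` (class `tsr_ground_truth`).
#' @export
make_slide <- function(layout, textures = texture_params(),
                       stains = default_stain_model(), I0 = 255,
                       patch_size = 224, min_coverage = 0.75,
                       keep_concentrations = FALSE) {
  stopifnot(inherits(layout, "synth_layout"))
  if (layout$width < patch_size || layout$height < patch_size) {
    stop(sprintf("canvas %d x %d is smaller than one %d px patch",
                 layout$width, layout$height, patch_size))
  }
  lab <- layout_labels(layout)
  conc <- with_seed(derive_seed(layout$seed, "textures"),
                    render_concentrations(lab, textures))
  S <- stains$stain_matrix
  n <- length(lab)
  od_flat <- cbind(conc$h[seq_len(n)], conc$e[seq_len(n)]) %*% t(S)
  rgb <- array(I0 * 10^(-od_flat), dim = c(nrow(lab), ncol(lab), 3L))
  slide <- slide_image(rgb, mpp = layout$mpp, id = layout$id)

  areas <- vapply(0:4, function(k) sum(lab == k), 0L)
  names(areas) <- c("background", "tumor", "stroma", "other", "adipose")
  cmeans <- lapply(stats::setNames(0:4, names(areas)), function(k) {
    idx <- lab == k
    if (!any(idx)) return(c(h = NA_real_, e = NA_real_))
    c(h = mean(conc$h[idx]), e = mean(conc$e[idx]))
  })
  gt <- structure(list(
    annotation = annotation_map(lab, id = layout$id),
    areas = areas,
    stain_model = stains,
    class_concentration_means = cmeans,
    tsr_patch = ground_truth_tsr(lab, size = patch_size,
                                 min_coverage = min_coverage),
    tsr_pixel = if (areas["tumor"] + areas["stroma"] > 0) {
      unname(areas["stroma"] / (areas["tumor"] + areas["stroma"]))
    } else NA_real_,
    tiling = list(size = patch_size, stride = patch_size,
                  min_coverage = min_coverage),
    concentrations = if (keep_concentrations) conc else NULL
  ), class = "tsr_ground_truth")
  list(slide = slide, ground_truth = gt)
}

#' Expected patch-count TSR of a label map
#'
#' Oracle tiling of an annotation label map: non-overlapping windows of
#' `size`, kept when the annotated-tissue fraction (classes tumor, stroma,
#' other) reaches `min_coverage`, each labeled by its majority annotated
#' class (ties broken tumor > stroma > other), and the TSR computed from the
#' resulting patch counts.
#'
#' @param annotation an [annotation_map()] or integer label matrix.
#' @param size window size (default 224); the stride equals `size`.
#' @param min_coverage inclusive coverage threshold (default 0.75).
#' @return list with `n_tumor`, `n_stroma`, `n_other`, `n_windows`, `tsr`
#'   (fraction, `NA` if no tumor or stroma windows).
#' @export
ground_truth_tsr <- function(annotation, size = 224, min_coverage = 0.75) {
  lab <- as.matrix(unclass(annotation))
  win <- enumerate_windows(ncol(lab), nrow(lab), size = size, stride = size)
  if (nrow(win) == 0L) {
    return(list(n_tumor = 0L, n_stroma = 0L, n_other = 0L, n_windows = 0L,
                tsr = NA_real_))
  }
  cnt <- sapply(1:3, function(k) {
    window_sum(integral_image(lab == k), win$x, win$y, size)
  })
  cnt <- matrix(cnt, nrow = nrow(win))
  keep <- rowSums(cnt) / size^2 >= min_coverage
  cnt <- cnt[keep, , drop = FALSE]
  maj <- max.col(cnt, ties.method = "first")  # tumor > stroma > other
  n <- tabulate(maj, 3L)
  list(n_tumor = n[1], n_stroma = n[2], n_other = n[3],
       n_windows = sum(keep),
       tsr = if (n[1] + n[2] > 0) n[2] / (n[1] + n[2]) else NA_real_)
}

#' Generate a class-balanced labeled patch dataset
#'
#' Renders `n_per_class` labeled patches for each of tumor, stroma and
#' *other*, emulating a class-balanced training corpus tiled from annotated
#' slides: most patches are a pure-class canvas, while a fraction
#' (`mixed_fraction`) carry a secondary-class region covering up to
#' `max_secondary` of the area — the composition an annotation-coverage
#' filter at 75% with majority labeling admits. Labels are always the
#' majority class. Deterministic for a fixed seed; the concentration fields
#' depend only on the seed and textures, not on the stain model.
#'
#' @param n_per_class patches per class (>= 1).
#' @param textures a [texture_params()].
#' @param stains generating [stain_model()].
#' @param seed integer seed.
#' @param size patch edge in pixels (default 224).
#' @param I0 white intensity.
#' @param mixed_fraction share of patches given a secondary-class region
#'   (default 0.3).
#' @param max_secondary maximum area fraction of the secondary region
#'   (default 0.25, the complement of the 75% coverage filter).
#' @param keep_concentrations attach the per-patch concentration fields
#'   (list `concentrations` parallel to `pixels`).
#' @return a labeled [patch_set()].
#' @export
make_patch_dataset <- function(n_per_class, textures = texture_params(),
                               stains = default_stain_model(), seed = 1L,
                               size = 224, I0 = 255,
                               mixed_fraction = 0.3, max_secondary = 0.25,
                               keep_concentrations = FALSE) {
  stopifnot(is.numeric(n_per_class), n_per_class >= 1,
            mixed_fraction >= 0, mixed_fraction <= 1,
            max_secondary >= 0, max_secondary < 0.5)
  n_per_class <- as.integer(n_per_class)
  S <- stains$stain_matrix
  pixels <- vector("list", 3L * n_per_class)
  concs <- if (keep_concentrations) vector("list", 3L * n_per_class) else NULL
  labels <- character(3L * n_per_class)
  with_seed(seed, {
    i <- 0L
    for (cl in TSR_CLASSES) {
      for (j in seq_len(n_per_class)) {
        i <- i + 1L
        p <- render_labeled_patch(cl, textures, S, size, I0,
                                  mixed_fraction, max_secondary)
        pixels[[i]] <- p$pixels
        if (keep_concentrations) concs[[i]] <- p$conc
        labels[i] <- cl
      }
    }
  })
  windows <- data.frame(slide_id = sprintf("synthpatch-%d-%04d", seed,
                                           seq_len(3L * n_per_class)),
                        x = 0L, y = 0L, size = size)
  ps <- patch_set(pixels, windows, labels,
                  params = list(seed = seed, size = size, source = "synthetic"))
  if (keep_concentrations) ps$concentrations <- concs
  ps
}

#' Generate a source/target domain pair of patch datasets
#'
#' Builds two class-balanced patch datasets under different texture and/or
#' stain parameters, giving a controlled domain shift (as between an
#' external public patch corpus and an in-house cohort) for exercising the
#' domain pre-training setups.
#'
#' @param textures_a,textures_b per-domain [texture_params()].
#' @param stains_a,stains_b per-domain [stain_model()]s.
#' @param n_per_class patches per class in each domain.
#' @param seed integer seed (domain B uses a derived sub-seed).
#' @param size patch edge in pixels.
#' @param min_color_shift floor (intensity units) on the mean per-channel
#'   color difference between domains; a shift below it is reported with a
#'   warning.
#' @return list with elements `a` and `b` (labeled [patch_set()]s) and
#'   `color_shift` (mean per-channel absolute difference of domain mean
#'   colors).
#' @export
make_domain_pair <- function(textures_a = texture_params(),
                             textures_b = texture_params(),
                             stains_a = default_stain_model(),
                             stains_b = default_stain_model(),
                             n_per_class = 50, seed = 1L, size = 224,
                             min_color_shift = 2) {
  stopifnot(n_per_class >= 1)
  if (identical(unclass(textures_a), unclass(textures_b)) &&
      identical(stains_a$stain_matrix, stains_b$stain_matrix) &&
      identical(stains_a$max_concentrations, stains_b$max_concentrations)) {
    warning("domain pair generated from identical parameter sets; no shift")
  }
  a <- make_patch_dataset(n_per_class, textures_a, stains_a,
                          seed = derive_seed(seed, "domain-a"), size = size)
  b <- make_patch_dataset(n_per_class, textures_b, stains_b,
                          seed = derive_seed(seed, "domain-b"), size = size)
  mean_color <- function(ps) {
    Reduce(`+`, lapply(ps$pixels, function(p) apply(p, 3L, mean))) / n_patches(ps)
  }
  shift <- mean(abs(mean_color(a) - mean_color(b)))
  if (shift < min_color_shift) {
    warning(sprintf("domain color shift %.2f below floor %.2f", shift,
                    min_color_shift))
  }
  list(a = a, b = b, color_shift = shift)
}

#' Rotate a stain model's vectors within their plane
#'
#' Utility for constructing shifted stain domains: rotates both stain
#' vectors by `degrees` within the plane they span (negative entries are
#' clipped and columns renormalized, so very large rotations saturate).
#'
#' @param model a [stain_model()].
#' @param degrees rotation angle.
#' @return a [stain_model()].
#' @export
rotate_stain_model <- function(model, degrees) {
  S <- model$stain_matrix
  # orthonormal basis of the stain plane
  q <- qr.Q(qr(S))
  co <- cos(degrees * pi / 180); si <- sin(degrees * pi / 180)
  R <- matrix(c(co, si, -si, co), 2, 2)
  S2 <- q %*% R %*% crossprod(q, S)
  stain_model(pmax(S2, 0), model$max_concentrations)
}
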