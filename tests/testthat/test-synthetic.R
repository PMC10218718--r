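test_that("a pure background canvas renders near-white everywhere", {
  lay <- synth_layout(256, 256, regions = list(), seed = 2, id = "bg")
  ms <- make_slide(lay, patch_size = 224)
  expect_true(all(unclass(ms$slide) >= 0.85 * 255))
  expect_equal(unname(ms$ground_truth$areas["background"]), 256L * 256L)
  expect_equal(sum(ms$ground_truth$areas), 256L * 256L)
})

test_that("half tumor / half stroma slide has expected patch-count TSR 0.5", {
  lay <- two_band_layout(448, 448, c("tumor", "stroma"), seed = 3)
  ms <- make_slide(lay, patch_size = 224)
  expect_equal(ms$ground_truth$tsr_patch$tsr, 0.5)
  expect_equal(ms$ground_truth$tsr_patch$n_windows, 4)
  expect_equal(ms$ground_truth$tsr_pixel, 0.5)
})

test_that("rendered image satisfies the Beer-Lambert forward model exactly", {
  lay <- random_slide_layout(480, 480, stroma_fraction = 0.5, border = 48,
                             seed = 5, n_seeds = 6)
  ms <- make_slide(lay, keep_concentrations = TRUE, patch_size = 224)
  S <- ms$ground_truth$stain_model$stain_matrix
  lab <- unclass(ms$ground_truth$annotation)
  od <- rgb_to_od(ms$slide)
  conc <- ms$ground_truth$concentrations
  for (k in 1:3) {
    idx <- lab == k
    mean_od <- c(mean(od[, , 1][idx]), mean(od[, , 2][idx]), mean(od[, , 3][idx]))
    want <- as.vector(S %*% c(mean(conc$h[idx]), mean(conc$e[idx])))
    expect_equal(mean_od, want, tolerance = 1e-6)
    # and the stored per-class means agree
    expect_equal(unname(ms$ground_truth$class_concentration_means[[k + 1]]),
                 c(mean(conc$h[idx]), mean(conc$e[idx])))
  }
})

test_that("ground-truth label map matches the generating regions exactly", {
  lay <- random_slide_layout(480, 480, stroma_fraction = 0.3, border = 48,
                             seed = 6, n_seeds = 8)
  ms <- make_slide(lay, patch_size = 224)
  expect_equal(unclass(ms$ground_truth$annotation), layout_labels(lay),
               ignore_attr = TRUE)
  # every pixel has exactly one class and areas partition the canvas
  expect_equal(sum(ms$ground_truth$areas), 480L * 480L)
})

test_that("expected patch TSR equals an independent brute-force tiling", {
  for (i in 1:5) {
    sf <- withr::with_seed(600 + i, runif(1, 0.1, 0.9))
    lay <- random_slide_layout(560, 560, stroma_fraction = sf, border = 48,
                               seed = 600 + i)
    ms <- make_slide(lay, patch_size = 224)
    lab <- unclass(ms$ground_truth$annotation)
    bf <- bf_tile_scan(lab, size = 224, stride = 224, threshold = 0.75)
    kept <- bf[bf$keep, ]
    n_t <- sum(kept$label == "tumor"); n_s <- sum(kept$label == "stroma")
    gt <- ms$ground_truth$tsr_patch
    expect_identical(gt$n_tumor, n_t)
    expect_identical(gt$n_stroma, n_s)
    expect_identical(gt$n_windows, nrow(kept))
    if (n_t + n_s > 0) expect_identical(gt$tsr, n_s / (n_t + n_s))
  }
})

test_that("undersized canvases are rejected with a sizing error", {
  lay <- synth_layout(100, 100, regions = list(), seed = 1)
  expect_error(make_slide(lay, patch_size = 224), "smaller than one")
})

test_that("patch datasets are class-balanced and deterministic", {
  ps <- make_patch_dataset(10, seed = 21, size = 64)
  expect_equal(n_patches(ps), 30)
  expect_equal(unname(table(ps$labels)), rep(10L, 3), ignore_attr = TRUE)
  expect_true(all(vapply(ps$pixels, function(p) all(dim(p) == c(64, 64, 3)), TRUE)))
  ps2 <- make_patch_dataset(10, seed = 21, size = 64)
  expect_identical(ps, ps2)
  expect_error(make_patch_dataset(0), "n_per_class")
})

test_that("stain model changes RGB but not the concentration fields", {
  alt <- rotate_stain_model(default_stain_model(), 10)
  a <- make_patch_dataset(3, stains = default_stain_model(), seed = 9,
                          size = 64, keep_concentrations = TRUE)
  b <- make_patch_dataset(3, stains = alt, seed = 9, size = 64,
                          keep_concentrations = TRUE)
  expect_identical(a$concentrations, b$concentrations)
  expect_false(identical(a$pixels, b$pixels))
})

test_that("streamed patch features equal the materialized-corpus path", {
  ref <- default_stain_model()
  st <- stream_patch_features(4, seed = 27, size = 96, reference = ref)
  ps <- normalize_patch_set(make_patch_dataset(4, seed = 27, size = 96), ref)
  expect_equal(st$X, extract_features(ps, reference = ref),
               ignore_attr = TRUE)
  expect_equal(as.character(st$y), as.character(ps$labels))
  # lazy cohorts carry the same ground truth and render the same slides
  eager <- make_cohort(2, width = 672, height = 672, seed = 28,
                       categories = c(30, 70))
  lazy <- make_cohort(2, width = 672, height = 672, seed = 28,
                      categories = c(30, 70), lazy = TRUE)
  expect_equal(lazy$true_patch_tsr, eager$true_patch_tsr)
  expect_equal(lazy$ground_truth[[1]]$areas, eager$ground_truth[[1]]$areas)
  expect_equal(unclass(lazy$slides[[1]]()), unclass(eager$slides[[1]]),
               ignore_attr = TRUE)
})

test_that("domain pairs carry a measurable, estimable stain shift", {
  ref <- default_stain_model()
  rot <- rotate_stain_model(ref, 10)
  dp <- make_domain_pair(stains_a = ref, stains_b = rot, n_per_class = 8,
                         size = 96, seed = 4)
  expect_equal(n_patches(dp$a), 24); expect_equal(n_patches(dp$b), 24)
  pool_od <- function(ps) do.call(rbind, lapply(ps$pixels, function(p) {
    matrix(rgb_to_od(p), ncol = 3)
  }))
  ea <- estimate_stain_matrix(pool_od(dp$a))
  eb <- estimate_stain_matrix(pool_od(dp$b))
  ang <- mean(c(stain_angle(ea$stain_matrix[, 1], eb$stain_matrix[, 1]),
                stain_angle(ea$stain_matrix[, 2], eb$stain_matrix[, 2])))
  expect_gt(ang, 6); expect_lt(ang, 14)
  expect_error(make_domain_pair(n_per_class = 0), "n_per_class")
  expect_warning(make_domain_pair(n_per_class = 2, size = 64,
                                  min_color_shift = 0), "identical")
})

test_that("a classifier trained on one domain degrades on a shifted domain", {
  ref <- default_stain_model()
  shifted_tex <- texture_params(stroma = list(e = c(0.40, 0.70)),
                                other = list(h = c(0.45, 0.75)),
                                noise_sd = 0.06)
  dp <- make_domain_pair(textures_b = shifted_tex,
                         stains_b = rotate_stain_model(ref, 12),
                         n_per_class = 40, size = 96, seed = 14)
  cfg <- train_config(seed = 14, epochs = 20)
  idx_tr <- withr::with_seed(14, sample(n_patches(dp$a), 90))
  train_a <- tsrslide:::patch_subset(dp$a, idx_tr)
  held_a <- tsrslide:::patch_subset(dp$a, setdiff(seq_len(n_patches(dp$a)), idx_tr))
  model <- run_setup("SETUP2", NULL, train_a, config = cfg)
  acc_a <- mean(predict(model, held_a, type = "class") == held_a$labels)
  acc_b <- mean(predict(model, dp$b, type = "class") == dp$b$labels)
  expect_lt(acc_b, acc_a)
})

test_that("slides and annotations round-trip through PNG + JSON sidecars", {
  lay <- random_slide_layout(320, 320, stroma_fraction = 0.6, border = 48,
                             seed = 15, n_seeds = 4)
  ms <- make_slide(lay, patch_size = 224)
  d <- withr::local_tempdir()
  write_slide_png(ms$slide, file.path(d, "s.png"))
  write_annotation_png(ms$ground_truth$annotation, file.path(d, "s_ann.png"))
  back <- read_slide_png(file.path(d, "s.png"), id = "s")
  expect_equal(dim(back), dim(ms$slide))
  expect_lt(max(abs(unclass(back) - unclass(ms$slide))), 0.51)  # 8-bit quantization
  ann <- read_annotation_png(file.path(d, "s_ann.png"))
  expect_equal(unclass(ann), unclass(ms$ground_truth$annotation),
               ignore_attr = TRUE)
})
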