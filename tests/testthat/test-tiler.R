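test_that("window enumeration handles the canonical grids", {
  w <- enumerate_windows(448, 448, size = 224, stride = 160)
  expect_equal(nrow(w), 4)
  expect_setequal(w$x, c(0, 160)); expect_setequal(w$y, c(0, 160))
  w1 <- enumerate_windows(224, 224, size = 224, stride = 224)
  expect_equal(w1, data.frame(x = 0L, y = 0L))
  expect_warning(w0 <- enumerate_windows(100, 100, size = 224), "no windows")
  expect_equal(nrow(w0), 0)
})

test_that("window enumeration equals brute force on random geometries", {
  for (i in 1:20) {
    g <- withr::with_seed(300 + i, {
      list(w = sample(100:900, 1), h = sample(100:900, 1),
           size = sample(c(32, 64, 101, 224), 1), stride = sample(c(7, 32, 64, 160, 224), 1))
    })
    if (g$size > g$w || g$size > g$h) next
    got <- enumerate_windows(g$w, g$h, g$size, g$stride)
    want <- bf_windows(g$w, g$h, g$size, g$stride)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("adjacent training windows overlap by exactly 64 pixels", {
  w <- enumerate_windows(896, 896, size = 224, stride = 160)
  xs <- sort(unique(w$x))
  expect_true(all(diff(xs) == 160))
  expect_true(all(xs[-1] < xs[-length(xs)] + 224))
  expect_equal(unique(xs[-length(xs)] + 224 - xs[-1]), 64)
})

test_that("annotation coverage threshold is inclusive at exactly 75%", {
  size <- 64
  slide <- slide_image(array(200, c(size, size, 3)), id = "cov")
  # exactly 75% of the window annotated (48 of 64 rows) -> kept
  ann75 <- matrix(0L, size, size); ann75[1:48, ] <- 1L
  ps75 <- tile_training(slide, annotation_map(ann75, id = "cov"), size = size,
                        overlap = 0, extract_pixels = FALSE)
  expect_equal(n_patches(ps75), 1)
  expect_equal(as.character(ps75$labels), "tumor")
  # just under 75% -> discarded
  ann74 <- ann75; ann74[48, 1:33] <- 0L
  ps74 <- tile_training(slide, annotation_map(ann74, id = "cov"), size = size,
                        overlap = 0, extract_pixels = FALSE)
  expect_equal(n_patches(ps74), 0)
})

test_that("mixed windows get the majority label with the fixed tie order", {
  size <- 64
  slide <- slide_image(array(200, c(size, size, 3)), id = "maj")
  ann <- matrix(0L, size, size)
  ann[1:30, ] <- 2L   # stroma plurality
  ann[31:58, ] <- 3L  # other minority
  ps <- tile_training(slide, annotation_map(ann, id = "maj"), size = size,
                      overlap = 0, extract_pixels = FALSE)
  expect_equal(as.character(ps$labels), "stroma")
  # exact tumor/stroma tie -> tumor (fixed class order)
  tie <- matrix(0L, size, size); tie[1:32, ] <- 2L; tie[33:64, ] <- 1L
  ps_tie <- tile_training(slide, annotation_map(tie, id = "maj"), size = size,
                          overlap = 0, extract_pixels = FALSE)
  expect_equal(as.character(ps_tie$labels), "tumor")
})

test_that("training tiling equals a brute-force window scan", {
  for (i in 1:6) {
    sf <- withr::with_seed(i, runif(1, 0.2, 0.8))
    lay <- random_slide_layout(480, 480, stroma_fraction = sf,
                               border = 48, seed = 400 + i, n_seeds = 8)
    ms <- make_slide(lay, patch_size = 96)
    lab <- unclass(ms$ground_truth$annotation)
    ps <- tile_training(ms$slide, ms$ground_truth$annotation, size = 96,
                        overlap = 32, extract_pixels = FALSE)
    bf <- bf_tile_scan(lab, size = 96, stride = 64, threshold = 0.75)
    kept <- bf[bf$keep, ]
    expect_equal(ps$windows$x, kept$x)
    expect_equal(ps$windows$y, kept$y)
    expect_equal(as.character(ps$labels), kept$label)
  }
})

test_that("inference tiling equals a brute-force mask scan", {
  for (i in 1:6) {
    lay <- random_slide_layout(480, 480, stroma_fraction = 0.5, border = 48,
                               seed = 500 + i, n_seeds = 8)
    ms <- make_slide(lay, patch_size = 96)
    m <- build_tissue_mask(ms$slide)
    ps <- tile_inference(ms$slide, m, size = 96, extract_pixels = FALSE)
    bf <- bf_tile_scan(unclass(ms$ground_truth$annotation), size = 96,
                       stride = 96, threshold = 0.75, mode = "mask",
                       mask = unclass(m))
    expect_equal(ps$windows[, c("x", "y")], bf[bf$keep, c("x", "y")],
                 ignore_attr = TRUE)
  }
})

test_that("tiling is deterministic and patches carry slide pixels", {
  lay <- random_slide_layout(480, 480, stroma_fraction = 0.5, border = 48,
                             seed = 77, n_seeds = 6)
  ms <- make_slide(lay, patch_size = 96)
  a <- tile_training(ms$slide, ms$ground_truth$annotation, size = 96, overlap = 32)
  b <- tile_training(ms$slide, ms$ground_truth$annotation, size = 96, overlap = 32)
  expect_identical(a, b)
  i <- 1L
  w <- a$windows[i, ]
  expect_identical(a$pixels[[i]],
                   unclass(ms$slide)[w$y + 1:96, w$x + 1:96, , drop = FALSE])
  # misaligned annotation is refused
  expect_error(tile_training(ms$slide, annotation_map(matrix(0L, 10, 10))),
               "aligned")
})
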