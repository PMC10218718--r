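test_that("F1 composes precision and recall as published metrics do", {
  expect_equal(round(f1_score(0.93, 0.97), 2), 0.95)
  expect_equal(f1_score(0, 0), 0)
  expect_equal(f1_score(1, 1), 1)
})

test_that("classification report matches brute-force counting", {
  y <- withr::with_seed(60, sample(c("tumor", "stroma", "other"), 50, TRUE))
  p <- withr::with_seed(61, sample(c("tumor", "stroma", "other"), 50, TRUE))
  rep <- classification_report(y, p)
  expect_equal(rep$accuracy, mean(y == p))
  for (cl in c("tumor", "stroma", "other")) {
    want <- bf_class_metrics(y, p, cl)
    row <- rep$per_class[rep$per_class$class == cl, ]
    expect_equal(row$precision, unname(want["precision"]))
    expect_equal(row$recall, unname(want["recall"]))
    expect_equal(row$f1, unname(want["f1"]))
  }
  expect_equal(sum(rep$confusion), 50)
})

test_that("perfect and degenerate predictions are handled explicitly", {
  y <- rep(c("tumor", "stroma", "other"), each = 4)
  rep <- classification_report(y, y)
  expect_equal(rep$accuracy, 1)
  expect_true(all(rep$per_class[, c("precision", "recall", "f1")] == 1))
  # a class never predicted -> precision 0 with a flag
  p <- rep("tumor", 12)
  rep2 <- classification_report(y, p)
  expect_true("stroma:precision" %in% rep2$zero_division)
  expect_equal(rep2$per_class$precision[rep2$per_class$class == "stroma"], 0)
  expect_error(classification_report(character(), character()), "empty")
})

test_that("pearson correlation covers the degenerate closed forms", {
  x <- c(1, 3, 4, 7, 9, 12)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(-x + 5, x), -1)
  y <- c(2, 1, 5, 8, 7, 11)
  want <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(y, x), want)
  expect_error(pearson_r(rep(1, 5), 1:5), "variance")
  expect_error(pearson_r(1, 1), "at least 2")
})

test_that("SEE is the root-mean-square deviation from the reference", {
  x <- c(10, 20, 30, 40)
  expect_equal(see(x, x), 0)
  expect_equal(see(x + 7, x), 7)
  expect_equal(see(x - 3, x), 3)
  # decomposition: SEE^2 ~ bias^2 + variance at large n
  v <- withr::with_seed(62, rnorm(20000, mean = 5, sd = 3))
  expect_equal(see(50 + v, rep(50, length(v)))^2, 5^2 + 3^2, tolerance = 0.02)
  expect_error(see(numeric(), numeric()), "empty")
})

test_that("Cohen's kappa matches the hand formula", {
  # 2x2 table [[40,10],[20,30]]: p_o = 0.70, p_e = 0.50, kappa = 0.40
  a <- c(rep("stroma-low", 50), rep("stroma-high", 50))
  b <- c(rep("stroma-low", 40), rep("stroma-high", 10),
         rep("stroma-low", 20), rep("stroma-high", 30))
  expect_equal(cohens_kappa(a, b), 0.40)
  expect_equal(cohens_kappa(b, a), 0.40)
  expect_equal(cohens_kappa(a, a), 1)
  # independent raters -> kappa near 0
  aa <- withr::with_seed(63, sample(c("lo", "hi"), 1e4, TRUE))
  bb <- withr::with_seed(64, sample(c("lo", "hi"), 1e4, TRUE))
  expect_lt(abs(cohens_kappa(aa, bb)), 0.05)
  # both raters constant and identical -> 1 by convention, with a warning
  expect_warning(k <- cohens_kappa(rep("lo", 5), rep("lo", 5)), "convention")
  expect_equal(k, 1)
  # invariant under simultaneous relabeling
  swap <- function(x) ifelse(x == "lo", "hi", "lo")
  expect_equal(cohens_kappa(swap(aa), swap(bb)), cohens_kappa(aa, bb))
})

test_that("per-category TSR evaluation summarizes a cohort correctly", {
  truth <- rep(seq(10, 90, 10), each = 150)
  # exact predictions: zero SEE, perfect correlation and agreement
  tab0 <- tsr_eval_table(truth, truth)
  expect_true(all(tab0$by_category$see == 0))
  expect_true(all(tab0$by_category$std == 0))
  expect_equal(tab0$r, 1)
  expect_equal(tab0$kappa, 1)
  expect_equal(sum(tab0$by_category$n), length(truth))
  # noisy predictions: category std recovered within 15%
  pred <- withr::with_seed(65, pmin(pmax(truth + rnorm(length(truth), 0, 5), 0), 100))
  tab <- tsr_eval_table(pred, truth)
  expect_true(all(abs(tab$by_category$std - 5) / 5 < 0.15))
  expect_equal(sum(tab$by_category$n), length(truth))
  expect_true(tab$see_overall >= 0 && tab$r > 0.9)
  # off-grid truth is refused, naming the entry
  expect_error(tsr_eval_table(c(10, 20), c(10, 25)), "position 2")
})

test_that("SEE never undercuts the bias within each category", {
  truth <- rep(seq(10, 90, 10), each = 12)
  pred <- withr::with_seed(66, truth + rnorm(length(truth), 2, 8))
  pred <- pmin(pmax(pred, 0), 100)
  tab <- tsr_eval_table(pred, truth)
  bias <- abs(tab$by_category$mean - tab$by_category$true_tsr)
  expect_true(all(tab$by_category$see >= bias - 1e-9))
})
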