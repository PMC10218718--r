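#' Default pipeline parameters
#'
#' The numeric defaults of the whole pipeline in one place: 224 px patches,
#' 64 px training overlap, inclusive 75% coverage thresholds for both
#' tiling regimes, and the 50% stroma-high/low cutoff.
#'
#' @return named list of defaults.
#' @export
default_run_params <- function() {
  list(size = 224L, overlap = 64L, min_annotated = 0.75, min_tissue = 0.75,
       cutoff = 50, mpp = 0.5)
}

#' Stain-normalize every patch of a set
#'
#' Applies [normalize_patch()] to each patch (pass-through fallback for
#' blank patches), replacing patches in place to keep peak memory at one
#' copy of the set.
#'
#' @param ps a [patch_set()] with pixel data.
#' @param reference reference [stain_model()].
#' @return the normalized `patch_set`.
#' @export
normalize_patch_set <- function(ps, reference = default_stain_model()) {
  stopifnot(inherits(ps, "patch_set"), !is.null(ps$pixels))
  for (i in seq_along(ps$pixels)) {
    ps$pixels[[i]] <- normalize_patch(ps$pixels[[i]], reference = reference,
                                      fallback = "passthrough")
  }
  ps
}

# tile + normalize + featurize a list of annotated slides
prepare_annotated <- function(slides, reference, params, normalize = TRUE) {
  sets <- lapply(slides, function(s) {
    ps <- tile_training(s$slide, s$annotation, size = params$size,
                        overlap = params$overlap,
                        min_annotated = params$min_annotated)
    if (normalize && n_patches(ps) > 0) ps <- normalize_patch_set(ps, reference)
    ps
  })
  ps <- do.call(patch_rbind, sets)
  list(ps = ps, X = extract_features(ps, reference = reference),
       y = ps$labels)
}

#' Classifier development workflow
#'
#' The slide-level model development protocol: tile and stain-normalize the
#' annotated training slides, choose hyperparameters by k-fold
#' cross-validation, choose the epoch budget by early stopping on a
#' validation split, retrain on all training patches for that many epochs
#' under the configured transfer-learning setup, and evaluate on patches
#' tiled from held-out test slides. The train/test split is enforced at
#' slide level — a slide id appearing in both lists is a hard error —
#' mirroring the whole-slide-image-level split the evaluation protocol
#' requires.
#'
#' @param train_slides,test_slides named lists; each element is
#'   `list(slide = slide_image, annotation = annotation_map)`.
#' @param config a [train_config()].
#' @param domain_set optional domain pre-training [patch_set()] (required
#'   by SETUP1/SETUP3 configs).
#' @param reference stain reference model.
#' @param params tiling/evaluation parameters, see [default_run_params()].
#' @param normalize stain-normalize patches (default TRUE).
#' @param out_dir if given, artifacts (model JSON, report CSV, manifest)
#'   are written there.
#' @return list with `model`, `report` (a [classification_report()] on the
#'   test patches), `cv`, `epochs`, `manifest`.
#' @export
run_dev_workflow <- function(train_slides, test_slides,
                             config = train_config(), domain_set = NULL,
                             reference = default_stain_model(),
                             params = default_run_params(),
                             normalize = TRUE, out_dir = NULL) {
  ids_tr <- vapply(train_slides, function(s) slide_id(s$slide), "")
  ids_te <- vapply(test_slides, function(s) slide_id(s$slide), "")
  overlap_ids <- intersect(ids_tr, ids_te)
  if (length(overlap_ids)) {
    stop("slide id(s) in both train and test lists: ",
         paste(overlap_ids, collapse = ", "))
  }
  train <- prepare_annotated(train_slides, reference, params, normalize)
  if (n_patches(train$ps) < config$k) stop("too few training patches")

  cv <- if (length(config$grid) > 1) {
    cross_validate(train$X, grid = config$grid, k = config$k, config = config,
                   labels = train$y, seed = config$seed)
  } else {
    list(best = config$grid[[1]], best_index = 1L,
         mean_scores = NA_real_, fold_scores = NULL)
  }
  config$grid <- c(list(cv$best), config$grid[-cv$best_index])

  es <- select_epochs_early_stopping(train$X, config = config,
                                     labels = train$y, seed = config$seed)
  model <- run_setup(config$setup, domain_set = domain_set,
                     target_train = train$X, labels = train$y,
                     config = config, reference = reference,
                     epochs = es$epochs)

  test <- prepare_annotated(test_slides, reference, params, normalize)
  pred <- predict(model, test$X, type = "class")
  report <- classification_report(test$y, pred)

  manifest <- list(
    seed = config$seed,
    n_train_slides = length(train_slides), n_test_slides = length(test_slides),
    n_train_patches = n_patches(train$ps), n_test_patches = n_patches(test$ps),
    train_class_counts = as.list(table(train$y)),
    hyper = cv$best, epochs = es$epochs,
    config_checksum = content_checksum(config),
    model_checksum = content_checksum(model[c("backbone", "params", "scaler")]),
    report_checksum = content_checksum(report))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_classifier(model, file.path(out_dir, "model.json"))
    utils::write.csv(report$per_class, file.path(out_dir, "class_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  list(model = model, report = report, cv = cv, epochs = es$epochs,
       manifest = manifest)
}

#' Cohort TSR scoring workflow
#'
#' Scores a cohort of slides: tissue mask, non-overlapping tiling, stain
#' normalization, patch classification and the per-slide TSR, then (when
#' true visual categories are supplied) the per-category evaluation table.
#' A slide that fails (e.g. no tissue) is recorded in `errors` and the run
#' continues.
#'
#' @param slides named list of [slide_image()]s, of
#'   `list(slide = ..., mask = ...)` to supply precomputed masks, or of
#'   zero-argument closures returning a [slide_image()] (lazy cohorts; the
#'   slide is rendered, scored and discarded one at a time).
#' @param model a `tsr_classifier` or [oracle_classifier()].
#' @param true_tsr optional named numeric vector of true visual TSR
#'   categories in percent (names = slide ids, values on the 10..90 grid).
#' @param reference stain reference; defaults to the model's.
#' @param params see [default_run_params()].
#' @param out_dir if given, the TSR table (CSV) and evaluation table are
#'   written there.
#' @return list with `table` (per-slide TSR data frame), `evaluation`
#'   (a [tsr_eval_table()] or NULL), `errors` (named character).
#' @export
run_scoring_workflow <- function(slides, model, true_tsr = NULL,
                                 reference = NULL,
                                 params = default_run_params(),
                                 out_dir = NULL) {
  if (length(slides) == 0L) {
    warning("empty slide list; nothing to score")
    return(list(table = data.frame(), evaluation = NULL, errors = character()))
  }
  errors <- character()
  results <- list()
  for (i in seq_along(slides)) {
    s <- slides[[i]]
    if (is.function(s)) s <- s()
    slide <- if (inherits(s, "slide_image")) s else s$slide
    mask <- if (inherits(s, "slide_image")) NULL else s$mask
    res <- tryCatch(
      estimate_slide_tsr(slide, mask = mask, model = model,
                         size = params$size, min_tissue = params$min_tissue,
                         reference = reference, cutoff = params$cutoff),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[slide_id(slide)] <- conditionMessage(res)
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  tab <- if (length(results)) tsr_result_table(results) else data.frame()
  evaluation <- NULL
  if (!is.null(true_tsr) && nrow(tab) > 0) {
    truth <- true_tsr[tab$slide_id]
    if (anyNA(truth)) {
      warning("true TSR missing for some slides; evaluation skipped")
    } else {
      evaluation <- tsr_eval_table(tab$tsr_percent, as.numeric(truth),
                                   cutoff = params$cutoff)
    }
  } else if (is.null(true_tsr)) {
    message("no true TSR values supplied; evaluation skipped")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "tsr_results.csv"),
                     row.names = FALSE)
    if (!is.null(evaluation)) {
      utils::write.csv(evaluation$by_category,
                       file.path(out_dir, "tsr_eval_by_category.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(r = evaluation$r,
                                see_overall = evaluation$see_overall,
                                kappa = evaluation$kappa, n = evaluation$n),
                           file.path(out_dir, "tsr_eval_overall.json"),
                           digits = NA, auto_unbox = TRUE)
    }
  }
  list(table = tab, evaluation = evaluation, errors = errors)
}

#' Generate a synthetic TSR cohort
#'
#' Renders `n_slides` synthetic slides whose nominal stroma fractions cycle
#' through the visual TSR categories (10%..90%), with exact ground truth
#' per slide. This is the package's stand-in for a scored clinical cohort.
#'
#' @param n_slides number of slides.
#' @param width,height slide size in pixels.
#' @param seed cohort seed; each slide derives its own.
#' @param categories TSR categories (percent) to cycle through.
#' @param textures,stains generation parameters.
#' @param patch_size,min_coverage ground-truth tiling parameters.
#' @param lazy when `TRUE`, `slides` holds generator closures instead of
#'   rendered slides (each renders its slide when called); ground truth is
#'   computed from the label maps either way. Use this for study-scale
#'   cohorts so only one slide is in memory at a time —
#'   [run_scoring_workflow()] accepts the closures directly.
#' @return list with `slides` (named list of [slide_image()]s, or of
#'   closures when `lazy`), `ground_truth` (named list), `true_category`
#'   (named vector, percent), `true_patch_tsr` (named vector, percent).
#' @export
make_cohort <- function(n_slides = 30, width = 1792, height = 1792,
                        seed = 1L, categories = seq(10, 90, by = 10),
                        textures = texture_params(),
                        stains = default_stain_model(),
                        patch_size = 224, min_coverage = 0.75,
                        lazy = FALSE) {
  cats <- rep(categories, length.out = n_slides)
  slides <- list(); gts <- list()
  true_cat <- numeric(0); true_patch <- numeric(0)
  for (i in seq_len(n_slides)) {
    sseed <- derive_seed(seed, paste0("cohort-slide-", i))
    lay <- random_slide_layout(width, height, stroma_fraction = cats[i] / 100,
                               seed = sseed,
                               id = sprintf("cohort-%02d-tsr%02d", i, cats[i]))
    sid <- lay$id
    if (lazy) {
      lab <- layout_labels(lay)
      gts[[sid]] <- list(
        annotation = NULL,
        areas = stats::setNames(vapply(0:4, function(k) sum(lab == k), 0L),
                                c("background", "tumor", "stroma", "other",
                                  "adipose")),
        stain_model = stains,
        tsr_patch = ground_truth_tsr(lab, size = patch_size,
                                     min_coverage = min_coverage),
        tiling = list(size = patch_size, stride = patch_size,
                      min_coverage = min_coverage))
      slides[[sid]] <- local({
        lay_i <- lay
        function() make_slide(lay_i, textures = textures, stains = stains,
                              patch_size = patch_size,
                              min_coverage = min_coverage)$slide
      })
    } else {
      made <- make_slide(lay, textures = textures, stains = stains,
                         patch_size = patch_size, min_coverage = min_coverage)
      slides[[sid]] <- made$slide
      gts[[sid]] <- made$ground_truth
    }
    true_cat[sid] <- cats[i]
    true_patch[sid] <- 100 * gts[[sid]]$tsr_patch$tsr
  }
  list(slides = slides, ground_truth = gts, true_category = true_cat,
       true_patch_tsr = true_patch)
}
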