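#' Training configuration for the patch classifier
#'
#' Bundles the transfer-learning setup, backbone choice, hyperparameter
#' grid, cross-validation and early-stopping settings. The three setups
#' mirror the pre-training sequences compared in the study design:
#' SETUP1 = reference initialization, pre-train on a domain corpus, then
#' fine-tune on the target training set; SETUP2 = reference initialization,
#' fine-tune directly on the target set; SETUP3 = random initialization,
#' pre-train on the domain corpus, then fine-tune. For the built-in compact
#' backbones "reference initialization" is a documented fixed-seed
#' initializer (the analogue of loading published pretrained weights),
#' while SETUP3 draws its initial weights from the run seed.
#'
#' @param setup `"SETUP1"`, `"SETUP2"` or `"SETUP3"`.
#' @param backbone backbone identifier; built-ins are `"softmax"`
#'   (multinomial logistic head over patch features) and `"mlp"` (one
#'   tanh hidden layer). Additional backbones can be registered with
#'   [register_backbone()].
#' @param grid nonempty list of hyperparameter candidates, each a list with
#'   `lr`, `optimizer` (`"sgd"` or `"momentum"`) and `batch_size`.
#' @param k cross-validation folds (>= 2).
#' @param val_fraction fraction of training patches held out for
#'   early-stopping validation (default 1/3).
#' @param max_epochs epoch budget for early stopping.
#' @param epochs fixed epoch count used when training stages directly.
#' @param patience early-stopping patience in epochs.
#' @param hidden hidden width of the `"mlp"` backbone.
#' @param l2 weight decay.
#' @param seed integer seed controlling every random choice in training.
#' @return a `train_config`.
#' @export
train_config <- function(setup = c("SETUP2", "SETUP1", "SETUP3"),
                         backbone = "softmax",
                         grid = list(list(lr = 0.2, optimizer = "momentum",
                                          batch_size = 32)),
                         k = 5, val_fraction = 1 / 3, max_epochs = 60,
                         epochs = 30, patience = 5, hidden = 8, l2 = 1e-4,
                         seed = 1L) {
  setup <- match.arg(setup)
  stopifnot(k >= 2, val_fraction > 0, val_fraction < 1, length(grid) >= 1,
            patience >= 1, max_epochs >= 1, epochs >= 1)
  structure(list(setup = setup, backbone = backbone, grid = grid, k = k,
                 val_fraction = val_fraction, max_epochs = max_epochs,
                 epochs = epochs, patience = patience, hidden = hidden,
                 l2 = l2, seed = as.integer(seed)),
            class = "train_config")
}

# --- backbone registry -----------------------------------------------------

backbone_registry <- new.env(parent = emptyenv())

#' Register a classifier backbone
#'
#' A backbone is a list of three functions: `init(d, hidden, mode, seed)`
#' returning a parameter list, `forward(params, X)` returning an `n x 3`
#' probability matrix, and `grad(params, X, Y)` returning the gradient list
#' (same shape as the parameters) of the mean cross-entropy loss. Published
#' deep architectures can be plugged in by wrapping their R bindings in
#' this interface.
#'
#' @param name backbone identifier.
#' @param backbone list with `init`, `forward`, `grad`.
#' @export
register_backbone <- function(name, backbone) {
  stopifnot(is.character(name), all(c("init", "forward", "grad") %in% names(backbone)))
  assign(name, backbone, envir = backbone_registry)
  invisible(name)
}

get_backbone <- function(name) {
  if (!exists(name, envir = backbone_registry)) {
    stop("unknown backbone: ", name)
  }
  get(name, envir = backbone_registry)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# seed used for the fixed "reference" initializer (the stand-in for loading
# published pretrained weights into the compact backbones)
REFERENCE_INIT_SEED <- 76543L

init_seed_for <- function(mode, seed) {
  if (mode == "reference") REFERENCE_INIT_SEED else seed
}

local({
  softmax_bb <- list(
    init = function(d, hidden, mode, seed) {
      with_seed(init_seed_for(mode, seed),
                list(W = matrix(stats::rnorm((d + 1) * 3, 0, 0.01), d + 1, 3)))
    },
    forward = function(params, X) softmax_rows(cbind(1, X) %*% params$W),
    grad = function(params, X, Y) {
      Xb <- cbind(1, X)
      P <- softmax_rows(Xb %*% params$W)
      list(W = crossprod(Xb, P - Y) / nrow(X))
    })
  mlp_bb <- list(
    init = function(d, hidden, mode, seed) {
      with_seed(init_seed_for(mode, seed), {
        list(W1 = matrix(stats::rnorm((d + 1) * hidden, 0, sqrt(1 / (d + 1))),
                         d + 1, hidden),
             W2 = matrix(stats::rnorm((hidden + 1) * 3, 0, 0.01), hidden + 1, 3))
      })
    },
    forward = function(params, X) {
      H <- tanh(cbind(1, X) %*% params$W1)
      softmax_rows(cbind(1, H) %*% params$W2)
    },
    grad = function(params, X, Y) {
      Xb <- cbind(1, X)
      A <- tanh(Xb %*% params$W1)
      Hb <- cbind(1, A)
      P <- softmax_rows(Hb %*% params$W2)
      D2 <- (P - Y) / nrow(X)
      dH <- (D2 %*% t(params$W2[-1, , drop = FALSE])) * (1 - A^2)
      list(W1 = crossprod(Xb, dH), W2 = crossprod(Hb, D2))
    })
  register_backbone("softmax", softmax_bb)
  register_backbone("mlp", mlp_bb)
})

# one-hot encode a factor over TSR_CLASSES
one_hot <- function(y) {
  Y <- matrix(0, length(y), 3L)
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

# Mini-batch gradient-descent training loop. X is standardized features,
# y a factor over TSR_CLASSES. Runs `epochs` epochs from `params`;
# optionally evaluates validation accuracy after each epoch via `val`.
# Returns list(params, history).
gd_train <- function(bb, params, X, y, epochs, lr, optimizer = "momentum",
                     batch_size = 32, l2 = 1e-4, seed = 1L,
                     val = NULL, stop_after = NULL) {
  Y <- one_hot(y)
  n <- nrow(X)
  vel <- lapply(params, function(p) p * 0)
  mom <- if (optimizer == "momentum") 0.9 else 0
  hist_acc <- numeric(0)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq.int(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        g <- bb$grad(params, X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
        for (k in names(params)) {
          vel[[k]] <- mom * vel[[k]] - lr * (g[[k]] + l2 * params[[k]])
          params[[k]] <- params[[k]] + vel[[k]]
        }
      }
      if (!is.null(val)) {
        P <- bb$forward(params, val$X)
        hist_acc[ep] <- mean(max.col(P, ties.method = "first") ==
                               as.integer(val$y))
        if (!is.null(stop_after) && ep - which.max(hist_acc) >= stop_after) break
      }
    }
  })
  list(params = params, val_acc = hist_acc)
}

# standardize features; returns list(X, center, scale)
fit_scaler <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale < 1e-8] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2L, scaler$center), 2L, scaler$scale, "/")
}

features_of <- function(data, reference, I0 = 255) {
  if (is.matrix(data)) return(data)
  extract_features(data, reference = reference, I0 = I0)
}

labels_of <- function(data, labels = NULL) {
  y <- labels %||% (if (inherits(data, "patch_set")) data$labels)
  if (is.null(y)) stop("labeled patches required")
  factor(as.character(y), levels = TSR_CLASSES)
}

#' Train a patch classifier under one transfer-learning setup
#'
#' Executes the stage sequence of the requested setup (see
#' [train_config()]): initialization, optional pre-training on a
#' domain-specific patch corpus, and fine-tuning on the target training
#' set, all with the first hyperparameter candidate of the grid (use
#' [cross_validate()] to choose it) and `config$epochs` epochs per training
#' stage. Every stage executed is recorded in the model's provenance.
#'
#' @param setup `"SETUP1"`, `"SETUP2"` or `"SETUP3"` (defaults to
#'   `config$setup`).
#' @param domain_set domain pre-training [patch_set()]; required for SETUP1
#'   and SETUP3, forbidden for SETUP2.
#' @param target_train labeled target [patch_set()].
#' @param config a [train_config()].
#' @param reference [stain_model()] the features are computed against.
#' @param epochs optional override of `config$epochs` for the fine-tuning
#'   stage.
#' @param labels target labels when `target_train` is a precomputed feature
#'   matrix rather than a labeled [patch_set()].
#' @return a `tsr_classifier`.
#' @export
run_setup <- function(setup = config$setup, domain_set = NULL, target_train,
                      config = train_config(), reference = default_stain_model(),
                      epochs = NULL, labels = NULL) {
  setup <- match.arg(setup, c("SETUP1", "SETUP2", "SETUP3"))
  needs_domain <- setup %in% c("SETUP1", "SETUP3")
  if (needs_domain && is.null(domain_set)) {
    stop(setup, " requires a domain pre-training set")
  }
  if (!needs_domain && !is.null(domain_set)) {
    stop(setup, " does not take a domain pre-training set")
  }
  bb <- get_backbone(config$backbone)
  hp <- config$grid[[1]]
  ft_epochs <- epochs %||% config$epochs

  Xt <- features_of(target_train, reference)
  yt <- labels_of(target_train, labels)
  stages <- list()

  init_mode <- if (setup == "SETUP3") "random" else "reference"
  params <- bb$init(ncol(Xt), config$hidden, init_mode, config$seed)
  stages[[1]] <- list(stage = paste0("init:", init_mode))

  if (needs_domain) {
    Xd <- features_of(domain_set, reference)
    yd <- labels_of(domain_set)
    scaler <- fit_scaler(Xd)
    Xds <- apply_scaler(Xd, scaler)
    fit <- gd_train(bb, params, Xds, yd, epochs = config$epochs, lr = hp$lr,
                    optimizer = hp$optimizer, batch_size = hp$batch_size,
                    l2 = config$l2, seed = derive_seed(config$seed, "pretrain"))
    params <- fit$params
    stages[[length(stages) + 1L]] <- list(stage = "pretrain:domain",
                                          epochs = config$epochs,
                                          n = length(yd))
  } else {
    scaler <- fit_scaler(Xt)
  }

  Xts <- apply_scaler(Xt, scaler)
  fit <- gd_train(bb, params, Xts, yt, epochs = ft_epochs, lr = hp$lr,
                  optimizer = hp$optimizer, batch_size = hp$batch_size,
                  l2 = config$l2, seed = derive_seed(config$seed, "finetune"))
  params <- fit$params
  stages[[length(stages) + 1L]] <- list(stage = "finetune:target",
                                        epochs = ft_epochs, n = length(yt))

  input_size <- if (inherits(target_train, "patch_set") &&
                    n_patches(target_train)) {
    target_train$windows$size[1]
  } else 224L
  structure(list(backbone = config$backbone, params = params,
                 scaler = scaler, classes = TSR_CLASSES,
                 input_size = input_size,
                 reference = reference,
                 reference_checksum = content_checksum(reference),
                 provenance = list(setup = setup, stages = stages,
                                   hyper = hp, seed = config$seed),
                 config = config),
            class = "tsr_classifier")
}

#' @export
print.tsr_classifier <- function(x, ...) {
  cat(sprintf("<tsr_classifier> backbone '%s', %s, stages: %s\n",
              x$backbone, x$provenance$setup,
              paste(vapply(x$provenance$stages, `[[`, "", "stage"),
                    collapse = " -> ")))
  invisible(x)
}

#' Predict class probabilities for patches
#'
#' @param object a `tsr_classifier`.
#' @param newdata a [patch_set()] (pixel data required; patches must match
#'   the model's input size and have been stain-normalized to the same
#'   reference as training) or a precomputed feature matrix.
#' @param type `"prob"` for the probability matrix, `"class"` for argmax
#'   labels (ties broken in class order tumor > stroma > other).
#' @param ... unused.
#' @return probability matrix (rows sum to 1) or factor of labels.
#' @export
predict.tsr_classifier <- function(object, newdata, type = c("prob", "class"),
                                   ...) {
  type <- match.arg(type)
  if (inherits(newdata, "patch_set")) {
    if (n_patches(newdata) == 0L) {
      P <- matrix(numeric(0), 0, 3, dimnames = list(NULL, object$classes))
      return(if (type == "prob") P else factor(character(), levels = object$classes))
    }
    if (any(newdata$windows$size != object$input_size)) {
      stop(sprintf("patch size %d does not match model input size %d",
                   newdata$windows$size[1], object$input_size))
    }
    X <- extract_features(newdata,
                          reference = object$reference %||% default_stain_model())
  } else X <- as.matrix(newdata)
  bb <- get_backbone(object$backbone)
  P <- bb$forward(object$params, apply_scaler(X, object$scaler))
  colnames(P) <- object$classes
  if (type == "prob") P
  else factor(object$classes[max.col(P, ties.method = "first")],
              levels = object$classes)
}

#' Select hyperparameters by k-fold cross-validation
#'
#' Partitions the training patches into `k` folds (pairwise disjoint, union
#' the whole set); each candidate is trained on `k - 1` folds and scored on
#' the held-out fold, and the candidate with the highest mean fold accuracy
#' wins (ties go to the first candidate in grid order).
#'
#' @param train labeled [patch_set()] or feature matrix (then supply
#'   `labels`).
#' @param grid hyperparameter candidates (defaults to `config$grid`).
#' @param k folds (default `config$k` = 5).
#' @param config a [train_config()].
#' @param reference stain reference for feature extraction.
#' @param labels labels when `train` is a feature matrix.
#' @param seed fold-assignment seed (defaults to `config$seed`).
#' @return list with `best` (winning candidate), `best_index`,
#'   `mean_scores`, `fold_scores` (candidates x folds matrix), and `folds`
#'   (fold id per sample).
#' @export
cross_validate <- function(train, grid = config$grid, k = config$k,
                           config = train_config(),
                           reference = default_stain_model(),
                           labels = NULL, seed = config$seed) {
  X <- features_of(train, reference)
  y <- labels_of(train, labels)
  n <- nrow(X)
  if (length(grid) < 1) stop("hyperparameter grid is empty")
  if (k > n) stop("more folds than training samples")
  folds <- with_seed(derive_seed(seed, "cv-folds"),
                     sample(rep(seq_len(k), length.out = n)))
  bb <- get_backbone(config$backbone)
  scores <- matrix(NA_real_, length(grid), k)
  for (gi in seq_along(grid)) {
    hp <- grid[[gi]]
    for (fi in seq_len(k)) {
      tr <- folds != fi
      scaler <- fit_scaler(X[tr, , drop = FALSE])
      params <- bb$init(ncol(X), config$hidden, "reference", config$seed)
      fit <- gd_train(bb, params, apply_scaler(X[tr, , drop = FALSE], scaler),
                      y[tr], epochs = config$epochs, lr = hp$lr,
                      optimizer = hp$optimizer, batch_size = hp$batch_size,
                      l2 = config$l2,
                      seed = derive_seed(seed, sprintf("cv-%d-%d", gi, fi)))
      P <- bb$forward(fit$params, apply_scaler(X[!tr, , drop = FALSE], scaler))
      scores[gi, fi] <- mean(max.col(P, ties.method = "first") ==
                               as.integer(y[!tr]))
    }
  }
  means <- rowMeans(scores)
  best <- which.max(means)  # first maximum = first in grid order on ties
  list(best = grid[[best]], best_index = best, mean_scores = means,
       fold_scores = scores, folds = folds)
}

#' First-best epoch under an early-stopping rule
#'
#' Given a per-epoch validation-accuracy sequence, returns the earliest
#' epoch achieving the best score seen before patience is exhausted
#' (training stops once `patience` epochs pass without improvement).
#'
#' @param val_acc numeric vector of per-epoch validation accuracies.
#' @param patience epochs without improvement before stopping.
#' @return integer epoch (1-based).
#' @export
choose_best_epoch <- function(val_acc, patience = 5) {
  stopifnot(length(val_acc) >= 1, patience >= 1)
  best <- 1L
  for (i in seq_along(val_acc)) {
    if (val_acc[i] > val_acc[best]) best <- i
    if (i - best >= patience) break
  }
  best
}

#' Choose the epoch budget by early stopping on a validation split
#'
#' Holds out `val_fraction` of the training patches, trains with per-epoch
#' validation until `patience` epochs pass without improvement (or
#' `config$max_epochs` is reached), and returns the earliest best epoch.
#' The final model is then conventionally retrained on the full training
#' set for exactly that many epochs (see [run_setup()]'s `epochs`
#' argument).
#'
#' @inheritParams cross_validate
#' @param val_fraction validation fraction (default `config$val_fraction`).
#' @param patience early-stopping patience (default `config$patience`).
#' @return list with `epochs` (chosen count), `history` (per-epoch
#'   validation accuracy), `n_val`.
#' @export
select_epochs_early_stopping <- function(train, val_fraction = config$val_fraction,
                                         patience = config$patience,
                                         config = train_config(),
                                         reference = default_stain_model(),
                                         labels = NULL, seed = config$seed) {
  X <- features_of(train, reference)
  y <- labels_of(train, labels)
  n <- nrow(X)
  n_val <- round(n * val_fraction)
  if (n_val < 1 || n_val >= n) stop("validation split is empty or exhausts the data")
  idx_val <- with_seed(derive_seed(seed, "earlystop-split"), sample.int(n, n_val))
  tr <- setdiff(seq_len(n), idx_val)
  scaler <- fit_scaler(X[tr, , drop = FALSE])
  bb <- get_backbone(config$backbone)
  hp <- config$grid[[1]]
  params <- bb$init(ncol(X), config$hidden, "reference", config$seed)
  fit <- gd_train(bb, params, apply_scaler(X[tr, , drop = FALSE], scaler),
                  y[tr], epochs = config$max_epochs, lr = hp$lr,
                  optimizer = hp$optimizer, batch_size = hp$batch_size,
                  l2 = config$l2, seed = derive_seed(seed, "earlystop-train"),
                  val = list(X = apply_scaler(X[idx_val, , drop = FALSE], scaler),
                             y = y[idx_val]),
                  stop_after = patience)
  list(epochs = choose_best_epoch(fit$val_acc, patience),
       history = fit$val_acc, n_val = n_val)
}

#' Oracle classifier backed by ground-truth annotation maps
#'
#' A stand-in classifier that labels each patch window by the majority
#' annotated class of the corresponding ground-truth annotation map
#' (probability 1 on that class). Used to separate tiling/TSR arithmetic
#' from classifier error in tests and calibration.
#'
#' @param annotations a single [annotation_map()] or a named list of them
#'   (keyed by slide id).
#' @return a `tsr_oracle_classifier`.
#' @export
oracle_classifier <- function(annotations) {
  if (inherits(annotations, "annotation_map")) {
    annotations <- stats::setNames(list(annotations), slide_id(annotations))
  }
  structure(list(annotations = annotations, classes = TSR_CLASSES,
                 input_size = 224),
            class = "tsr_oracle_classifier")
}

#' @export
predict.tsr_oracle_classifier <- function(object, newdata, type = c("prob", "class"),
                                          ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "patch_set"))
  w <- newdata$windows
  lab <- character(nrow(w))
  for (sid in unique(w$slide_id)) {
    ann <- object$annotations[[sid]] %||% object$annotations[[1]]
    rows <- which(w$slide_id == sid)
    cnt <- vapply(1:3, function(k) {
      window_sum(integral_image(unclass(ann) == k),
                 w$x[rows], w$y[rows], w$size[rows][1])
    }, numeric(length(rows)))
    cnt <- matrix(cnt, nrow = length(rows))
    lab[rows] <- TSR_CLASSES[max.col(cnt, ties.method = "first")]
  }
  y <- factor(lab, levels = TSR_CLASSES)
  if (type == "class") return(y)
  P <- one_hot(y)
  colnames(P) <- TSR_CLASSES
  P
}

#' Compare the three transfer-learning setups from one configuration
#'
#' Runs SETUP1/2/3 for each requested backbone on the same domain/target
#' data and reports test accuracy in a setups-by-backbones table, with the
#' executed stage sequence of every run attached.
#'
#' @param domain_set domain pre-training [patch_set()].
#' @param target_train,target_test labeled target [patch_set()]s.
#' @param config base [train_config()].
#' @param backbones backbone identifiers to sweep.
#' @param reference stain reference.
#' @return list with `table` (data frame backbone x SETUP1/2/3 accuracy)
#'   and `runs` (per-run provenance).
#' @export
compare_setups <- function(domain_set, target_train, target_test,
                           config = train_config(),
                           backbones = config$backbone,
                           reference = default_stain_model()) {
  setups <- c("SETUP1", "SETUP2", "SETUP3")
  runs <- list()
  tab <- data.frame(backbone = backbones)
  y_test <- labels_of(target_test)
  X_test <- features_of(target_test, reference)
  for (s in setups) tab[[s]] <- NA_real_
  for (bi in seq_along(backbones)) {
    for (s in setups) {
      cfg <- config; cfg$backbone <- backbones[bi]; cfg$setup <- s
      model <- run_setup(s, domain_set = if (s == "SETUP2") NULL else domain_set,
                         target_train = target_train, config = cfg,
                         reference = reference)
      pred <- predict(model, X_test, type = "class")
      acc <- mean(pred == y_test)
      tab[bi, s] <- acc
      runs[[paste(backbones[bi], s, sep = "/")]] <-
        list(accuracy = acc, provenance = model$provenance)
    }
  }
  list(table = tab, runs = runs)
}

#' Serialize a classifier to JSON
#'
#' Writes backbone weights plus a sidecar of metadata (class order, input
#' size, stain-reference checksum, provenance) as one JSON document.
#'
#' @param model a `tsr_classifier`.
#' @param path JSON file path.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "tsr_classifier"))
  jsonlite::write_json(list(
    backbone = model$backbone,
    params = lapply(model$params, function(m) list(dim = dim(m), data = as.vector(m))),
    scaler = model$scaler,
    classes = model$classes,
    input_size = model$input_size,
    reference = list(stain_matrix = model$reference$stain_matrix,
                     max_concentrations = model$reference$max_concentrations),
    reference_checksum = model$reference_checksum,
    provenance = model$provenance
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(j$params, function(p) matrix(p$data, p$dim[1], p$dim[2]))
  structure(list(backbone = j$backbone, params = params,
                 scaler = list(center = j$scaler$center, scale = j$scaler$scale),
                 classes = j$classes, input_size = j$input_size,
                 reference = stain_model(matrix(unlist(j$reference$stain_matrix), 3, 2),
                                         j$reference$max_concentrations),
                 reference_checksum = j$reference_checksum,
                 provenance = j$provenance),
            class = "tsr_classifier")
}
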