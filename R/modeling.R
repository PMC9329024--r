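# The 16-classifier suite: per target, the eight fingerprint models
# {RF, SVM, KNN, NN} x {MACCS, ECFP6}; shared across targets, the eight
# pooled proteochemometric (PCM) models {RF, SVM, KNN, NN} x
# {MACCS_protein, ECFP6_protein}, whose feature vector concatenates the
# compound fingerprint with the min-max-normalized, PCA-reduced protein
# descriptor block of the target. For T targets the suite holds 8*T + 8
# classifiers and any compound-target query receives exactly 16 votes.

ALGORITHMS <- c("RF", "SVM", "KNN", "NN")
FEATURE_KINDS <- c("MACCS", "ECFP6", "MACCS_protein", "ECFP6_protein")

#' Default model hyperparameters
#'
#' @return Named list of hyperparameters, overridable entry-wise through
#'   the `models` section of the pipeline configuration: `rf_ntree` (500),
#'   `knn_k` (5), `svm_cost` (1), `svm_gamma` (`NULL` = 1/n features),
#'   `nn_size` (16 hidden units), `nn_epochs` (300), `nn_lr` (0.01),
#'   `nn_decay` (1e-4).
#' @export
default_hyperparameters <- function() {
  list(rf_ntree = 500L, knn_k = 5L, svm_cost = 1, svm_gamma = NULL,
       nn_size = 16L, nn_epochs = 300L, nn_lr = 0.01, nn_decay = 1e-4)
}

#' Create a model specification
#'
#' @param algorithm one of `"RF"`, `"SVM"`, `"KNN"`, `"NN"`.
#' @param feature_kind one of `"MACCS"`, `"ECFP6"`, `"MACCS_protein"`,
#'   `"ECFP6_protein"`.
#' @param hyperparameters named list; missing entries take
#'   [default_hyperparameters()].
#' @param seed integer RNG seed for the fit.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(algorithm, feature_kind,
                       hyperparameters = list(), seed = 0L) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  feature_kind <- match.arg(feature_kind, FEATURE_KINDS)
  hp <- utils::modifyList(default_hyperparameters(), hyperparameters)
  structure(
    list(algorithm = algorithm, feature_kind = feature_kind,
         hyperparameters = hp, seed = as.integer(seed)),
    class = "model_spec"
  )
}

#' Canonical model name, e.g. `"RF_MACCS"` or `"KNN_ECFP6_protein"`
#'
#' @param spec a `model_spec`.
#' @return Character scalar.
#' @export
model_name <- function(spec) paste(spec$algorithm, spec$feature_kind, sep = "_")

#' Canonical order of the 16 classifiers voting on a compound-target pair
#'
#' The eight per-target fingerprint models come first, then the eight
#' pooled PCM models; within each block the algorithms run RF, SVM, KNN,
#' NN, each with its MACCS variant before its ECFP6 variant.
#'
#' @return Character vector of 16 model names.
#' @export
suite_model_names <- function() {
  c(t(outer(ALGORITHMS, FEATURE_KINDS[1:2], paste, sep = "_")),
    t(outer(ALGORITHMS, FEATURE_KINDS[3:4], paste, sep = "_")))
}

#' Stratified train/test split
#'
#' @param labels vector of class labels (two classes, each with >= 2
#'   members).
#' @param test_fraction fraction of each class reserved for the test set
#'   (default 0.2).
#' @param seed integer seed; identical seeds give identical splits.
#' @return An object of class `data_split` with integer index vectors
#'   `train` and `test`.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 0L) {
  stopifnot(test_fraction >= 0, test_fraction < 1)
  classes <- sort(unique(labels))
  for (cl in classes) {
    if (sum(labels == cl) < 2L) {
      stop(sprintf("class '%s' has fewer than 2 members", cl), call. = FALSE)
    }
  }
  test <- integer(0)
  with_seed(seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      n_test <- round(length(idx) * test_fraction)
      if (n_test > 0L) test <- c(test, sample(idx, n_test))
    }
  })
  test <- sort(test)
  structure(
    list(train = setdiff(seq_along(labels), test), test = test,
         test_fraction = test_fraction, seed = as.integer(seed)),
    class = "data_split"
  )
}

#' Stratified k-fold plan over the training partition
#'
#' Folds partition the training indices; fold sizes differ by at most one
#' both overall and within every class.
#'
#' @param split a [stratified_split()] result.
#' @param labels the full label vector the split refers to.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return An object of class `fold_plan`: a list of `k` disjoint integer
#'   index vectors (indices into the full data).
#' @export
make_folds <- function(split, labels, k = 5L, seed = 0L) {
  stopifnot(k >= 2L)
  train <- split$train
  classes <- sort(unique(labels[train]))
  counts <- vapply(classes, function(cl) sum(labels[train] == cl), integer(1))
  if (any(counts < k)) {
    stop(sprintf("class '%s' has fewer than k = %d training members",
                 classes[which.min(counts)], k), call. = FALSE)
  }
  assignment <- integer(length(train))
  offset <- 0L
  with_seed(seed, {
    for (cl in classes) {
      pos <- which(labels[train] == cl)
      pos <- sample(pos)
      assignment[pos] <- ((offset + seq_along(pos) - 1L) %% k) + 1L
      offset <- offset + length(pos)
    }
  })
  folds <- lapply(seq_len(k), function(f) sort(train[assignment == f]))
  structure(list(folds = folds, k = k, seed = as.integer(seed)),
            class = "fold_plan")
}

# --- learners ---------------------------------------------------------------

# Single-hidden-layer neural network, logistic output, cross-entropy loss
# with L2 decay, trained full-batch with Adam. Written with BLAS matrix ops
# so that fingerprint-sized inputs (~1000 features) train in seconds with
# O(n * d * h) cost per epoch.
nn_fit <- function(x, y, size = 16L, epochs = 300L, lr = 0.01,
                   decay = 1e-4, seed = 0L) {
  x <- as.matrix(x); d <- ncol(x); n <- nrow(x)
  params <- with_seed(seed, list(
    W1 = matrix(rnorm(d * size, sd = sqrt(2 / d)), d, size),
    b1 = numeric(size),
    W2 = matrix(rnorm(size, sd = sqrt(2 / size)), size, 1),
    b2 = 0
  ))
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  b1c <- 0.9; b2c <- 0.999; eps <- 1e-8
  for (t in seq_len(epochs)) {
    h_pre <- sweep(x %*% params$W1, 2, params$b1, "+")
    h <- pmax(h_pre, 0)
    z <- drop(h %*% params$W2) + params$b2
    p <- 1 / (1 + exp(-z))
    dz <- (p - y) / n
    grad <- list(
      W1 = crossprod(x, (matrix(dz, n, 1) %*% t(params$W2)) * (h_pre > 0)) +
        decay * params$W1,
      b1 = colSums((matrix(dz, n, 1) %*% t(params$W2)) * (h_pre > 0)),
      W2 = crossprod(h, dz) + decay * params$W2,
      b2 = sum(dz)
    )
    for (nm in names(params)) {
      m[[nm]] <- b1c * m[[nm]] + (1 - b1c) * grad[[nm]]
      v[[nm]] <- b2c * v[[nm]] + (1 - b2c) * grad[[nm]]^2
      mh <- m[[nm]] / (1 - b1c^t)
      vh <- v[[nm]] / (1 - b2c^t)
      params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  params
}

nn_predict <- function(params, x) {
  x <- as.matrix(x)
  h <- pmax(sweep(x %*% params$W1, 2, params$b1, "+"), 0)
  drop(1 / (1 + exp(-(h %*% params$W2 + params$b2))))
}

#' Train one classifier
#'
#' Count fingerprints are used raw by the tree learner and min-max scaled
#' (scaler fit on the training rows, frozen, clipped at predict time) by the
#' distance- and margin-based learners, which need commensurate feature
#' scales.
#'
#' @param spec a [model_spec()].
#' @param features numeric matrix of training features.
#' @param labels 0/1 vector (both classes present).
#' @return An object of class `trained_classifier` with a 0.5 decision
#'   threshold on the positive-class score.
#' @export
train_classifier <- function(spec, features, labels) {
  stopifnot(inherits(spec, "model_spec"))
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels), nrow(features) >= 2L)
  if (length(unique(labels)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  hp <- spec$hyperparameters
  scaler <- NULL
  x <- features
  if (spec$algorithm %in% c("KNN", "SVM", "NN")) {
    scaler <- fit_scaler(features)
    x <- apply_scaler(scaler, features)
  }
  y <- factor(labels, levels = c(0, 1))
  fit <- switch(
    spec$algorithm,
    RF = with_seed(spec$seed,
      randomForest::randomForest(x, y, ntree = hp$rf_ntree)),
    SVM = with_seed(spec$seed,
      e1071::svm(x, y, kernel = "radial", cost = hp$svm_cost,
                 gamma = hp$svm_gamma %||% (1 / ncol(x)),
                 probability = TRUE, scale = FALSE)),
    KNN = caret::knn3(x, y, k = hp$knn_k),
    NN = nn_fit(x, labels, size = hp$nn_size, epochs = hp$nn_epochs,
                lr = hp$nn_lr, decay = hp$nn_decay, seed = spec$seed)
  )
  structure(
    list(spec = spec, fit = fit, scaler = scaler, threshold = 0.5,
         meta = list(n = nrow(features), n_pos = sum(labels == 1L),
                     n_neg = sum(labels == 0L), n_features = ncol(features))),
    class = "trained_classifier"
  )
}

#' Positive-class scores of a trained classifier
#'
#' @param clf a [train_classifier()] result.
#' @param features numeric matrix (or single-row vector) of query features.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
predict_scores <- function(clf, features) {
  stopifnot(inherits(clf, "trained_classifier"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  if (ncol(features) != clf$meta$n_features) {
    stop(sprintf("feature length %d does not match the %d the model was trained on",
                 ncol(features), clf$meta$n_features), call. = FALSE)
  }
  x <- if (is.null(clf$scaler)) features else apply_scaler(clf$scaler, features)
  scores <- switch(
    clf$spec$algorithm,
    RF = predict(clf$fit, x, type = "prob")[, "1"],
    SVM = attr(predict(clf$fit, x, probability = TRUE),
               "probabilities")[, "1"],
    KNN = predict(clf$fit, x, type = "prob")[, "1"],
    NN = nn_predict(clf$fit, x)
  )
  unname(scores)
}

#' Binary votes (0/1) of a trained classifier
#'
#' @inheritParams predict_scores
#' @return Integer vector of 0/1 votes (score at or above the classifier's
#'   decision threshold).
#' @export
predict_votes <- function(clf, features) {
  as.integer(predict_scores(clf, features) >= clf$threshold)
}

# --- suite ------------------------------------------------------------------

#' Assemble a proteochemometric feature vector
#'
#' Concatenates a compound fingerprint with a projected protein descriptor
#' block, compound block first.
#'
#' @param fp numeric fingerprint vector (166 MACCS bits or 1024 ECFP6
#'   counts).
#' @param prot projected protein descriptor vector (length = effective
#'   number of retained components).
#' @return Numeric vector of length `length(fp) + length(prot)`.
#' @export
assemble_pcm <- function(fp, prot) {
  stopifnot(is.numeric(fp) || is.integer(fp), is.numeric(prot))
  if (length(fp) == 0L || length(prot) == 0L) {
    stop("both the compound and the protein block must be non-empty",
         call. = FALSE)
  }
  c(as.numeric(fp), as.numeric(prot))
}

feature_matrix_for <- function(kind, fps, protein_row = NULL) {
  base <- switch(sub("_protein$", "", kind), MACCS = fps$maccs, ECFP6 = fps$ecfp)
  if (grepl("_protein$", kind)) {
    stopifnot(!is.null(protein_row))
    base <- cbind(base, matrix(protein_row, nrow = nrow(base),
                               ncol = length(protein_row), byrow = TRUE))
  }
  base
}

#' Pool per-target rows into the PCM design
#'
#' Each row concatenates a compound fingerprint with its own target's
#' projected protein descriptor block; row and class counts are the sums of
#' the per-target counts.
#'
#' @param datasets named list of `activity_dataset` objects.
#' @param protein_blocks matrix of projected protein descriptors, one row
#'   per target (rownames = target ids).
#' @param fingerprints named list (by target) of `featurize_compounds()`
#'   results aligned with each dataset's records.
#' @param rows named list (by target) of integer row indices to pool
#'   (e.g. each target's training partition).
#' @param kind `"MACCS_protein"` or `"ECFP6_protein"`.
#' @return List with `x` (pooled feature matrix), `y` (0/1 labels),
#'   `target` (target id per row), `row` (source row index per row).
#' @export
pool_pcm_dataset <- function(datasets, protein_blocks, fingerprints, rows,
                             kind = "ECFP6_protein") {
  parts <- lapply(names(datasets), function(tid) {
    if (!tid %in% rownames(protein_blocks)) {
      stop("no protein sequence registered for target '", tid, "'",
           call. = FALSE)
    }
    idx <- rows[[tid]]
    fps <- lapply(fingerprints[[tid]], function(m) m[idx, , drop = FALSE])
    x <- feature_matrix_for(kind, fps, protein_blocks[tid, ])
    list(x = x,
         y = as.integer(datasets[[tid]]$records$label[idx] == "active"),
         target = rep(tid, length(idx)), row = idx)
  })
  list(
    x = do.call(rbind, lapply(parts, `[[`, "x")),
    y = unlist(lapply(parts, `[[`, "y")),
    target = unlist(lapply(parts, `[[`, "target")),
    row = unlist(lapply(parts, `[[`, "row"))
  )
}

#' Build the full model suite
#'
#' Trains, for every target, the eight fingerprint models on that target's
#' training partition, and the eight pooled PCM models on the union of all
#' training partitions. The protein descriptor block is min-max normalized
#' and PCA-reduced once, shared by all PCM models; the effective number of
#' retained components is `min(pca_k, T - 1, n descriptor features)`.
#'
#' @param datasets named list of `activity_dataset` objects (one per
#'   target).
#' @param registry named character vector of protein sequences, one per
#'   target id.
#' @param config optional list: `seed` (master seed, default 0),
#'   `test_fraction` (0.2), `cv_folds` (5), `pca_k` (150),
#'   `protein_families` (AAC, DPC, CTD), `models` (hyperparameter
#'   overrides, see [default_hyperparameters()]).
#' @return An object of class `model_suite`.
#' @export
build_suite <- function(datasets, registry, config = list()) {
  stopifnot(length(datasets) >= 1L)
  if (is.null(names(datasets))) {
    names(datasets) <- vapply(datasets, `[[`, character(1), "target_id")
  }
  missing <- setdiff(names(datasets), names(registry))
  if (length(missing) > 0L) {
    stop("no protein sequence registered for target(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  seed <- config$seed %||% 0L
  test_fraction <- config$test_fraction %||% 0.2
  cv_folds <- config$cv_folds %||% 5L
  pca_k <- config$pca_k %||% 150L
  families <- config$protein_families %||% c("AAC", "DPC", "CTD")
  hp <- config$models %||% list()

  registry <- registry[names(datasets)]
  desc <- protein_descriptor_matrix(registry, families = families)
  scaler <- fit_scaler(desc)
  projection <- if (length(registry) >= 2L) {
    fit_projection(apply_scaler(scaler, desc), pca_k)
  } else NULL
  protein_blocks <- if (is.null(projection)) {
    matrix(0, nrow = 1, ncol = 1, dimnames = list(names(registry), NULL))
  } else {
    project(projection, apply_scaler(scaler, desc))
  }
  rownames(protein_blocks) <- names(registry)

  per_target <- list()
  fingerprints <- list()
  splits <- list()
  for (tid in names(datasets)) {
    ds <- datasets[[tid]]
    labels <- as.integer(ds$records$label == "active")
    split <- stratified_split(labels, test_fraction,
                              derive_seed(seed, paste0("split:", tid)))
    fps <- featurize_compounds(ds$records$canonical_smiles)
    models <- list()
    for (kind in FEATURE_KINDS[1:2]) {
      x <- feature_matrix_for(kind, fps)
      for (alg in ALGORITHMS) {
        spec <- model_spec(alg, kind, hp,
                           derive_seed(seed, paste(tid, alg, kind, sep = ":")))
        models[[model_name(spec)]] <-
          train_classifier(spec, x[split$train, , drop = FALSE],
                           labels[split$train])
      }
    }
    per_target[[tid]] <- models
    fingerprints[[tid]] <- fps
    splits[[tid]] <- split
  }

  pcm_models <- list()
  train_rows <- lapply(splits, `[[`, "train")
  for (kind in FEATURE_KINDS[3:4]) {
    pooled <- pool_pcm_dataset(datasets, protein_blocks, fingerprints,
                               train_rows, kind)
    for (alg in ALGORITHMS) {
      spec <- model_spec(alg, kind, hp,
                         derive_seed(seed, paste("pcm", alg, kind, sep = ":")))
      pcm_models[[model_name(spec)]] <- train_classifier(spec, pooled$x, pooled$y)
    }
  }

  structure(
    list(
      targets = names(datasets),
      registry = registry,
      datasets = datasets,
      per_target_models = per_target,
      pcm_models = pcm_models,
      protein_scaler = scaler,
      projection = projection,
      protein_blocks = protein_blocks,
      fingerprints = fingerprints,
      splits = splits,
      config = list(seed = seed, test_fraction = test_fraction,
                    cv_folds = cv_folds, pca_k = pca_k, families = families,
                    models = utils::modifyList(default_hyperparameters(), hp))
    ),
    class = "model_suite"
  )
}

#' Number of classifiers in a suite
#'
#' `8 * T + 8` for `T` targets: eight fingerprint models per target plus
#' the eight pooled PCM models shared across targets.
#'
#' @param suite a `model_suite`.
#' @return Named integer vector with `per_target`, `pcm` and `total`.
#' @export
suite_cardinality <- function(suite) {
  per_target <- sum(vapply(suite$per_target_models, length, integer(1)))
  c(per_target = per_target, pcm = length(suite$pcm_models),
    total = per_target + length(suite$pcm_models))
}

#' @export
print.model_suite <- function(x, ...) {
  card <- suite_cardinality(x)
  cat(sprintf(
    "<model_suite> %d target(s), %d classifiers (%d per-target + %d pooled PCM)\n",
    length(x$targets), card["total"], card["per_target"], card["pcm"]))
  invisible(x)
}
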