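# Classification metrics: sensitivity SE = TP/(TP+FN), specificity
# SP = TN/(TN+FP), accuracy Q = (TP+TN)/total, Matthews correlation
# MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TP+FP)(TN+FN)(TN+FP)) and ROC AUC
# as the Mann-Whitney probability that a random positive outscores a random
# negative (ties counting 1/2). Any ratio with a zero denominator is 0 by
# declared convention.

#' Confusion counts from labels and predictions
#'
#' @param labels true 0/1 labels.
#' @param predictions predicted 0/1 labels.
#' @return Named integer vector `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(labels, predictions) {
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  stopifnot(length(labels) == length(predictions), length(labels) >= 1L)
  c(TP = sum(labels == 1L & predictions == 1L),
    TN = sum(labels == 0L & predictions == 0L),
    FP = sum(labels == 0L & predictions == 1L),
    FN = sum(labels == 1L & predictions == 0L))
}

#' Compute SE, SP, Q and MCC from confusion counts
#'
#' @param counts named vector with `TP`, `TN`, `FP`, `FN` (total >= 1).
#' @return Named numeric vector `SE`, `SP`, `Q`, `MCC`; undefined ratios
#'   are 0.
#' @export
compute_metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]]); fn <- as.numeric(counts[["FN"]])
  stopifnot(tp + tn + fp + fn >= 1)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  denom <- (tp + fn) * (tp + fp) * (tn + fn) * (tn + fp)
  c(SE = safe_div(tp, tp + fn),
    SP = safe_div(tn, tn + fp),
    Q = (tp + tn) / (tp + tn + fp + fn),
    MCC = if (denom == 0) 0 else (tp * tn - fn * fp) / sqrt(denom))
}

#' ROC AUC by the Mann-Whitney statistic
#'
#' Equals the probability that a randomly drawn positive receives a higher
#' score than a randomly drawn negative, with ties counting one half.
#'
#' @param labels true 0/1 labels (both classes present).
#' @param scores numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

metric_row <- function(labels, scores, threshold = 0.5) {
  counts <- confusion_counts(labels, as.integer(scores >= threshold))
  m <- compute_metrics(counts)
  c(AUC = roc_auc(labels, scores), m)
}

#' k-fold cross-validation of one model specification
#'
#' Out-of-fold predictions from all folds are pooled into a single
#' confusion table before the metrics are computed (well defined for MCC
#' even with small folds, unlike averaging per-fold coefficients).
#'
#' @param spec a [model_spec()].
#' @param features feature matrix over the full data the plan indexes.
#' @param labels 0/1 labels aligned with `features`.
#' @param fold_plan a [make_folds()] result.
#' @return Named numeric vector `AUC`, `SE`, `SP`, `Q`, `MCC` with
#'   attribute `n` (number of pooled out-of-fold predictions).
#' @export
cross_validate <- function(spec, features, labels, fold_plan) {
  stopifnot(inherits(fold_plan, "fold_plan"))
  features <- as.matrix(features)
  labels <- as.integer(labels)
  all_idx <- sort(unlist(fold_plan$folds))
  scores <- rep(NA_real_, length(labels))
  for (f in seq_len(fold_plan$k)) {
    held <- fold_plan$folds[[f]]
    train <- setdiff(all_idx, held)
    if (length(unique(labels[train])) < 2L) {
      stop(sprintf("fold %d leaves a single-class training portion", f),
           call. = FALSE)
    }
    clf <- train_classifier(spec, features[train, , drop = FALSE], labels[train])
    scores[held] <- predict_scores(clf, features[held, , drop = FALSE])
  }
  out <- metric_row(labels[all_idx], scores[all_idx])
  attr(out, "n") <- length(all_idx)
  out
}

#' Evaluate every classifier of a suite
#'
#' Produces one row per (target x fingerprint model) and per pooled PCM
#' model, on the held-out test partition and optionally under k-fold
#' cross-validation of the training partition.
#'
#' @param suite a [build_suite()] result.
#' @param partitions any of `"test"`, `"cv"`.
#' @return Data frame with columns `target`, `feature_kind`, `algorithm`,
#'   `partition`, `AUC`, `SE`, `SP`, `Q`, `MCC`, `n`. PCM rows carry target
#'   `"pooled"`.
#' @export
evaluate_suite <- function(suite, partitions = c("cv", "test")) {
  stopifnot(inherits(suite, "model_suite"))
  partitions <- match.arg(partitions, c("cv", "test"), several.ok = TRUE)
  rows <- list()
  add_row <- function(target, spec, partition, metrics, n) {
    rows[[length(rows) + 1L]] <<- data.frame(
      target = target, feature_kind = spec$feature_kind,
      algorithm = spec$algorithm, partition = partition,
      AUC = metrics[["AUC"]], SE = metrics[["SE"]], SP = metrics[["SP"]],
      Q = metrics[["Q"]], MCC = metrics[["MCC"]], n = n,
      stringsAsFactors = FALSE
    )
  }

  for (tid in suite$targets) {
    ds <- suite$datasets[[tid]]
    labels <- as.integer(ds$records$label == "active")
    split <- suite$splits[[tid]]
    fps <- suite$fingerprints[[tid]]
    fold_plan <- if ("cv" %in% partitions) {
      make_folds(split, labels, suite$config$cv_folds,
                 derive_seed(suite$config$seed, paste0("folds:", tid)))
    } else NULL
    for (nm in names(suite$per_target_models[[tid]])) {
      clf <- suite$per_target_models[[tid]][[nm]]
      x <- feature_matrix_for(clf$spec$feature_kind, fps)
      if (!is.null(fold_plan)) {
        m <- cross_validate(clf$spec, x, labels, fold_plan)
        add_row(tid, clf$spec, "cv", m, attr(m, "n"))
      }
      if ("test" %in% partitions && length(split$test) > 0L) {
        scores <- predict_scores(clf, x[split$test, , drop = FALSE])
        add_row(tid, clf$spec, "test",
                metric_row(labels[split$test], scores), length(split$test))
      }
    }
  }

  train_rows <- lapply(suite$splits, `[[`, "train")
  test_rows <- lapply(suite$splits, `[[`, "test")
  for (nm in names(suite$pcm_models)) {
    clf <- suite$pcm_models[[nm]]
    kind <- clf$spec$feature_kind
    if ("cv" %in% partitions) {
      pooled <- pool_pcm_dataset(suite$datasets, suite$protein_blocks,
                                 suite$fingerprints, train_rows, kind)
      split <- list(train = seq_along(pooled$y))
      plan <- make_folds(split, pooled$y, suite$config$cv_folds,
                         derive_seed(suite$config$seed, "folds:pcm"))
      m <- cross_validate(clf$spec, pooled$x, pooled$y, plan)
      add_row("pooled", clf$spec, "cv", m, attr(m, "n"))
    }
    if ("test" %in% partitions) {
      pooled <- pool_pcm_dataset(suite$datasets, suite$protein_blocks,
                                 suite$fingerprints, test_rows, kind)
      if (length(pooled$y) > 0L) {
        scores <- predict_scores(clf, pooled$x)
        add_row("pooled", clf$spec, "test",
                metric_row(pooled$y, scores), length(pooled$y))
      }
    }
  }
  do.call(rbind, rows)
}
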