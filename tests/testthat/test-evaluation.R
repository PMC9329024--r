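test_that("confusion metrics match hand-worked examples", {
  perfect <- compute_metrics(c(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(unname(perfect[c("SE", "SP", "Q", "MCC")]), c(1, 1, 1, 1))
  chance <- compute_metrics(c(TP = 5, TN = 5, FP = 5, FN = 5))
  expect_equal(unname(chance[c("SE", "SP", "Q", "MCC")]), c(0.5, 0.5, 0.5, 0))
  m <- compute_metrics(c(TP = 3, FN = 2, TN = 2, FP = 1))
  expect_equal(unname(m["SE"]), 0.6)
  expect_equal(unname(m["SP"]), 2 / 3, tolerance = 1e-9)
  expect_equal(unname(m["Q"]), 0.625)
  expect_equal(unname(m["MCC"]), 0.2582, tolerance = 1e-4)
})

test_that("zero denominators yield 0 by convention", {
  none_pos <- compute_metrics(c(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_equal(unname(none_pos["SE"]), 0)
  expect_equal(unname(none_pos["MCC"]), 0)
  all_pred_pos <- compute_metrics(c(TP = 3, TN = 0, FP = 4, FN = 0))
  expect_equal(unname(all_pred_pos["SP"]), 0)
  expect_equal(unname(all_pred_pos["MCC"]), 0)
})

test_that("metrics agree with brute-force arithmetic on random confusion tables", {
  set.seed(51)
  for (i in 1:1000) {
    counts <- setNames(sample(0:30, 4, replace = TRUE),
                       c("TP", "TN", "FP", "FN"))
    if (sum(counts) == 0) counts["TP"] <- 1
    got <- compute_metrics(counts)
    tp <- counts[["TP"]]; tn <- counts[["TN"]]
    fp <- counts[["FP"]]; fn <- counts[["FN"]]
    # independent arithmetic, written directly from the definitions
    se <- if (tp + fn > 0) tp / (tp + fn) else 0
    sp <- if (tn + fp > 0) tn / (tn + fp) else 0
    q <- (tp + tn) / sum(counts)
    den <- sqrt(tp + fn) * sqrt(tp + fp) * sqrt(tn + fn) * sqrt(tn + fp)
    mcc <- if (den == 0) 0 else (tp * tn - fn * fp) / den
    expect_identical(unname(got["Q"]), q)
    expect_equal(unname(got[c("SE", "SP", "MCC")]), c(se, sp, mcc),
                 tolerance = 1e-12)
  }
})

test_that("MCC is symmetric under class swap and antisymmetric under negation", {
  set.seed(52)
  for (i in 1:200) {
    counts <- setNames(sample(1:20, 4, replace = TRUE),
                       c("TP", "TN", "FP", "FN"))
    m <- compute_metrics(counts)
    swapped <- compute_metrics(c(TP = counts[["TN"]], TN = counts[["TP"]],
                                 FP = counts[["FN"]], FN = counts[["FP"]]))
    negated <- compute_metrics(c(TP = counts[["FN"]], TN = counts[["FP"]],
                                 FP = counts[["TN"]], FN = counts[["TP"]]))
    expect_equal(unname(m["MCC"]), unname(swapped["MCC"]), tolerance = 1e-12)
    expect_equal(unname(m["MCC"]), -unname(negated["MCC"]), tolerance = 1e-12)
  }
})

test_that("ROC AUC matches examples and exhaustive pair enumeration", {
  expect_equal(roc_auc(c(1, 0), c(0.9, 0.1)), 1)
  expect_equal(roc_auc(c(1, 0), c(0.1, 0.9)), 0)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.8, 0.6, 0.8, 0.2)), 0.625)
  expect_error(roc_auc(c(1, 1), c(0.5, 0.7)), "both classes")
  # O(n*m) pair enumeration oracle with ties counting one half
  pair_auc <- function(labels, scores) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    total <- 0
    for (p in pos) for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
    total / (length(pos) * length(neg))
  }
  set.seed(53)
  for (i in 1:40) {
    n <- sample(2:30, 1); m <- sample(2:30, 1)
    labels <- rep(c(1, 0), c(n, m))
    # coarse scores so that ties actually occur
    scores <- sample(seq(0, 1, 0.1), n + m, replace = TRUE)
    expect_equal(roc_auc(labels, scores), pair_auc(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("cross-validation pools out-of-fold predictions deterministically", {
  # duplicated points: every point's twin sits in some other fold's
  # training data, so pooled 1-NN predictions are perfect
  set.seed(54)
  base <- matrix(rnorm(20), 10, 2)
  x <- rbind(base, base)
  y <- rep(rep(c(0L, 1L), 5), 2)
  # hand-built plan: rows i and i + 10 are twins; fold f holds base pair
  # {2f-1, 2f} plus the twins of the NEXT fold's base pair, so every row's
  # twin always sits in some other fold's training data
  plan <- structure(list(
    folds = lapply(1:5, function(f) {
      nxt <- (f %% 5) + 1L
      sort(c(2L * f - 1L, 2L * f, 2L * nxt - 1L + 10L, 2L * nxt + 10L))
    }),
    k = 5L, seed = 0L), class = "fold_plan")
  spec <- model_spec("KNN", "MACCS", list(knn_k = 1L), seed = 1L)
  m <- cross_validate(spec, x, y, plan)
  expect_equal(unname(m["SE"]), 1)
  expect_equal(unname(m["SP"]), 1)
  # shuffling row presentation with the same fold plan gives the same report
  m2 <- cross_validate(spec, x, y, plan)
  expect_identical(m, m2)
})

test_that("2-member folds match a brute-force leave-pair-out oracle", {
  set.seed(55)
  x <- matrix(rnorm(20), 10, 2)
  y <- rep(c(0L, 1L), 5)
  sp <- stratified_split(y, 0, seed = 2L)
  plan <- make_folds(sp, y, k = 5L, seed = 3L)
  spec <- model_spec("KNN", "MACCS", list(knn_k = 1L), seed = 1L)
  got <- cross_validate(spec, x, y, plan)
  # independent loop: for each fold, 1-NN by explicit distance search
  scores <- numeric(10)
  for (f in plan$folds) {
    train <- setdiff(1:10, f)
    sc <- fit_scaler(x[train, ])
    xt <- apply_scaler(sc, x[train, ])
    for (i in f) {
      xi <- apply_scaler(sc, x[i, , drop = FALSE])
      d <- sqrt(rowSums(sweep(xt, 2, xi, "-")^2))
      scores[i] <- y[train][which.min(d)]
    }
  }
  expect_equal(unname(got["Q"]), mean((scores >= 0.5) == y))
  expect_equal(unname(got["AUC"]), roc_auc(y, scores))
})

test_that("suite evaluation emits the tables-style report", {
  suite <- toy_suite()
  rep <- evaluate_suite(suite, partitions = c("cv", "test"))
  # 2 targets x 8 models x 2 partitions + 8 PCM x 2 partitions
  expect_equal(nrow(rep), 2L * 8L * 2L + 8L * 2L)
  expect_true(all(c("target", "feature_kind", "algorithm", "partition",
                    "AUC", "SE", "SP", "Q", "MCC", "n") %in% names(rep)))
  expect_true(all(rep$AUC >= 0 & rep$AUC <= 1))
  expect_true(all(rep$MCC >= -1 & rep$MCC <= 1))
  expect_true(all(rep$partition %in% c("cv", "test")))
  expect_equal(sum(rep$target == "pooled"), 16L)
})
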