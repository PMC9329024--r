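test_that("stratified splitting reserves per-class fractions and is seeded", {
  labels <- rep(c(1L, 0L), c(40L, 60L))
  sp <- stratified_split(labels, 0.2, seed = 5L)
  expect_equal(sum(labels[sp$test] == 1L), 8L)
  expect_equal(sum(labels[sp$test] == 0L), 12L)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(labels))
  # determinism
  sp2 <- stratified_split(labels, 0.2, seed = 5L)
  expect_identical(sp$test, sp2$test)
  # boundary: no test set
  sp0 <- stratified_split(labels, 0, seed = 5L)
  expect_equal(length(sp0$test), 0L)
  expect_equal(length(sp0$train), 100L)
  expect_error(stratified_split(c(1L, 0L, 0L), 0.2), "fewer than 2")
})

test_that("fold plans partition the training set with balanced, stratified folds", {
  labels <- rep(c(1L, 0L), c(13L, 13L))
  sp <- stratified_split(labels, 0, seed = 1L)
  fp <- make_folds(sp, labels, k = 5L, seed = 2L)
  sizes <- lengths(fp$folds)
  expect_equal(sum(sizes), 26L)
  expect_lte(diff(range(sizes)), 1L)
  expect_equal(sort(unlist(fp$folds)), sp$train)
  # per-class fold counts within 1 on an imbalanced toy
  labels2 <- rep(c(1L, 0L), c(20L, 5L))
  sp2 <- stratified_split(labels2, 0, seed = 1L)
  fp2 <- make_folds(sp2, labels2, k = 5L, seed = 3L)
  for (cl in c(0L, 1L)) {
    counts <- vapply(fp2$folds, function(f) sum(labels2[f] == cl), integer(1))
    expect_lte(diff(range(counts)), 1L)
  }
  expect_error(make_folds(sp2, labels2, k = 6L), "fewer than k")
})

test_that("model specs carry the algorithm_feature naming convention", {
  expect_equal(model_name(model_spec("RF", "MACCS")), "RF_MACCS")
  expect_equal(model_name(model_spec("KNN", "ECFP6_protein")),
               "KNN_ECFP6_protein")
  expect_equal(length(suite_model_names()), 16L)
  expect_equal(suite_model_names()[1:2], c("RF_MACCS", "RF_ECFP6"))
  expect_error(model_spec("GBM", "MACCS"))
})

test_that("1-NN memorizes its training set and RF separates a margin toy", {
  set.seed(41)
  x <- matrix(rnorm(80), 40, 2)
  y <- as.integer(x[, 1] + x[, 2] > 0)
  # enforce a margin of 1
  x[y == 1, 1] <- x[y == 1, 1] + 1
  x[y == 0, 1] <- x[y == 0, 1] - 1
  knn1 <- train_classifier(model_spec("KNN", "MACCS",
                                      list(knn_k = 1L), seed = 1L), x, y)
  expect_equal(predict_votes(knn1, x), y)
  rf <- train_classifier(model_spec("RF", "MACCS", seed = 1L), x, y)
  expect_equal(mean(predict_votes(rf, x) == y), 1)
  svm <- train_classifier(model_spec("SVM", "MACCS", seed = 1L), x, y)
  expect_gte(mean(predict_votes(svm, x) == y), 0.95)
  nn <- train_classifier(model_spec("NN", "MACCS", seed = 1L), x, y)
  expect_gte(mean(predict_votes(nn, x) == y), 0.95)
})

test_that("training is deterministic under a fixed seed", {
  set.seed(42)
  x <- matrix(rnorm(200), 50, 4)
  y <- rbinom(50, 1, 0.5)
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  probe <- matrix(rnorm(20), 5, 4)
  for (alg in c("RF", "SVM", "KNN", "NN")) {
    c1 <- train_classifier(model_spec(alg, "MACCS", seed = 9L), x, y)
    c2 <- train_classifier(model_spec(alg, "MACCS", seed = 9L), x, y)
    expect_identical(predict_scores(c1, probe), predict_scores(c2, probe),
                     label = paste(alg, "scores"))
  }
  expect_error(train_classifier(model_spec("RF", "MACCS"), x, rep(1L, 50)),
               "single class")
})

test_that("pooling PCM rows is additive and appends the right protein block", {
  bm <- toy_benchmark()
  suite <- toy_suite()
  train_rows <- lapply(suite$splits, `[[`, "train")
  pooled <- pool_pcm_dataset(suite$datasets, suite$protein_blocks,
                             suite$fingerprints, train_rows, "MACCS_protein")
  expect_equal(nrow(pooled$x), sum(lengths(train_rows)))
  expect_equal(ncol(pooled$x), 166L + ncol(suite$protein_blocks))
  # each row carries its own target's protein block
  t1 <- suite$targets[1]
  rows_t1 <- which(pooled$target == t1)
  prot_cols <- (166L + 1L):ncol(pooled$x)
  expect_true(all(apply(pooled$x[rows_t1, prot_cols, drop = FALSE], 1,
                        function(r) all(r == suite$protein_blocks[t1, ]))))
  # pooling a single dataset is that dataset with the block appended
  single <- pool_pcm_dataset(suite$datasets[1], suite$protein_blocks,
                             suite$fingerprints[1], train_rows[1],
                             "ECFP6_protein")
  expect_equal(nrow(single$x), length(train_rows[[1]]))
  expect_equal(ncol(single$x), 1024L + ncol(suite$protein_blocks))
})

test_that("suite cardinality follows 8T + 8 and votes are always 16", {
  suite <- toy_suite()
  card <- suite_cardinality(suite)
  expect_equal(unname(card["total"]), 8L * 2L + 8L)
  expect_equal(unname(card["per_target"]), 16L)
  expect_equal(unname(card["pcm"]), 8L)
  v <- collect_votes(suite, "CCOc1ccccc1", suite$targets[1])
  expect_equal(length(v$votes), 16L)
  expect_equal(names(v$votes), suite_model_names())
  expect_equal(v$vote_count, sum(v$votes))
  # single-target suite: 8 + 8
  bm <- toy_benchmark()
  one <- build_suite(bm$datasets[1], bm$registry,
                     list(seed = 11L, models = fast_models()))
  expect_equal(unname(suite_cardinality(one)["total"]), 16L)
})

test_that("test rows never leak into training folds", {
  suite <- toy_suite()
  for (tid in suite$targets) {
    sp <- suite$splits[[tid]]
    labels <- as.integer(suite$datasets[[tid]]$records$label == "active")
    folds <- make_folds(sp, labels, k = 5L, seed = 1L)
    expect_length(intersect(unlist(folds$folds), sp$test), 0L)
    expect_length(intersect(sp$train, sp$test), 0L)
  }
})

test_that("suite building is reproducible end to end", {
  bm <- toy_benchmark()
  s1 <- build_suite(bm$datasets, bm$registry,
                    list(seed = 99L, models = fast_models()))
  s2 <- build_suite(bm$datasets, bm$registry,
                    list(seed = 99L, models = fast_models()))
  probe <- "c1cc(Cl)ccc1CCN"
  for (tid in s1$targets) {
    v1 <- collect_votes(s1, probe, tid)
    v2 <- collect_votes(s2, probe, tid)
    expect_identical(v1$votes, v2$votes)
  }
  expect_identical(mtqsar:::suite_digest(s1), mtqsar:::suite_digest(s2))
})
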