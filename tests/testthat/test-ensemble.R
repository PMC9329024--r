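test_that("interaction calls follow the at-least-cutoff rule", {
  cfg <- ensemble_config(cutoff = 9L)
  mk <- function(count) list(vote_count = count)
  expect_equal(call_interaction(mk(9L), cfg), "active")
  expect_equal(call_interaction(mk(8L), cfg), "inactive")
  for (cut in 1:16) {
    expect_equal(call_interaction(mk(16L), ensemble_config(cut)), "active")
    expect_equal(call_interaction(mk(0L), ensemble_config(cut)), "inactive")
  }
  expect_error(ensemble_config(0L), "\\[1, 16\\]")
  expect_error(ensemble_config(17L), "\\[1, 16\\]")
})

test_that("cutoff sweep reproduces hand-enumerated confusion tables", {
  sw <- sweep_cutoffs(c(12L, 10L, 7L, 3L), c(1, 1, 0, 0))
  r9 <- sw[sw$cutoff == 9, ]
  expect_equal(unname(unlist(r9[c("SE", "SP", "Q", "MCC")])), c(1, 1, 1, 1))
  r11 <- sw[sw$cutoff == 11, ]
  expect_equal(r11$SE, 0.5)
  expect_equal(r11$SP, 1)
  expect_equal(r11$Q, 0.75)
  expect_equal(r11$MCC, 0.5774, tolerance = 1e-4)
  # perfectly separated votes are perfect at every cutoff
  sep <- sweep_cutoffs(c(16L, 0L), c(1, 0))
  expect_true(all(sep$Q == 1))
  expect_true(all(abs(sep$MCC) == 1))
  # the sweep's AUC column is balanced accuracy; the ranking AUC of the
  # vote count is attached separately
  expect_equal(sw$AUC, (sw$SE + sw$SP) / 2)
  expect_equal(attr(sw, "vote_auc"), 1)
})

test_that("SE is non-increasing and SP non-decreasing across every sweep", {
  set.seed(61)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    votes <- sample(0:16, n, replace = TRUE)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    sw <- sweep_cutoffs(votes, labels)
    expect_true(all(diff(sw$SE) <= 1e-12))
    expect_true(all(diff(sw$SP) >= -1e-12))
  }
  expect_error(sweep_cutoffs(c(3L, 5L), c(1, 1)), "both classes")
})

test_that("vote collection answers only for registered targets", {
  suite <- toy_suite()
  expect_error(collect_votes(suite, "CCO", "NOPE"),
               "registered targets")
  v <- collect_votes(suite, "CCO", suite$targets[2])
  expect_true(all(v$votes %in% c(0L, 1L)))
})

test_that("batch prediction enumerates molecule x target with skip-and-log", {
  suite <- toy_suite()
  mols <- data.frame(
    molecule_id = c("a", "b", "c"),
    smiles = c("CCOc1ccccc1", "c1cc(F)ccc1CC", "CC(=O)NCC"),
    stringsAsFactors = FALSE
  )
  res <- predict_batch(suite, mols)
  expect_equal(nrow(res$predictions), 3L * 2L)
  expect_equal(nrow(res$rejections), 0L)
  expect_true(all(suite_model_names() %in% names(res$predictions)))
  expect_equal(res$predictions$vote_count,
               rowSums(res$predictions[, suite_model_names()]))
  # a bad SMILES among five: four predicted, one rejection row
  mols5 <- rbind(mols, data.frame(
    molecule_id = c("d", "bad"),
    smiles = c("CCN", "not][a][smiles"),
    stringsAsFactors = FALSE
  ))
  res5 <- predict_batch(suite, mols5, targets = suite$targets[1])
  expect_equal(nrow(res5$predictions), 4L)
  expect_equal(res5$rejections$molecule_id, "bad")
  # the batch cap is enforced with a clear message
  expect_error(
    predict_batch(suite, mols, config = ensemble_config(max_batch = 2L)),
    "exceeds the cap of 2"
  )
  # empty input gives an empty, well-formed table
  res0 <- predict_batch(suite, mols[0, ])
  expect_equal(nrow(res0$predictions), 0L)
})

test_that("per-target and PCM vote blocks respond to the right inputs", {
  suite <- toy_suite()
  # same compound, two targets: compound fingerprints identical, so any
  # vote differences come from per-target models or the protein block
  v1 <- collect_votes(suite, "CCOc1ccccc1C", suite$targets[1])
  v2 <- collect_votes(suite, "CCOc1ccccc1C", suite$targets[2])
  expect_equal(names(v1$votes), names(v2$votes))
  expect_equal(length(v1$votes), 16L)
})

test_that("networks collect distinct active calls with hand-counted degrees", {
  preds <- data.frame(
    molecule_id = c("c1", "c1", "c2", "c2", "c1"),
    target = c("t1", "t2", "t1", "t2", "t1"),
    call = c("active", "active", "active", "inactive", "active"),
    stringsAsFactors = FALSE
  )
  net <- build_network(preds)
  expect_equal(igraph::ecount(net), 3L)  # duplicate (c1, t1) collapses
  st <- degree_stats(net)
  expect_equal(unname(st$degrees[c("c1", "t1", "c2", "t2")]), c(2, 2, 1, 1))
  expect_equal(st$median_degree, 1.5)
  expect_equal(st$mean_targets_per_compound, 1.5)
  expect_equal(st$mean_compounds_per_target, 1.5)
  expect_equal(sum(st$degrees), 2 * igraph::ecount(net))
  # empty active set
  none <- build_network(preds[preds$call == "nope", ])
  expect_equal(igraph::ecount(none), 0L)
  expect_true(degree_stats(none)$empty)
})

test_that("median-degree filtering retains only strictly-above compounds", {
  preds <- data.frame(
    molecule_id = c("c1", "c1", "c2"),
    target = c("t1", "t2", "t1"),
    call = "active", stringsAsFactors = FALSE
  )
  net <- build_network(preds)
  filt <- filter_by_median_degree(net)
  kinds <- igraph::vertex_attr(filt, "kind")
  expect_equal(sort(igraph::V(filt)$name[kinds == "compound"]), "c1")
  expect_equal(sort(igraph::V(filt)$name[kinds == "target"]), c("t1", "t2"))
  # all compounds at equal degree: none strictly exceeds the median
  eq <- build_network(data.frame(molecule_id = c("c1", "c2"),
                                 target = c("t1", "t2"), call = "active",
                                 stringsAsFactors = FALSE))
  expect_warning(filt_eq <- filter_by_median_degree(eq), "all compounds dropped")
  expect_equal(sum(igraph::vertex_attr(filt_eq, "kind") == "compound"), 0L)
  # star: hub compound degree 5, median over all nodes is 1
  star <- build_network(data.frame(molecule_id = "hub",
                                   target = paste0("t", 1:5), call = "active",
                                   stringsAsFactors = FALSE))
  st <- degree_stats(star)
  expect_equal(unname(st$degrees["hub"]), 5)
  expect_equal(st$median_degree, 1)
  filt_star <- filter_by_median_degree(star)
  expect_true("hub" %in% igraph::V(filt_star)$name)
})

test_that("network exports are written in SIF and GraphML", {
  net <- build_network(data.frame(molecule_id = c("c1", "c2"),
                                  target = "t1", call = "active",
                                  stringsAsFactors = FALSE))
  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, sif)
  lines <- readLines(sif)
  expect_equal(length(lines), 2L)
  expect_true(all(grepl(" targets t1$", lines)))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  expect_true(file.size(gml) > 0)
})

test_that("molecule files are read in SMILES and SDF formats", {
  smi <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "c1ccccc1"), smi)
  mols <- read_molecules(smi)
  expect_equal(mols$molecule_id, c("ethanol", "mol2"))
  expect_equal(mols$smiles, c("CCO", "c1ccccc1"))
})
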