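# Shared fixtures. Expensive objects (benchmarks, suites) are built once
# per test run and memoized, so several test files can share them.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, builder(), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# Lean hyperparameters for toy suites: plenty for the planted signal at toy
# sizes, cheap enough to rebuild in seconds.
fast_models <- function() {
  list(rf_ntree = 100L, nn_epochs = 120L, nn_size = 8L)
}

toy_benchmark <- function() {
  memo("toy_benchmark", function() generate_benchmark(2L, 60L, seed = 11L))
}

toy_suite <- function() {
  memo("toy_suite", function() {
    bm <- toy_benchmark()
    build_suite(bm$datasets, bm$registry,
                list(seed = 11L, models = fast_models()))
  })
}

# The default-condition benchmark suite (5 targets x 400 compounds, default
# hyperparameters) used by the signal-recovery checks.
bench_suite <- function() {
  memo("bench_suite", function() {
    bm <- generate_benchmark(5L, 400L, seed = 101L)
    suite <- build_suite(bm$datasets, bm$registry, list(seed = 101L))
    list(benchmark = bm, suite = suite)
  })
}

# Raw activity records for curation tests: known pIC50 values, exact IC50s.
raw_records <- function(pic50s, target_id = "TGT",
                        smiles = NULL) {
  n <- length(pic50s)
  if (is.null(smiles)) {
    # n structurally distinct parseable molecules
    pool <- c("CCO", "CCCO", "CCCCO", "CCN", "CCCN", "CCCCN", "c1ccccc1",
              "Cc1ccccc1", "CCc1ccccc1", "c1ccncc1", "CC(C)O", "CC(C)N",
              "CCOC", "CCSC", "CC(=O)C", "CC(=O)N", "CCCl", "CCBr",
              "CCCC(=O)O", "CC(C)CO")
    stopifnot(n <= length(pool))
    smiles <- pool[seq_len(n)]
  }
  data.frame(
    compound_id = sprintf("c%03d", seq_len(n)),
    smiles = smiles,
    ic50 = 10^(-pic50s),
    target_id = target_id,
    stringsAsFactors = FALSE
  )
}
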