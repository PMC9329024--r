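# Synthetic chemogenomics benchmark with planted structure-activity signal.
#
# Molecules are assembled from a fixed grammar of chain-safe SMILES
# fragments (every fragment begins and ends on an atom with spare valence,
# so plain concatenation always yields a parseable molecule). Each target
# owns a small disjoint set of distinctive "signature" fragments; compounds
# carrying a signature fragment draw their pIC50 from N(mu0 + delta, sigma)
# and background compounds from N(mu0, sigma). With the defaults mu0 = 4.5,
# delta = 3, sigma = 0.5 the two potency modes are well separated: the
# probability that a compound's pIC50 crosses the midpoint against its
# fragment status is 2 * (1 - pnorm(delta / (2 * sigma))) ~ 0.27%.
# Protein sequences are random 200-600-mers: pooled PCM models can exploit
# them only as target identity encodings.

# Background fragments: common scaffolds and linkers.
.background_fragments <- c(
  "C", "CC", "CCC", "C(C)C", "CC(C)C", "CCCC",
  "c1ccccc1", "Cc1ccccc1", "C1CCCCC1", "C1CCCC1",
  "C1CCNCC1", "C1CCOCC1", "c1ccncc1", "C1CCCCC1C",
  "C(O)C", "CC(O)C", "C(N)C", "CC(=O)C", "CC(=O)NC", "COC",
  "CSC", "CN(C)C", "CC(C)(C)C", "c1ccc2ccccc2c1"
)

# Signature fragments: distinctive decorated rings, disjoint from the
# background pool, two per target.
.signature_fragments <- c(
  "c1cc(F)ccc1", "c1cc(Cl)ccc1", "c1cc(Br)ccc1", "c1cc(I)ccc1",
  "c1cc(C(F)(F)F)ccc1", "c1cc(C#N)ccc1", "c1cc(O)ccc1", "c1cc(N)ccc1",
  "c1cc(OC)ccc1", "c1cc(SC)ccc1", "c1cc(F)cnc1", "c1cc(Cl)cnc1",
  "c1cc(Br)cnc1", "c1cc(OC)cnc1", "c1cc(C#N)cnc1", "c1cc(N)cnc1",
  "C1CC(F)CCC1", "C1CC(Cl)CCC1", "C1CC(Br)CCC1", "C1CC(O)CCC1",
  "C1CC(N)CCC1", "C1CC(OC)CCC1", "c1cc(F)cc(F)c1", "c1cc(Cl)cc(Cl)c1",
  "c1cc(Br)cc(F)c1", "c1cc(OC)cc(OC)c1", "c1cc(C(F)(F)F)cnc1",
  "c1cc(O)cnc1", "C1CC(C(F)(F)F)CCC1", "C1CC(SC)CCC1",
  "c1cc(N(C)C)ccc1", "c1cc(N(C)C)cnc1"
)

#' Generate synthetic protein targets with planted fragment signatures
#'
#' @param n number of targets (each claims two signature fragments; at most
#'   `length(mtqsar:::.signature_fragments) / 2 = 16` targets).
#' @param seed integer seed; generation is bit-reproducible.
#' @return A list of `n` targets, each a list with `target_id`, `sequence`
#'   (random amino-acid string of length 200-600) and `signature`
#'   (character vector of fragment SMILES with attribute `weights`).
#' @export
generate_targets <- function(n, seed = 0L) {
  stopifnot(n >= 1L)
  max_n <- length(.signature_fragments) %/% 2L
  if (n > max_n) {
    stop(sprintf("at most %d synthetic targets are supported", max_n),
         call. = FALSE)
  }
  with_seed(derive_seed(seed, "targets"), {
    frag_order <- sample(.signature_fragments)
    lapply(seq_len(n), function(i) {
      len <- sample(200:600, 1)
      sig <- frag_order[(2L * i - 1L):(2L * i)]
      attr(sig, "weights") <- runif(2, 0.8, 1.2)
      list(
        target_id = sprintf("T%02d", i),
        sequence = paste(sample(AA_LETTERS, len, replace = TRUE),
                         collapse = ""),
        signature = sig
      )
    })
  })
}

# Assemble one molecule: 2-4 background fragments, optionally with one
# signature fragment spliced in at a random position.
assemble_molecule <- function(signature_fragment = NULL) {
  k <- sample(2:4, 1)
  frags <- sample(.background_fragments, k, replace = TRUE)
  if (!is.null(signature_fragment)) {
    pos <- sample(seq_len(k + 1L), 1)
    frags <- append(frags, signature_fragment, after = pos - 1L)
  }
  structure(paste(frags, collapse = ""), fragments = frags)
}

#' Generate a synthetic per-target activity dataset
#'
#' Roughly half of the compounds carry one of the target's signature
#' fragments; their pIC50 values are drawn `delta` log-units above the
#' background mode. The records are then curated through [build_dataset()]
#' so the result satisfies every activity-dataset invariant, with the
#' threshold picked by class balance.
#'
#' @param target a [generate_targets()] element.
#' @param n_compounds number of compounds before deduplication (>= 20).
#' @param seed integer seed.
#' @param delta separation between signature-matched and background mean
#'   pIC50 (default 3).
#' @param sigma activity noise standard deviation in pIC50 units
#'   (default 0.5).
#' @param mu0 background mean pIC50 (default 4.5).
#' @return An `activity_dataset` whose records carry an extra attribute
#'   `fragment_sets` (list of the fragment multiset of each canonical
#'   structure, for ground-truth bookkeeping).
#' @export
generate_activity_dataset <- function(target, n_compounds, seed = 0L,
                                      delta = 3, sigma = 0.5, mu0 = 4.5) {
  stopifnot(n_compounds >= 20L)
  gen <- with_seed(derive_seed(seed, paste0("activity:", target$target_id)), {
    has_sig <- rbinom(n_compounds, 1, 0.5) == 1L
    mols <- lapply(seq_len(n_compounds), function(i) {
      sig <- if (has_sig[i]) sample(target$signature, 1) else NULL
      assemble_molecule(sig)
    })
    pic50 <- rnorm(n_compounds, mu0 + delta * has_sig, sigma)
    list(mols = mols, has_sig = has_sig, pic50 = pic50)
  })
  raw <- data.frame(
    compound_id = sprintf("%s_c%04d", target$target_id,
                          seq_len(n_compounds)),
    smiles = vapply(gen$mols, as.character, character(1)),
    ic50 = 10^(-gen$pic50),
    target_id = target$target_id,
    stringsAsFactors = FALSE
  )
  ds <- suppressWarnings(build_dataset(raw, target$target_id))
  # fragment multisets keyed by canonical structure (post-curation rows)
  can <- standardize_batch(raw$smiles)$canonical
  frag_by_can <- list()
  for (i in seq_len(n_compounds)) {
    if (!is.na(can[i]) && is.null(frag_by_can[[can[i]]])) {
      frag_by_can[[can[i]]] <- attr(gen$mols[[i]], "fragments")
    }
  }
  attr(ds, "fragment_sets") <- frag_by_can[ds$records$canonical_smiles]
  ds
}

#' Generate a full synthetic multi-target benchmark
#'
#' @param n_targets number of targets.
#' @param n_compounds_per_target compounds generated per target.
#' @param seed master seed; regeneration with the same arguments is
#'   bit-reproducible.
#' @param delta,sigma,mu0 activity model parameters, see
#'   [generate_activity_dataset()].
#' @return A list of class `synthetic_benchmark`: `targets`, `registry`
#'   (named sequence vector), `datasets` (named list of
#'   `activity_dataset`), `ground_truth` (logical compound x target
#'   matrix: the compound carries a signature fragment of the target),
#'   `seed`, `delta`, `sigma`.
#' @export
generate_benchmark <- function(n_targets = 5L, n_compounds_per_target = 400L,
                               seed = 0L, delta = 3, sigma = 0.5, mu0 = 4.5) {
  stopifnot(n_targets >= 1L, n_compounds_per_target >= 20L)
  targets <- generate_targets(n_targets, seed)
  datasets <- lapply(targets, generate_activity_dataset,
                     n_compounds = n_compounds_per_target, seed = seed,
                     delta = delta, sigma = sigma, mu0 = mu0)
  names(datasets) <- vapply(targets, `[[`, character(1), "target_id")
  registry <- vapply(targets, `[[`, character(1), "sequence")
  names(registry) <- names(datasets)

  all_compounds <- unique(unlist(lapply(datasets, function(d) {
    d$records$canonical_smiles
  })))
  frag_sets <- list()
  for (d in datasets) {
    fs <- attr(d, "fragment_sets")
    for (i in seq_along(fs)) {
      key <- d$records$canonical_smiles[i]
      if (is.null(frag_sets[[key]])) frag_sets[[key]] <- fs[[i]]
    }
  }
  ground_truth <- ground_truth_matrix(all_compounds, frag_sets, targets)

  structure(
    list(targets = targets, registry = registry, datasets = datasets,
         ground_truth = ground_truth, seed = seed, delta = delta,
         sigma = sigma),
    class = "synthetic_benchmark"
  )
}

#' Ground-truth interaction matrix from fragment membership
#'
#' A (compound, target) pair is a ground-truth positive when the compound's
#' fragment multiset contains at least one of the target's signature
#' fragments — so a compound carrying signatures of two targets is positive
#' for both.
#'
#' @param compounds character vector of canonical SMILES (row names).
#' @param fragment_sets named list mapping each compound to its fragment
#'   multiset.
#' @param targets list of [generate_targets()] elements (column names).
#' @return Logical matrix, compounds x targets.
#' @export
ground_truth_matrix <- function(compounds, fragment_sets, targets) {
  out <- matrix(FALSE, length(compounds), length(targets),
                dimnames = list(compounds,
                                vapply(targets, `[[`, character(1),
                                       "target_id")))
  for (j in seq_along(targets)) {
    sig <- targets[[j]]$signature
    for (i in seq_along(compounds)) {
      fs <- fragment_sets[[compounds[i]]]
      out[i, j] <- !is.null(fs) && any(fs %in% sig)
    }
  }
  out
}

#' Write a benchmark to disk in pipeline input formats
#'
#' Emits `activities.csv` (raw records the curation stage consumes, one
#' file for all targets), `targets.fasta` and `ground_truth.csv`.
#'
#' @param benchmark a [generate_benchmark()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_benchmark <- function(benchmark, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  act <- do.call(rbind, lapply(benchmark$datasets, function(d) {
    data.frame(compound_id = d$records$compound_id,
               smiles = d$records$canonical_smiles,
               ic50 = 10^(-d$records$pic50),
               target_id = d$target_id,
               stringsAsFactors = FALSE)
  }))
  act_path <- file.path(dir, "activities.csv")
  write.csv(act, act_path, row.names = FALSE)
  fasta_path <- file.path(dir, "targets.fasta")
  writeLines(unlist(lapply(names(benchmark$registry), function(tid) {
    c(paste0(">", tid), benchmark$registry[[tid]])
  })), fasta_path)
  gt <- benchmark$ground_truth
  gt_df <- data.frame(compound = rownames(gt), gt, check.names = FALSE)
  gt_path <- file.path(dir, "ground_truth.csv")
  write.csv(gt_df, gt_path, row.names = FALSE)
  invisible(c(act_path, fasta_path, gt_path))
}
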