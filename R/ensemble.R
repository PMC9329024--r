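# Multivoting ensemble: each compound-target pair receives exactly 16
# binary votes (the 8 per-target fingerprint models followed by the 8
# pooled PCM models, in canonical order) and is called active when the
# number of positive votes reaches the configured cutoff (default 9, the
# calibrated optimum of the cutoff sweep; the call rule is vote_count >=
# cutoff).

#' Ensemble configuration
#'
#' @param cutoff integer in `[1, 16]`; a pair is called active when at
#'   least this many of the 16 classifiers vote positive.
#' @param max_batch maximum number of molecules accepted by
#'   [predict_batch()].
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(cutoff = 9L, max_batch = 1000L) {
  cutoff <- as.integer(cutoff)
  if (cutoff < 1L || cutoff > 16L) stop("cutoff must lie in [1, 16]",
                                        call. = FALSE)
  structure(list(cutoff = cutoff, max_batch = as.integer(max_batch)),
            class = "ensemble_config")
}

# Vote matrix (n molecules x 16 models, canonical column order) for one
# target, given precomputed fingerprints of the molecules.
votes_for_target <- function(suite, fps, target_id) {
  if (!target_id %in% suite$targets) {
    stop(sprintf("unknown target '%s'; registered targets: %s", target_id,
                 paste(suite$targets, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(fps$maccs)
  votes <- matrix(NA_integer_, n, 16,
                  dimnames = list(NULL, suite_model_names()))
  for (nm in names(suite$per_target_models[[target_id]])) {
    clf <- suite$per_target_models[[target_id]][[nm]]
    x <- feature_matrix_for(clf$spec$feature_kind, fps)
    votes[, nm] <- predict_votes(clf, x)
  }
  prot <- suite$protein_blocks[target_id, ]
  for (nm in names(suite$pcm_models)) {
    clf <- suite$pcm_models[[nm]]
    x <- feature_matrix_for(clf$spec$feature_kind, fps, prot)
    votes[, nm] <- predict_votes(clf, x)
  }
  votes
}

#' Collect the 16 votes for one compound-target pair
#'
#' @param suite a [build_suite()] result.
#' @param smiles a single SMILES string.
#' @param target_id a target registered in the suite.
#' @return A list of class `vote_vector`: `compound` (canonical SMILES),
#'   `target_id`, `votes` (named 16-element 0/1 vector in canonical model
#'   order) and `vote_count`.
#' @export
collect_votes <- function(suite, smiles, target_id) {
  stopifnot(inherits(suite, "model_suite"), length(smiles) == 1L)
  fps <- featurize_compounds(smiles)
  votes <- votes_for_target(suite, fps, target_id)[1, ]
  structure(
    list(compound = ob_convert(smiles, "CAN"), target_id = target_id,
         votes = votes, vote_count = sum(votes)),
    class = "vote_vector"
  )
}

#' Cutoff-threshold a vote vector into an interaction call
#'
#' @param votes a [collect_votes()] result (or any list with
#'   `vote_count`).
#' @param config an [ensemble_config()].
#' @return `"active"` if `vote_count >= cutoff`, else `"inactive"`.
#' @export
call_interaction <- function(votes, config = ensemble_config()) {
  if (votes$vote_count >= config$cutoff) "active" else "inactive"
}

#' Sweep the ensemble cutoff from 1 to 16
#'
#' For every cutoff the vote counts are thresholded into calls and SE, SP,
#' Q and MCC computed. The `AUC` column is the balanced accuracy
#' `(SE + SP) / 2` of the thresholded calls at that cutoff; the orthodox
#' ranking AUC of the vote count used as a score (ties = 1/2) is attached
#' once as attribute `vote_auc`. Because the positive set at cutoff c + 1
#' is a subset of the one at cutoff c, SE is non-increasing and SP
#' non-decreasing across the sweep.
#'
#' @param vote_counts integer vector of vote counts (0-16), one per
#'   compound-target pair.
#' @param labels true 0/1 labels for the pairs (both classes present).
#' @return Data frame with columns `cutoff`, `AUC`, `Q`, `SE`, `SP`, `MCC`
#'   and attribute `vote_auc`.
#' @export
sweep_cutoffs <- function(vote_counts, labels) {
  labels <- as.integer(labels)
  stopifnot(length(vote_counts) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to sweep cutoffs", call. = FALSE)
  }
  rows <- lapply(1:16, function(cut) {
    m <- compute_metrics(confusion_counts(labels,
                                          as.integer(vote_counts >= cut)))
    data.frame(cutoff = cut, AUC = (m[["SE"]] + m[["SP"]]) / 2,
               Q = m[["Q"]], SE = m[["SE"]], SP = m[["SP"]], MCC = m[["MCC"]])
  })
  out <- do.call(rbind, rows)
  attr(out, "vote_auc") <- roc_auc(labels, vote_counts)
  out
}

#' Read query molecules from a SMILES (.smi) or SDF file
#'
#' SMILES files carry one molecule per line (`smiles [id]`); SDF files are
#' parsed with ChemmineR and identified by their title block.
#'
#' @param path input file; format chosen by extension (`.sdf` vs anything
#'   else = SMILES).
#' @return Data frame with columns `molecule_id`, `smiles`.
#' @export
read_molecules <- function(path) {
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) {
    sdf <- ChemmineR::read.SDFset(path)
    ids <- ChemmineR::sdfid(sdf)
    smi <- as.character(ChemmineR::sdf2smiles(sdf))
    return(data.frame(molecule_id = ids, smiles = smi,
                      stringsAsFactors = FALSE))
  }
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  data.frame(
    molecule_id = vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1L) parts[[i]][2] else sprintf("mol%d", i)
    }, character(1)),
    smiles = vapply(parts, `[[`, character(1), 1),
    stringsAsFactors = FALSE
  )
}

#' Batch prediction over molecules and targets
#'
#' @param suite a [build_suite()] result.
#' @param molecules data frame with columns `molecule_id`, `smiles` (e.g.
#'   from [read_molecules()]).
#' @param targets targets to query (default: all registered).
#' @param config an [ensemble_config()]; inputs larger than
#'   `config$max_batch` molecules are refused.
#' @return A list with `predictions` (one row per molecule x target: the 16
#'   named votes, `vote_count` and `call`) and `rejections` (molecules
#'   skipped with reasons).
#' @export
predict_batch <- function(suite, molecules, targets = NULL,
                          config = ensemble_config()) {
  stopifnot(inherits(suite, "model_suite"),
            all(c("molecule_id", "smiles") %in% names(molecules)))
  targets <- targets %||% suite$targets
  if (nrow(molecules) > config$max_batch) {
    stop(sprintf("batch of %d molecules exceeds the cap of %d",
                 nrow(molecules), config$max_batch), call. = FALSE)
  }
  empty <- data.frame(matrix(integer(0), 0, 16,
                             dimnames = list(NULL, suite_model_names())),
                      check.names = FALSE)
  empty <- cbind(data.frame(molecule_id = character(0), smiles = character(0),
                            target = character(0), stringsAsFactors = FALSE),
                 empty, vote_count = integer(0), call = character(0))
  if (nrow(molecules) == 0L) {
    return(list(predictions = empty,
                rejections = data.frame(molecule_id = character(0),
                                        smiles = character(0),
                                        reason = character(0))))
  }
  std <- standardize_batch(molecules$smiles)
  ok <- !is.na(std$canonical)
  rejections <- data.frame(
    molecule_id = molecules$molecule_id[!ok],
    smiles = molecules$smiles[!ok],
    reason = if (any(!ok)) std$rejected$reason else character(0),
    stringsAsFactors = FALSE
  )
  if (!any(ok)) return(list(predictions = empty, rejections = rejections))

  fps <- featurize_compounds(std$canonical[ok])
  blocks <- lapply(targets, function(tid) {
    votes <- votes_for_target(suite, fps, tid)
    data.frame(
      molecule_id = molecules$molecule_id[ok],
      smiles = std$canonical[ok],
      target = tid,
      votes,
      vote_count = rowSums(votes),
      call = ifelse(rowSums(votes) >= config$cutoff, "active", "inactive"),
      stringsAsFactors = FALSE, check.names = FALSE
    )
  })
  predictions <- do.call(rbind, blocks)
  rownames(predictions) <- NULL
  list(predictions = predictions, rejections = rejections)
}

# --- interaction networks ---------------------------------------------------

#' Build a bipartite compound-target interaction network
#'
#' One edge per distinct (molecule, target) pair whose call is active.
#'
#' @param predictions the `predictions` element of a [predict_batch()]
#'   result (or any data frame with `molecule_id`, `target`, `call`).
#' @return An igraph graph with vertex attribute `kind` (`"compound"` or
#'   `"target"`).
#' @export
build_network <- function(predictions) {
  stopifnot(all(c("molecule_id", "target", "call") %in% names(predictions)))
  act <- predictions[predictions$call == "active",
                     c("molecule_id", "target"), drop = FALSE]
  act <- unique(act)
  compounds <- unique(act$molecule_id)
  targets <- unique(act$target)
  g <- igraph::graph_from_data_frame(
    act,
    directed = FALSE,
    vertices = data.frame(
      name = c(compounds, targets),
      kind = c(rep("compound", length(compounds)),
               rep("target", length(targets))),
      stringsAsFactors = FALSE
    )
  )
  g
}

#' Degree statistics of an interaction network
#'
#' @param network a [build_network()] result.
#' @return A list with `degrees` (named, all nodes), `median_degree` (over
#'   all nodes), `mean_targets_per_compound`, `mean_compounds_per_target`
#'   and `empty` flag.
#' @export
degree_stats <- function(network) {
  if (igraph::vcount(network) == 0L) {
    return(list(degrees = integer(0), median_degree = NA_real_,
                mean_targets_per_compound = NA_real_,
                mean_compounds_per_target = NA_real_, empty = TRUE))
  }
  deg <- igraph::degree(network)
  kind <- igraph::vertex_attr(network, "kind")
  list(
    degrees = deg,
    median_degree = median(deg),
    mean_targets_per_compound = mean(deg[kind == "compound"]),
    mean_compounds_per_target = mean(deg[kind == "target"]),
    empty = FALSE
  )
}

#' Retain compounds above the median node degree
#'
#' Compound nodes whose degree strictly exceeds the median degree of all
#' nodes (compounds and targets pooled) are retained with their incident
#' edges; target nodes are always retained. If no compound exceeds the
#' median (e.g. all compounds have equal degree) the compound set comes
#' back empty, with a warning.
#'
#' @param network a [build_network()] result.
#' @return The filtered igraph graph.
#' @export
filter_by_median_degree <- function(network) {
  stats <- degree_stats(network)
  if (stats$empty) return(network)
  kind <- igraph::vertex_attr(network, "kind")
  keep <- kind == "target" |
    (kind == "compound" & stats$degrees > stats$median_degree)
  if (!any(keep & kind == "compound")) {
    warning("no compound node exceeds the median degree; all compounds dropped",
            call. = FALSE)
  }
  igraph::induced_subgraph(network, which(keep))
}

#' Export a network in SIF format
#'
#' @param network a [build_network()] result.
#' @param path output file; each line is `compound targets target`.
#' @return Invisibly, `path`.
#' @export
write_sif <- function(network, path) {
  edges <- igraph::as_edgelist(network)
  lines <- if (nrow(edges) > 0L) {
    paste(edges[, 1], "targets", edges[, 2])
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Export a network in GraphML format
#'
#' @param network a [build_network()] result.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}
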