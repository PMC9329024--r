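# Protein sequence descriptors: amino-acid composition (AAC, 20), dipeptide
# composition (DPC, 400), optional tripeptide composition (TPC, 8000) and
# composition/transition/distribution descriptors (CTD, 147) over the seven
# canonical physicochemical groupings used throughout the CTD literature
# (hydrophobicity, normalized van der Waals volume, polarity, polarizability,
# charge, secondary structure, solvent accessibility), three classes each:
# 7 x 3 composition + 7 x 3 transition + 7 x 3 x 5 distribution = 147.

AA_LETTERS <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.ctd_groups <- list(
  hydrophobicity      = c("RKEDQN", "GASTPHY", "CLVIMFW"),
  normwaalsvolume     = c("GASTPDC", "NVEQIL", "MHKFRYW"),
  polarity            = c("LIFWCMVY", "PATGS", "HQRKNED"),
  polarizability      = c("GASDT", "CPNVEQIL", "KMHFRYW"),
  charge              = c("KR", "ANCQGHILMFPSTWYV", "DE"),
  secondarystruct     = c("EALMQKRH", "VIYCWFT", "GNPSD"),
  solventaccess       = c("ALFCGIVW", "RKQEND", "MSPTHY")
)

check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!(chars %in% AA_LETTERS))
  if (length(bad) > 0L) {
    stop(sprintf(
      "non-standard amino-acid letter '%s' at position %d", chars[bad[1]], bad[1]
    ), call. = FALSE)
  }
  if (length(chars) < 2L) stop("sequence must have length >= 2", call. = FALSE)
  chars
}

kmer_composition <- function(chars, k, alphabet = AA_LETTERS) {
  kmers <- apply(expand.grid(rep(list(alphabet), k),
                             stringsAsFactors = FALSE)[, k:1, drop = FALSE],
                 1, paste, collapse = "")
  n <- length(chars) - k + 1L
  counts <- setNames(numeric(length(kmers)), kmers)
  if (n > 0L) {
    obs <- vapply(seq_len(n), function(i) {
      paste(chars[i:(i + k - 1L)], collapse = "")
    }, character(1))
    tab <- table(obs)
    counts[names(tab)] <- as.numeric(tab)
    counts <- counts / n
  }
  counts
}

ctd_block <- function(chars) {
  n <- length(chars)
  out <- numeric(0)
  for (prop in names(.ctd_groups)) {
    classes <- .ctd_groups[[prop]]
    cls <- integer(n)
    for (g in 1:3) {
      cls[chars %in% strsplit(classes[g], "")[[1]]] <- g
    }
    comp <- vapply(1:3, function(g) mean(cls == g), numeric(1))
    names(comp) <- paste0(prop, ".C", 1:3)
    trans_pairs <- cbind(cls[-n], cls[-1])
    tr <- vapply(list(c(1, 2), c(1, 3), c(2, 3)), function(p) {
      sum((trans_pairs[, 1] == p[1] & trans_pairs[, 2] == p[2]) |
            (trans_pairs[, 1] == p[2] & trans_pairs[, 2] == p[1])) / (n - 1)
    }, numeric(1))
    names(tr) <- paste0(prop, ".T", c("12", "13", "23"))
    dist <- numeric(0)
    for (g in 1:3) {
      pos <- which(cls == g)
      qs <- if (length(pos) == 0L) rep(0, 5) else {
        idx <- pmax(1L, ceiling(length(pos) * c(0.0001, 0.25, 0.5, 0.75, 1)))
        100 * pos[idx] / n
      }
      names(qs) <- paste0(prop, ".D", g, ".", c("first", "25", "50", "75", "100"))
      dist <- c(dist, qs)
    }
    out <- c(out, comp, tr, dist)
  }
  out
}

#' Compute protein sequence descriptors
#'
#' @param sequence amino-acid string over the 20 standard letters, length
#'   at least 2.
#' @param families character vector drawn from `"AAC"`, `"DPC"`, `"TPC"`,
#'   `"CTD"`. The default (`AAC + DPC + CTD`, 567 features) keeps the block
#'   compact; adding `"TPC"` (8000 features) approaches the full inventory
#'   of classic sequence-descriptor suites.
#' @return A named numeric vector; composition-family blocks each sum to 1.
#' @export
compute_protein_descriptors <- function(sequence,
                                        families = c("AAC", "DPC", "CTD")) {
  families <- match.arg(families, c("AAC", "DPC", "TPC", "CTD"),
                        several.ok = TRUE)
  chars <- check_sequence(sequence)
  out <- numeric(0)
  if ("AAC" %in% families) {
    aac <- kmer_composition(chars, 1L)
    names(aac) <- paste0("AAC.", names(aac))
    out <- c(out, aac)
  }
  if ("DPC" %in% families) {
    dpc <- kmer_composition(chars, 2L)
    names(dpc) <- paste0("DPC.", names(dpc))
    out <- c(out, dpc)
  }
  if ("TPC" %in% families) {
    tpc <- kmer_composition(chars, 3L)
    names(tpc) <- paste0("TPC.", names(tpc))
    out <- c(out, tpc)
  }
  if ("CTD" %in% families) {
    ctd <- ctd_block(chars)
    names(ctd) <- paste0("CTD.", names(ctd))
    out <- c(out, ctd)
  }
  out
}

#' Read protein sequences from a FASTA file
#'
#' @param path path to a (possibly multi-record) FASTA file.
#' @return A named character vector of amino-acid sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_protein_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- vapply(strsplit(names(seqs), "[ \t]+"), `[[`, character(1), 1)
  out
}

# Descriptor matrix for a target registry (named vector of sequences).
protein_descriptor_matrix <- function(sequences,
                                      families = c("AAC", "DPC", "CTD")) {
  rows <- lapply(sequences, compute_protein_descriptors, families = families)
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(sequences)
  mat
}
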