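# Compound fingerprints: MACCS structural keys (166 bits, OpenBabel's key
# definitions) and a counted extended-connectivity fingerprint of radius 3
# folded into 1024 slots (ECFP6).
#
# The ECFP is computed by iterative neighbourhood hashing on the molecular
# graph: each atom starts from an invariant built from its element, heavy
# degree, bond-order sum and formal charge; at every iteration the invariant
# is rehashed together with the sorted (bond order, neighbour invariant)
# pairs, and every (atom, iteration) identifier contributes one count to its
# slot (identifier mod 1024). Invariance under SMILES re-spelling follows
# from canonicalizing the input and from the order-independent neighbour
# sort.

MACCS_LEN <- 166L
ECFP_LEN <- 1024L
ECFP_RADIUS <- 3L

.fp_cache <- new.env(parent = emptyenv())

hash_ints <- function(xs) {
  h <- 7
  for (x in xs) {
    h <- (h * 1000003 + (x %% 2147483647)) %% 2147483647
  }
  h
}

.elements <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B",
               "Si", "Se", "H", "Na", "K", "Li", "Mg", "Ca", "Zn", "Fe")

# Parse V2000 MOL blocks (one per input SMILES) into minimal graphs:
# list(elem = character, charge = integer, bonds = matrix[a1, a2, order]).
parse_mol_graphs <- function(smiles) {
  blocks <- ob_convert(smiles, "SDF")
  lapply(seq_along(blocks), function(i) {
    bl <- blocks[i]
    if (is.na(bl)) return(NULL)
    lines <- strsplit(bl, "\n", fixed = TRUE)[[1]]
    counts <- lines[4]
    natoms <- as.integer(substr(counts, 1, 3))
    nbonds <- as.integer(substr(counts, 4, 6))
    if (is.na(natoms) || natoms < 1L) return(NULL)
    atom_lines <- lines[5:(4 + natoms)]
    elem <- vapply(atom_lines, function(l) {
      strsplit(trimws(l), "[ \t]+")[[1]][4]
    }, character(1), USE.NAMES = FALSE)
    bonds <- matrix(integer(0), ncol = 3)
    if (nbonds > 0L) {
      bond_lines <- lines[(5 + natoms):(4 + natoms + nbonds)]
      bonds <- t(vapply(bond_lines, function(l) {
        c(as.integer(substr(l, 1, 3)), as.integer(substr(l, 4, 6)),
          as.integer(substr(l, 7, 9)))
      }, integer(3), USE.NAMES = FALSE))
    }
    charge <- integer(natoms)
    for (l in grep("^M  CHG", lines, value = TRUE)) {
      toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", l)), "[ \t]+")[[1]])
      k <- toks[1]
      for (j in seq_len(k)) {
        charge[toks[2 * j]] <- toks[2 * j + 1]
      }
    }
    list(elem = elem, charge = charge, bonds = bonds)
  })
}

ecfp_counts <- function(graph, nbits = ECFP_LEN, radius = ECFP_RADIUS) {
  natoms <- length(graph$elem)
  nbrs <- vector("list", natoms)
  if (nrow(graph$bonds) > 0L) {
    for (b in seq_len(nrow(graph$bonds))) {
      a1 <- graph$bonds[b, 1]; a2 <- graph$bonds[b, 2]; o <- graph$bonds[b, 3]
      nbrs[[a1]] <- rbind(nbrs[[a1]], c(a2, o))
      nbrs[[a2]] <- rbind(nbrs[[a2]], c(a1, o))
    }
  }
  elem_code <- match(graph$elem, .elements)
  elem_code[is.na(elem_code)] <- 100L +
    vapply(graph$elem[is.na(elem_code)], string_hash, integer(1)) %% 1000L
  degree <- vapply(nbrs, function(m) if (is.null(m)) 0L else nrow(m), integer(1))
  bosum <- vapply(nbrs, function(m) if (is.null(m)) 0L else sum(m[, 2]), integer(1))

  inv <- vapply(seq_len(natoms), function(i) {
    hash_ints(c(elem_code[i], degree[i], bosum[i], graph$charge[i] + 10))
  }, numeric(1))

  ids <- inv
  for (r in seq_len(radius)) {
    inv_new <- vapply(seq_len(natoms), function(i) {
      m <- nbrs[[i]]
      if (is.null(m)) return(hash_ints(c(r, inv[i])))
      pairs <- cbind(m[, 2], inv[m[, 1]])
      ord <- order(pairs[, 1], pairs[, 2])
      hash_ints(c(r, inv[i], t(pairs[ord, , drop = FALSE])))
    }, numeric(1))
    # atoms with no neighbours gain no new environment beyond radius 0
    grew <- degree > 0L
    ids <- c(ids, inv_new[grew])
    inv <- inv_new
  }
  counts <- integer(nbits)
  slot <- (ids %% nbits) + 1L
  for (s in slot) counts[s] <- counts[s] + 1L
  counts
}

maccs_bits <- function(smiles) {
  fp <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                               function(m) ChemmineOB::fingerprint_OB(list(m), "MACCS"))
  m <- do.call(rbind, fp)
  m[, seq_len(MACCS_LEN), drop = FALSE]
}

#' Compute MACCS structural keys
#'
#' @param smiles character vector of SMILES strings (canonicalized
#'   internally, so any spelling of the same molecule yields the same keys).
#' @return An integer matrix with one row per molecule and 166 binary
#'   columns.
#' @export
compute_maccs <- function(smiles) {
  featurize_compounds(smiles)$maccs
}

#' Compute counted extended-connectivity fingerprints (ECFP6)
#'
#' Circular substructure environments up to radius 3 are hashed and their
#' occurrence counts folded into 1024 slots.
#'
#' @param smiles character vector of SMILES strings.
#' @return An integer matrix with one row per molecule and 1024 non-negative
#'   count columns.
#' @export
compute_ecfp6 <- function(smiles) {
  featurize_compounds(smiles)$ecfp
}

#' Compute both fingerprint families for a set of molecules
#'
#' Results are cached per canonical SMILES for the lifetime of the session.
#'
#' @param smiles character vector of SMILES strings.
#' @return A list with matrices `maccs` (n x 166) and `ecfp` (n x 1024).
#'   Unparseable SMILES raise a `mtqsar_parse_error`.
#' @export
featurize_compounds <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  can <- ob_convert(smiles, "CAN")
  if (anyNA(can)) stop(parse_error(smiles[which(is.na(can))[1]]))

  uniq <- unique(can)
  missing <- uniq[!vapply(uniq, function(s) exists(s, envir = .fp_cache),
                          logical(1))]
  if (length(missing) > 0L) {
    mac <- maccs_bits(missing)
    graphs <- parse_mol_graphs(missing)
    for (i in seq_along(missing)) {
      if (is.null(graphs[[i]])) stop(parse_error(missing[i]))
      assign(missing[i],
             list(maccs = mac[i, ], ecfp = ecfp_counts(graphs[[i]])),
             envir = .fp_cache)
    }
  }
  cached <- lapply(can, get, envir = .fp_cache)
  list(
    maccs = do.call(rbind, lapply(cached, `[[`, "maccs")),
    ecfp = do.call(rbind, lapply(cached, `[[`, "ecfp"))
  )
}
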