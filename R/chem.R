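# Structure standardization on top of the OpenBabel backend (ChemmineOB).
#
# All molecule handling in the package funnels through ob_convert(), which
# batch-converts SMILES with title-based realignment: OpenBabel aborts a
# batch at the first unparseable entry, so entries missing from the batch
# output are retried one by one and only those that fail alone are reported
# as unparseable.

ob_no_opts <- function() data.frame(names = character(0), args = character(0))

ob_convert_one <- function(smiles, to, opts = NULL) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", to, paste0(smiles, " m1\n"),
                                               options = opts %||% ob_no_opts())),
    error = function(e) ""
  )
  if (!nzchar(out)) return(NA_character_)
  out
}

# Batch SMILES -> `to` ("CAN" or "SDF"). Returns a character vector aligned
# with `smiles`; NA marks unparseable entries. For "CAN" each element is one
# canonical SMILES; for "SDF" each element is one MOL block.
ob_convert <- function(smiles, to = "CAN", neutralize = FALSE) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  opts <- if (neutralize) data.frame(names = "neutralize", args = "") else ob_no_opts()
  ids <- paste0("m", seq_len(n))
  batch <- paste0(paste(smiles, ids, collapse = "\n"), "\n")
  raw <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", to, batch, options = opts)),
    error = function(e) ""
  )
  res <- rep(NA_character_, n)
  if (identical(to, "CAN")) {
    lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
    for (ln in lines) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) >= 2) {
        idx <- match(trimws(parts[2]), ids)
        if (!is.na(idx)) res[idx] <- parts[1]
      }
    }
  } else {
    blocks <- strsplit(raw, "$$$$\n", fixed = TRUE)[[1]]
    for (bl in blocks) {
      title <- trimws(strsplit(bl, "\n", fixed = TRUE)[[1]][1])
      idx <- match(title, ids)
      if (!is.na(idx)) res[idx] <- bl
    }
  }
  # retry entries the aborted batch never reached
  for (i in which(is.na(res))) {
    one <- ob_convert_one(smiles[i], to, opts)
    if (is.na(one)) next
    if (identical(to, "CAN")) {
      res[i] <- strsplit(one, "\t", fixed = TRUE)[[1]][1]
    } else {
      res[i] <- sub("\\$\\$\\$\\$\n?$", "", one)
    }
  }
  res
}

parse_error <- function(smiles, reason = "unparseable SMILES") {
  structure(
    class = c("mtqsar_parse_error", "error", "condition"),
    list(message = sprintf("%s: '%s'", reason, smiles), call = NULL,
         smiles = smiles)
  )
}

# Count heavy (non-hydrogen) atoms in a single SMILES fragment without a
# toolkit round trip. Bracket atoms count one each (unless hydrogen);
# outside brackets the organic subset plus aromatic symbols are counted.
heavy_atom_count <- function(smiles) {
  n <- 0L
  chars <- strsplit(smiles, "")[[1]]
  i <- 1L
  len <- length(chars)
  while (i <= len) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= len && chars[j] != "]") j <- j + 1L
      atom <- paste(chars[i:j], collapse = "")
      if (!grepl("^\\[[0-9]*H[0-9+\\-]*\\]$", atom)) n <- n + 1L
      i <- j + 1L
    } else if (ch %in% c("C", "B")) {
      # two-letter organic-subset halogens / single letters
      if (i < len && ((ch == "C" && chars[i + 1L] == "l") ||
                      (ch == "B" && chars[i + 1L] == "r"))) i <- i + 1L
      n <- n + 1L
      i <- i + 1L
    } else if (ch %in% c("N", "O", "P", "S", "F", "I",
                         "b", "c", "n", "o", "p", "s")) {
      n <- n + 1L
      i <- i + 1L
    } else {
      # bonds, ring closures, branches, %nn, stereo marks
      i <- i + 1L
    }
  }
  n
}

#' Standardize a SMILES structure to its canonical parent form
#'
#' Keeps the largest covalent fragment (salt stripping), neutralizes formal
#' charges where chemically valid, and returns the canonical SMILES of the
#' result. The operation is idempotent: applying it to its own output is a
#' no-op. Fragment-size ties are broken by the lexicographically smallest
#' canonical SMILES.
#'
#' @param smiles character vector of raw SMILES strings.
#' @return Character vector of canonical parent SMILES. Unparseable input
#'   raises a condition of class `mtqsar_parse_error` carrying the offending
#'   string; use [standardize_batch()] for skip-and-log behaviour.
#' @examples
#' \dontrun{
#' standardize_structure("NCC(=O)O.Cl")  # glycine, salt stripped
#' }
#' @export
standardize_structure <- function(smiles) {
  out <- standardize_batch(smiles)
  if (nrow(out$rejected) > 0L) {
    stop(parse_error(out$rejected$smiles[1]))
  }
  out$canonical
}

#' Standardize a batch of SMILES, skipping unparseable entries
#'
#' @param smiles character vector of raw SMILES strings.
#' @return A list with `canonical` (character, `NA` where rejected) and
#'   `rejected` (data frame of `smiles`, `reason`).
#' @export
standardize_batch <- function(smiles) {
  stopifnot(is.character(smiles))
  canonical <- rep(NA_character_, length(smiles))
  reasons <- rep(NA_character_, length(smiles))
  nonempty <- nzchar(trimws(smiles)) & !is.na(smiles)
  reasons[!nonempty] <- "empty SMILES"

  # pick the parent fragment of each record
  parents <- rep(NA_character_, length(smiles))
  for (i in which(nonempty)) {
    frags <- strsplit(smiles[i], ".", fixed = TRUE)[[1]]
    frags <- frags[nzchar(frags)]
    if (length(frags) == 0L) { reasons[i] <- "empty SMILES"; next }
    if (length(frags) == 1L) { parents[i] <- frags; next }
    counts <- vapply(frags, heavy_atom_count, integer(1))
    best <- frags[counts == max(counts)]
    if (length(best) > 1L) {
      cans <- ob_convert(best, "CAN")
      if (all(is.na(cans))) { reasons[i] <- "unparseable SMILES"; next }
      best <- sort(cans[!is.na(cans)])[1]
    }
    parents[i] <- best[1]
  }

  todo <- which(!is.na(parents))
  if (length(todo) > 0L) {
    cans <- ob_convert(parents[todo], "CAN", neutralize = TRUE)
    canonical[todo] <- cans
    reasons[todo][is.na(cans)] <- "unparseable SMILES"
  }
  rej <- which(is.na(canonical))
  list(
    canonical = canonical,
    rejected = data.frame(
      smiles = smiles[rej],
      reason = ifelse(is.na(reasons[rej]), "unparseable SMILES", reasons[rej]),
      stringsAsFactors = FALSE
    )
  )
}
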