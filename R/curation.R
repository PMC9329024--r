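# Curation of raw activity records into balanced per-target binary
# classification sets: structure standardization, pIC50 conversion,
# deduplication by canonical structure, balance-driven activity threshold
# selection and labelling.

#' Convert IC50 to pIC50
#'
#' @param ic50 positive numeric vector of IC50 values.
#' @param unit `"M"` (molar, the default) or `"nM"`.
#' @return `-log10(IC50 in mol/L)`.
#' @export
to_pic50 <- function(ic50, unit = c("M", "nM")) {
  unit <- match.arg(unit)
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("IC50 values must be positive and finite", call. = FALSE)
  }
  molar <- if (unit == "nM") ic50 * 1e-9 else ic50
  -log10(molar)
}

#' Deduplicate standardized compound records
#'
#' One record is kept per canonical SMILES; when duplicates disagree on
#' pIC50 the retained value is their median (robust to outlying assay
#' values). The output is sorted by canonical SMILES so the result is
#' deterministic regardless of input order. The spread of duplicate values
#' is recorded in `dup_min` / `dup_max` so that downstream labelling can
#' drop compounds whose duplicates straddle the activity threshold.
#'
#' @param records data frame with columns `compound_id`, `canonical_smiles`,
#'   `pic50`.
#' @return Deduplicated data frame with added `dup_min`, `dup_max` columns.
#' @export
deduplicate <- function(records) {
  cols <- c("compound_id", "canonical_smiles", "pic50")
  stopifnot(all(cols %in% names(records)))
  if (nrow(records) == 0L) {
    out <- records[, cols, drop = FALSE]
    out$dup_min <- numeric(0)
    out$dup_max <- numeric(0)
    return(out)
  }
  groups <- split(seq_len(nrow(records)), records$canonical_smiles)
  rows <- lapply(groups, function(idx) {
    vals <- records$pic50[idx]
    data.frame(
      compound_id = records$compound_id[idx[1]],
      canonical_smiles = records$canonical_smiles[idx[1]],
      pic50 = median(vals),
      dup_min = min(vals),
      dup_max = max(vals),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$canonical_smiles), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the class-balancing activity threshold
#'
#' Returns the candidate threshold `t` minimizing the class imbalance
#' `|#\{p >= t\} - #\{p < t\}|`; ties are broken by the smallest such `t`
#' (which favours calling compounds active).
#'
#' @param pic50s non-empty numeric vector of pIC50 values.
#' @param candidates non-empty numeric vector of candidate thresholds.
#' @return The selected threshold.
#' @export
select_balance_threshold <- function(pic50s, candidates) {
  stopifnot(length(pic50s) > 0L, length(candidates) > 0L)
  candidates <- sort(candidates)
  imbalance <- vapply(candidates, function(t) {
    abs(sum(pic50s >= t) - sum(pic50s < t))
  }, numeric(1))
  candidates[which.min(imbalance)]
}

#' Default candidate threshold grid
#'
#' Half-log-unit steps over the pIC50 range typically spanned by screening
#' data.
#'
#' @param from,to,by grid limits and step, in pIC50 units.
#' @return Numeric vector of candidate thresholds.
#' @export
threshold_grid <- function(from = 4, to = 9, by = 0.5) seq(from, to, by = by)

#' Build a curated per-target activity dataset
#'
#' Composes structure standardization, pIC50 conversion, deduplication,
#' balance-threshold selection and labelling. Records whose SMILES cannot
#' be parsed are skipped and logged in the `rejections` field. Compounds
#' whose duplicate measurements straddle the selected threshold while their
#' median lies within 0.3 pIC50 units of it are dropped as ambiguous.
#'
#' @param raw data frame with columns `compound_id`, `smiles`, `ic50`,
#'   `target_id` (all rows must share `target_id`).
#' @param target_id the target the records belong to.
#' @param candidates candidate thresholds (default [threshold_grid()]).
#' @param unit IC50 input unit, `"M"` or `"nM"`.
#' @param min_records datasets smaller than this after curation are flagged
#'   with `small = TRUE` (models built from them have a narrow application
#'   domain).
#' @return An object of class `activity_dataset`: a list with `target_id`,
#'   `records` (columns `compound_id`, `canonical_smiles`, `pic50`,
#'   `label`), `threshold`, `n_active`, `n_inactive`, `rejections`, `small`.
#' @export
build_dataset <- function(raw, target_id, candidates = threshold_grid(),
                          unit = c("M", "nM"), min_records = 40L) {
  unit <- match.arg(unit)
  stopifnot(all(c("compound_id", "smiles", "ic50") %in% names(raw)))
  if ("target_id" %in% names(raw) && nrow(raw) > 0L &&
      !all(raw$target_id == target_id)) {
    stop("all raw records must match target_id '", target_id, "'",
         call. = FALSE)
  }
  std <- standardize_batch(raw$smiles)
  ok <- !is.na(std$canonical)
  records <- data.frame(
    compound_id = as.character(raw$compound_id[ok]),
    canonical_smiles = std$canonical[ok],
    pic50 = to_pic50(raw$ic50[ok], unit = unit),
    stringsAsFactors = FALSE
  )
  records <- deduplicate(records)
  threshold <- select_balance_threshold(records$pic50, candidates)
  ambiguous <- records$dup_min < threshold & records$dup_max >= threshold &
    abs(records$pic50 - threshold) <= 0.3
  records <- records[!ambiguous, , drop = FALSE]
  records$label <- ifelse(records$pic50 >= threshold, "active", "inactive")
  records <- records[, c("compound_id", "canonical_smiles", "pic50", "label")]
  rownames(records) <- NULL
  ds <- structure(
    list(
      target_id = target_id,
      records = records,
      threshold = threshold,
      n_active = sum(records$label == "active"),
      n_inactive = sum(records$label == "inactive"),
      rejections = std$rejected,
      n_ambiguous_dropped = sum(ambiguous),
      small = nrow(records) < min_records
    ),
    class = "activity_dataset"
  )
  if (ds$small) {
    warning(sprintf("dataset for target '%s' has only %d records after curation",
                    target_id, nrow(records)), call. = FALSE)
  }
  validate_dataset(ds)
}

validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "activity_dataset"))
  r <- ds$records
  if (anyDuplicated(r$canonical_smiles) > 0L) {
    stop("duplicate canonical SMILES in dataset", call. = FALSE)
  }
  if (!all((r$pic50 >= ds$threshold) == (r$label == "active"))) {
    stop("label/threshold inconsistency", call. = FALSE)
  }
  if (ds$n_active + ds$n_inactive != nrow(r)) {
    stop("class counts do not sum to record count", call. = FALSE)
  }
  ds
}

#' @export
print.activity_dataset <- function(x, ...) {
  cat(sprintf(
    "<activity_dataset> target %s: %d compounds (%d active / %d inactive), threshold pIC50 >= %.2f\n",
    x$target_id, nrow(x$records), x$n_active, x$n_inactive, x$threshold))
  if (nrow(x$rejections) > 0L) {
    cat(sprintf("  %d record(s) rejected during standardization\n",
                nrow(x$rejections)))
  }
  invisible(x)
}

#' Read raw activity records from a CSV/TSV file
#'
#' @param path file with columns `compound_id`, `smiles`, `ic50`,
#'   `target_id` and optionally `unit` (per-file constant, `"M"` or `"nM"`).
#' @param sep field separator (`","` default; use `"\t"` for TSV).
#' @return A data frame of raw records; the declared unit is attached as
#'   attribute `unit`.
#' @export
read_activity_csv <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("compound_id", "smiles", "ic50", "target_id")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("activity file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unit <- if ("unit" %in% names(df) && nrow(df) > 0L) df$unit[1] else "M"
  attr(df, "unit") <- match.arg(unit, c("M", "nM"))
  df
}

#' Write a curated dataset as CSV plus a JSON sidecar
#'
#' @param ds an `activity_dataset`.
#' @param path output CSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return Invisibly, the two paths written.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "activity_dataset"))
  write.csv(ds$records, path, row.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(target_id = ds$target_id, threshold = ds$threshold,
         n_active = ds$n_active, n_inactive = ds$n_inactive,
         n_ambiguous_dropped = ds$n_ambiguous_dropped,
         small = ds$small,
         rejections = ds$rejections),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(c(path, sidecar))
}
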