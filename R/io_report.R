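# Long-format transition report IO.
#
# The canonical schema is one row per (protein, peptide, precursor charge,
# product ion, replicate) with an integrated peak area and an apex retention
# time. Column names in a file are mapped onto this schema via `column_map`,
# so exports from different chromatogram-extraction tools can be ingested
# without reshaping.

report_columns <- function() {
  c("protein_id", "peptide_seq", "precursor_charge", "precursor_mz",
    "product_ion", "product_mz", "replicate_id", "area", "apex_rt")
}

report_key_columns <- function() {
  c("protein_id", "peptide_seq", "precursor_charge", "product_ion",
    "replicate_id")
}

peptide_key_columns <- function() {
  c("protein_id", "peptide_seq", "precursor_charge")
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) abort_data(sprintf("empty file: %s", path))
  if (grepl("\t", first)) "\t" else ","
}

#' Read a transition-level quantification report
#'
#' Reads a delimited (CSV or TSV, auto-detected) long-format report with one
#' row per transition per replicate and validates it against the canonical
#' schema. Replicate identifiers are preserved verbatim; modified peptide
#' sequences are treated as opaque identifiers.
#'
#' Rows with out-of-range values (negative area, non-positive m/z, negative
#' retention time) are rejected, reported with their data-row numbers via a
#' warning, and returned in the `"rejects"` attribute, so that
#' `nrow(input) == nrow(records) + nrow(rejects)` always holds. A missing
#' required column is a configuration error; an unparseable numeric cell or
#' a duplicated transition key is a data error.
#'
#' @param path File path.
#' @param column_map Optional named character vector mapping canonical field
#'   names (see Details) to the header names used in the file, e.g.
#'   `c(protein_id = "Protein Name", area = "Area")`. Unmapped fields are
#'   looked up under their canonical names.
#' @return A tibble with columns `protein_id`, `peptide_seq`,
#'   `precursor_charge`, `precursor_mz`, `product_ion`, `product_mz`,
#'   `replicate_id`, `area`, `apex_rt`, and a `"rejects"` attribute.
#' @export
read_transition_report <- function(path, column_map = NULL) {
  if (!file.exists(path)) abort_config(sprintf("report file not found: %s", path))
  delim <- detect_delim(path)
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           trim_ws = TRUE, progress = FALSE,
                           show_col_types = FALSE)
  wanted <- report_columns()
  map <- setNames(wanted, wanted)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), wanted)
    if (length(bad)) {
      abort_config(sprintf("column_map refers to unknown field(s): %s",
                           paste(bad, collapse = ", ")))
    }
    map[names(column_map)] <- unname(column_map)
  }
  missing <- wanted[!map %in% names(raw)]
  if (length(missing)) {
    abort_config(sprintf("report is missing required column(s): %s (file header: %s)",
                         paste(missing, collapse = ", "),
                         paste(names(raw), collapse = ", ")))
  }
  out <- tibble::as_tibble(setNames(raw[unname(map)], wanted))
  out$.row <- seq_len(nrow(out))

  for (col in c("precursor_mz", "product_mz", "area", "apex_rt")) {
    vals <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(!is.na(out[[col]]) & out[[col]] != "" & is.na(vals))
    if (length(bad)) {
      abort_data(sprintf("unreadable numeric value in column '%s' at data row %d: '%s'",
                         col, bad[1], out[[col]][bad[1]]))
    }
    out[[col]] <- vals
  }
  charge <- suppressWarnings(as.integer(out$precursor_charge))
  bad <- which(!is.na(out$precursor_charge) & is.na(charge))
  if (length(bad)) {
    abort_data(sprintf("unreadable precursor charge at data row %d: '%s'",
                       bad[1], out$precursor_charge[bad[1]]))
  }
  out$precursor_charge <- charge

  reasons <- rep(NA_character_, nrow(out))
  flag <- function(cond, why) ifelse(is.na(reasons) & cond, why, reasons)
  reasons <- flag(is.na(out$protein_id) | out$protein_id == "", "missing protein_id")
  reasons <- flag(is.na(out$peptide_seq) | out$peptide_seq == "", "missing peptide_seq")
  reasons <- flag(is.na(out$replicate_id) | out$replicate_id == "", "missing replicate_id")
  reasons <- flag(is.na(out$precursor_charge) | out$precursor_charge < 1L, "invalid precursor_charge")
  reasons <- flag(is.na(out$precursor_mz) | out$precursor_mz <= 0, "precursor_mz not > 0")
  reasons <- flag(is.na(out$product_mz) | out$product_mz <= 0, "product_mz not > 0")
  reasons <- flag(is.na(out$area) | out$area < 0, "area negative or missing")
  reasons <- flag(is.na(out$apex_rt) | out$apex_rt < 0, "apex_rt negative or missing")

  rejects <- tibble::tibble(row = out$.row[!is.na(reasons)],
                            reason = reasons[!is.na(reasons)])
  if (nrow(rejects) > 0L) {
    warn(sprintf("rejected %d report row(s): %s", nrow(rejects),
                 paste(sprintf("row %d (%s)", head(rejects$row, 5L),
                               head(rejects$reason, 5L)), collapse = "; ")))
  }
  records <- out[is.na(reasons), ]
  records$.row <- NULL

  dup <- duplicated(records[report_key_columns()])
  if (any(dup)) {
    d <- records[which(dup)[1], report_key_columns()]
    abort_data(sprintf(
      "duplicate transition key: protein=%s peptide=%s charge=%d ion=%s replicate=%s",
      d$protein_id, d$peptide_seq, d$precursor_charge, d$product_ion, d$replicate_id))
  }
  attr(records, "rejects") <- rejects
  records
}

#' Write a transition report in the canonical schema
#'
#' Counterpart of [read_transition_report()]; used to persist simulated or
#' cleaned reports.
#'
#' @param records Tibble in the canonical report schema.
#' @param path Output path; `.tsv` extension selects tab delimiting.
#' @return `path`, invisibly.
#' @export
write_transition_report <- function(records, path) {
  missing <- setdiff(report_columns(), names(records))
  if (length(missing)) {
    abort_config(sprintf("records lack column(s): %s", paste(missing, collapse = ", ")))
  }
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(records[report_columns()], path, delim = delim, progress = FALSE)
  invisible(path)
}
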