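# Export of scheduled methods as instrument-ready transition lists, in two
# dialects: a generic triple-quadrupole "instrument" import format and a
# Skyline-style transition list for downstream data analysis.

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
}

method_rows <- function(method) {
  tg <- method$targets
  st <- method$standards
  tg$compound <- sprintf("%s.%d.%s", tg$peptide_seq, tg$precursor_charge, tg$product_ion)
  tg$protein_label <- tg$protein_id
  tg$sequence_label <- tg$peptide_seq
  if (!is.null(st) && nrow(st) > 0L) {
    st$compound <- sprintf("%s.%d.%s", st$name, st$precursor_charge, st$product_ion)
    st$protein_label <- "Standards"
    st$sequence_label <- st$name
    shared <- c("compound", "protein_label", "sequence_label", "precursor_charge",
                "precursor_mz", "product_ion", "product_mz",
                "predicted_rt", "window_start", "window_end", "ce")
    dplyr::bind_rows(tg[shared], st[shared])
  } else {
    tg[c("compound", "protein_label", "sequence_label", "precursor_charge",
         "precursor_mz", "product_ion", "product_mz",
         "predicted_rt", "window_start", "window_end", "ce")]
  }
}

#' Write scheduled methods as transition lists
#'
#' Writes one CSV per scheduled method. The `"instrument"` dialect carries
#' the columns a triple-quadrupole method editor imports (compound,
#' retention time, RT window, precursor and product m/z, collision energy);
#' the `"skyline"` dialect carries the columns a Skyline transition list
#' import expects. m/z values are written with 4 decimal places, retention
#' times and collision energies with 2. Standards' transitions are included
#' in every method file.
#'
#' @param methods List of `scheduled_method` objects from
#'   [partition_methods()].
#' @param dialect `"instrument"` or `"skyline"`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"method"`).
#' @return Character vector of the files written, invisibly.
#' @export
write_transition_list <- function(methods, dialect = c("instrument", "skyline"),
                                  dir, prefix = "method") {
  dialect <- match.arg(dialect)
  if (length(methods) == 0L) {
    warn("no scheduled methods to write; no files produced")
    return(invisible(character(0)))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(methods))
  for (i in seq_along(methods)) {
    m <- methods[[i]]
    rows <- method_rows(m)
    if (anyNA(rows$predicted_rt)) {
      abort_state(sprintf("method %d contains targets without an assigned retention time", m$index))
    }
    if (anyNA(rows$ce)) {
      abort_state(sprintf("method %d contains targets without an assigned collision energy", m$index))
    }
    out <- if (dialect == "instrument") {
      tibble::tibble(
        `Compound` = rows$compound,
        `Retention Time (min)` = fmt_num(rows$predicted_rt, 2),
        `RT Window (min)` = fmt_num(rows$window_end - rows$window_start, 2),
        `Precursor (m/z)` = fmt_num(rows$precursor_mz, 4),
        `Product (m/z)` = fmt_num(rows$product_mz, 4),
        `Collision Energy (V)` = fmt_num(rows$ce, 2)
      )
    } else {
      tibble::tibble(
        `Protein Name` = rows$protein_label,
        `Peptide Modified Sequence` = rows$sequence_label,
        `Precursor Mz` = fmt_num(rows$precursor_mz, 4),
        `Precursor Charge` = rows$precursor_charge,
        `Product Mz` = fmt_num(rows$product_mz, 4),
        `Fragment Ion` = rows$product_ion
      )
    }
    paths[i] <- file.path(dir, sprintf("%s_%02d.csv", prefix, m$index))
    readr::write_csv(out, paths[i], progress = FALSE)
  }
  invisible(paths)
}

#' Read a transition list written by [write_transition_list()]
#'
#' Mainly for round-trip verification of exported methods.
#'
#' @param path CSV path.
#' @param dialect `"instrument"` or `"skyline"`.
#' @return Tibble with normalized column names (`peptide_seq`,
#'   `precursor_mz`, `product_mz`, ... depending on dialect).
#' @export
read_transition_list <- function(path, dialect = c("instrument", "skyline")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_config(sprintf("transition list not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (dialect == "skyline") {
    tibble::tibble(
      protein_id = as.character(raw$`Protein Name`),
      peptide_seq = as.character(raw$`Peptide Modified Sequence`),
      precursor_mz = as.numeric(raw$`Precursor Mz`),
      precursor_charge = as.integer(raw$`Precursor Charge`),
      product_mz = as.numeric(raw$`Product Mz`),
      product_ion = as.character(raw$`Fragment Ion`)
    )
  } else {
    tibble::tibble(
      compound = as.character(raw$`Compound`),
      predicted_rt = as.numeric(raw$`Retention Time (min)`),
      rt_window = as.numeric(raw$`RT Window (min)`),
      precursor_mz = as.numeric(raw$`Precursor (m/z)`),
      product_mz = as.numeric(raw$`Product (m/z)`),
      ce = as.numeric(raw$`Collision Energy (V)`)
    )
  }
}
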