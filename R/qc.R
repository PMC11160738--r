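# Co-elution interference QC.
#
# A transition is interfered, in a given replicate, when its peak apex does
# not co-elute with the peptide's other transitions. This is formalized as
# a deviation test against the median apex of the peptide's transitions in
# that replicate: only relative apexes matter, so the call is invariant
# under any global retention-time shift.

#' Flag interfered transitions of one peptide in one replicate
#'
#' The reference apex is the median apex retention time over the peptide's
#' transitions in the replicate; a transition is flagged when its apex
#' deviates from the reference by more than `apex_tolerance_min`. With a
#' single transition co-elution is undefined and nothing is flagged. With
#' two transitions the median is their midpoint, so both are flagged when
#' they disagree by more than twice the tolerance.
#'
#' @param apex_rt Numeric vector of apex retention times (minutes) for one
#'   peptide's transitions in one replicate.
#' @param apex_tolerance_min Co-elution tolerance in minutes (> 0).
#' @return Logical vector: `TRUE` where interfered.
#' @examples
#' flag_interference(c(10.0, 10.0, 10.0, 10.5), 0.2)
#' @export
flag_interference <- function(apex_rt, apex_tolerance_min = 0.1) {
  if (!is.numeric(apex_rt) || length(apex_rt) == 0L) {
    abort_data("apex_rt must be a non-empty numeric vector")
  }
  if (!is.finite(apex_tolerance_min) || apex_tolerance_min <= 0) {
    abort_config("`apex_tolerance_min` must be positive (minutes)")
  }
  if (length(apex_rt) == 1L) return(FALSE)
  abs(apex_rt - median(apex_rt)) > apex_tolerance_min
}

#' Interference QC over a full transition report
#'
#' Applies [flag_interference()] within every (peptide, replicate) group and
#' aggregates across replicates with a strict AND: a transition is `clean`
#' only if it is unflagged in every replicate in which it was observed. A
#' transition unreliable in any replicate is unreliable for a targeted
#' assay.
#'
#' @param records Transition report tibble (canonical schema).
#' @param apex_tolerance_min Co-elution tolerance in minutes.
#' @return A `transition_qc` list with elements:
#'   * `flags`: per (transition, replicate) interference flags;
#'   * `transitions`: one row per transition with `clean`;
#'   * `peptides`: one row per peptide with `clean_transition_count`.
#' @export
qc_summary <- function(records, apex_tolerance_min = 0.1) {
  if (nrow(records) == 0L) abort_data("empty transition report")
  if (!is.finite(apex_tolerance_min) || apex_tolerance_min <= 0) {
    abort_config("`apex_tolerance_min` must be positive (minutes)")
  }
  flags <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(peptide_key_columns(), "replicate_id")))) |>
    dplyr::mutate(flagged = flag_interference(.data$apex_rt, apex_tolerance_min)) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c(report_key_columns(), "flagged")))

  transitions <- flags |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(peptide_key_columns(), "product_ion")))) |>
    dplyr::summarise(n_replicates = dplyr::n(),
                     n_flagged_replicates = sum(.data$flagged),
                     clean = !any(.data$flagged),
                     .groups = "drop")

  peptides <- transitions |>
    dplyr::group_by(dplyr::across(dplyr::all_of(peptide_key_columns()))) |>
    dplyr::summarise(n_transitions = dplyr::n(),
                     clean_transition_count = sum(.data$clean),
                     .groups = "drop")

  structure(list(flags = flags, transitions = transitions, peptides = peptides,
                 apex_tolerance_min = apex_tolerance_min),
            class = c("transition_qc", "list"))
}

#' Export a QC table
#'
#' One row per transition: key columns, per-replicate flags (wide), the
#' aggregated `clean` call, and the peptide's clean-transition count.
#'
#' @param qc A `transition_qc` object from [qc_summary()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_qc_table <- function(qc, path) {
  wide <- qc$flags |>
    tidyr::pivot_wider(names_from = "replicate_id", values_from = "flagged",
                       names_prefix = "flagged_")
  out <- wide |>
    dplyr::left_join(qc$transitions[, c(peptide_key_columns(), "product_ion", "clean")],
                     by = c(peptide_key_columns(), "product_ion")) |>
    dplyr::left_join(qc$peptides[, c(peptide_key_columns(), "clean_transition_count")],
                     by = peptide_key_columns())
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @export
print.transition_qc <- function(x, ...) {
  cat("<transition_qc>\n")
  cat(sprintf("  %d transitions over %d peptides; %d clean (tolerance %.3g min)\n",
              nrow(x$transitions), nrow(x$peptides), sum(x$transitions$clean),
              x$apex_tolerance_min))
  invisible(x)
}
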