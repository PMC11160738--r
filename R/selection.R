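# Ranked proxy-peptide and transition selection.
#
# Per protein the rules are: (1) when more peptides qualify than will be
# kept, only the short-list of the most intense peptides (by mean summed
# area of their top clean transitions) is considered; (2) from that
# short-list the peptides with the lowest replicate %CV are kept; (3) each
# kept peptide contributes its most intense interference-free transitions,
# in intensity-rank order. All ties break lexicographically (peptide
# sequence, then product m/z) so selection is deterministic.

#' Filter peptides that qualify as SRM targets
#'
#' Keeps quantifiable peptides with at least `min_clean_transitions`
#' interference-free co-eluting transitions and replicate %CV within
#' `cv_threshold_pct` (inclusive by default; strict `<` via
#' `cv_comparison = "lt"`).
#'
#' @param quant A `peptide_quant` from [summarize_peptides()].
#' @param config A [selection_config()].
#' @return Tibble of qualifying peptides. Peptides that fail carry their
#'   failure reason in the `"failures"` attribute
#'   (`too_few_clean_transitions`, `cv_above_threshold`,
#'   `not_quantifiable`).
#' @export
filter_quantifiable <- function(quant, config = selection_config()) {
  p <- quant$peptides
  if (nrow(p) == 0L) {
    out <- p
    attr(out, "failures") <- p
    return(out)
  }
  cv_ok <- if (config$cv_comparison == "lte") {
    p$cv_pct <= config$cv_threshold_pct
  } else {
    p$cv_pct < config$cv_threshold_pct
  }
  cv_ok[is.na(cv_ok)] <- FALSE
  clean_ok <- p$clean_transition_count >= config$min_clean_transitions
  keep <- p$quantifiable & clean_ok & cv_ok
  failures <- p[!keep, ]
  failures$reason <- dplyr::case_when(
    !failures$quantifiable ~ "not_quantifiable",
    failures$clean_transition_count < config$min_clean_transitions ~ "too_few_clean_transitions",
    TRUE ~ "cv_above_threshold"
  )
  out <- p[keep, ]
  attr(out, "failures") <- failures
  out
}

# one precursor charge per peptide sequence: keep the charge with the larger
# mean summed area (tie: lower charge); peptides, not precursors, are the
# selection unit
dedupe_charge <- function(peptides) {
  peptides |>
    dplyr::arrange(.data$protein_id, .data$peptide_seq,
                   dplyr::desc(.data$mean_summed_area), .data$precursor_charge) |>
    dplyr::distinct(.data$protein_id, .data$peptide_seq, .keep_all = TRUE)
}

#' Select assay targets per protein
#'
#' Applies the ranked selection rules to the qualifying peptides and
#' attaches each selected peptide's top clean transitions. Proteins with
#' fewer than `require_min_peptides_per_protein` qualifying peptides are
#' dropped and reported in the `dropped` log together with why their
#' peptides failed.
#'
#' @param quant A `peptide_quant` from [summarize_peptides()].
#' @param config A [selection_config()].
#' @param qualifying Qualifying peptides; defaults to
#'   `filter_quantifiable(quant, config)`.
#' @return An `srm_assay` list: `targets` (one row per selected peptide),
#'   `transitions` (one row per selected transition, rank-ordered), and
#'   `dropped` (per-protein drop log with failure-mode counts).
#' @export
select_assay <- function(quant, config = selection_config(),
                         qualifying = filter_quantifiable(quant, config)) {
  failures <- attr(qualifying, "failures")
  cand <- dedupe_charge(qualifying)

  selected <- cand |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) > config$n_peptides_per_protein) {
        shortlist <- df |>
          dplyr::arrange(dplyr::desc(.data$mean_summed_area), .data$peptide_seq) |>
          dplyr::slice_head(n = config$top_k_peptides_by_intensity)
        shortlist |>
          dplyr::arrange(.data$cv_pct, .data$peptide_seq) |>
          dplyr::slice_head(n = config$n_peptides_per_protein)
      } else {
        df
      }
    }) |>
    dplyr::ungroup()

  n_qual <- cand |> dplyr::count(.data$protein_id, name = "n_qualifying")
  kept_proteins <- n_qual$protein_id[n_qual$n_qualifying >= config$require_min_peptides_per_protein]
  dropped_short <- n_qual[!n_qual$protein_id %in% kept_proteins, ]
  selected <- selected[selected$protein_id %in% kept_proteins, ]

  # drop log: proteins with too few qualifying peptides, plus proteins whose
  # peptides all failed the quantifiability filter
  fail_counts <- if (!is.null(failures) && nrow(failures) > 0L) {
    failures |>
      dplyr::count(.data$protein_id, .data$reason) |>
      tidyr::pivot_wider(names_from = "reason", values_from = "n", values_fill = 0L)
  } else {
    tibble::tibble(protein_id = character(0))
  }
  for (col in c("too_few_clean_transitions", "cv_above_threshold", "not_quantifiable")) {
    if (!col %in% names(fail_counts)) fail_counts[[col]] <- integer(nrow(fail_counts))
  }
  all_proteins <- unique(c(quant$peptides$protein_id))
  dropped <- tibble::tibble(protein_id = setdiff(all_proteins, kept_proteins)) |>
    dplyr::left_join(n_qual, by = "protein_id") |>
    dplyr::mutate(n_qualifying = dplyr::coalesce(.data$n_qualifying, 0L)) |>
    dplyr::left_join(fail_counts, by = "protein_id") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~dplyr::coalesce(.x, 0L))) |>
    dplyr::mutate(reason = dplyr::case_when(
      .data$n_qualifying > 0L ~ "too_few_qualifying_peptides",
      .data$cv_above_threshold > 0L & .data$too_few_clean_transitions == 0L ~ "cv_above_threshold",
      .data$too_few_clean_transitions > 0L & .data$cv_above_threshold == 0L ~ "too_few_clean_transitions",
      TRUE ~ "mixed_or_not_quantifiable"
    )) |>
    dplyr::arrange(.data$protein_id)
  rm(dropped_short)

  targets <- selected |>
    dplyr::select(dplyr::all_of(c(peptide_key_columns(), "precursor_mz",
                                  "clean_transition_count", "mean_summed_area",
                                  "cv_pct", "mean_apex_rt"))) |>
    dplyr::arrange(.data$protein_id, .data$peptide_seq)

  transitions <- quant$transition_ranks |>
    dplyr::inner_join(targets[peptide_key_columns()], by = peptide_key_columns()) |>
    dplyr::filter(.data$intensity_rank <= config$n_transitions_per_peptide) |>
    dplyr::arrange(.data$protein_id, .data$peptide_seq, .data$intensity_rank) |>
    dplyr::select(dplyr::all_of(c(peptide_key_columns(), "product_ion",
                                  "product_mz", "mean_area", "intensity_rank")))

  structure(list(targets = targets, transitions = transitions, dropped = dropped,
                 config = config),
            class = c("srm_assay", "list"))
}

#' Compare a selection against a reference peptide list
#'
#' Quantifies the overlap between the peptides this workflow selected and a
#' previously established assay for the same proteins: shared peptides,
#' percent of the selection that is unique, proteins where both assays chose
#' identical peptide sets, and proteins with no shared peptide at all.
#'
#' @param assay An `srm_assay`, or a tibble of selected peptides with
#'   `protein_id`, `peptide_seq` (and `precursor_charge` when matching on
#'   charge).
#' @param reference Tibble with `protein_id`, `peptide_seq` and optionally
#'   `precursor_charge`.
#' @param match_on `"sequence_charge"` (exact modified sequence + charge) or
#'   `"sequence"`.
#' @return An `overlap_report` list.
#' @export
compare_to_reference <- function(assay, reference,
                                 match_on = c("sequence_charge", "sequence")) {
  match_on <- match.arg(match_on)
  selected <- if (inherits(assay, "srm_assay")) assay$targets else assay
  key_cols <- if (match_on == "sequence_charge") {
    c("peptide_seq", "precursor_charge")
  } else {
    "peptide_seq"
  }
  missing <- setdiff(c("protein_id", key_cols), names(reference))
  if (length(missing)) {
    abort_config(sprintf("reference lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  sel_keys <- dplyr::distinct(selected[, c("protein_id", key_cols)])
  ref_keys <- dplyr::distinct(reference[, c("protein_id", key_cols)])
  shared <- dplyr::inner_join(sel_keys, ref_keys, by = c("protein_id", key_cols))

  n_sel <- nrow(sel_keys)
  n_ref <- nrow(ref_keys)
  n_shared <- nrow(shared)
  pct_unique <- if (n_sel > 0) 100 * (n_sel - n_shared) / n_sel else NA_real_

  per_protein <- function(keys) split(do.call(paste, c(keys[key_cols], sep = "\r")),
                                      keys$protein_id)
  sel_by <- per_protein(sel_keys)
  ref_by <- per_protein(ref_keys)
  proteins <- sort(union(names(sel_by), names(ref_by)))
  identical_sel <- proteins[vapply(proteins, function(p) {
    length(sel_by[[p]]) > 0 && length(ref_by[[p]]) > 0 &&
      setequal(sel_by[[p]], ref_by[[p]])
  }, logical(1))]
  no_overlap <- proteins[vapply(proteins, function(p) {
    length(intersect(sel_by[[p]], ref_by[[p]])) == 0L
  }, logical(1))]

  structure(list(n_reference_peptides = n_ref, n_selected_peptides = n_sel,
                 n_shared = n_shared, pct_selected_unique = pct_unique,
                 proteins_with_identical_selection = identical_sel,
                 proteins_with_no_overlap = no_overlap,
                 match_on = match_on),
            class = c("overlap_report", "list"))
}

#' Export assay tables
#'
#' Writes the selected transitions and the dropped-protein log.
#'
#' @param assay An `srm_assay`.
#' @param path Transition CSV path.
#' @param dropped_path Optional drop-log CSV path.
#' @return `path`, invisibly.
#' @export
write_assay <- function(assay, path, dropped_path = NULL) {
  out <- assay$transitions |>
    dplyr::left_join(assay$targets[, c(peptide_key_columns(), "precursor_mz",
                                       "cv_pct", "mean_apex_rt")],
                     by = peptide_key_columns())
  readr::write_csv(out, path, progress = FALSE)
  if (!is.null(dropped_path)) {
    readr::write_csv(assay$dropped, dropped_path, progress = FALSE)
  }
  invisible(path)
}

#' @export
print.srm_assay <- function(x, ...) {
  cat("<srm_assay>\n")
  cat(sprintf("  %d proteins, %d peptides, %d transitions; %d proteins dropped\n",
              dplyr::n_distinct(x$targets$protein_id), nrow(x$targets),
              nrow(x$transitions), nrow(x$dropped)))
  invisible(x)
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report>\n")
  cat(sprintf("  reference: %d peptides; selected: %d; shared: %d (%.1f%% of selection unique)\n",
              x$n_reference_peptides, x$n_selected_peptides, x$n_shared,
              x$pct_selected_unique))
  cat(sprintf("  proteins with identical selection: %d; with no overlap: %d\n",
              length(x$proteins_with_identical_selection),
              length(x$proteins_with_no_overlap)))
  invisible(x)
}
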