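# End-to-end orchestration: report -> QC -> quantification -> selection
# ("build assay"), and assay -> calibration -> windows -> collision
# energies -> method partitioning ("schedule").

#' Build an SRM assay from a transition report
#'
#' Runs interference QC, optional TIC normalization, peptide
#' quantification (%CV of summed top clean transitions) and the ranked
#' per-protein selection rules, returning the assay together with a run
#' manifest of per-stage counts.
#'
#' When `dia_standards` (retention-time standards with their `measured_rt`
#' in the library runs) are supplied, each selected peptide's mean apex
#' retention time is converted to an iRT by inverting the library
#' calibration, so the assay can later be scheduled on any system via
#' [schedule_assay()].
#'
#' @param records Transition report tibble (from
#'   [read_transition_report()] or [generate_report()]).
#' @param config A [selection_config()].
#' @param dia_standards Optional standards tibble (`name`, `irt`,
#'   `measured_rt`) measured in the same runs as `records`.
#' @return An `assay_build` list: `assay` (`srm_assay`), `qc`, `quant`,
#'   and `manifest`.
#' @export
build_assay <- function(records, config = selection_config(),
                        dia_standards = NULL) {
  n_rep <- dplyr::n_distinct(records$replicate_id)
  if (n_rep < 2L) {
    abort_data("build_assay needs >= 2 replicates to compute replicate %CV")
  }
  normalized <- if (config$tic_normalize) tic_normalize(records) else records
  qc <- qc_summary(normalized, config$apex_tolerance_min)
  quant <- summarize_peptides(normalized, qc, config$n_transitions_per_peptide)
  qualifying <- filter_quantifiable(quant, config)
  assay <- select_assay(quant, config, qualifying)

  assay$targets$irt <- NA_real_
  if (!is.null(dia_standards)) {
    dia_cal <- calibrate_rt(dia_standards)
    assay$targets$irt <- irt_from_rt(dia_cal, assay$targets$mean_apex_rt)
    assay$dia_calibration <- dia_cal
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("srmforge")),
    config = unclass(config)[setdiff(names(config), "ce_coefficients")],
    counts = list(
      input_rows = nrow(records),
      replicates = n_rep,
      detected_peptides = dplyr::n_distinct(
        records[, c("protein_id", "peptide_seq", "precursor_charge")]),
      detected_proteins = dplyr::n_distinct(records$protein_id),
      quantifiable_peptides = sum(quant$peptides$quantifiable),
      qualifying_peptides = nrow(qualifying),
      qualifying_proteins = dplyr::n_distinct(qualifying$protein_id),
      selected_peptides = nrow(assay$targets),
      selected_proteins = dplyr::n_distinct(assay$targets$protein_id),
      selected_transitions = nrow(assay$transitions),
      dropped_proteins = nrow(assay$dropped)
    )
  )
  structure(list(assay = assay, qc = qc, quant = quant, manifest = manifest),
            class = c("assay_build", "list"))
}

#' Schedule an assay into instrument methods
#'
#' Calibrates iRT against the standards as measured on the target system,
#' predicts each target's retention time, assigns scheduling windows and
#' collision energies, and partitions the targets into capacity-feasible
#' methods, each carrying the full standard set.
#'
#' @param build An `assay_build` (or an `srm_assay` whose targets carry
#'   `irt`).
#' @param srm_standards Standards tibble with `name`, `irt`,
#'   `measured_rt` on the target system and one row per standard
#'   transition (`precursor_mz`, `precursor_charge`, `product_mz`,
#'   `product_ion`).
#' @param schedule A [schedule_config()].
#' @param gradient_length Gradient length in minutes (default 60).
#' @return An `srm_schedule` list: `methods`, `report` (per-method
#'   summary), `calibration`.
#' @export
schedule_assay <- function(build, srm_standards,
                           schedule = schedule_config(),
                           gradient_length = 60) {
  assay <- if (inherits(build, "assay_build")) build$assay else build
  if (!inherits(assay, "srm_assay")) {
    abort_config("`build` must be an assay_build or srm_assay")
  }
  if (is.null(srm_standards)) {
    abort_config("scheduling requires retention-time standards (none supplied)")
  }
  if (!"irt" %in% names(assay$targets) || anyNA(assay$targets$irt)) {
    abort_state(paste("assay targets carry no iRT; rebuild the assay with",
                      "`dia_standards` so library RTs can be converted to iRT"))
  }
  cal <- calibrate_rt(srm_standards)
  targets <- assign_windows(assay$targets, cal, schedule, gradient_length)
  targets$ce <- collision_energy(targets$precursor_mz, targets$precursor_charge,
                                 schedule$ce_coefficients)
  st <- prepare_standards(srm_standards, cal, schedule, gradient_length)
  methods <- partition_methods(targets, assay$transitions, st, schedule)
  structure(list(methods = methods, report = schedule_report(methods),
                 calibration = cal, schedule = schedule,
                 gradient_length = gradient_length),
            class = c("srm_schedule", "list"))
}

#' @export
print.assay_build <- function(x, ...) {
  cat("<assay_build>\n")
  c <- x$manifest$counts
  cat(sprintf("  detected: %d peptides / %d proteins\n",
              c$detected_peptides, c$detected_proteins))
  cat(sprintf("  qualifying: %d peptides / %d proteins\n",
              c$qualifying_peptides, c$qualifying_proteins))
  cat(sprintf("  selected: %d peptides / %d proteins; %d transitions (%d proteins dropped)\n",
              c$selected_peptides, c$selected_proteins,
              c$selected_transitions, c$dropped_proteins))
  invisible(x)
}

#' @export
print.srm_schedule <- function(x, ...) {
  cat("<srm_schedule>\n")
  print(x$calibration)
  cat(sprintf("  %d method(s); capacity %d concurrent transitions; %.1f-min windows\n",
              length(x$methods), x$schedule$max_concurrent_transitions,
              x$schedule$window_min))
  print(as.data.frame(x$report), row.names = FALSE)
  invisible(x)
}
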