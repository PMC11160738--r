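#' Selection configuration
#'
#' Thresholds and counts governing which peptides qualify as SRM targets and
#' how proxy peptides/transitions are picked per protein.
#'
#' The defaults encode the workflow's standard criteria: a peptide needs at
#' least 3 interference-free co-eluting transitions and a replicate %CV of at
#' most 20; per protein, when more than `n_peptides_per_protein` peptides
#' qualify, only the `top_k_peptides_by_intensity` most intense are
#' considered and the `n_peptides_per_protein` with lowest %CV are kept, each
#' contributing its `n_transitions_per_peptide` most intense clean
#' transitions.
#'
#' @param min_clean_transitions Minimum interference-free co-eluting
#'   transitions for a peptide to qualify (default 3).
#' @param cv_threshold_pct Replicate %CV threshold in percent (default 20).
#' @param cv_comparison `"lte"` keeps peptides with %CV <= threshold
#'   (default); `"lt"` uses a strict <.
#' @param top_k_peptides_by_intensity Intensity short-list size per protein
#'   (default 5).
#' @param n_peptides_per_protein Proxy peptides retained per protein
#'   (default 2).
#' @param n_transitions_per_peptide Transitions retained per selected peptide
#'   (default 5).
#' @param require_min_peptides_per_protein Proteins with fewer qualifying
#'   peptides are dropped and logged (default 1).
#' @param apex_tolerance_min Apex co-elution tolerance in minutes
#'   (default 0.1).
#' @param tic_normalize Normalize replicate areas to a common total before
#'   quantification (default `TRUE`).
#' @return A `selection_config` list.
#' @examples
#' selection_config(min_clean_transitions = 5, n_peptides_per_protein = 2)
#' @export
selection_config <- function(min_clean_transitions = 3L,
                             cv_threshold_pct = 20,
                             cv_comparison = c("lte", "lt"),
                             top_k_peptides_by_intensity = 5L,
                             n_peptides_per_protein = 2L,
                             n_transitions_per_peptide = 5L,
                             require_min_peptides_per_protein = 1L,
                             apex_tolerance_min = 0.1,
                             tic_normalize = TRUE) {
  cv_comparison <- match.arg(cv_comparison)
  cfg <- list(
    min_clean_transitions = as.integer(min_clean_transitions),
    cv_threshold_pct = as.numeric(cv_threshold_pct),
    cv_comparison = cv_comparison,
    top_k_peptides_by_intensity = as.integer(top_k_peptides_by_intensity),
    n_peptides_per_protein = as.integer(n_peptides_per_protein),
    n_transitions_per_peptide = as.integer(n_transitions_per_peptide),
    require_min_peptides_per_protein = as.integer(require_min_peptides_per_protein),
    apex_tolerance_min = as.numeric(apex_tolerance_min),
    tic_normalize = isTRUE(tic_normalize)
  )
  counts <- c("min_clean_transitions", "top_k_peptides_by_intensity",
              "n_peptides_per_protein", "n_transitions_per_peptide",
              "require_min_peptides_per_protein")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L) {
      abort_config(sprintf("`%s` must be an integer >= 1 (got %s)", nm, cfg[[nm]]))
    }
  }
  if (!is.finite(cfg$cv_threshold_pct) || cfg$cv_threshold_pct <= 0) {
    abort_config("`cv_threshold_pct` must be a positive percent value")
  }
  if (!is.finite(cfg$apex_tolerance_min) || cfg$apex_tolerance_min <= 0) {
    abort_config("`apex_tolerance_min` must be positive (minutes)")
  }
  structure(cfg, class = c("selection_config", "list"))
}

#' Default collision-energy coefficients
#'
#' Linear collision-energy equations CE = slope * precursor m/z + intercept,
#' one per precursor charge, in the style instrument vendors publish for
#' triple quadrupoles. These are editable defaults, not constants: pass your
#' instrument's optimized coefficients through [schedule_config()].
#'
#' @return Named list mapping charge (as character) to `c(slope, intercept)`.
#' @export
default_ce_coefficients <- function() {
  list(
    `2` = c(slope = 0.034, intercept = 3.314),
    `3` = c(slope = 0.044, intercept = 3.314)
  )
}

#' Scheduling configuration
#'
#' @param window_min Scheduled retention-time window width in minutes
#'   (default 5).
#' @param max_concurrent_transitions Instrument capacity: the maximum number
#'   of transitions monitored simultaneously (default 200).
#' @param dwell_ms Per-transition dwell time in milliseconds; export metadata
#'   only (default 10).
#' @param ce_coefficients Named list mapping precursor charge to
#'   `c(slope, intercept)` of the linear collision-energy equation
#'   (eV = slope * m/z + intercept). Charges without coefficients fall back
#'   to the highest defined charge.
#' @return A `schedule_config` list.
#' @export
schedule_config <- function(window_min = 5,
                            max_concurrent_transitions = 200L,
                            dwell_ms = 10,
                            ce_coefficients = default_ce_coefficients()) {
  if (!is.finite(window_min) || window_min <= 0) {
    abort_config("`window_min` must be positive (minutes)")
  }
  max_concurrent_transitions <- as.integer(max_concurrent_transitions)
  if (is.na(max_concurrent_transitions) || max_concurrent_transitions < 1L) {
    abort_config("`max_concurrent_transitions` must be an integer >= 1")
  }
  if (!is.list(ce_coefficients) || length(ce_coefficients) == 0L) {
    abort_config("`ce_coefficients` must be a non-empty named list of c(slope, intercept)")
  }
  structure(
    list(
      window_min = as.numeric(window_min),
      max_concurrent_transitions = max_concurrent_transitions,
      dwell_ms = as.numeric(dwell_ms),
      ce_coefficients = ce_coefficients
    ),
    class = c("schedule_config", "list")
  )
}

#' Read a pipeline configuration from YAML
#'
#' The file may contain top-level `selection:` and `schedule:` blocks whose
#' keys mirror the arguments of [selection_config()] and [schedule_config()].
#' Keys absent from the file keep their defaults; `overrides` (e.g. parsed
#' CLI flags) win over the file.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @param overrides Named list of `selection`/`schedule` overrides.
#' @return List with elements `selection` and `schedule`.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) abort_config(sprintf("config file not found: %s", path))
    yaml::read_yaml(path)
  }
  sel_args <- utils::modifyList(raw$selection %||% list(),
                                overrides$selection %||% list())
  sch_args <- utils::modifyList(raw$schedule %||% list(),
                                overrides$schedule %||% list())
  bad <- setdiff(names(sel_args), names(formals(selection_config)))
  if (length(bad)) abort_config(sprintf("unknown selection config key(s): %s",
                                        paste(bad, collapse = ", ")))
  bad <- setdiff(names(sch_args), names(formals(schedule_config)))
  if (length(bad)) abort_config(sprintf("unknown schedule config key(s): %s",
                                        paste(bad, collapse = ", ")))
  list(
    selection = do.call(selection_config, sel_args),
    schedule = do.call(schedule_config, sch_args)
  )
}

#' @export
print.selection_config <- function(x, ...) {
  cat("<selection_config>\n")
  cat(sprintf("  min clean transitions : %d\n", x$min_clean_transitions))
  cat(sprintf("  %%CV threshold         : %s %.1f%%\n",
              if (x$cv_comparison == "lte") "<=" else "<", x$cv_threshold_pct))
  cat(sprintf("  peptides/protein      : %d (short-list top %d by intensity)\n",
              x$n_peptides_per_protein, x$top_k_peptides_by_intensity))
  cat(sprintf("  transitions/peptide   : %d\n", x$n_transitions_per_peptide))
  cat(sprintf("  min peptides/protein  : %d\n", x$require_min_peptides_per_protein))
  cat(sprintf("  apex tolerance (min)  : %.3g; TIC normalize: %s\n",
              x$apex_tolerance_min, x$tic_normalize))
  invisible(x)
}

#' @export
print.schedule_config <- function(x, ...) {
  cat("<schedule_config>\n")
  cat(sprintf("  window: %.2f min; capacity: %d concurrent transitions; dwell: %.0f ms\n",
              x$window_min, x$max_concurrent_transitions, x$dwell_ms))
  cat(sprintf("  CE coefficients for charge(s): %s\n",
              paste(names(x$ce_coefficients), collapse = ", ")))
  invisible(x)
}
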