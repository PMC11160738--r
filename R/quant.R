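# Replicate normalization and peptide-level quantification metrics.

#' Total-ion-current normalization across replicates
#'
#' Rescales every area by `mean(replicate totals) / (own replicate total)`,
#' so all replicates end up with the same total area (the mean of the raw
#' totals) and run-to-run loading differences cancel. Scaling one
#' replicate's areas by any positive constant leaves its normalized areas
#' unchanged.
#'
#' @param records Transition report tibble.
#' @return The records with `area` replaced by its normalized value.
#' @export
tic_normalize <- function(records) {
  totals <- records |>
    dplyr::group_by(.data$replicate_id) |>
    dplyr::summarise(total = sum(.data$area), .groups = "drop")
  zero <- totals$replicate_id[totals$total <= 0]
  if (length(zero)) {
    abort_data(sprintf("replicate(s) with zero total area: %s",
                       paste(zero, collapse = ", ")))
  }
  grand_mean <- mean(totals$total)
  records |>
    dplyr::left_join(totals, by = "replicate_id") |>
    dplyr::mutate(area = .data$area * grand_mean / .data$total) |>
    dplyr::select(-"total")
}

#' Percent coefficient of variation
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation, the
#' replicate-stability statistic used to judge whether a peptide's summed
#' area is reproducible enough for a targeted assay.
#'
#' @param values Numeric vector of at least 2 finite intensities with a
#'   positive mean.
#' @return Percent CV (scalar).
#' @examples
#' percent_cv(c(1, 2, 3)) # 50
#' @export
percent_cv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values) || any(!is.finite(values))) {
    abort_data("percent_cv needs at least 2 finite values")
  }
  m <- mean(values)
  if (m <= 0) abort_data("percent_cv needs a positive mean")
  100 * sd(values) / m
}

#' Summarize peptides from clean transitions
#'
#' For every peptide, ranks its clean (interference-free in all replicates)
#' transitions by mean area across replicates, fixes the top
#' `min(n_transitions_for_sum, clean count)` as the quantification set, sums
#' that same set within each replicate, and computes the replicate %CV of
#' the sums. The transition set never differs between replicates; ranking
#' on the mean is the most stable single summary of a few replicates.
#' Peptides observed in fewer than 2 replicates are marked non-quantifiable
#' (`cv_pct` is `NA`).
#'
#' @param records Transition report tibble (optionally TIC-normalized).
#' @param qc A `transition_qc` from [qc_summary()] computed on the same
#'   records.
#' @param n_transitions_for_sum How many top clean transitions enter the
#'   per-replicate sums (default 5).
#' @return A `peptide_quant` list with elements:
#'   * `peptides`: per-peptide `clean_transition_count`, `mean_summed_area`,
#'     `cv_pct`, `mean_apex_rt`, `quantifiable`;
#'   * `replicate_sums`: the per-replicate summed areas;
#'   * `transition_ranks`: clean transitions with `mean_area`,
#'     `intensity_rank` and whether each is in the quantification set.
#' @export
summarize_peptides <- function(records, qc, n_transitions_for_sum = 5L) {
  n_transitions_for_sum <- as.integer(n_transitions_for_sum)
  if (is.na(n_transitions_for_sum) || n_transitions_for_sum < 1L) {
    abort_config("`n_transitions_for_sum` must be an integer >= 1")
  }
  clean_keys <- qc$transitions |>
    dplyr::filter(.data$clean) |>
    dplyr::select(dplyr::all_of(c(peptide_key_columns(), "product_ion")))
  clean_rec <- dplyr::inner_join(records, clean_keys,
                                 by = c(peptide_key_columns(), "product_ion"))

  # rank clean transitions on mean replicate area; deterministic tie-breaks
  ranks <- clean_rec |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(peptide_key_columns(), "product_ion", "product_mz")))) |>
    dplyr::summarise(mean_area = mean(.data$area), .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(peptide_key_columns())),
                   dplyr::desc(.data$mean_area), .data$product_mz, .data$product_ion) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(peptide_key_columns()))) |>
    dplyr::mutate(intensity_rank = dplyr::row_number(),
                  in_sum = .data$intensity_rank <= n_transitions_for_sum) |>
    dplyr::ungroup()

  sum_set <- ranks |>
    dplyr::filter(.data$in_sum) |>
    dplyr::select(dplyr::all_of(c(peptide_key_columns(), "product_ion")))
  replicate_sums <- clean_rec |>
    dplyr::inner_join(sum_set, by = c(peptide_key_columns(), "product_ion")) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(peptide_key_columns(), "replicate_id")))) |>
    dplyr::summarise(summed_area = sum(.data$area), .groups = "drop")

  apex <- clean_rec |>
    dplyr::group_by(dplyr::across(dplyr::all_of(peptide_key_columns()))) |>
    dplyr::summarise(mean_apex_rt = mean(.data$apex_rt),
                     precursor_mz = .data$precursor_mz[1], .groups = "drop")

  peptides <- replicate_sums |>
    dplyr::group_by(dplyr::across(dplyr::all_of(peptide_key_columns()))) |>
    dplyr::summarise(n_replicates = dplyr::n(),
                     mean_summed_area = mean(.data$summed_area),
                     cv_pct = if (dplyr::n() >= 2L && mean(.data$summed_area) > 0) {
                       percent_cv(.data$summed_area)
                     } else NA_real_,
                     .groups = "drop") |>
    dplyr::mutate(quantifiable = .data$n_replicates >= 2L & !is.na(.data$cv_pct)) |>
    dplyr::left_join(qc$peptides[, c(peptide_key_columns(), "clean_transition_count")],
                     by = peptide_key_columns()) |>
    dplyr::left_join(apex, by = peptide_key_columns())

  # peptides with no clean transitions at all still get a (non-quantifiable) row
  missing <- dplyr::anti_join(qc$peptides, peptides, by = peptide_key_columns())
  if (nrow(missing) > 0L) {
    peptides <- dplyr::bind_rows(
      peptides,
      missing |>
        dplyr::transmute(dplyr::across(dplyr::all_of(peptide_key_columns())),
                         n_replicates = 0L, mean_summed_area = NA_real_,
                         cv_pct = NA_real_, quantifiable = FALSE,
                         clean_transition_count = .data$clean_transition_count,
                         mean_apex_rt = NA_real_, precursor_mz = NA_real_)
    )
  }
  peptides <- dplyr::arrange(peptides,
                             dplyr::across(dplyr::all_of(peptide_key_columns())))

  structure(list(peptides = peptides, replicate_sums = replicate_sums,
                 transition_ranks = ranks,
                 n_transitions_for_sum = n_transitions_for_sum),
            class = c("peptide_quant", "list"))
}

#' Export the peptide summary table
#'
#' @param quant A `peptide_quant` from [summarize_peptides()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peptide_summary <- function(quant, path) {
  sums_wide <- quant$replicate_sums |>
    tidyr::pivot_wider(names_from = "replicate_id", values_from = "summed_area",
                       names_prefix = "summed_area_")
  out <- dplyr::left_join(quant$peptides, sums_wide, by = peptide_key_columns())
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @export
print.peptide_quant <- function(x, ...) {
  cat("<peptide_quant>\n")
  q <- x$peptides
  cat(sprintf("  %d peptides (%d quantifiable); top-%d clean transitions summed\n",
              nrow(q), sum(q$quantifiable), x$n_transitions_for_sum))
  if (any(q$quantifiable)) {
    cat(sprintf("  median %%CV of quantifiable peptides: %.2f\n",
                median(q$cv_pct[q$quantifiable])))
  }
  invisible(x)
}
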