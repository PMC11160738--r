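# Fixture builders and independent oracles used across the suite.

# minimal canonical report: one row per transition x replicate, constant
# apex per peptide, areas decaying with transition index
make_report <- function(n_proteins = 1, n_peptides = 2, n_transitions = 4,
                        n_replicates = 3, base_area = 1000, rt = 20) {
  grid <- expand.grid(
    p = seq_len(n_proteins), q = seq_len(n_peptides),
    t = seq_len(n_transitions), r = seq_len(n_replicates)
  )
  tibble::tibble(
    protein_id = sprintf("P%02d", grid$p),
    peptide_seq = sprintf("PEPTIDE%02dP%02dK", grid$q, grid$p),
    precursor_charge = 2L,
    precursor_mz = 500 + 10 * grid$q + grid$p,
    product_ion = sprintf("y%d+", grid$t + 2),
    product_mz = 300 + 50 * grid$t + grid$q,
    replicate_id = sprintf("rep%d", grid$r),
    area = base_area * 0.7^(grid$t - 1),
    apex_rt = rt + grid$q * 0.5
  )
}

# quant-like object built directly from a peptide table, for exercising the
# selection rules without running the full QC/quant stages
make_quant <- function(peptides) {
  empty_ranks <- tibble::tibble(
    protein_id = character(0), peptide_seq = character(0),
    precursor_charge = integer(0), product_ion = character(0),
    product_mz = numeric(0), mean_area = numeric(0),
    intensity_rank = integer(0), in_sum = logical(0)
  )
  defaults <- list(quantifiable = TRUE, n_replicates = 3L,
                   mean_apex_rt = 20, precursor_mz = 500)
  for (nm in names(defaults)) {
    if (!nm %in% names(peptides)) peptides[[nm]] <- defaults[[nm]]
  }
  structure(list(peptides = peptides, replicate_sums = NULL,
                 transition_ranks = empty_ranks, n_transitions_for_sum = 5L),
            class = c("peptide_quant", "list"))
}

# independent selection oracle: plain loops + exhaustive subset enumeration
# of rule (2), instead of the package's vectorized sort-and-slice path
oracle_select <- function(peptides, config) {
  qualifying <- peptides[
    peptides$quantifiable &
      peptides$clean_transition_count >= config$min_clean_transitions &
      (if (config$cv_comparison == "lte") peptides$cv_pct <= config$cv_threshold_pct
       else peptides$cv_pct < config$cv_threshold_pct), ]
  picked <- list()
  for (prot in sort(unique(qualifying$protein_id))) {
    cand <- qualifying[qualifying$protein_id == prot, ]
    # one charge per sequence: larger mean summed area, then lower charge
    keep <- rep(TRUE, nrow(cand))
    for (sq in unique(cand$peptide_seq)) {
      idx <- which(cand$peptide_seq == sq)
      if (length(idx) > 1) {
        best <- idx[order(-cand$mean_summed_area[idx], cand$precursor_charge[idx])][1]
        keep[setdiff(idx, best)] <- FALSE
      }
    }
    cand <- cand[keep, ]
    if (nrow(cand) < config$require_min_peptides_per_protein) next
    if (nrow(cand) > config$n_peptides_per_protein) {
      short <- cand[order(-cand$mean_summed_area, cand$peptide_seq), ]
      short <- short[seq_len(min(config$top_k_peptides_by_intensity, nrow(short))), ]
      n_take <- min(config$n_peptides_per_protein, nrow(short))
      combos <- utils::combn(nrow(short), n_take)
      best <- NULL
      best_score <- NULL
      for (j in seq_len(ncol(combos))) {
        rows <- combos[, j]
        score <- list(sum(short$cv_pct[rows]),
                      paste(sort(short$peptide_seq[rows]), collapse = "|"))
        better <- is.null(best) ||
          score[[1]] < best_score[[1]] - 1e-12 ||
          (abs(score[[1]] - best_score[[1]]) <= 1e-12 &&
             score[[2]] < best_score[[2]])
        if (better) {
          best <- rows
          best_score <- score
        }
      }
      cand <- short[best, ]
    }
    picked[[prot]] <- cand[, c("protein_id", "peptide_seq", "precursor_charge")]
  }
  empty <- tibble::tibble(protein_id = character(0),
                          peptide_seq = character(0),
                          precursor_charge = integer(0))
  out <- dplyr::bind_rows(c(list(empty), picked))
  out[order(out$protein_id, out$peptide_seq), ]
}

# random peptide table for oracle comparisons
random_peptide_table <- function(n_proteins, max_peptides) {
  n_pep <- sample(1:max_peptides, n_proteins, replace = TRUE)
  rows <- sum(n_pep)
  tibble::tibble(
    protein_id = rep(sprintf("PR%02d", seq_len(n_proteins)), n_pep),
    peptide_seq = sprintf("SEQ%04dK", sample(9999, rows)),
    precursor_charge = sample(2:3, rows, replace = TRUE),
    clean_transition_count = sample(1:8, rows, replace = TRUE),
    mean_summed_area = rlnorm(rows, 10, 1),
    cv_pct = runif(rows, 0, 40),
    quantifiable = runif(rows) > 0.05
  )
}

# dense-grid concurrency oracle, independent of the sweep-line path; the
# grid is augmented with the window starts so overlaps narrower than the
# step are still seen
grid_concurrency <- function(windows, n_standard_transitions = 0,
                             gradient_length = 60, dt = 0.01) {
  times <- unique(c(seq(0, gradient_length, by = dt), windows$window_start))
  counts <- vapply(times, function(t) {
    sum(windows$n_transitions[windows$window_start <= t & t < windows$window_end])
  }, numeric(1))
  max(counts) + n_standard_transitions
}

# windows for scheduling tests
random_windows <- function(n, gradient_length = 60, window_min = 5) {
  center <- runif(n, 0, gradient_length)
  tibble::tibble(
    peptide_seq = sprintf("W%03dK", seq_len(n)),
    window_start = pmax(0, center - window_min / 2),
    window_end = pmin(gradient_length, center + window_min / 2),
    n_transitions = sample(3:6, n, replace = TRUE)
  )
}
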