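# Seeded synthetic transition reports with planted ground truth.
#
# The generator emulates the replicate structure of a gas-phase
# fractionated DIA chromatogram library: proteins x peptides x product-ion
# transitions measured in (by default) 3 replicate experiments, lognormal
# peptide abundances, a geometric decay of transition intensity over rank
# (so "top N most intense" is well separated), multiplicative replicate
# noise shared across a peptide's transitions (injection/loading
# variation), small independent per-transition noise, a linear iRT -> RT
# model with jitter, planted interfered transitions (shifted apex) and
# planted unstable peptides (inflated replicate spread). Areas are emitted
# post-integration; raw chromatogram traces are out of scope.
#
# `noise_cv` is calibrated to the *observed* replicate %CV: with few
# replicates the sample CV is median-biased low (for n replicates by the
# factor sqrt(median chi-square_{n-1} / (n-1)), ~0.83 at n = 3), so the
# underlying lognormal sigma is inflated by the reciprocal factor. The
# planted noise level is therefore what the downstream %CV metric
# recovers.

AA_POOL <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]

cv_bias_correction <- function(n_replicates) {
  if (n_replicates < 2L) return(1)
  1 / sqrt(stats::qchisq(0.5, df = n_replicates - 1) / (n_replicates - 1))
}

lognormal_sdlog <- function(cv) sqrt(log(1 + cv^2))

random_peptide_seqs <- function(n) {
  gen <- function(k) {
    vapply(seq_len(k), function(i) {
      len <- sample(8:14, 1L)
      paste0(paste(sample(AA_POOL, len, replace = TRUE), collapse = ""),
             sample(c("K", "R"), 1L))
    }, character(1))
  }
  seqs <- gen(n)
  while (anyDuplicated(seqs)) {
    dup <- which(duplicated(seqs))
    seqs[dup] <- gen(length(dup))
  }
  seqs
}

#' Synthetic-data configuration
#'
#' Defines the conditions a generated report emulates. Defaults reflect a
#' triplicate narrow-window DIA library of a complex digest: a median
#' replicate %CV around 13.5, a small fraction of interfered transitions
#' whose apex is displaced well beyond the co-elution tolerance, and a
#' linear iRT-to-RT model spanning a 60-minute gradient.
#'
#' @param seed Integer RNG seed; the report is a pure function of the
#'   config including this seed.
#' @param n_proteins Number of proteins (ignored when `protein_plan` is
#'   given).
#' @param peptides_per_protein Integer range `c(min, max)`.
#' @param transitions_per_peptide Integer range `c(min, max)`.
#' @param n_replicates Replicate experiments (default 3).
#' @param abundance_meanlog,abundance_sdlog Lognormal peptide base
#'   abundance.
#' @param noise_cv Target observed per-peptide replicate %CV / 100
#'   (default 0.135). See the package vignette for the small-sample
#'   calibration.
#' @param transition_noise_cv Independent per-transition multiplicative
#'   noise (default 0.02).
#' @param frac_interfered_transitions Fraction of transitions planted as
#'   interfered (apex shifted); capped so interfered transitions stay a
#'   minority within each peptide.
#' @param interference_shift_min Apex displacement of interfered
#'   transitions, minutes (default 0.5 = 5x the default co-elution
#'   tolerance).
#' @param frac_unstable_peptides Fraction of peptides planted unstable.
#' @param unstable_extra_cv Extra replicate CV of unstable peptides when
#'   `unstable_mode = "lognormal"`.
#' @param unstable_mode `"lognormal"` samples extra replicate noise;
#'   `"spread"` applies a fixed log-spaced replicate fold-spread
#'   (deterministic CV of roughly 120%), which guarantees the planted
#'   unstable label is recovered at any seed.
#' @param rt_slope,rt_intercept,rt_jitter_sd Linear iRT -> RT model
#'   (min/iRT-unit, min, min).
#' @param irt_range iRT values are drawn uniformly from this range.
#' @param rank_decay Geometric decay ratio of transition intensity over
#'   rank (default 0.7).
#' @param protein_plan Optional peptide-level plan tibble (columns
#'   `protein_id`, `role`, `detected`, `n_transitions`, `unstable`,
#'   `n_interfered`); overrides the random structure. Used by presets.
#' @param preset Optional preset label carried in the config.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_proteins = 20L,
                             peptides_per_protein = c(2L, 5L),
                             transitions_per_peptide = c(5L, 8L),
                             n_replicates = 3L,
                             abundance_meanlog = log(1e5),
                             abundance_sdlog = 1,
                             noise_cv = 0.135,
                             transition_noise_cv = 0.02,
                             frac_interfered_transitions = 0.05,
                             interference_shift_min = 0.5,
                             frac_unstable_peptides = 0.05,
                             unstable_extra_cv = 0.5,
                             unstable_mode = c("lognormal", "spread"),
                             rt_slope = 0.5,
                             rt_intercept = 5,
                             rt_jitter_sd = 0.02,
                             irt_range = c(0, 100),
                             rank_decay = 0.7,
                             protein_plan = NULL,
                             preset = NULL) {
  unstable_mode <- match.arg(unstable_mode)
  fr <- c(frac_interfered_transitions, frac_unstable_peptides)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1)) {
    abort_config("fractions must lie in [0, 1]")
  }
  if (noise_cv < 0 || transition_noise_cv < 0) {
    abort_config("noise CVs must be >= 0")
  }
  if (length(transitions_per_peptide) != 2L || transitions_per_peptide[1] < 1L ||
      diff(transitions_per_peptide) < 0) {
    abort_config("`transitions_per_peptide` must be an ascending range with min >= 1")
  }
  if (length(peptides_per_protein) != 2L || peptides_per_protein[1] < 1L ||
      diff(peptides_per_protein) < 0) {
    abort_config("`peptides_per_protein` must be an ascending range with min >= 1")
  }
  if (n_replicates < 1L) abort_config("`n_replicates` must be >= 1")
  if (!is.null(protein_plan)) {
    need <- c("protein_id", "role", "detected", "n_transitions", "unstable",
              "n_interfered")
    missing <- setdiff(need, names(protein_plan))
    if (length(missing)) {
      abort_config(sprintf("protein_plan lacks column(s): %s",
                           paste(missing, collapse = ", ")))
    }
    if (any(protein_plan$n_transitions < 1L)) {
      abort_config("protein_plan has peptides with < 1 transition")
    }
    if (any(protein_plan$n_interfered > pmax(0L, (protein_plan$n_transitions - 1L) %/% 2L))) {
      abort_config("planted interference must stay a minority of a peptide's transitions")
    }
  }
  structure(
    list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
         peptides_per_protein = as.integer(peptides_per_protein),
         transitions_per_peptide = as.integer(transitions_per_peptide),
         n_replicates = as.integer(n_replicates),
         abundance_meanlog = abundance_meanlog,
         abundance_sdlog = abundance_sdlog,
         noise_cv = noise_cv, transition_noise_cv = transition_noise_cv,
         frac_interfered_transitions = frac_interfered_transitions,
         interference_shift_min = interference_shift_min,
         frac_unstable_peptides = frac_unstable_peptides,
         unstable_extra_cv = unstable_extra_cv, unstable_mode = unstable_mode,
         rt_slope = rt_slope, rt_intercept = rt_intercept,
         rt_jitter_sd = rt_jitter_sd, irt_range = as.numeric(irt_range),
         rank_decay = rank_decay, protein_plan = protein_plan, preset = preset),
    class = c("synthetic_config", "list")
  )
}

sample_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n) else sample(range[1]:range[2], n, replace = TRUE)
}

#' Generate a synthetic transition report with ground truth
#'
#' Deterministic given the config (same config, byte-identical output).
#' Every transition is labelled interfered or not and every peptide
#' unstable or not, so downstream interference flagging, %CV filtering and
#' selection can be checked against planted truth.
#'
#' @param config A [synthetic_config()].
#' @return An `srm_simulation` list: `report` (canonical transition-report
#'   tibble), `truth` (list of `peptides` and `transitions` label
#'   tibbles), and the `config`.
#' @export
generate_report <- function(config = synthetic_config()) {
  set.seed(config$seed)
  n_rep <- config$n_replicates

  # peptide-level plan (planted structure)
  if (!is.null(config$protein_plan)) {
    plan <- tibble::as_tibble(config$protein_plan)
  } else {
    n_pep <- sample_range(config$n_proteins, config$peptides_per_protein)
    plan <- tibble::tibble(
      protein_id = rep(sprintf("PROT%04d", seq_len(config$n_proteins)), n_pep)
    )
    plan$role <- "random"
    plan$detected <- TRUE
    plan$n_transitions <- sample_range(nrow(plan), config$transitions_per_peptide)
    plan$unstable <- runif(nrow(plan)) < config$frac_unstable_peptides
    max_interfered <- pmax(0L, (plan$n_transitions - 1L) %/% 2L)
    plan$n_interfered <- pmin(
      stats::rbinom(nrow(plan), plan$n_transitions, config$frac_interfered_transitions),
      max_interfered)
  }

  pep <- plan
  pep$peptide_seq <- random_peptide_seqs(nrow(pep))
  pep$precursor_charge <- sample(2:3, nrow(pep), replace = TRUE)
  pep$precursor_mz <- round(runif(nrow(pep), 400, 1000), 4)
  pep$irt <- runif(nrow(pep), config$irt_range[1], config$irt_range[2])
  pep$base_abundance <- rlnorm(nrow(pep), config$abundance_meanlog,
                               config$abundance_sdlog)
  pep$rt <- config$rt_slope * pep$irt + config$rt_intercept
  pep$.pep <- seq_len(nrow(pep))

  obs <- pep[pep$detected, ]

  # transition level
  tr <- obs[rep(seq_len(nrow(obs)), obs$n_transitions), ]
  tr$rank <- sequence(obs$n_transitions)
  tr$product_ion <- sprintf("y%d+", tr$n_transitions + 2L - tr$rank)
  tr$product_mz <- round(runif(nrow(tr), 200, 1300), 4)
  tr$rel_intensity <- config$rank_decay^(tr$rank - 1)
  # interfered transitions: a random minority subset within each peptide
  tr$.u <- runif(nrow(tr))
  tr <- tr |>
    dplyr::group_by(.data$.pep) |>
    dplyr::mutate(interfered = rank(.data$.u, ties.method = "first") <=
                    .data$n_interfered[1]) |>
    dplyr::ungroup()
  tr$shift_sign <- sample(c(-1, 1), nrow(tr), replace = TRUE)

  # replicate effects shared across a peptide's transitions
  s_noise <- lognormal_sdlog(config$noise_cv) * cv_bias_correction(n_rep)
  s_unst <- lognormal_sdlog(config$noise_cv + config$unstable_extra_cv) *
    cv_bias_correction(n_rep)
  rep_eff <- matrix(rnorm(nrow(obs) * n_rep), nrow(obs), n_rep)
  spread <- exp(seq(-1.5, 1.5, length.out = n_rep))
  rep_factor <- matrix(0, nrow(obs), n_rep)
  for (r in seq_len(n_rep)) {
    base_f <- exp(rep_eff[, r] * s_noise)
    unst_f <- if (config$unstable_mode == "spread") {
      spread[r] * exp(rep_eff[, r] * s_noise)
    } else {
      exp(rep_eff[, r] * s_unst)
    }
    rep_factor[, r] <- ifelse(obs$unstable, unst_f, base_f)
  }
  pep_row <- match(tr$.pep, obs$.pep)

  s_tr <- lognormal_sdlog(config$transition_noise_cv)
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    tr_noise <- if (s_tr > 0) exp(rnorm(nrow(tr), 0, s_tr)) else rep(1, nrow(tr))
    jitter <- rnorm(nrow(tr), 0, config$rt_jitter_sd)
    apex <- tr$rt + jitter +
      ifelse(tr$interfered, tr$shift_sign * config$interference_shift_min, 0)
    rows[[r]] <- tibble::tibble(
      protein_id = tr$protein_id, peptide_seq = tr$peptide_seq,
      precursor_charge = tr$precursor_charge, precursor_mz = tr$precursor_mz,
      product_ion = tr$product_ion, product_mz = tr$product_mz,
      replicate_id = sprintf("rep%d", r),
      area = tr$base_abundance * tr$rel_intensity * rep_factor[pep_row, r] * tr_noise,
      apex_rt = pmax(0, apex)
    )
  }
  report <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$protein_id, .data$peptide_seq, .data$product_mz,
                   .data$replicate_id)

  truth_peptides <- pep |>
    dplyr::select(dplyr::all_of(c("protein_id", "peptide_seq", "precursor_charge",
                                  "role", "detected", "unstable", "n_transitions",
                                  "n_interfered", "base_abundance", "irt", "rt")))
  truth_transitions <- tr |>
    dplyr::select(dplyr::all_of(c("protein_id", "peptide_seq", "precursor_charge",
                                  "product_ion", "product_mz", "rank",
                                  "rel_intensity", "interfered")))
  structure(list(report = report,
                 truth = list(peptides = truth_peptides,
                              transitions = truth_transitions),
                 config = config),
            class = c("srm_simulation", "list"))
}

#' Chronic-pain panel preset
#'
#' A planted re-query scenario: 87 candidate proteins of which 2 are never
#' detected; of the 85 detected, 67 are constructed to pass a 5-clean-
#' transition / 2-peptide / %CV filter (carrying 2-4 well-behaved peptides
#' with 6-8 clean transitions each) and 18 are constructed to fail exactly
#' one criterion, with the failure mode cycled deterministically over
#' too-few-peptides, too-few-clean-transitions and %CV-above-threshold.
#' Replicate noise is set to an observed %CV near 3, the precision regime
#' of a well-behaved scheduled triple-quadrupole assay.
#'
#' @param seed RNG seed for the generated intensities/retention times; the
#'   planted pass/fail structure is seed-independent.
#' @return A [synthetic_config()] carrying the preset `protein_plan`.
#' @export
preset_pain_panel <- function(seed = 7L) {
  n_total <- 87L
  ids <- sprintf("PAIN%03d", seq_len(n_total))
  undetected <- c(29L, 58L)
  detected_ids <- ids[-undetected]
  fail_pos <- round(seq(3, 83, length.out = 18L))
  modes <- rep(c("fail_few_peptides", "fail_few_clean", "fail_high_cv"), 6L)
  role <- rep("pass", length(detected_ids))
  role[fail_pos] <- modes

  rows <- list()
  for (i in seq_along(detected_ids)) {
    pid <- detected_ids[i]
    rows[[length(rows) + 1L]] <- switch(
      role[i],
      pass = {
        n_pep <- 2L + (i %% 3L)
        tibble::tibble(protein_id = pid, role = "pass", detected = TRUE,
                       n_transitions = 6L + (seq_len(n_pep) %% 3L),
                       unstable = FALSE, n_interfered = 0L)
      },
      fail_few_peptides = tibble::tibble(
        protein_id = pid, role = "fail_few_peptides", detected = TRUE,
        n_transitions = 6L, unstable = FALSE, n_interfered = 0L),
      fail_few_clean = tibble::tibble(
        protein_id = pid, role = "fail_few_clean", detected = TRUE,
        n_transitions = c(4L, 4L), unstable = FALSE, n_interfered = 0L),
      fail_high_cv = tibble::tibble(
        protein_id = pid, role = "fail_high_cv", detected = TRUE,
        n_transitions = c(6L, 6L), unstable = TRUE, n_interfered = 0L)
    )
  }
  for (u in undetected) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      protein_id = ids[u], role = "undetected", detected = FALSE,
      n_transitions = 6L, unstable = FALSE, n_interfered = 0L)
  }
  plan <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$protein_id)

  synthetic_config(seed = seed, protein_plan = plan,
                   n_replicates = 3L,
                   noise_cv = 0.03, transition_noise_cv = 0.02,
                   rt_jitter_sd = 0.01,
                   frac_interfered_transitions = 0,
                   frac_unstable_peptides = 0,
                   unstable_mode = "spread",
                   preset = "pain_panel")
}

#' Selection configuration matching the pain-panel re-query
#'
#' At least 5 interference-free co-eluting transitions, at least 2
#' qualifying peptides per protein, the 2 best peptides kept, 5 transitions
#' each. TIC normalization is off: the preset plants no shared loading
#' variation, and rescaling replicates against totals that contain the
#' planted-unstable signal would couple otherwise independent peptides.
#'
#' @return A [selection_config()].
#' @export
pain_panel_selection_config <- function() {
  selection_config(min_clean_transitions = 5L,
                   n_peptides_per_protein = 2L,
                   require_min_peptides_per_protein = 2L,
                   n_transitions_per_peptide = 5L,
                   tic_normalize = FALSE)
}

#' Synthetic retention-time standards
#'
#' A synthetic stand-in for a commercial retention-time calibration mixture:
#' `n_standards` peptides with evenly spaced iRT values, measured retention
#' times from a linear model plus noise, and `transitions_per_standard`
#' transitions each (13 x 3 = 39 transition rows by default).
#'
#' @param seed RNG seed.
#' @param n_standards Number of standard peptides (default 13).
#' @param transitions_per_standard Transitions per standard (default 3).
#' @param rt_slope,rt_intercept Linear iRT -> RT model of the system the
#'   standards were measured on.
#' @param rt_noise_sd Measurement noise on the standard retention times
#'   (min).
#' @return Tibble, one row per standard transition: `name`, `irt`,
#'   `measured_rt`, `precursor_mz`, `precursor_charge`, `product_mz`,
#'   `product_ion`.
#' @export
simulate_standards <- function(seed = 1L, n_standards = 13L,
                               transitions_per_standard = 3L,
                               rt_slope = 0.5, rt_intercept = 5,
                               rt_noise_sd = 0.05) {
  set.seed(seed)
  irt <- seq(-20, 100, length.out = n_standards)
  measured <- rt_slope * irt + rt_intercept + rnorm(n_standards, 0, rt_noise_sd)
  st <- tibble::tibble(
    name = sprintf("SYN-STD-%02d", seq_len(n_standards)),
    irt = irt, measured_rt = measured,
    precursor_mz = round(runif(n_standards, 400, 900), 4),
    precursor_charge = 2L
  )
  tr <- st[rep(seq_len(n_standards), each = transitions_per_standard), ]
  tr$product_ion <- sprintf("y%d+", rep(seq(4, 3 + transitions_per_standard),
                                        times = n_standards))
  tr$product_mz <- round(runif(nrow(tr), 200, 1300), 4)
  tr
}

#' Write a simulation to disk
#'
#' Writes the canonical report plus the ground-truth label tables.
#'
#' @param sim An `srm_simulation`.
#' @param dir Output directory.
#' @return Named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(report = file.path(dir, "report.csv"),
             truth_peptides = file.path(dir, "truth_peptides.csv"),
             truth_transitions = file.path(dir, "truth_transitions.csv"))
  write_transition_report(sim$report, paths[["report"]])
  readr::write_csv(sim$truth$peptides, paths[["truth_peptides"]], progress = FALSE)
  readr::write_csv(sim$truth$transitions, paths[["truth_transitions"]], progress = FALSE)
  invisible(paths)
}

#' @export
print.srm_simulation <- function(x, ...) {
  cat("<srm_simulation>\n")
  cat(sprintf("  %d report rows; %d peptides over %d proteins; seed %d%s\n",
              nrow(x$report), nrow(x$truth$peptides),
              dplyr::n_distinct(x$truth$peptides$protein_id), x$config$seed,
              if (!is.null(x$config$preset)) paste0("; preset ", x$config$preset) else ""))
  invisible(x)
}
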