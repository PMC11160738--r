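pep_row <- function(protein, seq, clean = 6, cv = 5, area = 1e5, charge = 2L) {
  tibble::tibble(protein_id = protein, peptide_seq = seq,
                 precursor_charge = charge, clean_transition_count = clean,
                 mean_summed_area = area, cv_pct = cv)
}

test_that("the quantifiability filter applies both thresholds from config", {
  peptides <- dplyr::bind_rows(
    pep_row("P1", "AAK", clean = 2, cv = 5),
    pep_row("P1", "CCK", clean = 5, cv = 19.9),
    pep_row("P1", "DDK", clean = 4, cv = 19.9),
    pep_row("P1", "EEK", clean = 3, cv = 20.0),
    pep_row("P1", "FFK", clean = 3, cv = 20.1)
  )
  q <- make_quant(peptides)
  # defaults: min 3 clean, %CV <= 20
  got <- filter_quantifiable(q, selection_config())
  expect_setequal(got$peptide_seq, c("CCK", "DDK", "EEK"))
  # a 5-clean-transition requirement
  got5 <- filter_quantifiable(q, selection_config(min_clean_transitions = 5))
  expect_setequal(got5$peptide_seq, "CCK")
  # strict comparison drops the boundary peptide
  gotlt <- filter_quantifiable(q, selection_config(cv_comparison = "lt"))
  expect_setequal(gotlt$peptide_seq, c("CCK", "DDK"))
  # empty input -> empty output
  empty <- make_quant(peptides[0, ])
  expect_equal(nrow(filter_quantifiable(empty, selection_config())), 0)
})

test_that("selection shortlists by intensity then keeps the lowest-CV peptides", {
  # 7 qualifying peptides; intensity ranks 4 and 5 carry the lowest CVs
  peptides <- dplyr::bind_rows(lapply(1:7, function(i) {
    pep_row("P1", sprintf("PEP%dK", i), area = 1e6 - i * 1e4,
            cv = c(10, 11, 12, 1, 2, 0.1, 0.2)[i])
  }))
  assay <- select_assay(make_quant(peptides), selection_config())
  expect_setequal(assay$targets$peptide_seq, c("PEP4K", "PEP5K"))
})

test_that("a protein with exactly the target number of peptides keeps them all", {
  peptides <- dplyr::bind_rows(
    pep_row("P1", "AAK", cv = 19), pep_row("P1", "CCK", cv = 3))
  assay <- select_assay(make_quant(peptides), selection_config())
  expect_setequal(assay$targets$peptide_seq, c("AAK", "CCK"))
})

test_that("ties break lexicographically by peptide sequence", {
  peptides <- dplyr::bind_rows(
    pep_row("P1", "ZZK", cv = 5, area = 100),
    pep_row("P1", "AAK", cv = 5, area = 100),
    pep_row("P1", "MMK", cv = 5, area = 100)
  )
  assay <- select_assay(make_quant(peptides), selection_config())
  expect_equal(sort(assay$targets$peptide_seq), c("AAK", "MMK"))
})

test_that("one precursor charge per sequence: the more intense charge wins", {
  peptides <- dplyr::bind_rows(
    pep_row("P1", "AAK", charge = 2L, area = 100),
    pep_row("P1", "AAK", charge = 3L, area = 900),
    pep_row("P1", "CCK", charge = 2L, area = 500)
  )
  assay <- select_assay(make_quant(peptides), selection_config())
  expect_equal(nrow(assay$targets), 2)
  aak <- assay$targets[assay$targets$peptide_seq == "AAK", ]
  expect_equal(aak$precursor_charge, 3L)
})

test_that("proteins below the qualifying-peptide minimum are dropped and logged", {
  peptides <- dplyr::bind_rows(
    pep_row("P1", "AAK"), pep_row("P1", "CCK"),
    pep_row("P2", "DDK"),
    pep_row("P3", "EEK", clean = 2), pep_row("P3", "FFK", clean = 1),
    pep_row("P4", "GGK", cv = 35), pep_row("P4", "HHK", cv = 40)
  )
  cfg <- selection_config(require_min_peptides_per_protein = 2)
  assay <- select_assay(make_quant(peptides), cfg)
  expect_setequal(unique(assay$targets$protein_id), "P1")
  drop <- setNames(assay$dropped$reason, assay$dropped$protein_id)
  expect_equal(drop[["P2"]], "too_few_qualifying_peptides")
  expect_equal(drop[["P3"]], "too_few_clean_transitions")
  expect_equal(drop[["P4"]], "cv_above_threshold")
})

test_that("raising the CV threshold never removes a qualifying peptide", {
  set.seed(501)
  for (i in 1:20) {
    q <- make_quant(random_peptide_table(6, 8))
    th <- sort(runif(2, 5, 40))
    lo <- filter_quantifiable(q, selection_config(cv_threshold_pct = th[1]))
    hi <- filter_quantifiable(q, selection_config(cv_threshold_pct = th[2]))
    key <- function(d) paste(d$protein_id, d$peptide_seq, d$precursor_charge)
    expect_true(all(key(lo) %in% key(hi)))
  }
})

test_that("selection agrees with exhaustive rule enumeration on random instances", {
  set.seed(502)
  for (i in 1:50) {
    peptides <- random_peptide_table(sample(1:10, 1), 8)
    cfg <- selection_config(
      min_clean_transitions = sample(3:5, 1),
      cv_threshold_pct = runif(1, 10, 35),
      n_peptides_per_protein = sample(1:3, 1),
      top_k_peptides_by_intensity = sample(3:6, 1),
      require_min_peptides_per_protein = sample(1:2, 1))
    got <- select_assay(make_quant(peptides), cfg)$targets
    want <- oracle_select(peptides, cfg)
    expect_equal(
      got[, c("protein_id", "peptide_seq", "precursor_charge")],
      want,
      ignore_attr = TRUE
    )
  }
})

test_that("selected peptides carry their top clean transitions in rank order", {
  sim <- generate_report(synthetic_config(
    seed = 503, n_proteins = 4, noise_cv = 0.02,
    frac_interfered_transitions = 0, frac_unstable_peptides = 0))
  b <- build_assay(sim$report, selection_config())
  per_pep <- split(b$assay$transitions$intensity_rank,
                   b$assay$transitions$peptide_seq)
  for (ranks in per_pep) expect_equal(ranks, seq_along(ranks))
  expect_true(all(lengths(per_pep) <= 5))
})

test_that("overlap reports mirror the assay-comparison arithmetic", {
  sel <- tibble::tibble(protein_id = rep(sprintf("P%d", 1:100), each = 2),
                        peptide_seq = sprintf("SEL%03dK", 1:200),
                        precursor_charge = 2L)
  # identity
  same <- compare_to_reference(sel, sel)
  expect_equal(same$pct_selected_unique, 0)
  expect_length(same$proteins_with_identical_selection, 100)
  expect_length(same$proteins_with_no_overlap, 0)
  # disjoint over the same proteins
  other <- sel
  other$peptide_seq <- sprintf("REF%03dK", 1:200)
  disj <- compare_to_reference(sel, other)
  expect_equal(disj$pct_selected_unique, 100)
  expect_length(disj$proteins_with_no_overlap, 100)
  # 200 selected, 50 shared -> 75% unique
  ref <- dplyr::bind_rows(sel[1:50, ], other[51:200, ])
  part <- compare_to_reference(sel, ref)
  expect_equal(part$n_shared, 50)
  expect_equal(part$pct_selected_unique, 75)
})
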