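test_that("a well-formed report reads into the expected records", {
  rep_file <- withr::local_tempfile(fileext = ".csv")
  write_transition_report(make_report(1, 2, 4, 3), rep_file)
  records <- read_transition_report(rep_file)
  expect_equal(nrow(records), 1 * 2 * 4 * 3)
  expect_equal(nrow(attr(records, "rejects")), 0)
  expect_setequal(unique(records$replicate_id), c("rep1", "rep2", "rep3"))
})

test_that("a missing required column is a configuration error naming it", {
  rep_file <- withr::local_tempfile(fileext = ".csv")
  r <- make_report()
  readr::write_csv(r[setdiff(names(r), "apex_rt")], rep_file)
  expect_error(read_transition_report(rep_file),
               "apex_rt", class = "srmforge_config_error")
})

test_that("column mapping and tab-delimited input are supported", {
  rep_file <- withr::local_tempfile(fileext = ".tsv")
  r <- make_report()
  names(r)[names(r) == "protein_id"] <- "Protein Name"
  names(r)[names(r) == "area"] <- "Area"
  readr::write_tsv(r, rep_file)
  records <- read_transition_report(
    rep_file, column_map = c(protein_id = "Protein Name", area = "Area"))
  expect_equal(nrow(records), nrow(r))
  expect_true(all(records$protein_id == "P01"))
})

test_that("generated reports round-trip through write/read unchanged", {
  sim <- generate_report(synthetic_config(seed = 11, n_proteins = 4))
  rep_file <- withr::local_tempfile(fileext = ".csv")
  write_transition_report(sim$report, rep_file)
  back <- read_transition_report(rep_file)
  attr(back, "rejects") <- NULL
  attr(back, "spec") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(sim$report), tolerance = 1e-12)
})

test_that("no row is silently dropped: records + rejects = input rows", {
  r <- make_report(1, 2, 4, 3)
  r$area[c(3, 10)] <- -5
  r$apex_rt[7] <- -1
  rep_file <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(r, rep_file)
  expect_warning(records <- read_transition_report(rep_file), "rejected 3")
  rejects <- attr(records, "rejects")
  expect_equal(nrow(records) + nrow(rejects), nrow(r))
  expect_setequal(rejects$row, c(3, 7, 10))
})

test_that("duplicate keys and unreadable numerics are data errors", {
  r <- make_report(1, 1, 3, 2)
  rep_file <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(rbind(r, r[1, ]), rep_file)
  expect_error(read_transition_report(rep_file), "duplicate",
               class = "srmforge_data_error")

  r2 <- make_report(1, 1, 3, 2)
  r2$area <- as.character(r2$area)
  r2$area[4] <- "not-a-number"
  readr::write_csv(r2, rep_file)
  expect_error(read_transition_report(rep_file), "row 4",
               class = "srmforge_data_error")
})

make_test_method <- function(n_targets = 2, n_transitions = 5, n_std = 1,
                             std_transitions = 3) {
  grid <- expand.grid(t = seq_len(n_transitions), q = seq_len(n_targets))
  targets <- tibble::tibble(
    protein_id = "P1", peptide_seq = sprintf("TARGETPEP%dK", grid$q),
    precursor_charge = 2L, precursor_mz = 500.1234 + grid$q,
    product_ion = sprintf("y%d+", grid$t + 2), product_mz = 600.5 + grid$t,
    mean_area = 10, intensity_rank = grid$t,
    irt = 50, predicted_rt = 30 + grid$q, window_start = 27.5 + grid$q,
    window_end = 32.5 + grid$q, ce = 20.4
  )
  sgrid <- expand.grid(t = seq_len(std_transitions), s = seq_len(n_std))
  standards <- tibble::tibble(
    name = sprintf("STD%d", sgrid$s), irt = 0, measured_rt = 10,
    precursor_mz = 450.9876, precursor_charge = 2L,
    product_mz = 700.1 + sgrid$t, product_ion = sprintf("y%d+", sgrid$t + 3),
    predicted_rt = 10, window_start = 0, window_end = 60, ce = 18.6
  )
  structure(list(index = 1L, targets = targets,
                 target_peptides = targets[!duplicated(targets$peptide_seq), ],
                 standards = standards, peak_concurrency = 0L, peak_time = 0),
            class = c("scheduled_method", "list"))
}

test_that("transition lists carry targets plus standards, one file per method", {
  dir <- withr::local_tempdir()
  m <- make_test_method(n_targets = 2, n_transitions = 5, std_transitions = 3)
  files <- write_transition_list(list(m), "instrument", dir)
  expect_length(files, 1)
  out <- readr::read_csv(files[1], show_col_types = FALSE)
  expect_equal(nrow(out), 2 * 5 + 3)
  expect_named(out, c("Compound", "Retention Time (min)", "RT Window (min)",
                      "Precursor (m/z)", "Product (m/z)", "Collision Energy (V)"))
  # m/z to 4 decimals, RT and CE to 2
  expect_match(format(out$`Precursor (m/z)`[1], nsmall = 4), "\\.\\d{4}$")
  expect_equal(out$`RT Window (min)`[1], 5)
})

test_that("an empty method list writes nothing and warns", {
  dir <- withr::local_tempdir()
  expect_warning(files <- write_transition_list(list(), "instrument", dir),
                 "no scheduled methods")
  expect_length(files, 0)
  expect_length(list.files(dir), 0)
})

test_that("skyline dialect round-trips peptide and m/z identities", {
  dir <- withr::local_tempdir()
  m <- make_test_method()
  files <- write_transition_list(list(m), "skyline", dir)
  back <- read_transition_list(files[1], "skyline")
  orig <- m$targets
  got <- back[back$protein_id != "Standards", ]
  expect_equal(got$peptide_seq, orig$peptide_seq)
  expect_equal(got$precursor_mz, round(orig$precursor_mz, 4))
  expect_equal(got$product_mz, round(orig$product_mz, 4))
})

test_that("targets without assigned RT or CE are a state error", {
  dir <- withr::local_tempdir()
  m <- make_test_method()
  m$targets$predicted_rt[2] <- NA
  expect_error(write_transition_list(list(m), "instrument", dir),
               class = "srmforge_state_error")
})

test_that("pipeline YAML config merges file values and overrides", {
  cfg_file <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("selection:", "  min_clean_transitions: 5",
               "  cv_threshold_pct: 30", "schedule:", "  window_min: 4"),
             cfg_file)
  cfgs <- read_pipeline_config(cfg_file,
                               overrides = list(selection = list(cv_threshold_pct = 25)))
  expect_equal(cfgs$selection$min_clean_transitions, 5L)
  expect_equal(cfgs$selection$cv_threshold_pct, 25)
  expect_equal(cfgs$schedule$window_min, 4)
  expect_error(read_pipeline_config(cfg_file, overrides = list(selection = list(bogus = 1))),
               class = "srmforge_config_error")
})
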