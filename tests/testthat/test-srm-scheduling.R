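test_that("RT calibration recovers the line through the standards", {
  two <- tibble::tibble(name = c("a", "b"), irt = c(0, 100),
                        measured_rt = c(10, 60))
  cal <- calibrate_rt(two)
  expect_equal(cal$slope, 0.5)
  expect_equal(cal$intercept, 10)
  expect_equal(cal$rmse, 0)

  exact <- tibble::tibble(name = letters[1:8], irt = seq(0, 70, 10),
                          measured_rt = 0.4 * seq(0, 70, 10) + 3)
  expect_equal(calibrate_rt(exact)$rmse, 0, tolerance = 1e-10)

  expect_error(calibrate_rt(two[1, ]), class = "srmforge_data_error")
  same_irt <- tibble::tibble(name = c("a", "b"), irt = c(5, 5),
                             measured_rt = c(1, 2))
  expect_error(calibrate_rt(same_irt), class = "srmforge_data_error")
})

test_that("iRT conversion inverts cleanly", {
  cal <- calibrate_rt(tibble::tibble(name = c("a", "b", "c"),
                                     irt = c(0, 50, 100),
                                     measured_rt = c(5, 30, 55)))
  irt <- c(-10, 0, 33.3, 100)
  expect_equal(irt_from_rt(cal, rt_from_irt(cal, irt)), irt)
})

test_that("windows are centred on the predicted RT and clipped to the gradient", {
  cal <- list(slope = 1, intercept = 0)
  class(cal) <- c("rt_calibration", "list")
  targets <- tibble::tibble(peptide_seq = c("AAK", "CCK", "EEK"),
                            irt = c(30, 1, 59.5))
  expect_warning(
    out <- assign_windows(targets, cal, schedule_config(window_min = 5),
                          gradient_length = 60),
    NA)
  expect_equal(out$window_start, c(27.5, 0, 57))
  expect_equal(out$window_end, c(32.5, 3.5, 60))
  expect_true(all(out$window_end - out$window_start <= 5 + 1e-12))

  outside <- tibble::tibble(peptide_seq = "ZZK", irt = 65)
  expect_warning(assign_windows(outside, cal, schedule_config(), 60),
                 "clipped")
})

test_that("collision energy follows the charge-specific linear equation", {
  co <- list(`2` = c(slope = 0.03, intercept = 2.9),
             `3` = c(slope = 0.05, intercept = 1.0))
  expect_equal(collision_energy(500, 2, co), 17.9)
  # charge without coefficients falls back to the highest defined charge
  expect_equal(collision_energy(500, 4, co), collision_energy(500, 3, co))
  expect_error(collision_energy(500, 2, list()),
               class = "srmforge_config_error")
  mz <- seq(400, 1000, 50)
  expect_true(all(diff(collision_energy(mz, 2, co)) >= 0))
})

test_that("the concurrency sweep counts overlapping windows with standards", {
  disjoint <- tibble::tibble(window_start = c(10, 30), window_end = c(15, 35),
                             n_transitions = c(5, 5))
  expect_equal(concurrency_profile(disjoint)$peak, 5)
  # identical windows plus a 39-transition standard backbone
  same <- tibble::tibble(window_start = c(20, 20), window_end = c(25, 25),
                         n_transitions = c(5, 5))
  expect_equal(concurrency_profile(same, n_standard_transitions = 39)$peak, 49)
  # abutting windows do not double-count under [start, end)
  abut <- tibble::tibble(window_start = c(10, 15), window_end = c(15, 20),
                         n_transitions = c(5, 7))
  expect_equal(concurrency_profile(abut)$peak, 7)
})

test_that("the sweep agrees with a dense-grid count on random schedules", {
  set.seed(601)
  for (i in 1:25) {
    w <- random_windows(sample(5:40, 1))
    s <- sample(0:39, 1)
    expect_equal(concurrency_profile(w, s)$peak, grid_concurrency(w, s))
  }
})

scheduling_fixture <- function(n_targets, transitions_each = 5, irt = NULL,
                               n_std = 13, std_transitions = 3) {
  targets <- tibble::tibble(
    protein_id = sprintf("P%03d", seq_len(n_targets)),
    peptide_seq = sprintf("TGT%03dK", seq_len(n_targets)),
    precursor_charge = 2L,
    precursor_mz = 500 + seq_len(n_targets),
    irt = if (is.null(irt)) seq(5, 95, length.out = n_targets) else irt
  )
  transitions <- targets[rep(seq_len(n_targets), each = transitions_each),
                         c("protein_id", "peptide_seq", "precursor_charge")]
  transitions$product_ion <- sprintf("y%d+", rep(seq_len(transitions_each) + 2,
                                                 n_targets))
  transitions$product_mz <- 600 + seq_len(nrow(transitions))
  transitions$mean_area <- 10
  transitions$intensity_rank <- rep(seq_len(transitions_each), n_targets)
  standards <- simulate_standards(1, n_standards = n_std,
                                  transitions_per_standard = std_transitions)
  list(targets = targets, transitions = transitions, standards = standards)
}

partitioned <- function(n_targets, capacity, irt = NULL, transitions_each = 5,
                        window_min = 5) {
  fx <- scheduling_fixture(n_targets, transitions_each, irt = irt)
  cal <- calibrate_rt(fx$standards)
  sch <- schedule_config(window_min = window_min,
                         max_concurrent_transitions = capacity)
  tg <- assign_windows(fx$targets, cal, sch, gradient_length = 60)
  tg$ce <- collision_energy(tg$precursor_mz, tg$precursor_charge,
                            sch$ce_coefficients)
  st <- srmforge:::prepare_standards(fx$standards, cal, sch, 60)
  partition_methods(tg, fx$transitions, st, sch)
}

test_that("everything fits in one method when capacity allows", {
  methods <- partitioned(10, capacity = 200)
  expect_length(methods, 1)
  expect_lte(methods[[1]]$peak_concurrency, 200)
})

test_that("fully-overlapping targets split per the closed-form method count", {
  # N identical-window targets of t transitions, s standards, capacity c:
  # methods = ceiling(N / floor((c - s) / t))
  N <- 12; t <- 5; s <- 39; c <- 60
  methods <- partitioned(N, capacity = c, irt = rep(50, N))
  expect_length(methods, ceiling(N / floor((c - s) / t)))
  for (m in methods) expect_lte(m$peak_concurrency, c)
})

test_that("an oversized single target is a capacity error naming it", {
  expect_error(partitioned(3, capacity = 43),  # 39 standards + 5 > 43
               "TGT", class = "srmforge_capacity_error")
})

test_that("methods conserve the transition multiset and pass the grid oracle", {
  set.seed(602)
  for (i in 1:5) {
    n <- sample(20:50, 1)
    cap <- sample(55:90, 1)
    irt <- runif(n, 0, 100)
    methods <- partitioned(n, capacity = cap, irt = irt)
    all_rows <- dplyr::bind_rows(lapply(methods, `[[`, "targets"))
    key <- paste(all_rows$peptide_seq, all_rows$product_ion)
    expect_equal(sort(key), unique(sort(key)))      # no duplicates
    expect_equal(length(key), n * 5)                # nothing lost
    for (m in methods) {
      expect_lte(grid_concurrency(m$target_peptides, nrow(m$standards)),
                 cap)
    }
  }
})

test_that("increasing capacity never increases the method count", {
  set.seed(603)
  irt <- runif(30, 0, 100)
  caps <- c(55, 70, 90, 120, 200)
  counts <- vapply(caps, function(cap) length(partitioned(30, cap, irt = irt)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})
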