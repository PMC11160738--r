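# Scheduled-SRM construction: iRT calibration, retention-time windows,
# collision energies, and capacity-limited partitioning of targets into
# instrument methods.

#' Fit a linear iRT-to-retention-time calibration
#'
#' Ordinary least squares of measured retention time on iRT over the
#' spiked standards. Because iRT is a system-independent retention index,
#' this single linear fit transfers scheduling information between LC
#' setups; the same operation, inverted, converts library retention times
#' to iRT.
#'
#' @param standards Tibble with `irt` and `measured_rt` (one row per
#'   standard peptide; extra columns ignored, duplicated names collapsed).
#' @return An `rt_calibration` with `slope` (min per iRT unit),
#'   `intercept` (min), `rmse` (min) and `n_standards`.
#' @export
calibrate_rt <- function(standards) {
  if (!all(c("irt", "measured_rt") %in% names(standards))) {
    abort_config("standards need `irt` and `measured_rt` columns")
  }
  st <- standards
  if ("name" %in% names(st)) st <- dplyr::distinct(st, .data$name, .keep_all = TRUE)
  st <- st[is.finite(st$irt) & is.finite(st$measured_rt), ]
  if (nrow(st) < 2L || length(unique(st$irt)) < 2L) {
    abort_data("RT calibration needs >= 2 standards with distinct iRT values")
  }
  fit <- lm(measured_rt ~ irt, data = st)
  res <- unname(fit$residuals)
  structure(list(slope = unname(coef(fit)[["irt"]]),
                 intercept = unname(coef(fit)[["(Intercept)"]]),
                 rmse = sqrt(mean(res^2)),
                 n_standards = nrow(st)),
            class = c("rt_calibration", "list"))
}

#' Convert between iRT and retention time
#'
#' @param cal An `rt_calibration`.
#' @param irt,rt Numeric vectors.
#' @return Predicted retention times (min) or iRT values.
#' @export
rt_from_irt <- function(cal, irt) cal$slope * irt + cal$intercept

#' @rdname rt_from_irt
#' @export
irt_from_rt <- function(cal, rt) (rt - cal$intercept) / cal$slope

#' @export
print.rt_calibration <- function(x, ...) {
  cat(sprintf("<rt_calibration> rt = %.4f * iRT + %.3f min (rmse %.3f min, n = %d)\n",
              x$slope, x$intercept, x$rmse, x$n_standards))
  invisible(x)
}

#' Assign scheduled retention-time windows
#'
#' Predicts each target's retention time from its iRT via the calibration
#' and centres a window of `window_min` minutes on it, clipped to the
#' gradient `[0, gradient_length]`. Targets whose predicted apex falls
#' outside the gradient are kept with a reduced-width clipped window and
#' reported in a warning.
#'
#' @param targets Tibble with an `irt` column.
#' @param cal An `rt_calibration`.
#' @param schedule A [schedule_config()].
#' @param gradient_length Gradient length in minutes (default 60).
#' @return `targets` with `predicted_rt`, `window_start`, `window_end`.
#' @export
assign_windows <- function(targets, cal, schedule = schedule_config(),
                           gradient_length = 60) {
  if (!"irt" %in% names(targets)) abort_config("targets need an `irt` column")
  if (anyNA(targets$irt)) abort_state("some targets have no iRT assigned")
  half <- schedule$window_min / 2
  out <- targets
  out$predicted_rt <- rt_from_irt(cal, out$irt)
  out$window_start <- pmax(0, out$predicted_rt - half)
  out$window_end <- pmin(gradient_length, out$predicted_rt + half)
  outside <- out$predicted_rt < 0 | out$predicted_rt > gradient_length
  if (any(outside)) {
    out$window_start[outside] <- pmax(0, pmin(out$window_start[outside], gradient_length))
    out$window_end[outside] <- pmax(0, pmin(out$window_end[outside], gradient_length))
    labels <- if ("peptide_seq" %in% names(out)) out$peptide_seq[outside] else which(outside)
    warn(sprintf("%d target(s) predicted outside the gradient; windows clipped: %s",
                 sum(outside), paste(head(labels, 5L), collapse = ", ")))
  }
  out
}

#' Peptide-specific collision energy
#'
#' Linear charge-dependent equation `CE = slope(z) * precursor m/z +
#' intercept(z)`, rounded to 0.1 eV. Charges without configured
#' coefficients fall back to the highest configured charge.
#'
#' @param precursor_mz Numeric vector of precursor m/z (Th).
#' @param charge Integer vector of precursor charges.
#' @param coefficients Named list mapping charge to `c(slope, intercept)`;
#'   see [default_ce_coefficients()].
#' @return Collision energies in eV.
#' @examples
#' collision_energy(500, 2, list(`2` = c(slope = 0.03, intercept = 2.9)))
#' @export
collision_energy <- function(precursor_mz, charge,
                             coefficients = default_ce_coefficients()) {
  if (!is.list(coefficients) || length(coefficients) == 0L) {
    abort_config("no collision-energy coefficients configured")
  }
  defined <- sort(as.integer(names(coefficients)))
  if (anyNA(defined)) abort_config("CE coefficient names must be integer charges")
  z <- rep_len(as.integer(charge), length(precursor_mz))
  z_used <- ifelse(z %in% defined, z, max(defined))
  ce <- vapply(seq_along(precursor_mz), function(i) {
    co <- coefficients[[as.character(z_used[i])]]
    unname(co[["slope"]]) * precursor_mz[i] + unname(co[["intercept"]])
  }, numeric(1))
  round(ce * 10) / 10
}

#' Concurrent-transition profile of a scheduled method
#'
#' Sweep-line count of simultaneously monitored transitions over the
#' scheduling windows, with the half-open convention `[start, end)` so
#' abutting windows do not double-count. Standards are monitored across
#' the whole gradient and contribute a constant.
#'
#' @param windows Tibble with `window_start`, `window_end` and
#'   `n_transitions` (one row per target).
#' @param n_standard_transitions Constant standard contribution
#'   (default 0).
#' @return List with `peak` (maximum concurrent transitions) and `at`
#'   (earliest time the maximum occurs, minutes).
#' @export
concurrency_profile <- function(windows, n_standard_transitions = 0L) {
  s <- as.integer(n_standard_transitions)
  if (nrow(windows) == 0L) return(list(peak = s, at = 0))
  ev <- rbind(
    data.frame(time = windows$window_start, delta = windows$n_transitions),
    data.frame(time = windows$window_end, delta = -windows$n_transitions)
  )
  # ends close before starts open at equal times ([start, end) convention)
  ev <- ev[order(ev$time, ev$delta), ]
  open <- cumsum(ev$delta)
  peak <- max(open)
  list(peak = peak + s, at = ev$time[which.max(open)])
}

prepare_standards <- function(standards, cal, schedule, gradient_length) {
  needed <- c("name", "irt", "precursor_mz", "precursor_charge",
              "product_mz", "product_ion")
  missing <- setdiff(needed, names(standards))
  if (length(missing)) {
    abort_config(sprintf("standards lack column(s): %s", paste(missing, collapse = ", ")))
  }
  st <- standards
  st$predicted_rt <- rt_from_irt(cal, st$irt)
  st$window_start <- 0
  st$window_end <- gradient_length
  st$ce <- collision_energy(st$precursor_mz, st$precursor_charge,
                            schedule$ce_coefficients)
  st
}

#' Partition scheduled targets into capacity-feasible methods
#'
#' Greedy first-fit: targets are taken in order of predicted retention time
#' (ties broken lexicographically by peptide sequence) and each is placed
#' into the first method where adding its transitions keeps the peak
#' concurrency, including the standards monitored over the whole gradient
#' in every method, within `max_concurrent_transitions`; a new method is
#' opened when none fits. Greedy placement is deterministic and
#' near-optimal for overlapping-interval instances but not guaranteed
#' minimal.
#'
#' @param targets Peptide-level tibble with windows assigned
#'   ([assign_windows()]) and the peptide key columns.
#' @param transitions Per-transition rows of the assay (from
#'   `srm_assay$transitions`).
#' @param standards Standards prepared with windows/CE (transition-level;
#'   internally given full-gradient windows).
#' @param schedule A [schedule_config()].
#' @return List of `scheduled_method` objects, each with per-transition
#'   `targets` rows, `standards` rows, and `peak_concurrency`.
#' @export
partition_methods <- function(targets, transitions, standards,
                              schedule = schedule_config()) {
  cap <- schedule$max_concurrent_transitions
  s <- nrow(standards)
  if (s >= cap) {
    abort_capacity(sprintf(
      "standards alone (%d transitions) reach the capacity of %d concurrent transitions",
      s, cap))
  }
  n_tr <- transitions |>
    dplyr::count(dplyr::across(dplyr::all_of(peptide_key_columns())),
                 name = "n_transitions")
  tg <- targets |>
    dplyr::left_join(n_tr, by = peptide_key_columns()) |>
    dplyr::arrange(.data$predicted_rt, .data$peptide_seq)
  if (anyNA(tg$n_transitions)) abort_state("some targets have no transitions")
  too_big <- tg$n_transitions + s > cap
  if (any(too_big)) {
    abort_capacity(sprintf(
      "target %s (%d transitions) cannot fit with %d standard transitions under capacity %d",
      tg$peptide_seq[too_big][1], tg$n_transitions[too_big][1], s, cap))
  }

  methods <- list()  # each: list of row indices into tg
  for (i in seq_len(nrow(tg))) {
    placed <- FALSE
    for (m in seq_along(methods)) {
      idx <- c(methods[[m]], i)
      prof <- concurrency_profile(tg[idx, ], n_standard_transitions = s)
      if (prof$peak <= cap) {
        methods[[m]] <- idx
        placed <- TRUE
        break
      }
    }
    if (!placed) methods[[length(methods) + 1L]] <- i
  }

  lapply(seq_along(methods), function(m) {
    mt <- tg[methods[[m]], ]
    rows <- transitions |>
      dplyr::inner_join(mt[, c(peptide_key_columns(), "precursor_mz", "irt",
                               "predicted_rt", "window_start", "window_end", "ce")],
                        by = peptide_key_columns()) |>
      dplyr::arrange(.data$predicted_rt, .data$peptide_seq, .data$intensity_rank)
    prof <- concurrency_profile(mt, n_standard_transitions = s)
    structure(list(index = m, targets = rows, target_peptides = mt,
                   standards = standards, peak_concurrency = prof$peak,
                   peak_time = prof$at),
              class = c("scheduled_method", "list"))
  })
}

#' Summarize a set of scheduled methods
#'
#' @param methods List of `scheduled_method` objects.
#' @return Tibble: method index, target/transition counts, peak
#'   concurrency, retention-time span.
#' @export
schedule_report <- function(methods) {
  dplyr::bind_rows(lapply(methods, function(m) {
    tibble::tibble(
      method = m$index,
      n_targets = nrow(m$target_peptides),
      n_transitions = nrow(m$targets),
      n_standard_transitions = nrow(m$standards),
      peak_concurrency = m$peak_concurrency,
      rt_start = min(m$target_peptides$window_start),
      rt_end = max(m$target_peptides$window_end)
    )
  }))
}

#' @export
print.scheduled_method <- function(x, ...) {
  cat(sprintf("<scheduled_method %d> %d targets, %d transitions (+%d standards), peak concurrency %d\n",
              x$index, nrow(x$target_peptides), nrow(x$targets),
              nrow(x$standards), x$peak_concurrency))
  invisible(x)
}
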