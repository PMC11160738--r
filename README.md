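# srmforge

Develop scheduled selected-reaction-monitoring (SRM) assays directly from
data-independent-acquisition (DIA) chromatogram libraries.

## What problem it solves

Targeted proteomics on a triple quadrupole measures predefined
precursor→product ion pairs (transitions), and a good assay hinges on
choosing, per protein, proxy peptides that respond well *in the sample
matrix* and transitions free of co-elution interference — information that
replicate DIA measurements of that same matrix already contain. `srmforge`
turns long-format, transition-level DIA quantification reports (one row
per protein / peptide / transition / replicate, with integrated peak area
and apex retention time) into instrument-ready scheduled SRM methods,
for proteomics researchers building targeted panels from existing DIA
data.

The pipeline:

1. **Interference QC** — within each (peptide, replicate), a transition is
   flagged when its peak apex deviates from the median apex of the
   peptide's transitions by more than a tolerance (default 0.1 min);
   a transition flagged in any replicate is not *clean*.
2. **Stability scoring** — per peptide, the top clean transitions by mean
   area (default 5, one fixed set across replicates) are summed within
   each replicate, optionally after total-ion-current normalization, and
   scored as `%CV = 100·sd/mean` (sample sd across replicates).
3. **Selection** — peptides qualify with ≥ `min_clean_transitions` clean
   transitions (default 3) and %CV ≤ threshold (default 20). Per protein:
   when more qualify than will be kept, short-list the 5 most intense,
   keep the 2 with lowest %CV, and take each kept peptide's 5 most
   intense clean transitions. All counts are configurable; ties break
   lexicographically so selection is deterministic.
4. **Scheduling** — a linear iRT calibration fitted on spiked
   retention-time standards (OLS of measured RT on iRT) converts library
   RTs to iRT and predicts RTs on the target system; each target gets a
   5-min window around its predicted RT and a charge-specific linear
   collision energy; a sweep-line concurrency count and greedy first-fit
   packing split the targets into methods that never exceed the
   concurrent-transition capacity (default 200), each method carrying the
   full standard set.

A seeded synthetic-data generator with planted ground truth (interfered
transitions, unstable peptides, known noise levels and RT model) makes
every stage testable end to end without instrument data.

## Worked example

Build the chronic-pain panel from the bundled synthetic preset — 87
candidate proteins, of which 85 are detected and 67 were planted to pass a
"≥ 2 peptides with ≥ 5 clean transitions and stable %CV" filter — then
schedule it on a second chromatographic system:

```r
library(srmforge)

sim   <- generate_report(preset_pain_panel(seed = 7))
build <- build_assay(sim$report, pain_panel_selection_config(),
                     dia_standards = simulate_standards(7))
build
#> <assay_build>
#>   detected: 231 peptides / 85 proteins
#>   qualifying: 207 peptides / 73 proteins
#>   selected: 134 peptides / 67 proteins; 670 transitions (18 proteins dropped)
```

Each of the 67 passing proteins contributes its 2 best peptides
(134 targets), each carrying its 5 most intense interference-free
transitions (670 transitions); the 18 planted-fail proteins appear in
`build$assay$dropped` with their failure reason. Scheduling against
standards measured on the target instrument:

```r
srm_std <- simulate_standards(8, rt_slope = 0.62, rt_intercept = 2.1)
sched   <- schedule_assay(build, srm_std, schedule_config(), gradient_length = 60)
sched
#> <rt_calibration> rt = 0.6197 * iRT + 2.093 min (rmse 0.046 min, n = 13)
#>   1 method(s); capacity 200 concurrent transitions; 5.0-min windows
#>  method n_targets n_transitions n_standard_transitions peak_concurrency
#>       1       134           670                     39              114
write_transition_list(sched$methods, "instrument", "methods/")
```

The calibration line is recovered from the 13 synthetic standards, the
whole assay fits one method (peak concurrency 114 of 200), and the export
writes one CSV per method in either a generic instrument dialect or a
Skyline-style transition list.

The same workflow runs from the shell via the bundled wrapper
(`system.file("cli", "srmforge", package = "srmforge")`) with subcommands
`simulate`, `build-assay`, `compare` and `schedule`, a YAML config
(`inst/extdata/config.yaml`) and per-key flag overrides.

See `vignettes/assay-development.Rmd` for the model details, the
generator's noise calibration, and design decisions.

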