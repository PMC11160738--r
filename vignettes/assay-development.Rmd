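---
title: "From DIA chromatogram libraries to scheduled SRM methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From DIA chromatogram libraries to scheduled SRM methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srmforge)
library(dplyr)
```

## The problem

Building a selected reaction monitoring (SRM) assay traditionally requires
iterative rounds of candidate selection and instrument refinement: for each
protein of interest one must choose proxy peptides that respond well in the
sample matrix, pick fragment-ion transitions free of interference, and
schedule everything within the duty cycle of a triple quadrupole.
Data-independent acquisition (DIA) measured on the same matrix already
contains that information — per-transition peak areas and apex retention
times across replicate injections — so an SRM assay can be mined directly
from replicate DIA quantification reports instead of re-measured.

`srmforge` implements that workflow end to end: interference flagging from
transition apex co-elution, peptide stability scoring as the percent
coefficient of variation (%CV) of summed transition areas across
replicates, ranked per-protein selection of proxy peptides and transitions,
indexed retention time (iRT) calibration, and capacity-limited partitioning
of scheduled targets into instrument methods.

## The model, stage by stage

### Interference from apex co-elution

All transitions of a truly measured peptide co-elute: their chromatographic
peak apexes coincide. Within each (peptide, replicate) group the reference
apex is the **median** apex retention time of the peptide's transitions; a
transition is flagged as interfered when its apex deviates from the
reference by more than `apex_tolerance_min` (default 0.1 min). The median
is robust so long as interfered transitions remain a minority of the group.
Degenerate groups are handled explicitly: with a single transition
co-elution is undefined and nothing is flagged; with two transitions the
median is their midpoint, so both are flagged when they disagree by more
than twice the tolerance — no arbitration between the pair is possible.

Flags are aggregated across replicates with a strict AND: a transition
interfered in *any* replicate is not `clean`. For a targeted assay that
will run on many samples, a transition that misbehaved in any of the
library replicates is not worth carrying.

The 0.1-min default tolerance is a deliberate formalization choice: it is
of the order of a chromatographic peak width at base on a 60-min gradient,
and the flagging rule is invariant under global retention-time shifts
(only relative apexes matter), monotone in the tolerance, and exactly
testable against planted truth.

### Replicate stability: %CV of summed areas

Replicate areas may first be total-ion-current (TIC) normalized: each area
is multiplied by (mean of replicate totals)/(own replicate total), after
which all replicates share the same total. This removes run-to-run loading
differences. Note the normalization couples peptides through the totals:
rescaling one replicate changes everyone's normalized areas by a factor
common to all replicates (ratios and %CV are unaffected).

For each peptide, clean transitions are ranked by their **mean** area
across replicates — the most stable single summary of a triplicate — and
the top `n_transitions_per_peptide` (default 5) form a fixed
quantification set. That same set is summed within every replicate (never
re-ranked per replicate), and the peptide's stability score is

$$\%CV = 100 \cdot \frac{s}{\bar{x}}$$

with $s$ the sample (n−1) standard deviation of the per-replicate sums.
Peptides observed in fewer than two replicates are non-quantifiable.

### Selection rules

Peptides qualify when they have at least `min_clean_transitions`
interference-free co-eluting transitions (default 3) and %CV within
`cv_threshold_pct` (default 20, inclusive comparison; a strict `<` is
available since both conventions occur in practice). Then, per protein:

1. when more peptides qualify than will be kept, only the
   `top_k_peptides_by_intensity` (default 5) most intense — by mean summed
   area — are considered;
2. from that short-list the `n_peptides_per_protein` (default 2) peptides
   with the lowest %CV are kept;
3. each kept peptide contributes its `n_transitions_per_peptide`
   (default 5) most intense clean transitions, in rank order.

Proteins with fewer than `require_min_peptides_per_protein` qualifying
peptides are dropped and logged with the dominant failure mode of their
peptides. All ties break lexicographically (peptide sequence, then product
m/z), making the selection a pure function of its inputs; the test suite
checks it against an independent exhaustive-enumeration oracle on
thousands of random instances.

Two boundary readings were genuinely open and are resolved as follows.
The intensity short-list of rule (1) is applied whenever more candidates
exist than will be kept — the only reading under which rule (2) is always
well defined. And when the same peptide sequence qualifies at several
precursor charge states, only the charge with the larger mean summed area
enters selection: peptides, not precursors, are the selection unit.

### iRT calibration and scheduling

Retention-time standards spiked into every sample anchor a linear map
between the dimensionless iRT scale and measured retention time. The
calibration is an ordinary least-squares fit (`measured_rt ~ irt`); fitted
on the library runs and inverted, it converts each selected peptide's mean
apex retention time into an iRT; fitted on the target instrument's runs,
it projects that iRT into a predicted retention time there. Both
directions use the same `calibrate_rt()` operation.

Each target is monitored for `window_min` minutes (default 5) centred on
its predicted retention time, clipped to the gradient; collision energy
follows the linear charge-specific equation
$CE = \text{slope}(z)\cdot m/z + \text{intercept}(z)$, rounded to 0.1 eV,
with coefficients shipped as editable configuration (the defaults are
generic triple-quadrupole values; instruments differ, so they should be
replaced by the vendor's optimized equation). Charges without coefficients
fall back to the highest configured charge.

The number of concurrently monitored transitions is computed by a
sweep-line over window endpoints with the half-open convention
$[start, end)$, so abutting windows do not double-count. Targets are
packed into methods by greedy first-fit in retention-time order: each
target goes into the first method where adding it keeps peak concurrency —
including the standards, which are conservatively modeled as monitored
over the entire gradient in every method — within
`max_concurrent_transitions` (default 200). Greedy first-fit is
deterministic and near-optimal on overlapping-interval instances;
minimality of the method count is *not* claimed, but every emitted method
is verified feasible by an independent dense-grid count, the transition
multiset is conserved exactly, and the method count is non-increasing in
the capacity.

## The synthetic-data generator

Every stage is testable without instrument data through a seeded generator
that emulates a replicate DIA chromatogram library: proteins × peptides ×
transitions × replicates, lognormal peptide abundances, a geometric decay
(ratio 0.7) of transition intensity over rank so that "top 5 most intense"
is well separated and free of fragile ties, replicate noise, and a linear
iRT→RT model with jitter. Planted defects carry ground-truth labels:
interfered transitions get their apex displaced by
`interference_shift_min` (default 0.5 min, five times the default
tolerance), unstable peptides get inflated replicate spread.

Three numerical choices deserve explanation:

* **Noise placement.** Replicate noise multiplies all transitions of a
  peptide in a replicate jointly (injection/loading variation), with only
  a small independent per-transition component (default CV 0.02). If
  per-transition noise dominated, summing five transitions would average
  it away and no planted noise level could be recovered from peptide-level
  %CV.
* **`noise_cv` is the target *observed* %CV.** With $n$ replicates the
  sample CV is median-biased low by the factor
  $\sqrt{\mathrm{med}(\chi^2_{n-1})/(n-1)}$ (≈ 0.83 at $n = 3$), so the
  generator inflates the underlying lognormal σ by the reciprocal. A
  planted `noise_cv = 0.10` therefore yields a downstream median %CV of
  10, which is what a generator of planted truth should mean by the
  parameter.
* **Planted instability in presets is deterministic.** In free simulation,
  unstable peptides receive extra sampled lognormal noise
  (`unstable_extra_cv`); with three replicates, however, a sampled
  high-CV peptide can occasionally realize a small sample CV and flip its
  planted label. Plan-driven presets therefore use a fixed log-spaced
  replicate fold-spread (CV ≈ 120%) so that pass/fail labels are
  unambiguous at every seed.

What the generator does **not** emulate: raw chromatogram peak shapes
(areas are emitted post-integration, matching where the pipeline's
contract starts), missing transitions within replicates, correlated
interference across co-eluting peptides, retention-time drift within a
run, detector saturation, or a realistic relationship between peptide
sequence and either m/z or response. Passing tests demonstrate the
*logic* of the workflow under the stated noise model, not performance on
real chromatographic data.

### The chronic-pain panel preset

`preset_pain_panel()` encodes a re-query scenario used as the package's
worked example: 87 candidate proteins, 2 of which are never detected; of
the 85 detected, 67 carry 2–4 well-behaved peptides with 6–8 clean
transitions each, and 18 are constructed to fail exactly one criterion,
cycling deterministically over too-few-peptides (6), too-few-clean-
transitions (6, peptides with only 4 transitions against a 5-transition
requirement) and %CV-above-threshold (6, planted-unstable peptides).
Replicate noise is set to an observed %CV near 3 — the precision regime of
a well-behaved scheduled triple-quadrupole assay. Running the matching
selection (`pain_panel_selection_config()`: ≥ 5 clean transitions, ≥ 2
qualifying peptides per protein, 2 peptides kept, 5 transitions each)
selects exactly the 67 planted-pass proteins:

```{r preset}
sim <- generate_report(preset_pain_panel(seed = 7))
build <- build_assay(sim$report, pain_panel_selection_config())
build
count(build$assay$dropped, reason)
```

134 target peptides (2 per passing protein) carrying 670 transitions.
The preset quantifies raw rather than TIC-normalized areas: it plants no
shared loading variation, so there is nothing for the normalization to
remove, and rescaling replicates against totals that contain the
planted-unstable signal would couple otherwise independent peptides and
blur the planted labels.

## Scheduling the example assay

```{r schedule}
dia_std <- simulate_standards(7)                     # standards in the library runs
build <- build_assay(sim$report, pain_panel_selection_config(),
                     dia_standards = dia_std)
srm_std <- simulate_standards(8, rt_slope = 0.62, rt_intercept = 2.1)
sched <- schedule_assay(build, srm_std, schedule_config(), gradient_length = 60)
sched$report
```

With 5-min windows and a 200-transition capacity this assay fits a single
method; tightening the capacity splits it into several, each still
carrying the full 13-standard backbone.

## Problem sizes and verification

The shipped test suite verifies, among others: exact recovery of planted
interference (apex shift twice the tolerance, jitter one tenth of it) over
100 seeds; recovery of a planted 10% replicate noise level by the median
%CV over 500 simulated peptides within 15% relative; selection equal to an
exhaustive enumeration oracle on 1000 random instances of up to 10
proteins × 8 peptides; the sweep-line concurrency equal to a dense-grid
count on 200 random schedules; and feasibility/conservation of every
partitioned method. These sizes were chosen as the smallest at which the
statistical checks are sharp; all are pure functions of fixed seeds.

## Known limitations

* Interference detection re-specifies an external tool's behaviour as a
  median-apex deviation test; it sees only apex positions, not peak
  shapes, and cannot detect an interference that shifts *all* transitions
  coherently.
* The %CV filter with three replicates is a noisy estimator; the
  threshold is a screening device, not a calibrated error rate.
* Greedy method partitioning is not optimal, and no attempt is made to
  re-select peptides so as to flatten concurrency across the gradient.
* Peptide uniqueness against a proteome (proteotypicity), response
  prediction, and calibration curves for quantification limits are out of
  scope; modified sequences are opaque identifiers and masses are never
  recomputed.
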