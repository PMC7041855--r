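---
title: "panelcnv: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{panelcnv: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelcnv)
```

# The problem

Multiplex amplicon panels sequence a few thousand PCR targets per patient,
with many patients per run. Read depth per amplicon is proportional to the
underlying copy number, but buried under amplicon-specific amplification
efficiency (several-fold spread), library size, primer-pool loading and
multiplicative noise. `panelcnv` removes those layers, standardizes each
patient, and segments significant amplicons into deletion/duplication
calls. The other patients of the run act as the reference cohort, which is
what makes the method attractive in diagnostics: no matched-control
sequencing is needed, but a control mode exists when CNV-free samples are
available.

# Normalization chain

Counts below `min_raw_reads` (default 20, the conventional floor under
which amplicon dropout is indistinguishable from a homozygous loss) are
masked, not zeroed; an amplicon masked in a strict majority of samples is
dropped panel-wide so cross-sample medians remain meaningful. The majority
rule (rather than "at least half") keeps the 2-sample edge case sane: one
masked cell must not erase the amplicon for the other sample.

The remaining steps are ratios, so the *units* of the counts never matter:

1. *pool shares*: count / (sample total within the same primer pool).
   Depths are only comparable within a multiplex reaction; with a
   single-pool design this is plain library-size normalization.
2. *reference scaling*: each sample is divided by the mean over a
   reference set — the `reference_fraction` (default 0.10, at least one)
   of amplicons with the lowest coefficient of variation across samples,
   computed on complete rows only. The fraction is a compromise: enough
   amplicons to average out their own noise (239 on a 2,394-amplicon
   panel), few enough to stay in the stable tail. Users can force or
   exclude amplicons.
3. *median ratio*: each amplicon is divided by its cross-sample median.
   The median is taken over **all** samples including the one being
   normalized (deterministic and symmetric; from five samples on, the
   difference from self-exclusion is at most one rank — the
   `include_self = FALSE` variant is available). With an even count the
   median is the mean of the central pair. In control mode the denominator
   uses the control samples only, and a single control degenerates to
   division by that control.

The resulting NRC is 1 at two copies, 0.5 at a heterozygous deletion, 1.5
at a duplication; on a noiseless no-CNV run the chain returns exactly 1,
which the test suite asserts at 1e-9. GC-content and amplicon-length
corrections are deliberately absent: the synthetic generator does not
simulate those biases, so chain and generator are internally consistent,
and real-data users should treat systematically unstable amplicons with
the exclusion list instead.

# Detection

Per patient, `z = (NRC − μ_p)/σ_p` with the mean and **population** SD
over all the patient's non-missing amplicons, genome-wide. Population SD
makes the standardization identity (mean 0, SD 1) exact and testable; CNV
amplicons are *not* excluded from the moments, so a very large event
inflates σ_p and dampens its own z — an accepted property of the method,
and the reason the built-in adaptivity ("thresholds adapt to the
patient's variability") needs no extra mechanism: the z cut is fixed at
`qnorm(1 − alpha)` (α = 0.01 one-tailed, threshold ≈ 2.326) and σ_p
supplies the adaptation. A boundary p exactly equal to α is significant.

Consequence worth knowing: an event spanning a fraction *q* of the panel
has, at best, |z| = sqrt((1−q)/q) on noiseless data, so events above
roughly 15% of the panel cannot reach the 0.01 threshold no matter how
clean the data. Panels should dwarf their largest expected event; the test
fixtures respect the same constraint.

Runs of at least `min_amplicons` (default 3) successive same-direction
significant amplicons on one chromosome become calls. "Successive" means
adjacent in design order (chromosome, start; ties broken by end then id):
no base-pair distance is required, and masked amplicons are skipped
transparently — they neither break a run nor count toward its length.

## Two-stage ratio

When several patients of a run share an event, the median at those
amplicons is biased and non-carriers can show mirror-image artifacts.
Stage 1 runs the chain with no exclusions; every amplicon inside a
sample's calls (merged gaps included) is then removed from *that sample's*
contribution to the denominators; the median ratio is recomputed and
detection repeated. Exactly two stages, no iteration to convergence — the
second pass already uses denominators from event-free samples. With
controls defined the denominators never contained patient data, so stage 2
is skipped. With no stage-1 calls the exclusion sets are empty and both
stages coincide.

## Merging

A single false-negative amplicon between two same-direction calls on a
chromosome is re-tested at the relaxed `alpha_relax` (0.05) in the call's
direction; if significant, the calls merge and the gap amplicon is
annotated `MERGED_GAP` (it keeps its neutral display state and does not
count as "correctly detected" in sensitivity bookkeeping, but does count
toward call length). Optionally, `max_merge_distance` merges
same-direction calls whose genomic gap is within a base-pair budget. Both
rules run to a fixed point, which terminates in at most one merge per
original call. The relaxation applies only *between* two calls, never as
an extension at a call's ends. Opposite directions never merge.

# Diagnostic tracks

CUSUM accumulates deviations beyond one SD around the patient mean, per
chromosome, restarting at zero:
S⁺ₙ = max(0, S⁺ₙ₋₁ + xₙ − (x̄+σ)), S⁻ₙ = min(0, S⁻ₙ₋₁ + xₙ − (x̄−σ)),
with x̄, σ the same genome-wide moments as the z-scores. A sustained
negative S⁻ excursion marks a candidate deletion, a positive S⁺ a
duplication — that is the mapping the recurrences imply (an NRC
persistently below x̄−σ drives S⁻ down), and the one implemented, even
though it is easy to state backwards in prose. CUSUM is a visual/numeric
diagnostic only; it never feeds the caller, and it locates events, not
breakpoints.

The Loess track is `stats::loess` — degree 1, tricube weights, Gaussian
family, single pass with no robustness iterations, exact ("direct")
surface — per chromosome, with span = `bandwidth` (default 0.25) as the
fraction of points per local window. The span is clamped from below so
each window holds at least three points; chromosomes with fewer than three
points omit the track with a warning. With bandwidth 1 on linear data the
fit reproduces ordinary least squares to machine precision, a property the
suite tests.

# Synthetic data: what it emulates, and not

`simulate_run` draws counts as
`round(library_size_j × efficiency_i × lognormal_noise)`:

* per-sample mean depth uniform in 500–2,000 reads — typical loading
  spread of a multiplexed benchtop run;
* per-amplicon efficiency log-normal with log-SD 0.5, shared across
  samples — amplicon efficiencies in multiplex PCR commonly span an order
  of magnitude; the value is fixed once, and since the chain is
  ratio-based its exact size is immaterial to the results;
* per-cell multiplicative noise with CV 0.05 (default), the level at which
  clean germline events are comfortably but not trivially detected;
  optional Poisson sampling on top.

The default design (`sim_design()`) is a 2,394-amplicon, 89-gene,
23-chromosome, two-pool panel containing one gene each of 98 (on chrX),
80, 58, 25, 10, 7 and 4 amplicons — the event sizes of the validation
experiments — plus filler genes of 25–26 amplicons. Events are injected
with `apply_cnv` via the cell-fraction mixture
`SRC = RRC·((1−f) + (c/2)·f)`, rounded half-up (counts are integers; at
these depths the rounding convention is irrelevant). Inside a diluted
deletion the expected NRC is 1 − f/2.

The generator does **not** simulate GC bias, pool-loading drift, FFPE
artifacts, batch effects or allele fractions. A green synthetic test
therefore establishes the statistical machinery — normalization algebra,
standardization, segmentation, merging, dilution response — not robustness
to platform-specific systematic error.

# Numerical and degenerate-input choices

* Zero variance in a sample (all NRC equal) is a hard error, not a silent
  zero-division: it only occurs on degenerate input.
* Cells whose median denominator pool is empty or zero are masked.
* A fully missing (sample, pool) pair is a hard error naming both.
* Reference selection requires at least two samples and one complete row;
  forced references missing in any sample are an error rather than a
  silent drop.
* Coordinates are 1-based inclusive internally; BED input is converted on
  read (`start + 1`), VCF output is 1-based as the format requires.

# Validation experiments

Three cohort-scale experiments ship with the package (and drive
`scripts/acceptance.R`): a dilution experiment (80-amplicon gene deleted
at fraction 0.60 in a 16-sample run — how many amplicons reach DEL), a
null-cohort specificity floor (456 samples, no CNVs, fraction of a
10-amplicon gene's cells free of calls), and a germline benchmark (22
events of 4–98 amplicons, 461 in total, injected across 11 runs at
germline ratios — amplicon-level sensitivity and events recovered). They
run in seconds to minutes because every step is vectorized matrix algebra.

# Known limitations

* Breakpoints are amplicon-resolution only; copy number is reported as
  direction (DEL/DUP) plus mean NRC, not an integer estimate.
* Events spanning a large fraction of the panel suppress their own z
  (see above); the CUSUM track is the intended safety net.
* The cross-sample median assumes most samples are normal at any locus;
  recurrent events in more than half the run require control mode.
* No GC/length correction; systematic per-amplicon artifacts should be
  excluded explicitly.
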