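---
title: "Minimal common amplification regions, qPCR copy calling, and outcome association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal common amplification regions, qPCR copy calling, and outcome association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcramp)
options(mcramp.log_level = "quiet")
```

## The analysis model

`mcramp` operates on four kinds of input: segmented copy-number profiles
(one mean log2 ratio per sample, chromosome and interval), gene annotation
(BED or GFF), long-format genomic qPCR cycle-threshold tables, and a
clinical table (Breslow thickness in mm plus metastasis-free and overall
follow-up). All genomic coordinates are 1-based and inclusive internally,
so an interval's length is `end - start + 1`; BED input is converted on
read. Chromosome names are normalized to `chrN`.

### Minimal common regions of amplification

Each sample's amplified intervals (segments whose fold change `2^log2`
exceeds the amplification threshold; gains can be included by flag) are
swept into a **support profile**: a step function giving, at every base,
the number of *distinct* samples amplified there. Intervals of one sample
are merged first, so no sample is counted twice at a position.

A **minimal common region** is extracted from every maximal run of depth
≥ `min_support` as the *locally deepest plateau*. The logic is that a
deeper sub-region is shared by more samples, and the region shared by a
set of samples is exactly the intersection of their amplicons — the
minimal common overlap of that set. Two numerical choices are worth
spelling out:

* *Plateau merging.* Adjacent equal-depth steps are merged into one
  plateau only when their supporting sample sets are identical. Equal
  depth with different supporters (one amplicon ends where another begins)
  yields two hotspots, each the intersection of its own supporter set.
  This keeps the invariants exact: a hotspot's support equals the size of
  its supporter set, and its interval is contained in every supporter's
  amplicon.
* *Length filter.* The ≤ `max_length` constraint (default 2.5 Mb) applies
  to the final hotspot, not to the contributing amplicons: a focal core
  shared by many samples still qualifies even if individual amplicons are
  broad.

Defaults (`min_support = 3`, `max_length = 2.5e6`) encode the recurrence
rule used for melanoma amplification hotspots. The property suite checks
the sweep-line implementation against a brute-force per-base oracle on
random toy cohorts (10 samples, 100 kb chromosomes, 100 cohorts), and the
invariants above are asserted directly.

Genes are attached by ≥ 1 bp overlap, with a deduplicated cohort-level
unique gene count. Hotspots are ranked against a clinical covariate by
Mann–Whitney contrasts (GAIN vs DIPLOID and AMPLIFICATION vs DIPLOID);
the exact null distribution is used when both groups have ≤ 8
observations and no ties, otherwise the normal approximation with tie
correction. Fully tied data return p = 1, and an empty contrast group is
flagged not-computable rather than raising an error. Contrasts are
two-sided by default, as sidedness is an analysis choice we do not impose.

### Efficiency-corrected qPCR quantification

Per-assay PCR efficiency is estimated from a calibrator dilution series by
least squares of mean Ct on log10(dilution): `E = 10^(-1/slope)`. A
perfect doubling assay has slope −3.3219 and E = 2; fits with E in
(2, 2.1] are flagged `super_efficient` but kept (plate-to-plate noise can
push an efficient assay slightly past 2), while E > 2.1 or a non-negative
slope is rejected. At least three distinct dilution levels are required.

The fold change of sample *s* over the diploid calibrator, normalized to a
reference gene *r* (default *LAMA1*, chosen in the original assay design
for its copy-number stability), is the Pfaffl / E^ΔCt ratio

$$\mathrm{ratio} = \frac{E_t^{\,Ct_{cal,t}-Ct_{s,t}}}{E_r^{\,Ct_{cal,r}-Ct_{s,r}}},$$

and `ddct_ratio()` is the same expression with both efficiencies fixed at
2 (asserted identical in the tests). Replicates aggregate as the mean of
internal replicates within each independent experiment, then the mean of
experiment means, matching a two-experiments × three-replicates design;
the reported SD is across experiment means and wells with within-run SD
above `qc_cutoff` (default 0.5 cycles) are flagged, not dropped. Because
it is not dictated by the assay design, the package defaults to one ratio
computed from the aggregated Cts, with `combine = "mean_of_ratios"`
(per-experiment ratios averaged) available as a sensitivity option; the
two coincide exactly on noise-free data.

Fold changes are cut into five states at 0.5 / 0.75 / 1.25 / 1.75. The
published wording leaves the boundary points ambiguous ("between 1.25 and
1.75", "above 1.75"); we assign exact boundary values to the non-diploid
state — deletions and gain include their outer bound, amplification is
strictly > 1.75 — which matches the wording and is measure-zero in
practice. The classification partitions (0, ∞) with no gaps and is
monotone in the ratio (property-tested on a dense grid including the
boundaries). Segment log2 ratios are classified by the same cut points
applied to `2^log2`, with independently configurable thresholds, since the
array-side calling convention of an upstream segmentation pipeline need
not equal the qPCR convention.

### Concordance and outcome

Cross-platform agreement is summarized two ways: the count of samples
whose qPCR log2 fold change and aCGH mean log2 ratio share a sign (an
`epsilon` dead zone around zero is available; the default 0 is the strict
sign rule, and zero only matches zero), and Pearson correlation with the
two-sided t test on n − 2 df. Copy-number vs expression uses Spearman's
rank correlation (Pearson on midranks).

Survival between two copy-state groups (default AMPLIFICATION vs DIPLOID,
other states excluded) is compared by Kaplan–Meier curves and the log-rank
test (`survival::survdiff`, hypergeometric variance with ties). The hazard
ratio is the Mantel–Haenszel estimate `(O1/E1)/(O2/E2)` with CI
`exp(ln HR ± 1.96·√(1/E1+1/E2))`; this matches the output of common
commercial survival software, which is the convention such cohort studies
typically report. A Cox estimate is available (`method = "cox"`) as a
sensitivity option. If a group has zero expected events the HR is flagged
not-computable while the log-rank statistic is still returned.

## The synthetic cohort generator

The generator exists so that every stage — io, calling, MCR detection,
association, survival — can be exercised against known truth. Its defaults
are fixed once to the study conditions the pipeline targets:

* **Cohort scale**: 31 genomes (discovery scale) on a chr1-sized
  chromosome; the validation-scale runs in `scripts/acceptance.R` use 64
  genomes with the published group structure (32 amplified, 20 gained, 12
  diploid).
* **Planted hotspot**: chr1:156826196–157106439 (the 1q23.1/*NTRK1*
  locus), amplified fraction 0.16 (the reported cohort frequency), gained
  fraction 0.10 (a plausible mid value; no frequency is published for the
  duplication group).
* **Passenger burden**: Poisson 5.7 amplicons per genome with log-normal
  lengths of mean 0.47 Mb (`sdlog` 0.8 — only the mean is published);
  passengers avoid planted loci so truth is unambiguous.
* **Probe spacing**: 50 kb, the genome-wide scale of a 60K CGH array; all
  simulated breakpoints snap to this grid.
* **Thickness**: log-normal, medians 2.3 / 3.0 / 4.7 mm for diploid /
  gained / amplified (the printed group medians), `sdlog` 0.35 chosen to
  give ranges of the printed order.
* **Survival**: exponential event times, hazard
  `baseline_rate × hr_amp^(amplified)`, administrative censoring at 120
  months. Defaults put amplified samples at higher hazard with
  `hr_amp = 1/0.30` (MFS) and `1/0.54` (OS), i.e. the published
  diploid-vs-amplified hazard ratios; baseline rates (0.008 and 0.005
  events/month) give realistic multi-year event curves.

Carrier allocation uses exact quotas (`round(fraction × n)`) so small
cohorts behave deterministically; Bernoulli sampling is a flag for power
studies. Planted log2 ratios are drawn uniformly inside state bands kept a
`guard_margin` (0.05 fold-change units) away from every classification cut
point, which guarantees caller–truth agreement in noise-free tests. Each
carrier's segment extends the planted core by 0–6 probe steps per side
with the first amplified carrier pinned at zero extension — mirroring the
fact that a published MCR boundary is by definition some sample's
breakpoint — so the cohort intersection recovers the planted interval
exactly, and the recovery tests can demand boundaries within one probe
spacing. For non-carrier samples the truth fold change at a planted locus
is the (diploid-band) ratio carried by the covering background segment, so
qPCR truth and array segments agree at every locus.

The Ct generator is the inverse of the quantification model:
`ct = ct_base − log_E(q) + N(0, ct_sd)` with q the copy ratio, 1, or the
dilution factor depending on well role. With `ct_sd = 0` the full pipeline
returns planted ratios to machine precision (asserted); with the default
0.15 cycles a few borderline samples cross the 0.75/1.75 boundaries, which
is the realistic failure mode of threshold calling.

One global seed fans out into per-component child seeds (drawn once via
`sample.int` after seeding), so cohort structure, segments, clinical data
and Ct noise are individually reproducible; identical seeds give
byte-identical outputs, which the pipeline tests assert on the written
files.

What the generator does **not** emulate: probe-level intensities and
segmentation error (segments are exact), tumor purity and ploidy shifts,
clonal heterogeneity, competing risks, and informative censoring. Passing
tests therefore demonstrate correctness of the statistical machinery under
the stated generative model, not robustness to those real-data
complications.

## Numerical and interface choices

* Duplicated qPCR wells (same sample, assay, role, dilution, experiment,
  replicate) are an error, never silently averaged; overlapping segments
  within one sample likewise.
* Strict `start < end` is enforced on all intervals (1 bp records are
  rejected), and zero-width BED features are an import error.
* Writers emit TSV with `#` provenance headers (package version, run
  parameters, configuration hash) and no timestamps, so identical
  configuration and seed give byte-identical files; readers skip `#`
  lines, making write→read round trips lossless.
* The configuration hash is a small rolling hash of the canonicalized
  (name-sorted) configuration list — it identifies runs, it is not
  cryptographic.
* `run_cli()` plus `inst/exec/mcramp` provide `simulate`, `hotspots`,
  `qpcr-call`, `concord` and `survival` subcommands with `--config`,
  `--out`, `--seed`, `--log-level`; the exported `cmd_*()` functions are
  the same entry points for use from R.

## Problem sizes used in the test suite

The suite runs the oracle comparison on 100 random 10-sample, 100 kb
cohorts; null survival calibration on 60 replicates of 100-sample cohorts;
and hazard-ratio coverage on 100 replicates of 400-sample cohorts at
`hr_amp = 0.3` — sizes chosen to make Monte-Carlo assertions stable while
keeping the default test run fast on a laptop.

## Known limitations

Hotspot significance is recurrence-based (support counts), not
background-corrected in the GISTIC sense; deletion hotspots are supported
only via the state-selection flag and are untuned; survival analysis is
two-group univariable (no multivariable Cox, no competing risks); and
absolute copy number, purity and multi-reference-gene normalization are
out of scope. Reproducing the published patient-level numbers requires
the original cohort's supplementary tables and deposited array profiles,
which are not redistributable with the package; the accession-gated checks
in the test suite document exactly where those files must be placed.

```{r example}
co <- simulate_cohort(cohort_spec(n_samples = 31, seed = 1))
detect_hotspots(co$segments)
```
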