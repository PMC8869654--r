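---
title: "Detection-aware differential abundance for label-free proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection-aware differential abundance for label-free proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfqpipe)
library(dplyr)
```

## The analysis problem

Label-free quantification (LFQ) reports a precursor-area intensity per
protein per sample, on an arbitrary per-run scale and with pervasive
missingness: a protein absent from one sample's report was *not detected*
there, which is informative but is not a measured zero. This package
implements a complete case-control analysis for such data, organised around
the design of a two-model diabetic kidney disease (DKD) study: an early and
a late disease stage, each with its own stage-matched controls, plus an
independent second tissue/model for validation. The pipeline answers three
questions in turn:

1. which proteins change in each case-vs-control comparison,
2. which of those change *consistently* across disease stages once aging
   effects in the controls are subtracted, and
3. whether the consistent changes replicate in the second tissue/model and
   are enriched for annotated functions.

## Model and procedure

**Normalization.** Each sample's detected intensities are rescaled to parts
per million of the sample total, $X' = X / \sum_i X_i \times 10^6$. The sum
runs over detected entries only: an absence carries no measured area and is
never imputed before normalization. This removes per-run loading and
instrument-response differences while preserving within-sample composition;
it also means fold-change ratios are composition-relative (a very large
spiked mass fraction in one group shifts every other protein's apparent
ratio slightly — visible in the simulator when many large spikes are
injected at once).

**Presence filter.** A protein is analysed in a comparison only if it was
detected in at least 55% of the samples of at least one of the two groups,
the fraction evaluated exactly (4 of 7 passes at 0.55, 3 of 7 fails). The
filter is scoped per comparison by default — each pair of groups judges
presence on its own samples — with an option to filter once across the whole
design. It is monotone in the threshold and idempotent.

**Detection-aware test.** Group differences are tested per protein with the
two-sided Mann-Whitney rank-sum test, with missing entries entering the test
as zeros. This is a deliberate modelling choice: absences then occupy the
tied bottom ranks, so a protein detected only in controls can still attain a
small p-value — which is exactly how "detected only in wild-type" proteins
earn a p-value in the published tables this pipeline reclassifies. The test
is exact (null distribution of the rank sum enumerated) whenever both groups
have at most 8 observations and the pooled values are tie-free; ties —
chiefly the imputed zeros — switch it to the normal approximation with tie
correction and, by default, a continuity correction. The continuity
correction is configurable because borderline p-values differ with and
without it and either convention is defensible; the default follows the
standard R convention. With the study's group sizes (3–8 per group) the
exact path covers every tie-free protein.

**Fold change and classification.** The reported ratio is the mean of
detected case values over the mean of detected control values — means of
normalized intensities, the only summary the workflow uses elsewhere. When
one group has no detections the ratio is a detection sentinel
(`only_in_case` / `only_in_control`) rather than a number. A protein is
**up** if $p \le \alpha$ and (ratio $\ge$ 1.5 or only-in-case), **down** if
$p \le \alpha$ and (ratio $\le$ 0.67 or only-in-control), otherwise
unchanged, with $\alpha = 0.05$ compared inclusively. No multiple-testing
correction is applied to the per-protein p-values (a BH-adjusted column can
be requested as annotation); the downstream consistency requirement acts as
the de facto replication filter.

**Consistency and aging correction.** A protein is *consistent* when it is
classified in the same direction in both stage comparisons. Candidates that
are themselves significant in the control-vs-control (aging) comparison are
then removed. Removal is direction-agnostic by default — any significant
aging change disqualifies, since an aging-confounded disease estimate is
untrustworthy in either direction — with a direction-matched option.
Aging correction is a pure subset operation and is idempotent.

**Enrichment.** Over-representation of a query list against GMT gene sets
uses the hypergeometric law with the *two-sided* doubled-smaller-tail
convention, $p = \min(1,\, 2\min(P(X \ge k), P(X \le k)))$, BH-corrected
across sets at adjusted $p \le 0.05$; a one-sided enrichment-only option is
provided. Set members are intersected with the background before testing,
and the recommended background is the set of proteins that passed the
presence filter in the relevant comparison — the universe actually
quantified, not the whole genome.

**Cross-study comparison and heatmaps.** Cross-study agreement is Spearman's
rank correlation between per-protein means of normalized intensity
(detected values, natural-log scale) and an external study's summary; being
rank-based it is invariant to monotone rescalings, so the log matters only
for interpretability. Heatmap export z-scales each protein row to mean 0,
variance 1 (sample sd, $n-1$) over detected entries, sets missing entries to
0 (the row mean) *after* scaling, and clusters rows and columns with Ward's
minimum-variance method (`ward.D2`) on Euclidean distances. Rows are sorted
lexicographically by accession before clustering so tied merges resolve
deterministically; zero-distance rows still merge first and end up adjacent.

## The synthetic-data generator

`generate_dataset()` produces master tables with known truth so every stage
is testable without any external download. Its defaults encode the study
conditions:

| parameter | default | meaning |
|---|---|---|
| design | 6 groups, n = 7/8/8/8/5/3 | the two-model, two-stage layout (39 samples) |
| `baseline_log_mean`, `baseline_log_sd` | 6, 1 | log10-normal baseline abundance, a typical LFQ dynamic range |
| `within_group_cv` | 0.20 | multiplicative log-normal noise, mean 1 |
| `detection_rate` | 1.0 | uniform thinning multiplier |
| `dropout_midpoint`, `dropout_steepness` | 3.5, 1.5 | logistic detection vs log10 abundance |

The noise term is drawn with `meanlog = -sdlog^2/2` so its expectation is
exactly 1 and the expected group ratio of a spiked protein equals its fold.
Dropout increases as abundance falls, which is what creates realistic
"only in wild-type" patterns when a protein is down-spiked; the midpoint of
3.5 (log10 ppm-scale-free abundance) puts roughly 5% of entries below
detection under the default baseline, matching the order of missingness seen
in glomerular LFQ tables. Setting `dropout_midpoint = -Inf` disables
abundance-dependent dropout for clean null simulations. One integer seed
drives a single RNG stream (and the caller's RNG state is restored), so
fixtures are bit-reproducible.

What the generator does **not** emulate: peptide-level inference, correlated
protein modules, batch structure, or intensity-dependent variance beyond the
single CV. Passing the recovery tests therefore shows the pipeline's
statistics behave as designed under an idealised LFQ law, not that any
particular biological dataset would yield the same lists.

## Numerical choices and degenerate inputs

- Normalization requires every sample to have at least one detected entry
  and refuses double application; column totals agree with $10^6$ to a
  relative $10^{-9}$.
- `mann_whitney()` returns exactly 1 when all pooled values are equal (the
  tie-corrected variance is 0 there and the test carries no information).
- Duplicate accessions within one report are a hard error: the engine's
  merge rule is unknown and silent aggregation could corrupt quantification.
- A ratio with both groups undetected is a hard error — such a protein
  should have been presence-filtered away.
- Z-scaling refuses constant rows (no variance to standardise) and names
  the offending accession.
- BH adjustment validates its inputs lie in $[0,1]$ before delegating to
  the standard step-up implementation.

## Problem sizes used in the shipped checks

The packaged test-and-verification runs use 2000-protein simulations under
the full 39-sample design for recovery (50 up-spikes at fold 4, 50
down-spikes at fold 0.25, CV 20%) and null calibration (no spikes, full
detection, where the observed fraction of $p \le 0.05$ is compared against
the exact test's achievable size at $n = 8$ vs 7 within a 99% binomial
interval), a 1000-protein run for the aging-confound scenario (43
disease-consistent spikes of which 4 carry an aging confound, recovered as
43 before and 39 after correction), and brute-force oracle enumerations up
to group sizes of 6 (rank tests) and universes of 12 (hypergeometric).
These sizes were chosen so the whole suite exercises every code path at
study-like dimensions while remaining quick to run.

## Known limitations

- Zero-imputed ranks make the test conservative-to-liberal in ways that
  depend on the missingness mechanism; the null calibration covers the
  missing-completely-at-random-by-abundance case only.
- The per-comparison presence filter means a protein can be "inconsistent"
  merely by failing detection in one stage; no rescue rule is applied.
- Enrichment results depend strongly on the chosen background; with a
  genome-wide background the two-sided convention can flag depletion as
  well as enrichment.
- The cross-study correlation requires the external study's per-protein
  summary; none is bundled.

## A worked example

```{r example, eval = FALSE}
spikes <- tibble::tibble(
  accession = c("SIM0001", "SIM0002"), groups = "INS2;INS4", fold = c(4, 0.25)
)
sim <- generate_dataset(synthetic_config(n_proteins = 500, spikes = spikes,
                                         seed = 1))
tab <- normalize_ppm(sim$table)
design <- paper_design()

cmp <- function(case, control) {
  presence_filter(tab, design, 0.55, c(case, control)) |>
    differential_abundance(design, case, control)
}
consistent <- consistent_across(cmp("INS2", "WT2"), cmp("INS4", "WT4")) |>
  aging_correction(cmp("WT4", "WT2"))
glance(consistent)
```
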