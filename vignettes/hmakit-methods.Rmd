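---
title: "Methods and design notes for hmakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for hmakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hmakit` reimplements, as a tested pipeline, the integrative analyses used to
characterize a hypomethylating agent (HMA) across a cancer cell-line panel:
sensitivity profiling, responder-stratified multi-omic biomarker screens,
context-stratified demethylation analysis, and combination-index synergy.
This vignette records the models, the tunable parameters, and the design
decisions that were genuinely open, in the package's own words.

## Sensitivity metrics

**AUC.** Per cell line, replicate viabilities are averaged per dose and the
mean viability is integrated over log10(dose) with the trapezoidal rule,
divided by the log-dose range, and clipped to [0, 1]. There is no canonical
cross-platform AUC formula; commercial panels report unnormalized areas on
platform-specific scales. The normalized trapezoid was chosen because every
downstream use (median split, tertile split, correlations) depends only on
the *ordering* of AUC values, which the normalization preserves, with 0 =
killed at every dose and 1 = fully viable matching the "low AUC = sensitive"
orientation.

**IC50.** A four-parameter logistic on log10(dose) — bottom bounded at 0,
top free — fitted by L-BFGS-B from the best of a 25 x 6 (midpoint x slope)
grid seed. The IC50 is the dose at which the fitted curve crosses half of the
*fitted top* (not 0.5 absolute), right-censored at the maximum assayed dose
when the curve never crosses. Censored lines are excluded from
IC50-dependent analyses with a logged count.

**Classification rules.** `flag_sensitive` marks AUC at or below the panel
median (ties at the median are sensitive). `classify_responders` sorts by
AUC (ties broken by cell-line identifier so the split is stable), assigns the
lowest `floor(n/3)` lines to the responder class and the highest `floor(n/3)`
to the nonresponder class, and excludes the intermediate remainder;
`floor(n/3)` guarantees equal-size extreme groups for balanced testing
(199 lines yield 66 / 67 / 66).

**Tissue enrichment.** The 2x2 odds ratio (sensitive/insensitive x
in-tissue/out-of-tissue) adds 0.5 to every cell when any cell is zero
(Haldane–Anscombe), with a Wald 95% CI on the log odds ratio. Because
forest-plot conventions vary, both a Fisher exact p and an uncorrected
chi-square p are reported; the Fisher p is the primary `p_value`.

## Methylome analysis

β-values come from background-subtracted methylated (M) and unmethylated (U)
intensities as `max(M, 0) / (|U| + |M| + 100)`; subtraction can leave
negative signals, so the numerator is floored and the denominator uses
absolute values, and the +100 offset (in the same arbitrary fluorescence
units) bounds β strictly below 1.

DMC calling compares treated with DMSO triplicates per probe: Δβ = mean
difference and a two-tailed unpaired t-test. The default pools variances
(Student), which is the plain reading of "unpaired t test"; Welch is exposed
via `var_equal = FALSE` because triplicates make either variance estimate
unstable and the choice is not documented in this field's reports. A probe
is demethylated at cutoff c ∈ {0, −0.05, −0.1, −0.2} when p < 0.05 and
Δβ < c; the four flags are nested by construction. No multiple-testing
correction is applied at the probe level — the stated criterion is raw
p < 0.05 — and this is deliberate and documented rather than a statistical
recommendation. Probes with any missing replicate are dropped and counted.
Screens are run on β-values, not M-values.

The normalized demethylation ratio for a genomic feature is simply
(# drug-A DMCs in the feature) / (# drug-B DMCs in the feature); a zero
denominator yields NA with a warning, never infinity.

## Genome annotation

All interval inputs are BED, 0-based half-open; probe positions are
single-base points. A probe at position p overlaps [start, end) iff
start ≤ p < end — the test suite pins this at both boundaries. Replication
timing is a signed score classified late (< 0), mid-early ([0, 1)), early
(≥ 1), boundaries included in the upper class. When overlapping timing
intervals cover one probe, the interval whose midpoint is nearest wins: the
rule is deterministic and independent of file order, which is all that is
required since real Repli-seq tiles rarely overlap. Probes on chromosomes a
track does not cover are uncovered (NA), not errors. Interval search is
delegated to `GenomicRanges::findOverlaps`; the tests verify it against an
independent all-pairs linear scan.

## Biomarker screens

Expression and promoter-methylation screens fit, per feature, ordinary least
squares of the feature on a nonresponder indicator plus a binary
hematopoietic-lineage covariate, with a two-sided t-test on the group
coefficient and Benjamini–Hochberg adjustment. OLS with the covariate is the
minimal model implementing "a binary covariate denoting hematopoietic
origin"; a logistic/beta alternative for methylation proportions was
rejected because the screen operates on region-level *mean* β values, which
are approximately Gaussian at this aggregation level. The coefficient is the
adjusted NR − R difference, so negative values are sensitivity-associated.
Regions are aggregated probe-mean-first, then tested (the alternative —
test probes, then aggregate — is not implemented; region means are the unit
the region-set score consumes, so testing the same quantity keeps the screen
and the score coherent).

Mutation association uses logistic regression of mutation status on the same
design. On (quasi-)separation — detected by non-convergence or absurd
standard errors — it falls back to Haldane-corrected per-lineage-stratum 2x2
odds ratios combined by inverse-variance weighting, with a Fisher exact p
from the pooled table, and flags the row. Whether the original analysis used
regression or stratified tables is unknowable from the report; both routes
are exposed and the flag makes the route auditable per gene.

The region-set score averages β across a region set per cell line and
correlates it with log2(IC50) (Pearson). Its permutation null draws
`n_iterations` same-size region sets uniformly without replacement from the
promoter universe and uses the add-one estimator
`(1 + #{|r_null| ≥ |r_obs|}) / (1 + n_iterations)`, two-sided on |r|, which
cannot return 0 and is uniform under the null — the calibration test draws
the observed set from the null itself and checks uniformity by KS test.
Full scale is 100,000 iterations; tests use 1,000–10,000.

## Synergy

Median-effect fits regress log10(fa/(1−fa)) on log10(dose) over points with
fractional effect strictly inside (0, 1); slope m, Dm = 10^(−intercept/m).
The combination index is the mutually exclusive two-term form
CI = d_a/Dx_a + d_b/Dx_b with Dx = Dm (fa/(1−fa))^(1/m). The mutually
nonexclusive third term is omitted: single CI values per dose cell are the
reported convention, and the two-term form is the default of the standard
software. fa is 1 − relative viability; cells with fa outside (0, 1) are
unscored, and a zero/zero dose pair gives the degenerate CI = 0. A sham
self-combination at half doses returns CI = 1 to 1e-9, which the tests
enforce for arbitrary noiseless median-effect drugs. Note the logit
transform amplifies assay noise at extreme fa, so parameter recovery is
assessed on average over draws, not per draw.

## The synthetic world

The generator's defaults are the stated conditions of the analysis it
emulates, chosen once:

* **Panel** (`panel_spec`): 300 lines; tissue mix with 25% blood;
  hematopoietic AUC shift −0.15; AUC noise sd 0.05; base AUC 0.65. The AUC
  distribution shape across a real panel is unpublished, so a clipped
  Gaussian is an explicit modeling choice surfaced as the `base_auc` field.
  Viability curves are unit-slope logistics whose midpoint is solved by root
  finding so the noiseless trapezoid AUC equals the planted value; replicate
  noise sd 0.04 on the viability fraction; IC50 = the logistic midpoint,
  censored past 10 µM. Doubling time is generated shorter for sensitive
  lines. The 10-dose series spans 1.5 nM–10 µM.
* **Methylome** (`methylome_spec`): 5,000 probes, 500 promoter regions x 8
  probes, 50 planted responder-hypermethylated regions at Δβ = 0.3,
  replicate sd 0.05, timing coupling −0.1. Response classes are *not*
  planted directly: the generator calls the tertile split on the panel it is
  given, keeping that operation on the critical path. Planted effects follow
  a class gradient (responder 1, intermediate 0.5, nonresponder 0) so the
  responder−nonresponder contrast equals the planted Δβ exactly while the
  intermediate lines stay ordered, letting the region-set score correlate
  with IC50 across the whole panel. β-values are produced on the intensity
  scale — gamma-distributed M and U (total ≈ 4000, shape 200) pushed through
  the β formula — so the formula path is exercised end to end; the +100
  offset shrinks planted effects by the factor 4000/4100 ≈ 0.976, which the
  recovery tests account for. The treatment experiment plants drug-A Δβ =
  coupling x timing (plus replicate noise) on a hypermethylated baseline
  (U(0.45, 0.85)) and a uniform, stronger Δβ = −0.15 for drug B. For the
  timing-coupling recovery test, replicate sd is set to 0.012 so measured
  Δβ noise is ≈ 0.01, the stated noise of that scenario.
* **Omics** (`omics_spec`): 1,000 genes, 50 planted markers at |log2FC| = 1
  (alternating sign), 50 lineage-confounded genes, expression noise sd 0.5;
  mutation background rate 0.1 with per-line rates rising for sensitive
  lines (so burden correlates with sensitivity); five planted resistance
  genes enriched in nonresponders at OR 4; 40 proteins of which six load on
  log2(IC50) at ±0.6.

One pseudo-chromosome (`chrS`, probes every 500 bp, 5 kb timing tiles,
random mark intervals) carries all tracks; interval logic does not need real
chromosome structure. What the generator does **not** emulate: type I/II
probe chemistry, probe-type normalization, CNV, batch effects, real LD-like
correlation between neighboring probes beyond shared region means, or
tissue-specific methylation programs. A green test therefore establishes
that the statistical machinery recovers planted structure at realistic noise
— not that the pipeline would reproduce any particular real-data result.

## Numerical choices and degenerate inputs

Seeds are explicit everywhere; derived seeds stay below 2^31. Determinism is
tested byte-for-byte. Zero-variance features get p = 1 and a flag (but an
exact zero-residual fit with a nonzero effect keeps p ≈ 0). Constant
correlation inputs, empty region sets, missing DMSO designs, and malformed
BED intervals raise classed errors (`hmakit_input_error`,
`hmakit_config_error`, `hmakit_design_error`, `hmakit_format_error`,
`hmakit_fit_error`). Tertile and median ties are resolved by documented,
stable rules rather than left to sort instability.

The null-calibration worlds use 100 lines / 500 genes (expression screens,
20 seeds) and 50 lines / 200 regions / 20-region sets (permutation
calibration, 200 repeats at 1,000 iterations): sizes chosen for runtime, not
effect — a null world is null at any size.

## Pipeline

`run_pipeline` executes the stages in dependency order from one JSON-able
config (JSON rather than YAML: no YAML parser is assumed available). The
manifest records the seed, the full config, and per-stage input/output MD5s.
A stage reruns when its parameter+input signature changes or its recorded
outputs no longer hash-match (so a tampered intermediate file is detected
and regenerated); otherwise it is skipped. The synergy stage simulates its
own monotherapy and additive combination data from configured median-effect
parameters — it demonstrates the CI machinery rather than consuming panel
data, since the generator does not produce combination matrices.

## Known limitations

* IC50s are point estimates; no confidence intervals on dose–response fits.
* The DMC t-test with n = 3 per arm has little power at small Δβ; the nested
  cutoffs quantify effect size but p < 0.05 at triplicate scale is the
  binding constraint.
* The mutation screen's separation fallback reports a pooled Fisher p, not a
  stratum-exact p.
* The permutation null preserves the IC50 vector and draws region sets; it
  does not model spatial correlation between neighboring promoter regions
  (none is generated).
* Absolute AUC values are not comparable across assay platforms; only
  orderings are used.
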