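---
title: "Methods: mutation trajectories and CHIP/CHOP stratification in NPM1-mutated AML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation trajectories and CHIP/CHOP stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipchop)
```

## The setting and the model

*NPM1*-mutated AML is the one AML subtype in which complete molecular
remission (CMR) is directly observable: *NPM1* transcripts are a
leukemia-specific marker, and qPCR negativity defines a cohort in which any
co-mutation still detectable at remission needs an explanation. The package
formalizes the competing explanations as mutation *trajectories*. Each
mutation of a patient, matched across up to three timepoints (diagnosis,
CMR, relapse; total order `DIAGNOSIS < CMR < RELAPSE`), has a presence
signature. Diagnosis-to-CMR signatures carry the three labels

* **LOST** — present at diagnosis, cleared at CMR (the mutation rode the
  leukemic clone);
* **PERSISTENT** — present at both (a clone surviving chemotherapy at
  remission);
* **ACQUIRED** — detectable only at CMR (a clone expanding under or after
  treatment);

and the three-timepoint extension distinguishes the seven non-empty
signatures `D_ONLY, D_CMR, D_CMR_R, D_R, CMR_R, R_ONLY, CMR_ONLY`.

The biological claim the pipeline operationalizes is that the *gene*
determines what a persistent or acquired mutation means. Genes whose
mutations typically persist through remission and relapse
(`D_CMR_R`-dominated) behave like clonal hematopoiesis of indeterminate
potential (**CHIP**-like: *DNMT3A*, *TET2*, *IDH1*, *IDH2*, *SRSF2*);
genes whose mutations are gained at CMR and kept at relapse, or appear de
novo at relapse, behave like clonal hematopoiesis of oncogenic potential
(**CHOP**-like: the complement). A patient's CMR stratum is `NONE` (no
persistent/acquired event), `CHIP_ONLY`, or `CHOP` — with CHOP dominance:
one persistent or acquired CHOP-gene event suffices, whatever else the
patient carries. Survival is then analyzed across these strata.

## Filtering rules and their parameters

**Germline exclusion.** Paired sampling substitutes for a matched normal: a
germline variant shows a VAF near 50% (heterozygous) or 100% (homozygous)
at *every* sampled timepoint, while somatic clones fluctuate. A matched
variant is flagged iff it is observed at every available timepoint of its
patient and every observation lies within `germlineTolerance` (default
**0.05**, fraction units) of 0.5 or of 1.0. The tolerance is a standard
heuristic at panel sequencing depth (~binomial noise on hundreds of reads
plus modest mapping bias); it is configurable. Two deliberate choices:

* absence at any sampled timepoint disqualifies (the literal "across all
  timepoints" reading) — a 50%-VAF diagnosis-only variant is treated as a
  somatic heterozygous-range clone, not germline;
* observations may match *different* centers across timepoints (0.49 then
  0.98), since loss of heterozygosity can move a germline variant between
  bands; `strictGermlineCenter = TRUE` demands one consistent center.

Presence-only calls (FLT3-ITD by fragment analysis) carry no VAF and are
never flagged.

**Detection cutoff.** At CMR a variant counts as detected iff VAF ≥ 1%
(`vafCutoffCmr = 0.01`, inclusive boundary). Whether the same cutoff was
applied at diagnosis and relapse in the source analyses is not stated; the
package defaults to the same 1% at all timepoints for symmetry, separately
configurable per timepoint. A CMR observation below the cutoff is *absent*
for trajectory purposes, so a diagnosis mutation dropping to 0.5% at CMR
classifies as LOST.

**Panel and coding restriction.** Panel cohorts keep panel genes plus the
*NPM1* index mutation and gene-scan calls; WGS-style cohorts instead honor
a per-row coding flag. The exact published 63-gene panel is not available;
the panel is configuration (`panelGenes`).

## Matching granularity

Events are matched at variant level — `(gene, variant_id)` — with gene-level
fallback when the identifier is blank on one side and the gene has exactly
one identified chain in that patient. Variant-level matching prevents two
distinct hits in one gene from being conflated into a single trajectory;
the fallback preserves gene-level behavior on identifier-less data (with a
warning). Per-gene summaries count matched *events*, not patient–gene
pairs; a patient carrying two distinct *DNMT3A* variants contributes two
events. The alternative per-patient-gene collapse would change fractions
only for multi-hit genes and is not the default because it discards the
distinction the matcher was built to keep.

## Clonal hierarchy

At diagnosis, VAF approximates clone size, so a co-mutation with VAF
clearly above *NPM1*'s places *NPM1* later in the hierarchy. The call is
`second_hit = (max co-mutation VAF − NPM1 VAF) > margin` with `margin =
0.02` by default — roughly two binomial standard errors at typical panel
depth — so that sampling noise does not produce spurious orderings; margin
0 reproduces the naive strict comparison (and is property-tested against a
brute-force oracle). The comparator is the *maximum* co-mutation VAF: one
ancestral clone suffices. Patients without an eligible co-mutation are
indeterminate. Copy-number distortion of VAFs (LOH, X-linked genes) is
deliberately ignored; VAFs are compared as reported.

## Gene schemes and stratification

`DTA` = {*DNMT3A*, *TET2*, *ASXL1*}; `CHIP5` = {*DNMT3A*, *TET2*, *IDH1*,
*IDH2*, *SRSF2*} (*ASXL1* excluded as a rarity in *NPM1*-mutated AML);
`CHIP6` = CHIP5 ∪ {*ASXL1*} (the WGS-cohort variant). Under every scheme
the positive set and its complement partition the non-*NPM1* gene
universe; *NPM1* itself is never categorized (error by design).

CMR stratification uses the union of PERSISTENT and ACQUIRED events;
persistent-only and acquired-only views are available (`basis=`) because
the two components are also analyzed separately. Relapse stratification
defaults to *any CHOP-gene event present at relapse* (`D_CMR_R`, `D_R`,
`CMR_R`, `R_ONLY`); an `acquiredOnly` switch restricts to events absent at
diagnosis (`CMR_R`, `R_ONLY`) — both semantics appear in the source
material, and the default follows the results-text reading. A patient with
both persistent and acquired CHIP events (and no CHOP event) is uniformly
`CHIP_ONLY`.

The inductive derivation (`deriveSchemeFromPatterns`) runs on the relapse
subcohort with `minEvents = 2` and modal-signature threshold 0.5: a gene is
proposed CHIP when ≥ 50% of its events span all three timepoints, CHOP when
≥ 50% are gained at CMR and kept at relapse or appear de novo; remaining
genes fall back to their diagnosis-to-CMR class (mostly-lost and
mostly-acquired genes both propose CHOP — lost genes ride the leukemic
clone, acquired ones expand under treatment; neither is premalignant
background). The thresholds are this package's concrete rendering of a
qualitative published derivation. The per-gene dominance threshold for
`MOSTLY_*` classes is **0.70**, placing a gene lost in 71% of events inside
the mostly-lost group, which is where the published grouping draws the
line.

## Survival analysis

Endpoints are durations in days. EFS runs from diagnosis (configurable to
CMR; the origin is not stated in the source) to relapse or death; OS to
death; OS-after-relapse from the relapse date, defined only for relapsed
patients; censoring at last follow-up. Estimation is delegated to the
`survival` package: product-limit curves, log-rank tests (pairwise
comparisons unadjusted, as is conventional when pairwise p values annotate
a global curve), and Cox partial likelihood with Efron tie handling
(day-granularity data tie heavily; Breslow by flag). Allogeneic HSCT
enters the multivariate model as a fixed binary covariate; a
time-dependent coding is a known refinement but is not what the modeled
tables describe. Age enters per decade, continuous. Wald 95% intervals
throughout. Monotone likelihood (perfect separation) is flagged per term
with an unbounded upper interval rather than reported as a finite artifact
of the convergence tolerance.

Independent oracles back these delegations in the test suite: hand
product-limit computations, the empirical survival function on
censoring-free data, the equality of the two-group log-rank statistic with
the Cox score test on tie-free data, and a four-subject worked example
maximized directly by golden-section search on the exact partial
likelihood. The worked example uses a covariate alternating in event order;
a covariate that separates early from late deaths has a monotone partial
likelihood with no finite maximizer and is instead used to test the
separation flag.

## The synthetic cohort generator

`simulateCohort` draws, per patient: diagnosis mutations per gene
(frequencies emulating the published diagnosis spectrum, e.g. *DNMT3A*
0.20, *IDH2* 0.14, *TET2* 0.11), founder VAFs from Beta(9, 13) (mode ≈
0.4), *NPM1* placed below the maximum co-mutation VAF for second-hit
patients (baseline fraction 0.80, log-odds increasing by 0.5 per decade of
age — second-hit patients also acquire 1.5× more at CMR, giving the
age/burden associations a planted effect to detect); loss/persistence per
gene, acquisitions per gene; relapse with probability 0.34 and a sequenced
relapse sample for 73% of relapses; exponential post-CMR death hazard
(0.20/year baseline) scaled by the CHIP5 stratum multiplier (`hr_chop` = 3,
`hr_chip` = 1 — CHIP persistence is non-prognostic by construction);
uniform administrative censoring between 1 and 8 years. Ground truth
(labels, strata, hazard multipliers, injected germline spikes) is emitted
alongside, and the generative definitions coincide with the analytic ones,
so the pipeline recovers truth exactly on clean simulations — that
property is a consistency check of definitions, not evidence about noisy
real data.

What the generator does **not** emulate: sequencing noise on VAFs near the
detection cutoff, purity/copy-number distortion, inter-gene co-occurrence
and mutual-exclusivity structure, non-exponential hazards, or informative
censoring. Passing tests therefore certify bookkeeping and statistical
machinery, not robustness to those real-data features.

Germline spikes are drawn within ±0.8 × tolerance of 0.5 or 1.0 at every
sampled timepoint, so filter recall on spikes is 100% by construction;
specificity is asserted only for somatic VAFs below 0.40, since a somatic
clone sitting in the heterozygous band at every timepoint is genuinely
indistinguishable from germline under this (or any matched-normal-free)
rule.

**Parameter-recovery design.** The Cox coverage/bias study simulates 200
cohorts of n = 500 with `hr_chop` = 3 and acquisition scaled ×6 (giving the
oncogenic stratum ≈ 30–40% prevalence, a power choice so each replicate
estimates the log-HR stably), then checks 95% Wald coverage of the true
log-hazard and absolute bias of the mean estimate. These problem sizes are
the package's simulation-study design and run in well under a minute.

## The reference fixture

`buildReferenceFixture()` is a fully deterministic 150-patient cohort whose
variant table is one frozen constraint-satisfying expansion of published
*aggregate* counts: 301 non-*NPM1* diagnosis mutations; 105 CMR mutations;
81 patients with no persistent/acquired CMR mutation and 69 with ≥ 1; 40
with persisting DTA and 22 with persisting non-DTA mutations; 23 with
persistent-or-acquired non-DTA mutations; 10 CHOP and 59 CHIP-only
patients; 52 relapses, 38 relapse samples carrying 84 mutations, 13 of 38
in the relapse CHOP stratum; and per-gene diagnosis-to-CMR fractions for
*DNMT3A* (29/56/15), *TET2* (52/31/17), *SRSF2* (45/38/17).

The integer event counts behind the rounded percentages were found once by
brute-force search over totals (all `(lost, persistent, acquired)` triples
with total ≤ 80 whose rounded percentages match): *DNMT3A* 20/38/10 (68
events), *TET2* 15/9/5 (29), *SRSF2* 13/11/5 (29). Many expansions satisfy
the constraints; this one is frozen, and every load re-runs the full
self-check through the actual pipeline (`checkReferenceFixture`). One
printed aggregate cannot be honored jointly with the others: 301 diagnosis
mutations over 150 patients is 2.0 per patient at one decimal, not the 2.1
printed beside the same count; the fixture keeps the count. VAFs,
demographics and survival times in the fixture are synthetic scaffolding —
the fixture pins mutation bookkeeping, and hazard-ratio point estimates are
validated on simulations instead, where truth is known.

## Degenerate inputs and numerical conventions

Empty variant tables load with a warning; unparseable VAF rows are
rejected row-wise and returned in an attribute. Manifest date skeletons
are validated per patient with itemized errors (relapse before CMR, death
without a date). An all-censored KM input yields S ≡ 1 with a notice.
Ties in clonal ordering share a min-rank and list alphabetically. FLT3-ITD
ratio exactly 0.5 maps to risk `NA` (the clinical brackets `< 0.5`,
`> 0.5` leave the boundary undefined). Percent summaries use `round()` to
the nearest integer. Calendar dates are converted to day offsets from
diagnosis on input, since every endpoint is a duration.

## Known limitations

No phylogenetic clone-tree reconstruction, cancer-cell-fraction or purity
adjustment; no population-database germline annotation; no competing-risks
or frailty models; no variant-level pathogenicity curation (a *DNMT3A*
R882 restriction is expressible only through `variant_id`). At most three
timepoints are supported, by design.
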