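---
title: "Rare-CNV case-control association: models and design choices"
author: "rcnvassoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-CNV case-control association: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcnvassoc)
```

# Scope

`rcnvassoc` implements the post-calling analysis of rare copy-number
variants (rCNVs) in an array-genotyped case-control cohort: quality
control and frequency filtering of CNV calls, genome-wide burden tests,
locus-list association with Firth penalized regression, a
CNV-type-specific rare-breakpoint genome-wide scan with CNV-region
(CNVR) definition, mirror-effect detection, and analytic burden power.
CNV *calling* from raw intensities (consensus of multiple callers,
array-level QC) is upstream of this package: the input is a called CNV
set in PLINK CNV text format plus a sample table with case-control
status and covariates.

# Data model and coordinate conventions

Calls live in a `CnvCallSet`, a `GRanges` of 1-based closed intervals
(the Bioconductor convention) with `sample_id`, `cnv_type`
(`DEL`/`DUP`), probe count and score, paired with a sample
`DataFrame`. PLINK CNV files give 1-based inclusive `BP1`/`BP2`, which
map directly; BED annotation files (0-based half-open) are converted by
`rtracklayer` on I/O. A call spanning `BP1..BP2` has length
`BP2 - BP1 + 1` bp. Multi-copy states are collapsed to `DEL`/`DUP`
(copy number 0/1 vs 3+): none of the downstream models consider extra
dosage, and copy-neutral `TYPE = 2` rows are rejected as errors. One
consequence of the closed convention is that two exactly abutting calls
share no breakpoint coordinate; with array-resolution breakpoints this
case is vanishingly rare.

Chromosome X calls are carried through all modules without
sex-specific dosage handling; this is a documented limitation rather
than an oversight, as no stage of the analysis defines a special rule
for hemizygosity.

# QC and rarity

`qcFilter()` retains calls strictly longer than 20 kb that are
supported by at least 10 probes. `cnvFrequency()` groups calls of the
same type by 50% reciprocal overlap (`min(ov/len(a), ov/len(b)) >=
0.5`) and counts distinct carriers over all samples; `filterRare()`
keeps calls with sample frequency strictly below 1%. Frequency grouping
is type-matched (a deletion never counts toward a duplication's
frequency); the rarity threshold's strictness at the boundary (exactly
1% is removed) follows the "<1%" definition. Both filters are
idempotent and log their removal counts (`filterLog()`).

Within the full pipeline the rarity-filtered calls feed the burden and
locus stages, while the breakpoint scan works from the QC'd calls and
applies the <1% bound *per breakpoint* (`filterRareBreakpoints()`).
The two placements differ materially for a risk CNV whose control
frequency is rare but whose case-enriched total frequency crosses 1%:
the breakpoint-level filter — the one the scan's definition of "rare
breakpoints" prescribes — keeps its sub-1% breakpoints testable,
whereas a call-level filter ahead of the scan would delete the signal
entirely.

# Firth penalized logistic regression

Rare carrier counts (often below ten, sometimes only in one arm) make
ordinary ML logistic regression unusable: under separation the MLE is
infinite and Wald inference collapses. The association engine therefore
maximizes the Jeffreys-prior-penalized log-likelihood
$\ell(\beta) + \tfrac12 \log \det I(\beta)$ (Firth's correction) by
Newton-Raphson on the hat-adjusted score with step-halving, so the
penalized log-likelihood never decreases. Convergence is declared when
the modified score falls below `1e-5` (at most 50 iterations, step cap
5 on the log-odds scale). P-values come from the penalized likelihood
ratio — the coefficient of interest is fixed at zero and the remaining
coefficients re-maximized with the full-model penalty — because Wald
p-values are anti-conservative under near-separation. Confidence
intervals are profile-penalized-likelihood bounds found by bisection on
the signed LRT; Wald CIs are available as a cheap alternative.
One-sided p-values are `p/2` in the risk direction and `1 - p/2`
otherwise. For the saturated one-predictor (2x2-table) model the
penalized estimate coincides with the Haldane +1/2-corrected
cross-ratio, which together with an independent numeric maximizer of
the penalized likelihood serves as the test oracle.

Association tests adjust for cohort membership and the first ancestry
principal component throughout (`status ~ carrier + cohort + pc1`).
Which covariates entered each of the original analyses is not fully
specified; using the same two everywhere is the package's choice.

# Burden analysis

`burdenProfiles()` computes five per-sample metrics from the rare,
QC'd calls: total distance (kb), CNV count, distinct haploinsufficient
genes (`pHaplo >= 0.86`) intersected by at least 1 bp by a deletion,
distinct triplosensitive genes (`pTriplo >= 0.94`) intersected by a
duplication, and the average per-CNV proportion of highly constrained
bases (mammalian PhyloP >= 2.27; primate PhastCons >= 0.96, each
flagging about 3.26% of the genome). Two readings of the dosage-gene
metric exist — counting CNV events or counting genes — and the package
counts each gene once per sample, the reading that matches a
"genes affected" burden; the per-CNV average (not a concatenated base
pool) is used for the constraint proportions. Samples without CNVs
keep zero burden and zero constrained proportion and stay in the
regression: dropping them would condition on carriership.

`burdenTest()` uses plain ML logistic regression (burden is not a rare
event at the sample level), scaling total distance per 100 kb; if the
fit separates it falls back to the Firth engine and flags the result.
Burden p-values are reported one-sided by default since burden
hypotheses are directional. `partitionBurden()` stratifies by type,
length (left-closed bins 20-100, 100-200, 200-500, >500 kb; only the
extreme bin edges are fixed by convention, left-closure is the
package's tie-break so a 100 kb call falls in the 100-200 kb bin) or
carrier-count bins from singletons up; per-sample stratified counts sum
exactly to the unstratified count.

# Locus-list association

Three annotation rules connect calls to curated locus lists
(`annotateLocus()`):

* `syndromic_50`: the call covers >= 50% of the region *or* the region
  covers >= 50% of the call (the wording of the 50% criterion is
  ambiguous about its denominator; the OR of both clauses covers both
  readings);
* `pleiotropic_seg`: the call is >= 100 kb with >= 50% of itself inside
  the segment, *or* the overlap is >= 25% of the segment;
* `exon_1bp`: >= 1 bp overlap with any exon interval of the locus's
  transcript — purely intronic calls never annotate.

A sample carries a locus if any of its calls annotates (a binary
exposure, not a call count). `locusScan()` runs the Firth test per
locus with the list's sidedness (two-sided for syndromic lists, whose
effect direction can be trait-dependent; one-sided risk for pleiotropic
disease-risk lists), skips zero-carrier loci as `unobserved`, and
declares significance at Bonferroni `0.05/n` with `n` the *full* list
length including unobserved loci. No FDR is used anywhere.
`bmiLinear()` adds the supplementary within-stratum OLS models of
lowest BMI on carriership.

# Rare-breakpoint GWAS

`enumerateBreakpoints()` collects each unique start/end position of a
called CNV. `encodeBreakpoints()` builds one sparse samples x
breakpoints matrix per CNV-type model: under the duplication-only model
a sample is ALT at a position covered by one of its duplications,
MISSING if only a deletion covers it, REF otherwise (the deletion-only
model is the reciprocal). Coverage is closed — `start <= p <= end` — so
every call is an observation at both of its own breakpoints. A sample
covered by both types at a position is ALT in both models: the encoding
table does not define this case, and letting the model's own type win
preserves each model's carrier sets. Extra copies beyond a single
gained or lost copy never change an entry.

`scanBreakpoints()` tests each rare (<1% of non-MISSING samples,
>= 1 ALT) breakpoint with covariate adjustment. The default engine is
two-stage: the covariate-only Firth null model is fitted once, then
each breakpoint gets a one-parameter Firth test of the carrier
coefficient with the null linear predictor as an offset. Because
non-carrier terms cancel from the penalized likelihood ratio, each test
touches only the carrier rows, making genome-wide scans orders of
magnitude faster than refitting the full model per breakpoint — the
same null-model-then-per-variant design that mixed-model GWAS engines
use. The full joint refit remains available (`engine = "joint"`); the
test suite checks that the two engines agree closely on simulated
scans, and the joint fit with profile CI is what CNVR leads report.

`clumpCnvrs()` turns the scan into regions: nominally significant
(`p <= 0.05`) breakpoints are processed by ascending p (ties: smaller
position — determinism), each surviving candidate becomes a lead, and
every breakpoint within +-300 kb with `r^2 >= 0.5` to the lead (squared
Pearson correlation of ALT indicators over pairwise-complete samples;
constant columns give `r^2 = 0` with a flag) is assigned to it. The
CNVR spans the lead and its assigned breakpoints and must be >= 20 kb,
span >= 10 probes, and have a risk-direction lead (`OR > 1`).
"Independent" leads are realized as greedy clumping with removal —
PLINK-clump semantics — since no operational definition is given.
CNVRs are annotated with intersecting genes, maximum constraint scores
and the constrained-base proportion of the span. `mirrorScan()` flags
pairs of nominally significant breakpoints from the two models within
300 kb with opposite effect directions, the mirror-dosage signature.
The Bonferroni denominator for a scan is the number of rare breakpoints
tested in that model.

# Analytic power

`poissonEffectSd(m, r)` converts a multiplicative case effect `r` on a
Poisson-distributed count with control mean `m` into
`m(r-1)/sqrt(m)` SD units, using the control-group SD — with inputs
(2.2, 1.21) this is 0.31, and the control-SD reading is the only one
consistent with a ~0.3-SD summary. `twoSamplePower()` is the standard
normal-approximation two-sample power; burden power defaults to
one-sided, which is required for 0.05 SD at 7414/5044 to clear 80%
(two-sided gives 78%). A Monte-Carlo cross-check (`mcTwoSamplePower()`)
is exposed and tested against the analytic form.

# The synthetic-data generator

`simulateCnvData()` emulates a post-calling call set from a single
seed. Its defaults are the study conditions: 7414 cases and 5044
controls; background CNV counts Poisson with means 0.9 duplications and
0.7 deletions per sample, placed uniformly over an hg38-like genome and
*independent of case-control status*, so the global burden is null by
construction (a `case_rate_multiplier` switch exists for power
experiments); log-normal lengths with median 102.8 kb (`sdlog = 0.8`,
a typical array-CNV spread; only the median is pinned by the emulated
study); probes every ~2.5 kb with Poisson jitter, so nearly all
generated calls pass the 10-probe rule and QC truncation moves the
retained median only slightly; two cohorts with realistically different
case/control composition (49%/73% cohort-1 membership); a standard
normal PC1 with a weak (`0.05` log-linear) effect on small-CNV counts;
98%/94% female cases/controls; and case/control lowest-BMI
distributions of 15.2 (SD 2.1) and 20.9 (SD 2.0) kg/m^2. Recurrent
loci are emulated by planting carriers whose calls cover a fixed
segment with endpoints jittered outward (`|N(0, jitter_sd)|`);
non-recurrent background calls are fully random. Null recurrent loci
give the carrier-frequency spectrum its multi-carrier tail. Planted
risk is injected retrospectively: carrier probability in cases is
`OR*f0 / (1 - f0 + OR*f0)` for control frequency `f0`, the exact
case-control tilt of a logistic risk model. `makeAnnotations()`
(seeded from `seed + 1`) draws genes with uniform dosage-sensitivity
scores (configurable fractions forced above 0.86/0.94), exons,
constraint tracks whose highly constrained elements cover 3.26% of the
genome per track (plus sub-threshold decoy elements), and locus lists
consisting of the planted loci plus random decoy segments.

What the generator does *not* emulate: raw intensity noise, caller
disagreement, batch-specific artifacts, X-dosage by sex, linkage
between CNVs and SNP background, or realistic gene/constraint
clustering. Passing tests therefore demonstrate the pipeline's
statistical behaviour under its own assumptions, not robustness to
array artifacts.

# Validation studies and problem sizes

Two simulation drivers back the statistical tests:

* `nullCalibrationStudy()` — 200 replicates of a 2000-sample study
  (1190 cases/810 controls, roughly the cohort's case fraction) on a
  three-chromosome 530 Mb genome, with ten planted null loci (OR 1) at
  0.8% carrier frequency. That frequency puts ~16 carriers behind each
  locus test: the largest count compatible with the <1% rarity bound at
  this n, and the regime where a 5% nominal rate is a meaningful
  calibration target. With fewer events any penalized-LRT p is
  discretely conservative — a singleton breakpoint can never reach
  p < 0.05 — which is the same reason genome-wide scans impose minimum
  minor-allele-count filters. Calibration is asserted on one draw per
  replicate per layer (`onePerReplicate()`), so the binomial bounds
  apply to exactly independent draws; within-replicate draws share the
  simulated cohort.
* `cnvrRecoveryStudy()` — 50 replicates at the full 7414/5044 on a
  four-chromosome 880 Mb genome with two planted 100 kb deletion loci
  (overall sample carrier frequency 0.005, OR 5; the control frequency
  is back-solved from the overall target because the <1% filters act on
  overall frequency) and a protective duplication partner (OR 1/5,
  control frequency 0.008 — a protective CNV needs control carriers to
  be detectable) sharing the second segment. Asserted: a deletion-model
  CNVR overlapping the first segment in >= 90% of replicates, and the
  mirror pair flagged in at least half.

The reduced genomes keep replicate studies tractable while leaving
per-sample call counts, lengths, covariates and all thresholds at the
study defaults; breakpoint density per Mb rises slightly, which if
anything makes recovery harder (more background clumps compete).

# Known limitations

Besides the generator's idealizations: the breakpoint scan's offset
engine conditions on the estimated covariate effects (negligible at
these sample sizes, and the joint engine is available); profile CI
search reports an infinite bound if the profile never crosses the
cutoff within a wide bracket (flagged, not silently truncated);
X-chromosome calls receive no sex-specific treatment; and the locus
lists bundled by the generator are synthetic stand-ins — real analyses
should supply curated lists as BED input.
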