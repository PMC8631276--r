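---
title: "Methods: stratified BWS testing and DMR-DEG linking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified BWS testing and DMR-DEG linking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrlink)
```

# The model and its assumptions

## Differential methylation: the age-stratified combined BWS test

DNA methylation drifts strongly with age, so a pooled tumor-vs-adjacent
comparison across a cohort with a wide age range confounds tumor effects
with cohort composition. `dmrlink` adjusts for age by stratifying: the
cohort is partitioned into *young* (age < 55), *medium* (55–65,
inclusive at both ends) and *old* (> 65) strata, each stratum is tested
separately, and the evidence is combined. Age 55 is not covered by
either of the conventional half-open interval descriptions; it is
assigned to the medium stratum so the three strata partition every
possible age.

Within a stratum, each CpG is compared between the tumor and adjacent
samples with the Baumgartner–Weiß–Schindler (BWS) rank statistic, which
weights squared rank deviations by the inverse of their null variance
and is therefore more sensitive to distribution-tail differences than
rank-sum tests. The test depends on data only through mid-ranks: it is
invariant to any strictly increasing transform, an important robustness
property for beta values whose variance depends on the mean.

The two-sided statistic does not say *which* group is shifted, so a
directional variant is used for one-sided testing: each squared rank
deviation d² in the component statistics is replaced by the signed
d·|d|, and the directional statistic is D = (B̃_Y − B̃_X)/2. This is an
assumption of the implementation — the signed-deviation construction is
the standard one-sided modification of the BWS family — and it is
verified in the test suite against exhaustive enumeration of all label
assignments on small samples. `p_right = Pr(D ≥ D_obs)` under label
permutation is small when the first sample is shifted left of the
second, and vice versa; swapping the samples swaps the two p-values.

Per CpG, the three per-stratum one-sided p-values are combined
Fisher-style on the decimal log scale, `T_side = −2 Σ log10(p_side)`,
and `T = max(T_left, T_right)` captures consistent evidence for either
direction. A large T requires the same direction to be supported in
*all* strata — single-stratum outliers are damped by the sum.

## Empirical null and the permutation scheme

T has no convenient closed-form null, so it is calibrated empirically.
The default scheme permutes tumor/adjacent labels freely within each
age stratum, preserving stratum composition exactly; a paired scheme
(within-patient label swaps) is available via `scheme = "paired"` for
data with strong within-pair dependence. When a stratum admits at most
10,000 distinct label arrangements, the permutation distribution is
enumerated exhaustively and per-stratum p-values are exact; otherwise
`n_perm` Monte Carlo arrangements are drawn and the add-one estimator
is used, so p ≥ 1/(n_perm + 1) and zero p-values cannot occur.

Null draws of T are pooled across CpGs. This is what makes small
empirical p-values reachable at all: with `null_per_cpg = 2` the null
pool holds `2 × n_cpgs` draws and the p-value resolution is
`1/(pool + 1)` rather than `1/(n_perm + 1)`. Requesting an `alpha`
below the achievable resolution raises a classed error that states the
remedy (more null draws per CpG, or a larger alpha).

One numerical subtlety matters for calibration. A null draw of T is
produced by relabelling the stratum with a *fresh* random arrangement
and scoring it against the same permutation reference sample, with the
same estimator, as the observed labeling. Scoring null draws by their
rank *within* the reference sample instead (a tempting shortcut)
treats observed and null arrangements asymmetrically in the presence of
ties and Monte Carlo error, and produces a measurable deviation from
uniformity of the empirical p-values; the fresh-arrangement scheme
makes observed and null p-values identically distributed under the null
by construction. The test suite checks both the type-I error at
α = 0.05 (within three Monte Carlo standard errors on 5,000 null CpGs)
and the Kolmogorov–Smirnov uniformity of the empirical p-values.

## DMR calling

DML merge in two steps: consecutive DML closer than 200 bp form
pre-regions, then every profiled CpG between a pre-region's first and
last DML joins as a member. The region end is the last member CpG + 1
(all internal coordinates are 0-based half-open; conversions happen
only at file boundaries — GTF is written 1-based inclusive, BED
0-based half-open). `min_cpgs` defaults to 1 — single-CpG regions are
kept, since the merging rule alone defines a region — but the parameter
exists because practice often drops them.

Per-DMR summaries: `mean_T` (arithmetic mean of member T), group-level
methylation (mean over member CpGs, then over group samples), and
`delta = methy_tumor − methy_adjacent`. The empirical p of `mean_T` is
computed against a null of means of member-count-sized draws from the
pooled CpG-level null — the CpG pool is the only null distribution
available without a dedicated DMR-level permutation pass, and averaging
resampled draws matches how `mean_T` itself is formed. Downstream
linking keeps only DMRs with |delta| ≥ 0.15 (inclusive), applied to all
three link routes including intergenic enhancers.

## Annotation and regulatory classification

Genomic-location labels are assigned by ≥ 1 bp overlap against
promoters (−1,500/+500 bp around each transcript's TSS, strand-aware),
5'/3' UTRs (when the gene model provides them), exons and introns; a
unique label uses the priority promoter > 5'UTR > 3'UTR > exon >
intron > intergenic. The "> 1 bp" phrasing in common annotation
descriptions is read as *any* overlap — a strict rule would
arbitrarily exclude 1-bp overlaps of point CpGs.

Chromatin-state maps (chromHMM-style labels per ChIP-seq sample,
tumor/non-tumor flagged) drive the promoter-like / enhancer-like calls:
any active-promoter-state overlap (or a promoter location label) makes
a DMR promoter-like; any active-enhancer-state overlap makes it
enhancer-like. Activity scores count the samples per class with such an
overlap, and a DMR is "activated in tumor" when its tumor score exceeds
its non-tumor score, "repressed" when smaller, "unchanged" on ties
(ties are excluded from activated/repressed numerators but kept in
denominators). Which samples count as tumor is plain metadata on the
state table — a cancer-derived cell line such as HepG2 can be assigned
to either class by flipping its flag, since published usage is
ambiguous on this point.

## DMR–DEG linking

Differential expression is taken from an external table when one is
available (`differential_expression(external = ...)` applies only the
DEG thresholds, FDR < 0.05 and |log2FC| > 0.5, and passes records
through verbatim). The built-in fallback is deliberately simple — a
paired Wilcoxon signed-rank test with BH adjustment and
`log2((mean tumor TPM + eps)/(mean adjacent TPM + eps))` — because
reimplementing a negative-binomial DE engine is not this package's
contribution. Genes with TPM < 0.01 in more than half the samples are
dropped first.

The three link routes and their windows: promoter-like DMRs vs genes
with a TSS within 2 kb of either DMR boundary (distance 0 when the TSS
falls inside the DMR); genic enhancer-like DMRs vs genes separated by
less than 100 kb; intergenic DMRs with active eRNA expression (≥ 3
reads in at least a ceiling-third of tumor or adjacent samples) vs
genes within ± 0.5 Mb. Reported distances are signed — TSS minus the
nearest DMR boundary, sign flipped for minus-strand genes so the
convention is consistent in transcription coordinates.

Promoter and genic links require a BH-adjusted Spearman p < 0.05
between DMR methylation and expression across all samples (adjustment
within each route's candidate set). Intergenic links must pass the
triple correlation — methylation–eRNA, eRNA–gene, methylation–gene —
each family BH-adjusted across candidate pairs by default ("significant"
without qualification is read as adjusted; `triple_adjust = "none"`
restores raw p-values). Genes already linked through a promoter are
excluded from both enhancer routes, so no gene is double-counted.
Links are classified by the joint sign of (delta, LFC) into HyperDown /
HypoUp (classical, negative regulation) and HyperUp / HypoDown
(non-classical).

High-confidence screening: promoter/genic links pass when the DMR
covers at least 80 % of a regulatory element (a gene-model promoter or
an active promoter/enhancer state interval). The denominator is the
*element* width — the literal reading of "overlapping at least 80 % of
a promoter region" — with `denominator = "dmr"` available because the
alternative reading (80 % of the DMR covered) is also defensible.
Intergenic links pass when eRNA–gene ρ ≥ 0.7.

## Replication accounting

Replication in an array-based cohort distinguishes failures the
platform *cannot* test from failures of signal: type I — no array probe
inside the DMR, or the target gene not expressed in the cohort;
type II — probes present but differential methylation, differential
expression, or a same-sign significant correlation not confirmed
(two-sided rank-sum and Spearman tests at p < 0.05, per-link verdicts
without multiple-testing adjustment by default; a BH flag exists).
Probe methylation is averaged within the DMR before testing, matching
the DMR-level discovery logic. Raw rate = replicated/discovery;
adjusted rate = replicated/(discovery − type I) — equivalently
replicated/(type II + replicated) — with zero denominators rendered
"/" in formatted tables.

## Clinical association

Univariate Cox (per unit or per SD), two-group log-rank, optimal
cutoffs scanning the value quantiles 0.1–0.9 in steps of 0.05 with a
10 % minimum group size, combined methylation+expression
stratification, and one-way stage ANOVA. Two optimism caveats are
deliberate design: reported optimal-cutoff p-values are *not* corrected
for the cutoff search (the package documents this and the test suite
demonstrates the optimism under the null), and the combined
stratification takes its orientation — which tail of each variable is
high-risk — from the discovery-phase signs rather than searching over
orientations, to limit the optimism to the cutoff grid alone.

# The synthetic cohort generator

`generate_cohort()` emulates the *statistical structure* of a paired
WGBS + RNA-seq + eRNA + ChIP-seq cohort, not its sequence content.
Defaults are the study conditions the package targets: 33 patients
(strata in roughly 10 : 13 : 10 proportion, ages drawn uniformly within
40–54 / 55–65 / 66–80), a planted beta-scale effect of 0.3, a target
methylation–expression Spearman magnitude of 0.7, planted |log2FC|
around 2, 8 CpGs per planted DMR, and Poisson eRNA counts with mean 20
(active) vs 0.5 (inactive). A fifth of planted links carry the
non-classical positive sign.

Methylation is logit-normal: beta values are the inverse logit of a
per-CpG baseline plus N(0, 0.35²) noise, which keeps values strictly
inside (0, 1) with tunable variance. A mild global age trend (−0.01
logit per year from age 60) is applied *identically to both tissues of
a patient*: ages shape the methylome, but the tumor/adjacent contrast
stays exactly null outside planted DMRs, and the free within-stratum
label permutation remains valid. Two real-data features are therefore
deliberately *not* emulated: tumor-specific age interactions, and
shared patient-level random effects (which would make pair members
dependent and the unpaired permutation scheme conservative). Passing
calibration tests on this generator consequently shows the test is
correct under exchangeability — not that real cohorts with strong
within-pair dependence are safe with the default scheme; the paired
scheme exists for that case.

Planted DMRs occupy widely separated cassettes whose coordinates are a
deterministic function of the planted counts alone. Each cassette hosts
one target gene and one planted DMR of one kind — in a promoter window,
inside a gene body (intron), or 450 kb from the nearest TSS
(intergenic) — plus chromatin-state elements nested inside the DMR
(hypermethylated DMRs painted active in non-tumor samples,
hypomethylated in tumor samples, so activation calls have planted
signal). Because the layout is seed-independent, generating a second
cohort with a different seed yields fresh noise over the *same* planted
truth: that is how `run_pipeline(replication = "simulate")` builds an
independent replication cohort, together with a sparse probe manifest
(35 % CpG coverage) that produces genuine type I failures.

Expression for linked genes is generated from the realized DMR
methylation through a Gaussian copula with the Pearson equivalent of
the target Spearman correlation (2·sin(πρ/6), slightly inflated to
absorb count/noise attenuation); intergenic targets are driven through
the eRNA latent variable so all three legs of the triple correlation
carry signal. Survival times are exponential with the hazard scaled by
the first planted gene's tumor expression; stages are ordered quartiles
of the same linear predictor plus noise.

# Numerical choices

* Ties: mid-ranks everywhere; an all-tied stratum returns p = 1 rather
  than erroring.
* Exhaustive enumeration threshold: 10,000 arrangements.
* Add-one p-value estimators throughout Monte Carlo paths; exact counts
  under enumeration.
* Floating-point tie tolerance in permutation comparisons:
  1e-9·(1 + |D|).
* The mean-T null resamples 2,000 member-sized draws per distinct DMR
  size.
* "One third of a group" uses the ceiling on non-integer group sizes.
* Undefined rates (zero denominators) are NA internally and "/" in
  formatted output.

# Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen
as the package's own operating point for validation: 5,000 CpGs,
30 patient pairs, 300–500 Monte Carlo permutations per stratum, and a
pooled null of 10,000 draws (p-resolution 1e-4, DML threshold 1e-3 for
recovery runs, 0.05 for calibration runs). Genome-scale use — tens of
millions of CpGs, permutation budgets of 10⁸ and DML thresholds of
1e-5 — is a matter of running the same functions longer; nothing in the
method changes, only the pool sizes.

# Known limitations

* The one-sided BWS construction is the signed-deviation variant; other
  directional modifications of the BWS family exist.
* The pooled null assumes CpGs share a common null distribution of T;
  strong heteroscedasticity across CpGs would argue for per-CpG nulls
  (available in principle by raising `null_per_cpg` and filtering, but
  not exposed as a separate mode).
* The DE fallback is rank-based and paired; it is less powerful than a
  negative-binomial engine on counts and exists to keep the pipeline
  self-contained when no external DE table is supplied.
* Optimal-cutoff survival p-values are optimistic by construction;
  treat them as descriptive screening quantities.
* The generator does not simulate reads, bisulfite conversion, copy
  number, or mutations; its fidelity claims are limited to the joint
  correlation structure described above.
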