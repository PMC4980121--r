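---
title: "Methods: genome-wide de novo mutation characterization on synthetic trio cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide de novo mutation characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and shape

`dnmtrio` re-implements, as a tested analysis pipeline, the statistical
machinery used to characterize de novo mutations (DNMs) in parent-child
trio whole-genome studies of autism: somatic/germline classification by
allelic fraction, clustered-DNM detection with parent-of-origin contrasts,
parental-age mutation models, mutation-rate elevation near de novo copy
number variants (CNVs), trinucleotide mutation spectra, a two-tier
damaging-variant classifier, a GC-corrected case-control burden test with
gene-set burden, and a Methylation Outlier Sample Test (MOST). Real trio
WGS data of this kind are access-controlled, so the package ships a
first-class synthetic-data module that generates cohorts with known ground
truth; the numbered scripts under `analysis/` drive the full sequence and
write their tables under `results/`.

All computation lives in the package functions; the scripts are thin
narrative drivers, and `scripts/acceptance.R` recomputes the headline
quantities from scratch.

# The synthetic cohort: what it emulates

`simulate_trio_cohort()` is the study-conditions generator. Its defaults
are the cohort conditions the pipeline is designed for, chosen once:

* **Cohort sizes** — 200 case trios, 258 control trios.
* **Mutation rates** — 50.9 germline de novo SNVs, 3.9 indels and 0.052
  de novo CNVs (>10 kb) per genome, Poisson-distributed per trio.
* **Paternal age** — uniform on 20-45 years; the Poisson mean gains
  `paternal_age_slope` (default 1.0 SNVs/year, the scale reported for
  human germline point mutation) around the age-range midpoint. Indel
  counts use the same slope scaled by the indel/SNV rate ratio. Because
  the simulator phases every variant and uses no extra-Poisson noise, the
  realized age-count correlation (~0.6-0.7) is stronger than the ~0.4
  typical of real cohorts, where phasing is partial and detection noisier;
  the age-model tests therefore check slope recovery, not a specific r.
* **Origin** — unclustered germline DNMs are paternal with probability
  0.756. Clusters (mean 0.55 per genome, sizes 2+Poisson(0.25)) are
  maternal with probability 0.85; 44% of cluster spans fall under 200 bp,
  the rest uniform up to the 20 kb window. The paper-scale contrast
  (~88% vs ~68% maternal under/over 200 bp) emerges from these two dials.
* **CNV proximity** — clusters of a CNV carrier fall inside the carrier's
  +/-100 kb CNV windows with probability
  `min(1, near_cnv_rate_multiplier * window_fraction)`. The default
  multiplier of 200 matches the order of magnitude of the observed/expected
  ratio in the motivating data (about 11 observed DNMs against well under
  one expected); smaller values make the binomial test's signal vanish at
  desk-scale genome sizes.
* **Somatic component** — 5.9% of calls are post-zygotic, with allelic
  fraction Beta(4, 16) (mean 0.2) against germline Beta(30, 30); the
  fixed <1/3 classifier separates the classes with deliberate overlap, so
  classified counts overestimate true somatic counts somewhat — as any
  threshold classifier on these distributions must.
* **Alleles** — substitutions are transitions with probability 2/3
  (Ti/Tv = 2); indels are half 1 bp deletions, half 1 bp insertions.
* **Predictor scores** — drawn from two-component benign/damaging
  mixtures per region class. A damaging draw receives scores satisfying
  its region's tier-1 rule; a benign draw receives scores that do not.
  The per-region weights (`damaging_weights`) are anchored to published
  anatomy: ~1.9% of DNMs exonic, ~80% of coding DNMs damaging (all
  missense plus LOF qualify), a ~2.5% overall damaging rate, and a
  coding/genic-noncoding/nongenic breakdown near 60/25/15. The damaging
  label is drawn first, at the aggregate rate
  `sum(region_probs * damaging_weights)` (logit-shifted by
  `log(damaging_or)` for case records; default 1.84, the headline case
  enrichment), and the region conditional on the label: the case/control
  odds ratio of tier-qualifying status then equals `damaging_or` without
  saturating the high-weight regions, and cases come out modestly
  coding-enriched, as real cohorts do. In the control cohort the realized
  tier-1 fraction equals the aggregate rate up to binomial noise — a
  property the tests assert.
* **GC confounding** — when `gc_confounding > 0`, case-cohort variant
  positions are weight-resampled toward GC-rich 50 bp flanks
  (log-weight per GC SD), reproducing the coverage-driven GC bias that
  motivates the GC covariate. The burden-calibration experiments use
  `simulate_burden_variants()`, a direct variant-level generator in which
  GC influences both cohort and set membership with the same log-odds and
  the conditional membership odds ratio is exactly `damaging_or`; this is
  the cleanest way to run 500-replicate calibration at n = 20,000.

The genome is 8 contigs of 12.5 Mb (100 Mb). That scale keeps placement
geometry meaningful — incidental same-sample 20 kb proximity contributes
roughly a third of clustered calls, diluting the clustered maternal
fraction from the planted 0.85 to ~0.6-0.65, exactly as chance proximity
does in real genomes (scaled up, since the genome is ~30x smaller) —
while remaining fast enough for hundred-seed calibration loops.

What the simulator does **not** emulate: linkage and repeat structure,
read-level errors, context-dependent mutation spectra (channels inherit
only the Ti/Tv bias and base composition), partial phasing (every record
carries an origin by default; real read-backed phasing resolves a
minority), multi-nucleotide events, and sex chromosomes. Passing tests
demonstrate the statistical machinery is correct and calibrated on data
with the assumed structure, not that the biological conclusions transfer
to any particular real cohort.

The methylation generator builds beta values from a logit-scale model:
bimodal per-probe baselines with modes near beta 0.25 and 0.75 — kept out
of the saturated regime deliberately, because near-saturated probes make
the inverse-logit squash strongly nonlinear and convert large (normal)
factor scores into spurious single-sample components, breaking the
normal-PC null structure the outlier test assumes and diagnoses — a
low-rank latent factor component (factor SDs decaying from 0.2),
covariate effects (sex, age, batch) on random 5% probe subsets, i.i.d.
noise (SD 0.4), and an inverse-logit squash.
Outliers are injected as shifts of one sample's latent factor score,
measured in factor SDs. Probe annotation places ~4% of probes on sex
chromosomes and flags ~5% as SNP-overlapping; detection failures are
i.i.d. at 1e-4, which removes ~2% of probes under the strict
any-sample rule. One of five cell-composition fractions is dropped before
output so the covariate design remains full-rank beside an intercept.

# Decision rules and their boundaries

**Somatic classification.** Fixed mode flags allelic fraction < 1/3; the
adaptive mode recomputes the threshold as mean - 2 SD of the cohort's SNV
allelic fractions and refuses to run under 30 records. Fixed is the
default.

**Clustering.** Two or more same-sample mutations within 20 kb. The
wording is ambiguous between a gap rule and a span rule; the default
chains consecutive records whose gap is at most 20 kb (boundary
inclusive) because the result is order-independent and transitive, and a
`rule = "span"` greedy variant is available. The acceptance suite proves
the gap rule identical to an all-pairs transitive-closure oracle.

**Origin contrasts.** Two-sided Fisher exact tests under R's
minimum-likelihood enumeration convention; unknown-origin and
somatic-candidate records are excluded from the tables; a zero margin
yields p = 1 with a warning rather than an error.

**CNV proximity.** Windows are CNV body plus 100 kb flanks, clipped at
contig bounds; overlapping windows contribute their union. By default
only the carrier's own DNMs count, and the binomial background
probability is the count-weighted mean of each carrier's own window
fraction — using the pooled union would inflate the expectation by
windows a carrier's DNMs cannot reach. `same_individual = FALSE` gives
the pooled variant. The p-value is the exact upper binomial tail.

**Tiers.** The genic tier-1 rules (all LOF; all missense; dPSI < -3.5
splicing-negative; all 5'UTR; 3'UTR with phastCons > 0), genic tier-2
rules (LOF; missense with >= 5 of 7 predictors damaging at mammalian
PhyloP >= 2.30, vertebrate-100 PhyloP >= 4.0, SIFT < 0.05, PolyPhen2 >=
0.90, Mutation Assessor >= 1.9, Mutation Taster >= 0.5, CADD >= 15;
dPSI < -5; all 5'UTR; 3'UTR with phastCons > 0 and PhyloP >= 1.5), and
the non-genic DeepBind-loss rules (wild-type >= 99.9th percentile,
variant <= 99th, phastCons > 0; tier 2 additionally in DHS) are applied
with their operators exactly as written; every boundary has a pinning
unit test. An absent score never satisfies a criterion. A variant
qualifying under several rules is counted once in summaries, in the
category of its first firing rule (LOF/missense in exonic or core-splice
regions count as coding). The chromatin-state x predictor screen that
originally selected the non-genic rules is out of scope; only the two
promoted rules are implemented. Stop-loss variants are treated as
missense for tier 1 only (their tier-2 status under the 5-of-7 set is
not specified in the source rules).

**Burden.** The full logistic model `case ~ GC + membership` against the
GC-only reduction, fitted by IRLS (tolerance 1e-8, 100 iterations), with
the 1-df likelihood-ratio p as primary — the stated model comparison is a
nested-model comparison, which is an LRT — and Wald p alongside. GC is
the 50 bp flanking fraction on its natural scale, not standardized. The
fit is per-variant over the pooled case+control variant list (membership
is a property of variants). The genic universe is exonic coding +
splicing + UTR + intronic; the non-genic universe excludes exonic and
splicing-qualifying variants. Gene-set burden uses two-sided Fisher on
(cohort x damaging) within set genes, sets of 50-1200 genes,
all-zero-table sets dropped, BH FDR across tested sets.

**MOST.** Probes on sex chromosomes, SNP-overlapping probes, and probes
with any detection p > 0.05 are removed. PCA uses per-probe centering and
unit-variance scaling, computed through the sample-space Gram matrix
(eigenvalues match `prcomp`'s `sdev^2`; the suite asserts this). The
eigenvalue null is parallel analysis: 20 randomized matrices, each probe
column independently permuted; component k is retained when its observed
eigenvalue exceeds the per-rank maximum of the permuted eigenvalues
("20 sets of eigenvalues" read as 20 randomizations compared rank by
rank; a global-maximum variant is selectable via `perm_rule`). Retention
is the contiguous run from PC1. Covariate adjustment is per-PC OLS
residualization against sex, ethnicity, age, cell fractions, batch and
chip order, with categorical covariates as indicators and a hard error on
rank-deficient designs. The Grubbs test uses G = max|x - mean|/SD with
the two-sided p from `min(1, 2n P(T_{n-2} > t*))`,
`t* = sqrt(n(n-2)G^2 / ((n-1)^2 - nG^2))` — the form that is calibrated
(rejection rate 0.047 at nominal 0.05, n = 185, checked on 10^4 null
samples); it is applied once per PC (a single candidate), with an
iterative variant deliberately omitted. BH FDR runs across retained PCs
separately for raw and adjusted scores, and a sample is an outlier only
when the same (sample, PC) pair passes FDR < 0.1 in both families. That
dual rule is what suppresses shifts explainable by covariates: a shifted
sample alone in its batch level is flagged on raw scores and exactly
absorbed by the batch indicator, so it is not reported. Shapiro-Wilk
normality p-values per retained PC are emitted as diagnostics only.
Loading enrichment takes the top fraction of probes by |loading|
separately within positive and negative loadings, maps probes to genes,
and Fisher-tests each gene set against the genes mapped by that sign's
probes (so selecting everything is exactly unenriched), BH-corrected per
sign.

# Numerical choices and degenerate inputs

* Fisher tests everywhere use `fisher.test`'s exact minimum-likelihood
  two-sided convention, verified against full hypergeometric enumeration
  for all margins up to n = 200.
* Binomial proximity p-values are exact tail sums, verified against
  direct log-space summation up to n = 2000.
* Reported percentages round half-up to one decimal, rates to two
  decimals; `round_half_up()` is exported because base `round()` is
  half-even and the printed worked examples (61.9 / 22.5 / 15.6; 3.19;
  43.9) depend on the convention.
* Poisson age-model coefficients take p-values from the t distribution
  with n - 3 degrees of freedom rather than the normal, matching the
  source convention for modest cohort sizes.
* Zero-variance probes are dropped (with a warning) before PCA;
  zero-variance spectra, zero transversions, all-N windows, empty
  distance groups, perfect separation, and constant membership are all
  hard errors rather than silent NaNs.
* Single-seed reproducibility: every generator draws from named
  substreams derived from one integer seed, so adding a generator does
  not perturb existing draws, and all pipelines are bit-reproducible
  given (inputs, seed). The column-permutation hot loop of parallel
  analysis runs in C++ with an xorshift stream seeded from R's RNG,
  keeping `set.seed` semantics at full speed.

# Problem sizes used in the tests

The calibration experiments run at the sizes the analyses are specified
for: burden type-I calibration at 500 cohorts of 20,000 variants
(GC-confounded, null enrichment) with the nominal-0.05 rejection band
[0.03, 0.07] and a demonstration that the GC-free fit inflates beyond
0.10; OR recovery at 200 replicates of true OR 2; origin recovery at 100
seeds of 200 trios; MOST specificity/sensitivity at 100 null and 100
injected 185 x 20,000 matrices; the clustering oracle at 10^4 random
configurations; Grubbs calibration at 10^4 null samples of size 185. The
analysis scripts run one full cohort end to end.

# Known limitations

* Read-backed phasing, variant calling, CNV calling and score computation
  (SIFT/PolyPhen2/CADD/SPIDEX/DeepBind/ANNOVAR) are out of scope; origins,
  calls and scores are inputs.
* The spectrum module does not fit or deconvolve mutational signatures;
  it builds, compares and summarises the 96-channel counts.
* The tier engine covers exactly the promoted rule sets; the exploratory
  294-combination non-genic screen is not implemented.
* idat processing, noob/SWAN normalization and cell-composition
  estimation are upstream of MOST's contract; it consumes normalized
  betas, detection p-values and numeric cell fractions.
* Indel coordinates are assumed left-normalized on input and are not
  re-normalized.
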