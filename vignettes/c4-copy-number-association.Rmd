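---
title: "Multiallelic C4 copy-number genotyping and association: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiallelic C4 copy-number genotyping and association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c4cnv)
```

## The problem

The complement component 4 locus is a multiallelic copy-number variant:
diploid genomes carry 0–5 copies of the C4A isotype and 0–4 copies of C4B,
with population modes at 2 copies of each (4 total). Copy number is commonly
measured by multiplex ligation-dependent probe amplification (MLPA), whose
peak heights are proportional to target copy number, and tested for disease
association — here, late-stage age-related macular degeneration (AMD), with
geographic atrophy (GA) and neovascular (NV) subtypes — under an additive
model in which the log-odds of disease are linear in the number of gene
copies. Because the locus sits ~30 kb from the CFB/C2 region that carries
strong known AMD signals, any copy-number association must also be shown to
be independent of those variants, which requires conditional models and a
view of the local haplotype structure.

`c4cnv` implements that full chain as reusable, tested components: dosage
normalization, integer copy-number calling with QC, additive logistic
association with stratification and conditioning, random-effects
meta-analysis across studies, small-scale EM haplotype reconstruction, and a
synthetic-data generator that provides ground truth for every stage.

## Dosage normalization

For each sample, each test probe height (C4A, C4B, or C4-ex30, the latter
binding both isotypes and hence measuring total C4) is divided by the summed
heights of two control loci (EP300, CREBBP):

$$r_{ij} = \frac{h_{ij}}{h_{i,\mathrm{EP300}} + h_{i,\mathrm{CREBBP}}},$$

and each ratio is rescaled by the batch median, $d_{ij} = r_{ij} /
\mathrm{median}_i(r_{ij})$. Two properties follow by construction and are
asserted in the tests: column medians are exactly 1 per batch, and any
per-sample multiplicative factor common to all five peaks (run intensity,
DNA input) cancels. Normalization batches default to the study label —
cases and controls pooled, since the modal diploid class then sits at
dosage 1 — and can be switched to plate level via `batch_key`.

When the total-C4 probe fails (as happens in practice for whole batches),
`impute_total_c4()` substitutes the mean of the two isotype dosages and
flags the value `imputed-from-mean`; `total_vs_mean_correlation()` reports
the Pearson correlation between measured totals and that mean on batches
where both exist, which justifies the substitution (on synthetic data at
realistic noise it exceeds 0.9; noise-free it is 1 exactly, provided the
batch is normalized as a single unit so the three probes share commensurate
median scalings).

## Integer copy-number calling

Normalized dosages cluster around equispaced centers $k \cdot s$, one per
integer copy number. `call_integer_cn()` fits the shared spacing $s$ per
batch by a grid search minimizing squared *fractional* residuals
$\sum_i (d_i/s - k_i)^2$ with $k_i = \mathrm{round}(d_i/s)$, refined by
alternating assignment and least squares. The fractional (units-of-$s$)
cost matters: an absolute least-squares criterion can drift toward a
smaller, misaligned spacing that shrinks residuals without aligning to the
clusters. The most populous subgroup is then anchored to the configured
modal copy number (2 for C4A and C4B, 4 for total C4; anchors are
configuration, not constants), neighboring subgroups receive consecutive
integers, and ties exactly on a boundary go to the lower integer — the
conservative direction, since zero and low calls feed a confirmation
worklist. A pure gap-partition variant (split the ordered dosages at gaps
larger than a fraction of the nominal spacing) is available via
`method = "gap"`; both methods satisfy the same invariants on clean data.

Three guards surround the fit:

* **Structure**: a Rayleigh uniformity test on the fractional residuals. A
  structureless smear gives uniform residuals (the test cannot reject
  uniformity; calling aborts with advice to inspect the noise), while real
  clusters concentrate residuals near 0. This test-based guard replaced a
  fixed residual cutoff during development because total C4 has genuinely
  wide clusters (spacing 1/4 with multiplicative noise growing in the copy
  number) that a fixed cutoff could not separate from noise.
* **Confidence**: each call's confidence is its scaled distance from the
  subgroup boundary (1 at a center, 0 at a boundary). A call is flagged
  `low_confidence` when confidence falls below a threshold *or* when its
  boundary margin is within 2.33 robust within-cluster standard deviations
  (about 1% Gaussian misassignment risk). The second, noise-adaptive rule is
  what makes degradation graceful: as noise grows, errors land in flagged
  calls rather than in confident ones.
* **Batch size**: batches under 30 samples are refused; subgroup structure
  cannot be estimated reliably below that.

Zero dosages are called 0 and flagged `suspected_homozygous_deletion`;
`flag_homozygous_deletions()` emits the confirmation worklist (wet-lab
isotype PCR itself is out of scope). `dosage_bias_qc()` addresses the known
failure mode of multiallelic CNV association — differential measurement
bias between cases and controls — by Welch-testing the raw unrounded
dosages of modal-class carriers between the groups, pooled and per study.

At the default synthetic noise (peak CV 0.04, the level at which simulated
dosage clusters look like published MLPA data), calling recovers ≥99% of
true C4A and C4B integers at n = 500; total C4 is intrinsically harder and
is covered by the consistency invariant (total = C4A + C4B in ≥99% of
confident, measured calls).

## Association models

`fit_cn_logistic()` fits the additive model by maximum likelihood
(IRLS via `stats::glm`), with Wald standard errors and symmetric 95%
intervals on the log-odds scale:

$$\mathrm{logit}\,P(\mathrm{case}) = \beta_0 + \beta_{CN}\cdot CN +
\beta_a\,\mathrm{age} + \beta_s\,\mathrm{female} + \gamma_{\mathrm{study}}
(+ \textstyle\sum_j \delta_j\,\mathrm{SNP}_j).$$

Sex is coded female = 1 (reference male), study enters as indicators with
the largest study as reference; these codings affect only nuisance terms.
Conditioning columns (SNP allele dosages, or posterior haplotype dosages)
are ordinary covariates. Complete/quasi-complete separation is detected and
reported as an error naming the term; strata with fewer than 10 cases or 10
controls are refused; missing covariates are handled by complete-case
exclusion with per-model n reported. Age strata are `<71`, `[71, 78]`,
`>78` years: the boundary ages are assigned to the middle band, a choice the
source material leaves open (its stratum counts do not sum to the full
cohort, so the convention is not recoverable); subtype strata each include
all controls.

## Random-effects meta-analysis

Per-study log odds ratios are pooled with the DerSimonian–Laird moment
estimator: $Q = \sum w_i(\beta_i - \bar\beta_{FE})^2$ with $w_i = 1/se_i^2$;
$\tau^2 = \max\!\big(0, (Q - (k-1))/(\sum w_i - \sum w_i^2/\sum w_i)\big)$;
random-effects weights $1/(se_i^2+\tau^2)$; $I^2 = \max(0,(Q-(k-1))/Q)
\cdot 100\%$; heterogeneity p from $Q \sim \chi^2_{k-1}$. No small-$k$
correction (no Knapp–Hartung) is applied: with three studies the plain Wald
pooling matches the symmetric intervals this analysis style reports. A
single study passes through unchanged. The implementation is checked
against an independently coded oracle to 1e-10 and against
`metafor::rma(method = "DL")`. Multiple testing across the three
copy-number loci uses Bonferroni with m = 3 (`bonferroni_correct()`).

## Haplotypes

Genome-scale statistical phasing is deliberately out of scope: the
conditioning panel is four SNPs (rs429608, rs114190211, rs204993,
rs142511358), for which the classical EM for unphased multilocus genotypes
is exact enough and dependency-free. The E-step enumerates all ordered
diplotypes compatible with each genotype (missing sites are summed over),
the M-step re-estimates frequencies from expected counts; the
log-likelihood is checked to be non-decreasing at every iteration and
convergence is declared below 1e-8. Initialization is the
linkage-equilibrium product of allele frequencies, which is deterministic.
Haplotypes under 1% frequency are collapsed into an `other` bin for
reporting.

Because the phase of the CNV against the SNP haplotypes is not observed,
the per-haplotype copy load is estimated by a no-intercept least-squares
regression of diploid copy number on the posterior-expected haplotype
dosages: with additive haploid contributions, coefficient $k$ is the mean
number of copies carried per copy of haplotype $k$, and since dosages sum
to 2 per sample, twice the frequency-weighted sum of the coefficients
equals the population mean diploid copy number (asserted to 1e-6). A
carrier-weighted mean is provided for comparison
(`method = "carrier"`) but the regression is the contract: it is the unique
linear estimand consistent with additive haploid contributions.
Posterior-expected (fractional) dosages, rather than best-guess phases, are
used in all regressions so phase uncertainty propagates.

## The synthetic-data generator

`sim_config()` fixes the study conditions; the defaults are the conditions
the analysis assumes, chosen once and documented here:

* **Cohort**: 1536 cases / 1109 controls across three studies with sampling
  fractions 0.392 / 0.352 / 0.256 (the relative sizes of the three
  contributing studies), case subtype mix GA 0.30 / NV 0.59 / GA+NV 0.11,
  age ~ N(74, 8²) years clipped to 40–99, 58% female.
* **Copy numbers** are generated per haploid genome — one CNV allele per
  SNP haplotype, drawn jointly from the haplotype table — and summed to
  diploid, which makes the haplotype–copy-number linkage coherent by
  construction. The published analysis observes only diploid totals, and no
  population copy-number table is reproduced with it, so the haploid
  frequencies are documented placeholders calibrated to the field's known
  diploid landscape: modes at C4A = 2, C4B = 2, total = 4, C4A range 0–5
  (diploid draws above 5 are rejected; probability ≈ 5e-4), C4B range 0–4,
  homozygous-deletion rates of ~2%. The default haplotype table (six
  haplotypes over the four conditioning SNPs) reproduces the published
  tagging structure — the adverse haplotype carries the rs204993 risk
  allele and a low mean C4A load (0.78 haploid copies), the protective one
  the rs429608 allele and a high load (1.60) — with otherwise synthetic
  allele patterns that do not claim to be the real ones.
* **Disease**: logit P(case) = 0.8 + ln(0.81)·C4A + 0.03·(age − 74) +
  0.1·female + study shift, i.e. the generating per-copy odds ratio is the
  0.81 the analysis is designed to recover. Case/control status is sampled
  by rejection from this population model until the quotas are met —
  simpler than retrospective inversion and adequate at this scale — and the
  refit is unbiased because acceptance depends only on status.
* **Peaks**: height = 1000 · (copies/2) · study batch scale · per-sample
  run intensity (lognormal, CV 0.15) · per-peak lognormal noise with
  CV 0.04. Multiplicative lognormal noise gives the unimodal, symmetric,
  strictly positive dosage clusters seen in real MLPA QC plots; the
  per-sample factor exists precisely so that the ratio normalization has
  something real to cancel. Control loci always carry 2 copies. Setting
  `omit_ex30_study` emulates a failed total-C4 probe for one study.

What the generator does **not** emulate: ligation-site polymorphisms that
miscall deletions (the motivation for the confirmation worklist), probe
cross-hybridization between the >99%-identical isotypes, plate-level (as
opposed to study-level) batch structure, linkage disequilibrium beyond the
four-SNP panel, and any sequence-level features of the locus. Passing
recovery tests on this generator therefore demonstrates that the pipeline's
inference chain is correct under its stated observation model, not that the
assay itself is artifact-free.

## Numerical and design choices

* Spacing grid: s ∈ [0.75, 1.30]/anchor in steps of 0.002/anchor, then
  alternating least squares to convergence (1e-12).
* Boundary ties round half *down* (toward deletion, which the worklist
  catches); `round_half_down` avoids banker's rounding.
* EM: tolerance 1e-8 on the log-likelihood, cap 500 iterations, ≤8 SNPs.
* Problem sizes in the tests: recovery simulations use 200 replicates at
  the full 1536/1109 design, 1000 null cohorts of 600, and calling
  recovery at n = 500 — sizes at which the Monte-Carlo error of each
  asserted quantity is several times smaller than its tolerance.
* Determinism: every stochastic stage is driven by `sim_config(seed=)`;
  `simulate_peaks` uses the derived sub-seed `seed + 1` so reruns are
  byte-identical without sharing the cohort stage's stream. The analysis
  stages are deterministic given their inputs.

## Known limitations

The equispaced-center model assumes a single shared spacing per locus and
batch; strong differential amplification between copy-number classes would
violate it (real pipelines mitigate this with reference-trace calibration,
which is out of scope here). The EM phaser is exponential in SNP count and
intentionally capped at 8 sites. Conditional models treat SNP dosages as
fixed and error-free. The structure guard is a significance test: in very
small batches (near the 30-sample floor) it has limited power against
smears.

## A worked run

```{r demo, eval = FALSE}
cfg <- sim_config(n_cases = 300, n_controls = 250, seed = 42,
                  omit_ex30_study = "AUS")
sim <- simulate_cohort(cfg)
peaks <- simulate_peaks(sim$truth, cfg)
geno <- simulate_linked_snps(sim$truth, cfg)
bundle <- run_pipeline(peaks, sim$cohort, geno, out_dir = "c4_demo")
writeLines(render_report(bundle)[1:20])
```

The README shows the numbers a run like this prints and how to read them.
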