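# c4cnv

Multiallelic copy-number genotyping and case-control association for the
complement **C4** locus from MLPA peak-height data.

The C4 gene region is a multiallelic copy-number variant: individuals carry
0–5 diploid copies of the C4A isotype and 0–4 of C4B (modes: 2, 2, and 4
total). In age-related macular degeneration (AMD), each additional C4A copy
is protective, and the question of interest is whether that protection is
independent of the strong known AMD signals in the neighboring CFB/C2
region. `c4cnv` implements the full analysis chain as a tested R package:

1. **Dosage normalization** — each MLPA test-probe peak height is divided
   by the summed control-probe heights (EP300 + CREBBP), then by the batch
   median: `d = (h_test / (h_EP300 + h_CREBBP)) / median(ratios)`.
2. **Integer copy-number calling** — dosages cluster at equispaced centers
   `k·s`; the spacing is fitted per batch, the most populous subgroup is
   anchored to the modal copy number, zero calls are flagged as suspected
   homozygous deletions, and a case/control differential-bias QC (Welch
   test on modal-class raw dosages) guards against genotyping artifacts.
3. **Association** — logistic regression with additive copy-number coding
   (`logit P(case) = β₀ + β·CN + covariates`), adjusted for age, sex and
   study, with stratified (age <71 / 71–78 / >78, sex, disease subtype) and
   SNP-conditioned variants.
4. **Meta-analysis** — DerSimonian–Laird random-effects pooling of
   per-study log odds ratios with Q, τ², I², and Bonferroni correction
   across the three loci (m = 3).
5. **Haplotypes** — EM reconstruction of the 4-SNP CFB/C2 haplotypes
   (rs429608, rs114190211, rs204993, rs142511358), average C4A copies per
   haplotype via no-intercept regression on posterior haplotype dosages,
   haplotype association and haplotype-conditioned copy-number models.
6. **Synthetic data** — a generator that emulates the whole observation
   model (haplotype-linked haploid copy numbers, lognormal peak noise,
   batch effects, a logistic disease model with per-copy OR 0.81) so every
   stage is testable against known truth.

See the vignette (`vignettes/c4-copy-number-association.Rmd`) for the
methods, parameter meanings, and design decisions.

## Worked example

```r
library(c4cnv)

cfg   <- sim_config(n_cases = 300, n_controls = 250, seed = 42,
                    omit_ex30_study = "AUS")   # AUS total-C4 probe fails
sim   <- simulate_cohort(cfg)
peaks <- simulate_peaks(sim$truth, cfg)
geno  <- simulate_linked_snps(sim$truth, cfg)

bundle <- run_pipeline(peaks, sim$cohort, geno, out_dir = "c4_demo")
```

The consolidated report (`c4_demo/report.txt`) contains, among other
tables, the headline forest table:

```
-- Headline meta-analyses (adjusted, all samples) --
Locus C4A (adjusted, stratum all)
  study              OR     lo95     hi95
  AUS             0.719    0.527    0.979
  MUE/TUE         0.453    0.275    0.745
  WUE             0.582    0.406    0.833
  pooled(RE)      0.607    0.476    0.773   p=5.31e-05 p_corr=0.000159
  Q=2.520 df=2 p_het=0.284 I2=20.6% tau2=0.0098
```

Each study row is the per-study adjusted logistic fit (OR per C4A copy
with 95% CI); the pooled row is the random-effects combination, with its
Bonferroni-corrected p (three loci tested); Q/I²/τ² quantify between-study
heterogeneity. ORs below 1 mean each additional C4A copy lowers disease
odds — at this small demo size the point estimate (0.61) scatters around
the generating value 0.81, which the recovery simulations pin down
precisely (see below). The haplotype report from the same run:

```
 label pattern       freq mean_c4a_copies
    H1    0000 0.33391225       1.0899478
    H2    0010 0.25090909       0.8190209
    H3    1000 0.22063320       1.5638071
    H4    0001 0.08818182       1.0407092
    H5    0100 0.07426956       1.0242712
    H6    1100 0.03209407       1.0891251
```

`freq` is the EM haplotype frequency; `mean_c4a_copies` the average haploid
C4A copies carried per haplotype copy — low on the adverse haplotype H2
(tagged by the rs204993 risk allele; generated at 0.78) and high on the
protective H3 (rs429608; generated at 1.60).

A thin command-line wrapper covering simulate / run / summary lives at
`inst/scripts/c4pipe.R`.

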