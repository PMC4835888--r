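small_cfg <- function(...) calling_config(min_batch_n = 3L, ...)

test_that("the hand-partitioned dosage example is called {1,1,2,2,2,3}", {
  d <- make_dosage_df(d_c4a = c(0.49, 0.51, 1.00, 1.01, 0.99, 1.52))
  for (m in c("equispaced", "gap")) {
    calls <- call_integer_cn(d, "C4A", small_cfg(method = m))
    expect_equal(calls$cn, c(1L, 1L, 2L, 2L, 2L, 3L), info = m)
  }
})

test_that("zero dosage is called 0 and flagged as suspected homozygous deletion", {
  d <- make_dosage_df(d_c4a = c(0, 0.52, 1.01, 0.99, 1.00, 1.49))
  calls <- call_integer_cn(d, "C4A", small_cfg())
  expect_equal(calls$cn[1], 0L)
  expect_match(calls$flags[1], "suspected_homozygous_deletion")
  wl <- flag_homozygous_deletions(calls)
  expect_equal(wl$sample_id, "S001")
  expect_equal(nrow(flag_homozygous_deletions(calls[-1, ])), 0)
})

test_that("integer calling recovers truth at noise CV 0.04 and degrades gracefully", {
  cfg <- sim_config(n_cases = 250, n_controls = 250, peak_noise_cv = 0.04,
                    study_labels = c(one = 1), seed = 41)
  sim <- simulate_cohort(cfg)
  d <- normalize_dosages(read_peak_table(simulate_peaks(sim$truth, cfg)))
  ca <- merge(call_integer_cn(d, "C4A"), sim$truth[, c("sample_id", "true_c4a")])
  cb <- merge(call_integer_cn(d, "C4B"), sim$truth[, c("sample_id", "true_c4b")])
  expect_gte(mean(ca$cn == ca$true_c4a), 0.99)
  expect_gte(mean(cb$cn == cb$true_c4b), 0.99)

  # at CV 0.10 errors concentrate in low-confidence calls
  cfg2 <- sim_config(n_cases = 250, n_controls = 250, peak_noise_cv = 0.10,
                     study_labels = c(one = 1), seed = 42)
  sim2 <- simulate_cohort(cfg2)
  d2 <- normalize_dosages(read_peak_table(simulate_peaks(sim2$truth, cfg2)))
  ca2 <- merge(call_integer_cn(d2, "C4A"), sim2$truth[, c("sample_id", "true_c4a")])
  hi <- !grepl("low_confidence", ca2$flags)
  expect_gt(mean(ca2$cn[hi] == ca2$true_c4a[hi]),
            mean(ca2$cn[!hi] == ca2$true_c4a[!hi]))
  expect_gte(mean(ca2$cn[hi] == ca2$true_c4a[hi]), 0.95)
})

test_that("called totals are consistent with isoform sums for confident measured calls", {
  cfg <- sim_config(n_cases = 300, n_controls = 300, peak_noise_cv = 0.04,
                    study_labels = c(one = 1), seed = 43)
  sim <- simulate_cohort(cfg)
  d <- normalize_dosages(read_peak_table(simulate_peaks(sim$truth, cfg)))
  calls <- rbind(call_integer_cn(d, "C4A"), call_integer_cn(d, "C4B"),
                 call_integer_cn(d, "totalC4"))
  wide <- reshape(as.data.frame(calls)[, c("sample_id", "locus", "cn", "flags")],
                  idvar = "sample_id", timevar = "locus", direction = "wide")
  conf <- !grepl("low_confidence", wide$flags.C4A) &
    !grepl("low_confidence", wide$flags.C4B) &
    !grepl("low_confidence", wide$flags.totalC4)
  agree <- wide$cn.totalC4 == wide$cn.C4A + wide$cn.C4B
  expect_gte(mean(agree[conf]), 0.99)
})

test_that("higher dosage never receives a lower integer within a batch", {
  set.seed(6)
  for (m in c("equispaced", "gap")) {
    k <- sample(0:4, 80, replace = TRUE, prob = c(0.05, 0.2, 0.45, 0.25, 0.05))
    d <- make_dosage_df(d_c4a = pmax(0, k / 2 + rnorm(80, 0, 0.04)))
    calls <- call_integer_cn(d, "C4A", calling_config(method = m))
    expect_true(all(diff(calls$cn[order(calls$dosage)]) >= 0), info = m)
  }
})

test_that("the most populous subgroup is anchored to the configured modal integer", {
  set.seed(61)
  # modal cluster at dosage 1 with satellites at 0.5 and 1.5
  d <- make_dosage_df(d_c4a = c(rnorm(60, 1, 0.02), rnorm(15, 0.5, 0.02),
                                rnorm(15, 1.5, 0.02)))
  calls2 <- call_integer_cn(d, "C4A", calling_config(anchors = c(C4A = 2L)))
  expect_equal(as.integer(names(which.max(table(calls2$cn)))), 2L)
  cfg3 <- calling_config(anchors = c(C4A = 3L, C4B = 2L, totalC4 = 4L))
  calls3 <- call_integer_cn(d, "C4A", cfg3)
  expect_equal(as.integer(names(which.max(table(calls3$cn)))), 3L)
})

test_that("tiny batches and structureless dosages are refused", {
  expect_error(call_integer_cn(make_dosage_df(d_c4a = c(1, 1, 1)), "C4A"),
               "refused")
  set.seed(62)
  smear <- make_dosage_df(d_c4a = runif(200, 0.4, 1.6))
  expect_error(call_integer_cn(smear, "C4A"), "no discernible")
})

test_that("homozygous-deletion worklist size tracks the generating deletion rate", {
  # haploid P(0) = 0.1 so diploid deletions occur at about 1%
  tab <- default_haplotype_table()
  probs <- matrix(rep(c(0.10, 0.66, 0.22, 0.02), each = 6), 6, 4)
  tab[, paste0("c4a_p", 0:3)] <- probs
  cfg <- sim_config(n_cases = 500, n_controls = 500, snp_haplotype_table = tab,
                    study_labels = c(one = 1), seed = 44)
  sim <- simulate_cohort(cfg)
  d <- normalize_dosages(read_peak_table(simulate_peaks(sim$truth, cfg)))
  wl <- flag_homozygous_deletions(call_integer_cn(d, "C4A"))
  expect_gte(nrow(wl), qbinom(0.005, 1000, 0.01))
  expect_lte(nrow(wl), qbinom(0.995, 1000, 0.01))
})

test_that("bias QC is calibrated under the null and detects an injected shift", {
  set.seed(71)
  pnull <- replicate(400, {
    calls <- make_calls(rep(2L, 120), dosage = rnorm(120, 1, 0.04))
    cohort <- make_cohort(rep(c("case", "control"), each = 60))
    dosage_bias_qc(calls, cohort)$p[1]
  })
  expect_gt(mean(pnull < 0.05), 0.02)
  expect_lt(mean(pnull < 0.05), 0.09)

  hits <- replicate(60, {
    dos <- c(rnorm(400, 1.05, 0.04), rnorm(400, 1, 0.04))
    calls <- make_calls(rep(2L, 800), dosage = dos)
    cohort <- make_cohort(rep(c("case", "control"), each = 400))
    dosage_bias_qc(calls, cohort)$p[1] < 0.01
  })
  expect_gte(mean(hits), 0.95)

  # identical groups: difference exactly 0; tiny groups: not testable
  calls <- make_calls(rep(2L, 8), dosage = rep(c(1, 1.1, 0.9, 1), 2))
  cohort <- make_cohort(rep(c("case", "control"), each = 4))
  qc <- dosage_bias_qc(calls, cohort)
  expect_equal(qc$diff[qc$scope == "pooled"], 0)
  qc2 <- dosage_bias_qc(calls[1:5, ], cohort)
  expect_match(qc2$note[qc2$scope == "pooled"], "not testable")
})

test_that("copy-number distribution proportions sum to 1 per group and match the generator", {
  calls <- make_calls(rep(2L, 10))
  cohort <- make_cohort(rep(c("case", "control"), each = 5))
  tab <- cn_distribution_summary(calls, cohort)
  expect_true(all(tab$prop == 1))

  cfg <- sim_config(n_cases = 600, n_controls = 600, per_copy_log_or = 0,
                    study_labels = c(one = 1), seed = 45)
  sim <- simulate_cohort(cfg)
  calls <- truth_calls(sim$truth)
  tab <- cn_distribution_summary(calls, sim$cohort)
  sums <- aggregate(prop ~ locus + study + status, tab, sum)
  expect_equal(sums$prop, rep(1, nrow(sums)), tolerance = 1e-12)
  # controls' distribution tracks the configured diploid marginal
  q <- cfg$cn_freqs_c4a
  dip <- convolve(q, rev(q), type = "open")  # diploid marginal from haploid
  ctrl <- tab[tab$status == "control" & tab$study == "pooled", ]
  for (k in 0:3) {
    obs <- ctrl$prop[ctrl$cn == k]
    obs <- if (length(obs)) obs else 0
    expect_lt(abs(obs - dip[k + 1]), 4 * sqrt(dip[k + 1] * (1 - dip[k + 1]) / 600) + 0.01)
  }
})
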