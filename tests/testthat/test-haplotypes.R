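test_that("one SNP: haplotype frequencies equal allele frequencies exactly", {
  set.seed(111)
  g <- data.frame(sample_id = sprintf("S%03d", 1:200),
                  rs1 = rbinom(200, 2, 0.3))
  hs <- em_haplotype_frequencies(g)
  af <- mean(g$rs1) / 2
  expect_equal(sort(unname(hs$freqs)), sort(c(af, 1 - af)), tolerance = 1e-9)
})

test_that("monomorphic input returns a single haplotype without iterating", {
  g <- data.frame(sample_id = sprintf("S%03d", 1:20), rs1 = 0L, rs2 = 0L)
  hs <- em_haplotype_frequencies(g)
  expect_equal(nrow(hs$table), 1)
  expect_equal(hs$table$freq, 1)
  expect_equal(hs$table$pattern, "00")
})

test_that("two SNPs in complete LD recover the two coupled haplotypes", {
  set.seed(112)
  n <- 150
  a <- rbinom(n, 2, 0.35)
  g <- data.frame(sample_id = sprintf("S%03d", 1:n), rs1 = a, rs2 = a)
  hs <- em_haplotype_frequencies(g)
  top <- hs$table[hs$table$freq > 0.01, ]
  expect_setequal(top$pattern, c("00", "11"))
  af <- mean(a) / 2
  expect_equal(top$freq[top$pattern == "11"], af, tolerance = 1e-6)
})

test_that("EM log-likelihood is non-decreasing and converges", {
  set.seed(113)
  cfg <- sim_config(n_cases = 150, n_controls = 150, seed = 114)
  sim <- simulate_cohort(cfg)
  g <- simulate_linked_snps(sim$truth, cfg)
  hs <- em_haplotype_frequencies(g)
  expect_true(all(diff(hs$loglik) >= -1e-9))
  expect_true(hs$converged)
  expect_equal(sum(hs$table$freq), 1, tolerance = 1e-9)
})

test_that("EM equals brute-force simplex maximization on 2-SNP instances", {
  set.seed(115)
  for (rep in 1:3) {
    n <- 18
    h <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
    f_true <- c(0.4, 0.3, 0.2, 0.1)
    pick <- function() h[sample(4, 1, prob = f_true), ]
    geno <- t(replicate(n, pick() + pick()))
    hs <- em_haplotype_frequencies(as.data.frame(geno))
    est <- setNames(rep(0, 4), c("00", "01", "10", "11"))
    est[hs$table$pattern] <- hs$table$freq
    oracle <- em_brute_force_2snp(geno)
    expect_equal(unname(est), unname(oracle[names(est)]), tolerance = 1e-4)
  }
})

test_that("seeded multi-start agrees with the deterministic start", {
  cfg <- sim_config(n_cases = 150, n_controls = 150, seed = 123)
  sim <- simulate_cohort(cfg)
  g <- simulate_linked_snps(sim$truth, cfg)
  hs1 <- em_haplotype_frequencies(g)
  hs5 <- em_haplotype_frequencies(g, n_starts = 5, start_seed = 7)
  expect_equal(hs5$table$freq, hs1$table$freq, tolerance = 1e-5)
  expect_equal(hs5$table$pattern, hs1$table$pattern)
})

test_that("missing genotypes are summed over rather than dropped", {
  set.seed(116)
  n <- 300
  a1 <- rbinom(n, 1, 0.3); a2 <- rbinom(n, 1, 0.3)
  g <- data.frame(sample_id = sprintf("S%03d", 1:n), rs1 = a1 + a2, rs2 = a1 + a2)
  g$rs2[1:30] <- NA
  hs <- em_haplotype_frequencies(g)
  top <- hs$table[hs$table$freq > 0.02, ]
  expect_setequal(top$pattern, c("00", "11"))
})

test_that("planted haplotype frequencies are recovered within 0.02 at n = 2500", {
  cfg <- sim_config(n_cases = 1250, n_controls = 1250, per_copy_log_or = 0,
                    seed = 117)
  sim <- simulate_cohort(cfg)
  g <- simulate_linked_snps(sim$truth, cfg)
  hs <- em_haplotype_frequencies(g)
  tab <- cfg$snp_haplotype_table
  pat <- apply(as.matrix(tab[, attr(tab, "snps")]), 1, paste, collapse = "")
  for (i in seq_along(pat)) {
    est <- hs$table$freq[hs$table$pattern == pat[i]]
    est <- if (length(est)) est else 0
    expect_lt(abs(est - tab$freq[i]), 0.02)
  }
  expect_equal(nrow(report_haplotypes(hs)[report_haplotypes(hs)$label != "other", ]),
               6)
})

test_that("per-haplotype mean copy number solves constructed identities", {
  # two haplotypes; diploid CN equals the number of H-alt copies carried
  set.seed(118)
  n <- 400
  a1 <- rbinom(n, 1, 0.4); a2 <- rbinom(n, 1, 0.4)
  g <- data.frame(sample_id = sprintf("S%03d", 1:n), rs1 = a1 + a2)
  hs <- em_haplotype_frequencies(g)
  calls <- make_calls(a1 + a2, sample_id = g$sample_id)
  hs <- haplotype_mean_cn(hs, calls)
  tab <- hs$table
  expect_equal(tab$mean_c4a_copies[tab$pattern == "1"], 1, tolerance = 1e-6)
  expect_equal(tab$mean_c4a_copies[tab$pattern == "0"], 0, tolerance = 1e-6)

  # uniform CN 2: every haplotype carries mean 1.0
  calls2 <- make_calls(rep(2L, n), sample_id = g$sample_id)
  hs2 <- haplotype_mean_cn(em_haplotype_frequencies(g), calls2)
  expect_equal(hs2$table$mean_c4a_copies, rep(1, nrow(hs2$table)),
               tolerance = 1e-6)
  # carrier-mean alternative agrees on the uniform fixture
  hs2c <- haplotype_mean_cn(em_haplotype_frequencies(g), calls2,
                            method = "carrier")
  expect_equal(hs2c$table$mean_c4a_copies, rep(1, nrow(hs2c$table)),
               tolerance = 1e-6)
})

test_that("frequency-weighted haplotype copy loads reproduce the population mean", {
  cfg <- sim_config(n_cases = 400, n_controls = 400, seed = 119)
  sim <- simulate_cohort(cfg)
  g <- simulate_linked_snps(sim$truth, cfg)
  hs <- em_haplotype_frequencies(g)
  hs <- haplotype_mean_cn(hs, truth_calls(sim$truth))
  cons <- attr(hs, "consistency")
  expect_equal(unname(cons["weighted"]), unname(cons["mean_cn"]),
               tolerance = 1e-6)
})

test_that("adverse and protective haplotype copy loads are recovered within 0.1", {
  cfg <- sim_config(n_cases = 1250, n_controls = 1250, per_copy_log_or = 0,
                    seed = 120)
  sim <- simulate_cohort(cfg)
  g <- simulate_linked_snps(sim$truth, cfg)
  hs <- haplotype_mean_cn(em_haplotype_frequencies(g), truth_calls(sim$truth))
  tab <- cfg$snp_haplotype_table
  true_means <- hap_table_means(tab)
  pat <- apply(as.matrix(tab[, attr(tab, "snps")]), 1, paste, collapse = "")
  for (i in seq_along(pat)) {
    est <- hs$table$mean_c4a_copies[hs$table$pattern == pat[i]]
    if (length(est) && !is.na(est))
      expect_lt(abs(est - true_means[i]), 0.1)
  }
  # the adverse haplotype carries fewer copies than the protective one
  h2 <- hs$table$mean_c4a_copies[hs$table$pattern == "0010"]
  h3 <- hs$table$mean_c4a_copies[hs$table$pattern == "1000"]
  expect_lt(h2, h3)
})

test_that("haplotype association is null-calibrated and finds planted effects", {
  set.seed(121)
  cover <- replicate(120, {
    n <- 500
    a1 <- rbinom(n, 1, 0.3); a2 <- rbinom(n, 1, 0.3)
    y <- rbinom(n, 1, 0.5)
    cohort <- make_cohort(ifelse(y == 1, "case", "control"),
                          age = rnorm(n, 74, 6))
    g <- data.frame(sample_id = cohort$sample_id, rs1 = a1 + a2)
    hs <- em_haplotype_frequencies(g)
    res <- haplotype_association(hs, cohort, covariates = c("age", "sex"))
    row <- res[which(hs$table$pattern[match(res$haplotype, hs$table$label)] == "1"), ]
    row$ci_low <= 1 && row$ci_high >= 1
  })
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)

  signs <- replicate(25, {
    n <- 2600
    a1 <- rbinom(n, 1, 0.25); a2 <- rbinom(n, 1, 0.25)
    y <- rbinom(n, 1, plogis(0.2 - 0.3 * (a1 + a2)))
    cohort <- make_cohort(ifelse(y == 1, "case", "control"),
                          age = rnorm(n, 74, 6))
    g <- data.frame(sample_id = cohort$sample_id, rs1 = a1 + a2)
    hs <- em_haplotype_frequencies(g)
    res <- haplotype_association(hs, cohort, covariates = c("age", "sex"))
    row <- res[which(hs$table$pattern[match(res$haplotype, hs$table$label)] == "1"), ]
    row$beta < 0 && row$p < 0.05
  })
  expect_gte(mean(signs), 0.95)
})

test_that("conditioning on a tagging haplotype attenuates the copy-number estimate", {
  set.seed(122)
  n <- 2500
  # the alt haplotype carries the copies AND drives disease
  a1 <- rbinom(n, 1, 0.35); a2 <- rbinom(n, 1, 0.35)
  flip <- function(a) ifelse(runif(n) < 0.92, a, 1 - a)
  cn <- flip(a1) + flip(a2)
  y <- rbinom(n, 1, plogis(0.3 - 0.45 * (a1 + a2)))
  cohort <- make_cohort(ifelse(y == 1, "case", "control"), age = rnorm(n, 74, 6))
  g <- data.frame(sample_id = cohort$sample_id, rs1 = a1 + a2)
  calls <- make_calls(cn, sample_id = cohort$sample_id)
  hs <- em_haplotype_frequencies(g)
  lab_tag <- hs$table$label[hs$table$pattern == "1"]
  uncond <- fit_cn_logistic(cohort, calls, "C4A", covariates = character(0))
  cond <- cn_conditioned_on_haplotype(cohort, calls, hs, lab_tag,
                                      covariates = character(0))
  expect_lt(abs(cond$beta), abs(uncond$beta))
  # conditioning on a haplotype from an unlinked SNP panel changes nothing
  g_un <- data.frame(sample_id = cohort$sample_id,
                     rs8 = rbinom(n, 1, 0.4) + rbinom(n, 1, 0.4),
                     rs9 = rbinom(n, 1, 0.3) + rbinom(n, 1, 0.3))
  hs_un <- em_haplotype_frequencies(g_un)
  cond_un <- cn_conditioned_on_haplotype(cohort, calls, hs_un,
                                         hs_un$table$label[1],
                                         covariates = character(0))
  expect_lt(abs(cond_un$beta - uncond$beta), 0.05)
})
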