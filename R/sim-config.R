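#' Default SNP-haplotype table linking CFB/C2 haplotypes to haploid C4A copies
#'
#' Six synthetic haplotypes over the four conditioning SNPs (rs429608,
#' rs114190211, rs204993, rs142511358). Allele patterns and frequencies are
#' illustrative defaults, not estimates of the real haplotypes: the real
#' allele patterns are only partially characterized (the adverse haplotype is
#' tagged by the rs204993 risk allele, the protective one by the rs429608
#' protective allele), and that tagging structure is what the defaults
#' reproduce. Each haplotype carries a distribution over haploid C4A copies
#' (0-3); the adverse haplotype H2 has a low mean haploid copy load, the
#' protective haplotype H3 a high one.
#'
#' @return data.frame with columns `label`, one 0/1 column per SNP, `freq`,
#'   and `c4a_p0`..`c4a_p3` (per-haplotype haploid C4A copy distribution).
#' @export
default_haplotype_table <- function() {
  snps <- c("rs429608", "rs114190211", "rs204993", "rs142511358")
  tab <- data.frame(
    label = paste0("H", 1:6),
    rs429608    = c(0L, 0L, 1L, 0L, 0L, 1L),
    rs114190211 = c(0L, 0L, 0L, 0L, 1L, 1L),
    rs204993    = c(0L, 1L, 0L, 0L, 0L, 0L),
    rs142511358 = c(0L, 0L, 0L, 1L, 0L, 0L),
    freq = c(0.35, 0.25, 0.20, 0.10, 0.06, 0.04),
    stringsAsFactors = FALSE
  )
  probs <- rbind(
    c(0.12, 0.76, 0.12, 0.00),  # H1 baseline
    c(0.30, 0.62, 0.08, 0.00),  # H2 adverse: low C4A load
    c(0.00, 0.45, 0.50, 0.05),  # H3 protective: high C4A load
    c(0.12, 0.76, 0.12, 0.00),  # H4
    c(0.15, 0.75, 0.10, 0.00),  # H5
    c(0.10, 0.70, 0.15, 0.05)   # H6
  )
  colnames(probs) <- paste0("c4a_p", 0:3)
  stopifnot(all(abs(rowSums(probs) - 1) < 1e-12))
  out <- cbind(tab, probs)
  attr(out, "snps") <- snps
  out
}

hap_snp_cols <- function(tab) {
  attr(tab, "snps") %||% setdiff(names(tab), c("label", "freq", grep("^c4a_p", names(tab), value = TRUE)))
}

hap_c4a_probs <- function(tab) {
  as.matrix(tab[, grep("^c4a_p", names(tab), value = TRUE), drop = FALSE])
}

#' Simulation configuration for synthetic C4 CNV cohorts
#'
#' Collects the generative quantities for [simulate_cohort()],
#' [simulate_peaks()] and [simulate_linked_snps()]: cohort composition,
#' haploid copy-number frequencies, the additive logistic disease model,
#' the MLPA peak observation model, and the SNP-haplotype linkage table.
#'
#' Copy numbers are generated per haploid genome (one CNV allele per
#' haplotype) and summed to diploid, so the haplotype-copy-number linkage is
#' coherent by construction. Haploid C4A copies are drawn per haplotype from
#' `snp_haplotype_table`; the implied haploid marginal must match
#' `cn_freqs_c4a` (it is derived from the table when left `NULL`).
#'
#' The disease model is
#' `logit P(case) = baseline_logit + per_copy_log_or * C4A +
#'  beta_age * (age - age_mean) + beta_sex * female + study_logit[study]`,
#' and case/control status is sampled by rejection until the requested counts
#' are reached.
#'
#' @param n_cases,n_controls requested cohort sizes (defaults: the three-study
#'   design of 1536 cases and 1109 controls).
#' @param study_labels named numeric vector of per-study sampling fractions.
#' @param snp_haplotype_table haplotype table as from
#'   [default_haplotype_table()].
#' @param cn_freqs_c4a haploid C4A copy distribution over 0..3; `NULL` derives
#'   it from the haplotype table. If supplied it is validated against the
#'   table's mixture.
#' @param cn_freqs_c4b haploid C4B copy distribution over 0..2.
#' @param per_copy_log_or log odds ratio per diploid C4A copy
#'   (default `log(0.81)`, protective).
#' @param baseline_logit logit of disease at the mean age, male, zero C4A
#'   copies.
#' @param beta_age,beta_sex covariate effects (per year; female vs male).
#' @param age_mean,age_sd age distribution in years (normal, clipped to
#'   40-99).
#' @param study_logit optional named per-study logit shifts (default 0).
#' @param subtype_probs late-stage subtype distribution among cases.
#' @param peak_noise_cv coefficient of variation of the multiplicative
#'   lognormal per-peak noise.
#' @param sample_scale_cv CV of the per-sample run-intensity factor (applies
#'   to all five probes of a sample and cancels in the ratio normalization).
#' @param batch_scale optional named per-study multiplicative peak scale.
#' @param base_height peak height of a two-copy probe at unit scales.
#' @param omit_ex30_study optional study label whose C4-ex30 peaks are
#'   omitted, emulating a failed total-C4 probe.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cases = 1536, n_controls = 1109,
                       study_labels = c(AUS = 0.392, WUE = 0.352, "MUE/TUE" = 0.256),
                       snp_haplotype_table = default_haplotype_table(),
                       cn_freqs_c4a = NULL,
                       cn_freqs_c4b = c(0.15, 0.72, 0.13),
                       per_copy_log_or = log(0.81),
                       baseline_logit = 0.8,
                       beta_age = 0.03,
                       beta_sex = 0.1,
                       age_mean = 74, age_sd = 8,
                       study_logit = NULL,
                       subtype_probs = c(GA = 0.30, NV = 0.59, "GA+NV" = 0.11),
                       peak_noise_cv = 0.04,
                       sample_scale_cv = 0.15,
                       batch_scale = NULL,
                       base_height = 1000,
                       omit_ex30_study = NULL,
                       seed = NULL) {
  if (!is_count(n_cases) || !is_count(n_controls))
    stop_c4("n_cases and n_controls must be positive integers")
  check_prob_vector(study_labels, "study_labels")
  if (is.null(names(study_labels))) stop_c4("study_labels must be named")
  tab <- snp_haplotype_table
  check_prob_vector(tab$freq, "snp_haplotype_table$freq")
  probs <- hap_c4a_probs(tab)
  if (any(abs(rowSums(probs) - 1) > 1e-9))
    stop_c4("per-haplotype C4A copy distributions must each sum to 1")
  mixture <- as.numeric(colSums(tab$freq * probs))
  if (is.null(cn_freqs_c4a)) {
    cn_freqs_c4a <- mixture
  } else {
    check_prob_vector(cn_freqs_c4a, "cn_freqs_c4a")
    if (length(cn_freqs_c4a) != length(mixture) ||
        any(abs(cn_freqs_c4a - mixture) > 1e-6))
      stop_c4(paste0(
        "cn_freqs_c4a is inconsistent with the haplotype table: the ",
        "frequency-weighted mixture of per-haplotype copy distributions is (",
        paste(sprintf("%.4f", mixture), collapse = ", "), ")"))
  }
  check_prob_vector(cn_freqs_c4b, "cn_freqs_c4b")
  check_prob_vector(subtype_probs, "subtype_probs")
  if (peak_noise_cv < 0) stop_c4("peak_noise_cv must be >= 0")
  if (sample_scale_cv < 0) stop_c4("sample_scale_cv must be >= 0")
  studies <- names(study_labels)
  study_logit <- study_logit %||% stats::setNames(rep(0, length(studies)), studies)
  batch_scale <- batch_scale %||% stats::setNames(rep(1, length(studies)), studies)
  if (!all(studies %in% names(study_logit)) || !all(studies %in% names(batch_scale)))
    stop_c4("study_logit and batch_scale must cover every study label")
  if (!is.null(omit_ex30_study) && !omit_ex30_study %in% studies)
    stop_c4("omit_ex30_study '%s' is not a study label", omit_ex30_study)
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    study_labels = study_labels,
    snp_haplotype_table = tab,
    cn_freqs_c4a = cn_freqs_c4a, cn_freqs_c4b = cn_freqs_c4b,
    per_copy_log_or = per_copy_log_or,
    baseline_logit = baseline_logit,
    beta_age = beta_age, beta_sex = beta_sex,
    age_mean = age_mean, age_sd = age_sd,
    study_logit = study_logit[studies],
    subtype_probs = subtype_probs,
    peak_noise_cv = peak_noise_cv, sample_scale_cv = sample_scale_cv,
    batch_scale = batch_scale[studies],
    base_height = base_height,
    omit_ex30_study = omit_ex30_study,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}
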