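# draw m individuals from the population model (no case/control quota yet)
draw_individuals <- function(m, config, id_offset = 0L) {
  tab <- config$snp_haplotype_table
  H <- nrow(tab)
  probs <- hap_c4a_probs(tab)
  studies <- names(config$study_labels)

  study <- sample(studies, m, replace = TRUE, prob = config$study_labels)
  hap1 <- sample.int(H, m, replace = TRUE, prob = tab$freq)
  hap2 <- sample.int(H, m, replace = TRUE, prob = tab$freq)
  draw_c4a <- function(hap) {
    out <- integer(m)
    u <- stats::runif(m)
    for (h in seq_len(H)) {
      idx <- hap == h
      if (any(idx)) out[idx] <- findInterval(u[idx], cumsum(probs[h, ]), left.open = TRUE)
    }
    out
  }
  h1_c4a <- draw_c4a(hap1)
  h2_c4a <- draw_c4a(hap2)
  kb <- length(config$cn_freqs_c4b) - 1L
  h1_c4b <- sample(0:kb, m, replace = TRUE, prob = config$cn_freqs_c4b)
  h2_c4b <- sample(0:kb, m, replace = TRUE, prob = config$cn_freqs_c4b)

  age <- pmin(99, pmax(40, stats::rnorm(m, config$age_mean, config$age_sd)))
  sex <- ifelse(stats::runif(m) < 0.58, "female", "male")

  true_c4a <- h1_c4a + h2_c4a
  true_c4b <- h1_c4b + h2_c4b
  lp <- config$baseline_logit +
    config$per_copy_log_or * true_c4a +
    config$beta_age * (age - config$age_mean) +
    config$beta_sex * (sex == "female") +
    unname(config$study_logit[study])
  status <- ifelse(stats::runif(m) < stats::plogis(lp), "case", "control")

  data.frame(
    study = study, hap1 = hap1, hap2 = hap2,
    h1_c4a = h1_c4a, h2_c4a = h2_c4a,
    true_c4a = true_c4a, true_c4b = true_c4b,
    age = age, sex = sex, status = status,
    stringsAsFactors = FALSE
  )
}

#' Simulate a case-control cohort with known C4 copy-number truth
#'
#' Draws individuals from the haplotype-linked haploid copy-number model and
#' the additive logistic disease model of a [sim_config()], by rejection,
#' until exactly `n_cases` cases and `n_controls` controls are collected.
#' Individuals whose diploid C4A count would exceed 5 are rejected and
#' redrawn (a rare event under the defaults), keeping calls within the
#' observed 0-5 (C4A) and 0-4 (C4B) ranges.
#'
#' @param config a [sim_config()].
#' @return list with components `truth` (per-sample true copy numbers,
#'   haplotype pair and haploid copy loads; never consumed by the analysis
#'   stages outside of tests) and `cohort` (the observable phenotype table:
#'   `sample_id`, `status`, `subtype`, `age`, `sex`, `study`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  need_case <- config$n_cases
  need_ctrl <- config$n_controls
  n_target <- need_case + need_ctrl
  max_draws <- 200L * n_target
  drawn <- 0L
  kept <- vector("list", 0L)
  n_case_seen <- 0L; n_ctrl_seen <- 0L
  while (need_case > 0L || need_ctrl > 0L) {
    if (drawn >= max_draws)
      stop_c4(paste0(
        "could not reach %d cases / %d controls after %d draws ",
        "(accepted %d cases, %d controls); the disease model logits are ",
        "likely degenerate"), config$n_cases, config$n_controls, drawn,
        config$n_cases - need_case, config$n_controls - need_ctrl)
    m <- min(max(2L * (need_case + need_ctrl), 500L), max_draws - drawn)
    blk <- draw_individuals(m, config)
    drawn <- drawn + m
    blk <- blk[blk$true_c4a <= 5L, , drop = FALSE]  # reject out-of-range diploids
    is_case <- blk$status == "case"
    take_case <- which(is_case)[seq_len(min(need_case, sum(is_case)))]
    take_ctrl <- which(!is_case)[seq_len(min(need_ctrl, sum(!is_case)))]
    keep <- sort(c(take_case, take_ctrl))
    need_case <- need_case - length(take_case)
    need_ctrl <- need_ctrl - length(take_ctrl)
    kept[[length(kept) + 1L]] <- blk[keep, , drop = FALSE]
  }
  all <- do.call(rbind, kept)
  rownames(all) <- NULL
  all$sample_id <- sprintf("S%05d", seq_len(nrow(all)))

  labels <- config$snp_haplotype_table$label
  subtype <- rep("none", nrow(all))
  case_idx <- all$status == "case"
  subtype[case_idx] <- sample(names(config$subtype_probs), sum(case_idx),
                              replace = TRUE, prob = config$subtype_probs)

  truth <- data.frame(
    sample_id = all$sample_id,
    true_c4a = as.integer(all$true_c4a),
    true_c4b = as.integer(all$true_c4b),
    true_total = as.integer(all$true_c4a + all$true_c4b),
    hap1 = labels[all$hap1], hap2 = labels[all$hap2],
    haplotype_pair = paste(labels[all$hap1], labels[all$hap2], sep = "/"),
    h1_c4a = as.integer(all$h1_c4a), h2_c4a = as.integer(all$h2_c4a),
    status = all$status, subtype = subtype,
    age = all$age, sex = all$sex, study = all$study,
    stringsAsFactors = FALSE
  )
  cohort <- truth[, c("sample_id", "status", "subtype", "age", "sex", "study")]
  list(truth = truth, cohort = cohort)
}

#' Simulate MLPA peak heights from true copy numbers
#'
#' Generates one peak per sample and probe among C4A, C4B, C4-ex30 and the
#' two-copy control loci EP300 and CREBBP:
#' `height = base_height * (copies / 2) * batch_scale[study] * sample_scale *
#'  lognormal(1, peak_noise_cv)`,
#' where `sample_scale` is a per-sample run-intensity factor shared by all
#' five probes (it cancels in the control-probe ratio, which is why the
#' normalization is ratio-based). A zero copy number yields an absent peak
#' (height exactly 0). If `config$omit_ex30_study` is set, that study's
#' C4-ex30 rows are dropped, emulating a failed total-C4 probe whose dosage
#' must later be imputed from the isoform mean.
#'
#' @param truth truth table from [simulate_cohort()].
#' @param config the [sim_config()] used to generate `truth`.
#' @return peak table: `sample_id`, `study`, `probe`, `height`.
#' @export
simulate_peaks <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  # derived sub-seed: reruns are byte-identical, draws are not shared with
  # the cohort stage
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  n <- nrow(truth)
  copies <- cbind("C4A" = truth$true_c4a, "C4B" = truth$true_c4b,
                  "C4-ex30" = truth$true_total, "EP300" = 2L, "CREBBP" = 2L)
  cv <- config$peak_noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  scv <- config$sample_scale_cv
  s_sdlog <- sqrt(log(1 + scv^2))
  sample_scale <- if (scv > 0)
    stats::rlnorm(n, meanlog = -s_sdlog^2 / 2, sdlog = s_sdlog) else rep(1, n)
  noise <- if (cv > 0)
    matrix(stats::rlnorm(n * 5L, meanlog = -sdlog^2 / 2, sdlog = sdlog), n, 5L)
  else matrix(1, n, 5L)
  batch <- unname(config$batch_scale[truth$study])
  heights <- config$base_height * (copies / 2) * batch * sample_scale * noise
  out <- data.frame(
    sample_id = rep(truth$sample_id, times = 5L),
    study = rep(truth$study, times = 5L),
    probe = rep(colnames(copies), each = n),
    height = as.vector(heights),
    stringsAsFactors = FALSE
  )
  if (!is.null(config$omit_ex30_study))
    out <- out[!(out$probe == "C4-ex30" & out$study == config$omit_ex30_study), ,
               drop = FALSE]
  out <- out[order(out$sample_id, match(out$probe, C4_PROBES)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive linked SNP genotypes from simulated haplotype pairs
#'
#' Converts each sample's haplotype pair (drawn jointly with its haploid C4A
#' copies in [simulate_cohort()]) into 0/1/2 allele dosages at the SNPs of
#' the configured haplotype table, so the configured haplotype-copy-number
#' association holds by construction.
#'
#' @param truth truth table from [simulate_cohort()].
#' @param config the matching [sim_config()].
#' @return data.frame: `sample_id` plus one 0/1/2 dosage column per SNP.
#' @export
simulate_linked_snps <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  tab <- config$snp_haplotype_table
  snps <- hap_snp_cols(tab)
  pat <- as.matrix(tab[, snps, drop = FALSE])
  rownames(pat) <- tab$label
  geno <- pat[truth$hap1, , drop = FALSE] + pat[truth$hap2, , drop = FALSE]
  out <- data.frame(sample_id = truth$sample_id, geno,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
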