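#' Per-study and pooled cohort summary
#'
#' The standard characteristics table: per study and pooled, the numbers of
#' cases (total and by late-stage subtype), controls, totals, mean (sd) age
#' of cases and controls, and percent female. Pooled percentages and means
#' are computed from the sample-level data, not by recombining rounded
#' per-study figures.
#'
#' @param cohort cohort table (`sample_id`, `status`, `subtype`, `age`,
#'   `sex`, `study`).
#' @return data.frame, one row per study plus a `"pooled"` row.
#' @export
cohort_summary <- function(cohort) {
  bad <- setdiff(unique(cohort$subtype), c("GA", "NV", "GA+NV", "none"))
  if (length(bad)) stop_c4("unknown subtype label(s): %s", paste(bad, collapse = ", "))
  one <- function(x, label) {
    ca <- x[x$status == "case", ]; co <- x[x$status == "control", ]
    data.frame(
      study = label,
      n_cases = nrow(ca),
      n_ga = sum(ca$subtype == "GA"),
      n_nv = sum(ca$subtype == "NV"),
      n_ga_nv = sum(ca$subtype == "GA+NV"),
      n_controls = nrow(co),
      n_total = nrow(x),
      age_cases_mean = mean(ca$age), age_cases_sd = stats::sd(ca$age),
      age_controls_mean = mean(co$age), age_controls_sd = stats::sd(co$age),
      pct_female_cases = 100 * mean(ca$sex == "female"),
      pct_female_controls = 100 * mean(co$sex == "female"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(sort(unique(cohort$study)),
                               function(s) one(cohort[cohort$study == s, ], s)))
  rbind(out, one(cohort, "pooled"))
}

#' Pool per-study summary rows into a combined row
#'
#' When only per-study summary statistics are available (no sample-level
#' data), the pooled row is formed by summing the counts and taking
#' count-weighted means; pooled standard deviations combine within- and
#' between-study variance, and pooled percentages are count-weighted.
#'
#' @param tbl data.frame of per-study rows in the [cohort_summary()] column
#'   layout.
#' @return one-row data.frame (`study = "pooled"`).
#' @export
pool_study_summaries <- function(tbl) {
  wmean <- function(m, n) sum(m * n) / sum(n)
  wsd <- function(s, m, n) {
    mp <- wmean(m, n)
    sqrt((sum((n - 1) * s^2) + sum(n * (m - mp)^2)) / (sum(n) - 1))
  }
  data.frame(
    study = "pooled",
    n_cases = sum(tbl$n_cases), n_ga = sum(tbl$n_ga), n_nv = sum(tbl$n_nv),
    n_ga_nv = sum(tbl$n_ga_nv), n_controls = sum(tbl$n_controls),
    n_total = sum(tbl$n_total),
    age_cases_mean = wmean(tbl$age_cases_mean, tbl$n_cases),
    age_cases_sd = wsd(tbl$age_cases_sd, tbl$age_cases_mean, tbl$n_cases),
    age_controls_mean = wmean(tbl$age_controls_mean, tbl$n_controls),
    age_controls_sd = wsd(tbl$age_controls_sd, tbl$age_controls_mean, tbl$n_controls),
    pct_female_cases = wmean(tbl$pct_female_cases, tbl$n_cases),
    pct_female_controls = wmean(tbl$pct_female_controls, tbl$n_controls),
    stringsAsFactors = FALSE)
}

#' Read a genotype table (dosage TSV or biallelic VCF)
#'
#' Dosage tables are tab-separated with a `sample_id` column and one 0/1/2
#' column per SNP. VCF input (biallelic records with a GT field) is parsed
#' through the vcfR package; the alternate-allele count becomes the dosage.
#'
#' @param path file path (`.vcf` / `.vcf.gz` triggers VCF parsing).
#' @return data.frame: `sample_id` plus one dosage column per SNP.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop_c4("genotype file '%s' not found", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop_c4("VCF input requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    dose <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_integer_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]))
    })
    ids <- vcfR::getID(v)
    ids[is.na(ids)] <- paste0("var", which(is.na(ids)))
    out <- data.frame(sample_id = colnames(gt), t(dose),
                      check.names = FALSE, stringsAsFactors = FALSE)
    names(out)[-1] <- ids
    rownames(out) <- NULL
    return(out)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop_c4("dosage table needs a sample_id column")
  snp_cols <- setdiff(names(df), "sample_id")
  for (s in snp_cols) {
    v <- df[[s]]
    if (any(!is.na(v) & !(v %in% 0:2)))
      stop_c4("column '%s' has dosages outside 0/1/2", s)
  }
  df
}

#' Read a phenotype/covariate table
#'
#' Tab-separated with columns `sample_id`, `status` (case/control),
#' `subtype` (GA/NV/GA+NV/none), `age`, `sex` (male/female), `study`.
#'
#' @param path TSV file path.
#' @return validated cohort data.frame.
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "status", "subtype", "age", "sex", "study")
  if (!all(need %in% names(df)))
    stop_c4("cohort table needs columns: %s", paste(need, collapse = ", "))
  if (any(!df$status %in% c("case", "control")))
    stop_c4("status must be 'case' or 'control'")
  if (any(df$status == "control" & df$subtype != "none"))
    stop_c4("controls must have subtype 'none'")
  if (any(!is.finite(df$age)) || any(df$age <= 0)) stop_c4("ages must be positive")
  df
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates normalization, copy-number calling, QC, association,
#' meta-analysis and (when genotypes are supplied) the conditional and
#' haplotype analyses; writes each stage's table to `out_dir` and a
#' consolidated plain-text report. A rerun with the same inputs and seed is
#' byte-identical apart from nothing — all stages downstream of the inputs
#' are deterministic.
#'
#' @param peaks peak table (from [read_peak_table()] or [simulate_peaks()]).
#' @param cohort cohort table.
#' @param genotypes optional genotype dosage table; when `NULL`, the
#'   conditional and haplotype stages are skipped with a notice.
#' @param out_dir output directory (created if missing); `NULL` writes
#'   nothing.
#' @param calling a [calling_config()].
#' @param loci loci to analyze.
#' @param strata_schemes stratification schemes to run (see
#'   [stratify_cohort()]).
#' @param m_tests Bonferroni divisor for the headline meta-analysis.
#' @return invisibly, a results bundle: dosages, calls, QC, summary tables,
#'   per-model results, meta results, haplotype outputs and the run log.
#' @export
run_pipeline <- function(peaks, cohort, genotypes = NULL, out_dir = NULL,
                         calling = calling_config(),
                         loci = c("C4A", "C4B", "totalC4"),
                         strata_schemes = c("age3", "sex", "subtype"),
                         m_tests = 3L) {
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))
  say("stage=config package=c4cnv version=%s loci=%s strata=%s m_tests=%d method=%s anchors=%s",
      as.character(utils::packageVersion("c4cnv")),
      paste(loci, collapse = ","),
      if (length(strata_schemes)) paste(strata_schemes, collapse = ",") else "none",
      m_tests, calling$method,
      paste(sprintf("%s=%d", names(calling$anchors), calling$anchors), collapse = ","))

  if (is.data.frame(peaks) && !inherits(peaks, "peak_table"))
    peaks <- read_peak_table(peaks)
  say("stage=input peaks=%d samples=%d", nrow(peaks), length(unique(peaks$sample_id)))

  dosages <- normalize_dosages(peaks)
  dosages <- impute_total_c4(dosages)
  say("stage=dosage samples=%d excluded=%d imputed_totals=%d",
      nrow(dosages), nrow(attr(dosages, "exclusions")),
      sum(dosages$total_source == "imputed-from-mean", na.rm = TRUE))

  calls <- do.call(rbind, lapply(loci, function(loc)
    call_integer_cn(dosages, loc, calling)))
  class(calls) <- c("cn_calls", "data.frame")
  say("stage=calling calls=%d zero_calls=%d", nrow(calls), sum(calls$cn == 0))

  deletions <- flag_homozygous_deletions(calls)
  qc <- dosage_bias_qc(calls, cohort, calling$anchors)
  cn_dist <- cn_distribution_summary(calls, cohort)
  summary_tbl <- cohort_summary(cohort)
  age_cor <- age_cn_correlation(cohort, calls)
  say("stage=qc bias_rows=%d deletion_worklist=%d", nrow(qc), nrow(deletions))

  strata <- list()
  for (sch in strata_schemes) strata[[sch]] <- stratify_cohort(cohort, sch)
  grid_strata <- c(list(all = cohort$sample_id), do.call(c, unname(strata)))

  results <- run_model_grid(cohort, calls, genotypes = NULL, loci = loci,
                            scopes = c("per_study", "pooled"),
                            adjustments = list(crude = character(0),
                                               adjusted = c("age", "sex")),
                            strata = grid_strata)
  meta <- meta_grid(results, m = m_tests)
  say("stage=association models=%d pooled=%d", nrow(results), nrow(meta))

  conditional <- NULL; haps <- NULL; hap_assoc <- NULL; hap_cond <- NULL
  if (!is.null(genotypes)) {
    snps <- setdiff(names(genotypes), "sample_id")
    conditional <- run_model_grid(cohort, calls, genotypes = genotypes,
                                  loci = "C4A", scopes = "pooled",
                                  adjustments = list(adjusted = c("age", "sex")),
                                  conditioning_sets = leave_one_out_sets(snps))
    haps <- em_haplotype_frequencies(genotypes)
    haps <- haplotype_mean_cn(haps, calls, locus = "C4A")
    hap_assoc <- haplotype_association(haps, cohort)
    hap_cond <- do.call(rbind, lapply(
      haps$table$label[haps$table$freq >= 0.01], function(h) {
        res <- tryCatch(cn_conditioned_on_haplotype(cohort, calls, haps, h),
                        error = function(e) conditionMessage(e))
        if (is.character(res))
          data.frame(conditioned_on = h, beta = NA_real_, se = NA_real_,
                     or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                     p = NA_real_, note = res, stringsAsFactors = FALSE)
        else {
          r <- as.data.frame(res)
          data.frame(conditioned_on = h,
                     r[, c("beta", "se", "or", "ci_low", "ci_high", "p")],
                     note = "ok", stringsAsFactors = FALSE)
        }
      }))
    say("stage=haplotypes k=%d conditional_models=%d",
        nrow(haps$table), nrow(conditional))
  } else {
    say("stage=haplotypes skipped: no genotype table supplied")
  }

  bundle <- list(dosages = dosages, calls = calls, deletions = deletions,
                 qc = qc, cn_distribution = cn_dist, summary = summary_tbl,
                 age_correlation = age_cor, results = results, meta = meta,
                 conditional = conditional, haplotypes = haps,
                 haplotype_association = hap_assoc,
                 haplotype_conditional = hap_cond, log = log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(as.data.frame(dosages), file.path(out_dir, "dosages.tsv"))
    write_tsv(as.data.frame(calls), file.path(out_dir, "calls.tsv"))
    write_tsv(deletions, file.path(out_dir, "deletion_worklist.tsv"))
    write_tsv(qc, file.path(out_dir, "dosage_bias_qc.tsv"))
    write_tsv(cn_dist, file.path(out_dir, "cn_distribution.tsv"))
    write_tsv(summary_tbl, file.path(out_dir, "cohort_summary.tsv"))
    write_tsv(age_cor, file.path(out_dir, "age_cn_correlation.tsv"))
    write_tsv(results, file.path(out_dir, "association_results.tsv"))
    write_tsv(meta, file.path(out_dir, "meta_results.tsv"))
    if (!is.null(conditional))
      write_tsv(conditional, file.path(out_dir, "conditional_results.tsv"))
    if (!is.null(haps)) {
      write_tsv(report_haplotypes(haps), file.path(out_dir, "haplotypes.tsv"))
      write_tsv(hap_assoc, file.path(out_dir, "haplotype_association.tsv"))
      write_tsv(hap_cond, file.path(out_dir, "haplotype_conditional.tsv"))
    }
    writeLines(render_report(bundle), file.path(out_dir, "report.txt"))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  invisible(bundle)
}

forest_table <- function(meta_row, per_study) {
  lines <- c(sprintf("Locus %s (%s, stratum %s)", meta_row$locus,
                     meta_row$model, meta_row$stratum),
             sprintf("  %-12s %8s %8s %8s", "study", "OR", "lo95", "hi95"))
  for (i in seq_len(nrow(per_study)))
    lines <- c(lines, sprintf("  %-12s %8.3f %8.3f %8.3f",
                              per_study$scope[i], per_study$or[i],
                              per_study$ci_low[i], per_study$ci_high[i]))
  c(lines,
    sprintf("  %-12s %8.3f %8.3f %8.3f   p=%.3g p_corr=%.3g", "pooled(RE)",
            meta_row$pooled_or, meta_row$ci_low, meta_row$ci_high,
            meta_row$p, meta_row$p_corrected),
    sprintf("  Q=%.3f df=%d p_het=%.3g I2=%.1f%% tau2=%.4f",
            meta_row$q_stat, meta_row$df, meta_row$p_heterogeneity,
            meta_row$i_squared, meta_row$tau_squared), "")
}

#' Render a plain-text consolidated report
#'
#' Deterministic text rendering of a [run_pipeline()] bundle: cohort
#' summary, QC verdicts, a forest table per locus for the headline
#' (adjusted, unstratified) meta-analysis, stratified summaries and the
#' haplotype report. Missing components produce a placeholder notice.
#'
#' @param bundle results bundle from [run_pipeline()].
#' @return character vector of report lines.
#' @export
render_report <- function(bundle) {
  out <- c("== C4 copy-number association pipeline report ==", "")
  out <- c(out, "-- Cohort summary --",
           utils::capture.output(print(bundle$summary, row.names = FALSE)), "")
  out <- c(out, "-- Dosage differential-bias QC (modal-class carriers) --",
           utils::capture.output(print(bundle$qc, row.names = FALSE)), "")
  out <- c(out, "-- Headline meta-analyses (adjusted, all samples) --")
  head_rows <- bundle$meta[bundle$meta$model == "adjusted" &
                             bundle$meta$stratum == "all" &
                             bundle$meta$conditioning == "none", , drop = FALSE]
  if (nrow(head_rows) == 0L) {
    out <- c(out, "  [missing: no headline meta-analysis rows]", "")
  } else {
    for (i in seq_len(nrow(head_rows))) {
      mr <- head_rows[i, ]
      per <- bundle$results[bundle$results$locus == mr$locus &
                              bundle$results$model == "adjusted" &
                              bundle$results$stratum == "all" &
                              bundle$results$scope != "pooled" &
                              bundle$results$note == "ok", , drop = FALSE]
      out <- c(out, forest_table(mr, per))
    }
  }
  strat <- bundle$meta[bundle$meta$stratum != "all", , drop = FALSE]
  if (nrow(strat)) {
    out <- c(out, "-- Stratified pooled estimates --",
             utils::capture.output(print(
               strat[, c("locus", "model", "stratum", "pooled_or",
                         "ci_low", "ci_high", "p")], row.names = FALSE)), "")
  }
  if (!is.null(bundle$haplotypes)) {
    out <- c(out, "-- Haplotypes (>= 1% frequency) --",
             utils::capture.output(print(report_haplotypes(bundle$haplotypes),
                                         row.names = FALSE)), "")
  } else {
    out <- c(out, "-- Haplotypes --", "  [skipped: no genotype table]", "")
  }
  out <- c(out, "-- Age vs copy-number correlation --",
           utils::capture.output(print(bundle$age_correlation, row.names = FALSE)))
  out
}
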