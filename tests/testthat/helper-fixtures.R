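# small in-code fixtures shared across test files

make_dosage_df <- function(d_c4a = NULL, d_c4b = NULL, d_total = NULL,
                           study = "b1") {
  n <- max(length(d_c4a), length(d_c4b), length(d_total))
  out <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    study = rep_len(study, n),
    d_c4a = if (is.null(d_c4a)) NA_real_ else d_c4a,
    d_c4b = if (is.null(d_c4b)) NA_real_ else d_c4b,
    d_total = if (is.null(d_total)) NA_real_ else d_total,
    total_source = if (is.null(d_total)) NA_character_ else "measured",
    stringsAsFactors = FALSE)
  class(out) <- c("dosage_matrix", "data.frame")
  out
}

make_calls <- function(cn, locus = "C4A",
                       sample_id = sprintf("S%03d", seq_along(cn)),
                       study = "b1", dosage = cn / 2, confidence = 1) {
  out <- data.frame(sample_id = sample_id, study = rep_len(study, length(cn)),
                    locus = locus, dosage = dosage, cn = as.integer(cn),
                    confidence = confidence, flags = "",
                    stringsAsFactors = FALSE)
  class(out) <- c("cn_calls", "data.frame")
  out
}

make_cohort <- function(status, age = 70, sex = "female", study = "b1",
                        subtype = NULL) {
  n <- length(status)
  subtype <- subtype %||% ifelse(status == "case", "NV", "none")
  data.frame(sample_id = sprintf("S%03d", seq_len(n)), status = status,
             subtype = subtype, age = rep_len(age, n), sex = rep_len(sex, n),
             study = rep_len(study, n), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 2x2 cohort: a exposed cases, b exposed controls, c unexposed cases,
# d unexposed controls; exposure coded as copy number 1 vs 0
make_2x2 <- function(a, b, c, d) {
  status <- c(rep("case", a), rep("control", b), rep("case", c), rep("control", d))
  cn <- c(rep(1L, a + b), rep(0L, c + d))
  cohort <- make_cohort(status, age = 70 + seq_along(status) %% 7)
  calls <- make_calls(cn, sample_id = cohort$sample_id)
  list(cohort = cohort, calls = calls)
}

# five-probe peak table for hand-specified copy numbers, noise free
make_peaks <- function(c4a, c4b, total = c4a + c4b, study = "b1", base = 1000,
                       sample_scale = 1) {
  n <- length(c4a)
  ids <- sprintf("S%03d", seq_len(n))
  sample_scale <- rep_len(sample_scale, n)
  study <- rep_len(study, n)
  rows <- lapply(seq_len(n), function(i) {
    data.frame(sample_id = ids[i], study = study[i],
               probe = c("C4A", "C4B", "C4-ex30", "EP300", "CREBBP"),
               height = base * sample_scale[i] *
                 c(c4a[i], c4b[i], total[i], 2, 2) / 2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# configured mean haploid C4A copies per haplotype of a haplotype table
hap_table_means <- function(tab) {
  probs <- as.matrix(tab[, paste0("c4a_p", 0:3)])
  as.vector(probs %*% (0:3))
}

# simulated calls straight from truth (bypassing peaks) for association tests
truth_calls <- function(truth, locus = "C4A") {
  col <- switch(locus, C4A = "true_c4a", C4B = "true_c4b", totalC4 = "true_total")
  make_calls(truth[[col]], locus = locus, sample_id = truth$sample_id,
             study = truth$study)
}
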