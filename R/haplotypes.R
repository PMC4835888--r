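# enumerate ordered per-site allele pairs compatible with a genotype value
site_pairs <- function(g) {
  if (is.na(g)) list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  else switch(as.character(g),
              "0" = list(c(0L, 0L)),
              "1" = list(c(0L, 1L), c(1L, 0L)),
              "2" = list(c(1L, 1L)),
              stop_c4("genotype dosages must be 0, 1, 2 or NA (got %s)", g))
}

# all ordered haplotype-index pairs compatible with one multilocus genotype;
# haplotype index = 1 + binary encoding of the allele pattern (site 1 = MSB)
genotype_pairs <- function(g) {
  h1 <- 0L; h2 <- 0L
  for (s in seq_along(g)) {
    opts <- site_pairs(g[s])
    a1 <- vapply(opts, `[`, integer(1), 1L)
    a2 <- vapply(opts, `[`, integer(1), 2L)
    h1 <- rep(h1 * 2L, each = length(opts)) + rep(a1, times = length(h1))
    h2 <- rep(h2 * 2L, each = length(opts)) + rep(a2, times = length(h2))
  }
  cbind(h1 + 1L, h2 + 1L)
}

#' EM estimation of haplotype frequencies from unphased genotypes
#'
#' The classical multilocus EM for a small biallelic SNP set: the E-step
#' computes diplotype posteriors given current haplotype frequencies
#' (missing genotypes are summed over), the M-step re-estimates frequencies
#' from expected haplotype counts; iteration stops when the log-likelihood
#' improves by less than `tol` (or after `max_iter` iterations). The
#' log-likelihood is non-decreasing by construction and is checked at every
#' step. Initialization is the linkage-equilibrium product of allele
#' frequencies, which is deterministic; monomorphic input returns the single
#' observed haplotype with frequency 1 without iterating.
#'
#' @param genotypes data.frame with `sample_id` plus one 0/1/2 dosage column
#'   per SNP (NA allowed), or a plain numeric matrix.
#' @param max_snps refuse larger panels (diplotype enumeration is
#'   exponential; the intended scale is the 4-SNP conditioning panel).
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @param n_starts number of EM starts: the first is always the
#'   deterministic linkage-equilibrium initialization, further ones draw
#'   random frequency vectors (seeded by `start_seed`) to guard against
#'   local optima; the run with the best final log-likelihood wins, ties
#'   going to the deterministic start.
#' @param start_seed seed for the extra random starts.
#' @return object of class `haplotype_set`: `table` (label H1..Hk by
#'   descending frequency, allele `pattern`, `freq`, `mean_c4a_copies`
#'   placeholder), `dosage` (n x k matrix of posterior-expected copies of
#'   each haplotype carried per sample), `sample_ids`, `snps`, `loglik`
#'   trace.
#' @export
em_haplotype_frequencies <- function(genotypes, max_snps = 8L,
                                     tol = 1e-8, max_iter = 500L,
                                     n_starts = 1L, start_seed = 1L) {
  if (is.data.frame(genotypes)) {
    ids <- if ("sample_id" %in% names(genotypes)) genotypes$sample_id
           else sprintf("S%05d", seq_len(nrow(genotypes)))
    gm <- as.matrix(genotypes[, setdiff(names(genotypes), "sample_id"), drop = FALSE])
  } else {
    gm <- as.matrix(genotypes)
    ids <- rownames(gm) %||% sprintf("S%05d", seq_len(nrow(gm)))
  }
  storage.mode(gm) <- "integer"
  S <- ncol(gm)
  if (S < 1L) stop_c4("no SNP columns")
  if (S > max_snps) stop_c4("%d SNPs exceed the supported maximum of %d", S, max_snps)
  if (any(!is.na(gm) & !(gm %in% 0:2))) stop_c4("genotype dosages must be 0, 1, 2 or NA")
  n <- nrow(gm)
  H <- 2L^S
  patterns <- do.call(rbind, lapply(0:(H - 1L), function(h)
    as.integer(intToBits(h))[S:1]))
  colnames(patterns) <- colnames(gm)

  # unique genotype rows and their compatible ordered diplotypes
  key <- apply(gm, 1L, paste, collapse = ",")
  uniq <- !duplicated(key)
  ukey <- key[uniq]
  umat <- gm[uniq, , drop = FALSE]
  idx <- match(key, ukey)
  counts <- tabulate(idx, nbins = length(ukey))
  pairs <- lapply(seq_len(nrow(umat)), function(i) genotype_pairs(umat[i, ]))

  # linkage-equilibrium initialization from observed allele frequencies
  p_allele <- colMeans(gm, na.rm = TRUE) / 2
  f_le <- vapply(seq_len(H), function(h)
    prod(ifelse(patterns[h, ] == 1L, p_allele, 1 - p_allele)), numeric(1))
  f_le <- f_le / sum(f_le)
  monomorphic <- all(p_allele %in% c(0, 1))

  em_run <- function(f) {
    loglik <- -Inf
    trace <- numeric(0)
    iter_max <- if (monomorphic) 1L else max_iter
    for (iter in seq_len(iter_max)) {
      exp_counts <- numeric(H)
      ll <- 0
      for (i in seq_along(pairs)) {
        pr <- pairs[[i]]
        w <- f[pr[, 1L]] * f[pr[, 2L]]
        tot <- sum(w)
        if (tot <= 0)
          stop_c4("genotype '%s' has zero likelihood under current frequencies",
                  ukey[i])
        post <- w / tot * counts[i]
        exp_counts <- exp_counts +
          tabulate2(pr[, 1L], post, H) + tabulate2(pr[, 2L], post, H)
        ll <- ll + counts[i] * log(tot)
      }
      if (ll < loglik - 1e-9)
        stop_c4("EM log-likelihood decreased (%.10g -> %.10g)", loglik, ll)
      trace <- c(trace, ll)
      converged <- is.finite(loglik) && (ll - loglik) < tol
      loglik <- ll
      f_new <- exp_counts / (2 * n)
      if (converged) break
      f <- f_new
    }
    list(f = f, trace = trace, loglik = loglik,
         converged = iter < iter_max || monomorphic)
  }

  best <- em_run(f_le)
  if (n_starts > 1L && !monomorphic) {
    for (s in seq_len(n_starts - 1L)) {
      f0 <- local({
        set.seed(start_seed + s)
        g <- -log(stats::runif(H))  # Dirichlet(1,...,1) draw
        g / sum(g)
      })
      cand <- em_run(f0)
      if (cand$loglik > best$loglik + 1e-9) best <- cand
    }
  }
  f <- best$f
  trace <- best$trace

  keep <- which(f > 1e-10)
  ord <- keep[order(-f[keep])]
  pat_str <- apply(patterns, 1L, paste, collapse = "")
  tab <- data.frame(label = paste0("H", seq_along(ord)),
                    pattern = pat_str[ord], freq = f[ord],
                    mean_c4a_copies = NA_real_, stringsAsFactors = FALSE)

  # posterior-expected haplotype dosage per sample (n x k), kept haps only
  dos_u <- matrix(0, nrow(umat), length(ord))
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    w <- f[pr[, 1L]] * f[pr[, 2L]]
    post <- w / sum(w)
    dos_u[i, ] <- tabulate2(match(pr[, 1L], ord), post, length(ord)) +
      tabulate2(match(pr[, 2L], ord), post, length(ord))
  }
  dosage <- dos_u[idx, , drop = FALSE]
  colnames(dosage) <- tab$label
  rownames(dosage) <- ids

  structure(list(table = tab, freqs = stats::setNames(f[ord], tab$label),
                 patterns = patterns[ord, , drop = FALSE],
                 dosage = dosage, sample_ids = ids,
                 snps = colnames(gm), loglik = trace,
                 n = n, converged = best$converged),
            class = "haplotype_set")
}

# weighted tabulate; NA bins (from match misses) are dropped
tabulate2 <- function(bin, w, nbins) {
  out <- numeric(nbins)
  ok <- !is.na(bin)
  if (any(ok)) {
    s <- rowsum(w[ok], bin[ok])
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("Haplotype set over %d SNPs (%s), n = %d samples\n",
              length(x$snps), paste(x$snps, collapse = ", "), x$n))
  print(report_haplotypes(x), row.names = FALSE)
  invisible(x)
}

#' Haplotype report with a rare-haplotype bin
#'
#' Collapses haplotypes below the reporting threshold (default 1%
#' frequency) into an `"other"` row.
#'
#' @param haps a `haplotype_set`.
#' @param min_freq reporting threshold.
#' @return data.frame: `label`, `pattern`, `freq`, `mean_c4a_copies`.
#' @export
report_haplotypes <- function(haps, min_freq = 0.01) {
  tab <- haps$table
  rare <- tab$freq < min_freq
  out <- tab[!rare, , drop = FALSE]
  if (any(rare))
    out <- rbind(out, data.frame(label = "other", pattern = "-",
                                 freq = sum(tab$freq[rare]),
                                 mean_c4a_copies = NA_real_,
                                 stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Average C4A copies carried per haplotype
#'
#' Because the phase of the CNV relative to the SNP haplotypes is not
#' observed, the per-haplotype copy load is estimated as the coefficients of
#' a no-intercept least-squares regression of the diploid copy number on the
#' posterior-expected haplotype dosages: with additive haploid contributions
#' the coefficient of haplotype k is the mean number of copies carried per
#' copy of k. Since the dosages of the full haplotype basis sum to 2 per
#' sample, `2 * sum(freq_k * mean_k)` equals the population mean diploid
#' copy number (checked to 1e-6 and stored in the `consistency` attribute).
#' A carrier-weighted mean (`method = "carrier"`) is provided for
#' comparison.
#'
#' @param haps a `haplotype_set`.
#' @param calls `cn_calls` providing the copy number (default locus C4A).
#' @param locus locus to average.
#' @param method `"regression"` (contract) or `"carrier"`.
#' @return `haps` with `table$mean_c4a_copies` filled (NA = not estimable).
#' @export
haplotype_mean_cn <- function(haps, calls, locus = "C4A",
                              method = c("regression", "carrier")) {
  method <- match.arg(method)
  df <- as.data.frame(calls)
  df <- df[df$locus == locus, c("sample_id", "cn")]
  m <- match(haps$sample_ids, df$sample_id)
  ok <- !is.na(m)
  y <- df$cn[m[ok]]
  D <- haps$dosage[ok, , drop = FALSE]
  if (length(y) < ncol(D))
    stop_c4("fewer samples with calls (%d) than haplotypes (%d)", length(y), ncol(D))
  if (method == "regression") {
    fit <- stats::lm.fit(D, y)
    coefs <- fit$coefficients
  } else {
    coefs <- colSums(D * (y / 2)) / colSums(D)
    coefs[colSums(D) == 0] <- NA_real_
  }
  haps$table$mean_c4a_copies <- unname(coefs[haps$table$label])
  f_emp <- colMeans(D) / 2
  contrib <- ifelse(is.na(coefs), 0, coefs) * f_emp
  attr(haps, "consistency") <- c(weighted = 2 * sum(contrib), mean_cn = mean(y))
  haps
}

#' Haplotype association with disease and haplotype-conditioned CNV models
#'
#' Fits, for each haplotype above the reporting threshold, a logistic model
#' of case status on the posterior-expected haplotype dosage (additive
#' coding, remaining haplotypes as reference), adjusted for covariates.
#'
#' @param haps a `haplotype_set`.
#' @param cohort cohort table.
#' @param covariates covariate set (default age, sex, study).
#' @param min_freq only haplotypes at or above this frequency are tested.
#' @return data.frame of per-haplotype association rows (`note` records
#'   per-cell failures).
#' @export
haplotype_association <- function(haps, cohort,
                                  covariates = c("age", "sex", "study"),
                                  min_freq = 0.01) {
  keep <- haps$table$label[haps$table$freq >= min_freq]
  rows <- lapply(keep, function(h) {
    pred <- data.frame(sample_id = haps$sample_ids, x = haps$dosage[, h],
                       stringsAsFactors = FALSE)
    res <- tryCatch(
      fit_cn_logistic(cohort, predictor = pred, covariates = covariates,
                      stratum_label = "all"),
      error = function(e) conditionMessage(e))
    if (is.character(res))
      return(data.frame(haplotype = h, beta = NA_real_, se = NA_real_,
                        or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        p = NA_real_, n_cases = NA_integer_,
                        n_controls = NA_integer_, note = res,
                        stringsAsFactors = FALSE))
    r <- as.data.frame(res)
    data.frame(haplotype = h, r[, c("beta", "se", "or", "ci_low", "ci_high",
                                    "p", "n_cases", "n_controls")],
               note = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Copy-number association conditioned on a haplotype dosage
#'
#' Refits the additive copy-number model with the posterior-expected dosage
#' of one haplotype added as a covariate, to test whether the copy-number
#' association is independent of that haplotype.
#'
#' @param cohort cohort table.
#' @param calls `cn_calls`.
#' @param haps a `haplotype_set`.
#' @param hap_label haplotype to condition on (e.g. `"H2"`).
#' @param locus copy-number locus.
#' @param covariates covariates for adjustment.
#' @return an `assoc_result` for the copy-number term.
#' @export
cn_conditioned_on_haplotype <- function(cohort, calls, haps, hap_label,
                                        locus = "C4A",
                                        covariates = c("age", "sex", "study")) {
  if (!hap_label %in% colnames(haps$dosage))
    stop_c4("haplotype '%s' not in the haplotype set", hap_label)
  cond <- data.frame(sample_id = haps$sample_ids,
                     hap = haps$dosage[, hap_label], stringsAsFactors = FALSE)
  names(cond)[2] <- paste0("dose_", hap_label)
  fit_cn_logistic(cohort, calls, locus, covariates = covariates,
                  conditioning = cond, stratum_label = "all")
}
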