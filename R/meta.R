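#' DerSimonian-Laird random-effects pooling of per-study log odds ratios
#'
#' Moment-based random-effects meta-analysis. With fixed-effect weights
#' `w_i = 1/se_i^2` and the inverse-variance mean `b_FE`, Cochran's
#' `Q = sum w_i (b_i - b_FE)^2` on `k - 1` df gives the between-study
#' variance `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`; the
#' pooled estimate uses random-effects weights `w*_i = 1/(se_i^2 + tau2)`,
#' with `se_pooled = (sum w*)^{-1/2}` and
#' `I^2 = max(0, (Q - (k-1))/Q) * 100` percent. The heterogeneity p-value is
#' `Q` against chi-square with `k - 1` df. A single study passes through
#' unchanged with `tau2 = 0` and `I^2` not applicable.
#'
#' @param beta per-study log odds ratios.
#' @param se per-study standard errors (all > 0).
#' @param labels optional study labels.
#' @return object of class `meta_result`: pooled beta/se/OR with 95% CI and
#'   Wald p, `q_stat`, `df`, `p_heterogeneity`, `i_squared` (percent, `NA`
#'   for k = 1), `tau_squared`, and the per-study inputs with random-effects
#'   weights.
#' @export
pool_random_effects <- function(beta, se, labels = NULL) {
  k <- length(beta)
  if (k < 1L || length(se) != k) stop_c4("need k >= 1 matching beta/se pairs")
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(se <= 0))
    stop_c4("all standard errors must be finite and > 0")
  labels <- labels %||% paste0("study", seq_len(k))
  if (k == 1L) {
    w_star <- 1 / se^2
    res <- list(pooled_beta = beta, pooled_se = se, q_stat = 0, df = 0L,
                p_heterogeneity = NA_real_, i_squared = NA_real_,
                tau_squared = 0)
  } else {
    w <- 1 / se^2
    beta_fe <- sum(w * beta) / sum(w)
    q <- sum(w * (beta - beta_fe)^2)
    df <- k - 1L
    tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
    w_star <- 1 / (se^2 + tau2)
    res <- list(
      pooled_beta = sum(w_star * beta) / sum(w_star),
      pooled_se = 1 / sqrt(sum(w_star)),
      q_stat = q, df = df,
      p_heterogeneity = stats::pchisq(q, df, lower.tail = FALSE),
      i_squared = max(0, (q - df) / q) * 100,
      tau_squared = tau2)
  }
  res$pooled_or <- exp(res$pooled_beta)
  res$ci_low <- exp(res$pooled_beta - 1.96 * res$pooled_se)
  res$ci_high <- exp(res$pooled_beta + 1.96 * res$pooled_se)
  res$p <- 2 * stats::pnorm(-abs(res$pooled_beta / res$pooled_se))
  res$k <- k
  res$studies <- data.frame(label = labels, beta = beta, se = se,
                            weight = w_star / sum(w_star),
                            stringsAsFactors = FALSE)
  class(res) <- "meta_result"
  res
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Random-effects pooling of %d studies\n", x$k))
  cat(sprintf("  pooled OR %.3f (%.3f; %.3f), beta %.4f (se %.4f), p %.3g\n",
              x$pooled_or, x$ci_low, x$ci_high, x$pooled_beta, x$pooled_se, x$p))
  if (x$k > 1L)
    cat(sprintf("  Q %.3f on %d df (p_het %.3g), I^2 %.1f%%, tau^2 %.4f\n",
                x$q_stat, x$df, x$p_heterogeneity, x$i_squared, x$tau_squared))
  invisible(x)
}

#' @export
as.data.frame.meta_result <- function(x, ...) {
  data.frame(k = x$k, pooled_beta = x$pooled_beta, pooled_se = x$pooled_se,
             pooled_or = x$pooled_or, ci_low = x$ci_low, ci_high = x$ci_high,
             p = x$p, q_stat = x$q_stat, df = x$df,
             p_heterogeneity = x$p_heterogeneity, i_squared = x$i_squared,
             tau_squared = x$tau_squared, stringsAsFactors = FALSE)
}

#' Pool per-study association results over a model grid
#'
#' Groups the per-study rows of a [run_model_grid()] result (by locus, model,
#' conditioning set and stratum), pools each group with
#' [pool_random_effects()], and applies a Bonferroni correction across the
#' loci of each headline group (the three copy-number loci are the multiple
#' tests).
#'
#' @param results data.frame from [run_model_grid()]; only rows with
#'   `scope != "pooled"` and `note == "ok"` enter the pooling.
#' @param m number of tests for the Bonferroni correction (default: number
#'   of distinct loci pooled).
#' @return data.frame: grouping columns, pooled estimates, heterogeneity
#'   statistics and `p_corrected`.
#' @export
meta_grid <- function(results, m = NULL) {
  per <- results[results$scope != "pooled" & results$note == "ok", , drop = FALSE]
  if (nrow(per) == 0L) stop_c4("no per-study results to pool")
  key <- interaction(per$locus, per$model, per$conditioning, per$stratum, drop = TRUE)
  m <- m %||% length(unique(per$locus))
  rows <- lapply(split(per, key), function(g) {
    mr <- pool_random_effects(g$beta, g$se, labels = g$scope)
    cbind(data.frame(locus = g$locus[1], model = g$model[1],
                     conditioning = g$conditioning[1], stratum = g$stratum[1],
                     stringsAsFactors = FALSE),
          as.data.frame(mr))
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- bonferroni_correct(out$p, m)
  out <- out[order(out$locus, out$model, out$conditioning, out$stratum), ]
  rownames(out) <- NULL
  out
}

#' Read per-study estimates for standalone meta-analysis
#'
#' Reads a tab-separated table (`study`, `locus`, optional `stratum`, `beta`,
#' `se`) so the pooling can be driven without the upstream stages.
#'
#' @param path TSV file path.
#' @return data.frame shaped like a [run_model_grid()] output (scope = study,
#'   note = "ok").
#' @export
read_study_estimates <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("study", "locus", "beta", "se")
  if (!all(need %in% names(df)))
    stop_c4("estimate table needs columns: %s", paste(need, collapse = ", "))
  data.frame(locus = df$locus, scope = df$study, model = "external",
             conditioning = "none",
             stratum = if ("stratum" %in% names(df)) df$stratum else "all",
             beta = df$beta, se = df$se, or = exp(df$beta),
             ci_low = exp(df$beta - 1.96 * df$se),
             ci_high = exp(df$beta + 1.96 * df$se),
             p = 2 * stats::pnorm(-abs(df$beta / df$se)),
             n_cases = NA_integer_, n_controls = NA_integer_,
             note = "ok", stringsAsFactors = FALSE)
}
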