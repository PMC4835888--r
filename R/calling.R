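#' Calling configuration
#'
#' Tuning parameters for [call_integer_cn()]. The anchors map the most
#' populous dosage subgroup of a batch to the population modal copy number
#' (2 for C4A and C4B, 4 for total C4 in European-ancestry cohorts); they are
#' configuration, not constants.
#'
#' @param anchors named integer vector of modal copy numbers per locus.
#' @param ranges named list of allowed integer ranges per locus.
#' @param min_batch_n batches below this size are refused (subgrouping on
#'   fewer samples is unreliable).
#' @param low_conf_threshold calls with confidence below this are flagged
#'   `low_confidence`.
#' @param boundary_z additionally flag a call `low_confidence` when its
#'   dosage sits closer to a subgroup boundary than `boundary_z` times the
#'   batch's robust within-subgroup spread (so the flag adapts to the noise
#'   level: at high noise more calls are flagged rather than being wrong
#'   with high confidence). The default 2.33 corresponds to roughly a 1%
#'   one-sided misassignment risk under Gaussian noise.
#' @param structure_alpha significance level of the Rayleigh uniformity test
#'   on the fractional residuals used as the subgroup-structure guard: if
#'   uniformity of the residuals cannot be rejected at this level (i.e. the
#'   dosages are a structureless smear rather than clusters at `k*s`),
#'   calling errors out and advises inspecting the noise level.
#' @param method `"equispaced"` (default): fit a shared spacing `s` so
#'   subgroup centers sit at `k*s` and assign each dosage its nearest center;
#'   `"gap"`: partition the ordered dosages at gaps larger than
#'   `gap_frac * s0` and index the resulting subgroups.
#' @param gap_frac gap threshold for the `"gap"` method, as a fraction of the
#'   nominal spacing.
#' @return list of class `calling_config`.
#' @export
calling_config <- function(anchors = default_anchors(),
                           ranges = default_cn_ranges(),
                           min_batch_n = 30L,
                           low_conf_threshold = 0.2,
                           boundary_z = 2.33,
                           structure_alpha = 0.01,
                           method = c("equispaced", "gap"),
                           gap_frac = 0.35) {
  method <- match.arg(method)
  structure(list(anchors = anchors, ranges = ranges,
                 min_batch_n = as.integer(min_batch_n),
                 low_conf_threshold = low_conf_threshold,
                 boundary_z = boundary_z,
                 structure_alpha = structure_alpha,
                 method = method, gap_frac = gap_frac),
            class = "calling_config")
}

# fit shared spacing s so dosages cluster at k*s; returns integer indices k
fit_equispaced <- function(d, anchor, config) {
  s0 <- 1 / anchor
  grid <- seq(0.75, 1.30, by = 0.002) * s0
  # cost in units of s (fractional residuals): scale-invariant, so the grid
  # search cannot drift to a smaller, misaligned spacing that shrinks the
  # absolute residuals without aligning to the clusters
  cost <- vapply(grid, function(s) {
    k <- pmax(0, round_half_down(d / s))
    sum((d / s - k)^2)
  }, numeric(1))
  s <- grid[which.min(cost)]
  for (it in 1:50) {  # alternate assignment / least-squares spacing
    k <- pmax(0L, round_half_down(d / s))
    if (sum(k^2) == 0) break
    s_new <- sum(d * k) / sum(k^2)
    if (abs(s_new - s) < 1e-12) { s <- s_new; break }
    s <- s_new
  }
  k <- pmax(0L, round_half_down(d / s))
  list(k = as.integer(k), s = s)
}

# partition sorted dosages at gaps > gap_frac * nominal spacing
fit_gap <- function(d, anchor, config) {
  s0 <- 1 / anchor
  o <- order(d)
  ds <- d[o]
  splits <- which(diff(ds) > config$gap_frac * s0)
  grp_sorted <- cumsum(c(1L, as.integer(seq_along(ds)[-1] %in% (splits + 1L))))
  grp <- integer(length(d)); grp[o] <- grp_sorted
  centers <- tapply(d, grp, mean)
  if (length(centers) > 1L) {
    s <- min(diff(sort(centers)))  # assumes at least two adjacent classes touch
  } else s <- s0
  kc <- round_half_down(centers / s)  # named by group index
  k <- as.integer(kc[as.character(grp)])
  list(k = pmax(0L, k), s = s)
}

#' Call integer copy numbers from normalized dosages
#'
#' Converts continuous normalized dosages into integer copy numbers, one
#' normalization batch (study) at a time. Dosages cluster around equispaced
#' centers `k*s` (one per copy-number class); the shared spacing `s` is
#' fitted per batch, each dosage is assigned its nearest center (ties at a
#' boundary go to the lower integer and are flagged), and the most populous
#' subgroup is anchored to the configured modal copy number. Confidence is
#' the scaled distance from the subgroup boundary: 1 at a center, 0 at a
#' boundary. Zero dosages are called 0 and flagged
#' `suspected_homozygous_deletion` (a confirmation worklist is produced by
#' [flag_homozygous_deletions()]).
#'
#' @param dosages a `dosage_matrix` from [normalize_dosages()] (totals may be
#'   imputed via [impute_total_c4()]).
#' @param locus one of `"C4A"`, `"C4B"`, `"totalC4"`.
#' @param config a [calling_config()].
#' @return data.frame of class `cn_calls`: `sample_id`, `study`, `locus`,
#'   `dosage`, `cn`, `confidence`, `flags` (semicolon-separated;
#'   `imputed_total` is carried over for imputed totals).
#' @export
call_integer_cn <- function(dosages, locus = c("C4A", "C4B", "totalC4"),
                            config = calling_config()) {
  locus <- match.arg(locus)
  col <- switch(locus, C4A = "d_c4a", C4B = "d_c4b", totalC4 = "d_total")
  anchor <- config$anchors[[locus]]
  rng <- config$ranges[[locus]]
  d_all <- dosages[[col]]
  keep <- !is.na(d_all)
  out <- data.frame(sample_id = dosages$sample_id[keep],
                    study = dosages$study[keep],
                    locus = locus,
                    dosage = d_all[keep],
                    cn = NA_integer_, confidence = NA_real_,
                    flags = "", stringsAsFactors = FALSE)
  for (b in unique(out$study)) {
    i <- which(out$study == b)
    d <- out$dosage[i]
    if (length(d) < config$min_batch_n)
      stop_c4("batch '%s' has %d samples at %s; calling below %d samples is refused",
              b, length(d), locus, config$min_batch_n)
    fit <- if (config$method == "equispaced") fit_equispaced(d, anchor, config)
           else fit_gap(d, anchor, config)
    k <- fit$k; s <- fit$s
    resid <- d / s - round(d / s)
    # Rayleigh test: structureless dosages give uniform fractional residuals,
    # genuine copy-number clusters concentrate them around 0
    rbar2 <- mean(cos(2 * pi * resid))^2 + mean(sin(2 * pi * resid))^2
    p_unif <- exp(-length(resid) * rbar2)
    if (p_unif > config$structure_alpha)
      stop_c4(paste0("batch '%s', locus %s: no discernible copy-number subgroup ",
                     "structure (residual uniformity p = %.3f); inspect the ",
                     "dosage noise level"), b, locus, p_unif)
    tabk <- table(k)
    k_mode <- as.integer(names(tabk)[which.max(tabk)])  # ties: smallest k
    shift <- anchor - k_mode
    cn <- k + shift
    cn[d == 0] <- 0L
    frac <- abs(d / s - k)               # distance from assigned center, units of s
    conf <- pmax(0, 1 - 2 * frac)
    conf[d == 0] <- 1
    flags <- character(length(d))
    sigma_hat <- stats::mad(resid, center = 0)  # within-subgroup spread, units of s
    margin <- 0.5 - abs(resid)                  # distance to the nearest boundary
    low <- conf < config$low_conf_threshold |
      margin < config$boundary_z * sigma_hat
    low[d == 0] <- FALSE
    oor <- cn < rng[1] | cn > rng[2]
    cn <- pmin(pmax(cn, rng[1]), rng[2])
    add_flag <- function(flags, which, flag)
      ifelse(which, ifelse(flags == "", flag, paste(flags, flag, sep = ";")), flags)
    flags <- add_flag(flags, low | oor, "low_confidence")
    flags <- add_flag(flags, cn == 0L, "suspected_homozygous_deletion")
    if (locus == "totalC4" && "total_source" %in% names(dosages)) {
      imput <- dosages$total_source[keep][i] == "imputed-from-mean"
      flags <- add_flag(flags, !is.na(imput) & imput, "imputed_total")
    }
    out$cn[i] <- as.integer(cn)
    out$confidence[i] <- conf
    out$flags[i] <- flags
  }
  class(out) <- c("cn_calls", "data.frame")
  out
}

#' Worklist of suspected homozygous deletions
#'
#' All zero-copy calls, with study and raw dosage, for downstream wet-lab
#' confirmation (homozygous deletions can be miscalled when a polymorphism
#' disrupts probe ligation).
#'
#' @param calls a `cn_calls` data.frame (one locus or several row-bound).
#' @return data.frame: `sample_id`, `study`, `locus`, `dosage`; zero rows if
#'   there are no zero calls.
#' @export
flag_homozygous_deletions <- function(calls) {
  z <- calls[calls$cn == 0L, c("sample_id", "study", "locus", "dosage"), drop = FALSE]
  rownames(z) <- NULL
  z
}

#' Differential-bias QC on raw dosages of modal-class carriers
#'
#' Batch effects could bias the continuous dosages differently in cases and
#' controls and manufacture spurious association. For each locus, restricted
#' to carriers of the modal copy number (2 for C4A/C4B, 4 for total C4), the
#' raw unrounded dosages of cases and controls are compared with Welch's
#' two-sample t-test, pooled and per study.
#'
#' @param calls row-bound `cn_calls` for the loci to test.
#' @param cohort cohort table with `sample_id` and `status`.
#' @param anchors modal copy number per locus.
#' @return data.frame: `locus`, `scope`, `n_cases`, `n_controls`,
#'   `mean_cases`, `mean_controls`, `diff`, `p`, `note`.
#' @export
dosage_bias_qc <- function(calls, cohort, anchors = default_anchors()) {
  df <- merge(as.data.frame(calls), cohort[, c("sample_id", "status")],
              by = "sample_id")
  rows <- list()
  for (loc in unique(df$locus)) {
    sub <- df[df$locus == loc & df$cn == anchors[[loc]], , drop = FALSE]
    scopes <- c("pooled", sort(unique(sub$study)))
    for (sc in scopes) {
      x <- if (sc == "pooled") sub else sub[sub$study == sc, , drop = FALSE]
      ca <- x$dosage[x$status == "case"]; co <- x$dosage[x$status == "control"]
      if (length(ca) < 2L || length(co) < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          locus = loc, scope = sc, n_cases = length(ca), n_controls = length(co),
          mean_cases = NA_real_, mean_controls = NA_real_, diff = NA_real_,
          p = NA_real_, note = "not testable: group with < 2 samples",
          stringsAsFactors = FALSE)
        next
      }
      p <- if (stats::sd(ca) == 0 && stats::sd(co) == 0) {
        if (mean(ca) == mean(co)) 1 else NA_real_
      } else stats::t.test(ca, co)$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        locus = loc, scope = sc, n_cases = length(ca), n_controls = length(co),
        mean_cases = mean(ca), mean_controls = mean(co),
        diff = mean(ca) - mean(co), p = p, note = "ok",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Copy-number frequency distribution
#'
#' Counts and proportions of each called integer per locus, split by
#' case/control status and study (plus pooled rows).
#'
#' @param calls row-bound `cn_calls`.
#' @param cohort cohort table with `sample_id` and `status`.
#' @return data.frame: `locus`, `study`, `status`, `cn`, `n`, `prop`
#'   (proportions sum to 1 within each locus x study x status group).
#' @export
cn_distribution_summary <- function(calls, cohort) {
  df <- merge(as.data.frame(calls), cohort[, c("sample_id", "status")],
              by = "sample_id")
  df_pooled <- df; df_pooled$study <- "pooled"
  df <- rbind(df, df_pooled)
  agg <- stats::aggregate(list(n = df$cn), by = list(
    locus = df$locus, study = df$study, status = df$status, cn = df$cn), length)
  tot <- stats::aggregate(list(total = agg$n), by = list(
    locus = agg$locus, study = agg$study, status = agg$status), sum)
  out <- merge(agg, tot)
  out$prop <- out$n / out$total
  out$total <- NULL
  out <- out[order(out$locus, out$study, out$status, out$cn), ]
  rownames(out) <- NULL
  out
}
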