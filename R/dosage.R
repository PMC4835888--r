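#' Read an MLPA peak-height export
#'
#' Reads a tab- or comma-separated peak table (sample, probe, peak height,
#' optional study label), maps nonstandard probe labels to the canonical set
#' (C4A, C4B, C4-ex30, EP300, CREBBP), and enforces the structural rules:
#' duplicated (sample, probe) rows are an error, and samples missing either
#' control probe are dropped and logged.
#'
#' @param path file path, or a data.frame already in memory.
#' @param probe_map optional named character vector mapping raw probe labels
#'   to canonical names, e.g. `c("C4ex30" = "C4-ex30")`.
#' @param sep field separator; inferred from the extension when `NULL`
#'   (`.csv` is comma, anything else tab).
#' @param study default study label for tables without a study column.
#' @param use_areas read peak areas instead of heights (off by default;
#'   heights are the standard input for this normalization). Requires an
#'   `area` column.
#' @return a validated peak table (`sample_id`, `study`, `probe`, `height`,
#'   extra columns preserved) with an `exclusions` attribute logging dropped
#'   samples and why.
#' @export
read_peak_table <- function(path, probe_map = NULL, sep = NULL,
                            study = "batch1", use_areas = FALSE) {
  if (is.data.frame(path)) {
    raw <- path
  } else {
    if (!file.exists(path)) stop_c4("peak table '%s' not found", path)
    sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    raw <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (nrow(raw) == 0L) stop_c4("peak table is empty")
  nms <- tolower(names(raw))
  pick <- function(cands) {
    i <- which(nms %in% cands)[1]
    if (is.na(i)) NA_integer_ else i
  }
  i_sample <- pick(c("sample_id", "sample", "sample.name", "sample_name"))
  i_probe  <- pick(c("probe", "probe_name", "marker", "peak", "label"))
  i_height <- if (use_areas) pick(c("area", "peak_area"))
              else pick(c("height", "peak_height", "dosage"))
  if (use_areas && is.na(i_height)) stop_c4("use_areas = TRUE but no area column found")
  i_study  <- pick(c("study", "study_label", "batch", "cohort"))
  if (is.na(i_sample) || is.na(i_probe) || is.na(i_height))
    stop_c4("peak table needs sample, probe and height columns (found: %s)",
            paste(names(raw), collapse = ", "))
  out <- data.frame(
    sample_id = as.character(raw[[i_sample]]),
    study = if (is.na(i_study)) study else as.character(raw[[i_study]]),
    probe = as.character(raw[[i_probe]]),
    height = as.numeric(raw[[i_height]]),
    stringsAsFactors = FALSE
  )
  extra <- setdiff(seq_along(raw), c(i_sample, i_probe, i_height, i_study))
  if (length(extra)) out <- cbind(out, raw[extra])

  if (!is.null(probe_map)) {
    hit <- out$probe %in% names(probe_map)
    out$probe[hit] <- unname(probe_map[out$probe[hit]])
  }
  unknown <- setdiff(unique(out$probe), C4_PROBES)
  if (length(unknown))
    stop_c4("unknown probe label(s) without mapping: %s",
            paste(unknown, collapse = ", "))
  if (any(is.na(out$height)) || any(out$height < 0))
    stop_c4("peak heights must be nonnegative numbers")

  key <- paste(out$sample_id, out$probe)
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop_c4("duplicated (sample, probe) rows: %s", paste(dups, collapse = "; "))
  }

  # every retained sample must carry both control probes
  has_ctrl <- tapply(out$probe, out$sample_id,
                     function(p) all(C4_CONTROL_PROBES %in% p))
  bad <- names(has_ctrl)[!has_ctrl]
  exclusions <- data.frame(sample_id = character(), reason = character(),
                           stringsAsFactors = FALSE)
  if (length(bad)) {
    exclusions <- data.frame(sample_id = bad,
                             reason = "missing control probe (EP300/CREBBP)",
                             stringsAsFactors = FALSE)
    out <- out[!out$sample_id %in% bad, , drop = FALSE]
  }
  if (nrow(out) == 0L) stop_c4("no samples left after control-probe QC")
  rownames(out) <- NULL
  attr(out, "exclusions") <- exclusions
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Normalize peak heights to probe dosages
#'
#' Implements the two-step ratio normalization: each test-probe height is
#' divided by the summed heights of the control loci EP300 and CREBBP,
#' `r = h_test / (h_EP300 + h_CREBBP)`, and each ratio is then divided by the
#' median of all ratios for that probe within its normalization batch,
#' `d = r / median(r)`. Column medians are therefore exactly 1 per batch, a
#' zero test peak gives dosage exactly 0, and any per-sample multiplicative
#' rescaling of all five peaks cancels.
#'
#' @param peaks a peak table from [read_peak_table()] (or equivalent
#'   data.frame).
#' @param batch_key column defining normalization batches (default `"study"`,
#'   mirroring per-study normalization; set to a plate column for plate-level
#'   batches).
#' @return a `dosage_matrix` data.frame: `sample_id`, `study`, `d_c4a`,
#'   `d_c4b`, `d_total`, `total_source` ("measured" or NA), with an
#'   `exclusions` attribute for samples whose control peak sum was zero.
#' @export
normalize_dosages <- function(peaks, batch_key = "study") {
  if (!batch_key %in% names(peaks))
    stop_c4("batch key '%s' is not a column of the peak table", batch_key)
  wide <- to_wide_peaks(peaks, batch_key)
  ctrl <- wide$EP300 + wide$CREBBP
  excl <- attr(peaks, "exclusions") %||%
    data.frame(sample_id = character(), reason = character(), stringsAsFactors = FALSE)
  bad <- !is.finite(ctrl) | ctrl <= 0
  if (any(bad)) {
    excl <- rbind(excl, data.frame(sample_id = wide$sample_id[bad],
                                   reason = "control peak sum is zero",
                                   stringsAsFactors = FALSE))
    wide <- wide[!bad, , drop = FALSE]
    ctrl <- ctrl[!bad]
  }
  if (nrow(wide) == 0L) stop_c4("no samples with positive control peaks")

  r_c4a <- wide$C4A / ctrl
  r_c4b <- wide$C4B / ctrl
  r_tot <- wide$`C4-ex30` / ctrl
  med_scale <- function(r, batch) {
    d <- r
    for (b in unique(batch)) {
      i <- batch == b & !is.na(r)
      if (!any(i)) next
      m <- stats::median(r[i])
      if (!is.finite(m) || m <= 0)
        stop_c4("batch '%s': median ratio is not positive; cannot normalize", b)
      d[batch == b] <- r[batch == b] / m
    }
    d
  }
  batch <- wide$.batch
  out <- data.frame(
    sample_id = wide$sample_id,
    study = wide$study,
    d_c4a = med_scale(r_c4a, batch),
    d_c4b = med_scale(r_c4b, batch),
    d_total = med_scale(r_tot, batch),
    total_source = ifelse(is.na(r_tot), NA_character_, "measured"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  attr(out, "batch_key") <- batch_key
  class(out) <- c("dosage_matrix", "data.frame")
  out
}

to_wide_peaks <- function(peaks, batch_key) {
  df <- as.data.frame(peaks)
  samples <- unique(df$sample_id)
  idx <- match(paste(rep(samples, each = 5L), rep(C4_PROBES, times = length(samples))),
               paste(df$sample_id, df$probe))
  h <- matrix(df$height[idx], ncol = 5L, byrow = TRUE,
              dimnames = list(NULL, C4_PROBES))
  first <- match(samples, df$sample_id)
  out <- data.frame(sample_id = samples,
                    study = if ("study" %in% names(df)) df$study[first] else "batch1",
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(h, check.names = FALSE))
  out$.batch <- as.character(df[[batch_key]][first])
  out
}

#' Impute missing total-C4 dosage from the isoform mean
#'
#' For samples whose C4-ex30 probe produced no measurement (e.g. a failed
#' probe in one study), the total-C4 dosage is taken as the mean of the C4A
#' and C4B dosages, `d_total = (d_c4a + d_c4b) / 2`, and flagged
#' `"imputed-from-mean"`. Samples with neither isoform dosage keep a missing
#' total and are logged.
#'
#' @param dosages a `dosage_matrix` from [normalize_dosages()].
#' @return the dosage matrix with imputed totals and updated `total_source`.
#' @export
impute_total_c4 <- function(dosages) {
  d <- dosages
  miss <- is.na(d$d_total)
  can <- miss & !is.na(d$d_c4a) & !is.na(d$d_c4b)
  d$d_total[can] <- (d$d_c4a[can] + d$d_c4b[can]) / 2
  d$total_source[can] <- "imputed-from-mean"
  still <- miss & !can
  log <- attr(dosages, "imputation_log") %||%
    data.frame(sample_id = character(), note = character(), stringsAsFactors = FALSE)
  if (any(still))
    log <- rbind(log, data.frame(sample_id = d$sample_id[still],
                                 note = "total left missing: no isoform dosages",
                                 stringsAsFactors = FALSE))
  attr(d, "imputation_log") <- log
  d
}

#' Correlation of measured total-C4 dosage with the isoform mean
#'
#' Validates the imputation rule on batches where the C4-ex30 probe worked:
#' Pearson correlation between the measured total dosage and
#' `(d_c4a + d_c4b)/2`, pooled and per study.
#'
#' @param dosages a `dosage_matrix`; only rows with `total_source ==
#'   "measured"` and both isoform dosages enter.
#' @return data.frame: `scope` ("pooled" or a study label), `n`, `r`, `note`
#'   (`"ok"`, or `"not testable: constant"` when a variable is constant).
#' @export
total_vs_mean_correlation <- function(dosages) {
  d <- dosages[!is.na(dosages$total_source) & dosages$total_source == "measured" &
                 !is.na(dosages$d_c4a) & !is.na(dosages$d_c4b), , drop = FALSE]
  if (nrow(d) < 3L)
    stop_c4("need at least 3 samples with measured total and both isoform dosages (have %d)",
            nrow(d))
  one <- function(x, scope) {
    m <- (x$d_c4a + x$d_c4b) / 2
    if (nrow(x) < 3L || stats::sd(x$d_total) == 0 || stats::sd(m) == 0)
      return(data.frame(scope = scope, n = nrow(x), r = NA_real_,
                        note = if (nrow(x) < 3L) "not testable: n < 3"
                               else "not testable: constant",
                        stringsAsFactors = FALSE))
    data.frame(scope = scope, n = nrow(x), r = stats::cor(x$d_total, m),
               note = "ok", stringsAsFactors = FALSE)
  }
  out <- one(d, "pooled")
  for (s in unique(d$study)) out <- rbind(out, one(d[d$study == s, ], s))
  rownames(out) <- NULL
  out
}
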