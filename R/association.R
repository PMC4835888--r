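# wide view of calls: one cn column per locus
calls_wide <- function(calls) {
  df <- as.data.frame(calls)
  out <- unique(df[, "sample_id", drop = FALSE])
  for (loc in unique(df$locus)) {
    sub <- df[df$locus == loc, c("sample_id", "cn")]
    names(sub)[2] <- paste0("cn_", loc)
    out <- merge(out, sub, by = "sample_id", all.x = TRUE)
  }
  out
}

# core logistic fit of one predictor term with covariate adjustment.
# data: data.frame with y (0/1), x (the predictor), covariate columns.
fit_logistic_term <- function(data, covariates, conditioning_cols = character(),
                              model_label = "", stratum_label = "all",
                              min_n = 10L) {
  keep_cols <- c("y", "x", covariates, conditioning_cols)
  df <- data[stats::complete.cases(data[, keep_cols, drop = FALSE]), , drop = FALSE]
  n_cases <- sum(df$y == 1); n_controls <- sum(df$y == 0)
  if (n_cases < min_n || n_controls < min_n)
    stop_c4("too few samples after filtering (%d cases, %d controls; need >= %d each)",
            n_cases, n_controls, min_n)
  terms <- c("x", covariates, conditioning_cols)
  # drop constant/single-level covariates (e.g. a single study in a stratum)
  usable <- vapply(terms, function(v) {
    col <- df[[v]]
    if (is.factor(col) || is.character(col)) length(unique(col)) > 1L
    else stats::sd(col) > 0
  }, logical(1))
  if (!usable[["x"]])
    stop_c4("predictor is constant in this stratum; not testable")
  terms <- terms[usable]
  form <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  if (any(!is.finite(co[, "Std. Error"])) || any(is.na(stats::coef(fit))))
    stop_c4("singular design (collinear covariates): %s",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  big <- abs(co[, "Estimate"]) > 15
  if (sep_warn || any(big)) {
    offender <- if (any(big)) rownames(co)[which.max(abs(co[, "Estimate"]))] else "x"
    stop_c4("complete or quasi-complete separation detected (term '%s')", offender)
  }
  beta <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
  structure(list(
    term = "x", beta = beta, se = se,
    or = exp(beta), ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    p = co["x", "Pr(>|z|)"],
    n_cases = n_cases, n_controls = n_controls,
    model = model_label, stratum = stratum_label,
    coefficients = co
  ), class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s [%s]: OR %.3f (%.3f; %.3f), beta %.4f (se %.4f), p %.3g, %d cases / %d controls\n",
              x$model, x$stratum, x$or, x$ci_low, x$ci_high, x$beta, x$se, x$p,
              x$n_cases, x$n_controls))
  invisible(x)
}

#' @export
as.data.frame.assoc_result <- function(x, ...) {
  data.frame(model = x$model, stratum = x$stratum, beta = x$beta, se = x$se,
             or = x$or, ci_low = x$ci_low, ci_high = x$ci_high, p = x$p,
             n_cases = x$n_cases, n_controls = x$n_controls,
             stringsAsFactors = FALSE)
}

# assemble the model frame joining cohort, calls/predictor, conditioning SNPs
build_model_frame <- function(cohort, calls = NULL, locus = "C4A",
                              conditioning = NULL, predictor = NULL) {
  df <- as.data.frame(cohort)
  df$y <- as.integer(df$status == "case")
  df$sex <- as.integer(df$sex == "female")        # female = 1, male = 0
  if ("study" %in% names(df)) {
    tab <- sort(table(df$study), decreasing = TRUE)
    df$study <- stats::relevel(factor(df$study), ref = names(tab)[1])
  }
  if (!is.null(predictor)) {
    stopifnot(all(c("sample_id", "x") %in% names(predictor)))
    df <- merge(df, predictor[, c("sample_id", "x")], by = "sample_id")
  } else {
    cw <- calls_wide(calls)
    col <- paste0("cn_", locus)
    if (!col %in% names(cw)) stop_c4("no calls for locus '%s'", locus)
    cw$x <- cw[[col]]
    df <- merge(df, cw[, c("sample_id", "x")], by = "sample_id")
  }
  cond_cols <- character()
  if (!is.null(conditioning)) {
    cc <- conditioning
    raw_cols <- setdiff(names(cc), "sample_id")
    safe <- make.names(raw_cols)  # rs ids are already syntactic; haplotype labels too
    names(cc)[match(raw_cols, names(cc))] <- safe
    df <- merge(df, cc, by = "sample_id")
    cond_cols <- safe
  }
  list(data = df, cond_cols = cond_cols)
}

#' Additive copy-number logistic association
#'
#' Fits the case-control logistic regression with the integer copy number at
#' one locus coded additively (the predictor is the number of gene copies),
#' adjusted for covariates, optionally conditioned on linked SNP dosages and
#' restricted to a stratum. Maximum likelihood via IRLS (`stats::glm`); Wald
#' standard errors, 95% CI on the log-odds scale, two-sided Wald p.
#'
#' @param cohort cohort table (`sample_id`, `status`, `subtype`, `age`,
#'   `sex`, `study`).
#' @param calls `cn_calls` (row-bound loci) providing the copy numbers.
#' @param locus locus whose copy number is the exposure.
#' @param covariates subset of `c("age", "sex", "study")`; study enters as
#'   indicator terms with the largest study as reference, sex as female = 1.
#' @param conditioning optional data.frame `sample_id` + SNP dosage columns
#'   added as covariates.
#' @param stratum optional character vector of sample ids (or logical mask on
#'   `cohort`) restricting the fit.
#' @param stratum_label label recorded in the result.
#' @param predictor optional data.frame (`sample_id`, `x`) replacing the
#'   copy-number exposure (used for haplotype-dosage models).
#' @return an `assoc_result`: log OR (`beta`), `se`, `or` with 95% CI, Wald
#'   `p`, per-group n, the model label and the full coefficient table.
#' @export
fit_cn_logistic <- function(cohort, calls = NULL, locus = "C4A",
                            covariates = c("age", "sex"),
                            conditioning = NULL, stratum = NULL,
                            stratum_label = "all", predictor = NULL) {
  if (!is.null(stratum)) {
    cohort <- if (is.logical(stratum)) cohort[stratum, , drop = FALSE]
              else cohort[cohort$sample_id %in% stratum, , drop = FALSE]
  }
  bm <- build_model_frame(cohort, calls, locus, conditioning, predictor)
  label <- paste0(
    if (is.null(predictor)) paste0("cn_", locus) else "predictor",
    " ~ ", if (length(covariates)) paste(covariates, collapse = "+") else "1",
    if (length(bm$cond_cols)) paste0(" | ", paste(bm$cond_cols, collapse = "+")) else "")
  fit_logistic_term(bm$data, covariates, bm$cond_cols,
                    model_label = label, stratum_label = stratum_label)
}

#' Stratify a cohort for subgroup association analyses
#'
#' Supported schemes: `"age3"` (youngest < 71 years, middle 71-78 inclusive,
#' oldest > 78 — the two boundary ages are assigned to the middle group),
#' `"sex"`, `"subtype"` (each late-stage subtype stratum includes all
#' controls), and `"age3xsex"`.
#'
#' @param cohort cohort table.
#' @param scheme stratification scheme.
#' @return named list of character vectors of sample ids; age/sex strata are
#'   disjoint, subtype strata share the controls.
#' @export
stratify_cohort <- function(cohort, scheme = c("age3", "sex", "subtype", "age3xsex")) {
  scheme <- match.arg(scheme)
  age_band <- function(age) ifelse(age < 71, "age<71",
                            ifelse(age <= 78, "age71-78", "age>78"))
  ids <- cohort$sample_id
  out <- switch(scheme,
    age3 = split(ids, factor(age_band(cohort$age),
                             levels = c("age<71", "age71-78", "age>78"))),
    sex = split(ids, factor(cohort$sex, levels = c("female", "male"))),
    subtype = {
      ctrl <- ids[cohort$status == "control"]
      subtypes <- setdiff(unique(cohort$subtype[cohort$status == "case"]), "none")
      stats::setNames(lapply(sort(subtypes), function(st)
        c(ids[cohort$status == "case" & cohort$subtype == st], ctrl)),
        sort(subtypes))
    },
    age3xsex = {
      f <- interaction(factor(age_band(cohort$age),
                              levels = c("age<71", "age71-78", "age>78")),
                       factor(cohort$sex, levels = c("female", "male")),
                       sep = ":", drop = FALSE)
      split(ids, f)
    })
  lapply(out, as.character)
}

#' Age versus copy-number correlation check
#'
#' Longevity has been linked to C4 copy number, so age could confound the
#' association; this reports the Pearson correlation of age with the called
#' copy number at each locus, with its test p-value, over all individuals.
#'
#' @param cohort cohort table with `age`.
#' @param calls row-bound `cn_calls`.
#' @return data.frame: `locus`, `n`, `r`, `p`, `note`.
#' @export
age_cn_correlation <- function(cohort, calls) {
  cw <- calls_wide(calls)
  df <- merge(cohort[, c("sample_id", "age")], cw, by = "sample_id")
  loci <- sub("^cn_", "", grep("^cn_", names(df), value = TRUE))
  rows <- lapply(loci, function(loc) {
    x <- df[[paste0("cn_", loc)]]
    ok <- !is.na(x) & !is.na(df$age)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0)
      return(data.frame(locus = loc, n = sum(ok), r = NA_real_, p = NA_real_,
                        note = "not testable: constant copy number",
                        stringsAsFactors = FALSE))
    ct <- stats::cor.test(df$age[ok], x[ok])
    data.frame(locus = loc, n = sum(ok), r = unname(ct$estimate), p = ct$p.value,
               note = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Leave-one-out conditioning sets for a SNP panel
#'
#' Builds the model set used to locate which conditioning variant drives an
#' attenuation: no conditioning, each leave-one-SNP-out subset, and the full
#' set.
#'
#' @param snps character vector of SNP column names.
#' @return named list of character vectors (`"none"` is `character(0)`).
#' @export
leave_one_out_sets <- function(snps) {
  sets <- c(list(none = character(0)),
            stats::setNames(lapply(snps, function(s) setdiff(snps, s)),
                            paste0("drop_", snps)),
            list(full = snps))
  sets
}

#' Run a grid of association models
#'
#' Assembles the standard model set: per-study and pooled fits, crude and
#' covariate-adjusted, over loci, optional conditioning sets and optional
#' strata. Per-cell failures (separation, empty strata, constant predictors)
#' are recorded in the `note` column and never abort the grid.
#'
#' @param cohort cohort table.
#' @param calls row-bound `cn_calls`.
#' @param genotypes optional data.frame `sample_id` + SNP dosage columns.
#' @param loci loci to model.
#' @param scopes `"per_study"`, `"pooled"`, or both.
#' @param adjustments list of covariate sets (named; pooled fits add `study`
#'   automatically when it has > 1 level).
#' @param conditioning_sets named list of SNP-name vectors (see
#'   [leave_one_out_sets()]); `NULL` means unconditioned only.
#' @param strata named list of sample-id vectors (see [stratify_cohort()]);
#'   `NULL` means no stratification.
#' @return data.frame with one row per grid cell: locus, scope, model,
#'   conditioning, stratum, estimates and `note` (`"ok"` or the error
#'   message).
#' @export
run_model_grid <- function(cohort, calls, genotypes = NULL,
                           loci = c("C4A", "C4B", "totalC4"),
                           scopes = c("per_study", "pooled"),
                           adjustments = list(adjusted = c("age", "sex")),
                           conditioning_sets = NULL,
                           strata = NULL) {
  loci <- intersect(loci, unique(calls$locus))
  cond_sets <- conditioning_sets %||% list(none = character(0))
  strata_list <- strata %||% list(all = cohort$sample_id)
  scope_defs <- list()
  if ("per_study" %in% scopes)
    for (s in sort(unique(cohort$study)))
      scope_defs[[s]] <- cohort$sample_id[cohort$study == s]
  if ("pooled" %in% scopes) scope_defs[["pooled"]] <- cohort$sample_id

  rows <- list()
  for (loc in loci) for (sc in names(scope_defs)) for (adj in names(adjustments))
    for (cs in names(cond_sets)) for (st in names(strata_list)) {
      snps <- cond_sets[[cs]]
      if (length(snps) && is.null(genotypes)) next
      ids <- intersect(scope_defs[[sc]], strata_list[[st]])
      covs <- adjustments[[adj]]
      if (sc == "pooled" && length(covs)) covs <- union(covs, "study")
      cond <- if (length(snps)) genotypes[, c("sample_id", snps), drop = FALSE] else NULL
      res <- tryCatch(
        fit_cn_logistic(cohort, calls, loc, covariates = covs,
                        conditioning = cond, stratum = ids, stratum_label = st),
        error = function(e) conditionMessage(e))
      base <- data.frame(locus = loc, scope = sc, model = adj,
                         conditioning = cs, stratum = st,
                         stringsAsFactors = FALSE)
      if (is.character(res)) {
        base <- cbind(base, data.frame(beta = NA_real_, se = NA_real_,
                                       or = NA_real_, ci_low = NA_real_,
                                       ci_high = NA_real_, p = NA_real_,
                                       n_cases = NA_integer_, n_controls = NA_integer_,
                                       note = res, stringsAsFactors = FALSE))
      } else {
        r <- as.data.frame(res)
        base <- cbind(base, r[, c("beta", "se", "or", "ci_low", "ci_high", "p",
                                  "n_cases", "n_controls")])
        base$note <- "ok"
      }
      rows[[length(rows) + 1L]] <- base
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
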