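#' Apply the study exclusion rule
#'
#' Drops records with missing histology or missing CTC count and reports
#' the bookkeeping: input, per-reason, and retained counts always sum.
#'
#' @param records Cohort `data.frame`.
#' @return A list: `retained` (data.frame) and `report` (list with
#'   `n_input`, `n_excluded`, `n_retained`, `reasons`).
#' @export
apply_exclusions <- function(records) {
  miss_hist <- is.na(records$histology)
  miss_ctc <- is.na(records$ctc_per_ml)
  excluded <- miss_hist | miss_ctc
  list(
    retained = records[!excluded, , drop = FALSE],
    report = list(
      n_input = nrow(records),
      n_excluded = sum(excluded),
      n_retained = sum(!excluded),
      reasons = c(missing_histology = sum(miss_hist),
                  missing_ctc = sum(miss_ctc & !miss_hist))
    )
  )
}

#' Stratify a cohort by enumeration method and treatment
#'
#' Partitions retained records into the four method x treatment cells;
#' in the IE/FC stratum, primary surgery is "cohort A" and neoadjuvant
#' therapy is "cohort B".
#'
#' @param records Cohort `data.frame` (post-exclusion).
#' @return A `stratified_cohorts` list: `subsets` (named list of
#'   data.frames keyed `METHOD.treatment`), `sizes` (named integer
#'   vector), `n_total`.
#' @export
stratify_cohort <- function(records) {
  subsets <- list()
  for (m in METHOD_LEVELS) {
    for (tr in TREATMENT_LEVELS) {
      key <- paste(m, tr, sep = ".")
      subsets[[key]] <- records[!is.na(records$method) & records$method == m &
                                  !is.na(records$treatment) &
                                  records$treatment == tr, , drop = FALSE]
    }
  }
  sizes <- vapply(subsets, nrow, integer(1))
  structure(list(subsets = subsets, sizes = sizes, n_total = nrow(records)),
            class = "stratified_cohorts")
}

#' Marker positivity rate by histology
#'
#' Fraction of subjects with any detectable marker (value > 0) per
#' histology, with a Fisher exact p-value for the 2x2 histology x
#' positivity table.
#'
#' @param records Cohort `data.frame`.
#' @param marker `"ctc"` or `"dtc"`.
#' @return A list: `rates` (named fraction per histology), `n` (non-missing
#'   per histology), `table` (2x2 counts), `p_value`.
#' @export
positivity_rate <- function(records, marker = c("ctc", "dtc")) {
  col <- MARKER_COLUMNS[[match.arg(marker)]]
  ok <- !is.na(records[[col]]) & !is.na(records$histology)
  d <- records[ok, , drop = FALSE]
  pos <- d[[col]] > 0
  tab <- matrix(0L, 2, 2,
                dimnames = list(HISTOLOGY_LEVELS, c("positive", "negative")))
  for (h in HISTOLOGY_LEVELS) {
    tab[h, "positive"] <- sum(pos & d$histology == h)
    tab[h, "negative"] <- sum(!pos & d$histology == h)
  }
  rates <- tab[, "positive"] / rowSums(tab)
  p <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    fisher_exact(tab)$p_value
  } else 1
  list(rates = rates, n = rowSums(tab), table = tab, p_value = p)
}

#' Compare marker counts between histologies
#'
#' Raw-scale group means with a Welch two-sample t-test, and optionally a
#' covariate-adjusted comparison: the marker (log10(x + 1)-transformed by
#' default, to tame the right skew) regressed on histology plus age, grade,
#' stage, and receptor subtype on complete cases; the adjusted p-value is
#' the Wald test of the histology coefficient.  Covariates with a single
#' observed level are dropped with a warning.
#'
#' @param records Cohort subset `data.frame`.
#' @param marker `"ctc"` or `"dtc"`.
#' @param adjust Fit the covariate-adjusted model as well?
#' @param transform Transform for testing/adjustment: `"log10p1"`
#'   (default) or `"identity"`.
#' @param welch_on_transformed Apply the Welch test on the transformed
#'   scale instead of the raw scale (default `FALSE`, mirroring reported
#'   raw means).
#' @return A `comparison_result` list: `means`, `n`, `difference` (ILC
#'   minus IDC, raw scale), `p_unadjusted`, `p_adjusted` (`NA` when
#'   `adjust = FALSE`), `transform`, `n_complete`, `dropped_covariates`.
#' @export
compare_counts <- function(records, marker = c("ctc", "dtc"), adjust = TRUE,
                           transform = c("log10p1", "identity"),
                           welch_on_transformed = FALSE) {
  col <- MARKER_COLUMNS[[match.arg(marker)]]
  transform <- match.arg(transform)
  tf <- if (transform == "log10p1") function(x) log10(x + 1) else identity
  ok <- !is.na(records[[col]]) & !is.na(records$histology)
  d <- records[ok, , drop = FALSE]
  x_ilc <- d[[col]][d$histology == "ILC"]
  x_idc <- d[[col]][d$histology == "IDC"]
  if (length(x_ilc) < 2 || length(x_idc) < 2) {
    stop("compare_counts: need at least 2 subjects per histology",
         call. = FALSE)
  }
  wt <- if (welch_on_transformed) welch_t(tf(x_ilc), tf(x_idc))
        else welch_t(x_ilc, x_idc)
  means <- c(ILC = mean(x_ilc), IDC = mean(x_idc))
  p_adj <- NA_real_
  n_complete <- NA_integer_
  dropped <- character(0)
  if (adjust) {
    md <- data.frame(
      y = tf(d[[col]]),
      histology = factor(d$histology, HISTOLOGY_LEVELS),
      age = d$age,
      grade = factor(d$grade, c(1, 2, 3)),
      stage = factor(d$stage, c(1, 2, 3)),
      subtype = factor(d$receptor_subtype, SUBTYPE_LEVELS)
    )
    md <- md[complete.cases(md), , drop = FALSE]
    covs <- c("age", "grade", "stage", "subtype")
    for (cv in covs) {
      v <- md[[cv]]
      nlev <- if (is.factor(v)) nlevels(droplevels(v)) else length(unique(v))
      if (nlev < 2) {
        dropped <- c(dropped, cv)
        warning(sprintf("compare_counts: covariate '%s' has a single level; dropped", cv),
                call. = FALSE)
      }
    }
    use <- setdiff(covs, dropped)
    fml <- stats::as.formula(paste("y ~ histology",
                                   paste(c("", use), collapse = " + ")))
    fit <- lm(fml, data = droplevels(md))
    ct <- summary(fit)$coefficients
    row <- grep("^histology", rownames(ct))
    p_adj <- unname(ct[row, "Pr(>|t|)"])
    n_complete <- nrow(md)
  }
  structure(list(means = means, n = c(ILC = length(x_ilc), IDC = length(x_idc)),
                 difference = unname(means["ILC"] - means["IDC"]),
                 p_unadjusted = wt$p_value, p_adjusted = p_adj,
                 transform = transform, n_complete = n_complete,
                 dropped_covariates = dropped),
            class = "comparison_result")
}

fmt_pct <- function(num, denom, digits = 1) {
  round(100 * num / denom, digits)
}

#' Cohort characteristics table by histology
#'
#' Summarizes age as mean (SD) with a Welch t-test p-value and receptor
#' subtype, stage, grade, and treatment as n (%) over non-missing subjects
#' with a Fisher exact p-value (r x c; Monte-Carlo fallback for infeasible
#' enumeration).  Percentages use non-missing denominators; unknown counts
#' are reported separately, matching the usual clinical-table convention.
#'
#' @param records Cohort subset `data.frame`.
#' @param variables Which variables to tabulate.
#' @return A `characteristics_table` list of per-variable entries; each
#'   categorical entry has a `levels` data.frame (level, n and pct per
#'   histology), `unknown` counts, `p_value`, `test`; the age entry has
#'   per-group `mean`, `sd`, `n`.
#' @export
characteristics_table <- function(records,
                                  variables = c("age", "receptor_subtype",
                                                "stage", "grade",
                                                "treatment")) {
  d <- records[!is.na(records$histology), , drop = FALSE]
  for (h in HISTOLOGY_LEVELS) {
    if (!any(d$histology == h)) {
      stop(sprintf("characteristics_table: group '%s' is empty", h),
           call. = FALSE)
    }
  }
  out <- list()
  for (v in variables) {
    if (v == "age") {
      x <- lapply(HISTOLOGY_LEVELS, function(h)
        d$age[d$histology == h & !is.na(d$age)])
      names(x) <- HISTOLOGY_LEVELS
      p <- if (all(lengths(x) >= 2)) welch_t(x$ILC, x$IDC)$p_value
           else NA_real_
      out[[v]] <- list(type = "continuous",
                       mean = vapply(x, mean, numeric(1)),
                       sd = vapply(x, sd, numeric(1)),
                       n = lengths(x),
                       unknown = vapply(HISTOLOGY_LEVELS, function(h)
                         sum(d$histology == h & is.na(d$age)), integer(1)),
                       p_value = p, test = "Welch two-sample t-test")
      next
    }
    vals <- d[[v]]
    levels_v <- sort(unique(vals[!is.na(vals)]))
    tab <- matrix(0L, length(levels_v), 2,
                  dimnames = list(as.character(levels_v), HISTOLOGY_LEVELS))
    for (h in HISTOLOGY_LEVELS) {
      for (lv in seq_along(levels_v)) {
        tab[lv, h] <- sum(!is.na(vals) & vals == levels_v[lv] &
                            d$histology == h)
      }
    }
    unknown <- vapply(HISTOLOGY_LEVELS, function(h)
      sum(is.na(vals) & d$histology == h), integer(1))
    denom <- colSums(tab)
    lev_df <- data.frame(level = as.character(levels_v),
                         stringsAsFactors = FALSE)
    for (h in HISTOLOGY_LEVELS) {
      lev_df[[paste0("n_", h)]] <- tab[, h]
      lev_df[[paste0("pct_", h)]] <- fmt_pct(tab[, h], denom[h])
    }
    p <- NA_real_
    test <- "Fisher's exact test"
    if (nrow(tab) >= 2 && all(colSums(tab) > 0) &&
        all(rowSums(tab) > 0)) {
      fr <- fisher_exact(tab)
      p <- fr$p_value
      test <- fr$method_name
    }
    out[[v]] <- list(type = "categorical", levels = lev_df,
                     unknown = unknown, p_value = p, test = test)
  }
  structure(out, class = "characteristics_table")
}

#' Survival analysis across marker-defined groups
#'
#' For one endpoint and one grouping (high/low from a single marker, or
#' the four-group CTC x DTC cross-classification), computes per-level
#' Kaplan-Meier curves, a log-rank test across levels (two-level groupings
#' use the in-package test; multi-level groupings the k-sample chi-square),
#' a univariate Cox model with the low (or low/low) level as reference,
#' and optionally a multivariate Cox model adding age, stage, grade, and
#' receptor subtype (complete cases).  Levels with zero events yield
#' non-estimable hazard ratios (flagged, not silently reported).
#'
#' @param records Cohort subset `data.frame`.
#' @param endpoint `"drfs"` or `"bcss"`.
#' @param labels Character vector of group labels aligned with `records`
#'   (from [classify_high_low()] or [four_group_label()]); `"missing"` /
#'   `"incomplete"` rows are dropped.
#' @param multivariate Fit the covariate-adjusted Cox model as well?
#' @return A `survival_by_group` list: `km` (per-level `km_curve`),
#'   `logrank_p`, `cox_univariate`, `cox_multivariate` (or `NULL`),
#'   `n_per_level`, `events_per_level`, `reference_level`, `endpoint`.
#' @export
survival_by_group <- function(records, endpoint = c("drfs", "bcss"), labels,
                              multivariate = TRUE) {
  endpoint <- match.arg(endpoint)
  stopifnot(length(labels) == nrow(records))
  keep <- !labels %in% c("missing", "incomplete") & !is.na(labels)
  d <- records[keep, , drop = FALSE]
  g <- labels[keep]
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  ok <- !is.na(d[[tcol]]) & !is.na(d[[ecol]])
  d <- d[ok, , drop = FALSE]; g <- g[ok]
  lvl_order <- c("low", "high", "low/low", "low/high", "high/low",
                 "high/high")
  lv <- unique(g)
  lv <- c(intersect(lvl_order, lv), setdiff(sort(lv), lvl_order))
  g <- factor(g, levels = lv)
  if (sum(d[[ecol]]) < 1) {
    stop("survival_by_group: no events in the subset", call. = FALSE)
  }
  km <- lapply(lv, function(l)
    km_estimate(d[[tcol]][g == l], d[[ecol]][g == l]))
  names(km) <- lv
  logrank_p <- if (nlevels(g) == 2) {
    logrank_test(survival_data(d[[tcol]], d[[ecol]], g))$p_value
  } else {
    sdf <- survdiff(Surv(d[[tcol]], d[[ecol]]) ~ g)
    pchisq(sdf$chisq, df = nlevels(g) - 1, lower.tail = FALSE)
  }
  cox_uni <- cox_fit(d[[tcol]], d[[ecol]], data.frame(group = g))
  cox_multi <- NULL
  if (multivariate) {
    md <- data.frame(time = d[[tcol]], event = d[[ecol]], group = g,
                     age = d$age,
                     stage = factor(d$stage, c(1, 2, 3)),
                     grade = factor(d$grade, c(1, 2, 3)),
                     subtype = factor(d$receptor_subtype, SUBTYPE_LEVELS))
    md <- droplevels(md[complete.cases(md), , drop = FALSE])
    covs <- Filter(function(cv) {
      v <- md[[cv]]
      if (is.factor(v)) nlevels(v) >= 2 else length(unique(v)) >= 2
    }, c("age", "stage", "grade", "subtype"))
    if (nlevels(md$group) >= 2 && sum(md$event) >= 1) {
      cox_multi <- cox_fit(md$time, md$event,
                           md[, c("group", covs), drop = FALSE])
    }
  }
  structure(list(km = km, logrank_p = logrank_p, cox_univariate = cox_uni,
                 cox_multivariate = cox_multi,
                 n_per_level = table(g),
                 events_per_level = tapply(d[[ecol]], g, sum),
                 reference_level = lv[1], endpoint = endpoint),
            class = "survival_by_group")
}
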