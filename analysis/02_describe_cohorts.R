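#!/usr/bin/env Rscript
# Cohort description: exclusions on the full-study cohort, stratification
# by enumeration method and treatment, CTC positivity in the CellSearch
# stratum, characteristics tables and marker-count comparisons for the
# IE/FC cohorts A (primary surgery) and B (neoadjuvant).

suppressPackageStartupMessages(library(ctcdtc))
dir.create("results", showWarnings = FALSE)

full <- read_cohort("results/cohort_full.csv")
ex <- apply_exclusions(full)
cat(sprintf("exclusions: %d in, %d dropped (%d no histology, %d no CTCs), %d retained\n",
            ex$report$n_input, ex$report$n_excluded,
            ex$report$reasons[["missing_histology"]],
            ex$report$reasons[["missing_ctc"]], ex$report$n_retained))

st <- stratify_cohort(ex$retained)
cat("stratum sizes:\n"); print(st$sizes)

cs <- ex$retained[ex$retained$method == "CellSearch", ]
pr <- positivity_rate(cs, "ctc")
cat(sprintf("CellSearch CTC positivity: ILC %.1f%% vs IDC %.1f%% (Fisher p = %.2f)\n",
            100 * pr$rates[["ILC"]], 100 * pr$rates[["IDC"]], pr$p_value))

iefc <- read_cohort("results/cohort_iefc.csv")
rows <- list()
for (tr in c("primary_surgery", "neoadjuvant")) {
  sub <- iefc[iefc$treatment == tr, ]
  label <- if (tr == "primary_surgery") "cohort A" else "cohort B"
  for (mk in c("ctc", "dtc")) {
    cc <- compare_counts(sub, mk, adjust = TRUE)
    cat(sprintf("%s %s: ILC mean %.2f (n=%d) vs IDC %.2f (n=%d); Welch p = %.3g, adjusted p = %.3g\n",
                label, toupper(mk), cc$means[["ILC"]], cc$n[["ILC"]],
                cc$means[["IDC"]], cc$n[["IDC"]], cc$p_unadjusted,
                cc$p_adjusted))
    rows[[length(rows) + 1]] <- data.frame(
      cohort = label, marker = mk, mean_ilc = cc$means[["ILC"]],
      mean_idc = cc$means[["IDC"]], n_ilc = cc$n[["ILC"]],
      n_idc = cc$n[["IDC"]], p_welch = cc$p_unadjusted,
      p_adjusted = cc$p_adjusted)
  }
}
write.csv(do.call(rbind, rows), "results/count_comparisons.csv",
          row.names = FALSE)

# characteristics tables, flattened to CSV
flatten_ct <- function(ct, cohort) {
  out <- list()
  for (v in names(ct)) {
    e <- ct[[v]]
    if (e$type == "continuous") {
      out[[v]] <- data.frame(cohort = cohort, variable = v, level = "",
                             n_ILC = e$n[["ILC"]], pct_ILC = NA,
                             n_IDC = e$n[["IDC"]], pct_IDC = NA,
                             mean_ILC = e$mean[["ILC"]], sd_ILC = e$sd[["ILC"]],
                             mean_IDC = e$mean[["IDC"]], sd_IDC = e$sd[["IDC"]],
                             p_value = e$p_value, test = e$test)
    } else {
      lv <- e$levels
      out[[v]] <- data.frame(cohort = cohort, variable = v, level = lv$level,
                             n_ILC = lv$n_ILC, pct_ILC = lv$pct_ILC,
                             n_IDC = lv$n_IDC, pct_IDC = lv$pct_IDC,
                             mean_ILC = NA, sd_ILC = NA, mean_IDC = NA,
                             sd_IDC = NA, p_value = e$p_value, test = e$test)
    }
  }
  do.call(rbind, out)
}
tabs <- rbind(
  flatten_ct(characteristics_table(iefc[iefc$treatment == "primary_surgery", ]),
             "cohort A"),
  flatten_ct(characteristics_table(iefc[iefc$treatment == "neoadjuvant", ]),
             "cohort B"))
write.csv(tabs, "results/characteristics_tables.csv", row.names = FALSE)
cat("wrote results/count_comparisons.csv and results/characteristics_tables.csv\n")
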