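test_that("exclusions drop missing histology or CTC and conserve counts", {
  co <- make_cohort(50, seed = 1)
  co$histology[1:4] <- NA
  co$ctc_per_ml[3:10] <- NA  # overlaps rows 3,4
  ex <- apply_exclusions(co)
  expect_equal(ex$report$n_input, 50)
  expect_equal(ex$report$n_excluded, 10)
  expect_equal(ex$report$n_retained, 40)
  expect_equal(ex$report$n_excluded + ex$report$n_retained,
               ex$report$n_input)
  expect_equal(sum(ex$report$reasons), ex$report$n_excluded)
  expect_false(any(is.na(ex$retained$histology)))
  expect_false(any(is.na(ex$retained$ctc_per_ml)))

  # no missingness: identity
  co2 <- make_cohort(20, seed = 2)
  ex2 <- apply_exclusions(co2)
  expect_equal(ex2$retained, co2)
  expect_equal(ex2$report$n_excluded, 0)

  # everything missing: zero retained, totals still conserved
  co3 <- make_cohort(5, seed = 3)
  co3$ctc_per_ml <- NA_real_
  ex3 <- apply_exclusions(co3)
  expect_equal(ex3$report$n_retained, 0)
  expect_equal(ex3$report$n_excluded, 5)
})

test_that("stratification partitions by method and treatment", {
  co <- make_cohort(60, seed = 4,
                    method = sample(c("IEFC", "CellSearch"), 60, TRUE))
  st <- stratify_cohort(co)
  expect_equal(sum(st$sizes), nrow(co))
  expect_equal(st$n_total, 60)
  for (key in names(st$subsets)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    s <- st$subsets[[key]]
    expect_true(all(s$method == parts[1]))
    expect_true(all(s$treatment == parts[2]))
  }

  co_iefc <- make_cohort(30, seed = 5, method = rep("IEFC", 30))
  st2 <- stratify_cohort(co_iefc)
  expect_equal(nrow(st2$subsets[["CellSearch.primary_surgery"]]), 0)
  expect_equal(nrow(st2$subsets[["CellSearch.neoadjuvant"]]), 0)
})

test_that("positivity rates and their Fisher test behave at the edges", {
  co <- make_cohort(40, seed = 6, ctc = rep(0, 40))
  pr <- positivity_rate(co, "ctc")
  expect_equal(unname(pr$rates), c(0, 0))
  expect_equal(pr$p_value, 1)

  co2 <- make_cohort(40, seed = 7, ctc = runif(40, 0.1, 5))
  pr2 <- positivity_rate(co2, "ctc")
  expect_equal(unname(pr2$rates), c(1, 1))

  # detection rates near 21.6% vs 23.4% at study-like group sizes are
  # compatible with no histology difference
  n_ilc <- 88; n_idc <- 520
  co3 <- make_cohort(n_ilc + n_idc, seed = 8,
                     histology = rep(c("ILC", "IDC"), c(n_ilc, n_idc)),
                     ctc = c(rep(c(1, 0), c(19, 69)),
                             rep(c(1, 0), c(122, 398))))
  pr3 <- positivity_rate(co3, "ctc")
  expect_equal(unname(pr3$rates["ILC"]), 19 / 88, tolerance = 1e-12)
  expect_equal(unname(pr3$rates["IDC"]), 122 / 520, tolerance = 1e-12)
  # cross-check against the direct 2x2 computation
  expect_equal(pr3$p_value,
               fisher.test(matrix(c(19, 69, 122, 398), 2,
                                  byrow = TRUE))$p.value,
               tolerance = 1e-12)
  expect_gt(pr3$p_value, 0.05)
})

test_that("count comparisons report raw means and adjusted p-values", {
  # two identical groups: difference 0, p 1
  vals <- rep(c(0, 1, 2, 5), 10)
  co <- make_cohort(80, seed = 9,
                    histology = rep(c("ILC", "IDC"), each = 40),
                    ctc = c(vals, vals))
  cc <- compare_counts(co, "ctc", adjust = FALSE)
  expect_equal(cc$difference, 0)
  expect_equal(cc$p_unadjusted, 1)

  # generator consistency: ILC - IDC mean CTC difference targets
  # 2.11 - 0.71 = 1.40 in the primary-surgery stratum at large n
  spec <- default_cohort_spec(seed = 123)
  spec$n_patients <- 5000L
  big <- generate_cohort(spec)
  surg <- big[big$treatment == "primary_surgery", ]
  cc2 <- compare_counts(surg, "ctc", adjust = TRUE)
  x_ilc <- surg$ctc_per_ml[surg$histology == "ILC"]
  x_idc <- surg$ctc_per_ml[surg$histology == "IDC"]
  se <- sqrt(var(x_ilc) / length(x_ilc) + var(x_idc) / length(x_idc))
  expect_lt(abs(cc2$difference - 1.40), 3 * se)
  expect_lt(cc2$p_unadjusted, 0.01)
  expect_lt(cc2$p_adjusted, 0.01)

  # no-confounding limit: with covariates independent of the marker and no
  # histology effect, the adjusted p tracks the same-scale unadjusted p
  diffs <- vapply(1:60, function(r) {
    null_co <- generate_cohort(validation_cohort_spec(150, seed = 3000 + r))
    cn <- suppressWarnings(compare_counts(null_co, "ctc", adjust = TRUE,
                                          welch_on_transformed = TRUE))
    abs(cn$p_adjusted - cn$p_unadjusted)
  }, numeric(1))
  expect_lt(mean(diffs), 0.15)

  # single-level covariate dropped with a warning
  co3 <- make_cohort(60, seed = 10)
  co3$stage <- 2L
  expect_warning(compare_counts(co3, "ctc", adjust = TRUE), "stage")
})

test_that("characteristics table reproduces printed cell conventions", {
  # subtype column mirroring the primary-surgery ILC counts:
  # 53 HR+HER2-, 1 HR-/HER2-, 6 HER2+, 1 unknown of 61
  ilc_sub <- c(rep("HR+HER2-", 53), rep("HR-/HER2-", 1), rep("HER2+", 6),
               NA)
  idc_sub <- c(rep("HR+HER2-", 153), rep("HR-/HER2-", 20), rep("HER2+", 38),
               rep(NA, 12))
  n <- length(ilc_sub) + length(idc_sub)
  co <- make_cohort(n, seed = 11,
                    histology = rep(c("ILC", "IDC"),
                                    c(length(ilc_sub), length(idc_sub))))
  co$receptor_subtype <- c(ilc_sub, idc_sub)
  ct <- characteristics_table(co)
  sub <- ct$receptor_subtype
  row <- sub$levels[sub$levels$level == "HR+HER2-", ]
  expect_equal(row$n_ILC, 53)
  expect_equal(row$pct_ILC, round(100 * 53 / 60, 1))  # 88.3% of non-missing
  expect_equal(unname(sub$unknown["ILC"]), 1)
  expect_equal(row$n_IDC, 153)
  expect_equal(row$pct_IDC, round(100 * 153 / 211, 1))
  expect_true(is.finite(sub$p_value))

  # age row carries Welch p
  expect_equal(ct$age$test, "Welch two-sample t-test")
  expect_true(ct$age$p_value >= 0 && ct$age$p_value <= 1)

  # empty group named in the error
  co_empty <- make_cohort(10, seed = 12, histology = rep("IDC", 10))
  expect_error(characteristics_table(co_empty), "ILC")

  # an all-missing variable is reported without a p-value
  co_na <- make_cohort(30, seed = 13)
  co_na$grade <- NA_integer_
  ct_na <- characteristics_table(co_na)
  expect_equal(sum(ct_na$grade$unknown), 30)
  expect_true(is.na(ct_na$grade$p_value))
})

test_that("survival by group recovers planted effects and flags degeneracy", {
  # identical survival in both groups: HR ~ 1
  tm <- rep(c(1, 2, 3, 4, 5), 2)
  ev <- rep(c(1, 0, 1, 1, 0), 2)
  co <- make_cohort(10, seed = 14)
  co$drfs_time <- tm
  co$drfs_event <- ev
  labels <- rep(c("low", "high"), each = 5)
  sv <- survival_by_group(co, "drfs", labels, multivariate = FALSE)
  expect_equal(sv$cox_univariate$coefficients$hazard_ratio, 1,
               tolerance = 1e-6)
  expect_equal(sv$reference_level, "low")

  # KM curves equal the per-stratum product-limit estimates exactly
  km_low <- km_estimate(tm[labels == "low"], ev[labels == "low"])
  expect_equal(sv$km$low$survival, km_low$survival)

  # planted hazard step recovered by the univariate Cox fit
  pl <- make_planted_cohort(800, seed = 21)
  lab <- classify_high_low(pl$cohort, "ctc", pl$threshold)
  sv2 <- survival_by_group(pl$cohort, "drfs", lab, multivariate = TRUE)
  cf <- sv2$cox_univariate$coefficients
  expect_lt(abs(cf$coef[1] - log(4)) / cf$se[1], 3)
  expect_lt(sv2$logrank_p, 0.001)
  expect_false(is.null(sv2$cox_multivariate))

  # four-group labels where only high/high subjects have events:
  # that contrast is flagged non-estimable, not given a finite HR
  co4 <- make_cohort(80, seed = 15)
  fg <- rep(c("low/low", "low/high", "high/low", "high/high"), each = 20)
  co4$drfs_event <- as.integer(fg == "high/high")
  sv4 <- survival_by_group(co4, "drfs", fg, multivariate = FALSE)
  cf4 <- sv4$cox_univariate$coefficients
  expect_true(any(cf4$non_estimable))
  expect_true(all(is.na(cf4$hazard_ratio[cf4$non_estimable])))
})

test_that("the full analysis runs end to end, skips, and is reproducible", {
  spec <- default_cohort_spec(seed = 77)
  spec$n_patients <- 240L
  co <- generate_cohort(spec)
  cfg <- analysis_config(mccv = mccv_config(n_iterations = 40, seed = 5),
                         seed = 5)
  rep1 <- run_full_analysis(co, cfg)
  expect_named(rep1, c("config", "exclusions", "stratification", "overall",
                       "cohort_a", "cohort_b", "cutpoints", "survival"))
  expect_equal(rep1$exclusions$n_input, 240)
  expect_equal(sum(unlist(rep1$stratification$sizes)),
               rep1$exclusions$n_retained)

  # byte-identical serialized reports under a fixed seed and config
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  write_report(rep1, p1)
  write_report(run_full_analysis(co, cfg), p2)
  expect_identical(readLines(p1), readLines(p2))

  # no neoadjuvant records: cohort B sections skipped, run still succeeds
  co_a <- co[co$treatment == "primary_surgery", ]
  rep2 <- run_full_analysis(co_a, cfg)
  expect_equal(rep2$cohort_b$n, 0)
  expect_true(isTRUE(rep2$cohort_b$counts$skipped))
})
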