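#' Default settings for the full analysis
#'
#' @param mccv An [mccv_config()] used for every cutpoint optimization
#'   (its `seed` is re-derived per histology x marker from `seed`).
#' @param transform Transform for covariate-adjusted count comparisons.
#' @param seed Master seed echoed into the report and used to derive all
#'   stage seeds.
#' @param min_subset_n Minimum subset size for running cutpoint
#'   optimization and survival models on a stratum.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(mccv = mccv_config(), transform = "log10p1",
                            seed = 1L, min_subset_n = 30L) {
  structure(list(mccv = mccv, transform = transform, seed = as.integer(seed),
                 min_subset_n = as.integer(min_subset_n)),
            class = "analysis_config")
}

#' Run the full cohort analysis
#'
#' Orchestrates every stage on a conforming cohort table: exclusions
#' (missing histology or CTC count), stratification by enumeration method
#' and treatment, marker positivity and count comparisons, characteristics
#' tables for the IE/FC primary-surgery (cohort A) and neoadjuvant
#' (cohort B) strata, Monte-Carlo cross-validated cutpoint optimization
#' per histology x marker on cohort A, and dichotomized plus four-group
#' survival analyses at the optimized thresholds.  Strata too small for a
#' stage are marked skipped rather than failing the run.  The report
#' echoes the configuration and master seed, so a fixed seed and config
#' give a byte-identical report.
#'
#' @param cohort Cohort `data.frame` (schema of [generate_cohort()]).
#' @param config An [analysis_config()].
#' @return A nested `analysis_report` list.
#' @export
run_full_analysis <- function(cohort, config = analysis_config()) {
  validate_cohort(cohort)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  excl <- stage("exclusions", apply_exclusions(cohort))
  strata <- stage("stratification", stratify_cohort(excl$retained))

  marker_skip <- function(sub, marker) {
    col <- MARKER_COLUMNS[[marker]]
    n_ok <- sum(!is.na(sub[[col]]))
    tab <- table(sub$histology[!is.na(sub[[col]])])
    n_ok < config$min_subset_n || length(tab) < 2 || any(tab < 2)
  }

  counts_section <- function(sub, label) {
    out <- list()
    for (mk in names(MARKER_COLUMNS)) {
      if (marker_skip(sub, mk)) {
        out[[mk]] <- list(skipped = TRUE)
      } else {
        cc <- compare_counts(sub, mk, adjust = TRUE,
                             transform = config$transform)
        out[[mk]] <- list(skipped = FALSE, means = as.list(cc$means),
                          n = as.list(cc$n), difference = cc$difference,
                          p_unadjusted = cc$p_unadjusted,
                          p_adjusted = cc$p_adjusted,
                          transform = cc$transform)
      }
    }
    out
  }

  iefc <- excl$retained[!is.na(excl$retained$method) &
                          excl$retained$method == "IEFC", , drop = FALSE]
  cellsearch <- excl$retained[!is.na(excl$retained$method) &
                                excl$retained$method == "CellSearch", ,
                              drop = FALSE]
  cohort_a <- strata$subsets[["IEFC.primary_surgery"]]
  cohort_b <- strata$subsets[["IEFC.neoadjuvant"]]

  overall <- list(
    n_retained = excl$report$n_retained,
    n_iefc = nrow(iefc),
    n_cellsearch = nrow(cellsearch),
    pct_iefc = fmt_pct(nrow(iefc), excl$report$n_retained),
    positivity = if (nrow(cellsearch) >= config$min_subset_n &&
                     length(unique(cellsearch$histology)) == 2) {
      pr <- positivity_rate(cellsearch, "ctc")
      list(skipped = FALSE, rates = as.list(pr$rates), n = as.list(pr$n),
           p_value = pr$p_value)
    } else list(skipped = TRUE)
  )

  characteristics <- function(sub) {
    if (nrow(sub) < 4 || length(unique(sub$histology)) < 2) {
      return(list(skipped = TRUE))
    }
    ct <- characteristics_table(sub)
    list(skipped = FALSE, table = unclass(ct))
  }

  run_cutpoints <- function(sub) {
    out <- list()
    i <- 0L
    for (h in HISTOLOGY_LEVELS) {
      hs <- sub[!is.na(sub$histology) & sub$histology == h, , drop = FALSE]
      for (mk in names(MARKER_COLUMNS)) {
        i <- i + 1L
        key <- paste(h, mk, sep = ".")
        n_ok <- sum(!is.na(hs[[MARKER_COLUMNS[[mk]]]]))
        if (n_ok < max(20L, config$min_subset_n)) {
          out[[key]] <- list(skipped = TRUE, n = n_ok)
          next
        }
        cfg <- config$mccv
        cfg$seed <- derive_seed(config$seed, 100 + i)
        res <- tryCatch(mccv_optimize(hs, mk, cfg),
                        error = function(e) NULL)
        out[[key]] <- if (is.null(res)) list(skipped = TRUE, n = n_ok) else {
          list(skipped = FALSE, n = n_ok,
               chosen_threshold = res$chosen_threshold,
               combined_p = res$combined_p,
               n_usable_iterations = res$n_usable_iterations,
               n_candidates = length(res$candidates))
        }
      }
    }
    out
  }

  cutpoints <- if (nrow(cohort_a) >= config$min_subset_n) {
    run_cutpoints(cohort_a)
  } else list(skipped = TRUE)

  cox_rows <- function(cx) {
    if (is.null(cx)) return(NULL)
    cf <- cx$coefficients
    lapply(seq_len(nrow(cf)), function(i) list(
      term = cf$term[i], hazard_ratio = cf$hazard_ratio[i],
      ci_low = cf$ci_low[i], ci_high = cf$ci_high[i],
      p_value = cf$p_value[i], non_estimable = cf$non_estimable[i]))
  }

  run_survival <- function(sub, cp) {
    out <- list()
    for (h in HISTOLOGY_LEVELS) {
      hs <- sub[!is.na(sub$histology) & sub$histology == h, , drop = FALSE]
      lab <- list()
      for (mk in names(MARKER_COLUMNS)) {
        key <- paste(h, mk, sep = ".")
        entry <- cp[[key]]
        if (is.null(entry) || isTRUE(entry$skipped)) {
          out[[key]] <- list(skipped = TRUE)
          next
        }
        lab[[mk]] <- classify_high_low(hs, mk, entry$chosen_threshold)
        eps <- list()
        for (ep in ENDPOINTS) {
          sv <- tryCatch(
            survival_by_group(hs, ep, lab[[mk]], multivariate = TRUE),
            error = function(e) NULL)
          eps[[ep]] <- if (is.null(sv)) list(skipped = TRUE) else list(
            skipped = FALSE, logrank_p = sv$logrank_p,
            n_per_level = as.list(sv$n_per_level),
            events_per_level = as.list(sv$events_per_level),
            cox_univariate = cox_rows(sv$cox_univariate),
            cox_multivariate = cox_rows(sv$cox_multivariate))
        }
        out[[key]] <- list(skipped = FALSE,
                           threshold = entry$chosen_threshold,
                           endpoints = eps)
      }
      if (length(lab) == 2) {
        fg <- four_group_label(lab$ctc, lab$dtc)
        eps <- list()
        for (ep in ENDPOINTS) {
          sv <- tryCatch(
            survival_by_group(hs, ep, fg, multivariate = TRUE),
            error = function(e) NULL)
          eps[[ep]] <- if (is.null(sv)) list(skipped = TRUE) else list(
            skipped = FALSE, logrank_p = sv$logrank_p,
            n_per_level = as.list(sv$n_per_level),
            events_per_level = as.list(sv$events_per_level),
            cox_univariate = cox_rows(sv$cox_univariate),
            cox_multivariate = cox_rows(sv$cox_multivariate))
        }
        out[[paste(h, "four_group", sep = ".")]] <-
          list(skipped = FALSE, endpoints = eps)
      }
    }
    out
  }

  survival_section <- if (!isTRUE(cutpoints$skipped) &&
                          nrow(cohort_a) >= config$min_subset_n) {
    run_survival(cohort_a, cutpoints)
  } else list(skipped = TRUE)

  structure(list(
    config = list(seed = config$seed, transform = config$transform,
                  mccv = unclass(config$mccv),
                  min_subset_n = config$min_subset_n),
    exclusions = excl$report,
    stratification = list(sizes = as.list(strata$sizes),
                          n_total = strata$n_total),
    overall = overall,
    cohort_a = list(n = nrow(cohort_a),
                    characteristics = characteristics(cohort_a),
                    counts = if (nrow(cohort_a) >= config$min_subset_n)
                      counts_section(cohort_a) else list(skipped = TRUE)),
    cohort_b = list(n = nrow(cohort_b),
                    characteristics = characteristics(cohort_b),
                    counts = if (nrow(cohort_b) >= config$min_subset_n)
                      counts_section(cohort_b) else list(skipped = TRUE)),
    cutpoints = cutpoints,
    survival = survival_section
  ), class = "analysis_report")
}

#' Hash a configuration for provenance stamping
#'
#' @param config Any serializable R object.
#' @return MD5 hex digest of the object's canonical JSON form.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Serialize an analysis report to JSON
#'
#' Writes the report with a provenance header (package version, config
#' hash, master seed) as deterministic JSON: the same report always
#' produces byte-identical output.
#'
#' @param report An `analysis_report` from [run_full_analysis()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  payload <- c(
    list(provenance = list(
      package = "ctcdtc",
      version = as.character(packageVersion("ctcdtc")),
      config_hash = config_hash(report$config),
      seed = report$config$seed
    )),
    unclass(report)
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 6,
                           pretty = TRUE, force = TRUE, null = "null",
                           na = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}
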