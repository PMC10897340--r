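# Substream seeds: one per column group, derived from the master seed so
# that adding a later column group never perturbs earlier draws.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1e6) * 1000 + 7 * offset + 1)
}

with_substream <- function(seed, offset, expr) {
  set.seed(derive_seed(seed, offset))
  expr
}

#' Generate a synthetic patient cohort
#'
#' Draws `spec$n_patients` patient records from the model described by a
#' [cohort_spec()]: histology, treatment and enumeration method as
#' independent Bernoulli draws; age normal within histology; receptor
#' subtype, stage and grade categorical within histology; CTC and DTC
#' counts from per-stratum zero-inflated log-normal models; and two
#' censored endpoints (DRFS, BCSS) with exponential event times and uniform
#' censoring.  If the survival model carries a `planted_cutpoint`, the
#' event hazard of the affected endpoint is multiplied by its hazard ratio
#' for patients whose marker value is strictly greater than the threshold.
#' Observed time is the minimum of event and censoring time; the event
#' indicator is 1 when the event time comes first.
#'
#' Generation is fully determined by `spec$seed`; per-column-group
#' substreams make the output byte-stable under schema extension.
#'
#' @param spec A validated [cohort_spec()].
#' @return A `data.frame` with one row per patient and the cohort schema
#'   columns (`patient_id`, `histology`, `age`, `receptor_subtype`,
#'   `stage`, `grade`, `treatment`, `method`, `ctc_per_ml`, `dtc_per_ml`,
#'   `drfs_time`, `drfs_event`, `bcss_time`, `bcss_event`).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_patients
  seed <- spec$seed

  histology <- with_substream(seed, 1,
    ifelse(runif(n) < spec$prop_ilc, "ILC", "IDC"))
  treatment <- with_substream(seed, 2,
    ifelse(runif(n) < spec$prop_neoadjuvant, "neoadjuvant", "primary_surgery"))
  method <- with_substream(seed, 3,
    ifelse(runif(n) < spec$prop_cellsearch, "CellSearch", "IEFC"))
  age <- with_substream(seed, 4, {
    mu <- spec$age_mean_by_histology[histology]
    sdv <- spec$age_sd_by_histology[histology]
    round(pmax(18, rnorm(n, mu, sdv)), 1)
  })
  draw_cat <- function(probs, levels) {
    u <- runif(n)
    out <- character(n)
    for (h in HISTOLOGY_LEVELS) {
      idx <- histology == h
      br <- cumsum(probs[[h]])
      out[idx] <- levels[findInterval(u[idx], c(0, br[-length(br)]),
                                      left.open = FALSE)]
    }
    out
  }
  receptor_subtype <- with_substream(seed, 5,
    draw_cat(spec$subtype_probs, SUBTYPE_LEVELS))
  stage <- with_substream(seed, 6,
    as.integer(draw_cat(spec$stage_probs, c("1", "2", "3"))))
  grade <- with_substream(seed, 7,
    as.integer(draw_cat(spec$grade_probs, c("1", "2", "3"))))

  draw_marker <- function(marker) {
    mm <- spec$marker_models
    val <- numeric(n)
    for (h in HISTOLOGY_LEVELS) {
      for (tr in TREATMENT_LEVELS) {
        row <- mm[mm$marker == marker & mm$histology == h &
                    mm$treatment == tr, ]
        idx <- which(histology == h & treatment == tr)
        if (!length(idx)) next
        zero <- runif(length(idx)) < row$zero_prob
        pos <- rlnorm(length(idx), row$meanlog, row$sdlog)
        val[idx] <- ifelse(zero, 0, pos)
      }
    }
    val
  }
  ctc_per_ml <- with_substream(seed, 8, draw_marker("ctc"))
  dtc_per_ml <- with_substream(seed, 9, draw_marker("dtc"))

  sm <- spec$survival_model
  marker_values <- list(ctc = ctc_per_ml, dtc = dtc_per_ml)
  draw_endpoint <- function(endpoint) {
    lambda <- rep(sm$rate[[endpoint]], n)
    pc <- sm$planted_cutpoint
    if (!is.null(pc) && identical(pc$endpoint, endpoint)) {
      hi <- marker_values[[pc$marker]] > pc$threshold
      lambda[hi] <- lambda[hi] * pc$hazard_ratio
    }
    t_event <- rexp(n, lambda)
    t_cens <- runif(n, sm$censor_min[[endpoint]], sm$censor_max[[endpoint]])
    list(time = pmin(t_event, t_cens),
         event = as.integer(t_event <= t_cens))
  }
  drfs <- with_substream(seed, 10, draw_endpoint("drfs"))
  bcss <- with_substream(seed, 11, draw_endpoint("bcss"))

  cohort <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    histology = histology,
    age = age,
    receptor_subtype = receptor_subtype,
    stage = stage,
    grade = grade,
    treatment = treatment,
    method = method,
    ctc_per_ml = ctc_per_ml,
    dtc_per_ml = dtc_per_ml,
    drfs_time = drfs$time,
    drfs_event = drfs$event,
    bcss_time = bcss$time,
    bcss_event = bcss$event,
    stringsAsFactors = FALSE
  )

  mr <- spec$missing_rates
  if (length(mr)) {
    with_substream(seed, 12, {
      for (col in names(mr)) {
        miss <- runif(n) < mr[[col]]
        cohort[[col]][miss] <- NA
      }
    })
  }
  cohort
}

#' Validate a cohort table against the schema
#'
#' @param cohort A `data.frame` to check.
#' @param context Label used in error messages (e.g. a file path).
#' @return The cohort, invisibly, if valid.
#' @export
validate_cohort <- function(cohort, context = "cohort") {
  fmt_err <- function(msg, rows = NULL) {
    where <- if (length(rows)) sprintf(" (row %s)",
                                       paste(head(rows, 5), collapse = ", "))
             else ""
    stop(sprintf("%s: %s%s", context, msg, where), call. = FALSE)
  }
  unknown <- setdiff(names(cohort), COHORT_COLUMNS)
  if (length(unknown)) fmt_err(paste("unknown column(s):",
                                     paste(unknown, collapse = ", ")))
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols)) fmt_err(paste("missing column(s):",
                                          paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(cohort$patient_id)) {
    fmt_err("duplicated patient_id",
            which(duplicated(cohort$patient_id)))
  }
  bad_hist <- which(!is.na(cohort$histology) &
                      !cohort$histology %in% HISTOLOGY_LEVELS)
  if (length(bad_hist)) fmt_err("histology must be ILC or IDC", bad_hist)
  for (col in MARKER_COLUMNS) {
    bad <- which(!is.na(cohort[[col]]) & cohort[[col]] < 0)
    if (length(bad)) fmt_err(sprintf("%s must be non-negative", col), bad)
  }
  for (ep in ENDPOINTS) {
    tcol <- paste0(ep, "_time"); ecol <- paste0(ep, "_event")
    bad_t <- which(!is.na(cohort[[tcol]]) & cohort[[tcol]] <= 0)
    if (length(bad_t)) fmt_err(sprintf("%s must be > 0", tcol), bad_t)
    bad_e <- which(!is.na(cohort[[ecol]]) & !cohort[[ecol]] %in% c(0, 1))
    if (length(bad_e)) fmt_err(sprintf("%s must be 0 or 1", ecol), bad_e)
  }
  invisible(cohort)
}

#' Write / read a cohort table
#'
#' The on-disk format is a UTF-8, comma-delimited file with one header row
#' using the exact schema column names; missing values are empty fields.
#' `read_cohort()` validates on load and reports the offending row on
#' format errors; `write_cohort()` refuses to write an invalid cohort, so
#' the round trip is the identity.
#'
#' @param cohort A schema-conforming cohort `data.frame`.
#' @param path File path.
#' @return `read_cohort()` returns the cohort `data.frame`;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  write.csv(cohort[, COHORT_COLUMNS], path, row.names = FALSE, na = "",
            quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                     colClasses = c(
                       patient_id = "character", histology = "character",
                       age = "numeric", receptor_subtype = "character",
                       stage = "integer", grade = "integer",
                       treatment = "character", method = "character",
                       ctc_per_ml = "numeric", dtc_per_ml = "numeric",
                       drfs_time = "numeric", drfs_event = "integer",
                       bcss_time = "numeric", bcss_event = "integer"
                     ),
                     fileEncoding = "UTF-8")
  validate_cohort(cohort, context = path)
  cohort
}
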