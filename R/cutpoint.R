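#' Monte-Carlo cross-validation settings for cutpoint optimization
#'
#' @param n_iterations Number of random half-split iterations (default
#'   1000, matching common practice for this procedure).
#' @param train_fraction Fraction of the subset used as the training half.
#' @param percentile_band Candidate thresholds are observed marker values
#'   whose percentile rank on the full subset lies inside this band
#'   (percent, default 20-80).
#' @param endpoint_policy How per-threshold log-rank p-values over the two
#'   endpoints are reduced to one number: `"combine_logit"` (default;
#'   logit-method combination of the DRFS and BCSS p-values),
#'   `"drfs_only"`, or `"bcss_only"`.
#' @param min_group_size Minimum subjects required on each side of a
#'   dichotomization, in both halves, for an iteration to count.
#' @param seed Seed for the half-split stream.
#' @return An `mccv_config` list.
#' @export
mccv_config <- function(n_iterations = 1000L, train_fraction = 0.5,
                        percentile_band = c(20, 80),
                        endpoint_policy = c("combine_logit", "drfs_only",
                                            "bcss_only"),
                        min_group_size = 5L, seed = 1L) {
  endpoint_policy <- match.arg(endpoint_policy)
  stopifnot(n_iterations >= 1, train_fraction > 0, train_fraction < 1,
            length(percentile_band) == 2,
            percentile_band[1] >= 0, percentile_band[2] <= 100,
            percentile_band[1] < percentile_band[2],
            min_group_size >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 train_fraction = train_fraction,
                 percentile_band = percentile_band,
                 endpoint_policy = endpoint_policy,
                 min_group_size = as.integer(min_group_size),
                 seed = as.integer(seed)),
            class = "mccv_config")
}

#' Candidate thresholds inside a percentile band
#'
#' Candidates are the distinct observed marker values whose percentile
#' rank — `100 * mean(values <= v)`, computed on the full subset, not per
#' split — lies inside the closed band.  Dichotomization is always
#' strictly greater ("marker-high" means value `>` threshold), so a value
#' with a large tied mass (e.g. zero in zero-inflated counts) is a
#' candidate whenever its rank reaches the band.
#'
#' @param values Non-missing marker values (at least 5 distinct).
#' @param band Percentile pair, e.g. `c(20, 80)`.
#' @return Sorted ascending vector of candidate thresholds (at least 2).
#' @export
candidate_thresholds <- function(values, band = c(20, 80)) {
  values <- values[!is.na(values)]
  distinct <- sort(unique(values))
  if (length(distinct) < 5) {
    stop("candidate_thresholds: need at least 5 distinct values",
         call. = FALSE)
  }
  rank_pct <- 100 * vapply(distinct, function(v) mean(values <= v),
                           numeric(1))
  cand <- distinct[rank_pct >= band[1] & rank_pct <= band[2]]
  if (length(cand) < 2) {
    stop("candidate_thresholds: fewer than 2 candidates in the band",
         call. = FALSE)
  }
  cand
}

#' Classify records as marker-high or marker-low
#'
#' Strictly-greater dichotomization: "high" means value `>` threshold;
#' a value equal to the threshold is "low"; missing values propagate.
#'
#' @param records Cohort `data.frame` (or a bare numeric vector of values).
#' @param marker `"ctc"` or `"dtc"` (ignored when `records` is a vector).
#' @param threshold Finite cutpoint in marker units (cells/mL).
#' @return Character vector of `"high"`, `"low"`, `"missing"`.
#' @export
classify_high_low <- function(records, marker = c("ctc", "dtc"), threshold) {
  stopifnot(is.finite(threshold))
  values <- if (is.numeric(records)) records
            else records[[MARKER_COLUMNS[[match.arg(marker)]]]]
  ifelse(is.na(values), "missing", ifelse(values > threshold, "high", "low"))
}

#' Cross-classify CTC and DTC high/low status
#'
#' @param ctc_label,dtc_label Labels from [classify_high_low()].
#' @return `"high/high"`, `"high/low"`, `"low/high"`, `"low/low"`, or
#'   `"incomplete"` when either component is missing.
#' @export
four_group_label <- function(ctc_label, dtc_label) {
  ifelse(ctc_label == "missing" | dtc_label == "missing", "incomplete",
         paste(ctc_label, dtc_label, sep = "/"))
}

# Reduce per-endpoint log-rank p-value vectors (one per candidate) to one
# vector according to the endpoint policy.
reduce_endpoint_p <- function(p_by_endpoint, policy) {
  switch(policy,
    drfs_only = p_by_endpoint$drfs,
    bcss_only = p_by_endpoint$bcss,
    combine_logit = {
      k <- 2
      eps <- 1e-15
      pd <- pmin(pmax(p_by_endpoint$drfs, eps), 1 - eps)
      pb <- pmin(pmax(p_by_endpoint$bcss, eps), 1 - eps)
      G <- -(log(pd / (1 - pd)) + log(pb / (1 - pb)))
      C <- sqrt(k * pi^2 * (5 * k + 2) / (3 * (5 * k + 4)))
      pt(G / C, df = 5 * k + 4, lower.tail = FALSE)
    })
}

#' Monte-Carlo cross-validated cutpoint optimization
#'
#' Selects the prognostic threshold for one marker on one cohort subset by
#' repeated random half-splitting.  The candidate grid is fixed on the
#' full subset ([candidate_thresholds()]).  Each iteration: (i) draw a
#' random training half; (ii) for every candidate threshold with at least
#' `min_group_size` subjects on each side of the training-half
#' dichotomization, compute the log-rank p-value per configured endpoint
#' and reduce them per the endpoint policy; (iii) select the
#' training-optimal threshold (ties broken toward the smaller threshold);
#' (iv) evaluate the policy-reduced log-rank p for that threshold on the
#' held-out half and record it.  Iterations with no admissible candidate,
#' or whose test half violates `min_group_size` at the selected threshold,
#' are counted unusable and excluded.  Finally the recorded test p-values
#' are grouped by selected threshold, each group is combined with
#' [logit_combine()], and the threshold with the smallest combined p is
#' returned (ties again toward the smaller threshold).
#'
#' @param records Cohort subset `data.frame`; rows with a missing marker
#'   value are dropped (at least 20 usable rows required).
#' @param marker `"ctc"` or `"dtc"`.
#' @param config An [mccv_config()].
#' @return A `cutpoint_result` list: `chosen_threshold`, `combined_p`,
#'   `per_threshold` (data.frame: threshold, times_selected, combined_p),
#'   `per_iteration` (data.frame: iteration, threshold, train_p, test_p,
#'   usable), `n_usable_iterations`, `candidates`, `marker`, `config`.
#' @export
mccv_optimize <- function(records, marker = c("ctc", "dtc"),
                          config = mccv_config()) {
  marker <- match.arg(marker)
  col <- MARKER_COLUMNS[[marker]]
  keep <- !is.na(records[[col]]) &
    !is.na(records$drfs_time) & !is.na(records$drfs_event) &
    !is.na(records$bcss_time) & !is.na(records$bcss_event)
  sub <- records[keep, , drop = FALSE]
  if (all(is.na(records[[col]]))) {
    stop("mccv_optimize: marker entirely missing", call. = FALSE)
  }
  n <- nrow(sub)
  if (n < 20) {
    stop("mccv_optimize: need at least 20 records with marker and endpoints",
         call. = FALSE)
  }
  values <- sub[[col]]
  cand <- candidate_thresholds(values, config$percentile_band)
  K <- length(cand)
  # n x K high/low membership, shared by every split
  G <- outer(values, cand, ">") * 1

  need_ep <- switch(config$endpoint_policy,
                    drfs_only = "drfs", bcss_only = "bcss",
                    combine_logit = ENDPOINTS)
  times <- lapply(ENDPOINTS, function(ep) sub[[paste0(ep, "_time")]])
  events <- lapply(ENDPOINTS, function(ep) sub[[paste0(ep, "_event")]])
  names(times) <- names(events) <- ENDPOINTS

  n_train <- max(1L, floor(n * config$train_fraction))
  iter_threshold <- rep(NA_real_, config$n_iterations)
  iter_train_p <- rep(NA_real_, config$n_iterations)
  iter_test_p <- rep(NA_real_, config$n_iterations)
  usable <- rep(FALSE, config$n_iterations)

  grid_p <- function(idx) {
    out <- list(drfs = NULL, bcss = NULL)
    for (ep in need_ep) {
      res <- logrank_grid(times[[ep]][idx], events[[ep]][idx],
                          G[idx, , drop = FALSE])
      out[[ep]] <- res$p_value
    }
    out
  }

  set.seed(config$seed)
  for (it in seq_len(config$n_iterations)) {
    train <- sample.int(n, n_train)
    test <- setdiff(seq_len(n), train)
    n_high_tr <- colSums(G[train, , drop = FALSE])
    admissible <- n_high_tr >= config$min_group_size &
      (n_train - n_high_tr) >= config$min_group_size
    if (!any(admissible)) next
    p_tr <- reduce_endpoint_p(grid_p(train), config$endpoint_policy)
    p_tr[!admissible] <- Inf
    k_sel <- which.min(p_tr)  # ties -> smallest threshold (first index)
    iter_threshold[it] <- cand[k_sel]
    iter_train_p[it] <- p_tr[k_sel]
    n_high_te <- sum(G[test, k_sel])
    if (n_high_te < config$min_group_size ||
        (length(test) - n_high_te) < config$min_group_size) next
    p_te <- reduce_endpoint_p(grid_p(test), config$endpoint_policy)[k_sel]
    iter_test_p[it] <- p_te
    usable[it] <- TRUE
  }

  if (!any(usable)) {
    stop("mccv_optimize: all iterations unusable", call. = FALSE)
  }
  sel <- iter_threshold[usable]
  tp <- iter_test_p[usable]
  groups <- sort(unique(sel))
  combined <- vapply(groups, function(th) logit_combine(tp[sel == th]),
                     numeric(1))
  times_selected <- vapply(groups, function(th) sum(sel == th), integer(1))
  best <- which.min(combined)  # ties -> smallest threshold (sorted groups)
  structure(list(
    chosen_threshold = groups[best],
    combined_p = combined[best],
    per_threshold = data.frame(threshold = groups,
                               times_selected = times_selected,
                               combined_p = combined),
    per_iteration = data.frame(iteration = seq_len(config$n_iterations),
                               threshold = iter_threshold,
                               train_p = iter_train_p,
                               test_p = iter_test_p,
                               usable = usable),
    n_usable_iterations = sum(usable),
    candidates = cand,
    marker = marker,
    config = config
  ), class = "cutpoint_result")
}
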