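#' Bundle survival data for one endpoint
#'
#' @param time Positive event/censoring times (years).
#' @param event Event indicators in {0, 1}.
#' @param group Optional group labels (anything coercible to factor).
#' @return A `survival_data` list with validated, equal-length fields.
#' @export
survival_data <- function(time, event, group = NULL) {
  if (!length(time)) stop("survival_data: empty input", call. = FALSE)
  if (length(event) != length(time)) {
    stop("survival_data: time and event lengths differ", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("survival_data: times must be positive and finite", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) {
    stop("survival_data: event indicators must be 0/1", call. = FALSE)
  }
  if (!is.null(group)) {
    if (length(group) != length(time)) {
      stop("survival_data: group length differs", call. = FALSE)
    }
    group <- factor(group)
    if (any(table(group) == 0)) group <- droplevels(group)
  }
  structure(list(time = as.numeric(time), event = as.integer(event),
                 group = group),
            class = "survival_data")
}

#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit survivor curve for a single sample, grouping
#' tied event times.  The curve steps only at event times; the median is
#' the earliest time at which the estimate drops to 0.5 or below (`NA` if
#' it never does).
#'
#' @param time,event As in [survival_data()]; or pass a `survival_data`
#'   object as `time`.
#' @return A `km_curve` list: `times` (ordered distinct event times),
#'   `survival`, `at_risk`, `n_events`, `median`, `n`.
#' @export
km_estimate <- function(time, event = NULL) {
  if (inherits(time, "survival_data")) {
    event <- time$event
    time <- time$time
  }
  sd <- survival_data(time, event)
  ord <- order(sd$time)
  t_s <- sd$time[ord]
  e_s <- sd$event[ord]
  n <- length(t_s)
  ut <- unique(t_s)
  first_idx <- match(ut, t_s)
  at_risk_all <- n - first_idx + 1L
  d_all <- as.integer(rowsum(e_s, t_s)[, 1])
  keep <- d_all > 0
  times <- ut[keep]
  at_risk <- at_risk_all[keep]
  d <- d_all[keep]
  surv <- cumprod(1 - d / at_risk)
  med <- if (any(surv <= 0.5)) times[which(surv <= 0.5)[1]] else NA_real_
  structure(list(times = times, survival = surv, at_risk = at_risk,
                 n_events = d, median = med, n = n),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @param t Times at which to evaluate the right-continuous step function.
#' @return Survival probabilities (1 before the first event time).
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(ti) {
    idx <- which(curve$times <= ti)
    if (length(idx)) curve$survival[max(idx)] else 1
  }, numeric(1))
}

# Log-rank O-E sums and hypergeometric variances for many binary groupings
# at once.  `group1` is an n x K logical/0-1 matrix; column k defines the
# "group 1" membership of each subject.  Returns per-column chi-square
# statistics (0 where the variance is zero) and the U and V components.
logrank_grid <- function(time, event, group1) {
  group1 <- as.matrix(group1) * 1
  n <- length(time)
  ord <- order(time)
  t_s <- time[ord]
  e_s <- event[ord]
  A <- group1[ord, , drop = FALSE]
  ut <- unique(t_s)
  first_idx <- match(ut, t_s)
  # at-risk count in group 1 just before each distinct time
  revcum <- apply(A[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
  d_all <- as.numeric(rowsum(e_s, t_s)[, 1])
  keep <- d_all > 0
  n_j <- (n - first_idx + 1L)[keep]
  d_j <- d_all[keep]
  N1 <- revcum[first_idx[keep], , drop = FALSE]
  D1 <- rowsum(A * e_s, t_s)[keep, , drop = FALSE]
  frac <- N1 / n_j
  U <- colSums(D1 - d_j * frac)
  vfac <- ifelse(n_j > 1, d_j * (n_j - d_j) / (n_j - 1), 0)
  V <- colSums(vfac * frac * (1 - frac))
  stat <- ifelse(V > 0, U^2 / V, 0)
  p <- ifelse(V > 0, pchisq(stat, df = 1, lower.tail = FALSE), 1)
  list(statistic = stat, p_value = p, U = U, V = V)
}

#' Two-group log-rank test
#'
#' Chi-square log-rank test comparing the survival of two groups, using
#' the observed-minus-expected sum with the hypergeometric variance at
#' each distinct event time (tied event times grouped; times contributing
#' zero variance are skipped).  The p-value is the upper tail of a
#' chi-square with 1 df.  With zero events overall the test is degenerate:
#' statistic 0, p = 1, `degenerate = TRUE`.
#'
#' @param data A [survival_data()] object with a two-level group.
#' @return A `test_result` list: `statistic`, `p_value`, `df`,
#'   `method_name`, `degenerate`.
#' @export
logrank_test <- function(data) {
  stopifnot(inherits(data, "survival_data"))
  if (is.null(data$group)) stop("logrank_test: group is required", call. = FALSE)
  g <- droplevels(factor(data$group))
  if (nlevels(g) != 2) {
    stop("logrank_test: exactly two non-empty groups required", call. = FALSE)
  }
  if (sum(data$event) == 0) {
    return(test_result(0, 1, df = 1, method_name = "log-rank",
                       degenerate = TRUE))
  }
  res <- logrank_grid(data$time, data$event,
                      matrix(as.integer(g == levels(g)[2]), ncol = 1))
  test_result(res$statistic, res$p_value, df = 1, method_name = "log-rank",
              degenerate = res$V == 0)
}

test_result <- function(statistic, p_value, df = NA_real_,
                        method_name = "", degenerate = FALSE, ...) {
  structure(list(statistic = as.numeric(statistic),
                 p_value = as.numeric(p_value), df = df,
                 method_name = method_name, degenerate = degenerate, ...),
            class = "test_result")
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value (delegates to [stats::t.test()]).
#'
#' @param x,y Numeric vectors, each of length at least 2.
#' @return A `test_result` with `statistic`, `df`, `p_value`, and the two
#'   group means in `estimate`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("welch_t: each sample needs at least 2 values", call. = FALSE)
  }
  ht <- t.test(x, y, var.equal = FALSE)
  test_result(unname(ht$statistic), ht$p.value, df = unname(ht$parameter),
              method_name = "Welch two-sample t-test",
              estimate = unname(ht$estimate))
}

#' Fisher's exact test for contingency tables
#'
#' Two-sided exact test: for 2x2 tables, the probability-mass rule (sum of
#' hypergeometric probabilities of tables no more probable than the one
#' observed).  For larger tables the exact network algorithm is used when
#' feasible; otherwise a seeded Monte-Carlo p-value with `B` table draws.
#'
#' @param table A matrix of non-negative integer counts with positive
#'   row and column margins.
#' @param B Number of Monte-Carlo draws for the r x c fallback.
#' @param mc_seed Seed for the Monte-Carlo fallback.
#' @return A `test_result`; `statistic` is `NA` (the test is defined by its
#'   p-value), `method_name` records whether enumeration or simulation was
#'   used.
#' @export
fisher_exact <- function(table, B = 1e5, mc_seed = 1L) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("fisher_exact: negative cell count", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("fisher_exact: table has a zero margin", call. = FALSE)
  }
  ht <- tryCatch(
    fisher.test(table),
    error = function(e) {
      set.seed(mc_seed)
      fisher.test(table, simulate.p.value = TRUE, B = B)
    }
  )
  simulated <- grepl("simulated", ht$method)
  test_result(NA_real_, ht$p.value,
              method_name = if (simulated) {
                sprintf("Fisher's exact test (Monte-Carlo, B=%d)", as.integer(B))
              } else "Fisher's exact test",
              margins = list(row = rowSums(table), col = colSums(table)))
}

#' Combine p-values by the logit method
#'
#' Mudholkar-George combination: `G = -sum(log(p_i / (1 - p_i)))` referred
#' to `G / C ~ t` with `nu = 5k + 4` degrees of freedom and
#' `C = sqrt(k * pi^2 * (5k + 2) / (3 * (5k + 4)))`, returning the upper
#' tail probability, so that small input p-values give a small combined
#' p-value.  Inputs are clipped into `[1e-15, 1 - 1e-15]` to keep the
#' logits finite.
#'
#' @param p_values Numeric vector of p-values (length at least 1).
#' @return The combined p-value in (0, 1).
#' @export
logit_combine <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop("logit_combine: no p-values supplied", call. = FALSE)
  eps <- 1e-15
  p <- pmin(pmax(p, eps), 1 - eps)
  k <- length(p)
  G <- -sum(log(p / (1 - p)))
  C <- sqrt(k * pi^2 * (5 * k + 2) / (3 * (5 * k + 4)))
  pt(G / C, df = 5 * k + 4, lower.tail = FALSE)
}

#' Cox proportional-hazards fit
#'
#' Fits a Cox model by partial-likelihood maximization with Efron handling
#' of tied event times (via [survival::coxph()]) and returns per-covariate
#' hazard ratios with Wald 95% confidence intervals and p-values.
#' Monotone-likelihood (perfect separation) is detected — coefficients
#' diverging with vanishing information — and flagged per covariate as
#' non-estimable rather than reported as a finite hazard ratio.
#'
#' @param time,event Endpoint vectors as in [survival_data()].
#' @param covariates A `data.frame` of covariates; factors are expanded to
#'   treatment contrasts against their first level.
#' @return A `cox_result` list: `coefficients` data.frame (term, coef,
#'   hazard_ratio, ci_low, ci_high, p_value, non_estimable), `n`,
#'   `n_events`, `loglik`, `converged`.
#' @export
cox_fit <- function(time, event, covariates) {
  sd <- survival_data(time, event)
  if (sum(sd$event) < 1) stop("cox_fit: no events", call. = FALSE)
  covariates <- as.data.frame(covariates)
  dat <- cbind(data.frame(.time = sd$time, .event = sd$event), covariates)
  fml <- stats::as.formula(paste(
    "Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- withCallingHandlers(
    coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|singular|beta may be infinite",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  # monotone likelihood: coefficient wandered to +/- ~10+ on the log scale
  non_est <- !is.finite(co) | !is.finite(se) | abs(co) > 9 | se > 100
  z <- co / se
  res <- data.frame(
    term = names(co),
    coef = unname(co),
    se = unname(se),
    hazard_ratio = exp(unname(co)),
    ci_low = exp(unname(co - 1.96 * se)),
    ci_high = exp(unname(co + 1.96 * se)),
    p_value = 2 * pnorm(-abs(unname(z))),
    non_estimable = unname(non_est),
    stringsAsFactors = FALSE
  )
  res$hazard_ratio[non_est] <- NA_real_
  res$ci_low[non_est] <- NA_real_
  res$ci_high[non_est] <- NA_real_
  structure(list(coefficients = res, n = fit$n, n_events = fit$nevent,
                 loglik = fit$loglik[length(fit$loglik)],
                 converged = !any(non_est)),
            class = "cox_result")
}
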