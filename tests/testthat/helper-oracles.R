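# Independent oracles and fixture builders shared across test files.

# Brute-force log-rank: explicit loop over distinct event times, computing
# at-risk sets and the hypergeometric mean/variance by direct subsetting.
oracle_logrank <- function(time, event, group1) {
  U <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n_t <- sum(at)
    n1 <- sum(at & group1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group1)
    U <- U + d1 - d * n1 / n_t
    if (n_t > 1) {
      V <- V + d * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d) / (n_t - 1)
    }
  }
  stat <- if (V > 0) U^2 / V else 0
  p <- if (V > 0) pchisq(stat, 1, lower.tail = FALSE) else 1
  list(statistic = stat, p_value = p, U = U, V = V)
}

# Efron-free hand partial likelihood for untied event times.
oracle_cox_logpl <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- time >= time[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}

# Minimal schema-conforming cohort for pipeline tests.
make_cohort <- function(n, seed = 1, histology = NULL, treatment = NULL,
                        method = NULL, ctc = NULL, dtc = NULL) {
  set.seed(seed)
  if (is.null(histology)) histology <- sample(c("ILC", "IDC"), n, TRUE)
  if (is.null(treatment)) treatment <- sample(c("primary_surgery",
                                                "neoadjuvant"), n, TRUE)
  if (is.null(method)) method <- rep("IEFC", n)
  if (is.null(ctc)) ctc <- round(rlnorm(n, 0, 1) *
                                   rbinom(n, 1, 0.7), 3)
  if (is.null(dtc)) dtc <- round(rlnorm(n, 1.5, 1) *
                                   rbinom(n, 1, 0.8), 3)
  data.frame(
    patient_id = sprintf("T%05d", seq_len(n)),
    histology = histology,
    age = round(rnorm(n, 52, 10), 1),
    receptor_subtype = sample(c("HR+HER2-", "HR-/HER2-", "HER2+"), n, TRUE,
                              prob = c(0.7, 0.1, 0.2)),
    stage = sample(1:3, n, TRUE),
    grade = sample(1:3, n, TRUE),
    treatment = treatment,
    method = method,
    ctc_per_ml = ctc,
    dtc_per_ml = dtc,
    drfs_time = round(runif(n, 0.5, 15), 3),
    drfs_event = rbinom(n, 1, 0.3),
    bcss_time = round(runif(n, 0.5, 18), 3),
    bcss_event = rbinom(n, 1, 0.2),
    stringsAsFactors = FALSE
  )
}

# Planted-effect validation cohort plus its planted threshold: the marker
# substream is independent of the survival substream, so regenerating with
# the planted cutpoint keeps the marker values (and grid) unchanged.
make_planted_cohort <- function(n, seed, hazard_ratio = 4) {
  base <- generate_cohort(validation_cohort_spec(n, seed = seed))
  tau <- as.numeric(quantile(base$ctc_per_ml, 0.5, type = 1))
  spec <- validation_cohort_spec(n, seed = seed, threshold = tau,
                                 hazard_ratio = hazard_ratio)
  list(cohort = generate_cohort(spec), threshold = tau)
}
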