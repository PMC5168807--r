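# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (explicit loops, direct formulas, survdiff/t.test)
# so they stay independent of the package's vectorized implementations.

# brute-force Harrell C: explicit O(n^2) double loop over ordered pairs
brute_force_cindex <- function(risk, time, event) {
  conc <- disc <- tied <- 0
  n <- length(risk)
  for (i in seq_len(n)) {
    if (!event[i]) next
    for (j in seq_len(n)) {
      if (j == i || time[i] >= time[j]) next
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] < risk[j]) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  total <- conc + disc + tied
  list(c_index = (conc + 0.5 * tied) / total, concordant = conc,
       discordant = disc, tied = tied, comparable = total)
}

# small random right-censored cohort
random_cohort <- function(n, censor_rate = 0.4, tie_times = FALSE) {
  time <- if (tie_times) sample(1:10, n, replace = TRUE) else rexp(n, 1 / 100)
  tibble::tibble(patient_id = sprintf("p%03d", seq_len(n)),
                 time_days = time,
                 event = runif(n) > censor_rate)
}

# exponential PH survival with a single covariate effect
simulate_ph <- function(n, beta, x = rnorm(n), censor_at = Inf) {
  t_event <- rexp(n, rate = exp(beta * x) / 500)
  time <- pmin(t_event, censor_at)
  tibble::tibble(time_days = time, event = t_event <= censor_at, x = x)
}

# tiny omics matrix builder
toy_matrix <- function(values, platform = "mrna", kind = "continuous",
                       features = NULL, patients = NULL) {
  if (is.null(features)) features <- sprintf("f%02d", seq_len(nrow(values)))
  if (is.null(patients)) patients <- sprintf("p%03d", seq_len(ncol(values)))
  dimnames(values) <- list(features, patients)
  omics_matrix(values, platform, kind)
}

# clinical table with given survival outcomes
toy_clinical <- function(time, event, ids = sprintf("p%03d", seq_along(time))) {
  n <- length(time)
  tibble::tibble(patient_id = ids,
                 gender = rep(c("female", "male"), length.out = n),
                 age = 60, grade = 2L, stage = 2L,
                 time_days = time, event = event)
}
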