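#' Configuration for resampling-based marker selection
#'
#' Defaults are the screening conditions of the pipeline: 100 random
#' split-half iterations, extreme-score cutoff at |Z| = 1, mean-score cutoff
#' at Z = 0, at least 10 patients per stratified group, two-sided alpha 0.05,
#' "short survivors" dead within 365 days, "long survivors" beyond 1825 days
#' (5 years), and the top 10 most frequently selected features reported.
#'
#' @param n_iterations number of random split-half iterations.
#' @param z_extreme Z-score cutoff for the extreme-score stratification.
#' @param z_mean Z-score cutoff for the mean-score stratification.
#' @param min_group minimum patients required in each stratified group.
#' @param alpha significance level for the per-half tests.
#' @param short_survival_days upper bound (days) for the short-survivor group
#'   (death observed at or before this time).
#' @param long_survival_days lower bound (days) for the long-survivor group
#'   (follow-up or death strictly beyond this time).
#' @param top_k how many top-frequency features to return per approach.
#' @param rng_seed optional integer seed; with a fixed seed every selection
#'   is bit-reproducible.
#' @return a `selection_config` list.
#' @export
selection_config <- function(n_iterations = 100, z_extreme = 1, z_mean = 0,
                             min_group = 10, alpha = 0.05,
                             short_survival_days = 365,
                             long_survival_days = 1825, top_k = 10,
                             rng_seed = NULL) {
  stopifnot(alpha > 0, alpha < 1, min_group >= 1,
            short_survival_days < long_survival_days, n_iterations >= 1,
            top_k >= 1)
  structure(list(n_iterations = n_iterations, z_extreme = z_extreme,
                 z_mean = z_mean, min_group = min_group, alpha = alpha,
                 short_survival_days = short_survival_days,
                 long_survival_days = long_survival_days, top_k = top_k,
                 rng_seed = rng_seed),
            class = "selection_config")
}

# rank candidates and cut to top_k: frequency desc, mean passing p asc,
# feature_id lexicographic (deterministic, reportable)
.rank_candidates <- function(freq, mean_p, votes, ids, platform, approach,
                             n_effective, top_k) {
  keep <- which(freq > 0)
  if (!length(keep)) {
    warning(sprintf("%s/%s: no feature was ever selected", platform, approach),
            call. = FALSE)
    return(tibble::tibble(feature_id = character(), platform = character(),
                          approach = character(), frequency = integer(),
                          n_iterations_effective = integer(),
                          direction = character(), mean_p = double()))
  }
  dir <- ifelse(votes[keep] > 0, "high_better",
                ifelse(votes[keep] < 0, "high_worse", "undetermined"))
  out <- tibble::tibble(feature_id = ids[keep], platform = platform,
                        approach = approach, frequency = as.integer(freq[keep]),
                        n_iterations_effective = as.integer(n_effective),
                        direction = dir, mean_p = mean_p[keep]) %>%
    dplyr::arrange(dplyr::desc(.data$frequency), .data$mean_p, .data$feature_id)
  utils::head(out, top_k)
}

# shared engine for the two Z-score stratification approaches.
# hi(z) / lo(z) are vectorized group predicates on a feature's Z values.
.score_selection <- function(z, clinical, cfg, hi, lo, approach) {
  al <- .align_cohort(z, clinical)
  v <- al$values
  n <- length(al$patient_ids)
  nf <- nrow(v)
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  freq <- integer(nf); votes <- integer(nf); psum <- numeric(nf)
  half_n <- floor(n / 2)
  for (it in seq_len(cfg$n_iterations)) {
    perm <- sample.int(n)
    halves <- list(perm[seq_len(half_n)], perm[(half_n + 1):n])
    pass_p <- rep(NA_real_, nf)   # binding p (max over halves) per passing feature
    oe_sum <- numeric(nf)
    passing <- seq_len(nf)
    for (h in 1:2) {
      idx <- halves[[h]]
      t_h <- al$time[idx]; e_h <- al$event[idx]
      still <- integer(0)
      for (f in passing) {
        zz <- v[f, idx]
        ghi <- !is.na(zz) & hi(zz)
        glo <- !is.na(zz) & lo(zz)
        if (sum(ghi) < cfg$min_group || sum(glo) < cfg$min_group) next
        use <- ghi | glo
        st <- .logrank_core(t_h[use], e_h[use], ghi[use])
        p <- stats::pchisq(st[1], df = 1, lower.tail = FALSE)
        if (is.na(p) || p >= cfg$alpha) next
        still <- c(still, f)
        pass_p[f] <- max(pass_p[f], p, na.rm = TRUE)
        oe_sum[f] <- oe_sum[f] + st[2]
      }
      passing <- still
      if (!length(passing)) break
    }
    if (length(passing)) {
      freq[passing] <- freq[passing] + 1L
      psum[passing] <- psum[passing] + pass_p[passing]
      # more deaths than expected in the high group => high is worse
      votes[passing] <- votes[passing] - sign(oe_sum[passing])
    }
  }
  mean_p <- ifelse(freq > 0, psum / freq, Inf)
  .rank_candidates(freq, mean_p, votes, rownames(v), platform_of(z), approach,
                   cfg$n_iterations, cfg$top_k)
}

#' Extreme-score stratification marker selection
#'
#' In each of `n_iterations` random split-halves of the training cohort,
#' patients with Z > `z_extreme` (extremely high) are compared against
#' patients with Z < `-z_extreme` (extremely low) by a log-rank test in the
#' first half; features significant there (p < `alpha`, both groups at least
#' `min_group` patients) are re-tested under the same rule in the second
#' half, and score one selection when both halves agree. Features are ranked
#' by selection frequency and the top `top_k` returned.
#'
#' @param z Z-scored [omics_matrix()] restricted to the training cohort
#'   (see [fit_zscore()] / [apply_zscore()]).
#' @param clinical clinical tibble covering the training patients.
#' @param cfg a [selection_config()].
#' @return tibble of marker candidates: `feature_id`, `platform`, `approach`,
#'   `frequency` (selecting iterations), `n_iterations_effective`,
#'   `direction` (`high_better` / `high_worse` / `undetermined`, the majority
#'   survival ordering across passing iterations), `mean_p`.
#' @export
extreme_score_selection <- function(z, clinical, cfg = selection_config()) {
  if (value_kind_of(z) != "zscore") stop("`z` must be Z-scored (apply_zscore)", call. = FALSE)
  zc <- cfg$z_extreme
  .score_selection(z, clinical, cfg,
                   hi = function(x) x > zc, lo = function(x) x < -zc,
                   approach = "extreme_score")
}

#' Mean-score stratification marker selection
#'
#' Same split-half resampling contract as [extreme_score_selection()], but
#' patients are stratified at the mean: Z > 0 (above average) versus
#' Z <= 0 (at or below average; exact zeros go to the low group).
#'
#' @inheritParams extreme_score_selection
#' @export
mean_score_selection <- function(z, clinical, cfg = selection_config()) {
  if (value_kind_of(z) != "zscore") stop("`z` must be Z-scored (apply_zscore)", call. = FALSE)
  zm <- cfg$z_mean
  .score_selection(z, clinical, cfg,
                   hi = function(x) x > zm, lo = function(x) x <= zm,
                   approach = "mean_score")
}

#' Extreme-survival stratification marker selection
#'
#' In each random split-half, each half defines a short-survivor group
#' (death observed within `short_survival_days`) and a long-survivor group
#' (follow-up or death beyond `long_survival_days`; patients censored before
#' the short window belong to neither). A feature scores one selection when a
#' Welch t-test between the two groups is significant in both halves. Halves
#' with fewer than `min_group` short or long survivors void the whole
#' iteration (it is excluded from the frequency denominator and counted in
#' the returned `n_iterations_effective`).
#'
#' @param m raw-valued [omics_matrix()] (this approach does not need
#'   Z-scores) restricted to the training cohort.
#' @inheritParams extreme_score_selection
#' @export
extreme_survival_selection <- function(m, clinical, cfg = selection_config()) {
  al <- .align_cohort(m, clinical)
  v <- al$values
  nf <- nrow(v)
  n <- length(al$patient_ids)
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  short <- al$event & al$time <= cfg$short_survival_days
  long <- al$time > cfg$long_survival_days
  freq <- integer(nf); votes <- integer(nf); psum <- numeric(nf)
  skipped <- 0L
  half_n <- floor(n / 2)
  for (it in seq_len(cfg$n_iterations)) {
    perm <- sample.int(n)
    halves <- list(perm[seq_len(half_n)], perm[(half_n + 1):n])
    ok <- vapply(halves, function(idx) {
      sum(short[idx]) >= cfg$min_group && sum(long[idx]) >= cfg$min_group
    }, logical(1))
    if (!all(ok)) {
      skipped <- skipped + 1L
      next
    }
    pass <- rep(TRUE, nf)
    pass_p <- rep(-Inf, nf)
    tsum <- numeric(nf)
    for (h in 1:2) {
      idx <- halves[[h]]
      w <- .welch_rows(v[, idx[short[idx]], drop = FALSE],
                       v[, idx[long[idx]], drop = FALSE])
      pass <- pass & !is.na(w$p) & w$p < cfg$alpha
      pass_p <- pmax(pass_p, w$p)
      tsum <- tsum + ifelse(is.na(w$t), 0, w$t)
    }
    if (any(pass)) {
      freq[pass] <- freq[pass] + 1L
      psum[pass] <- psum[pass] + pass_p[pass]
      # higher values among short survivors => high is worse
      votes[pass] <- votes[pass] - sign(tsum[pass])
    }
  }
  if (skipped > 0) {
    message(sprintf("extreme_survival_selection: %d of %d iterations skipped (ineligible halves)",
                    skipped, cfg$n_iterations))
  }
  mean_p <- ifelse(freq > 0, psum / freq, Inf)
  .rank_candidates(freq, mean_p, votes, rownames(v), platform_of(m),
                   "extreme_survival", cfg$n_iterations - skipped, cfg$top_k)
}

#' Combine marker lists from the three stratification approaches
#'
#' Union by feature id of the per-approach candidate lists (so up to
#' `3 * top_k` candidates), retaining each feature's maximum frequency and
#' merged approach provenance. Directions that disagree between approaches
#' become `undetermined`.
#'
#' @param ... marker candidate tibbles from the same platform and training
#'   round (or a single list of them).
#' @return tibble of candidates with `approach = "combined"` and a
#'   `provenance` column listing the contributing approaches.
#' @export
combined_selection <- function(...) {
  lists <- list(...)
  if (length(lists) == 1 && is.list(lists[[1]]) && !is.data.frame(lists[[1]])) {
    lists <- lists[[1]]
  }
  all <- dplyr::bind_rows(lists)
  if (nrow(all) == 0) return(all)
  if (length(unique(all$platform)) > 1) {
    stop("combined_selection expects lists from a single platform", call. = FALSE)
  }
  all %>%
    dplyr::group_by(.data$feature_id) %>%
    dplyr::summarise(
      platform = .data$platform[1],
      provenance = paste(sort(unique(.data$approach)), collapse = "+"),
      approach = "combined",
      frequency = max(.data$frequency),
      n_iterations_effective = max(.data$n_iterations_effective),
      direction = if (dplyr::n_distinct(.data$direction) == 1) .data$direction[1] else "undetermined",
      mean_p = min(.data$mean_p),
      .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$frequency), .data$mean_p, .data$feature_id)
}

#' Somatic-mutation marker screening
#'
#' For each gene (or individual variant, depending on how the binary matrix
#' was built — see [mutation_matrix()]), compares the survival of mutation
#' carriers against non-carriers with a single log-rank test on the full
#' training cohort; features with p < `alpha` and both groups of size at
#' least `min_group` are returned. No resampling is used for this platform,
#' so `frequency` is 1 and `n_iterations_effective` is 1.
#'
#' @param mut binary [omics_matrix()] (1 = mutated) on the training cohort.
#' @inheritParams extreme_score_selection
#' @export
mutation_gene_selection <- function(mut, clinical, cfg = selection_config()) {
  if (value_kind_of(mut) != "binary") stop("`mut` must be a binary matrix", call. = FALSE)
  al <- .align_cohort(mut, clinical)
  v <- al$values
  rows <- purrr::map_dfr(seq_len(nrow(v)), function(f) {
    x <- v[f, ]
    ok <- !is.na(x)
    carrier <- x[ok] == 1
    if (sum(carrier) < cfg$min_group || sum(!carrier) < cfg$min_group) return(NULL)
    st <- .logrank_core(al$time[ok], al$event[ok], carrier)
    p <- stats::pchisq(st[1], df = 1, lower.tail = FALSE)
    if (is.na(p) || p >= cfg$alpha) return(NULL)
    tibble::tibble(feature_id = rownames(v)[f], platform = platform_of(mut),
                   approach = "mutation", frequency = 1L,
                   n_iterations_effective = 1L,
                   direction = if (st[2] > 0) "high_worse" else if (st[2] < 0) "high_better" else "undetermined",
                   mean_p = p)
  })
  if (nrow(rows) == 0) {
    return(tibble::tibble(feature_id = character(), platform = character(),
                          approach = character(), frequency = integer(),
                          n_iterations_effective = integer(),
                          direction = character(), mean_p = double()))
  }
  dplyr::arrange(rows, .data$mean_p, .data$feature_id)
}

#' Write a marker candidate table
#'
#' @param candidates candidate tibble from a selection function.
#' @param path TSV output path.
#' @export
write_candidates <- function(candidates, path) {
  readr::write_tsv(candidates, path, progress = FALSE)
  invisible(path)
}
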