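#' Configuration for the best-subset Cox model search
#'
#' @param max_rank largest number of marker covariates tried for the three
#'   single-stratification approaches (models of rank 1 to `max_rank`).
#' @param max_rank_combined rank cap for the combined approach, whose
#'   candidate pool can reach `3 * top_k = 30` markers and whose exhaustive
#'   enumeration is therefore capped at rank 6.
#' @param clinical_covariates clinical covariate names used by
#'   [clinical_model()] and the integrated models.
#' @param max_subsets cap on enumerated subsets per rank; when
#'   `choose(pool, r)` exceeds it, the candidate pool is trimmed (in the
#'   given order, i.e. by selection frequency) to the largest pool that fits,
#'   with a logged downgrade.
#' @export
model_search_config <- function(max_rank = 10, max_rank_combined = 6,
                                clinical_covariates = c("gender", "age",
                                                        "grade", "stage"),
                                max_subsets = 2e5) {
  stopifnot(max_rank_combined >= 1, max_rank_combined <= max_rank,
            max_subsets >= 1)
  structure(list(max_rank = max_rank, max_rank_combined = max_rank_combined,
                 clinical_covariates = clinical_covariates,
                 max_subsets = max_subsets),
            class = "model_search_config")
}

# lexicographic successor of a k-combination of 1..n; NULL when exhausted
.next_combo <- function(idx, n) {
  k <- length(idx)
  i <- k
  while (i >= 1 && idx[i] == n - k + i) i <- i - 1
  if (i < 1) return(NULL)
  idx[i] <- idx[i] + 1
  if (i < k) idx[(i + 1):k] <- idx[i] + seq_len(k - i)
  idx
}

#' Exhaustive best-subset Cox model at a given rank
#'
#' Fits a Cox model for every size-`r` subset of the candidate markers on the
#' training data and returns the converged fit with the highest training
#' concordance index; ties are broken by lower AIC, then by the
#' lexicographically smallest covariate name set. Subsets are enumerated
#' streamingly (never materialized); if their number exceeds
#' `cfg$max_subsets` the pool is trimmed from the end with a message.
#'
#' @param data training tibble with `time_days`, `event` and one column per
#'   candidate marker (see [assemble_model_data()]).
#' @param candidates character vector of candidate column names, or a marker
#'   candidate tibble (its `feature_id` order — frequency rank — is used when
#'   trimming).
#' @param r model rank (number of marker covariates).
#' @param cfg a [model_search_config()].
#' @return the winning `surv_model`, with attributes `train_c` (its training
#'   C-index) and `n_subsets` (subsets actually fitted).
#' @export
best_model_per_rank <- function(data, candidates, r,
                                cfg = model_search_config()) {
  if (is.data.frame(candidates)) candidates <- candidates$feature_id
  stopifnot(r >= 1, length(candidates) >= r)
  pool <- candidates
  if (choose(length(pool), r) > cfg$max_subsets) {
    while (length(pool) > r && choose(length(pool) - 1, r) > cfg$max_subsets) {
      pool <- pool[-length(pool)]
    }
    pool <- pool[-length(pool)]
    if (length(pool) < r) pool <- candidates[seq_len(r)]
    message(sprintf("best_model_per_rank: pool trimmed %d -> %d so that C(%d, %d) <= %g subsets",
                    length(candidates), length(pool), length(pool), r, cfg$max_subsets))
  }
  best <- NULL; best_c <- -Inf; best_aic <- Inf; best_key <- ""
  n_fitted <- 0L; n_failed <- 0L
  idx <- seq_len(r)
  repeat {
    covs <- pool[idx]
    fit <- tryCatch(fit_cox(data, covs), error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      n_fitted <- n_fitted + 1L
      d <- data[stats::complete.cases(data[c("time_days", "event", covs)]), ]
      cx <- .cindex(risk_score(fit, d), d$time_days, d$event)
      key <- paste(sort(covs), collapse = "|")
      better <- !is.na(cx) &&
        (cx > best_c ||
           (cx == best_c && (fit$aic < best_aic ||
                               (fit$aic == best_aic && key < best_key))))
      if (better) {
        best <- fit; best_c <- cx; best_aic <- fit$aic; best_key <- key
      }
    } else {
      n_failed <- n_failed + 1L
    }
    idx <- .next_combo(idx, length(pool))
    if (is.null(idx)) break
  }
  if (is.null(best)) {
    stop(sprintf("no size-%d subset produced a converged fit (%d attempted, %d failed)",
                 r, n_fitted + n_failed, n_failed), call. = FALSE)
  }
  attr(best, "train_c") <- best_c
  attr(best, "n_subsets") <- n_fitted + n_failed
  best
}

# binary-code a two-level gender column; ordinals pass through as integers
.code_clinical <- function(clinical, covariates) {
  d <- clinical
  if ("gender" %in% covariates && !is.numeric(d$gender)) {
    lv <- sort(unique(stats::na.omit(d$gender)))
    if (length(lv) > 2) stop("gender must be binary", call. = FALSE)
    d$gender <- as.numeric(match(d$gender, lv) - 1)
  }
  d
}

#' Clinical-covariate-only Cox model
#'
#' Fits the reference model on the four clinical covariates: gender (binary
#' coded), age (continuous, years), and tumor grade and stage entered as
#' integer ordinal codes 1-4.
#'
#' @param clinical clinical tibble (training cohort).
#' @param cfg a [model_search_config()].
#' @return a `surv_model`.
#' @export
clinical_model <- function(clinical, cfg = model_search_config()) {
  covs <- cfg$clinical_covariates
  d <- .code_clinical(clinical, covs)
  complete <- mean(stats::complete.cases(d[covs]))
  if (complete < 0.9) {
    stop(sprintf("clinical covariates complete for only %.0f%% of patients (need 90%%)",
                 100 * complete), call. = FALSE)
  }
  fit_cox(d, covs)
}

#' Backward AIC covariate elimination for a Cox model
#'
#' Starts from the model containing all given covariates (markers plus, by
#' default, the clinical covariates), computed on the complete cases of the
#' full initial covariate set so AIC values are comparable across steps. At
#' each step the single covariate whose removal yields the lowest AIC is
#' dropped, as long as that AIC improves on the current model; the
#' minimal-AIC model encountered is returned. If the initial model cannot be
#' fitted, the search restarts from the clinical covariates alone (logged).
#'
#' @param data tibble with `time_days`, `event`, the marker columns and any
#'   clinical covariate columns (already binary/ordinal coded).
#' @param markers character vector of marker column names (or a candidate
#'   tibble).
#' @param clinical_covariates clinical covariate names to include in the
#'   initial model (may be empty).
#' @return the selected `surv_model` with attribute `aic_trace`, a tibble of
#'   the (strictly decreasing) AIC path: `step`, `dropped`, `aic`,
#'   `n_covariates`.
#' @export
backward_aic_integration <- function(data, markers,
                                     clinical_covariates = c("gender", "age",
                                                             "grade", "stage")) {
  if (is.data.frame(markers)) markers <- markers$feature_id
  covs <- unique(c(markers, intersect(clinical_covariates, names(data))))
  if (!length(covs)) stop("no covariates to select from", call. = FALSE)
  d <- data[stats::complete.cases(data[c("time_days", "event", covs)]), ]
  fit <- tryCatch(fit_cox(d, covs), error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    warning("initial full model failed; falling back to clinical-only start",
            call. = FALSE)
    covs <- intersect(clinical_covariates, names(data))
    if (!length(covs)) stop("no clinical covariates available for fallback", call. = FALSE)
    d <- data[stats::complete.cases(data[c("time_days", "event", covs)]), ]
    fit <- fit_cox(d, covs)
  }
  trace <- tibble::tibble(step = 0L, dropped = NA_character_, aic = fit$aic,
                          n_covariates = length(covs))
  step <- 0L
  while (length(covs) > 1) {
    drops <- purrr::map_dbl(covs, function(cv) {
      f <- tryCatch(fit_cox(d, setdiff(covs, cv)), error = function(e) NULL)
      if (is.null(f) || !f$converged) Inf else f$aic
    })
    if (min(drops) >= fit$aic) break
    step <- step + 1L
    gone <- covs[which.min(drops)]
    covs <- setdiff(covs, gone)
    fit <- fit_cox(d, covs)
    trace <- dplyr::bind_rows(trace,
                              tibble::tibble(step = step, dropped = gone,
                                             aic = fit$aic,
                                             n_covariates = length(covs)))
  }
  attr(fit, "aic_trace") <- trace
  fit
}

#' Multi-omics integrated model
#'
#' Pools the selected markers of several platforms (feature ids are expected
#' to be platform-prefixed, as produced by [assemble_model_data()], so
#' identical ids on different platforms stay distinct) and runs
#' [backward_aic_integration()] on their union. With `include_clinical =
#' TRUE` the clinical covariates join the initial model; the default pools
#' markers only. An empty union reduces to the clinical model.
#'
#' @param data model tibble containing all marker columns.
#' @param per_platform_markers list of marker-column character vectors (or
#'   candidate tibbles with a `column` or `feature_id` field).
#' @param include_clinical include gender/age/grade/stage in the start model.
#' @param cfg a [model_search_config()].
#' @export
multi_omics_model <- function(data, per_platform_markers,
                              include_clinical = FALSE,
                              cfg = model_search_config()) {
  cols <- unlist(purrr::map(per_platform_markers, function(x) {
    if (is.data.frame(x)) {
      if ("column" %in% names(x)) x$column else x$feature_id
    } else x
  }))
  cols <- unique(cols)
  clin_covs <- if (include_clinical) cfg$clinical_covariates else character()
  if (!length(cols)) {
    if (!length(clin_covs)) stop("no markers and no clinical covariates", call. = FALSE)
    return(clinical_model(data, cfg))
  }
  backward_aic_integration(data, cols, clinical_covariates = clin_covs)
}

#' Assemble a patient-by-covariate model table
#'
#' Joins the clinical table (gender binary coded, grade/stage as integer
#' ordinals) with the requested marker features from one or more omics
#' matrices. Marker columns are named `<platform>__<feature_id>` so the same
#' feature id on two platforms cannot collide; a `column` field mapping each
#' candidate to its column name is attached as attribute `marker_columns`.
#'
#' @param clinical clinical tibble.
#' @param omics named list of [omics_matrix()] (e.g. Z-scored training or
#'   test matrices), names = platforms.
#' @param markers marker candidate tibble (needs `feature_id` and `platform`)
#'   or named list of feature-id vectors.
#' @return tibble with `patient_id`, `time_days`, `event`, coded clinical
#'   covariates and one column per requested marker.
#' @export
assemble_model_data <- function(clinical, omics, markers) {
  d <- .code_clinical(clinical, "gender")
  if (is.data.frame(markers)) {
    mk <- markers[c("platform", "feature_id")]
  } else {
    mk <- dplyr::bind_rows(purrr::imap(markers, function(f, p) {
      tibble::tibble(platform = p, feature_id = f)
    }))
  }
  mk <- dplyr::distinct(mk)
  for (i in seq_len(nrow(mk))) {
    p <- mk$platform[i]; f <- mk$feature_id[i]
    m <- omics[[p]]
    if (is.null(m) || !f %in% rownames(m)) {
      stop(sprintf("marker %s not found on platform %s", f, p), call. = FALSE)
    }
    col <- paste0(p, "__", f)
    d[[col]] <- unclass(m)[f, match(d$patient_id, colnames(m))]
  }
  attr(d, "marker_columns") <- if (nrow(mk)) paste0(mk$platform, "__", mk$feature_id) else character()
  d
}
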