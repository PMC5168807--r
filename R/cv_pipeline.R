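#' Ordered k-fold cross-validation assignment
#'
#' Patients are sorted by ascending survival/follow-up time (ties broken by
#' event status descending, then patient id) and dealt round-robin to the k
#' sets, so the sets are balanced in survival time and vital status by
#' construction. The procedure is deterministic; the `seed` argument is
#' accepted for interface symmetry but unused.
#'
#' @param clinical clinical tibble.
#' @param k number of sets (3 in the reference design).
#' @param seed ignored (deterministic assignment).
#' @return tibble `patient_id`, `cv_set` (1..k); set sizes differ by at most 1.
#' @examples
#' \dontrun{
#' plan <- assign_cv_sets(cohort$clinical)  # 533 patients -> 178/178/177
#' }
#' @export
assign_cv_sets <- function(clinical, k = 3, seed = NULL) {
  stopifnot(k >= 2, nrow(clinical) >= k)
  ord <- order(clinical$time_days, -as.integer(clinical$event),
               clinical$patient_id)
  tibble::tibble(patient_id = clinical$patient_id[ord],
                 cv_set = rep_len(seq_len(k), nrow(clinical)))
}

# evaluate a fitted model on a cohort slice; NA when degenerate
.eval_model <- function(model, data) {
  d <- data[stats::complete.cases(data[c("time_days", "event", model$covariates)]), ]
  if (nrow(d) < 2) return(NA_real_)
  tryCatch(.cindex(risk_score(model, d), d$time_days, d$event),
           error = function(e) NA_real_)
}

.perf_row <- function(round, platform, approach, rank, model, train_c, test_c,
                      n_train, n_test) {
  tibble::tibble(round = round, platform = platform, approach = approach,
                 rank = rank, n_markers = length(model$covariates),
                 train_c = train_c, test_c = test_c,
                 n_train = n_train, n_test = n_test,
                 covariates = paste(model$covariates, collapse = ";"))
}

#' Run one cross-validation round
#'
#' For the given test set: fits Z-score transforms on the training patients
#' only, runs the four marker-selection approaches per platform, performs the
#' exhaustive best-subset Cox search at each rank (1..`max_rank`, capped at
#' `max_rank_combined` for the combined approach), and evaluates every
#' winning model on the held-out test set. Also fits the clinical-only
#' model, per-platform models integrated with clinical covariates through
#' backward AIC, the mutation-screen model (when a mutation matrix is
#' present) and the multi-omics union model. A failure on one platform is
#' logged and skips that platform, never the round.
#'
#' @param cohort list with `clinical` (tibble) and `omics` (named list of
#'   [omics_matrix()]; a platform named `mutation` is screened by
#'   [mutation_gene_selection()], all others by the stratification
#'   approaches).
#' @param plan CV assignment from [assign_cv_sets()].
#' @param test_set which set (1..k) is held out this round.
#' @param selection_cfg a [selection_config()]; its `rng_seed` seeds this
#'   round's resampling.
#' @param search_cfg a [model_search_config()].
#' @param platforms optional subset of platform names to run.
#' @return tibble of performance rows (`round`, `platform`, `approach`,
#'   `rank`, `train_c`, `test_c`, ...).
#' @export
run_round <- function(cohort, plan, test_set,
                      selection_cfg = selection_config(),
                      search_cfg = model_search_config(),
                      platforms = NULL) {
  clinical <- cohort$clinical
  test_ids <- plan$patient_id[plan$cv_set == test_set]
  train_ids <- setdiff(plan$patient_id, test_ids)
  clin_train <- clinical[clinical$patient_id %in% train_ids, ]
  clin_test <- clinical[clinical$patient_id %in% test_ids, ]
  omics <- cohort$omics
  if (!is.null(platforms)) omics <- omics[intersect(names(omics), platforms)]
  rows <- list()
  all_markers <- list()

  # clinical-only reference model
  cm <- tryCatch(clinical_model(clin_train, search_cfg), error = function(e) NULL)
  if (!is.null(cm)) {
    rows[[length(rows) + 1]] <- .perf_row(
      test_set, "clinical", "clinical_only", length(cm$covariates), cm,
      .eval_model(cm, .code_clinical(clin_train, "gender")),
      .eval_model(cm, .code_clinical(clin_test, "gender")),
      nrow(clin_train), nrow(clin_test))
  }

  for (p in names(omics)) {
    res <- tryCatch({
      m <- omics[[p]]
      if (identical(value_kind_of(m), "binary")) {
        .run_mutation_platform(m, clin_train, clin_test, test_set, p,
                               selection_cfg, search_cfg)
      } else {
        .run_quantitative_platform(m, clin_train, clin_test, test_set, p,
                                   selection_cfg, search_cfg)
      }
    }, error = function(e) {
      warning(sprintf("round %d, platform %s skipped: %s", test_set, p,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      rows[[length(rows) + 1]] <- res$rows
      all_markers[[p]] <- res$markers
    }
  }

  # multi-omics union model (markers only, per the reference design)
  if (length(all_markers) >= 1) {
    mo <- tryCatch({
      sel <- dplyr::bind_rows(purrr::map(all_markers, "candidates"))
      if (nrow(sel)) {
        dat_tr <- assemble_model_data(clin_train, purrr::map(all_markers, "train_matrix"), sel)
        dat_te <- assemble_model_data(clin_test, purrr::map(all_markers, "test_matrix"), sel)
        fit <- multi_omics_model(dat_tr, list(attr(dat_tr, "marker_columns")),
                                 include_clinical = FALSE, cfg = search_cfg)
        .perf_row(test_set, "multi_omics", "multi_omics",
                  length(fit$covariates), fit,
                  .eval_model(fit, dat_tr), .eval_model(fit, dat_te),
                  nrow(dat_tr), nrow(dat_te))
      } else NULL
    }, error = function(e) {
      warning(sprintf("round %d multi-omics model failed: %s", test_set,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(mo)) rows[[length(rows) + 1]] <- mo
  }
  dplyr::bind_rows(rows)
}

# selection + rank search + integration for one quantitative platform
.run_quantitative_platform <- function(m, clin_train, clin_test, round, p,
                                       selection_cfg, search_cfg) {
  zt <- fit_zscore(m, fit_ids = clin_train$patient_id)
  z <- apply_zscore(zt, m)
  z_train <- restrict_patients(z, clin_train$patient_id)
  m_train <- restrict_patients(m, clin_train$patient_id)
  sel <- list(
    extreme_score = extreme_score_selection(z_train, clin_train, selection_cfg),
    mean_score = mean_score_selection(z_train, clin_train, selection_cfg),
    extreme_survival = extreme_survival_selection(m_train, clin_train, selection_cfg))
  sel$combined <- combined_selection(sel[1:3])
  omx <- stats::setNames(list(z), p)
  rows <- list()
  union_all <- dplyr::bind_rows(sel[1:3])
  if (nrow(union_all) == 0) {
    warning(sprintf("platform %s: no markers selected by any approach", p),
            call. = FALSE)
    return(list(rows = NULL,
                markers = list(candidates = union_all, train_matrix = z, test_matrix = z)))
  }
  for (ap in names(sel)) {
    cand <- sel[[ap]]
    if (nrow(cand) == 0) next
    dat_tr <- assemble_model_data(clin_train, omx, cand)
    dat_te <- assemble_model_data(clin_test, omx, cand)
    cols <- attr(dat_tr, "marker_columns")
    cap <- if (ap == "combined") search_cfg$max_rank_combined else search_cfg$max_rank
    for (r in seq_len(min(cap, length(cols)))) {
      fit <- tryCatch(best_model_per_rank(dat_tr, cols, r, search_cfg),
                      error = function(e) NULL)
      if (is.null(fit)) next
      rows[[length(rows) + 1]] <- .perf_row(
        round, p, ap, r, fit, attr(fit, "train_c"), .eval_model(fit, dat_te),
        nrow(dat_tr), nrow(dat_te))
    }
  }
  # integrated with clinical covariates: combined-union markers + backward AIC
  int <- tryCatch({
    dat_tr <- assemble_model_data(clin_train, omx, sel$combined)
    dat_te <- assemble_model_data(clin_test, omx, sel$combined)
    fit <- backward_aic_integration(dat_tr, attr(dat_tr, "marker_columns"),
                                    clinical_covariates = search_cfg$clinical_covariates)
    .perf_row(round, p, "integrated_clinical", length(fit$covariates), fit,
              .eval_model(fit, dat_tr), .eval_model(fit, dat_te),
              nrow(dat_tr), nrow(dat_te))
  }, error = function(e) NULL)
  if (!is.null(int)) rows[[length(rows) + 1]] <- int
  list(rows = dplyr::bind_rows(rows),
       markers = list(candidates = sel$combined, train_matrix = z, test_matrix = z))
}

.run_mutation_platform <- function(m, clin_train, clin_test, round, p,
                                   selection_cfg, search_cfg) {
  m_train <- restrict_patients(m, clin_train$patient_id)
  cand <- mutation_gene_selection(m_train, clin_train, selection_cfg)
  if (nrow(cand) == 0) {
    return(list(rows = NULL,
                markers = list(candidates = cand, train_matrix = m, test_matrix = m)))
  }
  cand <- utils::head(cand, search_cfg$max_rank)
  omx <- stats::setNames(list(m), p)
  dat_tr <- assemble_model_data(clin_train, omx, cand)
  dat_te <- assemble_model_data(clin_test, omx, cand)
  cols <- attr(dat_tr, "marker_columns")
  fit <- fit_cox(dat_tr, cols)
  rows <- .perf_row(round, p, "mutation", length(cols), fit,
                    .eval_model(fit, dat_tr), .eval_model(fit, dat_te),
                    nrow(dat_tr), nrow(dat_te))
  list(rows = rows,
       markers = list(candidates = cand, train_matrix = m, test_matrix = m))
}

#' Run the full ordered cross-validation
#'
#' Executes [run_round()] once per CV set, deriving one selection seed per
#' round from the master seed (documented splitting: `master * 1000 + round`,
#' kept below 2^31), and row-binds the performance records.
#'
#' @inheritParams run_round
#' @param k number of CV sets.
#' @param master_seed integer master seed for the per-round resampling.
#' @export
run_cv <- function(cohort, k = 3, master_seed = 1,
                   selection_cfg = selection_config(),
                   search_cfg = model_search_config(), platforms = NULL) {
  plan <- assign_cv_sets(cohort$clinical, k = k)
  purrr::map_dfr(seq_len(k), function(r) {
    cfg <- selection_cfg
    cfg$rng_seed <- (master_seed * 1000 + r) %% .Machine$integer.max
    run_round(cohort, plan, r, selection_cfg = cfg, search_cfg = search_cfg,
              platforms = platforms)
  })
}

#' Aggregate performance rows across cross-validation rounds
#'
#' Per (platform, approach, rank) cell: mean and standard deviation of the
#' train and test C-indexes over the rounds. Cells missing one or more
#' rounds are flagged (`complete = FALSE`) rather than silently averaged.
#'
#' @param rows performance tibble from [run_cv()] / [run_round()].
#' @param k expected number of rounds.
#' @return tibble of per-cell summaries, class `perf_summary`.
#' @export
aggregate_performance <- function(rows, k = max(rows$round)) {
  out <- rows %>%
    dplyr::summarise(
      n_rounds = dplyr::n(),
      train_c_mean = mean(.data$train_c, na.rm = TRUE),
      train_c_sd = stats::sd(.data$train_c),
      test_c_mean = mean(.data$test_c, na.rm = TRUE),
      test_c_sd = stats::sd(.data$test_c),
      .by = c("platform", "approach", "rank")) %>%
    dplyr::mutate(complete = .data$n_rounds == k) %>%
    dplyr::arrange(.data$platform, .data$approach, .data$rank)
  class(out) <- c("perf_summary", class(out))
  out
}

#' Marker-stage association report
#'
#' For each requested feature (typically selected methylation markers),
#' Spearman correlation between the molecular value and the integer tumor
#' stage, with the corresponding monotone-trend p-value. Features observed in
#' fewer than 2 distinct stages, or constant, are skipped.
#'
#' @param m an [omics_matrix()].
#' @param clinical clinical tibble with a `stage` column.
#' @param features feature ids to report (default: all rows of `m`).
#' @return tibble `feature_id`, `rho`, `p_value`, `n`.
#' @export
stage_association_report <- function(m, clinical, features = rownames(m)) {
  al <- .align_cohort(m, clinical)
  stage <- clinical$stage[match(al$patient_ids, clinical$patient_id)]
  purrr::map_dfr(intersect(features, rownames(m)), function(f) {
    x <- al$values[f, ]
    ok <- !is.na(x) & !is.na(stage)
    if (sum(ok) < 3 || length(unique(stage[ok])) < 2 || length(unique(x[ok])) < 2) {
      return(NULL)
    }
    ct <- suppressWarnings(stats::cor.test(x[ok], stage[ok], method = "spearman",
                                           exact = FALSE))
    tibble::tibble(feature_id = f, rho = unname(ct$estimate),
                   p_value = ct$p.value, n = sum(ok))
  })
}

#' Methylation-expression interconnection report
#'
#' For paired (methylation probe, expression feature) markers: within-tissue
#' mean methylation, a Welch t-test of methylation in tumor versus normal
#' samples, and the cross-sample correlation between methylation and
#' expression (computed over samples measured on both platforms). Pairs with
#' fewer than 3 samples in a tissue are flagged.
#'
#' @param meth methylation [omics_matrix()] whose columns cover tumor and
#'   normal samples.
#' @param expr expression [omics_matrix()].
#' @param pairs tibble with columns `meth_feature`, `expr_feature`.
#' @param tissue named character vector sample id -> `"tumor"` / `"normal"`.
#' @return tibble, one row per pair: tumor/normal methylation means, t-test
#'   p-value, methylation-expression Pearson correlation, and a `flagged`
#'   indicator for underpowered pairs.
#' @export
meth_expr_report <- function(meth, expr, pairs, tissue) {
  purrr::pmap_dfr(pairs, function(meth_feature, expr_feature, ...) {
    mv <- unclass(meth)[meth_feature, ]
    tt <- tissue[colnames(meth)]
    tum <- mv[!is.na(tt) & tt == "tumor"]
    nrm <- mv[!is.na(tt) & tt == "normal"]
    flagged <- sum(!is.na(tum)) < 3 || sum(!is.na(nrm)) < 3
    p <- if (flagged) NA_real_ else welch_t_test(tum, nrm)$p_value
    shared <- intersect(colnames(meth), colnames(expr))
    ev <- unclass(expr)[expr_feature, shared]
    mv2 <- unclass(meth)[meth_feature, shared]
    ok <- !is.na(ev) & !is.na(mv2)
    r <- if (sum(ok) >= 3) stats::cor(mv2[ok], ev[ok]) else NA_real_
    tibble::tibble(meth_feature = meth_feature, expr_feature = expr_feature,
                   mean_meth_tumor = mean(tum, na.rm = TRUE),
                   mean_meth_normal = mean(nrm, na.rm = TRUE),
                   tumor_vs_normal_p = p, meth_expr_cor = r,
                   n_shared = sum(ok), flagged = flagged)
  })
}
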