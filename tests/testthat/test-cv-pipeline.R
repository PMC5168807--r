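small_pipeline_cohort <- function(seed, n = 240, n_features = 24,
                                  beta = log(3), n_planted = 2) {
  planted <- tibble::tibble(platform = "mrna", feature = seq_len(n_planted),
                            beta = rep(beta, n_planted))
  cfg <- simulation_config(n_patients = n, n_features = c(mrna = n_features),
                           n_mutation_genes = 0, planted = planted,
                           clinical_beta = c(gender = 0, age = 0, grade = 0, stage = 0),
                           censoring_fraction = 0.5,
                           platform_missing = c(mrna = 0), n_normals = c(),
                           rng_seed = seed)
  simulate_cohort(cfg)
}

test_that("ordered CV assignment balances sets and partitions the cohort", {
  # 533 patients -> 178 / 178 / 177
  co <- paper_shaped_cohort(seed = 5, n_features = c(mrna = 3))
  plan <- assign_cv_sets(co$clinical)
  expect_equal(unname(table(plan$cv_set)), c(178, 178, 177), ignore_attr = TRUE)
  expect_setequal(plan$patient_id, co$clinical$patient_id)

  # 3 patients -> 1/1/1
  tiny <- toy_clinical(c(5, 1, 9), c(TRUE, FALSE, TRUE))
  expect_equal(unname(table(assign_cv_sets(tiny)$cv_set)), c(1, 1, 1),
               ignore_attr = TRUE)

  # survival-time balance: per-set mean time within 5% of the cohort mean
  for (seed in seq(1, 20)) {
    cl <- small_pipeline_cohort(seed, n = 150, n_features = 2)$clinical
    plan <- assign_cv_sets(cl)
    overall <- mean(cl$time_days)
    per_set <- tapply(cl$time_days[match(plan$patient_id, cl$patient_id)],
                      plan$cv_set, mean)
    expect_true(all(abs(per_set - overall) < 0.05 * overall))
  }

  # deterministic regardless of row order
  cl <- small_pipeline_cohort(3, n = 90, n_features = 2)$clinical
  p1 <- assign_cv_sets(cl)
  p2 <- assign_cv_sets(cl[sample(nrow(cl)), ])
  expect_identical(dplyr::arrange(p1, patient_id), dplyr::arrange(p2, patient_id))
})

test_that("a full CV round recovers planted signal and never touches test data in training", {
  co <- small_pipeline_cohort(42)
  plan <- assign_cv_sets(co$clinical)
  sel_cfg <- selection_config(n_iterations = 40, rng_seed = 7)
  search_cfg <- model_search_config(max_rank = 2, max_rank_combined = 2)
  rows <- run_round(co, plan, test_set = 1, selection_cfg = sel_cfg,
                    search_cfg = search_cfg)
  expect_true(all(rows$train_c >= 0 & rows$train_c <= 1, na.rm = TRUE))
  expect_true(all(rows$test_c >= 0 & rows$test_c <= 1, na.rm = TRUE))
  r2 <- rows[rows$platform == "mrna" & rows$approach == "mean_score" & rows$rank == 2, ]
  expect_equal(nrow(r2), 1)
  expect_gt(r2$test_c, 0.6)

  # leakage audit: corrupt every test-set molecular value; training-side
  # results (selection, winners, training C) must be bit-identical
  co_bad <- co
  test_ids <- plan$patient_id[plan$cv_set == 1]
  v <- unclass(co_bad$omics$mrna)
  set.seed(1)
  v[, test_ids] <- matrix(rnorm(length(test_ids) * nrow(v), 50, 100),
                          nrow(v), length(test_ids))
  co_bad$omics$mrna <- omicsurv::omics_matrix(v, "mrna", "continuous")
  rows_bad <- run_round(co_bad, plan, test_set = 1, selection_cfg = sel_cfg,
                        search_cfg = search_cfg)
  expect_identical(rows$covariates, rows_bad$covariates)
  expect_identical(rows$train_c, rows_bad$train_c)
  expect_false(identical(rows$test_c, rows_bad$test_c))
})

test_that("three rounds cover every patient once as test and aggregate correctly", {
  co <- small_pipeline_cohort(43, n = 180, n_features = 12)
  plan <- assign_cv_sets(co$clinical)
  covered <- unlist(lapply(1:3, function(s) plan$patient_id[plan$cv_set == s]))
  expect_setequal(covered, co$clinical$patient_id)
  expect_equal(length(covered), length(unique(covered)))

  rows <- suppressWarnings(
    run_cv(co, master_seed = 11,
           selection_cfg = selection_config(n_iterations = 25),
           search_cfg = model_search_config(max_rank = 2, max_rank_combined = 2)))
  agg <- aggregate_performance(rows)
  expect_s3_class(agg, "perf_summary")
  expect_true(all(agg$n_rounds <= 3))

  # reproducibility end to end with a fixed master seed
  rows2 <- suppressWarnings(
    run_cv(co, master_seed = 11,
           selection_cfg = selection_config(n_iterations = 25),
           search_cfg = model_search_config(max_rank = 2, max_rank_combined = 2)))
  expect_identical(rows, rows2)
})

test_that("aggregation computes cross-round mean/sd and flags missing rounds", {
  rows <- tibble::tibble(round = 1:3, platform = "mrna", approach = "mean_score",
                         rank = 1, n_markers = 1,
                         train_c = c(0.8, 0.8, 0.8),
                         test_c = c(0.70, 0.74, 0.72),
                         n_train = 100, n_test = 50, covariates = "m")
  agg <- aggregate_performance(rows, k = 3)
  expect_equal(agg$test_c_mean, 0.72)
  expect_equal(agg$test_c_sd, sd(c(0.70, 0.74, 0.72)))
  expect_equal(agg$train_c_sd, 0)               # identical rounds -> sd 0
  expect_true(agg$complete)

  agg2 <- aggregate_performance(rows[1:2, ], k = 3)
  expect_false(agg2$complete)
})

test_that("stage association report finds coupled markers and skips degenerate ones", {
  planted <- tibble::tibble(platform = "methylation", feature = 1L,
                            beta = 0, stage_coupling = 1.0)
  cfg <- simulation_config(n_patients = 500,
                           n_features = c(methylation = 10),
                           n_mutation_genes = 0, planted = planted,
                           censoring_fraction = 0.5,
                           platform_missing = c(methylation = 0),
                           n_normals = c(), rng_seed = 31)
  co <- simulate_cohort(cfg)
  rep <- stage_association_report(co$omics$methylation, co$clinical)
  coupled <- rep[rep$feature_id == "methylation_0001", ]
  expect_gt(coupled$rho, 0)
  expect_lt(coupled$p_value, 0.05)
  # stage-independent markers stay near zero correlation
  null_rho <- rep$rho[rep$feature_id != "methylation_0001"]
  expect_gte(mean(abs(null_rho) < 0.1), 0.9)

  # constant marker is skipped
  v <- unclass(co$omics$methylation)
  v["methylation_0002", ] <- 0.5
  m2 <- omics_matrix(v, "methylation", "beta")
  rep2 <- stage_association_report(m2, co$clinical)
  expect_false("methylation_0002" %in% rep2$feature_id)
})

test_that("methylation-expression report recovers the planted anti-correlated pair", {
  co <- paper_shaped_cohort(seed = 9, n_features = c(mirna = 12, mrna = 6,
                                                     protein = 4,
                                                     methylation = 12, cnv = 4))
  meth_all <- cbind(unclass(co$omics$methylation), unclass(co$normals$methylation))
  meth <- omics_matrix(meth_all, "methylation", "beta")
  expr_all <- cbind(unclass(co$omics$mirna), unclass(co$normals$mirna))
  expr <- omics_matrix(expr_all, "mirna", "continuous")
  pairs <- tibble::tibble(meth_feature = "methylation_0005",
                          expr_feature = "mirna_0005")
  rep <- meth_expr_report(meth, expr, pairs, co$normals$tissue)
  expect_lt(rep$mean_meth_tumor, rep$mean_meth_normal)  # tumor hypomethylation
  expect_lt(rep$tumor_vs_normal_p, 0.01)
  expect_lt(rep$meth_expr_cor, -0.3)                    # anti-correlated pair
  expect_false(rep$flagged)

  # a feature paired with itself correlates perfectly
  self <- meth_expr_report(meth, meth,
                           tibble::tibble(meth_feature = "methylation_0002",
                                          expr_feature = "methylation_0002"),
                           co$normals$tissue)
  expect_equal(self$meth_expr_cor, 1)

  # an unrelated pair stays near zero
  null <- meth_expr_report(meth, expr,
                           tibble::tibble(meth_feature = "methylation_0009",
                                          expr_feature = "mirna_0009"),
                           co$normals$tissue)
  expect_lt(abs(null$meth_expr_cor), 0.15)

  # under 3 samples in a tissue -> flagged
  few <- co$normals$tissue
  few[names(few)[few == "normal"]] <- "tumor"
  flagged <- meth_expr_report(meth, expr, pairs, few)
  expect_true(flagged$flagged)
})
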