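# builds a training cohort with planted hazard effects on one platform
planted_training <- function(seed, n = 350, n_features = 30,
                             beta = log(3), n_planted = 1) {
  planted <- tibble::tibble(platform = "mrna",
                            feature = seq_len(n_planted),
                            beta = beta)
  cfg <- simulation_config(n_patients = n, n_features = c(mrna = n_features),
                           n_mutation_genes = 0, planted = planted,
                           clinical_beta = c(gender = 0, age = 0, grade = 0, stage = 0),
                           censoring_fraction = 0.5,
                           platform_missing = c(mrna = 0), n_normals = c(),
                           rng_seed = seed)
  co <- simulate_cohort(cfg)
  z <- apply_zscore(fit_zscore(co$omics$mrna), co$omics$mrna)
  list(clinical = co$clinical, z = z, raw = co$omics$mrna)
}

test_that("score-based selection recovers a planted marker with high frequency", {
  for (seed in c(101, 202, 303)) {
    tr <- planted_training(seed)
    cfg <- selection_config(rng_seed = seed)
    mean_sel <- mean_score_selection(tr$z, tr$clinical, cfg)
    expect_true("mrna_0001" %in% mean_sel$feature_id)
    f_mean <- mean_sel$frequency[mean_sel$feature_id == "mrna_0001"]
    expect_gte(f_mean, 90)
    # high values were planted to raise the hazard
    expect_equal(mean_sel$direction[mean_sel$feature_id == "mrna_0001"], "high_worse")

    ext_sel <- extreme_score_selection(tr$z, tr$clinical, cfg)
    expect_true("mrna_0001" %in% ext_sel$feature_id)
    f_ext <- ext_sel$frequency[ext_sel$feature_id == "mrna_0001"]
    expect_gte(f_ext, 50)
    # power ordering: mean-score stratification uses larger groups
    expect_gte(f_mean, f_ext)
  }
})

test_that("selection is seed-reproducible and invariant to patient order", {
  tr <- planted_training(7, n = 120, n_features = 12)
  cfg <- selection_config(n_iterations = 25, rng_seed = 99)
  a <- mean_score_selection(tr$z, tr$clinical, cfg)
  b <- mean_score_selection(tr$z, tr$clinical, cfg)
  expect_identical(a, b)

  perm <- sample(ncol(tr$z))
  z_perm <- tr$z[, perm]
  clin_perm <- tr$clinical[rev(seq_len(nrow(tr$clinical))), ]
  c <- mean_score_selection(z_perm, clin_perm, cfg)
  expect_identical(a, c)
})

test_that("null data rarely passes the two-half screen", {
  # per-feature per-iteration selection probability is ~ alpha^2; the
  # empirical rate over features and seeds must stay below 2 * alpha^2
  total_pass <- 0
  total_trials <- 0
  for (seed in c(11, 22, 33)) {
    tr <- planted_training(seed, n = 300, n_features = 40, beta = 0)
    cfg <- selection_config(rng_seed = seed)
    sel <- suppressWarnings(mean_score_selection(tr$z, tr$clinical, cfg))
    expect_true(all(sel$frequency < 100))
    total_pass <- total_pass + sum(sel$frequency)
    total_trials <- total_trials + 40 * 100
  }
  expect_lte(total_pass / total_trials, 2 * 0.05^2)
})

test_that("groups below the minimum size are never eligible", {
  # 9 patients above Z = 1 -> extreme-score groups can never reach 10
  set.seed(61)
  n <- 120
  z <- matrix(rnorm(n, 0, 0.1), 1, n)
  z[1, 1:9] <- 2      # exactly 9 extreme-high patients
  z[1, 10:40] <- -2   # plenty of extreme-low
  m <- toy_matrix(z, kind = "zscore", features = "f1")
  clin <- toy_clinical(rexp(n, 1 / 300), runif(n) > 0.3,
                       ids = colnames(m))
  out <- suppressWarnings(
    extreme_score_selection(m, clin, selection_config(n_iterations = 30, rng_seed = 1)))
  expect_equal(nrow(out), 0)

  # mean-score: a feature observed in only 15 patients can never split into
  # two groups of >= 10
  z2 <- matrix(NA_real_, 1, n)
  z2[1, 1:15] <- rnorm(15)
  m2 <- toy_matrix(z2, kind = "zscore", features = "f1")
  out2 <- suppressWarnings(
    mean_score_selection(m2, clin, selection_config(n_iterations = 30, rng_seed = 1)))
  expect_equal(nrow(out2), 0)
})

test_that("extreme-survival selection honors the 1-year/5-year windows", {
  # short group = observed death within 365 d; long group = anyone beyond
  # 1825 d (dead or censored); censored before 1 year belongs to neither.
  set.seed(71)
  n_short <- 14; n_long <- 14; n_neither <- 12
  time <- c(rep(100, n_short), rep(2000, n_long), rep(200, n_neither))
  event <- c(rep(TRUE, n_short),
             rep(c(TRUE, FALSE), length.out = n_long),  # deaths beyond 5y count as long
             rep(FALSE, n_neither))
  clin <- toy_clinical(time, event)
  # marker separates short from long; the 'neither' patients carry wild
  # values that would kill significance if they leaked into either group
  vals <- c(rnorm(n_short, 3, 0.3), rnorm(n_long, 0, 0.3),
            rep(c(-50, 50), length.out = n_neither))
  m <- toy_matrix(matrix(vals, 1), features = "marker")
  cfg <- selection_config(n_iterations = 60, min_group = 3, rng_seed = 5)
  sel <- extreme_survival_selection(m, clin, cfg)
  expect_true("marker" %in% sel$feature_id)
  expect_gte(sel$frequency[1] / sel$n_iterations_effective[1], 0.5)
  expect_equal(sel$direction[1], "high_worse")
})

test_that("ineligible extreme-survival halves skip the iteration, not the feature", {
  set.seed(72)
  # only 8 short survivors in the whole cohort: with min_group 10 every
  # iteration is ineligible and the effective denominator collapses to 0
  time <- c(rep(100, 8), rep(2000, 40))
  event <- c(rep(TRUE, 8), rep(FALSE, 40))
  clin <- toy_clinical(time, event)
  m <- toy_matrix(matrix(rnorm(48), 1), features = "f1")
  expect_message(
    out <- suppressWarnings(
      extreme_survival_selection(m, clin, selection_config(n_iterations = 10, rng_seed = 2))),
    "skipped")
  expect_equal(nrow(out), 0)

  # planted mean shift between short and long survivors is recovered
  tr <- planted_training(55, n = 400, n_features = 25, beta = log(4))
  sel <- extreme_survival_selection(tr$raw, tr$clinical,
                                    selection_config(rng_seed = 55))
  expect_true("mrna_0001" %in% sel$feature_id)
})

test_that("combined selection takes the union with max frequency and provenance", {
  mk <- function(ids, freq, approach, dir = "high_worse") {
    tibble::tibble(feature_id = ids, platform = "mrna", approach = approach,
                   frequency = freq, n_iterations_effective = 100L,
                   direction = dir, mean_p = 0.01)
  }
  # three disjoint top-10 lists -> 30 candidates
  a <- mk(sprintf("a%02d", 1:10), 100:91, "extreme_score")
  b <- mk(sprintf("b%02d", 1:10), 100:91, "mean_score")
  c <- mk(sprintf("c%02d", 1:10), 100:91, "extreme_survival")
  expect_equal(nrow(combined_selection(a, b, c)), 30)
  # identical lists -> 10
  expect_equal(nrow(combined_selection(a, a, a)), 10)
  # overlap: A, B, C of 10 each sharing a 5-feature core -> 20 distinct
  core <- sprintf("core%02d", 1:5)
  a2 <- mk(c(core, sprintf("a%02d", 1:5)), c(80:76, 70:66), "extreme_score")
  b2 <- mk(c(core, sprintf("b%02d", 1:5)), c(90:86, 60:56), "mean_score")
  c2 <- mk(c(core, sprintf("c%02d", 1:5)), c(50:46, 40:36), "extreme_survival")
  comb <- combined_selection(a2, b2, c2)
  expect_equal(nrow(comb), 20)
  # max frequency retained, provenance merged
  expect_equal(comb$frequency[comb$feature_id == "core01"], 90)
  expect_match(comb$provenance[comb$feature_id == "core01"],
               "extreme_score\\+extreme_survival\\+mean_score")
  # conflicting directions become undetermined
  d2 <- mk("core01", 10, "mean_score", dir = "high_better")
  both <- combined_selection(a2, d2)
  expect_equal(both$direction[both$feature_id == "core01"], "undetermined")
})

test_that("mutation screening selects hazardous genes and drops degenerate ones", {
  sim_mut <- function(seed) {
    set.seed(seed)
    n <- 350
    carriers <- sample(n, 30)
    v <- matrix(rbinom(5 * n, 1, 0.15), 5, n)
    v[1, ] <- 0; v[1, carriers] <- 1          # planted gene, HR 4
    v[5, ] <- 1                               # mutated in everyone -> excluded
    lp <- log(4) * v[1, ]
    t_event <- rexp(n, exp(lp) / 800)
    cens <- runif(n, 0, 2500)
    clin <- toy_clinical(pmin(t_event, cens), t_event <= cens)
    m <- toy_matrix(v, platform = "mutation", kind = "binary",
                    features = sprintf("g%d", 1:5), patients = clin$patient_id)
    mutation_gene_selection(m, clin, selection_config())
  }
  hits <- vapply(1:20, function(s) "g1" %in% sim_mut(s)$feature_id, logical(1))
  expect_gte(mean(hits), 0.95)
  sel <- sim_mut(3)
  expect_false("g5" %in% sel$feature_id)      # one empty group
  expect_true(all(sel$frequency == 1L))       # single test, no resampling

  # per-variant mode via mutation_matrix keying
  calls <- tibble::tibble(patient_id = c("p1", "p2", "p2"),
                          gene_id = c("gA", "gA", "gB"),
                          variant_id = c("gA:v1", "gA:v2", "gB:v1"))
  mv <- mutation_matrix(calls, paste0("p", 1:4), by = "variant")
  expect_setequal(rownames(mv), c("gA:v1", "gA:v2", "gB:v1"))
  mg <- mutation_matrix(calls, paste0("p", 1:4), by = "gene",
                        missing_ids = "p4")
  expect_equal(unname(unclass(mg)["gA", ]), c(1, 1, 0, NA))
})
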