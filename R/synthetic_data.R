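#' Configuration for the synthetic multi-omics cohort generator
#'
#' The generator plants known hazard effects into otherwise-null molecular
#' platforms, draws survival times from a Weibull proportional-hazards
#' mechanism and censors them with an independent uniform horizon calibrated
#' to a target censoring fraction, so every stage of the screening pipeline
#' can be tested against ground truth.
#'
#' @param n_patients cohort size.
#' @param n_features named integer vector of feature counts per continuous
#'   platform (any of `mirna`, `mrna`, `protein`, `methylation`, `cnv`).
#' @param n_mutation_genes number of genes in the somatic-mutation platform.
#' @param planted tibble of planted markers with columns `platform`,
#'   `feature` (1-based index within the platform), `beta` (log hazard ratio
#'   per SD of the feature), and optional columns `stage_coupling`
#'   (methylation only: latent shift per SD of stage) and `pair_sign`
#'   (methylation only: sign of an induced paired expression feature on the
#'   platform named in `pair_platform`, same feature index).
#' @param clinical_beta named vector of log hazard ratios for the clinical
#'   covariates `gender` (per level), `age` (per year), `grade`, `stage`
#'   (per ordinal step).
#' @param weibull_shape,weibull_scale baseline Weibull shape (1 =
#'   exponential) and scale in days.
#' @param censoring_fraction target fraction of censored patients, in (0, 1).
#' @param platform_missing named vector, fraction of patients per platform
#'   with the whole platform unassayed (whole-column missingness).
#' @param cell_missing_fraction extra scattered per-cell missingness applied
#'   to continuous platforms (exercises the more-than-half feature filter).
#' @param mutation_rate mean per-gene carrier probability.
#' @param n_normals named vector of normal-tissue sample counts for the
#'   platforms that get normal companions (methylation / expression).
#' @param rng_seed integer seed; a fixed seed makes the cohort bit-identical.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 533,
                              n_features = c(mirna = 100, mrna = 100,
                                             protein = 60, methylation = 100,
                                             cnv = 60),
                              n_mutation_genes = 50,
                              planted = NULL,
                              clinical_beta = c(gender = 0, age = 0.02,
                                                grade = 0.25, stage = 0.45),
                              weibull_shape = 1, weibull_scale = 2200,
                              censoring_fraction = 0.67,
                              platform_missing = c(mirna = 0.075, mrna = 0.028,
                                                   protein = 0.148, cnv = 0.041,
                                                   methylation = 0.105,
                                                   mutation = 0.1),
                              cell_missing_fraction = 0,
                              mutation_rate = 0.08,
                              n_normals = c(methylation = 60, mirna = 60),
                              rng_seed = 1L) {
  stopifnot(censoring_fraction > 0, censoring_fraction < 1, n_patients >= 10,
            weibull_shape > 0, weibull_scale > 0)
  if (is.null(planted)) {
    planted <- tibble::tibble(platform = character(), feature = integer(),
                              beta = double())
  }
  if (nrow(planted)) {
    bad <- planted$feature > n_features[planted$platform]
    if (any(bad, na.rm = TRUE)) stop("planted feature index out of platform bounds", call. = FALSE)
    stopifnot(all(is.finite(planted$beta)))
  }
  structure(list(n_patients = n_patients, n_features = n_features,
                 n_mutation_genes = n_mutation_genes, planted = planted,
                 clinical_beta = clinical_beta, weibull_shape = weibull_shape,
                 weibull_scale = weibull_scale,
                 censoring_fraction = censoring_fraction,
                 platform_missing = platform_missing,
                 cell_missing_fraction = cell_missing_fraction,
                 mutation_rate = mutation_rate, n_normals = n_normals,
                 rng_seed = rng_seed),
            class = "simulation_config")
}

.feature_ids <- function(platform, n) sprintf("%s_%04d", platform, seq_len(n))

#' Simulate a multi-omics cohort with known ground truth
#'
#' Continuous platforms are standard normal per feature; methylation beta
#' values arise from a logistic transform of a latent normal (optionally
#' coupled to tumor stage and anti-correlated with a paired expression
#' feature); gene-level copy number is drawn per gene and also emitted as a
#' per-patient segment table plus gene annotation in the file dialects the
#' readers expect; mutations are Bernoulli per gene. Survival times follow a
#' Weibull proportional-hazards model whose log hazard adds the clinical
#' terms and every planted molecular term; censoring is an independent
#' uniform horizon calibrated on the realized event times to hit the target
#' censoring fraction. Platform missingness masks whole patients per
#' platform (availability-table semantics); optional scattered cell
#' missingness is available on top.
#'
#' @param cfg a [simulation_config()].
#' @return list with `clinical`, `omics` (named list of [omics_matrix()],
#'   including gene-level `cnv` and binary `mutation`), `segments` +
#'   `gene_annotation` (the CNV ground truth in SEG/BED form),
#'   `mutation_calls` (MAF-like tibble), `normals` (normal-tissue matrices
#'   and a `tissue` label vector), and `ground_truth` (per-patient linear
#'   predictor, planted-marker registry, realized censoring fraction).
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  set.seed(cfg$rng_seed)
  n <- cfg$n_patients
  ids <- sprintf("PT%04d", seq_len(n))

  gender <- sample(c("female", "male"), n, replace = TRUE)
  age <- round(pmax(stats::rnorm(n, 60, 11), 18), 1)
  stage <- sample(1:4, n, replace = TRUE, prob = c(267, 57, 126, 86) / 533)
  grade <- pmin(pmax(stage + sample(c(-1L, 0L, 1L), n, replace = TRUE), 1L), 4L)

  lp <- cfg$clinical_beta[["gender"]] * (gender == "male") +
    cfg$clinical_beta[["age"]] * (age - mean(age)) +
    cfg$clinical_beta[["grade"]] * (grade - mean(grade)) +
    cfg$clinical_beta[["stage"]] * (stage - mean(stage))

  planted <- cfg$planted
  get_planted <- function(p) planted[planted$platform == p, , drop = FALSE]

  omics <- list()
  latents <- list()
  for (p in names(cfg$n_features)) {
    nf <- cfg$n_features[[p]]
    sdv <- if (p == "cnv") 0.35 else 1
    v <- matrix(stats::rnorm(nf * n, 0, sdv), nf, n,
                dimnames = list(.feature_ids(p, nf), ids))
    pl <- get_planted(p)
    if (p == "methylation") {
      if (nrow(pl)) for (i in seq_len(nrow(pl))) {
        f <- pl$feature[i]
        if (!is.null(pl$stage_coupling) && !is.na(pl$stage_coupling[i]) &&
            pl$stage_coupling[i] != 0) {
          v[f, ] <- v[f, ] + pl$stage_coupling[i] * as.numeric(scale(stage))
        }
        lp <- lp + pl$beta[i] * v[f, ] / stats::sd(v[f, ])
      }
      latents[[p]] <- v
      meth_base <- stats::rnorm(nf, 0, 1)   # reused for normal-tissue samples
      omics[[p]] <- omics_matrix(stats::plogis(meth_base + v), p, "beta")
    } else {
      if (nrow(pl)) for (i in seq_len(nrow(pl))) {
        lp <- lp + pl$beta[i] * v[pl$feature[i], ] / sdv
      }
      latents[[p]] <- v
      omics[[p]] <- omics_matrix(v, p,
                                 if (p == "cnv") "segment_mean" else "continuous")
    }
  }

  # induced expression partners of planted methylation markers
  pm <- get_planted("methylation")
  if (nrow(pm) && "pair_sign" %in% names(pm)) {
    for (i in seq_len(nrow(pm))) {
      if (is.na(pm$pair_sign[i]) || pm$pair_sign[i] == 0) next
      pp <- if ("pair_platform" %in% names(pm) && !is.na(pm$pair_platform[i])) {
        pm$pair_platform[i]
      } else "mirna"
      f <- pm$feature[i]
      v <- unclass(omics[[pp]])
      v[f, ] <- pm$pair_sign[i] * latents$methylation[pm$feature[i], ] +
        stats::rnorm(n, 0, 0.5)
      omics[[pp]] <- omics_matrix(v, pp, value_kind_of(omics[[pp]]))
    }
  }

  # mutations: Bernoulli carriers per gene; planted genes add their effect
  ng <- cfg$n_mutation_genes
  mut <- NULL
  if (ng > 0) {
    rates <- stats::runif(ng, 0.3 * cfg$mutation_rate, 2 * cfg$mutation_rate)
    mut <- matrix(stats::rbinom(ng * n, 1, rep(rates, times = n)), ng, n,
                  dimnames = list(.feature_ids("mutation", ng), ids))
    pmut <- get_planted("mutation")
    if (nrow(pmut)) for (i in seq_len(nrow(pmut))) {
      lp <- lp + pmut$beta[i] * mut[pmut$feature[i], ]
    }
    omics$mutation <- omics_matrix(mut, "mutation", "binary")
  }

  # Weibull PH survival + independent uniform censoring hitting the target
  u <- stats::runif(n)
  t_event <- cfg$weibull_scale * (-log(u) / exp(lp - mean(lp)))^(1 / cfg$weibull_shape)
  cens_prob <- function(cmax) mean(pmin(t_event / cmax, 1))
  lo <- min(t_event) / 2; hi <- max(t_event) * 100
  target <- cfg$censoring_fraction
  if (cens_prob(hi) > target || cens_prob(lo) < target) {
    stop(sprintf("censoring target %.2f unachievable (range %.3f-%.3f)",
                 target, cens_prob(hi), cens_prob(lo)), call. = FALSE)
  }
  cmax <- stats::uniroot(function(c) cens_prob(c) - target, c(lo, hi))$root
  t_cens <- stats::runif(n, 0, cmax)
  time <- round(pmin(t_event, t_cens), 1)
  event <- t_event <= t_cens

  clinical <- tibble::tibble(patient_id = ids, gender = gender, age = age,
                             grade = grade, stage = stage,
                             time_days = time, event = event)

  # CNV ground truth as SEG + BED: one segment per gene interval per patient
  ann <- NULL; segments <- NULL
  if (!is.null(omics$cnv)) {
  gene_len <- 5000; gap <- 5000
  ann <- tibble::tibble(gene_id = rownames(omics$cnv),
                        chromosome = "chr1",
                        start = (seq_len(nrow(omics$cnv)) - 1) * (gene_len + gap),
                        end = (seq_len(nrow(omics$cnv)) - 1) * (gene_len + gap) + gene_len,
                        strand = "+")
  cn <- unclass(omics$cnv)
  segments <- tibble::tibble(
    patient_id = rep(ids, each = nrow(cn)),
    chromosome = "chr1",
    start = rep(ann$start, times = n),
    end = rep(ann$end, times = n),
    segment_mean = as.vector(cn))
  }

  mutation_calls <- NULL
  if (!is.null(mut)) {
    hit <- which(mut == 1, arr.ind = TRUE)
    mutation_calls <- tibble::tibble(
      patient_id = ids[hit[, 2]],
      gene_id = rownames(mut)[hit[, 1]],
      variant_id = paste0(rownames(mut)[hit[, 1]], ":v", hit[, 2] %% 3 + 1))
  }

  # whole-patient platform missingness (availability-table semantics)
  for (p in names(omics)) {
    frac <- if (p %in% names(cfg$platform_missing)) cfg$platform_missing[[p]] else 0
    if (!is.na(frac) && frac > 0) {
      gone <- sample(ids, round(frac * n))
      v <- unclass(omics[[p]])
      v[, gone] <- NA_real_
      omics[[p]] <- omics_matrix(v, p, value_kind_of(omics[[p]]))
      if (p == "cnv") segments <- segments[!segments$patient_id %in% gone, ]
      if (p == "mutation") mutation_calls <- mutation_calls[!mutation_calls$patient_id %in% gone, ]
    }
    if (cfg$cell_missing_fraction > 0 && !identical(p, "mutation")) {
      v <- unclass(omics[[p]])
      mask <- stats::runif(length(v)) < cfg$cell_missing_fraction
      v[mask] <- NA_real_
      omics[[p]] <- omics_matrix(v, p, value_kind_of(omics[[p]]))
    }
  }

  # normal-tissue companions (hyper-methylated / low-expressing relative to
  # tumors at planted paired loci, matching the tumor-hypomethylation motif)
  normals <- list()
  tissue <- stats::setNames(rep("tumor", n), ids)
  for (p in names(cfg$n_normals)) {
    nn <- cfg$n_normals[[p]]
    if (is.na(nn) || nn < 1 || is.null(omics[[p]])) next
    nid <- sprintf("NM%04d", seq_len(nn))
    nf <- nrow(omics[[p]])
    if (p == "methylation") {
      lat <- matrix(stats::rnorm(nf * nn), nf, nn)
      if (nrow(pm)) lat[pm$feature, ] <- lat[pm$feature, , drop = FALSE] + 1.5
      vals <- stats::plogis(meth_base + lat)
    } else {
      vals <- matrix(stats::rnorm(nf * nn), nf, nn)
      if (nrow(pm) && "pair_sign" %in% names(pm)) {
        for (i in seq_len(nrow(pm))) {
          if (!is.na(pm$pair_sign[i]) && pm$pair_sign[i] != 0) {
            vals[pm$feature[i], ] <- vals[pm$feature[i], ] + 1.5 * pm$pair_sign[i]
          }
        }
      }
    }
    dimnames(vals) <- list(rownames(omics[[p]]), nid)
    normals[[p]] <- omics_matrix(vals, p, value_kind_of(omics[[p]]))
    tissue[nid] <- "normal"
  }

  list(clinical = clinical, omics = omics, segments = segments,
       gene_annotation = ann, mutation_calls = mutation_calls,
       normals = c(normals, list(tissue = tissue)),
       ground_truth = list(linear_predictor = stats::setNames(lp, ids),
                           planted = planted,
                           censoring_fraction = mean(!event)))
}

#' Reference-shaped synthetic cohort
#'
#' Convenience preset mirroring the reference cohort's shape: 533 patients
#' with roughly 176 observed deaths (censoring fraction 1 - 176/533), tumor
#' platform availability approximating the availability table (miRNA
#' 493/533, mRNA 518/533, protein 454/533, CNV 511/533, methylation
#' 477/533), a handful of planted markers per platform at mixed effect
#' sizes, a stage-coupled methylation marker, a methylation-expression
#' anti-correlated pair, a mutated gene with elevated hazard, and
#' normal-tissue companion samples for the methylation-expression report.
#'
#' @param seed integer seed.
#' @param n_features optional override of the per-platform feature counts.
#' @return as [simulate_cohort()].
#' @export
paper_shaped_cohort <- function(seed = 1L,
                                n_features = c(mirna = 120, mrna = 200,
                                               protein = 123,
                                               methylation = 150, cnv = 80)) {
  planted <- tibble::tibble(
    platform = c("mirna", "mirna", "mrna", "mrna", "protein",
                 "methylation", "methylation", "cnv", "mutation"),
    feature = c(1L, 2L, 1L, 2L, 1L, 5L, 6L, 1L, 1L),
    beta = c(log(3), -log(2), log(3), log(2), log(2.5),
             log(3), log(2), log(2), log(3)),
    stage_coupling = c(NA, NA, NA, NA, NA, 0.8, NA, NA, NA),
    pair_sign = c(NA, NA, NA, NA, NA, -1, NA, NA, NA),
    pair_platform = c(NA, NA, NA, NA, NA, "mirna", NA, NA, NA))
  # tolerate platform-subset overrides of n_features
  planted <- planted[planted$platform %in% c(names(n_features), "mutation") &
                       (is.na(planted$pair_platform) |
                          planted$pair_platform %in% names(n_features)), ]
  cfg <- simulation_config(
    n_patients = 533, n_features = n_features, n_mutation_genes = 60,
    planted = planted,
    censoring_fraction = 1 - 176 / 533,
    platform_missing = c(mirna = (533 - 493) / 533, mrna = (533 - 518) / 533,
                         protein = (533 - 454) / 533, cnv = (533 - 511) / 533,
                         methylation = (533 - 477) / 533, mutation = 0.05),
    mutation_rate = 0.1,
    n_normals = c(methylation = 358, mirna = 71),
    rng_seed = seed)
  simulate_cohort(cfg)
}

#' Write a simulated cohort to disk in the reader dialects
#'
#' Emits clinical TSV, one matrix TSV per continuous platform, a SEG file
#' plus BED-like gene annotation for copy number, and a MAF-like mutation
#' table — exactly the files [read_cohort()], [read_segments()],
#' [read_gene_annotation()] and [read_mutations()] consume.
#'
#' @param cohort list from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(clinical = file.path(dir, "clinical.tsv"))
  write_clinical(cohort$clinical, paths[["clinical"]])
  for (p in setdiff(names(cohort$omics), c("cnv", "mutation"))) {
    paths[[p]] <- file.path(dir, paste0(p, ".tsv"))
    write_omics_matrix(cohort$omics[[p]], paths[[p]])
  }
  if (!is.null(cohort$segments)) {
    paths[["segments"]] <- file.path(dir, "cnv.seg")
    write_segments(cohort$segments, paths[["segments"]])
    paths[["gene_annotation"]] <- file.path(dir, "genes.bed")
    write_gene_annotation(cohort$gene_annotation, paths[["gene_annotation"]])
  }
  if (!is.null(cohort$mutation_calls)) {
    paths[["mutations"]] <- file.path(dir, "mutations.maf.tsv")
    write_mutations(cohort$mutation_calls, paths[["mutations"]])
  }
  paths
}
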