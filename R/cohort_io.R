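#' Read a clinical table
#'
#' Expects a TSV with header
#' `patient_id gender age grade stage time_days event`; `event` is 0/1
#' (1 = death observed), `time_days` is days to death or last follow-up,
#' `grade` and `stage` are ordinal codes 1-4 (may be missing).
#'
#' @param path path to the TSV file.
#' @return tibble with one row per patient; `event` is logical.
#' @export
read_clinical <- function(path) {
  required <- c("patient_id", "gender", "age", "grade", "stage", "time_days", "event")
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (!all(required %in% names(x))) {
    stop(sprintf("%s: malformed header, missing column(s): %s", path,
                 paste(setdiff(required, names(x)), collapse = ", ")), call. = FALSE)
  }
  x <- x[required]
  for (col in c("age", "grade", "stage", "time_days", "event")) {
    raw <- x[[col]]
    suppressWarnings(num <- as.numeric(raw))   # strtod: correctly rounded
    bad <- which(is.na(num) & !(is.na(raw) | raw == "" | raw == "NA"))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric %s '%s' (line %d)", path, col, raw[bad[1]],
                   bad[1] + 1L), call. = FALSE)
    }
    x[[col]] <- num
  }
  if (anyDuplicated(x$patient_id)) {
    dup <- which(duplicated(x$patient_id))[1]
    stop(sprintf("%s: duplicate patient id '%s' (line %d)", path,
                 x$patient_id[dup], dup + 1L), call. = FALSE)
  }
  bad <- which(!is.na(x$time_days) & x$time_days < 0)
  if (length(bad)) {
    stop(sprintf("%s: negative survival time for patient '%s' (line %d)", path,
                 x$patient_id[bad[1]], bad[1] + 1L), call. = FALSE)
  }
  if (any(is.na(x$time_days)) || any(is.na(x$event))) {
    bad <- which(is.na(x$time_days) | is.na(x$event))[1]
    stop(sprintf("%s: missing survival time or event flag (line %d)", path, bad + 1L),
         call. = FALSE)
  }
  if (!all(x$event %in% c(0, 1))) {
    bad <- which(!x$event %in% c(0, 1))[1]
    stop(sprintf("%s: event must be 0 or 1 (line %d)", path, bad + 1L), call. = FALSE)
  }
  for (col in c("grade", "stage")) {
    v <- x[[col]]
    if (any(!is.na(v) & (v < 1 | v > 4 | v != round(v)))) {
      bad <- which(!is.na(v) & (v < 1 | v > 4 | v != round(v)))[1]
      stop(sprintf("%s: %s out of ordinal range 1-4 (line %d)", path, col, bad + 1L),
           call. = FALSE)
    }
  }
  x$event <- as.logical(x$event)
  validate_clinical(x)
}

#' Validate a clinical tibble
#'
#' Checks the invariants of the clinical data model (nonnegative times,
#' logical event, ordinal grade/stage) and returns the table unchanged.
#'
#' @param clinical tibble as returned by [read_clinical()].
#' @export
validate_clinical <- function(clinical) {
  stopifnot(is.data.frame(clinical))
  required <- c("patient_id", "gender", "age", "grade", "stage", "time_days", "event")
  miss <- setdiff(required, names(clinical))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(clinical$patient_id)) stop("duplicate patient ids", call. = FALSE)
  if (any(clinical$time_days < 0, na.rm = TRUE)) stop("negative survival time", call. = FALSE)
  if (!is.logical(clinical$event)) stop("event must be logical", call. = FALSE)
  tibble::as_tibble(clinical)
}

#' Read a feature matrix TSV
#'
#' First column holds feature ids, the remaining columns are patients; empty
#' cells or `NA` are missing values.
#'
#' @param path path to the TSV.
#' @inheritParams omics_matrix
#' @return an [omics_matrix()].
#' @export
read_omics_matrix <- function(path, platform, value_kind = "continuous") {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (ncol(x) < 2) stop(sprintf("%s: malformed header (need feature id + patients)", path),
                        call. = FALSE)
  feat <- x[[1]]
  vals <- as.matrix(x[-1])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !(is.na(vals) | vals == "" | vals == "NA"), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("%s: non-numeric value '%s' (line %d, column '%s')", path,
                 vals[bad[1, 1], bad[1, 2]], bad[1, 1] + 1L,
                 colnames(vals)[bad[1, 2]]), call. = FALSE)
  }
  dimnames(num) <- list(feat, colnames(vals))
  omics_matrix(num, platform, value_kind)
}

#' Read a full cohort from disk
#'
#' Reads the clinical table and one feature matrix per platform, then
#' restricts every matrix to the patients present in the clinical table;
#' matrix patients without a clinical row are dropped with a warning.
#'
#' @param clinical_path clinical TSV path.
#' @param matrix_paths named character vector or list, platform -> file path.
#' @param value_kinds optional named vector platform -> value kind; defaults
#'   by platform name (`methylation` -> beta, `cnv` -> segment_mean,
#'   `mutation` -> binary, otherwise continuous).
#' @return list with elements `clinical` (tibble) and `omics` (named list of
#'   [omics_matrix()]).
#' @export
read_cohort <- function(clinical_path, matrix_paths, value_kinds = NULL) {
  clinical <- read_clinical(clinical_path)
  default_kind <- function(p) {
    switch(p, methylation = "beta", cnv = "segment_mean", mutation = "binary",
           "continuous")
  }
  omics <- purrr::imap(as.list(matrix_paths), function(path, platform) {
    kind <- if (!is.null(value_kinds) && platform %in% names(value_kinds)) {
      value_kinds[[platform]]
    } else default_kind(platform)
    m <- read_omics_matrix(path, platform, kind)
    orphan <- setdiff(colnames(m), clinical$patient_id)
    if (length(orphan)) {
      warning(sprintf("%s: dropping %d patient(s) with no clinical record: %s",
                      platform, length(orphan),
                      paste(utils::head(orphan, 5), collapse = ", ")),
              call. = FALSE)
      m <- restrict_patients(m, clinical$patient_id)
    }
    m
  })
  list(clinical = clinical, omics = omics)
}

#' Keep features quantified in more than half of the cohort
#'
#' A feature is retained only when it has strictly more than `cohort_size / 2`
#' non-missing values; feature order is preserved. Idempotent.
#'
#' @param m an [omics_matrix()].
#' @param cohort_size number of patients in the full cohort (the denominator
#'   of the more-than-half rule; defaults to `ncol(m)`).
#' @export
filter_features <- function(m, cohort_size = ncol(m)) {
  stopifnot(cohort_size >= 1)
  nn <- rowSums(!is.na(unclass(m)))
  m[nn > cohort_size / 2, ]
}

#' Fit a per-feature Z-score transform
#'
#' Per-feature mean and sample standard deviation (n-1 denominator) computed
#' over the given fitting patients only, ignoring missing entries. Features
#' with fewer than two distinct non-missing values (zero variance) are
#' flagged as excluded rather than failing the fit.
#'
#' @param m an [omics_matrix()].
#' @param fit_ids patient ids the transform is estimated on (e.g. the
#'   training cohort's tumor samples).
#' @return a `zscore_transform` tibble with columns `feature_id`, `mean`,
#'   `sd`, `excluded`.
#' @export
fit_zscore <- function(m, fit_ids = colnames(m)) {
  fit_ids <- intersect(fit_ids, colnames(m))
  if (!length(fit_ids)) stop("no fitting patients present in the matrix", call. = FALSE)
  v <- unclass(m)[, fit_ids, drop = FALSE]
  n <- rowSums(!is.na(v))
  mu <- rowMeans(v, na.rm = TRUE)
  ss <- rowSums(v^2, na.rm = TRUE) - n * mu^2
  sd <- sqrt(pmax(ss, 0) / pmax(n - 1, 1))
  excluded <- n < 2 | sd <= 0 | !is.finite(sd)
  if (any(excluded)) {
    message(sprintf("fit_zscore: %d zero-variance feature(s) excluded", sum(excluded)))
  }
  out <- tibble::tibble(feature_id = rownames(m), mean = unname(mu),
                        sd = unname(sd), excluded = unname(excluded))
  class(out) <- c("zscore_transform", class(out))
  out
}

#' Apply a Z-score transform
#'
#' Standardizes every feature of `m` with the stored mean/sd; missing stays
#' missing. Features flagged excluded at fit time are dropped (they cannot be
#' standardized and are ineligible for downstream selection). Features of `m`
#' unknown to the transform are an error.
#'
#' @param transform a `zscore_transform` from [fit_zscore()].
#' @param m an [omics_matrix()].
#' @return an [omics_matrix()] with `value_kind = "zscore"`.
#' @export
apply_zscore <- function(transform, m) {
  unknown <- setdiff(rownames(m), transform$feature_id)
  if (length(unknown)) {
    stop("features not covered by the transform: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  tr <- transform[match(rownames(m), transform$feature_id), ]
  keep <- !tr$excluded
  z <- (unclass(m)[keep, , drop = FALSE] - tr$mean[keep]) / tr$sd[keep]
  omics_matrix(z, platform_of(m), "zscore")
}

#' Read a SEG-format copy-number segment table
#'
#' Columns: sample, chromosome, start, end, optionally num_probes, and
#' segment mean (the last column). Coordinates are 0-based half-open.
#'
#' @param path path to the SEG file.
#' @return tibble with columns `patient_id`, `chromosome`, `start`, `end`,
#'   `segment_mean`.
#' @export
read_segments <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (ncol(x) < 5) stop(sprintf("%s: SEG file needs at least 5 columns", path), call. = FALSE)
  out <- tibble::tibble(patient_id = as.character(x[[1]]),
                        chromosome = as.character(x[[2]]),
                        start = as.numeric(x[[3]]),
                        end = as.numeric(x[[4]]),
                        segment_mean = as.numeric(x[[ncol(x)]]))
  validate_segments(out)
}

#' Validate a segment table
#'
#' Requires `start < end` and, within each patient and chromosome,
#' non-overlapping segments (an overlap is an input error and is reported
#' with the offending pair).
#'
#' @param seg tibble as returned by [read_segments()].
#' @export
validate_segments <- function(seg) {
  if (any(seg$start >= seg$end)) {
    bad <- which(seg$start >= seg$end)[1]
    stop(sprintf("segment with start >= end: %s %s [%g, %g)", seg$patient_id[bad],
                 seg$chromosome[bad], seg$start[bad], seg$end[bad]), call. = FALSE)
  }
  chk <- seg %>%
    dplyr::arrange(.data$patient_id, .data$chromosome, .data$start) %>%
    dplyr::group_by(.data$patient_id, .data$chromosome) %>%
    dplyr::mutate(overlap_prev = .data$start < dplyr::lag(.data$end, default = -Inf)) %>%
    dplyr::ungroup()
  if (any(chk$overlap_prev)) {
    i <- which(chk$overlap_prev)[1]
    stop(sprintf("overlapping segments for patient %s on %s near position %g",
                 chk$patient_id[i], chk$chromosome[i], chk$start[i]), call. = FALSE)
  }
  tibble::as_tibble(seg)
}

#' Read a BED-like gene annotation
#'
#' Columns: chrom, start, end, gene_id, score (ignored), strand. Coordinates
#' are 0-based half-open; strand is carried but ignored by the copy-number
#' mapping (copy number is strand-agnostic).
#'
#' @param path path to the BED-like TSV (no header).
#' @return tibble with columns `gene_id`, `chromosome`, `start`, `end`, `strand`.
#' @export
read_gene_annotation <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chromosome", "start", "end",
                                           "gene_id", "score", "strand"),
                       show_col_types = FALSE, progress = FALSE)
  out <- tibble::tibble(gene_id = as.character(x$gene_id),
                        chromosome = as.character(x$chromosome),
                        start = as.numeric(x$start), end = as.numeric(x$end),
                        strand = as.character(x$strand))
  if (anyDuplicated(out$gene_id)) stop("duplicate gene_id in annotation", call. = FALSE)
  if (any(out$start >= out$end)) stop("gene with start >= end in annotation", call. = FALSE)
  out
}

#' Read MAF-like mutation calls
#'
#' A reduced MAF: one row per called somatic mutation with columns
#' `patient_id`, `gene_id`, `variant_id`.
#'
#' @param path path to the TSV.
#' @export
read_mutations <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  need <- c("patient_id", "gene_id", "variant_id")
  if (!all(need %in% names(x))) {
    stop(sprintf("%s: mutation table needs columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  tibble::as_tibble(x[need])
}

#' Binary mutation matrix from mutation calls
#'
#' Builds a features-by-patients 0/1 matrix from MAF-like calls, keyed either
#' on genes (gene-level screening) or on individual variants. Patients in
#' `patient_ids` with no call anywhere get all-zero columns; patients listed
#' in `missing_ids` (platform not assayed) get all-`NA` columns.
#'
#' @param calls tibble from [read_mutations()].
#' @param patient_ids full list of assayed patients (columns of the result).
#' @param by `"gene"` or `"variant"`.
#' @param missing_ids patients with no mutation data at all.
#' @return an [omics_matrix()] with `value_kind = "binary"`.
#' @export
mutation_matrix <- function(calls, patient_ids, by = c("gene", "variant"),
                            missing_ids = character()) {
  by <- match.arg(by)
  key <- if (by == "gene") calls$gene_id else calls$variant_id
  feats <- sort(unique(key))
  v <- matrix(0, length(feats), length(patient_ids),
              dimnames = list(feats, patient_ids))
  keep <- calls$patient_id %in% patient_ids
  v[cbind(match(key[keep], feats), match(calls$patient_id[keep], patient_ids))] <- 1
  v[, intersect(missing_ids, patient_ids)] <- NA_real_
  omics_matrix(v, "mutation", "binary")
}

#' Map copy-number segments to gene-level values
#'
#' For every gene and patient the gene's value is the overlap-length-weighted
#' mean of the segment means of all segments overlapping the gene interval;
#' genes with no overlapping segment for a patient are missing. Strand is
#' ignored. The result is deterministic and invariant to segment record order
#' and to splitting a segment into adjacent pieces with equal mean.
#'
#' @param seg segment tibble ([read_segments()]); validated for overlaps.
#' @param ann gene annotation tibble ([read_gene_annotation()]).
#' @return an [omics_matrix()] (`platform = "cnv"`, `value_kind = "segment_mean"`).
#' @export
map_genes_to_segments <- function(seg, ann) {
  seg <- validate_segments(seg)
  patients <- sort(unique(seg$patient_id))
  genes_gr <- GenomicRanges::GRanges(
    seqnames = ann$chromosome,
    ranges = IRanges::IRanges(start = ann$start + 1, end = ann$end))
  seg_gr <- GenomicRanges::GRanges(
    seqnames = seg$chromosome,
    ranges = IRanges::IRanges(start = seg$start + 1, end = seg$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(genes_gr, seg_gr))
  gi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  w <- pmin(ann$end[gi], seg$end[si]) - pmax(ann$start[gi], seg$start[si])
  out <- matrix(NA_real_, nrow(ann), length(patients),
                dimnames = list(ann$gene_id, patients))
  if (length(gi)) {
    agg <- tibble::tibble(gene = gi, patient = match(seg$patient_id[si], patients),
                          w = w, wm = w * seg$segment_mean[si]) %>%
      dplyr::summarise(value = sum(.data$wm) / sum(.data$w),
                       .by = c("gene", "patient"))
    out[cbind(agg$gene, agg$patient)] <- agg$value
  }
  omics_matrix(out, "cnv", "segment_mean")
}

# ---- writers (full-precision TSV so round trips are bit identical) ----

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else formatC(v, digits = 17, format = "g")
  }, character(1))
  out
}

#' Write cohort files in the dialects the readers expect
#'
#' Numeric values are written with 17 significant digits so that a
#' write-then-read round trip reproduces doubles bit-identically.
#'
#' @param clinical clinical tibble.
#' @param path output file path.
#' @name cohort_writers
#' @export
write_clinical <- function(clinical, path) {
  out <- clinical
  out$event <- as.integer(out$event)
  out$age <- .fmt_num(out$age)
  out$time_days <- .fmt_num(out$time_days)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname cohort_writers
#' @param m an [omics_matrix()].
#' @export
write_omics_matrix <- function(m, path) {
  df <- as.data.frame(matrix(.fmt_num(unclass(m)), nrow(m), ncol(m),
                             dimnames = list(NULL, colnames(m))),
                      optional = TRUE)
  df <- cbind(feature_id = rownames(m), df)
  readr::write_tsv(tibble::as_tibble(df), path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname cohort_writers
#' @param seg segment tibble.
#' @export
write_segments <- function(seg, path) {
  out <- tibble::tibble(sample = seg$patient_id, chromosome = seg$chromosome,
                        start = seg$start, end = seg$end,
                        segment_mean = .fmt_num(seg$segment_mean))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname cohort_writers
#' @param ann gene annotation tibble.
#' @export
write_gene_annotation <- function(ann, path) {
  out <- tibble::tibble(chromosome = ann$chromosome, start = ann$start,
                        end = ann$end, gene_id = ann$gene_id, score = 0,
                        strand = ann$strand)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname cohort_writers
#' @param calls mutation calls tibble.
#' @export
write_mutations <- function(calls, path) {
  readr::write_tsv(calls[c("patient_id", "gene_id", "variant_id")], path,
                   progress = FALSE)
  invisible(path)
}
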