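#' Construct an omics feature matrix
#'
#' A thin matrix-backed container for one molecular platform: rows are
#' features (genes, probes, miRNAs, proteins), columns are patients. Missing
#' measurements are `NA`. The platform name and the kind of value carried
#' (`continuous`, `beta`, `segment_mean` or `binary`) travel with the matrix
#' so downstream operations can check what they are given.
#'
#' @param values numeric matrix with unique rownames (feature ids) and unique
#'   colnames (patient ids).
#' @param platform platform label, e.g. `"mirna"`, `"mrna"`, `"protein"`,
#'   `"cnv"`, `"methylation"`, `"mutation"`.
#' @param value_kind one of `"continuous"`, `"beta"`, `"segment_mean"`,
#'   `"binary"`, `"zscore"`.
#' @return an `omics_matrix` object.
#' @examples
#' m <- omics_matrix(matrix(rnorm(6), 2, 3,
#'                          dimnames = list(c("f1", "f2"), c("p1", "p2", "p3"))),
#'                   platform = "mrna", value_kind = "continuous")
#' dim(m)
#' @export
omics_matrix <- function(values, platform,
                         value_kind = c("continuous", "beta", "segment_mean",
                                        "binary", "zscore")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry feature rownames and patient colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate patient ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  }
  ok <- values[!is.na(values)]
  if (value_kind == "beta" && length(ok) && (min(ok) < 0 || max(ok) > 1)) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  if (value_kind == "binary" && length(ok) && !all(ok %in% c(0, 1))) {
    stop("binary values must be 0 or 1", call. = FALSE)
  }
  structure(values, platform = platform, value_kind = value_kind,
            class = c("omics_matrix", class(values)))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> platform=%s kind=%s: %d features x %d patients (%.1f%% missing)\n",
              platform_of(x), value_kind_of(x), nrow(x), ncol(x),
              100 * mean(is.na(x))))
  invisible(x)
}

#' Platform and value-kind accessors
#' @param m an [omics_matrix()].
#' @return a character scalar.
#' @export
platform_of <- function(m) attr(m, "platform")

#' @rdname platform_of
#' @export
value_kind_of <- function(m) attr(m, "value_kind")

#' @export
`[.omics_matrix` <- function(x, i, j, drop = FALSE) {
  v <- x
  class(v) <- setdiff(class(v), "omics_matrix")
  if (missing(i)) i <- seq_len(nrow(v))
  if (missing(j)) j <- seq_len(ncol(v))
  omics_matrix(v[i, j, drop = FALSE], platform_of(x), value_kind_of(x))
}

#' Convert an omics matrix to a long tibble
#'
#' @param x an [omics_matrix()].
#' @param ... unused.
#' @return tibble with columns `feature_id`, `patient_id`, `value`.
#' @importFrom tibble as_tibble
#' @exportS3Method tibble::as_tibble
as_tibble.omics_matrix <- function(x, ...) {
  tibble::tibble(
    feature_id = rep(rownames(x), times = ncol(x)),
    patient_id = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x))
  )
}

#' Restrict an omics matrix to a patient subset
#'
#' Keeps only the listed patients, in the order given; patients absent from
#' the matrix are silently skipped (platform availability differs between
#' platforms).
#'
#' @param m an [omics_matrix()].
#' @param ids patient ids to keep.
#' @export
restrict_patients <- function(m, ids) {
  m[, intersect(ids, colnames(m))]
}

# align an omics matrix with a clinical table; returns values + survival
# vectors over the common patients. Patients are put in sorted-id order so
# that every downstream resampling draw depends only on ids, never on the
# incoming column order (selection frequencies are exchangeable under
# patient relabeling).
.align_cohort <- function(m, clinical) {
  ids <- sort(intersect(colnames(m), clinical$patient_id))
  if (length(ids) == 0) stop("no patients shared between matrix and clinical table", call. = FALSE)
  cl <- clinical[match(ids, clinical$patient_id), ]
  list(values = unclass(m)[, ids, drop = FALSE],
       patient_ids = ids,
       time = cl$time_days,
       event = cl$event)
}
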