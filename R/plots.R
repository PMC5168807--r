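#' Plot cross-validated performance by model rank
#'
#' One panel per platform, test-cohort C-index (mean over CV rounds) against
#' model rank, one line per selection approach — the standard way to read
#' which approach and how many markers a platform needs.
#'
#' @param summary a `perf_summary` tibble from [aggregate_performance()].
#' @param metric `"test_c_mean"` or `"train_c_mean"`.
#' @return a ggplot object.
#' @export
plot_performance_by_rank <- function(summary, metric = "test_c_mean") {
  d <- summary[summary$approach %in% c("extreme_score", "mean_score",
                                       "extreme_survival", "combined"), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data[[metric]],
                                  colour = .data$approach)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~platform) +
    ggplot2::scale_x_continuous(breaks = function(l) seq(1, max(l), by = 1)) +
    ggplot2::labs(x = "model rank (number of markers)",
                  y = "C-index (mean over CV rounds)", colour = "approach") +
    ggplot2::theme_bw()
}

#' Compare molecular, integrated and clinical-only models
#'
#' Bar chart of the best per-platform test C-index for molecular-only
#' models, the clinically integrated models, and the clinical-covariate-only
#' reference, with cross-round standard deviations as error bars.
#'
#' @param summary a `perf_summary` tibble from [aggregate_performance()].
#' @return a ggplot object.
#' @export
plot_clinical_integration <- function(summary) {
  mol <- summary %>%
    dplyr::filter(.data$approach %in% c("extreme_score", "mean_score",
                                        "extreme_survival", "combined",
                                        "mutation")) %>%
    dplyr::slice_max(.data$test_c_mean, n = 1, by = "platform",
                     with_ties = FALSE) %>%
    dplyr::mutate(model = "molecular only")
  int <- summary %>%
    dplyr::filter(.data$approach == "integrated_clinical") %>%
    dplyr::mutate(model = "molecular + clinical")
  clin <- summary %>%
    dplyr::filter(.data$approach == "clinical_only") %>%
    dplyr::mutate(model = "clinical only")
  d <- dplyr::bind_rows(mol, int, clin)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$platform, y = .data$test_c_mean,
                                  fill = .data$model)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$test_c_mean - .data$test_c_sd,
                                        ymax = .data$test_c_mean + .data$test_c_sd),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.25) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = NULL, y = "test C-index (mean ± sd over CV rounds)",
                  fill = NULL) +
    ggplot2::theme_bw()
}

#' @exportS3Method ggplot2::autoplot
autoplot.perf_summary <- function(object, ...) plot_performance_by_rank(object, ...)

#' Plot selection frequencies of top marker candidates
#'
#' @param candidates marker candidate tibble from a selection function.
#' @return a ggplot object.
#' @export
plot_selection_frequency <- function(candidates) {
  d <- dplyr::mutate(candidates,
                     feature_id = stats::reorder(.data$feature_id, .data$frequency))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frequency, y = .data$feature_id,
                                  fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "selection frequency (iterations passed)", y = NULL,
                  fill = "association") +
    ggplot2::theme_bw()
}
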