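#' Cancerous tissue percentage of a scan
#'
#' The statistic driving the scan-level rule: the percentage `p_c` of
#' valid tissue cells whose (argmax, or thresholded) call is cancerous.
#' Cells outside the tissue mask are excluded, and so are valid cells
#' whose argmax class is `BG` (scan background missed by the
#' segmentation step); the denominator is the remaining valid non-`BG`
#' cells.
#'
#' @param map A [prob_map()].
#' @param setting `"S1"` or `"S2"`.
#' @param prob_threshold Optional probability threshold passed to
#'   [binarize_map()] (default: argmax call).
#' @return `p_c` in percent, or `NA` (with a warning) when no valid
#'   non-background cell exists.
#' @export
cancer_ratio <- function(map, setting = "S1", prob_threshold = NULL) {
  stopifnot(inherits(map, "prob_map"))
  am <- argmax_map(map)
  keep <- map$valid & !is.na(am) & am != "BG"
  if (!any(keep)) {
    warning("no valid non-background cells; p_c undefined")
    return(NA_real_)
  }
  cancer <- binarize_map(map, setting, prob_threshold)
  100 * sum(cancer[keep]) / sum(keep)
}

#' Abstaining scan-level diagnosis rule
#'
#' Diagnoses a scan from its cancerous-tissue percentage `p_c`:
#' non-cancerous (`NC`) when `p_c <= t_lower`, cancerous (`C`) when
#' `p_c >= t_upper`, and abstain (`IHC`, further examination needed)
#' in between. Thresholds are percentages.
#'
#' @param p_c Numeric vector of cancerous-tissue percentages; `NA`
#'   (undefined) abstains with a warning.
#' @param t_lower,t_upper Lower and upper thresholds in percent,
#'   `0 <= t_lower < t_upper <= 100`.
#' @return Character vector over `c("NC", "IHC", "C")`.
#' @examples
#' abstain_diagnose(c(13.35, 1.87, 0.33), t_lower = 0.5, t_upper = 7)
#' @export
abstain_diagnose <- function(p_c, t_lower = 0.5, t_upper = 7) {
  stopifnot(t_lower >= 0, t_lower < t_upper, t_upper <= 100)
  if (anyNA(p_c)) warning("undefined p_c; abstaining for ", sum(is.na(p_c)),
                          " scan(s)")
  dplyr::case_when(
    is.na(p_c) ~ "IHC",
    p_c <= t_lower ~ "NC",
    p_c >= t_upper ~ "C",
    .default = "IHC"
  )
}

#' Diagnose a cohort table
#'
#' Tidy wrapper over [abstain_diagnose()]: takes a per-scan table with
#' a `p_c` column and adds a `diagnosis` column.
#'
#' @param cohort Data frame with a `p_c` column.
#' @inheritParams abstain_diagnose
#' @return The cohort as a tibble with `diagnosis` added.
#' @export
diagnose_cohort <- function(cohort, t_lower = 0.5, t_upper = 7) {
  stopifnot("p_c" %in% names(cohort))
  tibble::as_tibble(cohort) |>
    dplyr::mutate(diagnosis = abstain_diagnose(.data$p_c, t_lower, t_upper))
}

#' Accuracy/coverage trade-off over a threshold grid
#'
#' For every pair of thresholds, applies the abstaining rule to the
#' cohort and records the accuracy over the decided scans and the
#' proportion of scans decided. Pairs with `t_lower >= t_upper` are
#' kept with `valid = FALSE`. The default grids span every threshold
#' value discussed for the rule (lower 0--2%, upper 2--15%).
#'
#' @param cohort Data frame with columns `p_c` and `truth`
#'   (`"C"`/`"NC"`).
#' @param t_lower_grid,t_upper_grid Ascending numeric grids in percent.
#' @return A tibble of class `threshold_sweep` with columns `t_lower`,
#'   `t_upper`, `valid`, `n_decided`, `prop_decided`, `accuracy`
#'   (`NA` when no scan is decided).
#' @export
threshold_sweep <- function(cohort, t_lower_grid = seq(0, 2, by = 0.1),
                            t_upper_grid = 2:15) {
  stopifnot(all(c("p_c", "truth") %in% names(cohort)),
            all(cohort$truth %in% c("C", "NC")),
            !is.unsorted(t_lower_grid), !is.unsorted(t_upper_grid))
  res <- tidyr::expand_grid(t_lower = t_lower_grid, t_upper = t_upper_grid) |>
    dplyr::mutate(valid = .data$t_lower < .data$t_upper) |>
    dplyr::mutate(purrr::map2_dfr(.data$t_lower, .data$t_upper, function(tl, tu) {
      if (tl >= tu) {
        return(tibble::tibble(n_decided = NA_integer_,
                              prop_decided = NA_real_, accuracy = NA_real_))
      }
      decided <- cohort$p_c <= tl | cohort$p_c >= tu
      pred <- ifelse(cohort$p_c <= tl, "NC", "C")
      tibble::tibble(
        n_decided = sum(decided),
        prop_decided = mean(decided),
        accuracy = ifelse(any(decided),
                          mean(pred[decided] == cohort$truth[decided]),
                          NA_real_))
    }))
  class(res) <- c("threshold_sweep", class(res))
  res
}

#' Plot a threshold sweep
#'
#' Two heatmaps over the threshold grid: accuracy on decided scans and
#' proportion of scans decided.
#'
#' @param object A [threshold_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.threshold_sweep <- function(object, ...) {
  df <- object |>
    dplyr::filter(.data$valid) |>
    tidyr::pivot_longer(c("accuracy", "prop_decided"), names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$t_upper), factor(.data$t_lower),
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "upper threshold (%)", y = "lower threshold (%)",
                  fill = NULL)
}

#' Overall and macro-averaged accuracy
#'
#' `accuracy` is the overall fraction of correct predictions;
#' `avg_accuracy` (AvAcc) is the unweighted mean of per-class recalls
#' over classes with at least one true instance, robust to class
#' imbalance.
#'
#' @param predicted,truth Equal-length label vectors.
#' @return One-row tibble with `n`, `accuracy`, `avg_accuracy`.
#' @export
compute_metrics <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  if (length(truth) == 0) stop("empty input")
  recalls <- vapply(unique(truth), function(cl) {
    mean(predicted[truth == cl] == cl)
  }, numeric(1))
  tibble::tibble(n = length(truth),
                 accuracy = mean(predicted == truth),
                 avg_accuracy = mean(recalls))
}
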