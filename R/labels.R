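#' Tissue class labels and their severity order
#'
#' Annotated regions carry one of nine class labels: scan background
#' (`BG`), tissue background (`T`), normal healthy tissue (`N`),
#' acquisition artifact (`A`), and the five Gleason grades (`R1`--`R5`).
#' Severity is a strict total order used when merging sub-patch labels:
#' every Gleason grade ranks above every non-cancer label, and
#' `R1 < R2 < R3 < R4 < R5`. Among the non-cancer labels the order is
#' `BG < T < N < A`; only the cancer-over-non-cancer dominance matters
#' for grade propagation, so the non-cancer portion is configurable via
#' `non_cancer_order`.
#'
#' @param non_cancer_order Character vector ordering the four non-cancer
#'   codes from least to most severe.
#' @return `class_labels()` returns the nine codes in increasing
#'   severity order.
#' @examples
#' class_labels()
#' severity_rank(c("N", "R4"))
#' @export
class_labels <- function(non_cancer_order = c("BG", "T", "N", "A")) {
  stopifnot(setequal(non_cancer_order, c("BG", "T", "N", "A")))
  c(non_cancer_order, paste0("R", 1:5))
}

#' @rdname class_labels
#' @param labels Character vector of class codes.
#' @return `severity_rank()` returns an integer rank per label (1 = least
#'   severe); `NA` inputs stay `NA`.
#' @export
severity_rank <- function(labels, non_cancer_order = c("BG", "T", "N", "A")) {
  order <- class_labels(non_cancer_order)
  bad <- !is.na(labels) & !labels %in% order
  if (any(bad)) {
    stop("unknown class label(s): ", paste(unique(labels[bad]), collapse = ", "))
  }
  match(labels, order)
}

#' Which labels count as cancerous
#'
#' Two binarization settings are used throughout: `S1` treats all five
#' Gleason grades as cancerous; `S2` treats only grades 3--5 as
#' cancerous (grades 1 and 2 resemble healthy tissue closely enough
#' that pathologists are discouraged from reporting them). The setting
#' is always explicit.
#'
#' @param labels Character vector of class codes (`NA` allowed).
#' @param setting `"S1"` (R1--R5 cancerous) or `"S2"` (R3--R5).
#' @return Logical vector; `NA` for `NA` input.
#' @examples
#' is_cancerous(c("N", "R1", "R4"), "S1")
#' is_cancerous(c("N", "R1", "R4"), "S2")
#' @export
is_cancerous <- function(labels, setting = c("S1", "S2")) {
  setting <- match.arg(setting)
  severity_rank(labels) # validates codes
  cancer <- if (setting == "S1") paste0("R", 1:5) else paste0("R", 3:5)
  ifelse(is.na(labels), NA, labels %in% cancer)
}

#' Binary class grouping for a setting
#'
#' A partition of the nine classes into a cancerous and a non-cancerous
#' group, in the form accepted by [merge_class_groups()].
#'
#' @inheritParams is_cancerous
#' @return Named list of two character vectors.
#' @export
binary_grouping <- function(setting = c("S1", "S2")) {
  setting <- match.arg(setting)
  all <- class_labels()
  cancer <- all[is_cancerous(all, setting)]
  list(NC = setdiff(all, cancer), C = cancer)
}
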