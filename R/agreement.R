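#' Ordinal encoding of scan-level diagnoses
#'
#' `NC < IHC < C`: the "uncertain, further examination needed" call
#' sits between the two definite calls. Rank correlations depend only
#' on this order, not on the numeric values.
#'
#' @param x Character vector over `c("NC", "IHC", "C")`.
#' @return Integer vector (NC = 0, IHC = 1, C = 2).
#' @examples
#' encode_diagnosis(c("NC", "IHC", "C"))
#' @export
encode_diagnosis <- function(x) {
  codes <- c(NC = 0L, IHC = 1L, C = 2L)
  bad <- !x %in% names(codes)
  if (any(bad)) stop("unknown diagnosis label(s): ",
                     paste(unique(x[bad]), collapse = ", "))
  unname(codes[x])
}

#' Spearman rank correlation of two raters
#'
#' Tie-corrected Spearman coefficient (the Pearson correlation of
#' mid-ranks), as appropriate for heavily tied ordinal diagnoses.
#'
#' @param x,y Equal-length numeric (or encodable character) vectors of
#'   length at least 3.
#' @return The coefficient, or `NA` with a warning when either input
#'   has zero variance.
#' @export
spearman_cor <- function(x, y) {
  if (is.character(x)) x <- encode_diagnosis(x)
  if (is.character(y)) y <- encode_diagnosis(y)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance input; Spearman coefficient undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Pairwise rater-agreement matrix
#'
#' Computes all pairwise Spearman coefficients between rater columns of
#' a per-scan diagnosis table (human raters and/or an automated rule
#' column alike). Coefficients are stored at full precision; printing
#' and [tidy()] round half away from zero to 2 decimals, the precision
#' agreement tables are conventionally reported at.
#'
#' @param table Data frame of per-scan rows.
#' @param cols Columns to correlate; defaults to every column whose
#'   values are all in `c("C", "NC", "IHC")`.
#' @return An object of class `agreement_matrix` wrapping the symmetric
#'   coefficient matrix.
#' @examples
#' agreement_matrix(diagnosis_panel())
#' @export
agreement_matrix <- function(table, cols = NULL) {
  if (is.null(cols)) {
    cols <- names(table)[vapply(table, function(v) {
      is.character(v) && all(v %in% c("C", "NC", "IHC"))
    }, logical(1))]
  }
  stopifnot(length(cols) >= 2, all(cols %in% names(table)))
  enc <- vapply(cols, function(cn) as.numeric(encode_diagnosis(table[[cn]])),
                numeric(nrow(table)))
  k <- length(cols)
  mat <- diag(1, k)
  dimnames(mat) <- list(cols, cols)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      mat[i, j] <- mat[j, i] <- spearman_cor(enc[, i], enc[, j])
    }
  }
  structure(list(matrix = mat, cols = cols, n = nrow(table)),
            class = "agreement_matrix")
}

round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' @export
print.agreement_matrix <- function(x, digits = 2, ...) {
  cat("<agreement_matrix> Spearman, n =", x$n, "scans\n")
  print(round_half_up(x$matrix, digits))
  invisible(x)
}

#' Tidy an agreement matrix into pair rows
#'
#' @param x An [agreement_matrix()].
#' @param digits Reporting precision (half-away-from-zero rounding);
#'   use `Inf` for full precision.
#' @param ... Unused.
#' @return Tibble with one row per unordered pair: `rater1`, `rater2`,
#'   `estimate`.
#' @exportS3Method generics::tidy
tidy.agreement_matrix <- function(x, digits = 2, ...) {
  k <- length(x$cols)
  idx <- which(upper.tri(x$matrix), arr.ind = TRUE)
  est <- x$matrix[idx]
  if (is.finite(digits)) est <- round_half_up(est, digits)
  tibble::tibble(rater1 = x$cols[idx[, 1]], rater2 = x$cols[idx[, 2]],
                 estimate = est)
}

#' @exportS3Method ggplot2::autoplot
autoplot.agreement_matrix <- function(object, ...) {
  df <- tidyr::expand_grid(rater1 = object$cols, rater2 = object$cols) |>
    dplyr::mutate(estimate = object$matrix[cbind(
      match(.data$rater1, object$cols), match(.data$rater2, object$cols))])
  ggplot2::ggplot(df, ggplot2::aes(.data$rater2, .data$rater1,
                                   fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", round_half_up(.data$estimate))), size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman")
}

#' Packaged 46-scan diagnosis panel
#'
#' A published panel of 46 prostate whole-slide scans independently
#' diagnosed by nine expert histopathologists (`D1`--`D9`, labels
#' `C`/`NC`/`IHC`), together with the percentage of cancerous tissue
#' detected by an ensemble of deep classifiers (`c_tissue_pct`) and the
#' label output by the abstaining rule with thresholds 0.5% and 7%
#' (`rule`).
#'
#' @return Tibble with 46 rows.
#' @export
diagnosis_panel <- function() {
  readr::read_csv(system.file("extdata", "prostate_panel_46.csv",
                              package = "slidediag"),
                  col_types = readr::cols(
                    scan_id = readr::col_integer(),
                    c_tissue_pct = readr::col_double(),
                    .default = readr::col_character()))
}
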