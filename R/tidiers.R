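#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the grid-search metric surface
#'
#' @param x An `lce_fit` object.
#' @param ... Unused.
#' @return Tibble: one row per grid point with its metric.
#' @exportS3Method generics::tidy
tidy.lce_fit <- function(x, ...) x$surface

#' One-row fit summary
#'
#' @param x An `lce_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.lce_fit <- function(x, ...) {
  b <- x$best
  dplyr::tibble(
    a = b$a, w = if (is.null(b$w1)) b$w else NA_real_,
    w1 = if (is.null(b$w1)) NA_real_ else b$w1,
    w2 = if (is.null(b$w2)) NA_real_ else b$w2,
    decay = b$decay, lam = b$lam, k = b$k,
    metric = x$metric, value = x$best_metric,
    n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' Per-fold cross-validation results
#'
#' @param x An `lce_cv` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.lce_cv <- function(x, ...) x$folds

#' Cross-validation summary (mean and sd of the held-out metric)
#'
#' @param x An `lce_cv` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.lce_cv <- function(x, ...) {
  dplyr::tibble(
    metric = x$metric, n_folds = x$n_folds,
    mean_test = mean(x$folds$test_metric),
    sd_test = stats::sd(x$folds$test_metric)
  )
}

#' Precision-recall and ROC curve points
#'
#' @param x An `lce_eval` object.
#' @param ... Unused.
#' @return Long tibble with `curve` ("pr"/"roc"), `x`, `y`, `threshold`.
#' @exportS3Method generics::tidy
tidy.lce_eval <- function(x, ...) {
  pr <- x$pr_curve
  roc <- x$roc_curve
  dplyr::bind_rows(
    dplyr::tibble(curve = "pr", x = pr$recall, y = pr$precision,
                  threshold = pr$threshold),
    dplyr::tibble(curve = "roc", x = roc$fpr, y = roc$tpr,
                  threshold = roc$threshold)
  )
}

#' Scalar evaluation summary
#'
#' @param x An `lce_eval` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.lce_eval <- function(x, ...) {
  dplyr::tibble(auprc = x$auprc, auroc = x$auroc, pet_cor = x$pet_cor,
                n_pos = x$n_pos, n_neg = x$n_neg)
}
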