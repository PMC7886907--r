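#' Area under the precision-recall curve (average precision)
#'
#' Step-interpolated average precision: precision is evaluated at every
#' distinct score threshold and integrated against the recall increments.
#' This is the standard summary for heavily imbalanced genomic
#' classification tasks, where ROC area is dominated by the negatives.
#'
#' @param scores Numeric prediction scores (higher = more likely
#'   positive).
#' @param labels Binary labels (0/1 or logical); both classes must be
#'   present.
#' @return A scalar in (0, 1].
#' @export
auprc <- function(scores, labels) {
  y <- check_binary(scores, labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- y[o]
  block_end <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  tp <- cumsum(y)[block_end]
  np <- block_end
  prec <- tp / np
  rec <- tp / sum(y)
  sum(diff(c(0, rec)) * prec)
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney rank statistic; tied scores
#' receive average ranks.
#'
#' @inheritParams auprc
#' @return A scalar in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- check_binary(scores, labels)
  n1 <- sum(y)
  n0 <- sum(!y)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_binary <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("`scores` and `labels` must have the same length", call. = FALSE)
  y <- as.integer(as.logical(labels))
  if (anyNA(y) || anyNA(scores))
    stop("missing scores or labels", call. = FALSE)
  if (all(y == 1L) || all(y == 0L))
    stop("both classes must be present", call. = FALSE)
  y
}

#' Evaluate predicted loop probabilities against labels
#'
#' Computes AUPRC, AUROC, the full precision-recall and ROC curves, and
#' (when PET counts are available) the Pearson correlation between
#' predicted probability and `log2(1 + PET count)` over all pairs.
#'
#' @param pairs Labelled pair tibble with a score column and `label`.
#' @param score Name of the score column (default `"p_ij"`).
#' @return An `lce_eval` object; see [glance.lce_eval()] and
#'   [autoplot.lce_eval()].
#' @export
evaluate_pairs <- function(pairs, score = "p_ij") {
  if (!score %in% names(pairs) || !"label" %in% names(pairs))
    stop("`pairs` needs columns '", score, "' and 'label'", call. = FALSE)
  sc <- pairs[[score]]
  y <- check_binary(sc, pairs$label)
  o <- order(sc, decreasing = TRUE)
  s <- sc[o]
  yo <- y[o]
  block_end <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  tp <- cumsum(yo)[block_end]
  fp <- block_end - tp
  pr <- dplyr::tibble(threshold = s[block_end],
                      recall = tp / sum(y),
                      precision = tp / block_end)
  roc <- dplyr::tibble(threshold = s[block_end],
                       fpr = fp / sum(!y),
                       tpr = tp / sum(y))
  pet_cor <- if ("pet_count" %in% names(pairs))
    stats::cor(sc, log2(1 + pairs$pet_count)) else NA_real_
  structure(
    list(auprc = auprc(sc, y), auroc = auroc(sc, y),
         pr_curve = pr, roc_curve = roc, pet_cor = pet_cor,
         n_pos = sum(y), n_neg = sum(!y), score = score),
    class = "lce_eval"
  )
}

#' @export
print.lce_eval <- function(x, ...) {
  cat("<lce_eval>", x$n_pos, "positives /", x$n_neg, "negatives\n")
  cat(sprintf("  AUPRC = %.4f  AUROC = %.4f", x$auprc, x$auroc))
  if (!is.na(x$pet_cor))
    cat(sprintf("  cor(p, log2 PET) = %.3f", x$pet_cor))
  cat("\n")
  invisible(x)
}
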