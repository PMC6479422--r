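# Filtering and benchmarking arithmetic: confusion-matrix metrics for a
# labeled call set, simple fold-change threshold filters, and a ROC/AUC
# sweep whose trapezoidal area equals the pairwise rank statistic
# (ties counted 1/2).

#' Precision, recall, F1 and FDR from confusion counts
#'
#' @param tp,fp,fn Non-negative true-positive, false-positive and
#'   false-negative call counts.
#' @param digits Decimals to round the reported metrics to (default 3).
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `fdr`. Precision and FDR share the denominator `tp + fp`; recall uses
#'   `tp + fn`; a zero denominator is an error naming the metric.
#' @examples
#' confusion_metrics(tp = 1496, fp = 83, fn = 276)
#' @export
confusion_metrics <- function(tp, fp, fn, digits = 3L) {
  stopifnot(is.numeric(tp), is.numeric(fp), is.numeric(fn),
            tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp == 0) {
    stop("precision/FDR undefined: tp + fp = 0", call. = FALSE)
  }
  if (tp + fn == 0) {
    stop("recall undefined: tp + fn = 0", call. = FALSE)
  }
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- 2 * precision * recall / (precision + recall)
  fdr <- fp / (tp + fp)
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    precision = round(precision, digits),
    recall = round(recall, digits),
    f1 = round(f1, digits),
    fdr = round(fdr, digits)
  )
}

#' Filter annotated SV records on a fold-change threshold
#'
#' Records of the targeted `svtype` are retained iff their fold-change value
#' satisfies `comparator` against `cutoff`, or the value is missing (an
#' absent annotation cannot confidently reject a call). Records of any other
#' type always pass. Comparisons are strict, matching the usual published
#' cutoffs (DHFFC < 0.7 for deletions, DHBFC > 1.3 for duplications).
#'
#' @param records Tibble with columns `svtype` and the fold-change fields
#'   (`dhbfc`/`dhffc`, case-insensitive names accepted for `field`).
#' @param svtype SV type the filter targets (e.g. `"DEL"`).
#' @param field `"DHFFC"` or `"DHBFC"`.
#' @param comparator `"<"` or `">"`.
#' @param cutoff Threshold value.
#' @return The retained rows, as a tibble.
#' @export
apply_threshold_filter <- function(records, svtype, field = c("DHFFC", "DHBFC"),
                                   comparator = c("<", ">"), cutoff) {
  records <- tibble::as_tibble(records)
  field <- tolower(match.arg(toupper(field), c("DHFFC", "DHBFC")))
  comparator <- match.arg(comparator)
  stopifnot("svtype" %in% names(records))
  if (!field %in% names(records)) {
    stop(sprintf("records have no '%s' column", field), call. = FALSE)
  }
  x <- records[[field]]
  pass <- if (comparator == "<") x < cutoff else x > cutoff
  keep <- records$svtype != svtype | is.na(x) | pass
  records[keep, , drop = FALSE]
}

#' ROC curve and AUC for labeled fold-change scores
#'
#' Sweeps sensitivity/specificity over every distinct score threshold (tied
#' scores form one step) and integrates the curve with the trapezoidal rule,
#' which makes the AUC identical to the pairwise rank (Mann-Whitney)
#' statistic with ties counted 1/2. `direction = "lower"` means a lower
#' score indicates the event class (as for deletion DHFFC);
#' `direction = "higher"` fits duplication scores.
#'
#' @param scores Numeric fold-change values; records with missing scores are
#'   dropped with a message.
#' @param labels Logical (or coercible) truth labels: `TRUE` = event present
#'   at the stated genotype, `FALSE` = homozygous reference.
#' @param direction `"lower"` or `"higher"` (which tail indicates an event).
#' @return An object of class `sv_roc`: ROC points, AUC, class sizes. Use
#'   [generics::tidy()] for the point list, [generics::glance()] for the
#'   one-row summary, and [ggplot2::autoplot()] to plot.
#' @export
roc_and_auc <- function(scores, labels, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  drop <- is.na(scores)
  if (any(drop)) {
    message(sprintf("dropping %d record(s) with missing scores", sum(drop)))
    scores <- scores[!drop]
    labels <- labels[!drop]
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs at least one score of each label", call. = FALSE)
  }
  oriented <- if (direction == "lower") -scores else scores
  ord <- order(oriented, decreasing = TRUE)
  s <- oriented[ord]
  l <- labels[ord]
  # one ROC step per distinct score value (ties grouped)
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  cum_tp <- cumsum(l)[last_of_group]
  cum_fp <- cumsum(!l)[last_of_group]
  tpr <- c(0, cum_tp / n_pos)
  fpr <- c(0, cum_fp / n_neg)
  thresholds <- c(Inf, s[last_of_group])
  if (direction == "lower") thresholds <- -thresholds
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(
    list(
      points = tibble::tibble(
        threshold = thresholds,
        sensitivity = tpr,
        specificity = 1 - fpr
      ),
      auc = auc,
      n_pos = n_pos,
      n_neg = n_neg,
      n_dropped = sum(drop),
      direction = direction
    ),
    class = "sv_roc"
  )
}

#' @export
print.sv_roc <- function(x, ...) {
  cat(sprintf(
    "<sv_roc> AUC = %.4f (%d event, %d null scores; direction = %s)\n",
    x$auc, x$n_pos, x$n_neg, x$direction
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the ROC point list
#'
#' @param x An `sv_roc` object.
#' @param ... Unused.
#' @return Tibble with `threshold`, `sensitivity`, `specificity`.
#' @method tidy sv_roc
#' @export
tidy.sv_roc <- function(x, ...) {
  x$points
}

#' One-row ROC summary
#'
#' @param x An `sv_roc` object.
#' @param ... Unused.
#' @return Tibble with `auc`, `n_pos`, `n_neg`, `n_dropped`.
#' @method glance sv_roc
#' @export
glance.sv_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
                 n_dropped = x$n_dropped)
}

#' Plot an ROC curve
#'
#' @param object An `sv_roc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sv_roc
#' @export
autoplot.sv_roc <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Effect of a filter on false and true positives
#'
#' @param before,after Confusion counts before and after filtering: anything
#'   with `tp` and `fp` components (e.g. a [confusion_metrics()] row or a
#'   named list).
#' @return One-row tibble: `fp_removed_pct` and `tp_retained_pct`, as whole
#'   percentages.
#' @examples
#' summarize_filter_effect(list(tp = 1496, fp = 83), list(tp = 1483, fp = 32))
#' @export
summarize_filter_effect <- function(before, after) {
  b_tp <- before$tp; b_fp <- before$fp
  a_tp <- after$tp; a_fp <- after$fp
  stopifnot(is.numeric(b_tp), is.numeric(b_fp), is.numeric(a_tp),
            is.numeric(a_fp))
  if (a_tp > b_tp || a_fp > b_fp) {
    stop("filtering cannot increase tp or fp counts", call. = FALSE)
  }
  if (b_fp == 0) {
    stop("fp_removed undefined: no false positives before filtering",
         call. = FALSE)
  }
  if (b_tp == 0) {
    stop("tp_retained undefined: no true positives before filtering",
         call. = FALSE)
  }
  tibble::tibble(
    fp_removed_pct = round(100 * (b_fp - a_fp) / b_fp),
    tp_retained_pct = round(100 * a_tp / b_tp)
  )
}
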