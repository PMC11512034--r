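# Confusion matrices and the per-class / macro / micro metric suite.

#' Confusion matrix of a multiclass labelling
#'
#' @param truth,estimate Equal-length vectors of class indices in `1..n_classes`
#'   (rows of the matrix are true classes, columns predicted classes).
#' @param n_classes Number of classes K (defaults to the maximum label seen).
#' @param class_labels Optional K class names.
#' @return An object of class `confusion_matrix` wrapping the K x K integer
#'   count matrix.
#' @examples
#' confusion(c(1, 1, 2, 2), c(1, 2, 2, 2))
#' @export
confusion <- function(truth, estimate, n_classes = NULL, class_labels = NULL) {
  if (length(truth) == 0) abort("`truth` must be non-empty.")
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have equal length.")
  }
  truth <- as.integer(truth); estimate <- as.integer(estimate)
  if (is.null(n_classes)) n_classes <- max(truth, estimate)
  if (any(truth < 1 | truth > n_classes | estimate < 1 | estimate > n_classes)) {
    abort("labels must lie in 1..n_classes.")
  }
  counts <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(truth)) {
    counts[truth[i], estimate[i]] <- counts[truth[i], estimate[i]] + 1L
  }
  if (is.null(class_labels)) class_labels <- as.character(seq_len(n_classes))
  dimnames(counts) <- list(true = class_labels, predicted = class_labels)
  structure(list(counts = counts, class_labels = class_labels),
            class = "confusion_matrix")
}

#' Build a confusion matrix directly from counts
#'
#' Convenience constructor for matrices whose counts are already known
#' (e.g. transcribed from a published figure).
#'
#' @param counts A K x K non-negative integer matrix, rows = true class.
#' @inheritParams confusion
#' @export
as_confusion <- function(counts, class_labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || any(counts < 0)) {
    abort("`counts` must be a square non-negative matrix.")
  }
  storage.mode(counts) <- "integer"
  if (is.null(class_labels)) class_labels <- as.character(seq_len(nrow(counts)))
  dimnames(counts) <- list(true = class_labels, predicted = class_labels)
  structure(list(counts = counts, class_labels = class_labels),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d classes, %d samples\n",
              nrow(x$counts), sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' @describeIn confusion One row per cell: `true`, `predicted`, `count`.
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  k <- nrow(x$counts)
  tibble::tibble(
    true = rep(x$class_labels, times = k),
    predicted = rep(x$class_labels, each = k),
    count = as.integer(x$counts[cbind(rep(seq_len(k), times = k),
                                      rep(seq_len(k), each = k))])
  )
}

#' One-vs-rest counts for a single class
#'
#' Decomposes a confusion matrix into the four one-vs-rest counts of class
#' `c`: true positives (the diagonal cell), false negatives (rest of row
#' `c`), false positives (rest of column `c`) and true negatives (all
#' remaining cells). They always sum to the total sample count.
#'
#' @param m A [confusion()] matrix.
#' @param c Class index.
#' @return Named integer vector `N_TP`, `N_FP`, `N_TN`, `N_FN`.
#' @export
class_counts <- function(m, c) {
  if (!inherits(m, "confusion_matrix")) abort("`m` must be a confusion_matrix.")
  k <- nrow(m$counts)
  if (c < 1 || c > k) abort("class index out of range.")
  cm <- m$counts
  tp <- cm[c, c]
  fn <- sum(cm[c, ]) - tp
  fp <- sum(cm[, c]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(N_TP = tp, N_FP = fp, N_TN = tn, N_FN = fn)
}

metric_pct <- function(num, den) if (den == 0) 100 else 100 * num / den

#' Per-class, macro and micro evaluation metrics
#'
#' For every class `c` the one-vs-rest counts give the four standard
#' metrics, each in percent:
#' accuracy `(TP + TN) / (TP + TN + FP + FN)`, precision `TP / (TP + FP)`,
#' sensitivity `TP / (TP + FN)` and specificity `TN / (TN + FP)`; a `0/0`
#' ratio (class absent and never predicted) is defined as 100 so a perfect
#' labelling scores 100 everywhere. Macro values are unweighted class
#' means; micro precision and sensitivity pool the counts over classes and
#' both equal the overall correct classification rate
#' (`100 * trace / total`) in single-label problems.
#'
#' @param m A [confusion()] matrix.
#' @return An object of class `metrics_report`: `per_class` tibble,
#'   `macro` / `micro` named vectors, `overall_ccr`, `n_errors`, `n`.
#' @examples
#' cm <- as_confusion(diag(c(17, 16, 16, 18, 18)) + 0)
#' metrics(cm)$overall_ccr
#' @export
metrics <- function(m) {
  if (!inherits(m, "confusion_matrix")) abort("`m` must be a confusion_matrix.")
  total <- sum(m$counts)
  if (total == 0) abort("empty confusion matrix.")
  k <- nrow(m$counts)
  per <- purrr::map_dfr(seq_len(k), function(c) {
    cc <- class_counts(m, c)
    tibble::tibble(
      class = m$class_labels[c],
      N_TP = cc[["N_TP"]], N_FP = cc[["N_FP"]],
      N_TN = cc[["N_TN"]], N_FN = cc[["N_FN"]],
      accuracy = metric_pct(cc[["N_TP"]] + cc[["N_TN"]], total),
      precision = metric_pct(cc[["N_TP"]], cc[["N_TP"]] + cc[["N_FP"]]),
      sensitivity = metric_pct(cc[["N_TP"]], cc[["N_TP"]] + cc[["N_FN"]]),
      specificity = metric_pct(cc[["N_TN"]], cc[["N_TN"]] + cc[["N_FP"]])
    )
  })
  trace <- sum(diag(m$counts))
  micro_prec <- metric_pct(sum(per$N_TP), sum(per$N_TP) + sum(per$N_FP))
  micro_sens <- metric_pct(sum(per$N_TP), sum(per$N_TP) + sum(per$N_FN))
  structure(
    list(per_class = per,
         macro = c(accuracy = mean(per$accuracy),
                   precision = mean(per$precision),
                   sensitivity = mean(per$sensitivity),
                   specificity = mean(per$specificity)),
         micro = c(precision = micro_prec, sensitivity = micro_sens),
         overall_ccr = 100 * trace / total,
         n_errors = total - trace,
         n = total),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d, errors = %d, overall CCR %.2f%%\n",
              x$n, x$n_errors, x$overall_ccr))
  cat(sprintf("  macro: accuracy %.2f  precision %.2f  sensitivity %.2f  specificity %.2f\n",
              x$macro["accuracy"], x$macro["precision"],
              x$macro["sensitivity"], x$macro["specificity"]))
  invisible(x)
}

#' @describeIn metrics Per-class metric tibble.
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @describeIn metrics One-row summary (macro and micro aggregates, CCR).
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(
    macro_accuracy = x$macro[["accuracy"]],
    macro_precision = x$macro[["precision"]],
    macro_sensitivity = x$macro[["sensitivity"]],
    macro_specificity = x$macro[["specificity"]],
    micro_precision = x$micro[["precision"]],
    micro_sensitivity = x$micro[["sensitivity"]],
    overall_ccr = x$overall_ccr,
    n_errors = x$n_errors,
    n = x$n
  )
}

#' Overall correlation between targets and network outputs
#'
#' Pearson correlation over all flattened entries of the one-hot target
#' matrix and the network-output matrix; defined as 0 when either input has
#' zero variance.
#'
#' @param targets,outputs Equal-shape numeric matrices.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
overall_correlation <- function(targets, outputs) {
  targets <- as.numeric(targets); outputs <- as.numeric(outputs)
  if (length(targets) != length(outputs)) {
    abort("`targets` and `outputs` must have the same shape.")
  }
  if (sd(targets) == 0 || sd(outputs) == 0) return(0)
  cor(targets, outputs)
}

#' Summary table of classifier performance
#'
#' Combines several metric reports into the conventional summary layout:
#' one row per material x method, with the macro per-class accuracy,
#' precision, sensitivity and specificity (in percent, two decimals) plus
#' the overall correct classification rate.
#'
#' @param reports A named list of `metrics_report` objects, or a tibble with
#'   columns `material`, `method`, `report` (list-column).
#' @param digits Decimal digits for the rendered percentages.
#' @return A tibble with columns `material`, `method`, `accuracy`,
#'   `precision`, `sensitivity`, `specificity`, `overall_ccr`.
#' @export
metrics_summary <- function(reports, digits = 2) {
  if (inherits(reports, "metrics_report")) reports <- list(report = reports)
  if (is.data.frame(reports)) {
    tbl <- reports
  } else {
    nm <- names(reports)
    if (is.null(nm)) nm <- paste0("report_", seq_along(reports))
    parts <- strsplit(nm, "\\.")
    tbl <- tibble::tibble(
      material = vapply(parts, `[`, "", 1),
      method = vapply(parts, function(p) if (length(p) > 1) p[2] else "",
                      character(1)),
      report = unname(reports)
    )
  }
  purrr::pmap_dfr(tbl, function(material, method, report, ...) {
    tibble::tibble(
      material = material,
      method = method,
      accuracy = render_percent(report$macro["accuracy"], digits),
      precision = render_percent(report$macro["precision"], digits),
      sensitivity = render_percent(report$macro["sensitivity"], digits),
      specificity = render_percent(report$macro["specificity"], digits),
      overall_ccr = render_percent(report$overall_ccr, digits)
    )
  })
}
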