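# Sequential forward feature selection under a cross-validated
# least-squares deviance criterion.

# Held-out residual sum of squares, summed over stratified CV folds and
# divided by n, of a linear fit of the one-hot class indicators on the
# given feature columns. Features are z-scored with training-fold
# statistics only. An empty feature set scores the intercept-only model.
cv_deviance <- function(x, y, features, fold) {
  n <- nrow(x)
  rss <- 0
  for (f in sort(unique(fold))) {
    tr <- fold != f
    ytr <- y[tr, , drop = FALSE]
    yte <- y[!tr, , drop = FALSE]
    if (length(features) == 0) {
      pred <- matrix(colMeans(ytr), nrow(yte), ncol(y), byrow = TRUE)
    } else {
      xtr <- x[tr, features, drop = FALSE]
      st <- standardize_fit(xtr)
      xtr <- cbind(1, standardize_apply(xtr, st))
      xte <- cbind(1, standardize_apply(x[!tr, features, drop = FALSE], st))
      qr_tr <- qr(xtr)
      beta <- qr.coef(qr_tr, ytr)
      beta[is.na(beta)] <- 0
      pred <- xte %*% beta
    }
    rss <- rss + sum((yte - pred)^2)
  }
  rss / n
}

#' Criterion value of a candidate feature subset
#'
#' The deviance criterion used by [sfs_select()]: the cross-validated
#' residual sum of squares (per sample) of a least-squares fit of the
#' one-hot class indicators on the named features. Exposed so alternative
#' search strategies (e.g. exhaustive search on small problems) can be
#' scored identically.
#'
#' @param table A feature table (see [extract_feature_table()]).
#' @param features Character vector of feature names (may be empty).
#' @param cv_folds Number of stratified folds.
#' @param seed Seed controlling the fold assignment.
#' @return The criterion value (lower is better).
#' @export
sfs_criterion <- function(table, features, cv_folds = 5, seed = 1) {
  x <- feature_matrix(table)
  cls <- class_vector(table)
  y <- one_hot(cls)
  fold <- stratified_folds(cls, cv_folds, seed)
  cv_deviance(x, y, features, fold)
}

#' Sequential forward selection of efficient features
#'
#' Greedy forward search over the feature columns of `table`: at each step
#' every unselected feature is scored by the cross-validated deviance of the
#' enlarged subset (see [sfs_criterion()]); the best candidate is accepted
#' if it improves the current criterion by more than a relative `tol`, with
#' ties broken towards the lowest feature index. The search stops when no
#' candidate improves, or at `max_features`. The accepted ("efficient")
#' features are the compact signature used by the downstream classifiers —
#' on real pepper/sea-foam data this stage retains on the order of 17-18 of
#' the 266 features.
#'
#' @inheritParams sfs_criterion
#' @param max_features Maximum number of features to accept.
#' @param tol Minimum relative improvement to accept a feature.
#' @return An object of class `sfs_result`: `selected` (feature names in
#'   acceptance order), `selected_idx`, `criterion_trajectory` (criterion
#'   after each acceptance, preceded by the empty-set value), `n_selected`,
#'   `cv_folds`, `seed`.
#' @examples
#' \donttest{
#' ds <- generate_dataset(black_pepper_palette(), sea_foam_palette(),
#'                        sim_config(images_per_level = 4, image_size = c(64, 64)))
#' ft <- extract_feature_table(ds)
#' sel <- sfs_select(ft, max_features = 5)
#' sel$selected
#' }
#' @export
sfs_select <- function(table, cv_folds = 5, max_features = 20,
                       tol = 1e-6, seed = 1) {
  feats <- feature_cols(table)
  if (max_features > length(feats)) {
    abort("`max_features` exceeds the number of available features.")
  }
  cls <- class_vector(table)
  if (length(unique(cls)) < 2) abort("`table` must contain at least 2 classes.")
  if (nrow(table) <= cv_folds) abort("need more samples than folds.")
  x <- feature_matrix(table)
  y <- one_hot(cls)
  fold <- stratified_folds(cls, cv_folds, seed)

  selected <- integer(0)
  current <- cv_deviance(x, y, selected, fold)
  trajectory <- current
  repeat {
    if (length(selected) >= max_features) break
    candidates <- setdiff(seq_along(feats), selected)
    scores <- vapply(candidates, function(j) {
      cv_deviance(x, y, c(selected, j), fold)
    }, numeric(1))
    best <- which.min(scores) # first minimum -> lowest index wins ties
    if (current - scores[best] <= tol * max(current, .Machine$double.eps)) break
    selected <- c(selected, candidates[best])
    current <- scores[best]
    trajectory <- c(trajectory, current)
  }
  structure(
    list(selected = feats[selected],
         selected_idx = selected,
         criterion_trajectory = trajectory,
         n_selected = length(selected),
         cv_folds = cv_folds,
         seed = seed),
    class = "sfs_result"
  )
}

#' @export
print.sfs_result <- function(x, ...) {
  cat(sprintf("<sfs_result> %d efficient features (criterion %.4g -> %.4g, %d-fold CV)\n",
              x$n_selected, x$criterion_trajectory[1],
              x$criterion_trajectory[length(x$criterion_trajectory)],
              x$cv_folds))
  if (x$n_selected > 0) cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn sfs_select One row per accepted feature: `step`, `feature`,
#'   `feature_idx`, `criterion`.
#' @param x An `sfs_result`.
#' @param ... Unused.
#' @method tidy sfs_result
#' @export
tidy.sfs_result <- function(x, ...) {
  tibble::tibble(
    step = seq_len(x$n_selected),
    feature = x$selected,
    feature_idx = x$selected_idx,
    criterion = x$criterion_trajectory[-1]
  )
}

#' @describeIn sfs_select One-row summary of the search.
#' @method glance sfs_result
#' @export
glance.sfs_result <- function(x, ...) {
  tibble::tibble(
    n_selected = x$n_selected,
    initial_criterion = x$criterion_trajectory[1],
    final_criterion = x$criterion_trajectory[length(x$criterion_trajectory)],
    cv_folds = x$cv_folds,
    seed = x$seed
  )
}

#' Per-level means of the efficient features
#'
#' Formats the selection result the way efficient-feature tables are
#' reported: one row per selected feature (statistic and channel split out)
#' and one column of mean values per adulteration level.
#'
#' @param result An [sfs_select()] result.
#' @param table The feature table the selection was run on (must contain a
#'   `level` column).
#' @return A tibble with columns `feature`, `stat`, `channel`, then one
#'   `level_<percent>` column per adulteration level; empty when nothing
#'   was selected.
#' @export
report_efficient_features <- function(result, table) {
  if (!inherits(result, "sfs_result")) abort("`result` must be an sfs_result.")
  if (result$n_selected == 0) {
    return(tibble::tibble(feature = character(), stat = character(),
                          channel = character()))
  }
  lv <- if ("level" %in% names(table)) table$level else table$class_index
  long <- table[c(result$selected)]
  long$..level <- lv
  means <- long |>
    tidyr::pivot_longer(-"..level", names_to = "feature", values_to = "value") |>
    dplyr::group_by(.data$feature, .data$..level) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "..level", values_from = "value",
                       names_prefix = "level_")
  means <- means[match(result$selected, means$feature), ]
  parts <- regmatches(means$feature, regexpr("_", means$feature), invert = TRUE)
  tibble::tibble(
    feature = means$feature,
    stat = vapply(parts, `[`, "", 1),
    channel = vapply(parts, `[`, "", 2)
  ) |> dplyr::bind_cols(means[-1])
}

#' Serialise a selection result to JSON
#'
#' @param result An [sfs_select()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(result, path) {
  jsonlite::write_json(
    list(selected = result$selected,
         selected_idx = result$selected_idx,
         criterion_trajectory = result$criterion_trajectory,
         n_selected = result$n_selected,
         cv_folds = result$cv_folds,
         seed = result$seed),
    path, auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(selected = as.character(x$selected),
         selected_idx = as.integer(x$selected_idx),
         criterion_trajectory = as.numeric(x$criterion_trajectory),
         n_selected = as.integer(x$n_selected),
         cv_folds = as.integer(x$cv_folds),
         seed = as.integer(x$seed)),
    class = "sfs_result"
  )
}
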