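# Internal helpers shared across modules.

# Columns of a feature table that are metadata, not features.
.meta_cols <- c("sample_id", "class_index", "level", "material")

feature_cols <- function(table) {
  setdiff(names(table), .meta_cols)
}

feature_matrix <- function(table) {
  as.matrix(table[feature_cols(table)])
}

class_vector <- function(table) {
  as.integer(table[["class_index"]])
}

# One-hot 0/1 coding of integer classes 1..K (targets for MSE training).
one_hot <- function(classes, n_classes = max(classes)) {
  y <- matrix(0, length(classes), n_classes)
  y[cbind(seq_along(classes), classes)] <- 1
  y
}

# Column-wise z-score standardisation; zero-variance columns are left at 0
# by substituting unit scale (keeps degenerate synthetic inputs finite).
standardize_fit <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

standardize_apply <- function(x, st) {
  sweep(sweep(x, 2, st$center, "-"), 2, st$scale, "/")
}

# Stratified fold ids (1..k) for integer class labels, reproducible from seed.
stratified_folds <- function(classes, k, seed) {
  fold <- integer(length(classes))
  with_seed(seed, {
    for (cl in sort(unique(classes))) {
      idx <- which(classes == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# restores (or clears) the global .Random.seed afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# Deterministic per-stage child seeds below 2^31.
derive_seed <- function(seed, stage) {
  (as.numeric(seed) * 48271 + stage * 10007) %% 2147483647
}

#' Render a percentage the way printed tables do
#'
#' Printed reports are inconsistent about rounding: the same rate can appear
#' rounded to one decimal in the text and truncated to two decimals in a
#' table (88/90 renders as both 97.8 and 97.77). Both renderings are
#' available so either convention can be reproduced exactly.
#'
#' @param x Numeric vector of percentages.
#' @param digits Number of decimal digits to keep.
#' @param style `"round"` (round half away from zero) or `"truncate"`
#'   (drop digits beyond `digits`).
#' @return Numeric vector rendered at the requested precision.
#' @examples
#' render_percent(88 / 90 * 100, 1) # 97.8
#' render_percent(88 / 90 * 100, 2, style = "truncate") # 97.77
#' @export
render_percent <- function(x, digits = 2, style = c("round", "truncate")) {
  style <- match.arg(style)
  f <- 10^digits
  if (style == "round") {
    sign(x) * floor(abs(x) * f + 0.5) / f
  } else {
    trunc(x * f) / f
  }
}
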