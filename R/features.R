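# First-order statistics and co-occurrence texture features.

# 256-bin histogram over the plane's native [min, max] range; used for the
# mode and for first-order entropy. A constant plane occupies a single bin.
plane_histogram <- function(x, bins) {
  mn <- min(x); mx <- max(x)
  if (mx == mn) {
    counts <- c(length(x), rep(0L, bins - 1L))
    centers <- rep(mn, bins)
  } else {
    k <- pmin(floor((x - mn) / (mx - mn) * bins) + 1L, bins)
    counts <- tabulate(k, nbins = bins)
    centers <- mn + (seq_len(bins) - 0.5) * (mx - mn) / bins
  }
  list(counts = counts, centers = centers)
}

#' First-order colour statistics of one channel plane
#'
#' The nine per-channel colour statistics: mean, minimum, maximum, median
#' (midpoint convention on even counts), mode (centre of the argmax bin of a
#' 256-bin histogram over the plane's native range, ties to the lowest bin),
#' sample standard deviation (n - 1), coefficient of variation (`std/mean`,
#' 0 when the mean is 0), skewness `m3 / m2^1.5` and non-excess kurtosis
#' `m4 / m2^2` (a Gaussian plane gives 3), both 0 on zero-variance planes;
#' `mk` are central moments with `1/n` normalisation.
#'
#' @param plane A non-empty numeric matrix (or vector) of channel values.
#' @return Named numeric vector of the 9 statistics.
#' @examples
#' channel_stats(matrix(c(0, 0, 1, 1), 2))
#' @export
channel_stats <- function(plane) {
  x <- as.numeric(plane)
  if (length(x) == 0) abort("`plane` must be non-empty.")
  n <- length(x)
  mu <- mean(x)
  hist <- plane_histogram(x, 256L)
  mode <- hist$centers[which.max(hist$counts)]
  std <- if (n > 1) sd(x) else 0
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  c(mean = mu,
    min = min(x),
    max = max(x),
    median = median(x),
    mode = mode,
    std = std,
    cv = if (mu == 0) 0 else std / mu,
    skewness = if (m2 == 0) 0 else m3 / m2^1.5,
    kurtosis = if (m2 == 0) 0 else m4 / m2^2)
}

#' First-order histogram entropy of a plane
#'
#' Shannon entropy, in bits, of the normalised `bins`-bin histogram of the
#' plane over its native range: `-sum(p * log2(p))`, ranging from 0 for a
#' constant plane to `log2(bins)` for a uniformly filled histogram. This is
#' the 8-bit-scale entropy (maximum 8 bits at the default 256 bins) used as
#' the per-channel "entropy" feature.
#'
#' @inheritParams channel_stats
#' @param bins Number of histogram bins (>= 2).
#' @return Entropy in bits.
#' @examples
#' histogram_entropy(matrix(1, 4, 4)) # 0
#' @export
histogram_entropy <- function(plane, bins = 256) {
  x <- as.numeric(plane)
  if (length(x) == 0) abort("`plane` must be non-empty.")
  if (bins < 2) abort("`bins` must be >= 2.")
  p <- plane_histogram(x, as.integer(bins))$counts
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}

#' Gray-level co-occurrence matrix of a plane
#'
#' Quantises the plane to `levels` equal-width bins over its native
#' `[min, max]` range (a constant plane maps entirely to level 1) and
#' accumulates co-occurrence counts of level pairs at each spatial offset
#' `(dr, dc)`. The default offsets are the four distance-1 directions
#' (0, 45, 90, 135 degrees) accumulated into a single matrix, which with
#' symmetrisation (adding the transpose) gives a rotation-robust descriptor
#' for isotropic powder texture. The matrix is normalised to sum to 1.
#'
#' @inheritParams channel_stats
#' @param levels Number of quantisation levels (>= 2).
#' @param offsets List of integer `(dr, dc)` offsets.
#' @param symmetric Add the transpose before normalising?
#' @return An object of class `glcm`: the `levels x levels` probability
#'   matrix plus the parameters used.
#' @examples
#' g <- glcm_compute(matrix(c(0, 0, 1, 1), 2, byrow = TRUE), levels = 2,
#'                   offsets = list(c(0, 1)))
#' g$matrix
#' @export
glcm_compute <- function(plane, levels = 8,
                         offsets = list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1)),
                         symmetric = TRUE) {
  if (is.null(dim(plane))) plane <- matrix(as.numeric(plane), nrow = 1)
  if (length(plane) == 0) abort("`plane` must be non-empty.")
  levels <- as.integer(levels)
  if (levels < 2) abort("`levels` must be >= 2.")
  mn <- min(plane); mx <- max(plane)
  if (mx > mn) {
    q <- pmin(floor((plane - mn) / (mx - mn) * levels), levels - 1L)
  } else {
    q <- matrix(0L, nrow(plane), ncol(plane))
  }
  storage.mode(q) <- "integer"
  h <- nrow(q); w <- ncol(q)
  counts <- matrix(0, levels, levels)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    rows <- seq(max(1, 1 - dr), min(h, h - dr))
    cols <- seq(max(1, 1 - dc), min(w, w - dc))
    if (length(rows) == 0 || length(cols) == 0) next
    a <- q[rows, cols, drop = FALSE]
    b <- q[rows + dr, cols + dc, drop = FALSE]
    counts <- counts +
      matrix(tabulate(a * levels + b + 1L, nbins = levels^2),
             levels, levels, byrow = TRUE)
  }
  if (symmetric) counts <- counts + t(counts)
  total <- sum(counts)
  structure(
    list(matrix = if (total > 0) counts / total else counts,
         levels = levels, offsets = offsets, symmetric = symmetric),
    class = "glcm"
  )
}

#' Haralick-style features of a co-occurrence matrix
#'
#' Energy `sum(P^2)`, contrast `sum((i - j)^2 P)`, homogeneity
#' `sum(P / (1 + (i - j)^2))` and correlation
#' `sum((i - mu_i)(j - mu_j) P) / (sigma_i sigma_j)`; correlation is defined
#' as 1 when either marginal is degenerate (e.g. a constant image).
#'
#' @param g A [glcm_compute()] result.
#' @return Named numeric vector: `energy`, `contrast`, `correlation`,
#'   `homogeneity`.
#' @examples
#' glcm_features(glcm_compute(matrix(c(0, 1, 1, 0), 2), levels = 2))
#' @export
glcm_features <- function(g) {
  if (!inherits(g, "glcm")) abort("`g` must be a glcm object.")
  p <- g$matrix
  l <- g$levels
  i <- matrix(seq_len(l), l, l)
  j <- t(i)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  var_i <- sum((i - mu_i)^2 * p); var_j <- sum((j - mu_j)^2 * p)
  denom <- sqrt(var_i * var_j)
  c(energy = sum(p^2),
    contrast = sum((i - j)^2 * p),
    correlation = if (denom == 0) 1 else sum((i - mu_i) * (j - mu_j) * p) / denom,
    homogeneity = sum(p / (1 + (i - j)^2)))
}

#' Extract the 266-feature vector of one channel stack
#'
#' Applies the 14 per-channel statistics — the 9 colour statistics of
#' [channel_stats()], GLCM energy, first-order [histogram_entropy()], and
#' GLCM contrast, correlation and homogeneity — to each of the 19 channels,
#' in canonical order, giving exactly `19 * 14 = 266` named values
#' (`<stat>_<channel>`).
#'
#' @param stack A [to_channels()] result.
#' @param glcm_levels Quantisation levels for the co-occurrence matrices.
#' @param entropy_bins Histogram bins for the entropy feature.
#' @return Named numeric vector of length 266.
#' @examples
#' v <- extract_features(to_channels(array(0.5, c(16, 16, 3))))
#' length(v)
#' @export
extract_features <- function(stack, glcm_levels = 8, entropy_bins = 256) {
  if (!inherits(stack, "channel_stack")) {
    abort("`stack` must be a channel_stack from to_channels().")
  }
  out <- purrr::imap(unclass(stack), function(plane, ch) {
    cs <- channel_stats(plane)
    gf <- glcm_features(glcm_compute(plane, levels = glcm_levels))
    v <- c(cs, energy = unname(gf["energy"]),
           entropy = histogram_entropy(plane, entropy_bins),
           contrast = unname(gf["contrast"]),
           correlation = unname(gf["correlation"]),
           homogeneity = unname(gf["homogeneity"]))
    names(v) <- paste0(stat_names(), "_", ch)
    v
  })
  unlist(unname(out))
}

#' Extract a feature table from an image dataset
#'
#' Runs every image through centre cropping, 19-channel decomposition and
#' 266-feature extraction, returning one tidy row per image.
#'
#' @param dataset A tibble with columns `sample_id`, `class_index`, `level`
#'   and list-column `image` (as from [generate_dataset()] or
#'   [read_image_set()]).
#' @param keep_fraction Central crop fraction passed to [crop_center()].
#' @inheritParams extract_features
#' @return A tibble: `sample_id`, `class_index`, `level`, then the 266
#'   feature columns in canonical order.
#' @export
extract_feature_table <- function(dataset, keep_fraction = 0.8,
                                  glcm_levels = 8, entropy_bins = 256) {
  if (nrow(dataset) == 0) abort("`dataset` has no rows.")
  feats <- purrr::map(dataset$image, function(img) {
    extract_features(to_channels(crop_center(img, keep_fraction)),
                     glcm_levels = glcm_levels, entropy_bins = entropy_bins)
  })
  dplyr::bind_cols(
    tibble::tibble(sample_id = dataset$sample_id,
                   class_index = as.integer(dataset$class_index),
                   level = dataset$level),
    tibble::as_tibble(do.call(rbind, feats))
  )
}

#' Write / read a feature table as CSV
#'
#' The on-disk layout is fixed: first column `sample_id`, second column
#' `class_index`, then the 266 feature columns in canonical order.
#'
#' @param table A feature table tibble.
#' @param path CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the tibble.
#' @export
write_feature_table <- function(table, path) {
  cols <- c("sample_id", "class_index", feature_cols(table))
  readr::write_csv(table[cols], path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  tbl$class_index <- as.integer(tbl$class_index)
  tbl
}
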