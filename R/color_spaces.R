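#' Canonical channel and statistic names
#'
#' The 19 scalar channels extracted from an RGB image, in canonical order,
#' and the 14 per-channel statistics, in canonical order. Feature names are
#' `<stat>_<channel>` and a full feature vector has
#' `19 * 14 = 266` entries.
#'
#' @return Character vector of names.
#' @examples
#' length(channel_names()) * length(stat_names())
#' @export
channel_names <- function() {
  c("R", "G", "B", "Lstar", "astar", "bstar", "H", "S", "V",
    "NR", "NG", "NB", "Cr", "Cg", "Cb", "I1", "I2", "I3", "gray")
}

#' @rdname channel_names
#' @export
stat_names <- function() {
  c("mean", "min", "max", "median", "mode", "std", "cv", "skewness",
    "kurtosis", "energy", "entropy", "contrast", "correlation", "homogeneity")
}

as_rgb_array <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3) {
    abort("an RGB image must be an H x W x 3 array.")
  }
  if (anyNA(img) || min(img) < 0 || max(img) > 1) {
    abort("RGB values must lie in [0, 1].")
  }
  img
}

#' Crop the centred window of an image
#'
#' Powder photographs are cropped to their central area before analysis so
#' that dish edges and background never enter the feature statistics. The
#' window spans `floor(keep_fraction * H)` rows and
#' `floor(keep_fraction * W)` columns, centred with top/left bias when the
#' remainder is odd.
#'
#' @param img An `H x W x 3` RGB array in `[0, 1]`.
#' @param keep_fraction Fraction of each dimension to keep, in `(0, 1]`.
#' @return The cropped RGB array.
#' @examples
#' img <- array(runif(4 * 4 * 3), c(4, 4, 3))
#' dim(crop_center(img, 0.5))
#' @export
crop_center <- function(img, keep_fraction) {
  img <- as_rgb_array(img)
  if (!is.numeric(keep_fraction) || length(keep_fraction) != 1 ||
      is.na(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1) {
    abort("`keep_fraction` must be a single value in (0, 1].")
  }
  h <- dim(img)[1]; w <- dim(img)[2]
  h2 <- max(1L, floor(h * keep_fraction))
  w2 <- max(1L, floor(w * keep_fraction))
  r0 <- floor((h - h2) / 2)
  c0 <- floor((w - w2) / 2)
  img[(r0 + 1):(r0 + h2), (c0 + 1):(c0 + w2), , drop = FALSE]
}

#' Decompose an RGB image into 19 scalar channels
#'
#' Converts one RGB image into the 19 named planes used throughout the
#' pipeline: the raw R, G, B channels; CIELAB `L*`, `a*`, `b*` (sRGB
#' companding, D65 white, `L*` in 0-100); hexcone `H`, `S`, `V` all scaled
#' to `[0, 1]`; chromaticity coordinates `NR = R/(R+G+B)` etc. (set to 1/3
#' on black pixels to avoid NaNs); the mean-centred opponent channels
#' `Cr = R - (R+G+B)/3`, `Cg`, `Cb` (summing to zero); the Ohta channels
#' `I1 = (R+G+B)/3`, `I2 = (R-B)/2`, `I3 = (2G-R-B)/4`; and BT.601 luma
#' `gray = 0.2989 R + 0.5870 G + 0.1140 B`.
#'
#' @param img An `H x W x 3` RGB array with values in `[0, 1]`.
#' @return A `channel_stack`: a named list of 19 `H x W` matrices (in
#'   [channel_names()] order) with attribute `source_shape`.
#' @examples
#' st <- to_channels(array(0.5, c(8, 8, 3)))
#' names(st)[1:6]
#' @export
to_channels <- function(img) {
  img <- as_rgb_array(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  r <- matrix(img[, , 1], h, w)
  g <- matrix(img[, , 2], h, w)
  b <- matrix(img[, , 3], h, w)
  s <- r + g + b

  hsv <- grDevices::rgb2hsv(as.vector(r), as.vector(g), as.vector(b),
                            maxColorValue = 1)
  lab <- grDevices::convertColor(cbind(as.vector(r), as.vector(g), as.vector(b)),
                                 from = "sRGB", to = "Lab")

  nz <- s > 0
  nr <- ng <- nb <- matrix(1 / 3, h, w)
  nr[nz] <- r[nz] / s[nz]
  ng[nz] <- g[nz] / s[nz]
  nb[nz] <- b[nz] / s[nz]

  i1 <- s / 3
  planes <- list(
    R = r, G = g, B = b,
    Lstar = matrix(lab[, 1], h, w),
    astar = matrix(lab[, 2], h, w),
    bstar = matrix(lab[, 3], h, w),
    H = matrix(hsv[1, ], h, w),
    S = matrix(hsv[2, ], h, w),
    V = matrix(hsv[3, ], h, w),
    NR = nr, NG = ng, NB = nb,
    Cr = r - i1, Cg = g - i1, Cb = b - i1,
    I1 = i1, I2 = (r - b) / 2, I3 = (2 * g - r - b) / 4,
    gray = 0.2989 * r + 0.5870 * g + 0.1140 * b
  )
  structure(planes, source_shape = c(h, w), class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  sh <- attr(x, "source_shape")
  cat(sprintf("<channel_stack> %d x %d, 19 planes: %s\n",
              sh[1], sh[2], paste(names(x), collapse = " ")))
  invisible(x)
}
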