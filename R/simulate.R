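#' Powder colour palettes
#'
#' A palette describes the reflectance statistics of one ground material:
#' the mean RGB colour of its grains and a per-grain jitter standard
#' deviation that models the natural colour spread of individual particles.
#'
#' @param mean_rgb Length-3 numeric in `[0, 1]`: mean reflectance (R, G, B).
#' @param rgb_jitter_sd Length-3 non-negative numeric (< 0.5): per-grain
#'   colour standard deviation on each channel.
#' @param name Material name.
#' @return An object of class `powder_palette`.
#' @examples
#' powder_palette(c(0.55, 0.46, 0.33), name = "black pepper")
#' @export
powder_palette <- function(mean_rgb, rgb_jitter_sd = c(0.05, 0.05, 0.05),
                           name = "material") {
  mean_rgb <- as.numeric(mean_rgb)
  rgb_jitter_sd <- rep_len(as.numeric(rgb_jitter_sd), 3)
  if (length(mean_rgb) != 3 || any(!is.finite(mean_rgb)) ||
      any(mean_rgb < 0) || any(mean_rgb > 1)) {
    abort("`mean_rgb` must be three finite values in [0, 1].")
  }
  if (any(rgb_jitter_sd < 0) || any(rgb_jitter_sd >= 0.5)) {
    abort("`rgb_jitter_sd` must be non-negative and below 0.5.")
  }
  structure(
    list(mean_rgb = mean_rgb, rgb_jitter_sd = rgb_jitter_sd,
         name = as.character(name)),
    class = "powder_palette"
  )
}

#' @export
print.powder_palette <- function(x, ...) {
  cat(sprintf("<powder_palette> %s  mean RGB (%.2f, %.2f, %.2f)  jitter sd (%.3f, %.3f, %.3f)\n",
              x$name, x$mean_rgb[1], x$mean_rgb[2], x$mean_rgb[3],
              x$rgb_jitter_sd[1], x$rgb_jitter_sd[2], x$rgb_jitter_sd[3]))
  invisible(x)
}

#' Default material palettes
#'
#' `black_pepper_palette()` and `red_pepper_palette()` are anchored to the
#' measured mean RGB of the pure (0% adulterated) powders; the red-pepper
#' blue channel is back-solved from the reported mean gray value under
#' BT.601 luma weights. `sea_foam_palette()` is the light whitish adulterant
#' (meerschaum); its mean is a calibration default obtained by linearly
#' extrapolating the observed gray trend of adulterated pepper to a
#' hypothetical 100% level, not a measured value.
#'
#' @return A [powder_palette()].
#' @name default_palettes
#' @examples
#' black_pepper_palette()
NULL

#' @rdname default_palettes
#' @export
black_pepper_palette <- function() {
  powder_palette(c(0.55, 0.46, 0.33), name = "black pepper")
}

#' @rdname default_palettes
#' @export
red_pepper_palette <- function() {
  powder_palette(c(0.62, 0.37, 0.07), name = "red pepper")
}

#' @rdname default_palettes
#' @export
sea_foam_palette <- function() {
  powder_palette(c(0.87, 0.85, 0.82), name = "sea foam")
}

#' Simulation configuration
#'
#' Settings for the synthetic powder-image generator. The defaults emulate
#' the reference acquisition protocol: five adulteration levels (0, 5, 15,
#' 30 and 50% by mass), 18 images per level (90 per material), 256 x 256
#' pixel crops.
#'
#' @param levels Adulterant mass fractions in `[0, 1]`, strictly increasing.
#' @param images_per_level Images generated per level (>= 1).
#' @param image_size Integer `(H, W)`, both >= 32.
#' @param grain_scale Characteristic grain diameter in pixels.
#' @param illumination_gradient Amplitude of the smooth multiplicative
#'   illumination field, in `[0, 0.2]`; 0 disables it.
#' @param sensor_noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(images_per_level = 2, image_size = c(64, 64))
#' @export
sim_config <- function(levels = c(0, 0.05, 0.15, 0.30, 0.50),
                       images_per_level = 18,
                       image_size = c(256, 256),
                       grain_scale = 8,
                       illumination_gradient = 0.05,
                       sensor_noise_sd = 0.02,
                       seed = 1) {
  levels <- as.numeric(levels)
  if (length(levels) == 0 || any(levels < 0 | levels > 1) ||
      anyDuplicated(levels) || is.unsorted(levels, strictly = TRUE)) {
    abort("`levels` must be unique, ascending fractions in [0, 1].")
  }
  image_size <- as.integer(image_size)
  if (length(image_size) != 2 || any(image_size < 32)) {
    abort("`image_size` must be (H, W) with both dimensions >= 32.")
  }
  if (images_per_level < 1) abort("`images_per_level` must be >= 1.")
  if (illumination_gradient < 0 || illumination_gradient > 0.2) {
    abort("`illumination_gradient` must lie in [0, 0.2].")
  }
  if (sensor_noise_sd < 0) abort("`sensor_noise_sd` must be >= 0.")
  structure(
    list(levels = levels,
         images_per_level = as.integer(images_per_level),
         image_size = image_size,
         grain_scale = as.numeric(grain_scale),
         illumination_gradient = as.numeric(illumination_gradient),
         sensor_noise_sd = as.numeric(sensor_noise_sd),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Partition an H x W frame into grains: a jittered lattice of grain centres
# with spacing grain_scale, each pixel assigned to its nearest centre
# (a Voronoi mosaic restricted to the 3 x 3 cell neighbourhood).
grain_partition <- function(h, w, grain_scale) {
  gs <- max(2, grain_scale)
  ny <- ceiling(h / gs)
  nx <- ceiling(w / gs)
  cy <- outer(seq_len(ny), rep(1, nx)) * gs - gs / 2 +
    matrix(runif(ny * nx, -gs / 2, gs / 2), ny, nx)
  cx <- outer(rep(1, ny), seq_len(nx)) * gs - gs / 2 +
    matrix(runif(ny * nx, -gs / 2, gs / 2), ny, nx)
  py <- matrix(seq_len(h), h, w)
  px <- matrix(seq_len(w), h, w, byrow = TRUE)
  cell_y <- pmin(pmax(ceiling(py / gs), 1L), ny)
  cell_x <- pmin(pmax(ceiling(px / gs), 1L), nx)
  best_d <- matrix(Inf, h, w)
  best_id <- matrix(1L, h, w)
  for (dy in -1:1) {
    for (dx in -1:1) {
      gy <- pmin(pmax(cell_y + dy, 1L), ny)
      gx <- pmin(pmax(cell_x + dx, 1L), nx)
      id <- (gx - 1L) * ny + gy
      d <- (py - cy[id])^2 + (px - cx[id])^2
      upd <- d < best_d
      best_d[upd] <- d[upd]
      best_id[upd] <- id[upd]
    }
  }
  best_id
}

#' Generate one synthetic powder image
#'
#' Builds a granular mosaic: the frame is partitioned into grains of
#' characteristic size `grain_scale`; each grain is adulterant with
#' probability `w` and base material otherwise; each grain's colour is the
#' palette mean plus per-grain Gaussian jitter. A smooth zero-mean
#' multiplicative illumination tilt and additive Gaussian sensor noise are
#' then applied and the result is clipped to `[0, 1]` (sensor saturation).
#' With the illumination field off, the expected per-channel image mean is
#' the convex combination `(1 - w) * base + w * adulterant` of the palette
#' means.
#'
#' @param base,adulterant [powder_palette()] objects.
#' @param w Adulterant fraction in `[0, 1]`.
#' @param cfg A [sim_config()] (image size, grain scale, noise settings).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (as when called from [generate_dataset()]).
#' @return An `H x W x 3` numeric array with values in `[0, 1]`.
#' @examples
#' img <- generate_powder_image(black_pepper_palette(), sea_foam_palette(),
#'                              w = 0.3, cfg = sim_config(image_size = c(64, 64)),
#'                              seed = 7)
#' dim(img)
#' @export
generate_powder_image <- function(base, adulterant, w, cfg = sim_config(),
                                  seed = NULL) {
  if (!inherits(base, "powder_palette") || !inherits(adulterant, "powder_palette")) {
    abort("`base` and `adulterant` must be powder_palette objects.")
  }
  if (!is.numeric(w) || length(w) != 1 || is.na(w) || w < 0 || w > 1) {
    abort("`w` must be a single fraction in [0, 1].")
  }
  if (!inherits(cfg, "sim_config")) abort("`cfg` must be a sim_config.")
  if (!is.null(seed)) {
    return(with_seed(seed, generate_powder_image(base, adulterant, w, cfg)))
  }
  h <- cfg$image_size[1]
  w_px <- cfg$image_size[2]
  grains <- grain_partition(h, w_px, cfg$grain_scale)
  n_grain <- max(grains)
  is_adu <- rbinom(n_grain, 1, w) == 1
  img <- array(0, c(h, w_px, 3))
  for (ch in 1:3) {
    mu <- ifelse(is_adu, adulterant$mean_rgb[ch], base$mean_rgb[ch])
    jit <- ifelse(is_adu, adulterant$rgb_jitter_sd[ch], base$rgb_jitter_sd[ch])
    gcol <- mu + rnorm(n_grain) * jit
    img[, , ch] <- matrix(gcol[grains], h, w_px)
  }
  if (cfg$illumination_gradient > 0) {
    theta <- runif(1, 0, 2 * pi)
    u <- matrix(seq_len(h) / h - 0.5, h, w_px)
    v <- matrix(seq_len(w_px) / w_px - 0.5, h, w_px, byrow = TRUE)
    field <- 1 + 2 * cfg$illumination_gradient * (cos(theta) * u + sin(theta) * v)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * field
  }
  if (cfg$sensor_noise_sd > 0) {
    img <- img + rnorm(length(img)) * cfg$sensor_noise_sd
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Generate a labelled synthetic dataset
#'
#' Generates `images_per_level` images at every adulteration level of `cfg`
#' and labels them with class indices `1..K` in level order (class 1 is the
#' pure material). At the defaults this yields the reference design of 90
#' images per material: 18 at each of 0, 5, 15, 30 and 50% adulteration.
#'
#' @inheritParams generate_powder_image
#' @return A tibble with one row per image: `sample_id`, `class_index`
#'   (1..K), `level` (adulterant fraction) and `image` (list-column of
#'   `H x W x 3` arrays). The seed used is stored in attribute `seed_used`.
#' @examples
#' ds <- generate_dataset(black_pepper_palette(), sea_foam_palette(),
#'                        sim_config(images_per_level = 1, image_size = c(64, 64)))
#' nrow(ds)
#' @export
generate_dataset <- function(base, adulterant, cfg = sim_config()) {
  if (!inherits(cfg, "sim_config")) abort("`cfg` must be a sim_config.")
  grid <- tidyr::expand_grid(
    class_index = seq_along(cfg$levels),
    replicate = seq_len(cfg$images_per_level)
  )
  grid$level <- cfg$levels[grid$class_index]
  images <- with_seed(cfg$seed, {
    purrr::map(seq_len(nrow(grid)), function(i) {
      generate_powder_image(base, adulterant, grid$level[i], cfg)
    })
  })
  out <- tibble::tibble(
    sample_id = sprintf("%s_L%02d_%02d", gsub("\\s+", "_", base$name),
                        round(grid$level * 100), grid$replicate),
    class_index = as.integer(grid$class_index),
    level = grid$level,
    image = images
  )
  attr(out, "seed_used") <- cfg$seed
  out
}

#' Write / read an image set as PNG files plus a CSV manifest
#'
#' `write_image_set()` stores every image as an 8-bit PNG named
#' `<material>_L<level%>_<index>.png` and a `manifest.csv` with columns
#' `filename`, `class_index`, `level_fraction`, `seed`. `read_image_set()`
#' reads the manifest and PNGs back into the tibble layout of
#' [generate_dataset()]. The 8-bit quantisation means a written-then-read
#' image matches the original to within 1/255 per channel.
#'
#' @param dataset A tibble from [generate_dataset()].
#' @param dir Output (input) directory; created if missing.
#' @return `write_image_set()` returns the manifest tibble invisibly;
#'   `read_image_set()` returns the dataset tibble.
#' @export
write_image_set <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- attr(dataset, "seed_used")
  manifest <- tibble::tibble(
    filename = paste0(dataset$sample_id, ".png"),
    class_index = dataset$class_index,
    level_fraction = dataset$level,
    seed = if (is.null(seed)) NA_integer_ else seed
  )
  purrr::walk2(dataset$image, manifest$filename, function(img, fn) {
    png::writePNG(img, file.path(dir, fn))
  })
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' @rdname write_image_set
#' @export
read_image_set <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) abort(paste0("no manifest.csv under ", dir))
  manifest <- readr::read_csv(path, show_col_types = FALSE)
  out <- tibble::tibble(
    sample_id = sub("\\.png$", "", manifest$filename),
    class_index = as.integer(manifest$class_index),
    level = manifest$level_fraction,
    image = purrr::map(manifest$filename, function(fn) {
      img <- png::readPNG(file.path(dir, fn))
      if (length(dim(img)) == 2) img <- array(img, c(dim(img), 3))
      img[, , 1:3, drop = FALSE]
    })
  )
  if (nrow(manifest) > 0 && !is.na(manifest$seed[1])) {
    attr(out, "seed_used") <- manifest$seed[1]
  }
  out
}
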