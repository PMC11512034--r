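# Shared fixtures: noiseless palettes, small simulation configs, synthetic
# feature tables, random confusion matrices.

flat_palette <- function(rgb, name = "flat") {
  powder_palette(rgb, rgb_jitter_sd = c(0, 0, 0), name = name)
}

# Small, fast simulation settings; override any field via ...
tiny_sim <- function(...) {
  args <- list(...)
  defaults <- list(images_per_level = 2, image_size = c(64, 64), seed = 42)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Noise-free settings: constant grains, no illumination, no sensor noise.
clean_sim <- function(...) {
  tiny_sim(illumination_gradient = 0, sensor_noise_sd = 0, ...)
}

# Gaussian-blob feature table: K classes, d features, class centres
# `sep` apart on every informative dimension.
blob_table <- function(n_per_class = 20, n_classes = 5, n_features = 2,
                       sep = 4, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    cls <- rep(seq_len(n_classes), each = n_per_class)
    x <- matrix(rnorm(length(cls) * n_features, sd = sd),
                ncol = n_features)
    x <- x + sep * matrix(cls, length(cls), n_features)
    tbl <- tibble::as_tibble(as.data.frame(x))
    names(tbl) <- paste0("f", seq_len(n_features))
    dplyr::bind_cols(
      tibble::tibble(sample_id = paste0("s", seq_along(cls)),
                     class_index = cls),
      tbl
    )
  })
}

# Feature table whose first feature equals the class index exactly and
# whose remaining features are pure noise.
informative_table <- function(n_per_class = 12, n_classes = 5,
                              n_noise = 9, seed = 1, duplicate_first = FALSE) {
  withr::with_seed(seed, {
    cls <- rep(seq_len(n_classes), each = n_per_class)
    tbl <- tibble::tibble(class_index = cls,
                          signal = as.numeric(cls) + rnorm(length(cls), sd = 1e-3))
    if (duplicate_first) tbl$signal_copy <- tbl$signal
    noise <- matrix(rnorm(length(cls) * n_noise), ncol = n_noise)
    colnames(noise) <- paste0("noise", seq_len(n_noise))
    dplyr::bind_cols(tbl, tibble::as_tibble(as.data.frame(noise)))
  })
}

# Random confusion matrix with n samples spread over K^2 cells.
random_confusion <- function(n_classes = 5, n = 90, seed = 1) {
  withr::with_seed(seed, {
    truth <- sample.int(n_classes, n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.7, truth, sample.int(n_classes, n, replace = TRUE))
    confusion(truth, pred, n_classes)
  })
}

# Naive pair-enumeration GLCM oracle (independent of glcm_compute).
glcm_bruteforce <- function(plane, levels, offsets, symmetric = TRUE) {
  mn <- min(plane); mx <- max(plane)
  q <- if (mx > mn) pmin(floor((plane - mn) / (mx - mn) * levels), levels - 1)
  else matrix(0, nrow(plane), ncol(plane))
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(plane))) {
    for (cl in seq_len(ncol(plane))) {
      for (off in offsets) {
        r2 <- r + off[1]; c2 <- cl + off[2]
        if (r2 >= 1 && r2 <= nrow(plane) && c2 >= 1 && c2 <= ncol(plane)) {
          counts[q[r, cl] + 1, q[r2, c2] + 1] <-
            counts[q[r, cl] + 1, q[r2, c2] + 1] + 1
        }
      }
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}
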