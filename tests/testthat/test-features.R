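test_that("channel_stats follows the zero-variance and moment conventions", {
  const <- channel_stats(matrix(0.4, 5, 5))
  expect_equal(const[["mean"]], 0.4)
  expect_equal(const[["median"]], 0.4)
  expect_equal(const[["mode"]], 0.4)
  expect_equal(const[["min"]], 0.4)
  expect_equal(const[["max"]], 0.4)
  expect_equal(unname(const[c("std", "cv", "skewness", "kurtosis")]),
               rep(0, 4))

  twopoint <- channel_stats(matrix(c(0, 0, 1, 1), 2))
  expect_equal(twopoint[["mean"]], 0.5)
  expect_equal(twopoint[["std"]], sqrt(1 / 3), tolerance = 1e-9) # n-1 variant
  expect_equal(twopoint[["skewness"]], 0)
  expect_equal(twopoint[["kurtosis"]], 1.0) # non-excess

  expect_error(channel_stats(numeric(0)), "non-empty")
})

test_that("kurtosis of a large Gaussian plane approaches 3 (non-excess scale)", {
  plane <- withr::with_seed(7, matrix(rnorm(256^2, sd = 0.1), 256, 256))
  expect_equal(channel_stats(plane)[["kurtosis"]], 3, tolerance = 0.1 / 3)
})

test_that("histogram entropy spans 0 to log2(bins)", {
  expect_equal(histogram_entropy(matrix(1, 4, 4)), 0)
  # 256 distinct values spread uniformly fill every bin equally
  uniform <- matrix(rep(seq(0, 1, length.out = 256), each = 4), 32, 32)
  expect_equal(histogram_entropy(uniform), 8.0)
  expect_equal(histogram_entropy(matrix(c(0, 0, 1, 1), 2)), 1.0)
  expect_error(histogram_entropy(matrix(1), bins = 1), ">= 2")
})

test_that("glcm_compute matches hand-enumerated pair counts", {
  g <- glcm_compute(matrix(c(0, 0, 1, 1), 2, byrow = TRUE), levels = 2,
                    offsets = list(c(0, 1)))
  expect_equal(g$matrix, matrix(c(0.5, 0, 0, 0.5), 2))

  g2 <- glcm_compute(matrix(c(0, 1, 1, 0), 2, byrow = TRUE), levels = 2,
                     offsets = list(c(0, 1)))
  expect_equal(g2$matrix, matrix(c(0, 0.5, 0.5, 0), 2))

  gc <- glcm_compute(matrix(1, 3, 3), levels = 4)
  expect_equal(gc$matrix[1, 1], 1)
  expect_equal(sum(gc$matrix), 1)
})

test_that("glcm_compute agrees exactly with brute-force enumeration", {
  offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  for (seed in 1:20) {
    dims <- withr::with_seed(seed, sample(2:5, 2, replace = TRUE))
    lev <- withr::with_seed(seed + 100, sample(2:4, 1))
    plane <- withr::with_seed(seed + 200,
                              matrix(runif(prod(dims)), dims[1], dims[2]))
    got <- glcm_compute(plane, levels = lev, offsets = offsets)$matrix
    want <- glcm_bruteforce(plane, lev, offsets)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("glcm_features evaluates the closed forms", {
  perfect <- glcm_compute(matrix(c(0, 0, 1, 1), 2, byrow = TRUE), levels = 2,
                          offsets = list(c(0, 1)))
  expect_equal(glcm_features(perfect),
               c(energy = 0.5, contrast = 0, correlation = 1, homogeneity = 1))

  anti <- glcm_compute(matrix(c(0, 1, 1, 0), 2, byrow = TRUE), levels = 2,
                       offsets = list(c(0, 1)))
  expect_equal(glcm_features(anti),
               c(energy = 0.5, contrast = 1, correlation = -1,
                 homogeneity = 0.5))

  const <- glcm_compute(matrix(0.3, 4, 4), levels = 8)
  expect_equal(glcm_features(const),
               c(energy = 1, contrast = 0, correlation = 1, homogeneity = 1))
})

test_that("texture feature bounds hold on random planes", {
  for (seed in 1:10) {
    plane <- withr::with_seed(seed, matrix(runif(15 * 15), 15, 15))
    f <- glcm_features(glcm_compute(plane))
    expect_true(f[["energy"]] > 0 && f[["energy"]] <= 1)
    expect_true(f[["homogeneity"]] > 0 && f[["homogeneity"]] <= 1)
    expect_true(abs(f[["correlation"]]) <= 1)
    expect_gte(f[["contrast"]], 0)
    e <- histogram_entropy(plane)
    expect_true(e >= 0 && e <= 8)
    expect_equal(sum(glcm_compute(plane)$matrix), 1, tolerance = 1e-9)
  }
})

test_that("extract_features yields 266 canonically named values", {
  stack <- to_channels(array(runif(16 * 16 * 3), c(16, 16, 3)))
  v <- extract_features(stack)
  expect_length(v, 266)
  expected_names <- as.vector(vapply(channel_names(), function(ch) {
    paste0(stat_names(), "_", ch)
  }, character(14)))
  expect_identical(names(v), expected_names)
})

test_that("degenerate and channel-independence feature properties hold", {
  v <- extract_features(to_channels(array(0.5, c(16, 16, 3))))
  # BT.601 luma weights sum to 0.9999, not 1, so the constant is recovered
  # to that accuracy
  expect_equal(v[["mean_gray"]], 0.5, tolerance = 1e-3)
  expect_true(all(v[paste0("contrast_", channel_names())] == 0))
  expect_true(all(v[paste0("energy_", channel_names())] == 1))

  img <- withr::with_seed(3, array(runif(16 * 16 * 3, 0.2, 0.6), c(16, 16, 3)))
  shifted <- img
  shifted[, , 3] <- shifted[, , 3] + 0.2
  a <- extract_features(to_channels(img))
  b <- extract_features(to_channels(shifted))
  r_feats <- paste0(stat_names(), "_R")
  expect_equal(a[r_feats], b[r_feats])
})

test_that("feature tables extract per image and round-trip through CSV", {
  ds <- generate_dataset(black_pepper_palette(), sea_foam_palette(),
                         tiny_sim(levels = c(0, 0.5)))
  ft <- extract_feature_table(ds, keep_fraction = 0.8)
  expect_equal(nrow(ft), 4)
  expect_equal(ncol(ft), 3 + 266)
  expect_identical(names(ft)[1:3], c("sample_id", "class_index", "level"))

  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_identical(names(back), c("sample_id", "class_index",
                                  setdiff(names(ft), c("sample_id", "class_index", "level"))))
  expect_equal(as.matrix(back[-(1:2)]), as.matrix(ft[-(1:3)]),
               tolerance = 1e-12, ignore_attr = TRUE)
})
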