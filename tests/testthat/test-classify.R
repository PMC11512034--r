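test_that("stratified 60/20/20 split of 90 samples gives exactly 54/18/18", {
  tbl <- blob_table(n_per_class = 18, n_classes = 5, n_features = 3, seed = 2)
  sp <- split_dataset(tbl, c(0.6, 0.2, 0.2), seed = 7)
  expect_equal(vapply(sp, nrow, 0L),
               c(train = 54L, validation = 18L, test = 18L))
  # per-class counts within one sample of the target fractions
  for (part in sp) {
    counts <- table(factor(part$class_index, levels = 1:5))
    expect_true(all(counts >= floor(18 * nrow(part) / 90)))
    expect_true(all(counts <= ceiling(18 * nrow(part) / 90)))
  }
  # disjoint and exhaustive
  ids <- unlist(lapply(sp, function(p) p$sample_id))
  expect_setequal(ids, tbl$sample_id)
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("degenerate and repeated splits behave per contract", {
  tbl <- blob_table(n_per_class = 10, n_classes = 3, seed = 3)
  all_train <- split_dataset(tbl, c(1, 0, 0), seed = 1)
  expect_equal(nrow(all_train$train), nrow(tbl))
  expect_equal(nrow(all_train$validation), 0L)

  a <- split_dataset(tbl, c(0.6, 0.2, 0.2), seed = 5)
  b <- split_dataset(tbl, c(0.6, 0.2, 0.2), seed = 5)
  expect_identical(a, b)

  tiny <- dplyr::slice(tbl, 1:2) # one class, two samples
  expect_error(split_dataset(tiny, c(0.4, 0.3, 0.3)), "infeasible")
  expect_error(split_dataset(tbl, c(0.5, 0.5, 0.5)), "summing to 1")
})

test_that("the MLP separates well-separated blobs", {
  ccrs <- vapply(1:10, function(seed) {
    tbl <- blob_table(n_per_class = 18, n_classes = 5, n_features = 2,
                      sep = 4, seed = seed)
    sp <- split_dataset(tbl, c(0.6, 0.2, 0.2), seed = seed)
    m <- train_mlp(sp$train, sp$validation, hidden_size = 13,
                   cfg = mlp_config(seed = seed))
    mean(predict(m, sp$test) == sp$test$class_index)
  }, numeric(1))
  expect_gte(mean(ccrs), 0.95)
})

test_that("MLP output layer width equals the number of classes", {
  tbl <- blob_table(n_per_class = 8, n_classes = 5, seed = 4)
  m <- train_mlp(tbl, NULL, hidden_size = 3,
                 cfg = mlp_config(max_epochs = 30))
  raw <- predict(m, tbl, type = "raw")
  expect_equal(ncol(raw), 5)
  expect_true(all(raw > -1 & raw < 1)) # tanh output units
})

test_that("constant features stall training: patience halts it early", {
  tbl <- tibble::tibble(class_index = rep(1:3, each = 8), f1 = 1, f2 = 2)
  sp <- split_dataset(tbl, c(0.5, 0.25, 0.25), seed = 1)
  m <- train_mlp(sp$train, sp$validation, hidden_size = 4,
                 cfg = mlp_config(max_epochs = 2000, patience = 15))
  expect_lt(nrow(m$log), 2000)
  expect_equal(length(unique(predict(m, tbl))), 1L)
})

test_that("the structure sweep records every size and applies the tie-break", {
  tbl <- blob_table(n_per_class = 12, n_classes = 4, n_features = 2, seed = 6)
  sp <- split_dataset(tbl, c(0.6, 0.2, 0.2), seed = 6)
  cfg <- mlp_config(hidden_sizes = 1:5, max_epochs = 150, seed = 6)
  sw <- sweep_structures(sp$train, sp$validation, sp$test, cfg)
  expect_equal(nrow(sw$records), 5)
  expect_equal(max(sw$records$overall_ccr),
               sw$records$overall_ccr[sw$records$hidden_size == sw$chosen_hidden_size])
  expect_s3_class(tidy(sw), "tbl_df")
  expect_equal(glance(sw)$chosen_hidden_size, sw$chosen_hidden_size)

  single <- sweep_structures(sp$train, sp$validation, sp$test,
                             mlp_config(hidden_sizes = 3, max_epochs = 100))
  expect_equal(single$chosen_hidden_size, 3L)
})

test_that("one-vs-one SVM trains K(K-1)/2 machines and fits separable data", {
  tbl <- blob_table(n_per_class = 12, n_classes = 5, n_features = 2,
                    sep = 4, seed = 8)
  m <- train_svm_ovo(tbl, svm_config(cost = 1000))
  expect_equal(length(m$machines), 10) # 5 * 4 / 2
  expect_equal(mean(predict(m, tbl) == tbl$class_index), 1) # 100% train CCR
  expect_error(train_svm_ovo(dplyr::filter(tbl, class_index == 1)),
               "2 classes")
})

test_that("indistinguishable classes classify at chance level", {
  tbl <- withr::with_seed(10, tibble::tibble(
    sample_id = paste0("s", 1:200),
    class_index = rep(1:2, each = 100),
    f1 = rnorm(200), f2 = rnorm(200) # identical distributions
  ))
  sp <- split_dataset(tbl, c(0.8, 0, 0.2), seed = 10)
  m <- train_svm_ovo(sp$train, svm_config(cost = 1))
  ccr <- mean(predict(m, sp$test) == sp$test$class_index)
  expect_true(ccr > 0.25 && ccr < 0.75) # binomial noise around 1/2
})

test_that("label shuffling drops the MLP to chance level", {
  tbl <- blob_table(n_per_class = 30, n_classes = 3, n_features = 2,
                    sep = 4, seed = 12)
  tbl$class_index <- withr::with_seed(12, sample(tbl$class_index))
  sp <- split_dataset(tbl, c(0.6, 0.2, 0.2), seed = 12)
  m <- train_mlp(sp$train, sp$validation, hidden_size = 5,
                 cfg = mlp_config(max_epochs = 200, seed = 12))
  ccr <- mean(predict(m, sp$test) == sp$test$class_index)
  expect_lt(ccr, 1 / 3 + 0.35)
})

test_that("classifiers are invariant to rescaling and (SVM) reordering features", {
  tbl <- blob_table(n_per_class = 10, n_classes = 3, n_features = 4,
                    sep = 3, seed = 14)
  sp <- split_dataset(tbl, c(0.6, 0.2, 0.2), seed = 14)

  rescaled <- purrr::map(sp, function(p) dplyr::mutate(p, f2 = 10 * f2 + 5))
  m1 <- train_mlp(sp$train, sp$validation, 4, mlp_config(max_epochs = 100))
  m2 <- train_mlp(rescaled$train, rescaled$validation, 4,
                  mlp_config(max_epochs = 100))
  expect_equal(predict(m1, sp$test), predict(m2, rescaled$test))

  s1 <- train_svm_ovo(sp$train)
  s2 <- train_svm_ovo(rescaled$train)
  expect_equal(predict(s1, sp$test), predict(s2, rescaled$test))

  permuted <- sp$train[c("sample_id", "class_index", "f4", "f2", "f1", "f3")]
  s3 <- train_svm_ovo(permuted)
  expect_equal(predict(s3, sp$test), predict(s1, sp$test))
})
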