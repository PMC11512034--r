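# The reference 90-sample matrices described in the published text:
# diagonal counts per class plus the stated misclassification placements.
svm_black_matrix <- function() {
  m <- diag(c(17, 16, 16, 18, 18))
  m[1, 2] <- 1; m[2, 3] <- 2; m[3, 2] <- 2
  as_confusion(m)
}
svm_red_matrix <- function() {
  m <- diag(c(16, 18, 18, 18, 18))
  m[1, 2] <- 2
  as_confusion(m)
}

test_that("confusion counts samples into true x predicted cells", {
  cm <- confusion(rep(1:5, each = 18), rep(1:5, each = 18))
  expect_equal(unname(diag(cm$counts)), rep(18L, 5))
  expect_equal(sum(cm$counts), 90L)

  one_err <- confusion(c(1, rep(1:5, each = 2)), c(2, rep(1:5, each = 2)))
  expect_equal(one_err$counts[1, 2], 1L)

  expect_error(confusion(integer(0), integer(0)), "non-empty")
  expect_error(confusion(1:3, c(1, 2, 9), n_classes = 5), "1..n_classes")
})

test_that("class_counts decomposes matrices one-vs-rest", {
  perfect <- confusion(rep(1:5, each = 18), rep(1:5, each = 18))
  expect_equal(class_counts(perfect, 1),
               c(N_TP = 18, N_FP = 0, N_TN = 72, N_FN = 0))

  red <- svm_red_matrix() # 2 pure-material samples called 5% level
  expect_equal(class_counts(red, 1),
               c(N_TP = 16, N_FP = 0, N_TN = 72, N_FN = 2))
  expect_equal(class_counts(red, 2),
               c(N_TP = 18, N_FP = 2, N_TN = 70, N_FN = 0))
  expect_equal(sum(class_counts(red, 3)), 90)
})

test_that("metrics reproduce the published confusion-matrix arithmetic", {
  svm_black <- metrics(svm_black_matrix()) # 85 of 90 correct
  expect_equal(render_percent(svm_black$overall_ccr, 2), 94.44)

  # macro per-class accuracy depends only on the error count:
  # (K*N - 2E) / (K*N), here K = 5, N = 90, E = 4
  e4 <- diag(c(17, 17, 17, 17, 18))
  e4[1, 2] <- 1; e4[2, 3] <- 1; e4[3, 4] <- 1; e4[4, 5] <- 1
  e4 <- as_confusion(e4)
  expect_equal(sum(e4$counts), 90)
  expect_equal(render_percent(metrics(e4)$macro[["accuracy"]], 2), 98.22)

  all_right <- metrics(confusion(rep(1:5, 4), rep(1:5, 4)))
  expect_true(all(all_right$per_class$accuracy == 100))
  expect_true(all(unlist(all_right[c("macro", "micro")]) == 100))
  expect_equal(all_right$overall_ccr, 100)
})

test_that("macro accuracy is placement-independent: (K*N - 2E)/(K*N)", {
  for (seed in 1:10) {
    cm <- random_confusion(n_classes = 5, n = 90, seed = seed)
    rep <- metrics(cm)
    k <- 5; n <- 90; e <- rep$n_errors
    expect_equal(rep$macro[["accuracy"]], (k * n - 2 * e) / (k * n) * 100)
  }
})

test_that("micro precision and sensitivity equal the overall CCR", {
  for (seed in 1:25) {
    rep <- metrics(random_confusion(n_classes = sample(2:6, 1), seed = seed))
    expect_equal(rep$micro[["precision"]], rep$overall_ccr)
    expect_equal(rep$micro[["sensitivity"]], rep$overall_ccr)
    expect_true(all(rep$per_class$specificity[rep$per_class$N_FP == 0] == 100))
    vals <- unlist(rep$per_class[c("accuracy", "precision",
                                   "sensitivity", "specificity")])
    expect_true(all(vals >= 0 & vals <= 100))
  }
})

test_that("metrics(confusion(x, x)) is perfect for any labelling", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, sample.int(4, 30, replace = TRUE))
    rep <- metrics(confusion(x, x, 4))
    expect_equal(rep$overall_ccr, 100)
    expect_true(all(rep$per_class$accuracy == 100))
  }
})

test_that("overall correlation follows the Pearson contract", {
  y <- one_hot_targets <- diag(5)[rep(1:5, 10), ]
  expect_equal(overall_correlation(y, y), 1)
  expect_equal(overall_correlation(y, 1 - y), -1)
  expect_equal(overall_correlation(y, matrix(0.3, nrow(y), 5)), 0)
  r <- withr::with_seed(2, overall_correlation(y, matrix(runif(250), , 5)))
  expect_lt(abs(r), 0.15)
})

test_that("render_percent reproduces both printed conventions", {
  x <- 88 / 90 * 100
  expect_equal(render_percent(x, 1), 97.8)
  expect_equal(render_percent(x, 2, style = "truncate"), 97.77)
  expect_equal(render_percent(94.4444, 2), 94.44)
})

test_that("the summary table mirrors the published layout", {
  perfect <- metrics(confusion(rep(1:5, 18), rep(1:5, 18)))
  svm_black <- metrics(svm_black_matrix())
  sm <- metrics_summary(list("black pepper.ANN" = perfect,
                             "black pepper.SVM" = svm_black))
  expect_named(sm, c("material", "method", "accuracy", "precision",
                     "sensitivity", "specificity", "overall_ccr"))
  expect_equal(unlist(sm[1, 3:7]), rep(100, 5), ignore_attr = TRUE)
  expect_equal(sm$overall_ccr[2], 94.44)

  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(sm, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(sm))
})

test_that("tidy and glance views of reports are consistent", {
  rep <- metrics(svm_red_matrix())
  expect_equal(nrow(tidy(rep)), 5)
  g <- glance(rep)
  expect_equal(g$overall_ccr, rep$overall_ccr)
  expect_equal(g$n_errors, 2L)
  td <- tidy(svm_red_matrix())
  expect_equal(sum(td$count), 90)
})
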