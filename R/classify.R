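# Classifier protocols: stratified splitting, a tanh-sigmoid MLP with a
# hidden-layer-size sweep, and a one-vs-one Gaussian-kernel SVM.

#' Stratified random split of a feature table
#'
#' Partitions a feature table into disjoint, exhaustive train / validation /
#' test sets. Under stratification, class proportions in every partition
#' match the requested fractions to within one sample: the per-class counts
#' are chosen by cumulative largest-remainder rounding so the global totals
#' also land on the requested fractions (90 samples at 0.6/0.2/0.2 give
#' exactly 54/18/18).
#'
#' @param table A feature table with a `class_index` column.
#' @param fractions Length-3 non-negative `(train, validation, test)`
#'   fractions summing to 1; validation may be 0.
#' @param stratified Stratify on class?
#' @param seed Integer seed; same seed, same partition.
#' @return Named list of tibbles `train`, `validation`, `test`.
#' @examples
#' tbl <- tibble::tibble(class_index = rep(1:2, each = 10), f = rnorm(20))
#' sp <- split_dataset(tbl, c(0.6, 0.2, 0.2), seed = 1)
#' sapply(sp, nrow)
#' @export
split_dataset <- function(table, fractions = c(0.6, 0.2, 0.2),
                          stratified = TRUE, seed = 1) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    abort("`fractions` must be three non-negative values summing to 1.")
  }
  cls <- class_vector(table)
  groups <- if (stratified) split(seq_len(nrow(table)), cls) else
    list(seq_len(nrow(table)))

  assign <- integer(nrow(table))
  prev <- c(0, 0, 0)
  cum_n <- 0
  with_seed(seed, {
    for (idx in groups) {
      cum_n <- cum_n + length(idx)
      target <- fractions * cum_n
      alloc <- floor(target)
      rem <- target - alloc
      leftover <- cum_n - sum(alloc)
      if (leftover > 0) {
        take <- order(rem, decreasing = TRUE)[seq_len(leftover)]
        alloc[take] <- alloc[take] + 1
      }
      counts <- alloc - prev
      if (any(counts < 0)) { # pathological fractions; fall back within group
        counts <- pmax(counts, 0)
        counts[1] <- length(idx) - sum(counts[-1])
      }
      if (any(counts == 0 & fractions > 0)) {
        abort("stratified split infeasible: a class has too few samples for a non-empty partition.")
      }
      prev <- alloc
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep(1:3, times = counts)
    }
  })
  list(train = table[assign == 1, , drop = FALSE],
       validation = table[assign == 2, , drop = FALSE],
       test = table[assign == 3, , drop = FALSE])
}

#' Neural-network training configuration
#'
#' Settings for [train_mlp()] and [sweep_structures()]. The network is a
#' single-hidden-layer feedforward net with tanh-sigmoid activation on both
#' the hidden and the output layer, trained to minimise mean squared error
#' against 0/1 one-hot targets, with early stopping on the validation error.
#'
#' @param hidden_sizes Hidden-layer sizes to sweep (default 1..20).
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience: training halts after this many
#'   epochs without a new validation-error minimum.
#' @param learn_rate Step size of the full-batch Adam optimiser.
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `mlp_config`.
#' @export
mlp_config <- function(hidden_sizes = 1:20, max_epochs = 400, patience = 25,
                       learn_rate = 0.05, seed = 1) {
  if (length(hidden_sizes) == 0 || any(hidden_sizes < 1)) {
    abort("`hidden_sizes` must be a non-empty set of sizes >= 1.")
  }
  if (patience < 1) abort("`patience` must be >= 1.")
  structure(
    list(hidden_sizes = as.integer(hidden_sizes),
         max_epochs = as.integer(max_epochs),
         patience = as.integer(patience),
         learn_rate = as.numeric(learn_rate),
         seed = as.integer(seed)),
    class = "mlp_config"
  )
}

mlp_forward <- function(x, w1, b1, w2, b2) {
  z <- tanh(sweep(x %*% w1, 2, b1, "+"))
  list(hidden = z, output = tanh(sweep(z %*% w2, 2, b2, "+")))
}

#' Train a tanh-sigmoid MLP with validation early stopping
#'
#' Fits a single-hidden-layer feedforward network (tanh-sigmoid hidden and
#' output units) to one-hot 0/1 class targets by full-batch minimisation of
#' the mean squared error (Adam optimiser). After every epoch the validation
#' MSE is recorded; the returned weights are those of the epoch with the
#' lowest validation error, and training halts once `patience` epochs pass
#' without improvement. Features are z-scored with training-set statistics.
#'
#' @param train,validation Feature tables; `validation` may be `NULL`, in
#'   which case training runs for `max_epochs` with no early stopping.
#' @param hidden_size Number of hidden units (>= 1).
#' @param cfg An [mlp_config()].
#' @param n_classes Number of classes (defaults to the maximum label seen).
#' @return An object of class `mlp_model` with the fitted weights, the
#'   standardisation statistics, a per-epoch `log` tibble (`epoch`,
#'   `train_mse`, `validation_mse`) and `best_epoch`.
#' @examples
#' tbl <- tibble::tibble(class_index = rep(1:2, each = 20),
#'                       f1 = rnorm(40, rep(c(0, 3), each = 20)))
#' m <- train_mlp(tbl, NULL, hidden_size = 2,
#'                cfg = mlp_config(max_epochs = 50, seed = 1))
#' mean(predict(m, tbl) == tbl$class_index)
#' @export
train_mlp <- function(train, validation = NULL, hidden_size,
                      cfg = mlp_config(), n_classes = NULL) {
  if (nrow(train) == 0) abort("`train` is empty.")
  if (hidden_size < 1) abort("`hidden_size` must be >= 1.")
  feats <- feature_cols(train)
  cls <- class_vector(train)
  if (is.null(n_classes)) {
    n_classes <- max(cls, if (!is.null(validation) && nrow(validation) > 0)
      class_vector(validation) else 1L)
  }
  x <- feature_matrix(train)
  st <- standardize_fit(x)
  x <- standardize_apply(x, st)
  y <- one_hot(cls, n_classes)
  has_val <- !is.null(validation) && nrow(validation) > 0
  if (has_val) {
    xv <- standardize_apply(feature_matrix(validation), st)
    yv <- one_hot(class_vector(validation), n_classes)
  }
  d <- ncol(x); h <- as.integer(hidden_size); k <- n_classes
  n <- nrow(x)

  with_seed(cfg$seed + 101L * h, {
    r1 <- sqrt(6 / (d + h)); r2 <- sqrt(6 / (h + k))
    w1 <- matrix(runif(d * h, -r1, r1), d, h); b1 <- rep(0, h)
    w2 <- matrix(runif(h * k, -r2, r2), h, k); b2 <- rep(0, k)
  })
  params <- list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
  m <- v <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best <- list(err = Inf, epoch = 0L, params = params)
  log_train <- log_val <- numeric(0)
  stall <- 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    fwd <- mlp_forward(x, params$w1, params$b1, params$w2, params$b2)
    err <- fwd$output - y
    train_mse <- mean(err^2)
    # backprop of MSE through the two tanh layers
    d_out <- 2 * err * (1 - fwd$output^2) / (n * k)
    g_w2 <- t(fwd$hidden) %*% d_out
    g_b2 <- colSums(d_out)
    d_hid <- (d_out %*% t(params$w2)) * (1 - fwd$hidden^2)
    g_w1 <- t(x) %*% d_hid
    g_b1 <- colSums(d_hid)
    grads <- list(w1 = g_w1, b1 = g_b1, w2 = g_w2, b2 = g_b2)
    t_adam <- epoch
    for (nm in names(params)) {
      m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
      v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
      mhat <- m[[nm]] / (1 - beta1^t_adam)
      vhat <- v[[nm]] / (1 - beta2^t_adam)
      params[[nm]] <- params[[nm]] - cfg$learn_rate * mhat / (sqrt(vhat) + eps)
    }
    log_train <- c(log_train, train_mse)
    if (has_val) {
      fv <- mlp_forward(xv, params$w1, params$b1, params$w2, params$b2)
      val_mse <- mean((fv$output - yv)^2)
      log_val <- c(log_val, val_mse)
      if (val_mse < best$err - 1e-12) {
        best <- list(err = val_mse, epoch = epoch, params = params)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
  }
  if (!has_val) best <- list(err = NA_real_, epoch = length(log_train),
                             params = params)
  structure(
    list(w1 = best$params$w1, b1 = best$params$b1,
         w2 = best$params$w2, b2 = best$params$b2,
         center = st$center, scale = st$scale,
         features = feats, n_classes = n_classes,
         hidden_size = h, best_epoch = best$epoch,
         best_validation_error = best$err,
         log = tibble::tibble(
           epoch = seq_along(log_train),
           train_mse = log_train,
           validation_mse = if (has_val) log_val else NA_real_)),
    class = "mlp_model"
  )
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %d-%d-%d tanh-sigmoid net, best epoch %d (val MSE %.4g)\n",
              length(x$features), x$hidden_size, x$n_classes,
              x$best_epoch, x$best_validation_error))
  invisible(x)
}

#' Predict from a fitted MLP
#'
#' @param object An `mlp_model`.
#' @param newdata A feature table containing the model's feature columns.
#' @param type `"class"` for argmax class indices, `"raw"` for the matrix
#'   of network outputs (one column per class, tanh scale).
#' @param ... Unused.
#' @return Integer class indices, or the raw output matrix.
#' @export
predict.mlp_model <- function(object, newdata, type = c("class", "raw"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata[object$features])
  x <- standardize_apply(x, list(center = object$center, scale = object$scale))
  out <- mlp_forward(x, object$w1, object$b1, object$w2, object$b2)$output
  if (type == "raw") out else max.col(out, ties.method = "first")
}

#' Sweep hidden-layer sizes and select the best structure
#'
#' Trains one network per hidden size in `cfg$hidden_sizes` (structures
#' `d-1-K` up to `d-20-K` at the defaults) and records, for each, the best
#' validation error, the overall correlation between one-hot targets and
#' network outputs, and the overall correct classification rate — both
#' "overall" quantities computed on the pooled train + validation + test
#' data. The chosen structure attains the maximum overall CCR, with ties
#' broken by lower validation error, then smaller hidden size.
#'
#' @param train,validation,test Feature tables from [split_dataset()].
#' @param cfg An [mlp_config()].
#' @return An object of class `mlp_sweep`: `records` tibble (`hidden_size`,
#'   `best_validation_error`, `overall_correlation`, `overall_ccr`),
#'   `chosen_hidden_size`, `model` (the refitted chosen network).
#' @export
sweep_structures <- function(train, validation, test, cfg = mlp_config()) {
  all_data <- dplyr::bind_rows(train, validation, test)
  truth <- class_vector(all_data)
  n_classes <- max(truth)
  fit_one <- function(h) train_mlp(train, validation, h, cfg, n_classes)
  models <- purrr::map(cfg$hidden_sizes, fit_one)
  records <- purrr::map2_dfr(models, cfg$hidden_sizes, function(m, h) {
    raw <- predict(m, all_data, type = "raw")
    pred <- max.col(raw, ties.method = "first")
    tibble::tibble(
      hidden_size = h,
      best_validation_error = m$best_validation_error,
      overall_correlation = overall_correlation(one_hot(truth, n_classes), raw),
      overall_ccr = 100 * mean(pred == truth)
    )
  })
  ord <- order(-records$overall_ccr, records$best_validation_error,
               records$hidden_size)
  chosen <- ord[1]
  structure(
    list(records = records,
         chosen_hidden_size = records$hidden_size[chosen],
         model = models[[chosen]]),
    class = "mlp_sweep"
  )
}

#' @export
print.mlp_sweep <- function(x, ...) {
  cat(sprintf("<mlp_sweep> %d structures; chosen hidden size %d (overall CCR %.2f%%)\n",
              nrow(x$records), x$chosen_hidden_size,
              x$records$overall_ccr[x$records$hidden_size == x$chosen_hidden_size][1]))
  invisible(x)
}

#' @describeIn sweep_structures The per-structure records tibble.
#' @param x An `mlp_sweep`.
#' @param ... Unused.
#' @method tidy mlp_sweep
#' @export
tidy.mlp_sweep <- function(x, ...) x$records

#' @describeIn sweep_structures One-row summary of the chosen structure.
#' @method glance mlp_sweep
#' @export
glance.mlp_sweep <- function(x, ...) {
  rec <- x$records[x$records$hidden_size == x$chosen_hidden_size, ][1, ]
  tibble::tibble(
    chosen_hidden_size = x$chosen_hidden_size,
    best_validation_error = rec$best_validation_error,
    overall_correlation = rec$overall_correlation,
    overall_ccr = rec$overall_ccr,
    n_structures = nrow(x$records)
  )
}

#' Support-vector-machine configuration
#'
#' Gaussian (RBF) kernel soft-margin SVM settings, classified one-vs-one.
#' `lambda` is folded into the solver's termination tolerance; `gamma`
#' defaults to `1 / (n_features * mean feature variance)` computed on the
#' standardised training data.
#'
#' @param cost Soft-margin penalty C.
#' @param gamma RBF kernel width; `NULL` for the data-driven default.
#' @param lambda Solver tolerance.
#' @param seed Integer seed (splits and any solver randomness).
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(cost = 1000, gamma = NULL, lambda = 1e-7, seed = 1) {
  if (cost <= 0) abort("`cost` must be > 0.")
  if (!is.null(gamma) && gamma <= 0) abort("`gamma` must be > 0.")
  structure(list(cost = cost, gamma = gamma, lambda = lambda,
                 seed = as.integer(seed)),
            class = "svm_config")
}

#' Train a one-vs-one Gaussian-kernel SVM
#'
#' Trains one binary soft-margin RBF SVM per unordered class pair
#' (`K(K-1)/2` machines for `K` classes) on z-scored features. Prediction is
#' by majority vote over the machines, with ties broken by the largest
#' summed signed decision margin and then by the lowest class index.
#'
#' @param train A feature table with >= 2 classes.
#' @param cfg An [svm_config()].
#' @param n_classes Number of classes (defaults to the maximum label seen).
#' @return An object of class `svm_ovo`.
#' @export
train_svm_ovo <- function(train, cfg = svm_config(), n_classes = NULL) {
  cls <- class_vector(train)
  if (length(unique(cls)) < 2) abort("`train` must contain at least 2 classes.")
  if (is.null(n_classes)) n_classes <- max(cls)
  feats <- feature_cols(train)
  x <- feature_matrix(train)
  st <- standardize_fit(x)
  xs <- standardize_apply(x, st)
  gamma <- cfg$gamma
  if (is.null(gamma)) {
    gamma <- 1 / (ncol(xs) * mean(apply(xs, 2, var)))
    if (!is.finite(gamma) || gamma <= 0) gamma <- 1 / ncol(xs)
  }
  present <- sort(unique(cls))
  pairs <- utils::combn(present, 2, simplify = FALSE)
  machines <- with_seed(cfg$seed, {
    purrr::map(pairs, function(pr) {
      idx <- cls %in% pr
      yf <- factor(cls[idx], levels = pr)
      e1071::svm(xs[idx, , drop = FALSE], yf, kernel = "radial",
                 gamma = gamma, cost = cfg$cost, scale = FALSE,
                 tolerance = max(cfg$lambda, 1e-7))
    })
  })
  structure(
    list(machines = machines, pairs = pairs, features = feats,
         center = st$center, scale = st$scale, gamma = gamma,
         cost = cfg$cost, n_classes = n_classes),
    class = "svm_ovo"
  )
}

#' @export
print.svm_ovo <- function(x, ...) {
  cat(sprintf("<svm_ovo> %d binary RBF machines over %d classes (C = %g, gamma = %.4g)\n",
              length(x$machines), x$n_classes, x$cost, x$gamma))
  invisible(x)
}

#' Predict from a one-vs-one SVM
#'
#' @param object An `svm_ovo` model.
#' @param newdata A feature table containing the model's feature columns.
#' @param ... Unused.
#' @return Integer class indices.
#' @export
predict.svm_ovo <- function(object, newdata, ...) {
  x <- as.matrix(newdata[object$features])
  xs <- standardize_apply(x, list(center = object$center, scale = object$scale))
  n <- nrow(xs)
  votes <- matrix(0, n, object$n_classes)
  margin <- matrix(0, n, object$n_classes)
  for (i in seq_along(object$machines)) {
    pr <- object$pairs[[i]]
    p <- predict(object$machines[[i]], xs, decision.values = TRUE)
    dv <- as.numeric(attr(p, "decision.values")) # positive -> first level pr[1]
    win1 <- as.integer(p) == 1L
    votes[cbind(seq_len(n), ifelse(win1, pr[1], pr[2]))] <-
      votes[cbind(seq_len(n), ifelse(win1, pr[1], pr[2]))] + 1
    margin[, pr[1]] <- margin[, pr[1]] + dv
    margin[, pr[2]] <- margin[, pr[2]] - dv
  }
  vapply(seq_len(n), function(i) {
    ord <- order(-votes[i, ], -margin[i, ], seq_len(object$n_classes))
    ord[1]
  }, integer(1))
}
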