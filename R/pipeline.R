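# End-to-end experiment orchestration: simulate -> crop -> channels ->
# features -> select -> train -> evaluate, fully seeded and logged.

#' Experiment configuration
#'
#' Bundles every stage's settings into one object. A single global `seed`
#' deterministically derives per-stage seeds (simulation, fold assignment,
#' splits, weight initialisation), so a rerun with the same configuration
#' reproduces the experiment bit for bit.
#'
#' @param material Material name used in reports.
#' @param base,adulterant [powder_palette()] objects.
#' @param sim A [sim_config()]; its seed is overridden by the derived
#'   stage seed.
#' @param keep_fraction Central crop fraction.
#' @param glcm_levels,entropy_bins Feature-extraction settings.
#' @param selection List with `cv_folds`, `max_features`, `tol` for
#'   [sfs_select()].
#' @param ann List with `split` (train/validation/test fractions, default
#'   60/20/20) and `config` (an [mlp_config()]).
#' @param svm List with `split` (default 80/20) and `config`
#'   (an [svm_config()]).
#' @param seed Global integer seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(material = "black pepper",
                              base = black_pepper_palette(),
                              adulterant = sea_foam_palette(),
                              sim = sim_config(),
                              keep_fraction = 0.8,
                              glcm_levels = 8,
                              entropy_bins = 256,
                              selection = list(cv_folds = 5,
                                               max_features = 20,
                                               tol = 1e-6),
                              ann = list(split = c(0.6, 0.2, 0.2),
                                         config = mlp_config()),
                              svm = list(split = c(0.8, 0, 0.2),
                                         config = svm_config()),
                              seed = 1) {
  structure(
    list(material = material, base = base, adulterant = adulterant,
         sim = sim, keep_fraction = keep_fraction,
         glcm_levels = glcm_levels, entropy_bins = entropy_bins,
         selection = selection, ann = ann, svm = svm,
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from a YAML file
#'
#' Any key omitted from the file keeps its [experiment_config()] default,
#' so a config file only needs to state what differs from the reference
#' protocol. Palettes are given as `base:`/`adulterant:` maps with
#' `mean_rgb`, optional `rgb_jitter_sd` and `name`.
#'
#' @param path Path to a YAML file.
#' @param seed Optional seed overriding the file's `seed` key.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  pal <- function(x, default) {
    if (is.null(x)) return(default)
    powder_palette(unlist(x$mean_rgb),
                   if (is.null(x$rgb_jitter_sd)) c(0.05, 0.05, 0.05)
                   else unlist(x$rgb_jitter_sd),
                   if (is.null(x$name)) "material" else x$name)
  }
  take <- function(lst, nm, default) if (is.null(lst[[nm]])) default else lst[[nm]]
  sim_args <- raw$sim %||% list()
  sim <- sim_config(
    levels = unlist(take(sim_args, "levels", c(0, 0.05, 0.15, 0.30, 0.50))),
    images_per_level = take(sim_args, "images_per_level", 18),
    image_size = unlist(take(sim_args, "image_size", c(256, 256))),
    grain_scale = take(sim_args, "grain_scale", 8),
    illumination_gradient = take(sim_args, "illumination_gradient", 0.05),
    sensor_noise_sd = take(sim_args, "sensor_noise_sd", 0.02)
  )
  ann_args <- raw$ann %||% list()
  svm_args <- raw$svm %||% list()
  sel_args <- raw$selection %||% list()
  cfg <- experiment_config(
    material = take(raw, "material", "black pepper"),
    base = pal(raw$base, black_pepper_palette()),
    adulterant = pal(raw$adulterant, sea_foam_palette()),
    sim = sim,
    keep_fraction = take(raw, "keep_fraction", 0.8),
    glcm_levels = take(raw, "glcm_levels", 8),
    entropy_bins = take(raw, "entropy_bins", 256),
    selection = list(cv_folds = take(sel_args, "cv_folds", 5),
                     max_features = take(sel_args, "max_features", 20),
                     tol = take(sel_args, "tol", 1e-6)),
    ann = list(split = unlist(take(ann_args, "split", c(0.6, 0.2, 0.2))),
               config = mlp_config(
                 hidden_sizes = seq_len(take(ann_args, "max_hidden", 20)),
                 max_epochs = take(ann_args, "max_epochs", 400),
                 patience = take(ann_args, "patience", 25),
                 learn_rate = take(ann_args, "learn_rate", 0.05))),
    svm = list(split = unlist(take(svm_args, "split", c(0.8, 0, 0.2))),
               config = svm_config(cost = take(svm_args, "cost", 1000),
                                   gamma = svm_args$gamma,
                                   lambda = take(svm_args, "lambda", 1e-7))),
    seed = take(raw, "seed", 1)
  )
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full adulteration-detection experiment
#'
#' Executes every stage on synthetic data: image generation, centre crop,
#' 19-channel decomposition, 266-feature extraction, sequential feature
#' selection, the ANN hidden-size sweep (60/20/20 split at the defaults)
#' and the one-vs-one SVM (80/20 split), then evaluates both classifiers.
#' Confusion matrices and metric reports are produced in two scopes: over
#' all samples pooled ("paper-style", matching published 90-sample
#' matrices) and over the held-out test split only.
#'
#' @param cfg An [experiment_config()].
#' @param out_dir Optional directory; when given, the feature CSV,
#'   selection JSON, efficient-feature means, training log, predictions,
#'   metric reports, summary table and a run log of every seed and setting
#'   are written there.
#' @param write_images Also write the synthetic PNGs and manifest (slower;
#'   requires `out_dir`).
#' @return An object of class `experiment_result`; see Details.
#' @details The result bundles `features` (tibble), `selection`
#'   (`sfs_result`), `efficient_means`, `ann` (`mlp_sweep`), `svm`
#'   (`svm_ovo`), `predictions` (per sample: split membership and both
#'   classifiers' predictions), `confusion` and `reports` (nested lists
#'   by scope and method), `summary` / `summary_test` tibbles, `seeds`,
#'   and the `config`.
#' @export
run_experiment <- function(cfg, out_dir = NULL, write_images = FALSE) {
  if (!inherits(cfg, "experiment_config")) {
    abort("`cfg` must be an experiment_config.")
  }
  seeds <- list(
    sim = derive_seed(cfg$seed, 1),
    selection = derive_seed(cfg$seed, 2),
    ann_split = derive_seed(cfg$seed, 3),
    ann_train = derive_seed(cfg$seed, 4),
    svm_split = derive_seed(cfg$seed, 5),
    svm_train = derive_seed(cfg$seed, 6)
  )
  sim <- cfg$sim
  sim$seed <- as.integer(seeds$sim %% 2147483647)

  dataset <- generate_dataset(cfg$base, cfg$adulterant, sim)
  features <- extract_feature_table(dataset, cfg$keep_fraction,
                                    cfg$glcm_levels, cfg$entropy_bins)
  selection <- sfs_select(features,
                          cv_folds = cfg$selection$cv_folds,
                          max_features = cfg$selection$max_features,
                          tol = cfg$selection$tol,
                          seed = seeds$selection)
  efficient_means <- report_efficient_features(selection, features)
  reduced <- features[c(.meta_cols[.meta_cols %in% names(features)],
                        selection$selected)]

  # ANN protocol: 60/20/20 split, hidden-size sweep
  ann_cfg <- cfg$ann$config
  ann_cfg$seed <- as.integer(seeds$ann_train %% 2147483647)
  ann_split <- split_dataset(reduced, cfg$ann$split, seed = seeds$ann_split)
  ann <- sweep_structures(ann_split$train, ann_split$validation,
                          ann_split$test, ann_cfg)

  # SVM protocol: 80/20 split, one-vs-one Gaussian kernel
  svm_cfg <- cfg$svm$config
  svm_cfg$seed <- as.integer(seeds$svm_train %% 2147483647)
  svm_split <- split_dataset(reduced, cfg$svm$split, seed = seeds$svm_split)
  svm <- train_svm_ovo(svm_split$train, svm_cfg)

  k <- length(sim$levels)
  split_of <- function(split) {
    lab <- rep(c("train", "validation", "test"),
               vapply(split, nrow, 0L))
    ids <- unlist(purrr::map(split, "sample_id"), use.names = FALSE)
    lab[match(reduced$sample_id, ids)]
  }
  predictions <- tibble::tibble(
    sample_id = reduced$sample_id,
    class_index = reduced$class_index,
    level = reduced$level,
    ann_split = split_of(ann_split),
    svm_split = split_of(svm_split),
    ann_pred = predict(ann$model, reduced),
    svm_pred = predict(svm, reduced)
  )

  scope_report <- function(rows) {
    list(
      ann = metrics(confusion(predictions$class_index[rows$ann],
                              predictions$ann_pred[rows$ann], k)),
      svm = metrics(confusion(predictions$class_index[rows$svm],
                              predictions$svm_pred[rows$svm], k))
    )
  }
  all_rows <- list(ann = rep(TRUE, nrow(predictions)),
                   svm = rep(TRUE, nrow(predictions)))
  test_rows <- list(ann = predictions$ann_split == "test",
                    svm = predictions$svm_split == "test")
  reports <- list(full = scope_report(all_rows), test = scope_report(test_rows))
  confusion_of <- function(rows, pred) {
    confusion(predictions$class_index[rows], predictions[[pred]][rows], k)
  }
  confusions <- list(
    full = list(ann = confusion_of(all_rows$ann, "ann_pred"),
                svm = confusion_of(all_rows$svm, "svm_pred")),
    test = list(ann = confusion_of(test_rows$ann, "ann_pred"),
                svm = confusion_of(test_rows$svm, "svm_pred"))
  )
  make_summary <- function(rep2) {
    metrics_summary(tibble::tibble(
      material = cfg$material,
      method = c("ANN", "SVM"),
      report = list(rep2$ann, rep2$svm)
    ))
  }
  result <- structure(
    list(dataset = dataset, features = features, selection = selection,
         efficient_means = efficient_means, ann = ann, svm = svm,
         predictions = predictions, confusion = confusions,
         reports = reports,
         summary = make_summary(reports$full),
         summary_test = make_summary(reports$test),
         seeds = seeds, config = cfg),
    class = "experiment_result"
  )
  if (!is.null(out_dir)) write_experiment(result, out_dir, write_images)
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s: %d images, %d efficient features\n",
              x$config$material, nrow(x$features), x$selection$n_selected))
  cat("paper-style (all samples):\n")
  print(as.data.frame(x$summary))
  cat("held-out test split:\n")
  print(as.data.frame(x$summary_test))
  invisible(x)
}

write_experiment <- function(result, out_dir, write_images = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (write_images) {
    write_image_set(result$dataset, file.path(out_dir, "images"))
  }
  write_feature_table(result$features, file.path(out_dir, "features.csv"))
  write_selection(result$selection, file.path(out_dir, "selection.json"))
  readr::write_csv(result$efficient_means,
                   file.path(out_dir, "efficient_features.csv"))
  readr::write_csv(result$ann$model$log, file.path(out_dir, "ann_training_log.csv"))
  readr::write_csv(result$ann$records, file.path(out_dir, "ann_sweep.csv"))
  readr::write_csv(result$predictions, file.path(out_dir, "predictions.csv"))
  readr::write_csv(result$summary, file.path(out_dir, "summary_full.csv"))
  readr::write_csv(result$summary_test, file.path(out_dir, "summary_test.csv"))
  jsonlite::write_json(
    purrr::map(result$reports, function(scope) {
      purrr::map(scope, function(rep) {
        list(per_class = rep$per_class, macro = as.list(rep$macro),
             micro = as.list(rep$micro), overall_ccr = rep$overall_ccr,
             n_errors = rep$n_errors, n = rep$n)
      })
    }),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA
  )
  cfg <- result$config
  yaml::write_yaml(
    list(material = cfg$material,
         seed = cfg$seed,
         stage_seeds = result$seeds,
         keep_fraction = cfg$keep_fraction,
         glcm_levels = cfg$glcm_levels,
         entropy_bins = cfg$entropy_bins,
         sim = unclass(cfg$sim),
         selection = cfg$selection,
         ann = list(split = cfg$ann$split,
                    config = unclass(cfg$ann$config)),
         svm = list(split = cfg$svm$split,
                    config = unclass(cfg$svm$config)[c("cost", "lambda")]),
         base = unclass(cfg$base),
         adulterant = unclass(cfg$adulterant)),
    file.path(out_dir, "run_log.yaml")
  )
  invisible(out_dir)
}
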