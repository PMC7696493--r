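# Four-way model comparison: BP, SVM, PSO-BP, PSO-SVM on one shared
# train/test split of a synthetic ride.

#' Compare BP, SVM, PSO-BP and PSO-SVM on one synthetic benchmark
#'
#' Runs the full pipeline: simulate a ride, denoise the acceleration
#' channels, extract per-sample features, collapse each phase segment to its
#' median feature vector (one "group" per cycle and phase), split at cycle
#' granularity, standardize on the training groups only, then train and
#' evaluate all four models on the identical split. The SVM baseline uses
#' the fixed default (C, gamma); PSO-SVM tunes the shared pair by CV-fitness
#' swarm search; BP trains by gradient backpropagation; PSO-BP seeds the
#' network weights by swarm search.
#'
#' @param config a [sim_config()]; its `seed` is replaced by `seed`
#' @param seed master seed; the split, swarm and network seeds are derived
#'   from it (seed, seed+1, seed+2, seed+3)
#' @param denoise a [shrinkage_spec()], or `NULL` to skip denoising
#' @param svm_default fixed (C, gamma) for the untuned SVM
#' @param tune list: `folds`, `n_particles`, `max_iter` for the PSO-SVM
#'   search
#' @param mlp an [mlp_spec()] template for BP / PSO-BP (seed overridden)
#' @param bp_swarm list: `n_particles`, `max_iter` for the PSO-BP search
#' @param n_train_cycles,n_test_cycles cycle split (25/25 of 50 cycles gives
#'   the canonical 100 training and 100 testing groups)
#' @return object of class `model_comparison`: `reports` (one
#'   [metrics_report()] per model), `predictions` (actual vs predicted phase
#'   per test group, the actual-vs-predicted plot data), `tuned` ((C, gamma)
#'   chosen by PSO), `settings`
#' @export
compare_models <- function(config = sim_config(), seed = 1L,
                           denoise = shrinkage_spec(),
                           svm_default = list(C = 2, gamma = 1),
                           tune = list(folds = 10, n_particles = 12, max_iter = 30),
                           mlp = mlp_spec(),
                           bp_swarm = list(n_particles = 20, max_iter = 60),
                           n_train_cycles = 25, n_test_cycles = 25) {
  stopifnot(inherits(config, "sim_config"))
  config$seed <- as.integer(seed)
  rec <- generate_recording(config)
  if (!is.null(denoise)) rec <- denoise_recording(rec, denoise)
  groups <- group_medians(extract_features(rec))
  split <- split_cycles(groups, n_train_cycles, n_test_cycles, seed = seed)
  train <- standardize(split$train)
  test <- apply_standardization(split$test, train)

  # SVM with fixed default parameters
  svm_fit <- train_tree(train, C = svm_default$C, gamma = svm_default$gamma)
  pred_svm <- predict_tree(svm_fit, test$x)

  # PSO-SVM: shared (C, gamma) maximizing K-fold CV accuracy
  tuned <- tune_tree_pso(train, folds = tune$folds,
                         swarm = pso_config(n_particles = tune$n_particles,
                                            max_iter = tune$max_iter,
                                            seed = seed + 1L),
                         fold_seed = seed)
  pso_svm_fit <- train_tree(train, C = tuned$C, gamma = tuned$gamma)
  pred_pso_svm <- predict_tree(pso_svm_fit, test$x)

  # BP and PSO-BP
  mlp$seed <- seed + 2L
  bp_fit <- train_bp(train, mlp)
  pred_bp <- predict_mlp(bp_fit, test$x)
  pso_bp_fit <- train_pso_bp(train, mlp,
                             swarm = pso_config(n_particles = bp_swarm$n_particles,
                                                max_iter = bp_swarm$max_iter,
                                                seed = seed + 3L))
  pred_pso_bp <- predict_mlp(pso_bp_fit, test$x)

  preds <- list(BP = pred_bp, SVM = pred_svm,
                `PSO-BP` = pred_pso_bp, `PSO-SVM` = pred_pso_svm)
  structure(list(
    reports = lapply(preds, metrics_report, y_true = test$y),
    predictions = data.frame(group = seq_along(test$y), actual = test$y,
                             BP = pred_bp, SVM = pred_svm,
                             PSO_BP = pred_pso_bp, PSO_SVM = pred_pso_svm),
    tuned = tuned[c("C", "gamma", "fitness")],
    settings = list(seed = seed, svm_default = svm_default, tune = tune,
                    n_train_groups = length(split$train$y),
                    n_test_groups = length(test$y))),
    class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison on %d training / %d testing groups (seed %d)\n",
              x$settings$n_train_groups, x$settings$n_test_groups,
              x$settings$seed))
  for (m in names(x$reports))
    cat(sprintf("  %-7s recognition rate %6.2f%%\n", m,
                x$reports[[m]]$recognition_rate))
  cat(sprintf("  PSO-SVM tuned C = %.4g, gamma = %.4g (CV fitness %.3f)\n",
              x$tuned$C, x$tuned$gamma, x$tuned$fitness))
  invisible(x)
}

#' Write comparison artifacts
#'
#' Emits `metrics.json` (all reports), per-model metric tables
#' (`table_counts.csv`, `table_precision.csv`, `table_recall.csv`,
#' `table_f1.csv`, `table_g.csv`) and `plot_predictions.csv` (actual vs
#' predicted phase per test group).
#'
#' @param cmp a `model_comparison`
#' @param dir output directory (created if missing)
#' @return invisibly, the directory
#' @export
write_comparison <- function(cmp, dir) {
  stopifnot(inherits(cmp, "model_comparison"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(lapply(cmp$reports, function(r)
    list(recognition_rate = r$recognition_rate,
         per_phase_correct = r$per_phase_correct,
         node = as.data.frame(r$node),
         precision_summary = as.list(r$precision_summary))),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  models <- names(cmp$reports)
  grab <- function(fld) t(vapply(cmp$reports, function(r) r$node[, fld], numeric(3)))
  tab <- function(m) data.frame(model = models, m, check.names = FALSE)
  write.csv(tab(t(vapply(cmp$reports, function(r) r$per_phase_correct, numeric(4)))),
            file.path(dir, "table_counts.csv"), row.names = FALSE)
  write.csv(tab(round_half_up(grab("precision"), 2)),
            file.path(dir, "table_precision.csv"), row.names = FALSE)
  write.csv(tab(round_half_up(grab("recall"), 2)),
            file.path(dir, "table_recall.csv"), row.names = FALSE)
  write.csv(tab(round_half_up(grab("f1"), 2)),
            file.path(dir, "table_f1.csv"), row.names = FALSE)
  write.csv(tab(round_half_up(grab("g"), 2)),
            file.path(dir, "table_g.csv"), row.names = FALSE)
  write.csv(cmp$predictions, file.path(dir, "plot_predictions.csv"),
            row.names = FALSE)
  invisible(dir)
}
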