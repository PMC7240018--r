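# 32-bit FNV-1a hash of a character string; used to stamp artifacts with a
# fingerprint of the configuration that produced them. Arithmetic is done in
# doubles, splitting the multiply so every intermediate stays below 2^53.
fnv_hash <- function(text) {
  bytes <- as.integer(charToRaw(paste(text, collapse = "\n")))
  prime <- 16777619
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- ((h %% 65536) * prime + ((h %/% 65536) * prime %% 65536) * 65536) %%
      4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run: synthetic benchmark
#' parameters, the feature selection, the training configuration, and the
#' master seed every random draw derives from.
#'
#' @param out_dir output directory for artifacts.
#' @param seed master seed.
#' @param n_subjects,n_train,frames_per_subject,hardness,class_mix,
#'   dropout_prob synthetic benchmark parameters
#'   (see \code{\link{generate_benchmark}}).
#' @param feature_spec selected feature names.
#' @param train training configuration (\code{\link{train_config}}); its
#'   seed is overridden by the master seed.
#' @param run_cv whether to run k-fold cross-validation before the repeated
#'   simulations.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir = tempfile("skelpose_"), seed = 1L,
                            n_subjects = 12L, n_train = 10L,
                            frames_per_subject = 500L, hardness = "easy",
                            class_mix = c(0.241, 0.388, 0.144, 0.227),
                            dropout_prob = 0.02,
                            feature_spec = DEFAULT_SELECTION,
                            train = train_config(), run_cv = FALSE) {
  train$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_subjects = n_subjects, n_train = n_train,
                 frames_per_subject = frames_per_subject,
                 hardness = hardness, class_mix = class_mix,
                 dropout_prob = dropout_prob, feature_spec = feature_spec,
                 train = train, run_cv = run_cv),
            class = "pipeline_config")
}

# fingerprint of the scientific configuration; the output location is
# excluded so identical runs into different directories hash identically
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  fnv_hash(paste(deparse(cfg), collapse = ""))
}

#' Run the full pose-recognition pipeline
#'
#' Simulates the cohort, extracts and selects features, splits by subject,
#' optionally cross-validates, runs the repeated train/test simulations and
#' writes three artifacts into \code{config$out_dir}: \code{features.csv}
#' (the test-subject feature rows), \code{model.txt} (the last trained
#' model) and \code{report.txt} (the evaluation summary). Every artifact
#' carries the master seed and a configuration fingerprint; re-running with
#' the same configuration reproduces the artifacts byte for byte.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list: \code{benchmark}, \code{cv} (or NULL), \code{simulations},
#'   \code{summary}, \code{paths}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  bench <- generate_benchmark(
    n_subjects = config$n_subjects, n_train = config$n_train,
    frames_per_subject = config$frames_per_subject,
    class_mix = config$class_mix, hardness = config$hardness,
    seed = config$seed, feature_spec = config$feature_spec,
    dropout_prob = config$dropout_prob)

  cv <- NULL
  if (isTRUE(config$run_cv))
    cv <- cross_validate(bench$train$X, bench$train$y, config$train)

  sims <- repeated_simulations(bench$train, bench$test, config$train)
  if (length(sims$reports) == 0L)
    stop("pipeline stage 'repeated_simulations' failed: ",
         paste(sims$failures, collapse = "; "))
  summ <- summarize_simulations(sims)

  feat_path <- file.path(config$out_dir, "features.csv")
  test_df <- data.frame(subject_id = bench$test$subject_id,
                        label = bench$test$y,
                        bench$test$X, check.names = FALSE)
  utils::write.csv(format(test_df, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   feat_path, row.names = FALSE, quote = FALSE)
  model_path <- file.path(config$out_dir, "model.txt")
  write_model(sims$models[[length(sims$models)]], model_path,
              config$feature_spec)
  report_path <- file.path(config$out_dir, "report.txt")
  write_report(summ, report_path, seed = config$seed,
               config_hash = config_hash(config),
               failures = sims$failures)
  list(benchmark = bench, cv = cv, simulations = sims, summary = summ,
       paths = c(features = feat_path, model = model_path,
                 report = report_path))
}

#' Write an evaluation summary as structured text
#'
#' Key-value lines plus fixed-format tables: per-class metric means and SDs,
#' both total-accuracy readings, and the mean confusion matrix. Deterministic
#' output (no timestamps), so identical runs produce identical files.
#'
#' @param summary output of \code{\link{summarize_simulations}}.
#' @param path file path.
#' @param seed master seed to record.
#' @param config_hash configuration fingerprint to record.
#' @param failures character vector of recorded simulation failures.
#' @export
write_report <- function(summary, path, seed = NA, config_hash = "",
                         failures = character(0)) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("skelpose evaluation report")
  w("seed: %s", as.character(seed))
  w("config_hash: %s", config_hash)
  w("n_simulations: %d", summary$n_simulations)
  w("n_failures: %d", length(failures))
  w("total_accuracy_mean: %.6f", summary$total_accuracy[["mean"]])
  w("total_accuracy_sd: %.6f", summary$total_accuracy[["sd"]])
  w("mean_class_accuracy_mean: %.6f", summary$mean_class_accuracy[["mean"]])
  w("mean_class_accuracy_sd: %.6f", summary$mean_class_accuracy[["sd"]])
  w("")
  w("per-class metrics (mean, sd over simulations)")
  m <- summary$metrics
  for (i in seq_len(nrow(m)))
    w("class %d %-11s %.6f %.6f", m$class[i], m$metric[i], m$mean[i],
      m$sd[i])
  w("")
  w("mean confusion matrix (rows predicted, cols actual)")
  mc <- summary$mean_confusion
  for (r in seq_len(nrow(mc)))
    w("%s", paste(sprintf("%12.4f", mc[r, ]), collapse = " "))
  if (length(failures) > 0L) {
    w("")
    w("failures")
    for (f in failures) w("  %s", f)
  }
  invisible(path)
}
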