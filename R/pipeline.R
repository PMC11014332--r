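# End-to-end pipeline: rasterize -> taxonomy labels -> fold assignment ->
# feature ingest -> train with test-fold early stopping -> predict on the
# evaluation fold -> metrics report. Every stage writes plain CSV/JSON so
# each is independently invocable, and a manifest records the seed, a config
# hash and the leakage audit.

#' Pipeline run configuration
#'
#' @param events Path to an events CSV, or an in-memory event tibble, or a
#'   `synthetic_session`.
#' @param features Path to a pose-feature CSV, or a tibble; may be `NULL`
#'   when `events` is a `synthetic_session` (its features are used).
#' @param output_dir Directory for stage outputs; created if needed.
#' @param taxonomy Taxonomy name for classification (see [taxonomy_map()]).
#' @param targets A [fold_targets()].
#' @param fold_mode,n_candidates,cap Passed to [assign_folds()].
#' @param classifier A [classifier_config()].
#' @param auc_weights Optional per-class AUC weights (weight suppression).
#' @param substitute_missing Substitute the testing fold's scores for any
#'   class with no evaluation-fold frames (the rare-class rule).
#' @param seed Global seed; recorded in every output artifact.
#' @return A list of class `run_config`.
#' @export
run_config <- function(events, features = NULL, output_dir = tempfile("run_"),
                       taxonomy = "T2_activity_type",
                       targets = fold_targets(),
                       fold_mode = "exhaustive", n_candidates = 2000L,
                       cap = 3^10,
                       classifier = classifier_config(),
                       auc_weights = NULL, substitute_missing = TRUE,
                       seed = 1L) {
  if (is.character(events) && !file.exists(events)) {
    stop("validation error: events path does not exist: ", events)
  }
  if (is.character(features) && !file.exists(features)) {
    stop("validation error: features path does not exist: ", features)
  }
  structure(list(events = events, features = features,
                 output_dir = output_dir, taxonomy = taxonomy,
                 targets = targets, fold_mode = fold_mode,
                 n_candidates = as.integer(n_candidates), cap = cap,
                 classifier = classifier, auc_weights = auc_weights,
                 substitute_missing = isTRUE(substitute_missing),
                 seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full annotation-to-metrics pipeline
#'
#' Executes rasterization, taxonomy labeling, chi-square fold assignment,
#' classifier training with testing-fold early stopping, evaluation-fold
#' prediction and the metrics report, writing each stage's output under
#' `config$output_dir` plus a manifest (seed, config hash, leakage audit).
#' Classes with no evaluation-fold frames are, by default, evaluated on the
#' testing fold via AUC substitution.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report`: the fold assignment, trained model,
#'   predictions, [metrics_report()], leakage audit and manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  tax <- taxonomy_map(config$taxonomy)
  label_col <- tolower(strsplit(tax$name, "_")[[1]][1])

  session <- NULL
  events <- stage("ingest", {
    if (inherits(config$events, "synthetic_session")) {
      session <- config$events
      session$events
    } else if (is.character(config$events)) {
      parse_events(config$events)
    } else {
      validate_events(config$events)
    }
  })
  seconds <- stage("rasterize", label_seconds(rasterize_all(events)))
  utils::write.csv(seconds, file.path(config$output_dir, "seconds.csv"),
                   row.names = FALSE)

  profiles <- stage("profiles", video_profiles(seconds, tax, label_col))
  assignment <- stage("fold_assignment", assign_folds(
    profiles, config$targets, mode = config$fold_mode, seed = config$seed,
    n_candidates = config$n_candidates, cap = config$cap))
  write_fold_assignment(assignment,
                        file.path(config$output_dir, "folds.csv"),
                        file.path(config$output_dir, "folds.json"))

  features <- stage("features", {
    if (!is.null(config$features)) {
      if (is.character(config$features)) {
        read_pose_features(config$features)
      } else {
        config$features
      }
    } else if (!is.null(session)) {
      session$features
    } else {
      stop("no pose features supplied")
    }
  })
  key <- paste(features$video_id, features$second_index)
  labels <- seconds[[label_col]][match(key, paste(seconds$video_id,
                                                  seconds$second_index))]

  model <- stage("train", train_classifier(
    features, labels, assignment, classes = tax$classes,
    config = config$classifier, seed = config$seed))
  audit <- audit_leakage(model, assignment)
  if (!audit$ok) {
    stop("pipeline stage 'train' failed: leakage audit found evaluation ",
         "videos in training rows: ", paste(audit$offending, collapse = ", "))
  }

  fold_of <- assignment$mapping[features$video_id]
  predict_fold <- function(f) {
    idx <- which(fold_of == f)
    preds <- predict_frames(model, features[idx, , drop = FALSE])
    preds$true <- labels[idx]
    preds
  }
  eval_preds <- stage("predict", predict_fold("evaluation"))
  utils::write.csv(eval_preds,
                   file.path(config$output_dir, "predictions_evaluation.csv"),
                   row.names = FALSE)

  report <- stage("evaluate", {
    cm <- confusion_matrix(eval_preds$true, eval_preds$predicted, tax$classes)
    substitutions <- list()
    if (config$substitute_missing) {
      missing <- setdiff(tax$classes, unique(eval_preds$true))
      if (length(missing) > 0) {
        test_preds <- predict_fold("testing")
        for (cl in missing) {
          substitutions[[cl]] <- list(
            scores = as.matrix(test_preds[, tax$classes, drop = FALSE]),
            labels = test_preds$true)
        }
      }
    }
    metrics_report(cm,
                   scores = as.matrix(eval_preds[, tax$classes, drop = FALSE]),
                   labels = eval_preds$true,
                   weights = config$auc_weights,
                   substitutions = substitutions)
  })
  write_metrics_report(report, file.path(config$output_dir, "metrics.json"))

  manifest <- list(
    seed = config$seed,
    taxonomy = config$taxonomy,
    config_hash = rlang::hash(config[setdiff(names(config), "events")]),
    n_videos = length(unique(seconds$video_id)),
    n_seconds = nrow(seconds),
    fold_score = assignment$score,
    best_iteration = model$best_iteration,
    leakage_audit = audit,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  structure(list(assignment = assignment, model = model,
                 predictions = eval_preds, report = report,
                 leakage_audit = audit, manifest = manifest,
                 output_dir = config$output_dir),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> outputs in", x$output_dir, "\n")
  cat("fold score:", signif(x$assignment$score, 4),
      "| best round:", x$model$best_iteration,
      "| leakage audit:", if (x$leakage_audit$ok) "clean" else "VIOLATED",
      "\n\n")
  print(x$report)
  invisible(x)
}
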