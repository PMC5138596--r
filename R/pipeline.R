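#' Configure an end-to-end identification run
#'
#' Composes the stages curate (redundancy removal) -> feature extraction ->
#' balancing -> training -> evaluation -> prediction.  The
#' `"SVMProt-RF"` preset of the field is `feature_method = "ctd188"`,
#' `sampling = "under"`, Random-Forest learner.
#'
#' @param pos_fasta,neg_fasta Paths to positive / negative training FASTA.
#' @param query_fasta Optional path to query sequences to score.
#' @param out_dir Output run directory (created if absent).
#' @param feature_method `"ctd188"` (188-D descriptor) or `"pseaac"`
#'   (`20 + lambda` components).
#' @param cluster_threshold Identity threshold for redundancy removal of the
#'   positive set; `NULL` skips clustering.
#' @param sampling `"under"`, `"weighted"` or `"none"`.
#' @param class_weights Named class weights for `sampling = "weighted"`
#'   (default `c("R-gene" = 10, "non-R-gene" = 7)`, the fixed-ratio scheme
#'   for a ~7:10 imbalance).
#' @param learner A [learner_spec()].
#' @param pseaac A [pseaac_config()] used when `feature_method = "pseaac"`.
#' @param cv_folds Folds for the cross-validated report (`0` disables CV).
#' @param seed Integer master seed; every random stage derives from it and
#'   is recorded in the run outputs.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(pos_fasta, neg_fasta, query_fasta = NULL,
                            out_dir = "rgenescan_run",
                            feature_method = c("ctd188", "pseaac"),
                            cluster_threshold = 0.70,
                            sampling = c("under", "weighted", "none"),
                            class_weights = c("R-gene" = 10, "non-R-gene" = 7),
                            learner = learner_spec("random_forest"),
                            pseaac = pseaac_config(),
                            cv_folds = 10L,
                            seed = 1L) {
  structure(list(pos_fasta = pos_fasta, neg_fasta = neg_fasta,
                 query_fasta = query_fasta, out_dir = out_dir,
                 feature_method = match.arg(feature_method),
                 cluster_threshold = cluster_threshold,
                 sampling = match.arg(sampling),
                 class_weights = class_weights,
                 learner = learner, pseaac = pseaac,
                 cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  # output location is provenance, not a scientific parameter
  core <- config[setdiff(names(config), "out_dir")]
  flat <- paste(utils::capture.output(utils::str(core)), collapse = "\n")
  sprintf("%08x", as.integer(sum(utf8ToInt(flat) *
                                   (seq_along(utf8ToInt(flat)) %% 97 + 1)) %% 2^31))
}

extract_features_by <- function(records, config) {
  switch(config$feature_method,
         ctd188 = extract_188_batch(records),
         pseaac = extract_pseaac_batch(records, config$pseaac))
}

#' Run the full identification pipeline
#'
#' Executes, in order: read + sanitize inputs, redundancy removal of the
#' positive set, feature extraction, class balancing, model training, hold-out
#' and cross-validated evaluation, and (optionally) query prediction.  All
#' artifacts are written under `config$out_dir`; every output carries the
#' config hash, and a rerun with an identical config reproduces identical
#' contents.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `train`, `holdout`, `model`,
#'   `eval_holdout`, `eval_cv`, `predictions`, `summary`, `run_info`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  hash <- config_hash(config)
  logf("run start (config %s, seed %d)", hash, config$seed)

  stage <- "curate"
  result <- tryCatch({
    pos <- read_fasta(config$pos_fasta)
    neg <- read_fasta(config$neg_fasta)
    if (!is.null(config$cluster_threshold)) {
      n0 <- length(pos)
      pos <- dereplicate(pos, config$cluster_threshold)
      write_cluster_report(attr(pos, "clusters"),
                           file.path(config$out_dir, "clusters.tsv"))
      logf("curate: %d -> %d positive representatives at threshold %.2f",
           n0, length(pos), config$cluster_threshold)
    }

    stage <- "extract"
    feats <- rbind(extract_features_by(pos, config),
                   extract_features_by(neg, config))
    labels <- rep(c("R-gene", "non-R-gene"), c(length(pos), length(neg)))
    dataset <- labeled_dataset(feats, labels)
    write_features(feats, file.path(config$out_dir, "features.tsv"))
    logf("extract: %s features, %d x %d", config$feature_method,
         nrow(feats), ncol(feats))

    stage <- "balance"
    holdout <- NULL
    train <- dataset
    if (config$sampling == "under") {
      us <- under_sample(dataset, seed = config$seed)
      train <- us$train
      holdout <- us$holdout
      logf("balance: under-sampled to %d per class; %d-instance hold-out",
           min(table(dataset$labels)), nrow(holdout$features))
    } else if (config$sampling == "weighted") {
      train <- weighted_sample(dataset, config$class_weights)
      logf("balance: per-instance weights (%s)",
           paste(sprintf("%s=%g", names(config$class_weights),
                         config$class_weights), collapse = ", "))
    }

    stage <- "train"
    model <- train_model(train, config$learner, seed = config$seed)
    logf("train: %s on %d instances", config$learner$name, nrow(train$features))

    stage <- "evaluate"
    eval_holdout <- NULL
    if (!is.null(holdout) && nrow(holdout$features) > 0L) {
      eval_holdout <- evaluate_model(model, holdout, protocol = "holdout")
      write_eval_report(eval_holdout,
                        file.path(config$out_dir, "eval_holdout.json"))
      logf("evaluate holdout: Acc %.4f%%", eval_holdout$Acc)
    }
    eval_cv <- NULL
    if (config$cv_folds >= 2L) {
      eval_cv <- cross_validate(train, config$learner, k = config$cv_folds,
                                seed = config$seed)
      write_eval_report(eval_cv, file.path(config$out_dir, "eval_cv.json"))
      logf("evaluate cv%d: Acc %.4f%%, MCC %.4f", config$cv_folds,
           eval_cv$Acc, eval_cv$MCC)
    }

    stage <- "predict"
    predictions <- NULL
    summ <- NULL
    if (!is.null(config$query_fasta)) {
      query <- read_fasta(config$query_fasta)
      qfeats <- extract_features_by(query, config)
      predictions <- predict_model(model, qfeats)
      utils::write.table(predictions,
                         file.path(config$out_dir, "predictions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summ <- summarize_predictions(predictions)
      logf("predict: %d/%d records labeled R-gene (%s%%)",
           summ$n_positive, summ$n, summ$pct_formatted)
    }

    run_info <- list(config_hash = hash, seed = config$seed,
                     feature_method = config$feature_method,
                     sampling = config$sampling,
                     learner = config$learner$name)
    jsonlite::write_json(run_info, file.path(config$out_dir, "run_info.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    list(train = train, holdout = holdout, model = model,
         eval_holdout = eval_holdout, eval_cv = eval_cv,
         predictions = predictions, summary = summ, run_info = run_info)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  logf("run complete")
  invisible(result)
}

#' Summarize query predictions
#'
#' @param predictions data.frame from [predict_model()] with a `label`
#'   column.
#' @return List with `n`, `n_positive`, `pct_positive`
#'   (`100 * positives / total`) and `pct_formatted` (4 decimal places, the
#'   conventional reporting precision).
#' @examples
#' summarize_predictions(data.frame(label = c("R-gene", "non-R-gene")))
#' @export
summarize_predictions <- function(predictions) {
  if (is.null(predictions) || nrow(predictions) == 0L) {
    stop("no predictions to summarize")
  }
  n <- nrow(predictions)
  n_pos <- sum(predictions$label == "R-gene")
  pct <- 100 * n_pos / n
  list(n = n, n_positive = n_pos, pct_positive = pct,
       pct_formatted = sprintf("%.4f", pct))
}
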