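#' Specify a learner
#'
#' A light generic interface so the Random-Forest workhorse and off-the-shelf
#' baseline learners are interchangeable downstream.
#'
#' @param name One of `"random_forest"` (ranger backend; honors per-instance
#'   weights as bootstrap case weights), `"svm"` (e1071, RBF kernel) or
#'   `"naive_bayes"` (e1071).
#' @param ... Hyperparameters passed to the backend.  Random-forest defaults:
#'   `num_trees = 100`, `mtry = floor(sqrt(p))`, unlimited depth.
#' @return A `learner_spec` object.
#' @export
learner_spec <- function(name = c("random_forest", "svm", "naive_bayes"), ...) {
  name <- match.arg(name)
  structure(list(name = name, params = list(...)), class = "learner_spec")
}

#' Train a classifier on a labeled dataset
#'
#' @param train A [labeled_dataset()] with at least two instances per class.
#'   Per-instance weights, when present, are honored by the random-forest
#'   backend (weighted bootstrap).
#' @param spec A [learner_spec()]; default Random Forest.
#' @param seed Integer seed making training deterministic.
#' @return A `model_artifact`: list with the fitted backend object, the
#'   learner spec, the feature schema (column names in order) and training
#'   metadata (seed, instance counts, dataset hash).  Prediction refuses
#'   feature matrices whose schema differs from training.
#' @export
train_model <- function(train, spec = learner_spec("random_forest"), seed = 1L) {
  stopifnot(inherits(train, "labeled_dataset"), inherits(spec, "learner_spec"))
  tab <- table(train$labels)
  if (any(tab < 2L)) stop("training requires at least 2 instances per class")
  x <- train$features
  y <- train$labels
  seed <- as.integer(seed)
  fit <- switch(
    spec$name,
    random_forest = {
      p <- ncol(x)
      num_trees <- spec$params$num_trees %||% 100L
      mtry <- spec$params$mtry %||% max(1L, floor(sqrt(p)))
      ranger::ranger(
        x = x, y = y,
        num.trees = num_trees, mtry = min(mtry, p),
        min.node.size = spec$params$min_node_size %||% 1L,
        probability = TRUE, seed = seed, num.threads = 1L,
        case.weights = train$weights
      )
    },
    svm = {
      if (!requireNamespace("e1071", quietly = TRUE)) {
        stop("the 'svm' learner requires the e1071 package")
      }
      old <- .Random.seed_exists()
      set.seed(seed)
      m <- do.call(e1071::svm,
                   c(list(x = x, y = y, probability = TRUE), spec$params))
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      m
    },
    naive_bayes = {
      if (!requireNamespace("e1071", quietly = TRUE)) {
        stop("the 'naive_bayes' learner requires the e1071 package")
      }
      # naiveBayes derives the response name via substitute(); call directly
      e1071::naiveBayes(as.data.frame(x), y,
                        laplace = spec$params$laplace %||% 0)
    }
  )
  structure(list(spec = spec, fit = fit,
                 schema = colnames(x),
                 meta = list(seed = seed,
                             n_pos = unname(tab[["R-gene"]]),
                             n_neg = unname(tab[["non-R-gene"]]),
                             weighted = !is.null(train$weights),
                             dataset_hash = dataset_hash(train))),
            class = "model_artifact")
}

dataset_hash <- function(dataset) {
  # cheap content fingerprint for provenance, not cryptographic
  v <- c(dim(dataset$features), sum(dataset$features),
         as.integer(dataset$labels))
  sprintf("%08x", as.integer(sum(as.numeric(v) * seq_along(v)) %% 2^31))
}

#' @export
print.model_artifact <- function(x, ...) {
  cat(sprintf("model_artifact: %s, %d features, trained on %d/%d (seed %d)\n",
              x$spec$name, length(x$schema), x$meta$n_pos, x$meta$n_neg,
              x$meta$seed))
  invisible(x)
}

#' Score a feature matrix with a trained model
#'
#' @param model A `model_artifact` from [train_model()].
#' @param features Numeric matrix whose columns must match the training
#'   schema exactly (names and order; a column permutation is accepted and
#'   reordered).
#' @return data.frame with `id`, `score` (probability of the R-gene class)
#'   and `label` (`"R-gene"` iff `score >= 0.5`).
#' @export
predict_model <- function(model, features) {
  stopifnot(inherits(model, "model_artifact"))
  if (!is.matrix(features)) stop("features must be a matrix")
  if (nrow(features) == 0L) {
    return(data.frame(id = character(0), score = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  missing <- setdiff(model$schema, colnames(features))
  extra <- setdiff(colnames(features), model$schema)
  if (length(missing) || length(extra)) {
    stop("feature schema mismatch; missing: [",
         paste(utils::head(missing, 3L), collapse = ", "),
         "], extra: [", paste(utils::head(extra, 3L), collapse = ", "), "]")
  }
  features <- features[, model$schema, drop = FALSE]
  score <- switch(
    model$spec$name,
    random_forest = {
      pr <- stats::predict(model$fit, data = features, num.threads = 1L)$predictions
      pr[, "R-gene"]
    },
    svm = {
      pr <- stats::predict(model$fit, features, probability = TRUE)
      attr(pr, "probabilities")[, "R-gene"]
    },
    naive_bayes = {
      stats::predict(model$fit, as.data.frame(features), type = "raw")[, "R-gene"]
    }
  )
  data.frame(id = rownames(features) %||% as.character(seq_len(nrow(features))),
             score = unname(score),
             label = ifelse(score >= 0.5, "R-gene", "non-R-gene"),
             stringsAsFactors = FALSE)
}

#' Evaluate a trained model on a labeled dataset
#'
#' @param model A `model_artifact`.
#' @param dataset A [labeled_dataset()].
#' @param protocol Protocol tag recorded in the report.
#' @return An [eval_report()].
#' @export
evaluate_model <- function(model, dataset, protocol = "holdout") {
  pred <- predict_model(model, dataset$features)
  eval_report(dataset$labels, pred$score, protocol = protocol,
              seed = model$meta$seed)
}

#' Stratified k-fold cross-validation with pooled scoring
#'
#' Instances are assigned to `k` folds stratified by class; each fold is
#' scored by a model trained on the remaining folds; the pooled predictions
#' over all folds are scored once, yielding a single SN/SP/Acc/MCC/ROC-area
#' report.
#'
#' @param dataset A [labeled_dataset()].
#' @param spec A [learner_spec()].
#' @param k Number of folds (default 10); must not exceed the smaller class
#'   count.
#' @param seed Seed controlling fold assignment and per-fold training.
#' @return An [eval_report()] with `protocol = "cv<k>"`; pooled scores and
#'   fold assignment are attached as attributes `"scores"` and `"folds"`.
#' @export
cross_validate <- function(dataset, spec = learner_spec("random_forest"),
                           k = 10L, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  k <- as.integer(k)
  tab <- table(dataset$labels)
  if (any(tab == 0L)) stop("cross-validation requires both classes present")
  if (k < 2L || k > min(tab)) {
    stop("k must be between 2 and the smaller class count (", min(tab), ")")
  }
  n <- nrow(dataset$features)
  folds <- integer(n)
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  for (cl in levels(dataset$labels)) {
    idx <- which(dataset$labels == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  scores <- numeric(n)
  for (f in seq_len(k)) {
    hold <- folds == f
    model <- train_model(subset_dataset(dataset, which(!hold)), spec,
                         seed = as.integer(seed) + f)
    pred <- predict_model(model, dataset$features[hold, , drop = FALSE])
    scores[hold] <- pred$score
  }
  rep <- eval_report(dataset$labels, scores,
                     protocol = paste0("cv", k), seed = as.integer(seed))
  attr(rep, "scores") <- scores
  attr(rep, "folds") <- folds
  rep
}
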