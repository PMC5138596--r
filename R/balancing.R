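#' Construct a labeled dataset
#'
#' The container flowing into balancing and model evaluation: a feature
#' matrix, a binary label per row (positive class = R-gene) and optional
#' per-instance weights.
#'
#' @param features Numeric matrix with rownames (record ids).
#' @param labels Character or factor vector aligned with the rows; values
#'   `"R-gene"` / `"non-R-gene"` (a factor with those levels is accepted).
#' @param weights Optional positive per-instance weights.
#' @return A `labeled_dataset` object with elements `features`, `labels`
#'   (factor, levels `non-R-gene`, `R-gene`), `ids`, `weights`.
#' @export
labeled_dataset <- function(features, labels, weights = NULL) {
  if (!is.matrix(features) || is.null(rownames(features))) {
    stop("features must be a matrix with rownames (record ids)")
  }
  if (length(labels) != nrow(features)) {
    stop("labels length must equal the number of feature rows")
  }
  labels <- factor(as.character(labels), levels = c("non-R-gene", "R-gene"))
  if (anyNA(labels)) stop("labels must be 'R-gene' or 'non-R-gene'")
  if (anyNA(features)) stop("features contain missing values")
  if (!is.null(weights)) {
    if (length(weights) != nrow(features)) {
      stop("weights length must equal the number of feature rows")
    }
    if (any(!is.finite(weights)) || any(weights <= 0)) {
      stop("weights must be positive and finite")
    }
  }
  structure(list(features = features, labels = labels,
                 ids = rownames(features), weights = weights),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("labeled_dataset: %d instances x %d features (%d R-gene / %d non-R-gene)%s\n",
              nrow(x$features), ncol(x$features),
              tab[["R-gene"]], tab[["non-R-gene"]],
              if (is.null(x$weights)) "" else ", weighted"))
  invisible(x)
}

# Subset helper preserving the class.
subset_dataset <- function(dataset, idx) {
  labeled_dataset(dataset$features[idx, , drop = FALSE],
                  dataset$labels[idx],
                  weights = if (!is.null(dataset$weights)) dataset$weights[idx])
}

#' Balance classes by random under-sampling of the majority class
#'
#' The majority class is down-sampled uniformly without replacement to the
#' minority-class size; the unsampled majority instances form the hold-out
#' set.  Minority instances are never discarded.
#'
#' @param dataset A [labeled_dataset()] containing both classes.
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return List with `train` (balanced `labeled_dataset`) and `holdout`
#'   (`labeled_dataset` of the leftover majority instances; zero rows when
#'   the input is already balanced).
#' @examples
#' m <- matrix(rnorm(26), 13, 2, dimnames = list(paste0("s", 1:13), c("x", "y")))
#' d <- labeled_dataset(m, rep(c("R-gene", "non-R-gene"), c(3, 10)))
#' b <- under_sample(d, seed = 1)
#' table(b$train$labels); nrow(b$holdout$features)
#' @export
under_sample <- function(dataset, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  tab <- table(dataset$labels)
  if (any(tab == 0L)) stop("under-sampling requires both classes present")
  minority <- names(tab)[which.min(tab)]
  majority <- setdiff(levels(dataset$labels), minority)
  n_min <- min(tab)
  maj_idx <- which(dataset$labels == majority)
  min_idx <- which(dataset$labels == minority)
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  sampled <- sort(sample(maj_idx, n_min))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  train_idx <- sort(c(min_idx, sampled))
  hold_idx <- setdiff(maj_idx, sampled)
  list(train = subset_dataset(dataset, train_idx),
       holdout = subset_dataset_or_empty(dataset, hold_idx))
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

subset_dataset_or_empty <- function(dataset, idx) {
  if (length(idx) == 0L) {
    empty <- dataset$features[0L, , drop = FALSE]
    return(structure(list(features = empty,
                          labels = factor(character(0),
                                          levels = c("non-R-gene", "R-gene")),
                          ids = character(0), weights = NULL),
                     class = "labeled_dataset"))
  }
  subset_dataset(dataset, idx)
}

#' Balance classes by per-instance weighting
#'
#' Every instance is retained and receives its class weight.  With
#' `class_weights = NULL` ("auto" mode) weights are inverse class
#' frequencies normalized so the mean weight is 1.  Supplying named weights,
#' e.g. `c("R-gene" = 10, "non-R-gene" = 7)`, reproduces fixed-ratio
#' weighting for a roughly 7:10 positive:negative imbalance.
#'
#' @param dataset A [labeled_dataset()].
#' @param class_weights Optional named positive weights for the two classes.
#' @return The dataset with a `weights` component set; instance count and
#'   order unchanged.
#' @export
weighted_sample <- function(dataset, class_weights = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  lv <- levels(dataset$labels)
  if (is.null(class_weights)) {
    tab <- table(dataset$labels)
    if (any(tab == 0L)) stop("auto weighting requires both classes present")
    inv <- 1 / as.numeric(tab[lv])
    w_class <- stats::setNames(inv, lv)
    w <- w_class[as.character(dataset$labels)]
    w <- w / mean(w)
  } else {
    if (is.null(names(class_weights)) || !all(lv %in% names(class_weights))) {
      stop("class_weights must be named with both class labels: ",
           paste(lv, collapse = ", "))
    }
    if (any(class_weights <= 0)) stop("class weights must be positive")
    w <- as.numeric(class_weights[as.character(dataset$labels)])
  }
  labeled_dataset(dataset$features, dataset$labels, weights = unname(w))
}

#' Materialize a train/test split as labeled feature TSV files
#'
#' Writes two headered TSV files (`id`, features..., `label`, and `weight`
#' when present).  Ids of the two files are disjoint by construction.
#'
#' @param train,test `labeled_dataset` objects.
#' @param train_path,test_path Output paths.
#' @return Named character vector of the two paths, invisibly.
#' @export
split_train_test <- function(train, test, train_path, test_path) {
  write_labeled_tsv(train, train_path)
  write_labeled_tsv(test, test_path)
  invisible(c(train = train_path, test = test_path))
}

write_labeled_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  df <- data.frame(id = dataset$ids, dataset$features,
                   label = as.character(dataset$labels),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(dataset$weights)) df$weight <- dataset$weights
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled feature TSV written by [split_train_test()]
#'
#' @param path TSV path.
#' @return A `labeled_dataset`.
#' @export
read_labeled_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  feat_cols <- setdiff(names(df), c("id", "label", "weight"))
  m <- as.matrix(df[, feat_cols, drop = FALSE])
  rownames(m) <- df$id
  labeled_dataset(m, df$label, weights = df$weight)
}
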