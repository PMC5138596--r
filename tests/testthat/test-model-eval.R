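test_that("confusion matrices count the four cells like a hand tally", {
  labs <- c("R-gene", "R-gene", "non-R-gene", "non-R-gene")
  cm <- confusion(labs, labs)
  expect_equal(c(cm$TP, cm$FP, cm$TN, cm$FN), c(2L, 0L, 2L, 0L))
  flipped <- rev(labs)
  cm2 <- confusion(labs, flipped)
  expect_equal(c(cm2$TP, cm2$TN), c(0L, 0L))

  set.seed(121)
  labs <- sample(c("R-gene", "non-R-gene"), 100, replace = TRUE)
  pred <- sample(c("R-gene", "non-R-gene"), 100, replace = TRUE)
  cm3 <- confusion(labs, pred)
  # explicit loop oracle
  tp <- fp <- tn <- fn <- 0L
  for (i in 1:100) {
    if (labs[i] == "R-gene" && pred[i] == "R-gene") tp <- tp + 1L
    if (labs[i] == "non-R-gene" && pred[i] == "R-gene") fp <- fp + 1L
    if (labs[i] == "non-R-gene" && pred[i] == "non-R-gene") tn <- tn + 1L
    if (labs[i] == "R-gene" && pred[i] == "non-R-gene") fn <- fn + 1L
  }
  expect_equal(c(cm3$TP, cm3$FP, cm3$TN, cm3$FN), c(tp, fp, tn, fn))
  expect_equal(cm3$TP + cm3$FP + cm3$TN + cm3$FN, 100L)
})

test_that("SN/SP/Acc follow their definitions, with NaN for empty classes", {
  expect_equal(metric_sn_sp_acc(confusion_matrix(10, 0, 10, 0)),
               c(SN = 1, SP = 1, Acc = 100))
  expect_equal(metric_sn_sp_acc(confusion_matrix(0, 10, 0, 10)),
               c(SN = 0, SP = 0, Acc = 0))
  m <- metric_sn_sp_acc(confusion_matrix(TP = 831, FP = 313, TN = 687, FN = 169))
  expect_equal(unname(round(m, 3)), c(0.831, 0.687, 75.900))
  expect_warning(r <- metric_sn_sp_acc(confusion_matrix(0, 5, 5, 0)), "SN undefined")
  expect_true(is.nan(r[["SN"]]))
})

test_that("MCC matches its closed form on an exhaustive small grid", {
  expect_equal(metric_mcc(confusion_matrix(10, 0, 10, 0)), 1)
  expect_equal(round(metric_mcc(confusion_matrix(831, 313, 687, 169)), 3), 0.523)
  expect_warning(z <- metric_mcc(confusion_matrix(0, 0, 5, 5)), "convention")
  expect_equal(z, 0)
  for (tp in 0:5) for (fp in 0:5) for (tn in 0:5) for (fn in 0:5) {
    marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
    got <- suppressWarnings(metric_mcc(confusion_matrix(tp, fp, tn, fn)))
    want <- if (any(marg == 0)) 0 else {
      (tp * tn - fp * fn) / (sqrt(tp + fp) * sqrt(tp + fn) *
                               sqrt(tn + fp) * sqrt(tn + fn))
    }
    expect_equal(got, want)
    expect_true(got >= -1 && got <= 1)
  }
})

test_that("MCC is invariant under swapping both label and prediction signs", {
  cm <- confusion_matrix(TP = 30, FP = 12, TN = 25, FN = 8)
  swapped <- confusion_matrix(TP = 25, FP = 8, TN = 30, FN = 12)
  expect_equal(metric_mcc(cm), metric_mcc(swapped))
})

test_that("ROC area equals the all-pairs concordance oracle and pROC", {
  labs <- rep(c("R-gene", "non-R-gene"), each = 5)
  expect_equal(metric_roc_area(labs, c(6:10, 1:5) / 10), 1)
  expect_equal(metric_roc_area(labs, rep(0.5, 10)), 0.5)
  set.seed(131)
  for (i in 1:10) {
    labs <- sample(rep(c("R-gene", "non-R-gene"), each = 10))
    scores <- round(runif(20), 1)  # coarse scores force ties
    auc <- metric_roc_area(labs, scores)
    expect_equal(auc, oracle_roc_area(labs, scores))
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- as.numeric(pROC::auc(pROC::roc(
        response = labs, predictor = scores,
        levels = c("non-R-gene", "R-gene"), direction = "<", quiet = TRUE)))
      expect_equal(auc, ref)
    }
  }
})

test_that("training is deterministic and separates a separable toy exactly", {
  d <- toy_separable_dataset()
  m1 <- train_model(d, seed = 5)
  m2 <- train_model(d, seed = 5)
  p1 <- predict_model(m1, d$features)
  p2 <- predict_model(m2, d$features)
  expect_identical(p1$score, p2$score)
  expect_equal(p1$label, as.character(d$labels))  # 100% training accuracy
  # scores are invariant to row order
  perm <- sample(nrow(d$features))
  p3 <- predict_model(m1, d$features[perm, ])
  expect_equal(p3$score, p1$score[perm])
})

test_that("prediction enforces the training feature schema", {
  d <- toy_separable_dataset()
  m <- train_model(d, seed = 1)
  bad <- d$features
  colnames(bad) <- c("x", "z")
  expect_error(predict_model(m, bad), "schema mismatch.*z")
  # column permutation is reordered, not rejected
  p <- predict_model(m, d$features[, c("y", "x")])
  expect_equal(p$score, predict_model(m, d$features)$score)
  expect_equal(nrow(predict_model(m, d$features[0, , drop = FALSE])), 0L)
})

test_that("training rejects degenerate inputs", {
  d <- toy_separable_dataset()
  single <- d
  single$labels <- factor(rep("R-gene", nrow(d$features)),
                          levels = levels(d$labels))
  expect_error(train_model(structure(single, class = "labeled_dataset")),
               "2 instances per class")
  nan_feat <- d$features; nan_feat[1, 1] <- NA
  expect_error(labeled_dataset(nan_feat, d$labels), "missing")
})

test_that("per-instance weights steer the random forest", {
  # weights that massively favor the negative class drag scores down
  d <- synthetic_feature_dataset(30, 30, effect = 0.15, seed = 9)
  w_neg <- weighted_sample(d, c("R-gene" = 1e-3, "non-R-gene" = 1))
  m_plain <- train_model(d, seed = 2)
  m_neg <- train_model(w_neg, seed = 2)
  s_plain <- mean(predict_model(m_plain, d$features)$score)
  s_neg <- mean(predict_model(m_neg, d$features)$score)
  expect_lt(s_neg, s_plain)
})

test_that("stratified CV pools predictions, conserves counts and reproduces", {
  d <- synthetic_feature_dataset(20, 30, effect = 0.4, seed = 10)
  r <- cross_validate(d, k = 5, seed = 3)
  expect_equal(r$n, 50L)
  expect_equal(r$protocol, "cv5")
  folds <- attr(r, "folds")
  # stratification: each fold holds 4 positives and 6 negatives
  for (f in 1:5) {
    expect_equal(sum(d$labels[folds == f] == "R-gene"), 4L)
  }
  r2 <- cross_validate(d, k = 5, seed = 3)
  expect_identical(attr(r, "scores"), attr(r2, "scores"))
  expect_error(cross_validate(d, k = 25, seed = 1), "smaller class")
})

test_that("leave-one-out on a tiny toy runs at the k boundary", {
  d <- toy_separable_dataset(n_per_class = 5)
  r <- cross_validate(d, k = 5, seed = 1)
  expect_equal(r$n, 10L)
  expect_equal(r$Acc, 100)
})

test_that("balanced evaluation satisfies Acc = 100 (SN + SP) / 2 exactly", {
  d <- synthetic_feature_dataset(25, 25, effect = 0.2, seed = 11)
  r <- cross_validate(d, k = 5, seed = 4)
  expect_equal(r$Acc, 100 * (r$SN + r$SP) / 2, tolerance = 1e-12)
})

test_that("baseline learners run behind the same interface", {
  skip_if_not_installed("e1071")
  d <- toy_separable_dataset()
  for (lrn in c("svm", "naive_bayes")) {
    m <- train_model(d, learner_spec(lrn), seed = 1)
    p <- predict_model(m, d$features)
    expect_true(all(p$score >= 0 & p$score <= 1))
    expect_equal(p$label, as.character(d$labels))
  }
})

test_that("evaluation reports serialize to JSON with their confusion matrix", {
  d <- toy_separable_dataset()
  r <- evaluate_model(train_model(d, seed = 1), d, protocol = "holdout")
  f <- withr::local_tempfile(fileext = ".json")
  write_eval_report(r, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$Acc, r$Acc)
  expect_equal(back$confusion$TP, r$confusion$TP)
})
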