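study_labels <- rep(c("A", "NA"), c(71, 194))

test_that("stratified folds preserve class proportions and fold sizes", {
  plan <- stratified_kfold(study_labels, k = 5, seed = 1)
  expect_s3_class(plan, "fold_plan")
  sizes <- table(plan$fold)
  expect_true(all(sizes == 53))
  a_counts <- table(plan$fold[study_labels == "A"])
  expect_setequal(as.integer(a_counts), c(14, 14, 14, 14, 15))
  na_counts <- table(plan$fold[study_labels == "NA"])
  expect_true(all(na_counts %in% c(38, 39)))
})

test_that("fold plans are deterministic in the seed, variable across seeds", {
  p1 <- stratified_kfold(study_labels, k = 5, seed = 9)
  p2 <- stratified_kfold(study_labels, k = 5, seed = 9)
  p3 <- stratified_kfold(study_labels, k = 5, seed = 10)
  expect_identical(p1$fold, p2$fold)
  expect_false(identical(p1$fold, p3$fold))
  # different seeds keep identical per-fold class counts
  expect_equal(sort(as.integer(table(p3$fold[study_labels == "A"]))),
               sort(as.integer(table(p1$fold[study_labels == "A"]))))
})

test_that("degenerate fold requests error", {
  expect_error(stratified_kfold(study_labels, k = 1), "at least 2")
  expect_error(stratified_kfold(c("A", "A", "NA", "NA", "NA"), k = 3),
               "fewer than k")
})

test_that("subject-level grouping keeps both breasts in one fold", {
  labels <- rep(c("A", "NA"), c(20, 80))
  groups <- rep(sprintf("S%02d", 1:50), each = 2)
  plan <- stratified_kfold(labels, k = 5, seed = 3, groups = groups)
  expect_identical(plan$grouping, "group")
  per_group_folds <- tapply(plan$fold, groups, function(f) length(unique(f)))
  expect_true(all(per_group_folds == 1))
})

test_that("all four classifiers fit a separable toy exactly", {
  set.seed(131)
  x <- data.frame(f1 = c(rnorm(5, -3), rnorm(5, 3)),
                  f2 = c(rnorm(5, -3), rnorm(5, 3)))
  y <- rep(c("NA", "A"), each = 5)
  for (kind in c("lsvm", "qsvm", "lr", "ct")) {
    model <- train_classifier(kind, x, y)
    expect_identical(as.character(predict(model, x)), y, label = kind)
  }
})

test_that("the coarse tree never exceeds four internal splits", {
  set.seed(141)
  x <- data.frame(matrix(rnorm(200 * 5), 200, 5))
  y <- sample(c("A", "NA"), 200, replace = TRUE, prob = c(0.3, 0.7))
  model <- train_classifier("ct", x, y)
  n_splits <- sum(model$fit$frame$var != "<leaf>")
  expect_lte(n_splits, 4)
})

test_that("the quadratic kernel separates XOR clusters where linear cannot", {
  set.seed(151)
  centers <- expand.grid(c(-2, 2), c(-2, 2))
  x <- data.frame(
    f1 = rep(centers[, 1], each = 25) + rnorm(100, sd = 0.2),
    f2 = rep(centers[, 2], each = 25) + rnorm(100, sd = 0.2)
  )
  y <- rep(c("A", "NA", "NA", "A"), each = 25)  # same-sign product -> A
  qs <- train_classifier("qsvm", x, y)
  ls <- train_classifier("lsvm", x, y)
  acc <- function(m) mean(as.character(predict(m, x)) == y)
  expect_equal(acc(qs), 1)
  expect_lte(acc(ls), 0.75)
})

test_that("unknown kinds and constant columns are handled", {
  x <- data.frame(f1 = rnorm(20), flat = rep(1, 20))
  y <- rep(c("A", "NA"), 10)
  expect_error(train_classifier("mlp", x, y), "unknown classifier")
  expect_warning(m <- train_classifier("lsvm", x, y), "constant")
  expect_identical(m$std$features, "f1")
  expect_error(suppressWarnings(
    train_classifier("lr", data.frame(f = rep(0, 8)), rep(c("A", "NA"), 4))
  ), "constant")
})

test_that("metric arithmetic reproduces hand-computed confusion tables", {
  m <- compute_metrics(tp = 3, tn = 4, fp = 1, fn = 2)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$f1, 2 / 3)

  perfect <- compute_metrics(tp = 5, tn = 5, fp = 0, fn = 0)
  expect_true(all(unlist(perfect) == 1))

  deg <- compute_metrics(tp = 0, tn = 5, fp = 0, fn = 0)
  expect_equal(deg$precision, 0)
  expect_true("precision" %in% attr(deg, "undefined_metrics"))
})

test_that("F1 equals 2PR/(P+R) on random confusion counts", {
  set.seed(161)
  tp <- sample(0:50, 500, TRUE); tn <- sample(0:50, 500, TRUE)
  fp <- sample(0:50, 500, TRUE); fn <- sample(0:50, 500, TRUE)
  keep <- tp + tn + fp + fn > 0
  m <- compute_metrics(tp[keep], tn[keep], fp[keep], fn[keep])
  p <- m$precision; r <- m$recall
  ok <- p + r > 0
  expect_equal(m$f1[ok], 2 * p[ok] * r[ok] / (p[ok] + r[ok]),
               tolerance = 1e-12)
})

test_that("cross-validation pools every sample exactly once", {
  tbl <- study_feature_table(17, hotspot_delta = 2)
  plan <- stratified_kfold(tbl$label, k = 5, seed = 17)
  run <- cross_validate(tbl, c("max", "mean", "contrast"), "ct", plan)
  expect_identical(sort(run$predictions$.row), seq_len(nrow(tbl)))
  # pooled counts equal the summed per-fold counts
  pooled <- confusion_counts(run$predictions$truth, run$predictions$pred)
  expect_equal(pooled$tp, sum(run$folds$tp))
  expect_equal(pooled$tn, sum(run$folds$tn))
  expect_equal(pooled$fp, sum(run$folds$fp))
  expect_equal(pooled$fn, sum(run$folds$fn))
  # per-fold metrics agree with brute-force recomputation from predictions
  for (f in 1:5) {
    sub <- run$predictions[run$predictions$fold == f, ]
    cc <- confusion_counts(sub$truth, sub$pred)
    expect_equal(run$folds$accuracy[f],
                 (cc$tp + cc$tn) / nrow(sub), tolerance = 1e-12)
  }
  # rerun with the same seed is identical
  run2 <- cross_validate(tbl, c("max", "mean", "contrast"), "ct", plan)
  expect_identical(run$predictions, run2$predictions)
})

test_that("tidy and glance expose cross-validation results", {
  tbl <- study_feature_table(18, hotspot_delta = 2)
  plan <- stratified_kfold(tbl$label, k = 5, seed = 18)
  run <- cross_validate(tbl, c("max", "mean"), "lr", plan)
  td <- tidy(run)
  expect_equal(nrow(td), 25)  # 5 folds x 5 metrics
  gl <- glance(run)
  expect_equal(gl$n, 265)
  expect_true("mean_accuracy" %in% names(gl))
})

test_that("label permutation destroys the class signal", {
  tbl <- study_feature_table(19, hotspot_delta = 2)
  plan <- stratified_kfold(tbl$label, k = 5, seed = 19)
  observed <- cross_validate(tbl, c("max", "mean", "contrast"), "ct", plan)
  obs_acc <- mean(observed$folds$accuracy)
  set.seed(20)
  null_acc <- vapply(1:20, function(i) {
    shuffled <- tbl
    shuffled$label <- sample(shuffled$label)
    p <- stratified_kfold(shuffled$label, k = 5, seed = i)
    mean(cross_validate(shuffled, c("max", "mean", "contrast"), "ct",
                        p)$folds$accuracy)
  }, numeric(1))
  expect_gt(obs_acc, max(null_acc))
  expect_lt(abs(mean(null_acc) - study_majority_rate), 0.08)
})
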