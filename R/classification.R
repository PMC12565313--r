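#' Stratified k-fold plan
#'
#' Partitions samples into `k` folds preserving the class distribution: each
#' class is split as evenly as possible (per-fold class counts differ by at
#' most one) and class remainders are placed on the folds with the smallest
#' running totals, so fold sizes are also as equal as possible. With 265
#' samples split 71/194 and `k = 5`, every fold has exactly 53 samples with
#' 14--15 positives. Deterministic given `seed`.
#'
#' With `groups` (e.g. subject ids), grouping is subject-level: all samples of
#' a group share a fold, and groups are stratified by their group-level label
#' (positive if any member is positive). This prevents leakage between the two
#' breasts of one subject; per-fold class proportions are then approximate.
#'
#' @param labels Character/factor vector of per-sample labels.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the shuffling.
#' @param groups Optional grouping vector (same length as `labels`).
#' @param positive Positive-class label (default `"A"`), used for group-level
#'   stratification.
#' @return A `fold_plan`: list with `k`, integer `fold` assignments, `seed`
#'   and `grouping` (`"sample"` or `"group"`).
#' @export
stratified_kfold <- function(labels, k = 5, seed = 20251013, groups = NULL,
                             positive = "A") {
  labels <- as.character(labels)
  n <- length(labels)
  if (k < 2) stop("k must be at least 2 (no held-out fold otherwise)")

  assign_strata <- function(strata_labels) {
    m <- length(strata_labels)
    counts <- table(strata_labels)
    if (any(counts < k)) {
      stop("class '", names(counts)[which.min(counts)], "' has ",
           min(counts), " members, fewer than k = ", k)
    }
    fold <- integer(m)
    totals <- numeric(k)
    for (cl in names(sort(counts, decreasing = TRUE))) {
      idx <- which(strata_labels == cl)
      idx <- idx[sample.int(length(idx))]
      base <- length(idx) %/% k
      rem <- length(idx) %% k
      per_fold <- rep(base, k)
      if (rem > 0) {
        ord <- order(totals, sample.int(k))   # fill emptiest folds first
        per_fold[ord[seq_len(rem)]] <- base + 1
      }
      fold[idx] <- rep(seq_len(k), per_fold)
      totals <- totals + per_fold
    }
    fold
  }

  set.seed(seed)
  if (is.null(groups)) {
    fold <- assign_strata(labels)
    grouping <- "sample"
  } else {
    stopifnot(length(groups) == n)
    gid <- unique(groups)
    glab <- vapply(gid, function(g) {
      if (any(labels[groups == g] == positive)) positive else "neg"
    }, character(1))
    gfold <- assign_strata(glab)
    fold <- gfold[match(groups, gid)]
    grouping <- "group"
  }
  structure(list(k = as.integer(k), fold = fold, seed = as.integer(seed),
                 grouping = grouping),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("<fold_plan> k = ", x$k, ", n = ", length(x$fold), ", ",
      x$grouping, "-level, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

standardize_fit <- function(x) {
  center <- vapply(x, mean, numeric(1))
  scale <- vapply(x, stats::sd, numeric(1))
  keep <- is.finite(scale) & scale > 0
  if (!all(keep)) {
    warning("dropping constant feature column(s): ",
            paste(names(x)[!keep], collapse = ", "))
  }
  if (!any(keep)) stop("all feature columns are constant")
  list(center = center[keep], scale = scale[keep], features = names(x)[keep])
}

standardize_apply <- function(x, std) {
  x <- x[std$features]
  as.data.frame(Map(function(col, m, s) (col - m) / s,
                    x, std$center, std$scale))
}

#' Train one of the four benchmark classifiers
#'
#' `"lsvm"` and `"qsvm"` are support vector machines with a linear and a
#' degree-2 polynomial kernel (unit box constraint); `"lr"` is plain
#' maximum-likelihood logistic regression; `"ct"` is a coarse CART tree (Gini
#' impurity) post-pruned to at most `max_splits` internal splits, favouring
#' generalization. Features are standardized to the training mean/sd for the
#' SVMs and LR; constant columns are dropped with a warning.
#'
#' @param kind One of `"lsvm"`, `"qsvm"`, `"lr"`, `"ct"`.
#' @param x Data frame / tibble of numeric features.
#' @param y Labels (coerced to factor `negative, positive`).
#' @param positive Positive-class label (default `"A"`).
#' @param cost SVM box constraint (default 1).
#' @param max_splits Split cap for the coarse tree (default 4).
#' @return A `thermo_model` exposing `predict(model, newdata)`.
#' @export
train_classifier <- function(kind, x, y, positive = "A", cost = 1,
                             max_splits = 4) {
  if (!kind %in% c("lsvm", "qsvm", "lr", "ct")) {
    stop("unknown classifier kind '", kind, "'")
  }
  x <- as.data.frame(x)
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) < 2) stop("training data contains a single class")
  negative <- setdiff(classes, positive)[1]
  yf <- factor(y, levels = c(negative, positive))

  std <- NULL
  fit <- switch(
    kind,
    lsvm = {
      std <- standardize_fit(x)
      e1071::svm(standardize_apply(x, std), yf, kernel = "linear",
                 cost = cost, scale = FALSE)
    },
    qsvm = {
      std <- standardize_fit(x)
      e1071::svm(standardize_apply(x, std), yf, kernel = "polynomial",
                 degree = 2, coef0 = 1, cost = cost, scale = FALSE)
    },
    lr = {
      std <- standardize_fit(x)
      df <- standardize_apply(x, std)
      df$.y <- yf
      # perfect separation is legitimate on separable folds: the fitted
      # class boundary is still usable, so muffle glm.fit's alarms
      withCallingHandlers(
        glm(.y ~ ., data = df, family = binomial(),
            control = list(maxit = 100)),
        warning = function(w) {
          msg <- conditionMessage(w)
          if (grepl("fitted probabilities numerically 0 or 1", msg) ||
              grepl("algorithm did not converge", msg)) {
            invokeRestart("muffleWarning")
          }
        }
      )
    },
    ct = {
      df <- x
      df$.y <- yf
      tree <- rpart::rpart(.y ~ ., data = df, method = "class",
                           control = rpart::rpart.control(
                             cp = 0, minsplit = 5, minbucket = 2,
                             xval = 0, maxcompete = 0, maxsurrogate = 0))
      cpt <- tree$cptable
      ok <- which(cpt[, "nsplit"] <= max_splits)
      best <- ok[which.max(cpt[ok, "nsplit"])]
      rpart::prune(tree, cp = cpt[best, "CP"])
    }
  )
  structure(list(kind = kind, fit = fit, std = std,
                 features = names(x), levels = c(negative, positive),
                 positive = positive),
            class = "thermo_model")
}

#' Predict labels with a trained classifier
#'
#' @param object A `thermo_model`.
#' @param newdata Data frame with the training feature columns.
#' @param ... Unused.
#' @return Factor of predicted labels (`negative, positive` levels).
#' @export
predict.thermo_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[object$features]
  out <- switch(
    object$kind,
    lsvm = ,
    qsvm = predict(object$fit, standardize_apply(newdata, object$std)),
    lr = {
      p <- predict(object$fit, newdata = standardize_apply(newdata, object$std),
                   type = "response")
      factor(ifelse(p > 0.5, object$levels[2], object$levels[1]),
             levels = object$levels)
    },
    ct = predict(object$fit, newdata = newdata, type = "class")
  )
  factor(as.character(out), levels = object$levels)
}

#' @export
print.thermo_model <- function(x, ...) {
  cat("<thermo_model> ", x$kind, " on ", length(x$features),
      " features (positive = ", x$positive, ")\n", sep = "")
  invisible(x)
}

#' Confusion counts for binary predictions
#'
#' @param truth,pred Label vectors; `positive` is the anomalous class.
#' @param positive Positive-class label (default `"A"`).
#' @return One-row tibble `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred, positive = "A") {
  truth <- as.character(truth); pred <- as.character(pred)
  tibble(
    tp = sum(truth == positive & pred == positive),
    tn = sum(truth != positive & pred != positive),
    fp = sum(truth != positive & pred == positive),
    fn = sum(truth == positive & pred != positive)
  )
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)` and F1 `TP/(TP + (FP+FN)/2)`, as
#' proportions in `[0, 1]`. Metrics with a zero denominator are reported as 0
#' and named in the `undefined_metrics` attribute. Vectorized over equal
#' length count vectors.
#'
#' @param tp,tn,fp,fn Non-negative counts (or a single one-row tibble from
#'   [confusion_counts()] passed as `tp`).
#' @return Tibble with columns `accuracy`, `precision`, `recall`,
#'   `specificity`, `f1`.
#' @export
compute_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.data.frame(tp)) {
    counts <- tp
    tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  }
  total <- tp + tn + fp + fn
  if (any(total == 0)) stop("empty confusion table")
  ratio <- function(num, den) ifelse(den == 0, 0, num / den)
  out <- tibble(
    accuracy = (tp + tn) / total,
    precision = ratio(tp, tp + fp),
    recall = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    f1 = ratio(tp, tp + 0.5 * (fp + fn))
  )
  undefined <- c("precision", "recall", "specificity", "f1")[
    c(any(tp + fp == 0), any(tp + fn == 0), any(tn + fp == 0),
      any(tp + 0.5 * (fp + fn) == 0))]
  attr(out, "undefined_metrics") <- undefined
  out
}

#' Stratified cross-validation of one classifier
#'
#' Fits the classifier on `k - 1` folds and predicts the held-out fold, for
#' every fold of the plan; reports per-fold confusion counts and metrics, the
#' across-fold mean and standard deviation of each metric, and the pooled
#' out-of-fold predictions (each sample predicted exactly once), which feed
#' the bootstrap and McNemar evaluations.
#'
#' @param data Tibble with a `label` column and the feature columns in
#'   `features` (plus optional `subject_id`, `side` carried through).
#' @param features Character vector of feature column names to use.
#' @param kind Classifier kind, see [train_classifier()].
#' @param plan A `fold_plan` covering `nrow(data)` samples.
#' @param positive Positive-class label.
#' @param ... Passed to [train_classifier()].
#' @return A `thermo_cv`: list with `kind`, `plan`, per-fold tibble `folds`,
#'   pooled `predictions` tibble (`.row`, `fold`, `truth`, `pred`) and a
#'   `summary` tibble (`metric`, `mean`, `sd`).
#' @export
cross_validate <- function(data, features, kind, plan, positive = "A", ...) {
  stopifnot(inherits(plan, "fold_plan"))
  if (length(plan$fold) != nrow(data)) {
    stop("fold plan covers ", length(plan$fold), " samples but data has ",
         nrow(data), " rows")
  }
  missing <- setdiff(features, names(data))
  if (length(missing)) {
    stop("feature column(s) not in data: ", paste(missing, collapse = ", "))
  }
  labels <- as.character(data$label)

  fold_rows <- list()
  pred_rows <- list()
  for (f in seq_len(plan$k)) {
    train <- plan$fold != f
    test <- !train
    if (length(unique(labels[train])) < 2) {
      stop("fold ", f, ": training split contains a single class")
    }
    model <- train_classifier(kind, data[train, features, drop = FALSE],
                              labels[train], positive = positive, ...)
    pred <- predict(model, data[test, features, drop = FALSE])
    cc <- confusion_counts(labels[test], pred, positive)
    fold_rows[[f]] <- dplyr::bind_cols(tibble(fold = f), cc,
                                       compute_metrics(cc))
    pred_rows[[f]] <- tibble(
      .row = which(test), fold = f,
      subject_id = if ("subject_id" %in% names(data)) data$subject_id[test] else NA_character_,
      side = if ("side" %in% names(data)) data$side[test] else NA_character_,
      truth = labels[test], pred = as.character(pred)
    )
  }
  folds <- list_rbind(fold_rows)
  predictions <- arrange(list_rbind(pred_rows), .data$.row)

  metric_names <- c("accuracy", "precision", "recall", "specificity", "f1")
  summary <- tibble(
    metric = metric_names,
    mean = vapply(metric_names, function(m) mean(folds[[m]]), numeric(1)),
    sd = vapply(metric_names, function(m) stats::sd(folds[[m]]), numeric(1))
  )
  structure(list(kind = kind, plan = plan, folds = folds,
                 predictions = predictions, summary = summary,
                 positive = positive),
            class = "thermo_cv")
}

#' @export
print.thermo_cv <- function(x, ...) {
  acc <- x$summary$mean[x$summary$metric == "accuracy"]
  cat("<thermo_cv> ", x$kind, ", k = ", x$plan$k,
      ", mean accuracy ", sprintf("%.3f", acc), "\n", sep = "")
  invisible(x)
}
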