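metric_value <- function(truth, pred, metric, positive = "A") {
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  switch(metric,
         accuracy = (tp + tn) / (tp + tn + fp + fn),
         precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
         recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
         specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
         f1 = if (tp + 0.5 * (fp + fn) == 0) NA_real_ else
           tp / (tp + 0.5 * (fp + fn)),
         stop("unknown metric '", metric, "'"))
}

#' Percentile bootstrap confidence interval for a classification metric
#'
#' Resamples the observed `(truth, pred)` pairs with replacement `B` times,
#' recomputes the metric on each replicate, and returns the empirical mean
#' and the `(alpha/2, 1 - alpha/2)` percentiles. Replicates on which the
#' metric is undefined (e.g. no positives drawn) are skipped and counted; a
#' warning is attached when more than 10% are skipped. Models are not refit:
#' the resampling quantifies metric variability over the pooled out-of-fold
#' predictions.
#'
#' @param truth,pred Observed and predicted labels (equal length).
#' @param metric One of `"accuracy"`, `"precision"`, `"recall"`,
#'   `"specificity"`, `"f1"`.
#' @param B Bootstrap replications (default 2000); intervals require
#'   `B >= 100`.
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; results are reproducible bit-for-bit given it.
#' @param positive Positive-class label.
#' @return A `thermo_boot` one-row tibble: `metric`, `estimate`, `boot_mean`,
#'   `lower`, `upper`, `B`, `level`, `skipped`.
#' @export
bootstrap_ci <- function(truth, pred, metric = "accuracy", B = 2000,
                         level = 0.95, seed = 1L, positive = "A") {
  truth <- as.character(truth); pred <- as.character(pred)
  n <- length(truth)
  stopifnot(n >= 1, length(pred) == n, B >= 1)
  set.seed(seed)
  vals <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    metric_value(truth[idx], pred[idx], metric, positive)
  }, numeric(1))
  skipped <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("metric undefined on every bootstrap replicate")
  if (skipped / B > 0.1) {
    warning(sprintf("%.1f%% of bootstrap replicates skipped (metric undefined)",
                    100 * skipped / B))
  }
  alpha <- 1 - level
  bounds <- if (B >= 100) {
    unname(quantile(vals, c(alpha / 2, 1 - alpha / 2)))
  } else {
    c(NA_real_, NA_real_)
  }
  out <- tibble(
    metric = metric,
    estimate = metric_value(truth, pred, metric, positive),
    boot_mean = mean(vals),
    lower = bounds[1], upper = bounds[2],
    B = as.integer(B), level = level, skipped = as.integer(skipped)
  )
  structure(out, class = c("thermo_boot", class(out)), seed = seed)
}

#' Bootstrap confidence intervals for all metrics of a CV run
#'
#' Applies [bootstrap_ci()] to the pooled out-of-fold predictions of a
#' [cross_validate()] run, once per metric.
#'
#' @param run A `thermo_cv`.
#' @param B,level,seed See [bootstrap_ci()].
#' @return A `thermo_boot` tibble with one row per metric, plus a
#'   `classifier` column.
#' @export
evaluate_cv <- function(run, B = 2000, level = 0.95, seed = 1L) {
  stopifnot(inherits(run, "thermo_cv"))
  metrics <- c("accuracy", "precision", "recall", "specificity", "f1")
  rows <- lapply(seq_along(metrics), function(i) {
    bootstrap_ci(run$predictions$truth, run$predictions$pred, metrics[i],
                 B = B, level = level, seed = seed + i - 1L,
                 positive = run$positive)
  })
  out <- list_rbind(rows)
  out <- dplyr::bind_cols(tibble(classifier = run$kind), out)
  structure(out, class = c("thermo_boot", class(out)), seed = seed)
}

#' Exact McNemar test between two classifiers' predictions
#'
#' Counts the discordant samples `b` (first classifier correct, second wrong)
#' and `c` (first wrong, second correct) and computes the exact two-sided
#' binomial p-value `min(1, 2 P(X <= min(b, c)))` with `X ~ Binomial(b + c,
#' 1/2)`. `mode = "midp"` subtracts half the point mass at the observed count
#' (mid-p), a less conservative variant whose null distribution is closer to
#' uniform. With no discordant pairs the p-value is 1 (flagged).
#'
#' When `folds` is supplied, the per-fold discordance difference `b_f - c_f`
#' is summarised by its mean and a 95% percentile interval across folds.
#'
#' @param pred_a,pred_b Predictions of the two classifiers on identical
#'   samples.
#' @param truth True labels.
#' @param folds Optional fold index per sample.
#' @param mode `"exact"` (default) or `"midp"`.
#' @return A `thermo_mcnemar` list: `b`, `c`, `p_value`, `mode`,
#'   `no_discordance`, and (with folds) `difference`, `ci_lower`, `ci_upper`,
#'   `per_fold`.
#' @export
mcnemar_test <- function(pred_a, pred_b, truth, folds = NULL,
                         mode = c("exact", "midp")) {
  mode <- match.arg(mode)
  stopifnot(length(pred_a) == length(truth), length(pred_b) == length(truth))
  a_ok <- as.character(pred_a) == as.character(truth)
  b_ok <- as.character(pred_b) == as.character(truth)
  b <- sum(a_ok & !b_ok)
  c <- sum(!a_ok & b_ok)
  nd <- b + c
  p <- if (nd == 0) {
    1
  } else {
    m <- min(b, c)
    tail <- pbinom(m, nd, 0.5)
    if (mode == "midp") tail <- tail - 0.5 * dbinom(m, nd, 0.5)
    min(1, 2 * tail)
  }
  out <- list(b = b, c = c, p_value = p, mode = mode,
              no_discordance = nd == 0)
  if (!is.null(folds)) {
    per_fold <- vapply(sort(unique(folds)), function(f) {
      i <- folds == f
      sum(a_ok[i] & !b_ok[i]) - sum(!a_ok[i] & b_ok[i])
    }, numeric(1))
    out$per_fold <- per_fold
    out$difference <- mean(per_fold)
    qs <- unname(quantile(per_fold, c(0.025, 0.975), type = 7))
    out$ci_lower <- qs[1]
    out$ci_upper <- qs[2]
  }
  structure(out, class = "thermo_mcnemar")
}

#' @export
print.thermo_mcnemar <- function(x, ...) {
  cat("<thermo_mcnemar> b = ", x$b, ", c = ", x$c, ", ", x$mode,
      " p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Pairwise McNemar comparison of cross-validated classifiers
#'
#' Compares every unordered pair of CV runs on their pooled out-of-fold
#' predictions. All runs must share the same fold plan (identical
#' assignments), so predictions are paired sample by sample.
#'
#' @param runs Named list of `thermo_cv` objects (names default to kinds).
#' @param mode Passed to [mcnemar_test()].
#' @return A `thermo_pairwise` tibble: `pair`, `b`, `c`, `difference`,
#'   `ci_lower`, `ci_upper`, `p_value`.
#' @export
pairwise_compare <- function(runs, mode = c("exact", "midp")) {
  mode <- match.arg(mode)
  stopifnot(length(runs) >= 2)
  if (is.null(names(runs)) || any(names(runs) == "")) {
    names(runs) <- vapply(runs, function(r) r$kind, character(1))
  }
  ref <- runs[[1]]
  for (r in runs[-1]) {
    if (!identical(r$plan$fold, ref$plan$fold)) {
      stop("fold plans differ between runs; refit on a shared plan")
    }
    if (!identical(r$predictions$truth, ref$predictions$truth)) {
      stop("runs were evaluated on different samples")
    }
  }
  pairs <- utils::combn(names(runs), 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    ra <- runs[[pr[1]]]; rb <- runs[[pr[2]]]
    mc <- mcnemar_test(ra$predictions$pred, rb$predictions$pred,
                       ra$predictions$truth, folds = ra$predictions$fold,
                       mode = mode)
    tibble(pair = paste(pr[1], "vs", pr[2]), b = mc$b, c = mc$c,
           difference = mc$difference, ci_lower = mc$ci_lower,
           ci_upper = mc$ci_upper, p_value = mc$p_value)
  })
  out <- list_rbind(rows)
  structure(out, class = c("thermo_pairwise", class(out)), mode = mode)
}
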