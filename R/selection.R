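#' Welch two-sample t-test
#'
#' `t = (mean1 - mean2) / sqrt(s1^2/n1 + s2^2/n2)` with sample (n-1) variances
#' by default, Welch--Satterthwaite degrees of freedom, and a two-sided
#' p-value from the t distribution. `var = "population"` uses 1/n variances
#' for exact replication of population-moment formulations.
#'
#' Degenerate inputs: zero variance in both groups gives `t = 0, p = 1` when
#' the means are equal, and a `p = 0` sentinel with a warning when they are
#' not.
#'
#' @param x,y Numeric vectors (each of length >= 2, finite).
#' @param var `"sample"` (default) or `"population"` variance denominator.
#' @return A list with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4, p ~ 0.0213
welch_t <- function(x, y, var = c("sample", "population")) {
  var <- match.arg(var)
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- if (var == "sample") stats::var(x) else mean((x - m1)^2)
  v2 <- if (var == "sample") stats::var(y) else mean((y - m2)^2)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    if (m1 == m2) {
      return(list(statistic = 0, df = NA_real_, p_value = 1))
    }
    warning("zero variance in both groups with unequal means: p = 0 sentinel")
    return(list(statistic = sign(m1 - m2) * Inf, df = NA_real_, p_value = 0))
  }
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(statistic = t_stat, df = df, p_value = 2 * pt(-abs(t_stat), df))
}

feature_columns <- function(table) {
  candidates <- setdiff(names(table), c("subject_id", "side", "label", "fold"))
  candidates[vapply(table[candidates], is.numeric, logical(1))]
}

#' Select discriminative features with per-feature Welch t-tests
#'
#' Runs [welch_t()] on every numeric feature column between the anomalous
#' (`"A"`, class 1) and control (`"NA"`, class 2) breast samples and retains
#' features with `p_adjusted < alpha`. No multiplicity correction is applied
#' by default (raw threshold); `adjust = "holm"` or `"BH"` are available.
#'
#' @param table Feature tibble with a `label` column (`"A"`/`"NA"`) and
#'   numeric feature columns (e.g. from [extract_cohort_features()]).
#' @param alpha Significance level (default 0.05).
#' @param var Variance convention passed to [welch_t()].
#' @param adjust Multiple-testing adjustment (`p.adjust` method), default
#'   `"none"`.
#' @param positive Label of class 1 (default `"A"`).
#' @return A `thermo_selection` tibble: one row per feature with class means,
#'   class variances, group sizes, `statistic`, `df`, `p_value`, `p_adjusted`
#'   and `selected`; attributes `alpha` and `adjust`.
#' @export
select_features <- function(table, alpha = 0.05,
                            var = c("sample", "population"),
                            adjust = "none", positive = "A") {
  var <- match.arg(var)
  if (!"label" %in% names(table)) stop("table must contain a 'label' column")
  labels <- as.character(table$label)
  classes <- unique(labels)
  if (length(classes) < 2) {
    stop("single-class input: both classes are required for selection")
  }
  negative <- setdiff(classes, positive)[1]
  if (sum(labels == positive) < 2 || sum(labels == negative) < 2) {
    stop("each class needs at least 2 samples")
  }
  cols <- feature_columns(table)
  if (length(cols) == 0) stop("no numeric feature columns found")

  rows <- lapply(cols, function(f) {
    x <- table[[f]][labels == positive]
    y <- table[[f]][labels == negative]
    keep <- is.finite(x); x <- x[keep]
    keep <- is.finite(y); y <- y[keep]
    if (length(x) < 2 || length(y) < 2) {
      return(tibble(feature = f, mean_1 = NA_real_, mean_2 = NA_real_,
                    var_1 = NA_real_, var_2 = NA_real_,
                    n_1 = length(x), n_2 = length(y),
                    statistic = NA_real_, df = NA_real_, p_value = NA_real_))
    }
    wt <- welch_t(x, y, var = var)
    tibble(feature = f, mean_1 = mean(x), mean_2 = mean(y),
           var_1 = if (var == "sample") stats::var(x) else mean((x - mean(x))^2),
           var_2 = if (var == "sample") stats::var(y) else mean((y - mean(y))^2),
           n_1 = length(x), n_2 = length(y),
           statistic = wt$statistic, df = wt$df, p_value = wt$p_value)
  })
  out <- list_rbind(rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  out$selected <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  structure(out, class = c("thermo_selection", class(out)),
            alpha = alpha, adjust = adjust, positive = positive)
}

#' Apply the p-value threshold of the selection rule
#'
#' Marks rows of a `(feature, p_value)` table as selected when
#' `p_value < alpha`. Useful for re-applying the decision rule to published
#' per-feature p-values.
#'
#' @param table Tibble/data frame with columns `feature` and `p_value`.
#' @param alpha Significance level (default 0.05).
#' @return The table with a logical `selected` column added.
#' @export
#' @examples
#' apply_selection_threshold(dmr_reference_pvalues())
apply_selection_threshold <- function(table, alpha = 0.05) {
  stopifnot(all(c("feature", "p_value") %in% names(table)))
  out <- as_tibble(table)
  out$selected <- out$p_value < alpha
  out
}

#' Published per-feature p-values from a DMR breast-thermography study
#'
#' The per-feature Welch t-test p-values reported by a published
#' feature-selection analysis of the DMR (Database for Mastology Research)
#' clinical thermograms, for the 13 descriptors computed by this package.
#' Shipped so the selection decision rule can be exercised against published
#' reference values without the clinical images.
#'
#' @return A tibble with columns `feature` and `p_value` (13 rows).
#' @export
dmr_reference_pvalues <- function() {
  path <- system.file("extdata", "reference_pvalues.csv",
                      package = "thermobreast", mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Names of the selected features
#'
#' @param selection A `thermo_selection` (or any table with `feature` and
#'   `selected` columns).
#' @return Character vector of selected feature names.
#' @export
selected_features <- function(selection) {
  selection$feature[selection$selected]
}

#' @export
print.thermo_selection <- function(x, ...) {
  cat("<thermo_selection> alpha = ", attr(x, "alpha"), ", ",
      sum(x$selected), "/", nrow(x), " features selected\n", sep = "")
  NextMethod()
}
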