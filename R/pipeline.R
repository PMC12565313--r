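#' Configure a full pipeline run
#'
#' @param cohort A [cohort_config()] to simulate, or a manifest CSV path
#'   (written by [write_cohort()], or pointing at real radiometric data) via
#'   `manifest`.
#' @param manifest Optional manifest path; overrides `cohort` when given.
#' @param G,calibration,include_glcm_energy Feature settings, see
#'   [extract_features()].
#' @param alpha Selection significance level.
#' @param k Cross-validation folds.
#' @param grouping `"subject"` (default; both breasts of a subject share a
#'   fold) or `"sample"`.
#' @param classifiers Character vector of classifier kinds.
#' @param B,level Bootstrap replications and confidence level.
#' @param seed Integer seed driving fold shuffling and the bootstrap.
#' @param out_dir Optional output directory for stage artifacts.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(), manifest = NULL,
                            G = 256, calibration = NULL,
                            include_glcm_energy = FALSE,
                            alpha = 0.05, k = 5,
                            grouping = c("subject", "sample"),
                            classifiers = c("lsvm", "qsvm", "lr", "ct"),
                            B = 2000, level = 0.95, seed = 20251013,
                            out_dir = NULL) {
  grouping <- match.arg(grouping)
  structure(
    list(cohort = cohort, manifest = manifest, G = G,
         calibration = calibration,
         include_glcm_energy = include_glcm_energy, alpha = alpha, k = k,
         grouping = grouping, classifiers = classifiers, B = B,
         level = level, seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "out_dir")])
}

write_stage <- function(out_dir, name, obj) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, name)
  if (grepl("\\.csv$", name)) {
    write.csv(obj, path, row.names = FALSE)
  } else if (grepl("\\.json$", name)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Run the full thermogram-classification pipeline
#'
#' Executes simulate/load -> per-breast feature extraction -> Welch t-test
#' selection -> stratified k-fold cross-validation of every configured
#' classifier (on the selected features only) -> bootstrap confidence
#' intervals and pairwise McNemar comparisons. Synthetic and real manifests
#' traverse identical code paths. When `out_dir` is set, each stage writes its
#' artifact (`features.csv`, `selection.csv`, `selected_features.json`,
#' `cv_metrics.csv`, `bootstrap_ci.csv`, `mcnemar.csv`, `report.json`).
#'
#' @param config A [pipeline_config()].
#' @return A `thermo_report`: list with `features`, `selection`, `runs`,
#'   `cv_table` (per-classifier mean +/- sd per metric, in percent),
#'   `ci_table`, `mcnemar_table` and a `provenance` block
#'   (config hash, seed, package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  cohort <- if (!is.null(config$manifest)) {
    read_cohort(config$manifest)
  } else {
    generate_cohort(config$cohort)
  }

  features <- extract_cohort_features(
    cohort, G = config$G, calibration = config$calibration,
    include_glcm_energy = config$include_glcm_energy
  )
  write_stage(config$out_dir, "features.csv", features)

  selection <- select_features(features, alpha = config$alpha)
  write_stage(config$out_dir, "selection.csv", as.data.frame(selection))
  keep <- selected_features(selection)
  if (length(keep) == 0) stop("no features selected at alpha = ", config$alpha)
  write_stage(config$out_dir, "selected_features.json", keep)

  groups <- if (config$grouping == "subject") features$subject_id else NULL
  plan <- stratified_kfold(features$label, k = config$k, seed = config$seed,
                           groups = groups)
  runs <- lapply(config$classifiers, function(kind) {
    cross_validate(features, keep, kind, plan)
  })
  names(runs) <- config$classifiers

  cv_table <- list_rbind(lapply(runs, function(r) {
    wide <- r$summary |>
      mutate(value = sprintf("%.2f%% +/- %.3f", 100 * .data$mean, .data$sd)) |>
      select(all_of(c("metric", "value"))) |>
      tidyr::pivot_wider(names_from = "metric", values_from = "value")
    dplyr::bind_cols(tibble(classifier = r$kind), wide)
  }))
  write_stage(config$out_dir, "cv_metrics.csv", cv_table)

  ci_table <- list_rbind(imap(runs, function(r, nm) {
    evaluate_cv(r, B = config$B, level = config$level,
                seed = config$seed + match(nm, names(runs)))
  }))
  write_stage(config$out_dir, "bootstrap_ci.csv", as.data.frame(ci_table))

  mcnemar_table <- pairwise_compare(runs)
  write_stage(config$out_dir, "mcnemar.csv", as.data.frame(mcnemar_table))

  report <- structure(
    list(
      features = features,
      selection = selection,
      runs = runs,
      cv_table = cv_table,
      ci_table = ci_table,
      mcnemar_table = mcnemar_table,
      provenance = list(
        config_hash = config_hash(config),
        seed = config$seed,
        package_version = as.character(packageVersion("thermobreast"))
      )
    ),
    class = "thermo_report"
  )
  write_stage(config$out_dir, "report.json", list(
    provenance = report$provenance,
    selected_features = keep,
    cv = cv_table,
    bootstrap_ci = as.data.frame(ci_table),
    mcnemar = as.data.frame(mcnemar_table)
  ))
  report
}

#' @export
print.thermo_report <- function(x, ...) {
  cat("<thermo_report> seed ", x$provenance$seed,
      ", config ", substr(x$provenance$config_hash, 1, 8), "\n", sep = "")
  cat("selected features: ",
      paste(selected_features(x$selection), collapse = ", "), "\n", sep = "")
  print(x$cv_table)
  invisible(x)
}
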