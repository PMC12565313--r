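#' Tidy a feature-selection result
#'
#' @param x A `thermo_selection`.
#' @param ... Unused.
#' @return A plain tibble, one row per feature.
#' @method tidy thermo_selection
#' @export
tidy.thermo_selection <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "thermo_selection")
  out
}

#' @rdname tidy.thermo_selection
#' @method glance thermo_selection
#' @export
glance.thermo_selection <- function(x, ...) {
  tibble(n_features = nrow(x), n_selected = sum(x$selected),
         alpha = attr(x, "alpha"), adjust = attr(x, "adjust"))
}

#' Tidy a cross-validation run
#'
#' @param x A `thermo_cv`.
#' @param ... Unused.
#' @return Long tibble: `classifier`, `fold`, `metric`, `value`.
#' @method tidy thermo_cv
#' @export
tidy.thermo_cv <- function(x, ...) {
  out <- pivot_longer(x$folds,
                      cols = c("accuracy", "precision", "recall",
                               "specificity", "f1"),
                      names_to = "metric", values_to = "value")
  dplyr::bind_cols(tibble(classifier = x$kind), out)
}

#' @rdname tidy.thermo_cv
#' @method glance thermo_cv
#' @export
glance.thermo_cv <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  dplyr::bind_cols(tibble(classifier = x$kind, k = x$plan$k,
                          n = nrow(x$predictions)), wide)
}

#' Tidy bootstrap CI and McNemar tables
#'
#' @param x A `thermo_boot` or `thermo_pairwise`.
#' @param ... Unused.
#' @return A plain tibble.
#' @method tidy thermo_boot
#' @export
tidy.thermo_boot <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "thermo_boot")
  out
}

#' @rdname tidy.thermo_boot
#' @method tidy thermo_pairwise
#' @export
tidy.thermo_pairwise <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "thermo_pairwise")
  out
}

#' @rdname tidy.thermo_boot
#' @method tidy thermo_mcnemar
#' @export
tidy.thermo_mcnemar <- function(x, ...) {
  tibble(b = x$b, c = x$c, p_value = x$p_value, mode = x$mode,
         difference = x$difference %||% NA_real_,
         ci_lower = x$ci_lower %||% NA_real_,
         ci_upper = x$ci_upper %||% NA_real_)
}
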