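#' Plot a thermogram as a temperature raster
#'
#' @param x A `thermogram` (or numeric matrix), degC.
#' @param mask Optional logical matrix; out-of-mask pixels are dimmed.
#' @param limits Fill limits, defaults to the radiometric display range
#'   20--36 degC.
#' @return A ggplot object.
#' @export
plot_thermogram <- function(x, mask = NULL, limits = c(20, 36)) {
  grid <- unclass(as.matrix(x))
  df <- tibble(
    row = rep(seq_len(nrow(grid)), times = ncol(grid)),
    col = rep(seq_len(ncol(grid)), each = nrow(grid)),
    temp = as.vector(grid),
    in_mask = if (is.null(mask)) TRUE else as.vector(mask > 0)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$temp,
                                      alpha = .data$in_mask)) +
    ggplot2::scale_fill_viridis_c(option = "inferno", limits = limits,
                                  oob = scales_squish, name = "degC") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25),
                                guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}

# clamp out-of-bounds fill values instead of dropping them
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  pmin(pmax(x, range[1]), range[2])
}

#' Autoplot: per-feature selection p-values
#'
#' Lollipop chart of per-feature p-values on a log scale, with the selection
#' threshold drawn as a dashed line.
#'
#' @param object A `thermo_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot thermo_selection
#' @export
autoplot.thermo_selection <- function(object, ...) {
  alpha <- attr(object, "alpha")
  df <- mutate(as_tibble(object),
               p_shown = pmax(.data$p_value, 1e-16),
               feature = stats::reorder(.data$feature, .data$p_value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$p_shown,
                                   colour = .data$selected)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$feature, yend = 1)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "Welch t-test p-value",
                  colour = paste0("p < ", alpha))
}

#' Autoplot: per-fold cross-validation metrics
#'
#' @param object A `thermo_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot thermo_cv
#' @export
autoplot.thermo_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$fold)), size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = paste("Cross-validation:", object$kind),
                  x = NULL, y = "metric value", colour = "fold")
}
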