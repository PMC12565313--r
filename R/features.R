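#' @rdname extract_features
#' @format NULL
#' @export
thermo_feature_names <- c(
  "mean", "std", "variance", "skewness", "kurtosis", "entropy",
  "min", "max", "cv", "energy", "homogeneity", "contrast", "correlation"
)

sample_pixels <- function(sample) {
  if (inherits(sample, "breast_sample")) sample$pixels else as.numeric(sample)
}

#' Statistical descriptors of a breast sample
#'
#' Computes the first-order descriptors over the in-mask temperature pixels:
#' mean, population standard deviation and variance (1/n denominator),
#' a Pearson-type skewness `(mean - median) / sd`, non-excess kurtosis
#' `E[(x - mean)^4] / sd^4`, min, max, coefficient of variation
#' `sd / mean * 100` (percent), and the energy `E = sum of temperatures`
#' (degC x pixels). For a constant sample (`sd = 0`) skewness and kurtosis are
#' undefined and returned as `NA` with a warning; `cv` is 0.
#'
#' @param sample A `breast_sample` or a numeric vector of temperatures (degC).
#' @return A one-row tibble with columns
#'   `mean, std, variance, skewness, kurtosis, min, max, cv, energy`.
#' @export
#' @examples
#' statistical_features(c(1, 2, 3, 4))
statistical_features <- function(sample) {
  as_tibble(stat_features_list(sample_pixels(sample)))
}

# hot path shared with extract_features: no tibble construction
stat_features_list <- function(x) {
  if (length(x) < 2) stop("need at least 2 in-mask pixels")
  if (any(!is.finite(x))) stop("non-finite pixel values")
  mu <- mean(x)
  if (mu <= 0) stop("mean temperature must be positive (got ", mu, ")")
  sigma2 <- mean((x - mu)^2)
  sigma <- sqrt(sigma2)
  if (sigma == 0) {
    warning("constant sample: skewness and kurtosis are undefined")
    skew <- NA_real_
    kurt <- NA_real_
  } else {
    skew <- (mu - median(x)) / sigma
    kurt <- mean((x - mu)^4) / sigma2^2
  }
  list(
    mean = mu, std = sigma, variance = sigma2,
    skewness = skew, kurtosis = kurt,
    min = min(x), max = max(x),
    cv = if (sigma == 0) 0 else sigma / mu * 100,
    energy = sum(x)
  )
}

#' Quantize a breast sample to gray levels
#'
#' Maps in-mask temperatures to integer levels `0 .. G-1` by
#' `floor((clip(T, low, high) - low) / (high - low) * G)`, with `T = high`
#' mapping to `G - 1`. The default calibration is the sample's own in-mask
#' `(min, max)`; pass e.g. `calibration = c(20, 36)` for a fixed radiometric
#' display range shared across samples.
#'
#' @param sample A `breast_sample`, or a numeric matrix (full mask assumed).
#' @param G Number of gray levels (default 256).
#' @param calibration Length-2 `(low, high)` degC, or `NULL` for per-sample
#'   min/max.
#' @return A `quantized_sample`: list with integer matrix `levels`, logical
#'   `mask`, `G` and `calibration`.
#' @export
quantize_sample <- function(sample, G = 256, calibration = NULL) {
  if (inherits(sample, "breast_sample")) {
    crop <- sample$crop
    mask <- sample$mask
  } else {
    crop <- as.matrix(sample)
    mask <- matrix(TRUE, nrow(crop), ncol(crop))
  }
  stopifnot(G >= 2)
  if (is.null(calibration)) calibration <- range(crop[mask])
  low <- calibration[1]; high <- calibration[2]
  if (low > high) stop("calibration low must be <= high")
  levels <- matrix(0L, nrow(crop), ncol(crop))
  if (low == high) {
    warning("degenerate calibration (min == max): all levels set to 0")
  } else {
    clipped <- pmin(pmax(crop, low), high)
    lv <- floor((clipped - low) / (high - low) * G)
    lv[lv >= G] <- G - 1
    levels <- matrix(as.integer(lv), nrow(crop), ncol(crop))
  }
  structure(list(levels = levels, mask = mask, G = as.integer(G),
                 calibration = c(low, high)),
            class = "quantized_sample")
}

#' Gray-level co-occurrence matrix of a quantized sample
#'
#' Accumulates co-occurrence counts between each pixel and its neighbours at
#' distance one in the four directions 0, 45, 90 and 135 degrees; the four
#' directional matrices are integrated into one and symmetrized (each pair is
#' counted in both orders), then normalized to probabilities. Pairs with
#' either endpoint outside the mask are skipped, so non-breast pixels never
#' contribute texture.
#'
#' @param q A `quantized_sample`.
#' @return A `thermo_glcm`: list with the `G x G` probability matrix `P`, `G`,
#'   the marginal means `mu_x`, `mu_y` and deviations `sigma_x`, `sigma_y`.
#' @export
compute_glcm <- function(q) {
  stopifnot(inherits(q, "quantized_sample"))
  G <- q$G
  lv <- q$levels
  mask <- q$mask
  nr <- nrow(lv); nc <- ncol(lv)
  offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  codes <- integer(0)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    if (length(r1) < 1 || length(c1) < 1) next
    a <- lv[r1, c1, drop = FALSE]
    b <- lv[r1 + dr, c1 + dc, drop = FALSE]
    ok <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
    if (!any(ok)) next
    ia <- a[ok]; ib <- b[ok]
    codes <- c(codes, ia * G + ib, ib * G + ia)  # symmetric accumulation
  }
  if (length(codes) == 0) stop("no valid in-mask pixel pairs for the GLCM")
  counts <- tabulate(codes + 1L, nbins = G * G)
  P <- matrix(counts / sum(counts), G, G, byrow = TRUE)
  i <- seq_len(G) - 1
  px <- rowSums(P)
  py <- colSums(P)
  mu_x <- sum(i * px)
  mu_y <- sum(i * py)
  structure(list(P = P, G = G,
                 mu_x = mu_x, mu_y = mu_y,
                 sigma_x = sqrt(sum((i - mu_x)^2 * px)),
                 sigma_y = sqrt(sum((i - mu_y)^2 * py))),
            class = "thermo_glcm")
}

#' GLCM texture descriptors
#'
#' Homogeneity `sum P(i,j) / (1 + (i-j)^2)`, contrast `sum (i-j)^2 P(i,j)`,
#' and correlation `sum (i - mu_x)(j - mu_y) P(i,j) / (sigma_x sigma_y)`,
#' all over the normalized co-occurrence probabilities. For a constant image
#' (`sigma_x * sigma_y = 0`) correlation is reported as 1 with a warning.
#'
#' @param g A `thermo_glcm` from [compute_glcm()].
#' @return A one-row tibble `homogeneity`, `contrast`, `correlation`.
#' @export
glcm_features <- function(g) {
  stopifnot(inherits(g, "thermo_glcm"))
  G <- g$G
  i <- matrix(seq_len(G) - 1, G, G)
  j <- matrix(seq_len(G) - 1, G, G, byrow = TRUE)
  d <- i - j
  homogeneity <- sum(g$P / (1 + d^2))
  contrast <- sum(d^2 * g$P)
  if (g$sigma_x * g$sigma_y == 0) {
    warning("constant image: GLCM correlation undefined, reported as 1")
    correlation <- 1
  } else {
    correlation <- sum((i - g$mu_x) * (j - g$mu_y) * g$P) /
      (g$sigma_x * g$sigma_y)
  }
  tibble(homogeneity = homogeneity, contrast = contrast,
         correlation = correlation)
}

glcm_features_list <- function(g) {
  G <- g$G
  i <- matrix(seq_len(G) - 1, G, G)
  j <- matrix(seq_len(G) - 1, G, G, byrow = TRUE)
  d <- i - j
  correlation <- if (g$sigma_x * g$sigma_y == 0) {
    warning("constant image: GLCM correlation undefined, reported as 1")
    1
  } else {
    sum((i - g$mu_x) * (j - g$mu_y) * g$P) / (g$sigma_x * g$sigma_y)
  }
  list(homogeneity = sum(g$P / (1 + d^2)),
       contrast = sum(d^2 * g$P),
       correlation = correlation)
}

feature_row_list <- function(sample, G, calibration, include_glcm_energy) {
  stats <- stat_features_list(sample$pixels)
  q <- quantize_sample(sample, G = G, calibration = calibration)
  g <- compute_glcm(q)
  tex <- glcm_features_list(g)
  row <- c(
    list(subject_id = sample$subject_id %||% NA_character_,
         side = sample$side,
         label = sample$label %||% NA_character_),
    stats[c("mean", "std", "variance", "skewness", "kurtosis")],
    list(entropy = entropy_bits(q)),
    stats[c("min", "max", "cv", "energy")],
    tex
  )
  if (include_glcm_energy) row$glcm_energy <- glcm_energy(g)
  row
}

#' GLCM angular second moment
#'
#' `sum P(i,j)^2`; the optional 14th descriptor, excluded from the default
#' feature list.
#'
#' @param g A `thermo_glcm`.
#' @return A scalar in (0, 1].
#' @export
glcm_energy <- function(g) {
  stopifnot(inherits(g, "thermo_glcm"))
  sum(g$P^2)
}

#' Gray-level entropy in bits
#'
#' Shannon entropy `-sum p_i log2 p_i` of the in-mask gray-level histogram
#' over the same `G` quantized levels used for the GLCM; `0 log 0 = 0`.
#' Ranges over `[0, log2(G)]`.
#'
#' @param q A `quantized_sample`.
#' @return Entropy in bits.
#' @export
entropy_bits <- function(q) {
  stopifnot(inherits(q, "quantized_sample"))
  lv <- q$levels[q$mask]
  if (length(lv) < 1) stop("no in-mask pixels")
  p <- tabulate(lv + 1L, nbins = q$G)
  p <- p[p > 0] / length(lv)
  -sum(p * log2(p))
}

#' Extract the per-breast feature vector
#'
#' Composes quantization, GLCM texture, entropy and the statistical
#' descriptors into one named record: the 13 default descriptors
#' `r paste(thermo_feature_names, collapse = ", ")`, plus `glcm_energy`
#' (angular second moment) when `include_glcm_energy = TRUE`.
#'
#' @param sample A `breast_sample` (see [split_breasts()]).
#' @param G Gray levels for quantization (default 256).
#' @param calibration `NULL` for per-sample min/max (default) or a fixed
#'   `(low, high)` degC range.
#' @param include_glcm_energy Append the optional GLCM angular second moment?
#' @return A one-row tibble: `subject_id`, `side`, `label`, then the features
#'   in fixed order.
#' @export
extract_features <- function(sample, G = 256, calibration = NULL,
                             include_glcm_energy = FALSE) {
  stopifnot(inherits(sample, "breast_sample"))
  row <- feature_row_list(sample, G, calibration, include_glcm_energy)
  tibble::new_tibble(lapply(row, function(v) v), nrow = 1L)
}

#' Extract features for every breast of a cohort
#'
#' Splits each case's thermogram at the mask bounding-box midpoint via
#' [split_breasts()] (synthetic and real manifests traverse the same code
#' path) and extracts one feature row per breast.
#'
#' @param cohort A `thermo_cohort` from [generate_cohort()] or [read_cohort()].
#' @inheritParams extract_features
#' @return A tibble with one row per breast sample.
#' @export
extract_cohort_features <- function(cohort, G = 256, calibration = NULL,
                                    include_glcm_energy = FALSE) {
  stopifnot(inherits(cohort, "thermo_cohort"))
  rows <- vector("list", 2 * length(cohort$cases))
  for (i in seq_along(cohort$cases)) {
    case <- cohort$cases[[i]]
    sides <- split_breasts(case$thermogram, case$mask,
                           subject_id = case$subject_id,
                           labels = c(case$left_label, case$right_label))
    rows[[2 * i - 1]] <- feature_row_list(sides$left, G, calibration,
                                          include_glcm_energy)
    rows[[2 * i]] <- feature_row_list(sides$right, G, calibration,
                                      include_glcm_energy)
  }
  cols <- names(rows[[1]])
  out <- lapply(setNames(cols, cols), function(cn) {
    vapply(rows, function(r) r[[cn]],
           if (is.character(rows[[1]][[cn]])) character(1) else numeric(1))
  })
  tibble::new_tibble(out, nrow = length(rows))
}

#' Case-report table of headline features
#'
#' Reshapes a feature table into the compact per-breast report used when
#' discussing individual cases: identifier, label and the seven headline
#' descriptors.
#'
#' @param features A feature tibble from [extract_features()] /
#'   [extract_cohort_features()].
#' @return A tibble with columns `Name`, `Label`, `Mean`, `Entropy`, `Min`,
#'   `Max`, `Homogeneity`, `Contrast`, `Correlation`.
#' @export
feature_report <- function(features) {
  tibble(
    Name = paste0(features$subject_id, "-", toupper(substr(features$side, 1, 1))),
    Label = features$label,
    Mean = features$mean,
    Entropy = features$entropy,
    Min = features$min,
    Max = features$max,
    Homogeneity = features$homogeneity,
    Contrast = features$contrast,
    Correlation = features$correlation
  )
}
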