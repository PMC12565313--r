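#' Configure a synthetic thermal cohort
#'
#' Bundles the parameters of the synthetic thermogram generator. The defaults
#' emulate a frontal breast-thermography study cohort: a smooth bilateral
#' temperature field around 28 degC displayed on a 20--36 degC radiometric
#' scale, Gaussian sensor noise, and, on anomalous (cancer-labelled) breasts, a
#' radially decaying hotspot about 2 degC above baseline plus warm vessel-like
#' curvilinear structures at half the hotspot amplitude.
#'
#' @param n_control_subjects,n_cancer_subjects Number of control / cancer
#'   subjects (each subject contributes a left and a right breast sample).
#' @param grid_height,grid_width Thermogram dimensions in pixels. The default
#'   120 x 160 keeps desk-scale runs fast; full-camera 480 x 640 grids are
#'   supported.
#' @param baseline_temp Baseline skin temperature, degC.
#' @param lateral_gradient Total span (degC) of the smooth low-frequency
#'   within-breast variation (a seeded linear ramp with random direction).
#' @param noise_sd Per-pixel Gaussian noise standard deviation, degC.
#' @param hotspot_delta Hotspot amplitude (degC) added on anomalous breasts.
#' @param hotspot_radius Hotspot scale in pixels (Gaussian sigma is
#'   `hotspot_radius / 2`). Default scales with the grid.
#' @param vessel_count Number of vessel-like warm polylines per anomalous
#'   breast; drawn at amplitude `hotspot_delta / 2` and dilated to ~2 px width.
#' @param bilateral_cancer_fraction Proportion of cancer subjects with both
#'   breasts anomalous; applied as an exact count `round(f * n_cancer)` so the
#'   cohort composition is deterministic.
#' @param temp_clip Length-2 numeric `(low, high)` degC; all emitted
#'   temperatures are clipped to this range.
#' @param mask_gap Gap in pixels between the two breast masks at the vertical
#'   midline.
#' @param seed Integer seed; the cohort is reproduced bit-identically from it.
#'
#' @return An object of class `cohort_config` (a named list).
#' @seealso [generate_cohort()], [generate_breast_field()]
#' @export
#' @examples
#' cfg <- cohort_config(n_control_subjects = 3, n_cancer_subjects = 2,
#'                      grid_height = 40, grid_width = 60, seed = 1)
#' cohort <- generate_cohort(cfg)
#' cohort$manifest
cohort_config <- function(n_control_subjects = 99,
                          n_cancer_subjects = 42,
                          grid_height = 120,
                          grid_width = 160,
                          baseline_temp = 28,
                          lateral_gradient = 1,
                          noise_sd = 0.2,
                          hotspot_delta = 2,
                          hotspot_radius = NULL,
                          vessel_count = 2,
                          bilateral_cancer_fraction = 0,
                          temp_clip = c(20, 36),
                          mask_gap = NULL,
                          seed = 20251013) {
  if (is.null(hotspot_radius)) {
    hotspot_radius <- max(3L, round(min(grid_height, grid_width) / 12))
  }
  if (is.null(mask_gap)) {
    mask_gap <- max(2L, round(grid_width * 0.05))
  }
  stopifnot(
    n_control_subjects >= 0, n_cancer_subjects >= 0,
    grid_height >= 8, grid_width >= 8,
    noise_sd >= 0, hotspot_delta >= 0, hotspot_radius > 0,
    vessel_count >= 0,
    bilateral_cancer_fraction >= 0, bilateral_cancer_fraction <= 1,
    length(temp_clip) == 2, temp_clip[1] < temp_clip[2]
  )
  structure(
    list(
      n_control_subjects = as.integer(n_control_subjects),
      n_cancer_subjects = as.integer(n_cancer_subjects),
      grid_height = as.integer(grid_height),
      grid_width = as.integer(grid_width),
      baseline_temp = baseline_temp,
      lateral_gradient = lateral_gradient,
      noise_sd = noise_sd,
      hotspot_delta = hotspot_delta,
      hotspot_radius = hotspot_radius,
      vessel_count = as.integer(vessel_count),
      bilateral_cancer_fraction = bilateral_cancer_fraction,
      temp_clip = as.numeric(temp_clip),
      mask_gap = as.integer(mask_gap),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# deterministic per-subject sub-seed so cohorts are stable under reordering
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 1000003 * (index + 1)) %% 2147483647)
}

#' Breast region masks for a synthetic thermogram
#'
#' Two mirrored D-shaped half-ellipses (flat top, curved bottom) separated by a
#' gap at the vertical midline, so the mask always has two disjoint components
#' that the bounding-box splitter can separate.
#'
#' @param config A [cohort_config()].
#' @param jitter Length-2 multiplicative jitter on the (horizontal, vertical)
#'   semi-axes, used to vary breast size between subjects.
#' @return A list with logical matrices `left`, `right` and `both`.
#' @keywords internal
breast_masks <- function(config, jitter = c(1, 1)) {
  H <- config$grid_height
  W <- config$grid_width
  gap <- config$mask_gap
  a <- 0.18 * W * jitter[1]                   # horizontal semi-axis
  b <- 0.32 * H * jitter[2]                   # vertical extent of the D
  a <- min(a, (W - gap) / 2 - 1.5)            # keep components disjoint
  cy <- 0.35 * H                              # flat top row
  cx_left <- 0.27 * W
  cx_right <- W + 1 - cx_left
  row <- matrix(seq_len(H), H, W)
  col <- matrix(seq_len(W), H, W, byrow = TRUE)
  shape <- function(cx) {
    (row >= cy) & (((col - cx) / a)^2 + ((row - cy) / b)^2 <= 1)
  }
  left <- shape(cx_left)
  right <- shape(cx_right)
  mid <- (W + 1) / 2
  left[, col[1, ] >= mid - gap / 2 + 1] <- FALSE
  right[, col[1, ] <= mid + gap / 2 - 1] <- FALSE
  list(left = left, right = right, both = left | right)
}

random_in_mask <- function(mask) {
  idx <- which(mask)
  pos <- idx[sample.int(length(idx), 1L)]
  c(row = (pos - 1L) %% nrow(mask) + 1L,
    col = (pos - 1L) %/% nrow(mask) + 1L)
}

# warm polyline: random 8-neighbour walk dilated to ~2 px width
vessel_field <- function(mask, amplitude, n_steps) {
  H <- nrow(mask); W <- ncol(mask)
  field <- matrix(0, H, W)
  pos <- random_in_mask(mask)
  r <- pos[["row"]]; c <- pos[["col"]]
  for (s in seq_len(n_steps)) {
    for (dr in -1:0) for (dc in 0:1) {        # 2 px dilation
      rr <- min(max(r + dr, 1L), H); cc <- min(max(c + dc, 1L), W)
      field[rr, cc] <- amplitude
    }
    step <- sample(c(-1L, 0L, 1L), 2, replace = TRUE)
    r <- min(max(r + step[1], 1L), H)
    c <- min(max(c + step[2], 1L), W)
  }
  field
}

#' Generate the temperature field of one breast
#'
#' Builds `baseline + low-frequency lateral ramp + Gaussian noise`; when
#' `cancerous`, a radially (Gaussian) decaying hotspot of peak amplitude
#' `hotspot_delta` at a random in-mask centre and `vessel_count` warm polylines
#' at amplitude `hotspot_delta / 2` are overlaid. Anomaly layers combine by
#' elementwise maximum, so with zero noise and zero gradient the in-mask
#' maximum is exactly `baseline_temp + hotspot_delta` at the hotspot centre.
#' The result is clipped to `temp_clip`. Draws come from the current RNG
#' state; seed it (or use [generate_cohort()]) for reproducibility.
#'
#' @param config A [cohort_config()].
#' @param side `"left"` or `"right"`.
#' @param cancerous Logical; add hotspot and vessel structures?
#' @param mask Optional logical matrix for the breast; defaults to the
#'   config's own mask for `side`.
#' @return A numeric `grid_height x grid_width` matrix of temperatures (degC).
#' @export
generate_breast_field <- function(config, side = c("left", "right"),
                                  cancerous = FALSE, mask = NULL) {
  side <- match.arg(side)
  if (is.null(mask)) mask <- breast_masks(config)[[side]]
  H <- config$grid_height
  W <- config$grid_width
  if (!any(mask)) stop("empty breast mask for side '", side, "'")

  u <- matrix((seq_len(W) - 1) / max(W - 1, 1), H, W, byrow = TRUE)
  slope <- runif(1, -1, 1)   # random direction and magnitude, span <= gradient
  base <- config$baseline_temp + config$lateral_gradient * slope * (u - 0.5)
  noise <- if (config$noise_sd > 0) {
    matrix(rnorm(H * W, sd = config$noise_sd), H, W)
  } else {
    matrix(0, H, W)
  }

  anomaly <- matrix(0, H, W)
  if (cancerous && config$hotspot_delta > 0) {
    rows <- which(rowSums(mask) > 0)
    cols <- which(colSums(mask) > 0)
    extent <- max(diff(range(rows)), diff(range(cols)) ) / 2 + 1
    if (config$hotspot_radius > extent) {
      stop("hotspot_radius (", config$hotspot_radius,
           ") exceeds the breast extent (", round(extent, 1), " px)")
    }
    ctr <- random_in_mask(mask)
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    d2 <- (rr - ctr[["row"]])^2 + (cc - ctr[["col"]])^2
    sigma <- config$hotspot_radius / 2
    anomaly <- config$hotspot_delta * exp(-d2 / (2 * sigma^2))
    if (config$vessel_count > 0) {
      n_steps <- max(6L, round(0.25 * min(H, W)))
      for (v in seq_len(config$vessel_count)) {
        anomaly <- pmax(anomaly,
                        vessel_field(mask, config$hotspot_delta / 2, n_steps))
      }
    }
  }

  temp <- base + noise + anomaly
  pmin(pmax(temp, config$temp_clip[1]), config$temp_clip[2])
}

#' Generate a synthetic thermogram cohort
#'
#' Emulates a clinical breast-thermography cohort: each subject contributes one
#' thermogram (two breasts behind a two-component binary mask) and per-breast
#' labels, `"A"` for a thermally anomalous (cancer-consistent) breast and
#' `"NA"` for no anomaly. Cancer subjects have one breast labelled `A`, or both
#' for the `round(bilateral_cancer_fraction * n_cancer_subjects)` subjects
#' drawn bilateral. Each subject is generated from a sub-seed derived from
#' `(seed, subject index)`, so a fixed seed reproduces the cohort
#' bit-identically.
#'
#' @param config A [cohort_config()].
#' @return An object of class `thermo_cohort`: a list with `config`, `cases`
#'   (one list per subject with `thermogram`, `mask`, `left_label`,
#'   `right_label`, `subject_id`) and a `manifest` tibble
#'   (`subject_id`, `group`, `left_label`, `right_label`).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_control_subjects = 2,
#'   n_cancer_subjects = 1, grid_height = 40, grid_width = 60, seed = 7))
#' length(cohort$cases)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_ctl <- config$n_control_subjects
  n_can <- config$n_cancer_subjects
  if (n_ctl + n_can < 1) stop("cohort must contain at least one subject")

  set.seed(derive_seed(config$seed, 0L))
  n_bilateral <- round(config$bilateral_cancer_fraction * n_can)
  bilateral_ids <- if (n_can > 0 && n_bilateral > 0) {
    sort(sample.int(n_can, n_bilateral))
  } else {
    integer(0)
  }

  groups <- c(rep("control", n_ctl), rep("cancer", n_can))
  cases <- vector("list", n_ctl + n_can)
  man_left <- character(n_ctl + n_can)
  man_right <- character(n_ctl + n_can)
  man_id <- character(n_ctl + n_can)

  for (i in seq_along(groups)) {
    set.seed(derive_seed(config$seed, i))
    subject_id <- sprintf("S%03d", i)
    # each breast draws its own size jitter: keeps per-breast samples
    # independent under the null (left/right sizes differ in vivo anyway)
    jit_left <- runif(2, 0.95, 1.05)
    jit_right <- runif(2, 0.95, 1.05)
    masks <- list(
      left = breast_masks(config, jitter = jit_left)$left,
      right = breast_masks(config, jitter = jit_right)$right
    )
    masks$both <- masks$left | masks$right

    left_label <- "NA"; right_label <- "NA"
    if (groups[i] == "cancer") {
      cancer_index <- i - n_ctl
      if (cancer_index %in% bilateral_ids) {
        left_label <- "A"; right_label <- "A"
      } else if (sample(c(TRUE, FALSE), 1)) {
        left_label <- "A"
      } else {
        right_label <- "A"
      }
    }

    left <- generate_breast_field(config, "left", left_label == "A",
                                  mask = masks$left)
    right <- generate_breast_field(config, "right", right_label == "A",
                                   mask = masks$right)

    background <- config$temp_clip[1] + 2 +
      matrix(rnorm(config$grid_height * config$grid_width,
                   sd = config$noise_sd),
             config$grid_height, config$grid_width)
    grid <- pmin(pmax(background, config$temp_clip[1]), config$temp_clip[2])
    grid[masks$left] <- left[masks$left]
    grid[masks$right] <- right[masks$right]

    cases[[i]] <- list(
      thermogram = grid,
      mask = masks$both,
      left_label = left_label,
      right_label = right_label,
      subject_id = subject_id
    )
    man_id[i] <- subject_id
    man_left[i] <- left_label
    man_right[i] <- right_label
  }

  manifest <- tibble(subject_id = man_id, group = groups,
                     left_label = man_left, right_label = man_right)
  structure(
    list(config = config, cases = cases, manifest = manifest),
    class = "thermo_cohort"
  )
}

#' @export
print.thermo_cohort <- function(x, ...) {
  n_a <- sum(c(x$manifest$left_label, x$manifest$right_label) == "A")
  cat("<thermo_cohort> ", length(x$cases), " subjects, ",
      2 * length(x$cases), " breast samples (", n_a, " labelled A), grid ",
      x$config$grid_height, "x", x$config$grid_width, "\n", sep = "")
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes each thermogram as an ASCII grid of temperatures (space-separated,
#' one row per line, `.` decimal, 6 decimal places), each mask as a bilevel
#' PNG, and a manifest CSV with columns `subject_id`, `file`, `mask_file`,
#' `left_label`, `right_label`.
#'
#' @param cohort A `thermo_cohort`.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "thermo_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$cases, function(case) {
    grid_file <- paste0(case$subject_id, "_grid.txt")
    mask_file <- paste0(case$subject_id, "_mask.png")
    lines <- apply(case$thermogram, 1, function(r) {
      paste(sprintf("%.6f", r), collapse = " ")
    })
    writeLines(lines, file.path(dir, grid_file))
    png::writePNG(matrix(as.numeric(case$mask), nrow(case$mask)),
                  file.path(dir, mask_file))
    tibble(subject_id = case$subject_id, file = grid_file,
           mask_file = mask_file, left_label = case$left_label,
           right_label = case$right_label)
  })
  manifest <- list_rbind(rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' Accepts the same manifest schema for real radiometric data: point the
#' manifest's `file` column at plain-text temperature grids and `mask_file` at
#' bilevel PNG (or numeric CSV) masks.
#'
#' @param manifest_path Path to a manifest CSV.
#' @return A `thermo_cohort` (with `config = NULL` for external data).
#' @export
read_cohort <- function(manifest_path) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE, na.strings = "")
  dir <- dirname(manifest_path)
  required <- c("subject_id", "file", "mask_file", "left_label", "right_label")
  missing <- setdiff(required, names(man))
  if (length(missing)) {
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  }
  cases <- lapply(seq_len(nrow(man)), function(i) {
    list(
      thermogram = read_temperature_grid(file.path(dir, man$file[i])),
      mask = read_mask(file.path(dir, man$mask_file[i])),
      left_label = man$left_label[i],
      right_label = man$right_label[i],
      subject_id = man$subject_id[i]
    )
  })
  structure(
    list(config = NULL, cases = cases,
         manifest = as_tibble(man[c("subject_id", "left_label", "right_label")])),
    class = "thermo_cohort"
  )
}
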