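# Independent oracles and fixture builders shared across the test files.

# Build a breast_sample directly from a crop matrix + mask (bypasses I/O).
make_sample <- function(crop, mask = NULL, side = "left", subject_id = "T01",
                        label = "NA") {
  crop <- as.matrix(crop)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(crop), ncol(crop))
  thermobreast:::new_breast_sample(crop, mask, side, subject_id, label)
}

# Brute-force GLCM: enumerate every ordered pixel pair at the 8 symmetric
# unit offsets (0/45/90/135 degrees and their negations), both endpoints
# in-mask, and normalize counts. Independent of the shifted-matrix
# implementation.
brute_glcm <- function(levels, mask, G) {
  counts <- matrix(0, G, G)
  nr <- nrow(levels); nc <- ncol(levels)
  offsets <- list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
                  c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    for (off in offsets) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!mask[r2, c2]) next
      i <- levels[r, c] + 1; j <- levels[r2, c2] + 1
      counts[i, j] <- counts[i, j] + 1
    }
  }
  counts / sum(counts)
}

# Closed-form GLCM descriptors from a probability matrix.
brute_glcm_features <- function(P) {
  G <- nrow(P)
  i <- matrix(0:(G - 1), G, G)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum((0:(G - 1)) * px); mu_y <- sum((0:(G - 1)) * py)
  sx <- sqrt(sum(((0:(G - 1)) - mu_x)^2 * px))
  sy <- sqrt(sum(((0:(G - 1)) - mu_y)^2 * py))
  list(homogeneity = sum(P / (1 + (i - j)^2)),
       contrast = sum((i - j)^2 * P),
       correlation = sum((i - mu_x) * (j - mu_y) * P) / (sx * sy))
}

# Study-scale feature table: 71 A / 194 NA breast samples, emulating the
# clinical cohort composition (42 cancer subjects of which 29 bilateral give
# exactly 71 anomalous breasts; control breasts subsampled to 194, standing
# in for the study's quality exclusions).
study_feature_table <- function(seed, hotspot_delta = 2, noise_sd = 0.2,
                                grid = c(32, 48), G = 32) {
  cfg <- cohort_config(
    n_control_subjects = 99, n_cancer_subjects = 42,
    grid_height = grid[1], grid_width = grid[2],
    hotspot_delta = hotspot_delta, noise_sd = noise_sd,
    bilateral_cancer_fraction = 29 / 42, seed = seed
  )
  feats <- extract_cohort_features(generate_cohort(cfg), G = G)
  a <- which(feats$label == "A")
  na <- which(feats$label == "NA")
  stopifnot(length(a) == 71)
  set.seed(seed + 1L)
  keep_na <- sort(sample(na, 194))
  feats[sort(c(a, keep_na)), ]
}

# Majority rate of the 71/194 study composition.
study_majority_rate <- 194 / 265
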