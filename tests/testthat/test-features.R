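test_that("statistical descriptors match direct arithmetic", {
  f <- statistical_features(c(1, 2, 3, 4))
  expect_equal(f$mean, 2.5)
  expect_equal(f$std, sqrt(1.25), tolerance = 1e-12)   # population denominator
  expect_equal(f$variance, 1.25)
  expect_equal(f$skewness, 0)                          # median == mean
  expect_equal(f$kurtosis, 1.64, tolerance = 1e-12)
  expect_equal(f$min, 1)
  expect_equal(f$max, 4)
  expect_equal(f$cv, sqrt(1.25) / 2.5 * 100, tolerance = 1e-10)
  expect_equal(f$energy, 10)
})

test_that("a symmetric two-point sample has zero skewness and kurtosis one", {
  f <- statistical_features(c(27, 29))
  expect_equal(f$skewness, 0)
  expect_equal(f$kurtosis, 1)   # E[(x-mu)^4]/sigma^4 for a two-point mass
})

test_that("constant samples yield defined values plus an undefined sentinel", {
  expect_warning(f <- statistical_features(rep(25, 4)), "undefined")
  expect_equal(f$mean, 25)
  expect_equal(f$std, 0)
  expect_equal(f$min, 25)
  expect_equal(f$max, 25)
  expect_equal(f$cv, 0)
  expect_equal(f$energy, 100)
  expect_true(is.na(f$skewness))
  expect_true(is.na(f$kurtosis))
})

test_that("invalid statistical inputs error", {
  expect_error(statistical_features(25), "at least 2")
  expect_error(statistical_features(c(-3, 1)), "positive")
})

test_that("quantization follows the floor rule with endpoint mapping", {
  s <- make_sample(matrix(c(0, 4.9, 5.0, 10), 2, 2))
  q <- quantize_sample(s, G = 2, calibration = c(0, 10))
  expect_equal(sort(as.vector(q$levels)), c(0L, 0L, 1L, 1L))
  expect_equal(q$levels[matrix(c(0, 4.9, 5.0, 10), 2, 2) == 4.9], 0L)
  expect_equal(q$levels[matrix(c(0, 4.9, 5.0, 10), 2, 2) == 5.0], 1L)
  # endpoints: low -> 0, high -> G-1
  q2 <- quantize_sample(make_sample(matrix(c(20, 36), 1, 2)), G = 256,
                        calibration = c(20, 36))
  expect_equal(as.vector(q2$levels), c(0L, 255L))
})

test_that("quantization is monotone in temperature", {
  set.seed(4)
  temps <- sort(runif(50, 20, 36))
  q <- quantize_sample(make_sample(matrix(temps, 1)), G = 17,
                       calibration = c(20, 36))
  expect_true(all(diff(as.vector(q$levels)) >= 0))
})

test_that("degenerate per-sample calibration collapses to level zero", {
  expect_warning(q <- quantize_sample(make_sample(matrix(25, 2, 2))),
                 "degenerate")
  expect_true(all(q$levels == 0L))
})

test_that("the 2x2 GLCM example reproduces the hand-enumerated matrix", {
  s <- make_sample(matrix(c(0, 5, 0, 5), 2, 2))  # levels [[0,0],[1,1]]
  q <- quantize_sample(s, G = 2, calibration = c(0, 5))
  g <- compute_glcm(q)
  expect_equal(g$P[1, 1], 1 / 6, tolerance = 1e-15)
  expect_equal(g$P[2, 2], 1 / 6, tolerance = 1e-15)
  expect_equal(g$P[1, 2], 1 / 3, tolerance = 1e-15)
  expect_equal(g$P[2, 1], 1 / 3, tolerance = 1e-15)

  tex <- glcm_features(g)
  expect_equal(tex$contrast, 2 / 3, tolerance = 1e-15)
  expect_equal(tex$homogeneity, 2 / 3, tolerance = 1e-15)
  expect_equal(tex$correlation, -1 / 3, tolerance = 1e-12)
})

test_that("GLCM of a constant image is a single cell with degenerate features", {
  s <- make_sample(matrix(7, 3, 3))
  q <- suppressWarnings(quantize_sample(s, G = 4))
  g <- compute_glcm(q)
  expect_equal(g$P[1, 1], 1)
  expect_warning(tex <- glcm_features(g), "correlation")
  expect_equal(tex$contrast, 0)
  expect_equal(tex$homogeneity, 1)
  expect_equal(tex$correlation, 1)
})

test_that("an identity-diagonal GLCM has correlation 1 and contrast 0", {
  G <- 4
  g <- structure(list(P = diag(G) / G, G = G,
                      mu_x = mean(0:(G - 1)), mu_y = mean(0:(G - 1)),
                      sigma_x = sqrt(mean((0:(G - 1) - 1.5)^2)),
                      sigma_y = sqrt(mean((0:(G - 1) - 1.5)^2))),
                 class = "thermo_glcm")
  tex <- glcm_features(g)
  expect_equal(tex$correlation, 1, tolerance = 1e-12)
  expect_equal(tex$contrast, 0)
})

test_that("GLCM probabilities are symmetric and sum to one", {
  set.seed(21)
  for (rep in 1:20) {
    nr <- sample(2:8, 1); nc <- sample(2:8, 1)
    G <- sample(2:8, 1)
    lv <- matrix(sample(0:(G - 1), nr * nc, replace = TRUE), nr, nc)
    mask <- matrix(runif(nr * nc) < 0.8, nr, nc)
    if (sum(mask) < 4) next
    q <- structure(list(levels = lv, mask = mask, G = G,
                        calibration = c(0, 1)),
                   class = c("quantized_sample"))
    g <- tryCatch(compute_glcm(q), error = function(e) NULL)
    if (is.null(g)) next
    expect_equal(sum(g$P), 1, tolerance = 1e-12)
    expect_equal(g$P, t(g$P), tolerance = 1e-15)
  }
})

test_that("single-pixel masks have no co-occurring pairs", {
  mask <- matrix(FALSE, 3, 3); mask[2, 2] <- TRUE
  q <- structure(list(levels = matrix(0L, 3, 3), mask = mask, G = 2,
                      calibration = c(0, 1)),
                 class = "quantized_sample")
  expect_error(compute_glcm(q), "no valid")
})

test_that("entropy covers the closed-form anchor cases", {
  const <- suppressWarnings(quantize_sample(make_sample(matrix(25, 2, 2))))
  expect_equal(entropy_bits(const), 0)

  two <- quantize_sample(make_sample(matrix(c(0, 0, 10, 10), 2, 2)),
                         G = 2, calibration = c(0, 10))
  expect_equal(entropy_bits(two), 1)

  # one pixel per level over all 256 levels -> log2(256) = 8 bits
  vals <- (0:255 + 0.5) / 256 * 16 + 20
  uni <- quantize_sample(make_sample(matrix(vals, 16, 16)), G = 256,
                         calibration = c(20, 36))
  expect_equal(entropy_bits(uni), 8)
})

test_that("entropy is invariant under pixel permutation", {
  set.seed(31)
  vals <- runif(36, 20, 36)
  q1 <- quantize_sample(make_sample(matrix(vals, 6, 6)), G = 16,
                        calibration = c(20, 36))
  q2 <- quantize_sample(make_sample(matrix(sample(vals), 6, 6)), G = 16,
                        calibration = c(20, 36))
  expect_equal(entropy_bits(q1), entropy_bits(q2))
})

test_that("feature vectors have the fixed schema and order", {
  set.seed(41)
  s <- make_sample(matrix(runif(64, 24, 32), 8, 8), label = "NA")
  f <- extract_features(s, G = 32)
  expect_identical(names(f), c("subject_id", "side", "label",
                               thermo_feature_names))
  expect_equal(length(thermo_feature_names), 13)
  f14 <- extract_features(s, G = 32, include_glcm_energy = TRUE)
  expect_identical(names(f14)[-(1:3)], c(thermo_feature_names, "glcm_energy"))
  expect_equal(sum(!names(f14) %in% c("subject_id", "side", "label")), 14)
  # variance consistency and bound invariants
  expect_equal(f$variance, f$std^2, tolerance = 1e-9)
  expect_true(f$min <= f$mean && f$mean <= f$max)
  expect_true(f$homogeneity > 0 && f$homogeneity <= 1)
  expect_gte(f$contrast, 0)
  expect_true(abs(f$correlation) <= 1)
  expect_true(f$entropy >= 0 && f$entropy <= log2(32))
})

test_that("synthetic control breasts have means near baseline", {
  cfg <- cohort_config(n_control_subjects = 4, n_cancer_subjects = 0,
                       grid_height = 40, grid_width = 60,
                       noise_sd = 0.2, baseline_temp = 28, seed = 6)
  feats <- extract_cohort_features(generate_cohort(cfg), G = 64)
  expect_true(all(feats$mean > 27 & feats$mean < 29))
})

test_that("shifting all pixels by a constant shifts location features only", {
  set.seed(51)
  crop <- matrix(runif(64, 24, 30), 8, 8)
  s1 <- make_sample(crop)
  s2 <- make_sample(crop + 1.5)
  f1 <- extract_features(s1, G = 16, calibration = c(24, 30))
  f2 <- extract_features(s2, G = 16, calibration = c(25.5, 31.5))
  expect_equal(f2$mean, f1$mean + 1.5, tolerance = 1e-10)
  expect_equal(f2$min, f1$min + 1.5, tolerance = 1e-10)
  expect_equal(f2$max, f1$max + 1.5, tolerance = 1e-10)
  expect_equal(f2$energy, f1$energy + 1.5 * 64, tolerance = 1e-9)
  for (col in c("std", "variance", "skewness", "kurtosis", "entropy",
                "homogeneity", "contrast", "correlation")) {
    expect_equal(f2[[col]], f1[[col]], tolerance = 1e-9, label = col)
  }
})

test_that("case reports carry the seven headline descriptors", {
  set.seed(61)
  s <- make_sample(matrix(runif(64, 24, 32), 8, 8), label = "A",
                   subject_id = "S001", side = "left")
  rep <- feature_report(extract_features(s, G = 32))
  expect_identical(names(rep),
                   c("Name", "Label", "Mean", "Entropy", "Min", "Max",
                     "Homogeneity", "Contrast", "Correlation"))
  expect_identical(rep$Label, "A")
  expect_identical(rep$Name, "S001-L")
})
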