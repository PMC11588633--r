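glc <- function(counts) {
  structure(list(counts = counts), class = "glc_matrix")
}

test_that("co-occurrence features match hand-computed values", {
  # uniform 2x2 joint probability: contrast = sum p (i-j)^2 = 0.5
  f <- glcm_features(glc(matrix(1L, 2, 2)))
  expect_equal(f[["contrast"]], 0.5)
  expect_equal(f[["dissimilarity"]], 0.5)
  expect_equal(f[["joint_energy"]], 4 * 0.25^2)
  expect_equal(f[["joint_entropy"]], 2)
  expect_equal(f[["sum_average"]], 3)

  # degenerate single-entry distribution p(1,1) = 1
  single <- glcm_features(glc(matrix(c(4L, 0L, 0L, 0L), 2)))
  expect_equal(single[["joint_energy"]], 1)
  expect_equal(single[["joint_entropy"]], 0)
  expect_equal(single[["maximum_probability"]], 1)
  expect_true(is.nan(single[["correlation"]]))  # zero marginal variance

  # all-diagonal matrix: contrast 0
  diagm <- glcm_features(glc(diag(c(2L, 3L))))
  expect_equal(diagm[["contrast"]], 0)

  # exactly 20 features, always in the same order
  expect_identical(length(f), 20L)
  expect_true(all(c("inverse_cluster_shade", "inverse_cluster_tendency",
                    "gaussian_left_polar", "inverse_gaussian_left_polar")
                  %in% names(f)))
})

test_that("bespoke co-occurrence features follow their stated definitions", {
  cm <- matrix(c(2L, 1L, 0L, 1L), 2)
  p <- cm / sum(cm)
  f <- glcm_features(glc(cm))
  # Gaussian left polar: lower triangle i >= j weighted by the Gaussian
  sigma <- 2 / 4
  w <- exp(-(outer(1:2, 1:2, `-`))^2 / (2 * sigma^2))
  low <- row(p) >= col(p)
  expect_equal(f[["gaussian_left_polar"]], sum((p * w)[low]))
  expect_equal(f[["inverse_gaussian_left_polar"]], sum((p * (1 - w))[low]))
  # inverse cluster features computed on the normalized complement
  pc <- (max(p) - p) / sum(max(p) - p)
  mu_x <- sum(1:2 * rowSums(pc))
  mu_y <- sum(1:2 * colSums(pc))
  dev <- outer(1:2, 1:2, `+`) - mu_x - mu_y
  expect_equal(f[["inverse_cluster_shade"]], sum(dev^3 * pc))
  expect_equal(f[["inverse_cluster_tendency"]], sum(dev^2 * pc))
})

test_that("run-length features match hand-computed values", {
  lm <- make_level_map(array(c(1L, 1L, 2L, 2L, 2L), c(5, 1, 1)), 2)
  f <- glrlm_features(compute_glrlm(lm, 0))
  expect_equal(f[["run_percentage"]], 0.4)
  expect_identical(length(f), 15L)

  # single run of length L: short-run emphasis = 1/L^2
  single <- make_level_map(array(1L, c(4, 1, 1)), 2)
  fs <- glrlm_features(compute_glrlm(single, 0))
  expect_equal(fs[["short_run_emphasis"]], 1 / 16)
  expect_equal(fs[["long_run_emphasis"]], 16)
  expect_equal(fs[["run_variance"]], 0)

  # maximal fragmentation: every run has length 1
  frag <- make_level_map(array(c(1L, 2L, 1L, 2L), c(4, 1, 1)), 2)
  expect_equal(glrlm_features(compute_glrlm(frag, 0))[["run_percentage"]], 1)
})

test_that("size-zone features match hand-computed values", {
  lv <- array(0L, c(6, 1, 1))
  lv[1:6] <- 2L
  one_zone <- glszm_features(compute_glszm(make_level_map(lv, 2)))
  expect_equal(one_zone[["zone_percentage"]], 1 / 6)
  expect_equal(one_zone[["zone_variance"]], 0)
  expect_identical(length(one_zone), 14L)

  # all singleton zones
  lv2 <- array(c(1L, 2L, 1L, 2L), c(4, 1, 1))
  expect_equal(
    glszm_features(compute_glszm(make_level_map(lv2, 2)))[["zone_percentage"]],
    1)
})

test_that("dependence features match two-term hand sums", {
  gld <- function(counts) {
    structure(list(counts = counts), class = "gld_matrix")
  }
  # all voxels at dependence 0: SDE is maximal under the (k+1)^-2 weighting
  f0 <- gldm_features(gld(matrix(c(5L, 3L), 2, 1)))
  expect_equal(f0[["small_dependence_emphasis"]], 1)
  expect_equal(f0[["dependence_variance"]], 0)

  # uniform two-entry matrix at dependences 1 and 3
  cm <- matrix(0L, 1, 4)
  cm[1, 2] <- 1L  # dependence 1
  cm[1, 4] <- 1L  # dependence 3
  f <- gldm_features(gld(cm))
  expect_equal(f[["small_dependence_emphasis"]], (1 / 4 + 1 / 16) / 2)
  expect_equal(f[["large_dependence_emphasis"]], (4 + 16) / 2)
  expect_equal(f[["dependence_variance"]], 1)
  expect_identical(length(f), 12L)
})

test_that("grey-tone difference features handle the flat and textured cases", {
  tp <- texture_params(2, kernel = 1)
  flat <- ngtdm_features(make_level_map(array(1L, c(4, 4, 1)), 2), tp)
  expect_equal(flat[["busyness"]], 0)
  expect_equal(flat[["complexity"]], 0)
  expect_equal(flat[["coarseness"]], 1e6)  # capped sentinel
  expect_identical(length(flat), 5L)

  # 4x4 checkerboard of levels 1/2, kernel 1: s_i from the closed form
  lv <- array(0L, c(4, 4, 1))
  lv[, , 1] <- (outer(1:4, 1:4, `+`) %% 2L) + 1L
  cb <- compute_ngtdm(make_level_map(lv, 2), tp)
  oracle <- brute_ngtdm(make_level_map(lv, 2), 1)
  expect_equal(cb$s, oracle$s)
  expect_equal(cb$n, c(8, 8))
  f <- ngtdm_features(make_level_map(lv, 2), tp)
  expect_gt(f[["busyness"]], 0)
  expect_gt(f[["contrast"]], 0)
})
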