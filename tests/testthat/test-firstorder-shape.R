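test_that("first-order statistics match hand values", {
  v <- volume3d(array(c(0, 0.5, 1, 9), c(4, 1, 1)))
  roi <- mask3d(array(c(1L, 1L, 1L, 0L), c(4, 1, 1)))
  f <- firstorder_features(v, roi)
  expect_equal(f[["mean"]], 0.5)
  expect_equal(f[["range"]], 1)
  expect_equal(f[["minimum"]], 0)
  expect_equal(f[["maximum"]], 1)
  expect_identical(length(f), 15L)

  # percentile rule: empirical CDF with linear interpolation (type 4)
  v100 <- volume3d(array((1:100) / 100, c(100, 1, 1)))
  roi100 <- mask3d(array(1L, c(100, 1, 1)))
  f100 <- firstorder_features(v100, roi100)
  expect_equal(f100[["p25"]], 0.25)
  expect_equal(f100[["p90"]], 0.90)
  expect_equal(f100[["median"]], 0.505)

  # constant ROI: zero variance, NaN skewness/kurtosis sentinels
  fc <- firstorder_features(volume3d(array(0.4, c(3, 3, 1))),
                            mask3d(array(1L, c(3, 3, 1))))
  expect_equal(fc[["variance"]], 0)
  expect_true(is.nan(fc[["kurtosis"]]))
  expect_error(
    firstorder_features(v, mask3d(array(0L, c(4, 1, 1)))), "empty")
})

test_that("first-order statistics ignore voxel arrangement", {
  set.seed(4)
  vals <- runif(27)
  a <- firstorder_features(volume3d(array(vals, c(3, 3, 3))),
                           mask3d(array(1L, c(3, 3, 3))))
  b <- firstorder_features(volume3d(array(sample(vals), c(3, 3, 3))),
                           mask3d(array(1L, c(3, 3, 3))))
  expect_equal(a, b)
})

test_that("kurtosis is non-excess (normal sample near 3)", {
  set.seed(12)
  v <- volume3d(array(rnorm(40000), c(40, 40, 25)))
  f <- firstorder_features(v, mask3d(array(1L, c(40, 40, 25))))
  expect_equal(f[["kurtosis"]], 3, tolerance = 0.1)
  expect_equal(f[["skewness"]], 0, tolerance = 0.1)
})

digital_ball <- function(r, spacing = c(1, 1, 1)) {
  half <- ceiling(r / spacing) + 3
  dims <- 2 * half + 1
  ax <- lapply(1:3, function(a) ((seq_len(dims[a]) - half[a] - 1) * spacing[a])^2)
  q <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  mask3d(array(as.integer(q <= r^2), dims), spacing)
}

test_that("shape features recover analytic ball geometry", {
  ball <- digital_ball(20)
  f <- shape_features(ball)
  expect_identical(length(f), 20L)
  expect_gt(f[["sphericity"]], 0.95)
  expect_lte(f[["sphericity"]], 1.0)
  expect_equal(f[["voxel_volume"]], 4 / 3 * pi * 20^3, tolerance = 0.01)
  expect_equal(f[["surface_area"]], 4 * pi * 20^2, tolerance = 0.02)
  expect_equal(f[["max_3d_diameter"]], 40, tolerance = 0.05)
  expect_equal(f[["equivalent_sphere_diameter"]], 40, tolerance = 0.01)
  expect_equal(f[["elongation"]], 1, tolerance = 0.01)
})

test_that("volume and area scale as s^3 and s^2 with spacing", {
  base <- digital_ball(10, c(1, 1, 1))
  f1 <- shape_features(base)
  scaled <- mask3d(base$labels, c(2, 2, 2))
  f2 <- shape_features(scaled)
  expect_equal(f2[["voxel_volume"]] / f1[["voxel_volume"]], 8)
  expect_equal(f2[["mesh_volume"]] / f1[["mesh_volume"]], 8, tolerance = 1e-6)
  expect_equal(f2[["surface_area"]] / f1[["surface_area"]], 4,
               tolerance = 1e-6)
  expect_equal(f2[["max_3d_diameter"]] / f1[["max_3d_diameter"]], 2)
})

test_that("shape features are invariant to rigid motion of the mask", {
  set.seed(8)
  core <- array(as.integer(runif(4 * 5 * 3) < 0.7), c(4, 5, 3))
  core[2, 2, 2] <- 1L
  emb <- function(arr, ox, oy, oz) {
    lv <- array(0L, c(12, 12, 8))
    lv[ox + seq_len(dim(arr)[1]), oy + seq_len(dim(arr)[2]),
       oz + seq_len(dim(arr)[3])] <- arr
    mask3d(lv)
  }
  f1 <- shape_features(emb(core, 1, 1, 1))
  f2 <- shape_features(emb(core, 6, 4, 3))
  expect_equal(f1, f2, tolerance = 1e-9)
  # 90-degree rotation in an isotropic grid preserves 3D measures
  f3 <- shape_features(emb(aperm(core, c(2, 1, 3)), 3, 3, 2))
  for (nm in c("voxel_volume", "mesh_volume", "surface_area", "sphericity",
               "max_3d_diameter", "major_axis_length", "flatness")) {
    expect_equal(f3[[nm]], f1[[nm]], tolerance = 1e-9)
  }
})

test_that("single-slice ROI yields slab features with flatness sentinel", {
  sl <- array(0L, c(6, 6, 3))
  sl[2:5, 2:5, 2] <- 1L
  f <- shape_features(mask3d(sl))
  expect_equal(f[["voxel_volume"]], 16)
  expect_gt(f[["surface_area"]], 0)
  expect_true(is.nan(f[["flatness"]]))
  expect_equal(f[["slice_area"]], 16)
})

test_that("cube perimeter and 2D features are exact", {
  cube <- array(0L, c(8, 8, 3))
  cube[3:6, 3:6, ] <- 1L
  f <- shape_features(mask3d(cube))
  expect_equal(f[["slice_area"]], 16)
  # marching-squares perimeter of a 4x4 square: 4 sides of 3 + 4 corner cuts
  expect_equal(f[["slice_perimeter"]], 4 * 3 + 4 * sqrt(0.5))
})
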