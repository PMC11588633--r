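test_that("co-occurrence counts match the hand-enumerated 2x2 slice", {
  # slice with levels 1,2 alternating along the 0-degree direction:
  # two pairs (1,2), symmetrized
  lm <- make_level_map(array(c(1L, 2L, 1L, 2L), c(2, 2, 1)), 2)
  g <- compute_glcm(lm, texture_params(2, kernel = 1), angle = 0,
                    distance = 1)
  expect_identical(g$counts, matrix(c(0L, 2L, 2L, 0L), 2))

  # constant ROI: all mass on the diagonal
  cm <- compute_glcm(make_level_map(array(1L, c(3, 3, 1)), 2),
                     texture_params(2, kernel = 1), 0, 1)
  expect_identical(sum(cm$counts[1, 1]), sum(cm$counts))

  # total = 2 x ordered pairs
  set.seed(2)
  rlm <- random_level_map()
  for (a in c(0, 45, 90, 135)) {
    g <- compute_glcm(rlm, texture_params(4, kernel = 2), a, 2)
    expect_identical(sum(g$counts) %% 2L, 0L)
    expect_identical(g$counts, t(g$counts))
  }
})

test_that("run-length counts match the hand decomposition", {
  lm <- make_level_map(array(c(1L, 1L, 2L, 2L, 2L), c(5, 1, 1)), 2)
  m <- compute_glrlm(lm, angle = 0)
  expect_identical(m$counts[1, 2], 1L)
  expect_identical(m$counts[2, 3], 1L)
  expect_identical(sum(m$counts), 2L)

  # constant row is one maximal run
  const <- compute_glrlm(make_level_map(array(1L, c(6, 1, 1)), 2), 0)
  expect_identical(const$counts[1, 6], 1L)

  # out-of-ROI voxels break runs
  broken <- make_level_map(array(c(1L, 1L, 0L, 1L, 1L), c(5, 1, 1)), 2)
  mb <- compute_glrlm(broken, 0)
  expect_identical(mb$counts[1, 2], 2L)
})

test_that("size zones are 26-connected and 3D", {
  lv <- array(0L, c(4, 4, 2))
  lv[1:3, 1, 1] <- 2L           # 3-voxel zone of level 2
  lv[c(1, 2), 4, 2] <- 2L
  lv[3, 3, 1] <- 2L             # diagonally (in 3D) connected to the above
  m <- compute_glszm(make_level_map(lv, 2))
  expect_identical(m$counts[2, 3], 2L)  # two zones of size 3
  expect_identical(sum(m$counts), 2L)

  # constant ROI is a single zone
  const <- compute_glszm(make_level_map(array(2L, c(3, 3, 3)), 2))
  expect_identical(const$counts[2, 27], 1L)
})

test_that("dependence counts match the 3x3 constant-slice example", {
  m <- compute_gldm(make_level_map(array(1L, c(3, 3, 1)), 2),
                    texture_params(2, kernel = 1))
  # corners depend on 3 neighbors, edges on 5, the center on 8
  expect_identical(m$counts[1, 4], 4L)
  expect_identical(m$counts[1, 6], 4L)
  expect_identical(m$counts[1, 9], 1L)
  expect_identical(sum(m$counts), 9L)

  # isolated voxel has dependence 0
  iso <- array(0L, c(3, 3, 1))
  iso[2, 2, 1] <- 1L
  mi <- compute_gldm(make_level_map(iso, 2), texture_params(2, kernel = 1))
  expect_identical(mi$counts[1, 1], 1L)
})

test_that("matrix constructors match brute-force enumeration on random maps", {
  set.seed(17)
  for (rep in 1:25) {
    lm <- random_level_map(c(sample(3:6, 1), sample(3:6, 1), sample(1:3, 1)),
                           bin_count = sample(c(2L, 4L), 1))
    if (lm$n_roi == 0L) next
    for (a in c(0, 45, 90, 135)) {
      off <- pancradiomics:::angle_offset(a)
      g <- compute_glcm(lm, texture_params(lm$bin_count, kernel = 1), a, 1)
      expect_identical(unname(g$counts), brute_glcm(lm, off[1], off[2]))
      r <- compute_glrlm(lm, a)
      expect_counts_equal(r$counts, brute_glrlm(lm, off[1], off[2]))
    }
    z <- compute_glszm(lm)
    expect_counts_equal(z$counts, brute_glszm(lm))
    k <- sample(1:3, 1)
    dmat <- compute_gldm(lm, texture_params(lm$bin_count, kernel = k))
    expect_counts_equal(dmat$counts, brute_gldm(lm, k))
    nt <- compute_ngtdm(lm, texture_params(lm$bin_count, kernel = k))
    oracle <- brute_ngtdm(lm, k)
    expect_equal(nt$n, oracle$n)
    expect_equal(nt$s, oracle$s)
  }
})

test_that("conservation invariants hold on random maps", {
  set.seed(23)
  for (rep in 1:20) {
    lm <- random_level_map(c(5, 5, 2), bin_count = 4)
    if (lm$n_roi == 0L) next
    for (a in c(0, 45, 90, 135)) {
      r <- compute_glrlm(lm, a)
      expect_identical(sum(r$counts * col(r$counts)), lm$n_roi)
    }
    z <- compute_glszm(lm)
    expect_identical(sum(z$counts * col(z$counts)), lm$n_roi)
    dmat <- compute_gldm(lm, texture_params(4, kernel = 2))
    expect_identical(sum(dmat$counts), lm$n_roi)
  }
})

test_that("features are invariant to ROI translation within the grid", {
  set.seed(5)
  core <- array(sample.int(3, 27, replace = TRUE), c(3, 3, 3))
  emb <- function(ox, oy, oz) {
    lv <- array(0L, c(8, 8, 5))
    lv[ox + 1:3, oy + 1:3, oz + 1:3] <- core
    make_level_map(lv, 4)
  }
  a <- emb(0, 0, 0)
  b <- emb(4, 3, 1)
  tp <- texture_params(4, kernel = 2)
  expect_equal(glcm_features(compute_glcm(a, tp, 45, 2)),
               glcm_features(compute_glcm(b, tp, 45, 2)))
  expect_equal(glrlm_features(compute_glrlm(a, 90)),
               glrlm_features(compute_glrlm(b, 90)))
  expect_equal(glszm_features(compute_glszm(a)),
               glszm_features(compute_glszm(b)))
  expect_equal(gldm_features(compute_gldm(a, tp)),
               gldm_features(compute_gldm(b, tp)))
  expect_equal(ngtdm_features(a, tp), ngtdm_features(b, tp))
})

test_that("co-occurrence features are unchanged at angle + 180 degrees", {
  # symmetric accumulation: the reversed offset builds the same matrix
  set.seed(7)
  lm <- random_level_map(c(6, 6, 2), 4)
  for (a in c(0, 45, 90, 135)) {
    off <- pancradiomics:::angle_offset(a)
    fwd <- pancradiomics:::cpp_glcm(as.vector(lm$levels), dim(lm$levels),
                                    4L, off[1], off[2])
    rev <- pancradiomics:::cpp_glcm(as.vector(lm$levels), dim(lm$levels),
                                    4L, -off[1], -off[2])
    expect_identical(fwd, rev)
  }
})
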