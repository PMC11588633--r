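# small in-code fixtures shared across test files

tiny_case <- function(shape = c(4, 4, 2), spacing = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  vol <- volume3d(array(runif(prod(shape)), shape), spacing)
  tumor <- array(0L, shape)
  tumor[2:3, 2:3, ] <- 1L
  pancreas <- array(1L, shape)
  case_record("tiny", vol, mask3d(tumor, spacing, c(tumor = 1L)),
              mask3d(pancreas, spacing, c(pancreas = 1L)), "head")
}

# straight cylindrical mask along x: n_slabs slices of constant cross-section
cylinder_mask <- function(n_slabs = 100, radius = 4, pad = 2) {
  side <- 2L * radius + 2L * pad + 1L
  shape <- c(n_slabs, side, side)
  labels <- array(0L, shape)
  cy <- (side + 1) / 2
  disc <- outer(seq_len(side), seq_len(side), function(y, z) {
    (y - cy)^2 + (z - cy)^2 <= radius^2
  })
  for (x in seq_len(n_slabs)) {
    plane <- labels[x, , ]
    plane[disc] <- 1L
    labels[x, , ] <- plane
  }
  mask3d(labels, c(1, 1, 1), c(pancreas = 1L))
}

# descriptor-compatible random feature table for classifier tests
random_feature_table <- function(n_cases, n_features, seed = 1,
                                 planted = integer(0), shift = 3,
                                 labels = NULL) {
  set.seed(seed)
  grid <- grid_spec()
  desc <- grid_descriptors(grid)[seq_len(n_features), ]
  values <- matrix(rnorm(n_cases * n_features), n_cases)
  if (is.null(labels)) {
    labels <- rep(c("head", "body_tail"), length.out = n_cases)
  }
  for (jcol in planted) {
    values[labels == "head", jcol] <- values[labels == "head", jcol] + shift
  }
  tab <- feature_table(values, sprintf("case_%03d", seq_len(n_cases)), desc)
  attr(tab, "region_label") <- labels
  tab
}
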