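# Independent brute-force enumerators for the texture matrices. These stay
# deliberately naive (voxel-by-voxel loops in R) so they can serve as oracles
# for the compiled accumulators on small randomized level maps.

make_level_map <- function(levels, bin_count, spacing = c(1, 1, 1)) {
  levels <- array(as.integer(levels), dim = dim(levels))
  structure(
    list(levels = levels, bin_count = as.integer(bin_count),
         bin_edges = seq(0, 1, length.out = bin_count + 1),
         spacing = spacing, n_roi = sum(levels != 0L)),
    class = "level_map"
  )
}

random_level_map <- function(dims = c(6, 6, 3), bin_count = 4,
                             p_roi = 0.8) {
  lv <- array(0L, dims)
  in_roi <- array(runif(prod(dims)) < p_roi, dims)
  lv[in_roi] <- sample.int(bin_count, sum(in_roi), replace = TRUE)
  make_level_map(lv, bin_count)
}

brute_glcm <- function(lm, dx, dy) {
  lv <- lm$levels
  d <- dim(lv)
  counts <- matrix(0L, lm$bin_count, lm$bin_count)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    l1 <- lv[x, y, z]
    if (l1 == 0L) next
    x2 <- x + dx; y2 <- y + dy
    if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2]) next
    l2 <- lv[x2, y2, z]
    if (l2 == 0L) next
    counts[l1, l2] <- counts[l1, l2] + 1L
    counts[l2, l1] <- counts[l2, l1] + 1L
  }
  counts
}

brute_glrlm <- function(lm, dx, dy) {
  lv <- lm$levels
  d <- dim(lv)
  runs <- list()
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    l <- lv[x, y, z]
    if (l == 0L) next
    # run start: predecessor outside grid, outside ROI, or different level
    xp <- x - dx; yp <- y - dy
    if (xp >= 1 && xp <= d[1] && yp >= 1 && yp <= d[2] &&
        lv[xp, yp, z] == l) next
    len <- 0L
    cx <- x; cy <- y
    while (cx >= 1 && cx <= d[1] && cy >= 1 && cy <= d[2] &&
           lv[cx, cy, z] == l) {
      len <- len + 1L
      cx <- cx + dx; cy <- cy + dy
    }
    runs[[length(runs) + 1L]] <- c(l, len)
  }
  maxlen <- max(1L, max(vapply(runs, `[`, 0, 2L), 0L))
  counts <- matrix(0L, lm$bin_count, maxlen)
  for (r in runs) counts[r[1], r[2]] <- counts[r[1], r[2]] + 1L
  counts
}

brute_glszm <- function(lm) {
  lv <- lm$levels
  d <- dim(lv)
  visited <- array(FALSE, d)
  zones <- list()
  idx_all <- which(lv != 0L, arr.ind = TRUE)
  for (r in seq_len(nrow(idx_all))) {
    start <- idx_all[r, ]
    if (visited[start[1], start[2], start[3]]) next
    lev <- lv[start[1], start[2], start[3]]
    frontier <- matrix(start, ncol = 3)
    visited[start[1], start[2], start[3]] <- TRUE
    size <- 0L
    while (nrow(frontier) > 0) {
      nxt <- NULL
      for (k in seq_len(nrow(frontier))) {
        v <- frontier[k, ]
        size <- size + 1L
        for (ddx in -1:1) for (ddy in -1:1) for (ddz in -1:1) {
          if (ddx == 0 && ddy == 0 && ddz == 0) next
          w <- v + c(ddx, ddy, ddz)
          if (any(w < 1) || any(w > d)) next
          if (!visited[w[1], w[2], w[3]] && lv[w[1], w[2], w[3]] == lev) {
            visited[w[1], w[2], w[3]] <- TRUE
            nxt <- rbind(nxt, w)
          }
        }
      }
      frontier <- if (is.null(nxt)) matrix(numeric(0), ncol = 3) else nxt
    }
    zones[[length(zones) + 1L]] <- c(lev, size)
  }
  maxsize <- max(1L, max(vapply(zones, `[`, 0, 2L), 0L))
  counts <- matrix(0L, lm$bin_count, maxsize)
  for (zn in zones) counts[zn[1], zn[2]] <- counts[zn[1], zn[2]] + 1L
  counts
}

brute_gldm <- function(lm, kernel, alpha = 0L) {
  lv <- lm$levels
  d <- dim(lv)
  side <- 2L * kernel + 1L
  counts <- matrix(0L, lm$bin_count, side^2)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    l <- lv[x, y, z]
    if (l == 0L) next
    dep <- 0L
    for (ddx in -kernel:kernel) for (ddy in -kernel:kernel) {
      if (ddx == 0 && ddy == 0) next
      x2 <- x + ddx; y2 <- y + ddy
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2]) next
      l2 <- lv[x2, y2, z]
      if (l2 != 0L && abs(l2 - l) <= alpha) dep <- dep + 1L
    }
    counts[l, dep + 1L] <- counts[l, dep + 1L] + 1L
  }
  counts
}

brute_ngtdm <- function(lm, kernel) {
  lv <- lm$levels
  d <- dim(lv)
  n <- numeric(lm$bin_count)
  s <- numeric(lm$bin_count)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    l <- lv[x, y, z]
    if (l == 0L) next
    nb <- c()
    for (ddx in -kernel:kernel) for (ddy in -kernel:kernel) {
      if (ddx == 0 && ddy == 0) next
      x2 <- x + ddx; y2 <- y + ddy
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2]) next
      l2 <- lv[x2, y2, z]
      if (l2 != 0L) nb <- c(nb, l2)
    }
    if (length(nb) > 0) {
      n[l] <- n[l] + 1
      s[l] <- s[l] + abs(l - mean(nb))
    }
  }
  list(n = n, s = s)
}

# pad a run-length/size-zone style matrix on the right so dims match
pad_cols <- function(m, ncols) {
  if (ncol(m) >= ncols) return(m)
  cbind(m, matrix(0L, nrow(m), ncols - ncol(m)))
}

expect_counts_equal <- function(a, b) {
  nc <- max(ncol(a), ncol(b))
  expect_equal(unname(pad_cols(a, nc)), unname(pad_cols(b, nc)))
}
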