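test_that("filter_features drops sentinel and constant columns, idempotently", {
  tab <- random_feature_table(10, 6, seed = 2)
  tab$values[3, 2] <- NaN
  tab$values[5, 4] <- Inf
  tab$values[, 5] <- 1.7
  out <- filter_features(tab)
  expect_identical(ncol(out$values), 3L)
  expect_identical(sort(attr(out, "dropped")), sort(tab$descriptors$id[c(2, 4, 5)]))
  again <- filter_features(out)
  expect_identical(again$values, out$values)

  allbad <- tab
  allbad$values[] <- NaN
  expect_error(filter_features(allbad), "filtered out")
})

test_that("Welch screen matches stats::t.test and flags planted separation", {
  set.seed(33)
  tab <- random_feature_table(100, 20, seed = 33, planted = c(3, 7),
                              labels = rep(c("head", "body_tail"),
                                           c(58, 42)))
  lab <- attr(tab, "region_label")
  res <- ttest_screen(
    pancradiomics:::subset_cases(tab, lab == "head"),
    pancradiomics:::subset_cases(tab, lab == "body_tail"))
  # cross-check every column against the reference implementation
  for (jcol in c(1, 3, 10)) {
    ref <- t.test(tab$values[lab == "head", jcol],
                  tab$values[lab == "body_tail", jcol])
    expect_equal(res$stats$t[jcol], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$stats$p[jcol], ref$p.value, tolerance = 1e-12)
  }
  # an N(3,1) vs N(0,1) separation at n = 58/42 is overwhelming
  expect_lt(res$stats$p[3], 1e-10)
  expect_true(all(res$stats$significant[c(3, 7)]))
  expect_identical(res$n_significant, sum(res$stats$p < 0.05))
})

test_that("identical groups give t = 0, p = 1", {
  tab <- random_feature_table(4, 5, seed = 8,
                              labels = c("head", "head",
                                         "body_tail", "body_tail"))
  tab$values[3:4, ] <- tab$values[1:2, ]
  lab <- attr(tab, "region_label")
  res <- ttest_screen(pancradiomics:::subset_cases(tab, lab == "head"),
                      pancradiomics:::subset_cases(tab, lab == "body_tail"))
  expect_true(all(res$stats$t == 0))
  expect_true(all(res$stats$p == 1))
  expect_identical(res$n_significant, 0L)
})

test_that("swapping group labels negates t and preserves p", {
  tab <- random_feature_table(30, 12, seed = 14)
  lab <- attr(tab, "region_label")
  a <- pancradiomics:::subset_cases(tab, lab == "head")
  b <- pancradiomics:::subset_cases(tab, lab == "body_tail")
  r1 <- ttest_screen(a, b)
  r2 <- ttest_screen(b, a)
  expect_equal(r1$stats$t, -r2$stats$t)
  expect_equal(r1$stats$p, r2$stats$p)
})

test_that("null simulation calibrates the significant fraction to alpha", {
  set.seed(77)
  n_feat <- 4000
  values <- matrix(rnorm(100 * n_feat), 100)
  desc <- grid_descriptors(grid_spec())[seq_len(n_feat), ]
  tab <- feature_table(values, sprintf("c%03d", 1:100), desc)
  lab <- rep(c("head", "body_tail"), c(58, 42))
  res <- ttest_screen(pancradiomics:::subset_cases(tab, lab == "head"),
                      pancradiomics:::subset_cases(tab, lab == "body_tail"))
  tol <- 3 * sqrt(0.05 * 0.95 / n_feat)
  expect_lt(abs(res$fraction_significant - 0.05), tol)
})

test_that("mismatched descriptors and tiny groups are rejected", {
  tab <- random_feature_table(6, 4, seed = 4)
  lab <- attr(tab, "region_label")
  a <- pancradiomics:::subset_cases(tab, lab == "head")
  b <- pancradiomics:::subset_cases(tab, lab == "body_tail")
  b2 <- pancradiomics:::subset_features(b, c(TRUE, TRUE, TRUE, FALSE))
  expect_error(ttest_screen(a, b2), "descriptor mismatch")
  one <- pancradiomics:::subset_cases(a, 1)
  expect_error(ttest_screen(one, b), "at least two")
})

test_that("Manhattan export writes the CSV and a plot file", {
  tab <- random_feature_table(20, 8, seed = 9, planted = 2)
  lab <- attr(tab, "region_label")
  res <- ttest_screen(pancradiomics:::subset_cases(tab, lab == "head"),
                      pancradiomics:::subset_cases(tab, lab == "body_tail"))
  csv <- withr::local_tempfile(fileext = ".csv")
  out <- manhattan_export(res, csv)
  df <- read.csv(csv)
  expect_identical(nrow(df), 8L)
  expect_equal(df$neg_log10_p, -log10(df$p), tolerance = 1e-12)
  expect_true(file.exists(out[["plot"]]))
})
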