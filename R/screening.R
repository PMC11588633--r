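#' Screening configuration
#'
#' @param alpha two-sided significance threshold for the per-feature Welch
#'   t-test (default 0.05, no multiplicity correction).
#' @param fdr if `TRUE`, flag significance on Benjamini-Hochberg adjusted
#'   p-values instead (off by default; the primary analysis screens at the
#'   raw threshold).
#' @return An object of class `screening_config`.
#' @export
screening_config <- function(alpha = 0.05, fdr = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  structure(list(alpha = alpha, fdr = isTRUE(fdr)), class = "screening_config")
}

#' Drop unusable feature columns
#'
#' Removes every column that contains any non-finite value (the `NaN`/`Inf`
#' sentinels emitted for degenerate denominators) or that is constant across
#' all cases (a zero-variance column has no screening information and an
#' undefined t-statistic). Idempotent. The dropped descriptors are recorded
#' in the `dropped` attribute.
#'
#' @param table a non-empty [feature_table()].
#' @return The filtered [feature_table()].
#' @export
filter_features <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (ncol(table$values) == 0L) stop("feature table is empty", call. = FALSE)
  v <- table$values
  finite <- colSums(!is.finite(v)) == 0L
  varying <- finite  # only meaningful where finite
  rng_ok <- rep(FALSE, ncol(v))
  rng_ok[finite] <- apply(v[, finite, drop = FALSE], 2L,
                          function(x) max(x) > min(x))
  keep <- finite & rng_ok
  if (!any(keep)) stop("all feature columns were filtered out", call. = FALSE)
  lab <- attr(table, "region_label")
  out <- subset_features(table, keep)
  attr(out, "dropped") <- table$descriptors$id[!keep]
  attr(out, "region_label") <- lab
  out
}

# vectorized two-sided Welch t-test over feature columns
welch_columns <- function(x_head, x_bt) {
  n1 <- nrow(x_head)
  n2 <- nrow(x_bt)
  m1 <- colMeans(x_head)
  m2 <- colMeans(x_bt)
  v1 <- apply(x_head, 2L, var)
  v2 <- apply(x_bt, 2L, var)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               n1 + n2 - 2)
  p <- 2 * pt(-abs(t_stat), df)
  data.frame(t = t_stat, df = df, p = p)
}

#' Welch t-test screen of head vs body/tail features
#'
#' Compares every feature column between the two groups with a two-sided
#' Welch (unequal-variance) t-test; a feature is significant when its raw
#' p-value falls below `alpha`. No multiplicity correction is applied by
#' default. Identical groups give t = 0, p = 1. Both inputs must carry the
#' same descriptors and at least two cases each; run the tables through
#' [filter_features()] first (the test is undefined on sentinel values).
#'
#' @param head_rows,bodytail_rows [feature_table()]s of the two groups with
#'   identical descriptors.
#' @param config a [screening_config()].
#' @return An object of class `screening_result`: data.frame `stats` (id,
#'   family, t, df, p, significant) plus counts `n_tested`, `n_significant`,
#'   `fraction_significant`.
#' @export
ttest_screen <- function(head_rows, bodytail_rows,
                         config = screening_config()) {
  stopifnot(inherits(head_rows, "feature_table"),
            inherits(bodytail_rows, "feature_table"),
            inherits(config, "screening_config"))
  if (!identical(head_rows$descriptors$id, bodytail_rows$descriptors$id)) {
    stop("descriptor mismatch between groups", call. = FALSE)
  }
  if (nrow(head_rows$values) < 2L || nrow(bodytail_rows$values) < 2L) {
    stop("each group needs at least two cases", call. = FALSE)
  }
  w <- welch_columns(head_rows$values, bodytail_rows$values)
  p_flag <- if (config$fdr) p.adjust(w$p, "BH") else w$p
  stats <- data.frame(
    id = head_rows$descriptors$id,
    family = head_rows$descriptors$family,
    t = w$t, df = w$df, p = w$p,
    significant = p_flag < config$alpha,
    stringsAsFactors = FALSE
  )
  structure(
    list(stats = stats, alpha = config$alpha,
         n_tested = nrow(stats),
         n_significant = sum(stats$significant),
         fraction_significant = mean(stats$significant)),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf(
    "<screening_result> %d/%d features significant at alpha=%g (%.1f%%)\n",
    x$n_significant, x$n_tested, x$alpha, 100 * x$fraction_significant))
  invisible(x)
}

#' Export per-feature significance as CSV and Manhattan plot
#'
#' Writes a CSV of per-feature `-log10(p)` ordered by family grouping, and a
#' Manhattan-style scatter (features along x grouped and colored by family,
#' `-log10(p)` on y, dashed line at the significance threshold). The plot
#' device is PNG when the build supports it, otherwise PDF.
#'
#' @param result a [ttest_screen()] result.
#' @param path CSV output path; the plot lands next to it with the same stem.
#' @return Named character vector with the `csv` and `plot` paths written.
#' @export
manhattan_export <- function(result, path) {
  stopifnot(inherits(result, "screening_result"))
  df <- result$stats[order(result$stats$family, result$stats$id), ]
  df$neg_log10_p <- -log10(pmax(df$p, .Machine$double.xmin))
  df$position <- seq_len(nrow(df))
  write.csv(df[, c("id", "family", "t", "p", "neg_log10_p", "significant")],
            path, row.names = FALSE)
  gp <- ggplot2::ggplot(
    df, ggplot2::aes(x = position, y = neg_log10_p, color = family)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(result$alpha),
                        linetype = "dashed") +
    ggplot2::labs(x = "feature (grouped by family)",
                  y = expression(-log[10](p)), color = "family") +
    ggplot2::theme_minimal()
  stem <- sub("\\.csv$", "", path)
  plot_path <- paste0(stem, ".png")
  ok <- tryCatch({
    ggplot2::ggsave(plot_path, gp, width = 9, height = 4, dpi = 150)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    plot_path <- paste0(stem, ".pdf")
    ggplot2::ggsave(plot_path, gp, width = 9, height = 4)
  }
  invisible(c(csv = path, plot = plot_path))
}
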