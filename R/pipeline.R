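#' Pipeline configuration
#'
#' Loads (from a YAML file) or builds a validated end-to-end configuration:
#' phantom spec, feature grid, screening threshold, RFE cap and the
#' classifier list. Missing optional sections fall back to the package
#' defaults; `seed` and `classifiers` are required, and an unknown classifier
#' or a missing required field raises a schema error naming the field.
#'
#' @param path YAML file path (optional if `config` is given).
#' @param config named list overriding / replacing the file contents.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, config = list()) {
  base <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    base <- yaml::read_yaml(path)
  }
  cfg <- utils::modifyList(base, config)
  for (field in c("seed", "classifiers")) {
    if (is.null(cfg[[field]])) {
      stop("pipeline config is missing required field: ", field,
           call. = FALSE)
    }
  }
  bad <- setdiff(cfg$classifiers, bank_methods())
  if (length(bad) > 0) {
    stop("unknown classifier(s) in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  grid <- do.call(grid_spec, cfg$grid %||% list())
  screening <- do.call(screening_config, cfg$screening %||% list())
  rfe <- do.call(rfe_config, cfg$rfe %||% list())
  phantom_args <- cfg$phantom %||% list()
  phantom_args$seed <- phantom_args$seed %||% cfg$seed
  phantom <- do.call(phantom_spec, phantom_args)
  structure(
    list(seed = as.integer(cfg$seed), classifiers = cfg$classifiers,
         grid = grid, screening = screening, rfe = rfe, phantom = phantom,
         raw = cfg),
    class = "pipeline_config"
  )
}

serialize_config <- function(config) {
  list(
    seed = config$seed,
    classifiers = config$classifiers,
    grid = unclass(config$grid),
    screening = unclass(config$screening),
    rfe = unclass(config$rfe),
    phantom = unclass(config$phantom)
  )
}

#' Run the full pipeline
#'
#' Stage order: simulate (one training and one independently seeded testing
#' cohort), extract (feature tables), screen (filter + Welch t screen +
#' Manhattan export), train (classifier bank with RFE on the significant
#' features) and evaluate (per-method metrics as JSON). All artifacts —
#' feature tables, screening CSV and plot, evaluation report, the exact
#' configuration and a run log with versions, seed and config hash — are
#' written into `out_dir`. Rerunning the same configuration and seed
#' reproduces the feature tables byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose print stage progress.
#' @return Invisibly, a list with the main in-memory results
#'   (`screening`, `bank`, file `paths`).
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  paths <- list(config = file.path(out_dir, "config.yaml"))
  yaml::write_yaml(serialize_config(config), paths$config)

  say("stage simulate: generating cohorts")
  train_spec <- config$phantom
  test_spec <- config$phantom
  test_spec$seed <- config$phantom$seed + 1L
  train_cases <- generate_cohort(train_spec)
  test_cases <- generate_cohort(test_spec)

  say("stage extract: computing feature tables")
  train_tab <- extract_cohort(train_cases, config$grid)
  test_tab <- extract_cohort(test_cases, config$grid)
  paths$train_features <- file.path(out_dir, "train_features.csv")
  paths$test_features <- file.path(out_dir, "test_features.csv")
  write_feature_table(train_tab, paths$train_features)
  write_feature_table(test_tab, paths$test_features)
  train_labels <- attr(train_tab, "region_label")
  test_labels <- attr(test_tab, "region_label")
  write_labels(data.frame(case_id = train_tab$case_ids,
                          region_label = train_labels),
               file.path(out_dir, "train_labels.csv"))
  write_labels(data.frame(case_id = test_tab$case_ids,
                          region_label = test_labels),
               file.path(out_dir, "test_labels.csv"))

  say("stage screen: filtering and t-testing")
  filtered <- filter_features(train_tab)
  screen <- ttest_screen(
    subset_cases(filtered, train_labels == "head"),
    subset_cases(filtered, train_labels == "body_tail"),
    config$screening
  )
  paths$screening <- file.path(out_dir, "screening.csv")
  exported <- manhattan_export(screen, paths$screening)
  paths$manhattan <- unname(exported["plot"])

  say("stage train/evaluate: classifier bank")
  sig_ids <- screen$stats$id[screen$stats$significant]
  if (length(sig_ids) == 0L) {
    stop("no significant features to train on; lower alpha or revisit inputs",
         call. = FALSE)
  }
  train_sig <- subset_features(filtered, filtered$descriptors$id %in% sig_ids)
  bank <- run_bank(train_sig, train_labels, test_tab, test_labels,
                   config$rfe, config$seed, config$classifiers)

  report <- list(
    seed = config$seed,
    n_train = length(train_cases), n_test = length(test_cases),
    n_features = ncol(train_tab$values),
    n_tested = screen$n_tested,
    n_significant = screen$n_significant,
    fraction_significant = screen$fraction_significant,
    best_method = bank$best_method,
    methods = lapply(bank$reports, function(r) list(
      accuracy = r$accuracy_pct, sensitivity = r$sensitivity_pct,
      specificity = r$specificity_pct, auc = r$auc,
      confusion = as.vector(r$confusion)
    ))
  )
  paths$report <- file.path(out_dir, "evaluation.json")
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  log_lines <- c(
    paste("pancradiomics", as.character(utils::packageVersion("pancradiomics"))),
    R.version.string,
    paste("seed:", config$seed),
    paste("config md5:", unname(tools::md5sum(paths$config))),
    paste("run completed:", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  )
  paths$log <- file.path(out_dir, "run.log")
  writeLines(log_lines, paths$log)
  invisible(list(screening = screen, bank = bank, paths = paths))
}
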