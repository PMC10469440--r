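#' Run the full repeatability pipeline from a config
#'
#' Orchestrates the stages end-to-end: obtain a feature table (simulate, or
#' load from CSV), apply the quality filters, compute limits of detection,
#' fit the censored hierarchical model per feature, derive the requested
#' ICC estimands, optionally summarize by groups, and write every result
#' table plus a provenance manifest to `output_dir`. Reruns with the same
#' config and seed produce identical CSVs.
#'
#' The config is a nested list (or a path to a YAML file with the same
#' shape):
#' \preformatted{
#' seed: 1
#' output_dir: results/run1
#' simulate:                  # either `simulate` or `input`
#'   design: {center_sizes: [48, 25, 43, 41], repeat_fraction: 0.898}
#'   features: {n_features: 20}
#' input:
#'   feature_table: path.csv
#'   feature_info: info.csv   # optional mass/rt columns
#'   metadata: metadata.csv
#'   blank_table: blanks.csv  # optional
#' filters: {min_detection: 0.4, blank_fold: 5}
#' model: {levels: 3, adjusted: false, iterations: 2000, chains: 4}
#' estimands: [three_level, within_center]
#' grouping: grouping.csv     # optional feature_id,group CSV
#' }
#'
#' @param config Nested list or path to a YAML file.
#' @return Invisibly, a list with `results`, `qc`, `summaries` (or `NULL`)
#'   and `manifest`.
#' @examples
#' cfg <- system.file("extdata", "example_config.yaml", package = "metabicc")
#' \dontrun{
#' out <- run_pipeline(cfg) # writes results/example_run/
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  seed <- as.integer(config$seed)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulate)) {
    design <- do.call(study_design, config$simulate$design %||% list())
    spec <- do.call(feature_spec, config$simulate$features %||% list())
    sim <- simulate_study(design, spec, seed = seed)
    table <- sim$features
    metadata <- sim$metadata
    write.csv(sim$truth, file.path(out_dir, "ground_truth.csv"),
              row.names = FALSE)
    blank <- NULL
  } else {
    table <- read_feature_table(config$input$feature_table,
                                config$input$feature_info)
    metadata <- read.csv(config$input$metadata, stringsAsFactors = FALSE)
    blank <- if (!is.null(config$input$blank_table)) {
      read_feature_table(config$input$blank_table)
    }
  }

  filters <- config$filters %||% list()
  if (!is.null(blank)) {
    table <- blank_filter(table, blank,
                          fold = filters$blank_fold %||% 5)
    write.csv(attr(table, "report"),
              file.path(out_dir, "blank_filter_report.csv"),
              row.names = FALSE)
  }
  table <- detection_filter(table,
                            min_rate = filters$min_detection %||% 0.40)
  write.csv(attr(table, "report"),
            file.path(out_dir, "detection_filter_report.csv"),
            row.names = FALSE)
  qc <- compute_lod(table)
  write.csv(qc, file.path(out_dir, "feature_qc.csv"), row.names = FALSE)

  mc <- config$model %||% list()
  spec <- model_spec(
    levels = mc$levels %||% 3L,
    fixed_effects = if (isTRUE(mc$adjusted)) c("age", "sex", "bmi")
  )
  mcmc <- mcmc_settings(iterations = mc$iterations %||% 10000L,
                        chains = mc$chains %||% 4L)
  estimands <- unlist(config$estimands) %||%
    (if (spec$levels == 3L) c("three_level", "within_center")
     else "two_level_log")
  batch <- run_feature_batch(table, metadata, spec = spec, mcmc = mcmc,
                             master_seed = seed, estimands = estimands)
  write.csv(batch$results, file.path(out_dir, "icc_results.csv"),
            row.names = FALSE)

  summaries <- NULL
  if (!is.null(config$grouping)) {
    grouping <- read.csv(config$grouping, stringsAsFactors = FALSE)
    main <- batch$results[batch$results$estimand == estimands[1], ]
    summaries <- summarize_groups(main, grouping)
    write.csv(summaries, file.path(out_dir, "group_summaries.csv"),
              row.names = FALSE)
  }

  files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("metabicc")),
    seed = seed,
    model = list(levels = spec$levels,
                 adjusted = !is.null(spec$fixed_effects),
                 iterations = mcmc$iterations, chains = mcmc$chains,
                 burn_in = mcmc$burn_in),
    filters = list(min_detection = filters$min_detection %||% 0.40,
                   blank_fold = filters$blank_fold %||% 5),
    estimands = as.list(estimands),
    outputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      basename(files)))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(results = batch$results, qc = qc, summaries = summaries,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_config <- function(config) {
  problems <- character()
  if (is.null(config$seed)) problems <- c(problems, "`seed` is required")
  if (is.null(config$output_dir)) {
    problems <- c(problems, "`output_dir` is required")
  }
  if (is.null(config$simulate) && is.null(config$input)) {
    problems <- c(problems, "one of `simulate` or `input` is required")
  }
  if (!is.null(config$simulate) && !is.null(config$input)) {
    problems <- c(problems, "`simulate` and `input` are mutually exclusive")
  }
  if (!is.null(config$input) &&
      (is.null(config$input$feature_table) || is.null(config$input$metadata))) {
    problems <- c(problems, "`input` needs `feature_table` and `metadata`")
  }
  lv <- config$model$levels
  if (!is.null(lv) && !lv %in% c(2, 3)) {
    problems <- c(problems, "`model$levels` must be 2 or 3")
  }
  if (length(problems)) {
    stop("invalid config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(TRUE)
}
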