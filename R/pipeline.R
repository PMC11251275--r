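#' Run the full analysis pipeline
#'
#' Executes the stages simulate (optional) -> fit-kinetics ->
#' compare-groups -> attribute, writing result tables and a reproducibility
#' manifest (inputs, config, package version, seed, per-stage status) into
#' `out_dir`. A stage failure is recorded in the manifest and downstream
#' dependent stages are skipped; the function errors only on hard
#' configuration problems (e.g. a missing input file).
#'
#' @param config A `run_config` list (see [read_config()]) or path to a
#'   JSON config. Recognized keys: `seed`, `out_dir`, `simulate` (logical;
#'   generate the demo synthetic inputs), `traces_file`, `panel_file`,
#'   `constants` (overrides for [assay_constants()]), `thresholds`
#'   (`activity`, `saturation`, `reference_deviation`), `windowing`
#'   (`window_min`, `r2_min`), `statistics` (`adjust`), `attribution`
#'   (`splits`, `depth`, `min_leaf`, `seed`, `trees_per_split`).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  seed <- if (!is.null(config$seed)) config$seed else 1L
  out_dir <- if (!is.null(config$out_dir)) config$out_dir else "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  constants <- do.call(assay_constants,
                       as.list(config$constants %||% list()))
  thr <- config$thresholds %||% list()
  act_thr <- thr$activity %||% 0.5
  win <- config$windowing %||% list()
  att <- config$attribution %||% list()
  stat <- config$statistics %||% list()

  manifest <- list(
    package = "rubiscokin",
    version = as.character(utils::packageVersion("rubiscokin")),
    seed = seed, out_dir = out_dir, config = unclass(config),
    stages = list()
  )
  stage <- function(name, fun) {
    res <- tryCatch(list(ok = TRUE, value = fun()),
                    error = function(e) list(ok = FALSE,
                                             error = conditionMessage(e)))
    manifest$stages[[name]] <<- list(
      ok = res$ok, error = if (!res$ok) res$error else NULL)
    res
  }

  traces_file <- config$traces_file
  panel_file <- config$panel_file

  if (isTRUE(config$simulate)) {
    sim <- stage("simulate", function() {
      pan <- simulate_panel(spec_figure2(), seed = seed,
                            activity_threshold = act_thr)
      write_panel(pan$panel, file.path(out_dir, "panel.tsv"))
      # a small demo plate: first 4 variants of the panel
      truths <- head(pan$truth[pan$truth$status == "active", ], 4)
      series <- lapply(seq_len(nrow(truths)), function(i)
        simulate_titration_series(
          truth_record(truths$variant_id[i], truths$kcat_true[i],
                       site_conc_true = 40),
          constants, seed = seed + i))
      write_traces(series, file.path(out_dir, "traces.csv"))
      TRUE
    })
    if (sim$ok) {
      traces_file <- file.path(out_dir, "traces.csv")
      panel_file <- file.path(out_dir, "panel.tsv")
    }
  }

  if (!is.null(traces_file)) {
    if (!file.exists(traces_file))
      stop("traces file not found: ", traces_file, call. = FALSE)
    fitted <- stage("fit_kinetics", function() {
      traces <- read_traces(traces_file)
      series <- traces_to_series(traces, constants)
      results <- lapply(series, function(s)
        do.call(compute_kcat,
                c(list(s, activity_threshold = act_thr),
                  win[names(win) %in% c("window_min", "r2_min")])))
      tab <- kinetics_table(results)
      write.table(tab, file.path(out_dir, "kinetics.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      tab
    })
  }

  if (!is.null(panel_file)) {
    if (!file.exists(panel_file))
      stop("panel file not found: ", panel_file, call. = FALSE)
    panel <- read_panel(panel_file,
                        column_map = c(variant_id = "variant_id",
                                       kcat = "kcat"),
                        activity_threshold = act_thr)
    cmp <- stage("compare_groups", function() {
      res <- compare_figure2(panel, adjust = stat$adjust %||% "holm")
      jsonlite::write_json(res, file.path(out_dir, "comparisons.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      res
    })
    if (cmp$ok) {
      stage("attribute", function() {
        fm <- build_feature_matrix(panel)
        splits <- fit_forest_over_splits(
          fm$X, fm$y,
          n_splits = att$splits %||% 100,
          max_depth = att$depth %||% 3,
          min_leaf = att$min_leaf %||% 2,
          seed = att$seed %||% 42,
          trees_per_split = att$trees_per_split %||% 1)
        rep <- importance_report(splits, fm$X, fm$y)
        jsonlite::write_json(
          rep[, c("feature", "mean_abs_shap", "sd", "rank")],
          file.path(out_dir, "shap_report.json"),
          auto_unbox = TRUE, digits = NA)
        rep
      })
    }
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
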