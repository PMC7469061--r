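#' Default pipeline configuration
#'
#' One configuration drives the whole analysis:
#' simulate (or read) a cohort, preprocess, score, compare, classify.
#' Any element can be overridden through `...` (named sub-lists are merged).
#'
#' @param seed Master seed; per-stage seeds are spawned from it
#'   deterministically (see [run_pipeline()]).
#' @param ... Named overrides merged into the default list, e.g.
#'   `classify = list(n_repeats = 100)`.
#' @return A nested configuration list.
#' @export
default_pipeline_config <- function(seed = 11, ...) {
  config <- list(
    seed = seed,
    cohort = list(
      synthetic = TRUE,
      config = NULL,          # path to a cohort-config YAML, else defaults
      ffq = NULL, sociodemo = NULL, labels = NULL   # or input CSV paths
    ),
    preprocess = list(days_per_month = 30, keep_items = "all",
                      var_threshold = 1e-4, corr_threshold = 0.95,
                      missing_threshold = 0.2),
    score = list(config = NULL, composition = "default"),
    compare = list(alpha = 0.05),
    classify = list(n_repeats = 200, select_threshold = 0.01, retrain = TRUE,
                    num_trees = 500)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    config[[nm]] <- if (is.list(config[[nm]]) && is.list(dots[[nm]])) {
      modifyList(config[[nm]], dots[[nm]])
    } else {
      dots[[nm]]
    }
  }
  config
}

read_cohort_files <- function(paths) {
  ffq <- tibble::as_tibble(read.csv(paths$ffq, stringsAsFactors = FALSE))
  sociodemo <- tibble::as_tibble(read.csv(paths$sociodemo, stringsAsFactors = FALSE))
  labels <- tibble::as_tibble(read.csv(paths$labels, stringsAsFactors = FALSE))
  labels$location <- factor(labels$location, levels = c("island", "mainland"))
  if ("location" %in% names(sociodemo)) {
    sociodemo$location <- factor(sociodemo$location, levels = c("island", "mainland"))
  }
  structure(list(ffq = ffq, sociodemo = sociodemo, labels = labels,
                 config = NULL),
            class = "meddiet_cohort")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> score -> compare -> classify with
#' one configuration and one master seed, writing every stage output into
#' `out_dir` together with a JSON run manifest. The master seed spawns one
#' seed per randomized stage via `sample.int()` so that stages are
#' individually reproducible; identical config and seed give identical
#' outputs.
#'
#' @param config A pipeline configuration (list, see
#'   [default_pipeline_config()]) or the path to a YAML file holding one.
#' @param out_dir Output directory, created if needed.
#' @return The run manifest (list), invisibly. Manifest fields: config
#'   hash (stable under key reordering), seeds, output files, the variable
#'   removal log, stage status and timestamps.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1, 2)
  names(stage_seeds) <- c("simulate", "classify")

  manifest <- list(
    config_hash = rlang::hash(canonicalize(config)),
    master_seed = config$seed,
    stage_seeds = as.list(stage_seeds),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list(),
    outputs = character(0)
  )
  out_path <- function(name) file.path(out_dir, name)
  emit <- function(name) manifest$outputs <<- c(manifest$outputs, name)
  finish <- function(status, failed_stage = NULL) {
    manifest$completed <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    manifest$status <<- status
    if (!is.null(failed_stage)) manifest$failed_stage <<- failed_stage
    jsonlite::write_json(manifest, out_path("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      finish("failed", failed_stage = name)
      stop_meddiet("Pipeline stage '", name, "' failed: ", conditionMessage(res))
    }
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  # -- simulate / load -------------------------------------------------
  cohort <- run_stage("simulate", function() {
    if (isTRUE(config$cohort$synthetic)) {
      cc <- if (!is.null(config$cohort$config)) {
        read_cohort_config(config$cohort$config)
      } else {
        default_cohort_config()
      }
      ch <- generate_cohort(cc, seed = stage_seeds[["simulate"]])
      write_cohort(ch, out_dir)
      emit("ffq.csv"); emit("sociodemo.csv"); emit("labels.csv")
      ch
    } else {
      read_cohort_files(config$cohort)
    }
  })

  # -- preprocess + score ---------------------------------------------
  score_config <- if (!is.null(config$score$config)) {
    read_score_config(config$score$config)
  } else {
    default_score_config()
  }
  composition <- switch(
    as.character(config$score$composition %||% "default"),
    default = default_composition(),
    none = NULL,
    tibble::as_tibble(read.csv(config$score$composition, stringsAsFactors = FALSE))
  )

  prep <- run_stage("preprocess", function() {
    daily <- daily_frequencies(cohort$ffq,
                               days_per_month = config$preprocess$days_per_month)
    cumulative <- cumulative_group_frequencies(
      daily, keep_items = config$preprocess$keep_items)
    list(daily = daily, cumulative = cumulative)
  })

  scores <- run_stage("score", function() {
    mdss <- score_mdss(prep$daily, score_config)
    mdspreg <- score_mds_preg(prep$daily, composition, score_config)
    full <- dplyr::inner_join(mdss, mdspreg, by = "participant_id")
    write.csv(full, out_path("scores.csv"), row.names = FALSE)
    emit("scores.csv")
    full
  })

  table <- run_stage("assemble", function() {
    slim <- tibble::tibble(participant_id = scores$participant_id,
                           mdss_total = scores$mdss_total,
                           mdspreg_total = scores$mdspreg_total)
    tab <- assemble_cohort(slim, prep$cumulative, cohort$sociodemo, cohort$labels)
    tab <- filter_variables(tab,
                            var_threshold = config$preprocess$var_threshold,
                            corr_threshold = config$preprocess$corr_threshold,
                            missing_threshold = config$preprocess$missing_threshold)
    write.csv(tab, out_path("cohort.csv"), row.names = FALSE)
    emit("cohort.csv")
    log <- attr(tab, "removal_log")
    writeLines(
      c("variable\treason\tdetail",
        sprintf("%s\t%s\t%s", log$variable, log$reason, log$detail)),
      out_path("removal_log.txt"))
    emit("removal_log.txt")
    manifest$removed_variables <<- nrow(log)
    tab
  })

  run_stage("compare", function() {
    comparisons <- compare_all(table, alpha = config$compare$alpha)
    write.csv(comparisons, out_path("comparisons.csv"), row.names = FALSE)
    emit("comparisons.csv")
    groups <- unique(default_item_groups()$group)
    group_cols <- intersect(stats::na.omit(groups), names(table))
    pca <- pca_loadings(table[c("participant_id", group_cols)])
    write.csv(pca$loadings, out_path("pca_loadings.csv"), row.names = FALSE)
    emit("pca_loadings.csv")
    tryCatch({
      ggplot2::ggsave(out_path("pca_loadings.png"), plot_pca_loadings(pca),
                      width = 7, height = 6, dpi = 150)
      emit("pca_loadings.png")
    }, error = function(e) {
      manifest$notes <<- c(manifest$notes, paste("pca plot skipped:", conditionMessage(e)))
    })
    NULL
  })

  run_stage("classify", function() {
    summary <- repeat_classification(
      table, n_repeats = config$classify$n_repeats,
      base_seed = stage_seeds[["classify"]],
      num_trees = config$classify$num_trees)
    jsonlite::write_json(
      list(n_repeats = summary$n_repeats, metrics = summary$metrics),
      out_path("metrics_summary.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    emit("metrics_summary.json")
    write.csv(summary$importances, out_path("importances.csv"), row.names = FALSE)
    emit("importances.csv")
    selected <- select_variables(summary, config$classify$select_threshold)
    writeLines(selected, out_path("selected_variables.txt"))
    emit("selected_variables.txt")
    if (isTRUE(config$classify$retrain)) {
      retrained <- retrain_selected(
        table, selected, n_repeats = config$classify$n_repeats,
        base_seed = stage_seeds[["classify"]], original = summary,
        num_trees = config$classify$num_trees)
      jsonlite::write_json(
        list(n_repeats = retrained$n_repeats, metrics = retrained$metrics,
             comparison = attr(retrained, "comparison")),
        out_path("metrics_retrained.json"), auto_unbox = TRUE, digits = NA,
        dataframe = "rows")
      emit("metrics_retrained.json")
    }
    tryCatch({
      ggplot2::ggsave(out_path("importances.png"), plot_importances(summary),
                      width = 7, height = 8, dpi = 150)
      emit("importances.png")
    }, error = function(e) {
      manifest$notes <<- c(manifest$notes, paste("importance plot skipped:", conditionMessage(e)))
    })
    NULL
  })

  finish("ok")
  invisible(manifest)
}
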