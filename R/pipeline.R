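# End-to-end pipeline: manifest/features -> scores -> statistics ->
# figures, with a resolved-config log and stage skipping on current
# outputs.

#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline stages with the input/output
#' paths. Round-trips losslessly through JSON ([write_config()] /
#' [read_config()]).
#'
#' @param manifest_path token manifest CSV (audio path), or `NULL`.
#' @param features_path precomputed landmark feature CSV (bypasses audio),
#'   or `NULL`; one of the two inputs is required by [run_pipeline()].
#' @param out_dir output directory.
#' @param pitch a [pitch_params()] object.
#' @param metrics a [metric_params()] object.
#' @param stats_type ANOVA sum-of-squares type (`"II"`, `"I"`, `"III"`).
#' @param figures render figures.
#' @param overwrite recompute stages even when outputs are newer than
#'   inputs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest_path = NULL, features_path = NULL,
                            out_dir = "tonellipse_out",
                            pitch = pitch_params(),
                            metrics = metric_params(),
                            stats_type = "II",
                            figures = TRUE,
                            overwrite = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#' @param config a [pipeline_config()].
#' @param path JSON path.
#' @return `path` ([write_config()]) or the config ([read_config()]).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(lapply(config, function(x)
    if (is.list(x)) unclass(x) else x)), path, auto_unbox = TRUE,
    digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config()
  for (nm in names(raw)) {
    if (nm == "pitch") {
      cfg$pitch <- do.call(pitch_params, raw$pitch)
    } else if (nm == "metrics") {
      cfg$metrics <- do.call(metric_params, raw$metrics)
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  cfg
}

stage_current <- function(out, inputs) {
  file.exists(out) &&
    all(file.mtime(out) >= file.mtime(inputs[file.exists(inputs)]))
}

#' Run the full analysis pipeline
#'
#' Features (from audio via the pitch front-end, or loaded from a
#' precomputed landmark table) -> per-subject scores -> statistics ->
#' figures, writing each stage under `config$out_dir` and logging the
#' resolved configuration. Stages whose outputs are newer than their
#' inputs are skipped unless `config$overwrite` is set.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with `features`, `scores`,
#'   `stats`, `paths`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  assert_that(!is.null(config$manifest_path) || !is.null(config$features_path),
              "config needs a manifest_path or a features_path")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(config$out_dir, "config_resolved.json"))
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  feat_csv <- file.path(config$out_dir, "features.csv")
  demo <- NULL
  if (!is.null(config$manifest_path)) {
    man <- read_manifest(config$manifest_path)
    demo <- manifest_demographics(man)
    if (!config$overwrite && stage_current(feat_csv, config$manifest_path)) {
      note("features: up to date, skipping")
      features <- read_features(feat_csv)
    } else {
      note("features: extracting F0 landmarks from ", nrow(man), " tokens")
      features <- compute_features(man, config$pitch)
      excl <- attr(features, "exclusions")
      if (!is.null(excl) && sum(excl$n_excluded) > 0) {
        note("features: excluded ", sum(excl$n_excluded),
             " unanalyzable token(s)")
      }
      write_features(features, feat_csv)
    }
  } else {
    if (!config$overwrite && stage_current(feat_csv, config$features_path)) {
      note("features: up to date, skipping")
      features <- read_features(feat_csv)
    } else {
      note("features: loading precomputed table ", config$features_path)
      features <- read_features(config$features_path)
      write_features(features, feat_csv)
    }
    if (all(c("age_at_implantation", "duration_of_use") %in%
              names(features))) {
      demo <- unique(features[, c("subject_id", "group",
                                  "age_at_implantation",
                                  "duration_of_use")])
    }
  }

  score_csv <- file.path(config$out_dir, "scores_summary.csv")
  if (!config$overwrite && stage_current(score_csv, feat_csv)) {
    note("scores: up to date, skipping")
    scores <- NULL
  } else {
    note("scores: fitting tone regions and scoring subjects")
    scores <- cohort_scores(features, params = config$metrics)
    write_scores(scores, config$out_dir)
  }
  if (is.null(scores)) {
    scores <- list(
      summary = utils::read.csv(score_csv, stringsAsFactors = FALSE),
      contrasts = utils::read.csv(file.path(config$out_dir,
                                            "scores_contrasts.csv"),
                                  stringsAsFactors = FALSE),
      confusion = utils::read.csv(file.path(config$out_dir,
                                            "scores_confusion.csv"),
                                  stringsAsFactors = FALSE))
    class(scores) <- "cohort_scores"
  }

  note("stats: ANOVA / correlations / demographic model")
  stats <- tryCatch(cohort_statistics(scores, demographics = demo),
                    error = function(e) {
                      note("stats: skipped (", conditionMessage(e), ")")
                      NULL
                    })
  if (!is.null(stats)) {
    write_stats_json(stats, file.path(config$out_dir, "stats.json"))
    writeLines(utils::capture.output(print(stats)),
               file.path(config$out_dir, "stats.txt"))
  }

  fig_paths <- character(0)
  if (isTRUE(config$figures)) {
    note("figures: rendering")
    fig_paths <- render_figures(scores, features,
                                dir = file.path(config$out_dir, "figures"))
  }
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  structure(list(features = features, scores = scores, stats = stats,
                 paths = list(out_dir = config$out_dir, features = feat_csv,
                              scores = score_csv, figures = fig_paths)),
            class = "pipeline_result")
}

#' Serialize a `cohort_stats` object to JSON
#' @param stats a `cohort_stats` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(stats, path) {
  payload <- list(
    anova = lapply(stats$anova, function(a) as.list(as.data.frame(a))),
    contrast_rm = lapply(stats$contrast_rm, function(r) {
      if (is.null(r)) return(NULL)
      list(anova = as.list(r$anova),
           condition_means = as.list(r$condition_means),
           n_subjects = r$n_subjects)
    }),
    correlations = stats$correlations,
    glm = lapply(stats$glm, function(g) {
      list(coefficients = as.list(g$coefficients),
           r_squared = g$r_squared, n = g$n)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
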