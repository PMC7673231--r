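# Manifest and feature-table I/O with validation.

manifest_columns <- c("subject_id", "group", "chronological_age",
                      "age_at_implantation", "duration_of_use",
                      "word_id", "target_tone", "wav_path")

#' Read and validate a token manifest CSV
#'
#' The manifest has one row per recorded token with columns
#' `subject_id, group, chronological_age, age_at_implantation,
#' duration_of_use, word_id, target_tone, wav_path`. Validation collects
#' every problem (missing columns, bad group or tone labels, implanted
#' rows whose chronological age differs from implantation age + use
#' duration by more than 0.1 year) and raises a single itemized error.
#'
#' @param path CSV path.
#' @param demographic_tolerance allowed |chronological - (implantation +
#'   duration)| in years.
#' @return validated manifest data frame.
#' @export
read_manifest <- function(path, demographic_tolerance = 0.1) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  problems <- character(0)
  missing <- setdiff(manifest_columns, names(man))
  if (length(missing) > 0) {
    stop_invalid("manifest validation failed:\n  missing columns: ",
                 paste(missing, collapse = ", "))
  }
  bad_group <- which(!man$group %in% c("NH", "CI"))
  if (length(bad_group)) {
    problems <- c(problems, paste0("row ", bad_group, ": group '",
                                   man$group[bad_group],
                                   "' is not NH or CI"))
  }
  tone_num <- suppressWarnings(as.integer(man$target_tone))
  bad_tone <- which(is.na(tone_num) | !tone_num %in% 1:4)
  if (length(bad_tone)) {
    problems <- c(problems, paste0("row ", bad_tone, ": target_tone '",
                                   man$target_tone[bad_tone],
                                   "' is not in 1..4"))
  }
  ci <- which(man$group == "CI")
  ci_missing <- ci[is.na(man$age_at_implantation[ci]) |
                     is.na(man$duration_of_use[ci])]
  if (length(ci_missing)) {
    problems <- c(problems, paste0("row ", ci_missing,
                                   ": CI row missing age_at_implantation ",
                                   "or duration_of_use"))
  }
  ci_ok <- setdiff(ci, ci_missing)
  mismatch <- ci_ok[abs(man$chronological_age[ci_ok] -
                          (man$age_at_implantation[ci_ok] +
                             man$duration_of_use[ci_ok])) >
                      demographic_tolerance]
  if (length(mismatch)) {
    problems <- c(problems, paste0(
      "row ", mismatch, ": chronological_age differs from ",
      "age_at_implantation + duration_of_use by more than ",
      demographic_tolerance, " y"))
  }
  if (length(problems)) {
    stop_invalid("manifest validation failed:\n  ",
                 paste(problems, collapse = "\n  "))
  }
  man$target_tone <- tone_num
  man
}

#' Write a token manifest CSV
#' @param manifest manifest data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[, manifest_columns], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Per-subject demographics of a manifest
#' @param manifest manifest data frame.
#' @return one row per subject with the demographic columns.
#' @export
manifest_demographics <- function(manifest) {
  cols <- c("subject_id", "group", "chronological_age",
            "age_at_implantation", "duration_of_use")
  unique(manifest[, cols])
}

#' Write a landmark feature table CSV
#' @param features feature data frame ([compute_features()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  cols <- c("subject_id", "group", "word_id", "target_tone",
            "onset_hz", "mid_hz", "offset_hz",
            "onset_st", "mid_st", "offset_st", "n_corrected_frames")
  utils::write.csv(features[, intersect(cols, names(features))], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a landmark feature table CSV
#'
#' Recomputes the semitone columns from the Hz columns when absent, so a
#' Hz-only table is a valid input.
#'
#' @param path CSV path.
#' @return feature data frame.
#' @export
read_features <- function(path) {
  feat <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "group", "target_tone",
              "onset_hz", "mid_hz", "offset_hz")
  assert_that(all(needed %in% names(feat)), "feature table missing columns: ",
              paste(setdiff(needed, names(feat)), collapse = ", "))
  feat$target_tone <- as.integer(feat$target_tone)
  if (!all(c("onset_st", "mid_st", "offset_st") %in% names(feat))) {
    feat <- normalize_features(feat)
  }
  feat
}

#' Write cohort score tables as CSV (+ confusion matrices as JSON)
#'
#' @param scores a `cohort_scores` object.
#' @param dir output directory.
#' @return named paths, invisibly.
#' @export
write_scores <- function(scores, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(summary = file.path(dir, "scores_summary.csv"),
             contrasts = file.path(dir, "scores_contrasts.csv"),
             confusion_csv = file.path(dir, "scores_confusion.csv"),
             confusion_json = file.path(dir, "confusion_matrices.json"))
  utils::write.csv(scores$summary, paths["summary"], row.names = FALSE)
  utils::write.csv(scores$contrasts, paths["contrasts"], row.names = FALSE)
  utils::write.csv(scores$confusion, paths["confusion_csv"], row.names = FALSE)
  conf <- split(scores$confusion,
                list(scores$confusion$subject_id, scores$confusion$method),
                drop = TRUE)
  payload <- lapply(conf, function(d) {
    m <- matrix(d$value[order(d$region_tone, d$target_tone)], 4, 4)
    list(subject_id = d$subject_id[1], method = d$method[1],
         cells = apply(m, 2, as.numeric, simplify = FALSE))
  })
  jsonlite::write_json(unname(payload), paths["confusion_json"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
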