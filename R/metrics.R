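# Per-subject tone metrics: the six-contrast differentiability score and
# the 4x4 hit-rate confusion matrix, under the 2D (onset x offset) and 3D
# (onset x mid x offset) methods.

#' Geometry / scoring parameters
#'
#' @param sd_multiplier semiaxis length in SD units (default 2).
#' @param orientation `"covariance"` or `"aligned"` ellipse orientation.
#' @param n_samples Monte-Carlo samples per overlap estimate.
#' @param seed base seed for the Monte-Carlo overlap estimates.
#' @param min_tokens minimum analyzable tokens per tone for a region; the
#'   default `NULL` means `dim + 1`, the smallest count with a full-rank
#'   covariance.
#' @param ridge covariance ridge (semitone^2).
#' @return list of class `metric_params`.
#' @export
metric_params <- function(sd_multiplier = 2, orientation = "covariance",
                          n_samples = 2e5, seed = 20L, min_tokens = NULL,
                          ridge = 1e-6) {
  structure(list(sd_multiplier = sd_multiplier, orientation = orientation,
                 n_samples = n_samples, seed = as.integer(seed),
                 min_tokens = min_tokens, ridge = ridge),
            class = "metric_params")
}

method_columns <- function(method) {
  switch(method,
         "2D" = c("onset_st", "offset_st"),
         "3D" = c("onset_st", "mid_st", "offset_st"),
         stop_invalid("method must be '2D' or '3D'"))
}

# fit the four per-tone regions for one subject; NULL where a tone lacks
# enough analyzable tokens
fit_tone_regions <- function(features, method, params = metric_params()) {
  cols <- method_columns(method)
  dim <- length(cols)
  min_tok <- params$min_tokens %||% (dim + 1L)
  min_tok <- max(min_tok, dim + 1L)
  lapply(1:4, function(tn) {
    pts <- as.matrix(features[features$target_tone == tn &
                                stats::complete.cases(features[, cols]),
                              cols, drop = FALSE])
    if (nrow(pts) < min_tok) return(NULL)
    tryCatch(
      fit_region(pts, tone = tn, sd_multiplier = params$sd_multiplier,
                 orientation = params$orientation, ridge = params$ridge),
      error = function(e) NULL)
  })
}

#' Differentiability of one tone contrast
#'
#' Converts an overlap estimate into the contrast score
#' `[(1 - Ai/A1) + (1 - Ai/A2)] / 2`: 0 for identical regions, 1 for
#' disjoint ones. Values are clipped to \[0, 1\] against Monte-Carlo
#' jitter (the overlap estimate can slightly exceed the smaller measure).
#'
#' @param r1,r2 `tone_region`s.
#' @param overlap an `overlap_result` for the pair (computed with
#'   [overlap_measure()] if omitted).
#' @param ... passed to [overlap_measure()] when `overlap` is missing.
#' @return score in \[0, 1\].
#' @export
pairwise_differentiability <- function(r1, r2, overlap = NULL, ...) {
  if (any(c(r1$measure, r2$measure) <= 0)) {
    warning("degenerate region: differentiability undefined")
    return(NA_real_)
  }
  if (is.null(overlap)) overlap <- overlap_measure(r1, r2, ...)
  score <- ((1 - overlap$ai / r1$measure) + (1 - overlap$ai / r2$measure)) / 2
  min(1, max(0, score))
}

#' Per-subject tone differentiability
#'
#' Fits one tone region per tone from the subject's semitone landmarks
#' (2D: onset/offset; 3D: onset/mid/offset), estimates the pairwise
#' overlaps, and scores the six tone contrasts plus their mean. Contrasts
#' involving a tone with too few tokens are `NA` and excluded from the
#' average.
#'
#' @param features one subject's landmark feature rows (see
#'   [compute_features()]).
#' @param method `"2D"` or `"3D"`.
#' @param params a [metric_params()] object.
#' @return list of class `tone_differentiability`: `subject_id`, `method`,
#'   `contrasts` (named six-vector), `average`, `regions`.
#' @export
subject_differentiability <- function(features, method = "2D",
                                      params = metric_params()) {
  regions <- fit_tone_regions(features, method, params)
  if (sum(!vapply(regions, is.null, logical(1))) < 2L) {
    warning("fewer than 2 tones with valid regions; result undefined")
  }
  scores <- stats::setNames(rep(NA_real_, 6L), tone_contrasts())
  for (ct in tone_contrasts()) {
    ij <- contrast_tones(ct)
    r1 <- regions[[ij[1]]]; r2 <- regions[[ij[2]]]
    if (is.null(r1) || is.null(r2)) next
    ov <- overlap_measure(r1, r2, n_samples = params$n_samples,
                          seed = params$seed + 10L * ij[1] + ij[2])
    scores[ct] <- pairwise_differentiability(r1, r2, ov)
  }
  structure(
    list(subject_id = features$subject_id[1], method = method,
         contrasts = scores,
         average = if (all(is.na(scores))) NA_real_ else mean(scores, na.rm = TRUE),
         regions = regions),
    class = "tone_differentiability")
}

#' @export
print.tone_differentiability <- function(x, ...) {
  cat(sprintf("<tone_differentiability> subject %s, %s method\n",
              x$subject_id, x$method))
  print(round(x$contrasts, 3))
  cat(sprintf("average: %.3f\n", x$average))
  invisible(x)
}

#' Per-subject hit-rate confusion matrix
#'
#' Cell (i, j) is the proportion of target tone i among all tokens falling
#' inside tone region j; each defined column therefore sums to 1. A token
#' inside several regions contributes to every such column. Columns whose
#' region is missing or contains no tokens are undefined (`NA`) and are
#' excluded from the diagonal average.
#'
#' @inheritParams subject_differentiability
#' @return list of class `hit_rate_matrix`: `subject_id`, `method`,
#'   `cells` (4x4, rows = target tone, columns = region),
#'   `diagonal_average`, `regions`.
#' @export
hit_rate_matrix <- function(features, method = "2D",
                            params = metric_params()) {
  cols <- method_columns(method)
  regions <- fit_tone_regions(features, method, params)
  ok <- stats::complete.cases(features[, cols])
  pts <- as.matrix(features[ok, cols, drop = FALSE])
  tones <- features$target_tone[ok]
  cells <- matrix(NA_real_, 4, 4,
                  dimnames = list(target = 1:4, region = 1:4))
  for (j in 1:4) {
    if (is.null(regions[[j]]) || nrow(pts) == 0L) next
    inside <- region_contains(regions[[j]], pts)
    total <- sum(inside)
    if (total == 0L) next
    cells[, j] <- vapply(1:4, function(i) sum(inside & tones == i) / total,
                         numeric(1))
  }
  diagv <- diag(cells)
  structure(
    list(subject_id = features$subject_id[1], method = method, cells = cells,
         diagonal_average = if (all(is.na(diagv))) NA_real_
                            else mean(diagv, na.rm = TRUE),
         regions = regions),
    class = "hit_rate_matrix")
}

#' @export
print.hit_rate_matrix <- function(x, ...) {
  cat(sprintf("<hit_rate_matrix> subject %s, %s method\n",
              x$subject_id, x$method))
  print(round(x$cells, 3))
  cat(sprintf("diagonal average: %.3f\n", x$diagonal_average))
  invisible(x)
}

#' Score a whole cohort under both methods
#'
#' Computes per-subject differentiability and hit rate under the requested
#' methods and returns tidy long-form tables ready for the statistical
#' battery and for figure rendering.
#'
#' @param features cohort landmark feature table ([compute_features()]).
#' @param methods character subset of `c("2D", "3D")`.
#' @param params a [metric_params()] object.
#' @return list of class `cohort_scores`:
#'   `summary` (subject x method x measure long table, one row per
#'   average score), `contrasts` (per-contrast detail),
#'   `confusion` (per-cell detail), `group_means` (group x method x
#'   measure means and SDs).
#' @export
cohort_scores <- function(features, methods = c("2D", "3D"),
                          params = metric_params()) {
  subjects <- unique(features$subject_id)
  sum_rows <- list(); con_rows <- list(); cell_rows <- list()
  for (sid in subjects) {
    sub <- features[features$subject_id == sid, , drop = FALSE]
    grp <- sub$group[1]
    for (m in methods) {
      d <- suppressWarnings(subject_differentiability(sub, m, params))
      h <- suppressWarnings(hit_rate_matrix(sub, m, params))
      sum_rows[[length(sum_rows) + 1L]] <- data.frame(
        subject_id = sid, group = grp, method = m,
        measure = c("differentiability", "hit_rate"),
        value = c(d$average, h$diagonal_average), stringsAsFactors = FALSE)
      con_rows[[length(con_rows) + 1L]] <- data.frame(
        subject_id = sid, group = grp, method = m,
        contrast = names(d$contrasts), value = unname(d$contrasts),
        stringsAsFactors = FALSE)
      cell_rows[[length(cell_rows) + 1L]] <- data.frame(
        subject_id = sid, group = grp, method = m,
        target_tone = rep(1:4, 4), region_tone = rep(1:4, each = 4),
        value = as.vector(h$cells), stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, sum_rows)
  group_means <- stats::aggregate(
    value ~ group + method + measure, data = summary,
    FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                        sd = stats::sd(v, na.rm = TRUE)))
  group_means <- cbind(group_means[, 1:3],
                       mean = group_means$value[, "mean"],
                       sd = group_means$value[, "sd"])
  structure(
    list(summary = summary, contrasts = do.call(rbind, con_rows),
         confusion = do.call(rbind, cell_rows), group_means = group_means),
    class = "cohort_scores")
}

#' @export
print.cohort_scores <- function(x, ...) {
  cat(sprintf("<cohort_scores> %d subjects, methods: %s\n",
              length(unique(x$summary$subject_id)),
              paste(unique(x$summary$method), collapse = ", ")))
  print(x$group_means, row.names = FALSE)
  invisible(x)
}
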