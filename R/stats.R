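# Group statistics on the score tables: arcsine variance stabilization,
# factorial and repeated-measures ANOVA, Pearson correlation, and the
# demographic linear model for implanted subjects.

#' Arcsine square-root transform for proportions
#'
#' `asin(sqrt(p))`, the classical variance-stabilizing transform applied
#' to differentiability and hit-rate proportions before ANOVA / linear
#' modelling. Values within `1e-9` outside \[0, 1\] are clamped; anything
#' farther out is an error.
#'
#' @param p proportions in \[0, 1\] (NA passed through).
#' @return transformed values in \[0, pi/2\].
#' @export
arcsine_transform <- function(p) {
  bad <- !is.na(p) & (p < -1e-9 | p > 1 + 1e-9)
  assert_that(!any(bad), "proportions must lie in [0, 1]")
  asin(sqrt(pmin(1, pmax(0, p))))
}

#' Inverse of [arcsine_transform()]
#' @param x transformed values.
#' @return proportions `sin(x)^2`.
#' @export
arcsine_inverse <- function(x) sin(x)^2

#' Two-way factorial ANOVA on transformed scores
#'
#' Fits `value ~ f1 * f2` by least squares on arcsine-transformed scores
#' and reports the two main effects and their interaction. Sums of squares
#' are Type II by default (robust to mildly unbalanced group sizes); Type
#' I and III are selectable. With `within = TRUE` the second factor is
#' treated as a within-subject factor (requires a `subject` column) and
#' tested against its subject-interaction stratum.
#'
#' @param data data frame.
#' @param value,f1,f2 column names of the response and the two factors.
#' @param subject subject-id column (used when `within = TRUE`).
#' @param transform apply [arcsine_transform()] to the response first.
#' @param type sum-of-squares type, `"II"` (default), `"I"` or `"III"`.
#' @param within treat `f2` as within-subject.
#' @return data frame of class `anova_result` with one row per effect:
#'   `effect`, `F`, `df1`, `df2`, `p`.
#' @export
two_way_anova <- function(data, value = "value", f1 = "group", f2 = "method",
                          subject = "subject_id", transform = TRUE,
                          type = c("II", "I", "III"), within = FALSE) {
  type <- match.arg(type)
  df <- data.frame(y = data[[value]],
                   a = factor(data[[f1]]), b = factor(data[[f2]]))
  if (within) {
    assert_that(subject %in% names(data),
                "within = TRUE requires a subject column")
    df$s <- factor(data[[subject]])
  }
  df <- df[stats::complete.cases(df), ]
  assert_that(nlevels(droplevels(df$a)) >= 2 && nlevels(droplevels(df$b)) >= 2,
              "need at least 2 levels per factor")
  counts <- table(df$a, df$b)
  assert_that(all(counts >= 2),
              "unbalanced design: every factor cell needs >= 2 observations")
  if (transform) df$y <- arcsine_transform(df$y)

  if (within) {
    fit <- stats::aov(y ~ a * b + Error(s / b), data = df)
    sm <- summary(fit)
    tab_b <- as.data.frame(sm[["Error: s"]][[1]])
    tab_w <- as.data.frame(sm[["Error: s:b"]][[1]])
    rows <- rbind(
      anova_row(f1, tab_b, "a"),
      anova_row(f2, tab_w, "b"),
      anova_row(paste0(f1, ":", f2), tab_w, "a:b"))
  } else {
    fit <- stats::lm(y ~ a * b, data = df)
    tab <- if (type == "I") {
      as.data.frame(stats::anova(fit))
    } else {
      op <- options(contrasts = c("contr.sum", "contr.poly"))
      on.exit(options(op), add = TRUE)
      fit3 <- stats::lm(y ~ a * b, data = df)
      as.data.frame(car::Anova(if (type == "III") fit3 else fit, type = type))
    }
    names(tab) <- sub("Pr\\(>F\\)", "p", names(tab))
    resid_df <- tab["Residuals", "Df"]
    pick <- function(effect, label) {
      data.frame(effect = label, F = tab[effect, "F value"],
                 df1 = tab[effect, "Df"], df2 = resid_df,
                 p = tab[effect, "p"], stringsAsFactors = FALSE)
    }
    rows <- rbind(pick("a", f1), pick("b", f2), pick("a:b", paste0(f1, ":", f2)))
  }
  structure(rows, class = c("anova_result", "data.frame"))
}

anova_row <- function(label, tab, term) {
  i <- match(term, trimws(rownames(tab)))
  resid <- grep("Residuals", trimws(rownames(tab)))
  data.frame(effect = label, F = tab[i, "F value"], df1 = tab[i, "Df"],
             df2 = tab[resid, "Df"], p = tab[i, "Pr(>F)"],
             stringsAsFactors = FALSE)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject test of a condition factor (tone contrasts or tone
#' types) on transformed scores. Subjects missing any condition are
#' dropped listwise. Reports the uncorrected within-subject F test, the
#' Greenhouse-Geisser epsilon and corrected p, and Bonferroni-corrected
#' paired post-hoc t tests.
#'
#' @param data data frame in long form.
#' @param value,subject,condition column names.
#' @param transform apply [arcsine_transform()] first.
#' @return list of class `rm_anova_result`: `anova` (effect row with
#'   `F`, `df1`, `df2`, `p`, `gg_epsilon`, `p_gg`), `posthoc` (pairwise
#'   matrix of Bonferroni-adjusted p), `condition_means`, `n_subjects`.
#' @export
rm_anova_oneway <- function(data, value = "value", subject = "subject_id",
                            condition = "condition", transform = TRUE) {
  df <- data.frame(y = data[[value]], s = factor(data[[subject]]),
                   c = factor(data[[condition]]))
  df <- df[stats::complete.cases(df), ]
  assert_that(nlevels(droplevels(df$c)) >= 2, "need at least 2 conditions")
  # listwise deletion: keep subjects observed in every condition
  k <- nlevels(droplevels(df$c))
  keep <- names(which(tapply(df$c, df$s, function(z) length(unique(z))) == k))
  df <- droplevels(df[df$s %in% keep, ])
  assert_that(nlevels(df$s) >= 2, "need at least 2 complete subjects")
  if (transform) df$y <- arcsine_transform(df$y)

  wide <- stats::reshape(stats::aggregate(y ~ s + c, df, mean),
                         idvar = "s", timevar = "c", direction = "wide")
  Y <- as.matrix(wide[, -1, drop = FALSE])

  fit <- stats::aov(y ~ c + Error(s / c), data = df)
  tab <- as.data.frame(summary(fit)[["Error: s:c"]][[1]])
  i <- match("c", trimws(rownames(tab)))
  j <- grep("Residuals", trimws(rownames(tab)))
  Fv <- tab[i, "F value"]; df1 <- tab[i, "Df"]; df2 <- tab[j, "Df"]
  p <- tab[i, "Pr(>F)"]

  eps <- gg_epsilon(Y)
  p_gg <- stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)

  # paired t tests degenerate when differences are exactly constant
  ph <- tryCatch(
    stats::pairwise.t.test(df$y, df$c, paired = TRUE,
                           p.adjust.method = "bonferroni"),
    error = function(e) list(p.value = NULL))
  structure(
    list(anova = data.frame(effect = condition, F = Fv, df1 = df1, df2 = df2,
                            p = p, gg_epsilon = eps, p_gg = p_gg),
         posthoc = ph$p.value,
         condition_means = colMeans(Y),
         n_subjects = nrow(Y)),
    class = "rm_anova_result")
}

# Greenhouse-Geisser epsilon from the subjects x conditions matrix
gg_epsilon <- function(Y) {
  S <- stats::cov(Y)
  k <- ncol(Y)
  dbar <- mean(diag(S))
  sbar <- mean(S)
  num <- (k * (dbar - sbar))^2
  rm_i <- rowMeans(S)
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rm_i^2) + k^2 * sbar^2)
  eps <- num / den
  min(1, max(1 / (k - 1), eps))
}

#' @export
print.rm_anova_result <- function(x, ...) {
  print(x$anova, row.names = FALSE)
  cat(sprintf("%d complete subjects; Bonferroni post hocs available\n",
              x$n_subjects))
  invisible(x)
}

#' Pearson correlation with optional family-wise correction
#'
#' Sample Pearson correlation with the two-sided t-test p-value, after
#' pairwise deletion of missing values. A Bonferroni-adjusted p is also
#' reported for use inside a named family of `family_size` tests (the
#' raw p is always kept, mirroring reports that tabulate uncorrected
#' correlations alongside a Bonferroni remark).
#'
#' @param x,y numeric vectors of equal length.
#' @param family_size number of tests in the comparison family (default 1
#'   = no correction).
#' @return list: `r`, `p`, `p_bonferroni`, `n`.
#' @export
pearson_cor <- function(x, y, family_size = 1L) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  assert_that(length(x) >= 3, "need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, p_bonferroni = NA_real_,
                n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       p_bonferroni = min(1, ct$p.value * family_size), n = length(x))
}

#' Demographic linear model for implanted subjects
#'
#' Least-squares fit of a transformed score on age at implantation,
#' duration of device use, and their interaction (chronological age is
#' excluded by design: it is the sum of the other two predictors, so the
#' three are collinear).
#'
#' @param data data frame of implanted subjects with the response and
#'   `age_at_implantation`, `duration_of_use` columns.
#' @param response response column name (already on the analysis scale,
#'   or set `transform = TRUE` to arcsine-transform a proportion).
#' @param transform apply [arcsine_transform()] to the response.
#' @return list of class `glm_result`: `coefficients` (data frame with
#'   `term`, `beta`, `t`, `p`), `r_squared`, `n`, `fit` (the underlying
#'   `lm`).
#' @export
glm_fit <- function(data, response = "value", transform = FALSE) {
  needed <- c(response, "age_at_implantation", "duration_of_use")
  assert_that(all(needed %in% names(data)), "missing columns: ",
              paste(setdiff(needed, names(data)), collapse = ", "))
  df <- data.frame(y = data[[response]],
                   age = data$age_at_implantation,
                   dur = data$duration_of_use)
  df <- df[stats::complete.cases(df), ]
  if (transform) df$y <- arcsine_transform(df$y)
  fit <- stats::lm(y ~ age * dur, data = df)
  if (fit$rank < 4L) stop_invalid("collinear predictors: rank-deficient fit")
  sm <- summary(fit)
  co <- stats::coef(sm)
  terms_map <- c("(Intercept)" = "intercept", age = "age_at_implantation",
                 dur = "duration_of_use", "age:dur" = "age_x_duration")
  structure(
    list(coefficients = data.frame(
           term = unname(terms_map[rownames(co)]),
           beta = co[, "Estimate"], t = co[, "t value"],
           p = co[, "Pr(>|t|)"], row.names = NULL,
           stringsAsFactors = FALSE),
         r_squared = sm$r.squared, n = nrow(df), fit = fit),
    class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  print(transform(x$coefficients, beta = signif(beta, 4), t = signif(t, 4),
                  p = signif(p, 4)), row.names = FALSE)
  cat(sprintf("R^2 = %.3f (n = %d)\n", x$r_squared, x$n))
  invisible(x)
}

#' Run the full statistical battery on cohort scores
#'
#' Reproduces the standard report on a [cohort_scores()] object: per
#' measure, a two-way group x method ANOVA on arcsine-transformed
#' averages; per group and method, a one-way repeated-measures ANOVA over
#' tone contrasts (differentiability) with Bonferroni post hocs; the
#' measure-to-measure and method-to-method Pearson correlations; and, when
#' demographics are supplied, the demographic linear model per method and
#' measure for the implanted group.
#'
#' @param scores a `cohort_scores` object.
#' @param demographics optional data frame with `subject_id`,
#'   `age_at_implantation`, `duration_of_use` (one row per subject).
#' @return list of class `cohort_stats` with elements `anova`,
#'   `contrast_rm`, `correlations`, `glm`.
#' @export
cohort_statistics <- function(scores, demographics = NULL) {
  s <- scores$summary
  anova <- lapply(stats::setNames(nm = unique(s$measure)), function(me) {
    two_way_anova(s[s$measure == me, ], value = "value",
                  f1 = "group", f2 = "method")
  })
  contrast_rm <- list()
  for (g in unique(scores$contrasts$group)) {
    for (m in unique(scores$contrasts$method)) {
      sub <- scores$contrasts[scores$contrasts$group == g &
                                scores$contrasts$method == m, ]
      contrast_rm[[paste(g, m, sep = "_")]] <-
        tryCatch(rm_anova_oneway(sub, value = "value",
                                 subject = "subject_id",
                                 condition = "contrast"),
                 error = function(e) NULL)
    }
  }
  # per-subject columns for the four method x measure combinations
  key <- function(me, m) {
    v <- s$value[s$measure == me & s$method == m]
    names(v) <- s$subject_id[s$measure == me & s$method == m]
    v
  }
  ids <- unique(s$subject_id)
  cols <- list(d2 = key("differentiability", "2D")[as.character(ids)],
               d3 = key("differentiability", "3D")[as.character(ids)],
               h2 = key("hit_rate", "2D")[as.character(ids)],
               h3 = key("hit_rate", "3D")[as.character(ids)])
  correlations <- list(
    diff_vs_hit_2d = pearson_cor(cols$d2, cols$h2),
    diff_vs_hit_3d = pearson_cor(cols$d3, cols$h3),
    diff_2d_vs_3d  = pearson_cor(cols$d2, cols$d3),
    hit_2d_vs_3d   = pearson_cor(cols$h2, cols$h3))
  glm <- NULL
  if (!is.null(demographics)) {
    glm <- list()
    for (m in unique(s$method)) for (me in unique(s$measure)) {
      sub <- s[s$method == m & s$measure == me & s$group == "CI", ]
      sub <- merge(sub, demographics, by = "subject_id")
      if (nrow(sub) >= 8) {
        glm[[paste(me, m, sep = "_")]] <-
          glm_fit(sub, response = "value", transform = TRUE)
      }
    }
  }
  structure(list(anova = anova, contrast_rm = contrast_rm,
                 correlations = correlations, glm = glm),
            class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  for (me in names(x$anova)) {
    cat("Two-way ANOVA (", me, "):\n", sep = "")
    print(as.data.frame(x$anova[[me]]), row.names = FALSE)
  }
  cat("Correlations:\n")
  for (nm in names(x$correlations)) {
    co <- x$correlations[[nm]]
    cat(sprintf("  %-15s r = %.3f, p = %.3g (n = %d)\n", nm, co$r, co$p, co$n))
  }
  if (!is.null(x$glm)) {
    for (nm in names(x$glm)) {
      cat("GLM [", nm, "]: R^2 = ", sprintf("%.3f", x$glm[[nm]]$r_squared),
          "\n", sep = "")
    }
  }
  invisible(x)
}
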