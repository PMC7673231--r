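# Report figures, base graphics: ellipse scatter panels, contrast bar
# charts with SD bars, confusion-matrix heat tables, and method/measure
# correlation scatters.

tone_colors <- function() {
  c("1" = "#1b6ca8", "2" = "#2e8b57", "3" = "#d2691e", "4" = "#b22222")
}

ellipse_outline <- function(region, n = 181) {
  th <- seq(0, 2 * pi, length.out = n)
  u <- rbind(region$semiaxes[1] * cos(th), region$semiaxes[2] * sin(th))
  t(region$axes[, 1:2] %*% u + region$center[1:2])
}

plot_subject_ellipses <- function(features, subject_id,
                                  params = metric_params(), main = NULL) {
  sub <- features[features$subject_id == subject_id, ]
  regions <- fit_tone_regions(sub, "2D", params)
  cols <- tone_colors()
  ok <- stats::complete.cases(sub[, c("onset_st", "offset_st")])
  plot(sub$onset_st[ok], sub$offset_st[ok],
       col = cols[as.character(sub$target_tone[ok])], pch = 19, cex = 0.7,
       xlab = "F0 onset (semitones re tone-1 mean)",
       ylab = "F0 offset (semitones re tone-1 mean)",
       main = main %||% paste("Tone ellipses:", subject_id), asp = 1)
  any_undefined <- FALSE
  for (tn in 1:4) {
    r <- regions[[tn]]
    if (is.null(r)) { any_undefined <- TRUE; next }
    graphics::lines(ellipse_outline(r), col = cols[as.character(tn)], lwd = 2)
  }
  if (any_undefined) {
    graphics::mtext("undefined region(s): too few tokens", side = 3,
                    cex = 0.7, col = "grey40")
  }
  graphics::legend("topright", legend = paste("tone", 1:4), col = cols,
                   pch = 19, cex = 0.8, bty = "n")
  invisible(regions)
}

plot_contrast_bars <- function(contrasts, method, main = NULL) {
  sub <- contrasts[contrasts$method == method, ]
  labs <- c(tone_contrasts(), "avg")
  groups <- unique(sub$group)
  agg <- function(g) {
    d <- sub[sub$group == g, ]
    per <- vapply(tone_contrasts(), function(ct)
      mean(d$value[d$contrast == ct], na.rm = TRUE), numeric(1))
    avg_by_subj <- tapply(d$value, d$subject_id, mean, na.rm = TRUE)
    sds <- vapply(tone_contrasts(), function(ct)
      stats::sd(d$value[d$contrast == ct], na.rm = TRUE), numeric(1))
    list(mean = c(per, avg = mean(avg_by_subj, na.rm = TRUE)),
         sd = c(sds, avg = stats::sd(avg_by_subj, na.rm = TRUE)))
  }
  stats_by_group <- lapply(stats::setNames(nm = groups), agg)
  m <- do.call(rbind, lapply(stats_by_group, `[[`, "mean"))
  s <- do.call(rbind, lapply(stats_by_group, `[[`, "sd"))
  bp <- graphics::barplot(m, beside = TRUE, names.arg = labs,
                          col = c("grey20", "grey70")[seq_along(groups)],
                          ylim = c(0, 1.15), ylab = "differentiability",
                          main = main %||% paste("Tone contrasts,", method))
  pos <- is.finite(s) & s > 0
  if (any(pos)) {
    graphics::arrows(bp[pos], m[pos], bp[pos], pmin(1.1, (m + s)[pos]),
                     angle = 90, length = 0.03)
  }
  graphics::legend("bottomright", legend = groups,
                   fill = c("grey20", "grey70")[seq_along(groups)], bty = "n")
}

plot_confusion_heat <- function(confusion, group, method, main = NULL) {
  sub <- confusion[confusion$group == group & confusion$method == method, ]
  m <- matrix(NA_real_, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    m[i, j] <- mean(sub$value[sub$target_tone == i & sub$region_tone == j],
                    na.rm = TRUE)
  }
  graphics::image(1:4, 1:4, t(m[4:1, ]), zlim = c(0, 1), axes = FALSE,
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  xlab = "tone region", ylab = "target tone",
                  main = main %||% paste("Hit-rate matrix:", group, method))
  graphics::axis(1, at = 1:4, labels = 1:4)
  graphics::axis(2, at = 1:4, labels = 4:1)
  for (i in 1:4) for (j in 1:4) {
    graphics::text(j, 5 - i, sprintf("%.2f", m[i, j]),
                   col = if (!is.na(m[i, j]) && m[i, j] > 0.5) "white" else "black")
  }
  graphics::box()
}

plot_correlation <- function(x, y, xlab, ylab, groups = NULL, main = NULL) {
  cols <- if (is.null(groups)) "grey30" else
    ifelse(groups == "NH", "#2040c0", "#c03020")
  plot(x, y, col = cols, pch = ifelse(!is.null(groups) & groups == "NH", 19, 1),
       xlab = xlab, ylab = ylab, main = main, xlim = c(0, 1), ylim = c(0, 1))
  ok <- stats::complete.cases(x, y)
  if (sum(ok) >= 3 && stats::sd(x[ok]) > 0) {
    graphics::abline(stats::lm(y[ok] ~ x[ok]), col = "grey40")
    ct <- pearson_cor(x, y)
    graphics::legend("topleft",
                     legend = sprintf("r = %.3f, p = %.2g", ct$r, ct$p),
                     bty = "n")
  }
}

#' Render the standard report figures
#'
#' Writes PNG panels under `dir`: per-subject 2D ellipse scatter plots for
#' representative subjects, per-group pooled ellipse panels, contrast bar
#' charts with SD bars per method, group x method confusion-matrix heat
#' tables, and the measure/method correlation scatters.
#'
#' @param scores a `cohort_scores` object.
#' @param features the landmark feature table.
#' @param dir output directory.
#' @param max_subject_panels cap on per-subject panels (default 8).
#' @return character vector of written files, invisibly.
#' @export
render_figures <- function(scores, features, dir = "figures",
                           max_subject_panels = 8L) {
  if (is.null(scores) || nrow(scores$summary) == 0) {
    warning("no scores to plot")
    return(invisible(character(0)))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  png_to <- function(name, code, width = 900, height = 700) {
    path <- file.path(dir, name)
    grDevices::png(path, width = width, height = height, res = 110)
    on.exit(grDevices::dev.off(), add = TRUE)
    force(code)
    written <<- c(written, path)
  }
  # group-pooled ellipse panels
  for (g in unique(features$group)) {
    pooled <- features[features$group == g, ]
    pooled$subject_id <- g   # pool the group into one pseudo-subject
    png_to(paste0("ellipses_group_", g, ".png"),
           plot_subject_ellipses(pooled, g,
                                 main = paste("Tone ellipses, group", g)))
  }
  # representative per-subject panels
  subs <- unique(features$subject_id)
  subs <- subs[seq_len(min(length(subs), max_subject_panels))]
  for (sid in subs) {
    png_to(paste0("ellipses_", sid, ".png"), plot_subject_ellipses(features, sid))
  }
  for (m in unique(scores$contrasts$method)) {
    png_to(paste0("contrast_bars_", m, ".png"),
           plot_contrast_bars(scores$contrasts, m))
  }
  for (g in unique(scores$confusion$group)) {
    for (m in unique(scores$confusion$method)) {
      png_to(paste0("confusion_", g, "_", m, ".png"),
             plot_confusion_heat(scores$confusion, g, m))
    }
  }
  s <- scores$summary
  val <- function(me, m) {
    idx <- s$measure == me & s$method == m
    v <- s$value[idx]; names(v) <- s$subject_id[idx]; v
  }
  ids <- unique(s$subject_id)
  grp <- s$group[match(ids, s$subject_id)]
  if (all(c("2D", "3D") %in% s$method)) {
    png_to("correlations.png", {
      op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
      on.exit(graphics::par(op), add = TRUE)
      plot_correlation(val("differentiability", "2D")[as.character(ids)],
                       val("hit_rate", "2D")[as.character(ids)],
                       "differentiability (2D)", "hit rate (2D)", grp)
      plot_correlation(val("differentiability", "3D")[as.character(ids)],
                       val("hit_rate", "3D")[as.character(ids)],
                       "differentiability (3D)", "hit rate (3D)", grp)
      plot_correlation(val("differentiability", "2D")[as.character(ids)],
                       val("differentiability", "3D")[as.character(ids)],
                       "differentiability (2D)", "differentiability (3D)", grp)
      plot_correlation(val("hit_rate", "2D")[as.character(ids)],
                       val("hit_rate", "3D")[as.character(ids)],
                       "hit rate (2D)", "hit rate (3D)", grp)
    })
  }
  invisible(written)
}
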