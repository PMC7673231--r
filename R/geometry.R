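# Tone regions: covariance ellipses (2D) and ellipsoids (3D) with semiaxes
# tied to 2 SD of the landmark scatter, containment tests, and seeded
# Monte-Carlo overlap estimation.

#' Construct a tone region from an explicit summary
#'
#' Builds a `tone_region` directly from center / axes / semiaxes, for tests,
#' plotting and region I/O. [fit_region()] is the data-driven constructor.
#'
#' @param center numeric vector (length 2 or 3), semitones.
#' @param axes orthonormal matrix whose columns are the principal
#'   directions (defaults to the identity).
#' @param semiaxes positive semiaxis lengths, semitones, same length as
#'   `center`.
#' @param tone optional tone label (1-4).
#' @return object of class `tone_region` with fields `dim`, `tone`,
#'   `center`, `axes`, `semiaxes`, `measure` (area in semitone^2 for 2D,
#'   volume in semitone^3 for 3D) and `n_points`.
#' @export
region_from_summary <- function(center, axes = diag(length(center)),
                                semiaxes, tone = NA_integer_) {
  dim <- length(center)
  assert_that(dim %in% c(2L, 3L), "region dimension must be 2 or 3")
  axes <- as.matrix(axes)
  assert_that(all(dim(axes) == dim), "axes must be a dim x dim matrix")
  assert_that(max(abs(crossprod(axes) - diag(dim))) < 1e-8,
              "axes must be orthonormal")
  assert_that(length(semiaxes) == dim && all(is.finite(semiaxes)) &&
                all(semiaxes > 0), "semiaxes must be positive")
  measure <- if (dim == 2L) pi * prod(semiaxes) else (4 / 3) * pi * prod(semiaxes)
  structure(
    list(dim = dim, tone = as.integer(tone), center = as.numeric(center),
         axes = axes, semiaxes = as.numeric(semiaxes), measure = measure,
         n_points = NA_integer_),
    class = "tone_region")
}

#' @export
print.tone_region <- function(x, ...) {
  cat(sprintf(
    "<tone_region> %dD%s center (%s), semiaxes (%s) st, %s %.3f st^%d\n",
    x$dim,
    if (is.na(x$tone)) "" else paste0(" tone ", x$tone),
    paste(sprintf("%.2f", x$center), collapse = ", "),
    paste(sprintf("%.2f", x$semiaxes), collapse = ", "),
    if (x$dim == 2) "area" else "volume", x$measure, x$dim))
  invisible(x)
}

#' Fit a tone ellipse / ellipsoid to landmark points
#'
#' The region center is the coordinate-wise mean of the scatter; the
#' principal directions are the eigenvectors of the sample covariance
#' matrix and each semiaxis is `sd_multiplier` standard deviations along
#' its direction (default 2 SD, i.e. Mahalanobis radius 2). A small ridge
#' on the covariance diagonal stabilizes nearly degenerate scatters.
#'
#' @param points numeric matrix, one landmark vector per row (2 columns:
#'   onset/offset; 3 columns: onset/mid/offset), in semitones.
#' @param tone optional tone label.
#' @param sd_multiplier semiaxis length in SD units (default 2).
#' @param orientation `"covariance"` (principal axes, default) or
#'   `"aligned"` (axis-aligned, per-coordinate SDs).
#' @param ridge ridge added to the covariance diagonal (semitone^2).
#' @return a `tone_region`.
#' @export
fit_region <- function(points, tone = NA_integer_, sd_multiplier = 2,
                       orientation = c("covariance", "aligned"),
                       ridge = 1e-6) {
  orientation <- match.arg(orientation)
  points <- as.matrix(points)
  dim <- ncol(points)
  assert_that(dim %in% c(2L, 3L), "points must have 2 or 3 columns")
  assert_that(nrow(points) >= dim + 1L,
              "insufficient data: need at least dim+1 points, got ", nrow(points))
  assert_that(all(is.finite(points)), "landmark points must be finite")
  center <- colMeans(points)
  if (max(abs(sweep(points, 2, center))) == 0) {
    stop_invalid("degenerate region: all points identical")
  }
  S <- stats::cov(points) + diag(ridge, dim)
  if (orientation == "aligned") {
    axes <- diag(dim)
    vars <- diag(S)
  } else {
    e <- eigen(S, symmetric = TRUE)
    axes <- e$vectors
    vars <- pmax(e$values, 0)
  }
  r <- region_from_summary(center, axes, sd_multiplier * sqrt(vars), tone)
  r$n_points <- nrow(points)
  r
}

# local (principal-axis) coordinates of a point matrix, n x dim
region_local_coords <- function(region, points) {
  sweep(as.matrix(points), 2, region$center) %*% region$axes
}

#' Test whether points lie inside a tone region
#'
#' A point is inside when its squared Mahalanobis-type radius
#' `sum_k (u_k / semiaxis_k)^2` is at most 1, `u` being the point in the
#' region's principal-axis frame; the boundary counts as inside.
#'
#' @param region a `tone_region`.
#' @param points a vector (one point) or matrix (one point per row),
#'   dimension matching `region$dim`.
#' @return logical vector, one entry per point.
#' @export
region_contains <- function(region, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  assert_that(ncol(points) == region$dim,
              "point dimension does not match region dimension")
  u <- region_local_coords(region, points)
  rowSums(sweep(u, 2, region$semiaxes, "/")^2) <= 1 + 1e-12
}

# n uniform draws inside the region (unit-ball sampling mapped through the
# principal frame)
region_sample_uniform <- function(region, n) {
  d <- region$dim
  z <- matrix(stats::rnorm(n * d), n, d)
  z <- z / sqrt(rowSums(z^2))
  r <- stats::runif(n)^(1 / d)
  u <- z * r
  sweep(u %*% diag(region$semiaxes, d) %*% t(region$axes), 2,
        region$center, "+")
}

#' Monte-Carlo overlap measure of two tone regions
#'
#' Estimates the intersection area (2D) or volume (3D) `Ai` of two regions
#' by uniform sampling inside the smaller-measure region and counting the
#' fraction of draws that also fall inside the other; disjoint bounding
#' spheres short-circuit to an exact 0. The estimate is deterministic
#' given `seed` and leaves the caller's RNG state untouched.
#'
#' @param r1,r2 `tone_region`s of equal dimension.
#' @param n_samples Monte-Carlo sample count (default 2e5).
#' @param seed integer seed.
#' @return list of class `overlap_result`: `ai` (intersection measure),
#'   `rel_1 = ai / measure_1`, `rel_2 = ai / measure_2`, `estimator_sd`
#'   (binomial standard error of `ai`) and `n_samples`.
#' @export
overlap_measure <- function(r1, r2, n_samples = 2e5, seed = 1L) {
  assert_that(r1$dim == r2$dim, "regions have different dimensions")
  assert_that(n_samples >= 1e4, "n_samples must be at least 1e4")
  out <- function(ai, sd) {
    structure(list(ai = ai, rel_1 = ai / r1$measure, rel_2 = ai / r2$measure,
                   estimator_sd = sd, n_samples = as.integer(n_samples)),
              class = "overlap_result")
  }
  # fast reject: bounding spheres cannot touch
  if (sqrt(sum((r1$center - r2$center)^2)) >
        max(r1$semiaxes) + max(r2$semiaxes)) {
    return(out(0, 0))
  }
  if (r1$measure <= r2$measure) { small <- r1; other <- r2 }
  else { small <- r2; other <- r1 }
  p <- with_local_seed(seed, {
    pts <- region_sample_uniform(small, n_samples)
    mean(region_contains(other, pts))
  })
  ai <- p * small$measure
  out(ai, small$measure * sqrt(p * (1 - p) / n_samples))
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> Ai = %.4f (SE %.4f, n = %d), rel %.3f / %.3f\n",
              x$ai, x$estimator_sd, x$n_samples, x$rel_1, x$rel_2))
  invisible(x)
}

#' Serialize tone regions to JSON
#'
#' @param regions a `tone_region` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_json <- function(regions, path) {
  if (inherits(regions, "tone_region")) regions <- list(regions)
  payload <- lapply(regions, function(r) {
    list(dim = r$dim, tone = r$tone, center = r$center,
         axes = lapply(asplit(r$axes, 2), as.numeric),
         semiaxes = r$semiaxes, n_points = r$n_points)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read tone regions from JSON written by [write_regions_json()]
#'
#' @param path JSON path.
#' @return list of `tone_region`s.
#' @export
read_regions_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(row) {
    axes <- do.call(cbind, lapply(row$axes, function(col) unlist(col)))
    r <- region_from_summary(unlist(row$center), axes, unlist(row$semiaxes),
                             row$tone %||% NA_integer_)
    r$n_points <- row$n_points %||% NA_integer_
    r
  })
}
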