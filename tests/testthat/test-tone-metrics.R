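test_that("pairwise differentiability follows the overlap definition", {
  r <- region_from_summary(c(0, 0), diag(2), c(1, 1))
  far <- region_from_summary(c(10, 0), diag(2), c(1, 1))
  near <- region_from_summary(c(1, 0), diag(2), c(1, 1))

  expect_equal(pairwise_differentiability(r, r, n_samples = 2e4, seed = 1), 0,
               tolerance = 1e-3)
  expect_equal(pairwise_differentiability(r, far, n_samples = 2e4, seed = 1), 1)
  # unit circles one radius apart: score = 1 - lens/pi
  sc <- pairwise_differentiability(r, near, n_samples = 2e5, seed = 1)
  expect_equal(sc, 1 - circle_lens_area(1) / pi, tolerance = 0.01)
  # symmetry in the two regions
  expect_equal(sc, pairwise_differentiability(near, r, n_samples = 2e5,
                                              seed = 8),
               tolerance = 0.01)
})

test_that("well-separated tones score near 1; pooled tones near 0", {
  feat <- make_features(separated_centers(10), sd = 0.5, seed = 2)
  for (m in c("2D", "3D")) {
    d <- subject_differentiability(feat, m, fast_params())
    expect_true(all(d$contrasts > 0.99), info = m)
    expect_equal(d$average, mean(d$contrasts))
  }
  # identical token sets: identical regions, so every score is exactly 0
  ident <- make_features(separated_centers(6), seed = 3)
  for (tn in 2:4) {
    cols <- c("onset_st", "mid_st", "offset_st")
    ident[ident$target_tone == tn, cols] <- ident[ident$target_tone == 1, cols]
  }
  d1 <- subject_differentiability(ident, "2D", fast_params())
  expect_identical(unname(d1$contrasts), rep(0, 6))

  # all four tones from one common distribution: scores collapse to the
  # chance level of 9-point ellipse fits, far below separated clusters
  common <- make_features(matrix(0, 4, 3), sd = 1, seed = 3)
  for (m in c("2D", "3D")) {
    d0 <- subject_differentiability(common, m, fast_params())
    expect_lt(d0$average, 0.5)
  }
})

test_that("differentiability rises monotonically with cluster separation", {
  gaps <- c(0, 1.5, 3, 6, 12)
  means <- vapply(gaps, function(g) {
    centers <- matrix(c(0, 0, 0, g, g, g, -g, -g, -g, 2 * g, 0, -2 * g),
                      nrow = 4, byrow = TRUE)
    subject_differentiability(make_features(centers, sd = 1, seed = 4),
                              "2D", fast_params())$average
  }, numeric(1))
  expect_true(all(diff(means) > -0.02))   # monotone up to MC jitter
  expect_lt(means[1], 0.45)               # chance level of 9-point fits
  expect_gt(means[length(means)], 0.99)
})

test_that("contrasts without enough tokens stay undefined", {
  feat <- make_features(separated_centers(8), n_per_tone = 9, seed = 5)
  idx4 <- which(feat$target_tone == 4)
  feat <- feat[-idx4[-(1:2)], ]   # tone 4 down to 2 tokens: < dim+1
  d <- subject_differentiability(feat, "2D", fast_params())
  expect_true(all(is.na(d$contrasts[c("1v4", "2v4", "3v4")])))
  expect_equal(d$average, mean(d$contrasts[c("1v2", "1v3", "2v3")]))
})

test_that("hit-rate columns are proportions that sum to one", {
  feat <- make_features(separated_centers(10), sd = 0.5, seed = 6)
  h <- hit_rate_matrix(feat, "2D", fast_params())
  expect_equal(unname(colSums(h$cells)), rep(1, 4))
  expect_equal(unname(diag(h$cells)), rep(1, 4))   # fully separated
  expect_equal(h$diagonal_average, 1)

  mixed <- make_features(matrix(0, 4, 3), sd = 1, seed = 7)
  hm <- hit_rate_matrix(mixed, "3D", fast_params())
  defined <- !is.na(hm$cells[1, ])
  expect_true(all(abs(colSums(hm$cells[, defined, drop = FALSE]) - 1) < 1e-12))
  expect_true(all(hm$cells[!is.na(hm$cells)] >= 0 &
                    hm$cells[!is.na(hm$cells)] <= 1))
})

test_that("the shipped 12-point fixture matches exhaustive enumeration", {
  feat <- read.csv(system.file("extdata", "toy_hitrate.csv",
                               package = "tonellipse"))
  h <- hit_rate_matrix(feat, "2D", fast_params())
  # independent enumeration: brute-force point-in-ellipse over all tokens
  pts <- as.matrix(feat[, c("onset_st", "offset_st")])
  regions <- lapply(1:4, function(tn) {
    fit_region(pts[feat$target_tone == tn, ], tone = tn)
  })
  expected <- matrix(NA_real_, 4, 4)
  for (j in 1:4) {
    inside <- vapply(seq_len(nrow(pts)), function(i) {
      u <- t(regions[[j]]$axes) %*% (pts[i, ] - regions[[j]]$center)
      sum((u / regions[[j]]$semiaxes)^2) <= 1 + 1e-12
    }, logical(1))
    if (sum(inside) > 0) {
      expected[, j] <- vapply(1:4, function(i)
        sum(inside & feat$target_tone == i) / sum(inside), numeric(1))
    }
  }
  expect_equal(unname(h$cells), expected)
  defined <- which(!is.na(expected[1, ]))
  expect_equal(unname(colSums(expected[, defined, drop = FALSE])),
               rep(1, length(defined)))
})

test_that("cohort scoring returns tidy tables with expected shapes", {
  feat <- rbind(make_features(separated_centers(6), seed = 8,
                              subject_id = "A", group = "NH"),
                make_features(separated_centers(6), seed = 9,
                              subject_id = "B", group = "CI"))
  sc <- cohort_scores(feat, params = fast_params())
  expect_s3_class(sc, "cohort_scores")
  expect_equal(nrow(sc$summary), 2 * 2 * 2)       # subject x method x measure
  expect_equal(nrow(sc$contrasts), 2 * 2 * 6)
  expect_equal(nrow(sc$confusion), 2 * 2 * 16)
  expect_equal(sort(unique(sc$summary$measure)),
               c("differentiability", "hit_rate"))

  # a cohort of identical subjects has zero group SD
  same <- rbind(make_features(separated_centers(6), seed = 10,
                              subject_id = "C1", group = "NH"),
                within(make_features(separated_centers(6), seed = 10,
                                     subject_id = "C1", group = "NH"),
                       subject_id <- "C2"))
  sc2 <- cohort_scores(same, methods = "2D", params = fast_params())
  expect_true(all(sc2$group_means$sd < 1e-12))
})

test_that("3D scores dominate 2D scores on independent-noise cohorts", {
  cohort <- generate_cohort(cohort_spec(n_nh = 10, n_ci = 10, seed = 12))
  sc <- cohort_scores(cohort_features(cohort),
                      params = fast_params(n_samples = 1e4))
  s <- sc$summary
  for (me in c("differentiability", "hit_rate")) {
    m2 <- mean(s$value[s$method == "2D" & s$measure == me], na.rm = TRUE)
    m3 <- mean(s$value[s$method == "3D" & s$measure == me], na.rm = TRUE)
    expect_gt(m3, m2)
  }
})

test_that("the two measures correlate across a heterogeneous cohort", {
  # flattening spanning the full range creates genuine score spread
  cohort <- generate_cohort(cohort_spec(n_nh = 40, n_ci = 0, seed = 14,
                                        nh_lambda_range = c(0, 1),
                                        nh_sigma = 1.5))
  sc <- cohort_scores(cohort_features(cohort), methods = "2D",
                      params = fast_params(n_samples = 1e4))
  s <- sc$summary
  d <- s$value[s$measure == "differentiability"]
  h <- s$value[s$measure == "hit_rate"]
  expect_gt(pearson_cor(d, h)$r, 0.7)
})
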