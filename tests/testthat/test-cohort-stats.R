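test_that("arcsine transform matches its definition and inverts cleanly", {
  expect_equal(arcsine_transform(0), 0)
  expect_equal(arcsine_transform(1), pi / 2)
  expect_equal(arcsine_transform(0.5), pi / 4)
  expect_error(arcsine_transform(1.2), "\\[0, 1\\]")
  expect_error(arcsine_transform(-0.1), "\\[0, 1\\]")
  p <- seq(0, 1, by = 0.01)
  expect_equal(arcsine_inverse(arcsine_transform(p)), p, tolerance = 1e-12)
  expect_true(all(diff(arcsine_transform(p)) > 0))   # strictly increasing
})

test_that("two-way ANOVA separates real from null effects", {
  set.seed(30)
  n <- 50
  base <- expand.grid(group = c("NH", "CI"), method = c("2D", "3D"),
                      rep = seq_len(n))
  # null: constant + noise, both factors inert
  base$value <- arcsine_inverse(0.8 + rnorm(nrow(base), 0, 0.1))
  a0 <- two_way_anova(base)
  expect_true(all(a0$p > 0.05))

  # planted group offset of 0.3 transformed units, no method effect
  eff <- base
  y <- 0.6 + ifelse(eff$group == "NH", 0.3, 0) + rnorm(nrow(eff), 0, 0.1)
  eff$value <- arcsine_inverse(y)
  a1 <- two_way_anova(eff)
  expect_lt(a1$p[a1$effect == "group"], 0.001)
  expect_gt(a1$p[a1$effect == "method"], 0.05)

  # swapping the factor roles swaps the two main-effect rows exactly
  a2 <- two_way_anova(eff, f1 = "method", f2 = "group")
  expect_equal(a1$F[a1$effect == "group"], a2$F[a2$effect == "group"])
  expect_equal(a1$F[a1$effect == "method"], a2$F[a2$effect == "method"])

  # empty cells are refused with a design message
  broken <- eff[!(eff$group == "NH" & eff$method == "3D"), ]
  expect_error(two_way_anova(broken), "unbalanced")
})

test_that("within-subject variant tests the method factor against its stratum", {
  set.seed(32)
  n <- 30
  subj <- data.frame(subject_id = rep(sprintf("s%02d", 1:n), each = 2),
                     group = rep(rep(c("NH", "CI"), each = 2), length.out = 2 * n),
                     method = rep(c("2D", "3D"), n))
  subj_eff <- rep(rnorm(n, 0, 0.08), each = 2)
  y <- 0.7 + ifelse(subj$method == "3D", 0.15, 0) + subj_eff +
    rnorm(2 * n, 0, 0.03)
  subj$value <- arcsine_inverse(pmin(1.5, y))
  aw <- two_way_anova(subj, within = TRUE)
  expect_lt(aw$p[aw$effect == "method"], 0.001)
  expect_equal(nrow(aw), 3)
})

test_that("repeated-measures ANOVA handles degenerate and planted effects", {
  subjects <- sprintf("s%02d", 1:12)
  flat <- expand.grid(subject_id = subjects, condition = tone_contrasts())
  # exact additive null: subject effects plus condition-centered noise, so
  # the condition sum of squares is exactly zero while residuals are not
  set.seed(36)
  noise <- rnorm(nrow(flat), 0, 0.05)
  noise <- noise - ave(noise, flat$condition)
  flat$value <- rep(seq(0.3, 0.85, length.out = 12), times = 6) + noise
  r0 <- rm_anova_oneway(flat, transform = FALSE)
  expect_equal(r0$anova$F, 0, tolerance = 1e-10)

  # constant condition shift with zero residual noise: p at the floor
  shifted <- flat
  shifted$value <- rep(seq(0.3, 0.85, length.out = 12), times = 6) +
    ifelse(shifted$condition == "1v2", 0.05, 0)
  r1 <- rm_anova_oneway(shifted, transform = FALSE)
  expect_lt(r1$anova$p, 1e-12)
  expect_true(r1$anova$gg_epsilon >= 1 / 5 && r1$anova$gg_epsilon <= 1)

  expect_error(rm_anova_oneway(flat[flat$condition == "1v2", ]),
               "2 conditions")
})

test_that("post hocs single out a depressed contrast", {
  set.seed(33)
  n <- 40
  d <- expand.grid(subject_id = sprintf("s%02d", 1:n),
                   condition = tone_contrasts())
  d$value <- 0.75 - ifelse(d$condition == "2v3", 0.2, 0) +
    rnorm(nrow(d), 0, 0.05)
  d$value <- pmin(1, pmax(0, d$value))
  r <- rm_anova_oneway(d)
  expect_lt(r$anova$p_gg, 0.001)
  means <- r$condition_means
  expect_equal(names(which.min(means)), "y.2v3")
  # every Bonferroni-adjusted comparison against 2v3 is significant
  ph <- r$posthoc
  involving <- c(ph["2v3", !is.na(ph["2v3", ])],
                 ph[!is.na(ph[, "2v3"]), "2v3"])
  expect_true(all(involving < 0.01))
})

test_that("pearson correlation matches closed-form cases", {
  x <- c(1, 2, 4, 8, 9)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  set.seed(34)
  n <- 200
  rho <- 0.9
  x2 <- rnorm(n)
  y2 <- rho * x2 + sqrt(1 - rho^2) * rnorm(n)
  r <- pearson_cor(x2, y2)
  expect_true(r$r > 0.85 && r$r < 0.94)
  expect_lt(r$p, 1e-10)
  expect_equal(pearson_cor(x2, y2, family_size = 4)$p_bonferroni,
               min(1, r$p * 4))
  expect_warning(res <- pearson_cor(rep(1, 10), rnorm(10)), "zero variance")
  expect_true(is.na(res$r))
})

test_that("the demographic model recovers planted structure", {
  set.seed(35)
  n <- 200
  demo <- data.frame(age_at_implantation = runif(n, 0.5, 6),
                     duration_of_use = runif(n, 0.5, 8))
  demo$value <- 0.05 * demo$duration_of_use + rnorm(n, 0, 0.01)
  g <- glm_fit(demo)
  beta <- g$coefficients
  b_dur <- beta$beta[beta$term == "duration_of_use"]
  expect_lt(abs(b_dur - 0.05) / 0.05, 0.2)
  expect_lt(abs(beta$beta[beta$term == "age_at_implantation"]), 0.01)
  expect_lt(beta$p[beta$term == "duration_of_use"], 1e-10)

  # zero-noise linear response: perfect fit
  demo$value <- 0.2 + 0.03 * demo$age_at_implantation +
    0.05 * demo$duration_of_use
  expect_equal(suppressWarnings(glm_fit(demo)$r_squared), 1,
               tolerance = 1e-12)

  # response independent of both predictors: negligible R^2
  demo$value <- rnorm(n, 0.5, 0.1)
  expect_lt(glm_fit(demo)$r_squared, 0.05)

  # nesting: the interaction model never has lower R^2 than main effects
  demo$value <- 0.4 + 0.02 * demo$duration_of_use + rnorm(n, 0, 0.05)
  full <- glm_fit(demo)$r_squared
  reduced <- summary(lm(value ~ age_at_implantation + duration_of_use,
                        data = demo))$r.squared
  expect_gte(full, reduced)
})

test_that("cohort_statistics assembles the full battery", {
  cohort <- generate_cohort(cohort_spec(n_nh = 8, n_ci = 8, seed = 36))
  sc <- cohort_scores(cohort_features(cohort),
                      params = fast_params(n_samples = 1e4))
  st <- cohort_statistics(sc, manifest_demographics(cohort$manifest))
  expect_named(st$anova, c("differentiability", "hit_rate"))
  expect_lt(st$anova$differentiability$p[1], 0.01)   # group effect
  expect_equal(length(st$correlations), 4)
  expect_true(all(vapply(st$correlations, function(x) x$r, numeric(1)) > 0))
  expect_named(st$glm, c("differentiability_2D", "hit_rate_2D",
                         "differentiability_3D", "hit_rate_3D"),
               ignore.order = TRUE)
  expect_true(all(vapply(st$glm, function(g) g$r_squared, numeric(1)) >= 0))
})
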