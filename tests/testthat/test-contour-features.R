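test_that("autocorrelation tracker recovers known pitches", {
  sr <- 44100
  # pure tone: every voiced frame within 1 Hz
  t <- seq(0, 0.5, by = 1 / sr)
  ct <- extract_f0(sin(2 * pi * 220 * t), sr)
  expect_gt(sum(ct$voiced), 10)
  expect_true(all(abs(ct$f0_hz[ct$voiced] - 220) < 1))

  # harmonic-rich sawtooth: median within 1% of the fundamental
  saw <- 2 * ((330 * t) %% 1) - 1
  cts <- extract_f0(saw, sr)
  expect_lt(abs(median(cts$f0_hz[cts$voiced]) - 330) / 330, 0.01)

  # aperiodic noise: mostly unvoiced
  set.seed(4)
  ctn <- extract_f0(rnorm(0.5 * sr), sr)
  expect_lt(mean(ctn$voiced), 0.2)
})

test_that("tracker input contracts hold", {
  expect_error(extract_f0(sin(1:1000), 4000), "sample_rate")
  silent <- extract_f0(numeric(8820), 44100)
  expect_equal(sum(silent$voiced), 0)
  empty <- extract_f0(numeric(0), 44100)
  expect_equal(length(empty$frame_times), 0)
})

test_that("octave errors are repaired against the running median", {
  flat <- make_contour(rep(200, 20))
  doubled <- flat; doubled$f0_hz[10] <- 400
  fixed <- correct_octave_errors(doubled)
  expect_equal(fixed$f0_hz[10], 200)
  expect_equal(fixed$n_corrected, 1L)
  expect_equal(fixed$corrected_frames, 10L)

  halved <- flat; halved$f0_hz[7] <- 100
  expect_equal(correct_octave_errors(halved)$f0_hz[7], 200)

  rising <- make_contour(seq(180, 260, length.out = 25))
  expect_equal(correct_octave_errors(rising)$f0_hz, rising$f0_hz)

  short <- make_contour(c(200, 210), voiced = c(TRUE, TRUE))
  expect_warning(out <- correct_octave_errors(short), "unchanged")
  expect_equal(out$f0_hz, short$f0_hz)
})

test_that("smooth contours pass through octave repair untouched", {
  set.seed(11)
  for (i in 1:20) {
    base <- runif(1, 120, 400)
    slope <- runif(1, -4, 4)        # semitones over the contour
    n <- sample(10:40, 1)
    f0 <- base * 2^(seq(0, slope, length.out = n) / 12)
    ct <- make_contour(f0)
    expect_equal(correct_octave_errors(ct)$f0_hz, ct$f0_hz)
  }
})

test_that("landmark sampling uses voicing edges and the later-on-tie midpoint", {
  expect_equal(sample_landmarks(make_contour(c(150, 160, 170, 180, 190))),
               c(onset = 150, mid = 170, offset = 190))
  # even count: temporal midpoint ties between frames 2 and 3, later wins
  expect_equal(sample_landmarks(make_contour(c(150, 160, 170, 180))),
               c(onset = 150, mid = 170, offset = 180))
  expect_equal(sample_landmarks(make_contour(rep(200, 10))),
               c(onset = 200, mid = 200, offset = 200))
  # unvoiced frames are skipped entirely
  ct <- make_contour(c(NA, 150, 160, 170, NA),
                     voiced = c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(sample_landmarks(ct), c(onset = 150, mid = 160, offset = 170))
  expect_warning(res <- sample_landmarks(make_contour(c(150, 160),
                                                      voiced = c(TRUE, TRUE))),
                 "unanalyzable")
  expect_null(res)
})

test_that("tone-1 reference is the equal-weight mean of token means", {
  expect_equal(compute_reference(c(200, 220))$reference_m, 210)
  expect_equal(compute_reference(250)$reference_m, 250)
  expect_equal(compute_reference(rep(300, 9))$reference_m, 300)
  expect_warning(res <- compute_reference(numeric(0)), "excluded")
  expect_null(res)
})

test_that("semitone normalization matches its definition", {
  M <- 240
  expect_equal(semitone_normalize(M, M), 0)
  expect_equal(semitone_normalize(2 * M, M), 12)
  expect_equal(semitone_normalize(M * 2^(1 / 12), M), 1)
  expect_error(semitone_normalize(-5, M), "positive")
  expect_error(semitone_normalize(100, -1), "positive")
})

test_that("normalization is invariant to global transposition", {
  cohort <- generate_cohort(cohort_spec(n_nh = 2, n_ci = 0, seed = 5))
  feat <- cohort_features(cohort)
  shifted <- feat
  for (col in c("onset_hz", "mid_hz", "offset_hz", "token_mean_hz")) {
    shifted[[col]] <- shifted[[col]] * 1.37
  }
  renorm <- normalize_features(shifted[, setdiff(names(shifted),
                                                 c("onset_st", "mid_st",
                                                   "offset_st"))])
  for (col in c("onset_st", "mid_st", "offset_st")) {
    expect_equal(renorm[[col]], feat[[col]], tolerance = 1e-12)
  }
  # subject's tone-1 landmarks average out near 0 semitones
  t1 <- feat[feat$target_tone == 1 & feat$subject_id == feat$subject_id[1], ]
  expect_lt(abs(mean(c(t1$onset_st, t1$mid_st, t1$offset_st))), 0.5)
})

test_that("pitch round trip recovers landmarks within half a semitone", {
  sr <- 44100
  paths <- list(c(200, 200, 200), c(180, 215, 260), c(300, 220, 180))
  for (p in paths) {
    wav <- synthesize_waveform(p, duration = 0.4, sample_rate = sr)
    ct <- correct_octave_errors(extract_f0(wav, sr))
    lm3 <- sample_landmarks(ct)
    expect_true(all(abs(12 * log2(lm3 / p)) < 0.5),
                info = paste(p, collapse = "-"))
  }
})

test_that("compute_features runs the full front-end over a manifest", {
  cohort <- generate_cohort(cohort_spec(n_nh = 1, n_ci = 0, seed = 8,
                                        tokens_per_tone = 3))
  man <- cohort$manifest
  man$samples <- lapply(seq_len(nrow(man)), function(i)
    synthesize_waveform(as.numeric(cohort$landmarks_hz[i, ]), 0.3, 22050))
  man$sample_rate <- rep(22050, nrow(man))
  feat <- compute_features(man)
  expect_equal(nrow(feat), nrow(man))
  expect_true(all(is.finite(feat$onset_st)))
  # extracted Hz landmarks agree with the synthesized truth to 0.5 st
  err <- abs(12 * log2(feat$onset_hz / cohort$landmarks_hz$onset_hz))
  expect_lt(max(err), 0.5)
  excl <- attr(feat, "exclusions")
  expect_equal(sum(excl$n_excluded), 0)
})
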