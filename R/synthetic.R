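# Synthetic tone-production cohorts: per-subject tone templates, contour
# flattening and token noise emulate normal-hearing-like separated
# contours and implant-like flattened, noisier contours, so the whole
# pipeline is testable without recordings.

#' Default tone landmark templates
#'
#' Canonical (onset, mid, offset) landmark targets per Mandarin tone, in
#' semitones relative to the speaker reference: tone 1 high-flat, tone 2
#' rising, tone 3 low with a mid dip, tone 4 high-falling. The values are
#' generator defaults chosen so the four tones occupy the four
#' onset-offset quadrants and the tone 2 / tone 3 pair is the closest —
#' both between the full templates and between the template time-means
#' that flattened (implant-like) productions collapse onto.
#'
#' @return 4x3 numeric matrix, rows = tones 1-4, columns
#'   `onset`, `mid`, `offset`.
#' @export
default_templates <- function() {
  matrix(c(0,    0,    0,
           -4,  -3,    1,
           -3,  -5,  -0.4,
           4,    2,  -1.5),
         nrow = 4, byrow = TRUE,
         dimnames = list(tone = 1:4, c("onset", "mid", "offset")))
}

#' Construct a synthetic subject profile
#'
#' @param subject_id identifier.
#' @param group `"NH"` or `"CI"`.
#' @param reference_f0 speaker pitch anchor in Hz.
#' @param tone_templates 4x3 template matrix (see [default_templates()]).
#' @param flattening_lambda contour flattening in \[0, 1\]: 0 keeps the
#'   template shape, 1 collapses each tone to its own time-mean (a flat
#'   contour), emulating the flattened productions of implanted children.
#' @param token_noise_sd per-landmark Gaussian noise SD in semitones.
#' @param tokens_per_tone tokens produced per tone.
#' @param demographics optional list/row with `chronological_age`,
#'   `age_at_implantation`, `duration_of_use`.
#' @return list of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, group = c("NH", "CI"),
                            reference_f0 = 260,
                            tone_templates = default_templates(),
                            flattening_lambda = 0,
                            token_noise_sd = 1,
                            tokens_per_tone = 9L,
                            demographics = NULL) {
  group <- match.arg(group)
  assert_that(flattening_lambda >= 0 && flattening_lambda <= 1,
              "flattening_lambda must lie in [0, 1]")
  assert_that(token_noise_sd >= 0, "token_noise_sd must be >= 0")
  assert_that(tokens_per_tone >= 1, "tokens_per_tone must be >= 1")
  assert_that(reference_f0 > 0, "reference_f0 must be positive")
  structure(
    list(subject_id = subject_id, group = group, reference_f0 = reference_f0,
         tone_templates = tone_templates,
         flattening_lambda = flattening_lambda,
         token_noise_sd = token_noise_sd,
         tokens_per_tone = as.integer(tokens_per_tone),
         demographics = demographics),
    class = "subject_profile")
}

#' Draw one token's landmark triple for a subject
#'
#' The landmark triple is the tone template shrunk toward its own mean by
#' the flattening factor, plus independent Gaussian noise per coordinate:
#' `(1 - lambda) * template + lambda * mean(template) + N(0, sd)`. Hz
#' values are the semitone values re-expressed against the subject's
#' reference F0.
#'
#' @param profile a [subject_profile()].
#' @param tone tone category 1-4.
#' @return list with `st` (semitone triple, pre-normalization truth) and
#'   `hz` (the same triple in Hz). Uses the current RNG stream.
#' @export
generate_token_landmarks <- function(profile, tone) {
  tpl <- profile$tone_templates[tone, ]
  lam <- profile$flattening_lambda
  st <- (1 - lam) * tpl + lam * mean(tpl) +
    stats::rnorm(3, 0, profile$token_noise_sd)
  list(st = st, hz = semitone_to_hz(st, profile$reference_f0))
}

#' The balanced monosyllable word list
#'
#' Reconstructs the 36-word elicitation list: 18 monosyllables, each
#' carrying two tones, arranged so each of the six tone contrasts has
#' exactly three syllable pairs and each tone appears on exactly nine
#' words.
#'
#' @return data frame with `word_id`, `syllable`, `target_tone`,
#'   `contrast` (36 rows).
#' @export
word_list <- function() {
  syllables <- c("bei", "bi", "chi", "chuang", "deng", "hu", "jian", "mao",
                 "mi", "qiang", "san", "shu", "tang", "tu", "wa", "wu",
                 "ye", "yu")
  contrasts <- rep(tone_contrasts(), each = 3)   # 3 syllable pairs each
  rows <- lapply(seq_along(syllables), function(i) {
    tones <- contrast_tones(contrasts[i])
    data.frame(word_id = paste0(syllables[i], tones),
               syllable = syllables[i], target_tone = tones,
               contrast = contrasts[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort simulation settings
#'
#' Ranges follow the study design the generator emulates: landmark-level
#' tone productions for two groups, the normal-hearing group with nearly
#' template-faithful contours (lambda ~ U(0, 0.1), noise 1 st) and the
#' implanted group with flattened, noisier contours
#' (lambda ~ U(0.5, 0.9), noise 2 st); speaker reference F0 uniform on
#' 220-320 Hz (child voices); implantation age and device-use duration
#' sampled uniformly with chronological age their sum.
#'
#' @param n_nh,n_ci subjects per group.
#' @param seed cohort seed; fixes the whole cohort.
#' @param tokens_per_tone tokens per tone per subject (default 9, i.e. 36
#'   words).
#' @param nh_lambda_range,ci_lambda_range flattening ranges.
#' @param nh_sigma,ci_sigma landmark noise SDs (semitones).
#' @param ref_f0_range speaker reference F0 range (Hz).
#' @param implant_age_range,duration_range CI demographic ranges (years).
#' @param nh_age_range NH chronological-age range (years).
#' @param lambda_by_duration if `TRUE`, a CI subject's flattening is tied
#'   to device-use duration (longer use, less flattening) instead of being
#'   drawn independently, inducing a positive duration-score relation.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_nh = 50L, n_ci = 50L, seed = 1L,
                        tokens_per_tone = 9L,
                        nh_lambda_range = c(0, 0.1),
                        ci_lambda_range = c(0.5, 0.9),
                        nh_sigma = 1, ci_sigma = 2,
                        ref_f0_range = c(220, 320),
                        implant_age_range = c(0.5, 6),
                        duration_range = c(0.5, 8),
                        nh_age_range = c(2.3, 12.5),
                        lambda_by_duration = FALSE) {
  assert_that(n_nh >= 0 && n_ci >= 0, "group sizes must be >= 0")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws per-subject profiles and per-token landmarks for a full cohort.
#' Every subject produces the balanced 36-word list (9 tokens per tone at
#' the default `tokens_per_tone = 9`). The result is reproducible from
#' `spec$seed` and leaves the caller's RNG state untouched.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `synthetic_cohort` with `manifest` (one row per
#'   token: `subject_id`, `group`, demographics, `word_id`, `target_tone`,
#'   `wav_path = NA`), `landmarks_hz` (per-token Hz landmark columns
#'   `onset_hz`, `mid_hz`, `offset_hz` aligned with `manifest`),
#'   `profiles` (list of `subject_profile`), and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  words <- word_list()
  with_local_seed(spec$seed, {
    profiles <- list()
    man_rows <- list()
    lm_rows <- list()
    subj_meta <- list()
    for (g in c("NH", "CI")) {
      n <- if (g == "NH") spec$n_nh else spec$n_ci
      for (k in seq_len(n)) {
        sid <- sprintf("%s%03d", g, k)
        if (g == "NH") {
          lam <- stats::runif(1, spec$nh_lambda_range[1], spec$nh_lambda_range[2])
          sig <- spec$nh_sigma
          demo <- list(chronological_age =
                         stats::runif(1, spec$nh_age_range[1], spec$nh_age_range[2]),
                       age_at_implantation = NA_real_,
                       duration_of_use = NA_real_)
        } else {
          age_impl <- stats::runif(1, spec$implant_age_range[1],
                                   spec$implant_age_range[2])
          dur <- stats::runif(1, spec$duration_range[1], spec$duration_range[2])
          lam <- if (spec$lambda_by_duration) {
            # longer device use -> less flattening, mapped onto the CI range
            span <- diff(range(spec$duration_range))
            spec$ci_lambda_range[2] - diff(spec$ci_lambda_range) *
              (dur - spec$duration_range[1]) / span
          } else {
            stats::runif(1, spec$ci_lambda_range[1], spec$ci_lambda_range[2])
          }
          sig <- spec$ci_sigma
          demo <- list(chronological_age = age_impl + dur,
                       age_at_implantation = age_impl,
                       duration_of_use = dur)
        }
        prof <- subject_profile(
          subject_id = sid, group = g,
          reference_f0 = stats::runif(1, spec$ref_f0_range[1],
                                      spec$ref_f0_range[2]),
          flattening_lambda = lam, token_noise_sd = sig,
          tokens_per_tone = spec$tokens_per_tone, demographics = demo)
        profiles[[sid]] <- prof

        reps <- ceiling(spec$tokens_per_tone / 9)
        wl <- words[rep(seq_len(nrow(words)), reps), ]
        wl <- do.call(rbind, lapply(1:4, function(tn) {
          sub <- wl[wl$target_tone == tn, ]
          sub[seq_len(spec$tokens_per_tone), ]
        }))
        for (i in seq_len(nrow(wl))) {
          tok <- generate_token_landmarks(prof, wl$target_tone[i])
          man_rows[[length(man_rows) + 1L]] <- data.frame(
            subject_id = sid, group = g,
            chronological_age = demo$chronological_age,
            age_at_implantation = demo$age_at_implantation,
            duration_of_use = demo$duration_of_use,
            word_id = wl$word_id[i], target_tone = wl$target_tone[i],
            wav_path = NA_character_, stringsAsFactors = FALSE)
          lm_rows[[length(lm_rows) + 1L]] <- data.frame(
            onset_hz = tok$hz[[1]], mid_hz = tok$hz[[2]],
            offset_hz = tok$hz[[3]])
        }
      }
    }
    structure(
      list(manifest = do.call(rbind, man_rows),
           landmarks_hz = do.call(rbind, lm_rows),
           profiles = profiles, spec = spec),
      class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(vapply(x$profiles, function(p) p$group, character(1)))
  cat(sprintf("<synthetic_cohort> %d subjects (%s), %d tokens, seed %d\n",
              length(x$profiles),
              paste(names(tab), tab, sep = ": ", collapse = ", "),
              nrow(x$manifest), x$spec$seed))
  invisible(x)
}

#' Landmark feature table of a synthetic cohort
#'
#' Fast path around audio: assembles the Hz landmark table directly from
#' the generated landmarks and applies the tone-1 semitone normalization,
#' yielding the same feature-table dialect as [compute_features()].
#'
#' @param cohort a `synthetic_cohort`.
#' @return landmark feature data frame.
#' @export
cohort_features <- function(cohort) {
  feat <- cbind(
    cohort$manifest[, c("subject_id", "group", "word_id", "target_tone")],
    cohort$landmarks_hz)
  feat$n_corrected_frames <- 0L
  normalize_features(feat)
}

#' Synthesize a harmonic waveform following a pitch path
#'
#' Builds a deterministic, harmonic-rich periodic signal (a lowpassed
#' pulse-train approximation: harmonics at 1/h amplitude up to a cutoff)
#' whose instantaneous F0 follows the piecewise-linear path through the
#' onset / mid / offset landmarks. Used to exercise the pitch front-end
#' end-to-end.
#'
#' @param landmarks_hz numeric triple `(onset, mid, offset)` in Hz, or a
#'   longer vector treated as an evenly spaced F0 path.
#' @param duration seconds (> 0).
#' @param sample_rate Hz.
#' @param max_harmonic_hz harmonic cutoff (default 4000 Hz).
#' @return numeric sample vector in \[-1, 1\].
#' @export
synthesize_waveform <- function(landmarks_hz, duration = 0.4,
                                sample_rate = 44100,
                                max_harmonic_hz = 4000) {
  assert_that(duration > 0, "duration must be positive")
  assert_that(all(landmarks_hz > 0), "F0 path must be positive")
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  knots <- seq(0, duration, length.out = length(landmarks_hz))
  f0 <- stats::approx(knots, landmarks_hz, xout = t, rule = 2)$y
  phase <- cumsum(f0) / sample_rate
  n_harm <- max(1L, floor(min(max_harmonic_hz, 0.45 * sample_rate) /
                            max(landmarks_hz)))
  x <- numeric(n)
  for (h in seq_len(n_harm)) x <- x + sin(2 * pi * h * phase) / h
  # short raised-cosine fade to avoid onset/offset clicks
  fade <- max(2L, min(round(0.005 * sample_rate), floor(n / 4)))
  env <- rep(1, n)
  ramp <- 0.5 - 0.5 * cos(pi * seq_len(fade) / fade)
  env[seq_len(fade)] <- ramp
  env[(n - fade + 1L):n] <- rev(ramp)
  x <- x * env
  x / max(abs(x))
}

#' Write a synthetic cohort to disk as a WAV corpus + manifest
#'
#' Optional audio path: synthesizes one WAV per token from its landmark
#' triple and writes the manifest CSV pointing at the files.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @param duration,sample_rate passed to [synthesize_waveform()].
#' @return manifest data frame with populated `wav_path`, invisibly.
#' @export
write_cohort_audio <- function(cohort, dir, duration = 0.4,
                               sample_rate = 44100) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  for (i in seq_len(nrow(man))) {
    lm3 <- as.numeric(cohort$landmarks_hz[i, ])
    path <- file.path(dir, sprintf("%s_%s.wav", man$subject_id[i],
                                   man$word_id[i]))
    write_wav(synthesize_waveform(lm3, duration, sample_rate),
              sample_rate, path)
    man$wav_path[i] <- path
  }
  write_manifest(man, file.path(dir, "manifest.csv"))
  invisible(man)
}
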