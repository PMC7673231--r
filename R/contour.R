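# F0 front-end: short-time autocorrelation pitch tracking, automated
# octave-error repair, landmark sampling, and per-speaker semitone
# normalization against the tone-1 mean.

#' Pitch tracker parameters
#'
#' Parameters for the autocorrelation F0 tracker and the octave-error
#' repair stage. Defaults target child voices.
#'
#' @param f0_min,f0_max F0 search range in Hz.
#' @param frame_length analysis window length in seconds; must be at least
#'   two periods of `f0_min`.
#' @param hop frame hop in seconds.
#' @param voicing_threshold minimum normalized autocorrelation peak for a
#'   frame to count as voiced (dimensionless, in (0,1)).
#' @param octave_jump_threshold deviation from the running median (in
#'   semitones) at which a frame is treated as an octave error.
#' @param median_window octave-repair running-median window, in voiced frames.
#' @param edge_trim voiced frames to drop at each voicing edge before
#'   landmark sampling (default 0).
#' @return object of class `pitch_params`.
#' @export
pitch_params <- function(f0_min = 75, f0_max = 800,
                         frame_length = 0.04, hop = 0.01,
                         voicing_threshold = 0.45,
                         octave_jump_threshold = 7,
                         median_window = 5L,
                         edge_trim = 0L) {
  assert_that(f0_min > 0 && f0_max > f0_min, "need 0 < f0_min < f0_max")
  assert_that(frame_length >= 2 / f0_min,
              "frame_length must cover at least two periods of f0_min")
  assert_that(hop > 0 && hop <= frame_length, "need 0 < hop <= frame_length")
  assert_that(voicing_threshold > 0 && voicing_threshold < 1,
              "voicing_threshold must lie in (0,1)")
  assert_that(octave_jump_threshold > 0, "octave_jump_threshold must be > 0")
  structure(
    list(f0_min = f0_min, f0_max = f0_max, frame_length = frame_length,
         hop = hop, voicing_threshold = voicing_threshold,
         octave_jump_threshold = octave_jump_threshold,
         median_window = as.integer(median_window),
         edge_trim = as.integer(edge_trim)),
    class = "pitch_params")
}

new_f0_contour <- function(frame_times, f0_hz, voiced) {
  structure(
    list(frame_times = frame_times, f0_hz = f0_hz, voiced = voiced,
         n_corrected = 0L),
    class = "f0_contour")
}

#' @export
print.f0_contour <- function(x, ...) {
  nv <- sum(x$voiced)
  cat(sprintf("<f0_contour> %d frames, %d voiced", length(x$frame_times), nv))
  if (nv > 0) {
    cat(sprintf(", F0 %.1f-%.1f Hz", min(x$f0_hz[x$voiced]), max(x$f0_hz[x$voiced])))
  }
  cat(sprintf(", %d octave-corrected\n", x$n_corrected))
  invisible(x)
}

#' Extract an F0 contour by short-time autocorrelation
#'
#' Frames the signal, computes the normalized autocorrelation of each
#' (mean-removed, Hann-windowed) frame, and reports the lag of the highest
#' peak inside the `[f0_min, f0_max]` search range as that frame's F0, with
#' parabolic interpolation around the peak. Frames whose normalized peak
#' falls below `voicing_threshold` are flagged unvoiced. Silent or empty
#' input yields a contour with zero voiced frames rather than an error.
#'
#' @param samples mono PCM samples (any numeric scale).
#' @param sample_rate sampling rate in Hz; must be at least `8 * f0_max`.
#' @param params a [pitch_params()] object.
#' @return an object of class `f0_contour` with fields `frame_times`
#'   (seconds, frame centers), `f0_hz` (NA where unvoiced) and `voiced`.
#' @export
extract_f0 <- function(samples, sample_rate, params = pitch_params()) {
  assert_that(sample_rate >= 2 * params$f0_max * 4,
              "sample_rate too low for f0_max (need >= 8*f0_max)")
  samples <- as.numeric(samples)
  win <- max(2L, round(params$frame_length * sample_rate))
  hop <- max(1L, round(params$hop * sample_rate))
  lag_min <- max(2L, floor(sample_rate / params$f0_max))
  lag_max <- ceiling(sample_rate / params$f0_min)

  if (length(samples) < win || length(samples) == 0) {
    return(new_f0_contour(numeric(0), numeric(0), logical(0)))
  }
  starts <- seq(1L, length(samples) - win + 1L, by = hop)
  times <- (starts - 1 + (win - 1) / 2) / sample_rate
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / (win + 1))
  nfft <- 2^ceiling(log2(2L * win))
  # window-autocorrelation compensation: dividing the frame's normalized
  # autocorrelation by the window's removes the taper-induced decay with
  # lag, so low-F0 voiced peaks are not pushed under the voicing threshold
  wac <- Re(stats::fft(Mod(stats::fft(c(hann, numeric(nfft - win))))^2,
                       inverse = TRUE)) / nfft
  wac <- wac / wac[1]

  f0 <- rep(NA_real_, length(starts))
  voiced <- logical(length(starts))
  for (i in seq_along(starts)) {
    fr <- samples[starts[i]:(starts[i] + win - 1L)]
    fr <- (fr - mean(fr)) * hann
    e0 <- sum(fr^2)
    if (e0 <= .Machine$double.eps) next
    # autocorrelation via FFT (Wiener-Khinchin), normalized by lag-0 energy
    ac <- Re(stats::fft(Mod(stats::fft(c(fr, numeric(nfft - win))))^2,
                        inverse = TRUE)) / nfft
    ac <- ac / ac[1] / wac
    hi <- min(lag_max, win - 1L)
    if (lag_min >= hi) next
    seg <- ac[(lag_min + 1L):(hi + 1L)]          # ac[k+1] is lag k
    # candidate peaks = local maxima above the voicing threshold; a small
    # per-octave cost prefers the shortest lag among near-equal peaks so
    # period multiples (subharmonic lags) do not win ties
    m <- length(seg)
    is_max <- c(TRUE, seg[2:(m - 1)] > seg[1:(m - 2)] &
                  seg[2:(m - 1)] >= seg[3:m], TRUE)
    cand <- which(is_max & is.finite(seg) & seg >= params$voicing_threshold)
    if (length(cand) == 0L) next
    lags <- lag_min + cand - 1L
    strength <- seg[cand] - 0.05 * log2(lags / lag_min)
    k <- cand[which.max(strength)]
    peak <- seg[k]
    lag <- lag_min + k - 1L
    # parabolic interpolation around the integer-lag peak
    if (lag > lag_min && lag < hi) {
      y1 <- ac[lag]; y2 <- ac[lag + 1L]; y3 <- ac[lag + 2L]
      denom <- y1 - 2 * y2 + y3
      delta <- if (abs(denom) > .Machine$double.eps) 0.5 * (y1 - y3) / denom else 0
      delta <- max(-0.5, min(0.5, delta))
      lag <- lag + delta
    }
    cand <- sample_rate / lag
    if (cand >= params$f0_min && cand <= params$f0_max) {
      f0[i] <- cand
      voiced[i] <- TRUE
    }
  }
  new_f0_contour(times, f0, voiced)
}

#' Repair octave (doubling/halving) errors in an F0 contour
#'
#' Autocorrelation trackers occasionally report twice or half the true F0.
#' Each voiced frame is compared against the running median of its voiced
#' neighborhood (`median_window` voiced frames); a frame deviating by at
#' least `octave_jump_threshold` semitones is replaced by the octave
#' transposition (repeated doubling/halving) closest to that median, or
#' flagged unvoiced when no transposition lands within the threshold.
#' All other frames are returned unchanged. Medians are computed from the
#' input contour in a single pass, so the repair has no order dependence.
#'
#' @param contour an `f0_contour`.
#' @param params a [pitch_params()] object.
#' @return the repaired `f0_contour`; `$n_corrected` counts altered frames
#'   and `$corrected_frames` records their indices.
#' @export
correct_octave_errors <- function(contour, params = pitch_params()) {
  vidx <- which(contour$voiced)
  if (length(vidx) < 3L) {
    warning("fewer than 3 voiced frames; contour returned unchanged")
    return(contour)
  }
  f <- contour$f0_hz[vidx]
  half <- params$median_window %/% 2L
  n <- length(f)
  med <- vapply(seq_len(n), function(k) {
    lo <- max(1L, k - half); hi <- min(n, k + half)
    stats::median(f[lo:hi])
  }, numeric(1))

  out <- contour
  corrected <- integer(0)
  for (k in seq_len(n)) {
    dev <- abs(12 * log2(f[k] / med[k]))
    if (dev < params$octave_jump_threshold) next
    shifts <- f[k] * 2^(-4:4)
    devs <- abs(12 * log2(shifts / med[k]))
    best <- which.min(devs)
    i <- vidx[k]
    if (devs[best] < params$octave_jump_threshold) {
      out$f0_hz[i] <- shifts[best]
    } else {
      out$f0_hz[i] <- NA_real_
      out$voiced[i] <- FALSE
    }
    corrected <- c(corrected, i)
  }
  out$n_corrected <- length(corrected)
  out$corrected_frames <- corrected
  out
}

#' Sample the onset / midpoint / offset landmarks of a contour
#'
#' Onset and offset are the F0 of the first and last voiced frames (after
#' optional `edge_trim`); the midpoint is the F0 of the voiced frame
#' nearest the temporal midpoint of the voiced span, taking the later
#' frame on an exact tie.
#'
#' @param contour an `f0_contour` with at least 3 voiced frames.
#' @param params a [pitch_params()] object (only `edge_trim` is used).
#' @return named numeric vector `c(onset=, mid=, offset=)` in Hz, or `NULL`
#'   (with a warning) when the contour has fewer than 3 voiced frames after
#'   trimming — the token is unanalyzable.
#' @export
sample_landmarks <- function(contour, params = pitch_params()) {
  vidx <- which(contour$voiced)
  trim <- params$edge_trim
  if (trim > 0 && length(vidx) > 2 * trim) {
    vidx <- vidx[(trim + 1L):(length(vidx) - trim)]
  }
  if (length(vidx) < 3L) {
    warning("unanalyzable token: fewer than 3 voiced frames")
    return(NULL)
  }
  tv <- contour$frame_times[vidx]
  fv <- contour$f0_hz[vidx]
  t_mid <- (tv[1] + tv[length(tv)]) / 2
  d <- abs(tv - t_mid)
  # nearest voiced frame to the temporal midpoint; later frame on a tie
  k <- max(which(d <= min(d) + 1e-12))
  c(onset = fv[1], mid = fv[k], offset = fv[length(fv)])
}

#' Compute a speaker's tone-1 reference frequency M
#'
#' The semitone normalization reference is the speaker's tone-1 mean F0:
#' each tone-1 token contributes its token-level mean voiced F0 (or, for
#' landmark-only tokens, the mean of its three Hz landmarks), and M is the
#' equal-weight mean of those token means, so long and short tokens count
#' equally.
#'
#' @param token_means numeric vector of per-token mean F0 (Hz) of the
#'   speaker's analyzable tone-1 tokens.
#' @return list with `reference_m` (Hz) and `n_tokens`, or `NULL` (with a
#'   warning) when no tone-1 token is available — the speaker is excluded
#'   from normalized analysis.
#' @export
compute_reference <- function(token_means) {
  token_means <- token_means[is.finite(token_means)]
  if (length(token_means) == 0L) {
    warning("no analyzable tone-1 token; speaker excluded from normalization")
    return(NULL)
  }
  assert_that(all(token_means > 0), "tone-1 token mean F0 must be positive")
  list(reference_m = mean(token_means), n_tokens = length(token_means))
}

#' Convert Hz landmarks to semitones re the speaker reference
#'
#' Applies `12 * log2(f0 / M)` elementwise, mapping the speaker's tone-1
#' mean to 0 semitones and one octave above it to +12.
#'
#' @param values positive F0 values in Hz (vector or landmark triple).
#' @param reference_m speaker reference M in Hz (see [compute_reference()]).
#' @return values in semitones, same shape and names as the input.
#' @export
semitone_normalize <- function(values, reference_m) {
  assert_that(is.numeric(reference_m) && length(reference_m) == 1 &&
                reference_m > 0, "reference_m must be a positive scalar")
  assert_that(all(is.finite(values)) && all(values > 0),
              "F0 values must be positive and finite")
  hz_to_semitone(values, reference_m)
}

#' Compute the landmark feature table for a token manifest
#'
#' Runs the full front-end for every token: WAV read (or in-memory
#' samples), F0 extraction, octave repair, landmark sampling, per-speaker
#' tone-1 reference, and semitone normalization. Tokens with fewer than 3
#' voiced frames are excluded and counted per speaker; speakers with no
#' analyzable tone-1 token are excluded from the normalized columns.
#'
#' @param manifest data frame with columns `subject_id`, `group`,
#'   `word_id`, `target_tone` and either `wav_path` or a list-column
#'   `samples` plus `sample_rate`.
#' @param params a [pitch_params()] object.
#' @return data frame with one row per analyzable token: identifiers plus
#'   `onset_hz`, `mid_hz`, `offset_hz`, `onset_st`, `mid_st`, `offset_st`,
#'   `n_corrected_frames`. Attribute `exclusions` is a per-subject table of
#'   excluded token counts.
#' @export
compute_features <- function(manifest, params = pitch_params()) {
  required <- c("subject_id", "group", "word_id", "target_tone")
  assert_that(all(required %in% names(manifest)),
              "manifest missing columns: ",
              paste(setdiff(required, names(manifest)), collapse = ", "))
  n <- nrow(manifest)
  onset <- mid <- offset <- tokmean <- rep(NA_real_, n)
  ncorr <- integer(n)
  for (i in seq_len(n)) {
    if (!is.null(manifest$samples)) {
      wav <- list(samples = manifest$samples[[i]],
                  sample_rate = manifest$sample_rate[[i]])
    } else {
      wav <- read_wav(manifest$wav_path[[i]])
    }
    ct <- extract_f0(wav$samples, wav$sample_rate, params)
    if (sum(ct$voiced) >= 3L) ct <- correct_octave_errors(ct, params)
    lm3 <- if (sum(ct$voiced) >= 3L) sample_landmarks(ct, params) else NULL
    if (is.null(lm3)) next
    onset[i] <- lm3[["onset"]]; mid[i] <- lm3[["mid"]]; offset[i] <- lm3[["offset"]]
    tokmean[i] <- mean(ct$f0_hz[ct$voiced])
    ncorr[i] <- ct$n_corrected
  }
  ok <- is.finite(onset)
  excl <- stats::aggregate(list(n_excluded = !ok),
                           by = list(subject_id = manifest$subject_id), FUN = sum)
  feat <- data.frame(
    subject_id = manifest$subject_id[ok],
    group = manifest$group[ok],
    word_id = manifest$word_id[ok],
    target_tone = as.integer(manifest$target_tone[ok]),
    onset_hz = onset[ok], mid_hz = mid[ok], offset_hz = offset[ok],
    n_corrected_frames = ncorr[ok],
    stringsAsFactors = FALSE)
  feat$token_mean_hz <- tokmean[ok]
  feat <- normalize_features(feat)
  attr(feat, "exclusions") <- excl
  feat
}

#' Add semitone landmark columns to a Hz feature table
#'
#' Computes each speaker's tone-1 reference M and the semitone-normalized
#' landmark columns. Speakers without analyzable tone-1 tokens get NA
#' semitone columns (and a warning).
#'
#' @param features data frame with `subject_id`, `target_tone`,
#'   `onset_hz`, `mid_hz`, `offset_hz` and optionally `token_mean_hz`.
#' @return `features` with `onset_st`, `mid_st`, `offset_st` columns;
#'   attribute `references` maps subject to M.
#' @export
normalize_features <- function(features) {
  if (is.null(features$token_mean_hz)) {
    features$token_mean_hz <-
      rowMeans(features[, c("onset_hz", "mid_hz", "offset_hz")])
  }
  features$onset_st <- features$mid_st <- features$offset_st <- NA_real_
  refs <- data.frame(subject_id = unique(features$subject_id),
                     reference_m = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(nrow(refs))) {
    rows <- features$subject_id == refs$subject_id[j]
    t1 <- rows & features$target_tone == 1L
    ref <- compute_reference(features$token_mean_hz[t1])
    if (is.null(ref)) next
    refs$reference_m[j] <- ref$reference_m
    for (col in c("onset", "mid", "offset")) {
      features[rows, paste0(col, "_st")] <-
        semitone_normalize(features[rows, paste0(col, "_hz")], ref$reference_m)
    }
  }
  attr(features, "references") <- refs
  features
}
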