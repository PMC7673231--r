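# Shared fixtures: hand-built contours, landmark clouds and tiny cohorts.

# build an f0_contour directly from voiced F0 values (uniform 10 ms hop)
make_contour <- function(f0_hz, voiced = rep(TRUE, length(f0_hz)),
                         hop = 0.01) {
  tonellipse:::new_f0_contour(
    frame_times = (seq_along(f0_hz) - 1) * hop,
    f0_hz = ifelse(voiced, f0_hz, NA_real_),
    voiced = voiced)
}

# landmark feature table for one subject from per-tone 3D centers
# centers: 4x3 matrix (onset, mid, offset) in semitones
make_features <- function(centers, n_per_tone = 9, sd = 0.5, seed = 1,
                          subject_id = "S1", group = "NH") {
  set.seed(seed)
  rows <- lapply(1:4, function(tn) {
    pts <- matrix(rnorm(3 * n_per_tone, mean = rep(centers[tn, ], each = n_per_tone),
                        sd = sd), ncol = 3)
    data.frame(subject_id = subject_id, group = group,
               word_id = sprintf("w%d_%d", tn, seq_len(n_per_tone)),
               target_tone = tn,
               onset_st = pts[, 1], mid_st = pts[, 2], offset_st = pts[, 3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# four tone centers at least `gap` semitones apart in every pair
separated_centers <- function(gap = 10) {
  matrix(c(0, 0, 0,
           gap, gap, gap,
           -gap, -gap, -gap,
           2 * gap, 0, -2 * gap),
         nrow = 4, byrow = TRUE)
}

# closed-form area of the lens of two unit circles with centers d apart
circle_lens_area <- function(d) 2 * acos(d / 2) - (d / 2) * sqrt(4 - d^2)

fast_params <- function(n_samples = 2e4, seed = 99)
  metric_params(n_samples = n_samples, seed = seed)
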