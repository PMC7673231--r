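---
title: "Assessing Mandarin tone production with tone ellipses and ellipsoids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing Mandarin tone production with tone ellipses and ellipsoids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonellipse)
```

## The problem and the model

Mandarin distinguishes word meaning with four lexical tones carried by the
fundamental frequency (F0) contour of the syllable: tone 1 high-flat,
tone 2 rising, tone 3 low with a mid dip, tone 4 high-falling. Children
who receive cochlear implants before acquiring speech get degraded pitch
information from the device, and their produced tones are typically
flattened and more variable than those of normal-hearing peers. This
package quantifies how well a speaker's produced tones separate
acoustically, from recordings of a balanced monosyllabic word list (36
words: 18 syllables x 2 tones, nine words per tone, three word pairs per
tone contrast).

Each produced token is reduced to three F0 landmarks — onset, midpoint and
offset of the voiced span — and normalized to semitones relative to the
speaker's own tone-1 mean $M$:

$$\mathrm{semitone} = 12 \log_2 (F0 / M),$$

which removes between-speaker vocal-pitch differences (tone 1, the level
tone, serves as each speaker's anchor; the transform is exactly invariant
to global pitch transposition). A speaker's tokens of one tone then form a
scatter in landmark space, summarized by a covariance region whose
principal semiaxes are two standard deviations long: an ellipse in the
onset x offset plane (the 2D method) or an ellipsoid over
onset x midpoint x offset (the 3D method, which the midpoint makes
sensitive to the tone-3 dip).

Two scores follow from the four tone regions:

* **Differentiability** of a tone contrast, from the overlap measure $A_i$
  of the two regions with measures $A_1, A_2$:
  $$D = \tfrac{1}{2}\left[(1 - A_i/A_1) + (1 - A_i/A_2)\right],$$
  0 for identical regions, 1 for disjoint ones; six contrasts plus their
  mean per speaker and method.
* **Hit rate**: cell $(i, j)$ of the 4x4 confusion matrix is the
  proportion of target tone $i$ among all tokens inside region $j$, so
  every defined column sums to 1; the diagonal mean is the speaker's
  hit-rate score. A token inside several regions counts in every such
  column — the definition implies no exclusivity.

## The pitch front-end

`extract_f0()` uses short-time normalized autocorrelation (Hann window,
window-autocorrelation compensation, parabolic peak interpolation) with a
small per-octave lag cost so period multiples do not win ties. Defaults
target child voices: search range 75-800 Hz, 40 ms frames, 10 ms hop,
voicing threshold 0.45 — all configurable through `pitch_params()`.

Doubling/halving errors, the tracker's characteristic failure, are
repaired automatically rather than by hand on a spectrogram:
`correct_octave_errors()` compares each voiced frame with the running
median of its five-frame voiced neighborhood and re-transposes frames
deviating by at least 7 semitones by whole octaves (dropping them as
unvoiced if no octave lands inside the threshold). Corrected frame
indices are kept on the contour and surfaced in the feature table, giving
an audit trail.

Choices the method leaves open, resolved here as follows:

* *Midpoint*: the voiced frame nearest the temporal midpoint of the voiced
  span, taking the later frame on an exact tie; onset/offset are the
  voicing edges with an optional `edge_trim` (default 0 frames).
* *Tone-1 reference M*: the equal-weight mean of token-level mean voiced
  F0 over the speaker's tone-1 tokens, so long and short tokens contribute
  equally (a pooled-frames variant would weight long tokens more). Tokens
  supplied as landmark triples without a contour use the mean of the three
  landmarks as the token mean.
* Tokens with fewer than three voiced frames are excluded, not imputed,
  and exclusion counts are reported per speaker; speakers with no
  analyzable tone-1 token are excluded from normalized analysis.

## Region fitting and overlap

`fit_region()` centers the region at the coordinate-wise mean and takes
principal directions from the sample-covariance eigenvectors, semiaxes
`sd_multiplier` (default 2) standard deviations long. The published
description is ambiguous between full axes and semiaxes of two SDs in the
2D case; the package adopts semiaxes = 2 SD in both dimensions for
consistency, with `sd_multiplier` covering the other reading. An
axis-aligned orientation variant is available
(`orientation = "aligned"`); covariance orientation is the default since
the regions describe the major/minor axes of a scatter. A ridge of
$10^{-6}$ st² on the covariance diagonal stabilizes nearly degenerate
scatters; regions need at least `dim + 1` points, and boundary points
count as inside.

No closed form exists for general ellipse-ellipse (or ellipsoid)
intersection that is numerically robust, so `overlap_measure()` estimates
$A_i$ by seeded uniform rejection sampling inside the smaller region
(default 2 x 10^5 draws), short-circuiting to an exact zero when bounding
spheres are disjoint, and reporting the binomial standard error. The
estimator is validated in the test suite against the analytic circle-lens
and sphere-lens formulas (agreement within 1%), and is symmetric,
rotation-stable and monotone in center distance within its standard
error. Negative Monte-Carlo artifacts of $1 - A_i/A$ (possible when $A_i$
slightly exceeds the smaller measure) are clipped at 0. Per-speaker
scoring in tests and in the acceptance script uses 2 x 10^4 draws per
overlap: the resulting standard error, about 0.2% of the smaller region
measure, is far below every effect the package tests, at a tenth of the
cost.

## Statistics

Scores are proportions; following standard practice they are
variance-stabilized with the arcsine square-root transform before
modelling. The battery on a cohort (`cohort_statistics()`):

* a two-way group x method ANOVA per measure (Type II sums of squares by
  default, appropriate for mildly unbalanced groups; Type I/III and a
  within-subject treatment of the method factor are selectable);
* a one-way repeated-measures ANOVA over tone contrasts (or tone types),
  with Greenhouse-Geisser-corrected p reported alongside the uncorrected
  one and Bonferroni paired post hocs;
* Pearson correlations between the measures and between the methods, raw
  and optionally Bonferroni-adjusted over a named family;
* for implanted speakers, an ordinary-least-squares model of the
  transformed score on age at implantation, duration of device use and
  their interaction. Chronological age is excluded by construction: it is
  the sum of the other two predictors, so including it would make the
  design collinear.

The test suite calibrates the battery rather than trusting it: the
two-way ANOVA's type-I error under a null simulation (1,000 replicates of
8 observations per cell) must land in [0.03, 0.07] at nominal 0.05, and
the demographic model must recover a planted duration effect within 20%
at n = 200.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` draws speakers with a reference F0 uniform on 220-320
Hz (child voices; no age-F0 model is attempted) and per-tone landmark
templates in semitones. A token is the template shrunk toward its own
time-mean by a flattening factor $\lambda$ plus independent Gaussian
landmark noise:
$(1-\lambda)\,\mathrm{template} + \lambda\,\overline{\mathrm{template}} + \mathcal N(0, \sigma^2)$.
Normal-hearing-like speakers use $\lambda \sim U(0, 0.1)$, $\sigma = 1$
st; implant-like speakers use $\lambda \sim U(0.5, 0.9)$, $\sigma = 2$
st, encoding the two robust qualitative findings the generator is meant
to reproduce: flattened and noisier contours. Each speaker produces the
balanced 36-word list; implanted speakers get implantation age
$U(0.5, 6)$ y and use duration $U(0.5, 8)$ y with chronological age their
sum. An option ties $\lambda$ to duration of use (longer use, less
flattening) for studying duration-score correlations.

The default templates — tone 1 $(0,0,0)$, tone 2 $(-4,-3,1)$, tone 3
$(-3,-5,-0.4)$, tone 4 $(4,2,-1.5)$ — place the four tones in the four
onset-offset quadrants and make tones 2 and 3 the closest pair **both**
as full templates and between the template time-means. The second
condition matters: heavily flattened productions collapse onto the
time-means, so it is what keeps the 2 vs 3 contrast the most confusable
in the implant-like group too, matching the canonical finding. With an
earlier candidate whose time-means put tones 1 and 4 closest, the
flattened group's weakest contrast flipped to 1 vs 4 — a useful reminder
that the generator encodes assumptions, not data.

What passing tests on this generator do **not** show: real productions
have correlated landmark errors, tone-dependent variability, duration and
amplitude cues, coarticulation, and recording noise, none of which are
modelled. The synthetic cohort validates the *machinery* (geometry,
scoring, statistics, determinism), and the waveform path
(`synthesize_waveform()`, a lowpassed pulse-train whose instantaneous F0
follows the landmark path) validates the pitch front-end end-to-end; no
quantitative claim about clinical populations follows from either.

## Numerical choices and limitations

* Monte-Carlo overlap is deterministic given its seed and never perturbs
  the caller's RNG stream; identical configuration and seed give
  byte-identical score tables.
* Problem sizes used by the checked examples: cohorts of 50 + 50 speakers
  at 9 tokens per tone; 2 x 10^4 overlap draws per contrast (2 x 10^5 for
  oracle comparisons); 1,000 null-ANOVA replicates. These keep a full run
  in well under a minute on one core while leaving every tested effect
  many standard errors wide.
* Chance level of the differentiability score is not 0 for small samples:
  two 9-point ellipses fitted to draws from the *same* distribution
  differ by sampling error, giving per-contrast scores around 0.3-0.45.
  Scores are comparable across groups at fixed token counts — the study
  design's balanced 9 tokens per tone — but not across different token
  counts.
* Columns of the hit-rate matrix are undefined (NA, excluded from
  averages) when a tone's region cannot be fitted or contains no tokens;
  contrasts are undefined when either tone has fewer than `dim + 1`
  analyzable tokens. The package reports these rather than imputing.
* The repeated-measures ANOVA's F is 0/0 when scores are exactly constant
  per speaker across conditions; the degenerate post-hoc t tests are
  reported as absent rather than an error.
* WAV support is deliberately minimal (uncompressed PCM, mono or
  downmixed stereo); anything else should be converted upstream.
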