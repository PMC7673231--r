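# tonellipse

Acoustic assessment of Mandarin lexical tone production, built for
comparing pediatric cochlear-implant (CI) users with normal-hearing (NH)
peers from recordings of a balanced monosyllabic word list — or from
precomputed F0 landmark tables, or from a fully synthetic cohort when no
recordings are available.

Each produced token is reduced to the F0 onset, midpoint and offset of
its voiced span, normalized to semitones against the speaker's own tone-1
mean `M` (`semitone = 12·log2(F0/M)`). A speaker's tokens of each tone
form a scatter summarized by a covariance region with 2-SD semiaxes: a
tone **ellipse** in onset × offset space (2D method) or a tone
**ellipsoid** over onset × midpoint × offset (3D method). Two scores
follow:

- **Differentiability** of a tone contrast, from the region overlap `Ai`
  and region measures `A1`, `A2`:
  `D = [(1 − Ai/A1) + (1 − Ai/A2)] / 2` — 0 identical, 1 disjoint; six
  contrasts (1v2 … 3v4) plus their mean.
- **Hit rate**: confusion-matrix cell `(i, j)` is the proportion of
  target tone `i` among all tokens inside tone region `j` (columns sum
  to 1); the diagonal mean is the speaker's score.

Around the scores sit an autocorrelation pitch tracker with automated
octave-error repair, a cohort statistics battery (arcsine transform,
factorial and repeated-measures ANOVA, Pearson correlations, a
demographic linear model for implanted speakers), figure rendering, a
synthetic cohort generator, and a `tonellipse` command-line wrapper
(installed under `exec/`).

## Worked example

Score a synthetic cohort of 20 NH-like and 20 CI-like speakers (9 tokens
per tone each, landmark-level fast path):

```r
library(tonellipse)

cohort   <- generate_cohort(cohort_spec(n_nh = 20, n_ci = 20, seed = 42))
features <- cohort_features(cohort)
scores   <- cohort_scores(features,
                          params = metric_params(n_samples = 2e4, seed = 42))
print(scores)
#> <cohort_scores> 40 subjects, methods: 2D, 3D
#>  group method           measure      mean         sd
#>     CI     2D differentiability 0.5888245 0.08409355
#>     NH     2D differentiability 0.8988976 0.03516594
#>     CI     3D differentiability 0.7931438 0.06059587
#>     NH     3D differentiability 0.9857003 0.01664563
#>     CI     2D          hit_rate 0.4482688 0.06312017
#>     NH     2D          hit_rate 0.7979454 0.06867637
#>     CI     3D          hit_rate 0.5889420 0.07288025
#>     NH     3D          hit_rate 0.9550081 0.05234038
```

The NH-like group separates its tones far better than the CI-like group,
and the 3D method scores above the 2D method for both — the midpoint adds
information whenever contours are not flat. The statistical battery on
the same scores:

```r
stats <- cohort_statistics(scores, manifest_demographics(cohort$manifest))
print(stats)
#> Two-way ANOVA (differentiability):
#>        effect            F df1 df2            p
#>         group 4.912404e+02   1  76 6.580349e-35
#>        method 1.781273e+02   1  76 1.299825e-21
#>  group:method 6.685760e-05   1  76 9.934975e-01
#> ...
#> Correlations:
#>   diff_vs_hit_2d  r = 0.982, p = 6.03e-29 (n = 40)
#>   diff_vs_hit_3d  r = 0.971, p = 3.76e-25 (n = 40)
#>   diff_2d_vs_3d   r = 0.935, p = 1.1e-18 (n = 40)
#>   hit_2d_vs_3d    r = 0.931, p = 2.95e-18 (n = 40)
```

Per-speaker detail for one implant-like speaker — the 2v3 contrast is the
weakest, and its confusion matrix shows tones 2 and 3 absorbed into each
other's regions:

```r
subject_differentiability(features[features$subject_id == "CI001", ], "2D",
                          metric_params(n_samples = 2e4, seed = 42))
#> <tone_differentiability> subject CI001, 2D method
#>   1v2   1v3   1v4   2v3   2v4   3v4
#> 0.454 0.425 0.511 0.211 0.761 0.839
#> average: 0.534
```

From audio instead: write a manifest CSV (`subject_id, group,
chronological_age, age_at_implantation, duration_of_use, word_id,
target_tone, wav_path`) and run

```r
run_pipeline(pipeline_config(manifest_path = "manifest.csv",
                             out_dir = "out"))
```

which extracts F0 (`extract_f0()`), repairs octave errors, samples and
normalizes landmarks, writes `features.csv`, the score tables,
`stats.json` and the figure panels. The same stages are available from a
shell via `exec/tonellipse simulate|features|metrics|stats|figures|run`.

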