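# ssrsa

Spatiotemporal searchlight representational similarity analysis (ssRSA) in
R: relate time-varying **machine states** of a speech recogniser to
**brain states** measured in electrophysiological source space, without
assuming any correspondence between the two systems' internal formats.

## Who this is for

Researchers with (a) frame-level phonetic log-likelihood streams from an
automatic speech recogniser — per word, per 10 ms frame, one column per
triphone (left context, centre phone, right context) — and (b)
source-reconstructed EEG/MEG epochs (vertex × 1 ms samples per subject and
word), who want to map where and when cortical response geometry matches
the geometry of the recogniser's incremental phonetic analysis, expressed
in terms of articulatory features.

## The method

Both data streams are converted into the same currency: **representational
dissimilarity matrices** (RDMs), symmetric word-by-word matrices of
correlation distances (1 − Pearson r, in [0, 2]), computed in sliding 60 ms
windows at 10 ms steps (*dynamic RDMs*).

- **Model side**: for each phone φ, triphone log-likelihood columns sharing
  the centre phone φ are concatenated over the six frames of each window;
  correlation distances between words give φ's model RDM per window.
- **Brain side**: a searchlight patch (radius 20 mm) is centred on every
  masked vertex; within each window the patch samples form one response
  vector per word. Per-subject RDMs are averaged across subjects. A fixed
  100 ms lag aligns each speech window with the neural response to it.
- **Fit**: at each vertex and window, the data RDM *D* is regressed on all
  phone model RDMs simultaneously,

  *D* = β₁M₁ + β₍ₐ₎M₍ₐ₎ + … + β₍z₎M₍z₎ + *E*,

  with M₁ a constant predictor and *E* minimised in sum-squared error.
  Collinear (competitor-phone) designs are solved minimum-norm.
- **Features**: phone coefficients are aggregated into articulatory-feature
  fits, fit_f = Σ_φ χ_f(φ)·β_φ, using a binary phone-by-feature matrix
  (a 40-phone British English matrix ships as editable CSV).
- **Inference**: condition labels of the data RDMs are randomly permuted
  and the whole fit recomputed; per-feature null distributions pooled over
  vertices and permutations give quantile thresholds θ_f, and a vertex
  survives for feature f when fit_f > θ_f. Epoch-level maps average β_φ
  over windows before fitting features.

A second-order module audits the feature system against the model space
itself (Spearman model-by-model similarity, Davies–Bouldin indices,
distance-based η², non-metric MDS), and a synthetic-data module generates
all three inputs with known implanted ground truth so the full pipeline can
be validated end to end.

## Worked example

Generate a small synthetic study (12 words over an 8-phone inventory, 2
subjects, a 4×4×2 source grid) with the phone model [m] implanted at vertex
`v0001`, then run the full analysis:

```r
library(ssrsa)

inv <- c("p", "t", "k", "s", "m", "n", "aa", "ih")
set.seed(100)
strings <- lapply(1:12, function(i) sample(inv, 3, replace = TRUE))
names(strings) <- sprintf("w%02d", 1:12)
spec <- synthetic_spec(phone_strings = strings, inventory = inv,
                       epoch_ms = 150, grid_dims = c(4, 4, 2),
                       grid_spacing_mm = 15, n_subjects = 2,
                       implants = list(list(centre = "v0001", source = "m",
                                            amplitude = 1)),
                       seed = 100)
cfg <- searchlight_config(radius_mm = 20, window_ms = 60, step_ms = 10,
                          lag_ms = 100, epoch_ms = 150)

streams <- gen_likelihood_streams(spec)$streams
model_set <- build_model_set(streams, NULL, config_window_onsets(cfg), 60)
model_set
#> phone model set: 8 phones x 9 windows = 72 model RDM frames (12 conditions)

src <- gen_source_epochs(spec, model_set, cfg)
data_drdms <- build_data_drdms(src$epochs, src$mesh, cfg)
fit <- fit_drdms(data_drdms, model_set)
round(sort(epoch_average_betas(fit)$betas[, "v0001"], decreasing = TRUE), 3)
#>      m      s      n     ih      p      t     aa      k
#>  0.552  0.211  0.061  0.004  0.002 -0.021 -0.047 -0.068
```

The implanted phone [m] has by far the largest epoch-averaged coefficient
at the implant centre (the smaller positive [s] coefficient is competitor
spillover between correlated model RDMs — the reason inference is done on
features, not phones). Thresholding feature maps against a permutation
null:

```r
ind <- rbind(stop  = c(p=1, t=1, k=1, s=0, m=0, n=0, aa=0, ih=0),
             fric  = c(p=0, t=0, k=0, s=1, m=0, n=0, aa=0, ih=0),
             nasal = c(p=0, t=0, k=0, s=0, m=1, n=1, aa=0, ih=0),
             vowel = c(p=0, t=0, k=0, s=0, m=0, n=0, aa=1, ih=1))
fm <- feature_matrix(ind, c("manner", "manner", "manner", "broad"))
nulls <- build_null(data_drdms, model_set, fm, n_perm = 100, seed = 101)
maps <- threshold_feature_maps(feature_fit_map(fit, fm), nulls, q = 0.95)
maps$summary
#>   feature  threshold quantile n_surviving best_quantile
#> 1    stop 0.18323463     0.95           0            NA
#> 2    fric 0.06605074     0.95           9         0.990
#> 3   nasal 0.10092982     0.95           9         0.999
#> 4   vowel 0.11502075     0.95           0            NA
```

The nasal feature (carrying the implanted [m]) survives at the implant
centre and its spatial neighbourhood even at the most conservative standard
quantile, with the fit decaying away from `v0001`; features unrelated to
the implant show no surviving vertices. `run_pipeline()` wraps these stages
behind one validated config and persists hash-stamped CSV/TSV outputs.

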