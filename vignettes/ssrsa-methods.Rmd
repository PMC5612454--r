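---
title: "Dynamic searchlight RSA: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic searchlight RSA: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrsa)
```

## The problem

When a listener hears a spoken word, superior temporal cortex builds up an
incremental phonetic interpretation of the unfolding acoustic input. A speech
recogniser solves the same problem with explicit internal states: at every
10 ms frame it assigns log likelihoods to context-dependent phone units
(*triphones*: a centre phone with its left and right neighbours). `ssrsa`
implements a representational similarity analysis (RSA) that asks where and
when the geometry of these machine states matches the geometry of
source-reconstructed electrophysiological brain states, without assuming any
correspondence between the two systems' internal formats.

The common currency is the representational dissimilarity matrix (RDM): a
symmetric condition-by-condition matrix of response dissimilarities with a
zero diagonal. Every dissimilarity in the package is the correlation
distance, $1 - r$ with $r$ the Pearson correlation between two response
vectors, bounded in $[0, 2]$. A *dynamic* RDM (dRDM) is a sequence of RDM
frames indexed by sliding-window position, which is how both model and data
streams are represented.

## Model dRDMs from likelihood streams

For each phone $\phi$, the triphone columns whose centre phone is $\phi$ are
grouped, and each condition's log likelihoods over those columns are
concatenated across the six 10 ms frames of a 60 ms sliding window. The
correlation distances between these per-condition vectors form $\phi$'s
model RDM at that window position; stepping the window by 10 ms through the
epoch yields the model dRDM. Log likelihoods enter untransformed — no
exponentiation and no per-column normalisation — since the correlation
distance is invariant to affine rescaling of whole vectors and the raw
values are what the recogniser's states contain.

Two conventions are fixed once and used everywhere, because only
consistency matters:

* upper-triangle vectorization is row-major, diagonal excluded:
  $(1,2), (1,3), \dots, (1,n), (2,3), \dots$;
* window vectors are concatenated frame-major (all selected columns of
  frame 1, then frame 2, ...), and searchlight response vectors
  vertex-major (all window samples of vertex 1, then vertex 2, ...).
  Correlation distance is invariant to both choices.

Phones that never occur as a triphone centre in the stimulus set get no
model and are dropped with a warning rather than an error: an analysis of a
finite lexicon always retains only the phones common enough to model.

A degenerate (zero-variance) response vector anywhere — a constant
likelihood vector, a flat source trace — raises an error naming the
offending condition rather than propagating `NaN`. Silent `NaN`s would
corrupt the downstream GLM invisibly; a loud failure is cheaper.

## Window geometry and the 21-position convention

With a 270 ms epoch, 60 ms windows and 10 ms steps, the onset-aligned
enumeration $0, 10, \dots, 210$ contains 22 positions, but the standard
configuration this package mirrors indexes 21. `window_positions()`
therefore has two modes: `"all"` (every window that fits) and the
default `"standard"` (the same minus the final onset when more than one
position exists), which reproduces the 21-position count. The discrepancy
is a windowing-convention ambiguity — onset-aligned versus centre-aligned
enumeration — and the mode switch makes either available.

## Data dRDMs: the spatiotemporal searchlight

Source epochs are per-subject, per-condition vertex-by-time matrices at
1 ms sampling. A searchlight patch of radius 20 mm — 3D Euclidean distance
between vertex coordinates, not geodesic distance along the cortical
sheet — is centred on every masked vertex. Within each 60 ms window the
patch samples form one response vector per condition; the per-subject RDMs
are computed independently and then averaged entrywise across subjects,
giving one data RDM per (vertex, window).

A fixed 100 ms processing lag offsets the neural window relative to the
speech-input window it models: model window $[t, t+60)$ is compared with
data window $[t + 100, t + 160)$, so a 0–270 ms model epoch reads neural
data from 100–370 ms after acoustic onset. The lag is applied when data
dRDMs are built, so model and data streams share window indices from there
on.

## The multi-model GLM and feature aggregation

At each vertex and window, the data RDM $D$ is regressed simultaneously on
all phone model RDMs (upper-triangle vectors) with an explicit constant
predictor:

$$D = \beta_1 M_1 + \beta_{[a]} M_{[a]} + \cdots + \beta_{[z]} M_{[z]} + E,$$

minimising the summed squared error $E$. Predictors enter raw: the model is
stated on the RDMs themselves, and the feature stage sums raw coefficients,
so z-scoring predictors would silently reweight features. Acoustically
similar phones produce nearly collinear model RDMs; rank-deficient designs
are solved by the minimum-norm (SVD pseudoinverse) solution with a warning
and a condition-number report, never by dropping predictors — the remedy
for coefficient trade-off between competitor phones is the next stage, not
predictor selection.

Phone coefficients are converted to articulatory-feature fits by the
indicator sum

$$\mathrm{fit}_f = \sum_\phi \chi_f(\phi)\, \beta_\phi,$$

where $\chi_f(\phi) = 1$ when phone $\phi$ carries feature $f$. The
intercept is never included, and no normalisation by carrier count is
applied: the statistic is the plain indicator sum, and the unequal carrier
counts are compensated by giving each feature its own permutation null
rather than by rescaling the statistic. For whole-epoch summaries the
$\beta_\phi$ are averaged across windows *before* computing feature fits,
for observed maps and null distributions alike.

The packaged phone–feature matrix (40 British English phones, 24 binary
features in six category groups: broad class, consonant place, consonant
manner, vowel frontness, closeness, roundedness) is an editable CSV shipped
as configuration, not code — analyses with a different inventory or feature
system should load their own file.

## Permutation statistics

Under the null hypothesis that condition labels carry no phonetic
information, the labels of a data RDM are exchangeable: one random
permutation is applied to the rows and columns of every vertex's data RDMs
(models untouched), the GLM refitted, coefficients epoch-averaged and
feature fits recomputed. Samples are pooled over vertices and iterations
into one null per feature, and the empirical $q$-quantile (type-1,
inverted-CDF order statistic — conservative on large pools) gives the
feature threshold $\theta_f$. Default sizing aims at
$n_{\mathrm{perm}} \times n_{\mathrm{vertices}} \ge 10{,}000$ pooled
samples; smaller pools warn.

One permutation is shared by all vertices within an iteration (the default;
independent per-vertex permutations are available), keeping the spatial
structure of the null exchangeable with the observed map. No
multiple-comparison correction beyond the pooled-null quantile is applied —
a documented limitation; the per-feature summary instead reports the most
conservative standard quantile (0.95 / 0.99 / 0.999) at which any vertex
still survives.

## Second-order model-space diagnostics

Before any brain data enter, the feature system itself can be audited
against the model space. The model-by-model similarity matrix holds
Spearman rank correlations between the vectorized RDM frames of each pair
of phone models. For every feature that splits the modelled phones with at
least two members per class, two diagnostics are computed per window and
summarised by mean and standard deviation over the epoch:

* **Davies–Bouldin index** of the 2-cluster split,
  $(s_1 + s_2)/d_{12}$ — lower is better-separated. Points are the
  *rank-transformed* vectorized frames under Euclidean geometry, so the
  point space matches the Spearman geometry of the similarity matrix (the
  raw-vector alternative is available). Index values are only comparable
  between labellings of the same point set.
* **Distance-based $\eta^2$**, the share of pairwise squared-dissimilarity
  variance explained by the split, computed on $1 - \rho$ distances and
  judged against the conventional 0.01 / 0.06 / 0.14 benchmarks. With $N$
  models the estimator has a null bias of roughly $1/(N-1)$, so benchmark
  comparisons need $N$ comfortably above 20 — one reason the diagnostics
  are computed over the full modelled inventory.

`mds_embed()` provides a non-metric (stress-minimising) MDS picture of the
model space from the $1-\rho$ distances, with a classical-scaling
initialisation plus random restarts at fixed seeds. Non-metric stress only
constrains ranks, so among (near-)equal-stress solutions the one whose
embedded distances correlate best with the input dissimilarities is
returned, and that distance–dissimilarity correlation is reported as a
faithfulness diagnostic — it is never a test statistic.

## The synthetic-data generator

The generator emulates all three pipeline inputs with known ground truth:

* **Likelihood streams.** Each condition's phone string is laid over the
  epoch in equal-duration segments; the active (previous, current, next)
  triphone column gets a high log-likelihood baseline (default 0), all
  others a low baseline (default −10), plus i.i.d. Gaussian noise (default
  sd 1). String-edge phones reuse themselves as boundary context.
* **Mesh.** A regular 3D millimetre grid — Euclidean patch geometry is all
  the searchlight uses, so no cortical sheet is simulated; real meshes load
  through the TSV reader.
* **Source epochs.** Gaussian background noise (default sd 1) everywhere;
  at each implant patch and each window, responses realising the chosen
  model RDM's correlation geometry are added at the lagged window samples,
  scaled by the implant amplitude (default 1, i.e. unit signal on unit
  noise). Geometry injection works by converting the target RDM to
  similarities $S = 1 - d$, projecting $S$ onto the positive semidefinite
  cone by eigenvalue clipping (adequate for targets near valid correlation
  structure; a nearest-correlation iteration was not needed), factoring
  $S = LL^{\top}$ and drawing $X = LG$ with Gaussian $G$. Implant
  structure is shared across subjects; noise is independent per subject.
  Overlapping implant patches are rejected as ambiguous ground truth.

Full-scale defaults mirror the target study (400 conditions, 16 subjects,
270 ms epochs, 100 ms lag); every generator is a pure function of its spec
including the mandatory seed.

What the generator does *not* emulate: acoustic realism (formants,
coarticulation), sensor-space forward models, source-reconstruction
artefacts, spatially correlated physiological noise, or inter-subject
spatial misalignment. Passing validation on this synthetic family therefore
demonstrates that the pipeline's machinery is correct and calibrated under
its own assumptions — not that real cortical effects of any particular size
will be detected.

## Validation experiments and their sizes

Two packaged study designs make the statistical claims reproducible with
one call each; sizes were chosen to keep Monte-Carlo error well inside the
margins being checked while remaining desk-scale.

* `null_calibration_run()`: pure-noise epochs, 24 conditions, 2 subjects,
  a 6 × 6 × 4 grid at 15 mm spacing (144 masked vertices; at this spacing
  a 20 mm patch holds 7 vertices, so patches overlap only their immediate
  neighbours), 100 permutations (14,400 pooled null samples per feature),
  the packaged 40-phone matrix. A single run's survival fraction at
  $q = 0.95$ has a standard deviation near 0.01 — dominated by the spatial
  and between-feature correlation of the survival indicators, which is why
  it does not shrink much with mesh size — so calibration is assessed as
  the mean over 10 independently seeded runs (standard error ≈ 0.003
  against the nominal 0.05).
* `implant_recovery_run()`: one phone model implanted at a corner vertex
  of a 5 × 5 × 3 grid at 15 mm spacing, amplitude 1 on unit noise, 16
  conditions, 2 subjects, an 8-phone inventory with a compact 5-feature
  matrix, 140 permutations. Scored over 20 seeded runs: whether the
  implanted phone has the top epoch-averaged coefficient at the centre,
  whether the centre survives the $q=0.95$ threshold for the implanted
  phone's feature, and the survival rate among vertices at least 60 mm
  (three patch radii) from the implant, which should stay at the nominal
  false-positive level.

The test suite runs every stage at these reduced scales; structural counts
of the full-scale configuration (79,800-length vectors at 400 conditions,
840 model frames from 40 phones × 21 windows, 26,754 data RDMs from a
1,274-vertex mask) are verified exactly since they are size arithmetic, not
simulation.

## Numerical choices and degenerate inputs

* Correlation distances are clipped into $[0, 2]$ against floating-point
  overshoot; RDM symmetry is enforced by averaging with the transpose.
* Zero-variance vectors, empty feature rows, constant data RDMs and
  singleton Davies–Bouldin classes raise classed errors identifying the
  offender; the all-coincident $\eta^2$ case (0/0) is defined as 0 with a
  warning.
* The per-window GLM across vertices is computed from one SVD
  pseudoinverse applied to all vertices jointly; this is numerically
  identical to looped single fits (tested) and is what makes
  permutation nulls cheap — a permutation is a row reindexing of the
  vectorized data, so each null iteration is one matrix product per
  window.
* The quantile estimator for $\theta_f$ is type 1 (inverted CDF): on
  pooled samples it never interpolates below an observed order statistic.
* All seeds are explicit; helper `with_seed()` semantics save and restore
  the global RNG state, so package functions never perturb a caller's
  stream.

## Known limitations

* Euclidean, not geodesic, patch distances: patches can bridge a sulcus on
  a real cortical mesh.
* No multiple-comparison correction across vertices beyond the pooled-null
  quantile; maps should be read as descriptive with per-feature control.
* Eq-style raw-coefficient aggregation means features with many carriers
  have larger-variance fits; the per-feature nulls absorb this for
  thresholding, but fits are not comparable *between* features.
* Memory: a full-scale run (400 conditions, 1,274 vertices, 21 windows)
  holds on the order of $10^3$ data RDM frames of $400 \times 400$ in
  memory; the per-vertex map is built lazily enough for desk-scale work
  but a production run at full scale benefits from chunking over vertices.
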