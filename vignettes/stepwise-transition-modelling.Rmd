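---
title: "Stepwise OPLS-DA modelling of developmental proteomics gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise OPLS-DA modelling of developmental proteomics gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Wood formation proceeds through a spatial sequence of developmental zones:
mature phloem (P) outside, the dividing cambium (C), the cell expansion
zone (E), and maturing xylem, which this package follows through four
segments X1–X4 (early xylem near the cambium through secondary-wall
deposition to the cell-death zone). Thin tangential cryosections cut
parallel to the cambial surface give tissue-specific radial resolution, and
label-free LC-MS of the (partly pooled) section extracts yields a protein
× sample intensity matrix whose samples are ordered along the gradient.
Because the spatial order mirrors developmental time, modelling consecutive
zone pairs amounts to modelling developmental transitions.

`oplstep` implements that analysis end to end: top-3 protein
quantification, column-centered PCA for the global overview, one local
OPLS-DA model per consecutive zone pair, a per-transition effect profile
(`p_dist`), a meta-PCA comparing all transitions, and jack-knife
confidence intervals that classify every protein × transition cell as
up / down / no change.

## Quantification model

Protein abundance in a sample is the sum of its three most intense
peptides (the "top-3"/Hi3 estimate, which scales linearly with protein
amount). With fewer than three peptides all available peptides are summed
— discarding such proteins would bias the matrix against low-coverage
identifications, while the partial sum remains proportional to abundance.
A protein is considered identified only if at least one of its peptides is
sequence-unique; all peptides of identified proteins (shared ones
included) enter the top-3 ranking. Samples are normalised by their tissue
amount. Mass and volume differ only by a density factor, so the container
is agnostic about the unit: only the ratio between samples matters after
normalisation. Sections pooled into one analytical sample are aggregated
by thickness-weighted mean, which preserves concentration semantics (a
pooled extract is a mixture, not a stack) and makes the subsequent
per-tissue normalisation consistent; the pooled tissue amount is the sum
over member sections. Proteins undetected in a sample are recorded as
zero intensity with a `detected` flag, because centering and
latent-variable fits need complete matrices.

## Multivariate model

All matrices are column-centered with no scaling before modelling, so
high-abundance proteins dominate — intentional for intensity data, where
scaling would inflate noise from low-abundance proteins.

PCA is computed by singular value decomposition of the centered matrix;
the per-component explained variation is `R2X_a` = sigma_a^2 / SS(Xc),
and `R² = 1 − SS(E)/SS(X)` in general. Component signs are fixed by
making the largest-magnitude loading entry positive, so results are
deterministic across platforms.

OPLS splits the centered X into a single predictive component correlated
with the response y and `n_orth` orthogonal components:

    X = 1 x̄ + t_p p_p' + T_o P_o' + E
    y = ȳ  + t_p q_p + f

Orthogonal components are extracted iteratively (weight from the part of
the predictive loading not collinear with the predictive weight) and
deflated before the final predictive fit. OPLS-DA codes a two-class label
as {0, 1}, centers it, and orients the model so the mean predictive score
of the second ("to") class is positive — any affine recoding of the
response changes scores only by a positive scalar.

One convention matters downstream: the predictive loading `p_p` is stored
with unit Euclidean norm and all magnitude lives in `t_p`. The transition
effect profile is then

    d = ||t_p||,   p_dist = p_p * d

so `||p_dist|| = d` holds exactly, and `p_dist` carries both the
direction (which proteins change, with sign: positive = higher in the
"to" zone) and the magnitude of the transition. Each local model is fit
on the samples of its two zones only, with local centering — OPLS-DA is
defined per sub-model, and local centering keeps each transition's
loading free of the other zones' means. Samples from all replicate trees
enter each local model jointly. A PCA on the stacked `p_dist` rows
(column-centered, no scaling, at most `n_transitions − 1` components)
compares the transitions: antagonistic regimes — most upregulated
proteins becoming downregulated — appear with opposite-signed scores on
the separating component.

Note that `d` grows with the number of samples (for a fixed class
separation, `||t_p||` scales as sqrt(n)), so `d` values are comparable
between transitions of similar size, not across datasets.

## Model validation

Seven-fold cross-validation (the chemometrics convention), stratified by
class for discriminant models, yields `Q² = 1 − PRESS/SS`. Significance
is summarised by a CV-ANOVA style F ratio,
`F = ((SS − PRESS)/A) / (PRESS/(n − 1 − A))` with `A = 1 + n_orth`
components and p from `F(A, n − 1 − A)`; F is clamped at zero when PRESS
exceeds SS. This is a pragmatic screen, not an exact test — its value is
flagging transitions whose separation does not survive cross-validation.

A small-sample caveat: with roughly 10–20 samples per class, pure-noise
OPLS-DA shows `Q² > 0.05` in about 7–20 % of simulations (the usual
optimism of discriminant latent-variable models at small n); the tail
shrinks below 5 % from about 25 samples per class. Mean null Q² is
strongly negative at all sizes. Use the CV-ANOVA p, not a fixed Q²
threshold, as the significance gate for small zones.

## Jack-knife differential calls

Per-protein significance is assessed on the `p_dist` entries (loading ×
magnitude; the choice of scale does not affect which intervals exclude
zero within one transition, since `d` is a common factor). The transition
model is refit on each leave-one-segment-out subset, with segments equal
to the seven stratified cross-validation folds (leave-one-sample-out is
available via `segments = n`). Two corrections precede the variance
computation:

* **sign alignment** — each sub-model profile is flipped, if needed, to
  the full-model orientation, otherwise the sign indeterminacy of
  latent-variable loadings masquerades as variance;
* **scale alignment** — each sub-model profile is multiplied by
  `sqrt(n/n_g)`, because `d` scales as sqrt(n) and leave-out estimates
  would otherwise be systematically smaller, inflating the variance.

The classic jack-knife variance `(G−1)/G * sum_g (theta_g − theta_bar)²`
then gives `CI = estimate ± t(1−alpha/2, G−1) * SE`. A protein is "up"
when its interval is entirely positive, "down" when entirely negative,
"none" otherwise. On pure-noise simulations (500 proteins, 8 + 8
samples) the fraction called significant at alpha = 0.05 averages
0.046–0.049 over 100 replicates — the nominal level. No multiple-testing
correction is applied by default, matching the plain per-protein alpha
convention of jack-knife loading intervals; a Benjamini–Hochberg option
(`differential_analysis(bh = TRUE)`) is available but off.

The call grid is exported as a trend table coding down/none/up as
−1/0/+1 (red/black/green in the conventional display), with rows ordered
by agglomerative hierarchical clustering (Euclidean distance, average
linkage — common defaults for permutation-matrix displays; the choice
only affects row order, never the calls).

## The synthetic design

The generator emulates the sampling design of a four-tree tangential
cryosection study so every stage is exercisable without any download: 110,
122, 126 and 124 sections of 20 µm (≈0.5 mg) from trees 1–4, pooled to
27, 28, 28 and 28 samples. Phloem and cambium sections are analysed
singly (6 + 6 per tree), the expansion zone in pools of three, and the
xylem in twelve larger pools per tree, three per X segment; the exact
published pooling map is not reproduced in text form anywhere, so this
layout is the package's documented default consistent with the stated
pool counts.

Intensities are log-normal (multiplicative noise is the norm for
label-free LC-MS): per-protein base abundance `lognormal(log 1e5, 1)`,
a zone effect from one of nine archetype profiles (phloem marker,
phloem/cambium, ubiquitous, cambial, expansion, transient-X1,
early-xylem, mid/late-xylem, late-xylem — covering the profile classes
seen in wood gradients, including a laccase-like transient and a centered
monotone ramp through X3 for late-xylem proteins), a per-protein ×
per-tree offset (SD 0.08, reflecting consistent replicate trees), a
pool-level biological deviation (SD `noise_sd` = 0.25, ≈25 % CV), and a
small independent per-section term (SD 0.1). The biological term is
shared by the sections of a pool — adjacent sections are spatially
correlated — which also means the pooled within-zone SD matches
`noise_sd` regardless of pool size. Archetype steps between consecutive
zones are 0 or ±1 unit of `effect_size × noise_sd` (default effect size
3, i.e. planted shifts of 3 within-zone SDs), so every planted change has
one known magnitude; the mixing proportions put a planted change in
20–39 % of protein × transition cells depending on the transition.
Peptide tables decompose each pooled protein amount into 3–7 peptides
with log-normal ionisation efficiencies (sdlog 0.7) and 5 % multiplicative
noise, so top-3 recovery is testable; the first peptide of each protein
is always sequence-unique.

What the generator does *not* emulate: chromatographic drift, censoring
of low-abundance peptides (missingness), saturation, shared-peptide
ambiguity across protein groups, and real biological covariance between
proteins. Passing tests therefore demonstrate correctness of the
algorithms under the stated noise model, not robustness to every artefact
of real LC-MS data.

## Numerical choices and scale

Tolerances: the OPLS reconstruction identity holds to ~1e-15 relative;
rank deficiencies during orthogonal extraction are detected at 1e-10 of
the loading norm and reported with the achievable rank; degenerate
centered matrices raise "no variance". Ties in the top-3 ranking are
resolved by sort order, which cannot change the sum. Fold assignment is
round-robin after a seeded shuffle, stratified by class.

Default problem sizes used in the test-suite simulations — 500 proteins,
the 111-pool design, 100 null replicates, 20 recovery seeds — keep each
Monte-Carlo estimate stable (type-I rate SE ≈ 0.001; recovery cosines
0.96–0.99 per transition) while a full suite run stays under a minute.
The per-dataset cosine between an estimated `p_dist` and the expected
planted effect is bounded by the data's own sampling noise (a brute-force
two-zone mean-difference oracle attains the same value), which is why
recovery is judged on per-transition Monte-Carlo averages.

## Known limitations

* Single predictive component only (the two-class/single-response OPLS
  form); multi-response O2PLS and kernel variants are out of scope.
* `d` confounds effect magnitude with sample size across designs of
  different n (see above).
* The CV-ANOVA F approximation treats fold predictions as independent;
  with very small zones, its p-values are approximate.
* Jack-knife intervals assume the segment estimates are roughly
  exchangeable; with `segments = 7` and very unbalanced zones the
  stratification keeps segments comparable, but two samples per class is
  a hard lower bound for every leave-out fit.
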