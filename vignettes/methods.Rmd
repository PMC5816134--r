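---
title: "Methods: semantic spaces, acoustic alignment and triad embedding for the human vocal repertoire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semantic spaces, acoustic alignment and triad embedding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocalspace)
```

# The scientific problem

Human non-linguistic vocalizations — laughs, cries, screams, moans, sighs,
roars — can be described in two complementary vocabularies: by their
acoustic form (the *call type*) and by the emotion they are taken to
express. `vocalspace` implements a complete analysis pipeline for studying
how listeners categorise such sounds:

1. **Semantic spaces from naming data.** When many listeners attach verbal
   labels to the same stimuli, two sounds that often receive the same name
   are perceptually close. The package turns naming trials into
   per-stimulus label-choice profiles, computes Euclidean co-occurrence
   distances between profiles, averages distance matrices across
   languages, and embeds the result with classical multidimensional
   scaling.
2. **Clustering the repertoire.** Affinity propagation with a tunable
   preference quantile *q* splits or lumps the space; solutions are scored
   by the mean silhouette and by the adjusted Rand index against a
   reference partition (e.g. modal-name clusters or a known ground
   truth).
3. **Consistency, latency, certainty and order of naming.** Normalized
   Shannon entropy quantifies naming consistency per stimulus;
   hierarchical Bayesian models handle log-latencies (Gaussian, crossed
   random effects), ordinal certainty ratings (cumulative logit) and the
   preference for naming the sound before the emotion (logistic, with the
   screen layout absorbing the left-to-right bias).
4. **Acoustic alignment.** Nonnegative per-feature weights are learned so
   that weighted Euclidean distances over standardized acoustic features
   correlate maximally with the perceptual reference matrix; the weighted
   feature space is summarised by PCA, visualised through a multinomial
   decision map, and benchmarked with a cross-validated random-forest
   call-type classifier.
5. **Label-free perceptual spaces from triad judgments.** A Bayesian
   embedding model infers a d-dimensional configuration from
   "which two of these three sounds are most similar?" choices, with
   dimensionality selected by WAIC.

Everything is exercised end to end on synthetic data with a known ground
truth, so each stage's recovery behaviour is testable.

# The synthetic world

`make_world()` draws a Gaussian-mixture configuration: `n_types` call-type
centres in a `dim`-dimensional latent perceptual space, with `n_stimuli`
stimuli scattered around their type's centre. Two design choices matter:

* **Minimum centre separation.** Centres are isotropic Gaussian directions
  rescaled so that the *smallest* pairwise centre distance equals
  `separation` (default 3, in units of the graded within-type spread).
  Rescaling by the minimum rather than the mean guarantees that no two
  call types coincide for an unlucky seed; with a mean-based rescaling,
  individual centre pairs can land arbitrarily close together and the
  ground truth becomes unrecoverable in principle, which would make
  recovery tests meaningless.
* **Compact versus graded types.** Types listed in `compact_types`
  (default laugh and cry) use one fifth of the within-type spread. This
  reproduces the qualitative structure observed in perceptual data:
  laugh-like and cry-like sounds form tight, well-separated clusters while
  the remaining repertoire grades continuously from moans and sighs to
  screams.

Each stimulus also receives one of nine contextual-emotional categories
(amusement, anger, disgust, effort, fear, joy, pain, pleasure, sadness)
drawn from a type-specific distribution: laughter maps almost entirely
onto amusement/joy and crying onto sadness, while screams, moans and roars
are emotionally ambiguous. This mapping is what gives the synthetic
sound-name x emotion-name contingency tables their non-independence.

## Lexicons and the naming model

`make_lexicon()` places a prototype point in the latent space for every
label. Sound names come in synonym groups (laugh/giggle/chuckle, ...)
jittered around their type's centre (sd 0.7), so confusion concentrates
within a synonym group, as in real naming data where near-synonyms are
applied interchangeably. English has 16 sound names, Swedish and Russian
12; all three languages use 16 emotion names. Emotion-name prototypes are
context-probability-weighted blends of the type centres, additionally
compressed toward the centre of gravity (factor 0.55). The compression
encodes the empirical asymmetry that emotional interpretations of a call
are intrinsically more ambiguous than its acoustic classification; it is
what makes simulated emotion naming slower to stabilise, less certain and
higher-entropy than sound naming, without a separate mechanism.

`simulate_naming()` samples, for every participant x stimulus, a primary
label from a softmax over negative prototype distances with temperature
`naming_temperature` (default 1); any label whose choice probability
reaches `multi_label_threshold` (default 0.25) is added as an extra label.
Certainty (1-3) is an ordinal threshold model on the margin between the
two best labels plus logistic noise; the cuts (-2, 0) were chosen so that
roughly three quarters of simulated ratings are "Sure", the base rate
typical of naming studies with clearly audible stimuli. First-name
latencies are lognormal around 5 s with crossed participant/stimulus
random intercepts (sds 0.3 / 0.2, residual 0.5) and an emotion-minus-sound
location offset of 0.16 log-units. The order indicator ("named the sound
first") follows a logistic model combining a left-to-right bias
(layout log-odds 2.5) with an intrinsic sound-first preference (log-odds
1.2). The generator treats the order indicator and the two first-click
latencies as separate processes; real data couple them (the block visited
second cannot be clicked before the first), a simplification to keep the
latency model's recovery target exact. Passing tests on this generator
therefore demonstrate correct inference under the assumed model, not
robustness to the sequential structure of real response streams.

## Acoustic features and triads

`simulate_acoustics()` produces the conventional twelve acoustic variables
(amplitude and pitch medians/SDs, spectral quartile and entropy measures,
interburst statistics, burst counts, syllable lengths) as linear images of
the latent coordinates plus Gaussian noise (sd 1 by default, roughly the
scale of the informative signal), with optional pure-noise distractor
columns. `simulate_triads()` samples random triples per participant and
draws the chosen pair from the same softmax choice law the inference model
assumes.

# Statistical choices

**Co-occurrence distances.** Profiles are per-stimulus proportions over
the full label inventory, with multi-label trials contributing one count
per chosen label; distances are plain Euclidean between profile rows.
Proportions (rather than raw counts) make the matrix invariant to the
number of raters per stimulus, which matters when online sessions are
incomplete.

**Classical MDS.** `embed_space()` double-centres \(-D^2/2\) and
eigendecomposes; explained variance is reported as eigenvalue shares among
the nonnegative eigenvalues. On distances computed from genuine Euclidean
coordinates the embedding reproduces every distance to numerical
precision, which the test suite asserts at 1e-8.

**Affinity propagation.** Similarities are negative squared distances; the
self-preference is the `q` sample quantile of the off-diagonal
similarities. The implementation follows the canonical
responsibility/availability message passing with damping (default 0.9,
`max_iter` 1000, convergence after 50 stable iterations), plus two details
adopted from the mature reference implementations: an eps-scale
deterministic jitter on the similarities, which prevents degenerate
message oscillations, and a final refinement step in which each cluster
re-elects the member maximising total within-cluster similarity. With
both details in place, converged solutions attain the brute-force-optimal
net similarity on every random small instance we test; without them,
message passing occasionally settles in a neighbouring basin.

**Prototypicality-weighted centroids.** A cluster centroid is the
weighted mean of its members' coordinates with weight = mean certainty x
modal-name proportion, so centroids sit near the most confidently and
consistently named sounds.

**Normalized entropy.** Shannon entropy of the pooled label-choice counts
per stimulus, divided by \(\log_2\) of the number of alternatives and
expressed in percent, making 12-name and 16-name languages comparable.

**Hierarchical models.** The Gaussian log-latency model and the paired
entropy contrast use an in-package Gibbs sampler (conjugate normal updates
for coefficients and random effects; slice updates for the standard
deviations under half-normal(0, 1) priors; fixed effects get normal(0,
2.5) priors on the standardized scale). The ordinal certainty model and
the order-preference logistic model are fitted by MCMC through JAGS with
the same prior family. Priors are weakly informative defaults — the
analyses are dominated by the data at the sample sizes involved — and are
documented rather than tuned. The order-preference odds ratio is defined
as `exp(2 * intercept)` under +/-1 layout coding: the odds of naming the
sound first when sound names are on the *right*, relative to the
mirror-image behaviour, so pure left-to-right reading gives an OR of 1.

**Contingency analysis.** Each trial contributes one count per (sound
name, emotion name) pair chosen; Pearson's chi-square is computed without
continuity correction on the observed rows/columns with
df = (R-1)(C-1). Row and column orders for display come from
average-linkage clustering of the table profiles.

**Metric learning.** `optimize_weights()` maximises the upper-triangle
Pearson correlation between the weighted acoustic distance matrix and the
reference matrix over nonnegative weights, by multi-start Nelder-Mead on
log-weights followed by greedy zero-drop moves (setting single weights to
exactly zero whenever that does not reduce the correlation). The
log-parameterisation keeps weights positive without constraints; the
zero-drop moves implement feature-subset selection and weighting as one
mechanism. The optimizer never returns less than the uniform-weight
baseline; if no start improves on it, the uniform solution is returned
with a warning flag.

**Triad embedding.** Each stimulus gets independent normal(0, `prior_sd`)
coordinates (default sd 1); a triad's chosen pair follows a softmax over
negative pairwise distances with temperature fixed at 1 — the minimal
monotone link consistent with "the closest pair is the most likely
choice"; the distance scale is absorbed by the coordinate magnitudes, so a
free temperature would be redundant with the prior sd. Sampling is
adaptive random-walk Metropolis over per-stimulus coordinate blocks
(proposal scales tuned toward ~30% acceptance during warmup; the sweep
kernel is compiled C++). No identifiability constraints are imposed:
because the likelihood is isometry-invariant, all inference summaries are
distance-based — the reported matrix is the posterior mean of per-draw
distance matrices, *not* the distances between posterior-mean coordinates,
which rotation ambiguity would shrink toward zero. Convergence is
monitored on an isometry-invariant scalar (mean pairwise distance) via
ESS and split-chain R-hat; weak diagnostics raise a warning, never
silence. Participants contributing fewer than
`min_triads_per_participant` triads (default 10) are excluded, mirroring
the inclusion rule used for incomplete online sessions. Participant
heterogeneity is not modelled: a single configuration is shared by all
raters.

**WAIC.** lppd and the variance-based effective parameter count are
computed from the pointwise log-likelihood matrix; the per-observation
variance uses the 1/S divisor, which makes the estimate exactly invariant
to duplicating the draw set (with the S-1 divisor the invariance would
hold only asymptotically). `dimension_sweep()` additionally reports a
normalized negative WAIC (1 = best model, 0 = worst) for plotting.

**Procrustes.** `procrustes_align()` (translation + rotation/reflection +
uniform scaling, symmetric disparity) is provided for display only; no
inference is based on aligned coordinates.

# Numerical and degenerate-input conventions

* Silhouette: singleton clusters score 0, as does the degenerate a = b = 0
  case; a single cluster is an error.
* Modal-name ties break toward the earliest label in inventory order and
  are flagged in the output.
* `standardize_features()` uses the population (1/n) standard deviation,
  so a two-point feature (0, 2) maps exactly to (-1, 1).
* Distance matrices are validated (symmetry, zero diagonal,
  nonnegativity) at every module boundary; all matrices carry explicit
  stimulus-id dimnames and CSV round-trips preserve them.
* Every generator and sampler is a deterministic function of its
  arguments including `seed`; internal streams are derived from the seed
  so stages can be re-run independently.

# Problem sizes used in the test suite

The suite exercises the full default world (132 stimuli, 6 types, 2
compact, 3 languages x 20 raters) for the end-to-end recovery checks, the
documented triad scale (30 stimuli, 150 raters x 42 triads) for distance
recovery, and reduced sampler settings (1-2 chains, a few hundred draws)
elsewhere; replicate counts for calibration checks (e.g. 40 null
replicates for interval coverage) were chosen as the smallest sizes at
which the binomial tolerance is meaningful. The dimensionality-selection
replicates run at 20 stimuli x 1,200 triads, which is already decisive
for WAIC comparisons between d = 1 and d = 3.

# Known limitations

* The naming confusion model is a single-temperature softmax; it does not
  model participant-specific vocabularies, response styles, or fatigue.
* Certainty is driven by the top-2 label margin only, and the latency and
  order processes are independent given the random effects — real
  response streams are sequentially coupled.
* The triad model assumes one shared perceptual configuration; a
  per-participant temperature exists in the design space but is
  deliberately off by default.
* Acoustic features are linear in the latent space; real acoustic-to-
  percept maps are nonlinear, so the learned weights here quantify
  alignment, not a production model.
* Passing recovery tests on this generator validates the inference
  machinery under its assumed models — it does not certify performance on
  real recordings, which bring non-Gaussian clusters, labeller drift and
  missing data.
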