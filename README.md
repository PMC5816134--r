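# vocalspace

Analysis tools for the human **non-linguistic vocal repertoire**: how
listeners categorise laughs, cries, screams, moans, sighs and roars — by
acoustic form (*call type*) and by perceived emotion — and how those two
classifications relate.

The package is aimed at researchers in bioacoustics, voice perception and
cross-linguistic semantics who work with three kinds of tabular data:

* **naming trials** — one row per participant × stimulus, with the chosen
  sound name(s), emotion name(s), certainty ratings and response
  latencies;
* **acoustic feature tables** — one row per stimulus with twelve
  conventional acoustic variables (pitch, amplitude, spectral and
  burst/syllable statistics);
* **triad trials** — "which two of these three sounds are most similar?"
  judgments.

## What it computes

**Semantic spaces.** Stimuli are represented by their label-choice
profiles; the distance between two sounds is the Euclidean distance
between profiles, so sounds that often receive the same name are close:

d(s,t) = ‖p(s) − p(t)‖, with p(s) the vector of label-choice proportions.

Per-language matrices are averaged, embedded by classical MDS
(double-centre −D²/2, eigendecompose), and clustered by **affinity
propagation**, where the preference is the *q* sample quantile of the
off-diagonal similarities −d². Solutions are scored by mean silhouette and
adjusted Rand index.

**Naming consistency.** Normalized Shannon entropy per stimulus,

entropy = −Σᵢ (aᵢ/Σa) log₂(aᵢ/Σa) / log₂(n_alternatives) × 100 %,

plus Bayesian hierarchical models of log-latency (Gaussian, crossed
participant/stimulus random intercepts), ordinal certainty (cumulative
logit) and sound-first order preference (logistic, layout-adjusted), and a
sound-name × emotion-name contingency analysis (χ², random-forest
emotion-from-name prediction).

**Acoustic alignment.** Nonnegative feature weights w are learned to
maximise the Mantel-style correlation between weighted acoustic distances
√Σ_f (w_f (x_sf − x_tf))² and the perceptual reference matrix
(multi-start Nelder–Mead on log-weights with zero-drop feature
elimination), followed by PCA, a multinomial decision map and
cross-validated random-forest call-type classification.

**Triad embedding.** Stimuli get d-dimensional coordinates with normal
priors; a triad's chosen pair follows P(pair) ∝ exp(−d_pair/τ). The
posterior is sampled by adaptive random-walk Metropolis (C++ core), the
dimensionality is selected by **WAIC**, and the inferred distance matrix
(posterior mean of per-draw distances) is compared with the naming-based
references.

A fully parameterised synthetic-data generator (`make_world()`,
`simulate_naming()`, `simulate_acoustics()`, `simulate_triads()`) provides
ground truth for every stage.

## Worked example

```r
library(vocalspace)

world <- make_world(seed = 1)          # 132 stimuli, 6 call types, 2 compact
truth <- setNames(world$stimuli$true_type, world$stimuli$stimulus)

# three naming experiments, one per language, averaged into one space
dmats <- lapply(c("english", "swedish", "russian"), function(lang) {
  lex <- make_lexicon(world, lang)
  trials <- simulate_naming(world, lex, n_participants = 20, seed = 1)
  cooccurrence_distances(name_profile_matrix(trials, lex$sound_labels, "sound"))
})
averaged <- average_distance_matrices(dmats)

sweep_tab <- q_sweep(averaged, truth, q_grid = seq(0, 1, 0.05))
dplyr::filter(dplyr::select(sweep_tab, q:converged),
              q %in% c(0.1, 0.4, 0.65, 0.9, 1))
#> # A tibble: 5 × 5
#>       q n_clusters silhouette    ari converged
#>   <dbl>      <int>      <dbl>  <dbl> <lgl>
#> 1  0.1           6      0.721 0.896  TRUE
#> 2  0.4           6      0.721 0.896  TRUE
#> 3  0.65          7      0.699 0.909  TRUE
#> 4  0.9          26      0.606 0.616  TRUE
#> 5  1           112      0.106 0.0311 TRUE
```

Low-to-moderate preference quantiles recover the six generating call types
(ARI ≈ 0.9, silhouette 0.72); as q rises the algorithm splits the graded
middle of the repertoire into ever finer clusters. The laugh and cry
clusters are the most compact, mirroring real repertoires. The
embedding and a cladogram of the cluster centroids come from
`embed_space(averaged, 3)` and `hierarchical_cladogram()`; fitted objects
support `tidy()`, `glance()` and `autoplot()`.

```r
lex <- make_lexicon(world, "english")
trials <- simulate_naming(world, lex, n_participants = 20, seed = 1)
ent <- naming_entropies(trials, lex$sound_labels, lex$emotion_labels)
colMeans(ent[-1])
#>  entropy_sound entropy_emotion
#>       34.6            44.5
```

Sound names are chosen more consistently (lower entropy) than emotion
names, the package's synthetic analogue of the consistency asymmetry seen
in naming studies.

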