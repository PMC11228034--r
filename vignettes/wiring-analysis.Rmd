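---
title: "Wiring-structure analysis of bipartite connectome circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wiring-structure analysis of bipartite connectome circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbwire)
```

## The scientific problem

Expansion-layer circuits — mushroom bodies, cerebellum-like structures —
wire a large output population (Kenyon cells, KCs) to a smaller input
population (here visual projection neurons, VPNs, and local visual
interneurons, LVINs). Three wiring hypotheses span the design space:
**labelled lines** (each output listens to one dedicated channel),
**biased mixtures** (outputs sample combinations, but with structured
preferences), and **random mixtures** (each output samples its few inputs
independently, with probabilities set only by input availability). Which
regime a measured circuit occupies determines its coding properties:
random, sparse sampling yields a distributed combinatorial code; labelled
lines yield dedicated feature channels.

`mbwire` implements the statistical machinery for making that call on a
measured synapse-count matrix, plus the geometry needed to interpret the
inputs: synapse-type classification and receptive-field estimation.

## The data model

`build_matrix()` assembles an inputs × outputs synapse-count matrix from an
edge list. Two conventions matter:

- **Threshold.** A connection is counted only at ≥ `threshold` synapses
  (default 5, the standard proofreading-noise floor for EM connectomes).
  The threshold applies per (pre, post) pair *before* any type aggregation,
  so aggregation can never resurrect a sub-threshold pair.
- **Binarization.** The randomness machinery works on the 0/1 connection
  indicator, because the quantities the null preserves — input connection
  probabilities and per-output in-degree — are defined on binary
  connectivity. The participation ratio uses synapse weights instead (see
  below).

Duplicate (pre, post) rows in an edge list are treated as a malformed
export and rejected rather than summed.

## The shuffle null

`shuffle_preserving_marginals()` re-draws each output's inputs without
replacement, keeping the output's exact in-degree and sampling each input
with probability proportional to its connection count in the observed
matrix. This is the null of "random wiring given availability": it keeps
both non-uniform input popularity and the sparse in-degree distribution,
and destroys everything else. All tests use `n_shuffles = 1000` by default
and empirical 2.5/97.5 percentiles rather than normal approximations,
because match counts and co-occurrence counts at this scale are small and
skewed. Reported p-values use the (r+1)/(n+1) finite-ensemble correction.

A design point worth making explicit: the null estimates its sampling
weights from the observed matrix itself. When the true connection
probabilities are nearly uniform, the estimation noise in those weights
makes the null slightly *more* structured than the generating process, and
the observed leading eigenvalue sits low in the band. For heavy-tailed
probabilities — which is what measured circuits show, with a few input
types contributing an outsized share of synapses — this effect is second
order. This is why the synthetic generator's default connection-probability
profile is heavy-tailed (below), and why mid-spectrum components of a
random matrix can sit slightly outside the band even when the circuit is
exactly random; conclusions should rest on the leading components, which
calibrate cleanly.

## The synthetic generator

`generate_wiring()` draws matrices under the three hypotheses. Defaults
emulate the measured visual-KC circuit:

- 74 inputs × 147 outputs (the left-hemisphere VPN/LVIN → KCγ-d scale);
- per-output in-degrees drawn from {1, 2, 3, 3, 4, 5, 7}: a 1–7 range with
  median 3, matching the sparse sampling of visual Kenyon cells;
- input connection probabilities from `ranked_input_probs()`, normalized
  lognormal quantiles (`sdlog = 1`). Ranked synaptic-contribution curves of
  measured input populations are strongly skewed, and a lognormal rank
  profile reproduces that shape. `sdlog = 0` recovers uniform sampling for
  experiments that need it;
- retained synapse counts `threshold + Geometric(0.5)` — structural tests
  binarize anyway, so only the support matters;
- `labeled_line`: inputs and outputs partitioned into communities, outputs
  sample only within community, with per-draw contamination `noise`;
  `biased_mixture`: probabilities multiplied by a bias vector.

`generate_bilateral_pair()` produces left/right hemispheres that are either
independent draws (identical marginal structure, no pairwise stereotypy) or
mirrored copies paired through a type map. `generate_synapse_cloud()`
produces bouton-claw clouds (isotropic Gaussian, sd σ) and en-passant
clouds (uniform along a length-L segment plus transverse jitter, default
L/100). `make_hex_eyemap()` builds a hexagonal patch of ommatidial columns
(759 by default, 4° inter-ommatidial angle — a ~117°-wide patch) with unit
viewing directions and per-layer columnar markers 5 µm apart;
`generate_visual_system()` plants receptive fields as contiguous column
discs and lays skeleton points within a known distance of exactly those
markers.

What the generator does *not* emulate: true neuron morphology (skeletons
are labelled point sets), correlated proofreading artifacts, hemisphere
asymmetries in population size, and spatial correlations between
connectivity and receptive-field position. Tests passing on synthetic data
therefore validate the statistical machinery and its calibration, not the
biological conclusions one would draw from a particular real dataset.

## Statistics on the matrix

**Spectrum test** (`pca_spectrum_test`). Input-channel covariance with
outputs as observations, eigenvalues as variance fractions, compared
per-component against the shuffle band. On labelled-line wiring with k
communities, the between-community structure contributes ≥ k − 1 dominant
components, so the test flags ≥ 3 components above the band at k = 4.

**Participation ratio** (`participation_ratio`). PR = tr(C)²/tr(C²),
computed on synapse-weighted connectivity by default because the quantity
models the dimensionality of input *currents*, which scale with synaptic
weight; a binarized variant is available (`weighted = FALSE`) since the
construction of the covariance is a convention the data do not fix. PR is
invariant to input permutation and overall weight scaling, equals the
channel count for equal eigenvalues, and decreases under mean-preserving
concentration of spectral mass — the sense in which "a few dominant input
types" lowers dimensionality.

**Conditional input analysis** (`conditional_input_analysis`). The
co-occurrence count matrix is `A %*% t(A)` on binary connectivity; each
pair is z-scored against the shuffle null's mean and sd. Pairs whose null
sd is zero (forced or forbidden co-occurrences under the marginals) get
z = 0 with a degeneracy flag rather than ±∞. K-means on the z-matrix rows
runs over k = 2…10 (20 restarts, seeded); at the true community number it
recovers planted communities with adjusted Rand ≥ 0.9.

**Output clustering** (`cluster_outputs`). Spectral clustering
(Ng–Jordan–Weiss: cosine affinity of binary input profiles, normalized
Laplacian, row-normalized top-k eigenvectors, K-means). Cosine affinity is
exactly block-diagonal for noise-free labelled lines, and well behaved on
sparse binary profiles. Model selection uses the mean silhouette on the
spectral embedding (Euclidean distance). Judging whether *any* structure
exists uses the silhouette of the selected labels on the binary profiles
instead: K-means on a low-dimensional embedding always produces compact
partitions (embedding silhouettes of ~0.3–0.6 even for random wiring), so
the embedding silhouette ranks k but cannot certify structure. The
`no_clear_structure` flag fires when the profile silhouette falls below
0.25; random wiring sits near 0.05, planted blocks well above.

**Bilateral stereotypy** (`bilateral_identity_test`). Both hemispheres are
binarized and aggregated to input types through the type map (a type
connects if any member does), patterns compared exactly; each left output
counts once, outputs with no inputs are excluded from both sides. The
independent-mode null reshuffles both hemispheres; the mirrored-mode null
shuffles one and copies it, bounding what perfect stereotypy would give.
Pattern comparison uses a fixed random-projection key drawn from the test
seed: identical binary patterns give bitwise-identical keys and distinct
patterns collide with probability ~0 in double precision, making the
per-shuffle count a single matrix product.

## Synapse typing

For each pre/post connection with ≥ 3 synapses, the dispersion statistic is
the population variance of the Euclidean distances of its synapse locations
(nm) from their centroid. Two-point clouds have dispersion identically zero
(both points sit at d/2 from the centroid), hence the ≥ 3 rule; such
connections are `unclassified`. For a uniform segment of length L the
statistic converges to L²/48, an order of magnitude above a bouton of sd
L/20, which is the separation the classifier exploits. Calibration splits
the labelled set (stratified, seeded), places the cutoff at the midpoint
between the best-separating order statistics on the training half (ties to
the smallest cutoff), and reports held-out accuracy.

## Receptive fields

A column is covered when any skeleton point lies within `threshold_nm` of
its columnar marker in the chosen layer; coverage is monotone in the
threshold. Thresholds are calibrated per layer by maximizing mean Jaccard
overlap with annotated column sets over an explicit grid (ties to the
smallest threshold). The receptive field is the spherical convex hull of
the covered viewing directions, computed by gnomonic projection about the
covered-set centroid — valid because great circles map to lines; sets
spanning more than 150° of visual angle are rejected rather than silently
mis-hulled. RF size is the number of eye columns inside the hull, and the
centroid is the normalized mean direction. Effective fields of downstream
cells sum synapse-weighted hull indicators; each LVIN's composite field is
normalized to unit mass before weighting by its LVIN → KC synapse count so
direct and indirect components are comparable. The Mollweide projection
(equal-area; Newton iteration on 2θ + sin 2θ = π sin φ to 1e-12, poles
analytic) serves display and density-faithful comparisons.

## Numerical conventions and degenerate inputs

- Lexicographic ordering of neuron ids everywhere; all ties broken
  deterministically (rankings by id, matching by score then query then
  target id, threshold grids to the smallest value).
- Greedy cross-dataset matching processes candidate pairs in globally
  descending score order, which realizes the "strongest claim wins,
  displaced queries cascade to their next-best free target" procedure
  deterministically, including when three or more queries conflict.
- Every generator and test is a pure function of (arguments, seed); the
  pipeline derives per-stage seeds from the global seed and stage name via
  a 31-bit string hash, and restores the caller's RNG state.
- Degenerate cases: single-input matrices yield a warning and a trivial
  spectrum; all-zero matrices error in `participation_ratio`; empty
  skeletons warn and cover nothing; zero-variance null pairs get flagged
  z = 0; outputs with no inputs are excluded from clustering and bilateral
  counting with a notice.

## Problem sizes used in the shipped checks

The test-suite calibration experiments run at the measured circuit's scale
(74 × 147, 1000-shuffle nulls, 50 repetitions for coverage/power rates;
five pooled matrices for the conditional-input false-positive rate; 10⁴
points for the dispersion closed form; a 759-column eyemap with six
planted neurons for RF recovery). These sizes make each rate estimate's
binomial error small relative to the thresholds being asserted while
keeping a full run in minutes on one CPU.

## Known limitations

- The shuffle null's weight estimation makes mid-spectrum band positions
  approximate for near-uniform circuits (discussed above); leading
  components calibrate cleanly, and those carry the scientific conclusions.
- The spherical hull is undefined for fields wider than 150°; true
  panoramic fields would need a different hull construction.
- Accessory-medulla neurons have no columnar markers of their own in real
  eyemaps; their RFs depend on the layer convention chosen, and should be
  interpreted with that caveat.
- The real-data adapter surface is file-based (CSV/SWC exports); no live
  connectome-service queries are performed by this package.
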