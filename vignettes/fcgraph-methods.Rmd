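---
title: "Methods: graph-theoretical comparison of functional brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-theoretical comparison of functional brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`fcgraph` implements a complete pipeline for comparing the topology of
resting-state functional brain networks between two subject groups
(labelled `patient` and `control`). The input is one regional time-series
matrix per subject — typically 90 regions of an anatomical parcellation by
200 BOLD volumes — plus a subject manifest with group labels and clinical
covariates. The pipeline:

1. cleans each regional time course (volume discard, linear detrend, ideal
   band-pass),
2. builds the Pearson correlation matrix across regions,
3. binarizes it at every level of a sparsity grid,
4. computes global efficiency $E_{glo}$, local efficiency $E_{loc}$, mean
   clustering coefficient $C_p$, characteristic path length $L_p$ and
   nodal degree at every level,
5. normalizes $C_p$ and $L_p$ against degree-preserving random reference
   networks to obtain the small-world coefficients
   $\gamma = C_p / C_p^{rand}$, $\lambda = L_p / L_p^{rand}$,
   $\sigma = \gamma / \lambda$,
6. identifies degree-centrality hubs per group and classifies every edge
   as rich-club (hub–hub), feeder (hub–non-hub) or local
   (non-hub–non-hub), with per-subject connection strengths per class, and
7. runs group inference: per-level two-sample t-tests with
   Benjamini–Hochberg FDR, permutation tests on the class strengths,
   chi-square / Mann–Whitney demographics and Spearman correlations of
   network summaries against clinical covariates in the patient group.

A synthetic cohort generator produces ground-truth worlds with modular
covariance, planted hubs and controllable group effects, so that every
stage of the pipeline can be validated end to end without access to scan
data.

## Temporal preprocessing

Only the steps that act on extracted regional time series are implemented;
voxel-level image processing is out of scope. Defaults: the first 10
volumes are discarded (magnetization equilibration), each region is
detrended by least squares, and frequencies are retained strictly inside
(0.01, 0.08) Hz at TR = 2 s.

The band-pass is an *ideal rectangular filter* on the discrete Fourier
transform rather than an IIR design: the specification of the method names
only the band, and the ideal filter is exactly testable (a sinusoid on an
in-band DFT bin passes through unchanged; out-of-band bins are annihilated
to machine precision). One numerical subtlety matters: the kept-bin mask
must be exactly conjugate-symmetric, so bin folding is computed on integer
bin indices, `min(k, T-k)/(T*TR)`. Folding on floating-point frequencies
(`1/TR - f`) differs in the last ulp between a bin and its mirror, which
silently breaks the symmetry and leaks power through the final real part.
The DC bin is always removed, so filtered series have (numerically) zero
mean.

## Network construction

Edges are Pearson correlations between regional time courses;
self-connections are excluded (diagonal stored as 0). Binarization keeps
exactly $E = \mathrm{round}(s \cdot N(N-1)/2)$ edges (half-up rounding) at
sparsity $s$, taking the *largest positive* correlations; the default grid
is $s = 0.05, 0.06, \dots, 0.40$ (36 levels).

Design choices where the method description is silent:

* **Positive-only thresholding.** Negative correlations never become
  edges. This is the dominant convention for binarized resting-state
  graphs and keeps "connection strength" (sums of edge weights)
  well-defined and monotone.
* **Deterministic tie-breaking.** Ties at the cutoff are broken by
  lexicographic node order, so a sweep is reproducible and the graphs at
  increasing sparsity are strictly nested.
* **No Fisher z-transform.** Group-mean matrices average raw correlations.

## Graph metrics

Standard binary, undirected definitions are used (the original study's
exact formulas live in an unavailable supplement; this assumption is
deliberate and documented):

* $E_{glo} = \frac{1}{N(N-1)} \sum_{i \ne j} 1/d_{ij}$ with $1/\infty = 0$.
* $C_i = 2e_i / (k_i(k_i-1))$, $C_i = 0$ for $k_i < 2$; $C_p$ averages over
  *all* nodes, including low-degree ones (determinism on sparse graphs).
* $E_{loc}$ is the mean over nodes of $E_{glo}$ of the subgraph induced by
  each node's neighbors.
* $L_p$ is the mean hop distance over *finite* pairs. Graphs at the lowest
  sparsity levels are often disconnected; unreachable pairs are excluded,
  the profile records a connectedness flag, and a WARN line is logged.
  This keeps $L_p$ finite without inventing a disconnection penalty.

Distances use breadth-first search implemented in C++; the test suite
checks all metrics against independent brute-force oracles
(Floyd–Warshall, explicit triangle counting, exhaustive subgraph
enumeration) on hundreds of random graphs.

## Null models and small-world coefficients

Reference networks are Maslov–Sneppen degree-preserving rewirings: 10
attempted double-edge swaps per edge, ensembles of $M = 100$ nulls per
graph, arithmetic-mean aggregation of the null $C_p$ and $L_p$.
Disconnected nulls are retained (resampling would bias the ensemble toward
connectedness) and use the same finite-pair $L_p$ convention.

A correctness point discovered during development: with edges stored in
canonical (min, max) orientation, the literal proposal
$(a,b),(c,d) \to (a,d),(c,b)$ is *not* a reversible Markov chain, and the
bias is large enough to be visible in summary statistics (an Erdős–Rényi
graph, which should be its own null, showed $\sigma \approx 1.8$). The
implementation therefore assigns each picked edge a random orientation
before the proposal — the standard reversible chain — after which ER
graphs give $\sigma \approx 1$ and Watts–Strogatz graphs give
$\sigma > 1$, as they must.

Each null draws from its own RNG substream (a per-index seed derived by a
stage-keyed hash of the master seed), so ensembles are pure functions of
`(graph, M, seed)` and adding pipeline stages never perturbs other
stages' draws. The ensemble loop runs in C++ with a per-null `mt19937`;
roughly 50,000 ensembles are needed for a full cohort sweep, which rules
out R-level reseeding.

## Hubs, rich club, connection strengths

Hubs are defined per *group*: the group's connectivity matrices are
averaged elementwise, the mean matrix is thresholded at every grid level,
degree centrality is averaged across levels, and hubs are the regions at
least one standard deviation (population SD across regions) above the
across-region mean. Grid-averaging avoids privileging a single sparsity
when producing the one-hub-list-per-group output. On a regular graph
(SD = 0) no region qualifies — the degenerate case is resolved by
requiring strictly greater than the mean.

Edges are classified against the group hub set (rich-club / feeder /
local partition the edge set; this identity is asserted at every level for
every subject). A subject's strength for a class is the *sum* of Pearson
weights over that class's suprathreshold edges, averaged across grid
levels. Sum-not-mean is a documented choice ("connection strength"
conventionally sums weights); computing per-subject strengths against
*group* hubs keeps strengths comparable within group.

The normalized rich-club coefficient $\phi_{norm}(k) = \phi(k) /
\overline{\phi_{rand}(k)}$ over degree-preserving nulls is provided for
description, but hubs are defined by the SD rule, not by $\phi$ —
faithfulness to the stated procedure.

## Group inference

* **t-tests:** classical equal-variance Student tests per metric per
  sparsity level ("two-sample t-test" unqualified); Welch behind a flag.
* **FDR:** Benjamini–Hochberg step-up at $q = 0.01$ applied within one
  metric's family of 36 levels (matching per-metric corrected curves),
  not pooled across metrics.
* **Permutation tests:** group-label permutations of the class strengths,
  statistic $|\bar{A} - \bar{B}|$, $P = 100$ draws without uniqueness
  enforcement, add-one p-value $p = (1 + \#\{|\Delta_{perm}| \ge
  |\Delta_{obs}|\})/(P+1)$, so $p \ge 1/(P+1)$ and the estimator is
  exactly uniform on its attainable values under the null. The
  permutation RNG keys on the sorted subject IDs, making results
  invariant to input row order.
* **Demographics:** sex by 2×2 chi-square without continuity correction
  (switchable); age and education by Mann–Whitney U with tie-corrected
  normal approximation.
* **Spearman correlations** (average ranks, t-approximation p-values) are
  computed within the patient group only, against disease duration and
  ACTH — covariates that exist only for patients.

## The synthetic world

`ground_truth_spec()` describes the generative model: 90 regions in 6
equal modules; 12 planted hubs (2 per module); latent correlation 0.45
within modules, 0.10 between; +0.20 on hub-incident pairs; unit-variance
observation noise; 210 volumes so that 200 survive the discard rule.
Volumes are i.i.d. multivariate-normal draws — no temporal
autocorrelation — because every downstream statistic uses only zero-lag
correlations; the band-pass filter is exercised separately with sinusoid
fixtures.

The patient-like group multiplies the hub boost by 0.6 and within-module
non-hub correlations by 0.7. Effects are imposed on the *latent
covariance*, never on graph metrics directly, so recovery through the
pipeline is a genuine test. With these defaults the patient group emerges
from the pipeline with higher global efficiency, lower clustering, higher
$\sigma$ and lower rich-club/feeder/local strengths — the qualitative
pattern the pipeline is designed to detect. The local-strength contrast
is the weakest of the six (patients lose hub edges to the local class
even as each local edge weakens), and is the most likely to flip in a
given replicate.

The target matrix built entry-by-entry from these rules is *not* positive
semidefinite (hub rows elevated against many mutually weakly-correlated
regions push the smallest eigenvalue to about −2.9); it is repaired by
eigenvalue clipping at zero followed by rescaling to an exact unit
diagonal. Tests target the repaired matrix, and sampled correlations
converge to it elementwise.

Clinical covariates are drawn from published cohort moments (patient ACTH
86.10 ± 58.28 pg/ml, UFC 659.87 ± 357.29 µg/24 h, duration 4.76 ± 3.58 y,
plus age/sex/education for both groups), truncated at zero; control
clinical fields are left missing. Note the truncation shifts the ACTH
mean upward by ≈ 1.8 — visible at large n but inside the Monte-Carlo
tolerance of the generator tests.

What a green synthetic run does *not* establish: the generator has no
hemodynamic response, scanner noise spectrum, motion artifacts or
temporal autocorrelation, and its modular block structure is far cleaner
than real parcellated BOLD data. Green tests certify the *pipeline
machinery* (definitions, normalizations, inference calibration,
direction-of-effect sensitivity), not fidelity to any real cohort.

## Numerical and interface choices

* All delimited artifacts are written with 17 significant digits so
  write→read round-trips are bit-exact (a 10-significant-digit format
  would break the ≥12-decimal round-trip guarantee).
* Time-series files are plain numeric matrices (regions × time); an
  optional leading `#regions` comment line carries region labels,
  otherwise `R001..RNNN` are synthesized.
* Run configurations are JSON with keys exactly matching
  `analysis_config()` fields (no YAML parser is available in the target
  stack).
* Every source of randomness flows from a single master seed through
  stage-keyed substreams; a full pipeline run is byte-reproducible, and
  changing the seed changes permutation p-values and null ensembles but
  not observed raw metrics.

## Known limitations

* Weighted-graph analysis, covariate-adjusted group models, nodal
  mass-univariate testing and network-based statistics are out of scope.
* Whether the original analysis thresholded signed or absolute
  correlations, summed or averaged strengths, and used subject-level or
  group-level hubs is not stated there; the choices above are the
  package's own, exposed where reasonable as switches.
* Permutation tests with $P = 100$ cannot produce p-values below
  $1/101 \approx 0.0099$, so FDR at $q = 0.01$ on permutation p-values is
  at the edge of resolution; this mirrors the stated procedure rather
  than improving on it.
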