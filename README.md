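# fcgraph

Graph-theoretical group comparison of functional brain networks.

`fcgraph` is for researchers who have regional resting-state time series
(e.g. 90 parcellated BOLD signals per subject) for two groups — a patient
group and a control group — and want to know whether the *topology* of the
functional networks differs: integration (global efficiency), segregation
(clustering, local efficiency), small-worldness, and the organization of
hub connectivity (rich-club / feeder / local connections).

## The method

Per subject, regional time series are cleaned (first 10 volumes discarded,
linear detrend, ideal band-pass 0.01–0.08 Hz at TR = 2 s) and correlated
pairwise (Pearson). The correlation matrix is binarized at every sparsity
level s = 0.05, 0.06, …, 0.40 by keeping the `round(s·N(N−1)/2)` largest
positive correlations. At each level the package computes

* global efficiency `Eglo = mean over pairs of 1/d_ij`,
* local efficiency `Eloc` (mean efficiency of neighbor-induced subgraphs),
* mean clustering coefficient `Cp`, characteristic path length `Lp`,
* nodal degree centrality `k_i`,

and normalizes against M = 100 Maslov–Sneppen degree-preserving random
networks:

```
gamma = Cp / Cp_rand,   lambda = Lp / Lp_rand,   sigma = gamma / lambda
```

`sigma > 1` is the small-world signature. Hubs are regions whose
grid-averaged degree centrality on the group-mean network is ≥ 1 SD above
the across-region mean; every edge is then rich-club (hub–hub), feeder
(hub–non-hub) or local, and a subject's class strength is the summed
Pearson weight of that class's edges, averaged over the grid. Inference:
per-level two-sample t-tests with Benjamini–Hochberg FDR (q = 0.01) within
each metric family, permutation tests (P = 100) on class strengths,
chi-square / Mann–Whitney demographics, and Spearman correlations of
network summaries against clinical covariates (duration, ACTH) within the
patient group.

A synthetic cohort generator (modular latent covariance, planted hubs,
group effect multipliers) lets you validate the whole pipeline end to end;
see the methods vignette (`vignettes/fcgraph-methods.Rmd`) for the model
and every numerical choice.

## Worked example

Simulate a cohort of 10 patient-like and 10 control-like subjects in the
default 90-region world, write it to disk, and run the full pipeline with
a reduced grid (step 0.05) and 20 nulls per graph:

```r
library(fcgraph)
spec   <- ground_truth_spec()                      # 90 regions, 12 hubs
cohort <- simulate_cohort(spec, 10, seed = 42)
dir.create("demo/data", recursive = TRUE)
for (p in cohort$panels)
  write_timeseries(p, file.path("demo/data", paste0(p$subject_id, ".tsv")))
write_manifest(cohort$manifest, "demo/data/manifest.tsv")

cfg <- analysis_config(sparsity_step = 0.05, n_null_networks = 20, seed = 42)
bundle <- run_pipeline(cfg, "demo/data/manifest.tsv", "demo/data", "demo/out")
print(bundle$comparison)
```

which prints (about 12 s on one CPU):

```
<group_comparison>
  FDR-flagged sparsity levels per metric:
    cp       8
    eglo     0
    eloc     8
    gamma    8
    lambda   5
    lp       3
    sigma    6
  connection-strength permutation tests:
    rich_club  delta =  -1.2109  p = 0.1782
    feeder     delta = -10.0376  p = 0.0099
    local      delta = -18.1023  p = 0.0198
```

Reading this: the patient-like group differs from control in clustering
(`cp`: all 8 levels FDR-significant at q = 0.01) and in the normalized
small-world coefficients, and its feeder/local connection strengths are
lower (negative `delta = mean(patient) − mean(control)`; the permutation
floor is p = 1/101 ≈ 0.0099). The recovered control hub list is exactly
the 12 planted hub regions:

```r
sort(bundle$hubs$control$hubs)
#  "R001" "R002" "R016" "R017" "R031" "R032" "R046" "R047" "R061" "R062" "R076" "R077"
```

All artifacts (connectivity matrices, tidy per-level metric tables, hub
lists, class strengths, comparison tables, run log) are delimited text
under `demo/out/`. The same stages are scriptable via the CLI
(`inst/cli/fcgraph`): `simulate`, `construct`, `metrics`, `smallworld`,
`richclub`, `compare`, `report`, `pipeline`.

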