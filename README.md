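# fcnet

Resting-state functional-connectivity network analysis for parcellated
brain signals, with a calibrated synthetic cohort generator.

Functional MRI resting-state studies compare groups (e.g., patients vs
controls) through the correlation structure of regional BOLD signals.
`fcnet` implements that analysis chain end to end for region×time signal
matrices:

* **Connectivity** — row demeaning, global-signal removal, Pearson
  correlation matrices, a non-negative variant, and proportional
  thresholding to binary networks at fixed edge density (default 20%:
  every subject keeps the same number of edges, which makes topology
  comparable).
* **Topology** — characteristic path length *L*, clustering *C*, the
  benchmark-normalized ratios γ = *C*/*C*ᵣ and λ = *L*/*L*ᵣ against random
  *G(n,m)* graphs with matched nodes and edges, small-worldness
  σ = γ/λ = *C·L*ᵣ/(*C*ᵣ·*L*), and Newman modularity *Q* maximized by the
  seeded Louvain heuristic.
* **Spatial statistics** — Euclidean distance between centroids of
  connected regions as a proxy for connection reach; per-node mean neighbor
  distance; degree-based hub ranking (top 15) and cross-subject hub
  frequencies; seed-region connection profiles with group-specific partners
  and a pooled two-proportion z-test (|z| > 2) on shared partners.
* **Inference** — pooled two-sample t-tests for global measures, Pearson
  correlation tests (*t* on *n*−2 df), node-wise label-permutation tests
  (5,000 permutations, two-sided add-one p) with Benjamini–Hochberg FDR at
  5% per metric family.
* **Synthetic cohorts** — a latent-factor generator (global, module-level,
  long-range and noise components, AR(1)-smoothed, with an analytic
  correlation oracle) producing two-group cohorts: 16 controls vs 14 cases,
  110 regions (48 cortical + 7 subcortical per hemisphere, mirrored
  geometry), 128 volumes; cases have elevated global coupling and elevated
  long-range coupling at 16 spatially dispersed nodes.

The methods vignette (`vignettes/fcnet-methods.Rmd`) documents the model,
the numerical conventions, and the design decisions.

## Worked example

The `analysis/` directory holds the numbered workflow. Running

```sh
Rscript analysis/01_simulate_cohort.R   # cohort -> results/cohort/
Rscript analysis/02_connectivity.R      # correlation matrices and networks
Rscript analysis/03_network_metrics.R   # L, C, gamma, lambda, sigma, Q
Rscript analysis/04_group_comparison.R  # t-tests, permutation + FDR
Rscript analysis/05_hubs_and_seed.R     # hubs, right-caudate profile
```

takes well under a minute altogether. Step 3 prints the global battery
(this run's output):

```
Global aggregate measures (mean +/- SD):
measure                      control            case
L                             1.952 +/- 0.029     1.972 +/- 0.016
C                             0.536 +/- 0.023     0.542 +/- 0.010
gamma                         2.677 +/- 0.114     2.712 +/- 0.050
lambda                        1.079 +/- 0.016     1.090 +/- 0.009
sigma                         2.481 +/- 0.072     2.488 +/- 0.034
Q                             0.481 +/- 0.020     0.465 +/- 0.012
```

σ ≈ 2.5 in both groups: the thresholded networks are small-world (heavily
clustered relative to random graphs at near-random path length), and the
topology is similar across groups. Step 4 then shows where the groups do
differ — the raw-correlation grand mean is higher in cases
(t = −7.68, p < 10⁻⁴), and the mean neighbor Euclidean distance changes at
14 regions at 5% FDR (13 case-higher, 1 control-higher), concentrated at
the long-range-coupled nodes:

```
  mean_neighbor_distance   14 nodes (13 case-higher, 1 control-higher)
      ...
      caudate_R          control   88.4 mm  case  103.6 mm  q=0.0044 (case_higher)
```

i.e., case subjects' connections reach farther — exactly the effect the
generator encodes. Step 5 profiles the right caudate's partners per group
and tests shared partners' frequencies.

The same machinery is callable directly:

```r
library(fcnet)
cfg  <- generator_config()          # the default study conditions
rep  <- run_pipeline(run_config(generator = cfg, output_dir = "results/run"))
rep$global_comparison               # Table-style group comparison
```

`run_pipeline()` writes every table as TSV plus a JSON report, and is
bit-reproducible given `master_seed`. User-supplied cohorts load from the
same manifest/TSV format via `load_cohort()`; a relabeled manifest (e.g.,
splitting the case group by medication) reruns any subgroup contrast with
no new code.

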