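# soilgnn

Prediction of soil heavy-metal concentrations (cadmium and lead, mg/kg) at
georeferenced sampling sites with a multi-scale attention graph neural
network. Soil surveys violate the i.i.d. assumption behind most regression
models: nearby sites share parent material, climate and pollution
pathways, so their metal burdens co-vary in space. `soilgnn` is for
environmental geochemists and digital-soil-mapping practitioners who want
a spatially aware alternative to kriging or covariate-only machine
learning for survey-scale (tens to hundreds of sites) contamination data.

## The method

Sites become nodes of a spatial graph: every pair within a radius *d* km
(great-circle, haversine) is connected, disconnected components are
detected with the Boolean-power reachable matrix
*M<sub>G</sub>* = sgn((*A* + *I*)<sup>k</sup>) (its rank is the component
count) and bridged by shortest-distance repair edges, and edges are
weighted with a Gaussian kernel exp(−d<sub>ij</sub>² / 2θ²), θ = 5 km.
An optional variant masks the adjacency by environmental-type agreement
(organic-rich / mineral-rich / mixed, from organic-matter and Fe/Mn-oxide
thresholds) so that only same-type sites are directly linked.

The regressor stacks

- **MS-GCN** — three parallel graph convolutions with symmetrically
  normalized one-, two- and three-hop propagation operators
  *S<sub>k</sub>* = *D<sub>k</sub>*<sup>−1/2</sup>(*A<sub>w</sub>* + *I*)<sup>k</sup>*D<sub>k</sub>*<sup>−1/2</sup>,
  concatenated and rectified;
- **AGNN** — graph attention with scores
  e<sub>ij</sub> = LeakyReLU(a<sup>T</sup>[Wh<sub>i</sub> ‖ Wh<sub>j</sub>]),
  row-softmax weights α<sub>ij</sub> over the self-inclusive neighborhood,
  and aggregation h′<sub>i</sub> = Σ<sub>j</sub> α<sub>ij</sub> W h<sub>j</sub>;
- a linear head, trained per metal with squared-error loss, Adam
  (lr 0.001), 100 epochs, node mini-batches of 8 over full-graph forward
  passes.

Evaluation utilities implement MAE / RMSE / R², repeated random 80/20
splits, nested cross-validation (inner hyperparameter selection over
hidden width and graph radius), a paired-seed ablation runner
(full vs convolution-only vs attention-only), permutation feature
importance with sum-to-one weights, and prediction at new locations via a
joint train+new graph. A synthetic survey generator (spatially
autocorrelated latent field over five parent-material zones, zone-linked
pollution types, right-skewed targets) makes every stage testable without
any external data, and `morans_i()` quantifies the spatial autocorrelation
the graph should exploit.

## Worked example

```r
library(soilgnn)

# a synthetic survey with a dominant spatial field (Gaussian targets)
cfg_gen <- synthetic_config(n_sites = 150, zone_counts = c(20, 40, 40, 25, 25),
                            sigma2_s = 1, range_km = 10, noise_sd = 0.1,
                            log_link = FALSE, intercepts = c(cd = 8, pb = 110),
                            seed = 42)
survey <- simulate_survey(cfg_gen)

graph <- build_fixed_graph(survey$table, d = 10, theta = 5)
print(graph)
#> Spatial graph: 150 nodes, 359 edges (13 repair), d=10 km, theta=5 km
morans_i(survey$table$cd, graph$weights)
#> [1] 0.558

cfg <- msagnn_config(target = "cd")
spatial <- repeated_random_splits(survey$table, config = cfg,
                                  n_repeats = 5, seed = 42, graph = graph)
print(spatial)
#> Evaluation (5 repeats, 80/20 split, target cd):
#>  metric      mean         sd
#>     mae 0.7317782 0.08847527
#>    rmse 0.9459742 0.10870651
#>      r2 0.3706923 0.09722611

baseline <- repeated_random_splits(survey$table, list(identity = TRUE),
                                   cfg, n_repeats = 5, seed = 42)
print(baseline)
#> Evaluation (5 repeats, 80/20 split, target cd):
#>  metric      mean        sd
#>     mae 0.8932445 0.1220432
#>    rmse 1.1035965 0.1181013
#>      r2 0.1189048 0.2791558
```

The survey's Cd values cluster in space (Moran's I 0.56 on the weighted
graph), and the graph model recovers part of that structure: mean held-out
R² 0.37 against 0.12 for the same network trained on a self-only graph
(covariates alone), with correspondingly lower MAE and RMSE. With the
default log-link generator the targets are right-skewed
(`descriptive_stats(survey$table$cd)` reports skewness ≈ 2.9 and raw
kurtosis ≈ 14 at seed 42), which is the regime real Cd/Pb surveys show.

A command-line wrapper covering simulate / describe / build-graph / train
/ evaluate / ablate / importance / predict lives at `inst/cli/soilgnn`:

```sh
Rscript inst/cli/soilgnn simulate --seed 7 --out survey.csv
Rscript inst/cli/soilgnn build-graph --input survey.csv --d 10 --theta 5 --out graph.json
```

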