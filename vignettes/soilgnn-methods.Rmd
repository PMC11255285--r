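---
title: "Graph-based prediction of soil heavy metals: models and methods"
author: "soilgnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based prediction of soil heavy metals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilgnn)
```

## The problem

Cadmium and lead accumulate in surface soils around mining and industrial
areas, and their concentrations at unmonitored locations must be inferred
from a modest number of assayed sampling sites. Two properties of such
surveys defeat models that treat sites as independent draws: *spatial
dependence* (nearby sites share climate, parent material and pollution
pathways, so their metal burdens co-vary) and *spatial self-organisation*
(contamination forms coherent spatial patterns rather than i.i.d. noise).
`soilgnn` treats the survey as a graph — sites are nodes, plausible
spatial association is an edge — and fits a graph neural network that
propagates information along those edges while regressing the metal
concentration on fifteen site-level predictors (coordinates, pollution
type, crop, and eleven soil chemical/physical properties).

## Spatial graph construction

Distances between sites are great-circle distances from the haversine
formula on a sphere of radius 6371 km. The base graph connects every pair
of sites within a radius $d$ of each other (boundary inclusive). The
radius is exposed as a required-with-default parameter, `d = 10` km: at
the scale of a river-basin survey (sites clustered within zones a few km
across, zones tens of km apart) 10 km keeps the adjacency sparse while
giving almost every site in-zone neighbors, and the nested
cross-validation grid treats it as a tunable alongside the hidden width.

A radius graph is usually disconnected. Connectivity is decided by the
*reachable matrix*: iterate $A_i = \mathrm{sgn}((A + I)^i)$, the
elementwise sign of Boolean powers of the self-looped adjacency, until two
successive iterates agree. The fixpoint $M_G$ is the transitive closure;
its rank is the number of connected components and its distinct rows are
the component indicators. Components are then bridged by repeatedly adding
the globally shortest edge between nodes in different components — exactly
$C - 1$ repair edges, equivalent to a minimum spanning tree over
components, with ties broken by the lowest index pair so that the
construction is deterministic.

Edges are finally weighted with a Gaussian kernel,
$A_w(i,j) = \exp(-d_{ij}^2 / 2\theta^2)$ with $\theta = 5$ km. Repair
edges can be long enough that the kernel underflows; such weights are
floored at the smallest positive double so that a positive weight
corresponds exactly to an edge. Duplicate coordinates are legal and yield
weight-1 edges.

### Parent-material masking

Soils developed on different parent materials (limestone, sandy shale,
alluvium, diluvium, granite) carry different baseline metal loads, so a
second graph variant removes radius edges between sites of different
*environmental type* before the reachability/repair step: the adjacency is
multiplied elementwise by the same-type indicator matrix $M_{eit}$.
Masking never adds edges; repair edges are then the only cross-type edges.

The environmental type itself is a two-threshold decision table. The
organic index is the organic-matter content; the mineral index is the mean
of the dataset-standardised free/amorphous Fe and Mn fractions (a proxy,
since mineral content is not directly assayed). A site is organic-rich
when only the organic index exceeds its threshold, mineral-rich when only
the mineral index does, and mixed otherwise. No standard formula exists
for the index or its thresholds, so both
thresholds default to the 60th percentile of their index — splitting each
axis at a "clearly elevated" level — and the ambiguous both-above cell
resolves to mixed, symmetric with both-below. Both choices are exposed as
parameters.

Parent-material *zones* are found with density clustering (DBSCAN) on
great-circle distances, `eps_km = 15` and `min_samples = 4` by default:
a zone should be a contiguous cluster denser than the inter-zone spacing,
and four points within 15 km is a deliberately permissive core rule for
surveys of ~150 sites. Noise sites keep the label -1 and act as singleton
zones downstream. Whether clustering runs on coordinates alone or within
each parent-material class is a flag (`stratify_by_material`); coordinates
alone is the default since the material label is optional.

For monitoring campaigns whose site positions change over time, the masked
builder is applied independently per position snapshot, producing a
sequence of weighted adjacencies. Position forecasting itself is out of
scope; snapshots are supplied externally.

## The regressor

Features are encoded with train-only statistics: continuous predictors are
standardised by training-fold mean and sd (sd floored at $10^{-8}$ for
constant columns), `pollution_type` and `crop` are one-hot encoded over
training levels, and unseen levels at transform time map to an all-zero
block with a warning. Targets are likewise standardised on the training
fold and de-standardised for reporting, so metrics are in mg/kg.

**Multi-scale graph convolution.** Three parallel branches use the
symmetrically normalised propagation operators
$S_k = D_k^{-1/2}(A_w + I)^k D_k^{-1/2}$, $k = 1, 2, 3$, where $D_k$
holds the row sums of the $k$-th power. One-, two- and three-hop
receptive fields capture local, medium and broad spatial structure. Each
power is normalised by its own degree matrix — the degree matrix for the
higher powers is otherwise ambiguous — which keeps every operator
symmetric with spectral radius at most one. The branch outputs
$S_k H^{(0)} W^{(k)}$ are concatenated ("merged into one feature map";
a sum-merge is available behind a switch) and passed through a ReLU. The
weighted adjacency, not the binary one, feeds the operators: the kernel
weights exist precisely to grade neighbor influence by distance.

**Attention aggregation.** On top of the merged features, a graph
attention layer scores each neighbor pair
$e_{ij} = \mathrm{LeakyReLU}(a^\top [W h_i \,\|\, W h_j])$ with negative
slope 0.2 (the usual attention convention), normalises scores with a row
softmax over the self-inclusive neighborhood $\tilde N(i) = N(i) \cup
\{i\}$ — the self-loop keeps isolated and repair-attached nodes
well-defined — and aggregates $h_i' = \sum_j \alpha_{ij} W h_j$. Every
attention row sums to one by construction. A linear head maps the
aggregated features to the scalar prediction. One model is fitted per
metal.

**Ablation flags.** `use_msgcn` and `use_agnn` switch either stage off
(the remaining stage then reads the raw encoded features or feeds the
head directly); disabling both is a configuration error.

**Training.** Squared-error loss (matching the RMSE/R² evaluation), Adam
with learning rate 0.001, 100 epochs, batch size 8: each step runs a
full-graph forward pass and restricts the loss to the shuffled batch of
training nodes — graphs of a few hundred nodes make full-graph
propagation trivial, so "batch" governs only the loss mask and update
frequency. All randomness (initialisation, shuffling) flows from the
config seed; with single-threaded BLAS two runs are bit-identical.
Gradients are computed analytically (the test suite checks them against
central finite differences).

**Capacity defaults.** Hidden width 8 per branch and attention width 8,
one attention layer. These are deliberately small: with ~120 training
nodes and ~24 encoded features, wider models (16–32) drive the training
error down by fitting spurious feature directions and generalise worse;
width 8 was selected by validating capacity against synthetic surveys at
the target scale. The nested cross-validation helper exposes a grid
(default hidden width {32, 64} × radius {5, 10, 20} km) for data-driven
selection when the survey warrants it.

**Checkpointing** uses R native serialisation (`saveRDS`) — a single
file whose reload reproduces predictions bit-for-bit.

## Evaluation protocol

`regression_metrics` reports MAE, RMSE and $R^2 = 1 - \sum(O_i - P_i)^2 /
\sum(O_i - \bar O)^2$. A published variant of the $R^2$ numerator,
$\sum(P_i - \bar O)^2$, circulates in the application literature; it is
treated as a typographical slip of the standard form but remains available
behind `r2_form = "printed"` for comparison. MAE never exceeds RMSE; zero
observation variance flags $R^2$ undefined rather than erroring.

Two protocols wrap the model. *Repeated random splits*: 80/20 node splits
(the split fraction is a convention choice), encoder and model fitted on training nodes
only, metrics on held-out nodes, aggregated as mean ± sd; the graph is
built once over all sites, which leaks only positions, never targets.
*Nested cross-validation*: 10 outer folds for assessment, 3 inner folds
for hyperparameter selection by mean inner RMSE, winner refit per outer
fold, metrics pooled. Ablation runs share one master seed across arms so
per-split records are paired. Feature importance is permutation
importance on evaluation nodes — the attribution method behind published
normalised weights is typically unnamed; permutation importance is chosen
because it applies to any fitted model and yields non-negative weights
that normalise to one. A categorical variable is permuted before
encoding, so its one-hot block moves jointly, and the graph is held
fixed: the score measures the feature pathway, not graph rewiring.
Prediction at new locations builds a joint graph over training and new
sites with the same rules and returns predictions for the new sites only.

## The synthetic generator

`simulate_survey` emulates the statistical structure the method assumes,
not any particular survey's marginals: 142 sites by default, in five
parent-material zones of 18/36/42/22/24 sites inside a 2°×2° box around
23.5° N 111° E (a river-basin scale); a zero-mean Gaussian latent field
with exponential covariance $\sigma_s^2 \exp(-d_{ij}/r)$ (exponential
rather than squared-exponential — geochemical surfaces are rough at short
range; dense Cholesky with $10^{-8}$ jitter); covariates built as
zone-level baselines plus site noise inside plausible survey ranges;
pollution types assigned zone-dominantly with 20% within-zone mixing, so
pollution type is informative without aliasing zone; and log-scale targets
$\beta^\top z(\text{covariates}) + \text{pollution} + \text{crop} +
\text{field} + \varepsilon$, exponentiated by default so concentrations
are right-skewed with outliers, as real Cd/Pb distributions are. The
truth object retains every latent component, and the emitted target
reproduces noiseless-plus-noise exactly under the seed.

What the generator does *not* emulate: assay error structure, censoring at
detection limits, preferential sampling near suspected hotspots, and
covariate collinearity beyond shared zone structure. Tests passing on
synthetic surveys therefore show the pipeline recovers the structure it
models, not that real surveys satisfy that structure.

The *recovery experiment* compares the spatial model against a
covariate-only baseline — the same architecture and training loop on a
self-only graph (no edges), so the comparison isolates the graph — under
paired splits across seeds. Its generator conditions put most target
variance in the spatial field ($\sigma_s^2 = 1$ vs noise sd 0.1, range
equal to the graph radius, n = 150) and use a Gaussian link: $R^2$ on a
heavy-tailed mg/kg scale is dominated by a handful of tail sites and
would measure tail luck rather than spatial-structure recovery.
Intercepts sit far above the total variation so Gaussian concentrations
stay positive.

## Numerical and edge-case choices

- Kurtosis is reported in both conventions (raw, normal = 3; excess,
  normal = 0) with a flag recording which populates the headline field,
  because published survey tables rarely state the convention.
- The coefficient of variation is kept as a ratio and as percent, with
  nothing silently rescaled: published CV values are sometimes printed
  with a percent sign while plainly being ratios.
- $\Delta\log K$ uses base-10 logarithms, the absorbance convention, and
  SUVA254 converts mg/L DOC input to g/L so the output unit is
  L g$^{-1}$ cm$^{-1}$. Zero denominators flag the affected index as
  undefined instead of erroring.
- Reachability accepts reflexive input (self-loops cannot change
  components); non-symmetric input is a contract error.
- Degenerate splits (fewer than two test nodes) are redrawn and logged;
  constant training targets fall back to unit target scale.
- Non-finite training loss aborts with the epoch and batch named.

## Known limitations

- The attention score depends on the neighbor only —
  $a_1^\top P_i$ is constant within a softmax row and cancels — so the
  attention stage cannot learn to gate toward the node itself. Stacked
  on the convolution stage this makes the full model a twice-smoothed
  estimator; when a smooth latent field dominates and training sets are
  small, the attention-only ablation can match or slightly exceed the
  full model on held-out $R^2$. The acceptance suite reports this
  comparison honestly rather than asserting the full model's dominance
  into existence.
- $O(n^2)$ dense matrices throughout: intended for surveys of at most a
  few thousand sites, not rasters.
- Test-suite problem sizes are scaled to the method (surveys of 25–150
  sites, 3–5 repeats, up to ~150 epochs), which keeps the full suite in
  the minutes range while exercising every code path at the survey scale
  the method targets.
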