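---
title: "Mapping the system of sedentary-behaviour determinants with Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the system of sedentary-behaviour determinants with Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sedentary behaviour (SB) — waking activities in a sitting or reclining
posture with low energy expenditure — is shaped by an interdependent web
of individual, social, environmental and economic factors. Classical
regression treats determinants one at a time; `sosbn` instead models the
joint dependence structure of ~30 categorical survey factors with a
discrete Bayesian network (BN), then summarises the learned graph with
statistics that rank factors by their position relative to SB. The
variable roster follows the SOS-framework ("Systems of Sedentary
Behaviours"), which groups determinants into six clusters: psychology
and behaviour, institutional and home settings, physical health and
wellbeing, built and natural environment, social and cultural context,
and politics and economics.

The package is a complete, testable re-implementation of this analysis
pipeline exercised on synthetic Eurobarometer-like data. The original
survey microdata is not redistributable, so every stage is validated on
data simulated from a known ground-truth network — the point of the
synthetic-data module is that recovery of a *known* truth is checkable,
which no real-data analysis can offer.

## The model

A discrete BN over variables $X_1,\dots,X_p$ factorises the joint as
$P(x_1,\dots,x_p)=\prod_v P(x_v \mid \mathrm{pa}(v))$ with respect to a
DAG. Structure is learned with a hybrid algorithm:

1. **Restrict** (PC-stable skeleton): starting from the complete
   undirected graph, the edge $x\!-\!y$ is removed as soon as some
   conditioning set $S$ (drawn from the current neighbourhoods, sizes
   $0..\texttt{max\_sepset}$) makes $x \perp y \mid S$ by the
   $G^2$ test, $G^2 = 2\sum O \log(O/E)$, referred to a $\chi^2$ with
   degrees of freedom $(|x|-1)(|y|-1)\prod_{z\in S}|z|$, adjusted
   downward for unpopulated configurations. Neighbour sets are frozen
   per size level, which makes the result independent of variable
   ordering.
2. **Maximize** (hill climbing): greedy single-arc additions (only
   within the skeleton), deletions and reversals under the BIC score
   $\sum_v \big[\log L_v - \tfrac{\log n}{2}(|x_v|-1)\prod_{p\in
   \mathrm{pa}(v)}|p|\big]$. Moves are scanned in lexicographic
   (source, target, move-type) order and the first strict improvement
   is accepted, so the search is fully deterministic.

The survey analysis this mirrors cited a hybrid
constraint-plus-score method but its technical annex is not available;
the $G^2$/BIC/$\alpha=0.05$/max-sepset-2 defaults are the standard
discrete choices for that algorithm family and all four are exposed as
configuration knobs.

**Stability.** The dataset is resampled with replacement
`replicates` times (default 1,000, matching the survey analysis; desk
tests use 50–100 and say so), a network is learned per replicate, and
the *stability* of an edge is the fraction of replicates containing it
in either orientation. Edges with stability ≥ 40% form the averaged
network, classed *strong* (≥ 70%) or *weak* (40–70%). The 40% threshold
is deliberately liberal — the original analysis chose it to surface
more candidate associations — and results are presented undirected, to
avoid causal over-reading of arc directions.

**Statistics.** On the averaged network:

* *denseness*: $100\,m/\binom{p}{2}$, realised edges as a percentage of
  possible pairs;
* *distance to SB*: unweighted shortest-path edge count to the sitting
  node; unreachable nodes are "not connected";
* *cluster mean distance*: arithmetic mean of the finite distances of a
  cluster's nodes ("N.A." when no node of the cluster connects);
* *weighted betweenness*: on the subgraph of nodes connected to SB,
  with traversal cost $1/\text{stability}$, normalised by
  $(m-1)(m-2)/2$ pairs.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | CI-test significance level (restrict phase) |
| `max_sepset` | 2 | largest conditioning-set size tried |
| `score` | `"bic"` | network score (maximize phase) |
| `replicates` | 1000 | bootstrap replicates per stratum |
| `threshold` / `strong` | 0.40 / 0.70 | stability inclusion / class boundary |
| `include_pa` | `FALSE` | keep physical activity (sensitivity mode) |
| `effect_strength` | 2 | generator CPT sharpness (Dirichlet $1/\text{es}$) |

Physical activity is excluded from the default analysis because sitting
time and PA are strongly collinear and would dominate the learned
graph; the sensitivity mode (`include_pa = TRUE`) restores it.

## What the generator emulates — and what it does not

`build_ground_truth()` + `sample_dataset()` produce categorical data
from a known sparse DAG with the survey's variable roster: 31 SOS
factors plus sex and age group (33 variables; the overall network
analyses 32 nodes after dropping PA, the stratum networks 30). Macro
(regional) variables are drawn once per simulated region and copied to
its members; macro nodes may only have macro parents, so regional
constancy is preserved by construction. Sex and age group are exogenous
roots whose marginals are fixed to the published stratum shares (52.4%
female; age bands 9.9/29.8/36.5/23.8%), so the eight sex×age strata
have realistic sizes. All other CPT rows are Dirichlet($1/\text{
effect\_strength}$) draws: `effect_strength = 2` (rows ~ Dirichlet(0.5))
gives dependence that is detectable at survey sample sizes without
being deterministic — chosen once as a realistic middle ground, not
calibrated to any test.

`as_raw_survey()` expands the categorical sample into raw
Eurobarometer-shaped fields (IPAQ sitting codes, MPA/VPA minutes,
Likert items, the 18-category occupation item, ISO country codes,
regional numeric covariates …) by drawing uniformly inside each
category's band, so the operationalisation layer can be exercised end
to end; `apply_recodes()` inverts it exactly for every variable except
the two regional tertile factors (GDP, healthcare provision), whose
empirical cutpoints depend on the realised region mix.

What the generator does **not** emulate: real Eurobarometer marginals
and inter-item response patterns, "don't know/refusal" response styles
(all non-response is treated as missing), survey weights, and
informative missingness — the missingness module is missing-at-random
by construction (a logistic function of sex and age only, both always
observed). A green recovery test therefore establishes that the
pipeline recovers a known truth under clean MAR categorical data, not
that it would recover the (unknown) generating process of the real
survey.

## Numerical and convention choices

* **PA precedence.** The four printed activity classes overlap as
  quoted ("sufficiently" contains "highly"); they are evaluated
  highly → sufficiently → low → inactive, with *inactive* requiring
  MPA = VPA = 0. This is the only order that makes the four rules a
  partition.
* **Boundaries.** Climate bands use closed middle intervals
  ([10, 15] °C; [0.2, 2] mm/day); tertile boundary ties go to the lower
  tertile; "above average" is strict (ties map to 0). Deterministic
  conventions where the source is silent.
* **Still-studying respondents** have no stop-of-education age; their
  education band is taken from their current age (a lower bound on the
  eventual stop age), or set missing if age is unavailable.
* **Municipal support** is asked as a negative statement; agreement
  means *low* support.
* **df adjustment.** Sparse contingency tables reduce the $G^2$
  degrees of freedom per unpopulated configuration; a test with df = 0
  is reported as uninformative (p = 1) and never removes an edge nor
  counts as significant.
* **Betweenness weighting.** The source says stability-weighted without
  a formula; cost $1/\text{strength}$ is the standard
  strength-to-distance conversion and the default, with
  $1-\text{strength}$ available (`weighting = "complement"`).
  Normalisation by $(m-1)(m-2)/2$ makes values comparable across strata
  of different connectivity.
* **Hill-climbing ties.** First-improvement in lexicographic order plus
  an acceptance epsilon of 1e-8 gives bit-reproducible searches; the
  score trace is strictly increasing by construction.
* **Seeds.** Every replicate and stratum derives its own substream from
  the master seed, so results are independent of scheduling and
  byte-identical across runs and platforms.

## Worked example

```{r, eval = FALSE}
library(sosbn)
truth <- default_ground_truth(seed = 1)   # 10 nodes, 12 known edges
d     <- sample_dataset(truth, 5000, seed = 2)
st    <- bootstrap_networks(d, replicates = 100, seed = 3)
net   <- average_network(st, threshold = 0.40)
network_stats(net, attr(d, "schema"), target = "sitting")
```

At survey scale, `run_full_analysis()` drives the same steps for the
overall sample and each sex×age stratum and `export_reports()` writes
GraphML/DOT graphs, an edge-stability CSV per stratum, a summary table
(one column per stratum, with literal `"N.A."` for disconnected
clusters) and a JSON manifest.

## Known limitations

* Structure learning assumes complete cases (the analysis this mirrors
  excluded any record with a missing value); no imputation is offered.
* Ordered factors are treated as nominal in tests and scores; no
  ordinal-specific CI test is implemented.
* The PC-stable phase bounds conditioning sets at `max_sepset`
  (default 2); separating sets that require more conditioning variables
  leave extra skeleton edges, which the score phase usually, but not
  provably, prunes.
* Betweenness on near-tied shortest paths depends on floating-point
  comparisons; with continuous random stabilities ties have probability
  zero, but hand-crafted equal-cost paths may count differently than an
  exact rational enumeration.
* No causal interpretation of arc directions is supported; every
  reported graph is undirected by design.
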