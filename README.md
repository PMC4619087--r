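# commdyn — dynamic community analysis of fission-fusion societies

`commdyn` infers *dynamic communities* from time-stamped group sightings of
animals ("gambit of the group" association data) and compares societies
through the metrics of those communities. It is aimed at behavioral
ecologists with repeated-survey data — one row per (day, individual,
group) — who want more than an aggregated static network: which latent
communities the observed groups manifest, how long they persist, who
switches, who visits, and which of those dynamics separate species, sexes
or reproductive classes.

## The model

Every group at every time step and every individual at every step of its
observation window is assigned a community color. Relative to its color an
individual can **switch** (color change between consecutive steps, cost
α), **visit** (observed in a group of another color, cost β) or be
**absent** (unobserved while its community has a group present, cost γ).
The inference finds a coloring that (approximately) minimizes

    α · #switches + β · #visits + γ · #absences

by: linking groups at consecutive steps with Jaccard-overlap weights;
tracking them with per-step-pair maximum-weight bipartite matchings; giving
matched chains persistent colors (with a chain-merge refinement that lets a
community reclaim its color across sighting gaps when that lowers the
cost); and solving each individual's color sequence exactly by dynamic
programming. Equal costs (1, 1, 1) are the primary setting; only relative
values matter. The exact problem is NP-complete, so the package ships an
exhaustive small-instance oracle (`brute_force_oracle()`) against which the
heuristic is certified in the test suite.

A planted-truth generator (`generate()`, with `preset()`s sized like the
two field populations: 27 individuals × 44 daily samplings and 29 × 82)
implements the matching probabilistic membership model — per-step switching
and visiting probabilities below 0.5, imperfect detection, single-step
group fusions — so the whole pipeline is exercised end-to-end with known
ground truth. Static (density, paths, clustering, Louvain communities) and
temporal (time-respecting reachability, earliest-arrival latency) network
summaries, Table-style group/community/individual metrics, and a
statistical stage (standardized PCA on seven individual metrics, Welch
t-tests on component scores, Fisher exact test on ever-switching, radial
SVM under repeated stratified holdout) round out the analysis.

## Worked example

```r
library(commdyn)

g <- generate(preset("grevys-like", seed = 1))   # 27 ind., 44 steps
s <- infer(g$timeline, cost_settings(1, 1, 1))
s
#> <dynamic_communities> 6 communities, total cost 315

recovery_score(g$truth, s)
#> [1] 0.9638593

im <- individual_metrics(s)
round(colMeans(im[, c("community_size", "community_span",
                      "peer_coordination", "switching_cost")]), 3)
#>    community_size    community_span peer_coordination    switching_cost
#>             6.624            34.462             0.668             0.062
```

Six communities explain 44 days of sightings at a cost of 315 events; the
inferred colors agree with the planted truth for 96% of the per-day
individual pairs. The onager-like preset, by contrast, yields 167 mostly
singleton communities (mean size 1.39, peer coordination 0.28, switching
0.17) — the qualitative species contrast the dynamic analysis is designed
to expose, which the aggregated static networks largely hide.

The `analysis/` directory holds the full workflow as numbered scripts, run
from the repository root after installing the package:

```sh
Rscript analysis/01_simulate.R           # simulate both societies
Rscript analysis/02_network_summaries.R  # static + temporal measures
Rscript analysis/03_infer_communities.R  # dynamic community inference
Rscript analysis/04_community_metrics.R  # group/community/individual metrics
Rscript analysis/05_feature_analysis.R   # PCA, t-tests, Fisher, SVM
Rscript analysis/06_cost_sweep.R         # cost-sensitivity sweep
```

Each script narrates what it finds and writes its tables under `results/`.

## Methods

See `vignettes/dynamic-communities.Rmd` for the model, the algorithm and
its tie-breaking/refinement details, metric conventions, the generator's
assumptions, and known limitations.
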