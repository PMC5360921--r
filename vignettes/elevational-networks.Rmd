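---
title: "Elevational change in ant-plant networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elevational change in ant-plant networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elevnet)
```

## The scientific problem

Obligate ant-plant mutualisms — myrmecophyte trees housing single ant
colonies in domatia — form quantitative bipartite networks: a count matrix
$a_{ij}$ of how many individuals of plant species $i$ are occupied by ant
species $j$. Along a tropical elevational gradient both partners thin out,
and the central inferential question is whether the network *reorganizes*
with elevation or merely *shrinks*: a smaller sample from the same
community already has higher connectance and lower apparent specialization,
purely as a sampling artifact. `elevnet` implements the full analysis that
separates these explanations: per-elevation networks and metrics,
rarefaction prediction bands that embody the "shrinkage only" null,
marginal-preserving Monte Carlo tests for specialization, and trend tests
along the gradient — together with a synthetic census generator so the whole
chain is testable end to end.

## Network metrics

All metrics operate on the pruned integer count matrix (no all-zero rows or
columns), with row totals $k_i$, column totals $d_j$ and grand total $m$.

* **Connectance** — realized fraction of possible links,
  $\#\{a_{ij}>0\}/(IJ)$. Kept binary, the standard convention even for
  count data.
* **Generality / vulnerability** — weighted effective partner counts.
  For ants (generality):
  $G = \sum_j \frac{d_j}{m} e^{H_j}$, with $H_j$ the Shannon entropy of
  column $j$'s proportions; vulnerability is the row analogue. $e^{H}$ is
  the effective (Hill-number) count of partners, so a species using one
  partner contributes 1 regardless of counts.
* **Specialization $H_2'$** — with $H_2 = -\sum p_{ij}\ln p_{ij}$ over
  positive cells ($p_{ij}=a_{ij}/m$),
  $H_2' = (H_{2max}-H_2)/(H_{2max}-H_{2min})$, where the extrema are taken
  over *non-negative integer matrices with the observed marginals*. 0 means
  partner use is as random as the marginals allow, 1 maximally specialized.
* **Modularity** — Barber's bipartite $Q = \frac{1}{m}\sum_{ij}(a_{ij} -
  k_i d_j/m)\,\delta(c_i, c_j)$, maximized over module assignments.

### Numerical choices for the $H_2$ extrema

The integer-constrained entropy extrema have no closed form. We search
deterministic fill strategies and polish locally:

* minimum: greedy descending-marginal filling, best-fit filling
  (preferring exact row/column matches) and subset-sum completion of the
  largest marginal;
* maximum: proportional allocation with largest-remainder rounding, and
  incremental unit allocation into the cell with the largest entropy gain;
* polish: marginal-preserving $2\times2$ swaps of $t$ units and, on small
  matrices, 3-cycle moves.

The multi-start search and the full polish run only in the small-matrix
regime (both sides $\le 4$ species and $m \le 20$) where they are cheap;
there the result matches exhaustive enumeration over all feasible integer
matrices on every marginal pair up to $3\times3$, $m\le12$ (verified in the
test suite). Larger matrices use the single greedy start with unit-swap
polish (about 12 ms at $10\times7$, $m=45$). If the heuristic ever fell
short of a true extremum, $H_2'$ is clamped to $[0,1]$. One consequence
worth knowing: because the feasible set is integer-constrained, $H_2'$ is
*not* exactly invariant to multiplying all counts by a constant — the
extrema shift slightly as the lattice refines — only asymptotically so.

### Modularity optimization

Barber's $Q$ is maximized by seeded label propagation with local search:
each restart initializes module labels (singletons first, random
assignments after), then repeatedly moves each species to the module (or a
fresh one) with the largest $Q$ gain until a sweep makes no move; the best
of `restarts` (default 20) is kept. The optimizer is deterministic after
`set.seed()` and, on networks of up to 8 species, provably attains the
exhaustive-partition maximum (property-tested over 100 random networks
against full Bell-number enumeration). Annealing-based optimizers for this
problem are stochastic with no bit-exact reference; a deterministic
optimizer that is oracle-exact on small instances was preferred.

## Null models

**Rarefaction bands.** The reference community pools all identified
interaction events from the two lowest transects (700 and 800 m, the
richest). For each elevation the pool is subsampled *without replacement*
down to that elevation's observed number of events, 1000 times, and the
2.5th/97.5th percentiles (linear-interpolation definition, R type 7) of
every metric form the 95% prediction band. An observed metric outside its
band changed more than abundance decline alone can explain. Replicates
where a metric is undefined (e.g. $H_2'$ on a single-species side) are
dropped from the percentiles and counted; bands with more than half the
replicates undefined are flagged unreliable — small high-elevation samples
genuinely carry little information. Percentiles rather than a normal
approximation because resampling distributions of these metrics are
noticeably skewed near their bounds.

**Specialization null.** $H_2'$ is defined relative to marginal totals, so
its null must hold them fixed: tables are drawn from the multivariate
hypergeometric distribution over integer matrices with exactly the observed
marginals (the classic two-way-table randomization, via `stats::r2dtable`,
i.e. Patefield's algorithm). The p-value uses the add-one estimator
$(1+\#\{H_{2,null}' \ge H_{2,obs}'\})/(N+1)$, one-tailed "greater" because
the biological question is whether partner use is *more structured* than
random; the estimator is never 0 and is exactly uniform under the null.
Degree-distribution and binary swap nulls answer different questions and
are deliberately out of scope.

## Trend tests

Following standard practice for short elevational series:

| metric | transformation | test |
|---|---|---|
| plant/ant richness | none | OLS, AIC-selected degree 1–2 |
| connectance | square root | OLS, AIC-selected degree 1–2 |
| generality | log | OLS, AIC-selected degree 1–2 |
| vulnerability, $H_2'$, modularity | none | Hoeffding's D, permutation |

Model choice uses $AIC = n\ln(RSS/n) + 2k$ with $k$ = degree + 2
(coefficients plus error variance); additive constants cancel in the
comparison, so this ranks identically to `stats::AIC` at fixed $n$.
Hoeffding's D uses the classical midrank form; its p-value comes from a
permutation null (add-one, one-tailed on large D) rather than the
asymptotic table — at $n = 8$–$10$ the asymptotic approximation is
unreliable, and the permutation null is self-contained and reproducible
under seed. Undefined metric values are dropped pairwise and the reported
$n$ is the number of pairs actually used.

## The synthetic census generator

No machine-readable field census accompanies the analysis this package
implements, so `sim_config()` + `simulate_census()` generate communities
with the statistical structure the analysis assumes:

* ten 100 m transects, 700–1600 m a.s.l.; 23 plant and 10 ant species;
* Gaussian elevational range kernels truncated at 3 SD — the truncation is
  essential: without it species never drop out and there is no
  compositional turnover, which the headline inference hinges on;
* expected tree counts = lognormal peak abundance × range kernel ×
  multiplicative decline (default 0.78 per 100 m), Poisson-sampled;
* each tree independently occupied (default probability 0.66, within the
  60–72% occupancy typical of common myrmecophyte hosts), and each
  occupied tree assigned *exactly one* ant — a snapshot census of
  single-colony occupancy, with no colony dynamics or within-plant
  succession;
* partner assignment by one categorical draw from the plant's affinity
  vector (exponential raw weights raised to the specialization exponent
  $\gamma$ and renormalized, computed on the log scale so extreme
  $\gamma$ concentrates cleanly), restricted to ants whose range covers
  the elevation; trees with no ant in range stay unoccupied;
* $\gamma$ may vary along the gradient; the default declines from 3 to
  0.5, emulating partner use growing less selective as the partner pool
  thins — with `turnover = FALSE` every species spans the whole gradient
  and only abundance declines, giving the "shrinkage only" landscape the
  rarefaction bands are calibrated against;
* the first ant species is a gradient-spanning generalist, mirroring the
  dominant core species real ant-plant communities show at their upper
  limits;
* 8% of occupied trees are relabelled "uncertain" (an ant was present but
  could not be collected), exercising the exclusion rule: uncertain trees
  count as occupied for occupancy rates but carry no species identity and
  are excluded from networks by default (both flag-controlled);
* heights (lognormal, capped at the 15 m understorey census ceiling) and
  DBH are schema fidelity only — nothing downstream uses them; per-tree
  leaf counts fall into four ordered damage categories (0%, <5%, 5–33%,
  >33% missing leaf area) via a cumulative-logit model whose latent scale
  shifts with elevation (default +0.15 per 100 m, damage increasing
  upslope). The herbivory index is the leaf-count-weighted mean of the
  arithmetic category midpoints (0, 2.5, 19, 66.5%), configurable.

Under the defaults a census holds roughly 150 trees per transect at 700 m
falling to a handful at 1600 m, plant richness ~16 falling to ~1, and about
60% of trees occupied — the order of magnitude of a real single-mountain
myrmecophyte census. Reproducibility is strict: every elevation consumes an
independent child stream of the config seed, so identical config + seed
gives a byte-identical table and adding an elevation does not perturb the
others.

What the generator does *not* emulate: spatial structure within transects,
honeydew/coccid energetics, observer error in species identification, and
interannual turnover. Passing tests therefore demonstrate that the
*analysis chain* recovers the structure the generator plants — abundance
decline alone staying inside rarefaction bands, turnover plus specialization
shifts escaping them — not that any particular mountain behaves this way.

## The pipeline

`run_analysis()` composes everything: per-elevation metrics, bands (with an
outside-band flag per metric × elevation), $H_2'$ Monte Carlo tests,
trend table, a sensitivity rerun excluding the topmost elevation with data
(small top samples can dominate short-series trends), occupancy and
herbivory summaries, and a census accounting table (records used,
unoccupied, uncertain-excluded) so nothing is dropped silently. All stages
draw from child streams of one seed. The exported functions are the
interface; `write_report()` dumps every table as tidy CSV.

```{r example, eval = FALSE}
report <- run_analysis(config = sim_config(seed = 1), seed = 1)
report
report$trends
```

## Problem sizes and limitations

The shipped defaults (1000 rarefaction replicates, 1000 nulls, 10000
permutations) match standard practice for these resampling procedures; the
test suite uses 50–200 replicates per case, which is ample for the
calibration properties it checks. Known limitations: the $H_2$ extrema
heuristic is oracle-exact only where enumeration is feasible (it is clamped
and flagged beyond); the modularity optimizer is heuristic on large
networks (as all such optimizers are); and single-transect-per-elevation
designs confound transect and elevation — the sensitivity rerun probes, but
cannot remove, that confounding.
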