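# elevnet

Analysis of how quantitative bipartite interaction networks change along an
elevational gradient, built around the kind of census an ecologist collects
on a tropical mountainside: every understorey myrmecophyte (ant-plant)
tree on a series of transects, each occupied by at most one resident ant
colony. The package asks the question such surveys raise: when
high-elevation networks look more connected and less specialized, is the
community genuinely *reorganizing*, or does a smaller network merely look
that way because fewer individuals were sampled?

## What it computes

For each elevation's plant x ant count matrix `a[i, j]` (row totals `k_i`,
column totals `d_j`, grand total `m`):

* **connectance** — realized fraction of possible links;
* **generality / vulnerability** — abundance-weighted effective partner
  counts, `sum_j (d_j / m) * exp(H_j)` with `H_j` the Shannon entropy of
  column j (and the row analogue);
* **H2'** — network specialization:
  `(H2max - H2) / (H2max - H2min)` where `H2 = -sum p_ij log p_ij` and the
  extrema range over integer matrices with the observed marginals
  (heuristic search, exhaustively verified on small matrices);
* **Barber modularity Q** — `(1/m) sum_ij (a_ij - k_i d_j / m)
  delta(c_i, c_j)`, maximized by seeded label propagation;
* **rarefaction prediction bands** — 95% percentile envelopes of every
  metric under repeated subsampling (without replacement) of a pooled
  low-elevation community down to each elevation's observed abundance:
  the "abundance decline only" null;
* **Monte Carlo H2' tests** — observed specialization against
  marginal-preserving (Patefield) null tables, add-one p-values;
* **elevational trends** — AIC-selected linear/quadratic OLS for richness,
  sqrt-transformed connectance and log-transformed generality; a
  from-scratch midrank Hoeffding's D with permutation p-values for
  vulnerability, H2' and modularity.

A synthetic community generator (`sim_config()`, `simulate_census()`)
emulates the census design — 10 transects at 700–1600 m, 23 plant and 10
ant species with truncated Gaussian elevational ranges, declining
abundance, one ant per occupied tree, ~8% unidentifiable occupants,
ordinal herbivory scores — so the full pipeline is testable without field
data. See `vignettes/elevational-networks.Rmd` for the models, defaults
and their rationale.

## Worked example

```r
library(elevnet)

report <- run_analysis(config = sim_config(seed = 1),
                       n_replicates = 200, n_null = 200, n_perm = 1000,
                       seed = 1)
report
#> elevational network analysis report
#>   census: 625 records, 448 occupied (43 uncertain)
#>   elevations with interactions: 10
#>   metric x elevation outside rarefaction band: 10 of 69
#>   elevations with H2' above random (p < 0.05): 5 of 9

print(subset(report$trends, select = -method), digits = 3)
#>           metric transformation degree statistic r_squared  p_value  n
#> 1 plant_richness           none      2   22.9540     0.868 8.42e-04 10
#> 2   ant_richness           none      2  118.7697     0.971 3.97e-06 10
#> 3    connectance           sqrt      2   15.5473     0.816 2.66e-03 10
#> 4     generality            log      1   12.4270     0.608 7.79e-03 10
#> 5  vulnerability           none     NA    0.3929        NA 8.99e-03 10
#> 6       h2_prime           none     NA    0.2063        NA 3.30e-02  9
#> 7   modularity_q           none     NA    0.0357        NA 2.53e-01 10
```

Reading it: richness of both sides falls steeply with elevation (r² ≈
0.87–0.97); connectance changes curvilinearly (sqrt scale, r² = 0.82);
vulnerability and partner-use specialization H2' show significant
elevational dependence (Hoeffding's D = 0.39 and 0.21, permutation
p < 0.05); and 10 of 69 metric x elevation observations fall outside their
rarefaction bands — change beyond what abundance decline alone produces.
Five elevations show H2' above the marginal-preserving null (p < 0.05). `report$metrics`, `report$bands`, `report$null_tests`,
`report$occupancy` and `report$herbivory` hold the per-elevation tables;
`write_report(report, "out/")` dumps them as CSV.

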