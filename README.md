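# phenetwork

Tools for building and interrogating phenome-wide disease networks.
`phenetwork` is written for researchers who hold (i) PheWAS summary
statistics — per-phenotype top-hit SNP associations — and (ii) a linked
cohort of dated first diagnoses, and who want to know which genetically
linked diseases actually co-occur in patients, and in what temporal order.

## What it computes

**The disease network.** Top-hit SNPs are merged into LD units (connected
components of SNP pairs with r² ≥ 0.8 within 500 kb on one chromosome).
Two diseases are linked when they share a unit; the link weight sums the
geometric means of the per-unit absolute effect sizes,

    beta_12 = sum_i sqrt(beta1_i * beta2_i),

so several shared loci at equal effect sizes make a stronger link.

**Comorbidity overlay.** Per disease pair the Matthews correlation
coefficient

    MCC_ij = (C_ij N - P_i P_j) / sqrt(P_i P_j (N - P_i)(N - P_j))

(the Pearson correlation of the two binary indicator vectors) measures
co-occurrence strength and a one-sided Fisher exact test measures
enrichment; links surviving Bonferroni control form the validated
sub-network. Label-shuffle null networks quantify whether the overlap
exceeds chance.

**Topology.** Louvain modules under weighted Newman modularity; a
degree-independent neighbourhood-homogeneity H-score per disease (scaled
so 1 means a single-category neighbourhood, 0 the most even attainable
split); category-pair Z-scores against category-shuffle nulls.

**Trajectories.** For eligible sub-network pairs, a per-event logistic
model `outcome ~ prior_A + age + sex` (events truncated at the first B)
followed by a binomial majority-ordering test yields a directed network
annotated with median inter-diagnosis intervals, mortality rates and sink
flags.

**Synthetic data.** `sim_config()` / `simulate_study()` generate summary
statistics, LD tables, metadata and cohorts with *planted* shared loci,
comorbidity relative risks and temporal orderings plus truth records, so
the whole pipeline is testable without restricted data.

## Worked example

```r
library(phenetwork)

cfg <- sim_config(
  n_diseases = 10, hierarchy_depth = 0, n_snps = 120, n_patients = 3000,
  planted_ld_blocks = list(
    list(n_snps = 3, max_span = 4e5, r2_range = c(0.85, 0.95))),
  planted_shared_pairs = list(
    list(a = "101", b = "102", n_shared = 3, beta_range = c(0.2, 0.6)),
    list(a = "103", b = "104", n_shared = 1, beta_range = c(0.2, 0.6))),
  planted_comorbidity = list(list(a = "101", b = "102", rr = 4),
                             list(a = "103", b = "104", rr = 4)),
  planted_orderings = list(list(a = "101", b = "102", p_first = 0.95,
                                median_years = 2, sdlog = 0.5)),
  seed = 7)
study <- simulate_study(cfg)

units <- build_ld_blocks(study$associations, study$ld)$units
net   <- build_phenet(study$associations, units, study$meta)
tidy(net)
#> # A tibble: 2 × 5
#>   code_a code_b n_shared beta_weight shared_units
#>   <chr>  <chr>     <int>       <dbl> <chr>
#> 1 101    102           3       1.24  block_1_1;rs0004;rs0005
#> 2 103    104           1       0.486 rs0006
```

Both planted genetic links are recovered: diseases 101 and 102 share
three units (one 3-SNP LD block plus two bare SNPs) with summed link
weight 1.24. Overlaying the cohort:

```r
stats <- comorbidity_stats(study$events, nrow(study$patients))
sub   <- extract_sub_phenet(net, stats)
sub
#> <sub_phenet> 4 diseases, 2 co-occurrence-validated links
#>   (m = 2 tested, threshold 0.025)

overlap_null_distribution(net, stats, n_reps = 200, seed = 7)
#> <null_distribution> significant_unordered_pairs: observed 2,
#>   null mean 0.77 (200 reps, seed 7), empirical p < 0.005
```

Both links also show Bonferroni-significant co-occurrence, more than the
label-shuffle null expects. The directed stage recovers the planted
ordering 101 → 102 with its ~2-year median gap:

```r
traj <- build_directed_network(sub, study$events, study$patients)
tidy(traj)
#> # A tibble: 1 × 9
#>   first second beta1  beta1_p     x     n  binom_p median_interval time_bin
#> 1 101   102     2.36 4.46e-30    69    74 9.17e-16            2.20        2
```

69 of 74 dual-diagnosed patients got 101 first; the prior-disease
coefficient is strongly positive after age/sex adjustment, and the median
2.2-year interval falls in time bin 2 (1–3 years).

H-scores work directly from neighbour category counts; a node of degree
13 with 12 neighbours in one category scores

```r
h_score(c(12, 1), n_categories = 17)$h_scaled
#> [1] 0.8461538
```

Exports: `write_edgelist()` (four TSV schemas), `export_graphml()`,
`write_study()`/`write_truth_yaml()` for simulated inputs, and
`autoplot()` methods for networks and null distributions.

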