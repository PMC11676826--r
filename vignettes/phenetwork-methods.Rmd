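---
title: "Disease networks from PheWAS summary statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease networks from PheWAS summary statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenetwork)
library(dplyr)
```

## Overview

`phenetwork` implements a pipeline for studying how genetically linked
diseases relate to observed comorbidity and to the temporal order in which
diseases appear in patients' health records. It has four analytical layers:

1. **Network construction** — diseases (hierarchical phenocodes) are linked
   when they share associated SNPs or LD blocks in PheWAS summary
   statistics, with link weights derived from effect sizes.
2. **Comorbidity overlay** — patient-level first-diagnosis records provide
   per-pair co-occurrence statistics (Matthews correlation coefficient,
   one-sided Fisher exact test, Bonferroni control), which select the
   sub-network of links validated by observed co-occurrence.
3. **Topology characterisation** — Louvain modules under weighted Newman
   modularity, degree-independent neighbourhood-homogeneity H-scores, and
   category-interaction Z-scores, each judged against label-permutation
   null models.
4. **Trajectory inference** — a two-step directed analysis: per-event
   logistic models adjusted for age and sex, then binomial
   majority-ordering tests, yielding a directed network annotated with
   median inter-diagnosis intervals and mortality rates.

A fifth, first-class component is the synthetic-data generator: it emulates
the summary-statistics and cohort inputs with *planted* genetic links,
comorbidity relative risks and temporal orderings, so that every downstream
stage can be scored against a known truth.

## Phenocodes

Phenocodes group ICD billing codes into phenotypes arranged in a
three-level hierarchy; a code's level is its number of decimal digits
(`"411"` level 0, `"411.2"` level 1, `"250.11"` level 2). A diagnosis with
a lower-level code implies diagnoses with all its truncation-ancestors at
the same date; `expand_hierarchy()` applies this rule, keeping the minimum
date per code. Codes are handled strictly as strings (`"250.10"` and
`"250.1"` are different codes) and each code carries its own category from
the metadata table — categories are not inherited along the hierarchy,
because real metadata occasionally disagrees across levels and the table is
the authority.

## Network construction

Summary statistics are filtered at `pval < 1e-6` and `maf >= 0.001`
(defaults chosen to admit as many strong associations as possible while the
downstream comorbidity filter screens doubtful links). Because each row is
a per-phenotype *top hit* within a window, two diseases may tag the same
locus through different SNPs. `build_ld_blocks()` therefore merges SNPs
into units: pairs with r² ≥ 0.8 within 500 kb on one chromosome are edges,
and units are the connected components (single linkage — a chain may span
more than 500 kb overall; the pairwise constraint, not the block span, is
what the r² computation justifies). One global unit partition is built,
rather than per-disease-pair partitions; this is an interpretive choice and
keeps "shared unit" well defined.

For a unit *i* shared by diseases 1 and 2, the per-disease effect size
$\tilde\beta_{1i}$ is $|\beta|$ for a bare SNP, or the sum of member-SNP
$|\beta|$ for a block. The link weight is the summed geometric mean

$$\beta_{12} = \sum_{i=1}^{n}\sqrt{\tilde\beta_{1i}\,\tilde\beta_{2i}},$$

so that links backed by several shared loci are stronger at equal effect
sizes. A block counts as one shared unit regardless of how many of its
members hit both diseases; multiplicity enters only through the summed
$\tilde\beta$. Isolated diseases are dropped from the network.

## Comorbidity statistics

With $N$ patients, $P_i$ of whom carry disease $i$ and $C_{ij}$ carrying
both $i$ and $j$, the co-occurrence strength is the Matthews correlation
coefficient

$$\mathrm{MCC}_{ij} =
  \frac{C_{ij}N - P_iP_j}{\sqrt{P_iP_j(N-P_i)(N-P_j)}},$$

identically the Pearson correlation of the two binary indicator vectors
(this identity is enforced in the test suite to 1e-12 against an explicit
indicator-vector oracle). Enrichment is tested with the one-sided upper
tail of the hypergeometric distribution (Fisher exact). In *unordered*
mode every 2-subset of a patient's disease set counts; in *ordered* mode
only consecutive pairs of the date-sorted sequence count, so a history
A, B, C, D contributes A→B, B→C, C→D. Same-date diagnoses carry no
temporal information: tied codes form no ordered pair between themselves
and are ordered lexicographically for adjacency to neighbours.

`extract_sub_phenet()` keeps the network links with
`fisher_p < alpha / m`, where `m` counts links actually tested — pairs with
undefined MCC (zero or full prevalence) are excluded from both testing and
`m`, and both numbers are reported. The sub-network's link weights switch
to the MCC.

## Permutation null models

All "larger than chance?" questions are answered against label-shuffle
nulls: `shuffle_node_labels()` permutes which disease sits at which node,
leaving topology and weights intact, so the degree sequence is preserved
exactly. The overlap analysis counts, per replicate, how many (relabeled)
links land on pairs whose pre-computed comorbidity is
Bonferroni-significant; `empirical_p()` is the fraction of null values
*strictly* larger than the observation (ties favour significance — a
deliberate, documented choice matching the strict wording of the counting
rule), reported as `"< 1/n_reps"` when zero. The test suite uses 10³
replicates and 10⁴ is a configuration choice away; per-replicate seeds are
spawned from one master seed so results are independent of execution
order.

## H-scores, Z-scores and modules

The raw homogeneity score of a node with degree $k$ and neighbour category
counts $k_j$ is $H^* = \sum_j (k_j/k)^2$. Its attainable minimum depends
on $k$, so scores are min–max scaled:

$$H = \frac{H^* - H^*_{\min}}{1 - H^*_{\min}},\qquad
  H^*_{\min} = \begin{cases}1/k, & k \le c\\
  \textstyle\sum_j (n_j/k)^2, & k > c,\end{cases}$$

with $n_j$ the most even integer split of $k$ neighbours among $c$
categories. Degree-1 nodes are naturally homogeneous and score 1. The two
worked examples — 0.85 for degree 13 with a 12/1 split and 0.13 for degree
11 with a 4/2/1/1/1/1/1 split — pin this scaling down and are asserted in
the tests. The number of categories defaults to those present in the
network under analysis and is configurable; both worked examples are
insensitive to the choice because their degrees are below either count.

Group-mean H-scores (overall, per module, per category) are compared with
nulls in which *only the category labels are shuffled without replacement*;
empirical p-values are Bonferroni-multiplied by the number of groups.
Category-pair link counts $x_{ij}$ are standardised as
$z_{ij} = (x_{ij}-\mu_{ij})/\sigma_{ij}$ against the same replicate stream
(one stream per seed is shared between the H-score and Z-score analyses,
so the two analyses are mutually consistent), with a two-sided normal test
at `0.05 / (number of category pairs including self-pairs)`; the pair
count is always computed, never hard-coded. Pairs with $\sigma = 0$ are
reported unscored.

Modules come from Louvain optimisation (via igraph) of the weighted Newman
modularity

$$Q = \frac{1}{2m}\sum_{ij}\Big[A_{ij} - \frac{k_ik_j}{2m}\Big]\,
      \delta(c_i,c_j),\qquad m = \tfrac12\sum_{ij}A_{ij}.$$

The package carries its own `graph_modularity()` evaluator, used both to
report a partition's `Q` (recomputed, never trusted from the optimiser)
and as the correctness oracle in tests, where it is checked against a
brute-force double-sum to 1e-12 and against exhaustive partition search on
small graphs.

## Directed trajectories

Only sub-network pairs that are not ancestor–descendant within one
phenocode family are eligible (a level-2 diagnosis implies its ancestors at
the same instant, so such orderings are vacuous). For a directed
hypothesis A→B, every patient contributes one row per first-diagnosis
event, date-sorted and truncated at the first B event inclusive:

$$\log\frac{P(Y_{ij}=B)}{1-P(Y_{ij}=B)} =
  \beta_0 + \beta_1\sum_{k<j} I(Y_{ik}=A) + \beta_2\,\mathrm{Age}_{ij}
  + \beta_3\,\mathrm{Sex}_i.$$

Same-date A events do not count as prior. Step 1 keeps directions with
$\beta_1 > 0$ significant at `alpha1 / n_fitted` (Wald by default,
likelihood-ratio by option; the denominator is the realised number of
successfully fitted models — degenerate fits are flagged inestimable with
a reason, not raised). Step 2 applies the one-sided binomial test on the
frequency $x/n$ of A-before-B among dual-diagnosed patients (ties
excluded from both counts) at `alpha2 /` (number of step-1 survivors), and
keeps only the majority direction, which also rules out 2-cycles by
construction. Median inter-event intervals use patients with the kept
ordering and follow-up over 2 years; the same follow-up filter is applied
to the whole stage by default (configurable), follow-up being the span
between a patient's first and last recorded events since registry coverage
dates are out of scope. Mortality per disease is the cause-of-death count
(a death attributes to a disease when the disease or any descendant code
is a recorded cause) divided by the disease's prevalence; deaths without
any prior clinical record still count, so rates above 1 are possible and
are logged rather than clamped.

## The synthetic generator

`sim_config()` fixes the study conditions; all generators are pure
functions of it. Defaults: a 1987-08-01–2017-06-30 observation window with
patients aged 25–75 at its start (an adult population registry), 17
disease categories, three-level phenocode families, baseline prevalence
8%, and the same association filters the readers apply. Planted structure:

* **Shared loci** — each planted disease pair receives its requested
  number of shared units; planted LD blocks (r² drawn in a configured
  range ≥ 0.8, members within 500 kb steps) are consumed before bare
  SNPs. Non-planted pairs share nothing unless decoys are requested.
* **Comorbidity** — conditional Bernoulli: draw A, then B with probability
  `min(1, RR · P(B))` given A. This reproduces exactly the 2×2 structure
  the MCC and Fisher test consume without a full hazard model; the price
  is a slightly inflated marginal for B, so prevalence-accuracy guarantees
  apply to diseases not conditioned on.
* **Orderings** — among dual-diagnosed patients, A precedes B with the
  configured probability and the gap is log-normal with configured median
  and spread, strictly positive so planted pairs never tie.
* **Deaths** — per-disease attribution probabilities, plus an optional
  probability of death *without* any clinical record, which is what makes
  mortality rates above 1 reachable.

What the generator does **not** emulate: realistic genome-wide LD maps,
genotypes, population structure, registry coverage gaps, seasonal or
calendar effects, and diagnosis-code noise. Passing recovery tests
therefore show that the pipeline's inference machinery is correct and
well-calibrated under its stated model, not that any particular real
cohort satisfies that model.

## Numerical and design notes

* **Sequence-truncation bias.** Under a completely null cohort with few
  diseases per patient, the per-event logistic model is *intrinsically*
  anti-conservative for $\beta_1$: sequences stop at the first B, so for
  patients carrying only A and B there is no possible
  (prior-A = 1, outcome = 0) row. The bias shrinks as the event universe
  densifies (real registries map ~1,000 codes) and is precisely the
  "trivial progression" phenomenon the covariate adjustment and the
  binomial second step are there to control — in the all-null pipeline
  runs the step-2 filter removes essentially all spurious arcs. The
  regression's own type-I calibration is therefore demonstrated on data
  generated from the logistic model itself, which is its actual null.
* **Ties.** Same-date diagnoses never contribute ordered pairs, never set
  prior-A, and are excluded from binomial counts — ties carry no temporal
  information.
* **Strict inequality** in empirical p-values makes ties favourable to
  significance; documented above.
* **Serialisation** writes numerics at 17 significant digits so edge-list
  round trips are bit-exact.
* **Test problem sizes.** The suite uses networks of 4–20 nodes for
  oracle equivalences, cohorts of 2,000–5,000 patients with 5–12 diseases
  for calibration and recovery (20 seeds), and 10³ permutation
  replicates; these sizes give stable pass/fail behaviour at desk scale
  while every algorithmic path matches an independent oracle.

## A worked run

```{r pipeline}
cfg <- sim_config(
  n_diseases = 10, hierarchy_depth = 0, n_snps = 120, n_patients = 3000,
  planted_ld_blocks = list(
    list(n_snps = 3, max_span = 4e5, r2_range = c(0.85, 0.95))),
  planted_shared_pairs = list(
    list(a = "101", b = "102", n_shared = 3, beta_range = c(0.2, 0.6)),
    list(a = "103", b = "104", n_shared = 1, beta_range = c(0.2, 0.6))),
  planted_comorbidity = list(
    list(a = "101", b = "102", rr = 4),
    list(a = "103", b = "104", rr = 4)),
  planted_orderings = list(
    list(a = "101", b = "102", p_first = 0.95, median_years = 2,
         sdlog = 0.5)),
  seed = 7)
study <- simulate_study(cfg)

units <- build_ld_blocks(study$associations, study$ld)$units
net <- build_phenet(study$associations, units, study$meta)
net
glance(net)

stats <- comorbidity_stats(study$events, nrow(study$patients))
sub <- extract_sub_phenet(net, stats)
sub

nulls <- overlap_null_distribution(net, stats, n_reps = 200, seed = 7)
nulls

hs <- node_h_scores(net)
head(hs)

traj <- build_directed_network(sub, study$events, study$patients)
traj
tidy(traj)
```

## Known limitations

* LD units come from a pluggable r² table; the package never computes r²
  from genotypes, and a real LD extract must be supplied for real data.
* The ICD-to-phenocode map is consumed, not curated.
* The trajectory stage models pairs, not longer paths, and is not a
  time-to-event analysis: intervals are summaries, not hazard estimates.
* Follow-up is approximated by the span of observed events; true registry
  coverage windows, if available, would be preferable.
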