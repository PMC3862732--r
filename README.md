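# marrownet

Paired bone-marrow/peripheral-blood metabolomics with relevance-network
signatures.

## The problem this package addresses

In pediatric acute lymphoblastic leukemia, the bone marrow (BM) at
diagnosis is packed with leukemic blasts; after 29 days of induction
therapy the same compartment is tumor-free. When BM extracellular fluid
and peripheral blood (PB) plasma are sampled from the *same* patient at
both time points, the per-patient difference `BM − PB` isolates what the
marrow niche — cancerous or cured — contributes to the metabolome, with
each patient serving as their own control.

Single-metabolite comparisons miss coordinated behaviour: at diagnosis the
strongest feature of the niche is not any one concentration but a *cluster
of highly correlated lipid-metabolism metabolites*, which disappears at
remission and is replaced by correlated amino acids. `marrownet`
implements the full chain needed to detect such network-level signatures
in small paired cohorts, plus a synthetic-cohort generator that encodes
the study design (10 patients, 30-metabolite panel at published
concentration scales, planted correlation blocks) so every stage is
testable without patient-level data.

## What is computed

* **Univariate** (`compartment_comparison`, `ratio_features`): per-metabolite
  two-sided Wilcoxon rank-sum tests of BM vs PB, Benjamini–Hochberg FDR
  with the `pFDR<5%` / `5%≤pFDR<10%` reporting tiers, mean and fold
  differences, and the five standard derived ratios.
* **Multilevel models** (`mpca`, `mplsda`, `permutation_validate`, `cv_roc`):
  PCA/PLS-DA on the within-subject part of the paired data,
  leave-one-subject-out cross-validation, label-swap permutation p, and
  Youden sensitivity/specificity.
* **Correlation census** (`correlation_matrix`, `threshold_counts`,
  `hca_order`): pairwise Pearson/Spearman correlations with p-values from
  `t = r√(n−2)/√(1−r²)`, counts of pairs above `|r| > 0.75/0.85/0.93`, and
  UPGMA clustering of correlation profiles under the city-block distance.
* **Relevance network** (`build_relevance_network`, `enrichment_test`,
  `aracne_prune`, `fdr_retain`, `connected_components`): edges over the
  `BM − PB` differences carrying the Gaussian-copula mutual information
  `MI = −½·ln(1 − r²)`, admitted at a BH cutoff (FDR < 50%), classified as
  lipid / amino / other by their endpoints; Mann–Whitney enrichment of a
  class's edge p-values; ARACNE pruning (in every triangle the weakest-MI
  edge is removed, mark-then-sweep); retention of the FDR < 1% edges; and
  component summaries (node/edge counts, mean R², p, MI).
* **Pipeline** (`run_pipeline`, `report`): one seeded, fully reproducible
  run writing every stage artifact, a JSON manifest, and a plain-text
  report.

## Worked example

```r
library(marrownet)

cfg    <- cohort_config(seed = 42)     # study-sized synthetic cohort
cohort <- generate_cohort(cfg)
cohort
#> Concentration table: 50 samples x 30 metabolites
#>       0  8 29
#>   BM 10  0 10
#>   PB 10 10 10

res <- compartment_comparison(cohort, day = 0)
head(res[, c("metabolite", "mean_diff", "fold", "p", "q", "tier")], 5)
#>     metabolite mean_diff fold        p       q    tier
#> 1         urea    2035.9 1.55 0.000288 0.00731 pFDR<5%
#> 2      glycine     170.1 1.53 0.000487 0.00731 pFDR<5%
#> 3 hypoxanthine      10.8 2.16 0.000782 0.00782 pFDR<5%
#> 4      lactate    1287.0 1.63 0.001851 0.01388 pFDR<5%
#> 5    glutamate     236.2 2.32 0.002331 0.01399 pFDR<5%
```

The mean differences are in µM (urea ≈ 2000 µM higher in marrow in this
replicate); `q` is the BH-adjusted p-value and `tier` the reporting band.
The day-0 network then shows the lipid signature:

```r
net <- build_relevance_network(paired_differences(cohort, 0),
                               cohort_annotation(cfg), day = 0)
net
#> Relevance network: 30 nodes, 97 edges
#>   edge classes: amino=4, lipid=45, other=48

enrichment_test(net, "lipid")
#> Enrichment (lipid vs rest): U = 92.0, one-sided p = 3.23e-15
#>   (smaller p-values: lipid; n = 45 vs 52)
```

All 45 lipid–lipid pairs were admitted and their correlation p-values are
collectively far smaller than the rest of the network's — the planted
cancer-state signature, recovered. Pruning indirect edges and keeping the
FDR < 1% core leaves a tight lipid component:

```r
pruned <- fdr_retain(aracne_prune(net))
component_summary(connected_components(pruned)[[1]])
#>   n_nodes n_edges mean_r2   mean_p mean_mi
#> 1       7       7   0.885 0.000591    5.26
```

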