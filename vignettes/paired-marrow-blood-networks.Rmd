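---
title: "Methods: paired marrow/blood metabolomics and relevance-network signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired marrow/blood metabolomics and relevance-network signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marrownet)
```

## The analysis problem

In pediatric acute lymphoblastic leukemia (ALL), the bone marrow (BM) at
diagnosis is almost completely occupied by leukemic blasts, while after a
29-day induction course the same compartment is tumor-free. Sampling BM
extracellular fluid and peripheral blood (PB) plasma from the *same*
patient, at diagnosis (day 0) and at remission (day 29), turns each patient
into their own control: the per-patient difference `BM − PB` isolates what
the marrow niche adds to, or removes from, the circulating metabolome.

`marrownet` implements the full analysis chain for such paired cohorts:

1. **Univariate**: per-metabolite compartment comparisons (two-sided
   Wilcoxon rank-sum), Benjamini–Hochberg FDR control with the 5%/10%
   reporting tiers, mean and fold differences, and five derived ratio
   features (glutamate/glutamine, aspartate/asparagine, choline/creatine,
   unsaturated/saturated fatty acids, glutamine + pyroglutamate).
2. **Multilevel multivariate**: mPCA and mPLS-DA on the within-subject part
   of the paired data, with leave-one-subject-out cross-validation,
   permutation validation, and ROC-based sensitivity/specificity.
3. **Correlation census and clustering**: pairwise Pearson correlations
   with p-values, counts of pairs above `|r| > 0.75/0.85/0.93`, and UPGMA
   clustering of correlation profiles under the city-block distance.
4. **Network**: a relevance network over the `BM − PB` differences whose
   edges carry Gaussian-copula mutual information and correlation
   p-values, FDR-gated edge admission, edge-class enrichment
   (Mann–Whitney), ARACNE pruning by the data processing inequality, FDR
   < 1% retention, and connected-component summaries.

Because per-patient concentrations from the motivating study were never
deposited, the package ships a synthetic-cohort generator whose defaults
encode the study conditions, so that every stage — and the package's
headline property, recovery of a *network-level* metabolic signature — is
testable end to end.

## The relevance-network model

For metabolites $i, j$ with paired-difference vectors across patients, the
edge statistics are

* Pearson correlation $r_{ij}$ with the two-sided p-value from
  $t = r\sqrt{n-2}/\sqrt{1-r^2}$ at the pair's own complete-observation
  count $n$;
* mutual information under a Gaussian copula,
  $\mathrm{MI} = -\tfrac12 \ln(1 - \rho^2)$ (nats), computed from the
  Spearman rank correlation $\rho$ at the relevance stage and from the
  Pearson $r$ at the ARACNE stage. Keeping the two estimators for the two
  stages preserves the behaviour of the original two-tool workflow this
  pipeline consolidates.

Only metabolites with at least five nonzero, non-missing values enter the
candidate set (`min_nonzero = 5`); with ten patients, a metabolite below
that floor carries almost no rank information. Edges are admitted when
their p-value passes the Benjamini–Hochberg step-up cutoff over all
candidate pairs at `fdr_admit = 0.5`. An FDR of 50% sounds permissive, but
it is the *screening* stage: on study-sized cohorts it corresponds to
p-cutoffs around 0.06–0.09, and the permissiveness is deliberate so that
the enrichment comparison sees a broad edge family rather than only the
extreme tail.

Each admitted edge is classified `lipid` if **both** endpoints are
lipid-metabolism metabolites, `amino` if both are amino acids (including
derivatives and analogues), and `other` otherwise — an "edge between
amino acids" must connect two of them; mixed pairs are not class evidence.
Class annotations follow the Human Metabolome Database vocabulary and are
supplied as a two-column table.

**Enrichment.** Whether one class's correlations are collectively stronger
is tested by a Mann–Whitney comparison of that class's edge p-values
against the rest of the network (one-sided, toward smaller p-values), or
against the same class in the other day's network (two-sided). The exact
null distribution of U is used whenever the pooled values are tie-free and
total at most 50; the common situation of 1–3 edges of a class against ~45
of another makes the normal approximation too coarse exactly where the
signal lives (with a single opposing edge the approximation cannot reach
p < 0.05 two-sided even for maximally extreme ranks, while the exact test
can). Class-wise p-value distributions can be visualised with
`edge_pdf()`, a Gaussian kernel density with mass reflected at both ends
of the unit interval so that no density falls at $p \le 0$ and the curve
integrates to 1; the bandwidth defaults to Silverman's rule.

**ARACNE.** For every triangle, the edge with the smallest MI is marked,
and all marks are removed in a single sweep computed on the original graph
(sequential removal would depend on traversal order). At the default
tolerance 0 an edge is marked when its MI is less than *or equal to* the
minimum of the other two, so tied weakest edges are all removed and the
output is provably triangle-free — the conservative resolution of a
tie-break the DPI rule itself leaves open.

**Retention.** The surviving edges form their own BH family and only edges
with $q \le$ `fdr_retain` (default 1%) are kept. The procedure's published
description ("removed edges corresponding to FDR < 1%") contradicts its
stated purpose of highlighting regions of higher-than-average correlation;
this package keeps the significant edges, and exposes the literal reading
as `fdr_retain(mode = "remove")` for anyone who wants it. Components with
more than three nodes are then summarised by node/edge counts and
edge-averaged $R^2$, p and MI.

## Multilevel models for paired samples

`multilevel_split()` decomposes a samples-by-features matrix into subject
means (between part) and deviations from the subject mean (within part);
the reconstruction is exact and each subject's within rows sum to zero.
mPCA is the SVD of the column-centered within matrix — adding any constant
vector to both of a subject's samples provably cannot change it. No
unit-variance scaling is applied by default (the spectra convention, where
scaling would inflate baseline noise); `scale = TRUE` is available.

mPLS-DA fits NIPALS PLS1 against a ±1 class code with sequential
deflation, reporting per-LV captured variance. Cross-validation is
leave-one-subject-out: both of a subject's samples are held out together,
and the held-out pair is centered on its own mean — which uses no label
information — before projection. Validation statistics:

* the permutation p-value compares the observed cross-validated margin
  `mean(y * yhat)` with the margins of models refitted under
  within-subject label swaps. Swap masks are drawn uniformly over
  *non-degenerate* subsets: swapping no subject reproduces the observed
  model, and swapping every subject merely inverts the ±1 code, which the
  sign-symmetric fit undoes, reproducing the observed statistic exactly.
  With those two masks excluded, perfectly separable data yield
  `p = 1/(n_perm + 1)`, the smallest value the `(1 + #{perm ≥ obs})`
  estimator can produce — and it can never be 0.
* sensitivity and specificity come from the Youden-optimal threshold on the
  cross-validated scores. Orientation is fixed by the class code: a model
  that ranks the classes backwards is reported as the poor classifier it
  is, never silently sign-flipped.

## Preprocessing

For spectra-style matrices the package provides probabilistic quotient
normalization (per-sample division by the median quotient against the
median spectrum or an explicit reference), fixed-width binning, and the
generalized log transform
$g(y) = \ln\big((y + \sqrt{y^2 + \lambda^2})/2\big)$.

Conventions chosen where the field has no single standard: bins are
half-open intervals $[a, a + w)$ anchored at the axis minimum and
aggregated by **sum**, which conserves integrated intensity (binning a
region and summing it are then interchangeable); exclusion intervals
(solvent and reference signals) are applied before binning; $\lambda$
defaults to the 5th percentile of the nonzero intensities, a scale-free
rule that keeps the transform close to $\ln$ for well-measured values
while damping the variance of near-zero ones. Spectral *alignment* is out
of scope — this package starts from quantified tables or already aligned
bins, not raw spectra.

## What the synthetic cohort emulates

`cohort_config()` defaults encode the study conditions: 10 patients; BM
sampled at days 0 and 29 and PB at days 0, 8 and 29 (50 samples); a
30-metabolite panel (10 lipid-metabolism, 10 amino-acid, 10 other) whose
means and BM−PB shifts reproduce the published compartment means where
those are printed (lactate, urea, glutamate, triacylglyceride, glycine,
glucose, cholesterol esters, glutamine, 3-hydroxybutyrate) and use
realistic plasma values elsewhere; 5% missing cells, completely at random.

Concentrations are log-normal. On the standardized log scale each value is
a sum of three independent pieces: a per-block latent factor, a
patient-day effect shared by the two compartments, and idiosyncratic
noise. For a block planted in the `BM_minus_PB` space the factor enters
the two compartments with opposite signs, with loading
$a^2 = r(1-w)/(2-r)$ so that member differences correlate at the target
$r$ given the within-patient share $w$; for a single-compartment block
$a^2 = r$. The default blocks *are* the signature under study: a lipid
block (r ≈ 0.9) in the day-0 differences — the cancer state — and an
amino-acid block at day 29 — remission. The within-patient share defaults
to $w = 0.3$; the study reports no BM/PB covariance, so it is a parameter,
and it cancels from the difference space in any case. Negative target
correlations are supported only for two-member blocks, since mutual
negative equicorrelation of $m > 2$ variables is infeasible.

What the generator does **not** emulate: spectral artefacts (peak shape,
chemical-shift drift, baseline), informative missingness (cells are
removed completely at random, whereas real non-detects are
concentration-dependent), inter-metabolite correlation beyond the planted
blocks, and longitudinal autocorrelation across days. Passing tests
therefore demonstrate that the machinery recovers structure *of the kind
assumed*, not that the model captures every property of clinical data.

The spectra-like proxy `generate_feature_matrix()` serves the multilevel
and preprocessing stages: two samples per subject, log-normal intensities
around a common base spectrum, a subject random effect, an optional
per-sample dilution factor (what PQN removes), and a class-difference
direction whose log-scale magnitude `class_effect` is 0 for exchangeable
pairs.

## Numerical choices and degenerate inputs

* Rank-sum tests use the exact distribution for tie-free samples up to a
  combined size of 20 (univariate stage) and the tie-corrected normal
  approximation otherwise; the exact branch is verified against a full
  enumeration oracle in the test suite.
* Correlations with $|r| \ge 1$ are clamped to $1 - 10^{-12}$ before the
  MI transform; pairs with fewer than 3 complete observations, and pairs
  involving a constant vector, are reported missing rather than invented.
* BH q-values are capped at 1; admission by the p-cutoff is identical to
  BH selection at the same level (asserted against a brute-force oracle).
* UPGMA ties follow `stats::hclust`; the dendrogram (cophenetic structure)
  is invariant to input order even where the printed leaf order is not.
* Degenerate inputs fail loudly: empty samples, all-zero PQN rows,
  $\lambda = 0$ with zero intensities, subjects with a single sample, a
  class code with zero data covariance, and empty enrichment groups are
  all errors, not silent repairs.

## Validation problem sizes

The shipped test suite works at deliberately small scales chosen to make
the oracles exhaustive: full-enumeration rank-sum checks at combined
sizes ≤ 10, ARACNE against a brute-force triple oracle on 1000 random
graphs of ≤ 8 nodes, BH against the step-up definition on 10⁴ random
vectors, and 200-replicate recovery/calibration studies at the study size
(10 patients, 30 metabolites). The signature-recovery property — lipid
enrichment at day 0 and amino-acid enrichment at day 29, each one-sided
p < 0.05 — holds in well over 90% of replicates under the default
conditions; on null cohorts (no planted blocks) the same tests reject at
no more than the nominal rate. The cross-day two-sided comparison of
lipid edges is structurally weaker: when the day-29 network contains no,
or a single, chance-admitted lipid edge, the comparison is undefined or
power-limited, which a user comparing sparse class groups across
networks should keep in mind.

## Known limitations

* The rank-sum test is applied to paired compartments as an *unpaired*
  test, following the original workflow; the paired signed-rank
  alternative is available via `stats::wilcox.test(paired = TRUE)` on the
  difference columns but is deliberately not the default.
* Spearman p-values reuse the t approximation; for n = 10 this is
  adequate for screening but not exact.
* Edge classes condition on an annotation map that is total by
  construction; misannotation propagates directly to enrichment.
* The FDR admission family is the post-filter candidate set; with very
  few candidates the BH cutoff is unstable, and an empty network (with a
  warning) is a legitimate outcome.
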