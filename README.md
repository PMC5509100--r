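# deltabind

Unsupervised detection of **differential transcription-factor binding**
from chromatin-accessibility footprint scores measured in two cell
conditions.

## The problem

Chromatin accessibility assays (DNase-seq, ATAC-seq) can predict where a
factor is bound in a single cell type, but asking where a factor is bound
in one condition *and not* in another is much harder: across a typical
pair of cell lines only a few hundred of every 100,000 candidate motif
sites are differentially bound (prevalence ~0.1–1.3%), so a random ranking
achieves an average precision of roughly the prevalence itself (~0.4%).
Naive rankings by the raw difference of footprint scores, or by the
difference in read counts near the motif, are dominated by the score
scale's distortions and by fluctuations at strongly bound sites.

`deltabind` addresses this by working entirely in **rank space** and
decomposing the differential-binding probability into two learned parts.
Let `R_irj` be the rank of the binding score of site `i` in condition
`j ∈ {K, G}` ("bound" and "unbound" condition) and replicate `r`, with
`R_ij` the per-condition mean rank and `R_i` the vector of all ranks.
The differential-binding probability is

```
P(A_i, B_i | R_i) = P(A_i | R_i) · P(B_i | A_i, R_i)
```

where `A_i` is the event that site `i` is bound in condition K and `B_i`
the event that it is significantly more weakly bound in condition G:

* **`P(A | R)` — reproducibility.** On probit-transformed replicate ranks
  `z = Φ⁻¹(r/(N+1))`, a two-cluster mixture in the IDR (irreproducible
  discovery rate) parameterization is fitted by EM: an irreproducible
  cluster fixed at the standard bivariate normal (correlation 0), and a
  reproducible cluster `N((μ,μ), σ²[[1,ρ],[ρ,1]])` with weight `π₁` —
  genuine binding yields high, correlated replicate scores. The cluster
  posterior is then calibrated against mean bound-condition rank by
  isotonic regression, giving a monotone `P(A | R_iK)` curve.
* **`P(B | A, R)` — conditional weakening.** Within overlapping windows of
  bound-condition mean rank, the rank difference `D_i = R_iK − R_iG` is
  modeled as a three-category Gaussian mixture — no significant difference
  (mean 0), significantly lower in G (mean `+δ`), significantly higher in
  G (mean `−δ`) — fitted by a weighted EM in which each site carries its
  reproducibility posterior as weight (soft conditioning on `A`). The
  posterior of the `+δ` category is `P(B | A, R)`.

Because only ranks enter the model, the caller is invariant to any
monotone transform of the raw scores and works with scores from any
footprinting method. Two replicates are required for the bound condition;
one or two for the unbound condition.

The package also implements: the construction of high-confidence
differential ChIP-seq ground truth from upstream peak-caller statistics
(agreement stopping rule at max-proportion/1.6, strict q-value/p-value
threshold filter, 20 bp motif-proximity matching); the two baseline
rankers (raw score difference, read-count difference); evaluation under
extreme class imbalance (average precision, AUROC, precision at fixed
recall, label-permutation p-values, contingency statistics, factor-class
comparison); and a seeded synthetic-data generator so that every stage is
testable without external data.

## Worked example

```r
library(deltabind)
library(dplyr)

sim        <- simulate_scores(sim_config(n_sites = 20000, seed = 1))
rank_table <- to_ranks(sim$scores)
repro      <- fit_reproducibility(rank_table)
repro
#> Reproducibility mixture (IDR-style two-cluster fit)
#>   pi1 = 0.1637  mu = 0.659  sigma2 = 1.170  rho = 0.922
#>   46 EM iterations, converged, log-likelihood -55235.42, n = 20000

diffmix <- fit_diff_mixture(rank_table, repro)
calls   <- call_differential(rank_table, repro, diffmix)

scored <- inner_join(calls, sim$labels, by = "site_id")
pr <- precision_recall(scored, deltabind_score, label)
pr
#> Precision-recall: AUPR (average precision) = 0.07597 over 66 positives / 19934 negatives (prevalence 0.0033)
precision_at_recall(pr, 0.10)
#> [1] 0.1086957
auroc(scored, deltabind_score, label)
#> [1] 0.9195
```

About 16% of sites form a reproducible high-rank cluster with strongly
correlated replicates (`rho = 0.92`); the product score then concentrates
the 66 planted differential sites near the top of 20,000 candidates —
AUPR 0.076 against a random baseline at the prevalence 0.0033, i.e. a
~23-fold enrichment, with precision 11% at 10% recall. `autoplot(pr)`
draws the PR curve; `tidy(repro)`, `glance(repro)` and `tidy(diffmix)`
expose the fitted parameters.

The packaged CTCF/SNP co-occurrence table (differential DNase signal
versus differential CTCF binding at motif SNPs) illustrates why read
imbalance alone is a poor predictor:

```r
contingency_stats(read_contingency(
  system.file("extdata", "ctcf_snp_contingency.tsv", package = "deltabind")
))
#>           statistic numerator denominator      value percent
#> 1               ppv       566        3079 0.18382592      18
#> 2               npv      8032        8276 0.97051716      97
#> 3  prevalence_event       810       11355 0.07133421       7
#> 4 prevalence_signal      3079       11355 0.27115808      27
```

Accessibility imbalance predicts differential binding with only 18%
precision, although its absence is strongly predictive of no change (97%).

## Command line

Each pipeline stage is a subcommand of the bundled script, pure with
respect to (inputs, options, seed); the exact options and package version
are written next to every output:

```sh
DB=$(Rscript -e 'cat(system.file("scripts", "deltabind.R", package = "deltabind"))')
Rscript $DB simulate  --n-sites 20000 --seed 1 --out sim
Rscript $DB rank      --scores sim/scores.tsv --out ranks.tsv
Rscript $DB fit-repro --ranks ranks.tsv --out repro.json
Rscript $DB fit-diff  --ranks ranks.tsv --repro repro.json --out diff.json
Rscript $DB call      --ranks ranks.tsv --repro repro.json --diff diff.json --out calls.tsv
Rscript $DB eval      --calls calls.tsv --labels sim/labels.tsv --out eval
```

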