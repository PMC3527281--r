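# mircombine

Combinatorial microRNA target scoring with expression-weighted ensembles.

## The problem

A 3'UTR usually carries predicted binding sites for many co-expressed
miRNAs, and individual target predictors (energy-based site finders,
seed-match counters, regression scorers) disagree notoriously about which
genes are functional targets. Two pieces of information reconcile them:
the *abundance* of each miRNA — a strong site of an unexpressed miRNA does
nothing — and the *combinatorial* accumulation of sites on one transcript.
`mircombine` is for transcriptomics researchers who have per-tool binding
site tables and a miRNA expression profile and want a single calibrated
probability that a gene is under miRNA control, plus a principled way to
rank 3'UTR SNPs by how badly they disrupt that control.

## The model

For a site of binding free energy `E_ijk` (kcal/mol, miRNA *i*, site *j*,
gene *k*), occupancy follows the Fermi-Dirac form

    p_ijk = 1 / (1 + exp((E_ijk − μ_i) / RT)),    μ_i = RT · ln [miR_i]

where the chemical potential `μ_i` rises with the miRNA's abundance: more
abundant miRNAs fill weaker sites. The per-gene **FD score** sums `p_ijk`
over all sites of all considered miRNAs. For predictors whose scores
`S_ik` are not energies, the **WSUM score** is the expression-weighted sum
`Σ_i w_i S_ik` with `w_i = [miR_i] / Σ_j [miR_j]`. The per-tool gene
scores form a gene × tool feature matrix that a linear SVM (features
z-scored, rank-normalized against the training distribution for
cross-dataset use) fuses into a Platt-calibrated targeting probability in
[0, 1]. The expression-blind baseline ("naive" combination, an unweighted
sum of oriented site scores) is built in for comparison throughout.

For a 3'UTR variant, the pipeline is rerun on the reference and
alternative sequence and SNP:miRNA pairs are ranked by
`ΔP = P_ref · (P_ref − P_alt)` (default; a plain difference is also
available), which focuses the ranking on high-confidence reference
targets.

## Worked example

Simulate a benchmark with planted occupancy ground truth, score the four
simulated predictors, fit the ensemble, and predict:

```r
library(mircombine)

cfg      <- sim_config(n_genes = 500, n_mirnas = 12, seed = 42)
truth    <- simulate_dataset(cfg)
tools    <- simulate_tool_scores(truth, cfg)
features <- build_feature_matrix(score_simulated_tools(tools, truth))

lab <- truth$labels
fit <- fit_ensemble(features[lab$gene_id, ], lab$label, seed = 42)
summary(fit)
#> Linear-SVM targeting ensemble
#>
#> Training set: 125 positives, 125 negatives (19 support vectors)
#> Regularization C = 1; seed = 42; normalization = rank
#>
#>      tool    weight    center        sd
#>  energy_a 1.8561290 1.8837472 1.4639855
#>  energy_b 2.0999360 1.9373126 1.5176733
#>   score_c 0.2036446 0.9611416 0.5328863
#>   score_d 0.3579924 0.6546503 0.4461754
#>
#> bias = 0.4712; calibration: p = plogis(3.409 * d +0.474)

prob <- predict(fit, features)        # calibrated P(target) per gene
roc_auc(prob[lab$gene_id], lab$label)
#> ROC: AUC = 0.9984 (125 positives, 125 negatives, 248 points)
```

The fitted weights say most of the signal sits in the two energy tools
(whose FD scores use expression directly), and the ensemble recovers the
planted targets almost perfectly on the labelled set. Calling
`top_fraction_targets(scores, q = 0.1)` on any per-tool score table
returns its top-decile target call (boundary ties included).

The same functions are scriptable from a shell through the thin CLI in
`exec/mircombine` (`simulate`, `score`, `train`, `predict`, `evaluate`,
`rank-snps`); every output file begins with `#` metadata lines and is
byte-reproducible given the same configuration and seed.

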