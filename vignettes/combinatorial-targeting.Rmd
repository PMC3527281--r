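---
title: "Expression-weighted combination of miRNA target predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-weighted combination of miRNA target predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircombine)
```

## The occupancy model and its assumptions

Each predicted binding site of miRNA $i$ on gene $k$'s 3'UTR is treated as
an independent two-state system: empty or occupied by the miRNA-loaded
silencing complex. At equilibrium, the occupancy of a site with binding
free energy $E_{ijk}$ (kcal/mol, negative for favourable binding) is the
Fermi-Dirac form

$$p_{ijk} = \frac{1}{1 + e^{(E_{ijk} - \mu_i)/RT}},
  \qquad \mu_i = RT \ln [\mathrm{miR}_i],$$

where the chemical potential $\mu_i$ encodes the miRNA's abundance. The
per-gene **FD score** is $\sum_i \sum_j p_{ijk}$, bounded by the site
count. The assumptions are deliberate simplifications: sites fill
independently (no cooperativity or steric competition), the miRNA pool is
not depleted by binding (no titration), and the predictor's site energy is
an adequate proxy for the true free energy. The model's virtue is what it
suppresses: a weak site of an unexpressed miRNA has $E \gg \mu$ and
contributes essentially nothing, while strong sites of abundant miRNAs
saturate at 1. That is also why the FD combination tends to sharpen the
consensus between energy-based predictors — their tool-specific weak
predictions are flattened, while the shared strong-site signal survives.

For predictors whose site scores are not energies, the **WSUM score**
weights each miRNA's summed site scores by its relative abundance
$w_i = [\mathrm{miR}_i] / \sum_j [\mathrm{miR}_j]$, computed within the
analyzed miRNA set (so global unit changes cancel). A binary detector
contributes expression-weighted site counts. The expression-blind
**naive** combination — an unweighted sum of oriented site scores — is
retained as the baseline everywhere.

## Parameters that matter

* `RT` (kcal/mol, default 0.6163 = $1.987\times10^{-3} \cdot 310.15$,
  i.e. 37&nbsp;°C). Sets the sharpness of the occupancy transition: a site
  moves from 25&nbsp;% to 75&nbsp;% occupancy over $2 RT \ln 3 \approx
  1.35$ kcal/mol.
* `expression_scale` (default 1 in `thermo_config()`). Abundances usually
  arrive in arbitrary units (read counts), while $\mu = RT\ln(\cdot)$
  needs an activity-like quantity; this single factor converts one to the
  other and shifts every $\mu$ additively by $RT\ln(\text{scale})$.
  Because only the position of $\mu$ *relative to the site energies*
  matters, the factor should be chosen so the occupancy transition spans
  the energy range of interest (see the generator defaults below).
* `cost` (SVM regularization, default 1) and `normalize`
  (default `"rank"`): the ensemble's two knobs. Rank normalization maps a
  new dataset's per-tool score distribution onto the training
  distribution via quantile matching (ties share average ranks), making
  the fitted weights portable across datasets and species; `"mean"`
  rescaling is available as a cruder alternative.
* Seed-match surrogate energies (`seed_match_spec()`): 8mer −1.0,
  7mer-m8/7mer-A1 −0.75, 6mer −0.5 "energy units", strict Watson–Crick,
  no G:U wobble. These are transparent stand-ins used when no external
  predictor supplies real energies (notably in the SNP workflow); users
  with real per-site energies should pass them via a site table instead.

## The ensemble

Per-tool gene scores are assembled into a dense gene × tool matrix
(missing gene/tool entries are 0, i.e. "no detected sites"), z-scored with
training statistics and fed to a linear-kernel SVM (`e1071`). The decision
axis is oriented toward the positive class, and a Platt-style sigmoid
fitted to seeded out-of-fold decision values maps decisions monotonically
into $[0,1]$. The fitted object serializes to versioned JSON
(`write_ensemble()`/`read_ensemble()`) with bitwise-identical predictions
after a round trip.

## Ranking 3'UTR variants

`snp_delta_score()` substitutes the alternative allele (after checking the
reference base — the cheapest guard against off-by-one coordinate errors;
positions are 0-based half-open everywhere), rescans both sequences for
seed sites, and rescores each miRNA. Two ranking modes are provided
because the appropriate functional form is genuinely open:
`plain` ($\Delta = P_{ref} - P_{alt}$, antisymmetric under allele swap)
and the default `weighted`
($\Delta = P_{ref}(P_{ref} - P_{alt})$), which up-weights disruptions of
high-confidence reference targets — the variant screening use case. The
mode is recorded in every output. Without a fitted ensemble, the per-miRNA
probability is $1 - \prod_j (1 - p_j)$, the chance that at least one site
is occupied under independence; with an ensemble, the scanned sites are
combined into per-tool features using the methods recorded in the model.
When no expression table is given, uniform levels are assumed and a
warning logged — rankings then reflect site strength only.

## The synthetic benchmark: what it emulates, and what it does not

`sim_config()` defaults define the study conditions used throughout the
tests:

* 2000 genes, 25 expressed miRNAs; Poisson(6) true sites per gene
  assigned uniformly to miRNAs; site energies $N(-8, 3)$ truncated at 0
  kcal/mol.
* Abundances log-normal (median 500, $\sigma_{\log} = 2$ — spanning
  roughly three orders of magnitude, as small-RNA read counts do),
  floored at 50 reads (the conventional threshold for calling a miRNA
  expressed).
* `expression_scale` $= 10^{-10}$, placing the chemical potentials
  ($\mu \in$ roughly $[-12, -5]$ kcal/mol across the abundance range) in
  the middle of the energy distribution. This is the regime in which
  expression genuinely matters: only sites of well-expressed miRNAs are
  appreciably occupied. Read counts are proportional to copy numbers, and
  cellular miRNA concentrations are sub-micromolar, so a small conversion
  factor is also the physically sensible order of magnitude.
* Labels: positives are the top quarter of genes by true occupancy, an
  equal number of negatives is drawn from the bottom quarter — a balanced
  design mirroring how positive/negative sets are built from
  immunoprecipitation data.
* Four observing "tools": two energy tools and two score tools (one
  binary, one continuous), each seeing the true sites with dropout 0.2
  and score noise (sd 1.5 kcal/mol), **plus** tool-specific spurious weak
  sites (Poisson(6) per gene, energies $N(-4,2)$ truncated at 0). The
  spurious sites are the essential ingredient for realism: real
  predictors report large numbers of weak, mutually inconsistent sites,
  which is why their naive top-decile overlap is poor. The FD combination
  suppresses exactly this tool-private noise.

What the generator does **not** emulate: sequence-level composition
(sites are abstract intervals except in the scanner tests), miRNA pool
competition and titration, conservation signal, UTR-length biases, and
correlated errors between tools. Passing the synthetic benchmarks
therefore demonstrates that the machinery recovers an expression-driven
planted signal under realistic noise — not that any particular biological
dataset will show the same margins.

## Numerical choices

* Occupancy is evaluated through `plogis((mu - E)/RT)`, stable for
  arbitrarily extreme arguments; $E = \pm\infty$ are accepted as limits.
* Quantiles (top-fraction calling, rank normalization) use R's type-7
  linear interpolation; top-fraction boundary ties are all included, so a
  10&nbsp;% call can return slightly more than 10&nbsp;% of genes.
* Rank normalization maps a single score to the reference median
  (an $n=1$ empirical quantile is undefined); single-gene predictions in
  the SNP pipeline therefore bypass renormalization and score on the
  training scale.
* ROC curves threshold only between distinct scores; the trapezoidal area
  equals the tie-aware pairwise probability
  $P(s_+ > s_-) + \tfrac12 P(\text{tie})$.
* Backward elimination removes the least significant slope while its
  $p > \alpha$ (default 0.05), interaction before main effects
  (marginality). With a numerically perfect fit ($R^2 > 1 - 10^{-12}$)
  t-statistics are noise, so a term is retained only if its contribution
  to the fitted values exceeds $10^{-8}$ of the response scale.
  Rank-deficient designs are flagged (`collinear`), aliased terms treated
  as removable.
* Platt calibration falls back to a unit-slope logistic link if the
  calibration sample is degenerate (e.g. constant decision values), so
  predicted probabilities are always defined and monotone.
* Two-sample KS and Wilcoxon tests in the decile analysis use the `stats`
  implementations (exact KS p-values where R provides them); deciles with
  fewer than 3 genes are flagged and their tests skipped.

## Problem sizes used by the test suite

The acceptance checks run 100 seeded replicates of the full pipeline at
the default 2000-gene scale, comparing 5-fold cross-validated ensemble
AUC between the expression-aware and naive combinations (cross-validation
rather than a single split, to estimate each replicate's held-out AUC
with low variance), 1000 null datasets for the decile-test calibration,
and 200 random instances against brute-force oracles for the occupancy
sum and the AUC. These sizes are the package's choices for a thorough yet
quick default run; the generator accepts larger populations unchanged.

## Known limitations

* The SNP pipeline's built-in scanner feeds the *same* site table to every
  ensemble tool; with a fitted model, per-tool information enters only
  through the recorded combination methods. Supplying genuine per-tool
  site tables is preferable when available.
* Rank normalization needs a batch of scores from the new dataset; it is
  not defined pointwise.
* The FD model ignores site accessibility, cooperativity and AGO
  titration; its probabilities are occupancy estimates, not repression
  magnitudes.
* The additivity regression assumes aligned, per-gene fold-change vectors
  and does not model measurement error in the single-perturbation
  covariates.
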