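---
title: "Methods: building and validating a metaGRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and validating a metaGRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(metagrs)
```

## The model

A genomic risk score (GRS) for trait $k$ is a weighted allele count
$s_{ik} = \sum_j x_{ij}\,\alpha_{jk}$, where $x_{ij} \in \{0,1,2\}$ is
individual $i$'s dosage of the effect allele at SNP $j$ and
$\alpha_{jk}$ is the per-allele effect size taken from an external GWAS
of trait $k$. Because GWAS effect estimates are noisy and nearby SNPs
are correlated (linkage disequilibrium, LD), each component GRS is built
by *pruning and thresholding*: a greedy sweep removes any SNP whose
squared Pearson dosage correlation with an already-retained SNP within a
window exceeds $r^2_{\max}$, and the survivors are filtered on GWAS
p-value (or Benjamini–Hochberg FDR).

The *metaGRS* combines $K$ such component scores. Each component is
standardised to zero mean and unit variance in a derivation cohort
(storing its raw standard deviation $\sigma_k$), and an elastic-net
logistic regression of case status on the $K$ standardised scores gives
per-component log-odds $\gamma_1, \dots, \gamma_K$. The fitted stack is
then collapsed back to SNP level: because each component is linear in
dosages, the linear combination is too, and

$$w_j \;=\; \sum_{k=1}^{K} \frac{\gamma_k}{\sigma_k}\,\alpha_{jk},
\qquad \alpha_{jk} = 0 \text{ if SNP } j \notin \text{component } k,$$

is a single additive per-SNP weight vector. Scoring any cohort with $w$
differs from the $\gamma$-weighted sum of standardised component scores
only by the constant $\sum_k \gamma_k \mu_k / \sigma_k$ (the dropped
standardisation means), which is irrelevant once the collapsed score is
itself standardised. `collapse_weights()` implements this identity and
the test suite enforces it to within $10^{-8}$ on simulated stacks; the
emitted weights are unnormalised (no positive scale factor is applied),
since use-time standardisation makes any such factor irrelevant.

### Cross-validated penalty selection

`fit_stack_cv()` evaluates a grid of elastic-net mixing values
($\alpha \in \{0.1, 0.5, 0.9\}$ by default) each with a glmnet-scaled
path of penalty strengths (20 by default) using seeded,
case-status-stratified folds (10 by default). Covariates are never
penalised — penalising confounder coefficients would bias the component
log-odds. For each grid point we compute the AUC of the *pooled*
held-out linear predictors across folds; "cross-validated AUC" can also
be read as the mean of per-fold AUCs, so both are offered
(`cv_metric = "pooled"` or `"fold_mean"`), with pooled as the default
because it is well-defined even when a fold has few cases. The
maximising grid point is refit on the full derivation data. Fold
assignment is derived from the configured seed after sorting samples by
identifier, so the fit is bit-reproducible under any permutation of the
input rows.

## Survival evaluation

Validation treats incident disease as a time-to-event outcome with
**age as the time scale**: an individual enters the risk set at their
assessment age (left truncation / delayed entry) and exits at the event
or censoring age, administratively capped (75 years by default, since
events beyond that age are censored in the data this machinery is
designed for). `fit_cox()` fits

$$h_i(t) = h_{0,s(i)}(t)\, \exp(x_i^\top \beta)$$

stratified by sex ($s(i)$), weighted by each record's inverse
probability of selection into the validation set, with sandwich (robust)
standard errors clustered on the individual, and the Efron tie
approximation. The baseline cumulative hazard $\hat H_0(t)$ uses the
Breslow estimator; proportional hazards are checked with the global
scaled-Schoenfeld-residual test on the identity time transform.

Downstream summaries:

* **HR per SD** — `exp(beta)` with the robust Wald 95% CI, for a
  predictor entered in standard-deviation units.
* **Percentile-bin HRs** — one Cox fit with bin membership as a
  categorical predictor against a configurable reference bin (the middle
  45–55% by default), for risk-gradient displays.
* **Harrell's C under left truncation** — a pair is usable when the
  earlier event time falls strictly inside the other member's
  `(entry, exit]` window; tied scores count 1/2 and tied event times are
  not compared. The estimate and its infinitesimal-jackknife variance
  come from `survival::concordance`; the pair rule is validated against
  an exhaustive pair-counting oracle on every small fixture.
* **Kaplan–Meier and log-rank** — the product-limit estimator honours
  delayed entry via `survival::survfit`; the log-rank statistic is
  computed directly from the delayed-entry risk sets (at each event age,
  those with `entry < t <= exit`) because `survival::survdiff` does not
  accept counting-process data. On right-censored data (entry at zero)
  the two agree to numerical precision, which the tests assert.
* **Predicted cumulative incidence** —
  $1 - \exp(-\hat H_0(t)\, e^{x^\top \hat\beta})$ per sex stratum for a
  covariate profile of interest, with confidence intervals propagated on
  the log cumulative-hazard scale
  ($\hat H \cdot e^{\pm 1.96\, \mathrm{se}(\hat H)/\hat H}$); ages beyond
  the last event draw a warning and the curve is held flat.
* **Decile calibration** — a logistic model fitted in an event-enriched
  derivation set over-predicts absolute risk in an unenriched cohort by
  the ratio of baseline event rates; `calibration_by_decile()` divides
  the predicted *odds* by that `rate_ratio` (equivalently shifts the
  logistic intercept by $-\log$ `rate_ratio`, the standard transfer of a
  logistic absolute-risk model between sampling frames), cuts samples
  into deciles of the rescaled prediction, and compares the mean
  prediction with the observed event proportion under exact binomial
  intervals. If all predictions coincide the quantile cut degenerates to
  a single bin, which is reported as such.
* **Liability-scale conversion** — an observed-scale $R^2$ from a 0/1
  regression is transported to the liability scale under the normal
  threshold model with population prevalence $K$ and sample case
  fraction $P$. The default linear transform multiplies by
  $\frac{K(1-K)}{z^2}\cdot\frac{K(1-K)}{P(1-P)}$ with
  $z = \varphi(\Phi^{-1}(1-K))$, reducing to the classic
  $K(1-K)/z^2$ when $P = K$; because more than one variant of this
  conversion is in circulation, an ascertainment-corrected form
  $R^2_l = C R^2 / (1 + C\theta R^2)$ is available behind
  `method = "corrected"` (the two coincide at $P = K$, which the tests
  pin to $10^{-12}$). The default prevalence in the evaluation command is
  $K = 0.008$, the ischaemic-stroke prevalence implied by the published
  validation-cohort counts bundled in `inst/extdata` (3075 events among
  395,393 individuals), and explained heritability is reported over a
  grid of plausible $h^2$ from 0.1 to 0.4 as $R^2_l / h^2$.
* **Interaction tests** — Wald tests on a product term added to the Cox
  model (robust SE) or to a logistic model of the event indicator, for
  score-by-sex and score-by-medication questions.

## The cohort simulator

Restricted cohort data cannot ship with the package, so every module is
exercised against a generator whose defaults emulate a middle-aged
population cohort followed for incident ischaemic stroke:

* **Genotypes** — variants live in LD blocks (1 kb spacing, 1 Mb between
  blocks); a latent standard normal with exchangeable within-block
  correlation `within_block_r` is discretised at each variant's
  Hardy–Weinberg thresholds, giving hard-call dosages with the right
  marginal allele frequencies and tunable dosage LD. Discretisation
  attenuates the latent correlation, most strongly at low minor-allele
  frequency — a property to keep in mind when choosing `within_block_r`
  for a target dosage $r^2$.
* **Architectures** — trait effect vectors are drawn jointly via the
  Cholesky factor of the genetic correlation matrix over nested causal
  sets (a master permutation truncated at each trait's causal fraction,
  so correlated traits share causal variants); effects are scaled on an
  internal seeded reference panel so realised heritabilities match the
  specification including LD (the tests require agreement within 0.02).
* **Summary statistics** — per-allele estimates are the true effects
  plus noise with the standard GWAS sampling error
  $1/\sqrt{2 n\, \mathrm{maf}(1-\mathrm{maf})}$ and Wald p-values, drawn
  independently of any simulated target cohort (no sample overlap, the
  design the method assumes).
* **Risk factors** — SBP (mean 138, SD 20 mm Hg, correlated 0.25 with
  the outcome liability), DBP, BMI, LDL, smoking (10%), diabetes (4.7%),
  BP medication (~20%, more likely at high SBP) and lipid-lowering
  medication (~17%) roughly match published cohort descriptions.
  Measured SBP is 15 mm Hg lower in treated individuals, so the standard
  +15 mm Hg medication adjustment in `derive_risk_factors()`
  reconstructs the underlying value; LDL is likewise adjusted by
  +1.5 mmol/L under lipid-lowering treatment, and hypertension uses the
  expanded rule (medication, SBP > 140, DBP > 90, or a registry flag).
* **Survival** — event ages follow a Gompertz proportional-hazards model
  ($h_0(t) = \lambda e^{\rho t}$ with shape $\rho = 0.09$/year, so
  incidence roughly doubles every 8 years, as stroke incidence does);
  the female stratum is the reference rate and the male baseline is
  2.2-fold higher, matching the roughly twofold male excess in incident
  ischaemic stroke. Entry ages are uniform on 40–69; events at or before
  entry are excluded as prevalent (and returned in a flagged registry);
  exits are censored at entry + follow-up and at the administrative cap
  of 75. The default reference rate $\lambda = 2\times10^{-6}$ yields
  sub-1% incident fractions over a 7-year follow-up, similar to a real
  biobank; analyses that need denser events (examples, small pipeline
  runs) raise the rate explicitly.
* **Splits** — cases enter the derivation set with
  `case_oversample_factor` times the control probability, normalised to
  the target derivation size; validation records carry
  $1/(1 - p_{\text{select}})$ weights, the convention consumed by the
  weighted Cox fit. (How such weights were constructed in the original
  analyses is not documented; this explicit convention is the package's
  own and is stated wherever the weights are used.)

### What the simulator does and does not show

Passing tests on this generator demonstrate the *statistical machinery*:
exact collapse algebra, unbiased hazard-ratio recovery under the
proportional-hazards model the data truly follow, correct risk-set
handling under left truncation, calibrated null distributions for the
log-rank and interaction tests, and a reproducible pipeline. They do not
demonstrate performance on real genotypes: the generator has no
realistic LD maps or allele-frequency spectra, no population structure
or relatedness, no genotyping or imputation error (the INFO column is
synthetic noise used only to exercise QC plumbing), no competing risks,
and marginal GWAS effects equal the causal effects (no LD-induced
effect-size inflation between summary-statistic sources and target
panel). Headline numbers from the restricted-cohort analyses (HR 1.26
per SD, C-index 0.580, top-0.25% HR 3.0) are therefore treated as
recovery *targets in simulations that assume them true*, not as
reproducible outputs.

## Numerical and design choices

* **QC boundary** — the QC filter removes rows *strictly below* the
  INFO/MAF thresholds, so values exactly at a threshold pass.
* **Variant identity** — joins use (chromosome, position) with allele
  reconciliation rather than rsID, which is unreliable across sources;
  strand-ambiguous A/T and C/G variants are dropped during
  harmonisation (the conservative default, since their orientation
  cannot be inferred without frequency heuristics).
* **Missing dosages** — preserved as missing in I/O; mean-imputed per
  variant at scoring time only.
* **Pruning determinism** — when a pair violates $r^2_{\max}$ the
  earlier variant by position is kept. Under this tie-break a
  window-sliding sweep yields the same kept set for any slide
  granularity, so the `step` parameter is accepted for interface
  compatibility but cannot change results. $r^2$ is computed on dosage
  columns (genotype correlation), matching hard-call input. The default
  grid of thresholds is $\{0.1, 0.2, 0.5, 0.8\}$ with a 250 kb window;
  original per-trait grids are unpublished, so these are package
  defaults, not reproductions.
* **Candidate selection** — among the threshold grid, the score with the
  largest-magnitude fitted log hazard ratio on the tuning cohort wins;
  ties break toward the smaller $r^2_{\max}$ (the sparser score). The
  tuning cohort is an explicit argument rather than an implicit split.
* **Standard deviations** — always the $n-1$ denominator; the choice
  only rescales $\gamma/\sigma$ consistently and cancels in the
  collapsed score.
* **Partial correlations between components** — each pair of
  standardised scores is regressed both ways (a on b, b on a) with the
  adjustment covariates; the two slopes are averaged for the displayed
  matrix and the clustering, and BH adjustment runs over the
  $K(K-1)/2$ upper-triangle tests. Display order comes from
  average-linkage hierarchical clustering of $1 - |r|$.
* **Percentile bins** — quantile type 7 cut points with the outer edges
  widened to $\pm\infty$, so extreme scores always fall in the outer
  bins; an empty bin is a validation error rather than a silent drop.
* **Classed errors** — validation, format, degenerate-fit,
  empty-overlap and harmonisation failures raise distinct condition
  classes, which the command-line front end maps to exit code 2.

## Problem sizes in the test and acceptance runs

The bundled checks choose sizes that give each Monte-Carlo assertion
clear power while keeping a full run within minutes on one CPU:
hazard-ratio recovery uses 20 replicates of $n = 50{,}000$ with the
baseline rate raised to give roughly 10% cumulative events (so the Wald
band $[1.20, 1.32]$ sits about three standard errors wide);
cumulative-incidence consistency against Kaplan–Meier uses a single
$n = 100{,}000$ cohort at low incidence; the stacking-gain experiment
uses 20 replicates of a 4-trait architecture (genetic correlations 0.7,
0.5, 0.3 with the outcome trait) in which the outcome trait's GWAS
($n = 2{,}000$) is underpowered relative to the auxiliary GWAS
($n = 50{,}000$) — the regime that motivates a metaGRS in the first
place, where a disease's own GWAS captures its heritability poorly and
correlated traits carry independent information; with a well-powered
outcome GWAS the single-trait score approaches saturation and the
stack's advantage shrinks toward zero, which is worth remembering when
deciding whether a metaGRS is worth building at all.

## Known limitations

No genome-build liftover, no imputation, no competing-risk
(Fine–Gray) models, no time-varying covariates, and no summary-
statistic-only stacking (combination weights require an individual-level
derivation cohort). The simulator's genotypes are unphased hard calls —
sufficient for dosage-$r^2$ pruning and scoring, but not for
haplotype-level analyses. C-index confidence intervals use the
infinitesimal-jackknife variance; other interval constructions for
concordance exist and can differ slightly in small samples.
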