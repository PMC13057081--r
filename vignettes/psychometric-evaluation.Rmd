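---
title: "Psychometric evaluation of item banks with promkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Psychometric evaluation of item banks with promkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promkit)
```

## The measurement model

promkit evaluates polytomous patient-reported outcome (PRO) item banks —
bank, short form, and computerized adaptive test (CAT) applications —
under Samejima's graded response model (GRM). An item with $K$ ordered
categories has a discrimination $\alpha > 0$ and strictly increasing
thresholds $\beta_1 < \dots < \beta_{K-1}$; the cumulative probabilities
are

$$P^*_k(\theta) = \frac{1}{1 + e^{-\alpha(\theta - \beta_k)}},
\qquad P^*_0 = 1,\; P^*_K = 0,$$

and category probabilities are the successive differences
$P_k = P^*_k - P^*_{k+1}$. The latent trait $\theta$ is identified by a
standard normal prior (latent variance fixed at 1). Scores are reported
on the T metric, $T = 50 + 10\,\hat\theta$, anchored so that the
calibration population has mean 50 and SD 10; the package's acceptance
script verifies this anchor by scoring a large simulated calibration
sample with its own parameters.

Calibration (`fit_grm()`) is marginal maximum likelihood via EM: the
E-step places each respondent's posterior on a fixed quadrature grid,
the M-step maximizes each item's expected complete-data log-likelihood.
Scoring (`eap_score()`) is expected a posteriori (EAP): the posterior
mean, with the posterior SD reported as $SE(\theta)$. An
$SE(\theta) \le 0.32$ corresponds to reliability
$1 - SE^2 \approx 0.90$, the conventional bound for reliable individual
measurement.

## Numerical choices

* **Quadrature.** 61 equally spaced nodes on $[-4.5, 4.5]$, weighted by
  the $N(0,1)$ prior density with trapezoid end-point weights and
  renormalized. The trapezoid end weights matter: without them, response
  patterns whose posterior still has mass at the grid edge pick up an
  $O(h)$ boundary term and EAP estimates drift by a few $10^{-4}$ from a
  dense-grid computation; with them the 61-node grid agrees with a
  $10^5$-node integration to better than $10^{-4}$ across random
  patterns, which the test suite checks directly.
* **M-step.** Per-item quasi-Newton (BFGS) with analytic gradients on the
  reparameterization $(\log\alpha,\ \beta_1,\ \log\Delta\beta)$, which
  keeps discriminations positive and thresholds strictly ordered for
  every step the line search tries — a per-item Newton step on the raw
  scale can leave the admissible region. Convergence: largest absolute
  parameter change $< 10^{-4}$ or 500 EM cycles, with non-convergence
  flagged, never silent. The EM marginal log-likelihood trace is checked
  to be non-decreasing.
* **Unobserved categories** are collapsed away before calibration with
  the old-to-new mapping recorded (`category_maps`);
  `apply_category_maps()` recodes the raw data to the calibrated coding
  for downstream stages.
* **Ties** in CAT item selection are broken by the lowest item index so
  post-hoc replays are bit-for-bit deterministic.

## Assumption checks

Before calibration the pipeline checks the GRM's assumptions:

* **Unidimensionality.** A single-factor least-squares (minres) solution
  of the polychoric correlation matrix, with CFI/TLI/RMSEA computed from
  the ML discrepancy at that solution against the zero-correlation
  baseline and SRMR as the root mean squared residual correlation
  (thresholds: CFI/TLI $\ge 0.95$, RMSEA $\le 0.06$, SRMR $\le 0.08$).
  These are *unscaled* analogues of the robust indices a weighted
  least-squares estimator would report; robust corrections need weight
  matrices that polychoric two-step estimation does not produce, and the
  verdict thresholds are unchanged. Indefinite polychoric matrices are
  projected to the nearest positive semidefinite matrix (recorded).
  Polychoric correlations themselves are two-step ML: thresholds from
  inverse-normal marginals, then each pairwise correlation maximizing the
  bivariate-normal contingency likelihood (the bivariate normal CDF is
  evaluated by Gauss–Legendre quadrature of the single-integral form).
* **Essential unidimensionality.** An exploratory bifactor decomposition:
  oblique multi-factor solution (minres, varimax + promax), a single
  second-order factor of the factor intercorrelations, and the
  Schmid–Leiman orthogonalization. Supportive when explained common
  variance ECV $\ge 0.70$ and omega-hierarchical $\omega_h \ge 0.80$.
  The number of group factors defaults to 2 (configurable); with no
  stated exploratory structure this is the smallest count that can
  absorb a secondary cluster. `bifactor_indices_from_loadings()` exposes
  the exact algebra and is tested against hand-computed values.
* **Local independence.** Residual correlations
  $r_{ij} - \lambda_i\lambda_j$ after the single-factor solution; pairs
  above 0.20 are flagged and reported as "count (percent)".
* **Monotonicity and scalability.** Mokken-type coefficients
  ($H_{ij} = \mathrm{cov}/\mathrm{cov}_{\max}$ with the comonotonic
  maximum from sorted margins), with $H_i \ge 0.30$ and $H \ge 0.50$
  acceptable (a 0.60 convention for $H$ also circulates; the report
  carries a note rather than silently choosing). Monotonicity is checked
  on rest-score groups (default minimum size 50) counting significant
  decreases (one-sided $z$, $\alpha = 0.05$) larger than a minimum
  violation of 0.03 — without that floor, trivially small wiggles in
  30-odd tiny groups generate false alarms even for model-generated
  data.
* **Invariant item ordering.** The HT coefficient — H on the transposed
  matrix over person pairs with distinct totals — reported descriptively
  with the accuracy bands $<0.30$ / $0.30$–$0.39$ / $0.40$–$0.49$ /
  $\ge 0.50$; it is not used as a model assumption.

## Item fit

`sx2_item_fit()` implements the generalized Orlando–Thissen $S\text{-}X^2$
for polytomous items: the model-implied rest-score distribution (the
summed score over the *other* items) is built by convolving category
probability vectors at each quadrature node; observed and expected
(rest score × category) counts, conditioned on the observed rest-score
totals, are compared by Pearson $\chi^2$. Cells are collapsed until every
expected count is $\ge 1$ — categories within a score group first, from
the outer categories inward, then whole score groups from the
distribution tails inward. Degrees of freedom are the collapsed cell
count minus one per score group minus the item's free parameters,
floored at 1; items that cannot reach one degree of freedom are reported
untestable rather than given a p-value. Misfit is flagged at
$p < 0.001$. Under the generating model the flag rate stays below 1%
across 200 replicates (checked in the test suite).

`fit_plot_data()` supplies the observed-vs-expected diagnostics behind
item-fit plots. Respondents are binned by the EAP estimate from the
*other* items, and the expectation is the rest-posterior predictive
probability averaged per bin. Two tempting alternatives are biased even
when the model is true: binning on an estimate that includes the studied
item lets the item sort itself into favourable bins, and evaluating
category curves at the shrunken bin-mean $\hat\theta$ misses the
within-bin curvature; both produce spurious gaps of 0.05–0.10 in tail
bins. With rest-score conditioning, model-consistent data stay within
sampling error of their expectation in every bin, while a reversed item
still shows gaps above 0.2.

## Differential item functioning

`dif_scan()` is the ordinal-logistic DIF scan: per item and per pair of
group levels, three nested proportional-odds models on the observed
categories — trait only; trait + group; trait + group + trait×group —
fitted by the package's cumulative-logit maximizer (analytic gradients,
ordered cutpoints by construction; the test suite cross-checks its
likelihoods against an independent proportional-odds implementation).
Effect sizes are McFadden pseudo-$R^2$ differences between nested
models: uniform ($M_2 - M_1$), non-uniform ($M_3 - M_2$), and total,
which add exactly by construction. Values above 0.02 flag DIF. The
matching criterion is the EAP estimate from all items in a single pass;
iterative purification is deliberately not applied by default, since
threshold-based flagging on effect sizes this small is insensitive to it
at the study's scale. For covariates with more than two levels all
pairwise comparisons are computed and their mean reported alongside.

`dif_impact()` quantifies consequences rather than significance: the GRM
is re-estimated without the flagged items, everyone is re-scored, and
the report carries mean absolute and maximum T-score differences, the
percentage of respondents moving by $\ge 1$ T-point, mean $SE(\theta)$
and the reliable-measurement percentage before and after, plus both test
characteristic curves. For CAT applications `dif_cat_exposure()` reports
whether flagged items were ever administered and their information rank
at each respondent's trait level.

## Post-hoc CAT

`run_cat()` replays each respondent's stored full-bank responses through
an adaptive administration: the first item maximizes information at
$\theta = 0$; each next item maximizes posterior-weighted information
$\int I_j(\theta)\,p(\theta \mid \text{responses so far})\,d\theta$ on
the same quadrature grid as EAP scoring (internal consistency keeps the
stopping SE and the reported SE identical). The test stops once
$SE(\theta) \le 0.32$ after at least 4 items, or at the short-form
length. The minimum-items rule takes precedence: even if the interim SE
satisfies the threshold earlier, administration continues to item 4 —
the stopping rule is evaluated only from that point on. Efficiency is
$(1 - SE^2)/n_{\text{items}}$ per person; `relative_efficiency()` forms
ratios of mean efficiencies with percentile bootstrap intervals over
persons (1,000 resamples by default, seeded).

## The synthetic-data generator

No respondent-level survey data ship with the package, so
`generate_item_bank()`, `simulate_thetas()`, `simulate_responses()`,
`simulate_legacy_scale()` and `draw_reference_sample()` generate every
input with known ground truth. The defaults describe the study
conditions the pipeline is meant for:

* banks of 5–23 five-category items with discriminations drawn from
  $[1.2, 2.8]$ and thresholds spanning $[-2.2, 2.8]$ (the span is a
  contract: the generated bank's lowest and highest thresholds sit
  exactly on it);
* a survey-scale sample of ~500 respondents (calibration studies of this
  kind power for roughly that size), with covariate margins mirroring a
  general-population frame (child sex ≈ 51/49, parental education ≈
  13.5/36/50.5);
* a ceiling component: a fraction of respondents relocated to a narrow
  normal component (SD 0.25) centred 2.5 prior SDs toward the
  best-functioning extreme. This reproduces the raw-score ceiling of
  general-population samples — scores pile at "best possible
  functioning" — without degenerate constant response patterns, and it
  is what drives the empirical marginal reliability below the
  theoretical one for banks informative away from that extreme;
* a legacy 0–100 instrument generated from a second latent trait drawn
  bivariate-normal with the target correlation, its items reverse-scored
  as $(K - 1 - x)\cdot 100/(K-1)$ so that category 0 ("never a problem")
  maps to 100;
* a reference subsample drawn in two phases — deficit-driven admission
  until the target margins are filled, then top-up — with a maximum
  tolerated deviation of 2.5% per demographic category and explicit
  flags for infeasible strata.

What the generator does *not* emulate: item-specific response styles,
missing data (the surveys it mirrors use forced completion),
multidimensional traits, or real demographic microdata (covariates are
drawn independently of $\theta$ and of each other). A green test suite
therefore shows the pipeline recovers what it should under the model's
own assumptions, not that any particular field instrument satisfies
them. The true trait distribution of a given population is unknown;
the skewed option exposes a shape parameter rather than estimating one.

## Problem sizes and reproducibility

The test suite and the acceptance script run at the sizes the checks
need, chosen once: calibration recovery at $n = 5000$ (and at the
survey-scale $n = 529$), the T-score anchor at $n = 10^4$, type-I
calibration of $S\text{-}X^2$ over 200 replicates of $n = 2000$, DIF
null behaviour over 200 permuted replicates and power over 60 injected
replicates, CAT properties at $n = 1000$. A single study seed fans out
to per-stage child seeds (`child_seed()`), so every stage is
individually reproducible and reruns are numerically identical.

## Known limitations

* Fit indices are unscaled analogues, not WLSMV robust values; absolute
  RMSEA in particular is known to run high for ordinal single-factor
  fits at these sample sizes.
* The bifactor decomposition is exploratory; confirmatory bifactor
  models with standard errors are out of scope.
* DIF flagging is effect-size based (McFadden $R^2$); IRT-based Wald or
  likelihood-ratio DIF tests are not implemented.
* Single-item measures are summarized descriptively (mean, SD,
  correlation with a legacy scale); no IRT quantities are reported for
  them.
* The EAP grid covers $[-4.5, 4.5]$; respondents whose posterior mass
  would fall outside (possible only with extreme anchors) are shrunk to
  the grid edge.
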