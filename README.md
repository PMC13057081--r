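# promkit

IRT evaluation toolkit for patient-reported outcome (PRO) measures:
graded response model (GRM) calibration and T-score scoring together
with the full psychometric evaluation pipeline applied to PRO item
banks, short forms and computerized adaptive tests (CATs) — and a
synthetic-data generator that supplies every input with known ground
truth.

## Who this is for

Psychometricians and outcomes researchers who validate polytomous item
banks (PROMIS-style parent-proxy or self-report measures, legacy
quality-of-life scales) and need the whole chain in one tested, seeded,
scriptable package:

1. **Assumption checks** — polychoric correlations, single-factor fit
   (CFI/TLI/RMSEA/SRMR), exploratory bifactor indices (ECV, ω_h),
   residual-correlation local-independence flags, Mokken scalability
   (H, H_i), monotonicity against rest-score groups, invariant item
   ordering (HT).
2. **Calibration** — GRM by marginal maximum likelihood (EM on a fixed
   quadrature grid, N(0,1) prior fixing the latent scale).
3. **Item fit** — generalized Orlando–Thissen S-X² for polytomous data,
   with observed-vs-expected plot data.
4. **Scoring** — EAP estimates with posterior-SD standard errors,
   T-scores (T = 50 + 10·θ̂), raw sums.
5. **DIF** — ordinal-logistic scans with McFadden pseudo-R² effect
   sizes (flag > 0.02), uniform and non-uniform components, pairwise +
   mean comparisons for multi-level covariates, and an impact stage
   that re-calibrates without flagged items and reports T-score and
   reliability consequences.
6. **Post-hoc CAT** — maximum posterior weighted information selection,
   EAP interim scoring, SE ≤ 0.32 stopping (reliability ≈ 0.90) with
   minimum 4 / maximum short-form-length items, deterministic replay.
7. **Reliability / efficiency / validity / reference values** — mean
   SE(θ) and % reliable (with best-functioning ceiling exclusion),
   theoretical vs empirical marginal reliability, per-person efficiency
   (1 − SE²)/n_items with bootstrapped relative-efficiency ratios,
   construct-validity hypothesis ledgers, demographically stratified
   reference tables and version crosswalks.

The model: for an item with K ordered categories, discrimination α and
thresholds β₁ < … < β_{K−1},

    P*_k(θ) = 1 / (1 + exp(−α(θ − β_k))),   P*_0 = 1, P*_K = 0
    P_k(θ)  = P*_k(θ) − P*_{k+1}(θ)

See `vignettes/psychometric-evaluation.Rmd` for the full methods
account, including the numerical choices and the design rationale for
each stage.

## Worked example

```r
library(promkit)

bank      <- generate_item_bank(bank_spec(13, 5, short_form_items = 1:6), seed = 1)
pop       <- population_spec(529, ceiling_mass = 0.15,
               covariate_margins = list(child_sex = c(male = 0.51, female = 0.49)))
persons   <- simulate_thetas(pop, seed = 1)
responses <- simulate_responses(bank, persons, seed = 1)

report <- evaluate_measure(responses, covariates = persons["child_sex"],
                           direction = "symptom", short_form = 1:6,
                           n_boot = 1000, seed = 1)
```

This prints (via the report fields; exact numbers for these seeds):

```
CFI 0.936  TLI 0.923  RMSEA 0.105  SRMR 0.034
ECV 0.958  omega_h 0.961  H 0.604  HT 0.642 (high accuracy)
residual flags: 0 (0.0)
GRM converged: TRUE  items misfitting (S-X2, p<0.001): 0
bank: mean SE 0.260, 87.9% reliable; without ceiling: 92.6%
CAT: mean 4.9 items, mean SE 0.312, 84.5% reliable
relative efficiency CAT vs bank: 2.67 [2.63-2.71]
DIF-flagged items: none
marginal reliability: theoretical 0.926, empirical 0.929
```

Reading it: the 13-item bank is essentially unidimensional (ECV 0.96,
ω_h 0.96, no residual-correlation flags, H 0.60) — note that the
*unscaled* RMSEA runs high at n = 529 even for model-consistent ordinal
data, which is why the bifactor indices carry the unidimensionality
verdict. Calibration converged and no item misfits at p < 0.001. 87.9%
of respondents are measured reliably (SE(θ) ≤ 0.32, reliability ≈ 0.90)
by the full bank, rising to 92.6% once the best-possible-functioning
ceiling group is excluded. The simulated CAT needs 4.9 items on average
— versus 13 — while keeping 84.5% reliable, making it 2.67× as
efficient per item as the full bank (bootstrap 95% CI 2.63–2.71). No
item shows DIF by child sex, and the empirical marginal reliability
matches the theoretical one because this population is only mildly
ceiling-skewed.

A command-line wrapper is installed at `inst/cli/promkit`
(`promkit simulate|fit|...|report --config cfg.json --out DIR`); it is a
thin dispatcher over the same functions.

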