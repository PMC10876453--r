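---
title: "Methods: occurrence-based healthy dietary diversity scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occurrence-based healthy dietary diversity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orchidscore)
```

## The model

The ORCHID score measures *healthy dietary diversity* — variety of
healthful foods combined with moderation of energy-dense ones — for older
adults, from data that field interventions can realistically collect:
counts of eating occasions rather than weighed portions. Twenty food groups
are scored. Thirteen daily groups are counted from three 24-h dietary
recalls; seven weekly groups (poultry, eggs, fatty fish, lean fish and
shellfish, legumes, nuts, wholemeal products) from a food propensity
questionnaire, because three recall days undersample infrequently eaten
foods.

For group $g$ with occurrence count $n_g$, weight $w_g$ and (for
moderation groups) threshold $t_g$:

* positive rating: $C_g = n_g \, w_g$;
* threshold rating: $C_g = n_g$ if $n_g \le t_g$, and
  $C_g = (n_g - t_g)\, w_g$ otherwise.

The total is $\sum_g C_g$. The threshold formula is implemented literally,
which makes it discontinuous at $t_g$ when $w_g < 0$: the points earned up
to the threshold vanish once it is exceeded. Because the design intent
("considered positively until a threshold") can also be read as keeping
those points, `score_threshold()` offers an explicit `mode = "continuous"`
variant, $C_g = t_g + (n_g - t_g) w_g$ above the threshold; the literal
form stays the default for fidelity.

### Occurrence counting

A recall declaration counts only when its group's *daily* total reaches
half a standard portion — e.g. with the 50 g cooked-ham portion, a day
totalling less than 25 g of cooked ham contributes nothing, while a day at
or above 25 g counts each declaration of the group that day. Two readings
of "at exactly half" are possible; we gate inclusively ($\ge$), which is
the contrapositive of the worked rule ("less than 25 g ... not taken into
account"), and expose `inclusive = FALSE` for the strict reading.
Whether an occurrence is one *declaration* or one *qualifying day* is
ambiguous; we count declarations, since the gate is stated per declaration
and daily groups must be able to exceed three occurrences over three days
for the observed score ranges to be reachable.

Complex dishes are disaggregated with user-supplied recipes: ingredients
are ordered by descending mass and the smallest prefix reaching half the
recipe mass is retained (ties at the boundary are all kept, for
determinism), each main ingredient receiving the declared dish mass times
its recipe share. Ingredient grams then pool with same-group simple foods
of the same day before gating — the half-portion condition is stated
identically for main ingredients, and pooling is the only reading under
which a dish and its à-la-carte equivalent gate the same way.

### FPQ processing

Monthly frequencies are divided by 4.345 weeks/month (the calendar
average, configurable). Missing responses are imputed with a
missForest-style chained random-forest imputer (`ranger` forests, default
100 trees, columns revisited in order of increasing missingness until the
relative change of the imputed values stops decreasing, cap 10
iterations); observed cells are never modified, outputs are clamped at
zero, and a seed makes the completed matrix reproducible bit for bit.
Which predictors enter the imputation is user-configurable (any complete
covariate table can be supplied); by default the other FPQ columns are
used. Item frequencies are summed within each of the seven FPQ groups.

## Shipped configuration

The published per-group weights, thresholds and standard portions are not
fully recoverable from public text, so all scoring parameters live in an
editable YAML file (`orchid_config_path()`); the shipped defaults are a
structural approximation: ENNS/GEMRCN-style portions (cooked ham 50 g,
fruits/vegetables 80 g, ...), weight 1–3 positive ratings for healthful
groups (fruits and vegetables 2; fatty fish 3, reflecting its weekly
recommendation), and threshold ratings with negative weights (−1 to −3,
thresholds 1–4 occurrences per three days) for the six moderation groups:
sweetened products, sweetened beverages, salted aperitif products, deli
meats excluding cooked ham, meat excluding poultry, and butter/margarine/
fresh cream. Two groups could defensibly be rated either way; we rate
*oils* and *refined starches and potatoes* positively with weight 1 — they
are daily staples that the guidelines treat neutrally-to-favourably
(vegetable oils explicitly so), and a moderation reading belongs in a
user-edited config rather than the default. Under these defaults,
adversarial extremes reach totals below −60 and above +110, so both signs
and the published order of magnitude of score ranges are attainable; no
numeric equivalence with any survey is claimed.

## Diet-quality measures

*Solid energy density* is the pooled ratio
$100 \times \sum \text{kcal}_{\text{solid}} / \sum \text{g}_{\text{solid}}$
over all recall days — a pooled ratio, not a mean of daily ratios,
matching "total energy over the total weight consumed".

*MAR* is $100 \times \frac{1}{22}\sum_j \min(\text{intake}_j /
\text{RDA}_j, 1)$, with sex- and age-specific RDAs supplied as a CSV.

*PANDiet*: for each of 27 nutrients the probability of adequacy is
computed under a Gaussian model of the usual intake — mean equal to the
observed day-mean, standard error the day-to-day SD over $n \ge 2$ days
divided by $\sqrt n$. Adequacy nutrients score $P(\text{usual} \ge
\text{ref})$, moderation nutrients $P(\text{usual} \le \text{ref})$; the
two sub-scores are 100 × the mean probability of their nutrient sets, and
the total is their average. A zero observed SD is replaced by 10 % of the
reference (configurable `var_floor`), avoiding degenerate 0/1
probabilities on constant toy data. No measurement-error deconvolution
(NCI/SPADE-style usual-intake modelling) is attempted. The 22- and
27-nutrient reference tables shipped under `inst/extdata/` are synthetic
illustrations (plausible adult values assembled by the package authors) —
the real French reference values live in the literature cited by the
score's validation studies and must be supplied by the user.

## Validation battery

`validity_report()` reproduces the construct-validity analyses: Spearman
correlations of the score with component points and food-group intakes
(rank-based, as these are not normally distributed), Pearson correlations
with energy and diet-quality measures, survey-weighted quartile tables,
Wilcoxon sex tests, quartile-adjusted ANOVA, and chi-square tests of
categorical covariates across quartiles. Correlation strength follows the
published rule — high $|r| > 0.5$, moderate $0.5 \ge |r| > 0.2$, low
$|r| < 0.2$; the rule leaves $|r| = 0.2$ unlabelled, and we close the
lower boundary into "moderate" by symmetry with the closed upper one.
Survey weighting uses weighted quantiles for quartile cuts and linearised
(with-replacement) standard errors for weighted means, aggregated within
clusters first when cluster identifiers are supplied; Spearman
correlations stay unweighted, mirroring the original analysis. The exact
CI estimator of the original survey software is not published; the normal
approximation on the linearised SE is our choice.

## The synthetic generator

`generate_cohort()` emulates the *structure* of a national food-consumption
survey — three recall days, ~60 FPQ items, 20 food groups, nutrient intakes
correlated with food-group consumption — not any survey's marginal
distributions. One latent healthiness $h \sim N(0,1)$ per individual
drives everything: daily group occurrence counts are
$\text{Poisson}(\exp(\log \beta_g + \lambda_g h))$ with base rates
$\beta_g$ near field plausibility (vegetables 1.8/day, fruits 1.5/day,
fatty fish 0.12/day, ...) and loadings $\lambda_g$ carrying the expected
signs (fruits/vegetables/wholemeal positive, sweetened products/beverages
negative); per-occurrence grams are log-normal around the standard portion
(sdlog 0.35); 5 % of declarations are wrapped into two-ingredient complex
dishes with packaged recipes; FPQ item frequencies are noisy shares of the
same latent weekly rates, half reported per month, with 10 % MCAR holes;
nutrient intakes come from a density matrix that tilts reference nutrients
toward healthful groups and moderation nutrients (sugars, saturated fat,
sodium) toward energy-dense ones, with log-normal day-to-day noise (sdlog
0.15); covariates (education, smoking, physical activity, BMI) load on $h$
with the signs reported for diet quality, while sex, income and household
size are independent. The `energy_neutral` flag rescales each individual's
food masses to an energy target drawn independently of $h$, emulating a
diversity gradient that is not an energy gradient.

What passing tests on this cohort do **not** show: robustness to real-world
features the generator omits — correlated item non-response, reporting
error in portion sizes, seasonal menus, multi-dimensional dietary
patterns, and realistic food-composition covariance. Sign-recovery results
on the generator are evidence the pipeline is wired correctly, not
evidence about any population.

## Numerical choices and problem sizes

All randomness flows through explicit seeds (cohorts, imputation forests);
the imputer restricts ranger to one thread so results are reproducible
across machines. Degenerate inputs are handled explicitly: constant
variables yield NA correlations rather than errors, empty recall files
parse to empty tables, unknown food or dish codes warn and route to the
exclusion sentinel rather than aborting. Test simulations use cohorts of
100–3000 individuals and forests of 50–100 trees — sizes at which the
sign-recovery and rate-convergence checks are already stable; the
large-cohort checks pass `num_trees = 50` to the imputer, trading a little
imputation accuracy for speed without touching any statistical threshold.

## Known limitations

The shipped weights/thresholds are approximations; scores are not
comparable with values computed under the original expert-decided
parameters. FPQ imputation is single imputation — no uncertainty
propagation. The PANDiet here uses the within-person variance directly
rather than a deconvolved usual-intake distribution. Survey-design support
covers weights and one clustering level (no strata, no multi-stage
variance).
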