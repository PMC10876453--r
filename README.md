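# orchidscore

Occurrence-based healthy dietary diversity (ORCHID) scoring for older
adults, in R.

Most diet-quality and dietary-diversity indices need precisely weighed food
portions, which makes them hard to use in field prevention interventions.
The ORCHID score instead rates *consumption occurrences*: how many times a
person eats foods from each of twenty food groups, aligned with French
dietary guidelines for older adults, with an emphasis on protein-rich
foods. Thirteen groups eaten daily in the French population (vegetables,
fruits, dairy, starches, oils, the moderation groups, ...) are counted from
three 24-hour dietary recalls; seven infrequently eaten groups (poultry,
eggs, fatty fish, lean fish and shellfish, legumes, nuts, wholemeal
products) come from a food propensity questionnaire (FPQ) as weekly
frequencies.

## The score

For each food group *g* with occurrence count *n_g*:

- **positive rating** (groups whose consumption guidelines favour):
  `component_g = n_g × w_g`
- **threshold rating** (energy-dense groups to consume in moderation, with
  threshold *t_g*):
  `component_g = n_g` if `n_g ≤ t_g`, else `component_g = (n_g − t_g) × w_g`
  (with *w_g* typically negative)

The total score is the sum of the twenty components. A recall declaration
counts as an occurrence only if the group's *daily* consumption reaches
half a standard portion (e.g. 25 g for the 50 g cooked-ham portion);
complex dishes are first disaggregated into their main ingredients (the
smallest set of ingredients covering half of the recipe mass). Missing FPQ
responses are imputed with iterative random forests, and monthly
frequencies are converted to weekly ones (÷ 4.345).

The package also implements the three companion diet-quality measures used
to validate the score construct — solid energy density
(SED = 100 × kcal / g of solid foods), the mean adequacy ratio
(MAR = 100 × mean of intake/RDA capped at 1 over 22 nutrients) and the
PANDiet (mean probability of adequate usual intake over 27 nutrients, split
into adequacy and moderation sub-scores) — plus the survey-weighted
validation battery (quartile tables, Spearman/Pearson correlations with
strength labels, Wilcoxon/ANOVA/chi-square tests) and a seeded synthetic
dietary-survey generator with a controllable healthiness gradient.

The shipped scoring weights/thresholds and nutrient reference tables are
documented, editable approximations (the reference tables are labelled
synthetic); replace them with your own for any real analysis.

## Worked example

```r
library(orchidscore)

cfg <- load_group_config()                      # packaged default config
spec <- cohort_spec(n_individuals = 120, seed = 7)
co <- generate_cohort(spec)                     # synthetic survey bundle

flat <- disaggregate_recalls(co$recalls, co$recipes)
occ  <- count_occurrences(flat, co$mapping, cfg)
wk   <- fpq_weekly_occurrences(co$fpq, co$fpq_mapping, seed = 7)
res  <- compute_orchid(occ, wk, cfg)
res
#> ORCHID scores for 120 individuals
#>   mean 69.3 (sd 25.0), range 14.6 to 153.5

mar_refs <- read_reference_table(orchid_example_references("mar"), "mar")
pd_refs  <- read_reference_table(orchid_example_references("pandiet"), "pandiet")
met <- diet_quality_metrics(flat, co$nutrients, mar_refs, pd_refs, co$covariates)
s <- res$scores$total[match(met$individual_id, res$scores$individual_id)]
cor(s, met$sed)       #> -0.739  (higher score, lower energy density)
cor(s, met$pandiet)   #>  0.709  (higher score, better nutrient adequacy)
```

The mean/range above come from the package's synthetic cohort with its
default gradient, not from any survey. `orchid_demo()` chains
simulate → score → metrics → validate on packaged defaults and writes all
artifacts (occurrence, score and metrics CSVs, a JSON validity report, a
run log) to a directory; `inst/scripts/orchid.R` is a thin command-line
front end over the same functions.

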