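test_that("weighted means reproduce hand computations and reduce to unweighted", {
  # two-point toy: values {0, 10}, weights {1, 3} -> weighted mean 7.5
  ids <- paste0("p", 1:8)
  scores <- data.frame(individual_id = ids, total = 1:8)
  vars <- data.frame(individual_id = ids, v = c(0, 10, 0, 10, 0, 10, 0, 10))
  design <- data.frame(individual_id = ids, weight = c(1, 3, 1, 3, 1, 3, 1, 3))
  qt <- quartile_table(scores, vars, design)
  overall <- qt[qt$variable == "v" & qt$quartile == "all", ]
  expect_equal(overall$mean, 7.5)

  # equal weights equal the unweighted means to machine precision
  design1 <- data.frame(individual_id = ids, weight = rep(2, 8))
  qt1 <- quartile_table(scores, vars, design1)
  qt0 <- quartile_table(scores, vars)
  expect_equal(qt1$mean, qt0$mean, tolerance = 1e-14)

  expect_error(quartile_table(scores, vars,
                              transform(design, weight = c(-1, design$weight[-1]))),
               "positive")
  expect_error(quartile_table(scores[1:4, ], vars[1:4, ]), "at least 8")
})

test_that("quartile means of the score itself are strictly increasing", {
  set.seed(21)
  ids <- paste0("p", 1:100)
  scores <- data.frame(individual_id = ids, total = stats::rnorm(100))
  vars <- data.frame(individual_id = ids, self = scores$total)
  qt <- quartile_table(scores, vars)
  m <- qt$mean[qt$quartile != "all"]
  expect_true(all(diff(m) > 0))
  # quartile membership partitions with near-equal sizes
  sizes <- qt$n[qt$quartile != "all"]
  expect_equal(sum(sizes), 100)
  expect_lte(diff(range(sizes)), 1)
})

test_that("correlations label identity, antitone identity and constants correctly", {
  set.seed(31)
  x <- stats::rnorm(50)
  self <- correlate(x, x, "spearman")
  expect_equal(self$r, 1)
  expect_equal(self$strength, "high")
  anti <- correlate(x, -x, "spearman")
  expect_equal(anti$r, -1)
  expect_equal(anti$strength, "high")
  flat <- correlate(x, rep(2, 50), "pearson")
  expect_true(is.na(flat$r))
  expect_true(is.na(flat$strength))
})

test_that("strength labelling reproduces the published rule, boundary at 0.2 closed", {
  r <- c(0.9, 0.51, 0.5, 0.35, 0.21, 0.2, 0.19, 0.05, 0,
         -0.05, -0.2, -0.35, -0.6)
  expect_equal(correlation_strength(r),
               c("high", "high", "moderate", "moderate", "moderate",
                 "moderate", "low", "low", "low",
                 "low", "moderate", "moderate", "high"))
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(41)
  x <- stats::rnorm(60)
  y <- x + stats::rnorm(60)
  base <- correlate(x, y, "spearman")$r
  expect_equal(correlate(exp(x), y, "spearman")$r, base)
  expect_equal(correlate(x, y^3 + 5 * y, "spearman")$r, base)
})

test_that("group tests recover no-effect and hand-computed chi-square cases", {
  # identical distributions in both groups: Wilcoxon p near 1
  v <- rep(c(1, 2, 3, 4), 2)
  g <- rep(c("m", "f"), each = 4)
  wt <- group_tests(v, g, "wilcoxon")
  expect_equal(wt$p_value, 1, tolerance = 1e-9)

  # chi-square with identical margins per group: statistic 0
  v0 <- rep(c("yes", "no"), times = c(10, 10))
  g0 <- rep(c("a", "b"), 10)
  expect_equal(group_tests(v0, g0, "chisq")$statistic, 0)

  # perfectly separated 2x2 {{10,0},{0,10}}: statistic 20 uncorrected
  v1 <- rep(c("yes", "no"), each = 10)
  g1 <- rep(c("a", "b"), each = 10)
  expect_equal(group_tests(v1, g1, "chisq")$statistic, 20)

  expect_error(group_tests(1:5, rep("a", 5), "wilcoxon"), "2")
})

test_that("quartile-adjusted ANOVA reports the group effect", {
  set.seed(51)
  n <- 120
  q <- factor(sample(paste0("Q", 1:4), n, replace = TRUE))
  sex <- factor(sample(c("m", "f"), n, replace = TRUE))
  y <- as.integer(q) + (sex == "m") * 2 + stats::rnorm(n)
  res <- group_tests(y, sex, "anova_adjusted", quartile = q)
  expect_lt(res$p_value, 1e-6)
  y0 <- as.integer(q) + stats::rnorm(n)
  res0 <- group_tests(y0, sex, "anova_adjusted", quartile = q)
  expect_gt(res0$p_value, 0.01)
})

test_that("the validity report carries the full battery with expected signs", {
  spec <- cohort_spec(n_individuals = 100, seed = 17, fpq_missingness = 0)
  co <- generate_cohort(spec)
  flat <- disaggregate_recalls(co$recalls, co$recipes)
  occ <- count_occurrences(flat, co$mapping, spec$config)
  wk <- fpq_weekly_occurrences(co$fpq, co$fpq_mapping, seed = 17)
  res <- compute_orchid(occ, wk, spec$config)
  met <- diet_quality_metrics(flat, co$nutrients, mar_refs, pandiet_refs,
                              co$covariates)
  gi <- group_intakes(flat, co$mapping, spec$config)
  rep <- validity_report(res$scores, res$components, gi, met,
                         co$covariates, co$design)

  fruit_int <- rep$intake_correlations[
    rep$intake_correlations$group_id == "fruits", ]
  expect_gt(fruit_int$r, 0)
  sed_cor <- rep$metric_correlations[
    rep$metric_correlations$variable == "sed", ]
  expect_lt(sed_cor$r, 0)
  expect_equal(nrow(rep$component_correlations), 20)
  expect_true(!is.null(rep$sex_tests))
  expect_true(all(c("component_correlations", "intake_correlations",
                    "metric_correlations", "quartile_tables", "sex_tests",
                    "covariate_tests") %in% names(rep)))

  # serialises to valid JSON
  path <- withr::local_tempfile(fileext = ".json")
  write_validity_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_setequal(names(back), names(rep))
})

test_that("a cohort of identical individuals yields undefined correlations, no crash", {
  ids <- paste0("p", 1:10)
  scores <- data.frame(individual_id = ids, total = rep(5, 10))
  comp <- expand.grid(individual_id = ids,
                      group_id = default_cfg$group_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  comp$occurrences <- 1
  comp$points <- 1
  gi <- transform(comp[c("individual_id", "group_id")], grams_per_day = 50)
  met <- data.frame(individual_id = ids, sed = 150, mar = 80, pandiet = 60)
  covs <- data.frame(individual_id = ids,
                     sex = rep(c("m", "f"), 5), stringsAsFactors = FALSE)
  rep <- validity_report(scores, comp, gi, met, covs)
  expect_true(all(is.na(rep$metric_correlations$r)))
  expect_true(all(is.na(rep$component_correlations$r)))
})
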