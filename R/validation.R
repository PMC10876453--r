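# Construct-validity analysis battery: survey-weighted quartile summaries,
# correlations with strength labels, sex-stratified tests and categorical
# association with socio-demographics.

#' Weighted quantiles
#'
#' Quantiles of the weighted empirical distribution: the smallest observed
#' value whose cumulative normalised weight reaches the probability.
#'
#' @param x Numeric vector.
#' @param w Positive weights (default uniform).
#' @param probs Probabilities.
#' @return Quantile values.
#' @export
weighted_quantile <- function(x, w = rep(1, length(x)), probs) {
  if (any(w <= 0)) stop("weights must be positive")
  ord <- order(x)
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[ord][which(cw >= p - 1e-12)[1]], numeric(1))
}

#' Assign score quartiles
#'
#' Quartile membership from the (weighted) quartile cut points of the score;
#' values at a cut point go to the lower quartile.
#'
#' @param score Numeric score vector.
#' @param w Optional sampling weights.
#' @return Ordered factor Q1..Q4.
#' @export
score_quartiles <- function(score, w = rep(1, length(score))) {
  cuts <- weighted_quantile(score, w, c(0.25, 0.5, 0.75))
  q <- 1L + (score > cuts[1]) + (score > cuts[2]) + (score > cuts[3])
  factor(paste0("Q", q), levels = paste0("Q", 1:4), ordered = TRUE)
}

# Weighted mean with linearised (with-replacement) SE; clusters, when
# given, are aggregated first so the SE is cluster-robust.
.wmean_se <- function(x, w, cluster = NULL) {
  if (!is.null(cluster)) {
    tw <- rowsum(w, cluster)[, 1]
    tx <- rowsum(x * w, cluster)[, 1] / tw
    x <- tx
    w <- tw
  }
  W <- sum(w)
  mu <- sum(w * x) / W
  n <- length(x)
  se <- if (n > 1) sqrt(sum((w * (x - mu))^2) / W^2 * n / (n - 1)) else NA_real_
  sdv <- sqrt(sum(w * (x - mu)^2) / W)
  c(mean = mu, se = se, sd = sdv)
}

#' Variable summaries by score quartile
#'
#' For each variable: overall (weighted) mean, and per score quartile the
#' weighted mean, standard deviation and 95 % confidence interval (normal
#' approximation on the linearised standard error; cluster-robust when the
#' design carries cluster identifiers).
#'
#' @param scores data.frame `individual_id`, `total` ([compute_orchid()]
#'   `$scores`).
#' @param variables data.frame of numeric variables, with `individual_id`.
#' @param design Optional data.frame `individual_id`, `weight` (> 0) and
#'   optional `cluster`.
#' @return Tidy data.frame: `variable`, `quartile` (`"all"` or Q1..Q4),
#'   `mean`, `sd`, `ci_lo`, `ci_hi`, `n`.
#' @export
quartile_table <- function(scores, variables, design = NULL) {
  df <- merge(scores, variables, by = "individual_id")
  if (nrow(df) < 8) stop("need at least 8 individuals for quartiles")
  if (is.null(design)) {
    df$.w <- 1
    df$.cl <- NULL
  } else {
    if (any(design$weight <= 0)) stop("sampling weights must be positive")
    df <- merge(df, design, by = "individual_id")
    df$.w <- df$weight
    df$.cl <- if ("cluster" %in% names(design)) df$cluster else NULL
  }
  df$.q <- score_quartiles(df$total, df$.w)
  vars <- setdiff(names(variables), "individual_id")
  out <- list()
  for (v in vars) {
    rows <- lapply(c("all", levels(df$.q)), function(q) {
      sub <- if (q == "all") df else df[df$.q == q, , drop = FALSE]
      st <- .wmean_se(sub[[v]], sub$.w, sub$.cl)
      data.frame(variable = v, quartile = q, mean = st["mean"],
                 sd = st["sd"],
                 ci_lo = st["mean"] - 1.96 * st["se"],
                 ci_hi = st["mean"] + 1.96 * st["se"],
                 n = nrow(sub), stringsAsFactors = FALSE, row.names = NULL)
    })
    out[[v]] <- do.call(rbind, rows)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Correlation-strength label
#'
#' High strength when `|r| > 0.5`, moderate when `0.2 <= |r| <= 0.5`, low
#' when `|r| < 0.2` (the boundary `|r| = 0.2` is labelled moderate, closing
#' the lower bound symmetrically with the closed upper bound at 0.5).
#'
#' @param r Correlation coefficient(s).
#' @return Character vector in `{"high", "moderate", "low"}`, NA for NA r.
#' @export
correlation_strength <- function(r) {
  a <- abs(r)
  ifelse(is.na(a), NA_character_,
         ifelse(a > 0.5, "high", ifelse(a >= 0.2, "moderate", "low")))
}

#' Correlation between the score and a variable
#'
#' Spearman (rank-based, used for non-normal component and food-group
#' intake distributions) or Pearson correlation with a two-sided p-value and
#' the strength label of [correlation_strength()]. A constant input yields
#' an undefined correlation, reported as NA rather than an error.
#'
#' @param score,variable Paired numeric vectors (>= 3 finite pairs).
#' @param method `"spearman"` or `"pearson"`.
#' @return One-row data.frame `method`, `r`, `p_value`, `strength`.
#' @export
correlate <- function(score, variable, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- is.finite(score) & is.finite(variable)
  if (sum(ok) < 3) stop("need at least 3 paired finite observations")
  if (stats::sd(score[ok]) == 0 || stats::sd(variable[ok]) == 0) {
    return(data.frame(method = method, r = NA_real_, p_value = NA_real_,
                      strength = NA_character_, stringsAsFactors = FALSE))
  }
  ct <- suppressWarnings(
    stats::cor.test(score[ok], variable[ok], method = method, exact = FALSE))
  r <- unname(ct$estimate)
  data.frame(method = method, r = r, p_value = ct$p.value,
             strength = correlation_strength(r), stringsAsFactors = FALSE)
}

#' Two-group and quartile tests
#'
#' `wilcoxon`: rank-sum test of a variable between two groups (used for the
#' effect of sex on components and food-group intakes). `anova_adjusted`:
#' linear-model ANOVA of the variable on the group factor adjusted on the
#' score quartiles; the reported statistic and p-value are for the group
#' effect. `chisq`: Pearson chi-square test of independence (no continuity
#' correction) between a categorical variable and the group factor.
#'
#' @param variable Numeric vector (factor/character for `chisq`).
#' @param group Grouping factor (e.g. sex or score quartile).
#' @param kind `"wilcoxon"`, `"anova_adjusted"` or `"chisq"`.
#' @param quartile Score-quartile factor, required for `anova_adjusted`.
#' @return One-row data.frame `kind`, `statistic`, `p_value`.
#' @export
group_tests <- function(variable, group,
                        kind = c("wilcoxon", "anova_adjusted", "chisq"),
                        quartile = NULL) {
  kind <- match.arg(kind)
  group <- factor(group)
  if (any(table(group) == 0) || nlevels(group) < 2)
    stop("need at least 2 non-empty groups")
  if (kind == "wilcoxon") {
    if (nlevels(group) != 2) stop("wilcoxon requires exactly 2 groups")
    ht <- suppressWarnings(
      stats::wilcox.test(variable ~ group, exact = FALSE, correct = FALSE))
    res <- c(ht$statistic, ht$p.value)
  } else if (kind == "anova_adjusted") {
    if (is.null(quartile)) stop("anova_adjusted requires score quartiles")
    fit <- stats::lm(variable ~ factor(quartile) + group)
    an <- stats::anova(fit)
    res <- c(an["group", "F value"], an["group", "Pr(>F)"])
  } else {
    tab <- table(variable, group)
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    res <- c(ht$statistic, ht$p.value)
  }
  data.frame(kind = kind, statistic = unname(res[1]),
             p_value = unname(res[2]), stringsAsFactors = FALSE)
}

#' Full construct-validity report for a cohort
#'
#' Runs the whole validation battery: Spearman correlations of the total
#' score with each component's points and with each food group's mean daily
#' intake; Pearson correlations with energy and the diet-quality measures
#' (SED, MAR, PANDiet and sub-scores); quartile summary tables; Wilcoxon
#' sex tests on components; and chi-square association of categorical
#' covariates with the score quartile.
#'
#' @param scores data.frame `individual_id`, `total`.
#' @param components Long component table ([compute_orchid()] `$components`).
#' @param group_intakes data.frame `individual_id`, `group_id`,
#'   `grams_per_day` of mean daily food-group intakes.
#' @param metrics Diet-quality metrics ([diet_quality_metrics()]), including
#'   an `energy_kcal` column of mean daily energy if available.
#' @param covariates data.frame with `individual_id`, a `sex` column and any
#'   categorical covariates to test across quartiles.
#' @param design Optional survey design (`individual_id`, `weight`,
#'   optional `cluster`); Spearman correlations stay unweighted.
#' @return List of class `"orchid_validity"` with elements
#'   `component_correlations`, `intake_correlations`,
#'   `metric_correlations`, `quartile_tables`, `sex_tests`,
#'   `covariate_tests`. Serialise with [write_validity_report()].
#' @export
validity_report <- function(scores, components, group_intakes, metrics,
                            covariates, design = NULL) {
  s <- scores[order(scores$individual_id), , drop = FALSE]
  cor_block <- function(long, value_col, method) {
    keys <- sort(unique(long$group_id))
    do.call(rbind, lapply(keys, function(g) {
      sub <- long[long$group_id == g, , drop = FALSE]
      x <- merge(s, sub, by = "individual_id")
      cbind(data.frame(group_id = g, stringsAsFactors = FALSE),
            correlate(x$total, x[[value_col]], method))
    }))
  }
  comp_cor <- cor_block(components, "points", "spearman")
  intake_cor <- cor_block(group_intakes, "grams_per_day", "spearman")

  met <- merge(s, metrics, by = "individual_id")
  met_vars <- setdiff(names(metrics), "individual_id")
  metric_cor <- do.call(rbind, lapply(met_vars, function(v)
    cbind(data.frame(variable = v, stringsAsFactors = FALSE),
          correlate(met$total, met[[v]], "pearson"))))

  qt <- quartile_table(s, metrics, design)

  cov <- merge(s, covariates, by = "individual_id")
  sex_tests <- NULL
  if ("sex" %in% names(cov) && nlevels(factor(cov$sex)) == 2) {
    sex_tests <- do.call(rbind, lapply(sort(unique(components$group_id)),
      function(g) {
        x <- merge(cov, components[components$group_id == g, ],
                   by = "individual_id")
        cbind(data.frame(group_id = g, stringsAsFactors = FALSE),
              group_tests(x$points, x$sex, "wilcoxon"))
      }))
  }

  q <- score_quartiles(cov$total,
                       if (is.null(design)) rep(1, nrow(cov)) else
                         design$weight[match(cov$individual_id,
                                             design$individual_id)])
  cat_vars <- setdiff(names(covariates)[!vapply(covariates, is.numeric,
                                                logical(1))],
                      "individual_id")
  covariate_tests <- if (length(cat_vars) && nlevels(droplevels(q)) >= 2)
    do.call(rbind, lapply(cat_vars, function(v)
      cbind(data.frame(variable = v, stringsAsFactors = FALSE),
            group_tests(cov[[v]], droplevels(q), "chisq")))) else NULL

  structure(list(component_correlations = comp_cor,
                 intake_correlations = intake_cor,
                 metric_correlations = metric_cor,
                 quartile_tables = qt,
                 sex_tests = sex_tests,
                 covariate_tests = covariate_tests),
            class = "orchid_validity")
}

#' Write a validity report as JSON
#'
#' @param report [validity_report()] result.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_validity_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Mean daily food-group intakes (g/d)
#'
#' Maps each declaration to its ORCHID group and averages the summed grams
#' over the recall days, giving the mean daily intake of each of the twenty
#' groups per individual (zero for non-consumed groups). Excluded/unknown
#' foods are ignored.
#'
#' @param recalls Disaggregated recall declarations.
#' @param mapping Food-code to group mapping.
#' @param config Scoring configuration.
#' @param n_days Number of recall days (default 3).
#' @return data.frame `individual_id`, `group_id`, `grams_per_day`.
#' @export
group_intakes <- function(recalls, mapping, config, n_days = 3) {
  grp <- mapping$group_id[match(recalls$food_code, mapping$food_code)]
  keep <- !is.na(grp) & grp %in% config$group_id
  ids <- unique(recalls$individual_id)
  grid <- expand.grid(individual_id = ids, group_id = config$group_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$individual_id, grid$group_id), , drop = FALSE]
  rownames(grid) <- NULL
  grid$grams_per_day <- 0
  if (any(keep)) {
    key <- paste(recalls$individual_id[keep], grp[keep], sep = "\r")
    tot <- rowsum(recalls$grams[keep], key)
    hit <- match(paste(grid$individual_id, grid$group_id, sep = "\r"),
                 rownames(tot))
    grid$grams_per_day <- ifelse(is.na(hit), 0, tot[hit, 1] / n_days)
  }
  grid
}
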