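# Companion diet-quality measures used to validate the score: solid energy
# density (SED), mean adequacy ratio (MAR) and the PANDiet probability-of-
# adequate-nutrient-intake score.

# Match reference rows to an individual's sex / age band; 'all' matches
# everyone. Returns the per-nutrient reference value vector.
.match_references <- function(refs, value_col, sex, age_band) {
  ok <- (refs$sex == "all" | refs$sex == sex) &
    (refs$age_band == "all" | refs$age_band == age_band)
  r <- refs[ok, , drop = FALSE]
  # sex/age-specific rows shadow 'all' rows for the same nutrient
  specific <- r$sex != "all" | r$age_band != "all"
  r <- r[order(!specific), , drop = FALSE]
  r <- r[!duplicated(r$nutrient_id), , drop = FALSE]
  stats::setNames(r[[value_col]], r$nutrient_id)
}

#' Solid energy density (kcal per 100 g)
#'
#' Ratio of total energy to total mass consumed, counting solid foods only,
#' pooled over all recall days of an individual:
#' `SED = 100 x sum(energy of solids) / sum(grams of solids)`. Beverages do
#' not enter either sum, so adding beverage records leaves the SED
#' unchanged.
#'
#' @param declarations Recall declarations carrying `individual_id`,
#'   `grams`, `is_solid` and an `energy_kcal` column (energy of each
#'   declaration).
#' @return data.frame `individual_id`, `sed`.
#' @export
solid_energy_density <- function(declarations) {
  if (!"energy_kcal" %in% names(declarations))
    stop("declarations need an energy_kcal column")
  s <- declarations[declarations$is_solid, , drop = FALSE]
  ids <- unique(declarations$individual_id)
  g <- rowsum(s$grams, s$individual_id)
  e <- rowsum(s$energy_kcal, s$individual_id)
  i <- match(as.character(ids), rownames(g))
  if (anyNA(i) || any(g[i, 1] <= 0))
    stop("no solid food mass for individual(s): ",
         paste(ids[is.na(i) | g[i, 1] <= 0], collapse = ", "))
  data.frame(individual_id = ids, sed = 100 * e[i, 1] / g[i, 1],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mean adequacy ratio (MAR)
#'
#' Mean over the reference nutrients of the ratio of the individual's mean
#' daily intake to the sex- and age-specific recommended dietary allowance
#' (RDA), each ratio capped at 1, expressed as a percentage:
#' `MAR = 100 x mean(min(intake / RDA, 1))`. Bounded in `[0, 100]`.
#'
#' @param intakes Per-day nutrient intakes ([read_nutrient_intakes()]).
#' @param rda_table MAR reference table ([read_reference_table()] with
#'   `kind = "mar"`), conventionally 22 key nutrients.
#' @param demographics data.frame `individual_id`, `sex` and optionally
#'   `age_band`, used to select the applicable RDA rows.
#' @return data.frame `individual_id`, `mar`.
#' @export
mean_adequacy_ratio <- function(intakes, rda_table, demographics) {
  if (!"age_band" %in% names(demographics)) demographics$age_band <- "all"
  nutrients <- unique(rda_table$nutrient_id)
  out <- lapply(seq_len(nrow(demographics)), function(k) {
    id <- demographics$individual_id[k]
    rda <- .match_references(rda_table, "rda",
                             demographics$sex[k], demographics$age_band[k])
    x <- intakes[intakes$individual_id == id &
                   intakes$nutrient_id %in% nutrients, , drop = FALSE]
    mean_in <- tapply(x$amount, x$nutrient_id, mean)
    miss <- setdiff(nutrients, names(mean_in))
    if (length(miss))
      stop("individual '", id, "' lacks intake for nutrient(s): ",
           paste(miss, collapse = ", "))
    ratio <- pmin(mean_in[nutrients] / rda[nutrients], 1)
    data.frame(individual_id = id, mar = 100 * mean(ratio),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' PANDiet probability-of-adequate-nutrient-intake score
#'
#' For each nutrient the probability of adequacy (PA) is computed under a
#' Gaussian model of the usual intake: the usual-intake mean is the observed
#' day-mean with standard error `sd / sqrt(n)`, where `sd` is the
#' day-to-day standard deviation over the `n` recall days. For an `at_least`
#' nutrient `PA = P(usual intake >= reference)`; for an `at_most` nutrient
#' `PA = P(usual intake <= reference)`. The adequacy sub-score is 100 times
#' the mean PA over `at_least` nutrients, the moderation sub-score the same
#' over `at_most` nutrients, and the total is their average; all lie in
#' `[0, 100]`. A zero observed day-to-day standard deviation is replaced by
#' `var_floor` times the reference value so that constant intakes yield
#' well-defined (near-0/1) probabilities rather than degenerate ones.
#'
#' @param intakes Per-day nutrient intakes over at least two days.
#' @param refs PANDiet reference table ([read_reference_table()] with
#'   `kind = "pandiet"`), conventionally 27 nutrients.
#' @param demographics data.frame `individual_id`, `sex` and optionally
#'   `age_band`.
#' @param var_floor Fraction of the reference used as the standard
#'   deviation floor (default 0.10).
#' @return data.frame `individual_id`, `pandiet`, `pandiet_adequacy`,
#'   `pandiet_moderation`.
#' @export
pandiet <- function(intakes, refs, demographics, var_floor = 0.10) {
  if (!"age_band" %in% names(demographics)) demographics$age_band <- "all"
  nutrients <- unique(refs$nutrient_id)
  dir <- stats::setNames(refs$direction, refs$nutrient_id)[nutrients]
  out <- lapply(seq_len(nrow(demographics)), function(k) {
    id <- demographics$individual_id[k]
    ref <- .match_references(refs, "reference",
                             demographics$sex[k], demographics$age_band[k])
    x <- intakes[intakes$individual_id == id &
                   intakes$nutrient_id %in% nutrients, , drop = FALSE]
    n_days <- tapply(x$day, x$nutrient_id, function(d) length(unique(d)))
    miss <- setdiff(nutrients, names(n_days))
    if (length(miss))
      stop("individual '", id, "' lacks intake for nutrient(s): ",
           paste(miss, collapse = ", "))
    if (any(n_days < 2))
      stop("individual '", id,
           "' needs >= 2 recall days to estimate usual intake (nutrient ",
           names(n_days)[n_days < 2][1], ")")
    m <- tapply(x$amount, x$nutrient_id, mean)[nutrients]
    s <- tapply(x$amount, x$nutrient_id, stats::sd)[nutrients]
    n <- n_days[nutrients]
    s <- ifelse(s > 0, s, var_floor * ref[nutrients])
    se <- s / sqrt(n)
    z <- (m - ref[nutrients]) / se
    pa <- ifelse(dir == "at_least", stats::pnorm(z), stats::pnorm(-z))
    adeq <- 100 * mean(pa[dir == "at_least"])
    mod <- 100 * mean(pa[dir == "at_most"])
    data.frame(individual_id = id,
               pandiet = (adeq + mod) / 2,
               pandiet_adequacy = adeq,
               pandiet_moderation = mod,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' All three diet-quality measures for a cohort
#'
#' Convenience wrapper computing SED, MAR and the PANDiet (with sub-scores)
#' per individual and joining them into one table.
#'
#' @inheritParams solid_energy_density
#' @inheritParams mean_adequacy_ratio
#' @inheritParams pandiet
#' @return data.frame `individual_id`, `sed`, `mar`, `pandiet`,
#'   `pandiet_adequacy`, `pandiet_moderation`.
#' @export
diet_quality_metrics <- function(declarations, intakes, rda_table, refs,
                                 demographics, var_floor = 0.10) {
  sed <- solid_energy_density(declarations)
  mar <- mean_adequacy_ratio(intakes, rda_table, demographics)
  pd <- pandiet(intakes, refs, demographics, var_floor)
  out <- merge(sed, mar, by = "individual_id")
  out <- merge(out, pd, by = "individual_id")
  out[order(out$individual_id), , drop = FALSE]
}
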