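# Seeded generator of complete synthetic dietary-survey cohorts (recalls,
# recipes, FPQ, nutrient intakes, covariates, design weights) with a single
# latent diet-healthiness dimension, so the whole scoring and validation
# pipeline is testable without external survey microdata.

#' Paths of the synthetic example reference tables
#'
#' Illustrative (synthetic) MAR and PANDiet nutrient reference tables
#' shipped with the package. Values are plausible adult reference intakes
#' assembled by the package authors for demonstration and simulation; they
#' are not a normative nutrient reference and should be replaced for any
#' real analysis.
#'
#' @param kind `"mar"` (22 nutrients) or `"pandiet"` (27 nutrients).
#' @return File path.
#' @export
orchid_example_references <- function(kind = c("mar", "pandiet")) {
  kind <- match.arg(kind)
  system.file("extdata", paste0(kind, "_references_synthetic.csv"),
              package = "orchidscore", mustWork = TRUE)
}

#' Default per-group simulation parameters
#'
#' One row per ORCHID group: mean daily occurrence rate at average
#' healthiness (`base_rate`), loading of the log-rate on the latent
#' healthiness (`loading`), log-normal dispersion of per-occurrence grams
#' around the standard portion (`grams_sdlog`), energy density
#' (`energy_kcal_per_100g`) and solidity of the group's foods. Rates are
#' chosen to mimic a plausible French older-adult eating pattern: daily
#' staples (vegetables, fruits, starches) near one to two occurrences per
#' day, weekly foods (fish, legumes, nuts) well below one per day; loadings
#' carry the expected signs of a healthiness gradient (fruits, vegetables
#' and wholemeal products positive, energy-dense moderation groups
#' negative).
#'
#' @param config Scoring configuration providing portions and the group set.
#' @return data.frame of simulation parameters aligned with `config`.
#' @export
default_group_params <- function(config = load_group_config()) {
  p <- data.frame(
    group_id = c(
      "meat_excluding_poultry", "cooked_ham",
      "deli_meats_excluding_cooked_ham", "milk_and_fresh_dairy_products",
      "cheese", "refined_starches_and_potatoes", "vegetables", "fruits",
      "oils", "butter_margarine_and_fresh_cream", "salted_aperitif_products",
      "sweetened_products", "sweetened_beverages",
      "poultry", "eggs", "fatty_fish", "lean_fish_and_shellfish",
      "legumes", "nuts", "wholemeal_or_semi_wholemeal_products"),
    base_rate = c(0.7, 0.25, 0.3, 1.0, 0.8, 1.5, 1.8, 1.5,
                  1.2, 0.8, 0.25, 1.0, 0.4,
                  0.25, 0.3, 0.12, 0.15, 0.2, 0.3, 0.5),
    loading = c(-0.25, 0, -0.35, 0.15, 0, -0.1, 0.5, 0.5,
                0.1, -0.25, -0.35, -0.45, -0.5,
                0.1, 0, 0.3, 0.3, 0.25, 0.35, 0.6),
    energy_kcal_per_100g = c(200, 120, 330, 60, 350, 130, 35, 55,
                             880, 600, 500, 450, 40,
                             160, 140, 180, 110, 100, 600, 240),
    is_solid = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE,
                 TRUE, TRUE, TRUE, TRUE, FALSE,
                 TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    grams_sdlog = 0.35,
    stringsAsFactors = FALSE
  )
  p <- p[match(config$group_id, p$group_id), , drop = FALSE]
  if (anyNA(p$group_id)) stop("simulation parameters must cover all groups")
  rownames(p) <- NULL
  p
}

#' Specification of a synthetic dietary-survey cohort
#'
#' Bundles everything [generate_cohort()] needs: cohort size, number of
#' recall days, seed, per-group occurrence/grams/energy parameters, FPQ
#' item structure and missingness, the fraction of declarations wrapped
#' into complex dishes, nutrient reference tables (driving the nutrient
#' density matrix), day-to-day nutrient noise, and the energy-neutrality
#' flag (which rescales each individual's food masses so that total energy
#' intake is uncorrelated with the latent healthiness).
#'
#' @param n_individuals Cohort size.
#' @param n_days Recall days per individual (default 3).
#' @param seed Integer seed fixing the whole cohort.
#' @param config Scoring configuration.
#' @param group_params Per-group simulation parameters
#'   ([default_group_params()]).
#' @param items_per_group FPQ items mapped to each FPQ-source group.
#' @param n_fpq_items Total FPQ items (unmapped filler items pad the
#'   questionnaire to its usual length of about sixty items).
#' @param fpq_missingness Probability that an FPQ cell is missing (MCAR).
#' @param complex_dish_fraction Fraction of food declarations reported as a
#'   complex dish instead of the simple food.
#' @param nutrient_noise_sd SD of the multiplicative log-normal day-to-day
#'   noise on nutrient intakes.
#' @param energy_neutral Rescale intakes so energy is uncorrelated with the
#'   latent healthiness (default FALSE).
#' @return List of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_individuals = 500, n_days = 3, seed = 1,
                        config = load_group_config(),
                        group_params = default_group_params(config),
                        items_per_group = 3, n_fpq_items = 60,
                        fpq_missingness = 0.1,
                        complex_dish_fraction = 0.05,
                        nutrient_noise_sd = 0.15,
                        energy_neutral = FALSE) {
  validate_group_config(config)
  stopifnot(n_individuals >= 1, n_days >= 2,
            all(group_params$base_rate >= 0),
            fpq_missingness >= 0, fpq_missingness <= 1,
            complex_dish_fraction >= 0, complex_dish_fraction <= 1,
            nutrient_noise_sd >= 0)
  if (!identical(sort(group_params$group_id), sort(config$group_id)))
    stop("group_params must cover exactly the configured groups")
  structure(list(n_individuals = n_individuals, n_days = n_days,
                 seed = as.integer(seed), config = config,
                 group_params = group_params[match(config$group_id,
                                                   group_params$group_id), ],
                 items_per_group = items_per_group,
                 n_fpq_items = n_fpq_items,
                 fpq_missingness = fpq_missingness,
                 complex_dish_fraction = complex_dish_fraction,
                 nutrient_noise_sd = nutrient_noise_sd,
                 energy_neutral = energy_neutral),
            class = "cohort_spec")
}

# quality index in [-1, 1] used to tilt nutrient densities along the
# healthiness gradient
.group_quality <- function(loading) pmax(pmin(2 * loading, 1), -1)

#' Generate a synthetic dietary-survey cohort
#'
#' Per individual: a latent healthiness `h ~ N(0, 1)`; per day and group,
#' occurrence counts `~ Poisson(exp(log(base_rate) + loading * h))` with
#' per-occurrence grams log-normal around the group's standard portion; a
#' fraction of declarations wrapped into complex dishes with packaged
#' recipes; FPQ item frequencies consistent with the same latent rates plus
#' noise, with MCAR holes; per-day nutrient intakes from a density matrix
#' that concentrates reference nutrients in healthful groups and moderation
#' nutrients (sugars, saturated fat, sodium) in energy-dense ones, with
#' log-normal day-to-day noise; covariates (sex, education, smoking,
#' physical activity, BMI, income, household size) drawn with stated
#' loadings on `h`; and survey weights. With `energy_neutral = TRUE` each
#' individual's food masses and intakes are rescaled to an energy target
#' drawn independently of `h`.
#'
#' @param spec A [cohort_spec()].
#' @return List with elements `recalls`, `recipes`, `mapping`, `fpq`,
#'   `fpq_mapping`, `nutrients`, `covariates`, `design`, `truth` (latent
#'   healthiness and expected rates) and the generating `spec`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  set.seed(spec$seed)
  cfg <- spec$config
  gp <- spec$group_params
  n <- spec$n_individuals
  days <- spec$n_days
  G <- nrow(cfg)
  ids <- sprintf("id%05d", seq_len(n))

  h <- stats::rnorm(n)

  # --- recall declarations -------------------------------------------------
  grid <- expand.grid(i = seq_len(n), day = seq_len(days), g = seq_len(G),
                      KEEP.OUT.ATTRS = FALSE)
  lambda <- exp(log(pmax(gp$base_rate[grid$g], 1e-12)) +
                  gp$loading[grid$g] * h[grid$i])
  lambda[gp$base_rate[grid$g] == 0] <- 0
  counts <- stats::rpois(nrow(grid), lambda)
  ri <- rep(seq_len(nrow(grid)), counts)
  decl <- data.frame(
    individual_id = ids[grid$i[ri]],
    day = grid$day[ri],
    gidx = grid$g[ri],
    stringsAsFactors = FALSE
  )
  decl$grams <- stats::rlnorm(nrow(decl),
                              log(cfg$standard_portion_g[decl$gidx]),
                              gp$grams_sdlog[decl$gidx])
  decl$food_code <- paste0(cfg$group_id[decl$gidx], "_f",
                           sample.int(3, nrow(decl), replace = TRUE))
  decl$is_solid <- gp$is_solid[decl$gidx]
  decl$is_complex_dish <- FALSE
  decl$energy_kcal <- decl$grams * gp$energy_kcal_per_100g[decl$gidx] / 100

  # per individual-day group grams, before dish wrapping (nutrient basis)
  gkey <- paste(decl$individual_id, decl$day, sep = "\r")
  gmat <- matrix(0, n * days, G,
                 dimnames = list(
                   paste(rep(ids, each = days), rep(seq_len(days), n),
                         sep = "\r"), cfg$group_id))
  tot <- rowsum(decl$grams, paste(gkey, decl$gidx, sep = "\r"))
  parts <- strsplit(rownames(tot), "\r", fixed = TRUE)
  gmat[cbind(match(paste(vapply(parts, `[`, "", 1),
                         vapply(parts, `[`, "", 2), sep = "\r"),
                   rownames(gmat)),
             as.integer(vapply(parts, `[`, "", 3)))] <- tot[, 1]

  # wrap a fraction of declarations into complex dishes
  wrap <- stats::runif(nrow(decl)) < spec$complex_dish_fraction
  if (any(wrap)) {
    gi <- decl$gidx[wrap]
    decl$food_code[wrap] <- paste0("dish_", cfg$group_id[gi])
    decl$grams[wrap] <- decl$grams[wrap] / 0.6
    decl$is_complex_dish[wrap] <- TRUE
    decl$energy_kcal[wrap] <- decl$grams[wrap] *
      gp$energy_kcal_per_100g[gi] / 100
  }

  # water declarations (mapped to EXCLUDED), one per individual-day
  water <- data.frame(
    individual_id = rep(ids, each = days),
    day = rep(seq_len(days), n),
    gidx = NA_integer_,
    grams = pmax(stats::rnorm(n * days, 500, 100), 50),
    food_code = "water",
    is_solid = FALSE,
    is_complex_dish = FALSE,
    energy_kcal = 0,
    stringsAsFactors = FALSE
  )
  recalls <- rbind(decl, water)
  recalls$gidx <- NULL
  recalls <- recalls[order(recalls$individual_id, recalls$day,
                           recalls$food_code), , drop = FALSE]
  rownames(recalls) <- NULL

  # mapping and recipes
  mapping <- rbind(
    data.frame(food_code = paste0(rep(cfg$group_id, each = 3), "_f", 1:3),
               group_id = rep(cfg$group_id, each = 3),
               stringsAsFactors = FALSE),
    data.frame(food_code = paste0("dish_", cfg$group_id),
               group_id = "DISH_PLACEHOLDER", stringsAsFactors = FALSE),
    data.frame(food_code = c("water", "sauce_mix"),
               group_id = "EXCLUDED", stringsAsFactors = FALSE)
  )
  mapping <- mapping[mapping$group_id != "DISH_PLACEHOLDER", , drop = FALSE]
  recipes <- data.frame(
    dish_code = rep(paste0("dish_", cfg$group_id), each = 2),
    food_code = as.vector(rbind(paste0(cfg$group_id, "_f1"), "sauce_mix")),
    grams = rep(c(60, 40), G),
    stringsAsFactors = FALSE
  )

  # --- FPQ -----------------------------------------------------------------
  fpq_idx <- which(cfg$source == "fpq")
  mapped_items <- paste0(rep(cfg$group_id[fpq_idx],
                             each = spec$items_per_group),
                         "_item", seq_len(spec$items_per_group))
  n_filler <- max(spec$n_fpq_items -
                    length(mapped_items), 0)
  filler_items <- if (n_filler) sprintf("other_item%02d", seq_len(n_filler))
    else character(0)
  items <- c(mapped_items, filler_items)
  fpq_mapping <- data.frame(
    item_id = items,
    group_id = c(rep(cfg$group_id[fpq_idx], each = spec$items_per_group),
                 rep("EXCLUDED", n_filler)),
    stringsAsFactors = FALSE
  )
  share <- rep_len(c(0.5, 0.3, 0.2), spec$items_per_group)
  share <- share / sum(share)
  fpq_rows <- expand.grid(individual_id = ids, item_id = items,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mi <- match(fpq_rows$item_id, fpq_mapping$item_id)
  gi <- match(fpq_mapping$group_id[mi], cfg$group_id)  # NA for filler
  hi <- match(fpq_rows$individual_id, ids)
  weekly_rate <- ifelse(is.na(gi), 1.0,
                        7 * exp(log(pmax(gp$base_rate[ifelse(is.na(gi), 1, gi)],
                                         1e-12)) +
                                  gp$loading[ifelse(is.na(gi), 1, gi)] * h[hi]))
  item_rank <- as.integer(sub("^.*item", "", fpq_rows$item_id))
  item_rank[is.na(item_rank) | item_rank > length(share)] <- 1L
  wk <- weekly_rate * ifelse(is.na(gi), 1, share[item_rank]) *
    exp(stats::rnorm(nrow(fpq_rows), 0, 0.25))
  unit <- ifelse(item_rank %% 2 == 0, "per_month", "per_week")
  freq <- ifelse(unit == "per_month", wk * 4.345, wk)
  freq[stats::runif(length(freq)) < spec$fpq_missingness] <- NA
  fpq <- data.frame(individual_id = fpq_rows$individual_id,
                    item_id = fpq_rows$item_id,
                    frequency = freq, unit = unit, stringsAsFactors = FALSE)
  fpq <- fpq[order(fpq$individual_id, fpq$item_id), , drop = FALSE]
  rownames(fpq) <- NULL

  # --- nutrient intakes ----------------------------------------------------
  mar_refs <- read_reference_table(orchid_example_references("mar"), "mar")
  pd_refs <- read_reference_table(orchid_example_references("pandiet"),
                                  "pandiet")
  q <- .group_quality(gp$loading)
  adeq <- mar_refs$nutrient_id
  moder <- pd_refs$nutrient_id[pd_refs$direction == "at_most"]
  # nutrient x group densities per 100 g: a day totalling ~1000 g spread over
  # the groups lands near the reference for each nutrient
  dens <- rbind(
    outer(mar_refs$rda, 1 + 0.8 * q) / 10,
    outer(pd_refs$reference[pd_refs$direction == "at_most"], 1 - 0.8 * q) / 10
  )
  rownames(dens) <- c(adeq, moder)
  base_amt <- gmat %*% t(dens) / 100   # (ind-day) x nutrient
  noise <- matrix(exp(stats::rnorm(length(base_amt), 0,
                                   spec$nutrient_noise_sd)),
                  nrow(base_amt))
  amt <- base_amt * noise
  energy_day <- as.vector(gmat %*% gp$energy_kcal_per_100g / 100)

  # energy-neutral rescaling: per-individual factor towards an independent
  # energy target
  scale_i <- rep(1, n)
  if (spec$energy_neutral) {
    mean_energy <- rowsum(energy_day,
                          rep(ids, each = days))[, 1] / days
    target <- pmax(stats::rnorm(n, 2000, 250), 800)
    scale_i <- target / mean_energy
    sc_day <- scale_i[rep(seq_len(n), each = days)]
    amt <- amt * sc_day
    energy_day <- energy_day * sc_day
    sc_rec <- scale_i[match(recalls$individual_id, ids)]
    recalls$grams <- recalls$grams * sc_rec
    recalls$energy_kcal <- recalls$energy_kcal * sc_rec
  }

  nut_long <- data.frame(
    individual_id = rep(rep(ids, each = days), ncol(amt) + 1),
    day = rep(rep(seq_len(days), n), ncol(amt) + 1),
    nutrient_id = rep(c(colnames(amt), "energy_kcal"),
                      each = n * days),
    amount = c(as.vector(amt), energy_day),
    stringsAsFactors = FALSE
  )
  nut_long <- nut_long[order(nut_long$individual_id, nut_long$day,
                             nut_long$nutrient_id), , drop = FALSE]
  rownames(nut_long) <- NULL

  # --- covariates and design ----------------------------------------------
  edu_lat <- h + stats::rnorm(n, 0, 1.5)
  act_lat <- h + stats::rnorm(n, 0, 1.5)
  smoke_lat <- -h + stats::rnorm(n, 0, 1.5)
  covariates <- data.frame(
    individual_id = ids,
    sex = ifelse(stats::runif(n) < 0.58, "female", "male"),
    age_band = "60_plus",
    education = cut(edu_lat, c(-Inf, -0.5, 0.8, Inf),
                    labels = c("low", "mid", "high")),
    smoking = cut(smoke_lat, c(-Inf, 0.5, 1.2, Inf),
                  labels = c("never", "former", "current")),
    physical_activity = cut(act_lat, c(-Inf, -0.5, 0.8, Inf),
                            labels = c("low", "moderate", "high")),
    bmi = 26 - 1.2 * h + stats::rnorm(n, 0, 2.5),
    income = sample(c("low", "mid", "high"), n, replace = TRUE),
    household_size = 1 + stats::rpois(n, 0.9),
    stringsAsFactors = FALSE
  )
  covariates$education <- as.character(covariates$education)
  covariates$smoking <- as.character(covariates$smoking)
  covariates$physical_activity <- as.character(covariates$physical_activity)
  design <- data.frame(individual_id = ids,
                       weight = stats::runif(n, 0.5, 2),
                       stringsAsFactors = FALSE)

  truth <- list(
    healthiness = data.frame(individual_id = ids, h = h,
                             energy_scale = scale_i,
                             stringsAsFactors = FALSE),
    expected_daily_rates = outer(gp$base_rate, rep(1, n)) *
      exp(outer(gp$loading, h))
  )
  rownames(truth$expected_daily_rates) <- cfg$group_id
  colnames(truth$expected_daily_rates) <- ids

  list(recalls = recalls, recipes = recipes, mapping = mapping,
       fpq = fpq, fpq_mapping = fpq_mapping, nutrients = nut_long,
       covariates = covariates, design = design, truth = truth, spec = spec)
}

#' Ground truth of a generated cohort
#'
#' Returns the per-individual latent healthiness and expected group
#' occurrence rates, for parameter- and sign-recovery tests. Errors when
#' the cohort was not generated by the given spec.
#'
#' @param spec The [cohort_spec()] used for generation.
#' @param cohort A [generate_cohort()] result.
#' @return List `healthiness` (data.frame `individual_id`, `h`,
#'   `energy_scale`) and `expected_daily_rates` (group x individual matrix).
#' @export
ground_truth <- function(spec, cohort) {
  if (!identical(spec, cohort$spec))
    stop("cohort was not generated by this spec")
  cohort$truth
}
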