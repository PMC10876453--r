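test_that("solid energy density is the pooled energy/mass ratio of solids", {
  d <- make_recall("a", 1, "x", 500)
  d$energy_kcal <- 1000
  expect_equal(solid_energy_density(d)$sed, 200)

  # adding beverages leaves the SED unchanged
  bev <- make_recall("a", 1, "soda", 330, is_solid = FALSE)
  bev$energy_kcal <- 140
  expect_equal(solid_energy_density(rbind(d, bev))$sed, 200)

  # two days pool as one ratio, not a mean of daily ratios
  two <- rbind(make_recall("a", 1, "x", 400), make_recall("a", 2, "y", 200))
  two$energy_kcal <- c(800, 200)
  expect_equal(solid_energy_density(two)$sed, 100 * 1000 / 600)

  # no solid mass is an error
  expect_error(solid_energy_density(bev), "solid")
})

test_that("MAR closed forms: capped ratios average to the expected percentage", {
  ids <- "a"
  demo <- toy_demographics(ids)
  at_rda <- make_intakes("a", 2,
                         stats::setNames(as.list(mar_refs$rda),
                                         mar_refs$nutrient_id))
  expect_equal(mean_adequacy_ratio(at_rda, mar_refs, demo)$mar, 100)

  dbl <- make_intakes("a", 2,
                      stats::setNames(as.list(2 * mar_refs$rda),
                                      mar_refs$nutrient_id))
  expect_equal(mean_adequacy_ratio(dbl, mar_refs, demo)$mar, 100)

  # half the nutrients at 50 % of the RDA, half at or above: mean 75 %
  half <- mar_refs$rda
  half[1:11] <- half[1:11] / 2
  mix <- make_intakes("a", 2,
                      stats::setNames(as.list(half), mar_refs$nutrient_id))
  expect_equal(mean_adequacy_ratio(mix, mar_refs, demo)$mar, 75)

  # missing nutrient is an error naming it
  gap <- at_rda[at_rda$nutrient_id != "iron_mg", ]
  expect_error(mean_adequacy_ratio(gap, mar_refs, demo), "iron_mg")
})

test_that("MAR is invariant to a consistent unit rescaling of a nutrient", {
  demo <- toy_demographics("a")
  base <- make_intakes("a", 2,
                       stats::setNames(as.list(0.8 * mar_refs$rda),
                                       mar_refs$nutrient_id))
  refs2 <- mar_refs
  refs2$rda[refs2$nutrient_id == "calcium_mg"] <- 1000 *
    refs2$rda[refs2$nutrient_id == "calcium_mg"]
  base2 <- base
  sel <- base2$nutrient_id == "calcium_mg"
  base2$amount[sel] <- base2$amount[sel] * 1000
  expect_equal(mean_adequacy_ratio(base, mar_refs, demo)$mar,
               mean_adequacy_ratio(base2, refs2, demo)$mar)
})

test_that("PANDiet probability of adequacy is 0.5 at the reference and bounded", {
  refs1 <- data.frame(nutrient_id = "n1", sex = "all", age_band = "all",
                      reference = 100, direction = "at_least")
  demo <- toy_demographics("a")
  x <- make_intakes("a", 2, list(n1 = c(90, 110)))
  out <- pandiet(x, refs1, demo)
  expect_equal(out$pandiet_adequacy, 50)
  # with no moderation nutrients the moderation sub-score is NaN-free only
  # when at_most nutrients exist; build a 2-nutrient toy for the total
  refs2 <- rbind(refs1,
                 data.frame(nutrient_id = "n2", sex = "all", age_band = "all",
                            reference = 50, direction = "at_most"))
  x2 <- rbind(x, make_intakes("a", 2, list(n2 = c(10, 12))))
  out2 <- pandiet(x2, refs2, demo)
  expect_gt(out2$pandiet_moderation, 99.9)
  expect_equal(out2$pandiet, (out2$pandiet_adequacy +
                                out2$pandiet_moderation) / 2)
  expect_true(all(unlist(out2[-1]) >= 0 & unlist(out2[-1]) <= 100))
})

test_that("PANDiet reaches 100 in the certain-adequacy limit", {
  demo <- toy_demographics("a")
  amounts <- ifelse(pandiet_refs$direction == "at_least",
                    pandiet_refs$reference * 100,
                    pandiet_refs$reference / 100)
  x <- make_intakes("a", 3, stats::setNames(as.list(amounts),
                                            pandiet_refs$nutrient_id))
  # day-to-day jitter tiny relative to the gap
  x$amount <- x$amount * (1 + 1e-6 * (x$day - 2))
  out <- pandiet(x, pandiet_refs, demo)
  expect_equal(out$pandiet, 100, tolerance = 1e-9)
})

test_that("PANDiet closed form agrees with a Monte-Carlo oracle", {
  refs <- data.frame(nutrient_id = "n1", sex = "all", age_band = "all",
                     reference = 95, direction = "at_least")
  demo <- toy_demographics("a")
  x <- make_intakes("a", 2, list(n1 = c(90, 110)))
  pa <- pandiet(x, refs, demo)$pandiet_adequacy / 100
  # usual-intake mean ~ N(100, sd(90,110)/sqrt(2) = 10)
  set.seed(123)
  draws <- stats::rnorm(1e5, 100, 10)
  mc <- mean(draws >= 95)
  se <- sqrt(mc * (1 - mc) / 1e5)
  expect_lt(abs(pa - mc), 3 * se)
})

test_that("PA is monotone in day-mean and reference, in the right directions", {
  demo <- toy_demographics("a")
  pa_at <- function(mean_in, ref, dir) {
    refs <- data.frame(nutrient_id = "n", sex = "all", age_band = "all",
                       reference = ref, direction = dir)
    x <- make_intakes("a", 2, list(n = c(mean_in - 10, mean_in + 10)))
    out <- pandiet(x, refs, demo)
    if (dir == "at_least") out$pandiet_adequacy else out$pandiet_moderation
  }
  means <- seq(60, 140, by = 20)
  expect_true(all(diff(vapply(means, pa_at, numeric(1),
                              ref = 100, dir = "at_least")) > 0))
  expect_true(all(diff(vapply(means, pa_at, numeric(1),
                              ref = 100, dir = "at_most")) < 0))
  refs_up <- seq(60, 140, by = 20)
  expect_true(all(diff(vapply(refs_up, function(r)
    pa_at(100, r, "at_least"), numeric(1))) < 0))
})

test_that("zero day-to-day variance uses the floor; one day errors", {
  refs <- data.frame(nutrient_id = "n1", sex = "all", age_band = "all",
                     reference = 100, direction = "at_least")
  demo <- toy_demographics("a")
  const <- make_intakes("a", 3, list(n1 = c(120, 120, 120)))
  out <- pandiet(const, refs, demo)
  # sd floor 10 % of reference: z = (120-100)/(10/sqrt(3))
  expect_equal(out$pandiet_adequacy,
               100 * stats::pnorm(20 / (10 / sqrt(3))), tolerance = 1e-9)
  one_day <- make_intakes("a", 1, list(n1 = 120))
  expect_error(pandiet(one_day, refs, demo), "2 recall days")
})
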