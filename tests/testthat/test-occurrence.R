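test_that("main ingredients are the smallest half-mass prefix, ties included", {
  r1 <- data.frame(food_code = c("veg", "pasta", "cheese"),
                   grams = c(60, 30, 10))
  expect_equal(main_ingredients(r1)$food_code, "veg")
  r2 <- data.frame(food_code = c("veg", "pasta", "cheese"),
                   grams = c(40, 40, 20))
  expect_setequal(main_ingredients(r2)$food_code, c("veg", "pasta"))
  r3 <- data.frame(food_code = "only", grams = 80)
  expect_equal(main_ingredients(r3)$food_code, "only")
  # equal-mass tie at the boundary keeps all tied ingredients
  r4 <- data.frame(food_code = c("a", "b", "c"), grams = c(40, 30, 30))
  expect_setequal(main_ingredients(r4)$food_code, c("a", "b", "c"))
})

test_that("dish disaggregation scales ingredient grams by declared mass", {
  recipes <- data.frame(dish_code = "gratin",
                        food_code = c("veg", "pasta", "cheese"),
                        grams = c(60, 30, 10))
  d <- make_recall("a", 1, "gratin", 100, is_complex_dish = TRUE)
  out <- disaggregate_dish(d, recipes)
  expect_equal(out$food_code, "veg")
  expect_equal(out$grams, 60)
  expect_false(out$is_complex_dish)
  # a 50 g declaration of the same dish halves every ingredient
  d$grams <- 50
  expect_equal(disaggregate_dish(d, recipes)$grams, 30)
  # single-ingredient recipe passes grams through
  rec1 <- data.frame(dish_code = "soup", food_code = "veg", grams = 300)
  d2 <- make_recall("a", 1, "soup", 300, is_complex_dish = TRUE)
  expect_equal(disaggregate_dish(d2, rec1)$grams, 300)
})

test_that("unknown dish codes are excluded with a warning, not fatal", {
  recipes <- data.frame(dish_code = "gratin", food_code = "veg", grams = 60)
  d <- make_recall("a", 1, "mystery_stew", 100, is_complex_dish = TRUE)
  expect_warning(out <- disaggregate_dish(d, recipes), "mystery_stew")
  expect_equal(nrow(out), 0)
})

test_that("disaggregation never returns more mass than declared", {
  set.seed(11)
  for (k in 1:50) {
    n_ing <- sample(1:6, 1)
    recipes <- data.frame(dish_code = "d",
                          food_code = paste0("ing", seq_len(n_ing)),
                          grams = stats::runif(n_ing, 5, 200))
    d <- make_recall("a", 1, "d", stats::runif(1, 10, 400),
                     is_complex_dish = TRUE)
    out <- disaggregate_dish(d, recipes)
    expect_lte(sum(out$grams), d$grams + 1e-9)
    expect_gte(sum(out$grams), d$grams / 2 - 1e-9)  # mains cover half
  }
})

test_that("half-portion gate matches the cooked-ham worked rule", {
  # standard portion 50 g: a single 20 g declaration is below the 25 g gate
  r <- make_recall("a", 1, "cooked_ham_c1", 20)
  occ <- count_occurrences(r, toy_mapping, default_cfg)
  expect_equal(occ$occurrences[occ$group_id == "cooked_ham"], 0L)
  # two 20 g declarations pool to 40 g >= 25 g: both count
  r2 <- make_recall("a", c(1, 1), c("cooked_ham_c1", "cooked_ham_c2"),
                    c(20, 20))
  occ2 <- count_occurrences(r2, toy_mapping, default_cfg)
  expect_equal(occ2$occurrences[occ2$group_id == "cooked_ham"], 2L)
  # exactly half a portion counts (inclusive gate) ...
  r3 <- make_recall("a", 1, "cooked_ham_c1", 25)
  occ3 <- count_occurrences(r3, toy_mapping, default_cfg)
  expect_equal(occ3$occurrences[occ3$group_id == "cooked_ham"], 1L)
  # ... unless the strict gate is requested
  occ4 <- count_occurrences(r3, toy_mapping, default_cfg, inclusive = FALSE)
  expect_equal(occ4$occurrences[occ4$group_id == "cooked_ham"], 0L)
})

test_that("gating is per day: the same grams split across days can fail", {
  r <- make_recall("a", c(1, 2), c("cooked_ham_c1", "cooked_ham_c1"),
                   c(15, 15))
  occ <- count_occurrences(r, toy_mapping, default_cfg)
  expect_equal(occ$occurrences[occ$group_id == "cooked_ham"], 0L)
})

test_that("excluded and unknown foods contribute nothing", {
  r <- make_recall("a", c(1, 1, 2), c("water", "herbs", "water"),
                   c(500, 10, 300))
  occ <- count_occurrences(r, toy_mapping, default_cfg)
  expect_true(all(occ$occurrences == 0))
  expect_equal(sort(unique(occ$group_id)),
               sort(default_cfg$group_id[default_cfg$source == "recall"]))
  r2 <- make_recall("a", 1, "alien_food", 999)
  expect_warning(occ2 <- count_occurrences(r2, toy_mapping, default_cfg),
                 "alien_food")
  expect_true(all(occ2$occurrences == 0))
})

test_that("engine matches the naive enumeration oracle on random menus", {
  set.seed(202)
  for (k in 1:100) {
    menu <- random_menu()
    expect_identical(count_occurrences(menu, toy_mapping, default_cfg),
                     oracle_counts(menu, toy_mapping, default_cfg))
  }
})

test_that("adding a declaration never decreases any count (monotonicity)", {
  set.seed(303)
  for (k in 1:30) {
    menu <- random_menu()
    base <- count_occurrences(menu, toy_mapping, default_cfg)
    extra_code <- sample(toy_mapping$food_code, 1)
    menu2 <- rbind(menu, make_recall(sample(menu$individual_id, 1),
                                     sample.int(3, 1), extra_code,
                                     stats::runif(1, 0, 200)))
    more <- count_occurrences(menu2, toy_mapping, default_cfg)
    expect_true(all(more$occurrences >= base$occurrences))
  }
})

test_that("doubling every declared gram never decreases counts", {
  set.seed(404)
  for (k in 1:30) {
    menu <- random_menu()
    base <- count_occurrences(menu, toy_mapping, default_cfg)
    menu2 <- menu
    menu2$grams <- menu2$grams * 2
    more <- count_occurrences(menu2, toy_mapping, default_cfg)
    expect_true(all(more$occurrences >= base$occurrences))
  }
})

test_that("dish ingredients pool with same-group simple foods before gating", {
  recipes <- data.frame(dish_code = "ham_dish", food_code = "cooked_ham_c1",
                        grams = 100)
  r <- rbind(
    make_recall("a", 1, "cooked_ham_c1", 15),
    make_recall("a", 1, "ham_dish", 15, is_complex_dish = TRUE))
  flat <- disaggregate_recalls(r, recipes)
  occ <- count_occurrences(flat, toy_mapping, default_cfg)
  # 15 g simple + 15 g dish-derived pool to 30 g >= 25 g: both count
  expect_equal(occ$occurrences[occ$group_id == "cooked_ham"], 2L)
})
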