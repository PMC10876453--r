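# Shared fixtures and independent oracles used across the test files.

default_cfg <- load_group_config()

# Two food codes per recall group plus a couple of excluded codes.
toy_mapping <- local({
  rec <- default_cfg$group_id[default_cfg$source == "recall"]
  rbind(
    data.frame(food_code = paste0(rep(rec, each = 2), "_c", 1:2),
               group_id = rep(rec, each = 2), stringsAsFactors = FALSE),
    data.frame(food_code = c("water", "herbs"), group_id = "EXCLUDED",
               stringsAsFactors = FALSE)
  )
})

make_recall <- function(individual_id, day, food_code, grams,
                        is_solid = TRUE, is_complex_dish = FALSE) {
  n <- max(length(individual_id), length(food_code), length(grams))
  data.frame(individual_id = rep_len(individual_id, n),
             day = rep_len(day, n),
             food_code = rep_len(food_code, n),
             grams = rep_len(grams, n),
             is_solid = rep_len(is_solid, n),
             is_complex_dish = rep_len(is_complex_dish, n),
             stringsAsFactors = FALSE)
}

# Naive occurrence oracle: explicit loops over individual x day x group,
# pooling daily grams and applying the half-portion gate per declaration.
oracle_counts <- function(recalls, mapping, config, inclusive = TRUE) {
  rec <- config[config$source == "recall", ]
  ids <- unique(recalls$individual_id)
  out <- expand.grid(individual_id = ids, group_id = rec$group_id,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$individual_id, out$group_id), ]
  rownames(out) <- NULL
  out$occurrences <- 0L
  grp_of <- mapping$group_id[match(recalls$food_code, mapping$food_code)]
  grp_of[is.na(grp_of)] <- "EXCLUDED"
  for (r in seq_len(nrow(out))) {
    id <- out$individual_id[r]
    g <- out$group_id[r]
    portion <- rec$standard_portion_g[rec$group_id == g]
    n <- 0L
    for (d in unique(recalls$day)) {
      sel <- recalls$individual_id == id & recalls$day == d & grp_of == g
      daily <- sum(recalls$grams[sel])
      gate <- if (inclusive) daily >= portion / 2 else daily > portion / 2
      if (gate) n <- n + sum(sel)
    }
    out$occurrences[r] <- n
  }
  out
}

# Random toy menu: up to n_ind individuals x 3 days x n_decl declarations
# drawn from the toy mapping (including excluded codes), grams uniform up
# to 1.5 standard portions.
random_menu <- function(n_ind = 5, n_decl = 30) {
  ids <- paste0("p", seq_len(sample.int(n_ind, 1)))
  rows <- sample.int(nrow(toy_mapping), n_decl, replace = TRUE)
  codes <- toy_mapping$food_code[rows]
  grp <- toy_mapping$group_id[rows]
  portion <- default_cfg$standard_portion_g[
    match(grp, default_cfg$group_id)]
  portion[is.na(portion)] <- 100
  make_recall(sample(ids, n_decl, replace = TRUE),
              sample.int(3, n_decl, replace = TRUE),
              codes, stats::runif(n_decl, 0, 1.5 * portion))
}

# Complete occurrence/weekly tables for compute_orchid on hand-set values.
full_counts <- function(ids, set = list()) {
  rec <- default_cfg$group_id[default_cfg$source == "recall"]
  occ <- expand.grid(individual_id = ids, group_id = rec,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  occ$occurrences <- 0
  for (nm in names(set)) {
    occ$occurrences[occ$group_id == nm] <- set[[nm]]
  }
  occ
}

full_weekly <- function(ids, set = list()) {
  fpq <- default_cfg$group_id[default_cfg$source == "fpq"]
  wk <- expand.grid(individual_id = ids, group_id = fpq,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  wk$occurrences_per_week <- 0
  for (nm in names(set)) {
    wk$occurrences_per_week[wk$group_id == nm] <- set[[nm]]
  }
  wk
}

# Long intake table for one or more individuals: per-day amounts supplied
# as a named list nutrient -> vector over days.
make_intakes <- function(individual_id, days, amounts) {
  do.call(rbind, lapply(names(amounts), function(n)
    data.frame(individual_id = individual_id, day = seq_len(days),
               nutrient_id = n, amount = rep_len(amounts[[n]], days),
               stringsAsFactors = FALSE)))
}

toy_demographics <- function(ids, sex = "female") {
  data.frame(individual_id = ids, sex = rep_len(sex, length(ids)),
             stringsAsFactors = FALSE)
}

mar_refs <- read_reference_table(orchid_example_references("mar"), "mar")
pandiet_refs <- read_reference_table(orchid_example_references("pandiet"),
                                     "pandiet")
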