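# Occurrence engine: dish disaggregation, food-group mapping and the
# half-standard-portion daily gate that turns recall declarations into
# per-group consumption occurrence counts.

#' Main ingredients of a recipe
#'
#' Orders the ingredients by descending mass and keeps the smallest prefix
#' whose cumulative mass reaches half of the recipe's total mass; further
#' ingredients whose mass equals the last retained one are kept as well, so
#' that ties at the boundary are resolved deterministically.
#'
#' @param recipe data.frame with columns `food_code`, `grams` for one dish.
#' @return The rows of `recipe` that are main ingredients.
#' @export
main_ingredients <- function(recipe) {
  if (nrow(recipe) == 0) stop("recipe has no ingredients")
  ord <- order(-recipe$grams, recipe$food_code)
  recipe <- recipe[ord, , drop = FALSE]
  total <- sum(recipe$grams)
  k <- which(cumsum(recipe$grams) >= total / 2)[1]
  # include ingredients tied in mass with the k-th
  keep <- recipe$grams >= recipe$grams[k]
  recipe[keep, , drop = FALSE]
}

#' Disaggregate one complex-dish declaration into main-ingredient declarations
#'
#' The declared dish mass is distributed over the recipe's main ingredients
#' in proportion to their recipe masses: each ingredient receives
#' `recipe grams x declared grams / total recipe grams`. Only the main
#' ingredients (see [main_ingredients()]) are returned; minor ingredients are
#' dropped, so the returned masses sum to at most the declared dish mass.
#'
#' @param declaration One-row data.frame of a complex-dish declaration
#'   (columns as in [read_recalls()]).
#' @param recipes Recipe table (columns `dish_code`, `food_code`, `grams`).
#' @return data.frame of ingredient-level declarations (possibly empty when
#'   the dish is unknown, with a warning).
#' @export
disaggregate_dish <- function(declaration, recipes) {
  stopifnot(nrow(declaration) == 1)
  recipe <- recipes[recipes$dish_code == declaration$food_code, , drop = FALSE]
  if (nrow(recipe) == 0) {
    warning("unknown dish code '", declaration$food_code,
            "': declaration excluded from scoring")
    return(declaration[0, , drop = FALSE])
  }
  mains <- main_ingredients(recipe)
  scale <- declaration$grams / sum(recipe$grams)
  out <- declaration[rep(1L, nrow(mains)), , drop = FALSE]
  out$food_code <- mains$food_code
  out$grams <- mains$grams * scale
  out$is_complex_dish <- FALSE
  rownames(out) <- NULL
  out
}

#' Disaggregate all complex-dish declarations of a recall table
#'
#' Simple-food rows pass through unchanged; complex-dish rows are replaced by
#' their main-ingredient rows (see [disaggregate_dish()]). Ingredients
#' inherit the dish's day, individual and solidity flag.
#'
#' @param recalls Recall declarations ([read_recalls()]).
#' @param recipes Recipe table ([read_recipes()]).
#' @return data.frame of declarations with no complex dishes left.
#' @export
disaggregate_recalls <- function(recalls, recipes) {
  if (nrow(recalls) == 0 || !any(recalls$is_complex_dish)) return(recalls)
  complex <- recalls[recalls$is_complex_dish, , drop = FALSE]
  simple <- recalls[!recalls$is_complex_dish, , drop = FALSE]
  parts <- lapply(seq_len(nrow(complex)), function(i)
    disaggregate_dish(complex[i, , drop = FALSE], recipes))
  out <- rbind(simple, do.call(rbind, parts))
  rownames(out) <- NULL
  out
}

#' Count consumption occurrences from recall declarations
#'
#' Applies the half-standard-portion daily gate: within one individual, one
#' recall day and one recall-source ORCHID group, the declarations of the
#' group count as one occurrence each only when the day's pooled grams for
#' the group reach half the group's standard portion; otherwise that day
#' contributes no occurrence for the group. Occurrences are then summed over
#' the recall days. Foods mapped to `EXCLUDED` — and food codes absent from
#' the mapping, which are warned about — contribute nothing. Dish
#' ingredients must already be disaggregated ([disaggregate_recalls()]);
#' their grams pool with same-group simple foods before gating.
#'
#' @param recalls Declarations with complex dishes already disaggregated.
#' @param mapping Food-code to group mapping ([read_food_mapping()]).
#' @param config Scoring configuration ([load_group_config()]).
#' @param inclusive Gate with `>=` half a portion (default, matching the
#'   worked cooked-ham rule: 25 g of a 50 g portion counts) or strictly `>`.
#' @return data.frame `individual_id`, `group_id`, `occurrences` covering
#'   every individual and every recall-source group (zeros included).
#' @export
count_occurrences <- function(recalls, mapping, config, inclusive = TRUE) {
  validate_group_config(config)
  rec_cfg <- config[config$source == "recall", , drop = FALSE]
  individuals <- unique(recalls$individual_id)
  grid <- expand.grid(individual_id = individuals,
                      group_id = rec_cfg$group_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$individual_id, grid$group_id), , drop = FALSE]
  rownames(grid) <- NULL
  grid$occurrences <- 0L
  if (nrow(recalls) == 0) return(grid)

  group <- mapping$group_id[match(recalls$food_code, mapping$food_code)]
  unknown <- is.na(group)
  if (any(unknown)) {
    warning("food code(s) not in mapping, excluded from scoring: ",
            paste(unique(recalls$food_code[unknown]), collapse = ", "))
    group[unknown] <- "EXCLUDED"
  }
  keep <- group %in% rec_cfg$group_id
  if (!any(keep)) return(grid)
  d <- data.frame(individual_id = recalls$individual_id[keep],
                  day = recalls$day[keep],
                  group_id = group[keep],
                  grams = recalls$grams[keep],
                  stringsAsFactors = FALSE)

  key <- paste(d$individual_id, d$day, d$group_id, sep = "\r")
  total_g <- rowsum(d$grams, key)
  n_decl <- rowsum(rep(1L, nrow(d)), key)
  half <- rec_cfg$standard_portion_g / 2
  names(half) <- rec_cfg$group_id
  kg <- sub("^.*\r.*\r", "", rownames(total_g))
  gate <- if (inclusive) total_g[, 1] >= half[kg] else total_g[, 1] > half[kg]
  occ_day <- ifelse(gate, n_decl[, 1], 0L)

  ik <- sub("\r.*$", "", rownames(total_g))
  per_ig <- rowsum(occ_day, paste(ik, kg, sep = "\r"))
  gkey <- paste(grid$individual_id, grid$group_id, sep = "\r")
  hit <- match(gkey, rownames(per_ig))
  grid$occurrences <- ifelse(is.na(hit), 0L, as.integer(per_ig[hit, 1]))
  grid
}
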