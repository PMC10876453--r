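#' @keywords internal
"_PACKAGE"

# Canonical ORCHID food groups. Thirteen are scored from the three 24-h
# recalls (foods eaten daily in the French population and/or carrying a
# daily recommendation), seven from the food propensity questionnaire
# (infrequently eaten foods and/or weekly recommendations).
.recall_groups <- c(
  "meat_excluding_poultry",
  "cooked_ham",
  "deli_meats_excluding_cooked_ham",
  "milk_and_fresh_dairy_products",
  "cheese",
  "refined_starches_and_potatoes",
  "vegetables",
  "fruits",
  "oils",
  "butter_margarine_and_fresh_cream",
  "salted_aperitif_products",
  "sweetened_products",
  "sweetened_beverages"
)

.fpq_groups <- c(
  "poultry",
  "eggs",
  "fatty_fish",
  "lean_fish_and_shellfish",
  "legumes",
  "nuts",
  "wholemeal_or_semi_wholemeal_products"
)

#' Canonical ORCHID food groups
#'
#' The twenty ORCHID food groups with their data source: thirteen scored from
#' 24-h recall occurrences, seven from FPQ weekly frequencies.
#'
#' @return A data.frame with columns `group_id` and `source`
#'   (`"recall"` or `"fpq"`).
#' @export
orchid_groups <- function() {
  data.frame(
    group_id = c(.recall_groups, .fpq_groups),
    source = rep(c("recall", "fpq"), c(length(.recall_groups), length(.fpq_groups))),
    stringsAsFactors = FALSE
  )
}

#' Path to the default scoring configuration shipped with the package
#'
#' The shipped weights, thresholds and standard portions are a documented
#' approximation assembled from ENNS/GEMRCN-style standard portions and the
#' qualitative structure of the score (positive rating for groups whose
#' consumption the French dietary guidelines favour, threshold rating with
#' negative above-threshold weights for energy-dense groups to be consumed
#' in moderation). They are meant to be edited for any concrete deployment.
#'
#' @return File path of the packaged YAML configuration.
#' @export
orchid_config_path <- function() {
  system.file("extdata", "orchid_default_config.yaml",
              package = "orchidscore", mustWork = TRUE)
}

#' Load and validate an ORCHID scoring configuration
#'
#' A configuration holds, for each of the twenty ORCHID food groups, the
#' standard portion mass used by the half-portion gate, the data source
#' (recall or FPQ), the rating type (positive or threshold), the weight and
#' (for threshold-rated groups) the occurrence threshold.
#'
#' @param path YAML file; defaults to the packaged configuration.
#' @return A data.frame with one row per group and columns `group_id`,
#'   `label`, `standard_portion_g`, `source`, `rating`, `weight`,
#'   `threshold` (NA for positive-rated groups).
#' @examples
#' cfg <- load_group_config()
#' table(cfg$source)
#' @export
load_group_config <- function(path = orchid_config_path()) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$groups)) stop("configuration has no 'groups' block: ", path)
  rows <- lapply(names(raw$groups), function(g) {
    b <- raw$groups[[g]]
    data.frame(
      group_id = g,
      label = if (is.null(b$label)) g else b$label,
      standard_portion_g = as.numeric(b$portion_g %||% NA_real_),
      source = as.character(b$source %||% NA_character_),
      rating = as.character(b$rating %||% NA_character_),
      weight = as.numeric(b$weight %||% NA_real_),
      threshold = as.numeric(b$threshold %||% NA_real_),
      stringsAsFactors = FALSE
    )
  })
  config <- do.call(rbind, rows)
  validate_group_config(config)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate an ORCHID scoring configuration
#'
#' Checks the structural invariants of a complete configuration: exactly the
#' twenty canonical groups, the 13/7 recall/FPQ split, positive rating for
#' all FPQ-source groups, positive standard portions, and a non-negative
#' integer threshold present exactly for threshold-rated groups.
#'
#' @param config data.frame as returned by [load_group_config()].
#' @return The validated configuration, invisibly.
#' @export
validate_group_config <- function(config) {
  needed <- c("group_id", "standard_portion_g", "source", "rating", "weight")
  miss_col <- setdiff(needed, names(config))
  if (length(miss_col))
    stop("configuration lacks columns: ", paste(miss_col, collapse = ", "))
  if (!"threshold" %in% names(config)) config$threshold <- NA_real_

  dup <- config$group_id[duplicated(config$group_id)]
  if (length(dup))
    stop("duplicate group_id in configuration: ", paste(unique(dup), collapse = ", "))
  canon <- orchid_groups()
  missing_groups <- setdiff(canon$group_id, config$group_id)
  if (length(missing_groups))
    stop("configuration is missing group(s): ", paste(missing_groups, collapse = ", "))
  extra <- setdiff(config$group_id, canon$group_id)
  if (length(extra))
    stop("unknown group_id in configuration: ", paste(extra, collapse = ", "))

  src <- config$source[match(canon$group_id, config$group_id)]
  wrong_src <- canon$group_id[src != canon$source]
  if (any(is.na(src)) || length(wrong_src))
    stop("wrong data source for group(s): ", paste(wrong_src, collapse = ", "))

  if (!all(config$rating %in% c("positive", "threshold")))
    stop("rating must be 'positive' or 'threshold' for group(s): ",
         paste(config$group_id[!config$rating %in% c("positive", "threshold")],
               collapse = ", "))
  bad_fpq <- config$group_id[config$source == "fpq" & config$rating != "positive"]
  if (length(bad_fpq))
    stop("FPQ-source groups must use the positive rating: ",
         paste(bad_fpq, collapse = ", "))

  bad_portion <- config$group_id[!is.finite(config$standard_portion_g) |
                                   config$standard_portion_g <= 0]
  if (length(bad_portion))
    stop("standard_portion_g must be > 0 for group(s): ",
         paste(bad_portion, collapse = ", "))

  thr_needed <- config$rating == "threshold"
  no_thr <- config$group_id[thr_needed & !is.finite(config$threshold)]
  if (length(no_thr))
    stop("threshold rating requires a threshold for group(s): ",
         paste(no_thr, collapse = ", "))
  bad_thr <- config$group_id[thr_needed &
                               (config$threshold < 0 |
                                  config$threshold != round(config$threshold))]
  bad_thr <- bad_thr[!is.na(bad_thr)]
  if (length(bad_thr))
    stop("threshold must be a non-negative integer for group(s): ",
         paste(bad_thr, collapse = ", "))
  if (any(!is.finite(config$weight)))
    stop("weight missing for group(s): ",
         paste(config$group_id[!is.finite(config$weight)], collapse = ", "))
  invisible(config)
}
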