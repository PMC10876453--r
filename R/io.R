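# Readers and writers for the tabular survey inputs. All tables are plain
# CSV; readers enforce the type invariants and report offending data rows
# (1-based, excluding the header) so upstream coding errors are locatable.

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
}

#' Read 24-h recall food declarations
#'
#' Expected columns: `individual_id`, `day`, `food_code`, `grams`,
#' `is_solid`, `is_complex_dish`. Extra columns (e.g. `energy_kcal`) are
#' carried through unchanged.
#'
#' @param path CSV file.
#' @param n_days Declared number of recall days per individual (default 3).
#' @return data.frame of declarations, one row per eating-occasion food record.
#' @export
read_recalls <- function(path, n_days = 3) {
  df <- .read_csv(path)
  .require_cols(df, c("individual_id", "day", "food_code", "grams",
                      "is_solid", "is_complex_dish"), path)
  if (nrow(df) == 0) return(df)
  df$grams <- as.numeric(df$grams)
  bad <- which(!is.finite(df$grams) | df$grams < 0)
  if (length(bad))
    stop("negative or unparseable grams in ", path, " at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  df$day <- as.integer(df$day)
  bad_day <- which(is.na(df$day) | df$day < 1 | df$day > n_days)
  if (length(bad_day))
    stop("day outside 1..", n_days, " in ", path, " at row(s): ",
         paste(utils::head(bad_day, 5), collapse = ", "))
  df$is_solid <- as.logical(df$is_solid)
  df$is_complex_dish <- as.logical(df$is_complex_dish)
  df
}

#' Read the food-code to ORCHID-group mapping
#'
#' Columns `food_code`, `group_id`. `group_id` may be the sentinel
#' `"EXCLUDED"` for foods that do not enter the score (mostly water, spices,
#' herbs and sauces).
#'
#' @param path CSV file.
#' @param config Optional scoring configuration; when supplied, mapped
#'   group ids are checked against it.
#' @return data.frame with one row per food code.
#' @export
read_food_mapping <- function(path, config = NULL) {
  df <- .read_csv(path)
  .require_cols(df, c("food_code", "group_id"), path)
  dup <- df$food_code[duplicated(df$food_code)]
  if (length(dup))
    stop("food_code mapped more than once in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  if (!is.null(config)) {
    legal <- c(config$group_id, "EXCLUDED")
    bad <- setdiff(unique(df$group_id), legal)
    if (length(bad))
      stop("unknown group_id in ", path, ": ", paste(bad, collapse = ", "))
  }
  df
}

#' Read the recipe table for complex dishes
#'
#' Columns `dish_code`, `food_code`, `grams`: ingredient masses per declared
#' recipe portion.
#'
#' @param path CSV file.
#' @return data.frame, one row per (dish, ingredient).
#' @export
read_recipes <- function(path) {
  df <- .read_csv(path)
  .require_cols(df, c("dish_code", "food_code", "grams"), path)
  if (nrow(df) == 0) return(df)
  df$grams <- as.numeric(df$grams)
  bad <- which(!is.finite(df$grams) | df$grams <= 0)
  if (length(bad))
    stop("ingredient grams must be > 0 in ", path, " at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  df
}

#' Read food propensity questionnaire responses
#'
#' Columns `individual_id`, `item_id`, `frequency`, `unit`; an empty
#' frequency cell is a missing response. Units are `per_month` or
#' `per_week`.
#'
#' @param path CSV file.
#' @return data.frame of FPQ responses with NA for missing frequencies.
#' @export
read_fpq <- function(path) {
  df <- .read_csv(path)
  .require_cols(df, c("individual_id", "item_id", "frequency", "unit"), path)
  if (nrow(df) == 0) return(df)
  df$frequency <- suppressWarnings(as.numeric(df$frequency))
  bad <- which(!is.na(df$frequency) & df$frequency < 0)
  if (length(bad))
    stop("negative frequency in ", path, " at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad_unit <- which(!df$unit %in% c("per_month", "per_week"))
  if (length(bad_unit))
    stop("unknown frequency unit in ", path, " at row(s): ",
         paste(utils::head(bad_unit, 5), collapse = ", "))
  df
}

#' Read the FPQ item to ORCHID-group mapping
#'
#' Columns `item_id`, `group_id`; `group_id` must be one of the seven
#' FPQ-source groups or `"EXCLUDED"` for items not used by the score.
#'
#' @param path CSV file.
#' @return data.frame, one row per item.
#' @export
read_fpq_mapping <- function(path) {
  df <- .read_csv(path)
  .require_cols(df, c("item_id", "group_id"), path)
  legal <- c(.fpq_groups, "EXCLUDED")
  bad <- setdiff(unique(df$group_id), legal)
  if (length(bad))
    stop("FPQ items may map only to FPQ-source groups or EXCLUDED; bad: ",
         paste(bad, collapse = ", "))
  df
}

#' Read per-day nutrient intakes
#'
#' Long format, columns `individual_id`, `day`, `nutrient_id`, `amount`.
#' Daily energy is a row with `nutrient_id = "energy_kcal"`.
#'
#' @param path CSV file.
#' @return data.frame of daily intakes.
#' @export
read_nutrient_intakes <- function(path) {
  df <- .read_csv(path)
  .require_cols(df, c("individual_id", "day", "nutrient_id", "amount"), path)
  if (nrow(df) == 0) return(df)
  df$amount <- as.numeric(df$amount)
  bad <- which(!is.finite(df$amount) | df$amount < 0)
  if (length(bad))
    stop("negative or unparseable amount in ", path, " at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  df$day <- as.integer(df$day)
  df
}

#' Read a nutrient reference table
#'
#' For the MAR, columns `nutrient_id`, `sex`, `rda` (22 nutrients); for the
#' PANDiet, columns `nutrient_id`, `sex`, `reference`, `direction`
#' (`at_least`/`at_most`, 27 nutrients). `sex = "all"` applies to everyone;
#' an optional `age_band` column ( `"all"` default) restricts by age band.
#'
#' @param path CSV file.
#' @param kind `"mar"` or `"pandiet"`.
#' @return data.frame reference table.
#' @export
read_reference_table <- function(path, kind = c("mar", "pandiet")) {
  kind <- match.arg(kind)
  df <- .read_csv(path)
  value_col <- if (kind == "mar") "rda" else "reference"
  .require_cols(df, c("nutrient_id", "sex", value_col), path)
  if (!"age_band" %in% names(df)) df$age_band <- "all"
  df[[value_col]] <- as.numeric(df[[value_col]])
  if (any(!is.finite(df[[value_col]]) | df[[value_col]] <= 0))
    stop("reference values must be > 0 in ", path)
  if (kind == "pandiet") {
    .require_cols(df, "direction", path)
    bad <- setdiff(unique(df$direction), c("at_least", "at_most"))
    if (length(bad))
      stop("direction must be at_least or at_most in ", path, "; bad: ",
           paste(bad, collapse = ", "))
    multi <- tapply(df$direction, df$nutrient_id, function(d) length(unique(d)))
    if (any(multi > 1))
      stop("nutrient assigned to both sub-scores in ", path, ": ",
           paste(names(multi)[multi > 1], collapse = ", "))
  }
  df
}

#' Write a table as CSV
#'
#' Plain `write.csv` without row names, so that read and write round-trip.
#'
#' @param df data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
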