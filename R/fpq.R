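# FPQ processing: frequency-unit conversion to weekly occurrences,
# iterative random-forest imputation of missing responses, and aggregation
# of item frequencies into the seven FPQ-source ORCHID groups.

#' Average number of weeks in a month (365.25 / 12 / 7)
#' @export
WEEKS_PER_MONTH <- 365.25 / 12 / 7  # = 4.348..., conventionally quoted 4.345

#' Convert an FPQ frequency to occurrences per week
#'
#' Weekly frequencies pass through unchanged; monthly frequencies are
#' divided by the average weeks-per-month constant (default 4.345, the
#' calendar average rounded as conventionally quoted).
#'
#' @param frequency Non-negative numeric vector.
#' @param unit `"per_week"` or `"per_month"`, recycled against `frequency`.
#' @param weeks_per_month Conversion constant.
#' @return Occurrences per week; NA frequencies stay NA.
#' @examples
#' to_weekly(4.345, "per_month")  # 1
#' @export
to_weekly <- function(frequency, unit, weeks_per_month = 4.345) {
  if (any(!is.na(frequency) & frequency < 0))
    stop("frequency must be non-negative")
  bad <- setdiff(unique(unit), c("per_week", "per_month"))
  if (length(bad)) stop("unknown frequency unit: ", paste(bad, collapse = ", "))
  unit <- rep_len(unit, length(frequency))
  ifelse(unit == "per_month", frequency / weeks_per_month, frequency)
}

#' Pivot FPQ responses into an individuals-by-items weekly-frequency matrix
#'
#' @param fpq FPQ responses ([read_fpq()]).
#' @param weeks_per_month Conversion constant for monthly responses.
#' @return Numeric matrix, rows named by individual, columns by item;
#'   missing responses are NA.
#' @export
fpq_weekly_matrix <- function(fpq, weeks_per_month = 4.345) {
  wk <- to_weekly(fpq$frequency, fpq$unit, weeks_per_month)
  ids <- sort(unique(fpq$individual_id))
  items <- sort(unique(fpq$item_id))
  m <- matrix(NA_real_, length(ids), length(items),
              dimnames = list(as.character(ids), items))
  m[cbind(match(fpq$individual_id, ids), match(fpq$item_id, items))] <- wk
  m
}

#' Impute missing FPQ responses with iterative random forests
#'
#' missForest-style chained imputation: missing cells are initialised with
#' column means, then columns are revisited in order of increasing
#' missingness, each regressed (random forest) on the other FPQ columns and
#' the complete covariates, until the total change of the imputed values
#' stops decreasing or `max_iter` is reached. Observed cells are never
#' modified; imputed values are clamped at zero. The result is deterministic
#' for a given `seed`.
#'
#' @param fpq_matrix Numeric individuals-by-items matrix with NA holes
#'   ([fpq_weekly_matrix()]).
#' @param covariates Optional data.frame of complete individual-level
#'   predictors, rows aligned with the matrix rows.
#' @param seed Integer seed driving all forests.
#' @param max_iter Iteration cap (default 10).
#' @param num_trees Trees per forest (default 100).
#' @return List with `completed` (matrix, no NA), `imputed` (logical mask of
#'   originally missing cells) and `iterations` used.
#' @export
impute_fpq <- function(fpq_matrix, covariates = NULL, seed = 1,
                       max_iter = 10, num_trees = 100) {
  m <- as.matrix(fpq_matrix)
  storage.mode(m) <- "double"
  miss <- is.na(m)
  all_missing <- colnames(m)[colSums(!miss) == 0]
  if (length(all_missing))
    stop("FPQ item(s) with no observed response cannot be imputed: ",
         paste(all_missing, collapse = ", "))
  cov_mat <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(m))
      stop("covariates must have one row per individual")
    if (anyNA(covariates)) stop("covariates must be complete")
    chr <- vapply(covariates, is.character, logical(1))
    covariates[chr] <- lapply(covariates[chr], factor)
    # constant columns carry no information and break dummy coding
    keep <- vapply(covariates, function(x) length(unique(x)) > 1, logical(1))
    covariates <- covariates[keep]
    if (ncol(covariates))
      cov_mat <- stats::model.matrix(~ . - 1, data = covariates)
  }
  if (!any(miss))
    return(list(completed = m, imputed = miss, iterations = 0L))

  filled <- m
  col_means <- colMeans(m, na.rm = TRUE)
  for (j in seq_len(ncol(m))) filled[miss[, j], j] <- col_means[j]

  cols <- order(colSums(miss))
  cols <- cols[colSums(miss)[cols] > 0]
  prev_change <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    before <- filled
    for (j in cols) {
      resp <- m[, j]
      obs <- !miss[, j]
      x <- filled[, -j, drop = FALSE]
      if (!is.null(cov_mat)) x <- cbind(x, cov_mat)
      colnames(x) <- paste0("x", seq_len(ncol(x)))
      fit <- ranger::ranger(
        x = x[obs, , drop = FALSE], y = resp[obs],
        num.trees = num_trees, seed = seed + j,
        num.threads = 1, verbose = FALSE
      )
      pred <- stats::predict(fit, data = x[!obs, , drop = FALSE],
                             num.threads = 1, seed = seed + j)$predictions
      filled[!obs, j] <- pmax(pred, 0)
    }
    change <- sum((filled[miss] - before[miss])^2) /
      max(sum(filled[miss]^2), .Machine$double.eps)
    if (change >= prev_change || iter >= max_iter) {
      if (change >= prev_change) filled <- before
      break
    }
    prev_change <- change
  }
  list(completed = filled, imputed = miss, iterations = iter)
}

#' Weekly consumption occurrences for the seven FPQ-source ORCHID groups
#'
#' Converts responses to weekly frequencies, imputes missing cells when any
#' are present (requires `covariates` only if you want individual predictors
#' beyond the FPQ columns themselves), and sums item frequencies within each
#' mapped group. Items mapped to `EXCLUDED` and unmapped items are ignored;
#' a group with no mapped item yields zero with a warning.
#'
#' @param fpq FPQ responses ([read_fpq()]).
#' @param item_mapping Item-to-group mapping ([read_fpq_mapping()]).
#' @param covariates Optional complete covariate data.frame, rows in the
#'   order of `sort(unique(fpq$individual_id))`.
#' @param seed Seed for the imputation forests.
#' @param weeks_per_month Conversion constant.
#' @param num_trees Trees per imputation forest (default 100); fewer trees
#'   trade a little imputation accuracy for speed on large cohorts.
#' @return data.frame `individual_id`, `group_id`, `occurrences_per_week`,
#'   `imputed` (TRUE when any contributing item was imputed for that
#'   individual), covering all seven FPQ-source groups per individual.
#' @export
fpq_weekly_occurrences <- function(fpq, item_mapping, covariates = NULL,
                                   seed = 1, weeks_per_month = 4.345,
                                   num_trees = 100) {
  m <- fpq_weekly_matrix(fpq, weeks_per_month)
  imp <- impute_fpq(m, covariates = covariates, seed = seed,
                    num_trees = num_trees)
  comp <- imp$completed

  ids <- rownames(comp)
  out <- expand.grid(individual_id = ids, group_id = .fpq_groups,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$individual_id, out$group_id), , drop = FALSE]
  rownames(out) <- NULL
  out$occurrences_per_week <- 0
  out$imputed <- FALSE
  for (g in .fpq_groups) {
    items <- intersect(item_mapping$item_id[item_mapping$group_id == g],
                       colnames(comp))
    sel <- out$group_id == g
    if (!length(items)) {
      warning("no FPQ item mapped to group '", g, "': weekly occurrences 0")
      next
    }
    sub <- comp[, items, drop = FALSE]
    out$occurrences_per_week[sel] <-
      rowSums(sub)[match(out$individual_id[sel], ids)]
    out$imputed[sel] <-
      rowSums(imp$imputed[, items, drop = FALSE] > 0)[
        match(out$individual_id[sel], ids)] > 0
  }
  out
}
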