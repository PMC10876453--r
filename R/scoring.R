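# Component rating formulas and assembly of the 20-component ORCHID score.

#' Positive (proportional) component rating
#'
#' For food groups whose consumption the dietary guidelines favour:
#' `points = occurrences x weight`. Occurrences may be fractional (FPQ
#' weekly frequencies are reals).
#'
#' @param occurrences Non-negative numeric vector.
#' @param weight Component weight.
#' @return Component points.
#' @export
score_positive <- function(occurrences, weight) {
  if (any(occurrences < 0)) stop("occurrences must be non-negative")
  occurrences * weight
}

#' Threshold component rating
#'
#' For energy-dense food groups to be consumed in moderation. In the default
#' `literal` mode the published piecewise formula is applied as printed:
#' occurrences at or below the threshold score one point each
#' (`points = occurrences`); above the threshold,
#' `points = (occurrences - threshold) x weight`. With a negative weight the
#' printed formula is discontinuous at the threshold — the points earned up
#' to the threshold vanish once it is exceeded. The `continuous` mode keeps
#' them: `points = threshold + (occurrences - threshold) x weight` above the
#' threshold.
#'
#' @param occurrences Non-negative numeric vector.
#' @param threshold Non-negative occurrence threshold.
#' @param weight Above-threshold weight (typically negative).
#' @param mode `"literal"` (printed formula, default) or `"continuous"`.
#' @return Component points.
#' @examples
#' score_threshold(2, 3, -2)                       # 2 (below threshold)
#' score_threshold(5, 3, -2)                       # -4
#' score_threshold(5, 3, -2, mode = "continuous")  # -1
#' @export
score_threshold <- function(occurrences, threshold, weight,
                            mode = c("literal", "continuous")) {
  mode <- match.arg(mode)
  if (any(occurrences < 0)) stop("occurrences must be non-negative")
  if (any(threshold < 0)) stop("threshold must be non-negative")
  over <- occurrences > threshold
  pts <- occurrences
  base <- if (mode == "literal") 0 else threshold
  pts[over] <- (base + (occurrences - threshold) * weight)[over]
  pts
}

#' Compute the ORCHID score for a cohort
#'
#' Joins recall occurrence counts ([count_occurrences()]) and FPQ weekly
#' frequencies ([fpq_weekly_occurrences()]), applies the rating formula of
#' each group's configuration, and sums the twenty component point values
#' into the total score. Every individual must carry all 13 recall-source
#' counts (zeros allowed) and all 7 FPQ-source weekly frequencies.
#'
#' @param occurrences data.frame `individual_id`, `group_id`, `occurrences`
#'   for the recall-source groups.
#' @param weekly data.frame `individual_id`, `group_id`,
#'   `occurrences_per_week` for the FPQ-source groups.
#' @param config Scoring configuration ([load_group_config()]).
#' @param mode Threshold-rating mode, `"literal"` or `"continuous"`.
#' @return List of class `"orchid_result"`: `components` (long data.frame
#'   `individual_id`, `group_id`, `occurrences`, `points`) and `scores`
#'   (`individual_id`, `total`).
#' @export
compute_orchid <- function(occurrences, weekly, config,
                           mode = c("literal", "continuous")) {
  mode <- match.arg(mode)
  validate_group_config(config)
  wk <- data.frame(individual_id = weekly$individual_id,
                   group_id = weekly$group_id,
                   occurrences = weekly$occurrences_per_week,
                   stringsAsFactors = FALSE)
  occ <- rbind(
    occurrences[c("individual_id", "group_id", "occurrences")], wk)

  ids <- sort(unique(occ$individual_id))
  have <- paste(occ$individual_id, occ$group_id, sep = "\r")
  need <- expand.grid(individual_id = ids, group_id = config$group_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gap <- !paste(need$individual_id, need$group_id, sep = "\r") %in% have
  if (any(gap)) {
    g1 <- need[which(gap)[1], ]
    stop("individual '", g1$individual_id, "' is missing group '",
         g1$group_id, "'")
  }
  dup <- duplicated(have)
  if (any(dup))
    stop("duplicate occurrence record for individual '",
         occ$individual_id[dup][1], "', group '", occ$group_id[dup][1], "'")

  i <- match(occ$group_id, config$group_id)
  pos <- config$rating[i] == "positive"
  pts <- numeric(nrow(occ))
  pts[pos] <- score_positive(occ$occurrences[pos], config$weight[i][pos])
  if (any(!pos))
    pts[!pos] <- score_threshold(occ$occurrences[!pos],
                                 config$threshold[i][!pos],
                                 config$weight[i][!pos], mode = mode)
  occ$points <- pts
  occ <- occ[order(occ$individual_id, match(occ$group_id, config$group_id)), ]
  rownames(occ) <- NULL

  tot <- rowsum(occ$points, occ$individual_id)
  scores <- data.frame(individual_id = rownames(tot), total = tot[, 1],
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(list(components = occ, scores = scores), class = "orchid_result")
}

#' @export
print.orchid_result <- function(x, ...) {
  cat("ORCHID scores for", nrow(x$scores), "individuals\n")
  cat(sprintf("  mean %.1f (sd %.1f), range %.1f to %.1f\n",
              mean(x$scores$total), stats::sd(x$scores$total),
              min(x$scores$total), max(x$scores$total)))
  invisible(x)
}
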