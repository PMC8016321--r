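#' Rank stride-pattern variables by relevance
#'
#' Orders the 1200 variables by descending aggregated relevance; ties break
#' to the lower feature index (stable ordering).
#'
#' @param agg an `aggregated_relevance` (or bare numeric vector of scores).
#' @return integer vector of feature indices, most relevant first.
#' @examples
#' rank_variables(c(0.1, 0.9, 0.5))
#' @export
rank_variables <- function(agg) {
  v <- if (inherits(agg, "aggregated_relevance")) agg$values else as.numeric(agg)
  order(-v) # radix sort: stable, so ties keep ascending index order
}

#' Mask stride patterns to a retained variable subset
#'
#' Sets every feature outside `retained` to exactly 0 (the participant-mean
#' value on the standardized scale); retained features are unchanged. The
#' input is not mutated.
#'
#' @param patterns a `stride_patterns` tibble or feature matrix.
#' @param retained integer feature indices to keep (possibly empty).
#' @return object of the same shape as `patterns`.
#' @export
mask_patterns <- function(patterns, retained) {
  retained <- as.integer(retained)
  is_mat <- is.matrix(patterns)
  n_feat <- if (is_mat) ncol(patterns) else length(intersect(feature_names(), names(patterns)))
  if (length(retained) > 0 && (min(retained) < 1 || max(retained) > n_feat)) {
    stop("retained indices out of range 1..", n_feat)
  }
  drop_idx <- setdiff(seq_len(n_feat), retained)
  if (is_mat) {
    out <- patterns
    out[, drop_idx] <- 0
    return(out)
  }
  out <- patterns
  out[, feature_names()[drop_idx]] <- 0
  out
}

#' Accuracy as a function of the number of retained top-relevance variables
#'
#' For each `k` in `k_grid`, keeps the `k` most relevant variables (per
#' [rank_variables()]; the retained sets are nested across `k`), masks the
#' rest to zero, re-evaluates the *unchanged* trained model, and records the
#' unweighted participant-mean accuracy. The model is never retrained.
#'
#' @param model a trained `gait_net`.
#' @param patterns evaluation stride patterns with a `subject` column.
#' @param agg the `aggregated_relevance` used for ranking.
#' @param k_grid numbers of retained variables; the default grid is anchored
#'   at the landmark sizes 16, 200, 500 and the full 1200.
#' @return object of class `accuracy_curve`: tibble with columns `k` and
#'   `mean_accuracy` (%), with the ranking stored in attribute `ranking`.
#' @export
ablation_curve <- function(model, patterns, agg,
                           k_grid = c(16, 25, 50, 100, 200, 300, 500, 800, 1200)) {
  if (length(k_grid) == 0) stop("`k_grid` must not be empty")
  k_grid <- sort(unique(as.integer(k_grid)))
  ranking <- rank_variables(agg)
  if (any(k_grid < 0 | k_grid > length(ranking))) {
    stop("k values must lie in 0..", length(ranking))
  }
  acc <- vapply(k_grid, function(k) {
    masked <- mask_patterns(patterns, ranking[seq_len(k)])
    participant_accuracy(predict(model, masked)$.pred, patterns$subject)$mean_accuracy
  }, numeric(1))
  out <- tibble::tibble(k = k_grid, mean_accuracy = acc)
  attr(out, "ranking") <- ranking
  class(out) <- c("accuracy_curve", class(out))
  out
}

#' Accuracy from whole-channel subsets
#'
#' Retains all 100 samples of each named channel, masks every other variable
#' to zero, and evaluates the unchanged trained model (unweighted
#' participant-mean accuracy). With the five most relevant trajectories this
#' is the 500-variable reduced-measurement scenario.
#'
#' @param model a trained `gait_net`.
#' @param patterns evaluation stride patterns with a `subject` column.
#' @param channels character vector of channel identifiers (possibly empty).
#' @return mean accuracy in percent (scalar).
#' @export
channel_subset_accuracy <- function(model, patterns, channels) {
  if (length(channels) > 0 && !all(channels %in% gait_channels())) {
    stop("unknown channel(s): ", paste(setdiff(channels, gait_channels()), collapse = ", "))
  }
  retained <- if (length(channels) == 0) {
    integer(0)
  } else {
    planted_variable_set(channels, c(0, 1))
  }
  masked <- mask_patterns(patterns, retained)
  participant_accuracy(predict(model, masked)$.pred, patterns$subject)$mean_accuracy
}
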