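#' Layer-wise relevance propagation for a stride pattern
#'
#' Decomposes the pre-softmax output score of `target_class` into per-input
#' relevance contributions with the epsilon-stabilized LRP rule. Relevance is
#' initialized at the target's output score and redistributed layer by layer:
#' `R_j = sum_k a_j w_jk / (sum_j' a_j' w_j'k + eps * sign(sum)) * R_k`,
#' where `a` are the layer activations. The element-wise tanh is treated as
#' relevance-transparent (relevance passes through the nonlinearity
#' unchanged), so the total input relevance matches the target score up to a
#' relative leakage of order `eps`.
#'
#' @param model a trained `gait_net`.
#' @param pattern a single stride pattern: one-row `stride_patterns` tibble,
#'   or numeric vector of the model's input length.
#' @param target_class the class whose score is decomposed (string matching a
#'   model level, or integer index); conventionally the predicted class of a
#'   correctly classified pattern.
#' @param eps stabilizer added to the redistribution denominators (signed);
#'   must be positive unless every denominator is nonzero.
#' @return object of class `relevance_map`: list with `values` (signed
#'   relevance, one per input variable), `target_class`, `score` (the
#'   decomposed output score), and `eps`.
#' @export
lrp <- function(model, pattern, target_class, eps = 1e-6) {
  stopifnot(inherits(model, "gait_net"), eps >= 0)
  a0 <- if (is.numeric(pattern)) {
    as.numeric(pattern)
  } else {
    as.numeric(pattern_matrix(pattern)[1, ])
  }
  if (length(a0) != nrow(model$W1)) {
    stop("pattern length ", length(a0), " does not match the model input ", nrow(model$W1))
  }
  k <- if (is.character(target_class)) match(target_class, model$levels) else as.integer(target_class)
  if (is.na(k) || k < 1 || k > length(model$levels)) stop("unknown target class")

  stab <- function(z) {
    if (eps == 0 && any(z == 0)) {
      stop("zero denominator in relevance redistribution with eps = 0")
    }
    z + eps * ifelse(z >= 0, 1, -1)
  }
  z1 <- as.numeric(crossprod(model$W1, a0)) + model$b1
  a1 <- tanh(z1)
  z2 <- as.numeric(crossprod(model$W2, a1)) + model$b2
  score <- z2[k]

  # output layer -> hidden: only the target column carries relevance
  s2 <- sum(a1 * model$W2[, k])
  R1 <- a1 * model$W2[, k] / stab(s2) * score
  # hidden -> input (tanh transparent)
  s1 <- as.numeric(crossprod(model$W1, a0))
  R0 <- a0 * as.numeric(model$W1 %*% (R1 / stab(s1)))
  if (!all(is.finite(R0))) stop("non-finite relevance encountered; increase eps")
  structure(
    list(
      values = R0, target_class = model$levels[k], score = score, eps = eps
    ),
    class = "relevance_map"
  )
}

#' @export
print.relevance_map <- function(x, ...) {
  cat(
    sprintf(
      "<relevance_map> target '%s', score %.4g, total relevance %.4g (leakage %.2e)\n",
      x$target_class, x$score, sum(x$values),
      abs(sum(x$values) - x$score) / max(abs(x$score), .Machine$double.eps)
    )
  )
  invisible(x)
}

#' Relevance maps for all correctly classified stride patterns
#'
#' Runs the model over the given patterns and computes an LRP map for each
#' pattern the model assigns to its true subject; misclassified patterns are
#' excluded (their count is reported via a message).
#'
#' @param model a trained `gait_net`.
#' @param patterns a `stride_patterns` tibble with a `subject` column.
#' @param eps LRP stabilizer, see [lrp()].
#' @return a tibble with columns `subject`, `day`, `trial` (when present),
#'   `target_class`, `score`, and the 1200 relevance values in the feature
#'   columns; attribute `n_excluded` records the number of misclassified
#'   patterns.
#' @export
collect_relevance <- function(model, patterns, eps = 1e-6) {
  stopifnot(inherits(model, "gait_net"))
  if (!"subject" %in% names(patterns)) stop("`patterns` must carry a subject column")
  pred <- predict(model, patterns)$.pred
  correct <- as.character(pred) == as.character(patterns$subject)
  n_excl <- sum(!correct)
  if (!any(correct)) stop("no correctly classified patterns; nothing to decompose")
  if (n_excl > 0) {
    message("excluding ", n_excl, " misclassified pattern(s) from relevance analysis")
  }
  X <- pattern_matrix(patterns)
  rows <- which(correct)
  vals <- matrix(NA_real_, length(rows), ncol(X))
  scores <- numeric(length(rows))
  for (i in seq_along(rows)) {
    m <- lrp(model, X[rows[i], ], as.character(pred[rows[i]]), eps = eps)
    vals[i, ] <- m$values
    scores[i] <- m$score
  }
  colnames(vals) <- feature_names()
  out <- dplyr::bind_cols(
    dplyr::select(
      patterns[rows, , drop = FALSE],
      dplyr::any_of(c("subject", "day", "trial"))
    ),
    tibble::tibble(target_class = as.character(pred[rows]), score = scores),
    tibble::as_tibble(vals)
  )
  attr(out, "n_excluded") <- n_excl
  out
}

# one pass of the (0.25, 0.5, 0.25) kernel with replicate-edge padding
smooth_121_once <- function(x) {
  n <- length(x)
  xp <- c(x[1], x, x[n])
  0.25 * xp[1:n] + 0.5 * xp[2:(n + 1)] + 0.25 * xp[3:(n + 2)]
}

#' Weighted moving-average smoothing of a relevance trajectory
#'
#' Applies the three-point kernel that weights the previous and subsequent
#' points with 25% and the current point with 50%, with replicate-edge
#' padding, `passes` times (three by default; the triple application of the
#' kernel acts like a 7-tap binomial, i.e. near-gaussian, filter).
#'
#' @param x numeric vector (one 100-sample relevance trajectory).
#' @param passes number of applications.
#' @return smoothed vector, same length.
#' @export
smooth_relevance <- function(x, passes = 3) {
  for (i in seq_len(passes)) x <- smooth_121_once(x)
  x
}

#' Aggregate individual relevance maps into a group-level pattern
#'
#' The aggregation recipe: (1) each map is normalized by its own maximum
#' absolute relevance so strides are comparable; (2) the element-wise mean
#' across maps is taken; (3) the mean is rectified (absolute value by
#' default); (4) each 100-sample channel trajectory is smoothed independently
#' with the (0.25, 0.5, 0.25) kernel, three passes, replicate-edge padding
#' (smoothing does not cross channel seams); (5) the full 1200-vector is
#' min-max rescaled to `[0, 1]`.
#'
#' @param maps the tibble returned by [collect_relevance()], a list of
#'   `relevance_map` objects, or a numeric matrix (maps x 1200).
#' @param rectify `"abs"` (default, absolute relevance) or `"pos"`
#'   (positive part).
#' @param passes smoothing passes (3).
#' @return object of class `aggregated_relevance`: list with `values`
#'   (1200-vector in `[0, 1]`), `n_patterns`, `rectify`, `passes`.
#' @export
aggregate_relevance <- function(maps, rectify = c("abs", "pos"), passes = 3) {
  rectify <- match.arg(rectify)
  M <- if (is.matrix(maps)) {
    maps
  } else if (is.data.frame(maps)) {
    as.matrix(maps[, intersect(feature_names(), names(maps))])
  } else if (is.list(maps) && all(vapply(maps, inherits, logical(1), "relevance_map"))) {
    do.call(rbind, lapply(maps, function(m) m$values))
  } else {
    stop("`maps` must be a collect_relevance() tibble, a list of relevance maps, or a matrix")
  }
  if (nrow(M) < 1) stop("at least one relevance map is required")
  n_feat <- ncol(M)
  if (n_feat %% 100 != 0) stop("feature length must be a multiple of 100")
  mx <- apply(abs(M), 1, max)
  if (any(mx == 0)) stop("encountered an all-zero relevance map")
  avg <- colMeans(M / mx)
  rect <- if (rectify == "abs") abs(avg) else pmax(avg, 0)
  smoothed <- as.numeric(vapply(
    seq_len(n_feat %/% 100),
    function(ch) smooth_relevance(rect[((ch - 1) * 100 + 1):(ch * 100)], passes),
    numeric(100)
  ))
  rng <- range(smoothed)
  if (rng[2] == 0) stop("degenerate aggregate: mean relevance pattern is identically zero")
  if (rng[2] - rng[1] < .Machine$double.eps * max(abs(rng))) {
    warning("degenerate aggregate: relevance is constant; returning all ones")
    values <- rep(1, n_feat)
  } else {
    values <- (smoothed - rng[1]) / (rng[2] - rng[1])
  }
  structure(
    list(values = values, n_patterns = nrow(M), rectify = rectify, passes = passes),
    class = "aggregated_relevance"
  )
}

#' @export
print.aggregated_relevance <- function(x, ...) {
  cat(
    "<aggregated_relevance> over", x$n_patterns, "stride patterns |",
    "rectification:", x$rectify, "| smoothing passes:", x$passes, "\n"
  )
  invisible(x)
}

#' Summarize an aggregated relevance pattern
#'
#' Marginal sums of the group-level relevance: per time point (summed over
#' the 12 channels), per channel (summed over the 100 samples), and a
#' fractional stance split into early (1--30%), mid (31--70%) and late
#' (71--100%) phases.
#'
#' @param agg an `aggregated_relevance`.
#' @return list of tibbles `by_time` (`sample`, `relevance`), `by_channel`
#'   (`channel`, `relevance`, ordered as [gait_channels()]), and `by_phase`
#'   (`phase`, `relevance`, `share`).
#' @export
summarize_relevance <- function(agg) {
  stopifnot(inherits(agg, "aggregated_relevance"))
  info <- feature_info(seq_along(agg$values))
  df <- dplyr::mutate(info, relevance = agg$values)
  by_time <- df |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(relevance = sum(.data$relevance), .groups = "drop")
  by_channel <- df |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(relevance = sum(.data$relevance), .groups = "drop") |>
    dplyr::arrange(match(.data$channel, gait_channels()))
  by_phase <- df |>
    dplyr::mutate(phase = dplyr::case_when(
      .data$sample <= 30 ~ "early (1-30%)",
      .data$sample <= 70 ~ "mid (31-70%)",
      TRUE ~ "late (71-100%)"
    )) |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(relevance = sum(.data$relevance), .groups = "drop") |>
    dplyr::mutate(share = .data$relevance / sum(.data$relevance)) |>
    dplyr::arrange(match(.data$phase, c("early (1-30%)", "mid (31-70%)", "late (71-100%)")))
  list(by_time = by_time, by_channel = by_channel, by_phase = by_phase)
}
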