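#' Train the shallow gait-identification network
#'
#' Fits a fully connected network with one tanh hidden layer and a linear
#' output layer (softmax cross-entropy loss) that assigns stride patterns to
#' individuals. The architecture follows the shape of the data: 1200 input
#' nodes (one per stride-pattern variable) and one output node per individual;
#' the hidden size defaults to `min(2 * n_features, 60 * n_classes)`, which
#' gives the reference 1200-2400-50 layout for a 50-subject dataset and
#' shrinks proportionally for smaller synthetic cohorts.
#'
#' Training is mini-batch stochastic gradient descent (fixed learning rate,
#' optional momentum) over shuffled epochs, deterministic given `seed`.
#' Training stops at `max_epochs`, or earlier when the epoch training loss
#' improves by less than a relative `tol` for `patience` consecutive epochs or
#' falls below `loss_floor`.
#'
#' @param patterns a `stride_patterns` tibble (or any tibble with a `subject`
#'   column and the feature columns of [feature_names()]); features are
#'   expected in `[-1, 1]`.
#' @param hidden hidden-layer size; `NULL` for the default rule above.
#' @param batch_size mini-batch size (25, as in the reference setup).
#' @param max_epochs epoch limit (3000).
#' @param learning_rate fixed SGD step size.
#' @param momentum classical momentum coefficient (0 disables).
#' @param tol,patience,loss_floor early-stopping rule, see above.
#' @param seed integer seed controlling initialization and shuffling.
#' @return object of class `gait_net`: list with weights `W1`, `b1`, `W2`,
#'   `b2`, the class `levels`, and `training` metadata (loss trace, epochs
#'   run, settings, seed).
#' @examples
#' \donttest{
#' d <- generate_gait_data(synthetic_spec(n_subjects = 3, trials_per_day = 6, seed = 2))
#' p <- stride_patterns(d)
#' net <- fit_gait_net(dplyr::filter(p, day == 1), max_epochs = 50, seed = 1)
#' }
#' @export
fit_gait_net <- function(patterns, hidden = NULL, batch_size = 25,
                         max_epochs = 3000, learning_rate = 0.02,
                         momentum = 0.9, tol = 1e-5, patience = 30,
                         loss_floor = 1e-4, seed = 1L) {
  X <- pattern_matrix(patterns)
  y <- factor(patterns$subject)
  if (nlevels(y) < 2) stop("need at least 2 classes (subjects) to train")
  if (any(table(y) < 1)) stop("every class must have at least one pattern")
  n <- nrow(X)
  d <- ncol(X)
  C <- nlevels(y)
  H <- if (is.null(hidden)) min(2L * d, 60L * C) else as.integer(hidden)
  stopifnot(H >= 1, batch_size >= 1, max_epochs >= 1, learning_rate > 0)
  yi <- as.integer(y)
  Y <- matrix(0, n, C)
  Y[cbind(seq_len(n), yi)] <- 1

  withr::with_seed(as.integer(seed), {
    W1 <- matrix(stats::runif(d * H, -1, 1) / sqrt(d), d, H)
    b1 <- numeric(H)
    W2 <- matrix(stats::runif(H * C, -1, 1) / sqrt(H), H, C)
    b2 <- numeric(C)
    V1 <- matrix(0, d, H)
    v1 <- numeric(H)
    V2 <- matrix(0, H, C)
    v2 <- numeric(C)
    loss_trace <- numeric(0)
    best <- Inf
    bad <- 0L
    for (ep in seq_len(max_epochs)) {
      idx <- sample.int(n)
      total <- 0
      for (st in seq(1, n, by = batch_size)) {
        ii <- idx[st:min(st + batch_size - 1, n)]
        Xb <- X[ii, , drop = FALSE]
        Yb <- Y[ii, , drop = FALSE]
        A1 <- tanh(sweep(Xb %*% W1, 2, b1, "+"))
        Z2 <- sweep(A1 %*% W2, 2, b2, "+")
        Z2s <- Z2 - apply(Z2, 1, max)
        P <- exp(Z2s)
        P <- P / rowSums(P)
        total <- total - sum(log(pmax(P[Yb > 0], 1e-300)))
        dZ2 <- (P - Yb) / length(ii)
        dW2 <- crossprod(A1, dZ2)
        db2 <- colSums(dZ2)
        dZ1 <- (dZ2 %*% t(W2)) * (1 - A1^2)
        dW1 <- crossprod(Xb, dZ1)
        db1 <- colSums(dZ1)
        V2 <- momentum * V2 - learning_rate * dW2
        v2 <- momentum * v2 - learning_rate * db2
        V1 <- momentum * V1 - learning_rate * dW1
        v1 <- momentum * v1 - learning_rate * db1
        W2 <- W2 + V2
        b2 <- b2 + v2
        W1 <- W1 + V1
        b1 <- b1 + v1
      }
      loss <- total / n
      if (!is.finite(loss)) {
        stop("training loss became non-finite at epoch ", ep, "; reduce the learning rate")
      }
      loss_trace[ep] <- loss
      if (loss < best * (1 - tol)) {
        best <- loss
        bad <- 0L
      } else {
        bad <- bad + 1L
      }
      if (bad >= patience || loss < loss_floor) break
    }
    structure(
      list(
        W1 = W1, b1 = b1, W2 = W2, b2 = b2,
        levels = levels(y),
        training = list(
          seed = as.integer(seed), epochs_run = length(loss_trace),
          max_epochs = max_epochs, batch_size = batch_size,
          learning_rate = learning_rate, momentum = momentum,
          tol = tol, patience = patience, loss_floor = loss_floor,
          final_loss = loss_trace[length(loss_trace)],
          loss_trace = loss_trace,
          n_patterns = n, hidden = H, classes = C
        )
      ),
      class = "gait_net"
    )
  })
}

#' @export
print.gait_net <- function(x, ...) {
  tr <- x$training
  cat(
    sprintf(
      "<gait_net> %d-%d-%d tanh network | %d epochs, final loss %.4g\n",
      nrow(x$W1), tr$hidden, tr$classes, tr$epochs_run, tr$final_loss
    )
  )
  invisible(x)
}

# forward pass to pre-softmax scores
net_scores <- function(model, X) {
  A1 <- tanh(sweep(X %*% model$W1, 2, model$b1, "+"))
  sweep(A1 %*% model$W2, 2, model$b2, "+")
}

#' Predict subject identities for stride patterns
#'
#' Forward pass of a trained [fit_gait_net()] model. The label is the argmax
#' of the pre-softmax output scores; exact ties deterministically break to the
#' lowest class index.
#'
#' @param object a `gait_net`.
#' @param patterns a `stride_patterns` tibble or bare feature matrix whose
#'   width matches the model input.
#' @param type `"class"` returns a tibble of labels (plus truth when known);
#'   `"score"` returns the pre-softmax score matrix (needed for relevance
#'   propagation); `"prob"` returns softmax probabilities.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.gait_net <- function(object, patterns, type = c("class", "score", "prob"), ...) {
  type <- match.arg(type)
  X <- if (is.matrix(patterns)) patterns else pattern_matrix(patterns)
  if (ncol(X) != nrow(object$W1)) {
    stop("pattern length ", ncol(X), " does not match the model input ", nrow(object$W1))
  }
  S <- net_scores(object, X)
  colnames(S) <- object$levels
  if (type == "score") {
    return(S)
  }
  if (type == "prob") {
    P <- exp(S - apply(S, 1, max))
    return(P / rowSums(P))
  }
  pred <- factor(object$levels[max.col(S, ties.method = "first")], levels = object$levels)
  out <- tibble::tibble(.pred = pred)
  if (!is.matrix(patterns) && "subject" %in% names(patterns)) {
    out <- dplyr::bind_cols(
      dplyr::select(patterns, dplyr::any_of(c("subject", "day", "trial"))),
      out
    )
  }
  out
}

#' Participant-wise classification accuracy
#'
#' For each participant `p`, accuracy is the percentage of that participant's
#' stride patterns assigned to them: `Accuracy(p) = n_p / N_p * 100`, with
#' `n_p` correct out of `N_p` presented. The overall summary is the
#' *unweighted* mean across participants (each participant counts once
#' regardless of how many strides they contributed).
#'
#' @param predictions factor/character vector of predicted labels, or the
#'   tibble returned by [predict.gait_net()] (its `.pred` column is used).
#' @param truth factor/character vector of true labels; taken from the
#'   `subject` column of `predictions` when omitted.
#' @return object of class `accuracy_report`: list with `by_participant`
#'   (tibble `subject`, `n_correct`, `n_total`, `accuracy`), `mean_accuracy`
#'   (unweighted %), and `confusion` (a contingency table).
#' @examples
#' participant_accuracy(c("a", "a", "b", "b"), c("a", "b", "b", "b"))
#' @export
participant_accuracy <- function(predictions, truth = NULL) {
  if (is.data.frame(predictions)) {
    if (is.null(truth)) {
      if (!"subject" %in% names(predictions)) stop("no `truth` and no subject column")
      truth <- predictions$subject
    }
    predictions <- predictions$.pred
  }
  if (length(predictions) != length(truth)) stop("predictions and truth must align")
  truth <- factor(truth)
  predictions <- factor(as.character(predictions), levels = levels(truth))
  present <- table(truth)
  if (any(present == 0)) {
    dropped <- names(present)[present == 0]
    message("excluding participant(s) with no presented strides: ", paste(dropped, collapse = ", "))
    keep <- truth %in% names(present)[present > 0]
    truth <- droplevels(truth[keep])
    predictions <- factor(as.character(predictions[keep]), levels = levels(truth))
  }
  by_p <- tibble::tibble(subject = truth, correct = as.character(predictions) == as.character(truth)) |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(
      n_correct = sum(.data$correct, na.rm = TRUE),
      n_total = dplyr::n(),
      accuracy = .data$n_correct / .data$n_total * 100,
      .groups = "drop"
    )
  structure(
    list(
      by_participant = by_p,
      mean_accuracy = mean(by_p$accuracy),
      confusion = table(truth = truth, predicted = predictions)
    ),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(
    sprintf(
      "<accuracy_report> unweighted mean accuracy %.2f%% over %d participants (%d strides)\n",
      x$mean_accuracy, nrow(x$by_participant), sum(x$by_participant$n_total)
    )
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy methods for fitted gait networks and accuracy reports
#'
#' `tidy.gait_net()` summarizes the parameters per layer; `glance.gait_net()`
#' returns a one-row training summary. `tidy.accuracy_report()` returns the
#' per-participant accuracy table; `glance.accuracy_report()` a one-row
#' summary.
#'
#' @param x a `gait_net` or `accuracy_report`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy gait_net
#' @export
tidy.gait_net <- function(x, ...) {
  layer <- function(name, W, b) {
    tibble::tibble(
      layer = name, rows = nrow(W), cols = ncol(W),
      n_parameters = length(W) + length(b),
      weight_mean = mean(W), weight_sd = stats::sd(as.numeric(W)),
      bias_norm = sqrt(sum(b^2))
    )
  }
  dplyr::bind_rows(
    layer("input->hidden (tanh)", x$W1, x$b1),
    layer("hidden->output (linear)", x$W2, x$b2)
  )
}

#' @rdname tidy.gait_net
#' @method glance gait_net
#' @export
glance.gait_net <- function(x, ...) {
  tr <- x$training
  tibble::tibble(
    n_features = nrow(x$W1), hidden = tr$hidden, classes = tr$classes,
    n_patterns = tr$n_patterns, epochs_run = tr$epochs_run,
    batch_size = tr$batch_size, learning_rate = tr$learning_rate,
    momentum = tr$momentum, final_loss = tr$final_loss, seed = tr$seed
  )
}

#' @rdname tidy.gait_net
#' @method tidy accuracy_report
#' @export
tidy.accuracy_report <- function(x, ...) x$by_participant

#' @rdname tidy.gait_net
#' @method glance accuracy_report
#' @export
glance.accuracy_report <- function(x, ...) {
  tibble::tibble(
    mean_accuracy = x$mean_accuracy,
    n_participants = nrow(x$by_participant),
    n_strides = sum(x$by_participant$n_total),
    min_accuracy = min(x$by_participant$accuracy),
    prop_at_least_90 = mean(x$by_participant$accuracy >= 90)
  )
}
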