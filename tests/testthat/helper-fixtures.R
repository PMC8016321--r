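# Shared fixtures, generated in code and memoized so expensive objects are
# built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small processed dataset: 4 subjects, 6 trials/day
small_data <- function() {
  fixture("small_data", generate_gait_data(
    synthetic_spec(n_subjects = 4, trials_per_day = 6, seed = 421)
  ))
}

small_patterns <- function() {
  fixture("small_patterns", stride_patterns(small_data()))
}

# a quick, overfit-friendly trained net on the small dataset's day 1
small_net <- function() {
  fixture("small_net", {
    p1 <- dplyr::filter(small_patterns(), day == 1)
    fit_gait_net(p1, max_epochs = 400, seed = 1)
  })
}

# linearly separable toy patterns: class offsets in a single variable
toy_patterns <- function(n_class = 2, n_per = 10, sep_index = 5, seed = 99) {
  withr::with_seed(seed, {
    n <- n_class * n_per
    X <- matrix(stats::runif(n * 1200, -0.05, 0.05), n, 1200)
    lab <- rep(seq_len(n_class), each = n_per)
    X[, sep_index] <- -0.9 + 1.8 * (lab - 1) / max(1, n_class - 1)
    colnames(X) <- feature_names()
    out <- dplyr::bind_cols(
      tibble::tibble(subject = lab, day = 1L, trial = sequence(rep(n_per, n_class))),
      tibble::as_tibble(X)
    )
    class(out) <- c("stride_patterns", class(out))
    out
  })
}

# random small dense network in gait_net form (for LRP checks)
random_net <- function(d, H, C, seed = 1, bias = TRUE) {
  withr::with_seed(seed, {
    structure(
      list(
        W1 = matrix(stats::rnorm(d * H), d, H),
        b1 = if (bias) stats::rnorm(H) else numeric(H),
        W2 = matrix(stats::rnorm(H * C), H, C),
        b2 = if (bias) stats::rnorm(C) else numeric(C),
        levels = as.character(seq_len(C)),
        training = list(hidden = H, classes = C, epochs_run = 0, final_loss = NA)
      ),
      class = "gait_net"
    )
  })
}

# long-format trajectory table for standardization tests
long_from_matrix <- function(m, subject = 1, day = 1, channel = "hip_ab_ad") {
  # m: trials x samples
  tibble::tibble(
    subject = subject, day = day,
    trial = rep(seq_len(nrow(m)), each = ncol(m)),
    channel = channel,
    sample = rep(seq_len(ncol(m)), nrow(m)),
    value = as.numeric(t(m))
  )
}
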