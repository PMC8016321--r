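test_that("stance detection finds the thresholded contact interval", {
  v <- c(rep(0, 99), rep(800, 400), rep(0, 100))
  expect_identical(detect_stance(v, rate = 2400), c(heel_strike = 100L, toe_off = 500L))
  # brute-force oracle: first/last index at or above threshold
  idx <- which(v >= 15)
  expect_identical(unname(detect_stance(v, rate = 2400)), c(min(idx), max(idx) + 1L))

  expect_error(detect_stance(rep(0, 500)), "no stance")
  expect_error(detect_stance(c(rep(0, 10), NA, rep(0, 10))), "finite")
  # a noise spike shorter than min_duration does not qualify
  spiky <- c(rep(0, 50), rep(100, 5), rep(0, 45), rep(900, 300), rep(0, 50))
  expect_identical(
    unname(detect_stance(spiky, rate = 2400, min_duration = 0.05)),
    c(101L, 401L)
  )
  # two qualifying contacts: error in strict mode, longest otherwise
  double <- c(rep(0, 10), rep(500, 200), rep(0, 50), rep(500, 300), rep(0, 10))
  expect_error(detect_stance(double, rate = 2400), "single step")
  expect_identical(
    unname(detect_stance(double, rate = 2400, strict = FALSE)),
    c(261L, 561L)
  )
})

test_that("lowpass filter has unit DC gain, preserves passband, kills stopband", {
  rate <- 240
  n <- 2400
  t <- (seq_len(n) - 1) / rate
  expect_equal(lowpass(rep(3.7, n), rate, 15), rep(3.7, n))

  amp_ratio <- function(freq, cutoff) {
    y <- lowpass(sin(2 * pi * freq * t), rate, cutoff)
    core <- y[(n / 4):(3 * n / 4)]
    max(abs(core))
  }
  expect_equal(amp_ratio(1.5, 15), 1, tolerance = 0.01) # cutoff / 10
  expect_equal(amp_ratio(15, 15), 1 / sqrt(2), tolerance = 0.03) # -3 dB at cutoff
  expect_lt(amp_ratio(30, 15), 10^(-40 / 20)) # >= 40 dB at 2x cutoff
  expect_lt(amp_ratio(45, 15), 10^(-40 / 20)) # and beyond

  # zero phase: a symmetric pulse keeps its peak location
  x <- exp(-((seq_len(n) - 1200)^2) / (2 * 40^2))
  expect_equal(which.max(lowpass(x, rate, 15)), 1200, tolerance = 1)
  expect_error(lowpass(x, rate, 130), "Nyquist")
})

test_that("time normalization is shape-preserving onto 100 samples", {
  expect_equal(time_normalize(rep(2.5, 240)), rep(2.5, 100))
  ramp <- seq(0, 1, length.out = 240)
  expect_equal(time_normalize(ramp), seq(0, 1, length.out = 100), tolerance = 1e-12)
  # endpoints preserved exactly
  withr::with_seed(5, x <- cumsum(stats::rnorm(57)))
  y <- time_normalize(x)
  expect_identical(y[1], x[1])
  expect_identical(y[100], x[57])
  # no overshoot beyond the data range on a monotone step-like input
  step <- c(rep(0, 20), seq(0, 1, length.out = 5), rep(1, 20))
  ys <- time_normalize(step)
  expect_true(all(ys >= 0 - 1e-12 & ys <= 1 + 1e-12))
  expect_error(time_normalize(1:3), "at least 4")
})

test_that("monotone cubic interpolation matches an independent Fritsch-Carlson oracle", {
  # independent implementation of monotone cubic slopes
  fc_oracle <- function(x, y, xi) {
    n <- length(x)
    h <- diff(x)
    delta <- diff(y) / h
    m <- numeric(n)
    m[1] <- delta[1]
    m[n] <- delta[n - 1]
    for (i in 2:(n - 1)) {
      m[i] <- if (delta[i - 1] * delta[i] <= 0) 0 else 2 / (1 / delta[i - 1] + 1 / delta[i])
    }
    vapply(xi, function(z) {
      i <- max(which(x <= z))
      if (i == n) {
        return(y[n])
      }
      s <- (z - x[i]) / h[i]
      h00 <- 2 * s^3 - 3 * s^2 + 1
      h10 <- s^3 - 2 * s^2 + s
      h01 <- -2 * s^3 + 3 * s^2
      h11 <- s^3 - s^2
      h00 * y[i] + h10 * h[i] * m[i] + h01 * y[i + 1] + h11 * h[i] * m[i + 1]
    }, numeric(1))
  }
  withr::with_seed(11, y <- cumsum(abs(stats::rnorm(31)))) # strictly monotone data
  xi <- seq(1, 31, length.out = 100)
  got <- time_normalize(y)
  oracle <- fc_oracle(seq_len(31), y, xi)
  # same family of shape-preserving interpolants: identical knot values,
  # near-identical interiors, and no overshoot for either
  expect_equal(got[c(1, 100)], oracle[c(1, 100)])
  expect_lt(max(abs(got - oracle)) / diff(range(y)), 0.02)
  expect_true(all(got >= min(y) & got <= max(y)))
})

test_that("participant standardization matches its contracts in pointwise mode", {
  cfg <- preprocess_config(center = "trajectory", sd_mode = "pointwise")
  withr::with_seed(3, m <- matrix(stats::rnorm(8 * 100, mean = 5, sd = 2), 8, 100))
  df <- long_from_matrix(m)
  out <- standardize_participant(df, cfg)
  wide <- matrix(out$value[order(out$trial, out$sample)], 8, 100, byrow = TRUE)
  expect_lt(max(abs(colMeans(wide))), 1e-12)
  # per-sample SD (population form, the pipeline's estimator) is exactly 1
  sd_pop <- apply(wide, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_equal(sd_pop, rep(1, 100), tolerance = 1e-12)

  # two-point standardization: values {+a, -a} -> {+1, -1}
  two <- long_from_matrix(rbind(rep(3, 100), rep(-3, 100)))
  res <- standardize_participant(two, cfg)
  expect_setequal(round(res$value, 12), c(1, -1))

  # identical trials: all values floored to zero with a warning
  same <- long_from_matrix(rbind(1:100, 1:100))
  expect_warning(res0 <- standardize_participant(same, cfg), "floored")
  expect_true(all(res0$value == 0))

  expect_error(
    standardize_participant(long_from_matrix(matrix(1:100, 1, 100)), cfg),
    "at least 2 trials"
  )
})

test_that("standardized features are centred on the split mean trajectory", {
  withr::with_seed(14, {
    df <- dplyr::bind_rows(lapply(1:3, function(s) {
      d <- long_from_matrix(matrix(stats::rnorm(4 * 50, mean = s, sd = 1 + s / 2), 4, 50))
      d$subject <- s
      d
    }))
  })
  out <- standardize_participant(df, preprocess_config())
  means <- tapply(out$value, out$sample, mean)
  expect_lt(max(abs(means)), 1e-12)
})

test_that("scalar standardization removes per-participant offset and gain exactly", {
  withr::with_seed(4, m <- matrix(stats::rnorm(6 * 100, 10, 3), 6, 100))
  cfg <- preprocess_config() # scalar center, scalar sd
  base <- standardize_participant(long_from_matrix(m), cfg)
  shifted <- standardize_participant(long_from_matrix(2.5 * m + 7), cfg)
  expect_equal(base$value, shifted$value, tolerance = 1e-12)
})

test_that("rescaling is symmetric, order-preserving and attains +/-1", {
  df <- long_from_matrix(matrix(c(-2, 1, 4, 0.5, -1, 2), 2, 3))
  cfg_ch <- preprocess_config(rescale = "channel")
  out <- rescale_unit(df, cfg_ch)
  expect_equal(max(abs(out$value)), 1)
  expect_equal(out$value, df$value / 4) # channel max is 4
  # odd symmetry
  neg <- df
  neg$value <- -neg$value
  expect_equal(rescale_unit(neg, cfg_ch)$value, -out$value)
  # per-trial scope: each trial divided by its own maximum
  out_tr <- rescale_unit(df, preprocess_config(rescale = "trial"))
  per_trial_max <- ave(abs(df$value), df$trial, FUN = max)
  expect_equal(out_tr$value, df$value / per_trial_max)
  # all-zero channel left at zero with a warning
  z <- long_from_matrix(matrix(0, 2, 3))
  expect_warning(zz <- rescale_unit(z, cfg_ch), "all-zero")
  expect_true(all(zz$value == 0))
})

test_that("assembly maps channels and samples to the documented indices", {
  grid <- tidyr::expand_grid(
    subject = 1L, day = 1L, trial = 1L,
    channel = gait_channels(), sample = 1:100
  )
  k <- match(grid$channel, gait_channels())
  grid$value <- k / 12
  wide <- assemble_patterns(grid)
  m <- pattern_matrix(wide)
  for (kk in c(1, 5, 12)) {
    expect_true(all(m[1, (kk - 1) * 100 + 1:100] == kk / 12))
  }
  expect_error(
    assemble_patterns(dplyr::filter(grid, channel != "grf_ml")),
    "missing"
  )
})

test_that("the full pipeline emits deterministic patterns in [-1, 1]", {
  p <- small_patterns()
  expect_s3_class(p, "stride_patterns")
  m <- pattern_matrix(p)
  expect_equal(dim(m), c(nrow(p), 1200))
  expect_true(all(is.finite(m)))
  expect_true(all(m >= -1 & m <= 1))
  # every trial attains 1 in absolute value (per-trial rescaling)
  expect_equal(apply(abs(m), 1, max), rep(1, nrow(m)))
  # determinism: rebuilding from the same dataset is bit-identical
  p2 <- stride_patterns(small_data())
  expect_identical(p, p2)
})

test_that("per-participant offset or gain on a raw channel leaves patterns bit-identical", {
  d <- small_data()
  mod <- d
  mod$trials <- dplyr::mutate(mod$trials,
    angles = purrr::map2(angles, subject, function(a, s) {
      a$hip_ab_ad <- a$hip_ab_ad * (1 + 0.35 * s) + 4 * s # per-subject gain + offset
      a
    }),
    grf = purrr::map2(grf, subject, function(g, s) {
      g$grf_ml <- g$grf_ml * (1 + 0.1 * s) - 20 * s
      g
    })
  )
  expect_equal(stride_patterns(d), stride_patterns(mod), tolerance = 1e-10)
})
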