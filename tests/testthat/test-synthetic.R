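test_that("spec validation rejects impossible configurations", {
  expect_error(synthetic_spec(planted_channels = "no_such_channel"), "unknown planted")
  expect_error(synthetic_spec(planted_window = c(0.5, 0.2)))
  expect_error(synthetic_spec(planted_window = c(-0.2, 0.5)))
  expect_error(synthetic_spec(effect_size = -1))
  expect_error(synthetic_spec(trials_per_day = c(1, 2, 3)), "length-2")
  spec <- synthetic_spec(n_subjects = 5, seed = 3)
  expect_length(spec$channels, 12)
  expect_identical(spec$channels, gait_channels())
})

test_that("zero effect size yields identical templates and a warning", {
  spec <- synthetic_spec(n_subjects = 3, trials_per_day = 4, effect_size = 0, seed = 2)
  expect_warning(truth <- generate_templates(spec), "unidentifiable")
  phase <- seq(0, 1, length.out = 101)
  for (ch in c("hip_ab_ad", "grf_ml")) {
    t1 <- subject_template(truth, 1, ch, phase)
    for (s in 2:3) {
      expect_identical(subject_template(truth, s, ch, phase), t1)
    }
  }
})

test_that("subject deviations concentrate in the planted window and channels", {
  spec <- synthetic_spec(
    n_subjects = 6, trials_per_day = 4,
    planted_channels = "hip_ab_ad", planted_window = c(0, 0.3), seed = 8
  )
  truth <- generate_templates(spec)
  phase <- (1:100 - 0.5) / 100
  # numerically integrate squared between-subject deviation per channel/sample
  for (ch in c("hip_ab_ad", "knee_flex_ext", "grf_vert")) {
    curves <- sapply(1:6, function(s) subject_template(truth, s, ch, phase))
    dev2 <- rowSums((curves - rowMeans(curves))^2)
    if (ch == "hip_ab_ad") {
      expect_gt(sum(dev2[1:30]) / sum(dev2), 0.95)
      expect_gt(sum(dev2), 0)
    } else {
      expect_equal(sum(dev2), 0)
    }
  }
  # planted variable set bookkeeping matches the index utility
  expect_identical(
    truth$planted_variable_set,
    planted_variable_set("hip_ab_ad", c(0, 0.3))
  )
})

test_that("template generation is deterministic given the spec", {
  spec <- synthetic_spec(n_subjects = 3, trials_per_day = 4, seed = 77)
  t1 <- generate_templates(spec)
  t2 <- generate_templates(spec)
  expect_identical(t1$signatures, t2$signatures)
  expect_identical(t1$drift, t2$drift)
  tr1 <- generate_trial(t1, 2, 1, 3)
  tr2 <- generate_trial(t2, 2, 1, 3)
  expect_identical(tr1$angles, tr2$angles)
  expect_identical(tr1$grf, tr2$grf)
})

test_that("noise-free trials reproduce the template exactly", {
  spec <- synthetic_spec(
    n_subjects = 2, trials_per_day = 3,
    noise_sd_frac = 0, stance_sd = 0, seed = 5
  )
  truth <- suppressWarnings(generate_templates(spec))
  tr <- generate_trial(truth, 1, 1, 1)
  n <- nrow(tr$angles)
  phase <- (seq_len(n) - 1) / (n - 1)
  expect_equal(tr$angles$hip_ab_ad, subject_template(truth, 1, "hip_ab_ad", phase))
  expect_error(generate_trial(truth, 99, 1, 1), "unknown subject")
})

test_that("trial noise has the configured per-sample spread", {
  spec <- synthetic_spec(
    n_subjects = 1, trials_per_day = 2, planted_channels = character(0),
    stance_sd = 0, seed = 31
  )
  truth <- generate_templates(spec)
  trials <- lapply(1:400, function(i) generate_trial(truth, 1, 1, i)$angles$hip_flex_ext)
  m <- do.call(rbind, trials)
  template <- subject_template(
    truth, 1, "hip_flex_ext",
    (seq_len(ncol(m)) - 1) / (ncol(m) - 1)
  )
  target_sd <- truth$noise_sd[["hip_flex_ext"]]
  # per-sample SD across trials within 10% of the configured SD (Monte Carlo)
  sds <- apply(sweep(m, 2, template), 2, stats::sd)
  expect_lt(abs(mean(sds) - target_sd) / target_sd, 0.1)
})

test_that("day-2 trials without drift match the day-1 distribution", {
  spec <- synthetic_spec(
    n_subjects = 1, trials_per_day = 2, day2_drift = 0, seed = 13
  )
  truth <- generate_templates(spec)
  # summary statistic: trial mean of one planted channel
  stat <- function(day) {
    vapply(
      1:60,
      function(i) mean(generate_trial(truth, 1, day, i)$angles$hip_ab_ad),
      numeric(1)
    )
  }
  p <- stats::ks.test(stat(1), stat(2))$p.value
  expect_gt(p, 0.01)
})

test_that("trial counts respect the per-subject range and the 20-per-day cap", {
  spec <- synthetic_spec(n_subjects = 8, trials_per_day = c(29L, 40L), seed = 4)
  d <- generate_gait_data(spec)
  counts <- dplyr::count(d$trials, subject, day)
  expect_true(all(counts$n <= 20))
  totals <- dplyr::count(d$trials, subject)
  expect_true(all(totals$n >= 29 & totals$n <= 40))
})

test_that("raw rendering satisfies rigid-body and force-threshold contracts", {
  spec <- synthetic_spec(
    n_subjects = 2, trials_per_day = 3, noise_sd_frac = 0, seed = 9
  )
  truth <- suppressWarnings(generate_templates(spec))
  tr <- generate_trial(truth, 1, 1, 1)
  raw <- render_raw(tr)
  # inter-marker distances are time-constant (rigid body, noise-free)
  for (seg in names(raw$markers)) {
    arr <- raw$markers[[seg]]
    d12 <- apply(arr, 1, function(x) stats::dist(x)[1])
    expect_lt(diff(range(d12)), 1e-12)
  }
  # vertical force: >= 0 inside contact, below threshold outside
  v <- raw$grf[, "grf_vert"]
  hs <- raw$stance[["heel_strike"]]
  to <- raw$stance[["toe_off"]]
  expect_true(all(v[hs:(to - 1)] >= 15))
  expect_true(all(v[c(seq_len(hs - 1), to:length(v))] < 15))
})

test_that("all-zero angles keep every marker at its standing position", {
  spec <- synthetic_spec(n_subjects = 1, trials_per_day = 2, noise_sd_frac = 0, seed = 3)
  truth <- generate_templates(spec)
  tr <- generate_trial(truth, 1, 1, 1)
  tr$angles[] <- 0
  raw <- render_raw(tr)
  geom <- default_cluster_geometry()
  for (seg in names(geom)) {
    for (f in c(1, 10, dim(raw$markers[[seg]])[1])) {
      expect_equal(raw$markers[[seg]][f, , ], geom[[seg]], tolerance = 1e-12)
    }
  }
})

test_that("a constant planted rotation on the thigh is recovered as hip angles", {
  spec <- synthetic_spec(n_subjects = 1, trials_per_day = 2, noise_sd_frac = 0, seed = 3)
  truth <- generate_templates(spec)
  tr <- generate_trial(truth, 1, 1, 1)
  tr$angles[] <- 0
  tr$angles$hip_rot_int_ext <- 10 # 10 degrees about Z at the hip, all frames
  raw <- render_raw(tr)
  ang <- trial_joint_angles(raw)
  expect_equal(ang$hip_rot_int_ext, rep(10, nrow(ang)), tolerance = 1e-8)
  others <- setdiff(angle_channels(), "hip_rot_int_ext")
  expect_lt(max(abs(as.matrix(ang[, others]))), 1e-8)
})

test_that("raw rendering rejects gimbal-degenerate angle channels", {
  spec <- synthetic_spec(n_subjects = 1, trials_per_day = 2, noise_sd_frac = 0, seed = 3)
  truth <- generate_templates(spec)
  tr <- generate_trial(truth, 1, 1, 1)
  tr$angles$knee_ab_ad <- 88
  expect_error(render_raw(tr), "gimbal")
})

test_that("datasets round-trip through the delimited-table writer", {
  d <- generate_gait_data(synthetic_spec(n_subjects = 2, trials_per_day = 2, seed = 6))
  dir <- withr::local_tempdir()
  write_gait_data(d, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_gait_data(dir)
  expect_equal(nrow(back$trials), nrow(d$trials))
  expect_equal(back$trials$angles[[1]], d$trials$angles[[1]], tolerance = 1e-12)
  expect_equal(back$trials$grf[[3]], d$trials$grf[[3]], tolerance = 1e-12)
  expect_equal(
    sort(unlist(back$truth$planted_variable_set)),
    d$truth$planted_variable_set
  )
})
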