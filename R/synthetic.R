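#' Specification of a synthetic multi-subject gait dataset
#'
#' Describes the statistical structure of a generated dataset: number of
#' subjects, trials, where identity information is planted (channels and a
#' fractional stance window), how strong it is relative to stride-to-stride
#' noise, and the native sampling setup (240 Hz kinematics, 2400 Hz force).
#'
#' `trials_per_day` may be a single count (that many trials on each of the two
#' days) or a length-2 range for the *total* trials per subject over both days
#' (drawn uniformly, split across the days with at most 20 per day) --
#' defaulting to the 29--40 range of the emulated study, so class imbalance is
#' present by design.
#'
#' `effect_size` is the ratio of the between-subject template spread to the
#' within-subject trial noise, per planted channel: each subject's template
#' deviates from the common template by a smooth signature of
#' root-mean-square amplitude `effect_size * noise SD` inside
#' `planted_window`.
#'
#' @param n_subjects number of subjects.
#' @param trials_per_day single per-day count or length-2 total range.
#' @param planted_channels channels carrying identity information (subset of
#'   [gait_channels()]).
#' @param planted_window fractional stance interval holding the identity
#'   signature, default `c(0, 0.3)` (early stance, samples 1--30).
#' @param effect_size between-subject spread / within-subject noise (>= 0).
#' @param noise_sd_frac trial-noise SD as a fraction of each channel's common
#'   template range.
#' @param noise_corr_len correlation length of the smooth trial noise, as a
#'   fraction of stance duration.
#' @param day2_drift amplitude of the systematic day-2 template perturbation,
#'   in units of the channel noise SD.
#' @param stance_mean,stance_sd mean and spread of stance duration (seconds).
#' @param kinematic_rate,force_rate sampling rates in Hz.
#' @param seed integer seed; dataset generation is a pure function of the
#'   spec including this seed.
#' @return object of class `gait_spec`.
#' @examples
#' spec <- synthetic_spec(n_subjects = 4, trials_per_day = 5, seed = 1)
#' @export
synthetic_spec <- function(n_subjects = 50,
                           trials_per_day = c(29L, 40L),
                           planted_channels = c(
                             "hip_ab_ad", "hip_rot_int_ext", "knee_ab_ad",
                             "ankle_inv_ev", "grf_ml"
                           ),
                           planted_window = c(0, 0.3),
                           effect_size = 3.2,
                           noise_sd_frac = 0.05,
                           noise_corr_len = 0.05,
                           day2_drift = 0.3,
                           stance_mean = 0.25,
                           stance_sd = 0.015,
                           kinematic_rate = 240,
                           force_rate = 2400,
                           seed = 1L) {
  stopifnot(n_subjects >= 1, effect_size >= 0, noise_sd_frac >= 0)
  if (!all(planted_channels %in% gait_channels())) {
    stop("unknown planted channel(s): ",
      paste(setdiff(planted_channels, gait_channels()), collapse = ", "))
  }
  stopifnot(
    length(planted_window) == 2, planted_window[1] >= 0,
    planted_window[2] <= 1, planted_window[1] < planted_window[2],
    kinematic_rate > 0, force_rate > 0, stance_mean > 0, stance_sd >= 0,
    noise_corr_len > 0
  )
  if (length(trials_per_day) == 1) {
    stopifnot(trials_per_day >= 1)
  } else if (length(trials_per_day) == 2) {
    stopifnot(trials_per_day[1] >= 2, trials_per_day[2] >= trials_per_day[1])
  } else {
    stop("`trials_per_day` must be a count or a length-2 range")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      trials_per_day = as.integer(trials_per_day),
      channels = gait_channels(),
      planted_channels = planted_channels,
      planted_window = as.numeric(planted_window),
      effect_size = effect_size,
      noise_sd_frac = noise_sd_frac,
      noise_corr_len = noise_corr_len,
      day2_drift = day2_drift,
      stance_mean = stance_mean,
      stance_sd = stance_sd,
      kinematic_rate = kinematic_rate,
      force_rate = force_rate,
      seed = as.integer(seed)
    ),
    class = "gait_spec"
  )
}

#' @export
print.gait_spec <- function(x, ...) {
  cat(
    "<gait_spec>", x$n_subjects, "subjects, trials/day",
    paste(x$trials_per_day, collapse = "-"), "\n  planted:",
    paste(x$planted_channels, collapse = ", "), "in",
    sprintf("[%.0f%%, %.0f%%] of stance", 100 * x$planted_window[1], 100 * x$planted_window[2]),
    "\n  effect size", x$effect_size, "| seed", x$seed, "\n"
  )
  invisible(x)
}

# --- template machinery ------------------------------------------------------

# raised-cosine bump on [center - width, center + width], peak 1 at center
raised_cosine <- function(u, center, width) {
  out <- numeric(length(u))
  inside <- abs(u - center) <= width
  out[inside] <- 0.5 * (1 + cos(pi * (u[inside] - center) / width))
  out
}

# evaluate a bump parameter table (columns amp, center, width) on a phase grid
eval_bumps <- function(params, phase) {
  if (nrow(params) == 0) {
    return(numeric(length(phase)))
  }
  rowSums(mapply(
    function(a, c, w) a * raised_cosine(phase, c, w),
    params$amp, params$center, params$width
  ))
}

# Common (population) templates: documented constants built from raised-cosine
# bumps over normalized stance phase. Angles in degrees, forces in newtons.
# Shapes are stylized running curves; only their role as channels matters.
common_template_params <- function() {
  p <- function(channel, amp, center, width) {
    tibble::tibble(channel = channel, amp = amp, center = center, width = width)
  }
  dplyr::bind_rows(
    p("hip_flex_ext", c(35, -12), c(0.10, 0.80), c(0.45, 0.40)),
    p("hip_ab_ad", c(8, -3), c(0.30, 0.85), c(0.40, 0.25)),
    p("hip_rot_int_ext", c(-4, 6), c(0.15, 0.60), c(0.25, 0.45)),
    p("knee_flex_ext", c(28, 12), c(0.40, 0.95), c(0.35, 0.20)),
    p("knee_ab_ad", c(5, -2), c(0.35, 0.80), c(0.30, 0.25)),
    p("knee_rot_int_ext", c(6, -3), c(0.55, 0.15), c(0.40, 0.20)),
    p("ankle_dorsi_plant", c(15, -14), c(0.45, 0.95), c(0.40, 0.18)),
    p("ankle_ab_ad", c(4, -2), c(0.50, 0.10), c(0.45, 0.20)),
    p("ankle_inv_ev", c(-7, 3), c(0.30, 0.80), c(0.35, 0.30)),
    p("grf_ap", c(-160, 180), c(0.22, 0.72), c(0.20, 0.24)),
    p("grf_ml", c(55, 35), c(0.15, 0.60), c(0.16, 0.35)),
    p("grf_vert", c(500, 1600), c(0.12, 0.52), c(0.12, 0.45))
  )
}

# per-channel trial-noise SD implied by the spec (fraction of template range)
channel_noise_sd <- function(spec) {
  phase <- seq(0, 1, length.out = 200)
  params <- common_template_params()
  vapply(spec$channels, function(ch) {
    curve <- eval_bumps(params[params$channel == ch, ], phase)
    spec$noise_sd_frac * diff(range(curve))
  }, numeric(1))
}

derive_seed <- function(seed, ...) {
  ids <- c(...)
  mix <- (as.double(seed) * 48271 + sum(as.double(ids) * c(100003, 10007, 101)[seq_along(ids)])) %% 2147483629
  as.integer(mix)
}

#' Generate ground-truth subject templates
#'
#' Builds the common (population) template for every channel and, for each
#' subject, a smooth identity signature on the planted channels: a sum of
#' three raised-cosine bumps whose supports lie inside `planted_window`,
#' normalized to unit root-mean-square amplitude over the window and scaled by
#' `effect_size` times the channel's trial-noise SD. Non-planted channels are
#' identical across subjects. Deterministic given the spec (including its
#' seed).
#'
#' @param spec a [synthetic_spec()].
#' @return object of class `gait_truth`: list with `spec`, `common` (bump
#'   parameter table), `signatures` (per-subject bump parameter table),
#'   `drift` (day-2 perturbation parameters), `planted_variable_set` (feature
#'   indices), and `noise_sd` (per-channel SD).
#' @export
generate_templates <- function(spec) {
  stopifnot(inherits(spec, "gait_spec"))
  if (spec$effect_size == 0 && length(spec$planted_channels) > 0) {
    warning("effect_size is 0 with non-empty planted_channels: ",
      "all subjects share identical templates and the dataset is unidentifiable by construction")
  }
  noise_sd <- channel_noise_sd(spec)
  win <- spec$planted_window
  samples_grid <- (window_samples(win) - 0.5) / 100
  withr::with_seed(derive_seed(spec$seed, 1), {
    sig <- purrr::map_dfr(seq_len(spec$n_subjects), function(s) {
      purrr::map_dfr(spec$planted_channels, function(ch) {
        width <- stats::runif(3, 0.10, 0.14) * (win[2] - win[1]) / 0.3
        lo <- win[1] + 0.8 * width
        hi <- win[2] - 0.8 * width
        center <- stats::runif(3, lo, pmax(lo, hi))
        amp <- stats::rnorm(3)
        raw <- tibble::tibble(amp = amp, center = center, width = width)
        rms <- sqrt(mean(eval_bumps(raw, samples_grid)^2))
        if (rms < .Machine$double.eps) rms <- 1
        tibble::tibble(
          subject = s, channel = ch,
          amp = amp / rms * spec$effect_size * noise_sd[[ch]],
          center = center, width = width
        )
      })
    })
    drift <- purrr::map_dfr(seq_len(spec$n_subjects), function(s) {
      purrr::map_dfr(spec$channels, function(ch) {
        tibble::tibble(
          subject = s, channel = ch,
          amp = stats::rnorm(2, 0, spec$day2_drift * noise_sd[[ch]] / sqrt(2)),
          center = stats::runif(2, 0.15, 0.85),
          width = stats::runif(2, 0.15, 0.30)
        )
      })
    })
    structure(
      list(
        spec = spec,
        common = common_template_params(),
        signatures = sig,
        drift = drift,
        planted_variable_set = planted_variable_set(spec$planted_channels, win),
        noise_sd = noise_sd
      ),
      class = "gait_truth"
    )
  })
}

#' @export
print.gait_truth <- function(x, ...) {
  cat(
    "<gait_truth>", x$spec$n_subjects, "subject templates |",
    length(x$planted_variable_set), "planted feature indices\n"
  )
  invisible(x)
}

#' Evaluate a subject's template on a phase grid
#'
#' Returns the noise-free trajectory template (common curve plus the subject's
#' identity signature, plus the day-2 drift when `day = 2`) for one channel.
#'
#' @param truth a `gait_truth` object.
#' @param subject subject id (integer).
#' @param channel channel identifier.
#' @param phase numeric vector of stance fractions in `[0, 1]`.
#' @param day 1 or 2.
#' @return numeric vector of template values.
#' @export
subject_template <- function(truth, subject, channel, phase, day = 1) {
  stopifnot(inherits(truth, "gait_truth"))
  if (!channel %in% truth$spec$channels) stop("unknown channel: ", channel)
  if (!subject %in% seq_len(truth$spec$n_subjects)) stop("unknown subject: ", subject)
  com <- truth$common
  out <- eval_bumps(com[com$channel == channel, ], phase)
  sg <- truth$signatures
  if (nrow(sg) > 0) {
    sg <- sg[sg$subject == subject & sg$channel == channel, ]
    if (nrow(sg) > 0) out <- out + eval_bumps(sg, phase)
  }
  if (day == 2) {
    dr <- truth$drift
    if (nrow(dr) > 0) {
      dr <- dr[dr$subject == subject & dr$channel == channel, ]
      if (nrow(dr) > 0) out <- out + eval_bumps(dr, phase)
    }
  }
  out
}

# smooth correlated noise: white noise convolved with a gaussian kernel whose
# SD is `corr_len` (in units of the phase grid spacing), normalized to unit
# marginal SD, then scaled
smooth_noise <- function(n, corr_len_samples, sd = 1) {
  if (sd == 0) {
    return(numeric(n))
  }
  half <- max(1L, ceiling(3 * corr_len_samples))
  k <- stats::dnorm(seq(-half, half), sd = corr_len_samples)
  k <- k / sqrt(sum(k^2))
  w <- stats::rnorm(n + 2 * half)
  sd * stats::convolve(w, k, type = "filter")[seq_len(n)]
}

#' Generate one synthetic trial (processed trajectories at native rates)
#'
#' Draws a stance duration, evaluates the subject's template on the native
#' phase grids (kinematic channels at the kinematic rate, GRF channels at the
#' force rate) and adds smooth correlated trial noise. Reproducible: the trial
#' seed is derived from the spec seed and the (subject, day, trial) labels
#' unless supplied explicitly.
#'
#' @param truth a `gait_truth` from [generate_templates()].
#' @param subject subject id.
#' @param day 1 or 2.
#' @param trial trial number (used for seeding and labeling).
#' @param trial_seed optional explicit integer seed.
#' @return object of class `gait_trial`: list with `subject`, `day`, `trial`,
#'   `stance_s`, `angles` (tibble, 240 Hz stance frames x 9 channels, degrees)
#'   and `grf` (tibble, 2400 Hz stance frames x 3 channels, newtons).
#' @export
generate_trial <- function(truth, subject, day, trial = 1L, trial_seed = NULL) {
  stopifnot(inherits(truth, "gait_truth"))
  spec <- truth$spec
  if (!subject %in% seq_len(spec$n_subjects)) stop("unknown subject: ", subject)
  stopifnot(day %in% c(1, 2))
  if (is.null(trial_seed)) trial_seed <- derive_seed(spec$seed, subject, day, trial)
  withr::with_seed(trial_seed, {
    stance <- stats::rnorm(1, spec$stance_mean, spec$stance_sd)
    stance <- min(max(stance, spec$stance_mean - 3 * spec$stance_sd, 0.05),
      spec$stance_mean + 3 * spec$stance_sd)
    n_kin <- max(4L, round(stance * spec$kinematic_rate))
    n_force <- max(4L, round(stance * spec$force_rate))
    phase_kin <- (seq_len(n_kin) - 1) / (n_kin - 1)
    phase_force <- (seq_len(n_force) - 1) / (n_force - 1)
    one_channel <- function(ch, phase, n) {
      subject_template(truth, subject, ch, phase, day) +
        smooth_noise(n, spec$noise_corr_len * n, truth$noise_sd[[ch]])
    }
    angles <- purrr::map(angle_channels(), one_channel, phase = phase_kin, n = n_kin)
    names(angles) <- angle_channels()
    grf <- purrr::map(grf_channels(), one_channel, phase = phase_force, n = n_force)
    names(grf) <- grf_channels()
    grf$grf_vert <- pmax(grf$grf_vert, 0) # contact force cannot pull
    structure(
      list(
        subject = as.integer(subject), day = as.integer(day), trial = as.integer(trial),
        stance_s = stance,
        angles = tibble::as_tibble(angles),
        grf = tibble::as_tibble(grf)
      ),
      class = "gait_trial"
    )
  })
}

#' Generate a full two-day synthetic gait dataset
#'
#' Generates templates and all trials for every subject and both days. The
#' result is a pure function of the spec (and its seed).
#'
#' @param spec a [synthetic_spec()].
#' @return object of class `gait_data`: list with `trials` (tibble with
#'   columns `subject`, `day`, `trial`, `stance_s` and list-columns `angles`,
#'   `grf`), `truth` (the [generate_templates()] output) and `spec`.
#' @examples
#' d <- generate_gait_data(synthetic_spec(n_subjects = 2, trials_per_day = 3, seed = 1))
#' d$trials
#' @export
generate_gait_data <- function(spec) {
  stopifnot(inherits(spec, "gait_spec"))
  truth <- generate_templates(spec)
  counts <- withr::with_seed(derive_seed(spec$seed, 2), {
    purrr::map(seq_len(spec$n_subjects), function(s) {
      if (length(spec$trials_per_day) == 1) {
        c(spec$trials_per_day, spec$trials_per_day)
      } else {
        total <- sample(seq(spec$trials_per_day[1], spec$trials_per_day[2]), 1)
        d1 <- min(20L, ceiling(total / 2))
        c(d1, total - d1)
      }
    })
  })
  rows <- purrr::map_dfr(seq_len(spec$n_subjects), function(s) {
    purrr::map_dfr(1:2, function(d) {
      n <- counts[[s]][d]
      purrr::map_dfr(seq_len(n), function(tr) {
        t <- generate_trial(truth, s, d, tr)
        tibble::tibble(
          subject = t$subject, day = t$day, trial = t$trial,
          stance_s = t$stance_s, angles = list(t$angles), grf = list(t$grf)
        )
      })
    })
  })
  structure(list(trials = rows, truth = truth, spec = spec), class = "gait_data")
}

#' @export
print.gait_data <- function(x, ...) {
  cat(
    "<gait_data>", nrow(x$trials), "trials,", x$spec$n_subjects, "subjects, 2 days",
    "| planted:", paste(x$spec$planted_channels, collapse = ", "), "\n"
  )
  invisible(x)
}

# --- raw-mode rendering ------------------------------------------------------

#' Standing-pose marker-cluster geometry
#'
#' Marker coordinates (metres, lab frame: x = running direction,
#' y = perpendicular, z = up) of the pelvis (4 markers) and thigh, shank and
#' foot clusters (3 markers each) in the standing posture. Documented package
#' constants; segments rotate about their cluster centroid.
#'
#' @return named list of `markers x 3` matrices.
#' @export
default_cluster_geometry <- function() {
  m <- function(...) matrix(c(...), ncol = 3, byrow = TRUE)
  list(
    pelvis = m(
      0.10, 0.12, 1.00, 0.10, -0.12, 1.00,
      -0.10, 0.10, 1.04, -0.10, -0.10, 1.04
    ),
    thigh = m(0.05, 0.09, 0.76, 0.03, 0.12, 0.62, -0.04, 0.10, 0.69),
    shank = m(0.04, 0.09, 0.42, 0.02, 0.12, 0.29, -0.03, 0.10, 0.35),
    foot = m(0.12, 0.10, 0.05, -0.05, 0.08, 0.03, 0.02, 0.12, 0.10)
  )
}

#' Render a trial as raw marker trajectories and a force-plate record
#'
#' Forward kinematics for the synthetic generator: the nine angle channels are
#' recomposed into segment rotations (pelvis held at its standing orientation,
#' each distal segment rotated by the composed Z-X-Y joint rotation of its
#' proximal chain) and applied to the standing-pose marker clusters about
#' their centroids. The GRF channels are embedded in a longer 2400 Hz record
#' with sub-threshold noise padding before heel strike and after toe off;
#' marker trajectories are padded by holding the boundary posture. The
#' returned object records the intended stance boundaries (first/last force
#' sample of the longest run with vertical GRF at or above the threshold).
#'
#' @param trial a `gait_trial` from [generate_trial()].
#' @param geometry standing cluster geometry, see [default_cluster_geometry()].
#' @param lead_in,lead_out padding duration (seconds) before/after stance.
#' @param pad_noise_sd SD (newtons) of the sub-threshold padding noise,
#'   clipped to stay strictly below `threshold`.
#' @param threshold vertical-GRF contact threshold in newtons.
#' @param pad_seed integer seed for the padding noise (derived from the trial
#'   labels when `NULL`).
#' @return object of class `raw_trial`: list with `subject`, `day`, `trial`,
#'   `markers` (named list of `frames x markers x 3` arrays at 240 Hz), `grf`
#'   (`frames x 3` matrix at 2400 Hz, columns [grf_channels()]), `standing`
#'   (the geometry), rates, and `stance` (intended heel-strike/toe-off force
#'   sample indices, half-open `[heel_strike, toe_off)`).
#' @export
render_raw <- function(trial, geometry = default_cluster_geometry(),
                       lead_in = 0.2, lead_out = 0.2, pad_noise_sd = 5,
                       threshold = 15, pad_seed = NULL) {
  stopifnot(inherits(trial, "gait_trial"))
  kin_rate <- 240
  force_rate <- 2400
  ratio <- force_rate / kin_rate
  n_kin <- nrow(trial$angles)
  n_force <- nrow(trial$grf)
  if (any(abs(as.matrix(trial$angles)[, c("hip_ab_ad", "knee_ab_ad", "ankle_inv_ev")]) > 85)) {
    stop("middle (X) rotation within 5 degrees of gimbal lock; cannot render raw markers")
  }
  lead_kin <- round(lead_in * kin_rate)
  tail_kin <- round(lead_out * kin_rate)
  lead_force <- lead_kin * ratio
  tail_force <- tail_kin * ratio

  # segment rotations per kinematic frame
  axes <- joint_channel_axes()
  ang <- trial$angles
  seg_rots <- lapply(seq_len(n_kin), function(f) {
    triple <- function(joint) {
      map <- axes[[joint]]
      v <- c(
        angle_z = as.numeric(ang[f, names(map)[map == "angle_z"]]),
        angle_x = as.numeric(ang[f, names(map)[map == "angle_x"]]),
        angle_y = as.numeric(ang[f, names(map)[map == "angle_y"]])
      )
      compose_zxy(v["angle_z"], v["angle_x"], v["angle_y"])
    }
    R_pelvis <- diag(3)
    R_thigh <- R_pelvis %*% triple("hip")
    R_shank <- R_thigh %*% triple("knee")
    R_foot <- R_shank %*% triple("ankle")
    list(pelvis = R_pelvis, thigh = R_thigh, shank = R_shank, foot = R_foot)
  })
  frames_total <- lead_kin + n_kin + tail_kin
  markers <- lapply(names(geometry), function(seg) {
    ref <- geometry[[seg]]
    cen <- colMeans(ref)
    arr <- array(NA_real_, c(frames_total, nrow(ref), 3))
    for (f in seq_len(frames_total)) {
      fk <- min(max(f - lead_kin, 1L), n_kin) # hold boundary posture in padding
      R <- seg_rots[[fk]][[seg]]
      arr[f, , ] <- sweep(sweep(ref, 2, cen) %*% t(R), 2, cen, "+")
    }
    arr
  })
  names(markers) <- names(geometry)

  # force record with sub-threshold padding
  if (is.null(pad_seed)) {
    pad_seed <- derive_seed(trial$subject * 7L + 3L, trial$day, trial$trial)
  }
  grf_stance <- as.matrix(trial$grf)
  grf_full <- withr::with_seed(pad_seed, {
    pad <- function(n) {
      p <- matrix(stats::rnorm(n * 3, 0, pad_noise_sd), n, 3)
      pmin(pmax(p, -(threshold - 1)), threshold - 1)
    }
    rbind(pad(lead_force), grf_stance, pad(tail_force))
  })
  colnames(grf_full) <- grf_channels()

  # intended stance boundaries: longest run of vertical force >= threshold in
  # the un-padded stance segment, offset into the full record
  above <- grf_stance[, "grf_vert"] >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  if (length(runs) == 0) stop("stance vertical GRF never reaches the contact threshold")
  best <- runs[which.max(r$lengths[runs])]
  stance <- c(
    heel_strike = as.integer(lead_force + starts[best]),
    toe_off = as.integer(lead_force + ends[best]) + 1L
  )

  structure(
    list(
      subject = trial$subject, day = trial$day, trial = trial$trial,
      markers = markers, grf = grf_full, standing = geometry,
      kinematic_rate = kin_rate, force_rate = force_rate,
      stance = stance, lead_in_frames = lead_kin
    ),
    class = "raw_trial"
  )
}

#' @export
print.raw_trial <- function(x, ...) {
  cat(
    "<raw_trial> subject", x$subject, "day", x$day, "trial", x$trial,
    "|", dim(x$markers$pelvis)[1], "kinematic frames,", nrow(x$grf), "force samples\n"
  )
  invisible(x)
}
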