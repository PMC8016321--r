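#' Preprocessing configuration
#'
#' Collects the tunable parameters of the stride-pattern pipeline: stance
#' detection threshold, lowpass cutoffs, and the scope switches of the
#' per-participant standardization and of the final rescaling.
#'
#' @param threshold vertical-GRF contact threshold (newtons), default 15.
#' @param min_duration minimum stance duration (seconds) a run must last to
#'   qualify as a contact; rejects threshold-crossing noise spikes.
#' @param angle_cutoff,grf_cutoff lowpass -3 dB cutoffs (Hz) for the
#'   joint-angle and GRF channels.
#' @param center per-participant centering scope: `"scalar"` (default)
#'   subtracts each participant's per-channel mean level; `"trajectory"`
#'   subtracts the participant's pointwise average trajectory. See Details.
#' @param sd_mode per-participant scale: `"scalar"` (default) divides by the
#'   RMS of the pointwise across-trial SDs of the channel; `"pointwise"`
#'   divides each sample by its own across-trial SD.
#' @param sd_eps floor applied to the SD to avoid division by zero; floored
#'   samples are reported via a warning.
#' @param rescale rescaling scope: `"trial"` (default) divides each trial's
#'   1200-vector by its own maximum absolute standardized value, preserving
#'   the relative amplitudes of the channels; `"channel"` divides each channel
#'   by its maximum absolute standardized value over the day split being
#'   processed.
#'
#' @details
#' Both centering scopes remove per-participant offset and gain effects (body
#' size, marker placement, force magnitude) from every channel -- features are
#' bit-identical under any per-participant per-channel affine change of a raw
#' channel. They differ in what else is removed: `"trajectory"` additionally
#' subtracts the participant's mean movement *shape*, leaving only
#' stride-to-stride residuals, so between-participant template differences do
#' not survive into the feature vectors; `"scalar"` preserves the shape
#' information that identification models feed on. The package defaults to
#' `"scalar"` so that planted identity structure (and real between-subject
#' differences) remain measurable end to end; the residual-only variant is
#' retained as an explicit analysis choice.
#'
#' @return object of class `gait_config`.
#' @export
preprocess_config <- function(threshold = 15, min_duration = 0.05,
                              angle_cutoff = 15, grf_cutoff = 50,
                              center = c("scalar", "trajectory"),
                              sd_mode = c("scalar", "pointwise"),
                              sd_eps = 1e-8,
                              rescale = c("trial", "channel")) {
  stopifnot(threshold > 0, min_duration >= 0, angle_cutoff > 0, grf_cutoff > 0, sd_eps > 0)
  structure(
    list(
      threshold = threshold, min_duration = min_duration,
      angle_cutoff = angle_cutoff, grf_cutoff = grf_cutoff,
      center = match.arg(center), sd_mode = match.arg(sd_mode),
      sd_eps = sd_eps, rescale = match.arg(rescale)
    ),
    class = "gait_config"
  )
}

#' Detect the stance phase from a vertical ground-reaction-force record
#'
#' Heel strike and toe off are the boundaries of the longest contiguous run of
#' samples with vertical GRF at or above `threshold` (15 N by default); runs
#' shorter than `min_duration` are ignored as noise spikes. The interval is
#' half-open: `heel_strike` is the first sample of the run and `toe_off` the
#' first sample after it.
#'
#' @param vertical_grf numeric vector (newtons), finite.
#' @param rate sampling rate in Hz (used to apply `min_duration`).
#' @param threshold contact threshold in newtons.
#' @param min_duration minimum qualifying contact duration in seconds.
#' @param strict if `TRUE` (default), more than one qualifying run is an
#'   error (a trial is guaranteed to contain a single step on the plate).
#' @return named integer vector `c(heel_strike, toe_off)`.
#' @examples
#' v <- c(rep(0, 99), rep(800, 400), rep(0, 100))
#' detect_stance(v, rate = 2400)
#' @export
detect_stance <- function(vertical_grf, rate = 2400, threshold = 15,
                          min_duration = 0.05, strict = TRUE) {
  if (!all(is.finite(vertical_grf))) stop("`vertical_grf` must be finite")
  above <- vertical_grf >= threshold
  if (!any(above)) stop("no stance found: vertical GRF never reaches ", threshold, " N")
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  qual <- which(r$values & r$lengths >= min_duration * rate)
  if (length(qual) == 0) {
    stop("no stance found: no contact lasts at least ", min_duration, " s")
  }
  if (strict && length(qual) > 1) {
    stop(
      "found ", length(qual), " qualifying contacts but expected a single step ",
      "on the force plate; use strict = FALSE to take the longest"
    )
  }
  best <- qual[which.max(r$lengths[qual])]
  c(heel_strike = as.integer(starts[best]), toe_off = as.integer(ends[best]) + 1L)
}

#' Zero-phase lowpass filter
#'
#' Forward-backward (zero-phase) 4th-order Butterworth lowpass whose two-pass
#' amplitude response is -3 dB at `cutoff` (the single-pass cutoff is
#' pre-warped accordingly), at least -40 dB at twice the cutoff, and exactly
#' unity at DC (the signal mean is removed before filtering and restored
#' after). The signal is reflection-padded so edge transients do not reach the
#' output.
#'
#' @param x numeric signal.
#' @param rate sampling rate in Hz.
#' @param cutoff -3 dB cutoff in Hz; must be below the Nyquist rate.
#' @return filtered signal, same length as `x`.
#' @export
lowpass <- function(x, rate, cutoff) {
  if (cutoff >= rate / 2) stop("`cutoff` must be below the Nyquist frequency ", rate / 2, " Hz")
  if (!all(is.finite(x))) stop("`x` must be finite")
  n <- length(x)
  if (n < 4) stop("signal too short to filter")
  order <- 4
  # single-pass cutoff such that |H|^2 (the two-pass gain) is 1/sqrt(2) at `cutoff`
  fc <- cutoff / (sqrt(2) - 1)^(1 / (2 * order))
  fc <- min(fc, 0.99 * rate / 2)
  bf <- signal::butter(order, fc / (rate / 2))
  m <- mean(x)
  xc <- x - m
  pad <- min(n - 1L, max(24L, ceiling(3 * rate / cutoff)))
  padded <- c(2 * xc[1] - xc[(pad + 1):2], xc, 2 * xc[n] - xc[(n - 1):(n - pad)])
  y <- signal::filtfilt(bf, padded)
  y[(pad + 1):(pad + n)] + m
}

#' Time-normalize a trajectory to 100 samples
#'
#' Shape-preserving (monotone) piecewise-cubic interpolation onto `n_out`
#' equally spaced points spanning the first to the last input sample.
#' Endpoints are reproduced exactly and the interpolant does not overshoot the
#' local data range on monotone stretches.
#'
#' @param x numeric trajectory, length >= 4.
#' @param n_out number of output samples (100 for stride patterns).
#' @return numeric vector of length `n_out`.
#' @export
time_normalize <- function(x, n_out = 100) {
  n <- length(x)
  if (n < 4) stop("need at least 4 samples to time-normalize (got ", n, ")")
  if (!all(is.finite(x))) stop("`x` must be finite")
  pracma::pchip(seq_len(n), x, seq(1, n, length.out = n_out))
}

# --- participant standardization --------------------------------------------

# long-format worker: df has columns subject, day, trial, channel, sample, value
standardize_long <- function(df, center, sd_mode, sd_eps) {
  floored <- FALSE
  out <- df |>
    dplyr::group_by(.data$subject, .data$day, .data$channel)
  if (dplyr::n_groups(out) > 0) {
    n_trials <- out |> dplyr::summarise(n = dplyr::n_distinct(.data$trial), .groups = "drop")
    if (any(n_trials$n < 2)) {
      stop("standardization needs at least 2 trials per participant/day")
    }
  }
  out <- out |>
    dplyr::mutate(
      .m = if (center == "scalar") {
        mean(.data$value)
      } else {
        stats::ave(.data$value, .data$sample)
      }
    ) |>
    dplyr::group_by(.data$sample, .add = TRUE) |>
    dplyr::mutate(.sd_pt = sqrt(mean((.data$value - mean(.data$value))^2))) |>
    dplyr::group_by(.data$subject, .data$day, .data$channel) |>
    dplyr::mutate(
      .s = if (sd_mode == "scalar") sqrt(mean(.data$.sd_pt^2)) else .data$.sd_pt
    ) |>
    dplyr::ungroup()
  if (any(out$.s < sd_eps)) {
    floored <- TRUE
    out$.s <- pmax(out$.s, sd_eps)
  }
  out <- out |>
    dplyr::mutate(value = (.data$value - .data$.m) / .data$.s) |>
    dplyr::select(-".m", -".s", -".sd_pt") |>
    # centre the standardized features on the split-level mean trajectory so
    # that 0 is the no-information value (required by masked-to-zero
    # semantics); a function of already-standardized values only, so the
    # per-participant affine invariance is untouched
    dplyr::group_by(.data$day, .data$channel, .data$sample) |>
    dplyr::mutate(value = .data$value - mean(.data$value)) |>
    dplyr::ungroup()
  if (floored) {
    warning("zero-variance samples encountered; standard deviation floored at ", sd_eps)
  }
  out
}

#' Standardize trajectories within each participant
#'
#' Implements the per-participant standardization of the pipeline on a long
#' table of time-normalized trajectories (columns `subject`, `day`, `trial`,
#' `channel`, `sample`, `value`). Statistics are computed within each
#' participant x day x channel group: the participant mean is subtracted
#' (`center = "scalar"`: the channel's mean level; `"trajectory"`: the
#' pointwise average trajectory) and the value is divided by the
#' participant's SD (`sd_mode = "scalar"`: RMS of the pointwise across-trial
#' SDs; `"pointwise"`: the across-trial SD at each sample, in which case the
#' per-sample mean across trials becomes 0 and the SD 1 wherever not floored).
#' Zero-variance samples are floored at `sd_eps` and flagged with a warning.
#'
#' @param df long tibble as described above.
#' @param config a [preprocess_config()].
#' @return the tibble with `value` standardized.
#' @export
standardize_participant <- function(df, config = preprocess_config()) {
  stopifnot(all(c("subject", "day", "trial", "channel", "sample", "value") %in% names(df)))
  standardize_long(df, config$center, config$sd_mode, config$sd_eps)
}

#' Rescale standardized trajectories to \[-1, 1\]
#'
#' Symmetric rescaling: division by the maximum absolute standardized value,
#' computed per channel over the day split being processed (default) or per
#' trial vector (`rescale = "trial"`). Zero maps to zero, the output lies in
#' `[-1, 1]`, and each scaling group attains 1 in absolute value (all-zero
#' groups are left at zero with a warning).
#'
#' @inheritParams standardize_participant
#' @return the tibble with `value` rescaled.
#' @export
rescale_unit <- function(df, config = preprocess_config()) {
  stopifnot(all(c("day", "channel", "value") %in% names(df)))
  group_cols <- if (config$rescale == "channel") {
    c("day", "channel")
  } else {
    c("subject", "day", "trial")
  }
  out <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::mutate(.max = max(abs(.data$value))) |>
    dplyr::ungroup()
  if (any(out$.max == 0)) {
    warning("all-zero channel encountered during rescaling; left at zero")
  }
  out |>
    dplyr::mutate(value = ifelse(.data$.max > 0, .data$value / .data$.max, 0)) |>
    dplyr::select(-".max")
}

#' Assemble stride patterns from long trajectories
#'
#' Pivots a long table of normalized trajectories into the wide
#' trials x 1200 stride-pattern layout. Feature `i` corresponds to channel
#' `(i-1) %/% 100 + 1` and sample `(i-1) %% 100 + 1` in the order of
#' [gait_channels()]; the mapping is exposed by [feature_index()] /
#' [feature_info()].
#'
#' @param df long tibble with columns `subject`, `day`, `trial`, `channel`,
#'   `sample`, `value` containing all 12 channels x 100 samples per trial.
#' @return a `stride_patterns` tibble: `subject`, `day`, `trial` plus the 1200
#'   feature columns named as in [feature_names()].
#' @export
assemble_patterns <- function(df) {
  chans <- unique(df$channel)
  if (!setequal(chans, gait_channels())) {
    stop(
      "expected exactly the 12 channels of gait_channels(); missing: ",
      paste(setdiff(gait_channels(), chans), collapse = ", "),
      if (length(setdiff(chans, gait_channels()))) {
        paste0("; unknown: ", paste(setdiff(chans, gait_channels()), collapse = ", "))
      } else {
        ""
      }
    )
  }
  counts <- df |>
    dplyr::count(.data$subject, .data$day, .data$trial)
  if (any(counts$n != 1200)) stop("each trial must contribute exactly 12 x 100 values")
  wide <- df |>
    dplyr::mutate(feature = sprintf("%s_t%03d", .data$channel, .data$sample)) |>
    dplyr::select("subject", "day", "trial", "feature", "value") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "value") |>
    dplyr::select(dplyr::all_of(c("subject", "day", "trial", feature_names()))) |>
    dplyr::arrange(.data$subject, .data$day, .data$trial)
  class(wide) <- c("stride_patterns", class(wide))
  wide
}

#' Build stride patterns from a gait dataset
#'
#' Full preprocessing pipeline: each trial's angle channels are lowpass
#' filtered at `angle_cutoff` (240 Hz native rate) and GRF channels at
#' `grf_cutoff` (2400 Hz), every channel is time-normalized to 100 samples,
#' trajectories are standardized within participant and day split, rescaled
#' to `[-1, 1]` per channel within the split, and concatenated into
#' 1 x 1200 stride patterns.
#'
#' @param data a `gait_data` object from [generate_gait_data()], or a tibble
#'   shaped like its `$trials` component.
#' @param config a [preprocess_config()].
#' @return a `stride_patterns` tibble (see [assemble_patterns()]).
#' @examples
#' d <- generate_gait_data(synthetic_spec(n_subjects = 2, trials_per_day = 3, seed = 1))
#' p <- stride_patterns(d)
#' dim(p)
#' @export
stride_patterns <- function(data, config = preprocess_config()) {
  trials <- if (inherits(data, "gait_data")) data$trials else data
  stopifnot(all(c("subject", "day", "trial", "angles", "grf") %in% names(trials)))
  kin_rate <- if (inherits(data, "gait_data")) data$spec$kinematic_rate else 240
  force_rate <- if (inherits(data, "gait_data")) data$spec$force_rate else 2400
  long <- purrr::pmap_dfr(
    trials[c("subject", "day", "trial", "angles", "grf")],
    function(subject, day, trial, angles, grf) {
      norm_one <- function(v, rate, cutoff) time_normalize(lowpass(v, rate, cutoff))
      vals <- c(
        purrr::map(as.list(angles)[angle_channels()], norm_one,
          rate = kin_rate, cutoff = config$angle_cutoff
        ),
        purrr::map(as.list(grf)[grf_channels()], norm_one,
          rate = force_rate, cutoff = config$grf_cutoff
        )
      )
      tibble::tibble(
        subject = subject, day = day, trial = trial,
        channel = rep(gait_channels(), each = 100),
        sample = rep(1:100, 12),
        value = unlist(vals, use.names = FALSE)
      )
    }
  )
  long |>
    standardize_participant(config) |>
    rescale_unit(config) |>
    assemble_patterns()
}

#' Convert a raw trial to processed stance trajectories
#'
#' Runs the measurement-side half of the pipeline on a raw trial: stance is
#' segmented from the vertical force record with [detect_stance()], the GRF
#' channels are cropped to the contact interval, joint angles are recovered
#' from the marker clusters with [trial_joint_angles()] and cropped to the
#' kinematic frames that fall inside the contact interval.
#'
#' @param raw a `raw_trial` (see [render_raw()]).
#' @param config a [preprocess_config()] (threshold and minimum duration).
#' @return a `gait_trial` object (see [generate_trial()]), with attribute
#'   `kin_frames` giving the retained kinematic frame indices of the raw
#'   record.
#' @export
raw_to_trial <- function(raw, config = preprocess_config()) {
  stopifnot(inherits(raw, "raw_trial"))
  stance <- detect_stance(raw$grf[, "grf_vert"],
    rate = raw$force_rate,
    threshold = config$threshold, min_duration = config$min_duration
  )
  ratio <- raw$force_rate / raw$kinematic_rate
  # kinematic frames whose sampling instants fall inside the contact interval
  f_start <- floor((stance[["heel_strike"]] - 1) / ratio) + 1L
  f_end <- ceiling((stance[["toe_off"]] - 1) / ratio)
  angles_full <- trial_joint_angles(raw)
  kin_frames <- seq.int(f_start, min(f_end, nrow(angles_full)))
  grf <- tibble::as_tibble(raw$grf[stance[["heel_strike"]]:(stance[["toe_off"]] - 1L), , drop = FALSE])
  out <- structure(
    list(
      subject = raw$subject, day = raw$day, trial = raw$trial,
      stance_s = (stance[["toe_off"]] - stance[["heel_strike"]]) / raw$force_rate,
      angles = angles_full[kin_frames, angle_channels()],
      grf = grf
    ),
    class = "gait_trial"
  )
  attr(out, "kin_frames") <- kin_frames
  attr(out, "stance") <- stance
  out
}

#' Extract the feature matrix of a stride-pattern table
#'
#' @param patterns a `stride_patterns` tibble.
#' @return numeric matrix (trials x 1200) with the feature columns.
#' @export
pattern_matrix <- function(patterns) {
  feats <- intersect(feature_names(), names(patterns))
  if (length(feats) != 1200) stop("`patterns` does not contain the 1200 feature columns")
  m <- as.matrix(patterns[, feature_names()])
  rownames(m) <- NULL
  m
}
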