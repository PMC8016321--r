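#' Stride-pattern channels and feature indexing
#'
#' A stride pattern concatenates 12 stance-phase trajectories, each
#' time-normalized to 100 samples, into a single 1200-dimensional feature
#' vector. `gait_channels()` returns the twelve channel identifiers in the
#' fixed concatenation order: nine joint-angle trajectories (three per joint,
#' hip / knee / ankle) followed by the three ground-reaction-force components.
#'
#' Feature index `i` (1-based, `1..1200`) maps to channel
#' `(i - 1) %/% 100 + 1` and within-channel sample `(i - 1) %% 100 + 1`.
#' Sample `s` covers the stance-phase interval `[(s-1)%, s%)`, so
#' "early stance (1--30%)" is samples 1--30.
#'
#' @return `gait_channels()`: character vector of length 12.
#' @examples
#' gait_channels()
#' feature_index("hip_ab_ad", 1:3)
#' feature_info(c(1, 101, 1200))
#' @export
gait_channels <- function() {
  c(
    "hip_flex_ext", "hip_ab_ad", "hip_rot_int_ext",
    "knee_flex_ext", "knee_ab_ad", "knee_rot_int_ext",
    "ankle_dorsi_plant", "ankle_ab_ad", "ankle_inv_ev",
    "grf_ap", "grf_ml", "grf_vert"
  )
}

#' @rdname gait_channels
#' @return `angle_channels()`: the nine kinematic channels (240 Hz native
#'   rate); `grf_channels()`: the three kinetic channels (2400 Hz).
#' @export
angle_channels <- function() gait_channels()[1:9]

#' @rdname gait_channels
#' @export
grf_channels <- function() gait_channels()[10:12]

#' @rdname gait_channels
#' @param channel character, channel identifier(s) from [gait_channels()].
#' @param sample integer sample(s) in `1:100`.
#' @return `feature_index()`: integer feature index/indices in `1:1200`.
#' @export
feature_index <- function(channel, sample) {
  ch <- match(channel, gait_channels())
  if (anyNA(ch)) {
    stop("unknown channel(s): ", paste(setdiff(channel, gait_channels()), collapse = ", "))
  }
  sample <- as.integer(sample)
  if (any(sample < 1L | sample > 100L)) stop("`sample` must be in 1:100")
  (ch - 1L) * 100L + sample
}

#' @rdname gait_channels
#' @param index integer feature index/indices in `1:1200`.
#' @return `feature_info()`: a tibble with columns `index`, `channel`, `sample`.
#' @export
feature_info <- function(index) {
  index <- as.integer(index)
  if (any(index < 1L | index > 1200L)) stop("`index` must be in 1:1200")
  tibble::tibble(
    index = index,
    channel = gait_channels()[(index - 1L) %/% 100L + 1L],
    sample = (index - 1L) %% 100L + 1L
  )
}

#' @rdname gait_channels
#' @return `feature_names()`: the 1200 feature names in concatenation order,
#'   e.g. `"hip_ab_ad_t007"`.
#' @export
feature_names <- function() {
  as.character(vapply(
    gait_channels(),
    function(ch) sprintf("%s_t%03d", ch, 1:100),
    character(100)
  ))
}

#' Map a fractional stance window to sample indices
#'
#' Converts a fractional interval of stance (e.g. `c(0, 0.3)` for the first
#' 30%) into within-channel sample indices. The window is half-open on the
#' percent grid: `c(0, 0.3)` maps to samples 1--30.
#'
#' @param window numeric length-2, fractions of stance in `[0, 1]`.
#' @return integer vector of sample indices.
#' @examples
#' window_samples(c(0, 0.3))
#' @export
window_samples <- function(window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (window[1] < 0 || window[2] > 1) stop("`window` must lie within [0, 1]")
  first <- floor(window[1] * 100) + 1L
  last <- round(window[2] * 100)
  seq.int(first, max(first, last))
}

#' Feature indices carrying planted identity information
#'
#' For a synthetic specification, the planted variable set is the image of
#' `planted_channels x planted_window` under the feature concatenation order.
#'
#' @param channels character, planted channel identifiers.
#' @param window numeric length-2 fractional stance window.
#' @return sorted integer vector of feature indices.
#' @export
planted_variable_set <- function(channels, window) {
  samples <- window_samples(window)
  sort(unlist(lapply(channels, feature_index, sample = samples), use.names = FALSE))
}
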