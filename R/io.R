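#' Write and read a gait dataset as delimited tables plus a JSON manifest
#'
#' `write_gait_data()` saves one CSV per trial (angle channels and GRF
#' channels in separate files, since their native rates differ), a
#' dataset-level `manifest.json` (subject ids, days, rates, file paths, seed
#' and an echo of the spec) and, when ground truth is present,
#' `ground_truth.json` with the planted variable indices and labels.
#' `read_gait_data()` restores the dataset from such a directory.
#'
#' @param data a `gait_data` object.
#' @param dir target directory (created if missing).
#' @return `write_gait_data()`: the manifest path, invisibly;
#'   `read_gait_data()`: a `gait_data`-shaped list (without template
#'   parameters; the planted indices and labels are restored).
#' @export
write_gait_data <- function(data, dir) {
  stopifnot(inherits(data, "gait_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trials <- data$trials
  files <- purrr::pmap_dfr(
    trials[c("subject", "day", "trial", "angles", "grf")],
    function(subject, day, trial, angles, grf) {
      base <- sprintf("s%02d_d%d_t%02d", subject, day, trial)
      af <- file.path(dir, paste0(base, "_angles.csv"))
      gf <- file.path(dir, paste0(base, "_grf.csv"))
      utils::write.csv(angles, af, row.names = FALSE)
      utils::write.csv(grf, gf, row.names = FALSE)
      tibble::tibble(
        subject = subject, day = day, trial = trial,
        angles_file = basename(af), grf_file = basename(gf)
      )
    }
  )
  manifest <- list(
    package = "gaitprint",
    kinematic_rate = data$spec$kinematic_rate,
    force_rate = data$spec$force_rate,
    seed = data$spec$seed,
    spec = unclass(data$spec),
    trials = files
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  if (!is.null(data$truth)) {
    jsonlite::write_json(
      list(
        planted_variable_set = data$truth$planted_variable_set,
        labels = trials[c("subject", "day", "trial")]
      ),
      file.path(dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(file.path(dir, "manifest.json"))
}

#' @rdname write_gait_data
#' @export
read_gait_data <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  files <- tibble::as_tibble(manifest$trials)
  trials <- purrr::pmap_dfr(files, function(subject, day, trial, angles_file, grf_file) {
    tibble::tibble(
      subject = subject, day = day, trial = trial,
      angles = list(tibble::as_tibble(utils::read.csv(file.path(dir, angles_file)))),
      grf = list(tibble::as_tibble(utils::read.csv(file.path(dir, grf_file))))
    )
  })
  truth_path <- file.path(dir, "ground_truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else {
    NULL
  }
  spec <- manifest$spec
  structure(
    list(trials = trials, truth = truth, spec = spec),
    class = "gait_data"
  )
}

#' Write and read stride patterns as a matrix file with a JSON sidecar
#'
#' The feature matrix (trials x 1200) goes to a CSV; labels and the
#' channel/sample index map go to a sidecar JSON.
#'
#' @param patterns a `stride_patterns` tibble.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.labels.json`.
#' @return `write_stride_patterns()`: `path`, invisibly;
#'   `read_stride_patterns()`: the restored `stride_patterns` tibble.
#' @export
write_stride_patterns <- function(patterns, path) {
  utils::write.csv(as.data.frame(patterns[, feature_names()]), path, row.names = FALSE)
  jsonlite::write_json(
    list(
      labels = patterns[, intersect(c("subject", "day", "trial"), names(patterns))],
      index_map = feature_info(1:1200)
    ),
    paste0(path, ".labels.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_stride_patterns
#' @export
read_stride_patterns <- function(path) {
  feats <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  side <- jsonlite::read_json(paste0(path, ".labels.json"), simplifyVector = TRUE)
  out <- dplyr::bind_cols(tibble::as_tibble(side$labels), feats)
  class(out) <- c("stride_patterns", class(out))
  out
}

#' Serialize a trained network to a single portable file
#'
#' The model is stored with `saveRDS()` as a plain list (layout: `W1`, `b1`,
#' `W2`, `b2`, `levels`, `training`, plus a `format` version tag), so it can
#' be reloaded across platforms and R sessions.
#'
#' @param model a `gait_net`.
#' @param path file path.
#' @return `write_gait_net()`: `path`, invisibly; `read_gait_net()`: the
#'   restored `gait_net`.
#' @export
write_gait_net <- function(model, path) {
  stopifnot(inherits(model, "gait_net"))
  saveRDS(c(unclass(model), list(format = "gait_net/1")), path)
  invisible(path)
}

#' @rdname write_gait_net
#' @export
read_gait_net <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "gait_net/1")) stop("not a serialized gait_net file")
  obj$format <- NULL
  structure(obj, class = "gait_net")
}
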