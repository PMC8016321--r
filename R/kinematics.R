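#' Elementary rotation matrices
#'
#' Right-handed rotations about the lab axes (x = running direction,
#' y = perpendicular/medio-lateral, z = vertical), acting on column vectors.
#'
#' @param angle rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_z <- function(angle) {
  a <- angle * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' @rdname rot_z
#' @keywords internal
rot_x <- function(angle) {
  a <- angle * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' @rdname rot_z
#' @keywords internal
rot_y <- function(angle) {
  a <- angle * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Compose a rotation from a Z-X-Y cardan angle triple
#'
#' Returns `Rz(angle_z) %*% Rx(angle_x) %*% Ry(angle_y)`, the rotation
#' parameterization used for all joint angles in this package.
#'
#' @param angle_z,angle_x,angle_y cardan angles in degrees.
#' @return 3x3 proper orthogonal matrix.
#' @seealso [cardan_zxy()] for the inverse.
#' @export
compose_zxy <- function(angle_z, angle_x, angle_y) {
  rot_z(angle_z) %*% rot_x(angle_x) %*% rot_y(angle_y)
}

check_rotation <- function(R, tol = 1e-8) {
  if (!is.matrix(R) || any(dim(R) != 3) || anyNA(R)) {
    stop("`R` must be a numeric 3x3 matrix without missing values")
  }
  if (max(abs(crossprod(R) - diag(3))) > tol || det(R) < 0) {
    stop("`R` is not a proper orthogonal rotation matrix")
  }
  invisible(R)
}

#' Z-X-Y cardan decomposition of a rotation matrix
#'
#' Decomposes a proper orthogonal matrix into the angle triple
#' `(angle_z, angle_x, angle_y)` such that
#' `Rz(angle_z) %*% Rx(angle_x) %*% Ry(angle_y)` reproduces the input, with
#' `angle_x` on the principal branch (-90, 90) degrees. The decomposition is
#' degenerate (gimbal lock) when the middle rotation approaches +/-90 degrees;
#' this is reported as an error.
#'
#' @param R 3x3 proper orthogonal matrix.
#' @return named numeric vector `c(angle_z, angle_x, angle_y)` in degrees.
#' @examples
#' cardan_zxy(compose_zxy(10, -5, 30))
#' @export
cardan_zxy <- function(R) {
  check_rotation(R)
  sx <- R[3, 2]
  if (abs(sx) >= 1 - 1e-9) {
    stop(
      "gimbal lock: |middle (X) rotation| is within numerical reach of 90 degrees ",
      sprintf("(sin = %.12f); the Z-X-Y angle triple is not identifiable", sx)
    )
  }
  c(
    angle_z = atan2(-R[1, 2], R[2, 2]),
    angle_x = asin(sx),
    angle_y = atan2(-R[3, 1], R[3, 3])
  ) * 180 / pi
}

#' Least-squares rigid rotation between two marker clusters
#'
#' Fits the proper rotation `R` and translation `t` minimizing the sum of
#' squared distances `sum(|current_i - (R (reference_i - ref_centroid) +
#' cur_centroid)|^2)` over the cluster's markers (orthogonal Procrustes via
#' SVD, with the reflection guarded against by sign-correcting the smallest
#' singular direction). This is how segment orientation relative to the
#' standing trial is obtained from a marker cluster.
#'
#' @param reference k x 3 matrix of marker positions in the reference
#'   (standing) pose, `k >= 3`, markers not collinear.
#' @param current k x 3 matrix of the same markers in the current frame.
#' @return object of class `cluster_pose`: list with `rotation` (3x3),
#'   `translation` (length-3, displacement of the cluster centroid) and
#'   `residual` (root-mean-square fit error in the units of the input).
#' @examples
#' ref <- matrix(rnorm(12), 4, 3)
#' fit_rigid_rotation(ref, ref)$residual
#' @export
fit_rigid_rotation <- function(reference, current) {
  reference <- as.matrix(reference)
  current <- as.matrix(current)
  if (ncol(reference) != 3 || ncol(current) != 3 || nrow(reference) != nrow(current)) {
    stop("`reference` and `current` must be k x 3 matrices with matching rows")
  }
  k <- nrow(reference)
  if (k < 3) stop("at least 3 markers are required to fit a rotation")
  ref_c <- colMeans(reference)
  cur_c <- colMeans(current)
  A <- sweep(reference, 2, ref_c)
  B <- sweep(current, 2, cur_c)
  # collinearity: the centered reference must span a plane
  sv_ref <- svd(A, nu = 0, nv = 0)$d
  scale_ref <- max(sv_ref[1], .Machine$double.eps)
  if (sv_ref[2] / scale_ref < 1e-8) {
    stop("degenerate marker cluster: reference markers are (near-)collinear")
  }
  H <- crossprod(A, B) # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- sweep(A %*% t(R), 2, cur_c, "+")
  structure(
    list(
      rotation = R,
      translation = cur_c - ref_c,
      residual = sqrt(mean(rowSums((current - fitted)^2)))
    ),
    class = "cluster_pose"
  )
}

#' @export
print.cluster_pose <- function(x, ...) {
  ang <- tryCatch(cardan_zxy(x$rotation), error = function(e) rep(NA_real_, 3))
  cat("<cluster_pose> cardan Z-X-Y (deg):",
    paste(sprintf("%.2f", ang), collapse = ", "),
    sprintf("| residual %.2e\n", x$residual)
  )
  invisible(x)
}

#' Joint angles from two segment poses
#'
#' Decomposes the relative rotation `t(proximal) %*% distal` (the distal
#' segment expressed in the proximal segment's frame) with [cardan_zxy()].
#' Because every pose is measured relative to the standing trial, the standing
#' posture maps to an all-zero angle triple by construction.
#'
#' @param proximal,distal `cluster_pose` objects (or bare 3x3 rotation
#'   matrices) for the proximal and distal segment of the same frame.
#' @return named numeric vector `c(angle_z, angle_x, angle_y)` in degrees.
#' @export
joint_angles <- function(proximal, distal) {
  Rp <- if (inherits(proximal, "cluster_pose")) proximal$rotation else proximal
  Rd <- if (inherits(distal, "cluster_pose")) distal$rotation else distal
  check_rotation(Rp)
  check_rotation(Rd)
  cardan_zxy(crossprod(Rp, Rd))
}

# anatomical naming of the Z-X-Y angles, given the lab axis convention:
# rotation about y (medio-lateral) = sagittal plane (flexion-extension /
# dorsi-plantarflexion), about x (running direction) = frontal plane
# (ab-adduction / in-eversion), about z (vertical) = transverse plane
# (internal-external rotation / ankle ab-adduction).
joint_channel_axes <- function() {
  list(
    hip = c(hip_rot_int_ext = "angle_z", hip_ab_ad = "angle_x", hip_flex_ext = "angle_y"),
    knee = c(knee_rot_int_ext = "angle_z", knee_ab_ad = "angle_x", knee_flex_ext = "angle_y"),
    ankle = c(ankle_ab_ad = "angle_z", ankle_inv_ev = "angle_x", ankle_dorsi_plant = "angle_y")
  )
}

#' Joint-angle trajectories from a raw marker-cluster trial
#'
#' For every frame, fits the rigid rotation of each marker cluster (pelvis,
#' thigh, shank, foot) relative to its standing-trial position and derives the
#' hip (pelvis-thigh), knee (thigh-shank) and ankle (shank-foot) angles via the
#' Z-X-Y cardan sequence. Anatomical channel names follow the package's axis
#' convention: the Y (medio-lateral) component is flexion-extension
#' (dorsi-plantarflexion at the ankle), the X (running-direction) component is
#' ab-adduction (in-eversion at the ankle), and the Z (vertical) component is
#' internal-external rotation (ab-adduction at the ankle).
#'
#' @param trial a `raw_trial` object (see [render_raw()]) or a named list of
#'   cluster arrays `frames x markers x 3`.
#' @param standing named list of standing-pose cluster matrices `markers x 3`;
#'   defaults to the geometry stored in the trial.
#' @return tibble with `frame` and the nine angle channels (degrees).
#' @export
trial_joint_angles <- function(trial, standing = NULL) {
  clusters <- if (inherits(trial, "raw_trial")) trial$markers else trial
  if (is.null(standing)) {
    if (!inherits(trial, "raw_trial")) {
      stop("`standing` must be supplied when `trial` is a bare cluster list")
    }
    standing <- trial$standing
  }
  needed <- c("pelvis", "thigh", "shank", "foot")
  if (!all(needed %in% names(clusters)) || !all(needed %in% names(standing))) {
    stop("clusters pelvis/thigh/shank/foot are required in both trial and standing")
  }
  n_frames <- dim(clusters$pelvis)[1]
  chains <- list(
    hip = c("pelvis", "thigh"),
    knee = c("thigh", "shank"),
    ankle = c("shank", "foot")
  )
  axes <- joint_channel_axes()
  out <- matrix(NA_real_, n_frames, 9,
    dimnames = list(NULL, angle_channels())
  )
  for (f in seq_len(n_frames)) {
    poses <- lapply(needed, function(seg) {
      fit_rigid_rotation(standing[[seg]], clusters[[seg]][f, , , drop = TRUE])
    })
    names(poses) <- needed
    for (joint in names(chains)) {
      ang <- joint_angles(poses[[chains[[joint]][1]]], poses[[chains[[joint]][2]]])
      map <- axes[[joint]]
      out[f, names(map)] <- ang[map]
    }
  }
  dplyr::bind_cols(tibble::tibble(frame = seq_len(n_frames)), tibble::as_tibble(out))
}
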