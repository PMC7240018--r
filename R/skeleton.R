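#' Reduce a 25-joint device skeleton to the 17-joint model
#'
#' Keeps 16 anatomical joints per a fixed source-joint mapping and adds
#' \code{Hc}, the arithmetic midpoint of the two hip joints. Hands, thumbs and
#' mid-spine joints of the device model are dropped as unreliable for static
#' pose description.
#'
#' @param raw 25 x 3 numeric matrix of device joint coordinates (meters),
#'   rows in \code{\link{KINECT25_NAMES}} order.
#' @param joint_map named integer vector mapping the 16 kept joints into the
#'   25-joint skeleton; default \code{\link{DEFAULT_JOINT_MAP}}.
#' @return list with \code{joints} (17 x 3 matrix, rows named by
#'   \code{\link{JOINT_NAMES}}) and \code{tracked} (logical). Any missing or
#'   non-finite source coordinate yields an untracked result with every
#'   coordinate set to \code{\link{SENTINEL}}.
#' @export
reduce_skeleton <- function(raw, joint_map = DEFAULT_JOINT_MAP) {
  raw <- as.matrix(raw)
  if (nrow(raw) != 25L || ncol(raw) != 3L)
    stop("raw skeleton must be a 25 x 3 coordinate matrix")
  keep <- setdiff(JOINT_NAMES, "Hc")
  if (!all(keep %in% names(joint_map)))
    stop("joint_map must name all 16 kept joints")
  hips <- c(joint_map[["iliac_L"]], joint_map[["iliac_R"]])
  used <- c(joint_map[keep], hips)
  if (any(!is.finite(raw[used, ]))) {
    joints <- matrix(SENTINEL, N_JOINTS, 3L,
                     dimnames = list(JOINT_NAMES, c("x", "y", "z")))
    return(list(joints = joints, tracked = FALSE))
  }
  joints <- rbind(raw[joint_map[keep], , drop = FALSE],
                  (raw[hips[1], ] + raw[hips[2], ]) / 2)
  dimnames(joints) <- list(JOINT_NAMES, c("x", "y", "z"))
  list(joints = joints, tracked = TRUE)
}

#' Rigid camera-to-room transform
#'
#' A proper rigid roto-translation \code{p_room = R p_cam + t}. The rotation
#' must be orthonormal with determinant +1 (tolerance 1e-9).
#'
#' @param rotation 3 x 3 rotation matrix (dimensionless).
#' @param translation length-3 translation vector (meters).
#' @return object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("calibration error: rotation must be 3x3 and translation length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("calibration error: rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("calibration error: rotation is not proper (det != +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation:", paste(format(x$translation), collapse = " "), "\n")
  invisible(x)
}

#' Invert a rigid transform
#'
#' @param x a \code{\link{rigid_transform}}.
#' @return the inverse transform (room-to-camera if \code{x} was
#'   camera-to-room).
#' @export
invert_transform <- function(x) {
  stopifnot(inherits(x, "rigid_transform"))
  rigid_transform(t(x$rotation), -as.vector(t(x$rotation) %*% x$translation))
}

#' Rotation about the room vertical (Z) axis
#'
#' @param yaw_deg rotation angle about Z, degrees.
#' @param translation optional translation, meters.
#' @return a \code{\link{rigid_transform}}.
#' @export
yaw_transform <- function(yaw_deg, translation = c(0, 0, 0)) {
  a <- yaw_deg * pi / 180
  rigid_transform(matrix(c(cos(a), sin(a), 0,
                           -sin(a), cos(a), 0,
                           0, 0, 1), 3, 3), translation)
}

#' Roto-translate skeleton frames into the room-fixed frame
#'
#' Applies \code{p -> R p + t} to every joint of every tracked frame, mapping
#' camera coordinates into the absolute room frame (right-handed, Z vertical,
#' origin in a room corner). Untracked (sentinel) frames pass through
#' unchanged.
#'
#' @param frames frame table (see \code{\link{make_frames}}).
#' @param calib camera-to-room \code{\link{rigid_transform}}.
#' @return the frame table with transformed coordinates.
#' @export
to_room_frame <- function(frames, calib) {
  validate_frames(frames)
  if (!inherits(calib, "rigid_transform"))
    stop("calibration error: calib must be a rigid_transform")
  tr <- which(frames$tracked)
  if (length(tr) == 0L) return(frames)
  R <- calib$rotation
  t <- calib$translation
  for (j in seq_len(N_JOINTS)) {
    cols <- sprintf("j%02d_%s", j, c("x", "y", "z"))
    p <- as.matrix(frames[tr, cols])
    frames[tr, cols] <- sweep(p %*% t(R), 2L, t, "+")
  }
  frames
}
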