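#' Joint model constants
#'
#' The pipeline works on a reduced 17-joint skeleton: 16 joints kept from the
#' device's 25-joint model plus \code{Hc}, the midpoint of the two hip joints.
#' Joints are indexed 1..17 in a fixed order; left/right pairs occupy
#' consecutive (odd, even) indices for joints 3-16.
#'
#' @format A character vector of length 17 (names of the reduced joints, in
#'   index order).
#' @export
JOINT_NAMES <- c(
  "head", "C7",
  "acromion_L", "acromion_R",
  "elbow_L", "elbow_R",
  "wrist_L", "wrist_R",
  "iliac_L", "iliac_R",
  "knee_L", "knee_R",
  "malleolus_L", "malleolus_R",
  "foot_L", "foot_R",
  "Hc"
)

#' @rdname JOINT_NAMES
#' @export
N_JOINTS <- 17L

#' Sentinel value marking untracked frames
#'
#' When skeletal tracking loses the subject, every parameter of the frame is
#' set to this value so that the four per-camera streams stay aligned in time.
#' The sentinel is absorbing: geometry and feature operations never turn an
#' untracked frame back into a tracked one.
#'
#' @export
SENTINEL <- 999.0

#' Device joint names for the 25-joint source skeleton
#'
#' Standard joint order of the depth-camera SDK skeleton that
#' \code{\link{reduce_skeleton}} consumes.
#'
#' @export
KINECT25_NAMES <- c(
  "SpineBase", "SpineMid", "Neck", "Head",
  "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
  "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
  "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
  "HipRight", "KneeRight", "AnkleRight", "FootRight",
  "SpineShoulder", "HandTipLeft", "ThumbLeft", "HandTipRight", "ThumbRight"
)

#' Default mapping from the 25-joint device skeleton to the 16 kept joints
#'
#' Named integer vector: names are reduced-joint names (all but \code{Hc},
#' which is derived as the hip midpoint), values index into the 25-joint
#' skeleton. \code{C7} is taken from the device's \code{SpineShoulder} joint,
#' the anatomically closest landmark to the shoulder segment's midpoint.
#' The mapping is an argument of \code{\link{reduce_skeleton}} and can be
#' overridden.
#'
#' @export
DEFAULT_JOINT_MAP <- c(
  head        = 4L,   # Head
  C7          = 21L,  # SpineShoulder
  acromion_L  = 5L,   # ShoulderLeft
  acromion_R  = 9L,   # ShoulderRight
  elbow_L     = 6L,
  elbow_R     = 10L,
  wrist_L     = 7L,
  wrist_R     = 11L,
  iliac_L     = 13L,  # HipLeft
  iliac_R     = 17L,  # HipRight
  knee_L      = 14L,
  knee_R      = 18L,
  malleolus_L = 15L,  # AnkleLeft
  malleolus_R = 19L,  # AnkleRight
  foot_L      = 16L,
  foot_R      = 20L
)

# coordinate column names of the frame table: j01_x, j01_y, j01_z, ..., j17_z
coord_columns <- function() {
  as.vector(t(outer(sprintf("j%02d", seq_len(N_JOINTS)),
                    c("x", "y", "z"), paste, sep = "_")))
}

frame_meta_columns <- function() c("timestamp", "camera_id", "subject_id", "tracked")

#' Extract one joint's coordinates from a frame table
#'
#' @param frames a skeleton frame data.frame (see \code{\link{read_frames}}
#'   for the column contract).
#' @param joint joint index 1-17 or a name from \code{\link{JOINT_NAMES}}.
#' @return numeric matrix, n frames x 3 (X, Y, Z in meters).
#' @export
joint_matrix <- function(frames, joint) {
  if (is.character(joint)) joint <- match(joint, JOINT_NAMES)
  stopifnot(length(joint) == 1L, !is.na(joint), joint >= 1L, joint <= N_JOINTS)
  cols <- sprintf("j%02d_%s", joint, c("x", "y", "z"))
  as.matrix(frames[, cols, drop = FALSE])
}

validate_frames <- function(frames) {
  needed <- c(frame_meta_columns(), coord_columns())
  miss <- setdiff(needed, names(frames))
  if (length(miss) > 0L)
    stop("frame table is missing columns: ", paste(miss, collapse = ", "))
  invisible(frames)
}

#' Construct a skeleton frame table from a joint coordinate array
#'
#' @param joints n x 17 x 3 array, or a single 17 x 3 matrix, of joint
#'   coordinates in meters.
#' @param timestamp,camera_id,subject_id,tracked per-frame metadata, recycled
#'   to the number of frames.
#' @return data.frame with the frame-table columns (metadata then 51
#'   coordinate columns \code{j01_x..j17_z}).
#' @export
make_frames <- function(joints, timestamp = 0, camera_id = 1L,
                        subject_id = "S01", tracked = TRUE) {
  if (is.matrix(joints)) {
    stopifnot(nrow(joints) == N_JOINTS, ncol(joints) == 3L)
    joints <- array(joints, dim = c(1L, N_JOINTS, 3L))
  }
  stopifnot(length(dim(joints)) == 3L, dim(joints)[2] == N_JOINTS,
            dim(joints)[3] == 3L)
  n <- dim(joints)[1]
  coords <- matrix(0, n, 3L * N_JOINTS)
  for (j in seq_len(N_JOINTS))
    coords[, (3L * (j - 1L)) + 1:3] <- joints[, j, ]
  colnames(coords) <- coord_columns()
  out <- data.frame(
    timestamp = rep_len(as.numeric(timestamp), n),
    camera_id = rep_len(as.integer(camera_id), n),
    subject_id = rep_len(as.character(subject_id), n),
    tracked = rep_len(as.logical(tracked), n),
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(coords))
}

#' Mark frames as untracked, overwriting coordinates with the sentinel
#'
#' @param frames frame table.
#' @param which logical or integer index of rows to blank; default all.
#' @return the frame table with \code{tracked = FALSE} and all coordinates set
#'   to \code{\link{SENTINEL}} on the selected rows.
#' @export
set_untracked <- function(frames, which = seq_len(nrow(frames))) {
  frames$tracked[which] <- FALSE
  frames[which, coord_columns()] <- SENTINEL
  frames
}
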