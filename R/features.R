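#' Relative (articular) angle specifications
#'
#' The 16 angles between consecutive body segments, each measured in the
#' plane the two segments span: angle at \code{vertex} between the segments
#' \code{vertex->a} and \code{vertex->b}. The enumeration follows the
#' head-to-foot ordering of the kinematic chain; \code{tau2} (the right
#' shoulder-axis/trunk angle) is omitted as the near-complement of
#' \code{tau1} on an almost collinear shoulder axis.
#'
#' @format data.frame with columns \code{symbol}, \code{a}, \code{vertex},
#'   \code{b} (joint names).
#' @export
ANGLE_SPECS <- data.frame(
  symbol = c("mu1", "mu2", "xi", "tau1", "eta1", "eta2", "theta1", "theta2",
             "delta1", "delta2", "gamma1", "gamma2", "beta1", "beta2",
             "alpha1", "alpha2"),
  a      = c("head", "head", "head", "acromion_L", "C7", "C7",
             "acromion_L", "acromion_R", "C7", "C7", "Hc", "Hc",
             "iliac_L", "iliac_R", "knee_L", "knee_R"),
  vertex = c("C7", "C7", "C7", "C7", "acromion_L", "acromion_R",
             "elbow_L", "elbow_R", "Hc", "Hc", "iliac_L", "iliac_R",
             "knee_L", "knee_R", "malleolus_L", "malleolus_R"),
  b      = c("acromion_L", "acromion_R", "Hc", "Hc", "elbow_L", "elbow_R",
             "wrist_L", "wrist_R", "iliac_L", "iliac_R", "knee_L", "knee_R",
             "malleolus_L", "malleolus_R", "foot_L", "foot_R"),
  stringsAsFactors = FALSE
)

# Z feature names follow the joint labelling: numbered joints keep their
# index, the two derived midpoints keep their anatomical labels.
z_feature_names <- function() {
  nm <- paste0("Z_", c("1", "C7", as.character(3:16), "Hc"))
  nm
}

#' Canonical 37-feature field order
#'
#' 17 height-scaled vertical coordinates (\code{Z_1}, \code{Z_C7},
#' \code{Z_3..Z_16}, \code{Z_Hc}), then the 16 normalized relative angles in
#' \code{\link{ANGLE_SPECS}} order, then the 4 normalized absolute angles
#' \code{A_pitch}, \code{A_roll} (trunk) and \code{B_pitch}, \code{B_roll}
#' (head).
#'
#' @return character vector of length 37.
#' @export
feature_names <- function() {
  c(z_feature_names(), ANGLE_SPECS$symbol,
    c("A_pitch", "A_roll", "B_pitch", "B_roll"))
}

#' Default 10-attribute selection
#'
#' The ReliefF-selected subset used by the classifier, in its canonical
#' order.
#'
#' @export
DEFAULT_SELECTION <- c("A_pitch", "A_roll", "B_pitch", "B_roll",
                       "xi", "mu2", "delta2", "Z_1", "Z_C7", "Z_Hc")

#' Angle between two body segments sharing a vertex
#'
#' Computes the articular angle at \code{vertex} between the segments towards
#' \code{a} and \code{b}, in the plane spanned by the two segments:
#' \code{acos} of the normalized dot product, in degrees in [0, 180].
#'
#' @param a,vertex,b length-3 vectors or n x 3 matrices of coordinates
#'   (meters).
#' @param min_norm segments shorter than this (meters) are degenerate.
#' @return numeric vector of angles in degrees; degenerate segments yield
#'   \code{NA} (callers map the whole frame to untracked).
#' @export
relative_angle <- function(a, vertex, b, min_norm = 1e-9) {
  a <- rbind(a); vertex <- rbind(vertex); b <- rbind(b)
  u <- a - vertex[rep_len(seq_len(nrow(vertex)), nrow(a)), , drop = FALSE]
  v <- b - vertex[rep_len(seq_len(nrow(vertex)), nrow(b)), , drop = FALSE]
  nu <- sqrt(rowSums(u * u))
  nv <- sqrt(rowSums(v * v))
  ok <- nu > min_norm & nv > min_norm
  # atan2(|u x v|, u.v) is the arccos of the normalized dot product in a
  # form that stays accurate for nearly collinear segments
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  ang <- atan2(sqrt(rowSums(cr * cr)), rowSums(u * v)) * 180 / pi
  ang[!ok] <- NA_real_
  unname(ang)
}

#' Compute the 16 relative angles of a frame table
#'
#' Applies \code{\link{relative_angle}} to the triplets in
#' \code{\link{ANGLE_SPECS}}. Untracked frames and frames with any degenerate
#' segment produce \code{NA} rows (mapped to sentinel by
#' \code{\link{assemble_features}}).
#'
#' @param frames frame table in room coordinates.
#' @return n x 16 numeric matrix of angles in degrees, columns named by
#'   symbol.
#' @export
compute_relative_angles <- function(frames) {
  validate_frames(frames)
  out <- matrix(NA_real_, nrow(frames), nrow(ANGLE_SPECS),
                dimnames = list(NULL, ANGLE_SPECS$symbol))
  tr <- frames$tracked
  if (!any(tr)) return(out)
  sub <- frames[tr, , drop = FALSE]
  for (i in seq_len(nrow(ANGLE_SPECS))) {
    out[tr, i] <- relative_angle(joint_matrix(sub, ANGLE_SPECS$a[i]),
                                 joint_matrix(sub, ANGLE_SPECS$vertex[i]),
                                 joint_matrix(sub, ANGLE_SPECS$b[i]))
  }
  out
}

# unit horizontal body-lateral axis per frame: shoulder axis projected on the
# floor plane; falls back to the iliac-crest axis, then the room X axis.
body_lateral_axis <- function(frames, min_norm = 1e-6) {
  n <- nrow(frames)
  m <- (joint_matrix(frames, "acromion_R") -
        joint_matrix(frames, "acromion_L"))
  m[, 3] <- 0
  nm <- sqrt(rowSums(m * m))
  bad <- nm < min_norm
  if (any(bad)) {
    alt <- (joint_matrix(frames, "iliac_R") -
            joint_matrix(frames, "iliac_L"))
    alt[, 3] <- 0
    na <- sqrt(rowSums(alt * alt))
    use <- bad & na >= min_norm
    m[use, ] <- alt[use, ]
    nm[use] <- na[use]
    still <- bad & na < min_norm
    if (any(still)) {
      m[still, ] <- matrix(c(1, 0, 0), sum(still), 3, byrow = TRUE)
      nm[still] <- 1
      message(sum(still), " frame(s): shoulder and pelvis axes nearly ",
              "vertical; pitch/roll referenced to the room X axis")
    }
  }
  m / nm
}

#' Signed pitch and roll of the trunk or head segment
#'
#' Decomposes the segment vector (trunk: \code{C7 - Hc}; head:
#' \code{head - C7}) against a body-heading frame: with \code{z} the room
#' vertical, \code{m} the unit horizontal projection of the shoulder axis
#' (right minus left) and \code{f = z x m} the facing direction,
#' \code{pitch = atan2(v.f, v.z)} and \code{roll = atan2(v.m, v.z)}, each in
#' (-180, 180] degrees. Positive pitch is a forward lean; the sign is what
#' separates a forward slump from a backward collapse in the
#' "dangerous sitting" class. If the shoulder axis is nearly vertical the
#' iliac-crest axis is used, then the room X axis.
#'
#' @param frames frame table in room coordinates.
#' @param segment \code{"trunk"} or \code{"head"}.
#' @return n x 2 matrix with columns \code{pitch}, \code{roll} (degrees);
#'   untracked frames give \code{NA}.
#' @export
segment_pitch_roll <- function(frames, segment = c("trunk", "head")) {
  validate_frames(frames)
  segment <- match.arg(segment)
  out <- matrix(NA_real_, nrow(frames), 2L,
                dimnames = list(NULL, c("pitch", "roll")))
  tr <- frames$tracked
  if (!any(tr)) return(out)
  sub <- frames[tr, , drop = FALSE]
  v <- if (segment == "trunk") {
    joint_matrix(sub, "C7") - joint_matrix(sub, "Hc")
  } else {
    joint_matrix(sub, "head") - joint_matrix(sub, "C7")
  }
  m <- body_lateral_axis(sub)
  # f = z x m for z = (0,0,1): (-m_y, m_x, 0)
  f <- cbind(-m[, 2], m[, 1], 0)
  vz <- v[, 3]
  out[tr, "pitch"] <- atan2(rowSums(v * f), vz) * 180 / pi
  out[tr, "roll"] <- atan2(rowSums(v * m), vz) * 180 / pi
  out
}

#' Height-scaled vertical joint coordinates
#'
#' Divides every joint's Z coordinate by the subject's height, making the
#' vertical features dimensionless and comparable across subjects.
#'
#' @param frames frame table in room coordinates.
#' @param height subject stature in meters (one value, must lie in
#'   [1.0, 2.5]).
#' @return n x 17 matrix named per \code{\link{feature_names}}; untracked
#'   frames carry the sentinel.
#' @export
scale_vertical <- function(frames, height) {
  validate_frames(frames)
  if (!is.numeric(height) || length(height) != 1L || !is.finite(height) ||
      height <= 0)
    stop("configuration error: height must be a positive number (meters)")
  if (height < 1.0 || height > 2.5)
    stop("configuration error: height ", height, " m outside [1.0, 2.5]")
  z <- as.matrix(frames[, sprintf("j%02d_z", seq_len(N_JOINTS))])
  out <- z / height
  out[!frames$tracked, ] <- SENTINEL
  colnames(out) <- z_feature_names()
  out
}

#' Assemble the 37-element per-frame feature vector
#'
#' Builds, per frame: the 17 height-scaled vertical coordinates, the 16
#' relative angles normalized by 180 degrees (range [0, 1]) and the 4 signed
#' absolute angles (trunk/head pitch and roll) normalized by 180 degrees
#' (range (-1, 1]). Untracked frames, and tracked frames with degenerate
#' geometry, yield a row of sentinel values.
#'
#' @param frames frame table in room coordinates.
#' @param height subject stature in meters, either a single number or a named
#'   vector indexed by \code{subject_id}.
#' @return data.frame: \code{timestamp}, \code{camera_id}, \code{subject_id},
#'   \code{tracked}, then the 37 feature columns in
#'   \code{\link{feature_names}} order.
#' @export
assemble_features <- function(frames, height) {
  validate_frames(frames)
  n <- nrow(frames)
  if (length(height) > 1L || !is.null(names(height))) {
    if (is.null(names(height)))
      stop("configuration error: multiple heights must be named by subject_id")
    miss <- setdiff(unique(frames$subject_id), names(height))
    if (length(miss) > 0L)
      stop("configuration error: no height for subject(s) ",
           paste(miss, collapse = ", "))
    h <- as.numeric(height[frames$subject_id])
  } else {
    h <- rep_len(as.numeric(height), n)
  }
  if (any(!is.finite(h) | h <= 0))
    stop("configuration error: heights must be positive (meters)")

  zs <- as.matrix(frames[, sprintf("j%02d_z", seq_len(N_JOINTS))]) / h
  colnames(zs) <- z_feature_names()
  rel <- compute_relative_angles(frames) / 180
  pr <- cbind(segment_pitch_roll(frames, "trunk"),
              segment_pitch_roll(frames, "head")) / 180
  colnames(pr) <- c("A_pitch", "A_roll", "B_pitch", "B_roll")

  feat <- cbind(zs, rel, pr)[, feature_names(), drop = FALSE]
  bad <- !frames$tracked | apply(is.na(feat), 1L, any)
  if (any(bad & frames$tracked))
    message(sum(bad & frames$tracked),
            " tracked frame(s) had degenerate geometry; mapped to untracked")
  feat[bad, ] <- SENTINEL
  out <- cbind(frames[, frame_meta_columns()], as.data.frame(feat))
  out$tracked <- !bad
  rownames(out) <- NULL
  out
}

#' Select a feature subset in a fixed order
#'
#' @param features feature table from \code{\link{assemble_features}} (or a
#'   bare matrix/data.frame of feature columns).
#' @param spec character vector of feature names to keep, in output order;
#'   default \code{\link{DEFAULT_SELECTION}}.
#' @return the input with only the metadata and the selected feature columns,
#'   in spec order. Sentinel rows propagate unchanged.
#' @export
select_features <- function(features, spec = DEFAULT_SELECTION) {
  unknown <- setdiff(spec, feature_names())
  if (length(unknown) > 0L)
    stop("configuration error: unknown feature name(s): ",
         paste(unknown, collapse = ", "))
  miss <- setdiff(spec, names(features))
  if (length(miss) > 0L)
    stop("configuration error: feature table lacks column(s): ",
         paste(miss, collapse = ", "))
  meta <- intersect(frame_meta_columns(), names(features))
  features[, c(meta, spec), drop = FALSE]
}
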