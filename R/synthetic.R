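#' Anthropometric model of a subject
#'
#' Segment lengths are expressed as fractions of stature, following standard
#' anthropometric tables; the vertical chain (ankle height + shank + thigh +
#' trunk + head segment) sums to ~0.96 of stature, the level of the head
#' joint rather than the vertex.
#'
#' @param height stature in meters (study cohort spans 1.55-1.90 m).
#' @param ratios named list of segment/height fractions; defaults cover
#'   head (C7 to head joint), trunk (Hc to C7), upper arm, forearm, thigh,
#'   shank, foot length, shoulder half-width, pelvis half-width and ankle
#'   height.
#' @return list of class \code{anthropometry} with absolute segment lengths
#'   in meters.
#' @export
anthropometry <- function(height,
                          ratios = list(head = 0.130, trunk = 0.288,
                                        upper_arm = 0.186, forearm = 0.146,
                                        thigh = 0.245, shank = 0.246,
                                        foot = 0.152, shoulder_hw = 0.129,
                                        pelvis_hw = 0.065, ankle_h = 0.039)) {
  stopifnot(is.numeric(height), length(height) == 1L, height > 0)
  if (any(unlist(ratios) <= 0)) stop("anthropometric ratios must be positive")
  chain <- ratios$ankle_h + ratios$shank + ratios$thigh + ratios$trunk +
    ratios$head
  if (abs(chain - 0.96) > 0.05 * 1)
    warning("vertical chain ratios sum to ", round(chain, 3),
            ", far from the head-joint level ~0.96 of stature")
  lengths <- lapply(ratios, function(r) r * height)
  structure(c(list(height = height), lengths), class = "anthropometry")
}

deg2rad <- function(d) d * pi / 180

# Rotation of v about the (unit, horizontal) right-lateral axis m by alpha
# degrees, sending z toward the facing direction f for positive alpha.
rot_sagittal <- function(v, m, f, alpha_deg) {
  a <- deg2rad(alpha_deg)
  z <- c(0, 0, 1)
  # components of v in the (z, f, m) frame
  vz <- sum(v * z); vf <- sum(v * f); vm <- sum(v * m)
  (vz * cos(a) + vf * -sin(a)) * z + (vf * cos(a) + vz * sin(a)) * f + vm * m
}

#' Construct a 17-joint skeleton from pose parameters
#'
#' Forward-kinematic construction in room coordinates (Z vertical). The pose
#' is described by the pelvis location/height, a heading (facing direction in
#' the floor plane), signed trunk and head pitch/roll, and sagittal-plane hip
#' and knee interior angles (180 = straight limb, 90 = right angle).
#'
#' @param anthro an \code{\link{anthropometry}}.
#' @param location length-2 (x, y) floor position of the pelvis, meters.
#' @param heading facing direction, degrees about Z (0 = room +X).
#' @param hc_z pelvis (Hc) height above the floor, meters.
#' @param trunk_pitch,trunk_roll,head_pitch,head_roll signed degrees;
#'   positive pitch leans toward the facing direction.
#' @param hip_angle,knee_angle interior sagittal angles in degrees
#'   (per-side scalars or length-2 \code{c(left, right)}).
#' @param elbow_angle interior arm-forearm angle, degrees (arms hang along
#'   the trunk).
#' @param ankle_angle interior leg-foot angle, degrees (90 = foot
#'   perpendicular to the shank; larger = plantarflexed).
#' @return 17 x 3 joint matrix, rows named per \code{\link{JOINT_NAMES}}.
#' @export
build_skeleton <- function(anthro, location = c(0, 0), heading = 0,
                           hc_z = 0.53 * anthro$height,
                           trunk_pitch = 0, trunk_roll = 0,
                           head_pitch = 0, head_roll = 0,
                           hip_angle = 180, knee_angle = 180,
                           elbow_angle = 170, ankle_angle = 90) {
  stopifnot(inherits(anthro, "anthropometry"))
  hip_angle <- rep_len(hip_angle, 2L)
  knee_angle <- rep_len(knee_angle, 2L)
  phi <- deg2rad(heading)
  f <- c(cos(phi), sin(phi), 0)       # facing direction
  m <- c(sin(phi), -cos(phi), 0)      # right-lateral axis (R - L)
  z <- c(0, 0, 1)

  dir_from_pitch_roll <- function(p, r) {
    if (abs(p) >= 89.999) {
      sign(p) * f
    } else {
      v <- z + tan(deg2rad(p)) * f + tan(deg2rad(r)) * m
      v / sqrt(sum(v^2))
    }
  }
  d_trunk <- dir_from_pitch_roll(trunk_pitch, trunk_roll)
  d_head <- dir_from_pitch_roll(head_pitch, head_roll)

  J <- matrix(NA_real_, N_JOINTS, 3L,
              dimnames = list(JOINT_NAMES, c("x", "y", "z")))
  hc <- c(location[1], location[2], hc_z)
  c7 <- hc + anthro$trunk * d_trunk
  J["Hc", ] <- hc
  J["C7", ] <- c7
  J["head", ] <- c7 + anthro$head * d_head
  J["acromion_L", ] <- c7 - anthro$shoulder_hw * m
  J["acromion_R", ] <- c7 + anthro$shoulder_hw * m
  J["iliac_L", ] <- hc - anthro$pelvis_hw * m
  J["iliac_R", ] <- hc + anthro$pelvis_hw * m

  # arms hang along the trunk with a slight elbow bend
  d_arm <- -d_trunk
  d_forearm <- rot_sagittal(d_arm, m, f, 180 - elbow_angle)
  for (side in c("L", "R")) {
    sh <- J[paste0("acromion_", side), ]
    el <- sh + anthro$upper_arm * d_arm
    J[paste0("elbow_", side), ] <- el
    J[paste0("wrist_", side), ] <- el + anthro$forearm * d_forearm
  }

  for (i in 1:2) {
    side <- c("L", "R")[i]
    hip <- J[paste0("iliac_", side), ]
    # thigh at hip_angle from the trunk direction, opening toward the front
    d_thigh <- rot_sagittal(d_trunk, m, f, hip_angle[i])
    knee <- hip + anthro$thigh * d_thigh
    d_shank <- rot_sagittal(d_thigh, m, f, 180 - knee_angle[i])
    ank <- knee + anthro$shank * d_shank
    # foot at the interior ankle angle from the shank; of the two sagittal
    # candidates keep the one further from the floor (never digs in)
    cand1 <- rot_sagittal(-d_shank, m, f, ankle_angle)
    cand2 <- rot_sagittal(-d_shank, m, f, -ankle_angle)
    d_foot <- if (cand1[3] >= cand2[3]) cand1 else cand2
    J[paste0("knee_", side), ] <- knee
    J[paste0("malleolus_", side), ] <- ank
    J[paste0("foot_", side), ] <- ank + anthro$foot * d_foot
  }
  J
}

#' Class-specific pose parameter distributions
#'
#' Jitter ranges per pose class and benchmark hardness. \code{easy} keeps
#' the four classes well separated; \code{hard} widens the sitting head/trunk
#' pitch jitter and lets the dangerous-sitting forward head pitch reach down
#' to 15 degrees, so the class 2 and class 4 pitch distributions overlap the
#' way occluded seated tracking does.
#'
#' @param class pose class 1-4.
#' @param anthro an \code{\link{anthropometry}}.
#' @param hardness \code{"easy"} or \code{"hard"}.
#' @return list of \code{build_skeleton} arguments (pose parameters sampled
#'   from the class's jitter ranges; uses the current RNG stream).
#' @export
sample_pose_params <- function(class, anthro,
                               hardness = c("easy", "hard")) {
  hardness <- match.arg(hardness)
  H <- anthro$height
  seat_z <- 0.29 * H
  base <- list(trunk_roll = stats::rnorm(1, 0, 2),
               head_roll = stats::rnorm(1, 0, 3))
  p <- switch(as.character(class),
    "1" = list(hc_z = 0.53 * H * stats::runif(1, 0.985, 1.01),
               trunk_pitch = stats::rnorm(1, 0, 3),
               head_pitch = stats::rnorm(1, 0, 4),
               hip_angle = 180 - abs(stats::rnorm(1, 0, 3)),
               knee_angle = 180 - abs(stats::rnorm(1, 0, 3))),
    "2" = {
      jit <- if (hardness == "easy") 8 else 20
      list(hc_z = seat_z * stats::runif(1, 0.93, 1.07),
           trunk_pitch = stats::runif(1, -jit, jit),
           head_pitch = stats::runif(1, -jit, jit),
           hip_angle = stats::rnorm(1, 90, 5),
           knee_angle = stats::rnorm(1, 90, 5))
    },
    "3" = list(hc_z = stats::runif(1, 0.08, 0.12),
               trunk_pitch = 90, head_pitch = 90,
               trunk_roll = 0, head_roll = 0,
               hip_angle = 180 - abs(stats::rnorm(1, 0, 5)),
               knee_angle = 180 - abs(stats::rnorm(1, 0, 8)),
               ankle_angle = 150),
    "4" = {
      lo <- if (hardness == "easy") 30 else 15
      forward <- stats::runif(1) < 0.5
      if (forward) {
        list(hc_z = seat_z * stats::runif(1, 0.93, 1.07),
             trunk_pitch = stats::runif(1, 5, 30),
             head_pitch = stats::runif(1, lo, 60),
             hip_angle = stats::rnorm(1, 90, 5),
             knee_angle = stats::rnorm(1, 90, 5))
      } else {
        list(hc_z = seat_z * stats::runif(1, 0.93, 1.07),
             trunk_pitch = stats::runif(1, -40, -20),
             head_pitch = stats::runif(1, -60, -25),
             hip_angle = stats::rnorm(1, 100, 5),
             knee_angle = stats::rnorm(1, 100, 8))
      }
    },
    stop("class must be 1, 2, 3 or 4"))
  utils::modifyList(base, p)
}

#' Generate one canonical noiseless frame of a pose class
#'
#' @param class pose class 1-4.
#' @param anthro an \code{\link{anthropometry}}.
#' @param seed integer seed for the jitter draw.
#' @param hardness jitter regime, see \code{\link{sample_pose_params}}.
#' @param location,heading placement in the room.
#' @return 17 x 3 joint matrix in room coordinates.
#' @export
make_pose_template <- function(class, anthro, seed = 1L,
                               hardness = "easy",
                               location = c(2, 2), heading = 0) {
  set.seed(as.integer(seed))
  p <- sample_pose_params(class, anthro, hardness)
  do.call(build_skeleton,
          c(list(anthro = anthro, location = location, heading = heading), p))
}

#' Tracking noise model
#'
#' @param sigma per-coordinate Gaussian position noise, meters.
#' @param dropout_prob probability that a whole frame is lost (sentinel).
#' @return list of class \code{noise_model}.
#' @export
noise_model <- function(sigma = 0.01, dropout_prob = 0.0) {
  stopifnot(sigma >= 0, dropout_prob >= 0, dropout_prob <= 1)
  structure(list(sigma = sigma, dropout_prob = dropout_prob),
            class = "noise_model")
}

#' Script of poses for one recording session
#'
#' @param class pose classes, in order.
#' @param duration per-pose hold durations, seconds (poses were held for
#'   10 s in the study protocol).
#' @param x,y,heading placement per pose (recycled).
#' @param transition_s duration of the interpolated transition between
#'   consecutive poses, seconds.
#' @return data.frame of class \code{session_script}.
#' @export
session_script <- function(class, duration = 10, x = 2, y = 2, heading = 0,
                           transition_s = 1) {
  if (length(class) == 0L) stop("empty session script")
  stopifnot(all(class %in% 1:4), all(duration > 0), transition_s >= 0)
  out <- data.frame(class = as.integer(class),
                    duration = rep_len(duration, length(class)),
                    x = rep_len(x, length(class)),
                    y = rep_len(y, length(class)),
                    heading = rep_len(heading, length(class)))
  attr(out, "transition_s") <- transition_s
  class(out) <- c("session_script", "data.frame")
  out
}

#' Simulate a labeled skeleton stream for one session
#'
#' Generates frames at the requested rate in room coordinates. Within a pose
#' segment, pose parameters are re-jittered per frame from the class
#' template's ranges; between segments, joints are linearly interpolated over
#' the transition window and labeled \code{LABEL_TRANSITION}. Gaussian
#' position noise is added last, then whole-frame dropout replaces frames by
#' the sentinel (label \code{LABEL_UNTRACKED}). Fully reproducible from the
#' seed.
#'
#' @param script a \code{\link{session_script}}.
#' @param anthro an \code{\link{anthropometry}}.
#' @param noise a \code{\link{noise_model}}.
#' @param frame_rate frames per second, in (0, 30].
#' @param subject_id,camera_id metadata for the emitted frames.
#' @param seed integer seed.
#' @param hardness jitter regime (see \code{\link{sample_pose_params}}).
#' @return list with \code{frames} (frame table) and \code{labels}
#'   (data.frame: timestamp, camera_id, subject_id, label).
#' @export
generate_session <- function(script, anthro, noise = noise_model(),
                             frame_rate = 30, subject_id = "S01",
                             camera_id = 1L, seed = 1L, hardness = "easy") {
  if (!inherits(script, "session_script") || nrow(script) == 0L)
    stop("empty session script")
  stopifnot(frame_rate > 0, frame_rate <= 30)
  set.seed(as.integer(seed))
  dt <- 1 / frame_rate
  trans_s <- attr(script, "transition_s")
  n_trans <- round(trans_s * frame_rate)

  seg_joints <- list(); seg_labels <- list()
  prev_last <- NULL
  for (s in seq_len(nrow(script))) {
    nf <- round(script$duration[s] * frame_rate)
    jj <- array(0, dim = c(nf, N_JOINTS, 3L))
    for (i in seq_len(nf)) {
      p <- sample_pose_params(script$class[s], anthro, hardness)
      jj[i, , ] <- do.call(build_skeleton,
        c(list(anthro = anthro,
               location = c(script$x[s], script$y[s]),
               heading = script$heading[s]), p))
    }
    if (!is.null(prev_last) && n_trans > 0L) {
      w <- seq_len(n_trans) / (n_trans + 1)
      tj <- array(0, dim = c(n_trans, N_JOINTS, 3L))
      for (i in seq_len(n_trans))
        tj[i, , ] <- (1 - w[i]) * prev_last + w[i] * jj[1, , ]
      seg_joints[[length(seg_joints) + 1L]] <- tj
      seg_labels[[length(seg_labels) + 1L]] <- rep(LABEL_TRANSITION, n_trans)
    }
    seg_joints[[length(seg_joints) + 1L]] <- jj
    seg_labels[[length(seg_labels) + 1L]] <- rep(script$class[s], nf)
    prev_last <- jj[nf, , ]
  }
  n <- sum(vapply(seg_joints, function(a) dim(a)[1], 1L))
  joints <- array(0, dim = c(n, N_JOINTS, 3L))
  at <- 1L
  for (a in seg_joints) {
    k <- dim(a)[1]
    joints[at:(at + k - 1L), , ] <- a
    at <- at + k
  }
  labels <- unlist(seg_labels)

  if (noise$sigma > 0)
    joints <- joints + array(stats::rnorm(length(joints), 0, noise$sigma),
                             dim = dim(joints))
  frames <- make_frames(joints, timestamp = (seq_len(n) - 1L) * dt,
                        camera_id = camera_id, subject_id = subject_id)
  if (noise$dropout_prob > 0) {
    drop <- stats::runif(n) < noise$dropout_prob
    if (any(drop)) {
      frames <- set_untracked(frames, drop)
      labels[drop] <- LABEL_UNTRACKED
    }
  }
  list(frames = frames,
       labels = data.frame(timestamp = frames$timestamp,
                           camera_id = frames$camera_id,
                           subject_id = frames$subject_id,
                           label = labels))
}

#' Project a room-frame stream into per-camera views
#'
#' Applies the inverse of each camera's camera-to-room calibration, yielding
#' the streams the cameras would record; \code{\link{to_room_frame}} with the
#' same calibration recovers the original coordinates.
#'
#' @param frames room-frame table.
#' @param calibrations list of camera-to-room \code{\link{rigid_transform}}s,
#'   one per camera.
#' @return list of frame tables, one per camera (with \code{camera_id} set).
#' @export
apply_camera_views <- function(frames, calibrations) {
  validate_frames(frames)
  lapply(seq_along(calibrations), function(k) {
    cal <- calibrations[[k]]
    if (!inherits(cal, "rigid_transform"))
      stop("calibration ", k, " is not a rigid_transform")
    out <- to_room_frame(frames, invert_transform(cal))
    out$camera_id <- k
    out
  })
}

# integer class counts summing to n, proportional to mix (largest remainder)
apportion <- function(n, mix) {
  raw <- n * mix / sum(mix)
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Generate a full synthetic benchmark through the feature pipeline
#'
#' Simulates a cohort of subjects (heights uniform on the study range
#' 1.55-1.90 m), runs each stream through feature assembly and selection,
#' removes transition/untracked frames and splits by whole subject. Class
#' frame budgets follow the study database's class mix. \code{hardness}
#' controls separability: \code{easy} uses sigma = 0.01 m noise and disjoint
#' pitch ranges; \code{hard} uses sigma = 0.05 m and overlapping class-2/4
#' head-pitch distributions.
#'
#' @param n_subjects,n_train cohort size and training-subject count.
#' @param frames_per_subject frames generated per subject (before dropout).
#' @param class_mix class proportions; default matches the study database
#'   (0.241, 0.388, 0.144, 0.227).
#' @param hardness \code{"easy"} or \code{"hard"}.
#' @param seed master seed.
#' @param feature_spec selected feature names
#'   (default \code{\link{DEFAULT_SELECTION}}).
#' @param frame_rate frames per second.
#' @param dropout_prob whole-frame dropout probability.
#' @return list: \code{train}, \code{test} (each a \code{pose_dataset}),
#'   \code{heights}, \code{train_subjects}, \code{test_subjects},
#'   \code{hardness}.
#' @export
generate_benchmark <- function(n_subjects = 12L, n_train = 10L,
                               frames_per_subject = 500L,
                               class_mix = c(0.241, 0.388, 0.144, 0.227),
                               hardness = c("easy", "hard"), seed = 1L,
                               feature_spec = DEFAULT_SELECTION,
                               frame_rate = 30, dropout_prob = 0.02) {
  hardness <- match.arg(hardness)
  if (n_train >= n_subjects) stop("n_train must be < n_subjects")
  if (frames_per_subject < 100L)
    warning("fewer than 100 frames per subject: metrics will be unstable")
  sigma <- if (hardness == "easy") 0.01 else 0.05
  set.seed(as.integer(seed))
  heights <- stats::runif(n_subjects, 1.55, 1.90)
  names(heights) <- sprintf("S%02d", seq_len(n_subjects))
  sub_seeds <- sample.int(2^31 - 2, n_subjects)

  feats <- list(); labs <- list()
  for (i in seq_len(n_subjects)) {
    sid <- names(heights)[i]
    anthro <- anthropometry(heights[[i]])
    counts <- apportion(frames_per_subject, class_mix)
    script <- session_script(class = 1:4, duration = counts / frame_rate,
                             x = 2, y = 2,
                             heading = stats::runif(1, 0, 360),
                             transition_s = 0)
    ses <- generate_session(script, anthro,
                            noise_model(sigma, dropout_prob),
                            frame_rate = frame_rate, subject_id = sid,
                            seed = sub_seeds[i], hardness = hardness)
    fv <- suppressMessages(assemble_features(ses$frames, heights[[i]]))
    feats[[i]] <- select_features(fv, feature_spec)
    labs[[i]] <- ses$labels$label
  }
  features <- do.call(rbind, feats)
  labels <- unlist(labs)
  ds <- suppressMessages(build_dataset(features, labels))
  split <- split_by_subject(ds, n_train = n_train, seed = seed + 1L)
  c(split, list(heights = heights, hardness = hardness))
}
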