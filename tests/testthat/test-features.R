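test_that("relative_angle matches analytic cases", {
  o <- c(0, 0, 0)
  expect_equal(relative_angle(c(0, 1, 0), o, c(1, 0, 0)), 90)
  expect_equal(relative_angle(c(0, 0, 1), o, c(0, 0, -1)), 180)
  expect_equal(relative_angle(c(1, 1, 0), o, c(1, 0, 0)), 45)
  expect_true(is.na(relative_angle(c(0, 0, 1e-12), o, c(1, 0, 0))))
})

test_that("the 16 relative angles follow the documented joint triplets", {
  frames <- sample_frame_table(6)
  ang <- compute_relative_angles(frames)
  expect_identical(colnames(ang), ANGLE_SPECS$symbol)
  # spot-check against the arccos oracle on raw coordinates
  for (i in c(1, 4, 9, 16)) {
    manual <- relative_angle(joint_matrix(frames, ANGLE_SPECS$a[i]),
                             joint_matrix(frames, ANGLE_SPECS$vertex[i]),
                             joint_matrix(frames, ANGLE_SPECS$b[i]))
    expect_equal(ang[, i], manual)
  }
})

test_that("a knee flexed to 90 degrees yields beta = 90 on that side", {
  a <- anthropometry(1.7)
  J <- build_skeleton(a, hip_angle = 180, knee_angle = c(90, 180))
  fr <- make_frames(J)
  ang <- compute_relative_angles(fr)
  expect_equal(unname(ang[1, "beta1"]), 90, tolerance = 1e-9)
  expect_equal(unname(ang[1, "beta2"]), 180, tolerance = 1e-9)
})

test_that("arms along the shoulder axis give straight-arm theta of 180", {
  a <- anthropometry(1.7)
  J <- build_skeleton(a)
  # T-pose by hand: arms out along the shoulder axis
  for (side in c("L", "R")) {
    s <- sign((side == "R") - 0.5) * 2
    sh <- J[paste0("acromion_", side), ]
    dir <- c(0, -s, 0)  # heading 0: lateral axis is -y for right
    J[paste0("elbow_", side), ] <- sh + 0.3 * dir
    J[paste0("wrist_", side), ] <- sh + 0.55 * dir
  }
  ang <- compute_relative_angles(make_frames(J))
  expect_equal(unname(ang[1, "theta1"]), 180, tolerance = 1e-6)
  expect_equal(unname(ang[1, "theta2"]), 180, tolerance = 1e-6)
})

test_that("relative angles are invariant under proper rigid transforms", {
  set.seed(11)
  frames <- sample_frame_table(25)
  ang0 <- compute_relative_angles(frames)
  for (rep in 1:4) {
    moved <- to_room_frame(frames, random_rigid())
    expect_lt(max(abs(compute_relative_angles(moved) - ang0)), 1e-9)
  }
})

test_that("pitch/roll decomposition matches constructed trunk attitudes", {
  a <- anthropometry(1.7)
  up <- make_frames(build_skeleton(a))
  pr <- segment_pitch_roll(up, "trunk")
  expect_equal(unname(pr[1, ]), c(0, 0), tolerance = 1e-9)
  for (p in c(-40, 12, 30, 75)) {
    fr <- make_frames(build_skeleton(a, trunk_pitch = p))
    expect_equal(unname(segment_pitch_roll(fr, "trunk")[1, "pitch"]), p,
                 tolerance = 1e-9)
    expect_equal(unname(segment_pitch_roll(fr, "trunk")[1, "roll"]), 0,
                 tolerance = 1e-9)
  }
  flat <- make_frames(build_skeleton(a, trunk_pitch = 90, hc_z = 0.1))
  expect_equal(unname(segment_pitch_roll(flat, "trunk")[1, "pitch"]), 90,
               tolerance = 1e-9)
  # head pitch is absolute (against vertical), independent of the trunk
  nod <- make_frames(build_skeleton(a, trunk_pitch = 10, head_pitch = 35))
  expect_equal(unname(segment_pitch_roll(nod, "head")[1, "pitch"]), 35,
               tolerance = 1e-9)
})

test_that("pitch/roll are invariant to yaw rotations and translations", {
  # roll is gimbal-singular for a segment lying exactly along the facing
  # direction (v.z = v.m = 0), so compare wrap-aware and away from the
  # singularity; pitch has no such configuration in these frames
  angdiff <- function(a, b) abs(((a - b + 180) %% 360) - 180)
  set.seed(13)
  frames <- sample_frame_table(15)
  pr0 <- cbind(segment_pitch_roll(frames, "trunk"),
               segment_pitch_roll(frames, "head"))
  m0 <- skelpose:::body_lateral_axis(frames)
  roll_singular <- function(v) {
    sqrt(rowSums(v * m0)^2 + v[, 3]^2) < 1e-9
  }
  v_trunk <- joint_matrix(frames, "C7") - joint_matrix(frames, "Hc")
  v_head <- joint_matrix(frames, "head") - joint_matrix(frames, "C7")
  singular <- cbind(roll_singular(v_trunk), roll_singular(v_head))
  for (rep in 1:3) {
    tf <- yaw_transform(runif(1, 0, 360), runif(3, -2, 2))
    moved <- to_room_frame(frames, tf)
    pr1 <- cbind(segment_pitch_roll(moved, "trunk"),
                 segment_pitch_roll(moved, "head"))
    d <- angdiff(pr1, pr0)
    d[, c(2, 4)][singular] <- 0
    expect_lt(max(d), 1e-6)
  }
})

test_that("scale_vertical divides Z by height and propagates the sentinel", {
  fr <- sample_frame_table(4, height = 1.8)
  z <- scale_vertical(fr, 1.8)
  expect_equal(dim(z), c(4L, 17L))
  expect_equal(z[, "Z_1"], joint_matrix(fr, "head")[, 3] / 1.8)
  fr2 <- set_untracked(fr, 2)
  z2 <- scale_vertical(fr2, 1.8)
  expect_true(all(z2[2, ] == SENTINEL))
  expect_error(scale_vertical(fr, -1), "configuration")
  expect_error(scale_vertical(fr, 3.1), "configuration")
})

test_that("assemble_features yields 37 ordered, normalized fields", {
  fr <- sample_frame_table(8, height = 1.66)
  fv <- assemble_features(fr, 1.66)
  expect_identical(names(fv), c("timestamp", "camera_id", "subject_id",
                                "tracked", feature_names()))
  expect_length(feature_names(), 37L)
  vals <- as.matrix(fv[, feature_names()])
  expect_true(all(is.finite(vals)))
  rel <- vals[, ANGLE_SPECS$symbol]
  expect_true(all(rel >= 0 & rel <= 1))
  pr <- vals[, c("A_pitch", "A_roll", "B_pitch", "B_roll")]
  expect_true(all(pr > -1 & pr <= 1))
  # normalization: stored value = degrees / 180
  ang <- compute_relative_angles(fr)
  expect_equal(vals[, "xi"], unname(ang[, "xi"] / 180))
})

test_that("untracked frames assemble to 37 sentinels", {
  fr <- set_untracked(sample_frame_table(3), 2)
  fv <- assemble_features(fr, 1.7)
  expect_true(all(fv[2, feature_names()] == SENTINEL))
  expect_false(fv$tracked[2])
  expect_true(all(fv$tracked[c(1, 3)]))
})

test_that("uniform scaling about Hc with matching height leaves features alone", {
  fr <- sample_frame_table(5, height = 1.6)
  s <- 1.15
  scaled <- fr
  hc <- joint_matrix(fr, "Hc")
  for (j in 1:17) {
    cols <- sprintf("j%02d_%s", j, c("x", "y", "z"))
    scaled[, cols] <- hc + s * (joint_matrix(fr, j) - hc)
  }
  # relative angles: invariant under any uniform scaling
  expect_lt(max(abs(compute_relative_angles(scaled) -
                    compute_relative_angles(fr))), 1e-9)
  # Z features: invariant when height scales by the same factor about z=0
  scaled_z <- fr
  for (j in 1:17) {
    col <- sprintf("j%02d_z", j)
    scaled_z[, col] <- s * fr[, col]
  }
  expect_equal(scale_vertical(scaled_z, 1.6 * s), scale_vertical(fr, 1.6))
})

test_that("select_features returns the default ten attributes in order", {
  fr <- sample_frame_table(5)
  fv <- assemble_features(fr, 1.75)
  sel <- select_features(fv)
  expect_identical(setdiff(names(sel), c("timestamp", "camera_id",
                                         "subject_id", "tracked")),
                   c("A_pitch", "A_roll", "B_pitch", "B_roll", "xi", "mu2",
                     "delta2", "Z_1", "Z_C7", "Z_Hc"))
  all37 <- select_features(fv, feature_names())
  expect_equal(all37[, feature_names()], fv[, feature_names()])
  expect_error(select_features(fv, c("A_pitch", "bogus")), "configuration")
  sent <- assemble_features(set_untracked(fr), 1.75)
  expect_true(all(select_features(sent)[, DEFAULT_SELECTION] == SENTINEL))
})
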