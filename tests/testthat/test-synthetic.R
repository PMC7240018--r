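test_that("pose templates respect their class construction bounds", {
  for (h in c(1.55, 1.72, 1.90)) {
    a <- anthropometry(h)
    for (s in 1:8) {
      standing <- make_pose_template(1, a, seed = s)
      expect_gte(standing["head", "z"], 0.9 * h)
      expect_lte(standing["head", "z"], h)
      lying <- make_pose_template(3, a, seed = s)
      expect_lte(max(lying[, "z"]), 0.35)
      sitting <- make_pose_template(2, a, seed = s)
      expect_gte(sitting["Hc", "z"] / h, 0.25)
      expect_lte(sitting["Hc", "z"] / h, 0.35)
    }
  }
})

test_that("dangerous-sitting templates carry the head/trunk pitch signature", {
  a <- anthropometry(1.7)
  for (s in 1:20) {
    fr <- make_frames(make_pose_template(4, a, seed = s))
    b_pitch <- segment_pitch_roll(fr, "head")[1, "pitch"]
    a_pitch <- segment_pitch_roll(fr, "trunk")[1, "pitch"]
    expect_true(b_pitch >= 30 || a_pitch <= -20,
                label = sprintf("seed %d: B_pitch %.1f / A_pitch %.1f",
                                s, b_pitch, a_pitch))
  }
})

test_that("ground-truth labels agree with re-derived pose features", {
  # noiseless frames of each class must land in the class's own feature
  # region: this ties the generator's labels to the feature definitions
  a <- anthropometry(1.8)
  script <- session_script(class = 1:4, duration = 1, transition_s = 0)
  ses <- generate_session(script, a, noise_model(0, 0), frame_rate = 10,
                          seed = 2)
  fv <- assemble_features(ses$frames, 1.8)
  y <- ses$labels$label
  a_pitch <- fv$A_pitch * 180
  z_hc <- fv$Z_Hc
  expect_true(all(abs(a_pitch[y == 1]) < 15))
  expect_true(all(z_hc[y == 1] > 0.45))
  expect_true(all(z_hc[y %in% c(2, 4)] < 0.4))
  expect_true(all(z_hc[y == 3] < 0.12))
  b_pitch <- fv$B_pitch * 180
  expect_true(all(b_pitch[y == 4] >= 30 | a_pitch[y == 4] <= -20))
})

test_that("generate_session produces the scripted frame counts and labels", {
  a <- anthropometry(1.68)
  ses <- generate_session(session_script(1, duration = 10), a,
                          noise_model(0, 0), frame_rate = 30, seed = 1)
  expect_equal(nrow(ses$frames), 300L)
  expect_true(all(ses$labels$label == 1L))
  expect_equal(ses$frames$timestamp,
               (0:299) / 30)
})

test_that("transitions are labeled and removable", {
  a <- anthropometry(1.68)
  script <- session_script(c(1, 2), duration = 2, transition_s = 1)
  ses <- generate_session(script, a, noise_model(0, 0), frame_rate = 10,
                          seed = 3)
  expect_equal(sum(ses$labels$label == LABEL_TRANSITION), 10L)
  expect_equal(nrow(ses$frames), 50L)
  # interpolated frames sit between the neighbouring poses
  tr <- which(ses$labels$label == LABEL_TRANSITION)
  expect_true(all(diff(joint_matrix(ses$frames, "Hc")[tr, 3]) < 0))
})

test_that("dropout count falls in the binomial 99% interval", {
  a <- anthropometry(1.75)
  ses <- generate_session(session_script(2, duration = 100), a,
                          noise_model(0, dropout_prob = 0.1),
                          frame_rate = 10, seed = 17)
  n_untracked <- sum(ses$labels$label == LABEL_UNTRACKED)
  expect_gte(n_untracked, qbinom(0.005, 1000, 0.1))
  expect_lte(n_untracked, qbinom(0.995, 1000, 0.1))
  expect_true(all(as.matrix(
    ses$frames[ses$labels$label == LABEL_UNTRACKED, -(1:4)]) == SENTINEL))
})

test_that("sessions are bit-identical under the same seed", {
  a <- anthropometry(1.6)
  script <- session_script(c(3, 1), duration = 2)
  s1 <- generate_session(script, a, noise_model(0.02, 0.05), seed = 99)
  s2 <- generate_session(script, a, noise_model(0.02, 0.05), seed = 99)
  expect_identical(s1, s2)
})

test_that("camera views invert their calibrations exactly", {
  frames <- sample_frame_table(10)
  set.seed(23)
  calibs <- replicate(4, random_rigid(), simplify = FALSE)
  streams <- apply_camera_views(frames, calibs)
  expect_length(streams, 4L)
  coords <- function(fr) as.matrix(fr[, -(1:4)])
  for (k in 1:4) {
    back <- to_room_frame(streams[[k]], calibs[[k]])
    expect_lt(max(abs(coords(back) - coords(frames))), 1e-9)
  }
  ident <- apply_camera_views(frames, replicate(4, rigid_transform(diag(3)),
                                                simplify = FALSE))
  expect_equal(coords(ident[[1]]), coords(ident[[4]]))
  # a pure yaw camera leaves room Z untouched even before the round trip
  yawed <- apply_camera_views(frames, list(yaw_transform(90)))[[1]]
  expect_equal(coords(yawed)[, seq(3, 51, by = 3)],
               coords(frames)[, seq(3, 51, by = 3)])
})

test_that("benchmark splits subjects disjointly with the database class mix", {
  b <- generate_benchmark(n_subjects = 6, n_train = 4,
                          frames_per_subject = 300, seed = 5)
  expect_length(intersect(unique(b$train$subject_id),
                          unique(b$test$subject_id)), 0L)
  prop <- dataset_summary(c(b$train$y, b$test$y))$proportion
  expect_true(all(abs(prop - c(0.241, 0.388, 0.144, 0.227)) < 0.02))
})

test_that("a 1-nearest-neighbour oracle separates the easy benchmark", {
  b <- generate_benchmark(n_subjects = 6, n_train = 4,
                          frames_per_subject = 200, seed = 6)
  # plain 1-NN on the 10 selected features
  pred <- apply(b$test$X, 1, function(x) {
    b$train$y[which.min(colSums((t(b$train$X) - x)^2))]
  })
  expect_gte(mean(pred == b$test$y), 0.95)
})

test_that("generator output round-trips through the frame file format", {
  a <- anthropometry(1.81)
  ses <- generate_session(session_script(c(2, 4), duration = 1), a,
                          noise_model(0.01, 0.1), frame_rate = 10, seed = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_frames(ses$frames, path)
  back <- read_frames(path)
  expect_identical(back$subject_id, ses$frames$subject_id)
  expect_identical(back$tracked, ses$frames$tracked)
  expect_lt(max(abs(as.matrix(back[, -(1:4)]) -
                    as.matrix(ses$frames[, -(1:4)]))), 1e-9)
  # sentinel frames survive bit-exactly
  sent <- !back$tracked
  if (any(sent))
    expect_true(all(as.matrix(back[sent, -(1:4)]) == SENTINEL))
})
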