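test_that("write/read round trip is the identity on valid pose sequences", {
  sim <- synth_pose(behavior_script(kinematic = "turn_left"), n_frames = 300,
                    seed = 1)
  path <- withr::local_tempfile(fileext = ".h5")
  write_pose(sim$pose, path)
  back <- read_pose(path)
  expect_equal(back$keypoints, sim$pose$keypoints, tolerance = 1e-6)
  expect_equal(back$confidence, sim$pose$confidence, tolerance = 1e-12)
  expect_identical(back$n_frames, sim$pose$n_frames)
  expect_identical(back$fps, sim$pose$fps)
  expect_identical(back$keypoint_names, sim$pose$keypoint_names)

  # 1-frame sequence is a valid minimal file
  one <- pose_sequence(array(1, dim = c(1, 12, 2)), matrix(1, 1, 12))
  p1 <- withr::local_tempfile(fileext = ".h5")
  write_pose(one, p1)
  expect_identical(read_pose(p1)$n_frames, 1L)
})

test_that("two writes of the same sequence store identical payload datasets", {
  pose <- random_pose(50, seed = 42)
  p1 <- withr::local_tempfile(fileext = ".h5")
  p2 <- withr::local_tempfile(fileext = ".h5")
  write_pose(pose, p1)
  write_pose(pose, p2)
  expect_identical(rhdf5::h5read(p1, "poseest/points"),
                   rhdf5::h5read(p2, "poseest/points"))
  expect_identical(rhdf5::h5read(p1, "poseest/confidence"),
                   rhdf5::h5read(p2, "poseest/confidence"))
})

test_that("malformed files and invalid field values are rejected by name", {
  pose <- random_pose(20, seed = 7)
  path <- withr::local_tempfile(fileext = ".h5")
  write_pose(pose, path)
  # truncate the confidence dataset to 11 keypoints
  bad <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(bad)
  rhdf5::h5createGroup(bad, "poseest")
  rhdf5::h5write(pose$keypoints, bad, "poseest/points")
  rhdf5::h5write(pose$confidence[, 1:11], bad, "poseest/confidence")
  rhdf5::h5closeAll()
  expect_error(read_pose(bad), "poseest/confidence")

  bad2 <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(bad2)
  rhdf5::h5createGroup(bad2, "poseest")
  rhdf5::h5write(pose$keypoints, bad2, "poseest/points")
  rhdf5::h5closeAll()
  expect_error(read_pose(bad2), "poseest/confidence")
  expect_error(read_pose(withr::local_tempfile(fileext = ".h5")), "not found")

  expect_error(pose_sequence(pose$keypoints, pose$confidence * 2),
               "\\[0, 1\\]")
  expect_error(pose_sequence(pose$keypoints - 1000, pose$confidence),
               "non-negative")
  expect_error(pose_sequence(pose$keypoints, pose$confidence, fps = 0),
               "fps")
})

test_that("validate_pose coverage equals a brute-force count", {
  # half the frames confident, half not
  n <- 100
  conf <- rbind(matrix(0.2, n / 2, 12), matrix(0.9, n / 2, 12))
  kp <- array(1, dim = c(n, 12, 2))
  pose <- pose_sequence(kp, conf)
  rep <- validate_pose(pose, 0.3)
  expect_equal(unname(rep$keypoint_coverage), rep(0.5, 12))
  expect_equal(rep$coverage, 0.5)
  expect_equal(sum(rep$frame_valid), n / 2)

  # extremes
  pose1 <- pose_sequence(kp, matrix(1, n, 12))
  expect_equal(unname(validate_pose(pose1, 0.3)$keypoint_coverage),
               rep(1, 12))
  pose0 <- pose_sequence(kp, matrix(0, n, 12))
  expect_equal(validate_pose(pose0, 0.3)$coverage, 0)

  # brute force on random confidences
  pose_r <- random_pose(73, seed = 3)
  rep_r <- validate_pose(pose_r, 0.7)
  brute <- mean(apply(pose_r$confidence >= 0.7, 2, mean))
  expect_equal(rep_r$coverage, brute)
  for (k in 1:12)
    expect_equal(unname(rep_r$keypoint_coverage[k]),
                 mean(pose_r$confidence[, k] >= 0.7))
})

test_that("interpolation fills short gaps and invalidates long ones", {
  n <- 40
  kp <- array(0, dim = c(n, 12, 2))
  for (k in 1:12) for (d in 1:2) kp[, k, d] <- seq(10, 400, length.out = n)
  conf <- matrix(1, n, 12)
  conf[11:13, 5] <- 0.1   # 3-frame gap -> interpolated
  conf[20:27, 6] <- 0.1   # 8-frame gap -> invalid frames
  pose <- pose_sequence(kp, conf)
  pose$keypoints[11:13, 5, ] <- 0     # corrupt the gap
  out <- interpolate_pose(pose, 0.3, max_gap = 5)
  valid <- attr(out, "valid_mask")
  # linear fill restores the linear trajectory exactly
  expect_equal(out$keypoints[11:13, 5, 1], kp[11:13, 5, 1])
  expect_true(all(valid[11:13]))
  expect_false(any(valid[20:27]))
  expect_true(all(valid[-(20:27)]))
})
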