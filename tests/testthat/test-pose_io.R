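scene <- generate_scene(scene_params("readiness"))

test_that("pose files round-trip through write and read", {
  path <- withr::local_tempfile(fileext = ".json")
  write_pose_file(scene, path, render = 100)
  poses <- read_pose_file(path)
  expect_length(poses, 1)
  raw <- poses[[1]]
  expect_s3_class(raw, "raw_pose")
  # rendered hind-ankle pixel matches the writer's arithmetic exactly
  H <- round(2.2 * 100)
  expect_equal(unname(raw$keypoints["rankle", 1:2]),
               c(scene$posture$hind$ankle[1] * 100,
                 H - scene$posture$hind$ankle[2] * 100))
  expect_equal(unname(raw$keypoints["nose", "confidence"]), 0)
})

test_that("malformed and empty pose files behave as specified", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(version = 1.3,
                            people = list(list(pose_keypoints_2d = rep(0, 74)))),
                       path, auto_unbox = TRUE)
  expect_error(read_pose_file(path), "74", class = "limbstat_error_parse")

  writeLines('{"version": 1.3, "people": []}', path)
  expect_identical(read_pose_file(path), list())

  writeLines("not json at all {", path)
  expect_error(read_pose_file(path), class = "limbstat_error_parse")
  expect_error(read_pose_file("no/such/file.json"),
               class = "limbstat_error_io")
})

make_raw <- function(edit = identity, base = NULL) {
  if (is.null(base)) {
    path <- tempfile(fileext = ".json")
    on.exit(unlink(path))
    write_pose_file(scene, path, render = 100)
    base <- read_pose_file(path)[[1]]
  }
  kp <- base$keypoints
  raw_pose(edit(kp), source_id = "edited")
}

test_that("estimate_scale uses shank length over pixel knee-ankle distance", {
  kp <- matrix(0, 25, 3)
  kp[11, ] <- c(0, 0, 1)    # rknee (0-based 10)
  kp[12, ] <- c(0, 48, 1)   # rankle (0-based 11)
  raw <- raw_pose(kp)
  expect_equal(estimate_scale(raw, default_model), 0.01)
  kp[14, ] <- c(10, 0, 1)   # lknee (13)
  kp[15, ] <- c(10, 50, 1)  # lankle (14)
  expect_equal(estimate_scale(raw_pose(kp), default_model),
               mean(c(0.01, 0.48 / 50)))
  kp[15, ] <- c(10, 0, 1)   # coincident with lknee
  expect_error(estimate_scale(raw_pose(kp), default_model),
               class = "limbstat_error_degenerate_pose")
  kp[, 3] <- 0
  expect_error(estimate_scale(raw_pose(kp), default_model),
               class = "limbstat_error_insufficient_keypoints")
})

test_that("calibration recovers world coordinates at any render scale", {
  for (s in c(1, 7.3, 100, 541.7)) {
    path <- withr::local_tempfile(fileext = ".json")
    write_pose_file(scene, path, render = s, image_height = round(2.2 * s))
    pos <- calibrate(read_pose_file(path)[[1]], default_model,
                     calibration_config())
    for (side in c("hind", "front"))
      for (pt in c("hip", "knee", "ankle", "heel", "toe"))
        expect_lt(max(abs(pos[[side]][[pt]] - scene$posture[[side]][[pt]])),
                  1e-9)
    expect_lt(max(abs(pos$trunk_anchor - scene$posture$trunk_anchor)), 1e-9)
    expect_identical(pos$support_state, "double")
    expect_identical(pos$facing_sign, 1)
  }
})

test_that("already-metric y-up input with unit scale is an identity", {
  # build a raw pose whose 'pixels' are the world coordinates themselves
  kp <- matrix(0, 25, 3)
  put <- function(name, p) {
    i <- switch(name, neck = 2, midhip = 9, rhip = 10, rknee = 11,
                rankle = 12, lhip = 13, lknee = 14, lankle = 15,
                lbigtoe = 20, lheel = 22, rbigtoe = 23, rheel = 25)
    kp[i, ] <<- c(p, 0.95)
  }
  pos0 <- scene$posture
  midhip <- (pos0$hind$hip + pos0$front$hip) / 2
  put("neck", 2 * pos0$trunk_anchor - midhip); put("midhip", midhip)
  put("rhip", pos0$hind$hip); put("rknee", pos0$hind$knee)
  put("rankle", pos0$hind$ankle); put("rheel", pos0$hind$heel)
  put("rbigtoe", pos0$hind$toe)
  put("lhip", pos0$front$hip); put("lknee", pos0$front$knee)
  put("lankle", pos0$front$ankle); put("lheel", pos0$front$heel)
  put("lbigtoe", pos0$front$toe)
  pos <- calibrate(raw_pose(kp), default_model,
                   calibration_config(scale = 1, flip_y = FALSE))
  for (side in c("hind", "front"))
    for (pt in c("hip", "knee", "ankle", "heel", "toe"))
      expect_equal(pos[[side]][[pt]], pos0[[side]][[pt]], tolerance = 1e-12)
})

test_that("missing required keypoints raise insufficient-keypoints", {
  raw <- make_raw(function(kp) { kp["rankle", 3] <- 0; kp })
  expect_error(calibrate(raw, default_model), "rankle",
               class = "limbstat_error_insufficient_keypoints")
})

test_that("no grounded foot raises no-support", {
  # tilt both feet: heels stay, toes lifted far above tolerance (y-down px)
  raw <- make_raw(function(kp) {
    kp["rbigtoe", 2] <- kp["rbigtoe", 2] - 15  # 0.15 m at 100 px/m
    kp["lbigtoe", 2] <- kp["lbigtoe", 2] - 15
    kp
  })
  expect_error(calibrate(raw, default_model),
               class = "limbstat_error_no_support")
})

test_that("leg labeling is invariant to mirroring", {
  path <- withr::local_tempfile(fileext = ".json")
  write_pose_file(scene, path, render = 100)
  raw <- read_pose_file(path)[[1]]
  pos <- calibrate(raw, default_model)
  kp <- raw$keypoints
  kp[, 1] <- 500 - kp[, 1] # reflect all x-pixels
  mpos <- calibrate(raw_pose(kp), default_model)
  expect_identical(mpos$facing_sign, -1)
  # the same anatomical leg remains the hind leg: y-profiles agree and the
  # x-profiles are mirror images (up to the reflection offset)
  expect_equal(mpos$hind$knee[2], pos$hind$knee[2], tolerance = 1e-9)
  expect_equal(mpos$hind$knee[1] + pos$hind$knee[1], 500 * 0.01,
               tolerance = 1e-9)
})

test_that("select_person prefers the best-detected person", {
  path <- withr::local_tempfile(fileext = ".json")
  write_pose_file(scene, path, render = 100)
  raw <- read_pose_file(path)[[1]]
  weak <- raw$keypoints
  weak[, 3] <- weak[, 3] * 0.5
  doc <- list(version = 1.3, people = list(
    list(pose_keypoints_2d = as.vector(t(weak))),
    list(pose_keypoints_2d = as.vector(t(raw$keypoints)))))
  two <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, two, auto_unbox = TRUE, digits = NA)
  expect_message(best <- select_person(read_pose_file(two)), "2 people")
  expect_equal(unname(best$keypoints["rankle", 3]), 0.95)
  expect_error(select_person(list()), class = "limbstat_error_no_people")
})
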