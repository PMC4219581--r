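test_that("the default rig is valid and self-consistent", {
  rig <- build_rig(rig_config())
  expect_length(rig, 5L)
  for (cam in rig) {
    expect_s3_class(cam, "camera_matrix")
    expect_equal(qr(cam$P)$rank, 3L)
  }
  expect_error(rig_config(n_cameras = 1),
               class = "posture3d_precondition_error")

  # every default-scene marker is visible to at least two cameras
  for (mk in list(make_calibration_object(1)$world_points,
                  make_student_posture()$markers, make_mannequin(1))) {
    fr <- capture(rig, mk, 0)
    seen <- tapply(!fr$missing, fr$marker, sum)
    expect_true(all(seen >= 2))
  }

  # round trip: DLT from the synthetic calibration object reproduces
  # each generating matrix up to scale
  obj <- make_calibration_object(1)
  for (cam in rig) {
    cal <- dlt_calibrate(obj$world_points, project(cam, obj$world_points))
    expect_lt(min(norm(cal$camera$P - cam$P, "F"),
                  norm(cal$camera$P + cam$P, "F")), 1e-6)
  }
})

test_that("the calibration object is non-coplanar and deterministic", {
  obj <- make_calibration_object(5)
  M <- as.matrix(obj$world_points[, c("x", "y", "z")])
  expect_equal(nrow(M), 25L)
  expect_equal(qr(sweep(M, 2, colMeans(M)))$rank, 3L)

  expect_identical(make_calibration_object(5)$world_points,
                   obj$world_points)
  expect_false(identical(make_calibration_object(6)$world_points,
                         obj$world_points))

  # least-squares plane fit (SVD oracle): residuals far exceed 20 mm
  Mc <- sweep(M, 2, colMeans(M))
  normal <- svd(Mc)$v[, 3]
  rms_resid <- sqrt(mean((Mc %*% normal)^2))
  expect_gt(rms_resid, 20)
})

test_that("mannequin positions are rigid transforms of one template", {
  p1 <- make_mannequin(1)
  M1 <- as.matrix(p1[, c("x", "y", "z")])
  hip <- colMeans(M1[p1$name %in% c("hip_left", "hip_right"), ])

  rot_about_hip <- function(deg) {
    t <- deg * pi / 180
    R <- matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
    sweep(sweep(M1, 2, hip) %*% t(R), 2, hip, `+`)
  }
  M3 <- as.matrix(make_mannequin(3)[, c("x", "y", "z")])
  expect_equal(M3, rot_about_hip(180), ignore_attr = TRUE,
               tolerance = 1e-9)
  M4 <- as.matrix(make_mannequin(4)[, c("x", "y", "z")])
  expect_equal(M4, rot_about_hip(135), ignore_attr = TRUE,
               tolerance = 1e-9)

  D1 <- as.matrix(dist(M1))
  for (p in 2:7) {
    Dp <- as.matrix(dist(as.matrix(make_mannequin(p)[, c("x", "y", "z")])))
    expect_lt(max(abs(Dp - D1)), 1e-9)
  }
  expect_error(make_mannequin(8), "position")
})

test_that("student forward kinematics honours its lateral parameters", {
  neutral <- make_student_posture()
  expect_equal(unname(unclass(neutral$truth)[c("HLB", "NLB", "HR", "TTR")]),
               c(0, 0, 0, 0), tolerance = 1e-9)

  bent <- make_student_posture(lateral_bend = 7, head_rotation = 11,
                               trunk_rotation = 9)
  mirrored <- make_student_posture(lateral_bend = -7, head_rotation = -11,
                                   trunk_rotation = -9)
  lat <- c("HLB", "NLB", "HR", "TTR")
  expect_equal(unclass(mirrored$truth)[lat], -unclass(bent$truth)[lat],
               tolerance = 1e-9)
  expect_true(all(abs(unclass(bent$truth)[lat]) > 1))

  expect_error(make_student_posture(hf = 170), "unreachable")
})

test_that("capture is deterministic and honours visibility masks", {
  rig <- build_rig(rig_config())
  po <- make_student_posture()

  exact <- capture(rig, po$markers, 0)
  pr1 <- project(rig$cam1, po$markers, bounds_check = TRUE)
  sub <- exact[exact$camera_id == "cam1", ]
  expect_equal(sub$u, pr1$u)
  expect_equal(sub$v, pr1$v)

  a <- capture(rig, po$markers, 0.5, seed = 33)
  b <- capture(rig, po$markers, 0.5, seed = 33)
  expect_identical(a, b)
  c <- capture(rig, po$markers, 0.5, seed = 34)
  expect_false(identical(a, c))

  masked <- capture(rig, po$markers, 0, visibility = list(sternum = "cam2"))
  st <- masked[masked$marker == "sternum", ]
  expect_equal(sum(st$missing), 4L)
  expect_false(st$missing[st$camera_id == "cam2"])
})

test_that("rendered disks are detected at sub-pixel accuracy", {
  skip_if_not_installed("EBImage")
  rig <- build_rig(rig_config())

  # single marker on the optical axis of the straight-side camera
  wp <- world_points("m", 0, 0, 850)
  img <- render_frame(rig$cam2, wp)
  expected <- project(rig$cam2, wp, bounds_check = TRUE)
  det <- detect_centroids(img, expected = expected)
  expect_equal(nrow(det), 1L)
  expect_lt(sqrt((det$u - expected$u)^2 + (det$v - expected$v)^2), 0.1)

  # empty scene detects nothing
  blank <- matrix(0, 480, 640)
  expect_equal(nrow(detect_centroids(blank)), 0L)

  # full 9-marker render from an oblique camera: all centroids recovered
  po <- make_student_posture()
  exp9 <- project(rig$cam1, po$markers, bounds_check = TRUE)
  det9 <- detect_centroids(render_frame(rig$cam1, po$markers),
                           expected = exp9)
  expect_equal(nrow(det9), 9L)
  errs <- sqrt((det9$u - exp9$u)^2 + (det9$v - exp9$v)^2)
  expect_true(all(errs < 0.25))
  expect_length(attr(det9, "ambiguous"), 0L)

  # near-superimposed markers from the straight-side view are flagged
  exp2 <- project(rig$cam2, po$markers, bounds_check = TRUE)
  det2 <- detect_centroids(render_frame(rig$cam2, po$markers),
                           expected = exp2)
  expect_gt(length(attr(det2, "ambiguous")), 0L)
})

test_that("repeated-measures simulation reflects its variance components", {
  pure <- simulate_repeated_measures(10, 3, var_subject = 25,
                                     var_error = 0, seed = 2)
  spread <- tapply(pure$value, pure$subject, function(v) diff(range(v)))
  expect_true(all(spread == 0))
  expect_equal(icc_oneway(pure$subject, pure$value)$coefficient, 1)

  flat <- vapply(1:50, function(s) {
    d <- simulate_repeated_measures(24, 3, var_subject = 0,
                                    var_error = 10, seed = s)
    icc_oneway(d$subject, d$value)$coefficient
  }, numeric(1))
  expect_lt(mean(flat), 0.15)

  expect_identical(simulate_repeated_measures(seed = 8),
                   simulate_repeated_measures(seed = 8))
})

test_that("the full loop recovers generated angles through calibration", {
  rig <- build_rig(rig_config())
  obj <- make_calibration_object(1)
  calib_frame <- capture(rig, obj$world_points, 0)
  cams <- lapply(names(rig), function(id) {
    sub <- calib_frame[calib_frame$camera_id == id, ]
    dlt_calibrate(obj$world_points,
                  image_points(sub$marker, sub$u, sub$v),
                  id)$camera
  })
  names(cams) <- names(rig)

  po <- make_student_posture()
  ms <- reconstruct_markers(capture(cams, po$markers, 0), cams,
                            placement_model("student"))
  ang <- compute_posture_angles(derive_landmarks(ms))
  expect_equal(unclass(ang)[1:9], unclass(po$truth)[1:9],
               tolerance = 1e-6)
})
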