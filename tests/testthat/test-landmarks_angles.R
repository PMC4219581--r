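student <- placement_model("student")

# minimal hand-built student marker set: upright trunk, head directly
# above the OCI, everything symmetric
upright_markers <- function() {
  world_points(
    c("canthus_left", "canthus_right", "tragus_left", "tragus_right",
      "c7", "t5", "trochanter_left", "trochanter_right", "sternum"),
    x = c(-30, 30, -70, 70, 0, 0, -150, 150, 0),
    y = c(0, 0, 0, 0, 0, 0, 0, 0, 180),
    z = c(1700, 1700, 1070, 1070, 950, 800, 500, 500, 800))
}

test_that("derived landmarks are the anatomical midpoints", {
  lf <- derive_landmarks(upright_markers(), student)
  expect_equal(lf$points$cyclops, c(0, 0, 1700))
  expect_equal(lf$points$oci, c(0, 0, 1070))
  expect_equal(lf$points$mid_trochanter, c(0, 0, 500))
  expect_equal(unname(lf$axes), diag(3))
})

test_that("the local frame stays orthonormal under a tilted pelvis", {
  mk <- upright_markers()
  i <- match(c("trochanter_left", "trochanter_right"), mk$name)
  # pelvis line tilted 10 degrees out of horizontal
  mk$z[i] <- 500 + c(-150, 150) * tan(10 * pi / 180)
  lf <- derive_landmarks(mk, student)
  A <- lf$axes
  expect_equal(unname(A[3, "X"]), 0)                # X projected horizontal
  expect_equal(crossprod(A), diag(3), ignore_attr = TRUE,
               tolerance = 1e-12)
  # right-handedness: X x Y = Z
  expect_equal(as.numeric(c(
    A[2, 1] * A[3, 2] - A[3, 1] * A[2, 2],
    A[3, 1] * A[1, 2] - A[1, 1] * A[3, 2],
    A[1, 1] * A[2, 2] - A[2, 1] * A[1, 2])), A[, 3], tolerance = 1e-12)
})

test_that("missing markers propagate without aborting the other angles", {
  mk <- upright_markers()
  expect_error(derive_landmarks(mk[mk$name != "trochanter_left", ], student),
               "no local frame")

  lf <- derive_landmarks(mk[mk$name != "canthus_left", ], student)
  expect_true("cyclops" %in% lf$missing)
  ang <- compute_posture_angles(lf)
  expect_true(all(is.na(ang[c("HF", "CC", "HR")])))
  expect_false(anyNA(ang[c("NF", "CT", "TF", "HLB", "NLB", "TTR")]))
})

test_that("canonical configurations give the expected angles", {
  ang <- compute_posture_angles(derive_landmarks(upright_markers(), student))
  expect_equal(unname(ang["HF"]), 0)            # Cyclops above OCI
  expect_equal(unname(ang["HLB"]), 0)
  expect_equal(unname(ang["NLB"]), 0)
  expect_equal(unname(ang["TTR"]), 0)

  # collinear Cyclops-OCI-C7 gives a straight cranio-cervical angle
  expect_equal(unname(ang["CC"]), 180)
})

test_that("all nine angles match the independent brute-force oracle", {
  for (s in 1:50) {
    mk <- random_posture(s)
    ang <- compute_posture_angles(derive_landmarks(mk, student))
    expect_equal(unclass(ang)[1:9], oracle_angles(mk), tolerance = 1e-9)
  }
})

test_that("sagittal-only forward kinematics round-trips the targets", {
  for (targ in list(c(70, 45, -15), c(66, 20, -22), c(80, 60, 5))) {
    po <- make_student_posture(hf = targ[1], nf = targ[2], tf = targ[3])
    ang <- compute_posture_angles(derive_landmarks(po$markers, student))
    expect_equal(unname(ang["HF"]), targ[1], tolerance = 1e-6)
    expect_equal(unname(ang["NF"]), targ[2], tolerance = 1e-6)
    expect_equal(unname(ang["TF"]), targ[3], tolerance = 1e-6)
    # in pure sagittal geometry CC reconciles with HF and NF
    expect_equal(unname(ang["CC"]), 180 + targ[2] - targ[1],
                 tolerance = 1e-9)
  }
})

test_that("angles are invariant under rigid motion of the subject", {
  po <- make_student_posture(lateral_bend = 6, head_rotation = -12,
                             trunk_rotation = 8)
  base <- compute_posture_angles(derive_landmarks(po$markers, student))
  for (s in 1:10) {
    set.seed(s)
    mk <- transform_markers(po$markers, rot_deg = runif(1, -180, 180),
                            shift = rnorm(3, 0, 500))
    ang <- compute_posture_angles(derive_landmarks(mk, student))
    expect_equal(unclass(ang)[1:9], unclass(base)[1:9], tolerance = 1e-9)
  }
})

test_that("sagittal-plane mirroring negates the lateral and rotational angles", {
  for (s in 1:10) {
    mk <- random_posture(s + 500)
    ang <- unclass(compute_posture_angles(derive_landmarks(mk, student)))
    mir <- unclass(compute_posture_angles(
      derive_landmarks(mirror_markers(mk), student)))
    lat <- c("HLB", "NLB", "HR", "TTR")
    sag <- c("HF", "NF", "CC", "CT", "TF")
    expect_equal(mir[lat], -ang[lat], tolerance = 1e-9)
    expect_equal(mir[sag], ang[sag], tolerance = 1e-9)
  }
})

test_that("corrected NLB is immune to the frontal-projection fault", {
  # pure lateral bend: corrected equals the frontal-projected NLB
  po <- make_student_posture(nf = 0, lateral_bend = 8)
  lf <- derive_landmarks(po$markers, student)
  expect_equal(nlb_sagittal_corrected(lf),
               unname(unclass(po$truth)["NLB"]), tolerance = 1e-9)

  # pure sagittal flexion: no lateral deviation at all
  po0 <- make_student_posture(nf = 30, lateral_bend = 0)
  expect_equal(nlb_sagittal_corrected(derive_landmarks(po0$markers, student)),
               0, tolerance = 1e-9)

  # combined: the frontal projection overstates the 5-degree bend,
  # the corrected angle recovers it
  po2 <- make_student_posture(nf = 30, lateral_bend = 5)
  lf2 <- derive_landmarks(po2$markers, student)
  projected <- unname(unclass(po2$truth)["NLB"])
  expect_gt(abs(projected - 5), 0.25)
  expect_equal(nlb_sagittal_corrected(lf2), 5, tolerance = 0.5)
})

test_that("trial validation separates out-of-range from missing", {
  po <- make_student_posture()
  ang <- po$truth
  expect_true(validate_trial(ang)$pass)

  wild <- ang
  wild["HF"] <- 200
  v <- validate_trial(wild)
  expect_false(v$pass)
  expect_equal(unname(v$status["HF"]), "fail")

  gone <- ang
  gone["CT"] <- NA_real_
  v2 <- validate_trial(gone)
  expect_false(v2$pass)
  expect_equal(unname(v2$status["CT"]), "missing")
  expect_true(validate_trial(gone, required = setdiff(names(v2$status),
                                                      "CT"))$pass)
})
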