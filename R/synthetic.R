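#' Virtual five-camera rig configuration
#'
#' Describes a multi-camera rig of the kind used for classroom posture
#' capture: low-cost 640x480 CMOS cameras mounted on two cross-bars that
#' flank the seated subject, every camera aimed at the centre of the
#' capture volume.  The default geometry places three cameras on the
#' right bar (x = +2400 mm, y = -1500/0/1500) and two on the left bar
#' (x = -2400 mm, y = -900/900) at heights near 1.3 m, with a 1000 px
#' focal length (a 6 mm lens on a 6 um-pixel sensor).
#'
#' @param n_cameras number of cameras, >= 2 (default 5).
#' @param positions optional n x 3 matrix of camera positions (mm);
#'   defaults to the cross-bar layout above (first `n_cameras` of 5).
#' @param target aim point of all cameras (mm), default trunk centre
#'   `c(0, 0, 850)`.
#' @param focal_px focal length in pixels.
#' @param resolution sensor c(width, height) px.
#' @param jitter_mm sd of Gaussian jitter added to camera positions
#'   (deterministic per `seed`); 0 disables.
#' @param seed RNG seed for the jitter.
#' @return list of class `rig_config`.
#' @export
rig_config <- function(n_cameras = 5L, positions = NULL,
                       target = c(0, 0, 850), focal_px = 1000,
                       resolution = c(640L, 480L), jitter_mm = 0,
                       seed = 1L) {
  n_cameras <- as.integer(n_cameras)
  if (n_cameras < 2L)
    stop_precondition("a rig needs at least 2 cameras to triangulate")
  if (is.null(positions)) {
    default_pos <- rbind(c(2400, -1500, 1350),
                         c(2400,     0, 1250),
                         c(2400,  1500, 1350),
                         c(-2400, -900, 1300),
                         c(-2400,  900, 1300))
    if (n_cameras > nrow(default_pos))
      stop("default cross-bar layout provides at most 5 cameras")
    positions <- default_pos[seq_len(n_cameras), , drop = FALSE]
  } else {
    positions <- matrix(as.numeric(positions), ncol = 3L)
    if (nrow(positions) != n_cameras)
      stop("positions must have one row per camera")
  }
  structure(list(n_cameras = n_cameras, positions = positions,
                 target = as.numeric(target), focal_px = focal_px,
                 resolution = as.integer(resolution),
                 jitter_mm = jitter_mm, seed = seed),
            class = "rig_config")
}

# ideal pinhole camera looking from `position` at `target`, image v-axis
# pointing downward, principal point at the sensor centre
lookat_camera <- function(position, target, focal_px, resolution,
                          camera_id) {
  fwd <- unit(target - position)
  up <- c(0, 0, 1)
  if (abs(sum(fwd * up)) > 0.999) up <- c(0, 1, 0)   # looking straight down
  right <- unit(cross3(fwd, up))
  down <- cross3(fwd, right)
  R <- rbind(right, down, fwd)
  K <- matrix(c(focal_px, 0, 0,
                0, focal_px, 0,
                (resolution[1L] - 1) / 2, (resolution[2L] - 1) / 2, 1),
              3L, 3L)
  P <- K %*% cbind(R, -R %*% position)
  camera_matrix(P, camera_id, resolution, ref_point = target)
}

#' Build the virtual camera rig
#'
#' Deterministically constructs one [camera_matrix()] per camera from the
#' configuration.  A camera whose aim point does not fall on its own
#' sensor (i.e. facing away from the capture volume) is a configuration
#' error.
#'
#' @param config a [rig_config()].
#' @return named list of [camera_matrix()] (`cam1`, `cam2`, ...).
#' @export
build_rig <- function(config = rig_config()) {
  pos <- config$positions
  if (config$jitter_mm > 0)
    pos <- pos + with_seed(config$seed,
      matrix(stats::rnorm(length(pos), 0, config$jitter_mm), nrow(pos)))
  cams <- lapply(seq_len(config$n_cameras), function(i)
    lookat_camera(pos[i, ], config$target, config$focal_px,
                  config$resolution, sprintf("cam%d", i)))
  names(cams) <- vapply(cams, `[[`, "", "camera_id")
  ctr <- world_points("centre", config$target[1L], config$target[2L],
                      config$target[3L])
  for (cam in cams) {
    pr <- project(cam, ctr, bounds_check = TRUE)
    if (pr$missing)
      stop_degenerate("camera ", cam$camera_id,
                      " does not view the capture volume centre")
  }
  cams
}

#' Synthetic calibration object
#'
#' Emulates a board of 25 wooden dowels of varying lengths with a
#' reflective sphere on each tip: a 5x5 grid (150 mm pitch) with dowel
#' heights drawn uniformly between 50 and 400 mm above a board at
#' z = 600 mm.  The height variation makes the point set non-coplanar by
#' construction.  Deterministic per seed.
#'
#' @param seed RNG seed.
#' @param board_z board height above the floor (mm).
#' @return list of class `calibration_object` with `world_points` (a
#'   25-row [world_points()]) and `description`.
#' @export
make_calibration_object <- function(seed = 1L, board_z = 600) {
  grid <- expand.grid(x = seq(-300, 300, by = 150),
                      y = seq(-300, 300, by = 150))
  heights <- with_seed(seed, stats::runif(25L, 50, 400))
  wp <- world_points(sprintf("dowel_%02d", 1:25),
                     grid$x, grid$y, board_z + heights)
  structure(list(world_points = wp,
                 description = sprintf(
                   "5x5 dowel board, z %.0f-%.0f mm (seed %d)",
                   board_z + 50, board_z + 400, seed)),
            class = "calibration_object")
}

# canonical 14-marker mannequin template, facing +Y, hips centred above
# the origin at table height; coordinates in mm
mannequin_template <- function() {
  world_points(
    c("canthus_left", "canthus_right", "tragus_left", "tragus_right",
      "ac_joint_left", "ac_joint_right", "shoulder_left",
      "shoulder_right", "hip_left", "hip_right", "c7", "t5", "t8",
      "sternum"),
    x = c(-31, 31, -70, 70, -150, 150, -180, 180, -140, 140, 0, 0, 0, 0),
    y = c(40, 40, -20, -20, -30, -30, -10, -10, 0, 0, -70, -90, -95, 60),
    z = c(1310, 1310, 1300, 1300, 1160, 1160, 1150, 1150, 700, 700,
          1180, 1050, 980, 1100))
}

#' Synthetic mannequin in one of seven captured positions
#'
#' A rigid 14-marker torso template placed in the seven poses used for
#' validity testing: (1) facing the Y-plane; (2) facing the X-plane;
#' (3) rotated 180 deg from position 1; (4) rotated 135 deg
#' counter-clockwise; (5) tilted forward; (6) rotated 45 deg and tilted
#' forward-left; (7) tilted forward-left.  All poses are rigid transforms
#' of the same template (tilts of `tilt_deg` about a horizontal axis
#' through the hip centre), so inter-marker distances are identical
#' across positions.
#'
#' @param position integer 1..7.
#' @param tilt_deg forward/lateral tilt used by positions 5-7 (degrees).
#' @return a 14-row [world_points()].
#' @export
make_mannequin <- function(position = 1L, tilt_deg = 15) {
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > 7L)
    stop("mannequin position must be 1..7")
  tpl <- mannequin_template()
  M <- as.matrix(tpl[, c("x", "y", "z")])
  hip_ctr <- colMeans(M[tpl$name %in% c("hip_left", "hip_right"), ])
  rot_deg <- c(0, -90, 180, 135, 0, 45, 0)[position]
  R <- rotz(rot_deg)
  tilt_towards <- function(M, h, deg) {      # tilt top towards unit h
    axis <- cross3(c(0, 0, 1), h)
    t(apply(M, 1L, function(p)
      hip_ctr + rotate_about(p - hip_ctr, axis, deg2rad(deg))))
  }
  M <- t(R %*% (t(M) - hip_ctr) + hip_ctr)
  fwd <- as.numeric(R %*% c(0, 1, 0))
  left <- as.numeric(R %*% c(-1, 0, 0))
  if (position == 5L) M <- tilt_towards(M, fwd, tilt_deg)
  if (position %in% c(6L, 7L))
    M <- tilt_towards(M, unit(fwd + left), tilt_deg)
  world_points(tpl$name, M[, 1L], M[, 2L], M[, 3L])
}

#' Default anthropometry for the synthetic student
#'
#' Segment lengths in millimetres used by [make_student_posture()].  Only
#' angle recovery is ever asserted downstream, so these set the scale of
#' the scene, not its correctness.
#'
#' @param trunk_mm C7 to mid-trochanter distance.
#' @param neck_mm C7 to OCI distance.
#' @param head_mm OCI to Cyclops distance.
#' @param inter_tragus_mm,inter_canthus_mm,inter_trochanter_mm marker
#'   separations.
#' @param t5_drop_mm distance from C7 to T5 along the trunk line.
#' @param chest_depth_mm T5 to sternum distance (anterior).
#' @param seat_z_mm height of the trochanters above the floor.
#' @return named list.
#' @export
anthropometry <- function(trunk_mm = 450, neck_mm = 120, head_mm = 110,
                          inter_tragus_mm = 140, inter_canthus_mm = 62,
                          inter_trochanter_mm = 300, t5_drop_mm = 150,
                          chest_depth_mm = 180, seat_z_mm = 500) {
  out <- as.list(environment())
  if (any(unlist(out) <= 0)) stop("segment lengths must be positive")
  out
}

#' Forward-kinematic synthetic student posture
#'
#' Builds the 9-marker student marker set whose sagittal angles are, by
#' construction, exactly the requested targets: the trunk line is tilted
#' `tf` from the vertical (negative posterior), the neck line `nf` and the
#' head line `hf`.  Optional out-of-sagittal perturbations are applied as
#' forward rotations: `lateral_bend` tilts the neck-plus-head segment out
#' of the sagittal plane about the neck's anterior normal at C7 (positive
#' to the subject's right), `head_rotation` turns the head about the neck
#' axis and `trunk_rotation` turns the sternum about the trunk axis
#' (positive to the right in the reported angle conventions).  With all
#' three at zero the frontal/transverse angles are exactly zero.
#'
#' The returned ground-truth angles are computed from the generated
#' markers themselves (via [derive_landmarks()] and
#' [compute_posture_angles()]) so downstream recovery tests compare
#' against the geometry actually generated.
#'
#' @param hf,nf,tf sagittal targets in degrees (head/neck flexion in
#'   [0, 120]/[0, 90], trunk flexion in [-60, 60]).
#' @param lateral_bend,head_rotation,trunk_rotation out-of-sagittal
#'   perturbations in degrees (each limited to +/-45).
#' @param anthro an [anthropometry()] list.
#' @return list of class `student_posture`: `markers` (9-row
#'   [world_points()]), `truth` (a `posture_angles` vector),
#'   `targets` (the requested parameters).
#' @export
make_student_posture <- function(hf = 70, nf = 45, tf = -15,
                                 lateral_bend = 0, head_rotation = 0,
                                 trunk_rotation = 0,
                                 anthro = anthropometry()) {
  if (hf < 0 || hf > 120 || nf < 0 || nf > 90 || tf < -60 || tf > 60 ||
      abs(lateral_bend) > 45 || abs(head_rotation) > 45 ||
      abs(trunk_rotation) > 45)
    stop("unreachable posture: targets outside the plausible ranges")
  xhat <- c(1, 0, 0)
  mid_troch <- c(0, 0, anthro$seat_z_mm)
  troch_l <- mid_troch - xhat * anthro$inter_trochanter_mm / 2
  troch_r <- mid_troch + xhat * anthro$inter_trochanter_mm / 2
  tfr <- deg2rad(tf); nfr <- deg2rad(nf); hfr <- deg2rad(hf)
  beta <- deg2rad(lateral_bend)

  trunk_dir <- c(0, sin(tfr), cos(tfr))
  c7 <- mid_troch + anthro$trunk_mm * trunk_dir
  t5 <- c7 - anthro$t5_drop_mm * trunk_dir
  trunk_normal <- c(0, cos(tfr), -sin(tfr))          # anterior
  sternum <- t5 + anthro$chest_depth_mm * trunk_normal
  if (trunk_rotation != 0)
    sternum <- t5 + rotate_about(sternum - t5, trunk_dir,
                                 -deg2rad(trunk_rotation))

  neck_dir0 <- c(0, sin(nfr), cos(nfr))
  neck_normal <- c(0, cos(nfr), -sin(nfr))           # anterior, _|_ neck
  neck_dir <- rotate_about(neck_dir0, neck_normal, beta)
  oci <- c7 + anthro$neck_mm * neck_dir

  head_dir <- rotate_about(c(0, sin(hfr), cos(hfr)), neck_normal, beta)
  ear_axis <- rotate_about(xhat, neck_normal, beta)
  if (head_rotation != 0) {
    g <- -deg2rad(head_rotation)
    head_dir <- rotate_about(head_dir, neck_dir, g)
    ear_axis <- rotate_about(ear_axis, neck_dir, g)
  }
  cyclops <- oci + anthro$head_mm * head_dir
  markers <- world_points(
    c("canthus_left", "canthus_right", "tragus_left", "tragus_right",
      "c7", "t5", "trochanter_left", "trochanter_right", "sternum"),
    x = c(cyclops[1] - ear_axis[1] * anthro$inter_canthus_mm / 2,
          cyclops[1] + ear_axis[1] * anthro$inter_canthus_mm / 2,
          oci[1] - ear_axis[1] * anthro$inter_tragus_mm / 2,
          oci[1] + ear_axis[1] * anthro$inter_tragus_mm / 2,
          c7[1], t5[1], troch_l[1], troch_r[1], sternum[1]),
    y = c(cyclops[2] - ear_axis[2] * anthro$inter_canthus_mm / 2,
          cyclops[2] + ear_axis[2] * anthro$inter_canthus_mm / 2,
          oci[2] - ear_axis[2] * anthro$inter_tragus_mm / 2,
          oci[2] + ear_axis[2] * anthro$inter_tragus_mm / 2,
          c7[2], t5[2], troch_l[2], troch_r[2], sternum[2]),
    z = c(cyclops[3] - ear_axis[3] * anthro$inter_canthus_mm / 2,
          cyclops[3] + ear_axis[3] * anthro$inter_canthus_mm / 2,
          oci[3] - ear_axis[3] * anthro$inter_tragus_mm / 2,
          oci[3] + ear_axis[3] * anthro$inter_tragus_mm / 2,
          c7[3], t5[3], troch_l[3], troch_r[3], sternum[3]))
  frame <- derive_landmarks(markers, placement_model("student"))
  truth <- compute_posture_angles(frame)
  structure(list(markers = markers, truth = truth,
                 targets = list(hf = hf, nf = nf, tf = tf,
                                lateral_bend = lateral_bend,
                                head_rotation = head_rotation,
                                trunk_rotation = trunk_rotation)),
            class = "student_posture")
}

#' Capture a synchronised multi-camera frame
#'
#' Projects the world markers through every camera, adds i.i.d. Gaussian
#' pixel noise, and emits out-of-frame or occluded markers as missing
#' (the "none" value).  Deterministic for a given seed.
#'
#' @param cameras named list of [camera_matrix()].
#' @param markers a [world_points()] set.
#' @param noise_px Gaussian pixel noise sd (0 = exact projections).
#' @param visibility optional named list: marker name -> character vector
#'   of camera ids that can see it (all others record it missing).
#' @param seed RNG seed for the noise.
#' @param frame_id identifier stored as an attribute.
#' @return long `data.frame` of class `marker_observations` with columns
#'   `camera_id`, `marker`, `u`, `v`, `missing`.
#' @export
capture <- function(cameras, markers, noise_px = 0, visibility = NULL,
                    seed = 1L, frame_id = 1L) {
  rows <- with_seed(seed, lapply(names(cameras), function(id) {
    pr <- project(cameras[[id]], markers, bounds_check = TRUE)
    if (noise_px > 0) {
      n <- nrow(pr)
      pr$u <- pr$u + stats::rnorm(n, 0, noise_px)
      pr$v <- pr$v + stats::rnorm(n, 0, noise_px)
      res <- cameras[[id]]$resolution
      oob <- !pr$missing & (pr$u < 0 | pr$u > res[1L] - 1L |
                              pr$v < 0 | pr$v > res[2L] - 1L)
      pr$missing <- pr$missing | oob
      pr$u[pr$missing] <- NA_real_
      pr$v[pr$missing] <- NA_real_
    }
    if (!is.null(visibility)) {
      for (mk in names(visibility)) {
        i <- which(pr$marker == mk)
        if (length(i) && !(id %in% visibility[[mk]])) {
          pr$missing[i] <- TRUE
          pr$u[i] <- NA_real_; pr$v[i] <- NA_real_
        }
      }
    }
    data.frame(camera_id = id, marker = pr$marker, u = pr$u, v = pr$v,
               missing = pr$missing, stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "frame_id") <- frame_id
  class(out) <- c("marker_observations", "data.frame")
  out
}

#' Simulate repeated measurements of one angle
#'
#' One-way random-effects generating model: value_ij = mu + b_i + e_ij
#' with b_i ~ N(0, var_subject) and e_ij ~ N(0, var_error).  Used to
#' parameterise reliability simulations from published variance
#' components.
#'
#' @param n_subjects number of subjects.
#' @param k occasions per subject (2 or 3).
#' @param var_subject,var_error variance components (>= 0).
#' @param grand_mean mu.
#' @param seed RNG seed.
#' @return `data.frame` with columns `subject`, `occasion`, `value`.
#' @export
simulate_repeated_measures <- function(n_subjects = 24L, k = 3L,
                                       var_subject = 1, var_error = 1,
                                       grand_mean = 0, seed = 1L) {
  if (var_subject < 0 || var_error < 0) stop("variances must be >= 0")
  if (!k %in% c(2L, 3L)) stop("k occasions must be 2 or 3")
  with_seed(seed, {
    b <- stats::rnorm(n_subjects, 0, sqrt(var_subject))
    e <- stats::rnorm(n_subjects * k, 0, sqrt(var_error))
    data.frame(subject = rep(sprintf("s%02d", seq_len(n_subjects)),
                             each = k),
               occasion = rep(seq_len(k), n_subjects),
               value = grand_mean + rep(b, each = k) + e,
               stringsAsFactors = FALSE)
  })
}

#' Two cameras subtending a given line-of-sight angle
#'
#' Places two cameras in the horizontal plane so that their rays to
#' `point` meet at `angle_deg`.  Used to study how depth accuracy
#' degrades at extreme line-of-sight angles (a dorsal midline marker seen
#' from side-flanking bars approaches 180 deg).
#'
#' @param angle_deg desired inter-camera ray angle at the point.
#' @param point the world point of interest (mm).
#' @param distance_mm camera-to-point distance.
#' @param focal_px,resolution sensor model.
#' @return named list of two [camera_matrix()] objects.
#' @export
make_los_pair <- function(angle_deg, point = c(0, 0, 850),
                          distance_mm = 2400, focal_px = 1000,
                          resolution = c(640L, 480L)) {
  half <- deg2rad(angle_deg) / 2
  offs <- list(c(sin(half), cos(half), 0), c(-sin(half), cos(half), 0))
  cams <- lapply(seq_along(offs), function(i)
    lookat_camera(point + distance_mm * offs[[i]], point, focal_px,
                  resolution, sprintf("los%d", i)))
  names(cams) <- c("los1", "los2")
  cams
}
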