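# Independent brute-force oracle for the nine postural angles: standalone
# explicit arccos/atan2 per angle definition, sharing no code with the
# package implementation.
oracle_angles <- function(markers) {
  mk <- lapply(stats::setNames(seq_len(nrow(markers)), markers$name),
               function(i) as.numeric(markers[i, c("x", "y", "z")]))
  cyc <- (mk$canthus_left + mk$canthus_right) / 2
  oci <- (mk$tragus_left + mk$tragus_right) / 2
  mt <- (mk$trochanter_left + mk$trochanter_right) / 2
  xv <- mk$trochanter_right - mk$trochanter_left
  X <- c(xv[1], xv[2], 0) / sqrt(xv[1]^2 + xv[2]^2)
  Y <- c(-X[2], X[1], 0)                       # Z x X written out
  Z <- c(0, 0, 1)
  dot <- function(u, v) sum(u * v)
  nrm <- function(u) sqrt(sum(u^2))
  ang3 <- function(u, v)
    acos(max(-1, min(1, dot(u, v) / (nrm(u) * nrm(v))))) * 180 / pi

  v_hf <- cyc - oci
  v_nf <- oci - mk$c7
  v_tf <- mk$c7 - mt
  v_hlb <- mk$tragus_right - oci
  v_hr <- cyc - oci
  v_ttr <- mk$t5 - mk$sternum

  c(HF = ang3(v_hf, Z),
    NF = ang3(v_nf, Z),
    CC = ang3(cyc - oci, mk$c7 - oci),
    CT = ang3(oci - mk$c7, mk$t5 - mk$c7),
    TF = ang3(v_tf, Z) * (if (dot(v_tf, Y) < 0) -1 else 1),
    HLB = atan2(-dot(v_hlb, Z), dot(v_hlb, X)) * 180 / pi,
    NLB = atan2(dot(v_nf, X), dot(v_nf, Z)) * 180 / pi,
    HR = atan2(dot(v_hr, X), dot(v_hr, Y)) * 180 / pi,
    TTR = atan2(-dot(v_ttr, X), -dot(v_ttr, Y)) * 180 / pi)
}

# random posture with out-of-sagittal components, rigidly displaced, for
# property sweeps; deterministic per seed
random_posture <- function(seed) {
  set.seed(seed)
  po <- make_student_posture(
    hf = runif(1, 40, 100), nf = runif(1, 20, 70),
    tf = runif(1, -30, 10), lateral_bend = runif(1, -10, 10),
    head_rotation = runif(1, -20, 20), trunk_rotation = runif(1, -15, 15))
  transform_markers(po$markers, rot_deg = runif(1, -180, 180),
                    shift = c(runif(2, -150, 150), runif(1, -50, 50)))
}

# rigid transform of a marker set: rotation about the vertical axis then
# translation
transform_markers <- function(markers, rot_deg = 0, shift = c(0, 0, 0)) {
  t <- rot_deg * pi / 180
  R <- matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  M <- as.matrix(markers[, c("x", "y", "z")]) %*% t(R)
  world_points(markers$name, M[, 1] + shift[1], M[, 2] + shift[2],
               M[, 3] + shift[3])
}

# mirror a student marker set across the sagittal plane (x -> -x with
# left/right labels swapped so the set stays anatomically labelled)
mirror_markers <- function(markers) {
  nm <- markers$name
  swap <- function(s) {
    out <- s
    out[grepl("_left$", s)] <- sub("_left$", "_right", s[grepl("_left$", s)])
    out[grepl("_right$", s)] <- sub("_right$", "_left", s[grepl("_right$", s)])
    out
  }
  world_points(swap(nm), -markers$x, markers$y, markers$z)
}

# random full-perspective camera for projection property tests
random_camera <- function(seed) {
  set.seed(seed)
  f <- runif(1, 500, 1500)
  K <- matrix(c(f, 0, 0, 0, f, 0, runif(1, 200, 400),
                runif(1, 150, 300), 1), 3, 3, byrow = TRUE)
  axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
  th <- runif(1, 0, pi)
  S <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(th) * S + (1 - cos(th)) * S %*% S
  C <- rnorm(3, 0, 1000)
  list(P = K %*% cbind(R, -R %*% C), C = C, R = R)
}
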