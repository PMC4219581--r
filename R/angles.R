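ANGLE_NAMES <- c("HF", "NF", "CC", "CT", "TF", "HLB", "NLB", "HR", "TTR")

# components of world vector v in the local frame: (lateral a, anterior b,
# vertical c)
local_comps <- function(v, axes) as.numeric(crossprod(axes, v))

#' Nine sitting postural angles
#'
#' Computes the standard nine postural angles from a [derive_landmarks()]
#' frame using normalised dot products (the dot-product-cosine rule) with
#' signs taken from the local axes.  All angles are in degrees.
#'
#' \describe{
#'   \item{HF (head flexion)}{angle of the OCI-to-Cyclops line with the
#'     vertical axis; 0 when the Cyclops is directly above the OCI.}
#'   \item{NF (neck flexion)}{angle of the C7-to-OCI line with the
#'     vertical axis.}
#'   \item{CC (cranio-cervical)}{three-point angle Cyclops-OCI-C7.}
#'   \item{CT (cervico-thoracic)}{three-point angle OCI-C7-T5.}
#'   \item{TF (trunk flexion)}{angle of the mid-trochanter-to-C7 line with
#'     the vertical; negative when C7 lies posterior to the
#'     mid-trochanter point (a backward lean).}
#'   \item{HLB (head lateral bending)}{frontal-plane tilt of the
#'     OCI-to-right-tragus line; with the default `"horizontal"`
#'     reference a level head scores 0, head bending to the subject's
#'     left is negative.  The `"vertical"` reference instead measures
#'     from the vertical through the OCI (level head = 90).}
#'   \item{NLB (neck lateral bending)}{frontal-plane projection of the
#'     C7-to-OCI line against the vertical; negative to the left.  See
#'     [nlb_sagittal_corrected()] for a projection-fault-free variant.}
#'   \item{HR (head rotation)}{transverse-plane angle of the
#'     OCI-to-Cyclops line against the anterior axis; negative to the
#'     left.}
#'   \item{TTR (thoracic trunk rotation)}{transverse-plane angle of the
#'     sternum-to-T5 line; with the default `"posterior"` reference a
#'     symmetric torso scores 0 (the line points straight backward),
#'     rotation to the subject's left is negative.  The `"anterior"`
#'     reference measures against +Y instead (neutral = 180).}
#' }
#'
#' Angles whose landmarks are missing are returned `NA` and flagged; a
#' zero-length segment (coincident landmarks) is a degenerate-angle error.
#'
#' @param frame a `landmark_frame`.
#' @param hlb_reference `"horizontal"` (default) or `"vertical"`.
#' @param ttr_reference `"posterior"` (default) or `"anterior"`.
#' @return named numeric vector of class `posture_angles` (length 9,
#'   degrees) with attribute `missing` (named logical).
#' @export
compute_posture_angles <- function(frame,
                                   hlb_reference = c("horizontal", "vertical"),
                                   ttr_reference = c("posterior", "anterior")) {
  hlb_reference <- match.arg(hlb_reference)
  ttr_reference <- match.arg(ttr_reference)
  p <- frame$points
  ax <- frame$axes
  deg <- function(x) x * 180 / pi

  seg <- function(a, b) {              # vector a -> b, NULL if either missing
    if (is.null(p[[a]]) || is.null(p[[b]])) return(NULL)
    v <- p[[b]] - p[[a]]
    if (sqrt(sum(v^2)) < 1e-9)
      stop("degenerate angle: landmarks '", a, "' and '", b, "' coincide")
    v
  }
  vert_angle <- function(v) angle_between_deg(v, c(0, 0, 1))
  three_pt <- function(a, b, c) {      # angle at b
    v1 <- seg(b, a); v2 <- seg(b, c)
    if (is.null(v1) || is.null(v2)) return(NA_real_)
    angle_between_deg(v1, v2)
  }

  out <- stats::setNames(rep(NA_real_, 9L), ANGLE_NAMES)

  v <- seg("oci", "cyclops")
  if (!is.null(v)) out["HF"] <- vert_angle(v)
  v <- seg("c7", "oci")
  if (!is.null(v)) out["NF"] <- vert_angle(v)
  out["CC"] <- three_pt("cyclops", "oci", "c7")
  out["CT"] <- three_pt("oci", "c7", "t5")
  v <- seg("mid_trochanter", "c7")
  if (!is.null(v)) {
    lc <- local_comps(v, ax)
    out["TF"] <- vert_angle(v) * if (lc[2L] < 0) -1 else 1
  }
  v <- seg("oci", "tragus_right")
  if (!is.null(v)) {
    lc <- local_comps(v, ax)         # frontal plane: lateral a, vertical c
    out["HLB"] <- if (hlb_reference == "horizontal")
      deg(atan2(-lc[3L], lc[1L])) else deg(atan2(lc[1L], lc[3L]))
  }
  v <- seg("c7", "oci")
  if (!is.null(v)) {
    lc <- local_comps(v, ax)
    out["NLB"] <- deg(atan2(lc[1L], lc[3L]))
  }
  v <- seg("oci", "cyclops")
  if (!is.null(v)) {
    lc <- local_comps(v, ax)         # transverse plane: lateral a, anterior b
    out["HR"] <- deg(atan2(lc[1L], lc[2L]))
  }
  v <- seg("sternum", "t5")
  if (!is.null(v)) {
    lc <- local_comps(v, ax)
    out["TTR"] <- if (ttr_reference == "posterior")
      deg(atan2(-lc[1L], -lc[2L])) else deg(atan2(lc[1L], lc[2L]))
  }
  attr(out, "missing") <- is.na(out)
  class(out) <- "posture_angles"
  out
}

#' @export
print.posture_angles <- function(x, ...) {
  v <- unclass(x); attr(v, "missing") <- NULL
  cat("Posture angles (deg):\n")
  print(round(v, 2))
  invisible(x)
}

#' Neck lateral bending without the frontal-projection fault
#'
#' The conventional NLB projects the C7-to-OCI line onto the frontal plane
#' before measuring its deviation from the vertical.  When lateral bending
#' is combined with sagittal neck flexion, the projection inflates the
#' apparent lateral angle (the segment shortens in the frontal view but
#' its lateral offset does not).  This variant instead measures the
#' elevation of the segment out of the sagittal plane - the true lateral
#' deviation - which coincides with the projected NLB when no sagittal
#' flexion is present and is immune to the fault otherwise.  Negative to
#' the subject's left.
#'
#' @param frame a `landmark_frame` with OCI and C7 present.
#' @return signed degrees.
#' @export
nlb_sagittal_corrected <- function(frame) {
  p <- frame$points
  if (is.null(p$oci) || is.null(p$c7))
    stop("OCI and C7 are required for corrected NLB")
  v <- p$oci - p$c7
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) stop("degenerate angle: OCI and C7 coincide")
  a <- sum(v * frame$axes[, "X"])
  asin(min(1, max(-1, a / nv))) * 180 / pi
}

#' Acceptable ranges for trial validation
#'
#' A successful trial requires every computed angle to fall inside its
#' acceptable range.  The defaults are deliberately wide envelopes around
#' ranges reported for seated adolescents (e.g. HF 66-80, CC 151-160,
#' CT 149-152, TF -13 to -22); they catch reconstruction blunders, not
#' atypical posture.
#'
#' @param ... named `c(low, high)` overrides, e.g. `HF = c(40, 110)`.
#' @return named list of class `acceptable_ranges`.
#' @export
acceptable_ranges <- function(...) {
  rng <- list(HF = c(40, 110), NF = c(10, 90), CC = c(120, 180),
              CT = c(100, 180), TF = c(-45, 20), HLB = c(-30, 30),
              NLB = c(-30, 30), HR = c(-45, 45), TTR = c(-45, 45))
  over <- list(...)
  for (nm in names(over)) {
    v <- as.numeric(over[[nm]])
    if (length(v) != 2L || !(v[1L] < v[2L]))
      stop("range for ", nm, " must be c(low, high) with low < high")
    rng[[nm]] <- v
  }
  structure(rng, class = "acceptable_ranges")
}

#' Validate a trial against acceptable ranges
#'
#' @param angles a [compute_posture_angles()] result.
#' @param ranges an [acceptable_ranges()] list.
#' @param required angle names that must not be missing for the trial to
#'   pass (default: all nine).
#' @return list with `status` (named character: `"pass"`, `"fail"` or
#'   `"missing"` per angle) and `pass` (overall logical: every non-missing
#'   angle in range and no required angle missing).
#' @export
validate_trial <- function(angles, ranges = acceptable_ranges(),
                           required = ANGLE_NAMES) {
  v <- unclass(angles)
  status <- stats::setNames(rep("pass", length(ANGLE_NAMES)), ANGLE_NAMES)
  for (nm in ANGLE_NAMES) {
    if (is.na(v[nm])) {
      status[nm] <- "missing"
    } else {
      r <- ranges[[nm]]
      if (v[nm] < r[1L] || v[nm] > r[2L]) status[nm] <- "fail"
    }
  }
  overall <- !any(status == "fail") &&
    !any(status[required] == "missing")
  list(status = status, pass = overall)
}
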