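#' World points
#'
#' Construct a set of named 3D world points (millimetres).  World points
#' describe fiducial markers on the calibration object or reflective
#' markers on a subject, expressed in the shared laboratory coordinate
#' frame (Z vertically upward).
#'
#' @param name character vector of unique marker labels.
#' @param x,y,z finite numeric coordinates in millimetres.
#' @return a `data.frame` of class `world_points` with columns
#'   `name`, `x`, `y`, `z`.
#' @export
world_points <- function(name, x, y, z) {
  name <- as.character(name)
  if (anyDuplicated(name)) stop("world point names must be unique")
  coords <- cbind(as.numeric(x), as.numeric(y), as.numeric(z))
  if (length(name) != nrow(coords) || any(!is.finite(coords)))
    stop("world point coordinates must be finite and match names in length")
  out <- data.frame(name = name, x = coords[, 1], y = coords[, 2],
                    z = coords[, 3], stringsAsFactors = FALSE)
  class(out) <- c("world_points", "data.frame")
  out
}

#' Image points
#'
#' Per-camera 2D pixel observations of named markers.  The pixel origin is
#' the top-left corner, `u` increases rightward, `v` downward, and pixel
#' centres sit at integer coordinates.  A marker that was not visible
#' carries `missing = TRUE` and `NA` coordinates (the "none" value of the
#' manual marker-selection step this replaces).
#'
#' @param marker character vector of marker labels.
#' @param u,v pixel coordinates; `NA` allowed only where `missing` is TRUE.
#' @param missing logical flag per marker.
#' @return a `data.frame` of class `image_points` with columns
#'   `marker`, `u`, `v`, `missing`.
#' @export
image_points <- function(marker, u, v, missing = NULL) {
  marker <- as.character(marker)
  u <- as.numeric(u); v <- as.numeric(v)
  if (is.null(missing)) missing <- !is.finite(u) | !is.finite(v)
  missing <- as.logical(missing)
  if (any(!missing & (!is.finite(u) | !is.finite(v))))
    stop("non-missing image points must have finite u, v")
  u[missing] <- NA_real_; v[missing] <- NA_real_
  out <- data.frame(marker = marker, u = u, v = v, missing = missing,
                    stringsAsFactors = FALSE)
  class(out) <- c("image_points", "data.frame")
  out
}

#' Camera projection matrix
#'
#' A pinhole camera as a 3x4 homogeneous projective matrix P mapping world
#' coordinates (mm) to pixels.  P is defined only up to a nonzero scale;
#' for storage it is put in a canonical form: unit Frobenius norm, with the
#' sign chosen so that a supplied in-front reference point (or, failing
#' that, a positive determinant of the left 3x3 block) has positive
#' projective depth.
#'
#' @param P numeric 3x4 matrix of rank 3.
#' @param camera_id label for the camera.
#' @param resolution integer c(width, height) in pixels; default 640x480
#'   (the sensor of the low-cost CMOS cameras the rig is built from).
#' @param ref_point optional world point known to be in front of the
#'   camera, used to fix the canonical sign.
#' @return an object of class `camera_matrix`.
#' @export
camera_matrix <- function(P, camera_id = "cam", resolution = c(640L, 480L),
                          ref_point = NULL) {
  P <- matrix(as.numeric(P), 3L, 4L)
  if (any(!is.finite(P))) stop("camera matrix entries must be finite")
  if (qr(P)$rank < 3L) stop("camera matrix must have rank 3")
  P <- P / sqrt(sum(P^2))
  if (!is.null(ref_point)) {
    w <- sum(P[3L, ] * c(as.numeric(ref_point)[1:3], 1))
    if (w < 0) P <- -P
  } else if (det(P[, 1:3]) < 0) {
    P <- -P
  }
  structure(list(camera_id = as.character(camera_id), P = P,
                 resolution = as.integer(resolution)),
            class = "camera_matrix")
}

#' @export
print.camera_matrix <- function(x, ...) {
  cat("<camera_matrix>", x$camera_id, "-",
      paste(x$resolution, collapse = "x"), "px\n")
  print(signif(x$P, 5))
  invisible(x)
}

#' Camera optical centre
#'
#' The world-frame position of the camera, i.e. the right null vector of
#' P dehomogenised.
#'
#' @param camera a [camera_matrix()].
#' @return numeric length-3 position (mm).
#' @export
camera_center <- function(camera) {
  v <- svd(camera$P, nu = 0L, nv = 4L)$v[, 4L]
  if (abs(v[4L]) < 1e-12) stop("camera centre at infinity")
  v[1:3] / v[4L]
}

#' Project world points through a camera
#'
#' Applies the homogeneous map u ~ P [x y z 1]' with perspective division.
#' Points behind or exactly at the camera plane (projective depth ~ 0)
#' raise a degenerate-projection error.  With `bounds_check = TRUE`,
#' points falling outside the sensor are returned as missing.
#'
#' @param camera a [camera_matrix()].
#' @param points a [world_points()] data frame (or anything with x,y,z and
#'   name columns).
#' @param bounds_check logical; mark projections outside `resolution` as
#'   missing.
#' @return an [image_points()] data frame, one row per input point.
#' @export
project <- function(camera, points, bounds_check = FALSE) {
  X <- rbind(t(as.matrix(points[, c("x", "y", "z")])), 1)
  h <- camera$P %*% X
  w <- h[3L, ]
  if (any(abs(w) < 1e-12))
    stop("degenerate projection: point at the camera's principal plane")
  u <- h[1L, ] / w
  v <- h[2L, ] / w
  miss <- rep(FALSE, length(u))
  if (bounds_check) {
    res <- camera$resolution
    miss <- u < 0 | u > res[1L] - 1L | v < 0 | v > res[2L] - 1L | w < 0
  }
  image_points(points$name, ifelse(miss, NA_real_, u),
               ifelse(miss, NA_real_, v), miss)
}

# Hartley-style normalisation: translate centroid to origin, scale so the
# mean distance from the origin is sqrt(d).  Returns the (d+1)x(d+1)
# homogeneous transform and the transformed coordinates.
normalize_points <- function(M) {
  d <- ncol(M)
  ctr <- colMeans(M)
  Mc <- sweep(M, 2L, ctr)
  meand <- mean(sqrt(rowSums(Mc^2)))
  s <- if (meand > 0) sqrt(d) / meand else 1
  T <- diag(d + 1L)
  T[seq_len(d), seq_len(d)] <- diag(s, d)
  T[seq_len(d), d + 1L] <- -s * ctr
  list(T = T, M = Mc * s)
}

#' Direct linear transformation (DLT) camera calibration
#'
#' Estimates the 3x4 camera matrix from world-to-image correspondences of
#' the fiducial markers by the normalised DLT: both point sets are
#' centred and isotropically scaled, the stacked linear system is solved
#' by SVD, and the result is denormalised and stored canonically.  No
#' iterative refinement is performed, so the estimate is deterministic.
#'
#' @param world a [world_points()] set of fiducial marker positions (mm).
#' @param image an [image_points()] set observed by the camera, matched to
#'   `world` by marker name; missing observations are dropped.
#' @param camera_id label for the calibrated camera.
#' @param resolution sensor size c(width, height) px.
#' @param degeneracy_tol singular-value ratio above which the
#'   configuration (e.g. coplanar fiducials) is declared degenerate.
#' @return a list of class `dlt_calibration` with elements `camera`
#'   (the [camera_matrix()]), `rms` (reprojection RMS in px over the
#'   inputs) and `n` (number of correspondences used).
#' @export
dlt_calibrate <- function(world, image, camera_id = "cam",
                          resolution = c(640L, 480L),
                          degeneracy_tol = 0.99) {
  m <- merge(as.data.frame(world), as.data.frame(image),
             by.x = "name", by.y = "marker")
  m <- m[!m$missing & is.finite(m$u) & is.finite(m$v), , drop = FALSE]
  if (nrow(m) < 6L)
    stop_precondition("insufficient correspondences: DLT needs at least ",
                      "6 non-missing points, got ", nrow(m))
  W <- as.matrix(m[, c("x", "y", "z")])
  U <- as.matrix(m[, c("u", "v")])
  nw <- normalize_points(W)
  nu <- normalize_points(U)
  Xn <- cbind(nw$M, 1)
  n <- nrow(m)
  A <- matrix(0, 2L * n, 12L)
  A[seq(1L, 2L * n, 2L), 1:4] <- Xn
  A[seq(1L, 2L * n, 2L), 9:12] <- -nu$M[, 1L] * Xn
  A[seq(2L, 2L * n, 2L), 5:8] <- Xn
  A[seq(2L, 2L * n, 2L), 9:12] <- -nu$M[, 2L] * Xn
  sv <- svd(A)
  d <- sv$d
  if (d[11L] < .Machine$double.eps^0.5 ||
      d[12L] / d[11L] > degeneracy_tol)
    stop_degenerate("degenerate configuration: fiducial points are ",
                    "(near-)coplanar or otherwise do not determine the camera")
  Pn <- matrix(sv$v[, 12L], 3L, 4L, byrow = TRUE)
  P <- solve(nu$T) %*% Pn %*% nw$T
  cam <- camera_matrix(P, camera_id, resolution, ref_point = colMeans(W))
  rms <- reprojection_error(cam, world, image)
  structure(list(camera = cam, rms = rms, n = n), class = "dlt_calibration")
}

#' @export
print.dlt_calibration <- function(x, ...) {
  cat("DLT calibration:", x$camera$camera_id, "- n =", x$n,
      ", reprojection RMS =", format(x$rms, digits = 4), "px\n")
  invisible(x)
}

#' Reprojection RMS error
#'
#' Root-mean-square Euclidean pixel distance between observed image points
#' and the projections of the matching world points.  Missing observations
#' are excluded; an all-missing set is an error.
#'
#' @inheritParams dlt_calibrate
#' @param camera a [camera_matrix()].
#' @return RMS error in pixels.
#' @export
reprojection_error <- function(camera, world, image) {
  m <- merge(as.data.frame(world), as.data.frame(image),
             by.x = "name", by.y = "marker")
  m <- m[!m$missing & is.finite(m$u) & is.finite(m$v), , drop = FALSE]
  if (nrow(m) == 0L) stop("no non-missing observations to compare")
  pr <- project(camera, world_points(m$name, m$x, m$y, m$z))
  sqrt(mean((pr$u - m$u)^2 + (pr$v - m$v)^2))
}
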