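#' Triangulate a single marker from multiple camera views
#'
#' Linear homogeneous triangulation: for each camera the two cross-product
#' constraints u (p3.X) = p1.X and v (p3.X) = p2.X are stacked and the
#' world point taken as the right singular vector of the system.  The
#' residual reported is the mean reprojection error over the contributing
#' cameras.  At least two non-missing observations are required, mirroring
#' a rig in which a marker not captured by at least two cameras cannot be
#' reconstructed.
#'
#' @param observations named list (by camera id) of numeric `c(u, v)`
#'   pixel observations; entries that are `NULL` or contain `NA` are
#'   treated as missing.
#' @param cameras named list of [camera_matrix()] objects covering at
#'   least the observed camera ids.
#' @param min_ray_angle_deg rays meeting at less than this angle are
#'   flagged ill-conditioned (warning attribute, not an error).
#' @return list with `point` (xyz, mm), `residual` (px),
#'   `n_cameras`, `ill_conditioned` (logical).
#' @export
triangulate_point <- function(observations, cameras,
                              min_ray_angle_deg = 0.5) {
  obs <- Filter(function(o) !is.null(o) && all(is.finite(o[1:2])),
                observations)
  if (length(obs) < 2L)
    stop_precondition("untriangulated: marker not captured by at least two cameras")
  ids <- names(obs)
  if (!all(ids %in% names(cameras)))
    stop("observations reference cameras without a calibration: ",
         paste(setdiff(ids, names(cameras)), collapse = ", "))
  A <- matrix(0, 2L * length(obs), 4L)
  for (i in seq_along(obs)) {
    P <- cameras[[ids[i]]]$P
    uv <- as.numeric(obs[[i]])
    A[2L * i - 1L, ] <- uv[1L] * P[3L, ] - P[1L, ]
    A[2L * i, ]      <- uv[2L] * P[3L, ] - P[2L, ]
  }
  v <- svd(A)$v[, 4L]
  if (abs(v[4L]) < 1e-14)
    stop("triangulation degenerate: point at infinity")
  X <- v[1:3] / v[4L]
  errs <- vapply(seq_along(obs), function(i) {
    pr <- project(cameras[[ids[i]]], world_points("m", X[1], X[2], X[3]))
    sqrt((pr$u - obs[[i]][1L])^2 + (pr$v - obs[[i]][2L])^2)
  }, numeric(1L))
  max_angle <- 0
  ctrs <- lapply(ids, function(id) camera_center(cameras[[id]]))
  for (i in seq_along(ctrs)) for (j in seq_len(i - 1L)) {
    a <- X - ctrs[[i]]; b <- X - ctrs[[j]]
    ang <- angle_between_deg(a, b)
    if (ang > max_angle) max_angle <- ang
  }
  list(point = X, residual = mean(errs), n_cameras = length(obs),
       ill_conditioned = max_angle < min_ray_angle_deg)
}

#' Reconstruct all markers of a frame
#'
#' Runs [triangulate_point()] for every marker named by the placement
#' model.  Markers visible in fewer than two cameras are reported with
#' status `"untriangulated"` and `NA` coordinates; the trial is never
#' aborted by partial visibility.  Markers present in the observations but
#' unknown to the placement model are an error (a mismatched placement
#' model corrupts marker identities silently otherwise).
#'
#' @param frame a marker observation set: `data.frame` with columns
#'   `camera_id`, `marker`, `u`, `v`, `missing` (see [capture()]).
#' @param cameras named list of [camera_matrix()].
#' @param model a [placement_model()] naming the expected markers.
#' @return `data.frame` of class `marker_set_3d` with columns `marker`,
#'   `x`, `y`, `z`, `n_cameras`, `residual`, `status`.
#' @export
reconstruct_markers <- function(frame, cameras, model) {
  frame <- as.data.frame(frame)
  unknown <- setdiff(unique(frame$marker), model$markers)
  if (length(unknown) > 0L)
    stop("placement-model mismatch: unexpected marker(s) ",
         paste(unknown, collapse = ", "))
  out <- data.frame(marker = model$markers, x = NA_real_, y = NA_real_,
                    z = NA_real_, n_cameras = 0L, residual = NA_real_,
                    status = "untriangulated", stringsAsFactors = FALSE)
  for (k in seq_along(model$markers)) {
    mk <- model$markers[k]
    rows <- frame[frame$marker == mk & !frame$missing &
                    is.finite(frame$u) & is.finite(frame$v), , drop = FALSE]
    if (nrow(rows) < 2L) next
    obs <- stats::setNames(
      lapply(seq_len(nrow(rows)), function(i) c(rows$u[i], rows$v[i])),
      rows$camera_id)
    tri <- triangulate_point(obs, cameras)
    out$x[k] <- tri$point[1L]; out$y[k] <- tri$point[2L]
    out$z[k] <- tri$point[3L]
    out$n_cameras[k] <- tri$n_cameras
    out$residual[k] <- tri$residual
    out$status[k] <- "reconstructed"
  }
  class(out) <- c("marker_set_3d", "data.frame")
  out
}

#' Angle between two cameras' lines of sight to a point
#'
#' The angle, in degrees, between the rays running from each camera's
#' optical centre to the world point.  Angles near 0 deg (cameras on the
#' same cross-bar, point far away) or near 180 deg (point between
#' side-flanking cameras, e.g. a dorsal spinous-process marker) degrade
#' the depth component of triangulation.
#'
#' @param camera_a,camera_b [camera_matrix()] objects.
#' @param point numeric xyz (mm) or a one-row [world_points()].
#' @return angle in degrees in [0, 180].
#' @export
line_of_sight_angle <- function(camera_a, camera_b, point) {
  if (is.data.frame(point)) point <- as.numeric(point[1L, c("x", "y", "z")])
  ca <- camera_center(camera_a); cb <- camera_center(camera_b)
  va <- point - ca; vb <- point - cb
  if (sqrt(sum(va^2)) < 1e-9 || sqrt(sum(vb^2)) < 1e-9)
    stop("point coincides with a camera centre")
  if (sqrt(sum((ca - cb)^2)) < 1e-9) return(0)
  angle_between_deg(va, vb)
}

# unsigned angle between two 3D vectors, degrees, robust at the ends
angle_between_deg <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-length vector in angle computation")
  cosv <- sum(a * b) / (na * nb)
  cosv <- min(1, max(-1, cosv))
  acos(cosv) * 180 / pi
}
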