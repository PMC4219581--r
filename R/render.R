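#' Render a synthetic marker image
#'
#' Draws the projected markers as bright anti-aliased disks on a dark
#' background (the black-cloth backdrop of the physical rig).  Pixel
#' intensity falls off linearly over one pixel at the disk edge, so the
#' intensity-weighted centroid of a rendered disk is an unbiased estimate
#' of the projected centre.
#'
#' @param camera a [camera_matrix()].
#' @param markers a [world_points()] set.
#' @param disk_radius_px disk radius in pixels (a 14 mm sphere at ~2.5 m
#'   with a 1000 px focal length is ~3 px across; default 4).
#' @param background background intensity in [0, 1).
#' @return numeric matrix `resolution[2]` x `resolution[1]` (rows = v,
#'   columns = u, both zero-based at the top-left pixel centre), values
#'   in [0, 1].
#' @export
render_frame <- function(camera, markers, disk_radius_px = 4,
                         background = 0) {
  res <- camera$resolution
  img <- matrix(background, nrow = res[2L], ncol = res[1L])
  pr <- project(camera, markers, bounds_check = TRUE)
  r <- disk_radius_px
  for (i in which(!pr$missing)) {
    u0 <- pr$u[i]; v0 <- pr$v[i]
    us <- max(0L, floor(u0 - r - 1)):min(res[1L] - 1L, ceiling(u0 + r + 1))
    vs <- max(0L, floor(v0 - r - 1)):min(res[2L] - 1L, ceiling(v0 + r + 1))
    d <- sqrt(outer((vs - v0)^2, (us - u0)^2, `+`))
    disk <- pmin(1, pmax(0, r + 0.5 - d))
    img[vs + 1L, us + 1L] <- pmax(img[vs + 1L, us + 1L], disk)
  }
  img
}

#' Detect marker centroids in a rendered image
#'
#' Automated replacement for manual marker clicking: the image is
#' thresholded, connected components are labelled (EBImage), and each
#' blob's intensity-weighted centroid is computed.  When the expected
#' projections are supplied, each detection is matched to the nearest
#' expected marker; a blob claimed by two expected markers (overlapping
#' disks) is flagged ambiguous.
#'
#' @param image matrix from [render_frame()].
#' @param threshold intensity threshold as a fraction of the image
#'   maximum.
#' @param expected optional [image_points()] of expected projections used
#'   to assign marker names.
#' @param match_radius_px maximum centre-to-centre distance for a match.
#' @return an [image_points()] data frame of detections (marker names
#'   `blob_k` when `expected` is NULL), with attribute `ambiguous`
#'   (character vector of marker names involved in overlapping blobs).
#' @export
detect_centroids <- function(image, threshold = 0.5, expected = NULL,
                             match_radius_px = 10) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("detect_centroids requires the EBImage package")
  mx <- max(image)
  if (mx <= 0)
    return(structure(image_points(character(0), numeric(0), numeric(0)),
                     ambiguous = character(0)))
  lab <- EBImage::bwlabel(image > threshold * mx)
  lab <- as.matrix(lab)
  nlab <- max(lab)
  if (nlab == 0)
    return(structure(image_points(character(0), numeric(0), numeric(0)),
                     ambiguous = character(0)))
  cu <- cv <- numeric(nlab)
  for (k in seq_len(nlab)) {
    idx <- which(lab == k, arr.ind = TRUE)
    w <- image[idx]
    cu[k] <- sum((idx[, 2L] - 1) * w) / sum(w)   # col -> u
    cv[k] <- sum((idx[, 1L] - 1) * w) / sum(w)   # row -> v
  }
  ambiguous <- character(0)
  if (is.null(expected)) {
    out <- image_points(sprintf("blob_%d", seq_len(nlab)), cu, cv)
  } else {
    exp_ok <- expected[!expected$missing, , drop = FALSE]
    assigned <- rep(NA_integer_, nrow(exp_ok))
    for (j in seq_len(nrow(exp_ok))) {
      dd <- sqrt((cu - exp_ok$u[j])^2 + (cv - exp_ok$v[j])^2)
      k <- which.min(dd)
      if (length(k) && dd[k] <= match_radius_px) assigned[j] <- k
    }
    dup <- assigned[!is.na(assigned)][duplicated(assigned[!is.na(assigned)])]
    if (length(dup))
      ambiguous <- exp_ok$marker[assigned %in% dup]
    out <- image_points(exp_ok$marker,
                        ifelse(is.na(assigned), NA_real_, cu[assigned]),
                        ifelse(is.na(assigned), NA_real_, cv[assigned]))
  }
  attr(out, "ambiguous") <- ambiguous
  out
}
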