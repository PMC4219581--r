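#' Derive anatomical landmarks and the subject-local frame
#'
#' From the reconstructed markers, three derived points are built:
#' the Cyclops (midpoint of the two canthus markers), the OCI (midpoint of
#' the two tragus markers) and the mid-trochanter point.  The local
#' coordinate system follows the convention used for seated subjects:
#' the X axis runs from the left to the right greater trochanter projected
#' onto the horizontal plane, the Z axis is the world vertical (upward),
#' and Y = Z x X points anteriorly; the triad is orthonormal and
#' right-handed by construction.  For the mannequin model the hip markers
#' stand in for the trochanters.
#'
#' Missing canthus/tragus markers flag the corresponding derived point as
#' missing; a missing trochanter (no pelvis line) means no local frame can
#' be built and is an error.
#'
#' @param markers a `marker_set_3d` from [reconstruct_markers()], or any
#'   data.frame with columns `marker`, `x`, `y`, `z` (and optionally
#'   `status`).
#' @param model a [placement_model()]; `"student"` and `"mannequin"`
#'   are supported.
#' @return list of class `landmark_frame`: `points` (named list of xyz),
#'   `axes` (3x3 matrix, columns X, Y, Z), `missing` (names of
#'   unavailable points).
#' @export
derive_landmarks <- function(markers, model = placement_model("student")) {
  df <- as.data.frame(markers)
  if (is.null(df$marker) && !is.null(df$name)) df$marker <- df$name
  if (!is.null(df$status)) df <- df[df$status != "untriangulated" |
                                      is.finite(df$x), , drop = FALSE]
  get <- function(nm) {
    i <- match(nm, df$marker)
    if (is.na(i) || !all(is.finite(as.numeric(df[i, c("x", "y", "z")]))))
      return(NULL)
    as.numeric(df[i, c("x", "y", "z")])
  }
  lname <- if (model$model_name == "mannequin") "hip_left" else "trochanter_left"
  rname <- if (model$model_name == "mannequin") "hip_right" else "trochanter_right"
  lt <- get(lname); rt <- get(rname)
  if (is.null(lt) || is.null(rt))
    stop("no local frame: both pelvis (trochanter/hip) markers are required")
  pts <- list()
  missing <- character(0)
  for (nm in model$markers) {
    p <- get(nm)
    if (is.null(p)) missing <- c(missing, nm) else pts[[nm]] <- p
  }
  mid2 <- function(a, b, out) {
    if (!is.null(pts[[a]]) && !is.null(pts[[b]])) pts[[out]] <<- (pts[[a]] + pts[[b]]) / 2
    else missing <<- c(missing, out)
  }
  mid2("canthus_left", "canthus_right", "cyclops")
  mid2("tragus_left", "tragus_right", "oci")
  pts$mid_trochanter <- (lt + rt) / 2
  xv <- rt - lt
  xv[3] <- 0                       # project pelvis line to horizontal
  nx <- sqrt(sum(xv^2))
  if (nx < 1e-9)
    stop("degenerate pelvis line: trochanters vertically aligned")
  X <- xv / nx
  Z <- c(0, 0, 1)
  Y <- c(Z[2] * X[3] - Z[3] * X[2],
         Z[3] * X[1] - Z[1] * X[3],
         Z[1] * X[2] - Z[2] * X[1])  # Z x X, anterior
  axes <- cbind(X = X, Y = Y, Z = Z)
  structure(list(points = pts, axes = axes, missing = unique(missing),
                 model_name = model$model_name),
            class = "landmark_frame")
}

#' @export
print.landmark_frame <- function(x, ...) {
  cat("<landmark_frame>", x$model_name, "-", length(x$points), "points")
  if (length(x$missing)) cat(";", length(x$missing), "missing")
  cat("\n")
  invisible(x)
}
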