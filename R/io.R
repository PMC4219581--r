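#' Read and write world-point CSV files
#'
#' Calibration objects and ground-truth marker sets travel as CSV with
#' columns `name,x,y,z` (millimetres).
#'
#' @param path file path.
#' @param points a [world_points()] data frame.
#' @return `read_world_points` returns a [world_points()] data frame.
#' @export
read_world_points <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_format("cannot parse ", path,
                                                 ": ", conditionMessage(e)))
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop_format(path, " lacks required columns name,x,y,z")
  if (any(!is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop_format(path, " has non-finite coordinates")
  world_points(df$name, df$x, df$y, df$z)
}

#' @rdname read_world_points
#' @export
write_world_points <- function(points, path) {
  utils::write.csv(as.data.frame(points)[, c("name", "x", "y", "z")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read and write marker observation CSV files
#'
#' Per-camera files have columns `marker,u,v` with empty fields for
#' missing ("none") markers; multi-camera files add a leading
#' `camera_id` column.
#'
#' @param path file path.
#' @param camera_id camera label to attach when reading a per-camera file
#'   that has no `camera_id` column.
#' @param obs a `marker_observations` data frame (or [image_points()]
#'   when writing a single camera's observations).
#' @return `read_observations` returns a `marker_observations`
#'   data frame with columns `camera_id`, `marker`, `u`, `v`, `missing`.
#' @export
read_observations <- function(path, camera_id = NULL) {
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  ragged <- which(nf != nf[1L])
  if (length(ragged))
    stop_format(path, ": truncated or ragged row at line(s) ",
                paste(ragged, collapse = ", "))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_format("cannot parse ", path,
                                                 ": ", conditionMessage(e)))
  if (!all(c("marker", "u", "v") %in% names(df)))
    stop_format(path, " lacks required columns marker,u,v")
  if (is.null(df$camera_id)) {
    if (is.null(camera_id))
      camera_id <- sub("\\.[^.]*$", "", basename(path))
    df$camera_id <- camera_id
  }
  u <- suppressWarnings(as.numeric(df$u))
  v <- suppressWarnings(as.numeric(df$v))
  bad <- (!is.na(df$u) & df$u != "" & is.na(u)) |
    (!is.na(df$v) & df$v != "" & is.na(v))
  if (any(bad))
    stop_format(path, ": non-numeric image coordinates at line(s) ",
                paste(which(bad) + 1L, collapse = ", "))
  out <- data.frame(camera_id = df$camera_id, marker = df$marker,
                    u = u, v = v, missing = is.na(u) | is.na(v),
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_observations", "data.frame")
  out
}

#' @rdname read_observations
#' @export
write_observations <- function(obs, path) {
  df <- as.data.frame(obs)
  if (is.null(df$camera_id))
    df <- data.frame(marker = df$marker, u = df$u, v = df$v)
  else df <- df[, c("camera_id", "marker", "u", "v")]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write camera matrices as CSV
#'
#' One row per camera: `camera_id`, the 12 matrix entries row-major
#' (`p11` ... `p34`), and the sensor `width`/`height`.
#'
#' @param path file path.
#' @param cameras named list of [camera_matrix()].
#' @return `read_cameras` returns a named list of [camera_matrix()].
#' @export
read_cameras <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_format("cannot parse ", path,
                                                 ": ", conditionMessage(e)))
  pcols <- sprintf("p%d%d", rep(1:3, each = 4L), rep(1:4, 3L))
  if (!all(c("camera_id", pcols) %in% names(df)))
    stop_format(path, " lacks camera matrix columns (camera_id, p11..p34)")
  cams <- lapply(seq_len(nrow(df)), function(i) {
    P <- matrix(as.numeric(df[i, pcols]), 3L, 4L, byrow = TRUE)
    res <- if (all(c("width", "height") %in% names(df)))
      c(df$width[i], df$height[i]) else c(640L, 480L)
    camera_matrix(P, df$camera_id[i], res)
  })
  names(cams) <- df$camera_id
  cams
}

#' @rdname read_cameras
#' @export
write_cameras <- function(cameras, path) {
  rows <- lapply(cameras, function(cam) {
    p <- as.vector(t(cam$P))
    df <- as.data.frame(as.list(stats::setNames(
      p, sprintf("p%d%d", rep(1:3, each = 4L), rep(1:4, 3L)))))
    cbind(data.frame(camera_id = cam$camera_id), df,
          data.frame(width = cam$resolution[1L],
                     height = cam$resolution[2L]))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a reconstructed marker set to CSV
#'
#' One CSV per trial with columns
#' `marker,x,y,z,n_cameras,residual,status`.
#'
#' @param marker_set a `marker_set_3d` from [reconstruct_markers()].
#' @param path file path.
#' @export
write_marker_set <- function(marker_set, path) {
  utils::write.csv(as.data.frame(marker_set), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read a long-format measurements CSV
#'
#' Columns `subject,occasion,instrument,angle,value` — the interchange
#' format for the statistics battery.
#'
#' @param path file path.
#' @return data frame with those five columns.
#' @export
read_measurements <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_format("cannot parse ", path,
                                                 ": ", conditionMessage(e)))
  need <- c("subject", "occasion", "instrument", "angle", "value")
  if (!all(need %in% names(df)))
    stop_format(path, " lacks required columns ",
                paste(need, collapse = ","))
  df$value <- suppressWarnings(as.numeric(df$value))
  df
}

#' Per-angle validity and reliability summary
#'
#' For every angle in a long-format measurements table, computes the
#' full battery: Bland-Altman agreement between the first two instruments
#' (paired by subject and occasion), Pearson r and Lin's CCC on the same
#' pairs, and the one-way random-effects ICC with variance components on
#' the repeated occasions of the first instrument.  Angles or analyses
#' whose preconditions are unmet (a single instrument, single occasions)
#' are reported `NA` with a warning rather than failing the run.
#'
#' @param data data frame with columns
#'   `subject,occasion,instrument,angle,value`.
#' @return tidy data frame, one row per angle, with columns `angle`, `n`,
#'   `d`, `s`, `upper`, `lower`, `width`, `cv`, `r`, `ccc`,
#'   `ccc_ci_lower`, `ccc_ci_upper`, `icc`, `ci_lower`, `ci_upper`,
#'   `var_subject`, `var_error`, `category`.
#' @export
agreement_table <- function(data) {
  instruments <- unique(data$instrument)
  rows <- lapply(unique(data$angle), function(ang) {
    da <- data[data$angle == ang & is.finite(data$value), , drop = FALSE]
    out <- data.frame(angle = ang, n = NA_integer_, d = NA_real_,
                      s = NA_real_, upper = NA_real_, lower = NA_real_,
                      width = NA_real_, cv = NA_real_, r = NA_real_,
                      ccc = NA_real_, ccc_ci_lower = NA_real_,
                      ccc_ci_upper = NA_real_, icc = NA_real_,
                      ci_lower = NA_real_, ci_upper = NA_real_,
                      var_subject = NA_real_, var_error = NA_real_,
                      category = NA_character_, stringsAsFactors = FALSE)
    if (length(instruments) >= 2L) {
      a <- da[da$instrument == instruments[1L], ]
      b <- da[da$instrument == instruments[2L], ]
      m <- merge(a, b, by = c("subject", "occasion"))
      if (nrow(m) >= 2L) {
        ba <- bland_altman(m$value.x, m$value.y)
        out$n <- ba$n; out$d <- ba$d; out$s <- ba$s
        out$upper <- ba$upper; out$lower <- ba$lower
        out$width <- ba$width; out$cv <- ba$cv
        if (nrow(m) >= 3L) {
          out$r <- tryCatch(as.numeric(pearson_r(m$value.x, m$value.y)),
                            error = function(e) NA_real_)
          cc <- tryCatch(lin_ccc(m$value.x, m$value.y),
                         error = function(e) NULL)
          if (!is.null(cc)) {
            out$ccc <- cc$coefficient
            out$ccc_ci_lower <- cc$ci_lower
            out$ccc_ci_upper <- cc$ci_upper
          }
        }
      }
    }
    rel <- da[da$instrument == instruments[1L], ]
    ic <- tryCatch(icc_oneway(rel$subject, rel$value),
                   error = function(e) {
                     warning("ICC skipped for ", ang, ": ",
                             conditionMessage(e), call. = FALSE)
                     NULL
                   })
    if (!is.null(ic)) {
      out$icc <- ic$coefficient
      out$ci_lower <- ic$ci_lower; out$ci_upper <- ic$ci_upper
      out$var_subject <- ic$var_subject; out$var_error <- ic$var_error
      out$category <- ic$category
    }
    out
  })
  do.call(rbind, rows)
}
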