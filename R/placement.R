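#' Marker placement models
#'
#' A placement model names the markers expected in a capture and which
#' anatomical landmark each one is.  Three built-in models are provided:
#' `"student"` (9 markers: both canthi, both tragi, C7 and T5 spinous
#' processes, both greater trochanters, superior sternum), `"mannequin"`
#' (14 markers: both canthi, tragi, acromioclavicular joints, shoulder
#' midpoints and hips, plus C7/T5/T8 spinous processes and the sternum)
#' and `"calibration"` (the 25 fiducials of the calibration object).
#'
#' @param model_name one of `"student"`, `"mannequin"`, `"calibration"`,
#'   or `"custom"` (then `markers` must be given).
#' @param markers character vector of marker names for a custom model.
#' @return list of class `placement_model` with `model_name`, `markers`.
#' @export
placement_model <- function(model_name = c("student", "mannequin",
                                           "calibration", "custom"),
                            markers = NULL) {
  model_name <- match.arg(model_name)
  markers <- switch(model_name,
    student = c("canthus_left", "canthus_right", "tragus_left",
                "tragus_right", "c7", "t5", "trochanter_left",
                "trochanter_right", "sternum"),
    mannequin = c("canthus_left", "canthus_right", "tragus_left",
                  "tragus_right", "ac_joint_left", "ac_joint_right",
                  "shoulder_left", "shoulder_right", "hip_left",
                  "hip_right", "c7", "t5", "t8", "sternum"),
    calibration = sprintf("dowel_%02d", 1:25),
    custom = {
      if (is.null(markers)) stop("custom model requires marker names")
      as.character(markers)
    })
  if (anyDuplicated(markers)) stop("marker names must be unique")
  structure(list(model_name = model_name, markers = markers),
            class = "placement_model")
}

#' Read / write a placement model as YAML
#'
#' Serialised as a mapping with keys `model_name` and `markers`.
#'
#' @param path file path.
#' @param model a [placement_model()].
#' @return `read_placement_model` returns a [placement_model()].
#' @export
read_placement_model <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$markers)) stop("placement model file lacks 'markers': ", path)
  nm <- if (is.null(y$model_name)) "custom" else y$model_name
  if (nm %in% c("student", "mannequin", "calibration")) {
    pm <- placement_model(nm)
    if (!setequal(pm$markers, unlist(y$markers)))
      pm <- placement_model("custom", markers = unlist(y$markers))
    pm
  } else placement_model("custom", markers = unlist(y$markers))
}

#' @rdname read_placement_model
#' @export
write_placement_model <- function(model, path) {
  yaml::write_yaml(list(model_name = model$model_name,
                        markers = as.list(model$markers)), path)
  invisible(path)
}
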