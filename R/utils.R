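# classed conditions so the command-line layer can map failures to exit
# codes (format / degenerate-geometry / statistical-precondition)
stop_classed <- function(class, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1L))))
}
stop_format <- function(...) stop_classed("posture3d_format_error", ...)
stop_degenerate <- function(...) stop_classed("posture3d_degenerate_error", ...)
stop_precondition <- function(...) stop_classed("posture3d_precondition_error", ...)

# evaluate code under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.  seed = NULL runs code as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

# Rodrigues rotation of vector v about unit axis by angle (radians)
rotate_about <- function(v, axis, angle) {
  a <- unit(axis)
  v * cos(angle) + cross3(a, v) * sin(angle) +
    a * sum(a * v) * (1 - cos(angle))
}

# rotation matrix about the vertical (z) axis, counter-clockwise degrees
rotz <- function(deg) {
  t <- deg2rad(deg)
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3L, 3L)
}
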