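# Scene specifications: declarative object descriptions, composite shapes and
# validation.  A SceneSpec is pure data (no closures), so fixed seeds yield
# byte-identical specs and specs can be hashed for manifests.

SHAPES <- c("sphere", "box", "curtain", "ramp", "arch",
            "open_container", "closed_container")
BEHAVIORS <- c("static", "free", "rolling", "scripted")

#' Declare an object for a scene
#'
#' @param id stable integer identity; also the mask channel the object owns
#'   (channel 0 is reserved for floor and sky).
#' @param shape one of `"sphere"`, `"box"`, `"curtain"`, `"ramp"`, `"arch"`,
#'   `"open_container"`, `"closed_container"`.  Composite shapes decompose
#'   into box primitives sharing this object's id.
#' @param size for spheres the radius; otherwise per-axis half extents
#'   (length 3).  All extents must be strictly positive.
#' @param color RGB triple in \[0, 1\].
#' @param mass unitless positive scalar (affects collision scripting only).
#' @param pos,vel initial position and velocity (world units, units/second).
#' @param quat initial orientation as a unit quaternion.
#' @param behavior `"static"`, `"free"` (ballistic flight, comes to rest on
#'   the ground), `"rolling"` (constant in-plane velocity, may reflect off
#'   heavy static boxes), or `"scripted"` (keyframed motion).
#' @param script data-only keyframe description for scripted objects; see
#'   [scriptCurtain()], [scriptTilt()].
#' @param reflect_ids ids of heavy static objects this object reflects off.
#' @param kick_ids ids of lighter objects this object displaces on impact
#'   when it lands (drop/throw collisions).
#' @param invisible_frames integer frame indices (1-based) at which the
#'   object is excluded from rendering and its mask channel left empty.
#' @return an `ObjectSpec` list.
#' @export
objectSpec <- function(id, shape, size, color, mass = 10,
                       pos = c(0, 0, 0), vel = c(0, 0, 0),
                       quat = quat_identity(), behavior = "static",
                       script = NULL, reflect_ids = integer(0),
                       kick_ids = integer(0), invisible_frames = integer(0)) {
  shape <- match.arg(shape, SHAPES)
  behavior <- match.arg(behavior, BEHAVIORS)
  if (shape == "sphere") {
    if (length(size) != 1 || size <= 0) stopf("sphere size must be one positive radius")
  } else {
    if (length(size) != 3 || any(size <= 0)) stopf("box-like size must be 3 positive half extents")
  }
  if (length(color) != 3 || any(color < 0) || any(color > 1)) {
    stopf("color must be an RGB triple in [0, 1]")
  }
  if (mass <= 0) stopf("mass must be positive")
  structure(list(
    id = as.integer(id), shape = shape, size = as.numeric(size),
    color = as.numeric(color), mass = as.numeric(mass),
    pos = as.numeric(pos), vel = as.numeric(vel),
    quat = quat_normalize(quat), behavior = behavior, script = script,
    reflect_ids = as.integer(reflect_ids),
    kick_ids = as.integer(kick_ids),
    invisible_frames = as.integer(invisible_frames)
  ), class = "physvoe_object")
}

#' Keyframed vertical (curtain/screen/cover) motion
#'
#' The object's z position follows a piecewise-linear schedule over the video:
#' it holds `z_hi` until `t_down`, descends to `z_lo` by `t_bottom`, holds,
#' then rises from `t_up` back to `z_hi` by `t_top`.  Times are in seconds.
#' Omit the rise (set `t_up = Inf`) for one-way drops.
#' @export
scriptCurtain <- function(z_hi, z_lo, t_down, t_bottom, t_up = Inf, t_top = Inf) {
  list(kind = "curtain", z_hi = z_hi, z_lo = z_lo, t_down = t_down,
       t_bottom = t_bottom, t_up = t_up, t_top = t_top)
}

#' Keyframed tilt about a horizontal hinge line (falling plank)
#'
#' The object rotates about the horizontal axis `axis` ("x" or "y") through
#' the hinge point, from `angle0` (radians, measured from the ground plane)
#' towards `angle1`, with angle(t) following a quadratic ease-in between
#' `t0` and `t1` (mimicking accelerating rotational fall), clamped at
#' `angle_stop` if given (plank propped on an object).
#' @export
scriptTilt <- function(hinge, axis = "y", angle0, angle1, t0, t1,
                       angle_stop = NULL) {
  list(kind = "tilt", hinge = as.numeric(hinge), axis = axis,
       angle0 = angle0, angle1 = angle1, t0 = t0, t1 = t1,
       angle_stop = angle_stop)
}

#' Declare a scene
#'
#' @param objects list of [objectSpec()] entries; ids must be unique, in
#'   `1 .. K_max - 1` (channel 0 is the floor).
#' @param camera `"fixed"` (stationary canonical pose), `"drifting"`, a camera
#'   pose from [cameraPose()] (held stationary), or a T x 7 camera track.
#' @param floor_colors 2 x 3 matrix of the checkerboard RGB colors.
#' @param seed integer seed recorded with the spec.
#' @param blocks optional list describing the freeform building blocks the
#'   scene was composed from.
#' @param duration video duration in seconds.
#' @param meta free-form metadata list.
#' @return a `SceneSpec`.
#' @export
sceneSpec <- function(objects, camera = "fixed", floor_colors = NULL,
                      seed = 0L, blocks = list(), duration = 2,
                      meta = list()) {
  ids <- vapply(objects, function(o) o$id, integer(1))
  if (anyDuplicated(ids)) stopf("object ids must be unique")
  if (length(ids) && any(ids < 1)) stopf("object ids start at 1 (0 is the floor)")
  if (is.null(floor_colors)) {
    floor_colors <- rbind(c(0.45, 0.45, 0.45), c(0.8, 0.8, 0.8))
  }
  structure(list(
    objects = objects, camera = camera,
    floor_colors = floor_colors, seed = as.integer(seed),
    blocks = blocks, duration = duration, meta = meta
  ), class = "physvoe_scene")
}

#' @export
print.physvoe_scene <- function(x, ...) {
  cat(sprintf("<SceneSpec: %d objects, %d blocks, seed %d>\n",
              length(x$objects), length(x$blocks), x$seed))
  for (o in x$objects) {
    cat(sprintf("  [%d] %-16s %-8s mass %-4g pos (%.2f, %.2f, %.2f)\n",
                o$id, o$shape, o$behavior, o$mass, o$pos[1], o$pos[2], o$pos[3]))
  }
  invisible(x)
}

# Decompose an object into render/collision primitives (spheres and oriented
# boxes) in the object's local frame.  Composite shapes are fixed part lists
# with parameterized extents; every part carries the parent id.
object_parts <- function(obj) {
  s <- obj$size
  if (obj$shape == "sphere") {
    return(list(list(kind = "sphere", offset = c(0, 0, 0), radius = s)))
  }
  if (obj$shape %in% c("box", "curtain", "ramp")) {
    # curtain is just a thin wide box; ramp a box given a tilted quat
    return(list(list(kind = "box", offset = c(0, 0, 0), half = s)))
  }
  if (obj$shape == "arch") {
    # two pillars plus a lintel; s = overall half extents (x: half width,
    # y: half depth, z: half height); pillar width = 30% of span
    pw <- 0.3 * s[1]
    ph <- s[3] * 0.75
    lt <- s[3] * 0.25
    return(list(
      list(kind = "box", offset = c(-(s[1] - pw), 0, -(s[3] - ph)), half = c(pw, s[2], ph)),
      list(kind = "box", offset = c(s[1] - pw, 0, -(s[3] - ph)), half = c(pw, s[2], ph)),
      list(kind = "box", offset = c(0, 0, s[3] - lt), half = c(s[1], s[2], lt))
    ))
  }
  if (obj$shape %in% c("open_container", "closed_container")) {
    # s = interior half extents; wall thickness 15% of the smaller span
    w <- 0.15 * min(s[1:2])
    parts <- list(
      list(kind = "box", offset = c(-(s[1] + w / 2), 0, 0), half = c(w / 2, s[2] + w, s[3])),
      list(kind = "box", offset = c(s[1] + w / 2, 0, 0), half = c(w / 2, s[2] + w, s[3])),
      list(kind = "box", offset = c(0, -(s[2] + w / 2), 0), half = c(s[1], w / 2, s[3])),
      list(kind = "box", offset = c(0, s[2] + w / 2, 0), half = c(s[1], w / 2, s[3]))
    )
    lid <- list(kind = "box", offset = c(0, 0, if (obj$shape == "open_container") -(s[3] - w / 2) else s[3] - w / 2),
                half = c(s[1], s[2], w / 2))
    return(c(parts, list(lid)))
  }
  stopf("unknown shape %s", obj$shape)
}

# height of the object's lowest point below its center (for ground rest)
object_bottom <- function(obj) {
  if (obj$shape == "sphere") obj$size else obj$size[3]
}
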