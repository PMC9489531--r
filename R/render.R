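# Ray-cast renderer.  Perspective projection with nearest-hit depth ordering
# (exact per-pixel painter's algorithm); flat object colors; checkerboard
# floor as the depth cue; sky and floor share mask channel 0.

RENDER_DEFAULTS <- list(
  fov = 0.9,               # vertical field of view, radians
  checker = 1.5,           # checker tile size, world units
  sky = c(0.72, 0.80, 0.92)
)

# world_state: list of primitives, each
#   list(kind = "sphere"/"box", center, radius / half + quat, color, channel)
# Returns list(image = H x W x 3 double in [0,1], channel = H x W integer,
# with 0 = floor/sky).

#' Render one frame of a world state
#'
#' @param world_state list of primitives in world coordinates; each primitive
#'   has `kind` ("sphere" or "box"), `center`, `radius` or `half` + `quat`,
#'   `color` and `channel`.
#' @param camera_pose pose from [cameraPose()].
#' @param floor_colors 2 x 3 matrix of checkerboard RGB colors.
#' @param H,W output resolution.
#' @param opts renderer options (fov, checker size, sky color).
#' @param rays optional precomputed rays for a stationary camera.
#' @return list with `image` (H x W x 3, values in \[0,1\]) and `channel`
#'   (H x W integer mask labels; 0 is floor/sky).  The mask label of a pixel
#'   is the nearest primitive along its ray, so occluded portions of objects
#'   are absent from their own channel.
#' @export
renderFrame <- function(world_state, camera_pose, floor_colors,
                        H = 64, W = 64, opts = RENDER_DEFAULTS, rays = NULL) {
  if (is.null(rays)) rays <- camera_rays(camera_pose, H, W, opts$fov)
  o <- rays$origin; d <- rays$dirs
  n <- nrow(d)

  tbest <- ray_floor(o, d)
  chan <- integer(n)                      # 0 = floor/sky
  # floor checker colors
  col <- matrix(opts$sky, nrow = n, ncol = 3, byrow = TRUE)
  fhit <- is.finite(tbest)
  if (any(fhit)) {
    px <- o[1] + tbest[fhit] * d[fhit, 1]
    py <- o[2] + tbest[fhit] * d[fhit, 2]
    parity <- (floor(px / opts$checker) + floor(py / opts$checker)) %% 2
    col[fhit, ] <- floor_colors[parity + 1, , drop = FALSE]
  }

  for (prim in world_state) {
    t <- if (prim$kind == "sphere") {
      ray_sphere(o, d, prim$center, prim$radius)
    } else {
      ray_box(o, d, prim$center, prim$half, prim$quat)
    }
    closer <- t < tbest
    if (any(closer)) {
      tbest[closer] <- t[closer]
      chan[closer] <- prim$channel
      col[closer, ] <- matrix(prim$color, nrow = sum(closer), ncol = 3, byrow = TRUE)
    }
  }

  list(image = array(col, dim = c(H, W, 3)),
       channel = matrix(chan, nrow = H, ncol = W))
}

# Convert an integer-labelled channel matrix to the K-channel binary stack.
channel_to_masks <- function(channel, K) {
  H <- nrow(channel); W <- ncol(channel)
  m <- array(0L, dim = c(K, H, W))
  for (k in seq_len(K) - 1L) m[k + 1L, , ] <- (channel == k) * 1L
  m
}

#' Convert between channel-stacked and integer-labelled masks
#'
#' The on-disk and in-memory form is the binary channel stack (K x H x W per
#' frame, channels mutually disjoint).  `masksToLabels` collapses a stack to a
#' single integer plane (0-based labels); `labelsToMasks` inverts it.
#' @param masks K x H x W binary array.
#' @export
masksToLabels <- function(masks) {
  K <- dim(masks)[1]
  lab <- matrix(0L, dim(masks)[2], dim(masks)[3])
  for (k in seq_len(K) - 1L) lab[masks[k + 1L, , ] > 0] <- k
  lab
}

#' @rdname masksToLabels
#' @param labels H x W integer matrix of 0-based labels.
#' @param K number of channels in the output stack.
#' @export
labelsToMasks <- function(labels, K) channel_to_masks(labels, K)
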