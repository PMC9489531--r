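# Quaternions, camera poses and ray generation.
#
# Conventions: right-handed world coordinates, z up, ground plane z = 0.
# Quaternions are length-4 numeric vectors (w, x, y, z), unit norm, and encode
# the rotation taking body-frame vectors into world frame.

quat_identity <- function() c(1, 0, 0, 0)

quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stopf("degenerate quaternion")
  q / n
}

#' Rotation matrix (world-from-body) for a unit quaternion
#' @noRd
quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Inverse of quat_to_mat (Shepperd's method, numerically safe branches).
mat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  quat_normalize(q)
}

# Quaternion for rotation by `angle` radians about unit axis.
quat_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct a camera pose looking from `pos` towards `target`
#'
#' @param pos length-3 camera position in world units.
#' @param target length-3 point the camera looks at.
#' @return a camera pose: `list(pos, quat)` with the quaternion encoding the
#'   world-from-camera rotation (camera axes: right, up, back).
#' @export
cameraPose <- function(pos, target) {
  f <- target - pos
  fn <- sqrt(sum(f^2))
  if (fn < 1e-9) stopf("camera position equals its target")
  f <- f / fn
  up <- c(0, 0, 1)
  r <- cross3(f, up)
  rn <- sqrt(sum(r^2))
  if (rn < 1e-9) { # looking straight up/down: pick arbitrary right axis
    r <- c(1, 0, 0)
  } else {
    r <- r / rn
  }
  u <- cross3(r, f)
  R <- cbind(r, u, -f)
  list(pos = as.numeric(pos), quat = mat_to_quat(R))
}

# Flatten a camera pose to the 7-vector (position, quaternion) used by models.
pose_to_vec <- function(pose) c(pose$pos, pose$quat)

vec_to_pose <- function(v) list(pos = v[1:3], quat = quat_normalize(v[4:7]))

#' Pixel ray directions for a pinhole camera
#'
#' Rays are returned in R array (column-major) pixel order: row index varies
#' fastest, matching `array(, c(H, W))` indexing.
#'
#' @param pose camera pose from [cameraPose()].
#' @param H,W image size in pixels.
#' @param fov vertical field of view in radians.
#' @return list with `origin` (length 3) and `dirs` (H*W x 3, unit rows).
#' @noRd
camera_rays <- function(pose, H, W, fov = 0.9) {
  R <- quat_to_mat(pose$quat)
  r <- R[, 1]; u <- R[, 2]; f <- -R[, 3]
  th <- tan(fov / 2)
  aspect <- W / H
  i <- rep(seq_len(H), times = W)        # image row (top = 1)
  j <- rep(seq_len(W), each = H)         # image column
  xn <- (2 * (j - 0.5) / W - 1) * th * aspect
  yn <- (1 - 2 * (i - 0.5) / H) * th
  d <- cbind(xn, yn, 1) %*% rbind(r, u, f)
  d <- d / sqrt(rowSums(d^2))
  list(origin = pose$pos, dirs = d)
}

# ---- ray / primitive intersections (vectorized over rays) -------------------

EPS_T <- 1e-6

# distance along each ray to the z=0 plane; Inf where the ray misses
ray_floor <- function(origin, dirs) {
  dz <- dirs[, 3]
  t <- rep(Inf, nrow(dirs))
  ok <- abs(dz) > 1e-12
  tt <- -origin[3] / dz[ok]
  tt[tt <= EPS_T] <- Inf
  t[ok] <- tt
  t
}

ray_sphere <- function(origin, dirs, center, radius) {
  oc <- origin - center
  b <- dirs %*% oc                      # N x 1
  cc <- sum(oc^2) - radius^2
  disc <- b^2 - cc
  t <- rep(Inf, nrow(dirs))
  hit <- disc >= 0
  if (any(hit)) {
    sq <- sqrt(disc[hit])
    t1 <- -b[hit] - sq
    t2 <- -b[hit] + sq
    tt <- ifelse(t1 > EPS_T, t1, ifelse(t2 > EPS_T, t2, Inf))
    t[hit] <- tt
  }
  t
}

# Oriented box: `center`, `half` extents (length 3), quaternion `quat`.
ray_box <- function(origin, dirs, center, half, quat = NULL) {
  if (is.null(quat) || isTRUE(all(quat == c(1, 0, 0, 0)))) {
    po <- origin - center
    do <- dirs
  } else {
    R <- quat_to_mat(quat)
    po <- as.numeric(crossprod(R, origin - center))
    do <- dirs %*% R
  }
  do[do == 0] <- 1e-300
  tmin <- rep(-Inf, nrow(dirs)); tmax <- rep(Inf, nrow(dirs))
  for (a in 1:3) {
    t1 <- (-half[a] - po[a]) / do[, a]
    t2 <- (half[a] - po[a]) / do[, a]
    lo <- pmin(t1, t2); hi <- pmax(t1, t2)
    tmin <- pmax(tmin, lo); tmax <- pmin(tmax, hi)
  }
  t <- ifelse(tmax >= pmax(tmin, EPS_T),
              ifelse(tmin > EPS_T, tmin, tmax), Inf)
  t
}
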