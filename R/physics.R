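# Simplified deterministic physics core.
#
# Point-mass translation with exact constant-acceleration integration,
# ground/support contact with inelastic rest, constant-velocity rolling with
# exact-time impulse reflection off heavy static boxes, equal-mass velocity
# exchange for rolling sphere collisions, and scripted keyframed motions
# (curtain descent/retraction, plank overturn, ramp rolls).  Events the core
# cannot produce dynamically are keyframed with physically plausible timing.

GRAVITY_DEFAULT <- 9.8

CANONICAL_CAMERA_POS <- c(0, -9, 3.2)
CANONICAL_CAMERA_TARGET <- c(0, 0, 1)

canonical_camera <- function() cameraPose(CANONICAL_CAMERA_POS, CANONICAL_CAMERA_TARGET)

#' Random camera drift track
#'
#' Frame 0 is the canonical start pose shared by all scenes; from there the
#' camera position performs a clipped Gaussian random walk inside `bounds`
#' while its look-at point drifts inside the scene region, so the camera
#' keeps observing the relevant part of the scene.  Degenerate (zero-extent)
#' bounds yield a constant track.
#'
#' @param rng_seed integer seed; fixed seeds give reproducible tracks.
#' @param T number of frames (>= 1).
#' @param bounds 2 x 3 matrix (rows: lower, upper) for the camera position.
#' @param look_bounds 2 x 3 matrix bounding the look-at point.
#' @param step_sd random-walk step s.d. in world units per frame.
#' @return T x 7 matrix; each row is (position, quaternion).
#' @export
driftCamera <- function(rng_seed, T, bounds = NULL, look_bounds = NULL,
                        step_sd = 0.12) {
  if (T < 1) stopf("T must be >= 1")
  if (is.null(bounds)) {
    bounds <- rbind(CANONICAL_CAMERA_POS - c(1.5, 1.0, 0.8),
                    CANONICAL_CAMERA_POS + c(1.5, 1.0, 0.8))
  }
  if (is.null(look_bounds)) {
    look_bounds <- rbind(CANONICAL_CAMERA_TARGET - c(1.2, 1.2, 0.5),
                         CANONICAL_CAMERA_TARGET + c(1.2, 1.2, 0.5))
  }
  with_seed(rng_seed, {
    track <- matrix(0, nrow = T, ncol = 7)
    p <- CANONICAL_CAMERA_POS
    l <- CANONICAL_CAMERA_TARGET
    track[1, ] <- pose_to_vec(cameraPose(p, l))
    if (T > 1) {
      for (t in 2:T) {
        p <- clamp(p + stats::rnorm(3, 0, step_sd), bounds[1, ], bounds[2, ])
        l <- clamp(l + stats::rnorm(3, 0, step_sd * 0.7),
                   look_bounds[1, ], look_bounds[2, ])
        track[t, ] <- pose_to_vec(cameraPose(p, l))
      }
    }
    track
  })
}

# ---- scripted motion -------------------------------------------------------

curtain_z <- function(s, t) {
  if (t <= s$t_down) return(s$z_hi)
  if (t <= s$t_bottom) {
    f <- (t - s$t_down) / (s$t_bottom - s$t_down)
    return(s$z_hi + f * (s$z_lo - s$z_hi))
  }
  if (t <= s$t_up) return(s$z_lo)
  if (t <= s$t_top) {
    f <- (t - s$t_up) / (s$t_top - s$t_up)
    return(s$z_lo + f * (s$z_hi - s$z_lo))
  }
  s$z_hi
}

tilt_angle <- function(s, t) {
  th <- if (t <= s$t0) {
    s$angle0
  } else if (t >= s$t1) {
    s$angle1
  } else {
    f <- (t - s$t0) / (s$t1 - s$t0)
    s$angle0 + (s$angle1 - s$angle0) * f^2   # quadratic ease-in: accelerating fall
  }
  if (!is.null(s$angle_stop)) {
    th <- if (s$angle1 < s$angle0) max(th, s$angle_stop) else min(th, s$angle_stop)
  }
  th
}

# state of a scripted object at time t (seconds)
script_state <- function(obj, t) {
  s <- obj$script
  if (is.null(s)) stopf("scripted object %d lacks a script", obj$id)
  if (s$kind == "curtain") {
    p <- obj$pos; p[3] <- curtain_z(s, t)
    return(list(pos = p, quat = obj$quat))
  }
  if (s$kind == "tilt") {
    th <- tilt_angle(s, t)
    q <- quat_axis_angle(c(1, 0, 0), -th)
    R <- quat_to_mat(q)
    center <- s$hinge + as.numeric(R %*% obj$pos)  # obj$pos = offset from hinge when flat
    return(list(pos = center, quat = q))
  }
  if (s$kind == "ramp_roll") {
    # accelerate from rest down the incline, then constant speed on the floor
    t_slope <- s$t_slope
    if (t <= t_slope) {
      dist <- 0.5 * s$accel * t^2
      return(list(pos = s$p0 + dist * s$dir, quat = obj$quat))
    }
    v_end <- s$accel * t_slope
    p_end <- s$p0 + 0.5 * s$accel * t_slope^2 * s$dir
    flat <- c(s$dir[1], s$dir[2], 0)
    nf <- sqrt(sum(flat^2)); if (nf > 1e-9) flat <- flat / nf
    p <- p_end + v_end * (t - t_slope) * flat
    p[3] <- s$floor_z
    return(list(pos = p, quat = obj$quat))
  }
  stopf("unknown script kind %s", s$kind)
}

#' Keyframed accelerating roll down a ramp
#' @param p0 start position (on the incline surface).
#' @param dir unit downhill direction.
#' @param accel acceleration along the slope (typically g * sin(alpha)).
#' @param t_slope time spent on the incline before reaching the floor.
#' @param floor_z resting height on the floor (sphere radius).
#' @export
scriptRampRoll <- function(p0, dir, accel, t_slope, floor_z) {
  dir <- dir / sqrt(sum(dir^2))
  list(kind = "ramp_roll", p0 = as.numeric(p0), dir = as.numeric(dir),
       accel = accel, t_slope = t_slope, floor_z = floor_z)
}

# ---- simulation ------------------------------------------------------------

# exact contact time for a sphere rolling at constant velocity against a
# static axis-aligned box expanded by the radius; returns Inf if no contact
# within [0, dt]
roll_contact_time <- function(pos, vel, box_center, box_half, radius, dt) {
  half <- box_half + radius
  tmin <- -Inf; tmax <- Inf
  for (a in 1:2) {                      # in-plane axes only
    v <- vel[a]
    if (abs(v) < 1e-12) {
      if (abs(pos[a] - box_center[a]) > half[a]) return(Inf)
    } else {
      t1 <- (box_center[a] - half[a] - pos[a]) / v
      t2 <- (box_center[a] + half[a] - pos[a]) / v
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmax < tmin || tmin > dt || tmax < 0 || tmin < -1e-9) return(Inf)
  max(tmin, 0)
}

# outward face normal of the box at a contact position (largest-ratio axis)
box_contact_normal <- function(pos, box_center, box_half) {
  rel <- (pos - box_center)[1:2] / (box_half[1:2] + 1e-9)
  if (abs(rel[1]) >= abs(rel[2])) c(sign(rel[1]), 0, 0) else c(0, sign(rel[2]), 0)
}

#' Simulate a scene into a video with masks and a camera track
#'
#' Advances the simplified physics core over `n_steps` uniform substeps of the
#' scene's duration and renders `frames` frames at uniformly strided substeps
#' (including the first and last).  The result satisfies the video-record
#' invariants: per-pixel-disjoint masks, consistent channel identity (channel
#' k always depicts object id k), channel 0 = floor and sky.
#'
#' @param spec a [sceneSpec()].
#' @param n_steps number of simulation substeps (>= frames).
#' @param frames number of rendered frames T.
#' @param size image height/width in pixels (square frames).
#' @param K number of mask channels (including channel 0).
#' @param g gravitational acceleration, world units / s^2.
#' @param opts renderer options.
#' @return a `VideoRecord`: list with `frames` (T x H x W x 3 integer array,
#'   0..255), `masks` (T x K x H x W binary integer array), `camera` (T x 7),
#'   and `meta` (seed, spec hash, events, warnings).
#' @export
simulateScene <- function(spec, n_steps = 3000, frames = 15, size = 64,
                          K = 8, g = GRAVITY_DEFAULT, opts = RENDER_DEFAULTS) {
  T <- frames
  if (n_steps < T) stopf("n_steps must be >= frames")
  H <- size; W <- size
  dur <- spec$duration
  dt <- dur / n_steps
  rec_steps <- if (T == 1) 0L else round((seq_len(T) - 1) * n_steps / (T - 1))

  ids <- vapply(spec$objects, function(o) o$id, integer(1))
  if (length(ids) && max(ids) > K - 1) {
    stopf("object id %d exceeds available mask channels (K - 1 = %d)",
          max(ids), K - 1)
  }

  camera <- resolve_camera(spec, T)

  # mutable state
  nobj <- length(spec$objects)
  pos <- lapply(spec$objects, function(o) o$pos)
  vel <- lapply(spec$objects, function(o) o$vel)
  quat <- lapply(spec$objects, function(o) o$quat)
  rest <- logical(nobj)
  behav <- vapply(spec$objects, function(o) o$behavior, character(1))
  events <- list()

  # static supports: axis-aligned box parts of static objects
  supports <- list()
  for (oi in seq_len(nobj)) {
    o <- spec$objects[[oi]]
    if (o$behavior != "static") next
    R <- quat_to_mat(o$quat)
    if (max(abs(R - diag(3))) > 1e-9) next      # only axis-aligned supports
    for (p in object_parts(o)) {
      if (p$kind != "box") next
      supports[[length(supports) + 1]] <- list(
        center = o$pos + p$offset, half = p$half, id = o$id)
    }
  }
  # heavy static boxes that rolling objects can reflect off
  reflectors <- list()
  for (oi in seq_len(nobj)) {
    o <- spec$objects[[oi]]
    if (o$behavior == "static" && o$shape %in% c("box", "arch")) {
      reflectors[[as.character(o$id)]] <- list(center = o$pos, half = o$size)
    }
  }

  set_scripted <- function(t_sec) {
    for (oi in seq_len(nobj)) {
      if (behav[oi] == "scripted") {
        st <- script_state(spec$objects[[oi]], t_sec)
        pos[[oi]] <<- st$pos
        quat[[oi]] <<- st$quat
      }
    }
  }

  advance <- function(step_idx) {
    t_now <- (step_idx - 1) * dt
    for (oi in seq_len(nobj)) {
      o <- spec$objects[[oi]]
      if (behav[oi] == "free" && !rest[oi]) {
        p <- pos[[oi]]; v <- vel[[oi]]
        bottom <- object_bottom(o)
        # support height under current xy
        sup <- 0
        for (s in supports) {
          if (abs(p[1] - s$center[1]) <= s$half[1] &&
              abs(p[2] - s$center[2]) <= s$half[2]) {
            top <- s$center[3] + s$half[3]
            if (top <= p[3] - bottom + 1e-9) sup <- max(sup, top)
          }
        }
        np <- p + v * dt + c(0, 0, -0.5 * g * dt^2)
        nv <- v + c(0, 0, -g * dt)
        if (np[3] - bottom <= sup && nv[3] < 0) {
          # exact contact time, then inelastic rest
          a <- -0.5 * g; b <- v[3]; cc <- p[3] - bottom - sup
          disc <- b^2 - 4 * a * cc
          tc <- if (disc >= 0) (-b - sqrt(disc)) / (2 * a) else dt
          tc <- clamp(tc, 0, dt)
          np <- p + v * tc + c(0, 0, -0.5 * g * tc^2)
          np[3] <- sup + bottom
          nv <- c(0, 0, 0)
          rest[oi] <<- TRUE
          events[[length(events) + 1]] <<- list(step = step_idx, type = "rest", id = o$id)
          # displace lighter objects underneath (drop/throw collision)
          for (oj in seq_len(nobj)) {
            if (oj == oi) next
            tgt <- spec$objects[[oj]]
            if (!(tgt$id %in% o$kick_ids)) next
            if (tgt$mass >= o$mass || behav[oj] == "scripted") next
            dxy <- sqrt(sum((pos[[oj]][1:2] - np[1:2])^2))
            if (dxy < 1.2 * (max(if (tgt$shape == "sphere") tgt$size else max(tgt$size[1:2])) +
                             if (o$shape == "sphere") o$size else max(o$size[1:2]))) {
              dir <- pos[[oj]][1:2] - np[1:2]
              nn <- sqrt(sum(dir^2)); dir <- if (nn > 1e-6) dir / nn else c(1, 0)
              vel[[oj]] <<- c(dir * 1.3, 0)
              behav[oj] <<- "rolling"
              events[[length(events) + 1]] <<- list(step = step_idx, type = "kick", id = tgt$id)
            }
          }
        }
        pos[[oi]] <<- np; vel[[oi]] <<- nv
      } else if (behav[oi] == "rolling") {
        p <- pos[[oi]]; v <- vel[[oi]]
        remaining <- dt
        guard <- 0
        repeat {
          guard <- guard + 1
          tc_best <- Inf; hit <- NULL
          for (rid in o$reflect_ids) {
            rf <- reflectors[[as.character(rid)]]
            if (is.null(rf)) next
            r <- if (o$shape == "sphere") o$size else max(o$size[1:2])
            tc <- roll_contact_time(p, v, rf$center, rf$half, r, remaining)
            if (tc < tc_best) { tc_best <- tc; hit <- rf }
          }
          if (!is.finite(tc_best) || guard > 4) {
            p <- p + v * remaining
            break
          }
          p <- p + v * tc_best
          n <- box_contact_normal(p, hit$center, hit$half)
          v <- v - 2 * sum(v * n) * n
          events[[length(events) + 1]] <<- list(step = step_idx, type = "reflect", id = o$id)
          remaining <- remaining - tc_best
        }
        pos[[oi]] <<- p; vel[[oi]] <<- v
      }
    }
    # rolling sphere pair collisions: equal-mass exchange along center line
    roll_idx <- which(behav == "rolling")
    if (length(roll_idx) > 1) {
      for (a in roll_idx) {
        for (b in roll_idx) {
          if (b <= a) next
          oa <- spec$objects[[a]]; ob <- spec$objects[[b]]
          if (oa$shape != "sphere" || ob$shape != "sphere") next
          dv <- pos[[a]] - pos[[b]]
          dist <- sqrt(sum(dv^2))
          if (dist < oa$size + ob$size && dist > 1e-9) {
            n <- dv / dist
            va <- vel[[a]]; vb <- vel[[b]]
            pa <- sum(va * n); pb <- sum(vb * n)
            if (pa - pb < 0) {          # approaching
              vel[[a]] <<- va + (pb - pa) * n
              vel[[b]] <<- vb + (pa - pb) * n
              events[[length(events) + 1]] <<- list(step = step_idx, type = "bounce",
                                                    id = oa$id)
            }
          }
        }
      }
    }
  }

  # render helper at the current state
  frames_arr <- array(0L, dim = c(T, H, W, 3))
  masks_arr <- array(0L, dim = c(T, K, H, W))
  static_cam <- is_static_camera(camera)
  rays_cache <- if (static_cam) camera_rays(vec_to_pose(camera[1, ]), H, W, opts$fov) else NULL

  render_now <- function(fi) {
    prims <- list()
    for (oi in seq_len(nobj)) {
      o <- spec$objects[[oi]]
      if (fi %in% o$invisible_frames) next
      R <- quat_to_mat(quat[[oi]])
      for (p in object_parts(o)) {
        center <- pos[[oi]] + as.numeric(R %*% p$offset)
        prims[[length(prims) + 1]] <- if (p$kind == "sphere") {
          list(kind = "sphere", center = center, radius = p$radius,
               color = o$color, channel = o$id)
        } else {
          list(kind = "box", center = center, half = p$half,
               quat = quat[[oi]], color = o$color, channel = o$id)
        }
      }
    }
    pose <- vec_to_pose(camera[fi, ])
    rf <- renderFrame(prims, pose, spec$floor_colors, H, W, opts,
                      rays = if (static_cam) rays_cache else NULL)
    frames_arr[fi, , , ] <<- as.integer(round(rf$image * 255))
    masks_arr[fi, , , ] <<- channel_to_masks(rf$channel, K)
  }

  fi <- 1L
  set_scripted(0)
  for (k in 0:n_steps) {
    if (k > 0) {
      advance(k)
      set_scripted(k * dt)
    }
    if (fi <= T && rec_steps[fi] == k) {
      for (oi in seq_len(nobj)) {
        if (any(!is.finite(pos[[oi]])) || any(!is.finite(vel[[oi]]))) {
          stopf("non-finite state for object %d at step %d", ids[oi], k)
        }
      }
      render_now(fi)
      fi <- fi + 1L
    }
    if (fi > T) break
  }

  warn <- character(0)
  for (oi in seq_len(nobj)) {
    o <- spec$objects[[oi]]
    if (length(o$invisible_frames) == 0 &&
        sum(masks_arr[, o$id + 1L, , ]) == 0) {
      warn <- c(warn, sprintf("object %d never visible in the render frustum", o$id))
    }
  }

  videoRecord(frames_arr, masks_arr, camera,
              meta = list(seed = spec$seed, spec_hash = hash_object(spec),
                          events = events, warnings = warn,
                          concept = spec$meta$concept %||% NA_character_))
}

is_static_camera <- function(camera) {
  nrow(camera) == 1 || all(abs(sweep(camera, 2, camera[1, ])) < 1e-12)
}

resolve_camera <- function(spec, T) {
  cam <- spec$camera
  if (is.matrix(cam)) {
    if (nrow(cam) != T || ncol(cam) != 7) stopf("camera track must be T x 7")
    return(cam)
  }
  if (is.list(cam) && !is.null(cam$pos)) {
    return(matrix(pose_to_vec(cam), nrow = T, ncol = 7, byrow = TRUE))
  }
  if (identical(cam, "fixed")) {
    return(matrix(pose_to_vec(canonical_camera()), nrow = T, ncol = 7, byrow = TRUE))
  }
  if (identical(cam, "drifting")) {
    return(driftCamera(derive_seed(spec$seed, 777L), T))
  }
  stopf("unrecognized camera directive")
}
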