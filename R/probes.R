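# Probe factory: matched probe tuples for five physical concepts, built by
# the splicing construction.  Each tuple holds two physically possible and
# two physically impossible videos; the impossible videos recombine the
# possible videos' start/end segments around a shared (pixel-identical)
# common frame, so both probe types contain exactly the same frames and the
# same adjacent frame pairs.  Violations therefore cannot be detected from
# any single frame or frame pair, only from longer temporal context.

CONCEPTS <- c("continuity", "persistence", "unchangeableness",
              "solidity", "inertia")

#' Construct a probe tuple
#'
#' @param concept one of `"continuity"`, `"persistence"`,
#'   `"unchangeableness"`, `"solidity"`, `"inertia"`.
#' @param possible,impossible lists of two `VideoRecord`s each.
#' @param violation_onset integer length 2: for each impossible video, the
#'   1-based index of its first aphysical frame (in `2 .. T`).
#' @param seed generating seed.
#' @param meta metadata (scene specs, common-frame index, roles).
#' @export
probeTuple <- function(concept, possible, impossible, violation_onset,
                       seed = 0L, meta = list()) {
  concept <- match.arg(concept, CONCEPTS)
  if (length(possible) != 2 || length(impossible) != 2) {
    stopf("a probe tuple holds exactly 2 possible and 2 impossible videos")
  }
  dims <- lapply(c(possible, impossible), function(v) dim(v$frames))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stopf("all four videos must share T, H, W")
  }
  cams <- lapply(c(possible, impossible), function(v) v$camera)
  if (!all(vapply(cams, function(cm) isTRUE(all.equal(cm, cams[[1]])), logical(1))) ||
      !is_static_camera(cams[[1]])) {
    stopf("probe cameras must be identical stationary tracks")
  }
  T <- dims[[1]][1]
  if (length(violation_onset) != 2 ||
      any(violation_onset < 2) || any(violation_onset > T)) {
    stopf("violation_onset must lie in 2..T for each impossible video")
  }
  structure(list(concept = concept, possible = possible,
                 impossible = impossible,
                 violation_onset = as.integer(violation_onset),
                 seed = as.integer(seed), meta = meta),
            class = "physvoe_probe")
}

#' @export
print.physvoe_probe <- function(x, ...) {
  d <- dim(x$possible[[1]]$frames)
  cat(sprintf("<ProbeTuple: %s, %d frames %dx%d, violation onset %s, seed %d>\n",
              x$concept, d[1], d[2], d[3],
              paste(x$violation_onset, collapse = "/"), x$seed))
  invisible(x)
}

# ---- splicing --------------------------------------------------------------

video_take <- function(rec, idx, source = NULL) {
  # assemble a new record taking frame `idx[t]` of video `source[t]` from a
  # list of records (frame-level splice); masks and cameras follow frames
  recs <- if (is.null(source)) list(rec) else rec
  src <- source %||% rep(1L, length(idx))
  d <- dim(recs[[1]]$frames); K <- dim(recs[[1]]$masks)[2]
  T <- length(idx)
  fr <- array(0L, dim = c(T, d[2], d[3], 3))
  mk <- array(0L, dim = c(T, K, d[2], d[3]))
  for (t in seq_len(T)) {
    fr[t, , , ] <- recs[[src[t]]]$frames[idx[t], , , ]
    mk[t, , , ] <- recs[[src[t]]]$masks[idx[t], , , ]
  }
  videoRecord(fr, mk, recs[[1]]$camera[seq_len(T), , drop = FALSE],
              meta = recs[[1]]$meta)
}

#' Split two matched possible videos into splice segments
#'
#' @param A,B possible `VideoRecord`s sharing the pixel-identical frame at
#'   `common_index`.
#' @param common_index 1-based index of the shared frame.
#' @return a `SegmentSet`: start/end segments for A and B plus the common
#'   frame.
#' @export
segmentSet <- function(A, B, common_index) {
  T <- nFrames(A)
  if (common_index < 2 || common_index > T - 1) {
    stopf("common_index must leave nonempty start and end segments")
  }
  if (!identical(A$frames[common_index, , , ], B$frames[common_index, , , ])) {
    stopf("videos are not pixel-identical at the common frame")
  }
  structure(list(A = A, B = B, common_index = as.integer(common_index)),
            class = "physvoe_segments")
}

#' Splice segments into a probe tuple
#'
#' Possible videos run start A -> common -> end A and start B -> common ->
#' end B; impossible videos use the mismatched end segments (A -> common ->
#' end B and B -> common -> end A).  The violation onset is the first frame
#' after the common frame.
#'
#' @param segments a `SegmentSet` from [segmentSet()].
#' @param concept concept tag for the resulting tuple.
#' @param seed seed recorded in the tuple.
#' @param meta extra metadata.
#' @export
splice <- function(segments, concept, seed = 0L, meta = list()) {
  A <- segments$A; B <- segments$B; ci <- segments$common_index
  T <- nFrames(A)
  idx <- seq_len(T)
  impA <- video_take(list(A, B), idx, c(rep(1L, ci), rep(2L, T - ci)))
  impB <- video_take(list(A, B), idx, c(rep(2L, ci), rep(1L, T - ci)))
  probeTuple(concept, possible = list(A, B), impossible = list(impA, impB),
             violation_onset = c(ci + 1L, ci + 1L), seed = seed,
             meta = c(meta, list(common_index = ci)))
}

# ---- verification ----------------------------------------------------------

#' Verify the matched-frame guarantees of a probe tuple
#'
#' Performs two pixel-exact checks: (i) frame match, the multiset of frames
#' over both impossible videos equals the multiset over both possible
#' videos; (ii) pair match, every ordered adjacent frame pair occurring in
#' an impossible video occurs as an adjacent pair in some possible video
#' (all adjacent transitions are physically possible even when the video as
#' a whole is not).
#'
#' @param tuple a `ProbeTuple`.
#' @return list with logicals `frame_match`, `pair_match`, `pass`, and on
#'   failure `first_offence` naming the first offending video/frame index.
#' @export
verifyProbeTuple <- function(tuple) {
  poss <- tuple$possible; imp <- tuple$impossible
  T <- nFrames(poss[[1]])

  keys_p <- c(frame_keys(poss[[1]]), frame_keys(poss[[2]]))
  keys_i <- c(frame_keys(imp[[1]]), frame_keys(imp[[2]]))
  get_frame <- function(set, j) {
    v <- if (j <= T) set[[1]] else set[[2]]
    video_frame(v, if (j <= T) j else j - T)
  }

  frame_match <- TRUE; first_offence <- NULL
  op <- order(keys_p); oi <- order(keys_i)
  if (!identical(keys_p[op], keys_i[oi])) {
    frame_match <- FALSE
  } else {
    for (j in seq_along(op)) {
      if (!identical(get_frame(poss, op[j]), get_frame(imp, oi[j]))) {
        frame_match <- FALSE; break
      }
    }
  }
  if (!frame_match) {
    # locate first impossible frame with no pixel-equal partner remaining
    used <- logical(2 * T)
    for (j in seq_len(2 * T)) {
      f <- get_frame(imp, j)
      hit <- FALSE
      for (l in which(!used)) {
        if (keys_p[l] == keys_i[j] && identical(get_frame(poss, l), f)) {
          used[l] <- TRUE; hit <- TRUE; break
        }
      }
      if (!hit) {
        first_offence <- list(check = "frame", video = ifelse(j <= T, 1L, 2L),
                              frame = ifelse(j <= T, j, j - T))
        break
      }
    }
  }

  # adjacent ordered pairs of the possible videos
  pair_keys_p <- character(0); pair_loc <- list()
  for (v in 1:2) {
    kp <- frame_keys(poss[[v]])
    for (t in seq_len(T - 1)) {
      pair_keys_p <- c(pair_keys_p, paste(kp[t], kp[t + 1], sep = "=>"))
      pair_loc[[length(pair_loc) + 1]] <- c(v, t)
    }
  }
  pair_match <- TRUE
  for (v in 1:2) {
    ki <- frame_keys(imp[[v]])
    for (t in seq_len(T - 1)) {
      key <- paste(ki[t], ki[t + 1], sep = "=>")
      cand <- which(pair_keys_p == key)
      ok <- FALSE
      for (ci in cand) {
        pv <- pair_loc[[ci]][1]; pt <- pair_loc[[ci]][2]
        if (identical(video_frame(imp[[v]], t), video_frame(poss[[pv]], pt)) &&
            identical(video_frame(imp[[v]], t + 1), video_frame(poss[[pv]], pt + 1))) {
          ok <- TRUE; break
        }
      }
      if (!ok) {
        pair_match <- FALSE
        if (is.null(first_offence)) {
          first_offence <- list(check = "pair", video = v, frame = t)
        }
        break
      }
    }
    if (!pair_match) break
  }

  list(frame_match = frame_match, pair_match = pair_match,
       pass = frame_match && pair_match, first_offence = first_offence)
}

# ---- generation helpers ----------------------------------------------------

probe_retry <- function(rng_seed, max_tries, build) {
  last_err <- NULL
  for (a in seq_len(max_tries)) {
    s <- if (a == 1) as.integer(rng_seed) else derive_seed(rng_seed, a)
    out <- tryCatch(build(s), error = function(e) e)
    if (!inherits(out, "error")) return(out)
    last_err <- out
  }
  stopf("probe generation failed after %d attempts: %s", max_tries,
        conditionMessage(last_err))
}

frame_times <- function(T = 15, n_steps = 700, duration = 2) {
  k <- if (T == 1) 0 else round((seq_len(T) - 1) * n_steps / (T - 1))
  k * duration / n_steps
}

rand_color <- function() stats::runif(3, 0.05, 0.95)

# two colors at a guaranteed perceptual distance
distinct_colors <- function(n, min_dist = 0.45) {
  repeat {
    cols <- replicate(n, rand_color(), simplify = FALSE)
    ok <- TRUE
    if (n > 1) {
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        if (sqrt(sum((cols[[i]] - cols[[j]])^2)) < min_dist) ok <- FALSE
      }
    }
    if (ok) return(cols)
  }
}

rand_floor <- function() rbind(rand_color(), rand_color())

# ---- concept probes --------------------------------------------------------

#' Continuity probe: a ball rolls behind two pillars
#'
#' Possible videos: a ball rolls horizontally behind two pillars whose width
#' matches the ball's diameter, visible before, between and after them; and
#' the identical scene with no visible ball.  Impossible videos are built by
#' visibility masking: in one the ball never appears between the pillars, in
#' the other it appears only between them.  The construction deviates from
#' the generic segment swap but still satisfies both matching checks,
#' because fully-occluded frames are pixel-identical to empty-scene frames.
#'
#' @param rng_seed integer seed.
#' @param profile scale profile from [runProfile()].
#' @param max_tries generation retries before signalling failure.
#' @return a verified `ProbeTuple`.
#' @export
makeContinuityProbe <- function(rng_seed, profile = deskProfile(),
                                max_tries = 25L) {
  probe_retry(rng_seed, max_tries, function(s) with_seed(s, {
    T <- profile$T
    tau <- frame_times(T, profile$n_steps, profile$duration)
    i1 <- 5L; i2 <- 9L                 # fully-occluded frames
    gap_frames <- (i1 + 1L):(i2 - 1L)
    r <- stats::runif(1, 0.42, 0.5)
    y_ball <- 2.2; y_pil <- 0.6
    cam <- canonical_camera()
    d_ball <- y_ball - cam$pos[2]; d_pil <- y_pil - cam$pos[2]
    dirn <- sample(c(-1, 1), 1)
    speed <- stats::runif(1, 1.8, 2.6) / (tau[i2] - tau[i1])
    xc <- stats::runif(1, -0.3, 0.3)
    xb <- function(t) xc + dirn * speed * (t - tau[7])
    xp <- c(xb(tau[i1]), xb(tau[i2])) * d_pil / d_ball   # perspective-aligned
    h_pil <- stats::runif(1, 1.1, 1.4)
    cols <- distinct_colors(3)
    floor_cols <- rand_floor()

    ball <- objectSpec(1, "sphere", r, cols[[1]], mass = 10,
                       pos = c(xb(0), y_ball, r),
                       vel = c(dirn * speed, 0, 0), behavior = "rolling")
    pil <- function(id, x, col) objectSpec(id, "box", c(r, 0.12, h_pil), col,
                                           pos = c(x, y_pil, h_pil))
    objs <- list(ball, pil(2, xp[1], cols[[2]]), pil(3, xp[2], cols[[3]]))
    spec1 <- sceneSpec(objs, camera = cam, floor_colors = floor_cols, seed = s,
                       meta = list(concept = "continuity"))
    objs2 <- objs
    objs2[[1]]$invisible_frames <- seq_len(T)
    spec2 <- sceneSpec(objs2, camera = cam, floor_colors = floor_cols, seed = s,
                       meta = list(concept = "continuity"))

    sim <- function(sp) simulateScene(sp, n_steps = profile$n_steps,
                                      frames = T, size = profile$size,
                                      K = profile$K)
    p1 <- suppressWarnings(sim(spec1)); p2 <- suppressWarnings(sim(spec2))

    # occlusion must be total at the flanking frames, and the ball must show
    # before, between and after the pillars
    for (i in c(i1, i2)) {
      if (sum(p1$masks[i, 2, , ]) != 0) stopf("ball not fully occluded at frame %d", i)
      if (!identical(p1$frames[i, , , ], p2$frames[i, , , ])) {
        stopf("occluded frame differs from empty frame")
      }
    }
    if (sum(p1$masks[gap_frames, 2, , ]) == 0) stopf("ball never visible between pillars")
    if (sum(p1$masks[1:(i1 - 1), 2, , ]) == 0) stopf("ball not visible before pillars")
    if (sum(p1$masks[(i2 + 1):T, 2, , ]) == 0) stopf("ball not visible after pillars")

    src1 <- rep(1L, T); src1[gap_frames] <- 2L            # never between
    src2 <- rep(2L, T); src2[gap_frames] <- 1L            # only between
    imp1 <- video_take(list(p1, p2), seq_len(T), src1)
    imp2 <- video_take(list(p1, p2), seq_len(T), src2)

    tuple <- probeTuple("continuity", possible = list(p1, p2),
                        impossible = list(imp1, imp2),
                        violation_onset = c(gap_frames[1], gap_frames[1]),
                        seed = s,
                        meta = list(specs = list(spec1, spec2),
                                    occluded_frames = c(i1, i2)))
    ver <- verifyProbeTuple(tuple)
    if (!ver$pass) stopf("verification failed")
    tuple
  }))
}

#' Object-persistence probe: a falling screen propped by a hidden object
#'
#' A drawbridge-style rigid plank rotates from flat (towards the camera) up
#' and over away from it.  In one possible video it lands on an object
#' behind the hinge and remains propped while occluding it; in the other
#' the scene is empty and the plank falls flat.  Splicing at a frame where
#' the object is fully occluded and both planks share the same angle yields
#' impossible videos in which the object silently vanishes or appears.
#' @inheritParams makeContinuityProbe
#' @export
makePersistenceProbe <- function(rng_seed, profile = deskProfile(),
                                 max_tries = 25L) {
  probe_retry(rng_seed, max_tries, function(s) with_seed(s, {
    T <- profile$T
    tau <- frame_times(T, profile$n_steps, profile$duration)
    cam <- cameraPose(c(0, -9, 2.0), c(0, 0.5, 0.8))
    y_h <- -0.6
    sy <- stats::runif(1, 1.0, 1.2)       # plank half length
    hx <- stats::runif(1, 1.3, 1.7)
    hz_o <- stats::runif(1, 0.25, 0.35)   # object half height
    dy <- stats::runif(1, 0.7, 1.0)
    x_o <- stats::runif(1, -0.35, 0.35)
    y_o <- y_h + dy
    cols <- distinct_colors(2)
    floor_cols <- rand_floor()
    theta_p <- pi - atan2(2 * hz_o, (y_o - 0.3) - y_h)   # propped angle
    t0 <- 0.2; t1 <- 1.5

    plank <- function(stop_at) {
      objectSpec(1, "box", c(hx, sy, 0.06), cols[[1]], mass = 40,
                 pos = c(0, -sy, 0.06),    # offset from hinge when flat
                 behavior = "scripted",
                 script = scriptTilt(hinge = c(0, y_h, 0), angle0 = 0,
                                     angle1 = pi, t0 = t0, t1 = t1,
                                     angle_stop = stop_at))
    }
    obj <- objectSpec(2, "box", c(0.3, 0.3, hz_o), cols[[2]], mass = 10,
                      pos = c(x_o, y_o, hz_o))
    specA <- sceneSpec(list(plank(theta_p), obj), camera = cam,
                       floor_colors = floor_cols, seed = s,
                       meta = list(concept = "persistence"))
    specB <- sceneSpec(list(plank(NULL)), camera = cam,
                       floor_colors = floor_cols, seed = s,
                       meta = list(concept = "persistence"))
    sim <- function(sp) simulateScene(sp, n_steps = profile$n_steps,
                                      frames = T, size = profile$size,
                                      K = profile$K)
    A <- suppressWarnings(sim(specA)); B <- suppressWarnings(sim(specB))

    sched <- vapply(tau, function(t) tilt_angle(list(angle0 = 0, angle1 = pi,
                                                     t0 = t0, t1 = t1,
                                                     angle_stop = NULL), t),
                    numeric(1))
    cand <- which(sched <= theta_p)
    cand <- cand[cand >= 2 & cand <= T - 1]
    ci <- NA_integer_
    for (i in rev(cand)) {
      if (sum(A$masks[i, 3, , ]) == 0 &&
          identical(A$frames[i, , , ], B$frames[i, , , ])) { ci <- i; break }
    }
    if (is.na(ci)) stopf("no fully-occluded shared frame found")
    if (sum(A$masks[1, 3, , ]) == 0) stopf("object not visible initially")
    if (any(apply(A$masks[ci:T, 3, , , drop = FALSE], 1, sum) != 0)) {
      stopf("object peeks out after occlusion onset")
    }
    if (identical(A$frames[T, , , ], B$frames[T, , , ])) {
      stopf("endings do not diverge")
    }
    splice(segmentSet(A, B, ci), "persistence", seed = s,
           meta = list(specs = list(specA, specB), propped_angle = theta_p))
  }))
}

#' Unchangeableness probe: objects swap while occluded by a screen
#'
#' A lineup of static objects is covered by a single full-width screen that
#' descends and then rises.  The two possible videos use mirrored object
#' arrangements; splicing at a fully-covered frame yields impossible videos
#' in which object positions (hence apparent colour/shape at a location)
#' have changed behind the screen.
#' @inheritParams makeContinuityProbe
#' @export
makeUnchangeablenessProbe <- function(rng_seed, profile = deskProfile(),
                                      max_tries = 25L) {
  probe_retry(rng_seed, max_tries, function(s) with_seed(s, {
    T <- profile$T
    tau <- frame_times(T, profile$n_steps, profile$duration)
    cam <- cameraPose(c(0, -9, 2.6), c(0, 0, 1))
    cols <- distinct_colors(3)
    floor_cols <- rand_floor()
    shapes <- sample(c("sphere", "box"), 2, replace = TRUE)
    sz <- stats::runif(2, 0.3, 0.45)
    xpos <- c(-1, 1) * stats::runif(1, 0.9, 1.3)
    y_obj <- 1.2
    mk_obj <- function(id, shape, size, col, x) {
      if (shape == "sphere") {
        objectSpec(id, "sphere", size, col, pos = c(x, y_obj, size))
      } else {
        objectSpec(id, "box", rep(size, 3), col, pos = c(x, y_obj, size))
      }
    }
    screen <- objectSpec(3, "curtain", c(2.4, 0.07, 1.5), cols[[3]],
                         pos = c(0, -0.5, 5.0), behavior = "scripted",
                         script = scriptCurtain(z_hi = 5.0, z_lo = 1.5,
                                                t_down = 0.15, t_bottom = 0.75,
                                                t_up = 1.25, t_top = 1.85))
    build <- function(order12) {
      o1 <- mk_obj(1, shapes[1], sz[1], cols[[1]], xpos[order12[1]])
      o2 <- mk_obj(2, shapes[2], sz[2], cols[[2]], xpos[order12[2]])
      sceneSpec(list(o1, o2, screen), camera = cam,
                floor_colors = floor_cols, seed = s,
                meta = list(concept = "unchangeableness"))
    }
    specA <- build(c(1, 2)); specB <- build(c(2, 1))
    sim <- function(sp) simulateScene(sp, n_steps = profile$n_steps,
                                      frames = T, size = profile$size,
                                      K = profile$K)
    A <- suppressWarnings(sim(specA)); B <- suppressWarnings(sim(specB))
    covered <- which(vapply(seq_len(T), function(i) {
      sum(A$masks[i, 2:3, , ]) == 0 &&
        identical(A$frames[i, , , ], B$frames[i, , , ])
    }, logical(1)))
    covered <- covered[covered >= 2 & covered <= T - 1]
    if (!length(covered)) stopf("screen never fully covers the lineup")
    ci <- max(covered)
    if (sum(A$masks[1, 2, , ]) == 0 || sum(A$masks[1, 3, , ]) == 0) {
      stopf("objects not visible before the screen descends")
    }
    if (identical(A$frames[T, , , ], B$frames[T, , , ])) {
      stopf("arrangements render identically; colours/shapes too similar")
    }
    splice(segmentSet(A, B, ci), "unchangeableness", seed = s,
           meta = list(specs = list(specA, specB)))
  }))
}

#' Solidity probe: a block dropped into a container
#'
#' The camera views inside the top of an open container but not its bottom.
#' Two blocks sharing one cross-section and colour but differing in height
#' are dropped so that their top faces coincide in height while falling;
#' at the common frame both are partially hidden behind the container's
#' front wall with identical visible portions.  The tall block comes to
#' rest visibly protruding, the short one fully hidden.  The mismatched
#' endings show a block that should have stayed visible disappearing (as
#' if it fell through container and floor) and a block that remains
#' visible at the top when it should have fallen further.
#' @inheritParams makeContinuityProbe
#' @export
makeSolidityProbe <- function(rng_seed, profile = deskProfile(),
                              max_tries = 25L) {
  probe_retry(rng_seed, max_tries, function(s) with_seed(s, {
    T <- profile$T
    tau <- frame_times(T, profile$n_steps, profile$duration)
    cam <- cameraPose(c(0, -6.5, 2.6), c(0, 0.6, 1.6))
    cols <- distinct_colors(2)
    floor_cols <- rand_floor()
    s_in <- c(0.55, 0.55, 1.0)              # interior half extents
    cont_z <- 1.05
    container <- objectSpec(1, "open_container", s_in, cols[[1]], mass = 5,
                            pos = c(0, 0.6, cont_z))
    half_xy <- 0.3
    h_tall <- stats::runif(1, 1.05, 1.15)   # half heights
    h_short <- stats::runif(1, 0.3, 0.38)
    z_common <- stats::runif(1, 2.4, 2.6)   # shared top height at common frame
    ci <- 5L
    top0 <- z_common + 0.5 * GRAVITY_DEFAULT * tau[ci]^2
    blk <- function(hh) objectSpec(2, "box", c(half_xy, half_xy, hh), cols[[2]],
                                   mass = 40, pos = c(0, 0.6, top0 - hh),
                                   behavior = "free")
    specA <- sceneSpec(list(container, blk(h_tall)), camera = cam,
                       floor_colors = floor_cols, seed = s,
                       meta = list(concept = "solidity"))
    specB <- sceneSpec(list(container, blk(h_short)), camera = cam,
                       floor_colors = floor_cols, seed = s,
                       meta = list(concept = "solidity"))
    sim <- function(sp) simulateScene(sp, n_steps = profile$n_steps,
                                      frames = T, size = profile$size,
                                      K = profile$K)
    A <- suppressWarnings(sim(specA)); B <- suppressWarnings(sim(specB))
    if (!identical(A$frames[ci, , , ], B$frames[ci, , , ])) {
      stopf("falling blocks not pixel-identical at the common frame")
    }
    if (sum(A$masks[ci, 3, , ]) == 0) stopf("block invisible at common frame")
    if (sum(A$masks[T, 3, , ]) == 0) stopf("tall block should rest visibly")
    if (sum(B$masks[T, 3, , ]) != 0) stopf("short block should rest hidden")
    if (sum(B$masks[1, 3, , ]) == 0) stopf("block not visible initially")
    splice(segmentSet(A, B, ci), "solidity", seed = s,
           meta = list(specs = list(specA, specB)))
  }))
}

#' Directional-inertia probe: a ball reflecting off a heavy block
#'
#' A ball rolls at an angle towards a heavy static block and reflects its
#' velocity about the angle of incidence.  The second possible video is the
#' exact time reversal (it starts at the first video's end point and ends
#' at its start point).  Swapping the trajectories at the contact frame
#' makes the ball head back towards its initial location, violating
#' directional inertia.
#' @inheritParams makeContinuityProbe
#' @export
makeInertiaProbe <- function(rng_seed, profile = deskProfile(),
                             max_tries = 25L) {
  probe_retry(rng_seed, max_tries, function(s) with_seed(s, {
    T <- profile$T
    tau <- frame_times(T, profile$n_steps, profile$duration)
    ci <- (T + 1L) %/% 2L                 # contact at the middle frame (t = 1 s)
    t_contact <- tau[ci]
    cam <- canonical_camera()
    cols <- distinct_colors(2)
    floor_cols <- rand_floor()
    r <- stats::runif(1, 0.4, 0.5)
    bh <- c(stats::runif(1, 0.5, 0.7), 0.5, 0.6)
    bpos <- c(stats::runif(1, -0.4, 0.4), 1.8, 0.6)
    block <- objectSpec(1, "box", bh, cols[[1]], mass = 60, pos = bpos)
    alpha <- stats::runif(1, 25, 55) * pi / 180
    s1 <- sample(c(-1, 1), 1)
    u <- c(s1 * sin(alpha), cos(alpha), 0)
    cx <- bpos[1] + stats::runif(1, -0.6, 0.6) * bh[1]
    C <- c(cx, bpos[2] - bh[2] - r, r)
    L1 <- stats::runif(1, 2.6, 3.4)
    speed <- L1 / t_contact
    u_out <- u - 2 * sum(u * c(0, 1, 0)) * c(0, 1, 0)   # reflect about face normal
    P0 <- C - u * L1
    P1 <- C + u_out * L1
    ball <- function(p, v) objectSpec(2, "sphere", r, cols[[2]], mass = 10,
                                      pos = p, vel = v, behavior = "rolling",
                                      reflect_ids = 1L)
    specA <- sceneSpec(list(block, ball(P0, u * speed)), camera = cam,
                       floor_colors = floor_cols, seed = s,
                       meta = list(concept = "inertia"))
    specB <- sceneSpec(list(block, ball(P1, -u_out * speed)), camera = cam,
                       floor_colors = floor_cols, seed = s,
                       meta = list(concept = "inertia"))
    sim <- function(sp) simulateScene(sp, n_steps = profile$n_steps,
                                      frames = T, size = profile$size,
                                      K = profile$K)
    A <- suppressWarnings(sim(specA)); B <- suppressWarnings(sim(specB))
    if (!identical(A$frames[ci, , , ], B$frames[ci, , , ])) {
      stopf("trajectories not pixel-identical at the contact frame")
    }
    if (sum(A$masks[1, 3, , ]) == 0 || sum(A$masks[T, 3, , ]) == 0) {
      stopf("ball leaves the frustum")
    }
    if (identical(A$frames[T, , , ], B$frames[T, , , ])) stopf("degenerate geometry")
    splice(segmentSet(A, B, ci), "inertia", seed = s,
           meta = list(specs = list(specA, specB), contact_point = C,
                       incidence_angle = alpha))
  }))
}

probe_maker <- function(concept) {
  switch(concept,
         continuity = makeContinuityProbe,
         persistence = makePersistenceProbe,
         unchangeableness = makeUnchangeablenessProbe,
         solidity = makeSolidityProbe,
         inertia = makeInertiaProbe,
         stopf("unknown concept %s", concept))
}

#' Generate a verified probe set
#'
#' @param concept concept name.
#' @param n_tuples number of tuples.
#' @param seed integer seed; tuple i uses a seed derived from (seed, i).
#' @param out optional directory; when given, tuples are written as a
#'   dataset with a manifest (see [writeDataset()]).
#' @param profile scale profile.
#' @param verify re-verify every tuple (on by default).
#' @return invisibly, the list of tuples (also written to `out` if given).
#' @export
generateProbeSet <- function(concept, n_tuples, seed, out = NULL,
                             profile = deskProfile(), verify = TRUE) {
  concept <- match.arg(concept, CONCEPTS)
  maker <- probe_maker(concept)
  tuples <- vector("list", n_tuples)
  for (i in seq_len(n_tuples)) {
    tuples[[i]] <- maker(derive_seed(seed, i), profile = profile)
    if (verify && !verifyProbeTuple(tuples[[i]])$pass) {
      stopf("tuple %d failed verification", i)
    }
  }
  if (!is.null(out)) writeDataset(tuples, out, kind = "probe", seed = seed)
  invisible(tuples)
}
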