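# Freeform training scenes: procedurally composed physical events.
# Building blocks compose by advertising and/or consuming locations of
# interest; with some probability blocks do not compose and coexist
# independently.  Object masses follow the stereotyped table: rolled and
# stacked objects 10, dropped/thrown objects 40 (four times heavier, so they
# displace what they hit), containers 4 or 5, arches 60 in total.

FREEFORM_BLOCKS <- c("rolling", "ground_collision", "drop_collision",
                     "curtain", "stack", "covering", "containment", "ramp")

#' Freeform generator configuration
#'
#' @param blocks enabled building-block types.
#' @param n_blocks_range inclusive range for the number of blocks per scene.
#' @param p_compose probability that a block consumes an advertised location
#'   of interest rather than placing itself independently.
#' @param K_max number of mask channels; scenes use at most `K_max - 1`
#'   movable objects (channel 0 is reserved for the floor).
#' @export
freeformConfig <- function(blocks = FREEFORM_BLOCKS,
                           n_blocks_range = c(2L, 4L),
                           p_compose = 0.6, K_max = 4L) {
  blocks <- match.arg(blocks, FREEFORM_BLOCKS, several.ok = TRUE)
  list(blocks = blocks, n_blocks_range = as.integer(n_blocks_range),
       p_compose = p_compose, K_max = as.integer(K_max))
}

# number of object ids each block consumes
block_cost <- function(kind, config) {
  switch(kind, rolling = 1L, ground_collision = 2L, drop_collision = 1L,
         curtain = 1L, stack = if (config$K_max >= 8) 3L else 2L,
         covering = 1L, containment = 1L, ramp = 2L)
}

rand_pos <- function() c(stats::runif(1, -2.2, 2.2), stats::runif(1, -0.5, 2.6))

# Each builder returns list(objects = list of objectSpec, advertise = list of
# xy locations of interest, desc = block descriptor record).
build_block <- function(kind, ids, target_xy, duration) {
  adv <- list()
  objs <- list()
  if (kind == "rolling") {
    r <- stats::runif(1, 0.35, 0.5)
    to <- target_xy %||% rand_pos()
    ang <- stats::runif(1, 0, 2 * pi)
    dist <- stats::runif(1, 2.5, 4)
    from <- to + dist * c(cos(ang), sin(ang))
    v <- (to - from) / (0.8 * duration)
    objs[[1]] <- objectSpec(ids[1], "sphere", r, rand_color(), mass = 10,
                            pos = c(from, r), vel = c(v, 0),
                            behavior = "rolling")
    adv <- list(from)
  } else if (kind == "ground_collision") {
    r <- stats::runif(2, 0.35, 0.5)
    meet <- target_xy %||% rand_pos()
    ang <- stats::runif(1, 0, 2 * pi)
    d1 <- stats::runif(1, 1.8, 2.8); d2 <- stats::runif(1, 1.8, 2.8)
    p1 <- meet + d1 * c(cos(ang), sin(ang))
    p2 <- meet - d2 * c(cos(ang), sin(ang))
    t_meet <- 0.55 * duration
    objs[[1]] <- objectSpec(ids[1], "sphere", r[1], rand_color(), mass = 10,
                            pos = c(p1, r[1]), vel = c((meet - p1) / t_meet, 0),
                            behavior = "rolling")
    objs[[2]] <- objectSpec(ids[2], "sphere", r[2], rand_color(), mass = 10,
                            pos = c(p2, r[2]), vel = c((meet - p2) / t_meet, 0),
                            behavior = "rolling")
  } else if (kind == "drop_collision") {
    half <- stats::runif(3, 0.25, 0.4)
    at <- target_xy %||% rand_pos()
    h <- stats::runif(1, 2.5, 4)
    objs[[1]] <- objectSpec(ids[1], "box", half, rand_color(), mass = 40,
                            pos = c(at + stats::runif(2, -0.1, 0.1), h),
                            vel = c(0, 0, 0), behavior = "free",
                            kick_ids = setdiff(seq_len(7L), ids[1]))
    adv <- list(at)
  } else if (kind == "curtain") {
    w <- stats::runif(1, 1.2, 2.0)
    x <- stats::runif(1, -1.5, 1.5)
    objs[[1]] <- objectSpec(ids[1], "curtain", c(w, 0.07, 1.3), rand_color(),
                            mass = 10, pos = c(x, 0.2, 4.5),
                            behavior = "scripted",
                            script = scriptCurtain(z_hi = 4.5, z_lo = 1.3,
                                                   t_down = 0.15 * duration,
                                                   t_bottom = 0.45 * duration,
                                                   t_up = 0.6 * duration,
                                                   t_top = 0.9 * duration))
  } else if (kind == "stack") {
    at <- target_xy %||% rand_pos()
    n <- length(ids)
    z <- 0
    for (i in seq_len(n)) {
      half <- stats::runif(1, 0.28, 0.42)
      objs[[i]] <- objectSpec(ids[i], "box", rep(half, 3), rand_color(),
                              mass = 10, pos = c(at, z + half))
      z <- z + 2 * half
    }
    adv <- list(at)
  } else if (kind == "covering") {
    at <- target_xy %||% rand_pos()
    s <- stats::runif(1, 0.45, 0.6)
    objs[[1]] <- objectSpec(ids[1], "closed_container", c(s, s, s * 1.2),
                            rand_color(), mass = 4,
                            pos = c(at, 3.4), behavior = "free")
    adv <- list(at)
  } else if (kind == "containment") {
    at <- target_xy %||% rand_pos()
    s <- stats::runif(1, 0.5, 0.65)
    objs[[1]] <- objectSpec(ids[1], "open_container", c(s, s, s * 1.3),
                            rand_color(), mass = 5, pos = c(at, s * 1.3 + 0.01))
    adv <- list(at)
  } else if (kind == "ramp") {
    at <- target_xy %||% rand_pos()
    alpha <- stats::runif(1, 0.35, 0.55)
    len <- stats::runif(1, 1.6, 2.2)
    ang <- stats::runif(1, 0, 2 * pi)
    downhill <- c(cos(ang), sin(ang))
    base <- at - downhill * len * cos(alpha)
    ramp_q <- quat_axis_angle(c(-sin(ang), cos(ang), 0), -alpha)
    objs[[1]] <- objectSpec(ids[1], "ramp", c(0.8, len, 0.08), rand_color(),
                            mass = 10,
                            pos = c(base + downhill * len * cos(alpha) / 2,
                                    len * sin(alpha) / 2 + 0.08),
                            quat = ramp_q)
    r <- stats::runif(1, 0.3, 0.4)
    top <- c(base, len * sin(alpha) + r + 0.16)
    slope_dir <- c(downhill * cos(alpha), -sin(alpha))
    t_slope <- sqrt(2 * len / (GRAVITY_DEFAULT * sin(alpha)))
    objs[[2]] <- objectSpec(ids[2], "sphere", r, rand_color(), mass = 10,
                            pos = top, behavior = "scripted",
                            script = scriptRampRoll(p0 = top, dir = slope_dir,
                                                    accel = GRAVITY_DEFAULT * sin(alpha),
                                                    t_slope = t_slope,
                                                    floor_z = r))
    adv <- list(at)
  }
  list(objects = objs, advertise = adv,
       desc = list(kind = kind, ids = ids,
                   target = if (!is.null(target_xy)) target_xy else NULL))
}

#' Sample a freeform scene specification
#'
#' Chooses two to four enabled building blocks (subject to the mask-channel
#' budget), composes them through advertised/consumed locations of interest,
#' and randomizes appearances (random RGB object colours and checkerboard
#' floor colours) and positions.  Fixed seeds give byte-identical specs.
#'
#' @param rng_seed integer seed.
#' @param config a [freeformConfig()].
#' @param max_tries bounded retries for unsatisfiable compositions.
#' @return a `SceneSpec` with a drifting camera.
#' @export
sampleFreeformScene <- function(rng_seed, config = freeformConfig(),
                                max_tries = 20L) {
  for (a in seq_len(max_tries)) {
    s <- if (a == 1) as.integer(rng_seed) else derive_seed(rng_seed, 5000L + a)
    out <- with_seed(s, try_sample_freeform(s, config))
    if (!is.null(out)) return(out)
  }
  stopf("could not compose a freeform scene after %d attempts", max_tries)
}

try_sample_freeform <- function(s, config) {
  budget <- config$K_max - 1L
  n_blocks <- sample(seq(config$n_blocks_range[1], config$n_blocks_range[2]), 1)
  kinds <- character(0)
  used <- 0L
  for (b in seq_len(n_blocks)) {
    fits <- Filter(function(k) used + block_cost(k, config) <= budget,
                   config$blocks)
    if (!length(fits)) break
    k <- if (length(fits) == 1) fits[[1]] else sample(fits, 1)
    kinds <- c(kinds, k)
    used <- used + block_cost(k, config)
  }
  if (length(kinds) < config$n_blocks_range[1]) return(NULL)

  next_id <- 1L
  objs <- list()
  advertised <- list()
  descs <- list()
  for (k in kinds) {
    cost <- block_cost(k, config)
    ids <- seq.int(next_id, length.out = cost)
    next_id <- next_id + cost
    tgt <- NULL
    if (length(advertised) && stats::runif(1) < config$p_compose) {
      tgt <- advertised[[sample.int(length(advertised), 1)]]
    }
    blk <- build_block(k, ids, tgt, duration = 2)
    objs <- c(objs, blk$objects)
    advertised <- c(advertised, blk$advertise)
    descs[[length(descs) + 1]] <- blk$desc
  }
  sceneSpec(objs, camera = "drifting", floor_colors = rand_floor(),
            seed = s, blocks = descs, meta = list(kind = "freeform"))
}

#' Generate a freeform video dataset
#'
#' @param n number of videos.
#' @param seed master seed; video i uses a seed derived from (seed, i).
#' @param out optional dataset directory.
#' @param profile scale profile controlling resolution, steps and channels.
#' @param config freeform generator configuration; defaults to all blocks at
#'   the profile's channel budget.
#' @return invisibly, the list of `VideoRecord`s.
#' @export
generateFreeform <- function(n, seed, out = NULL, profile = deskProfile(),
                             config = NULL) {
  if (is.null(config)) config <- freeformConfig(K_max = profile$K)
  vids <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- sampleFreeformScene(derive_seed(seed, i), config)
    vids[[i]] <- suppressWarnings(
      simulateScene(sp, n_steps = profile$n_steps, frames = profile$T,
                    size = profile$size, K = profile$K))
  }
  if (!is.null(out)) writeDataset(vids, out, kind = "freeform", seed = seed,
                                  config = config)
  invisible(vids)
}
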