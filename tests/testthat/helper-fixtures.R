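# Shared tiny fixtures, built in code.  tiny_profile() keeps unit tests fast;
# the acceptance suite uses the full desk profile.

tiny_profile <- function() {
  prof <- deskProfile()
  prof$size <- 16L
  prof$n_steps <- 350L
  prof$enc_hidden <- 48L
  prof$dec_hidden <- 16L
  prof$D <- 4L
  prof$H_lstm <- 32L
  prof$proj_dim <- 24L
  prof$mlp_units <- 16L
  prof$cam_embed <- 8L
  prof
}

# cache expensive fixtures across test files within one run
.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

drop_sphere_spec <- function(h = 3.5, r = 0.5, seed = 1L) {
  sceneSpec(list(objectSpec(1, "sphere", r, c(0.9, 0.2, 0.2), mass = 40,
                            pos = c(0, 0.5, h), behavior = "free")),
            camera = "fixed", seed = seed)
}

# symbolic-frame video records: each "frame" is a tiny uniform image with a
# distinct gray level, so frames compare exactly and are easy to name
symbolic_video <- function(levels, K = 2L, size = 4L) {
  T <- length(levels)
  fr <- array(0L, dim = c(T, size, size, 3))
  for (t in seq_len(T)) fr[t, , , ] <- as.integer(levels[t])
  mk <- array(0L, dim = c(T, K, size, size))
  mk[, 1, , ] <- 1L
  cam <- matrix(rep(pose_to_vec(physvoe:::canonical_camera()), each = T), T, 7)
  videoRecord(fr, mk, cam)
}

voe_fix <- function() cached("voe_fix", {
  prof <- tiny_profile()
  list(prof = prof,
       perc = perceptionInit(prof, seed = 31),
       tup = physvoe:::probe_maker("unchangeableness")(401L, profile = prof))
})

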