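# Scale profiles.  The full-scale profile records the reference configuration
# (64x64 frames, 8 slots, 16-d codes, 2056 LSTM units, 1680-d buffer
# projection, RMSProp 1e-4, 1e6 perception steps, 1.3e6 dynamics steps with a
# 1e-4 -> 4e-5 schedule after 3e5 steps, batch sizes 64/128) as documented
# configuration.  The desk profile is a deliberately small configuration that
# runs end-to-end on one CPU; it is not a replication of full scale.

#' Named hyperparameter profiles
#'
#' @param scale `"desk"` (small, CPU-friendly) or `"full"` (the documented
#'   full-scale defaults).
#' @return a named list of configuration values.
#' @export
runProfile <- function(scale = c("desk", "full")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    list(
      scale = "full",
      T = 15L, size = 64L, K = 8L, n_steps = 3000L, duration = 2,
      D = 16L, H_lstm = 2056L, proj_dim = 1680L,
      mlp_units = 512L, mlp_layers = 3L, cam_embed = 16L,
      enc_hidden = 256L, dec_hidden = 64L,
      beta = 0.1, gamma = 10,
      perception_lr = 1e-4, perception_steps = 1e6L, perception_batch = 64L,
      dynamics_lr = 1e-4, dynamics_lr_after = 4e-5, dynamics_lr_switch = 3e5L,
      dynamics_steps = 1.3e6L, dynamics_batch = 128L,
      n_train_videos = 300000L
    )
  } else {
    list(
      scale = "desk",
      T = 15L, size = 24L, K = 4L, n_steps = 400L, duration = 2,
      D = 8L, H_lstm = 256L, proj_dim = 128L,
      mlp_units = 64L, mlp_layers = 3L, cam_embed = 16L,
      enc_hidden = 128L, dec_hidden = 24L,
      beta = 0.1, gamma = 10,
      perception_lr = 1e-3, perception_steps = 700L, perception_batch = 8L,
      dynamics_lr = 1e-3, dynamics_lr_after = 4e-4, dynamics_lr_switch = 500L,
      dynamics_steps = 800L, dynamics_batch = 8L,
      n_train_videos = 2000L
    )
  }
}

#' @rdname runProfile
#' @export
deskProfile <- function() runProfile("desk")

#' @rdname runProfile
#' @export
fullProfile <- function() runProfile("full")
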