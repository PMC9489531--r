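# Dynamics predictor: the InteractionLSTM.  Per-slot LSTM with shared
# weights and object-specific activations; an interaction network computing
# pairwise messages from each slot's previous cell state to all cell states
# (MLP rho) and to all projected object buffers (MLP lambda), aggregated as
# concat(sum, max); camera conditioning (current pose for the interactions,
# next pose for the LSTM); and a residual connection from the current object
# code to the prediction.
#
# The forward pass is written once against a small op interface and run
# either on plain matrices (evaluation) or on the autodiff tape (training),
# so the two paths cannot drift apart.

#' Dynamics model configuration
#'
#' @param variant `"plato"` (object slots), `"fep"` (flat, equal parameters:
#'   a single slot with the same code dimension, hence exactly PLATO's
#'   dynamics parameter count) or `"fec"` (flat, equal capacity: a single
#'   slot with a K*D-dimensional code).
#' @param profile scale profile.
#' @return a config list (K, D, T, H, proj, mlp units/layers, camera
#'   embedding size).
#' @export
dynamicsConfig <- function(variant = c("plato", "fep", "fec"),
                           profile = deskProfile()) {
  variant <- match.arg(variant)
  K <- switch(variant, plato = profile$K, 1L)
  D <- switch(variant, plato = profile$D, fep = profile$D,
              fec = profile$K * profile$D)
  list(variant = variant, K = as.integer(K), D = as.integer(D),
       T = profile$T, H = profile$H_lstm, P = profile$proj_dim,
       U = profile$mlp_units, E = profile$cam_embed)
}

#' Flat baseline configuration
#'
#' Flat models encode the entire scene in a single slot; their mask input is
#' a single channel uniformly filled with 1.
#' @param kind `"fep"` or `"fec"`.
#' @param profile scale profile.
#' @export
makeFlatVariant <- function(kind = c("fep", "fec"), profile = deskProfile()) {
  dynamicsConfig(match.arg(kind), profile)
}

dynamics_param_shapes <- function(cfg) {
  insz <- cfg$P + 2L * cfg$U + cfg$E
  list(
    proj_W = c((cfg$T - 1L) * cfg$D, cfg$P), proj_b = c(1, cfg$P),
    cam_int_W = c(7, cfg$E), cam_int_b = c(1, cfg$E),
    cam_lstm_W = c(7, cfg$E), cam_lstm_b = c(1, cfg$E),
    rho_W1 = c(2L * cfg$H + cfg$E, cfg$U), rho_b1 = c(1, cfg$U),
    rho_W2 = c(cfg$U, cfg$U), rho_b2 = c(1, cfg$U),
    rho_W3 = c(cfg$U, cfg$U), rho_b3 = c(1, cfg$U),
    lam_W1 = c(cfg$H + cfg$P + cfg$E, cfg$U), lam_b1 = c(1, cfg$U),
    lam_W2 = c(cfg$U, cfg$U), lam_b2 = c(1, cfg$U),
    lam_W3 = c(cfg$U, cfg$U), lam_b3 = c(1, cfg$U),
    lstm_Wx = c(insz, 4L * cfg$H), lstm_Wh = c(cfg$H, 4L * cfg$H),
    lstm_b = c(1, 4L * cfg$H),
    head_W = c(cfg$H, cfg$D), head_b = c(1, cfg$D)
  )
}

#' Exact trainable-parameter count of the dynamics predictor
#'
#' Shared slot weights mean the count is independent of K: the flat
#' equal-parameters baseline matches PLATO exactly, while the flat
#' equal-capacity baseline exceeds it through the wider buffer projection
#' and prediction head.
#' @param cfg a [dynamicsConfig()].
#' @return integer parameter count.
#' @export
countParameters <- function(cfg) {
  sum(vapply(dynamics_param_shapes(cfg), prod, numeric(1)))
}

#' Initialise a dynamics model
#' @param cfg a [dynamicsConfig()].
#' @param seed integer seed for weight initialisation.
#' @export
dynamicsInit <- function(cfg, seed = 1L) {
  with_seed(seed, {
    shapes <- dynamics_param_shapes(cfg)
    params <- list()
    for (nm in names(shapes)) {
      s <- shapes[[nm]]
      params[[nm]] <- if (s[1] == 1) matrix(0, 1, s[2]) else
        matrix(stats::rnorm(prod(s), 0, 1 / sqrt(s[1])), s[1], s[2])
    }
    structure(list(cfg = cfg, params = params, seed = as.integer(seed)),
              class = "physvoe_dynamics")
  })
}

#' @export
print.physvoe_dynamics <- function(x, ...) {
  cat(sprintf("<dynamics %s: K=%d D=%d H=%d proj=%d, %d params>\n",
              x$cfg$variant, x$cfg$K, x$cfg$D, x$cfg$H, x$cfg$P,
              countParameters(x$cfg)))
  invisible(x)
}

# ---- op backends -----------------------------------------------------------

plain_ops <- function() {
  elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 30)) - 1)
  list(
    input = function(x) as.matrix(x),
    value = function(h) h,
    mm = function(a, b) a %*% b,
    bias = function(a, b) a + rep(as.numeric(b), each = nrow(a)),
    add = function(a, b) a + b,
    mul = function(a, b) a * b,
    cbind = function(l) do.call(cbind, l),
    rbind = function(l) do.call(rbind, l),
    sum_all = function(a) matrix(sum(a), 1, 1),
    rows = function(a, idx) a[idx, , drop = FALSE],
    cols = function(a, jdx) a[, jdx, drop = FALSE],
    group_sum = function(a, groups, ngroup) {
      out <- rowsum(a, group = groups)
      full <- matrix(0, ngroup, ncol(a))
      full[as.integer(rownames(out)), ] <- out
      full
    },
    group_max = function(a, groups, ngroup) {
      out <- matrix(-Inf, ngroup, ncol(a))
      for (r in seq_len(nrow(a))) {
        gset <- groups[r]
        out[gset, ] <- pmax(out[gset, ], a[r, ])
      }
      out
    },
    elu = elu,
    gelu = function(x) x * stats::pnorm(x),
    sigmoid = function(x) 1 / (1 + exp(-x)),
    tanh = function(x) tanh(x)
  )
}

tape_ops <- function(tp) {
  list(
    input = function(x) ad_input(tp, x),
    value = function(h) ad_value(tp, h),
    mm = function(a, b) ad_matmul(tp, a, b),
    bias = function(a, b) ad_bias(tp, a, b),
    add = function(a, b) ad_add(tp, a, b),
    mul = function(a, b) ad_mul(tp, a, b),
    cbind = function(l) ad_cbind(tp, l),
    rbind = function(l) ad_rbind(tp, l),
    sum_all = function(a) ad_sum(tp, a),
    rows = function(a, idx) ad_rows(tp, a, idx),
    cols = function(a, jdx) ad_cols(tp, a, jdx),
    group_sum = function(a, groups, ngroup) ad_group_sum(tp, a, groups, ngroup),
    group_max = function(a, groups, ngroup) ad_group_max(tp, a, groups, ngroup),
    elu = function(a) ad_elu(tp, a),
    gelu = function(a) ad_gelu(tp, a),
    sigmoid = function(a) ad_sigmoid(tp, a),
    tanh = function(a) ad_tanh(tp, a)
  )
}

mlp3 <- function(ops, x, W1, b1, W2, b2, W3, b3) {
  h1 <- ops$gelu(ops$bias(ops$mm(x, W1), b1))
  h2 <- ops$gelu(ops$bias(ops$mm(h1, W2), b2))
  ops$gelu(ops$bias(ops$mm(h2, W3), b3))
}

#' Project zero-padded object buffers
#'
#' Each slot's flattened history ((T-1) x D, zero-padded at the future end)
#' is mapped by one linear layer to the projection space and passed through
#' the Exponential Linear Unit.  All-zero padding therefore maps to the
#' activation of the map's bias.
#' @param model dynamics model.
#' @param buffer matrix with (T-1)*D columns; rows are slots.
#' @return rows x P matrix.
#' @export
projectBuffer <- function(model, buffer) {
  ops <- plain_ops()
  p <- model$params
  ops$elu(ops$bias(ops$mm(as.matrix(buffer), p$proj_W), p$proj_b))
}

# pairwise index vectors for B scenes of K slots, rows ordered scene-major
pair_index <- function(B, K) {
  from <- rep(seq_len(B * K), each = K)
  to <- integer(B * K * K)
  idx <- 1L
  for (b in seq_len(B)) for (k in seq_len(K)) for (j in seq_len(K)) {
    to[idx] <- (b - 1L) * K + j; idx <- idx + 1L
  }
  list(from = from, to = to)
}

# one InteractionLSTM step over ops; all arguments are backend handles
# except cfg/B/pidx.  Returns list(pred, cell, hidden, int).
ilstm_step <- function(ops, ids, cfg, B, pidx, codes_t, projbuf,
                       cells, hiddens, camE_int_rows, camE_lstm_rows,
                       cam_pair) {
  K <- cfg$K; H <- cfg$H
  from_cells <- ops$rows(cells, pidx$from)
  rho_in <- ops$cbind(list(from_cells, ops$rows(cells, pidx$to), cam_pair))
  msg_rho <- mlp3(ops, rho_in, ids$rho_W1, ids$rho_b1, ids$rho_W2,
                  ids$rho_b2, ids$rho_W3, ids$rho_b3)
  lam_in <- ops$cbind(list(from_cells, ops$rows(projbuf, pidx$to), cam_pair))
  msg_lam <- mlp3(ops, lam_in, ids$lam_W1, ids$lam_b1, ids$lam_W2,
                  ids$lam_b2, ids$lam_W3, ids$lam_b3)
  groups <- c(pidx$from, pidx$from)
  msgs <- ops$rbind(list(msg_rho, msg_lam))
  int_sum <- ops$group_sum(msgs, groups, B * K)
  int_max <- ops$group_max(msgs, groups, B * K)
  int_k <- ops$cbind(list(int_sum, int_max))
  lstm_in <- ops$cbind(list(projbuf, int_k, camE_lstm_rows))
  gates <- ops$bias(ops$add(ops$mm(lstm_in, ids$lstm_Wx),
                            ops$mm(hiddens, ids$lstm_Wh)), ids$lstm_b)
  gi <- ops$sigmoid(ops$cols(gates, seq_len(H)))
  gf <- ops$sigmoid(ops$cols(gates, H + seq_len(H)))
  gg <- ops$tanh(ops$cols(gates, 2L * H + seq_len(H)))
  go <- ops$sigmoid(ops$cols(gates, 3L * H + seq_len(H)))
  cell_new <- ops$add(ops$mul(gf, cells), ops$mul(gi, gg))
  hidden_new <- ops$mul(go, ops$tanh(cell_new))
  pred <- ops$add(ops$bias(ops$mm(hidden_new, ids$head_W), ids$head_b),
                  codes_t)                       # residual from z_k^t
  list(pred = pred, cell = cell_new, hidden = hidden_new, int = int_k)
}

cam_embed <- function(ops, ids, cam, which = c("int", "lstm")) {
  which <- match.arg(which)
  W <- if (which == "int") ids$cam_int_W else ids$cam_lstm_W
  b <- if (which == "int") ids$cam_int_b else ids$cam_lstm_b
  ops$elu(ops$bias(ops$mm(cam, W), b))
}

#' Pairwise interaction for one set of slot states
#'
#' Exposes the interaction-network computation on plain matrices: messages
#' from each slot's cell state to every cell state (including itself) and
#' to every slot's projected buffer, with the current camera embedding
#' appended to each message input, aggregated as concat(sum, max).
#'
#' @param model dynamics model.
#' @param cells K x H matrix of previous cell states.
#' @param projbuf K x P matrix of projected buffers.
#' @param cam_now length-7 camera vector for the current frame.
#' @return K x 2U matrix of per-slot interactions.
#' @export
interactionMessages <- function(model, cells, projbuf, cam_now) {
  ops <- plain_ops()
  cfg <- model$cfg; K <- nrow(cells)
  pidx <- pair_index(1L, K)
  camE <- cam_embed(ops, model$params, matrix(cam_now, 1), "int")
  cam_pair <- camE[rep(1L, K * K), , drop = FALSE]
  from_cells <- cells[pidx$from, , drop = FALSE]
  msg_rho <- mlp3(ops, cbind(from_cells, cells[pidx$to, , drop = FALSE], cam_pair),
                  model$params$rho_W1, model$params$rho_b1,
                  model$params$rho_W2, model$params$rho_b2,
                  model$params$rho_W3, model$params$rho_b3)
  msg_lam <- mlp3(ops, cbind(from_cells, projbuf[pidx$to, , drop = FALSE], cam_pair),
                  model$params$lam_W1, model$params$lam_b1,
                  model$params$lam_W2, model$params$lam_b2,
                  model$params$lam_W3, model$params$lam_b3)
  msgs <- rbind(msg_rho, msg_lam)
  groups <- c(pidx$from, pidx$from)
  cbind(ops$group_sum(msgs, groups, K), ops$group_max(msgs, groups, K))
}

# teacher-forced forward over a batch of code sequences.
# codes_list: list of B arrays T x K x D; cameras: list of B T x 7 matrices.
# Returns predictions for t = 2..T as list over t of (B*K x D) and the loss.
dynamics_forward <- function(model, codes_list, cameras, ops = plain_ops(),
                             ids = NULL, collect = TRUE) {
  cfg <- model$cfg
  K <- cfg$K; D <- cfg$D; T <- cfg$T; H <- cfg$H
  B <- length(codes_list)
  if (is.null(ids)) ids <- lapply(model$params, ops$input)
  pidx <- pair_index(B, K)
  cam_rows <- rep(seq_len(B), each = K)
  cam_pair_rows <- rep(seq_len(B), each = K * K)

  buffer <- matrix(0, B * K, (T - 1L) * D)
  cells <- ops$input(matrix(0, B * K, H))
  hiddens <- ops$input(matrix(0, B * K, H))
  zero <- ops$input(matrix(0, 1, 1))
  loss <- NULL
  preds <- if (collect) vector("list", T - 1L) else NULL

  codes_mat <- function(t) {
    m <- matrix(0, B * K, D)
    for (b in seq_len(B)) m[(b - 1L) * K + seq_len(K), ] <- codes_list[[b]][t, , ]
    m
  }
  cam_mat <- function(t) {
    m <- matrix(0, B, 7)
    for (b in seq_len(B)) m[b, ] <- cameras[[b]][t, ]
    m
  }

  for (t in seq_len(T - 1L)) {
    zt <- codes_mat(t)
    buffer[, ((t - 1L) * D + 1L):(t * D)] <- zt
    projbuf <- ops$elu(ops$bias(ops$mm(ops$input(buffer), ids$proj_W),
                                ids$proj_b))
    camE_int <- cam_embed(ops, ids, ops$input(cam_mat(t)), "int")
    camE_lstm <- cam_embed(ops, ids, ops$input(cam_mat(t + 1L)), "lstm")
    st <- ilstm_step(ops, ids, cfg, B, pidx,
                     codes_t = ops$input(zt), projbuf = projbuf,
                     cells = cells, hiddens = hiddens,
                     camE_int_rows = NULL,
                     camE_lstm_rows = ops$rows(camE_lstm, cam_rows),
                     cam_pair = ops$rows(camE_int, cam_pair_rows))
    cells <- st$cell; hiddens <- st$hidden
    if (collect) preds[[t]] <- st$pred
    diff <- ops$add(st$pred, ops$input(-codes_mat(t + 1L)))
    term <- ops$sum_all(ops$mul(diff, diff))
    loss <- if (is.null(loss)) term else ops$add(loss, term)
  }
  list(loss = loss, preds = preds, ids = ids)
}

#' Teacher-forced object-code prediction loss
#'
#' Sum over t = 1..T-1 and all K slots of the squared error between the
#' observed next object codes and the model's predictions.
#' @param model dynamics model.
#' @param codes T x K x D array of observed object codes for one video.
#' @param camera T x 7 camera track.
#' @return scalar loss.
#' @export
dynamicsLoss <- function(model, codes, camera) {
  out <- dynamics_forward(model, list(codes), list(camera), collect = FALSE)
  out$loss[1, 1]
}

#' Teacher-forced next-step predictions for one video
#'
#' @param model dynamics model.
#' @param codes T x K x D array of observed codes.
#' @param camera T x 7 camera track.
#' @return (T-1) x K x D array; entry t is the prediction for frame t+1.
#' @export
dynamicsPredict <- function(model, codes, camera) {
  cfg <- model$cfg
  out <- dynamics_forward(model, list(codes), list(camera), collect = TRUE)
  preds <- array(0, dim = c(cfg$T - 1L, cfg$K, cfg$D))
  for (t in seq_len(cfg$T - 1L)) preds[t, , ] <- out$preds[[t]]
  preds
}

#' Closed-loop rollout after a teacher-forced prefix
#'
#' Frames 1..`prefix` use observed codes; afterwards the model's own
#' predictions are fed back as inputs.  Diagnostic use only.
#' @param model dynamics model.
#' @param codes T x K x D observed codes.
#' @param camera T x 7 camera track.
#' @param prefix number of teacher-forced frames.
#' @return (T-1) x K x D array of predictions.
#' @export
dynamicsRollout <- function(model, codes, camera, prefix = 5L) {
  cfg <- model$cfg
  K <- cfg$K; D <- cfg$D; T <- cfg$T; H <- cfg$H
  ops <- plain_ops()
  ids <- model$params
  pidx <- pair_index(1L, K)
  buffer <- matrix(0, K, (T - 1L) * D)
  cells <- matrix(0, K, H); hiddens <- matrix(0, K, H)
  preds <- array(0, dim = c(T - 1L, K, D))
  inp <- codes[1, , , drop = FALSE]
  zt <- matrix(codes[1, , ], K, D)
  for (t in seq_len(T - 1L)) {
    buffer[, ((t - 1L) * D + 1L):(t * D)] <- zt
    projbuf <- ops$elu(ops$bias(buffer %*% ids$proj_W, ids$proj_b))
    camE_int <- cam_embed(ops, ids, matrix(camera[t, ], 1), "int")
    camE_lstm <- cam_embed(ops, ids, matrix(camera[t + 1L, ], 1), "lstm")
    st <- ilstm_step(ops, ids, cfg, 1L, pidx, zt, projbuf, cells, hiddens,
                     NULL, camE_lstm[rep(1L, K), , drop = FALSE],
                     camE_int[rep(1L, K * K), , drop = FALSE])
    cells <- st$cell; hiddens <- st$hidden
    preds[t, , ] <- st$pred
    zt <- if (t + 1L <= prefix) matrix(codes[t + 1L, , ], K, D) else st$pred
  }
  preds
}

#' Train the dynamics predictor
#'
#' Teacher-forced next-code prediction with RMSProp; the learning rate
#' drops to `dynamics_lr_after` after `dynamics_lr_switch` steps.  Object
#' codes are fresh posterior samples per frame (seeded).
#'
#' @param encoded list with `codes` (list of T x K x D arrays) and
#'   `cameras` (list of T x 7 matrices), e.g. from [encodeVideos()].
#' @param cfg dynamics configuration.
#' @param profile scale profile (steps, batch, learning rates).
#' @param seed integer seed.
#' @param steps,batch optional overrides.
#' @param verbose print progress.
#' @return trained `physvoe_dynamics` with `history` attribute.
#' @export
trainDynamics <- function(encoded, cfg, profile = deskProfile(), seed = 1L,
                          steps = NULL, batch = NULL, verbose = FALSE) {
  steps <- as.integer(steps %||% profile$dynamics_steps)
  batch <- as.integer(batch %||% profile$dynamics_batch)
  model <- dynamicsInit(cfg, seed = seed)
  state <- NULL
  history <- numeric(0)
  n <- length(encoded$codes)
  with_seed(derive_seed(seed, 47L), {
    for (s in seq_len(steps)) {
      vi <- sample.int(n, batch, replace = TRUE)
      tp <- ad_tape()
      ops <- tape_ops(tp)
      ids <- ad_params(tp, model$params)
      out <- dynamics_forward(model, encoded$codes[vi], encoded$cameras[vi],
                              ops = ops, ids = ids, collect = FALSE)
      grads <- ad_backward(tp, out$loss)
      g <- ad_param_grads(grads, ids, model$params)
      lr <- if (s <= profile$dynamics_lr_switch) profile$dynamics_lr else
        profile$dynamics_lr_after
      up <- rmsprop_update(model$params, g, state, lr)
      model$params <- up$params; state <- up$state
      if (s %% 25L == 0L || s == 1L) {
        v <- ad_value(tp, out$loss)[1, 1]
        history <- c(history, v)
        if (verbose) message(sprintf("dynamics step %d  loss %.4f", s, v))
      }
    }
  })
  attr(model, "history") <- history
  model
}
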