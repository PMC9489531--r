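# Perception module: a slotted component VAE.  Each frame is decomposed by
# the ground-truth masks into K object image-mask pairs; a shared encoder
# maps each pair to a D-dimensional diagonal-Gaussian posterior (the floor
# slot has its own parameter set), and a spatial broadcast decoder maps a
# sampled code back to an object image and mask.  Empty channels are tasked
# with reconstructing an all-zero object image and mask, so after training
# the code space represents "no object" near the unit-Gaussian prior.

init_mat <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
}
init_row <- function(nc) matrix(0, 1, nc)

perception_param_shapes <- function(H, W, D, eh, dh) {
  inp <- H * W * 4L
  list(enc_W1 = c(inp, eh), enc_b1 = c(1, eh),
       enc_Wmu = c(eh, D), enc_bmu = c(1, D),
       enc_Wlv = c(eh, D), enc_blv = c(1, D),
       dec_W1 = c(D + 2L, dh), dec_b1 = c(1, dh),
       dec_W2 = c(dh, dh), dec_b2 = c(1, dh),
       dec_W3 = c(dh, 4L), dec_b3 = c(1, 4L))
}

init_param_set <- function(shapes) {
  out <- list()
  for (nm in names(shapes)) {
    s <- shapes[[nm]]
    out[[nm]] <- if (s[1] == 1) init_row(s[2]) else init_mat(s[1], s[2])
  }
  out
}

#' Initialise a perception model
#'
#' @param profile scale profile (uses size, K, D, enc_hidden, dec_hidden,
#'   beta, gamma).
#' @param seed integer seed for weight initialisation.
#' @return a `physvoe_perception` model.  Non-floor slots share one weight
#'   set; the floor slot (mask channel 0) has its own encoder and decoder
#'   parameters.
#' @export
perceptionInit <- function(profile = deskProfile(), seed = 1L) {
  with_seed(seed, {
    shapes <- perception_param_shapes(profile$size, profile$size, profile$D,
                                      profile$enc_hidden, profile$dec_hidden)
    structure(list(
      H = profile$size, W = profile$size, K = profile$K, D = profile$D,
      beta = profile$beta, gamma = profile$gamma,
      sigma = 0.3,                       # fixed decoder scale for the image NLL
      floor_slot = 1L,
      shared = init_param_set(shapes),
      floor = init_param_set(shapes),
      seed = as.integer(seed)
    ), class = "physvoe_perception")
  })
}

#' @export
print.physvoe_perception <- function(x, ...) {
  cat(sprintf("<perception: %dx%d px, K=%d slots, D=%d codes, %d params>\n",
              x$H, x$W, x$K, x$D,
              sum(vapply(c(x$shared, x$floor), length, numeric(1)))))
  invisible(x)
}

# slot input rows: masked image channels + the mask itself, flattened
slot_inputs <- function(image, masks) {
  K <- dim(masks)[1]
  HW <- prod(dim(image)[1:2])
  X <- matrix(0, K, HW * 4L)
  for (k in seq_len(K)) {
    m <- masks[k, , ]
    X[k, ] <- c(as.numeric(image) * as.numeric(m), as.numeric(m))
  }
  X
}

bias_add <- function(A, b) A + rep(as.numeric(b), each = nrow(A))

enc_forward <- function(p, X) {
  h <- bias_add(X %*% p$enc_W1, p$enc_b1)
  neg <- h < 0
  h[neg] <- exp(pmin(h[neg], 30)) - 1           # ELU
  mu <- bias_add(h %*% p$enc_Wmu, p$enc_bmu)
  lv <- bias_add(h %*% p$enc_Wlv, p$enc_blv)
  lv <- pmin(pmax(lv, -8), 8)
  list(mean = mu, log_variance = lv)
}

#' Encode an image and its masks into K slot posteriors
#'
#' @param model a perception model.
#' @param image H x W x 3 array with values in \[0, 1\].
#' @param masks K x H x W binary array.
#' @return list with `mean` and `log_variance`, both K x D; row k is the
#'   Gaussian posterior for mask channel k-1.  Empty channels still produce
#'   posteriors.  Permuting two non-floor mask channels permutes the
#'   corresponding rows (shared weights).
#' @export
perceptionEncode <- function(model, image, masks) {
  if (!identical(dim(image), c(model$H, model$W, 3L)) &&
      !identical(dim(image), as.integer(c(model$H, model$W, 3)))) {
    stopf("image must be %d x %d x 3", model$H, model$W)
  }
  if (!identical(as.integer(dim(masks)),
                 as.integer(c(model$K, model$H, model$W)))) {
    stopf("masks must be %d x %d x %d", model$K, model$H, model$W)
  }
  X <- slot_inputs(image, masks)
  fs <- model$floor_slot
  mu <- matrix(0, model$K, model$D); lv <- mu
  sh <- enc_forward(model$shared, X[-fs, , drop = FALSE])
  fl <- enc_forward(model$floor, X[fs, , drop = FALSE])
  mu[-fs, ] <- sh$mean; mu[fs, ] <- fl$mean
  lv[-fs, ] <- sh$log_variance; lv[fs, ] <- fl$log_variance
  list(mean = mu, log_variance = lv)
}

#' Reparameterised sample from slot posteriors
#'
#' @param posterior list with `mean`, `log_variance` (K x D).
#' @param rng_seed integer seed; the draw is reproducible given the seed.
#' @return K x D matrix of object codes.
#' @export
sampleCode <- function(posterior, rng_seed = NULL) {
  with_seed(rng_seed, {
    eps <- matrix(stats::rnorm(length(posterior$mean)),
                  nrow(posterior$mean), ncol(posterior$mean))
    posterior$mean + exp(posterior$log_variance / 2) * eps
  })
}

# broadcast grid: pixel coordinates in [-1, 1], column-major pixel order
broadcast_grid <- function(H, W) {
  i <- rep(seq_len(H), times = W); j <- rep(seq_len(W), each = H)
  cbind(2 * (j - 0.5) / W - 1, 1 - 2 * (i - 0.5) / H)
}

dec_forward <- function(p, codes, grid) {
  # codes: n x D; returns list(rgb = n*HW x 3 (sigmoid), mask_logit = n*HW).
  # ReLU hidden units, as usual for spatial broadcast decoders.  Bias and
  # activation are applied column-wise in place: the row count is n*HW and
  # full-matrix temporaries dominate the evaluation cost otherwise.
  n <- nrow(codes); HW <- nrow(grid)
  Z <- codes[rep(seq_len(n), each = HW), , drop = FALSE]
  G <- grid[rep(seq_len(HW), times = n), , drop = FALSE]
  X <- cbind(Z, G)
  relu_bias <- function(h, b) {
    b <- as.numeric(b)
    for (j in seq_along(b)) {
      cj <- h[, j] + b[j]
      cj[cj < 0] <- 0
      h[, j] <- cj
    }
    h
  }
  h <- relu_bias(X %*% p$dec_W1, p$dec_b1)
  h <- relu_bias(h %*% p$dec_W2, p$dec_b2)
  o <- h %*% p$dec_W3
  b3 <- as.numeric(p$dec_b3)
  for (j in 1:4) o[, j] <- o[, j] + b3[j]
  list(rgb = 1 / (1 + exp(-o[, 1:3, drop = FALSE])), mask_logit = o[, 4])
}

#' Decode one object code to an object image and mask logits
#'
#' The code is broadcast over a spatial grid with coordinate channels and
#' passed through a per-pixel network (a spatial broadcast decoder with 1x1
#' convolutions).
#' @param model perception model.
#' @param code length-D numeric vector (or 1 x D matrix).
#' @param floor decode with the floor slot's parameters.
#' @return list with `image` (H x W x 3 in \[0,1\]), `mask_logit` (H x W)
#'   and `mask` (H x W in \[0,1\]).
#' @export
perceptionDecode <- function(model, code, floor = FALSE) {
  grid <- broadcast_grid(model$H, model$W)
  p <- if (floor) model$floor else model$shared
  d <- dec_forward(p, matrix(code, nrow = 1), grid)
  list(image = array(d$rgb, dim = c(model$H, model$W, 3)),
       mask_logit = matrix(d$mask_logit, model$H, model$W),
       mask = matrix(1 / (1 + exp(-d$mask_logit)), model$H, model$W))
}

# decode a K x D code matrix to per-slot rgb (K x HW x 3 flattened) quickly
decode_slots <- function(model, codes) {
  grid <- broadcast_grid(model$H, model$W)
  fs <- model$floor_slot
  HW <- model$H * model$W
  out_rgb <- array(0, dim = c(nrow(codes), HW, 3))
  out_ml <- matrix(0, nrow(codes), HW)
  nonf <- setdiff(seq_len(nrow(codes)), fs)
  if (length(nonf)) {
    d <- dec_forward(model$shared, codes[nonf, , drop = FALSE], grid)
    for (i in seq_along(nonf)) {
      rows <- ((i - 1) * HW + 1):(i * HW)
      out_rgb[nonf[i], , ] <- d$rgb[rows, ]
      out_ml[nonf[i], ] <- d$mask_logit[rows]
    }
  }
  d <- dec_forward(model$floor, codes[fs, , drop = FALSE], grid)
  out_rgb[fs, , ] <- d$rgb
  out_ml[fs, ] <- d$mask_logit
  list(rgb = out_rgb, mask_logit = out_ml)
}

#' Reconstruct a full scene image from a set of object codes
#'
#' Per-slot decodes are combined with their decoded mask probabilities,
#' normalised across slots; disjoint full-confidence slots reduce to a
#' pixel sum.  Output values stay in \[0, 1\].
#' @param model perception model.
#' @param codes K x D matrix of codes (row `floor_slot` decodes with floor
#'   parameters).
#' @return H x W x 3 array.
#' @export
reconstructScene <- function(model, codes) {
  d <- decode_slots(model, codes)
  pm <- 1 / (1 + exp(-d$mask_logit))          # K x HW
  wsum <- pmax(colSums(pm), 1e-8)
  img <- matrix(0, model$H * model$W, 3)
  for (k in seq_len(nrow(codes))) {
    img <- img + (pm[k, ] / wsum) * d$rgb[k, , ]
  }
  array(clamp(img, 0, 1), dim = c(model$H, model$W, 3))
}

# ---- variational objective -------------------------------------------------

# build the loss on a tape for a batch of (image, masks) pairs.
# Returns list(tape, loss_id, shared_ids, floor_ids, value).
perception_loss_tape <- function(model, images, masks_list, eps_list) {
  tp <- ad_tape()
  ids_sh <- ad_params(tp, model$shared)
  ids_fl <- ad_params(tp, model$floor)
  grid <- broadcast_grid(model$H, model$W)
  HW <- model$H * model$W
  B <- length(images)
  fs <- model$floor_slot
  K <- model$K

  # stack slot rows for all images: shared rows and floor rows separately
  Xs <- list(); Xf <- list(); Ts <- list(); Tf <- list(); Ms <- list(); Mf <- list()
  Es <- list(); Ef <- list()
  for (b in seq_len(B)) {
    X <- slot_inputs(images[[b]], masks_list[[b]])
    tgt_rgb <- X[, 1:(3 * HW), drop = FALSE]
    tgt_m <- X[, (3 * HW + 1):(4 * HW), drop = FALSE]
    Xs[[b]] <- X[-fs, , drop = FALSE]; Xf[[b]] <- X[fs, , drop = FALSE]
    Ts[[b]] <- tgt_rgb[-fs, , drop = FALSE]; Tf[[b]] <- tgt_rgb[fs, , drop = FALSE]
    Ms[[b]] <- tgt_m[-fs, , drop = FALSE]; Mf[[b]] <- tgt_m[fs, , drop = FALSE]
    Es[[b]] <- eps_list[[b]][-fs, , drop = FALSE]
    Ef[[b]] <- eps_list[[b]][fs, , drop = FALSE]
  }
  branch <- function(ids, X, tgt_rgb, tgt_m, epsm) {
    x <- ad_input(tp, X)
    h <- ad_elu(tp, ad_bias(tp, ad_matmul(tp, x, ids$enc_W1), ids$enc_b1))
    mu <- ad_bias(tp, ad_matmul(tp, h, ids$enc_Wmu), ids$enc_bmu)
    lv <- ad_bias(tp, ad_matmul(tp, h, ids$enc_Wlv), ids$enc_blv)
    sd <- ad_exp(tp, ad_scale(tp, lv, 0.5))
    z <- ad_add(tp, mu, ad_mul(tp, sd, ad_input(tp, epsm)))
    # KL(q || N(0, I)) = 0.5 * sum(exp(lv) + mu^2 - 1 - lv)
    klt <- ad_sum(tp, ad_sub(tp, ad_add(tp, ad_exp(tp, lv),
                                        ad_mul(tp, mu, mu)),
                             ad_bias(tp, lv, ad_input(tp, matrix(1, 1, ncol(X) * 0 + model$D)))))
    kl <- ad_scale(tp, klt, 0.5)
    # broadcast decode
    n <- nrow(X)
    Zrep <- ad_rows(tp, z, rep(seq_len(n), each = HW))
    dec_in <- ad_cbind(tp, list(Zrep, ad_input(tp, grid[rep(seq_len(HW), times = n), ])))
    d1 <- ad_relu(tp, ad_bias(tp, ad_matmul(tp, dec_in, ids$dec_W1), ids$dec_b1))
    d2 <- ad_relu(tp, ad_bias(tp, ad_matmul(tp, d1, ids$dec_W2), ids$dec_b2))
    o <- ad_bias(tp, ad_matmul(tp, d2, ids$dec_W3), ids$dec_b3)
    rgb <- ad_sigmoid(tp, ad_cols(tp, o, 1:3))
    mlog <- ad_cols(tp, o, 4L)
    # reshape targets to (n*HW) x 3 / x 1, pixel-major per slot
    tr <- matrix(0, n * HW, 3); tm <- matrix(0, n * HW, 1)
    for (r in seq_len(n)) {
      rows <- ((r - 1) * HW + 1):(r * HW)
      tr[rows, ] <- matrix(tgt_rgb[r, ], HW, 3)
      tm[rows, 1] <- tgt_m[r, ]
    }
    diff <- ad_sub(tp, rgb, ad_input(tp, tr))
    recon <- ad_scale(tp, ad_sum(tp, ad_mul(tp, diff, diff)),
                      1 / (2 * model$sigma^2))
    bce <- ad_bce_logits(tp, mlog, tm)
    list(loss = ad_add(tp, ad_add(tp, recon,
                                  ad_scale(tp, bce, model$gamma)),
                       ad_scale(tp, kl, model$beta)))
  }
  l_sh <- branch(ids_sh, do.call(rbind, Xs), do.call(rbind, Ts),
                 do.call(rbind, Ms), do.call(rbind, Es))
  l_fl <- branch(ids_fl, do.call(rbind, Xf), do.call(rbind, Tf),
                 do.call(rbind, Mf), do.call(rbind, Ef))
  loss <- ad_add(tp, l_sh$loss, l_fl$loss)
  # constant part of the Gaussian NLL so a perfect reconstruction reports its
  # analytic floor rather than zero
  const <- B * K * HW * 3 * 0.5 * log(2 * pi * model$sigma^2)
  list(tape = tp, loss_id = loss, shared_ids = ids_sh, floor_ids = ids_fl,
       value = ad_value(tp, loss)[1, 1] + const)
}

#' Variational objective for a batch
#'
#' Sum over slots of the masked-image Gaussian reconstruction NLL (fixed
#' decoder scale), the gamma-weighted mask binary cross-entropy, and the
#' beta-weighted KL of each slot posterior from the unit Gaussian.
#'
#' @param model perception model.
#' @param images list of H x W x 3 arrays in \[0,1\].
#' @param masks_list list of K x H x W binary arrays.
#' @param rng_seed seed for the reparameterisation draws.
#' @return scalar loss value.
#' @export
perceptionLoss <- function(model, images, masks_list, rng_seed = 1L) {
  eps_list <- with_seed(rng_seed, lapply(images, function(i) {
    matrix(stats::rnorm(model$K * model$D), model$K, model$D)
  }))
  perception_loss_tape(model, images, masks_list, eps_list)$value
}

#' Train the perception module
#'
#' RMSProp on the variational objective over individual frames drawn from
#' the training videos.  Weights are returned frozen (plain arrays); the
#' full-scale schedule is recorded in [fullProfile()], desk-scale defaults
#' in [deskProfile()].
#'
#' @param videos list of `VideoRecord`s.
#' @param profile scale profile (learning rate, steps, batch size).
#' @param seed integer seed (weights, batch order, reparameterisation).
#' @param steps,batch,lr optional overrides of the profile values.
#' @param verbose print progress.
#' @return trained `physvoe_perception` model with a `history` attribute
#'   (loss per logged step).
#' @export
trainPerception <- function(videos, profile = deskProfile(), seed = 1L,
                            steps = NULL, batch = NULL, lr = NULL,
                            verbose = FALSE) {
  steps <- as.integer(steps %||% profile$perception_steps)
  batch <- as.integer(batch %||% profile$perception_batch)
  lr <- lr %||% profile$perception_lr
  model <- perceptionInit(profile, seed = seed)
  nv <- length(videos); T <- nFrames(videos[[1]])
  state_sh <- NULL; state_fl <- NULL
  history <- numeric(0)
  with_seed(derive_seed(seed, 31L), {
    for (s in seq_len(steps)) {
      vi <- sample.int(nv, batch, replace = TRUE)
      ti <- sample.int(T, batch, replace = TRUE)
      images <- lapply(seq_len(batch), function(i) {
        video_frame(videos[[vi[i]]], ti[i]) / 255
      })
      masks_list <- lapply(seq_len(batch), function(i) {
        array(videos[[vi[i]]]$masks[ti[i], , , ], dim = dim(videos[[vi[i]]]$masks)[2:4])
      })
      eps_list <- lapply(seq_len(batch), function(i) {
        matrix(stats::rnorm(model$K * model$D), model$K, model$D)
      })
      lt <- perception_loss_tape(model, images, masks_list, eps_list)
      grads <- ad_backward(lt$tape, lt$loss_id)
      g_sh <- ad_param_grads(grads, lt$shared_ids, model$shared)
      g_fl <- ad_param_grads(grads, lt$floor_ids, model$floor)
      up <- rmsprop_update(model$shared, g_sh, state_sh, lr)
      model$shared <- up$params; state_sh <- up$state
      up <- rmsprop_update(model$floor, g_fl, state_fl, lr)
      model$floor <- up$params; state_fl <- up$state
      if (s %% 25L == 0L || s == 1L) {
        history <- c(history, lt$value)
        if (verbose) message(sprintf("perception step %d  loss %.1f", s, lt$value))
      }
    }
  })
  attr(model, "history") <- history
  model
}
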