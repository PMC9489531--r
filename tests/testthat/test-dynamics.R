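tiny_cfg <- function(variant = "plato") dynamicsConfig(variant, tiny_profile())

rand_codes <- function(cfg, seed = 9) {
  set.seed(seed)
  array(rnorm(cfg$T * cfg$K * cfg$D), c(cfg$T, cfg$K, cfg$D))
}

rand_cam <- function(T, seed = 10) {
  set.seed(seed)
  m <- matrix(rnorm(T * 7), T, 7)
  q <- m[, 4:7, drop = FALSE]
  m[, 4:7] <- q / sqrt(rowSums(q^2))
  m
}

test_that("parameter parity: FEP matches PLATO exactly, FEC adds ~4M", {
  pp <- fullProfile()
  n_plato <- countParameters(dynamicsConfig("plato", pp))
  n_fep <- countParameters(dynamicsConfig("fep", pp))
  n_fec <- countParameters(dynamicsConfig("fec", pp))
  expect_identical(n_fep, n_plato)
  extra <- n_fec - n_plato
  expect_gt(extra, 2e6)
  expect_lt(extra, 8e6)
})

test_that("flat variants collapse to one slot with the stated code sizes", {
  pp <- fullProfile()
  fep <- makeFlatVariant("fep", pp); fec <- makeFlatVariant("fec", pp)
  expect_identical(fep$K, 1L); expect_identical(fep$D, 16L)
  expect_identical(fec$K, 1L); expect_identical(fec$D, 128L)
  expect_identical(dynamicsConfig("plato", pp)$K, 8L)
})

test_that("buffer projection is a per-slot linear map with ELU", {
  cfg <- tiny_cfg()
  m <- dynamicsInit(cfg, seed = 1)
  buf <- matrix(rnorm(cfg$K * (cfg$T - 1) * cfg$D), cfg$K)
  out <- projectBuffer(m, buf)
  expect_equal(dim(out), c(cfg$K, cfg$P))
  # zero weights: every row is the (activated) bias image
  m0 <- m; m0$params$proj_W[] <- 0; m0$params$proj_b[] <- 0.7
  out0 <- projectBuffer(m0, buf)
  expect_true(all(abs(sweep(out0, 2, out0[1, ])) < 1e-12))
  expect_equal(out0[1, ], rep(0.7, cfg$P))
  # zero padding maps to the activated bias of the map
  zp <- projectBuffer(m, matrix(0, 1, (cfg$T - 1) * cfg$D))
  elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
  expect_equal(as.numeric(zp), as.numeric(elu(m$params$proj_b)))
  # linearity before the activation, against a random-matrix oracle
  pre <- function(x) x %*% m$params$proj_W +
    rep(as.numeric(m$params$proj_b), each = nrow(x))
  x1 <- matrix(rnorm((cfg$T - 1) * cfg$D), 1); x2 <- matrix(rnorm((cfg$T - 1) * cfg$D), 1)
  expect_equal(pre(x1 + x2) + pre(0 * x1), pre(x1) + pre(x2), tolerance = 1e-10)
})

test_that("interaction messages match a brute-force pairwise enumeration", {
  cfg <- tiny_cfg()
  m <- dynamicsInit(cfg, seed = 3)
  K <- 2L
  set.seed(4)
  cells <- matrix(rnorm(K * cfg$H), K, cfg$H)
  projbuf <- matrix(rnorm(K * cfg$P), K, cfg$P)
  cam <- rand_cam(1)[1, ]
  got <- interactionMessages(m, cells, projbuf, cam)
  # independent oracle: explicit loops over every (from, to) pair
  p <- m$params
  gelu <- function(x) x * pnorm(x)
  mlp <- function(x, W1, b1, W2, b2, W3, b3) {
    h <- gelu(x %*% W1 + as.numeric(b1)[col(x %*% W1)])
    h <- gelu(h %*% W2 + as.numeric(b2)[col(h %*% W2)])
    gelu(h %*% W3 + as.numeric(b3)[col(h %*% W3)])
  }
  camE <- matrix(cam, 1) %*% p$cam_int_W + as.numeric(p$cam_int_b)
  camE <- ifelse(camE > 0, camE, exp(camE) - 1)
  for (k in 1:K) {
    msgs <- NULL
    for (j in 1:K) {
      msgs <- rbind(msgs, mlp(cbind(cells[k, , drop = FALSE],
                                    cells[j, , drop = FALSE], camE),
                              p$rho_W1, p$rho_b1, p$rho_W2, p$rho_b2,
                              p$rho_W3, p$rho_b3))
    }
    for (j in 1:K) {
      msgs <- rbind(msgs, mlp(cbind(cells[k, , drop = FALSE],
                                    projbuf[j, , drop = FALSE], camE),
                              p$lam_W1, p$lam_b1, p$lam_W2, p$lam_b2,
                              p$lam_W3, p$lam_b3))
    }
    oracle <- c(colSums(msgs), apply(msgs, 2, max))
    expect_equal(as.numeric(got[k, ]), oracle, tolerance = 1e-10)
  }
})

test_that("interactions are invariant to the order of the to-set", {
  cfg <- tiny_cfg()
  m <- dynamicsInit(cfg, seed = 3)
  K <- 3L
  set.seed(8)
  cells <- matrix(rnorm(K * cfg$H), K, cfg$H)
  projbuf <- matrix(rnorm(K * cfg$P), K, cfg$P)
  cam <- rand_cam(1)[1, ]
  a <- interactionMessages(m, cells, projbuf, cam)
  perm <- c(2, 3, 1)
  b <- interactionMessages(m, cells[perm, ], projbuf[perm, ], cam)
  # row for slot k is unchanged up to the same permutation of rows
  expect_equal(b, a[perm, ], tolerance = 1e-10)
})

test_that("a single slot with empty buffer reduces to self-messages", {
  cfg <- tiny_cfg()
  m <- dynamicsInit(cfg, seed = 5)
  cells <- matrix(rnorm(cfg$H), 1)
  projbuf <- projectBuffer(m, matrix(0, 1, (cfg$T - 1) * cfg$D))
  cam <- rand_cam(1)[1, ]
  got <- interactionMessages(m, cells, projbuf, cam)
  expect_equal(dim(got), c(1L, 2L * cfg$U))
  # only the two self-messages exist: sum and max reduce over them alone
  p <- m$params
  gelu <- function(x) x * pnorm(x)
  mlp <- function(x, W1, b1, W2, b2, W3, b3) {
    h <- gelu(x %*% W1 + as.numeric(b1)[col(x %*% W1)])
    h <- gelu(h %*% W2 + as.numeric(b2)[col(h %*% W2)])
    gelu(h %*% W3 + as.numeric(b3)[col(h %*% W3)])
  }
  camE <- matrix(cam, 1) %*% p$cam_int_W + as.numeric(p$cam_int_b)
  camE <- ifelse(camE > 0, camE, exp(camE) - 1)
  mr <- mlp(cbind(cells, cells, camE), p$rho_W1, p$rho_b1, p$rho_W2,
            p$rho_b2, p$rho_W3, p$rho_b3)
  ml <- mlp(cbind(cells, projbuf, camE), p$lam_W1, p$lam_b1, p$lam_W2,
            p$lam_b2, p$lam_W3, p$lam_b3)
  expect_equal(as.numeric(got), c(mr + ml, pmax(mr, ml)), tolerance = 1e-10)
})

test_that("the step prediction is residual around the current code", {
  cfg <- tiny_cfg()
  m <- dynamicsInit(cfg, seed = 2)
  m$params$head_W[] <- 0; m$params$head_b[] <- 0
  codes <- rand_codes(cfg)
  preds <- dynamicsPredict(m, codes, rand_cam(cfg$T))
  for (t in seq_len(cfg$T - 1)) {
    expect_equal(preds[t, , ], codes[t, , ], tolerance = 0)
  }
})

test_that("the full step is equivariant to slot permutation", {
  cfg <- tiny_cfg()
  m <- dynamicsInit(cfg, seed = 2)
  codes <- rand_codes(cfg)
  cam <- rand_cam(cfg$T)
  p <- dynamicsPredict(m, codes, cam)
  perm <- c(3, 1, 4, 2)
  p2 <- dynamicsPredict(m, codes[, perm, , drop = FALSE], cam)
  expect_equal(p2, p[, perm, , drop = FALSE], tolerance = 1e-9)
})

test_that("the teacher-forced loss equals a naive double loop", {
  cfg <- tiny_cfg()
  m <- dynamicsInit(cfg, seed = 6)
  codes <- rand_codes(cfg, seed = 11)
  cam <- rand_cam(cfg$T, seed = 12)
  loss <- dynamicsLoss(m, codes, cam)
  preds <- dynamicsPredict(m, codes, cam)
  acc <- 0
  for (t in seq_len(cfg$T - 1)) {
    for (k in seq_len(cfg$K)) {
      acc <- acc + sum((codes[t + 1, k, ] - preds[t, k, ])^2)
    }
  }
  expect_equal(loss, acc, tolerance = 1e-9)
  # perfect predictor: zero loss
  mz <- m; mz$params$head_W[] <- 0; mz$params$head_b[] <- 0
  const_codes <- codes; for (t in 2:cfg$T) const_codes[t, , ] <- const_codes[1, , ]
  expect_equal(dynamicsLoss(mz, const_codes, cam), 0, tolerance = 1e-18)
})

test_that("rollout feeds predictions back after the prefix", {
  cfg <- tiny_cfg()
  m <- dynamicsInit(cfg, seed = 2)
  codes <- rand_codes(cfg)
  cam <- rand_cam(cfg$T)
  ro <- dynamicsRollout(m, codes, cam, prefix = 3)
  expect_equal(dim(ro), c(cfg$T - 1L, cfg$K, cfg$D))
  # within the prefix, rollout equals teacher forcing
  tf <- dynamicsPredict(m, codes, cam)
  expect_equal(ro[1:2, , ], tf[1:2, , ], tolerance = 1e-9)
})

test_that("training reduces the loss on a linear-motion fixture", {
  cfg <- tiny_cfg()
  prof <- tiny_profile()
  set.seed(5)
  mk <- function() {
    z0 <- matrix(rnorm(cfg$K * cfg$D), cfg$K, cfg$D)
    v <- matrix(rnorm(cfg$K * cfg$D, 0, 0.1), cfg$K, cfg$D)
    arr <- array(0, c(cfg$T, cfg$K, cfg$D))
    for (t in seq_len(cfg$T)) arr[t, , ] <- z0 + (t - 1) * v
    arr
  }
  codes <- lapply(1:16, function(i) mk())
  cams <- lapply(1:16, function(i) { m <- matrix(0, cfg$T, 7); m[, 4] <- 1; m })
  m <- trainDynamics(list(codes = codes, cameras = cams), cfg, prof, seed = 1,
                     steps = 150, batch = 4)
  h <- attr(m, "history")
  expect_gt(h[1], tail(h, 1))
  expect_lt(tail(h, 1), 0.5 * h[1])
})
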