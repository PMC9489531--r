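# Violation-of-expectation evaluation: pixel-space surprise, probe-tuple
# scoring, frame-wise curves, seed-level statistics and the visual-experience
# bookkeeping.
#
# Surprise compares decoded observed codes against decoded predicted codes
# (both through the perception decoder) rather than raw frames or raw codes:
# codes of empty slots have high posterior variance but all decode to the
# same blank image, so pixel-space error ignores that nuisance variability,
# and within a tuple the possible and impossible videos contain identical
# objects, so object size does not bias the comparison.

#' Encode a video into sampled object codes
#'
#' @param perception trained perception model.
#' @param video a `VideoRecord`.
#' @param rng_seed seed for the per-frame reparameterisation draws (a fresh
#'   sample per frame, seeds derived deterministically).
#' @return T x K x D array of codes.
#' @export
encodeVideo <- function(perception, video, rng_seed = 1L) {
  T <- nFrames(video)
  K <- perception$K; fs <- perception$floor_slot
  nonf <- setdiff(seq_len(K), fs)
  Xn <- matrix(0, T * length(nonf), perception$H * perception$W * 4L)
  Xf <- matrix(0, T, perception$H * perception$W * 4L)
  r <- 1L
  for (t in seq_len(T)) {
    img <- video_frame(video, t) / 255
    msk <- array(video$masks[t, , , ], dim = dim(video$masks)[2:4])
    X <- slot_inputs(img, msk)
    Xn[r:(r + length(nonf) - 1L), ] <- X[nonf, , drop = FALSE]
    Xf[t, ] <- X[fs, ]
    r <- r + length(nonf)
  }
  sh <- enc_forward(perception$shared, Xn)
  fl <- enc_forward(perception$floor, Xf)
  codes <- array(0, dim = c(T, K, perception$D))
  for (t in seq_len(T)) {
    mu <- matrix(0, K, perception$D); lv <- mu
    rows <- (t - 1L) * length(nonf) + seq_along(nonf)
    mu[nonf, ] <- sh$mean[rows, , drop = FALSE]
    lv[nonf, ] <- sh$log_variance[rows, , drop = FALSE]
    mu[fs, ] <- fl$mean[t, ]; lv[fs, ] <- fl$log_variance[t, ]
    codes[t, , ] <- sampleCode(list(mean = mu, log_variance = lv),
                               derive_seed(rng_seed, t))
  }
  codes
}

#' Encode a list of videos for dynamics training
#'
#' @param perception trained perception model.
#' @param videos list of `VideoRecord`s.
#' @param rng_seed master seed.
#' @return list with `codes` (list of T x K x D arrays) and `cameras`.
#' @export
encodeVideos <- function(perception, videos, rng_seed = 1L) {
  codes <- lapply(seq_along(videos), function(i) {
    encodeVideo(perception, videos[[i]], derive_seed(rng_seed, i))
  })
  cameras <- lapply(videos, function(v) v$camera)
  list(codes = codes, cameras = cameras)
}

# decode several T x K x D code arrays; each video becomes a (T x K*HW*3)
# matrix (row t = all slots' decoded pixels), which keeps the surprise
# computation free of strided array slicing
decode_videos_mat <- function(perception, codes_list) {
  K <- dim(codes_list[[1]])[2]
  D <- dim(codes_list[[1]])[3]
  HW <- perception$H * perception$W
  fs <- perception$floor_slot
  nonf <- setdiff(seq_len(K), fs)
  grid <- broadcast_grid(perception$H, perception$W)
  Ts <- vapply(codes_list, function(cz) dim(cz)[1], integer(1))
  flat_n <- matrix(0, sum(Ts) * length(nonf), D)
  flat_f <- matrix(0, sum(Ts), D)
  r <- 1L; rf <- 1L
  for (v in seq_along(codes_list)) {
    cz <- codes_list[[v]]
    for (t in seq_len(Ts[v])) {
      for (k in nonf) { flat_n[r, ] <- cz[t, k, ]; r <- r + 1L }
      flat_f[rf, ] <- cz[t, fs, ]; rf <- rf + 1L
    }
  }
  dn <- dec_forward(perception$shared, flat_n, grid)
  df <- dec_forward(perception$floor, flat_f, grid)
  out <- vector("list", length(codes_list))
  r <- 0L; rf <- 0L
  for (v in seq_along(codes_list)) {
    M <- matrix(0, Ts[v], K * HW * 3L)
    for (t in seq_len(Ts[v])) {
      for (k in nonf) {
        M[t, ((k - 1L) * HW * 3L + 1L):(k * HW * 3L)] <-
          dn$rgb[(r * HW + 1):((r + 1) * HW), ]
        r <- r + 1L
      }
      M[t, ((fs - 1L) * HW * 3L + 1L):(fs * HW * 3L)] <-
        df$rgb[(rf * HW + 1):((rf + 1) * HW), ]
      rf <- rf + 1L
    }
    out[[v]] <- M
  }
  out
}

# decode a T x K x D code array to per-frame per-slot RGB, (T, K, HW, 3)
decode_video_rgb <- function(perception, codes) {
  T <- dim(codes)[1]; K <- dim(codes)[2]
  HW <- perception$H * perception$W
  fs <- perception$floor_slot
  grid <- broadcast_grid(perception$H, perception$W)
  out <- array(0, dim = c(T, K, HW, 3))
  nonf <- setdiff(seq_len(K), fs)
  flat <- matrix(0, T * length(nonf), dim(codes)[3])
  r <- 1L
  for (t in seq_len(T)) for (k in nonf) { flat[r, ] <- codes[t, k, ]; r <- r + 1L }
  d <- dec_forward(perception$shared, flat, grid)
  r <- 1L
  for (t in seq_len(T)) for (k in nonf) {
    rows <- ((r - 1) * HW + 1):(r * HW)
    out[t, k, , ] <- d$rgb[rows, ]
    r <- r + 1L
  }
  flatf <- matrix(0, T, dim(codes)[3])
  for (t in seq_len(T)) flatf[t, ] <- codes[t, fs, ]
  df <- dec_forward(perception$floor, flatf, grid)
  for (t in seq_len(T)) {
    rows <- ((t - 1) * HW + 1):(t * HW)
    out[t, fs, , ] <- df$rgb[rows, ]
  }
  out
}

# sum over slots and pixels of squared decoded differences, per frame
pixel_surprise <- function(obs_mat, pred_mat) {
  rowSums((obs_mat - pred_mat)^2)
}

#' Prediction strategies for evaluation
#'
#' `"dynamics"` wraps a trained (or untrained) dynamics model;
#' `"copy_last"` predicts the current codes unchanged (a one-step baseline
#' that the pair-matching guarantee renders uninformative); `"oracle"`
#' predicts the memorized codes of the possible video sharing the probe's
#' start segment (perfect knowledge of the physically consistent
#' continuation).
#' @param kind predictor kind.
#' @param model dynamics model (required for `"dynamics"`).
#' @export
voePredictor <- function(kind = c("dynamics", "copy_last", "oracle"),
                         model = NULL) {
  kind <- match.arg(kind)
  if (kind == "dynamics" && is.null(model)) stopf("dynamics predictor needs a model")
  structure(list(kind = kind, model = model), class = "physvoe_predictor")
}

#' Per-frame surprise for one video
#'
#' @param perception trained perception model.
#' @param predictor a [voePredictor()] (`"oracle"` is tuple-bound and not
#'   supported here).
#' @param video a `VideoRecord` with at least 2 frames.
#' @param rng_seed seed for the code samples.
#' @return list with `per_frame` ((T-1)-vector, entry t compares frame t+1)
#'   and `total`.
#' @export
surpriseTrace <- function(perception, predictor, video, rng_seed = 1L) {
  if (nFrames(video) < 2) stopf("surprise needs at least 2 frames")
  if (predictor$kind == "oracle") stopf("oracle predictor is tuple-bound; use scoreTuple")
  codes <- encodeVideo(perception, video, rng_seed)
  T <- dim(codes)[1]
  preds <- predict_codes(predictor, codes, video$camera)
  dec <- decode_videos_mat(perception, list(codes, preds))
  per_frame <- pixel_surprise(dec[[1]][2:T, , drop = FALSE], dec[[2]])
  list(per_frame = per_frame, total = sum(per_frame))
}

predict_codes <- function(predictor, codes, camera) {
  T <- dim(codes)[1]
  if (predictor$kind == "dynamics") {
    dynamicsPredict(predictor$model, codes, camera)
  } else if (predictor$kind == "copy_last") {
    codes[seq_len(T - 1), , , drop = FALSE]
  } else {
    stopf("unsupported predictor kind %s", predictor$kind)
  }
}

#' Score one probe tuple
#'
#' Computes the summed surprise over the two possible and the two
#' impossible videos, the relative surprise (impossible - possible) /
#' (impossible + possible), and the binary accuracy: 1 when the impossible
#' surprise is strictly greater (ties count as incorrect; a degenerate
#' perfect model with zero total surprise scores relative surprise 0).
#'
#' @param tuple a `ProbeTuple`.
#' @param perception trained perception model.
#' @param predictor a [voePredictor()].
#' @param rng_seed seed for the code samples (per-video seeds derived).
#' @return a `VoEResult` list: surprise sums, relative surprise, accuracy,
#'   and the four per-frame traces (possible then impossible).
#' @export
scoreTuple <- function(tuple, perception, predictor, rng_seed = 1L) {
  scoreTupleMany(tuple, perception, list(predictor), rng_seed)[[1]]
}

#' @rdname scoreTuple
#' @param predictors list of [voePredictor()]s evaluated on shared encoded
#'   codes and shared decodes (one result per predictor).
#' @export
scoreTupleMany <- function(tuple, perception, predictors, rng_seed = 1L) {
  vids <- c(tuple$possible, tuple$impossible)
  codes <- lapply(seq_len(4), function(i) {
    encodeVideo(perception, vids[[i]], derive_seed(rng_seed, i))
  })
  T <- dim(codes[[1]])[1]
  dec_obs <- decode_videos_mat(perception, codes)
  out <- vector("list", length(predictors))
  for (pi in seq_along(predictors)) {
    predictor <- predictors[[pi]]
    dec_pred <- NULL
    if (predictor$kind == "dynamics") {
      fw <- dynamics_forward(predictor$model, codes,
                             lapply(vids, function(v) v$camera),
                             collect = TRUE)
      K <- predictor$model$cfg$K; D <- predictor$model$cfg$D
      preds <- lapply(seq_len(4), function(v) {
        arr <- array(0, dim = c(T - 1L, K, D))
        for (t in seq_len(T - 1L)) {
          arr[t, , ] <- fw$preds[[t]][(v - 1L) * K + seq_len(K), , drop = FALSE]
        }
        arr
      })
      dec_pred <- decode_videos_mat(perception, preds)
    }
    traces <- vector("list", 4)
    for (i in seq_len(4)) {
      pred_rgb <- if (predictor$kind == "oracle") {
        # impossible video i-2 shares its start segment with possible i-2
        src <- if (i <= 2) i else i - 2L
        dec_obs[[src]][2:T, , drop = FALSE]
      } else if (predictor$kind == "copy_last") {
        dec_obs[[i]][seq_len(T - 1), , drop = FALSE]
      } else {
        dec_pred[[i]]
      }
      traces[[i]] <- pixel_surprise(dec_obs[[i]][2:T, , drop = FALSE],
                                    pred_rgb)
    }
    poss <- sum(traces[[1]]) + sum(traces[[2]])
    imp <- sum(traces[[3]]) + sum(traces[[4]])
    rel <- if (imp + poss > 0) (imp - poss) / (imp + poss) else 0
    out[[pi]] <- list(possible_surprise = poss, impossible_surprise = imp,
                      relative_surprise = rel, accuracy = as.integer(imp > poss),
                      traces = traces, violation_onset = tuple$violation_onset,
                      concept = tuple$concept)
  }
  out
}

#' Frame-wise relative surprise curve
#'
#' Applies the tuple-level normalization at each frame: for frame f,
#' (impossible_f - possible_f) / (impossible_f + possible_f), with surprise
#' summed over each probe type's two videos, averaged across tuples.
#' @param results list of results from [scoreTuple()].
#' @return list with `frames` (indices 2..T), `mean_curve`, `per_tuple`
#'   matrix, and `onset` (mean violation onset, for plotting).
#' @export
framewiseRelativeSurprise <- function(results) {
  per_tuple <- t(vapply(results, function(r) {
    poss_f <- r$traces[[1]] + r$traces[[2]]
    imp_f <- r$traces[[3]] + r$traces[[4]]
    ifelse(imp_f + poss_f > 0, (imp_f - poss_f) / (imp_f + poss_f), 0)
  }, numeric(length(results[[1]]$traces[[1]]))))
  list(frames = seq_len(ncol(per_tuple)) + 1L,
       mean_curve = colMeans(per_tuple),
       per_tuple = per_tuple,
       onset = mean(vapply(results, function(r) mean(r$violation_onset),
                           numeric(1))))
}

#' One-sample, one-tailed seed-level statistics
#'
#' Treats each seed's mean metric as one observation and tests whether the
#' across-seed mean exceeds the chance value (0 for relative surprise, 0.5
#' for accuracy) with a one-tailed single-sample t-test; the 95% CI is the
#' usual normal-theory interval (normality across seeds is assumed, not
#' tested).
#' @param per_seed_means numeric vector of per-seed metric means.
#' @param null_value chance value to test against.
#' @return a `SeedStats` list: `mean`, `sd`, `t`, `df`, `p_one_tailed`,
#'   `ci95` and `n`.
#' @export
aggregateSeeds <- function(per_seed_means, null_value = 0) {
  x <- as.numeric(per_seed_means)
  n <- length(x)
  if (n < 2) stopf("need at least two seeds")
  M <- mean(x); s <- stats::sd(x)
  se <- s / sqrt(n)
  df <- n - 1
  tstat <- if (se == 0) {
    if (M == null_value) 0 else sign(M - null_value) * Inf
  } else (M - null_value) / se
  p <- stats::pt(tstat, df = df, lower.tail = FALSE)
  ci <- M + c(-1, 1) * stats::qt(0.975, df) * se
  list(mean = M, sd = s, t = tstat, df = df, p_one_tailed = p,
       ci95 = ci, n = n)
}

#' Visual-experience bookkeeping
#'
#' @param n_videos number of training videos.
#' @param seconds_per_video video duration in seconds.
#' @param wakeful_hours_per_day assumed wakeful hours per day.
#' @return list with `seconds`, `continuous_days` (seconds / 86,400) and
#'   `wakeful_days` (seconds / (3,600 * wakeful hours)).
#' @export
visualExperience <- function(n_videos, seconds_per_video = 2,
                             wakeful_hours_per_day = 8) {
  seconds <- n_videos * seconds_per_video
  list(seconds = seconds,
       continuous_days = seconds / 86400,
       wakeful_days = seconds / (3600 * wakeful_hours_per_day))
}

#' Evaluate predictors over probe sets and seeds
#'
#' @param probe_sets named list: concept -> list of `ProbeTuple`s.
#' @param perception trained perception model.
#' @param predictors list of [voePredictor()]s, one per seed (e.g. dynamics
#'   models trained with different weight-initialisation seeds).
#' @param rng_seed master seed for evaluation-time code samples.
#' @param report_file optional path for a machine-readable JSON report.
#' @return report: per concept, per-seed accuracy and relative-surprise
#'   means, seed statistics (when >= 2 seeds), and frame-wise curves.
#' @export
runExperiment <- function(probe_sets, perception, predictors,
                          rng_seed = 1L, report_file = NULL) {
  report <- list()
  for (concept in names(probe_sets)) {
    tuples <- probe_sets[[concept]]
    acc_means <- numeric(length(predictors))
    rel_means <- numeric(length(predictors))
    curves <- list()
    for (sdi in seq_along(predictors)) {
      results <- lapply(seq_along(tuples), function(i) {
        scoreTuple(tuples[[i]], perception, predictors[[sdi]],
                   rng_seed = derive_seed(rng_seed, sdi * 100000L + i))
      })
      acc_means[sdi] <- mean(vapply(results, `[[`, numeric(1), "accuracy"))
      rel_means[sdi] <- mean(vapply(results, `[[`, numeric(1),
                                    "relative_surprise"))
      curves[[sdi]] <- framewiseRelativeSurprise(results)$mean_curve
    }
    entry <- list(
      n_tuples = length(tuples), n_seeds = length(predictors),
      accuracy_per_seed = acc_means, relative_surprise_per_seed = rel_means,
      mean_accuracy = mean(acc_means),
      mean_relative_surprise = mean(rel_means),
      framewise_mean = colMeans(do.call(rbind, curves))
    )
    if (length(predictors) >= 2) {
      entry$accuracy_stats <- aggregateSeeds(acc_means, 0.5)
      entry$relative_surprise_stats <- aggregateSeeds(rel_means, 0)
    }
    report[[concept]] <- entry
  }
  report$grand_mean_accuracy <-
    mean(vapply(report[names(probe_sets)], `[[`, numeric(1), "mean_accuracy"))
  report$grand_mean_relative_surprise <-
    mean(vapply(report[names(probe_sets)], `[[`, numeric(1),
                "mean_relative_surprise"))
  if (!is.null(report_file)) {
    jsonlite::write_json(report, report_file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  report
}
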