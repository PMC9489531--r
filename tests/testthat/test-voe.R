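test_that("surprise equals an independent per-(frame, slot, pixel) loop", {
  fx <- voe_fix()
  video <- fx$tup$possible[[1]]
  pred <- voePredictor("copy_last")
  tr <- surpriseTrace(fx$perc, pred, video, rng_seed = 5)
  # brute force: re-derive codes, decode slot by slot via the public decoder,
  # and accumulate squared pixel differences with explicit loops
  codes <- encodeVideo(fx$perc, video, 5)
  T <- dim(codes)[1]; K <- dim(codes)[2]
  manual <- numeric(T - 1)
  for (t in seq_len(T - 1)) {
    acc <- 0
    for (k in seq_len(K)) {
      obs <- perceptionDecode(fx$perc, codes[t + 1, k, ], floor = (k == 1))$image
      prd <- perceptionDecode(fx$perc, codes[t, k, ], floor = (k == 1))$image
      for (ch in 1:3) acc <- acc + sum((obs[, , ch] - prd[, , ch])^2)
    }
    manual[t] <- acc
  }
  expect_equal(tr$per_frame, manual, tolerance = 1e-9)
  expect_equal(tr$total, sum(manual), tolerance = 1e-9)
  expect_true(all(tr$per_frame >= 0))
})

test_that("a predictor reproducing the observed codes has zero surprise", {
  fx <- voe_fix()
  r <- scoreTuple(fx$tup, fx$perc, voePredictor("oracle"), rng_seed = 3)
  expect_equal(r$possible_surprise, 0, tolerance = 1e-12)
  expect_gt(r$impossible_surprise, 0)
  expect_identical(r$accuracy, 1L)
  expect_equal(r$relative_surprise, 1)
})

test_that("relative surprise and accuracy follow their definitions", {
  summ <- function(poss, imp) {
    rel <- if (imp + poss > 0) (imp - poss) / (imp + poss) else 0
    list(rel = rel, acc = as.integer(imp > poss))
  }
  expect_equal(summ(1, 3), list(rel = 0.5, acc = 1L))
  expect_equal(summ(2, 2), list(rel = 0, acc = 0L))   # ties are incorrect
  expect_equal(summ(0, 0), list(rel = 0, acc = 0L))   # degenerate perfect model
  set.seed(2)
  for (i in 1:200) {
    poss <- runif(1, 0, 10); imp <- runif(1, 0, 10)
    s <- summ(poss, imp)
    expect_true(s$rel >= -1 && s$rel <= 1)
    expect_equal(s$rel, -summ(imp, poss)$rel)         # antisymmetry
  }
})

test_that("scoreTuple agrees with scoreTupleMany and is seed-stable", {
  fx <- voe_fix()
  p <- voePredictor("copy_last")
  a <- scoreTuple(fx$tup, fx$perc, p, rng_seed = 9)
  b <- scoreTupleMany(fx$tup, fx$perc, list(p, voePredictor("oracle")),
                      rng_seed = 9)
  expect_equal(a$possible_surprise, b[[1]]$possible_surprise)
  expect_equal(a$traces, b[[1]]$traces)
  a2 <- scoreTuple(fx$tup, fx$perc, p, rng_seed = 9)
  expect_identical(a, a2)
})

test_that("frame-wise curves apply the normalization at each frame", {
  fx <- voe_fix()
  rs <- lapply(1:2, function(i) {
    scoreTuple(fx$tup, fx$perc, voePredictor("copy_last"), rng_seed = i)
  })
  fw <- framewiseRelativeSurprise(rs)
  expect_length(fw$mean_curve, nFrames(fx$tup$possible[[1]]) - 1)
  r <- rs[[1]]
  manual <- (r$traces[[3]] + r$traces[[4]] - r$traces[[1]] - r$traces[[2]]) /
    (r$traces[[3]] + r$traces[[4]] + r$traces[[1]] + r$traces[[2]])
  expect_equal(fw$per_tuple[1, ], manual, tolerance = 1e-12)
  expect_true(all(abs(fw$per_tuple) <= 1 + 1e-12))
})

test_that("seed statistics reproduce the published-style t computation", {
  # five seed means with mean 0.044 and s.d. 0.006 give t = M/(s/sqrt(5))
  x <- c(0.044, 0.044 + 0.006 * c(-1, 1, -1, 1) * sqrt(5) / 2)
  x <- 0.044 + (x - mean(x)) * 0.006 / sd(x)
  st <- aggregateSeeds(x, 0)
  expect_equal(st$mean, 0.044, tolerance = 1e-12)
  expect_equal(st$sd, 0.006, tolerance = 1e-12)
  expect_equal(st$t, 0.044 / (0.006 / sqrt(5)), tolerance = 1e-9)
  expect_equal(st$t, 16.39783, tolerance = 1e-4)
  expect_identical(st$df, 4)

  # all seeds at the null: t = 0, p = 0.5
  st0 <- aggregateSeeds(rep(0.5, 4), 0.5)
  expect_equal(st0$t, 0)
  expect_equal(st0$p_one_tailed, 0.5)

  # agreement with the reference t-test implementation on random draws
  set.seed(3)
  for (i in 1:25) {
    x <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1), sd = runif(1, 0.1, 1))
    st <- aggregateSeeds(x, 0.2)
    tt <- t.test(x, mu = 0.2, alternative = "greater")
    expect_equal(st$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(st$p_one_tailed, tt$p.value, tolerance = 1e-10)
    expect_equal(st$ci95, as.numeric(t.test(x)$conf.int), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("visual experience bookkeeping matches the closed forms", {
  v <- visualExperience(300000, 2, 8)
  expect_equal(v$seconds, 600000)
  expect_equal(v$continuous_days, 600000 / 86400)   # ~6.94 d
  expect_equal(v$wakeful_days, 600000 / (3600 * 8)) # ~20.8 d
  z <- visualExperience(0, 2, 8)
  expect_equal(unlist(z), c(seconds = 0, continuous_days = 0, wakeful_days = 0))
  v5 <- visualExperience(50000, 2, 8)
  expect_equal(v5$seconds, 100000)
  expect_equal(v5$continuous_days * 24, 27.7778, tolerance = 1e-4)
})

test_that("runExperiment aggregates concepts, seeds and writes JSON", {
  fx <- voe_fix()
  sets <- list(unchangeableness = list(fx$tup))
  preds <- list(voePredictor("copy_last"), voePredictor("oracle"))
  out <- file.path(tempdir(), "voe_report.json")
  rep <- runExperiment(sets, fx$perc, preds, rng_seed = 2, report_file = out)
  expect_true(file.exists(out))
  parsed <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(parsed$unchangeableness$n_seeds, 2)
  expect_equal(rep$unchangeableness$accuracy_per_seed[2], 1)  # oracle seed
  expect_true(!is.null(rep$unchangeableness$accuracy_stats$t))
  unlink(out)
})

test_that("surprise rejects videos shorter than two frames", {
  fx <- voe_fix()
  v1 <- fx$tup$possible[[1]]
  v1$frames <- v1$frames[1, , , , drop = FALSE]
  v1$masks <- v1$masks[1, , , , drop = FALSE]
  v1$camera <- v1$camera[1, , drop = FALSE]
  expect_error(surpriseTrace(fx$perc, voePredictor("copy_last"), v1),
               "2 frames")
})
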