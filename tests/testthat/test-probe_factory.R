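test_that("splice recombines start and end segments around the common frame", {
  # symbolic frames {a1, a2, c, x1, x2} / {b1, b2, c, y1, y2}
  A <- symbolic_video(c(10, 20, 128, 30, 40))
  B <- symbolic_video(c(50, 60, 128, 70, 80))
  tup <- splice(segmentSet(A, B, 3L), "inertia", seed = 1L)
  lev <- function(v) v$frames[, 1, 1, 1]
  expect_identical(lev(tup$impossible[[1]]), c(10L, 20L, 128L, 70L, 80L))
  expect_identical(lev(tup$impossible[[2]]), c(50L, 60L, 128L, 30L, 40L))
  expect_identical(tup$violation_onset, c(4L, 4L))
  expect_true(verifyProbeTuple(tup)$pass)
})

test_that("identical end segments make a degenerate but valid splice", {
  A <- symbolic_video(c(10, 20, 128, 30, 40))
  B <- symbolic_video(c(50, 60, 128, 30, 40))
  tup <- splice(segmentSet(A, B, 3L), "inertia")
  expect_identical(tup$impossible[[1]]$frames, tup$possible[[1]]$frames)
  expect_identical(tup$impossible[[2]]$frames, tup$possible[[2]]$frames)
  expect_true(verifyProbeTuple(tup)$pass)
})

test_that("segmentSet rejects mismatched common frames and bad indices", {
  A <- symbolic_video(c(10, 20, 30, 40, 50))
  B <- symbolic_video(c(11, 21, 31, 41, 51))
  expect_error(segmentSet(A, B, 3L), "common frame")
  expect_error(segmentSet(A, A, 1L), "nonempty")
  expect_error(segmentSet(A, A, 5L), "nonempty")
})

test_that("frame-match detects a single perturbed pixel and reports it", {
  A <- symbolic_video(c(10, 20, 128, 30, 40))
  B <- symbolic_video(c(50, 60, 128, 70, 80))
  tup <- splice(segmentSet(A, B, 3L), "solidity")
  tup$impossible[[1]]$frames[4, 2, 2, 1] <- 255L
  v <- verifyProbeTuple(tup)
  expect_false(v$frame_match)
  expect_identical(v$first_offence$check, "frame")
  expect_identical(v$first_offence$video, 1L)
  expect_identical(v$first_offence$frame, 4L)
})

test_that("pair-match catches frame permutations that frame-match misses", {
  A <- symbolic_video(c(10, 20, 128, 30, 40))
  B <- symbolic_video(c(50, 60, 128, 70, 80))
  tup <- splice(segmentSet(A, B, 3L), "persistence")
  # permute a possible video's frames inside an impossible slot: same frame
  # multiset, but novel adjacent pairs
  perm <- c(2L, 1L, 4L, 3L, 5L)
  tup$impossible[[1]]$frames <- A$frames[perm, , , , drop = FALSE]
  tup$impossible[[1]]$masks <- A$masks[perm, , , , drop = FALSE]
  tup$impossible[[2]]$frames <- B$frames
  tup$impossible[[2]]$masks <- B$masks
  v <- verifyProbeTuple(tup)
  expect_true(v$frame_match)
  expect_false(v$pair_match)
  # brute-force check of the same property
  keyf <- function(vv, t) paste(as.integer(vv$frames[t, , , ]), collapse = ",")
  poss_pairs <- unlist(lapply(tup$possible, function(vv) {
    vapply(1:4, function(t) paste(keyf(vv, t), keyf(vv, t + 1), sep = "->"),
           character(1))
  }))
  imp_pairs <- vapply(1:4, function(t) {
    paste(keyf(tup$impossible[[1]], t), keyf(tup$impossible[[1]], t + 1),
          sep = "->")
  }, character(1))
  expect_true(any(!imp_pairs %in% poss_pairs))
})

test_that("every concept factory produces verified, counterbalanced tuples", {
  prof <- tiny_profile()
  for (cc in physvoe:::CONCEPTS) {
    tup <- cached(paste0("probe_", cc),
                  physvoe:::probe_maker(cc)(301L, profile = prof))
    expect_s3_class(tup, "physvoe_probe")
    expect_identical(tup$concept, cc)
    expect_length(tup$possible, 2)
    expect_length(tup$impossible, 2)
    v <- verifyProbeTuple(tup)
    expect_true(v$frame_match, info = cc)
    expect_true(v$pair_match, info = cc)
    T <- nFrames(tup$possible[[1]])
    expect_true(all(tup$violation_onset >= 2 & tup$violation_onset <= T))
    # stationary, shared camera
    expect_true(physvoe:::is_static_camera(tup$possible[[1]]$camera))
    expect_identical(tup$possible[[1]]$camera, tup$impossible[[2]]$camera)
  }
})

test_that("probe factories are deterministic per seed", {
  prof <- tiny_profile()
  a <- makeInertiaProbe(77L, prof)
  b <- makeInertiaProbe(77L, prof)
  expect_identical(a$possible[[1]]$frames, b$possible[[1]]$frames)
  expect_identical(a$impossible[[2]]$frames, b$impossible[[2]]$frames)
})

test_that("possible probe videos re-simulate exactly from their scene specs", {
  prof <- tiny_profile()
  tup <- cached("probe_solidity",
                physvoe:::probe_maker("solidity")(301L, profile = prof))
  for (i in 1:2) {
    spec <- tup$meta$specs[[i]]
    re <- suppressWarnings(
      simulateScene(spec, n_steps = prof$n_steps, frames = prof$T,
                    size = prof$size, K = prof$K))
    expect_identical(re$frames, tup$possible[[i]]$frames)
  }
})

test_that("continuity probes hide the ball by visibility masking", {
  prof <- tiny_profile()
  tup <- cached("probe_continuity",
                physvoe:::probe_maker("continuity")(301L, profile = prof))
  occ <- tup$meta$occluded_frames
  T <- nFrames(tup$possible[[1]])
  gap <- (occ[1] + 1):(occ[2] - 1)
  # impossible-1 never shows the ball between the pillars
  expect_true(all(tup$impossible[[1]]$masks[gap, 2, , ] == 0L))
  # and matches the empty scene there, the rolling scene elsewhere
  for (t in gap) {
    expect_identical(tup$impossible[[1]]$frames[t, , , ],
                     tup$possible[[2]]$frames[t, , , ])
  }
  for (t in setdiff(seq_len(T), gap)) {
    expect_identical(tup$impossible[[1]]$frames[t, , , ],
                     tup$possible[[1]]$frames[t, , , ])
  }
  # impossible-2 shows it only between the pillars
  expect_true(sum(tup$impossible[[2]]$masks[gap, 2, , ]) > 0)
  expect_true(all(tup$impossible[[2]]$masks[setdiff(seq_len(T), gap), 2, , ] == 0L))
  # onset is the first frame where the ball should appear but does not
  expect_identical(tup$violation_onset, c(gap[1], gap[1]))
})

test_that("inertia probes obey angle-of-incidence symmetry", {
  prof <- tiny_profile()
  tup <- cached("probe_inertia",
                physvoe:::probe_maker("inertia")(301L, profile = prof))
  spec <- tup$meta$specs[[1]]
  ball <- spec$objects[[2]]
  v_in <- ball$vel
  C <- tup$meta$contact_point
  # time-reversed partner starts where the reflected trajectory ends
  specB <- tup$meta$specs[[2]]
  v_out <- -specB$objects[[2]]$vel
  n <- c(0, 1, 0)
  expect_equal(sum(v_in * n), -sum(v_out * n), tolerance = 1e-9)
  tangential <- function(v) v - sum(v * n) * n
  expect_equal(tangential(v_in), tangential(v_out), tolerance = 1e-9)
  # incidence angle preserved
  ang <- function(v) acos(abs(sum(v * n)) / sqrt(sum(v^2)))
  expect_equal(ang(v_in), ang(v_out), tolerance = 1e-9)
})

test_that("generateProbeSet writes a readable, verified dataset", {
  prof <- tiny_profile()
  dir <- file.path(tempdir(), "probeset_test")
  tuples <- generateProbeSet("unchangeableness", 2, seed = 5L, out = dir,
                             profile = prof)
  ds <- readDataset(dir)
  expect_identical(ds$manifest$kind, "probe")
  expect_identical(ds$manifest$count, 2L)
  expect_true(all(ds$manifest$concepts == "unchangeableness"))
  expect_identical(ds$items[[1]]$possible[[1]]$frames,
                   tuples[[1]]$possible[[1]]$frames)
  unlink(dir, recursive = TRUE)
})
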