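# VideoRecord: the universal unit of data.  T frames of RGB pixels (uint8
# values stored as integers), a K-channel binary mask stack per frame, and a
# camera pose track.

#' Construct a video record
#'
#' @param frames T x H x W x 3 integer array with values in 0..255.
#' @param masks T x K x H x W binary integer array; channels are mutually
#'   disjoint per pixel, channel identity is consistent across frames
#'   (channel k always depicts object id k), channel 0 (index 1) is the
#'   floor/background.
#' @param camera T x 7 matrix of per-frame (position, quaternion).
#' @param meta metadata list (seed, spec hash, concept tag, events).
#' @export
videoRecord <- function(frames, masks, camera, meta = list()) {
  rec <- structure(list(frames = frames, masks = masks, camera = camera,
                        meta = meta), class = "physvoe_video")
  validateVideoRecord(rec)
  rec
}

#' Validate video-record invariants
#'
#' Checks array shapes, value ranges, per-pixel mask disjointness and full
#' coverage (floor/object channels partition every pixel), and unit-norm
#' camera quaternions.  Errors on the first violation.
#' @param rec a `VideoRecord`.
#' @return `rec`, invisibly.
#' @export
validateVideoRecord <- function(rec) {
  dF <- dim(rec$frames); dM <- dim(rec$masks)
  if (length(dF) != 4 || dF[4] != 3) stopf("frames must be T x H x W x 3")
  if (length(dM) != 4) stopf("masks must be T x K x H x W")
  if (dM[1] != dF[1] || dM[3] != dF[2] || dM[4] != dF[3]) {
    stopf("mask dimensions do not match frames")
  }
  if (min(rec$frames) < 0 || max(rec$frames) > 255) stopf("frame values outside 0..255")
  if (!all(rec$masks %in% c(0L, 1L))) stopf("masks must be binary")
  # per pixel per frame, channels sum to exactly 1 (floor covers the rest)
  sums <- apply(rec$masks, c(1, 3, 4), sum)
  if (any(sums != 1L)) stopf("mask channels must partition every pixel")
  if (!is.matrix(rec$camera) || ncol(rec$camera) != 7 || nrow(rec$camera) != dF[1]) {
    stopf("camera must be a T x 7 matrix")
  }
  qn <- sqrt(rowSums(rec$camera[, 4:7, drop = FALSE]^2))
  if (any(abs(qn - 1) > 1e-6)) stopf("camera quaternions must be unit norm")
  invisible(rec)
}

#' @export
print.physvoe_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<VideoRecord: %d frames, %dx%d px, %d mask channels%s>\n",
              d[1], d[2], d[3], dim(x$masks)[2],
              if (!is.null(x$meta$concept) && !is.na(x$meta$concept))
                paste0(", concept ", x$meta$concept) else ""))
  invisible(x)
}

#' Number of frames in a video record
#' @param rec a `VideoRecord`.
#' @export
nFrames <- function(rec) dim(rec$frames)[1]

# one frame as an H x W x 3 integer array
video_frame <- function(rec, t) {
  array(rec$frames[t, , , ], dim = dim(rec$frames)[2:4])
}

# fast per-frame content keys for multiset comparisons: two independent
# weighted sums; equality candidates are then confirmed with identical()
frame_keys <- function(rec) {
  d <- dim(rec$frames)
  n <- prod(d[2:4])
  w1 <- sin(seq_len(n) * 0.7253) * 1e4
  w2 <- cos(seq_len(n) * 0.3571) * 1e4
  T <- d[1]
  k <- matrix(0, T, 2)
  for (t in seq_len(T)) {
    v <- as.numeric(rec$frames[t, , , ])
    k[t, ] <- c(sum(v * w1), sum(v * w2))
  }
  apply(round(k, 6), 1, paste, collapse = "|")
}
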