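# Dataset serialization: one directory per dataset with a `manifest.json`
# and one array bundle per item.  Bundles are written with R serialization
# (version 2, uncompressed-deterministic gzip), giving lossless bit-exact
# round trips and stable checksums for a fixed seed.

MANIFEST_VERSION <- 1L

#' Write a dataset of video records or probe tuples
#'
#' @param items list of `VideoRecord`s (kind "freeform") or `ProbeTuple`s
#'   (kind "probe").
#' @param path output directory (created if needed).
#' @param kind `"freeform"` or `"probe"`.
#' @param seed generating seed stored in the manifest.
#' @param config optional generator configuration (hashed into the manifest).
#' @return `path`, invisibly.
#' @export
writeDataset <- function(items, path, kind = c("freeform", "probe"),
                         seed = 0L, config = NULL) {
  kind <- match.arg(kind)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  n <- length(items)
  files <- character(n)
  seeds <- integer(n)
  concepts <- character(n)
  for (i in seq_len(n)) {
    it <- items[[i]]
    files[i] <- sprintf("item_%05d.rds", i)
    seeds[i] <- if (kind == "probe") it$seed else (it$meta$seed %||% NA_integer_)
    concepts[i] <- if (kind == "probe") it$concept else
      (it$meta$concept %||% NA_character_)
    saveRDS(it, file.path(path, files[i]), version = 2, compress = "gzip")
  }
  shape <- if (n > 0) {
    rec <- if (kind == "probe") items[[1]]$possible[[1]] else items[[1]]
    as.integer(dim(rec$frames))
  } else integer(0)
  manifest <- list(
    schema_version = MANIFEST_VERSION,
    kind = kind, count = n, shape = shape,
    K = if (n > 0) {
      rec <- if (kind == "probe") items[[1]]$possible[[1]] else items[[1]]
      as.integer(dim(rec$masks)[2])
    } else NA_integer_,
    seed = as.integer(seed),
    item_seeds = seeds, concepts = concepts, files = files,
    config_hash = if (is.null(config)) NA_character_ else hash_object(config)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a dataset directory
#'
#' Validates that every file referenced by the manifest exists and that item
#' shapes are consistent; errors otherwise.
#' @param path dataset directory written by [writeDataset()].
#' @return list with `items` and `manifest`.
#' @export
readDataset <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stopf("no manifest.json under %s", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  items <- vector("list", manifest$count)
  for (i in seq_len(manifest$count)) {
    f <- file.path(path, manifest$files[i])
    if (!file.exists(f)) stopf("manifest references missing file %s", manifest$files[i])
    items[[i]] <- readRDS(f)
    rec <- if (manifest$kind == "probe") items[[i]]$possible[[1]] else items[[i]]
    if (!identical(as.integer(dim(rec$frames)), as.integer(manifest$shape))) {
      stopf("item %d has inconsistent shape", i)
    }
  }
  list(items = items, manifest = manifest)
}

#' Export a video's frames as PNG files for inspection
#'
#' Requires the `png` package (optional); writes one file per frame.
#' @param rec a `VideoRecord`.
#' @param dir output directory.
#' @export
exportFramesPNG <- function(rec, dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stopf("PNG export requires the 'png' package")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  T <- nFrames(rec)
  for (t in seq_len(T)) {
    img <- video_frame(rec, t) / 255
    png::writePNG(img, file.path(dir, sprintf("frame_%02d.png", t)))
  }
  invisible(dir)
}

#' Deterministic miniature fixtures for tests and examples
#'
#' Builds tiny scenes (small resolution, few objects, short videos): an
#' empty scene, a ballistic drop, a roll-and-reflect scene, an occlusion
#' pass, and one miniature probe tuple per concept.
#' @param seed integer seed.
#' @param size image size in pixels for the plain scenes.
#' @return named list of `VideoRecord`s / `ProbeTuple`s.
#' @export
makeFixtures <- function(seed = 1L, size = 16L) {
  prof <- deskProfile()
  prof$size <- 24L; prof$n_steps <- 350L
  empty <- simulateScene(sceneSpec(list(), camera = "fixed", seed = seed),
                         n_steps = 140, frames = 5, size = size, K = 4)
  drop <- simulateScene(
    sceneSpec(list(objectSpec(1, "sphere", 0.5, c(0.9, 0.2, 0.2), mass = 40,
                              pos = c(0, 0.5, 3.5), behavior = "free")),
              camera = "fixed", seed = seed),
    n_steps = 350, frames = 8, size = size, K = 4)
  reflect <- simulateScene(
    sceneSpec(list(
      objectSpec(1, "box", c(0.6, 0.5, 0.6), c(0.2, 0.2, 0.8), mass = 60,
                 pos = c(0.4, 1.8, 0.6)),
      objectSpec(2, "sphere", 0.45, c(0.9, 0.8, 0.1), mass = 10,
                 pos = c(0.4 - 3 * sin(0.6), 1.8 - 0.5 - 0.45 - 3 * cos(0.6), 0.45),
                 vel = 3 * c(sin(0.6), cos(0.6), 0), behavior = "rolling",
                 reflect_ids = 1L)),
      camera = "fixed", seed = seed),
    n_steps = 350, frames = 10, size = size, K = 4)
  occl <- simulateScene(
    sceneSpec(list(
      objectSpec(1, "box", c(0.5, 0.12, 1.2), c(0.3, 0.6, 0.3), pos = c(0, 0.6, 1.2)),
      objectSpec(2, "sphere", 0.45, c(0.8, 0.3, 0.7), mass = 10,
                 pos = c(-3, 2.2, 0.45), vel = c(3, 0, 0), behavior = "rolling")),
      camera = "fixed", seed = seed),
    n_steps = 350, frames = 10, size = size, K = 4)
  probes <- lapply(stats::setNames(CONCEPTS, CONCEPTS), function(cc) {
    probe_maker(cc)(derive_seed(seed, match(cc, CONCEPTS)), profile = prof)
  })
  c(list(empty = empty, ballistic = drop, reflect = reflect,
         occlusion = occl), probes)
}
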