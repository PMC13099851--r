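#' Construct a scene sequence
#'
#' Timestamped RGB frames from the head-mounted scene camera. Frames are
#' numeric arrays `height x width x 3` with intensities on the 0-255 scale;
#' all frames must share the same dimensions.
#'
#' @param frames List of `H x W x 3` numeric arrays.
#' @param frame_timestamps Numeric vector of frame times (ms), strictly
#'   increasing, one per frame.
#' @param source Optional path the frames were read from.
#' @return An object of class `scene_sequence`.
#' @export
scene_sequence <- function(frames, frame_timestamps, source = NA_character_) {
  stopifnot(is.list(frames))
  frame_timestamps <- as.numeric(frame_timestamps)
  if (length(frames) != length(frame_timestamps)) {
    stop("frame count and timestamp count differ", call. = FALSE)
  }
  if (length(frame_timestamps) >= 2L && any(diff(frame_timestamps) <= 0)) {
    stop("frame_timestamps must be strictly increasing", call. = FALSE)
  }
  if (length(frames) > 0L) {
    dims <- vapply(frames, function(f) dim(f)[1:3], integer(3))
    if (any(is.na(dims)) || any(dims[3, ] != 3L)) {
      stop("every frame must be an H x W x 3 array", call. = FALSE)
    }
    if (length(frames) > 1L && (length(unique(dims[1, ])) > 1L ||
                                length(unique(dims[2, ])) > 1L)) {
      stop("all frames must have identical dimensions", call. = FALSE)
    }
  }
  structure(
    list(frames = frames, frame_timestamps = frame_timestamps, source = source),
    class = "scene_sequence"
  )
}

#' @export
print.scene_sequence <- function(x, ...) {
  n <- length(x$frames)
  d <- if (n > 0L) paste(dim(x$frames[[1L]])[1:2], collapse = "x") else "?"
  cat(sprintf("<scene_sequence> %d frames (%s px), %.1f-%.1f ms\n",
              n, d,
              if (n > 0L) min(x$frame_timestamps) else NA,
              if (n > 0L) max(x$frame_timestamps) else NA))
  invisible(x)
}

#' Read a scene sequence from a directory of PNG frames
#'
#' The directory must contain numbered PNG images plus a `frames.csv`
#' sidecar with columns `frame_index,timestamp_ms` (frame_index matching the
#' alphanumeric sort order of the PNG files). Video containers are not
#' supported in this build: no video-decoding library is available, so
#' pre-extract frames to PNG.
#'
#' @param path Path to a frame directory.
#' @return A [scene_sequence()].
#' @export
read_scene <- function(path) {
  if (!dir.exists(path)) {
    if (file.exists(path)) {
      stop("video-file input is not supported in this build; ",
           "extract frames to a PNG directory with a frames.csv sidecar",
           call. = FALSE)
    }
    stop("scene path does not exist: ", path, call. = FALSE)
  }
  sidecar <- file.path(path, "frames.csv")
  if (!file.exists(sidecar)) {
    stop("frame directory must contain a frames.csv sidecar ",
         "(frame_index,timestamp_ms)", call. = FALSE)
  }
  ts <- read.csv(sidecar, stringsAsFactors = FALSE)
  if (!all(c("frame_index", "timestamp_ms") %in% names(ts))) {
    stop("frames.csv must have columns frame_index,timestamp_ms", call. = FALSE)
  }
  ts <- ts[order(ts$frame_index), , drop = FALSE]
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) != nrow(ts)) {
    stop(sprintf("frame count (%d) does not match timestamp count (%d)",
                 length(files), nrow(ts)), call. = FALSE)
  }
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
    img * 255
  })
  scene_sequence(frames, ts$timestamp_ms, source = path)
}

#' Write a scene sequence to a directory of PNG frames
#'
#' Writes numbered PNGs plus the `frames.csv` sidecar that [read_scene()]
#' expects.
#'
#' @param scene A [scene_sequence()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "scene_sequence"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- length(scene$frames)
  for (i in seq_len(n)) {
    img <- pmin(pmax(scene$frames[[i]] / 255, 0), 1)
    png::writePNG(img, file.path(path, sprintf("frame_%05d.png", i)))
  }
  write.csv(
    data.frame(frame_index = seq_len(n), timestamp_ms = scene$frame_timestamps),
    file.path(path, "frames.csv"), row.names = FALSE
  )
  invisible(path)
}
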