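#' Multi-channel image stack
#'
#' The universal carrier for image data in tagbright: a 4-dimensional array
#' indexed `[row, col, frame, channel]` together with the physical pixel size
#' (nm) and, for time series, the frame interval (s). Single images are
#' stacks with one frame; single-channel data have one channel. Axis
#' convention is `(row, col) = (y, x)`, 1-based, matching R matrices.
#'
#' Two-channel scenes always store the reporter (GFP / anti-HA) as channel 1
#' and the dye marker as channel 2; `channel_names` records the mapping.
#'
#' @param data numeric array of 2 (y,x), 3 (y,x,frame) or 4 (y,x,frame,channel)
#'   dimensions; coerced to 4-D internally.
#' @param pixel_size_nm physical edge length of one pixel, nanometres (> 0).
#' @param frame_interval_s time between consecutive frames, seconds (> 0).
#' @param channel_names optional character vector naming the channels.
#' @return an object of class `ImageStack`.
#' @export
image_stack <- function(data, pixel_size_nm, frame_interval_s = 1,
                        channel_names = NULL) {
  if (!is.numeric(data)) stop("`data` must be numeric")
  d <- dim(data)
  if (is.null(d)) stop("`data` must be a matrix or array")
  if (length(d) == 2L) dim(data) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(data) <- c(d, 1L)
  else if (length(d) != 4L) stop("`data` must have 2, 3 or 4 dimensions")
  stopifnot(is.finite(pixel_size_nm), pixel_size_nm > 0,
            is.finite(frame_interval_s), frame_interval_s > 0)
  if (is.null(channel_names)) {
    channel_names <- if (dim(data)[4] == 2L) c("reporter", "marker")
                     else paste0("ch", seq_len(dim(data)[4]))
  }
  stopifnot(length(channel_names) == dim(data)[4])
  structure(list(data = data,
                 pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s,
                 channel_names = channel_names),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ImageStack: %d x %d px, %d frame(s), %d channel(s) [%s]\n",
              d[1], d[2], d[3], d[4], paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  pixel size %.4g nm, frame interval %.4g s\n",
              x$pixel_size_nm, x$frame_interval_s))
  invisible(x)
}

#' Number of frames / channels in a stack
#' @param stack an `ImageStack`.
#' @return integer count.
#' @export
n_frames <- function(stack) dim(stack$data)[3]

#' @rdname n_frames
#' @export
n_channels <- function(stack) dim(stack$data)[4]

#' Extract one frame of one channel as a matrix
#'
#' @param stack an `ImageStack`.
#' @param frame frame index (1-based).
#' @param channel channel index or name.
#' @return numeric matrix `(y, x)`.
#' @export
get_frame <- function(stack, frame = 1L, channel = 1L) {
  stopifnot(inherits(stack, "ImageStack"))
  if (is.character(channel)) {
    channel <- match(channel, stack$channel_names)
    if (is.na(channel)) stop("unknown channel name")
  }
  d <- dim(stack$data)
  stopifnot(frame >= 1, frame <= d[3], channel >= 1, channel <= d[4])
  stack$data[, , frame, channel]
}

#' Frame acquisition times
#' @param stack an `ImageStack`.
#' @return numeric vector of times in seconds, starting at 0.
#' @export
frame_times <- function(stack) (seq_len(n_frames(stack)) - 1) * stack$frame_interval_s

#' Write / read an ImageStack as multi-page TIFF plus YAML sidecar
#'
#' Pages are stored frame-major with channels interleaved within each frame
#' (reporter page first, then marker, for two-channel stacks). Intensities
#' are stored as 32-bit samples scaled by a factor recorded in the sidecar,
#' so arbitrary detector counts round-trip; pixel size and frame interval
#' also live in the sidecar (`<path>.yaml`).
#'
#' @param stack an `ImageStack`.
#' @param path output TIFF file path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  mx <- max(stack$data, 1e-12)
  pages <- list()
  for (f in seq_len(n_frames(stack)))
    for (ch in seq_len(n_channels(stack)))
      pages[[length(pages) + 1L]] <- stack$data[, , f, ch] / mx
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  side <- list(pixel_size_nm = stack$pixel_size_nm,
               frame_interval_s = stack$frame_interval_s,
               channel_names = as.list(stack$channel_names),
               n_frames = n_frames(stack),
               n_channels = n_channels(stack),
               intensity_scale = mx,
               page_order = "frame-major, channels interleaved")
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  nf <- side$n_frames; nc <- side$n_channels
  stopifnot(length(pages) == nf * nc)
  d <- dim(pages[[1]])
  arr <- array(0, c(d[1], d[2], nf, nc))
  i <- 1L
  for (f in seq_len(nf)) for (ch in seq_len(nc)) {
    arr[, , f, ch] <- pages[[i]] * side$intensity_scale
    i <- i + 1L
  }
  image_stack(arr, side$pixel_size_nm, side$frame_interval_s,
              unlist(side$channel_names))
}
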