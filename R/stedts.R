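# STED time-series processing: frame summing, kymographs, background-
# corrected intensity-over-time curves with mono-exponential bleach fits,
# and initial-intensity estimation.

#' Sum consecutive frames of a stack
#'
#' Non-overlapping blocks of `n` raw frames are summed (not averaged) to
#' form each output frame, as is conventional when STED raw frames are
#' accumulated for display and analysis; a trailing partial block is
#' dropped. The frame interval scales by `n`. Accumulation happens in
#' double precision, so integer inputs cannot overflow or clip.
#'
#' @param stack an [image_stack()].
#' @param n frames per block (>= 1, <= number of frames).
#' @return a new `ImageStack` with `floor(n_frames / n)` frames.
#' @export
sum_frames <- function(stack, n) {
  stopifnot(inherits(stack, "ImageStack"), n >= 1)
  n <- as.integer(n)
  nf <- n_frames(stack)
  if (n > nf) stop("cannot sum ", n, " frames: stack has only ", nf)
  n_out <- nf %/% n
  d <- dim(stack$data)
  out <- array(0, c(d[1], d[2], n_out, d[4]))
  for (b in seq_len(n_out)) {
    idx <- ((b - 1L) * n + 1L):(b * n)
    for (ch in seq_len(d[4]))
      out[, , b, ch] <- apply(stack$data[, , idx, ch, drop = FALSE], c(1, 2), sum)
  }
  image_stack(out, stack$pixel_size_nm, stack$frame_interval_s * n,
              stack$channel_names)
}

# Sample positions along the segment p0 -> p1 at `step`-px spacing,
# averaged across `width` perpendicular offsets (1-px spaced, centered).
sample_line <- function(img, p0, p1, width_px = 1L, step = 1) {
  v <- p1 - p0
  len <- sqrt(sum(v^2))
  if (len == 0) stop("line endpoints are identical")
  u <- v / len
  perp <- c(-u[2], u[1])
  ts <- seq(0, len, by = step)
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, length.out = width_px)
  acc <- 0
  for (o in offs) {
    rows <- p0[1] + ts * u[1] + o * perp[1]
    cols <- p0[2] + ts * u[2] + o * perp[2]
    acc <- acc + bilinear_sample(img, rows, cols)
  }
  list(values = acc / width_px, t_px = ts)
}

#' Kymograph along a line
#'
#' For every frame, intensities are bilinearly sampled along the segment
#' `p0 -> p1` at 1-pixel steps and averaged across `width_px` perpendicular
#' offsets; columns are frames ordered by time, rows are positions along
#' the line.
#'
#' @param stack an [image_stack()].
#' @param p0,p1 numeric `(row, col)` endpoints, inside the frame.
#' @param width_px averaging width perpendicular to the line (>= 1).
#' @param channel channel index or name.
#' @return object of class `Kymograph`: `data` (position x time matrix),
#'   `p0`, `p1`, `step_px`, `times`, `pixel_size_nm`.
#' @export
kymograph <- function(stack, p0, p1, width_px = 1L, channel = 1L) {
  stopifnot(inherits(stack, "ImageStack"), width_px >= 1)
  d <- dim(stack$data)
  chk <- function(p) p[1] >= 1 && p[1] <= d[1] && p[2] >= 1 && p[2] <= d[2]
  if (!chk(p0) || !chk(p1)) stop("line endpoints must lie inside the frame")
  if (all(p0 == p1)) stop("line endpoints are identical")
  cols <- lapply(seq_len(d[3]), function(f)
    sample_line(get_frame(stack, f, channel), p0, p1, width_px)$values)
  structure(list(data = do.call(cbind, cols), p0 = p0, p1 = p1,
                 step_px = 1, times = frame_times(stack),
                 pixel_size_nm = stack$pixel_size_nm),
            class = "Kymograph")
}

#' Background-corrected intensity over time with a bleach fit
#'
#' Per frame, `corrected = mean(roi) - mean(background)`. A
#' mono-exponential-plus-offset photobleaching model
#' `I(t) = offset + I0 * 2^(-t / halflife)` is fitted by nonlinear least
#' squares; when the curve is non-decreasing (no bleaching to fit) the fit
#' is skipped and flagged.
#'
#' @param stack an [image_stack()].
#' @param roi_mask logical matrix of signal pixels.
#' @param background_mask logical matrix of background pixels; must be
#'   disjoint from `roi_mask` and non-empty. Constant across frames.
#' @param channel channel index or name.
#' @return object of class `BleachCurve`: `times`, `raw`, `corrected`,
#'   `fit` (list `I0`, `halflife_s`, `offset` or NULL), `fit_r2`,
#'   `no_decay` flag.
#' @export
intensity_timecourse <- function(stack, roi_mask, background_mask, channel = 1L) {
  stopifnot(inherits(stack, "ImageStack"), is.logical(roi_mask),
            is.logical(background_mask))
  if (!any(roi_mask)) stop("empty ROI mask")
  if (!any(background_mask)) stop("empty background mask")
  if (any(roi_mask & background_mask)) stop("ROI and background masks overlap")
  nf <- n_frames(stack)
  raw <- corrected <- numeric(nf)
  for (f in seq_len(nf)) {
    img <- get_frame(stack, f, channel)
    raw[f] <- mean(img[roi_mask])
    corrected[f] <- raw[f] - mean(img[background_mask])
  }
  times <- frame_times(stack)
  out <- list(times = times, raw = raw, corrected = corrected,
              fit = NULL, fit_r2 = NA_real_, no_decay = FALSE)
  slope <- stats::coef(stats::lm(corrected ~ times))[2]
  if (!is.finite(slope) || slope >= 0) {
    out$no_decay <- TRUE
    return(structure(out, class = "BleachCurve"))
  }
  i0_start <- max(corrected[1], 1e-6)
  hl_start <- {
    # crude start: time to fall to half the initial value
    below <- which(corrected <= i0_start / 2)
    if (length(below)) max(times[below[1]], stack$frame_interval_s)
    else max(times) / 2
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(corrected ~ offset + I0 * 2^(-times / hl),
                      start = list(offset = min(corrected), I0 = i0_start,
                                   hl = hl_start),
                      lower = c(-Inf, 0, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    pred <- stats::predict(fit)
    ss_res <- sum((corrected - pred)^2)
    ss_tot <- sum((corrected - mean(corrected))^2)
    out$fit <- list(I0 = unname(cf["I0"]), halflife_s = unname(cf["hl"]),
                    offset = unname(cf["offset"]))
    out$fit_r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  }
  structure(out, class = "BleachCurve")
}

#' @export
print.BleachCurve <- function(x, ...) {
  cat(sprintf("BleachCurve: %d frames over %.3g s\n", length(x$times),
              max(x$times)))
  if (x$no_decay) cat("  no decay: bleach fit skipped\n")
  else if (!is.null(x$fit))
    cat(sprintf("  fit: I0 = %.4g, halflife = %.4g s, offset = %.4g (R2 %.3f)\n",
                x$fit$I0, x$fit$halflife_s, x$fit$offset, x$fit_r2))
  invisible(x)
}

#' Initial intensity of a bleach curve
#'
#' Mean of the first `n_initial` background-corrected values (default 1,
#' i.e. the first summed frame).
#'
#' @param curve a [intensity_timecourse()] result (or any list with a
#'   `corrected` field).
#' @param n_initial number of leading frames to average (>= 1).
#' @return intensity value.
#' @export
initial_intensity <- function(curve, n_initial = 1L) {
  corr <- curve$corrected
  if (length(corr) == 0L) stop("empty curve")
  stopifnot(n_initial >= 1, n_initial <= length(corr))
  mean(corr[seq_len(n_initial)])
}
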