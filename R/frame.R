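# Frame container and image preprocessing (camera artifact correction,
# background estimation/subtraction).

#' Create a video frame
#'
#' A frame is a 2-D grid of intensities in the 8-bit range (stored as
#' real values so corrections keep sub-integer precision) plus a frame
#' index and the pixel size in micrometres.  Coordinates used throughout
#' the package: \code{x} = column, \code{y} = row, origin at the centre
#' of the top-left pixel, so intensity at integer \code{(x, y)} is
#' \code{pixels[y + 1, x + 1]}.
#'
#' @param pixels numeric matrix (rows = image height, columns = width);
#'   at least 8 x 8 so one detector box fits.
#' @param frame_index integer >= 0.
#' @param pixel_size_um micrometres per pixel (> 0).
#' @return an object of class \code{wt_frame}.
#' @export
wt_frame <- function(pixels, frame_index = 0L, pixel_size_um = 40) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 8L || ncol(pixels) < 8L)
    stop("frame must be at least 8 x 8 pixels")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("frame intensities must be finite and >= 0")
  if (frame_index < 0) stop("frame_index must be >= 0")
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be > 0")
  structure(list(pixels = pixels,
                 frame_index = as.integer(frame_index),
                 pixel_size_um = as.numeric(pixel_size_um)),
            class = "wt_frame")
}

#' @export
print.wt_frame <- function(x, ...) {
  cat(sprintf("<wt_frame #%d  %d x %d px  %.3g um/px  range [%.4g, %.4g]>\n",
              x$frame_index, ncol(x$pixels), nrow(x$pixels),
              x$pixel_size_um, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.wt_frame <- function(x) dim(x$pixels)

as_frame <- function(x, frame_index = 0L, pixel_size_um = 40) {
  if (inherits(x, "wt_frame")) x
  else wt_frame(x, frame_index, pixel_size_um)
}

#' Correct the odd-line intensity bias
#'
#' Some high-speed cameras produce a fixed-pattern artifact in which
#' odd-numbered scan lines are systematically darker than even lines.
#' The gain is estimated from the frame itself as
#' \code{g = mean(even rows) / mean(odd rows)} (rows counted from 0, so
#' "odd" rows are matrix rows 2, 4, ...); odd rows are multiplied by
#' \code{g} and the result is clipped back to the 8-bit range.
#'
#' The estimator is a single scalar per frame: the artifact is a
#' per-line fixed pattern, and whiskers occupy so few pixels that their
#' contribution to the row means is negligible.
#'
#' @param frame a \code{\link{wt_frame}} (or a plain matrix).
#' @return the corrected frame.  If the odd rows are all zero the gain
#'   is undefined; the frame is returned unchanged with a warning.
#' @export
correct_line_bias <- function(frame) {
  frame <- as_frame(frame)
  px <- frame$pixels
  if (nrow(px) < 2L) stop("need at least 2 rows")
  odd <- seq(2L, nrow(px), by = 2L)   # 0-based odd rows
  even <- seq(1L, nrow(px), by = 2L)
  m_odd <- mean(px[odd, , drop = FALSE])
  if (m_odd == 0) {
    warning("all-zero odd rows: line-bias gain undefined, frame unchanged")
    return(frame)
  }
  g <- mean(px[even, , drop = FALSE]) / m_odd
  px[odd, ] <- px[odd, ] * g
  hi <- max(255, max(frame$pixels))
  px[px > hi] <- hi
  px[px < 0] <- 0
  frame$pixels <- px
  frame
}

#' Estimate the static background of a video
#'
#' Whiskers are dark objects moving over a bright, static background, so
#' the background at each pixel is estimated as the maximum intensity
#' observed at that pixel over the whole video.
#'
#' @param video a list of \code{\link{wt_frame}} objects (or matrices),
#'   all the same size.
#' @return a \code{wt_frame} holding the per-pixel maximum.
#' @export
estimate_background <- function(video) {
  if (length(video) < 1L) stop("need at least one frame")
  frames <- lapply(video, as_frame)
  d <- dim(frames[[1L]]$pixels)
  bg <- frames[[1L]]$pixels
  for (i in seq_along(frames)[-1L]) {
    if (!identical(dim(frames[[i]]$pixels), d))
      stop(sprintf("frame %d has mismatched shape (%d x %d, expected %d x %d)",
                   i - 1L, nrow(frames[[i]]$pixels), ncol(frames[[i]]$pixels),
                   d[1L], d[2L]))
    bg <- pmax(bg, frames[[i]]$pixels)
  }
  wt_frame(bg, 0L, frames[[1L]]$pixel_size_um)
}

#' Subtract an estimated background from a frame
#'
#' Computes \code{max_intensity - clip(background - frame, 0, max)}, so
#' illumination inhomogeneities are flattened while whiskers remain dark
#' objects on a bright field (the transform is monotone in the frame
#' intensity).
#'
#' @param frame,background frames of identical size.
#' @param max_intensity the bright level of the output (default 255).
#' @return the corrected \code{wt_frame}.
#' @export
subtract_background <- function(frame, background, max_intensity = 255) {
  frame <- as_frame(frame); background <- as_frame(background)
  if (!identical(dim(frame$pixels), dim(background$pixels)))
    stop("frame and background have different shapes")
  d <- background$pixels - frame$pixels
  d[d < 0] <- 0
  d[d > max_intensity] <- max_intensity
  frame$pixels <- max_intensity - d
  frame
}
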