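# The parameterized line detector: a pre-tabulated bank of pixel
# stencils indexed by sub-pixel offset (0.1 px), width (0.2 px) and
# angle (2.5 deg), plus the correlation and per-step optimization
# primitives used by the tracer.

WT_OFF_STEP <- 0.1
WT_W_STEP <- 0.2
WT_A_STEP <- 2.5
WT_W_MIN <- 0.4
WT_W_MAX <- 6.0

#' Create a detector bank
#'
#' The detector models a whisker as a rectangular intensity valley: two
#' parallel step-edge elements of length \code{length_px} (20 px, the
#' distance over which even highly curved whiskers stay approximately
#' straight), separated by the width \code{w}.  Each element is realized
#' as a +1 band (1 px thick, outside the line) adjacent to a -1 band
#' (1 px thick, inside) -- the discrete Laplacian of the valley profile.
#' Pixel stencils are the exact area integral of this piecewise-constant
#' function over each pixel square, normalized to zero sum (offset
#' invariance) with positive and negative mass 1 each (so responses are
#' contrast-linear and approximately equal the valley depth on a matched
#' line).  Stencils are rasterized lazily and memoized per lattice point.
#'
#' @param length_px detector element length in pixels (default 20).
#' @return an object of class \code{wt_bank}.
#' @export
detector_bank <- function(length_px = 20L) {
  structure(list(ptr = .wt_bank_new(as.integer(length_px)),
                 length_px = as.integer(length_px),
                 offset_step = WT_OFF_STEP, width_step = WT_W_STEP,
                 angle_step = WT_A_STEP,
                 width_range = c(WT_W_MIN, WT_W_MAX)),
            class = "wt_bank")
}

#' @export
print.wt_bank <- function(x, ...) {
  cat(sprintf("<wt_bank  length %d px, lattice 0.1 px / 0.2 px / 2.5 deg>\n",
              x$length_px))
  invisible(x)
}

snap_offset <- function(o) {
  i <- round((o + 0.5) / WT_OFF_STEP)
  i <- ((i %% 10) + 10) %% 10          # wrap 0.5 -> -0.5 (same lattice cell)
  -0.5 + i * WT_OFF_STEP
}
snap_width <- function(w) {
  pmin(WT_W_MAX, pmax(WT_W_MIN, WT_W_MIN + round((w - WT_W_MIN) / WT_W_STEP) * WT_W_STEP))
}
snap_angle <- function(a) (round((a %% 360) / WT_A_STEP) * WT_A_STEP) %% 360

#' Detector parameters on the quantization lattice
#'
#' @param offset length-2 sub-pixel displacement from the anchor pixel,
#'   components in [-0.5, 0.5), snapped to 0.1 px.
#' @param width line width in px, snapped to 0.2 px within [0.4, 6].
#' @param angle orientation in degrees, snapped to 2.5 deg mod 360.
#' @return list of class \code{wt_detector_params}.
#' @export
detector_params <- function(offset = c(0, 0), width = 2, angle = 0) {
  structure(list(offset = snap_offset(as.numeric(offset)),
                 width = snap_width(as.numeric(width)),
                 angle = snap_angle(as.numeric(angle))),
            class = "wt_detector_params")
}

#' Rasterize one detector to its pixel stencil
#'
#' @param bank a \code{\link{detector_bank}}.
#' @param params a \code{\link{detector_params}}.
#' @return data.frame with \code{dx}, \code{dy} (pixel displacements
#'   from the anchor) and \code{w} (weights; zero sum, absolute sum 2).
#' @export
rasterize_detector <- function(bank, params) {
  s <- .wt_stencil(bank$ptr, params$offset[1L], params$offset[2L],
                   params$width, params$angle)
  data.frame(dx = s$dx, dy = s$dy, w = s$w)
}

#' Detector response at an anchor pixel
#'
#' Dot product of the stencil weights with the image; positive and
#' maximal when a dark line of matching width and angle on a bright
#' background runs under the detector.  Stencil pixels outside the image
#' read the frame's mean intensity (neutral under the zero-sum weights).
#'
#' @param bank a \code{\link{detector_bank}}.
#' @param frame a \code{\link{wt_frame}} or matrix.
#' @param anchor integer \code{c(x, y)} anchor pixel.
#' @param params a \code{\link{detector_params}}.
#' @param frame_mean optional precomputed mean intensity.
#' @return scalar response.
#' @export
detector_response <- function(bank, frame, anchor, params, frame_mean = NULL) {
  frame <- as_frame(frame)
  if (is.null(frame_mean)) frame_mean <- mean(frame$pixels)
  .wt_response(bank$ptr, frame$pixels, frame_mean,
               as.integer(anchor[1L]), as.integer(anchor[2L]),
               params$offset[1L], params$offset[2L],
               params$width, params$angle)
}

#' One lattice optimization step
#'
#' Exhaustive search over the lattice neighbourhood of \code{prev}: all
#' 100 sub-pixel offsets, angles within +-10 deg and widths within
#' +-0.4 px.  Score ties are broken toward the smallest change from
#' \code{prev} (angle first, then width, then offset), so on a uniform
#' image (all responses 0) \code{prev} itself is returned.
#'
#' @inheritParams detector_response
#' @param prev the previous step's \code{\link{detector_params}}.
#' @return list with \code{params} (the maximizer) and \code{score}.
#' @export
optimize_step <- function(bank, frame, anchor, prev, frame_mean = NULL) {
  frame <- as_frame(frame)
  if (is.null(frame_mean)) frame_mean <- mean(frame$pixels)
  r <- .wt_optimize_step(bank$ptr, frame$pixels, frame_mean,
                         as.integer(anchor[1L]), as.integer(anchor[2L]),
                         prev$offset[1L], prev$offset[2L],
                         prev$width, prev$angle)
  list(params = detector_params(offset = r[1:2], width = r[3], angle = r[4]),
       score = r[5])
}
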