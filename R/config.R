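# Run configuration: every tunable of the pipeline with its default.

#' Face configuration
#'
#' Describes where the face is and how anatomy maps onto image axes.
#' The face mask is either a half-plane bounded by one image edge
#' (\code{side} + \code{mask_offset_px}) or a circle
#' (\code{mask = list(center = c(x, y), radius = r)}) circumscribing the
#' snout.  The anterior-posterior axis runs along the face edge;
#' \code{anterior} names the image direction of increasing anteriority
#' (whiskers are labeled W1 = most posterior upward).
#'
#' @param side image edge the face lies on: "left", "right", "top",
#'   "bottom".
#' @param anterior direction of the anterior end of the snout: "up" or
#'   "down" for left/right faces, "left" or "right" for top/bottom.
#' @param mask_offset_px distance of the mask boundary from the face
#'   edge, px.
#' @param follicle_extrapolation_px distance the follicle lies past the
#'   mask, inside the face (rig-specific; the follicle itself is not
#'   imaged).
#' @param interest_point_arc_mm arc distance from the mask reference
#'   point to the curvature interest point (default 5 mm).
#' @param window_mm length of the curvature measurement window centred
#'   on the interest point; must lie in [1, 2.5] mm (default 2).
#' @param mask optional circle mask overriding the edge half-plane.
#' @return list of class \code{wt_face_config}.
#' @export
wt_face_config <- function(side = c("left", "right", "top", "bottom"),
                           anterior = NULL,
                           mask_offset_px = 8,
                           follicle_extrapolation_px = 10,
                           interest_point_arc_mm = 5,
                           window_mm = 2,
                           mask = NULL) {
  side <- match.arg(side)
  vertical <- side %in% c("left", "right")
  if (is.null(anterior)) anterior <- if (vertical) "up" else "left"
  ok <- if (vertical) c("up", "down") else c("left", "right")
  if (!anterior %in% ok)
    stop(sprintf("anterior must be one of %s for side '%s'",
                 paste(ok, collapse = "/"), side))
  if (window_mm < 1 || window_mm > 2.5)
    stop("window_mm must lie in [1, 2.5]")
  if (mask_offset_px < 0 || follicle_extrapolation_px < 0 ||
      interest_point_arc_mm <= 0)
    stop("face distances must be non-negative")
  if (!is.null(mask)) {
    if (!is.list(mask) || is.null(mask$center) || is.null(mask$radius))
      stop("mask must be list(center = c(x, y), radius = r)")
  }
  structure(list(side = side, anterior = anterior,
                 mask_offset_px = mask_offset_px,
                 follicle_extrapolation_px = follicle_extrapolation_px,
                 interest_point_arc_mm = interest_point_arc_mm,
                 window_mm = window_mm, mask = mask),
            class = "wt_face_config")
}

# unit vectors of the face frame: lateral points away from the face,
# anterior along the snout toward the nose.
face_axes <- function(face) {
  lateral <- switch(face$side,
                    left = c(1, 0), right = c(-1, 0),
                    top = c(0, 1), bottom = c(0, -1))
  anterior <- switch(face$anterior,
                     up = c(0, -1), down = c(0, 1),
                     left = c(-1, 0), right = c(1, 0))
  list(lateral = lateral, anterior = anterior)
}

#' Stop-test thresholds
#'
#' The four per-step reliability tests of the tracer, each with a
#' user-adjustable threshold: minimum detector correlation, maximum
#' left-right intensity asymmetry about the detector, minimum mean
#' intensity about the detector (as a fraction of the frame mean), and
#' maximum angular change per 1 px step.  \code{max_gap_px} bounds the
#' linear extrapolation used to jump distrusted regions (occlusions,
#' crossings).
#'
#' @param min_score minimum response; \code{NULL} (default) resolves to
#'   0.2 x the frame's intensity range at trace time.  The detector's
#'   response on a matched line approximately equals the line's
#'   contrast, while degenerate configurations the optimizer can wander
#'   into (straddling a crossing, riding a flank) respond at roughly
#'   0.2-0.4 of that, so the distrust threshold must sit between the
#'   two; a threshold near zero only rejects empty background.
#' @param max_asymmetry maximum |IL - IR| / (IL + IR) of the flanking
#'   bands (default 0.25).
#' @param min_mean_intensity minimum mean intensity under the detector
#'   footprint, as a fraction of the frame mean (default 0.5).
#' @param max_angle_step_deg maximum angle change per step (default 25).
#' @param max_gap_px maximum occlusion gap jumped, px (default 8).
#' @return list of class \code{wt_stop_tests}.
#' @export
stop_tests <- function(min_score = NULL, max_asymmetry = 0.25,
                       min_mean_intensity = 0.5, max_angle_step_deg = 25,
                       max_gap_px = 8L) {
  vals <- c(max_asymmetry, min_mean_intensity, max_angle_step_deg, max_gap_px)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all stop-test thresholds must be positive")
  if (!is.null(min_score) && (!is.finite(min_score) || min_score <= 0))
    stop("min_score must be positive (or NULL for automatic)")
  structure(list(min_score = min_score, max_asymmetry = max_asymmetry,
                 min_mean_intensity = min_mean_intensity,
                 max_angle_step_deg = max_angle_step_deg,
                 max_gap_px = as.integer(max_gap_px)),
            class = "wt_stop_tests")
}

resolve_min_score <- function(thresholds, frame) {
  if (!is.null(thresholds$min_score)) return(thresholds$min_score)
  0.2 * diff(range(frame$pixels))
}

#' Pipeline configuration
#'
#' All tunables of the trace / link / measure pipeline in one validated
#' object.  Defaults follow the tracker's standard settings: 50 px seed
#' grid, eccentricity threshold 0.95, 20 px detector, 2 px / 50 percent
#' redundancy rule.
#'
#' @param grid_spacing_px seed grid spacing (default 50).
#' @param ecc_threshold seed eccentricity threshold (default 0.95).
#' @param detector_length_px detector element length (default 20).
#' @param thresholds a \code{\link{stop_tests}} object.
#' @param dedup_dist_px,dedup_frac redundancy rule: a curve is redundant
#'   if a contiguous interval within \code{dedup_dist_px} of another
#'   curve covers more than \code{dedup_frac} of its arc length.
#' @param n_whiskers known whisker count N, or NULL to estimate.
#' @param pixel_size_um micrometres per pixel.
#' @param face a \code{\link{wt_face_config}}.
#' @param pole optional \code{list(center = c(x, y), radius = r)} of the
#'   stimulus pole.
#' @param correct_line_bias apply odd-line gain correction before
#'   tracing (default TRUE).
#' @param subtract_background estimate and subtract a max-intensity
#'   background before tracing (default FALSE; head-fixed data normally
#'   does not need it).
#' @param seed RNG seed (used by \code{simulate} only).
#' @return list of class \code{wt_config}.
#' @export
wt_config <- function(grid_spacing_px = 50L, ecc_threshold = 0.95,
                      detector_length_px = 20L,
                      thresholds = stop_tests(),
                      dedup_dist_px = 2, dedup_frac = 0.5,
                      n_whiskers = NULL, pixel_size_um = 40,
                      face = wt_face_config(),
                      pole = NULL,
                      correct_line_bias = TRUE,
                      subtract_background = FALSE,
                      seed = NULL) {
  if (grid_spacing_px < 1) stop("grid_spacing_px must be >= 1")
  if (ecc_threshold < 0 || ecc_threshold > 1)
    stop("ecc_threshold must be in [0, 1]")
  if (detector_length_px < 4) stop("detector_length_px must be >= 4")
  if (!inherits(thresholds, "wt_stop_tests"))
    stop("thresholds must be a stop_tests() object")
  if (dedup_dist_px <= 0) stop("dedup_dist_px must be > 0")
  if (dedup_frac <= 0 || dedup_frac >= 1) stop("dedup_frac must be in (0, 1)")
  if (!is.null(n_whiskers) && n_whiskers < 1)
    stop("n_whiskers must be >= 1 when given")
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (!inherits(face, "wt_face_config"))
    stop("face must be a wt_face_config() object")
  if (!is.null(pole) && (is.null(pole$center) || is.null(pole$radius)))
    stop("pole must be list(center = c(x, y), radius = r)")
  structure(list(grid_spacing_px = as.integer(grid_spacing_px),
                 ecc_threshold = ecc_threshold,
                 detector_length_px = as.integer(detector_length_px),
                 thresholds = thresholds,
                 dedup_dist_px = dedup_dist_px, dedup_frac = dedup_frac,
                 n_whiskers = if (is.null(n_whiskers)) NULL else as.integer(n_whiskers),
                 pixel_size_um = pixel_size_um,
                 face = face, pole = pole,
                 correct_line_bias = isTRUE(correct_line_bias),
                 subtract_background = isTRUE(subtract_background),
                 seed = seed),
            class = "wt_config")
}
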