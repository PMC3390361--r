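# Candidate initiation sites: local line-likeness scored by the
# eccentricity of strip-minima positions in a 7x7 box.

BOX <- 7L
BOX_HALF <- 3L

#' Strip minima of the two 7x7 box partitions
#'
#' A 7x7 box centred on a pixel is split into two partitions: A = its 7
#' one-pixel-wide columns, B = its 7 rows.  When a dark line crosses the
#' box, one partition's strips each cross the line once, so their
#' per-strip intensity minima fall on the backbone and are collinear.
#'
#' Ties within a strip go to the first pixel in row-major scan order
#' (top-to-bottom within a column, left-to-right within a row).
#'
#' @param frame a \code{\link{wt_frame}} or matrix.
#' @param center integer \code{c(x, y)}; the box must lie inside the
#'   frame (callers pre-filter), otherwise an error is raised.
#' @return list with \code{points_a}, \code{points_b}: 7 x 2 matrices of
#'   (x, y) minima positions.
#' @export
box_minima_partitions <- function(frame, center) {
  frame <- as_frame(frame)
  px <- frame$pixels
  cx <- as.integer(center[1L]); cy <- as.integer(center[2L])
  if (cx - BOX_HALF < 0L || cy - BOX_HALF < 0L ||
      cx + BOX_HALF > ncol(px) - 1L || cy + BOX_HALF > nrow(px) - 1L)
    stop(sprintf("7x7 box at (%d, %d) does not fit inside the frame", cx, cy))
  box <- px[(cy - BOX_HALF + 1L):(cy + BOX_HALF + 1L),
            (cx - BOX_HALF + 1L):(cx + BOX_HALF + 1L)]
  pa <- matrix(0, BOX, 2L); pb <- matrix(0, BOX, 2L)
  for (i in seq_len(BOX)) {
    j <- which.min(box[, i])           # first minimum, scanning down
    pa[i, ] <- c(cx - BOX_HALF - 1L + i, cy - BOX_HALF - 1L + j)
    k <- which.min(box[i, ])           # first minimum, scanning right
    pb[i, ] <- c(cx - BOX_HALF - 1L + k, cy - BOX_HALF - 1L + i)
  }
  list(points_a = pa, points_b = pb)
}

#' Eccentricity and orientation of a point cloud
#'
#' Principal components of the 2x2 covariance of the positions: with
#' eigenvalues \code{l1 >= l2 >= 0} the eccentricity of the fitted
#' Gaussian's ellipse is \code{sqrt(1 - l2/l1)} (1 for collinear points,
#' 0 for an isotropic cloud), and the orientation is that of the major
#' axis, in degrees mod 180.
#'
#' @param points n x 2 matrix of (x, y) positions, n >= 2.
#' @return list with \code{eccentricity} and \code{angle_deg}.  All
#'   points identical is a documented degenerate case: eccentricity 0,
#'   angle 0.
#' @export
eccentricity_and_orientation <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 points")
  mx <- mean(points[, 1L]); my <- mean(points[, 2L])
  dx <- points[, 1L] - mx; dy <- points[, 2L] - my
  cxx <- mean(dx * dx); cyy <- mean(dy * dy); cxy <- mean(dx * dy)
  half <- sqrt(max(0, (cxx - cyy)^2 / 4 + cxy^2))
  l1 <- (cxx + cyy) / 2 + half
  l2 <- (cxx + cyy) / 2 - half
  if (l1 <= 0) return(list(eccentricity = 0, angle_deg = 0))
  ecc <- sqrt(max(0, 1 - l2 / l1))
  if (abs(cxy) > 1e-15) v <- c(l1 - cyy, cxy)
  else if (cxx >= cyy)  v <- c(1, 0)
  else                  v <- c(0, 1)
  ang <- (atan2(v[2L], v[1L]) * 180 / pi) %% 180
  list(eccentricity = ecc, angle_deg = ang)
}

# Eccentricity/orientation at many integer centres via the C++ scan.
# Returns a data.frame(x, y, eccentricity, angle_deg).  The C++ routine
# mirrors box_minima_partitions + eccentricity_and_orientation, with two
# additional rules needed in the field (see the methods vignette):
# exactly-constant boxes score 0, and partition ties go to the partition
# with the darker minima.
seed_scan <- function(frame, centers_x, centers_y) {
  frame <- as_frame(frame)
  m <- .wt_seed_scan(frame$pixels, as.integer(centers_x), as.integer(centers_y))
  data.frame(site_x = as.integer(centers_x), site_y = as.integer(centers_y),
             eccentricity = m[, 1L], angle_deg = m[, 2L],
             x = round(m[, 3L]), y = round(m[, 4L]))
}

#' Find tracing initiation sites on a sparse grid
#'
#' Evaluates the 7x7 eccentricity detector at every pixel lying on
#' horizontal and vertical grid lines spaced \code{grid_spacing_px}
#' apart (whiskers span hundreds of pixels, so such a grid crosses each
#' whisker at least once), keeping sites whose eccentricity exceeds
#' \code{ecc_threshold}.
#'
#' @param frame a \code{\link{wt_frame}} or matrix.
#' @param grid_spacing_px grid line spacing in pixels (default 50).
#' @param ecc_threshold eccentricity cutoff in [0, 1] (default 0.95).
#' @return data.frame with columns \code{x}, \code{y} (the estimated
#'   backbone position: the rounded centroid of the chosen partition's
#'   minima -- tracing starts there, not at the box centre),
#'   \code{site_x}, \code{site_y} (the evaluated grid site),
#'   \code{angle_deg} and \code{eccentricity}, sorted by decreasing
#'   eccentricity (row-major site position breaks exact ties).  May
#'   have zero rows.
#' @export
find_seeds <- function(frame, grid_spacing_px = 50L, ecc_threshold = 0.95) {
  frame <- as_frame(frame)
  if (grid_spacing_px < 1L) stop("grid_spacing_px must be >= 1")
  if (ecc_threshold < 0 || ecc_threshold > 1)
    stop("ecc_threshold must be in [0, 1]")
  H <- nrow(frame$pixels); W <- ncol(frame$pixels)
  xr <- BOX_HALF:(W - BOX_HALF - 1L)   # centres where the box fits
  yr <- BOX_HALF:(H - BOX_HALF - 1L)
  gx <- seq(0L, W - 1L, by = as.integer(grid_spacing_px))
  gy <- seq(0L, H - 1L, by = as.integer(grid_spacing_px))
  gx <- gx[gx %in% xr]; gy <- gy[gy %in% yr]
  cx <- c(rep(xr, times = length(gy)), rep(gx, each = length(yr)))
  cy <- c(rep(gy, each = length(xr)), rep(yr, times = length(gx)))
  key <- cx * H + cy
  keep <- !duplicated(key)
  res <- seed_scan(frame, cx[keep], cy[keep])
  res <- res[res$eccentricity > ecc_threshold, , drop = FALSE]
  res <- res[order(-res$eccentricity, res$site_y, res$site_x), , drop = FALSE]
  rownames(res) <- NULL
  res
}
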