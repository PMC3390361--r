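# Scoring traced/linked output against synthetic ground truth.

# fraction of visible backbone points lying within dist_px of the curve
backbone_coverage <- function(backbone, visible_mask, curve_pts, dist_px) {
  vb <- backbone[visible_mask, , drop = FALSE]
  if (!nrow(vb)) return(NA_real_)
  mean(dist_to_polyline(vb, curve_pts) <= dist_px)
}

#' Score tracing and linking against ground truth
#'
#' For every visible ground-truth whisker instance: it counts as
#' \emph{detected} when some traced curve lies within \code{dist_px}
#' mean distance of its backbone and covers at least
#' \code{min_coverage} of its visible length; its \emph{identity} is
#' correct when exactly one curve carries its W label and that curve
#' lies within \code{dist_px} mean distance of the backbone.
#'
#' @param curves_by_frame traced curves (per frame).
#' @param truth_by_frame per-frame truth from \code{\link{render_frame}}
#'   / \code{\link{make_benchmark}}.
#' @param linking optional \code{\link{link_video}} result; identity
#'   columns are NA without it.
#' @param dist_px distance tolerance (default 2).
#' @param min_coverage visible-length coverage required for detection
#'   (default 0.5).
#' @return data.frame with one row per (frame, whisker): columns
#'   \code{frame}, \code{whisker}, \code{visible}, \code{detected},
#'   \code{id_correct}.
#' @export
score_against_truth <- function(curves_by_frame, truth_by_frame,
                                linking = NULL, dist_px = 2,
                                min_coverage = 0.5) {
  rows <- list()
  for (t in seq_along(truth_by_frame)) {
    tr <- truth_by_frame[[t]]
    curves <- curves_by_frame[[t]]
    labs <- if (!is.null(linking)) linking$frames[[t]]$labels else NULL
    mean_d <- function(cv, bb) mean(dist_to_polyline(cv$points, bb))
    for (w in tr$whiskers) {
      if (!w$visible) {
        rows[[length(rows) + 1L]] <-
          data.frame(frame = tr$frame_index, whisker = w$id, visible = FALSE,
                     detected = NA, id_correct = NA)
        next
      }
      detected <- FALSE
      for (cv in curves) {
        if (mean_d(cv, w$backbone) <= dist_px &&
            isTRUE(backbone_coverage(w$backbone, w$visible_mask,
                                     cv$points, dist_px) >= min_coverage)) {
          detected <- TRUE
          break
        }
      }
      idc <- NA
      if (!is.null(labs)) {
        hit <- which(labs == paste0("W", w$id))
        idc <- length(hit) == 1L &&
          mean_d(curves[[hit]], w$backbone) <= dist_px
      }
      rows[[length(rows) + 1L]] <-
        data.frame(frame = tr$frame_index, whisker = w$id, visible = TRUE,
                   detected = detected, id_correct = idc)
    }
  }
  do.call(rbind, rows)
}
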