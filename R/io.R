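# File formats: minimal baseline TIFF (8-bit grayscale, uncompressed,
# both byte orders), PGM sequences, JSON-lines curve files, truth JSON,
# measurement TSV and JSON configs.  All writers are versioned and
# round-trip losslessly through their readers.

CURVES_FORMAT_VERSION <- 1L
TRUTH_FORMAT_VERSION <- 1L

# ---- TIFF -------------------------------------------------------------
# No TIFF package exists in this stack, so a minimal baseline codec is
# implemented here: 8-bit grayscale, one strip per page, no compression.

#' Write a multi-page 8-bit grayscale TIFF
#'
#' @param pages a matrix or list of matrices (intensities 0..255; values
#'   are rounded and clamped).
#' @param path output file.
#' @export
write_tiff <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  con <- file(path, "wb")
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L)
  n <- length(pages)
  # layout: header(8) | per page: pixel data then IFD
  offset <- 8L
  data_off <- integer(n); ifd_off <- integer(n)
  sizes <- vapply(pages, length, 0L)
  n_entries <- 8L
  for (i in seq_len(n)) {
    data_off[i] <- offset
    ifd_off[i] <- offset + sizes[i] + (sizes[i] %% 2L)   # word-align IFD
    offset <- ifd_off[i] + 2L + n_entries * 12L + 4L
  }
  w4(ifd_off[1L])
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count); w4(value)
  }
  for (i in seq_len(n)) {
    m <- pages[[i]]
    m[] <- pmin(255, pmax(0, round(m)))
    # row-major pixel order: transpose the column-major matrix
    writeBin(as.raw(t(m)), con)
    if (sizes[i] %% 2L) writeBin(as.raw(0L), con)
    w2(n_entries)
    entry(256L, 3L, 1L, ncol(m))           # ImageWidth
    entry(257L, 3L, 1L, nrow(m))           # ImageLength
    entry(258L, 3L, 1L, 8L)                # BitsPerSample
    entry(259L, 3L, 1L, 1L)                # Compression: none
    entry(262L, 3L, 1L, 1L)                # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off[i])       # StripOffsets
    entry(278L, 3L, 1L, nrow(m))           # RowsPerStrip
    entry(279L, 4L, 1L, sizes[i])          # StripByteCounts
    w4(if (i < n) ifd_off[i + 1L] else 0L)
  }
  invisible(path)
}

#' Read a multi-page 8-bit grayscale TIFF
#'
#' Supports baseline uncompressed single-sample images in either byte
#' order; anything else (RGB, palettes, compression, 16-bit) is
#' rejected with an informative error.
#'
#' @param path TIFF file.
#' @return list of intensity matrices.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8L) stop(sprintf("'%s' is not a TIFF file", path))
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
            else stop(sprintf("'%s' is not a TIFF file", path))
  rd <- function(off, size, n = 1L)
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = size == 4L, endian = endian)
  if (rd(2L, 2L) != 42L) stop(sprintf("'%s' is not a TIFF file", path))
  ifd <- rd(4L, 4L)
  pages <- list()
  while (ifd != 0L) {
    ne <- rd(ifd, 2L)
    tags <- list()
    for (k in seq_len(ne)) {
      base <- ifd + 2L + (k - 1L) * 12L
      tag <- rd(base, 2L); type <- rd(base + 2L, 2L); cnt <- rd(base + 4L, 4L)
      vsize <- c(1L, 1L, 2L, 4L)[min(type, 4L)]
      val <- if (vsize * cnt <= 4L) rd(base + 8L, vsize, cnt)
             else rd(rd(base + 8L, 4L), vsize, cnt)
      tags[[as.character(tag)]] <- val
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    W <- g(256L); H <- g(257L)
    if (is.null(W) || is.null(H)) stop(sprintf("'%s': malformed IFD", path))
    bps <- g(258L, 1L); comp <- g(259L, 1L); spp <- g(277L, 1L)
    if (any(bps != 8L) || spp != 1L)
      stop(sprintf("'%s' page %d: only 8-bit single-channel grayscale supported",
                   path, length(pages) + 1L))
    if (comp != 1L)
      stop(sprintf("'%s' page %d: compressed TIFF not supported", path,
                   length(pages) + 1L))
    offs <- g(273L); cnts <- g(279L, rep(W * H, length(offs)))
    rows_per_strip <- g(278L, H)
    px <- raw(0)
    for (s in seq_along(offs))
      px <- c(px, raw[(offs[s] + 1L):(offs[s] + cnts[s])])
    m <- matrix(as.integer(px[seq_len(W * H)]), nrow = H, ncol = W,
                byrow = TRUE)
    pages[[length(pages) + 1L]] <- m
    ifd <- rd(ifd + 2L + ne * 12L, 4L)
  }
  pages
}

# ---- PGM sequences ----------------------------------------------------

read_pgm <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  magic <- if (length(raw) >= 2L) rawToChar(raw[1:2]) else ""
  if (!magic %in% c("P2", "P5"))
    stop(sprintf("'%s' is not a PGM file", path))
  if (magic == "P2") {
    tok <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
    W <- as.integer(tok[2L]); H <- as.integer(tok[3L])
    vals <- as.integer(tok[-(1:4)])
    return(matrix(vals, H, W, byrow = TRUE))
  }
  # P5: parse header tokens then read binary payload
  pos <- 3L; tokens <- integer(0)
  while (length(tokens) < 3L) {
    while (pos <= length(raw) && rawToChar(raw[pos]) %in% c(" ", "\n", "\r", "\t"))
      pos <- pos + 1L
    if (rawToChar(raw[pos]) == "#") {
      while (rawToChar(raw[pos]) != "\n") pos <- pos + 1L
      next
    }
    start <- pos
    while (pos <= length(raw) &&
           !rawToChar(raw[pos]) %in% c(" ", "\n", "\r", "\t")) pos <- pos + 1L
    tokens <- c(tokens, as.integer(rawToChar(raw[start:(pos - 1L)])))
  }
  pos <- pos + 1L   # single whitespace after maxval
  W <- tokens[1L]; H <- tokens[2L]
  if (tokens[3L] > 255L) stop(sprintf("'%s': 16-bit PGM not supported", path))
  matrix(as.integer(raw[pos:(pos + W * H - 1L)]), H, W, byrow = TRUE)
}

write_pgm <- function(m, path) {
  m[] <- pmin(255, pmax(0, round(m)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("P5\n%d %d\n255\n", ncol(m), nrow(m))), con)
  writeBin(as.raw(t(m)), con)
  invisible(path)
}

#' Read a video as a list of frames
#'
#' Accepts a multi-page TIFF file or a directory of numbered
#' single-channel PGM images (e.g. \code{frame_000.pgm}); frames are
#' returned in index order and gaps in the numbering are an error.
#'
#' @param path TIFF file or directory.
#' @param pixel_size_um pixel size attached to each frame.
#' @return list of \code{\link{wt_frame}}.
#' @export
read_video <- function(path, pixel_size_um = 40) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.pgm$", full.names = TRUE)
    if (!length(files)) stop(sprintf("no .pgm frames found in '%s'", path))
    nums <- suppressWarnings(as.integer(gsub("\\D", "", basename(files))))
    if (any(is.na(nums))) stop("PGM file names must contain frame numbers")
    o <- order(nums); files <- files[o]; nums <- nums[o]
    expect <- seq(nums[1L], by = 1L, length.out = length(nums))
    if (!identical(nums, expect))
      stop(sprintf("missing frame numbers: %s",
                   paste(setdiff(seq(nums[1L], max(nums)), nums), collapse = ", ")))
    pages <- lapply(files, read_pgm)
  } else {
    pages <- read_tiff(path)
  }
  lapply(seq_along(pages), function(i)
    wt_frame(pages[[i]], i - 1L, pixel_size_um))
}

# ---- curve files (JSON lines) -----------------------------------------

#' Write traced curves to a JSON-lines file
#'
#' One JSON object per curve with fields \code{frame}, \code{curve_id},
#' \code{x}, \code{y}, \code{score}, \code{width} and optionally
#' \code{label}, preceded by a versioned header line.
#'
#' @param curves_by_frame list (per frame) of lists of
#'   \code{\link{wt_curve}}.
#' @param path output file.
#' @param linking optional \code{\link{link_video}} result whose labels
#'   are attached to the records.
#' @export
write_curves <- function(curves_by_frame, path, linking = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(format = "whiskr-curves",
                                   version = CURVES_FORMAT_VERSION,
                                   n_frames = length(curves_by_frame)),
                              auto_unbox = TRUE), con)
  for (t in seq_along(curves_by_frame)) {
    curves <- curves_by_frame[[t]]
    for (i in seq_along(curves)) {
      cv <- curves[[i]]
      rec <- list(frame = cv$frame_index, curve_id = i - 1L,
                  x = round(cv$points[, 1L], 4), y = round(cv$points[, 2L], 4),
                  score = round(cv$scores, 3), width = round(cv$widths, 2))
      if (!is.null(linking)) rec$label <- linking$frames[[t]]$labels[i]
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' Read a JSON-lines curve file
#'
#' @param path file written by \code{\link{write_curves}}.
#' @return list with \code{curves_by_frame} (indexed by frame order),
#'   \code{labels_by_frame} (NULL when unlabeled) and the header.
#' @export
read_curves <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop(sprintf("'%s' is empty", path))
  header <- jsonlite::fromJSON(lines[1L])
  if (!identical(header$format, "whiskr-curves"))
    stop(sprintf("'%s' is not a whiskr curves file", path))
  n_frames <- header$n_frames
  curves <- rep(list(list()), n_frames)
  labels <- rep(list(character(0)), n_frames)
  any_labels <- FALSE
  for (ln in lines[-1L]) {
    rec <- jsonlite::fromJSON(ln)
    t <- rec$frame + 1L
    cv <- wt_curve(cbind(rec$x, rec$y), rec$score, rec$width, rec$frame)
    curves[[t]][[length(curves[[t]]) + 1L]] <- cv
    labels[[t]] <- c(labels[[t]],
                     if (is.null(rec$label)) NA_character_ else rec$label)
    if (!is.null(rec$label)) any_labels <- TRUE
  }
  list(curves_by_frame = curves,
       labels_by_frame = if (any_labels) labels else NULL,
       header = header)
}

#' Export curves as TSV
#'
#' Flat interoperability format: one row per traced point with columns
#' frame, curve_id, point_index, x, y, score, width (and label when
#' available).
#'
#' @inheritParams write_curves
#' @export
write_curves_tsv <- function(curves_by_frame, path, linking = NULL) {
  rows <- list()
  for (t in seq_along(curves_by_frame)) {
    curves <- curves_by_frame[[t]]
    for (i in seq_along(curves)) {
      cv <- curves[[i]]
      df <- data.frame(frame = cv$frame_index, curve_id = i - 1L,
                       point_index = seq_len(nrow(cv$points)) - 1L,
                       x = round(cv$points[, 1L], 4),
                       y = round(cv$points[, 2L], 4),
                       score = round(cv$scores, 3),
                       width = round(cv$widths, 2))
      if (!is.null(linking)) df$label <- linking$frames[[t]]$labels[i]
      rows[[length(rows) + 1L]] <- df
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), curve_id = integer(0),
               point_index = integer(0), x = numeric(0), y = numeric(0),
               score = numeric(0), width = numeric(0))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- truth and measurements -------------------------------------------

#' Write synthetic ground truth as JSON
#' @param truth list of per-frame truth entries from
#'   \code{\link{render_frame}}.
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  slim <- lapply(truth, function(tr) {
    list(frame_index = tr$frame_index,
         whiskers = lapply(tr$whiskers, function(w)
           list(id = w$id, visible = w$visible,
                angle_deg = w$angle_deg, base_angle_deg = w$base_angle_deg,
                bezier = lapply(w$bezier, as.numeric),
                backbone = round(unname(w$backbone), 3))))
  })
  jsonlite::write_json(list(format = "whiskr-truth",
                            version = TRUTH_FORMAT_VERSION, frames = slim),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a truth JSON file
#' @param path file written by \code{\link{write_truth}}.
#' @return list with per-frame entries (backbones as matrices).
#' @export
read_truth <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  if (!identical(obj$format, "whiskr-truth"))
    stop(sprintf("'%s' is not a whiskr truth file", path))
  obj$frames
}

#' Write whisker measurements as TSV
#'
#' One row per (frame, whisker); the header names carry the units.
#' Missing values are written as empty fields.
#'
#' @param records data.frame of \code{\link{measure_whisker}} rows.
#' @param path output file.
#' @export
write_measurements <- function(records, path) {
  hdr <- c("frame", "label", "length_px", "angle_deg", "curvature_per_mm",
           "follicle_x", "follicle_y", "tip_x", "tip_y", "score",
           "contact_x", "contact_y", "contact_dist_px")
  out <- records[, hdr]
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Load a configuration file
#'
#' JSON object whose keys mirror the arguments of
#' \code{\link{wt_config}}, \code{\link{stop_tests}} and
#' \code{\link{wt_face_config}} (nested under \code{thresholds} /
#' \code{face}).  Unknown keys are an error.
#'
#' @param path JSON file.
#' @return a validated \code{\link{wt_config}}.
#' @export
read_config <- function(path) {
  obj <- jsonlite::fromJSON(path)
  build_config_from_list(obj)
}

build_config_from_list <- function(obj) {
  known <- c("grid_spacing_px", "ecc_threshold", "detector_length_px",
             "thresholds", "dedup_dist_px", "dedup_frac", "n_whiskers",
             "pixel_size_um", "face", "pole", "correct_line_bias",
             "subtract_background", "seed")
  bad <- setdiff(names(obj), known)
  if (length(bad))
    stop(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  args <- obj
  if (!is.null(obj$thresholds))
    args$thresholds <- do.call(stop_tests, obj$thresholds)
  if (!is.null(obj$face))
    args$face <- do.call(wt_face_config, obj$face)
  if (!is.null(obj$pole))
    args$pole <- list(center = as.numeric(obj$pole$center),
                      radius = as.numeric(obj$pole$radius))
  do.call(wt_config, args)
}
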