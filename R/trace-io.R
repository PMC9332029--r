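# Detection traces and behavior ground truth: domain objects and file formats.
#
# A detection trace is the output of a per-frame object detector watching the
# bed region: for every frame there are zero or more labeled bounding boxes.
# Frames with zero boxes are first-class data (the "no bounding box" state
# drives the nobody status), so both on-disk formats represent them
# explicitly rather than by omission.

#' Behaviors recognized by the monitor
#'
#' The four bed-related behaviors, in queue order: queue 1 holds "moving
#' away" statuses and recognizes \code{off_bed}, queue 2 holds neutral
#' statuses (\code{on_bed}), queue 3 "moving toward" (\code{return}), and
#' queue 4 missing-detection statuses (\code{nobody}).
#'
#' @return Character vector of the four behavior names.
#' @export
scq_behaviors <- function() c("off_bed", "on_bed", "return", "nobody")

#' Construct a bounding box
#'
#' Boxes are stored center-form: \code{cx}, \code{cy} are the center of the
#' box in image pixels, origin at the top-left of the image, x rightward and
#' y downward. Detections reported corner-form can be converted with
#' \code{box_from_corners}.
#'
#' @param label Category tag, typically \code{"head"} or \code{"trunk"}.
#' @param cx,cy Center coordinates in pixels.
#' @param w,h Box width and height in pixels; must be positive.
#' @param conf Detector confidence in \[0, 1\].
#' @return A one-row data frame with columns \code{label, cx, cy, w, h, conf}.
#' @export
#' @examples
#' bounding_box("head", 100, 200, 40, 40, 0.9)
bounding_box <- function(label, cx, cy, w, h, conf = 1) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.finite(w) || !is.finite(h) || w <= 0 || h <= 0)
    stop("bounding box width and height must be positive", call. = FALSE)
  if (!is.finite(conf) || conf < 0 || conf > 1)
    stop("bounding box confidence must lie in [0, 1]", call. = FALSE)
  data.frame(label = label, cx = as.numeric(cx), cy = as.numeric(cy),
             w = as.numeric(w), h = as.numeric(h), conf = as.numeric(conf),
             stringsAsFactors = FALSE)
}

#' @rdname bounding_box
#' @param x0,y0 Top-left corner of the box in pixels.
#' @export
box_from_corners <- function(label, x0, y0, w, h, conf = 1) {
  bounding_box(label, x0 + w / 2, y0 + h / 2, w, h, conf)
}

# Internal canonical empty box-row (a frame with no detections).
.empty_box_row <- function(frame, t) {
  n <- length(frame)
  data.frame(frame = frame, t = t, label = rep(NA_character_, n),
             cx = rep(NA_real_, n), cy = rep(NA_real_, n),
             w = rep(NA_real_, n), h = rep(NA_real_, n),
             conf = rep(NA_real_, n), stringsAsFactors = FALSE)
}

.trace_cols <- c("frame", "t", "label", "cx", "cy", "w", "h", "conf")

#' Construct a detection trace
#'
#' A detection trace holds per-frame detections in long form: one row per
#' bounding box, and for frames with no detections a single row whose box
#' columns are all \code{NA}. Frame indices are 0-based and must be strictly
#' increasing; timestamps are nondecreasing and default to
#' \code{frame / frame_rate} when missing.
#'
#' @param frames Data frame with columns
#'   \code{frame, t, label, cx, cy, w, h, conf} (column \code{t} optional).
#'   A zero-row data frame yields an empty trace.
#' @param frame_rate Capture frame rate R in frames per second.
#' @return An object of class \code{"detection_trace"}: a list with elements
#'   \code{frames} (the validated long-form data frame) and
#'   \code{frame_rate}.
#' @export
detection_trace <- function(frames, frame_rate = 15) {
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("frame_rate must be a positive scalar", call. = FALSE)
  frames <- as.data.frame(frames, stringsAsFactors = FALSE)
  if (nrow(frames) == 0L) {
    frames <- .empty_box_row(integer(0), numeric(0))
  }
  if (!"t" %in% names(frames)) frames$t <- frames$frame / frame_rate
  missing_cols <- setdiff(.trace_cols, names(frames))
  if (length(missing_cols))
    stop("trace is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  frames <- frames[.trace_cols]
  frames$frame <- as.integer(frames$frame)
  frames$t <- ifelse(is.na(frames$t), frames$frame / frame_rate, frames$t)
  for (col in c("cx", "cy", "w", "h", "conf"))
    frames[[col]] <- as.numeric(frames[[col]])
  frames$label <- as.character(frames$label)
  obj <- structure(list(frames = frames, frame_rate = frame_rate),
                   class = "detection_trace")
  validate_trace(obj)
  obj
}

validate_trace <- function(trace) {
  fr <- trace$frames
  if (nrow(fr) == 0L) return(invisible(trace))
  if (any(fr$frame < 0L))
    stop("frame indices must be nonnegative", call. = FALSE)
  u <- unique(fr$frame)
  if (is.unsorted(u, strictly = TRUE))
    stop("frame indices must be strictly increasing", call. = FALSE)
  tt <- fr$t[!duplicated(fr$frame)]
  if (is.unsorted(tt))
    stop("timestamps must be nondecreasing", call. = FALSE)
  has_box <- !is.na(fr$label)
  if (any(has_box)) {
    b <- fr[has_box, ]
    if (any(!is.finite(b$cx) | !is.finite(b$cy)))
      stop("boxes must have finite center coordinates", call. = FALSE)
    if (any(!is.finite(b$w) | !is.finite(b$h) | b$w <= 0 | b$h <= 0))
      stop("boxes must have positive width and height", call. = FALSE)
    if (any(!is.finite(b$conf) | b$conf < 0 | b$conf > 1))
      stop("box confidence must lie in [0, 1]", call. = FALSE)
  }
  # an empty row must be the only row of its frame
  empty_frames <- fr$frame[!has_box]
  if (any(empty_frames %in% fr$frame[has_box]))
    stop("a frame cannot mix empty and non-empty box rows", call. = FALSE)
  invisible(trace)
}

#' Number of frames in a detection trace
#' @param trace A \code{detection_trace}.
#' @return Integer count of distinct frames.
#' @export
n_frames <- function(trace) length(unique(trace$frames$frame))

#' @export
print.detection_trace <- function(x, ...) {
  nf <- n_frames(x)
  nb <- sum(!is.na(x$frames$label))
  cat(sprintf("Detection trace: %d frames at %g fps (%.2f s), %d boxes, %d empty frames\n",
              nf, x$frame_rate, if (nf) max(x$frames$t) else 0, nb, nf - sum(unique(x$frames$frame) %in% x$frames$frame[!is.na(x$frames$label)])))
  invisible(x)
}

.infer_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("jsonl", "csv")))
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
}

# full-precision float serialization so write/read round-trips exactly
.num_chr <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

#' Read a detection trace from disk
#'
#' Two formats are supported. CSV: columns
#' \code{frame,t,label,cx,cy,w,h,conf}, one row per box; a frame with no
#' detections is a row with empty box columns. JSONL: one JSON object per
#' frame, \code{{"frame": int, "t": float, "boxes": [\{"label", "cx", "cy",
#' "w", "h", "conf"\}]}}, where \code{boxes} may be empty.
#'
#' @param path File to read.
#' @param format \code{"jsonl"} or \code{"csv"}; inferred from the file
#'   extension when \code{NULL}.
#' @param frame_rate Frame rate to attach to the trace.
#' @return A \code{detection_trace}.
#' @export
read_trace <- function(path, format = NULL, frame_rate = 15) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  format <- .infer_format(path, format)
  if (format == "csv") {
    df <- tryCatch(
      utils::read.csv(path, stringsAsFactors = FALSE,
                      colClasses = c(frame = "integer", t = "numeric",
                                     label = "character", cx = "numeric",
                                     cy = "numeric", w = "numeric",
                                     h = "numeric", conf = "numeric")),
      error = function(e) stop("malformed trace CSV '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    df$label[!is.na(df$label) & df$label == ""] <- NA_character_
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                      error = function(e) stop("malformed JSONL at line ", i,
                                               " of '", path, "': ",
                                               conditionMessage(e),
                                               call. = FALSE))
      if (is.null(rec$frame))
        stop("malformed JSONL at line ", i, " of '", path,
             "': missing 'frame'", call. = FALSE)
      t <- if (is.null(rec$t)) NA_real_ else as.numeric(rec$t)
      boxes <- rec$boxes
      if (is.null(boxes) || NROW(boxes) == 0L) {
        rows[[i]] <- .empty_box_row(as.integer(rec$frame), t)
      } else {
        boxes <- as.data.frame(boxes, stringsAsFactors = FALSE)
        rows[[i]] <- data.frame(frame = as.integer(rec$frame), t = t,
                                label = as.character(boxes$label),
                                cx = as.numeric(boxes$cx),
                                cy = as.numeric(boxes$cy),
                                w = as.numeric(boxes$w),
                                h = as.numeric(boxes$h),
                                conf = as.numeric(boxes$conf),
                                stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    if (is.null(df)) df <- .empty_box_row(integer(0), numeric(0))
  }
  detection_trace(df, frame_rate = frame_rate)
}

#' Write a detection trace to disk
#'
#' Inverse of \code{\link{read_trace}}; floats are serialized at full
#' precision so a write/read round-trip reproduces the trace exactly.
#'
#' @param trace A \code{detection_trace}.
#' @param path Output file.
#' @param format \code{"jsonl"} or \code{"csv"}; inferred from the extension
#'   when \code{NULL}.
#' @return Invisibly, \code{path}.
#' @export
write_trace <- function(trace, path, format = NULL) {
  stopifnot(inherits(trace, "detection_trace"))
  format <- .infer_format(path, format)
  fr <- trace$frames
  if (format == "csv") {
    lines <- c(paste(.trace_cols, collapse = ","),
               if (nrow(fr)) paste(fr$frame, .num_chr(fr$t),
                                   ifelse(is.na(fr$label), "", fr$label),
                                   .num_chr(fr$cx), .num_chr(fr$cy),
                                   .num_chr(fr$w), .num_chr(fr$h),
                                   .num_chr(fr$conf), sep = ","))
    writeLines(lines, path)
  } else {
    # lines are assembled by hand so floats keep full (%.17g) precision
    idx <- split(seq_len(nrow(fr)), factor(fr$frame, levels = unique(fr$frame)))
    lines <- vapply(idx, function(i) {
      boxes <- fr[i, , drop = FALSE]
      boxes <- boxes[!is.na(boxes$label), , drop = FALSE]
      box_json <- if (nrow(boxes))
        paste(sprintf('{"label":%s,"cx":%s,"cy":%s,"w":%s,"h":%s,"conf":%s}',
                      vapply(boxes$label, jsonlite::toJSON, character(1),
                             auto_unbox = TRUE),
                      .num_chr(boxes$cx), .num_chr(boxes$cy),
                      .num_chr(boxes$w), .num_chr(boxes$h),
                      .num_chr(boxes$conf)),
              collapse = ",")
      else ""
      sprintf('{"frame":%d,"t":%s,"boxes":[%s]}',
              fr$frame[i[1]], .num_chr(fr$t[i[1]]), box_json)
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read ground-truth behavior segments
#'
#' Segment files are CSV with columns \code{behavior,start_frame,end_frame}
#' (frames inclusive, 0-based). Rows may appear in any order; the result is
#' sorted by \code{start_frame} and validated to be non-overlapping.
#'
#' @param path CSV file to read.
#' @return Data frame of class \code{c("behavior_segments", "data.frame")}
#'   with columns \code{behavior, start_frame, end_frame}.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("segment file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed segment CSV '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  behavior_segments(df)
}

#' @rdname read_segments
#' @param segments Data frame with columns
#'   \code{behavior, start_frame, end_frame} to validate and sort.
#' @export
behavior_segments <- function(segments) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  need <- c("behavior", "start_frame", "end_frame")
  if (!all(need %in% names(segments)))
    stop("segments need columns behavior, start_frame, end_frame",
         call. = FALSE)
  segments <- segments[need]
  segments$behavior <- as.character(segments$behavior)
  segments$start_frame <- as.integer(segments$start_frame)
  segments$end_frame <- as.integer(segments$end_frame)
  bad <- setdiff(segments$behavior, scq_behaviors())
  if (length(bad))
    stop("unknown behavior(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(segments$start_frame > segments$end_frame))
    stop("segment start_frame must not exceed end_frame", call. = FALSE)
  segments <- segments[order(segments$start_frame), , drop = FALSE]
  rownames(segments) <- NULL
  if (nrow(segments) > 1L &&
      any(segments$start_frame[-1L] <= segments$end_frame[-nrow(segments)]))
    stop("behavior segments overlap", call. = FALSE)
  class(segments) <- c("behavior_segments", "data.frame")
  segments
}

#' @rdname read_segments
#' @export
write_segments <- function(segments, path) {
  segments <- behavior_segments(segments)
  utils::write.csv(as.data.frame(segments), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
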