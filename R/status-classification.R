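# Stage 2: per-frame activity status from bounding-box center movement.
#
# The status of frame i compares the Euclidean distance of the current box
# center to a reference initial position P0 against the same distance one
# frame earlier:
#
#   +1  moved away from P0 by at least epsilon
#    0  neutral (|change| < epsilon)
#   -1  moved toward P0 by at least epsilon
#   -2  no bounding box in the frame
#
# P0 is fixed once per trace: the image origin, a predefined (typically
# bed-anchored) point, or the first detected position.

#' Classifier configuration
#'
#' @param epsilon Distance threshold in pixels; movement of the box center's
#'   distance-to-P0 smaller than \code{epsilon} between consecutive frames is
#'   neutral. Default 5 px, sized for 640x360 input.
#' @param p0_mode How the reference position P0 is chosen: the image origin
#'   (top-left pixel), a fixed predefined point (e.g. the bed center), or the
#'   first detected box center in the trace.
#' @param p0_fixed Numeric \code{c(x, y)}; required iff
#'   \code{p0_mode = "fixed"}.
#' @param label_priority Which box label to track when several are present;
#'   the first label in this vector that occurs in a frame wins, and within
#'   a label the highest-confidence box is used.
#' @return An object of class \code{"classifier_config"}.
#' @export
classifier_config <- function(epsilon = 5,
                              p0_mode = c("origin", "fixed", "first_detection"),
                              p0_fixed = NULL,
                              label_priority = c("head", "trunk")) {
  p0_mode <- match.arg(p0_mode)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    stop("epsilon must be a nonnegative scalar", call. = FALSE)
  if (p0_mode == "fixed") {
    if (is.null(p0_fixed) || length(p0_fixed) != 2L || !is.numeric(p0_fixed))
      stop("p0_mode = 'fixed' requires p0_fixed = c(x, y)", call. = FALSE)
  } else if (!is.null(p0_fixed)) {
    stop("p0_fixed is only meaningful with p0_mode = 'fixed'", call. = FALSE)
  }
  structure(list(epsilon = epsilon, p0_mode = p0_mode,
                 p0_fixed = if (is.null(p0_fixed)) NULL else as.numeric(p0_fixed),
                 label_priority = as.character(label_priority)),
            class = "classifier_config")
}

#' @export
print.classifier_config <- function(x, ...) {
  p0 <- switch(x$p0_mode,
               origin = "origin (0, 0)",
               fixed = sprintf("fixed (%g, %g)", x$p0_fixed[1], x$p0_fixed[2]),
               first_detection = "first detected position")
  cat(sprintf("Status classifier: epsilon = %g px, P0 = %s, track priority: %s\n",
              x$epsilon, p0, paste(x$label_priority, collapse = " > ")))
  invisible(x)
}

#' Center of a bounding box
#'
#' @param box A one-row box data frame (as from \code{\link{bounding_box}})
#'   or anything with \code{cx}/\code{cy} fields.
#' @return Numeric \code{c(x, y)} in pixels.
#' @export
center_of <- function(box) c(as.numeric(box$cx)[1], as.numeric(box$cy)[1])

#' Select the tracked position in one frame
#'
#' When a frame contains several detections, the tracked position is the
#' center of a single box chosen by label priority (first listed label
#' present wins) and, within a label, by highest confidence.
#'
#' @param boxes Data frame of the frame's boxes with columns
#'   \code{label, cx, cy, conf} (rows with \code{NA} label are ignored).
#' @param priority Character vector of labels in decreasing priority.
#' @return \code{c(x, y)} or \code{NULL} when the frame has no usable box.
#' @export
select_position <- function(boxes, priority = c("head", "trunk")) {
  boxes <- boxes[!is.na(boxes$label), , drop = FALSE]
  if (nrow(boxes) == 0L) return(NULL)
  pr <- match(boxes$label, priority)
  pr[is.na(pr)] <- length(priority) + 1L
  best <- order(pr, -boxes$conf)[1L]
  c(boxes$cx[best], boxes$cy[best])
}

#' Number of frames in a time slot
#'
#' A slot of W seconds at R frames per second spans \code{W * R} frames
#' (rounded to the nearest integer, at least 1).
#'
#' @param W Slot length in seconds; must be positive.
#' @param R Frame rate in fps; must be positive.
#' @return Integer frame count.
#' @export
#' @examples
#' window_frame_count(1, 15)  # 15
window_frame_count <- function(W, R) {
  if (!is.numeric(W) || length(W) != 1L || !is.finite(W) || W <= 0)
    stop("W must be a positive number of seconds", call. = FALSE)
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop("R must be a positive frame rate", call. = FALSE)
  max(1L, as.integer(round(W * R)))
}

#' Classify the movement status of one frame
#'
#' @param prev_pos Previous tracked position \code{c(x, y)}, or \code{NULL}
#'   if nothing has been observed yet (then P0 stands in for it).
#' @param cur_pos Current tracked position, or \code{NULL} when the frame
#'   has no box.
#' @param p0 Reference initial position \code{c(x, y)}.
#' @param epsilon Distance threshold in pixels.
#' @return Integer status: \code{1}, \code{0}, \code{-1} or \code{-2}.
#' @export
#' @examples
#' classify_status(c(3, 4), c(6, 8), p0 = c(0, 0), epsilon = 2)  # +1
classify_status <- function(prev_pos, cur_pos, p0, epsilon) {
  if (is.null(cur_pos)) return(-2L)
  if (is.null(prev_pos)) prev_pos <- p0
  d_cur <- sqrt(sum((cur_pos - p0)^2))
  d_prev <- sqrt(sum((prev_pos - p0)^2))
  if (d_cur - d_prev >= epsilon) 1L
  else if (d_prev - d_cur >= epsilon) -1L
  else 0L
}

#' Classify a whole detection trace
#'
#' Applies \code{\link{select_position}} and \code{\link{classify_status}}
#' frame by frame. The previous position carries across missing-detection
#' gaps: a box reappearing after a dropout is compared against where it was
#' last seen, not against P0, so a mid-behavior detection failure does not
#' fabricate movement. The first detected frame is compared against P0.
#'
#' @param trace A \code{\link{detection_trace}}.
#' @param config A \code{\link{classifier_config}}.
#' @return Data frame with one row per frame, columns
#'   \code{frame, t, status, cx, cy} (\code{cx}/\code{cy} are \code{NA} for
#'   status \code{-2}).
#' @export
classify_trace <- function(trace, config = classifier_config()) {
  stopifnot(inherits(trace, "detection_trace"),
            inherits(config, "classifier_config"))
  fr <- trace$frames
  ufr <- unique(fr$frame)
  nf <- length(ufr)
  out <- data.frame(frame = ufr,
                    t = fr$t[!duplicated(fr$frame)],
                    status = integer(nf), cx = NA_real_, cy = NA_real_)
  if (nf == 0L) return(out)

  # tracked position per frame (vectorized label-priority + confidence pick)
  has_box <- !is.na(fr$label)
  if (any(has_box)) {
    b <- fr[has_box, , drop = FALSE]
    pr <- match(b$label, config$label_priority)
    pr[is.na(pr)] <- length(config$label_priority) + 1L
    ord <- order(b$frame, pr, -b$conf)
    b <- b[ord, , drop = FALSE]
    pick <- b[!duplicated(b$frame), , drop = FALSE]
    m <- match(pick$frame, out$frame)
    out$cx[m] <- pick$cx
    out$cy[m] <- pick$cy
  }

  p0 <- switch(config$p0_mode,
               origin = c(0, 0),
               fixed = config$p0_fixed,
               first_detection = {
                 i <- which(!is.na(out$cx))[1]
                 if (is.na(i))
                   stop("p0_mode = 'first_detection' needs at least one ",
                        "frame with a detection", call. = FALSE)
                 c(out$cx[i], out$cy[i])
               })

  d <- sqrt((out$cx - p0[1])^2 + (out$cy - p0[2])^2)
  obs <- which(!is.na(d))
  status <- rep(-2L, nf)
  if (length(obs)) {
    d_prev <- c(0, d[obs[-length(obs)]])  # first detection: previous is P0
    diff <- d[obs] - d_prev
    status[obs] <- ifelse(diff >= config$epsilon, 1L,
                          ifelse(-diff >= config$epsilon, -1L, 0L))
  }
  out$status <- status
  out
}
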