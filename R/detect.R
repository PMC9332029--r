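# High-level entry point: detection trace -> behavior events, as one call.

#' Recognize bed-related behaviors in a detection trace
#'
#' Runs the two post-detection stages in sequence: per-frame status
#' classification (\code{\link{classify_trace}}) followed by Status
#' Classification Queueing (\code{\link{run_scq}}), and derives the
#' per-frame behavior-index trace. This is the programmatic equivalent of
#' the \code{run} command of the bundled \code{scqmon} script.
#'
#' @param trace A \code{\link{detection_trace}}.
#' @param scq An \code{\link{scq_config}}; its frame rate should match the
#'   trace's.
#' @param classifier A \code{\link{classifier_config}}.
#' @param debounce If \code{TRUE}, consecutive events of the same behavior
#'   are collapsed to the first one (a sustained behavior otherwise
#'   re-emits every L_j statuses).
#' @return Object of class \code{"scq_result"}: list with elements
#'   \code{statuses} (per-frame status stream), \code{events} (recognized
#'   behaviors), \code{index} (per-frame behavior-index trace),
#'   \code{n_frames}, \code{frame_rate} and the two configurations.
#' @export
#' @examples
#' case <- generate(ward_scenario("horizontal", seed = 1, clean = TRUE))
#' fit <- detect_behaviors(case$trace,
#'                         classifier = scenario_classifier(case$scenario))
#' fit
#' evaluate_clips(fit$events, case$truth)
detect_behaviors <- function(trace, scq = scq_config(),
                             classifier = classifier_config(),
                             debounce = FALSE) {
  stopifnot(inherits(trace, "detection_trace"), inherits(scq, "scq_config"),
            inherits(classifier, "classifier_config"))
  statuses <- classify_trace(trace, classifier)
  events <- run_scq(statuses, scq)
  if (debounce && nrow(events) > 1L) {
    keep <- c(TRUE, events$behavior[-1L] != events$behavior[-nrow(events)])
    events <- events[keep, , drop = FALSE]
    rownames(events) <- NULL
  }
  nf <- nrow(statuses)
  idx <- behavior_index_trace(events, n_frames = max(nf, 1L),
                              frame_rate = trace$frame_rate)
  structure(list(statuses = statuses, events = events, index = idx,
                 n_frames = nf, frame_rate = trace$frame_rate,
                 scq = scq, classifier = classifier, debounce = debounce),
            class = "scq_result")
}

#' @export
print.scq_result <- function(x, ...) {
  cat(sprintf("SCQ behavior recognition: %d frames (%.1f s), %d event(s)\n",
              x$n_frames, x$n_frames / x$frame_rate, nrow(x$events)))
  if (nrow(x$events)) {
    ev <- x$events
    cat(sprintf("  %-8s at frame %5d (t = %6.2f s)\n",
                ev$behavior, ev$frame, ev$t), sep = "")
  }
  invisible(x)
}

#' @export
summary.scq_result <- function(object, ...) {
  st <- table(factor(object$statuses$status, levels = c(1, 0, -1, -2)))
  ev <- table(factor(object$events$behavior, levels = scq_behaviors()))
  out <- list(n_frames = object$n_frames,
              duration_s = object$n_frames / object$frame_rate,
              status_counts = st, event_counts = ev,
              M = object$scq$M, L = object$scq$L,
              epsilon = object$classifier$epsilon)
  class(out) <- "summary.scq_result"
  out
}

#' @export
print.summary.scq_result <- function(x, ...) {
  cat(sprintf("Frames: %d (%.1f s)\n", x$n_frames, x$duration_s))
  cat(sprintf("Statuses  +1 (away): %d   0 (neutral): %d   -1 (toward): %d   -2 (no box): %d\n",
              x$status_counts[["1"]], x$status_counts[["0"]],
              x$status_counts[["-1"]], x$status_counts[["-2"]]))
  cat("Events   ", paste(sprintf("%s: %d", names(x$event_counts),
                                 as.integer(x$event_counts)),
                         collapse = "   "), "\n")
  cat(sprintf("SCQ window M = %d, queue lengths %s, epsilon = %g px\n",
              x$M, paste(x$L, collapse = "/"), x$epsilon))
  invisible(x)
}

#' Plot a recognition result
#'
#' Two stacked panels against time: the tracked x-coordinate (with gaps at
#' missing detections and recognized events marked), and the behavior-index
#' step trace (on bed = 0, off bed = 1, return = -1, nobody = 2).
#'
#' @param x An \code{"scq_result"}.
#' @param ... Unused.
#' @export
plot.scq_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 1.5, 1), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(op))
  st <- x$statuses
  graphics::plot(st$t, st$cx, type = "l", xlab = "", ylab = "x center [px]",
                 main = "tracked position")
  if (nrow(x$events))
    graphics::abline(v = x$events$t, col = "red3", lty = 3)
  graphics::plot(x$index$t, x$index$index, type = "s", ylim = c(-1.5, 2.5),
                 xlab = "time [s]", ylab = "behavior index",
                 main = "recognized behavior", yaxt = "n")
  graphics::axis(2, at = c(-1, 0, 1, 2),
                 labels = c("return", "on bed", "off bed", "nobody"), las = 1)
  invisible(x)
}
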