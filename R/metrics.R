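# Evaluation: confusion-count metrics for the detector stage, and the
# clip-based protocol for behavior recognition. A "clip" is a contiguous
# ground-truth segment of one behavior; it counts as recognized when at
# least one event of that behavior is emitted inside it, and recognition
# rates are tallied per behavior over all clips.

#' Confusion counts
#'
#' @param tp,fp,tn,fn Nonnegative counts of true positives, false
#'   positives, true negatives and false negatives.
#' @return Object of class \code{"confusion_counts"}.
#' @export
#' @examples
#' precision(confusion_counts(tp = 262, fp = 51))   # Horizontal High row
confusion_counts <- function(tp = 0, fp = 0, tn = 0, fn = 0) {
  x <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!is.finite(x)) || any(x < 0))
    stop("confusion counts must be nonnegative", call. = FALSE)
  structure(as.list(x), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts: TP %g, FP %g, TN %g, FN %g\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Detection accuracy, precision, recall and F1
#'
#' Standard definitions: accuracy \code{(TP+TN)/(TP+TN+FP+FN)}, precision
#' \code{TP/(TP+FP)}, recall \code{TP/(TP+FN)} and F1 the harmonic mean of
#' precision and recall. An undefined metric (zero denominator) is an
#' error, never a silent 0.
#'
#' @param x A \code{\link{confusion_counts}}.
#' @return Fraction in \[0, 1\].
#' @export
accuracy <- function(x) {
  stopifnot(inherits(x, "confusion_counts"))
  tot <- x$tp + x$tn + x$fp + x$fn
  if (tot == 0) stop("accuracy undefined: all counts are zero", call. = FALSE)
  (x$tp + x$tn) / tot
}

#' @rdname accuracy
#' @export
precision <- function(x) {
  stopifnot(inherits(x, "confusion_counts"))
  if (x$tp + x$fp == 0)
    stop("precision undefined: TP + FP is zero", call. = FALSE)
  x$tp / (x$tp + x$fp)
}

#' @rdname accuracy
#' @export
recall <- function(x) {
  stopifnot(inherits(x, "confusion_counts"))
  if (x$tp + x$fn == 0)
    stop("recall undefined: TP + FN is zero", call. = FALSE)
  x$tp / (x$tp + x$fn)
}

#' @rdname accuracy
#' @export
f1_score <- function(x) {
  p <- precision(x)
  r <- recall(x)
  if (p + r == 0) stop("F1 undefined: precision + recall is zero", call. = FALSE)
  2 * p * r / (p + r)
}

#' Round a fraction to a whole percent, half up
#'
#' Reported tables print whole percents with halves rounded up
#' (so 0.845 prints as 85).
#'
#' @param x Fractions in \[0, 1\].
#' @return Integer percent values.
#' @export
percent_round <- function(x) as.integer(floor(100 * x + 0.5))

#' Clip-based recognition evaluation
#'
#' Scores an event stream against ground-truth clips: a clip is recognized
#' iff at least one event carrying the clip's behavior falls inside its
#' frame range (inclusive). Events of other behaviors falling inside a clip
#' are tallied as confusions; events outside every clip of their behavior do
#' not affect the rates. With \code{max_latency_s} set, only events within
#' that many seconds of the clip start count (a stricter reading for stress
#' tests; off by default).
#'
#' @param events Event data frame (\code{behavior, frame, t}).
#' @param truth \code{\link{behavior_segments}} ground truth.
#' @param max_latency_s Optional latency bound in seconds.
#' @param frame_rate Frame rate used to convert \code{max_latency_s}.
#' @return Object of class \code{"clip_eval"}: list with \code{clips} (per
#'   clip, with a \code{recognized} flag), \code{by_behavior} (data frame
#'   \code{behavior, n_clips, n_recognized, rate}) and \code{confusion}
#'   (matrix of event counts, truth behavior x event behavior).
#' @export
evaluate_clips <- function(events, truth, max_latency_s = NULL,
                           frame_rate = 15) {
  truth <- behavior_segments(truth)
  behs <- scq_behaviors()
  clips <- as.data.frame(truth)
  clips$recognized <- FALSE
  confusion <- matrix(0L, 4L, 4L, dimnames = list(truth = behs, event = behs))
  if (nrow(events)) {
    for (i in seq_len(nrow(clips))) {
      lim <- clips$end_frame[i]
      if (!is.null(max_latency_s))
        lim <- min(lim, clips$start_frame[i] +
                          as.integer(round(max_latency_s * frame_rate)))
      inside <- events$frame >= clips$start_frame[i] & events$frame <= lim
      if (!any(inside)) next
      ev <- events$behavior[inside]
      clips$recognized[i] <- any(ev == clips$behavior[i])
      tb <- table(factor(ev, levels = behs))
      confusion[clips$behavior[i], ] <- confusion[clips$behavior[i], ] +
        as.integer(tb)
    }
  }
  n_clips <- as.integer(table(factor(clips$behavior, levels = behs)))
  n_rec <- as.integer(tapply(clips$recognized,
                             factor(clips$behavior, levels = behs),
                             sum, default = 0L))
  by_behavior <- data.frame(behavior = behs, n_clips = n_clips,
                            n_recognized = n_rec,
                            rate = ifelse(n_clips > 0, n_rec / n_clips, NA),
                            stringsAsFactors = FALSE)
  structure(list(clips = clips, by_behavior = by_behavior,
                 confusion = confusion),
            class = "clip_eval")
}

#' @export
print.clip_eval <- function(x, ...) {
  cat("Clip-based recognition\n")
  b <- x$by_behavior[x$by_behavior$n_clips > 0, , drop = FALSE]
  for (i in seq_len(nrow(b)))
    cat(sprintf("  %-8s %3d%% (%d/%d)\n", b$behavior[i],
                percent_round(b$rate[i]), b$n_recognized[i], b$n_clips[i]))
  off_diag <- sum(x$confusion) - sum(diag(x$confusion))
  cat(sprintf("  confused events inside clips of another behavior: %d\n",
              off_diag))
  invisible(x)
}

#' Aggregate clip evaluation across several cases
#'
#' Counts are summed across cases before rates are computed, matching the
#' protocol of pooling all clips of a behavior from every sequence.
#'
#' @param events_list List of event data frames, one per case.
#' @param truth_list List of matching ground-truth segment tables.
#' @param ... Passed on to \code{\link{evaluate_clips}}.
#' @return A \code{"clip_eval"} with pooled counts; \code{clips} gains a
#'   \code{case} column.
#' @export
batch_evaluate <- function(events_list, truth_list, ...) {
  stopifnot(length(events_list) == length(truth_list),
            length(events_list) >= 1L)
  evals <- Map(evaluate_clips, events_list, truth_list,
               MoreArgs = list(...))
  clips <- do.call(rbind, lapply(seq_along(evals), function(i)
    cbind(case = i, evals[[i]]$clips)))
  behs <- scq_behaviors()
  n_clips <- as.integer(table(factor(clips$behavior, levels = behs)))
  n_rec <- as.integer(tapply(clips$recognized,
                             factor(clips$behavior, levels = behs),
                             sum, default = 0L))
  confusion <- Reduce(`+`, lapply(evals, `[[`, "confusion"))
  by_behavior <- data.frame(behavior = behs, n_clips = n_clips,
                            n_recognized = n_rec,
                            rate = ifelse(n_clips > 0, n_rec / n_clips, NA),
                            stringsAsFactors = FALSE)
  structure(list(clips = clips, by_behavior = by_behavior,
                 confusion = confusion),
            class = "clip_eval")
}
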